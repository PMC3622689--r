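#' Fit a fluorescence-to-concentration calibration line
#'
#' Ordinary least squares fit of `concentration = slope * fluorescence
#' + intercept` to a dilution series imaged at the acquisition
#' settings. Linearity is the working assumption in the fluorophore's
#' dilution regime; values converted outside the observed fluorescence
#' range are flagged as extrapolated rather than rejected.
#'
#' @param dilution_table Data frame with columns `concentration_uM` and
#'   `fluorescence` (>= 3 rows, >= 2 distinct concentrations).
#' @return An object of class `CalibrationCurve` with `slope`
#'   (uM per fluorescence unit), `intercept` (uM), `r_squared` and
#'   `valid_range` (observed fluorescence range).
#' @export
fit_calibration <- function(dilution_table) {
  stopifnot(is.data.frame(dilution_table),
            all(c("concentration_uM", "fluorescence") %in%
                  names(dilution_table)))
  if (nrow(dilution_table) < 3L) {
    stop("calibration fit needs at least 3 dilution points")
  }
  if (length(unique(dilution_table$concentration_uM)) < 2L) {
    stop("calibration fit needs at least 2 distinct concentrations")
  }
  if (stats::var(dilution_table$fluorescence) == 0) {
    stop("calibration fit needs non-constant fluorescence")
  }
  fit <- stats::lm(concentration_uM ~ fluorescence, data = dilution_table)
  cf <- stats::coef(fit)
  if (cf[["fluorescence"]] <= 0) {
    stop("calibration slope must be positive; check the dilution table")
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((dilution_table$concentration_uM -
                   mean(dilution_table$concentration_uM))^2)
  structure(list(slope = unname(cf[["fluorescence"]]),
                 intercept = unname(cf[["(Intercept)"]]),
                 r_squared = 1 - ss_res / ss_tot,
                 valid_range = range(dilution_table$fluorescence)),
            class = "CalibrationCurve")
}

#' Build a calibration curve from known coefficients
#'
#' Convenience constructor for simulation and testing, bypassing the
#' least-squares fit.
#'
#' @param slope uM per fluorescence unit (> 0).
#' @param intercept uM.
#' @param valid_range Fluorescence range considered interpolation.
#' @return A `CalibrationCurve`.
#' @export
calibration_curve <- function(slope, intercept = 0, valid_range = c(0, 1)) {
  stopifnot(slope > 0, valid_range[1] < valid_range[2])
  structure(list(slope = slope, intercept = intercept, r_squared = NA_real_,
                 valid_range = valid_range),
            class = "CalibrationCurve")
}

#' @export
print.CalibrationCurve <- function(x, ...) {
  cat(sprintf("CalibrationCurve: conc = %.4g * fluor + %.4g uM (r2 = %.4f), valid fluor [%.3g, %.3g]\n",
              x$slope, x$intercept, x$r_squared,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Convert fluorescence to drug concentration
#'
#' Affine conversion through a [fit_calibration()] line. Values outside
#' the curve's valid fluorescence range are still converted, but the
#' returned vector carries a logical `extrapolated` attribute marking
#' them.
#'
#' @param curve A `CalibrationCurve`.
#' @param fluor Numeric vector of fluorescence values.
#' @return Numeric vector of concentrations (uM) with attribute
#'   `extrapolated`.
#' @export
fluorescence_to_concentration <- function(curve, fluor) {
  stopifnot(inherits(curve, "CalibrationCurve"))
  conc <- curve$slope * fluor + curve$intercept
  attr(conc, "extrapolated") <-
    fluor < curve$valid_range[1] | fluor > curve$valid_range[2]
  conc
}

#' Per-cell nuclear drug concentrations over a movie
#'
#' For every frame and every segmented cell, the drug-channel
#' fluorescence is averaged over the cell's member pixels and converted
#' to concentration through the calibration line; per frame, the mean
#' and standard deviation over cells summarize the population. Frames
#' without cells are recorded with `NA` summaries rather than dropped.
#'
#' @param regions_list List of `LabeledRegions`, one per frame (e.g.
#'   `segment_stack(...)$frames`).
#' @param stack The [channel_stack()] the regions were derived from.
#' @param drug_channel Name of the drug channel in `stack`.
#' @param curve A `CalibrationCurve`.
#' @return An object of class `ConcentrationSeries`: `per_cell` (data
#'   frame `frame`, `time_s`, `cell_id`, `area_px`, `mean_fluor`,
#'   `conc_uM`, `extrapolated`) and `per_frame` (data frame `frame`,
#'   `time_s`, `n_cells`, `mean_uM`, `sd_uM`).
#' @export
cell_concentrations <- function(regions_list, stack, drug_channel, curve) {
  stopifnot(inherits(curve, "CalibrationCurve"))
  if (length(regions_list) != n_frames(stack)) {
    stop("regions_list length must equal the stack frame count")
  }
  dt <- if (stack$axis == "time") stack$frame_interval_s else NA_real_
  per_cell <- vector("list", length(regions_list))
  per_frame <- vector("list", length(regions_list))
  for (fi in seq_along(regions_list)) {
    lr <- regions_list[[fi]]
    t_s <- if (is.na(dt)) NA_real_ else (fi - 1) * dt
    fr <- get_frame(stack, drug_channel, fi)
    n <- nrow(lr$regions)
    if (n == 0L) {
      per_cell[[fi]] <- NULL
      per_frame[[fi]] <- data.frame(frame = fi, time_s = t_s, n_cells = 0L,
                                    mean_uM = NA_real_, sd_uM = NA_real_)
      next
    }
    idx <- which(lr$label_map > 0L)
    mf <- as.numeric(tapply(fr[idx], lr$label_map[idx], mean))
    conc <- fluorescence_to_concentration(curve, mf)
    per_cell[[fi]] <- data.frame(frame = fi, time_s = t_s,
                                 cell_id = lr$regions$id,
                                 area_px = lr$regions$area_px,
                                 mean_fluor = mf,
                                 conc_uM = as.numeric(conc),
                                 extrapolated = attr(conc, "extrapolated"))
    per_frame[[fi]] <- data.frame(frame = fi, time_s = t_s, n_cells = n,
                                  mean_uM = mean(conc),
                                  sd_uM = if (n > 1L) stats::sd(conc) else 0)
  }
  structure(list(per_cell = do.call(rbind, per_cell),
                 per_frame = do.call(rbind, per_frame)),
            class = "ConcentrationSeries")
}

#' @export
print.ConcentrationSeries <- function(x, ...) {
  cat(sprintf("ConcentrationSeries: %d frame(s), %d cell-frame record(s)\n",
              nrow(x$per_frame),
              if (is.null(x$per_cell)) 0L else nrow(x$per_cell)))
  invisible(x)
}

#' Drug concentration in a vessel region of interest
#'
#' Mean drug-channel fluorescence over a rectangular ROI per frame,
#' converted to concentration — the vessel input function read directly
#' from the image.
#'
#' @param stack A [channel_stack()].
#' @param drug_channel Drug channel name.
#' @param roi Integer vector `c(row1, row2, col1, col2)` (inclusive,
#'   1-based) inside the frame bounds.
#' @param curve A `CalibrationCurve`.
#' @return Data frame with `frame`, `time_s`, `vessel_uM`.
#' @export
vessel_curve <- function(stack, drug_channel, roi, curve) {
  d <- dim(stack$channels[[1]][[1]])
  if (length(roi) != 4L || roi[1] < 1 || roi[3] < 1 || roi[2] > d[1] ||
      roi[4] > d[2] || roi[1] > roi[2] || roi[3] > roi[4]) {
    stop(sprintf("roi [%s] outside %dx%d frame bounds",
                 paste(roi, collapse = ", "), d[1], d[2]))
  }
  nf <- n_frames(stack)
  dt <- if (stack$axis == "time") stack$frame_interval_s else NA_real_
  v <- vapply(seq_len(nf), function(fi) {
    mean(get_frame(stack, drug_channel, fi)[roi[1]:roi[2], roi[3]:roi[4]])
  }, numeric(1))
  data.frame(frame = seq_len(nf),
             time_s = if (is.na(dt)) NA_real_ else (seq_len(nf) - 1) * dt,
             vessel_uM = as.numeric(fluorescence_to_concentration(curve, v)))
}

#' Fraction of cells below a therapeutic concentration
#'
#' Strict less-than convention: a cell exactly at the threshold counts
#' as therapeutic. The default 1.5 uM is the PARP-inhibitor efficacy
#' threshold used for the subtherapeutic readout.
#'
#' @param concentrations Numeric vector of per-cell concentrations (uM).
#' @param threshold Therapeutic threshold in uM.
#' @return Fraction in `[0, 1]`, or `NA` for an empty input.
#' @export
subtherapeutic_fraction <- function(concentrations, threshold = 1.5) {
  if (!length(concentrations)) return(NA_real_)
  mean(concentrations < threshold)
}

#' Nuclear fraction of the cellular drug signal
#'
#' Approximates the cytosol as a ring obtained by dilating the nuclear
#' mask with a disk and subtracting the nuclei, then reports the share
#' of total drug fluorescence falling on nuclear pixels:
#' `sum(drug[nuclear]) / sum(drug[nuclear | ring])`.
#'
#' @param nuclei A `LabeledRegions` of the nuclear segmentation.
#' @param drug_frame Drug-channel matrix for the same frame.
#' @param ring_radius Dilation radius in pixels defining the cytosolic
#'   ring width.
#' @return Fraction in `[0, 1]`, or `NA` if there is no drug signal.
#' @export
nuclear_fraction <- function(nuclei, drug_frame, ring_radius = 5L) {
  stopifnot(inherits(nuclei, "LabeledRegions"), ring_radius >= 1)
  nuc <- nuclei$label_map > 0L
  if (!any(nuc)) stop("nuclear mask is empty")
  cyto <- dilate_mask(nuc, ring_radius) & !nuc
  tot <- sum(drug_frame[nuc]) + sum(drug_frame[cyto])
  if (tot <= 0) return(NA_real_)
  sum(drug_frame[nuc]) / tot
}

#' Closed-form one-compartment uptake curve
#'
#' Solution of `dC/dt = k_in * C_v(t) - k_out * C` with a
#' single-exponential vessel bolus `C_v(t) = peak * exp(-k_decay * t)`
#' and `C(0) = 0`:
#' `C(t) = k_in * peak * (exp(-k_decay t) - exp(-k_out t)) / (k_out - k_decay)`,
#' with the appropriate limits when `k_out = k_decay` or `k_out = 0`.
#'
#' @param t Time (s), vector.
#' @param k_in Uptake rate constant (1/s).
#' @param k_out Efflux rate constant (1/s).
#' @param peak Vessel peak concentration (uM).
#' @param k_decay Vessel decay constant (1/s).
#' @return Concentration (uM) at each `t`.
#' @export
uptake_curve <- function(t, k_in, k_out, peak, k_decay) {
  if (abs(k_out - k_decay) < 1e-12) {
    if (k_decay < 1e-300) return(k_in * peak * t)
    k_in * peak * t * exp(-k_decay * t)
  } else if (k_out == 0) {
    k_in * peak * (1 - exp(-k_decay * t)) / k_decay
  } else {
    k_in * peak * (exp(-k_decay * t) - exp(-k_out * t)) / (k_out - k_decay)
  }
}

#' Fit the vessel bolus model to a measured vessel curve
#'
#' Nonlinear least squares of `peak * exp(-k_decay * t)`.
#'
#' @param times Time points (s).
#' @param vessel_uM Measured vessel concentrations (uM).
#' @param start Optional list of starting values `peak`, `k_decay`.
#' @return List with `peak` and `k_decay`.
#' @export
fit_vessel_decay <- function(times, vessel_uM, start = NULL) {
  if (is.null(start)) {
    start <- list(peak = max(vessel_uM),
                  k_decay = 1 / max(times[times > 0], 1))
  }
  df <- data.frame(t = times, y = vessel_uM)
  fit <- minpack.lm::nlsLM(y ~ peak * exp(-k_decay * t), data = df,
                           start = start,
                           lower = c(peak = 0, k_decay = 0))
  as.list(stats::coef(fit))
}

#' Recover uptake kinetics from a mean-cell concentration curve
#'
#' Nonlinear least-squares re-fit of the one-compartment uptake model
#' ([uptake_curve()]) to a measured mean nuclear concentration time
#' course, given the vessel bolus parameters (typically themselves fit
#' from the vessel ROI with [fit_vessel_decay()]).
#'
#' @param times Time points (s).
#' @param mean_uM Measured mean cell concentrations (uM).
#' @param peak,k_decay Vessel bolus parameters.
#' @param start Optional starting values list `k_in`, `k_out`.
#' @return List with `k_in` and `k_out` (1/s).
#' @export
fit_uptake <- function(times, mean_uM, peak, k_decay, start = NULL) {
  if (is.null(start)) {
    # crude initializer: early slope ~ k_in * peak
    i2 <- max(2L, which.max(times >= times[length(times)] / 4))
    k_in0 <- max((mean_uM[i2] - mean_uM[1]) / (times[i2] - times[1]) / peak,
                 1e-6)
    start <- list(k_in = k_in0, k_out = k_decay / 10)
  }
  df <- data.frame(t = times, y = mean_uM)
  fit <- minpack.lm::nlsLM(
    y ~ k_in * peak * (exp(-k_decay * t) - exp(-k_out * t)) / (k_out - k_decay),
    data = df, start = start,
    lower = c(k_in = 0, k_out = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  as.list(stats::coef(fit))
}
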