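#' Specification of a synthetic intravital scene
#'
#' Defines the conditions under which ground-truthed two-channel movies
#' are generated: a field of elliptical, soft-edged nuclei with
#' heterogeneous brightness, a drug channel driven by a
#' single-exponential vessel bolus with first-order cellular uptake, a
#' linear fluorescence calibration, shot/read noise, optional speckle
#' artifacts and global integer drift. Every random draw is fixed by
#' `seed`.
#'
#' Defaults emulate a dense intravital field: 50 nuclei of 5-9 px
#' radius at 0.3-1.0 relative brightness in a 256 px field, Gaussian
#' noise of 0.01 on the `[0, 1]` intensity scale, frames every 75 s,
#' and a 10 uM vessel peak decaying with a ~30 min time constant
#' feeding per-cell uptake at `k_in = 2e-4`/s with efflux
#' `k_out = 5e-5`/s.
#'
#' @param n_cells Number of nuclei.
#' @param field_size Square field side in pixels.
#' @param radius_range Nucleus radius range (px).
#' @param brightness_range Per-cell nuclear brightness range in `(0, 1]`.
#' @param overlap_allowed If `FALSE` (default), nuclei are placed with
#'   at least `min_gap_px` between their boundaries.
#' @param min_gap_px Minimum boundary gap between nuclei (px).
#' @param speckle_count Number of single-pixel bright speckles added to
#'   the nuclear channel per frame.
#' @param noise_sigma Gaussian noise standard deviation on `[0, 1]`.
#' @param drift_px_per_frame Maximum per-frame global integer drift
#'   (uniform in `-d..d` per axis, cumulative); 0 disables drift.
#' @param cell_step_sd_px Standard deviation of each cell's per-frame
#'   random-walk step (px).
#' @param n_frames Number of frames.
#' @param frame_interval_s Seconds between frames.
#' @param kinetics List with `vessel_peak_uM`, `k_decay`, `k_in`,
#'   `k_out` (rates in 1/s).
#' @param uptake_heterogeneity Range of the per-cell multiplicative
#'   uptake factor.
#' @param calibration List with `slope` (uM per fluorescence unit) and
#'   `intercept` (uM) of the simulated calibration line.
#' @param with_vessel If `TRUE`, a rectangular vessel ROI is rendered
#'   in the drug channel.
#' @param seed Integer seed fixing all draws.
#' @return An object of class `SceneSpec`.
#' @export
scene_spec <- function(n_cells = 50L, field_size = 256L,
                       radius_range = c(5, 9),
                       brightness_range = c(0.3, 1.0),
                       overlap_allowed = FALSE, min_gap_px = 2,
                       speckle_count = 0L, noise_sigma = 0.01,
                       drift_px_per_frame = 0L, cell_step_sd_px = 0.5,
                       n_frames = 10L, frame_interval_s = 75,
                       kinetics = list(vessel_peak_uM = 10,
                                       k_decay = 1 / 1800,
                                       k_in = 2e-4, k_out = 5e-5),
                       uptake_heterogeneity = c(0.85, 1.15),
                       calibration = list(slope = 20, intercept = -0.4),
                       with_vessel = TRUE, seed = 1L) {
  stopifnot(n_cells >= 1, field_size >= 32,
            brightness_range[1] > 0, brightness_range[2] <= 1,
            noise_sigma >= 0, speckle_count >= 0, n_frames >= 1,
            kinetics$k_decay >= 0, kinetics$k_in >= 0, kinetics$k_out >= 0,
            calibration$slope > 0)
  structure(list(n_cells = as.integer(n_cells),
                 field_size = as.integer(field_size),
                 radius_range = radius_range,
                 brightness_range = brightness_range,
                 overlap_allowed = isTRUE(overlap_allowed),
                 min_gap_px = min_gap_px,
                 speckle_count = as.integer(speckle_count),
                 noise_sigma = noise_sigma,
                 drift_px_per_frame = as.integer(drift_px_per_frame),
                 cell_step_sd_px = cell_step_sd_px,
                 n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 kinetics = kinetics,
                 uptake_heterogeneity = uptake_heterogeneity,
                 calibration = calibration,
                 with_vessel = isTRUE(with_vessel),
                 seed = as.integer(seed)),
            class = "SceneSpec")
}

# rejection-sampled cell placement; returns n x 2 matrix of centers.
# cluster_frac > 0 places that fraction of cells as near-contact
# satellites of already-placed cells (boundary gap 0..2 px)
place_cells <- function(n, field, radii, min_gap, overlap_allowed,
                        forbidden = NULL, cluster_frac = 0,
                        max_attempts = 200L * n) {
  centers <- matrix(NA_real_, n, 2)
  margin <- radii + 2
  placed <- 0L
  n_cluster <- floor(cluster_frac * n)
  att <- 0L
  while (placed < n && att < max_attempts) {
    att <- att + 1L
    k <- placed + 1L
    as_satellite <- placed > 0L && k > n - n_cluster
    if (as_satellite) {
      host <- sample.int(placed, 1)
      ang <- stats::runif(1, 0, 2 * pi)
      dist <- radii[host] + radii[k] + stats::runif(1, 0.5, 2)
      p <- centers[host, ] + dist * c(cos(ang), sin(ang))
    } else {
      p <- stats::runif(2, margin[k], field - margin[k])
    }
    if (p[1] < margin[k] || p[1] > field - margin[k] ||
        p[2] < margin[k] || p[2] > field - margin[k]) next
    if (!is.null(forbidden) &&
        p[1] - radii[k] < forbidden[2] + 2 && p[1] + radii[k] > forbidden[1] - 2 &&
        p[2] - radii[k] < forbidden[4] + 2 && p[2] + radii[k] > forbidden[3] - 2) next
    if (!overlap_allowed && placed > 0L) {
      dd <- sqrt((centers[1:placed, 1] - p[1])^2 +
                   (centers[1:placed, 2] - p[2])^2)
      gap_ok <- dd >= radii[1:placed] + radii[k] +
        (if (as_satellite) 0.5 else min_gap)
      if (!all(gap_ok)) next
    }
    placed <- k
    centers[k, ] <- p
  }
  if (placed < n) {
    stop(sprintf("infeasible packing: placed %d of %d cells in %d attempts",
                 placed, n, att))
  }
  centers
}

# render one nuclear frame and the union support mask.
# cells: data frame with center_row, center_col, a, b (semi-axes px),
# theta, brightness. Soft 1-px edge: intensity ramps linearly from the
# boundary inwards; the true mask is the hard support (elliptical
# radius <= 1).
render_nuclei <- function(cells, field) {
  g <- matrix(0, field, field)
  mask <- matrix(FALSE, field, field)
  for (k in seq_len(nrow(cells))) {
    a <- cells$a[k]; b <- cells$b[k]; th <- cells$theta[k]
    r_max <- max(a, b) + 2
    r0 <- max(1L, floor(cells$center_row[k] - r_max))
    r1 <- min(field, ceiling(cells$center_row[k] + r_max))
    c0 <- max(1L, floor(cells$center_col[k] - r_max))
    c1 <- min(field, ceiling(cells$center_col[k] + r_max))
    ii <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)
    jj <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
    du <- ii - cells$center_row[k]; dv <- jj - cells$center_col[k]
    u <- cos(th) * du + sin(th) * dv
    v <- -sin(th) * du + cos(th) * dv
    d <- sqrt((u / a)^2 + (v / b)^2)          # 1 at the boundary
    scale <- sqrt(a * b)                      # px per unit of d, approx.
    prof <- pmin(pmax((1 - d) * scale + 0.5, 0), 1) * cells$brightness[k]
    sub <- g[r0:r1, c0:c1]
    g[r0:r1, c0:c1] <- pmax(sub, prof)
    mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | (d <= 1)
  }
  list(frame = g, mask = mask)
}

quantize16 <- function(x) round(x * 65535) / 65535

#' Generate a ground-truthed synthetic two-channel movie
#'
#' Produces a `nuclear` + `drug` [channel_stack()] together with the
#' exact ground truth used to build it. The nuclear channel is the
#' maximum over per-cell elliptical profiles with a 1-px soft edge,
#' plus Gaussian noise and optional single-pixel speckles. The drug
#' channel renders a vessel rectangle following
#' `C_v(t) = peak * exp(-k_decay t)` and per-cell nuclear drug at the
#' closed-form one-compartment uptake concentration ([uptake_curve()]),
#' both inverted through the calibration line into fluorescence. A
#' cumulative global integer drift and per-cell random walks provide
#' motion. Frames are quantized to the 16-bit grid so written stacks
#' round-trip exactly.
#'
#' For `axis = "z"` the same nuclei are rendered in every slice (no
#' motion, no noise-free kinetics time course; the drug channel is
#' rendered at a fixed 1 h time point).
#'
#' @param spec A [scene_spec()].
#' @param axis `"time"` for a movie, `"z"` for a Z-stack.
#' @return A list with `stack` (the [channel_stack()]) and `truth`, a
#'   list holding `cells` (radii, brightness, uptake multipliers),
#'   `paths` (per-frame true centers, a `n_frames`-long list of
#'   matrices), `masks` (per-frame true nuclear masks), `conc` (an
#'   `n_frames x n_cells` matrix of true concentrations, uM), `times`,
#'   `vessel_roi` (`c(row1, row2, col1, col2)` or `NULL`),
#'   `vessel_conc`, `drift` (per-frame cumulative offsets) and `spec`.
#' @export
generate_movie <- function(spec = scene_spec(), axis = c("time", "z")) {
  axis <- match.arg(axis)
  stopifnot(inherits(spec, "SceneSpec"))
  set.seed(spec$seed)
  S <- spec$field_size
  n <- spec$n_cells
  radii <- stats::runif(n, spec$radius_range[1], spec$radius_range[2])
  bright <- stats::runif(n, spec$brightness_range[1], spec$brightness_range[2])
  aspect <- stats::runif(n, 0.85, 1.18)
  theta <- stats::runif(n, 0, pi)
  umult <- stats::runif(n, spec$uptake_heterogeneity[1],
                        spec$uptake_heterogeneity[2])
  vessel_roi <- if (spec$with_vessel) c(1L, 16L, 1L, 48L) else NULL
  centers <- place_cells(n, S, radii, spec$min_gap_px, spec$overlap_allowed,
                         forbidden = vessel_roi)
  nf <- spec$n_frames
  times <- if (axis == "time") (seq_len(nf) - 1) * spec$frame_interval_s
           else rep(3600, nf)
  kin <- spec$kinetics
  cal <- spec$calibration
  conc <- outer(uptake_curve(times, kin$k_in, kin$k_out,
                             kin$vessel_peak_uM, kin$k_decay), umult)
  vessel_conc <- kin$vessel_peak_uM * exp(-kin$k_decay * times)
  to_fluor <- function(c_uM) pmin(pmax((c_uM - cal$intercept) / cal$slope, 0), 1)

  # per-cell random walks and cumulative global drift
  paths <- vector("list", nf)
  paths[[1]] <- centers
  if (nf > 1L && axis == "time") {
    for (fi in 2:nf) {
      step <- matrix(stats::rnorm(2 * n, 0, spec$cell_step_sd_px), n, 2)
      p <- paths[[fi - 1]] + step
      p[, 1] <- pmin(pmax(p[, 1], radii + 2), S - radii - 2)
      p[, 2] <- pmin(pmax(p[, 2], radii + 2), S - radii - 2)
      paths[[fi]] <- p
    }
  } else if (nf > 1L) {
    for (fi in 2:nf) paths[[fi]] <- centers
  }
  drift <- matrix(0L, nf, 2)
  if (spec$drift_px_per_frame > 0L && nf > 1L && axis == "time") {
    d <- spec$drift_px_per_frame
    steps <- matrix(sample(-d:d, 2 * (nf - 1), replace = TRUE), nf - 1, 2)
    drift[2:nf, ] <- apply(steps, 2, cumsum)
  }

  nuclear <- vector("list", nf)
  drug <- vector("list", nf)
  masks <- vector("list", nf)
  for (fi in seq_len(nf)) {
    cells <- data.frame(center_row = paths[[fi]][, 1],
                        center_col = paths[[fi]][, 2],
                        a = radii * aspect, b = radii / aspect,
                        theta = theta, brightness = bright)
    rn <- render_nuclei(cells, S)
    g_nuc <- rn$frame
    # constant tissue background in the drug channel; the calibration
    # intercept maps it to 0 uM, so noise is not clipped at zero signal
    g_drug <- matrix(to_fluor(0), S, S)
    if (!is.null(vessel_roi)) {
      g_drug[vessel_roi[1]:vessel_roi[2], vessel_roi[3]:vessel_roi[4]] <-
        to_fluor(vessel_conc[fi])
    }
    # drug fills the nuclear compartment: uniform on the hard support
    lab_cells <- data.frame(cells, fluor = to_fluor(conc[fi, ]))
    for (k in seq_len(n)) {
      a <- lab_cells$a[k]; b <- lab_cells$b[k]; th <- lab_cells$theta[k]
      r_max <- max(a, b) + 2
      r0 <- max(1L, floor(lab_cells$center_row[k] - r_max))
      r1 <- min(S, ceiling(lab_cells$center_row[k] + r_max))
      c0 <- max(1L, floor(lab_cells$center_col[k] - r_max))
      c1 <- min(S, ceiling(lab_cells$center_col[k] + r_max))
      ii <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)
      jj <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
      du <- ii - lab_cells$center_row[k]; dv <- jj - lab_cells$center_col[k]
      u <- cos(th) * du + sin(th) * dv
      v <- -sin(th) * du + cos(th) * dv
      inside <- (u / a)^2 + (v / b)^2 <= 1
      sub <- g_drug[r0:r1, c0:c1]
      sub[inside] <- pmax(sub[inside], lab_cells$fluor[k])
      g_drug[r0:r1, c0:c1] <- sub
    }
    if (spec$noise_sigma > 0) {
      g_nuc <- g_nuc + stats::rnorm(S * S, 0, spec$noise_sigma)
      g_drug <- g_drug + stats::rnorm(S * S, 0, spec$noise_sigma)
    }
    if (spec$speckle_count > 0L) {
      sp <- sample.int(S * S, spec$speckle_count)
      g_nuc[sp] <- g_nuc[sp] + stats::runif(spec$speckle_count, 0.5, 1)
    }
    g_nuc <- pmin(pmax(g_nuc, 0), 1)
    g_drug <- pmin(pmax(g_drug, 0), 1)
    msk <- rn$mask
    if (any(drift[fi, ] != 0L)) {
      g_nuc <- shift_frame(g_nuc, drift[fi, 1], drift[fi, 2])
      g_drug <- shift_frame(g_drug, drift[fi, 1], drift[fi, 2])
      msk <- shift_frame(msk + 0, drift[fi, 1], drift[fi, 2]) > 0.5
      paths[[fi]] <- paths[[fi]] +
        matrix(drift[fi, ], n, 2, byrow = TRUE)
    }
    nuclear[[fi]] <- quantize16(g_nuc)
    drug[[fi]] <- quantize16(g_drug)
    masks[[fi]] <- msk
  }
  stack <- channel_stack(list(nuclear = nuclear, drug = drug), axis = axis,
                         frame_interval_s = spec$frame_interval_s)
  truth <- list(cells = data.frame(id = seq_len(n), radius = radii,
                                   aspect = aspect, theta = theta,
                                   brightness = bright,
                                   uptake_multiplier = umult),
                paths = paths, masks = masks, conc = conc, times = times,
                vessel_roi = vessel_roi, vessel_conc = vessel_conc,
                drift = drift, spec = spec)
  list(stack = stack, truth = truth)
}

#' Generate single-frame fixtures of the four imaging complications
#'
#' Returns one synthetic frame plus its exact ground-truth mask, which
#' stands in for a reviewer's manual segmentation. The four kinds are
#' the canonical hard cases for thresholding intravital data:
#' `multibright` (well-spaced nuclei spanning at least a 3x brightness
#' ratio), `dense` (a packed field at a single brightness level, at
#' least 30 percent of nuclei within 2 px of a neighbor),
#' `dense_multibright` (both complications combined) and `highmag`
#' (few large nuclei with intracellular intensity texture).
#'
#' @param kind One of `"multibright"`, `"dense"`, `"dense_multibright"`,
#'   `"highmag"`.
#' @param seed Integer seed.
#' @return A list with `frame` (numeric matrix), `manual` (logical
#'   ground-truth mask) and `kind`.
#' @export
generate_metric_fixtures <- function(kind = c("multibright", "dense",
                                              "dense_multibright", "highmag"),
                                     seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  S <- 192L
  cfg <- switch(kind,
    multibright = list(n = 30L, rr = c(5, 9), br = c(0.25, 0.95),
                       cluster = 0, noise = 0.01, haze = c(0.05, 0.22)),
    dense = list(n = 60L, rr = c(5, 8), br = c(0.78, 0.82),
                 cluster = 0.6, noise = 0.01, haze = c(0.05, 0.22)),
    dense_multibright = list(n = 60L, rr = c(5, 8), br = c(0.25, 0.95),
                             cluster = 0.6, noise = 0.01,
                             haze = c(0.05, 0.22)),
    highmag = list(n = 6L, rr = c(20, 28), br = c(0.6, 0.9),
                   cluster = 0, noise = 0.01, haze = c(0.03, 0.12)))
  radii <- stats::runif(cfg$n, cfg$rr[1], cfg$rr[2])
  bright <- stats::runif(cfg$n, cfg$br[1], cfg$br[2])
  if (kind %in% c("multibright", "dense_multibright")) {
    bright[1] <- cfg$br[1]; bright[2] <- cfg$br[2]   # guarantee 3x span
  }
  centers <- place_cells(cfg$n, S, radii, min_gap = 2,
                         overlap_allowed = FALSE, cluster_frac = cfg$cluster)
  aspect <- stats::runif(cfg$n, 0.85, 1.18)
  cells <- data.frame(center_row = centers[, 1], center_col = centers[, 2],
                      a = radii * aspect, b = radii / aspect,
                      theta = stats::runif(cfg$n, 0, pi),
                      brightness = bright)
  rn <- render_nuclei(cells, S)
  # smooth out-of-focus background haze, as in vivo fields show
  ii <- matrix(seq_len(S), S, S); jj <- matrix(seq_len(S), S, S, byrow = TRUE)
  ph <- stats::runif(4, 0, 2 * pi)
  fq <- stats::runif(4, 0.5, 1.5)
  s <- (sin(2 * pi * fq[1] * ii / S + ph[1]) *
          sin(2 * pi * fq[2] * jj / S + ph[2]) +
        sin(2 * pi * fq[3] * (ii + jj) / (2 * S) + ph[3]) *
          sin(2 * pi * fq[4] * (ii - jj) / (2 * S) + ph[4]) + 2) / 4
  haze <- cfg$haze[1] + (cfg$haze[2] - cfg$haze[1]) * s
  g <- pmax(rn$frame, haze)
  if (kind == "highmag") {
    # intracellular detail: smooth multiplicative intensity texture
    tex <- 1 + 0.2 * sin(ii / 4) * cos(jj / 5)
    g <- g * tex
  }
  g <- pmin(pmax(g + stats::rnorm(S * S, 0, cfg$noise), 0), 1)
  if (kind %in% c("dense", "dense_multibright")) {
    near <- near_neighbor_fraction(centers, radii, gap = 2)
    if (near < 0.3) stop("dense fixture postcondition violated")  # nocov
  }
  list(frame = quantize16(g), manual = rn$mask, kind = kind)
}

# fraction of cells whose boundary is within `gap` px of a neighbor's
near_neighbor_fraction <- function(centers, radii, gap = 2) {
  n <- nrow(centers)
  d <- as.matrix(stats::dist(centers))
  near <- vapply(seq_len(n), function(i) {
    any(d[i, -i] - radii[i] - radii[-i] <= gap)
  }, logical(1))
  mean(near)
}

#' Two-blob fixture for locally-adaptive vs global thresholding
#'
#' A bright blob (0.9) and a dim blob (level drawn from
#' `dim_range`, overlapping the background's upper range) on a
#' left-to-right background ramp from 0 to 0.25, plus mild noise. The
#' dim blob is placed in the left part of the field where the local
#' background is low, so a locally-adaptive threshold can separate it
#' while a single global threshold set for the bright blob cannot.
#'
#' @param seed Integer seed.
#' @param dim_level Dim blob intensity; default drawn uniformly from
#'   `dim_range`.
#' @param dim_range Range of the dim level draw.
#' @param size Field side in px.
#' @return A list with `frame`, `dim_mask`, `bright_mask`,
#'   `dim_level`.
#' @export
two_blob_fixture <- function(seed = 1L, dim_level = NULL,
                             dim_range = c(0.25, 0.5), size = 96L) {
  set.seed(seed)
  S <- size
  jj <- matrix(seq_len(S) - 1, S, S, byrow = TRUE)
  bg <- 0.25 * jj / (S - 1)
  if (is.null(dim_level)) dim_level <- stats::runif(1, dim_range[1], dim_range[2])
  rb <- stats::runif(1, 11, 14)
  rd <- stats::runif(1, 6, 9)
  repeat {
    cd <- c(stats::runif(1, 0.2 * S, 0.8 * S), stats::runif(1, 0.17 * S, 0.42 * S))
    cb <- c(stats::runif(1, 0.2 * S, 0.8 * S), stats::runif(1, 0.62 * S, 0.85 * S))
    if (sqrt(sum((cd - cb)^2)) >= rb + rd + 10) break
  }
  ii <- matrix(seq_len(S), S, S)
  jj1 <- matrix(seq_len(S), S, S, byrow = TRUE)
  dmask <- sqrt((ii - cd[1])^2 + (jj1 - cd[2])^2) <= rd
  bmask <- sqrt((ii - cb[1])^2 + (jj1 - cb[2])^2) <= rb
  g <- bg
  g[dmask] <- dim_level
  g[bmask] <- 0.9
  g <- pmin(pmax(g + stats::rnorm(S * S, 0, 0.01), 0), 1)
  list(frame = quantize16(g), dim_mask = dmask, bright_mask = bmask,
       dim_level = dim_level)
}

#' Simulate a calibration dilution series
#'
#' @param slope,intercept True line (concentration = slope * fluor +
#'   intercept).
#' @param concentrations_uM Dilution concentrations.
#' @param noise_sd Gaussian noise on the measured fluorescence.
#' @param seed Integer seed.
#' @return Data frame with `concentration_uM`, `fluorescence`.
#' @export
synthetic_dilution_table <- function(slope = 20, intercept = 0,
                                     concentrations_uM = c(0.1, 0.5, 1, 2,
                                                           5, 10, 15),
                                     noise_sd = 0.002, seed = 1L) {
  set.seed(seed)
  fluor <- (concentrations_uM - intercept) / slope +
    stats::rnorm(length(concentrations_uM), 0, noise_sd)
  data.frame(concentration_uM = concentrations_uM,
             fluorescence = pmax(fluor, 0))
}
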