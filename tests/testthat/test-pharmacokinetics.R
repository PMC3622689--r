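test_that("calibration fitting recovers exact and noisy lines", {
  exact <- data.frame(concentration_uM = c(0.2, 0.4, 0.6),
                      fluorescence = c(0.1, 0.2, 0.3))
  cv <- fit_calibration(exact)
  expect_equal(cv$slope, 2)
  expect_equal(cv$intercept, 0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$valid_range, c(0.1, 0.3))

  # closed-form OLS oracle via the normal equations
  tab <- data.frame(concentration_uM = c(1, 2.5, 4.2),
                    fluorescence = c(0.05, 0.14, 0.22))
  x <- tab$fluorescence; y <- tab$concentration_uM
  slope <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  intercept <- mean(y) - slope * mean(x)
  cv2 <- fit_calibration(tab)
  expect_equal(cv2$slope, slope)
  expect_equal(cv2$intercept, intercept)

  expect_error(fit_calibration(exact[1:2, ]), "at least 3")
  same_conc <- data.frame(concentration_uM = c(1, 1, 1),
                          fluorescence = c(0.1, 0.2, 0.3))
  expect_error(fit_calibration(same_conc), "2 distinct")
  flat <- data.frame(concentration_uM = c(1, 2, 3),
                     fluorescence = c(0.1, 0.1, 0.1))
  expect_error(fit_calibration(flat), "non-constant")
})

test_that("fluorescence conversion is affine and flags extrapolation", {
  cv <- calibration_curve(2, 0.1, valid_range = c(0.1, 0.3))
  expect_equal(as.numeric(fluorescence_to_concentration(cv, 0.2)), 0.5)
  a <- 0.15; b <- 0.22
  f <- function(x) as.numeric(fluorescence_to_concentration(cv, x))
  expect_equal(f(a) + f(b), f(a + b) + f(0))       # affine identity
  flags <- attr(fluorescence_to_concentration(cv, c(0.05, 0.2, 0.5)),
                "extrapolated")
  expect_equal(flags, c(TRUE, FALSE, TRUE))
})

test_that("per-cell concentrations are exact on uniform drug frames", {
  m <- matrix(FALSE, 32, 32)
  m[4:9, 4:9] <- TRUE; m[20:27, 18:25] <- TRUE
  drug <- matrix(0.25, 32, 32)
  st <- channel_stack(list(nuclear = list(m + 0), drug = list(drug)))
  lr <- label_regions(m, st, 1)
  cv <- calibration_curve(10, 1)
  ser <- cell_concentrations(list(lr), st, "drug", cv)
  expect_equal(ser$per_cell$conc_uM, c(3.5, 3.5))
  expect_equal(ser$per_frame$sd_uM, 0)
  expect_equal(ser$per_frame$mean_uM, 3.5)
  expect_equal(ser$per_frame$time_s, 0)
})

test_that("frames without cells are recorded as undefined, not dropped", {
  st <- channel_stack(list(nuclear = list(matrix(0, 8, 8)),
                           drug = list(matrix(0.3, 8, 8))))
  empty <- label_regions(matrix(FALSE, 8, 8), st, 1)
  ser <- cell_concentrations(list(empty), st, "drug", calibration_curve(1))
  expect_equal(ser$per_frame$n_cells, 0L)
  expect_true(is.na(ser$per_frame$mean_uM))
  expect_null(ser$per_cell)
})

test_that("per-cell estimates track ground truth within the noise bound", {
  spec <- scene_spec(n_frames = 20, seed = 9)
  mv <- generate_movie(spec)
  cv <- calibration_curve(spec$calibration$slope, spec$calibration$intercept)
  regs <- lapply(seq_len(20), function(fi)
    label_regions(mv$truth$masks[[fi]], mv$stack, fi))
  ser <- cell_concentrations(regs, mv$stack, "drug", cv)
  sig_conc <- spec$noise_sigma * spec$calibration$slope
  truth_area <- pi * mv$truth$cells$radius^2
  ok <- 0L; tot <- 0L
  for (fi in seq_len(20)) {
    lr <- regs[[fi]]
    mm <- match_regions_to_truth(lr$regions, mv$truth$paths[[fi]])
    for (q in seq_len(nrow(mm))) {
      if (mm[q, "dist"] > 3) next
      a_ratio <- lr$regions$area_px[mm[q, "region"]] /
        truth_area[mm[q, "cell"]]
      if (abs(a_ratio - 1) > 0.25) next           # merged regions excluded
      est <- ser$per_cell$conc_uM[ser$per_cell$frame == fi &
                                    ser$per_cell$cell_id == mm[q, "region"]]
      tol <- 3 * sig_conc / sqrt(lr$regions$area_px[mm[q, "region"]])
      tot <- tot + 1L
      if (abs(est - mv$truth$conc[fi, mm[q, "cell"]]) < tol) ok <- ok + 1L
    }
  }
  expect_gte(ok / tot, 0.99)
})

test_that("the vessel curve reads back the simulated input function", {
  spec <- scene_spec(n_frames = 10, noise_sigma = 0, seed = 3)
  mv <- generate_movie(spec)
  cv <- calibration_curve(spec$calibration$slope, spec$calibration$intercept)
  vc <- vessel_curve(mv$stack, "drug", mv$truth$vessel_roi, cv)
  # zero-noise: inversion through the calibration line is exact to the
  # 16-bit quantization of the stored fluorescence
  q_uM <- spec$calibration$slope / 65535
  expect_lt(max(abs(vc$vessel_uM - mv$truth$vessel_conc)), q_uM)
  expect_error(vessel_curve(mv$stack, "drug", c(1, 300, 1, 10), cv),
               "outside")
  # 1x1 roi equals that pixel's converted values
  v11 <- vessel_curve(mv$stack, "drug", c(2, 2, 3, 3), cv)
  px <- vapply(1:10, function(fi) get_frame(mv$stack, "drug", fi)[2, 3],
               numeric(1))
  expect_equal(v11$vessel_uM,
               as.numeric(fluorescence_to_concentration(cv, px)))
})

test_that("uniform frames give a constant vessel curve", {
  st <- channel_stack(list(drug = list(matrix(0.2, 8, 8),
                                       matrix(0.2, 8, 8))))
  vc <- vessel_curve(st, "drug", c(2, 5, 2, 5), calibration_curve(10))
  expect_equal(vc$vessel_uM, c(2, 2))
})

test_that("subtherapeutic fraction uses a strict less-than cutoff", {
  expect_equal(subtherapeutic_fraction(c(2, 3, 4)), 0)
  expect_equal(subtherapeutic_fraction(c(1, 1.2, 2, 3)), 0.5)
  expect_equal(subtherapeutic_fraction(c(1.5, 2)), 0)   # boundary counts as therapeutic
  expect_equal(subtherapeutic_fraction(c(0.5, 2), threshold = 0), 0)
  expect_true(is.na(subtherapeutic_fraction(numeric(0))))
  # non-increasing when every cell gains a constant amount
  set.seed(50)
  conc <- runif(30, 0, 3)
  fr <- vapply(seq(0, 2, 0.25), function(d)
    subtherapeutic_fraction(conc + d), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("nuclear fraction splits signal between nucleus and cytosolic ring", {
  m <- matrix(FALSE, 40, 40); m[15:24, 15:24] <- TRUE
  st <- channel_stack(list(nuclear = list(m + 0)))
  lr <- label_regions(m, st, 1)
  drug_in <- matrix(0, 40, 40); drug_in[m] <- 0.8
  expect_equal(nuclear_fraction(lr, drug_in, 5), 1.0)
  # uniform drug: fraction equals the area ratio, counted by brute force
  uni <- matrix(0.5, 40, 40)
  dil <- dilate_mask(m, 5)
  a_nuc <- sum(m); a_all <- sum(dil)
  expect_equal(nuclear_fraction(lr, uni, 5), a_nuc / a_all)
  expect_true(is.na(nuclear_fraction(lr, matrix(0, 40, 40), 5)))
})

test_that("the uptake curve solves the one-compartment model", {
  k_in <- 2e-4; k_out <- 5e-5; peak <- 10; k_decay <- 1 / 1800
  t <- seq(0, 7500, by = 75)
  C <- uptake_curve(t, k_in, k_out, peak, k_decay)
  # analytic derivative of the closed form equals the ODE right-hand side
  dC <- k_in * peak * (-k_decay * exp(-k_decay * t) +
                         k_out * exp(-k_out * t)) / (k_out - k_decay)
  Cv <- peak * exp(-k_decay * t)
  expect_lt(max(abs(dC - (k_in * Cv - k_out * C))), 1e-8)
  # k_out = 0 closed form: k_in * peak * (1 - exp(-k_decay t)) / k_decay
  C0 <- uptake_curve(t, k_in, 0, peak, k_decay)
  expect_equal(C0, k_in * peak * (1 - exp(-k_decay * t)) / k_decay)
  expect_equal(uptake_curve(0, k_in, k_out, peak, k_decay), 0)
})

test_that("kinetic parameters are recoverable from simulated mean curves", {
  k_in <- 2e-4; k_out <- 5e-5; peak <- 10; k_decay <- 1 / 1800
  t <- seq(0, 7500, by = 75)
  set.seed(51)
  y <- uptake_curve(t, k_in, k_out, peak, k_decay) + rnorm(length(t), 0, 0.01)
  v <- peak * exp(-k_decay * t) + rnorm(length(t), 0, 0.02)
  vfit <- fit_vessel_decay(t, v)
  expect_equal(vfit$peak, peak, tolerance = 0.02)
  expect_equal(vfit$k_decay, k_decay, tolerance = 0.02)
  ufit <- fit_uptake(t, y, vfit$peak, vfit$k_decay)
  expect_equal(ufit$k_in, k_in, tolerance = 0.05)
  expect_equal(ufit$k_out, k_out, tolerance = 0.1)
})
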