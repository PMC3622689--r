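test_that("misclassification error matches direct pixel counting", {
  manual <- matrix(FALSE, 4, 4)
  manual[2, 2:3] <- TRUE; manual[3, 2:3] <- TRUE     # 4 foreground px
  test <- manual
  test[2, 2] <- FALSE                                 # miss 1 foreground
  test[4, 4] <- TRUE                                  # add 1 false foreground
  expect_equal(misclassification_error(manual, test), 2 / 16)
  expect_equal(misclassification_error(manual, manual), 0)
  expect_equal(misclassification_error(manual, !manual), 1)
  expect_error(misclassification_error(manual, matrix(FALSE, 3, 3)),
               "shapes differ")
})

test_that("ME is complement-symmetric and strictly increased by any flip", {
  set.seed(40)
  manual <- random_mask(8, 8)
  test <- random_mask(8, 8)
  expect_equal(misclassification_error(manual, test),
               misclassification_error(!manual, !test))
  base <- misclassification_error(manual, manual)
  for (k in sample(64, 5)) {
    flipped <- manual
    flipped[k] <- !flipped[k]
    expect_gt(misclassification_error(manual, flipped), base)
  }
})

test_that("region-count nonuniformity follows |R_T - R_o| / R_o", {
  expect_equal(trnu(12, 12), 0)
  expect_equal(trnu(10, 15), 0.5)
  expect_equal(trnu(10, 0), 1)
  expect_equal(trnu(10, 15), trnu(20, 30))     # scale-free
  expect_error(trnu(0, 5), "no regions")
  expect_error(trnu(10, 5, trnu_def = "other"), "unknown")
})

test_that("variance nonuniformity compares population variances of foregrounds", {
  fr <- matrix(c(0.2, 0.4, 0.6, 0.8, rep(0, 12)), 4, 4)
  manual <- matrix(c(rep(TRUE, 4), rep(FALSE, 12)), 4, 4)
  test <- matrix(c(FALSE, TRUE, TRUE, FALSE, rep(FALSE, 12)), 4, 4)
  # sigma_M = popvar(0.2,0.4,0.6,0.8) = 0.05; sigma_T = popvar(0.4,0.6) = 0.01
  expect_equal(vnu(fr, manual, test), 0.8)
  expect_equal(vnu(fr, manual, manual), 0)
  expect_equal(vnu(fr, manual, matrix(FALSE, 4, 4)), 1)   # empty test fg
  const <- matrix(0.5, 4, 4)
  expect_error(vnu(const, manual, test), "variance is 0")
  # scale-free: multiplying the frame scales both variances by c^2
  expect_equal(vnu(fr * 0.37, manual, test), vnu(fr, manual, test))
})

test_that("metric values match brute-force oracles on random mask pairs", {
  set.seed(41)
  for (rep in 1:50) {
    manual <- random_mask(10, 12, p = runif(1, 0.2, 0.8))
    test <- random_mask(10, 12, p = runif(1, 0.2, 0.8))
    expect_identical(misclassification_error(manual, test),
                     oracle_me(manual, test))
    fr <- matrix(runif(120), 10, 12)
    if (sum(manual) >= 2 && ivpharm:::pop_var(fr[manual]) > 0) {
      expect_equal(vnu(fr, manual, test), oracle_vnu(fr, manual, test))
    }
    r_o <- max(oracle_flood_label(manual))
    r_t <- max(ivpharm:::label_components8(test))
    if (r_o >= 1) {
      expect_equal(trnu(r_o, r_t), abs(r_t - r_o) / r_o)
    }
  }
})

test_that("evaluate_thresholds averages metrics over multiple reviewers", {
  f <- generate_metric_fixtures("multibright", seed = 3)
  manual2 <- f$manual
  manual2[1, 1] <- !manual2[1, 1]                 # second reviewer differs
  rows <- evaluate_thresholds(f$frame, list(f$manual, manual2),
                              methods = c("otsu", "ray"), image_id = "fx")
  expect_equal(nrow(rows), 2L)
  r1 <- evaluate_thresholds(f$frame, f$manual, methods = "otsu")
  r2 <- evaluate_thresholds(f$frame, manual2, methods = "otsu")
  expect_equal(rows$me[rows$method == "otsu"], mean(c(r1$me, r2$me)))
})

test_that("Friedman statistic matches the closed-form rank-sum formula", {
  # 3 methods x 4 images, strict orderings built by hand
  rows <- expand.grid(method = c("A", "B", "C"), image_id = 1:4,
                      stringsAsFactors = FALSE)
  rows$me <- c(0.1, 0.2, 0.3,  0.15, 0.25, 0.35,
               0.1, 0.3, 0.2,  0.05, 0.15, 0.25)
  rows$trnu <- rows$me
  rows$vnu <- rows$me
  rep_ <- compare_methods(rows)
  # ranks per image: A=1 B=2 C=3 thrice, and A=1 C=2 B=3 once
  R <- c(A = 4, B = 9, C = 11)
  n <- 4; k <- 3
  stat <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  expect_equal(rep_$friedman$statistic[1], stat)
  # cross-check against the standard implementation on untied data
  m <- matrix(rows$me, n, k, byrow = TRUE)
  ref <- stats::friedman.test(m)
  expect_equal(rep_$friedman$statistic[1], unname(ref$statistic))
  expect_equal(rep_$friedman$p_value[1], ref$p.value)
  # ranks within each image are a permutation of 1..k
  for (img in 1:4) {
    rk <- rep_$rows$rank_me[rep_$rows$image_id == img]
    expect_equal(sort(rk), 1:3)
  }
})

test_that("all-tied designs give statistic 0 and suppress pairwise tests", {
  rows <- expand.grid(method = c("A", "B", "C"), image_id = 1:4,
                      stringsAsFactors = FALSE)
  rows$me <- 0.2; rows$trnu <- 0.1; rows$vnu <- 0.3
  rep_ <- compare_methods(rows)
  expect_equal(rep_$friedman$statistic, c(0, 0, 0))
  expect_equal(nrow(rep_$pairwise), 0L)
  expect_true(all(rep_$rows$rank_me == 2))        # mid-ranks
})

test_that("pairwise Wilcoxon tests run only where Friedman is significant", {
  set.seed(42)
  rows <- expand.grid(method = c("A", "B", "C"), image_id = 1:8,
                      stringsAsFactors = FALSE)
  # me: A always best, C always worst -> strongly significant
  rows$me <- rep(c(0.1, 0.2, 0.3), 8) + rep(runif(8, 0, 0.01), each = 3)
  rows$trnu <- runif(24)                          # no structure
  rows$vnu <- rep(c(0.1, 0.2, 0.3), 8)
  rep_ <- compare_methods(rows)
  expect_lt(rep_$friedman$p_value[1], 0.05)
  expect_true("me" %in% rep_$pairwise$metric)
  expect_equal(sum(rep_$pairwise$metric == "me"), 3L)   # all pairs
  if (rep_$friedman$p_value[2] >= 0.05) {
    expect_false("trnu" %in% rep_$pairwise$metric)
  }
})

test_that("two-method and malformed designs are handled", {
  rows <- expand.grid(method = c("A", "B"), image_id = 1:3,
                      stringsAsFactors = FALSE)
  rows$me <- c(0.1, 0.2, 0.1, 0.2, 0.1, 0.2)
  rows$trnu <- rows$me; rows$vnu <- rows$me
  rep_ <- compare_methods(rows)
  expect_equal(dim(rep_$rank_table), c(2L, 3L))
  expect_true(all(is.finite(rep_$friedman$statistic)))
  expect_error(compare_methods(rows[-1, ]), "incomplete design")
})

test_that("method ranking reproduces the qualitative ordering by image family", {
  # multi-brightness fields: the locally-adaptive method must not rank
  # behind the global clustering method
  mb <- do.call(rbind, lapply(1:4, function(i) {
    f <- generate_metric_fixtures("multibright", seed = 70 + i)
    evaluate_thresholds(f$frame, f$manual, image_id = paste0("mb", i))
  }))
  r_mb <- rowMeans(compare_methods(mb)$rank_table)
  expect_lte(r_mb["ray"], r_mb["otsu"])

  # single-brightness dense fields: all three methods perform
  # approximately equally (misclassification errors in a narrow band)
  dn <- do.call(rbind, lapply(1:4, function(i) {
    f <- generate_metric_fixtures("dense", seed = 80 + i)
    evaluate_thresholds(f$frame, f$manual, image_id = paste0("dn", i))
  }))
  for (img in unique(dn$image_id)) {
    me <- dn$me[dn$image_id == img]
    expect_lt(max(me) - min(me), 0.015)
    expect_lt(max(me), 0.03)
  }
})
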