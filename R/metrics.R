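#' Misclassification error
#'
#' Fraction of pixels whose foreground/background assignment in the
#' test mask disagrees with the manual reference:
#' `ME = 1 - (|B_o & B_T| + |F_o & F_T|) / (|B_o| + |F_o|)`, where
#' `F`/`B` are the foreground/background pixel sets of the manual (`o`)
#' and test (`T`) masks. 0 means perfect agreement, 1 total
#' disagreement.
#'
#' @param manual Logical matrix: the manual reference mask.
#' @param test Logical matrix: the mask under evaluation.
#' @return A number in `[0, 1]`.
#' @export
misclassification_error <- function(manual, test) {
  if (!identical(dim(manual), dim(test))) {
    stop(sprintf("mask shapes differ: %dx%d vs %dx%d",
                 nrow(manual), ncol(manual), nrow(test), ncol(test)))
  }
  1 - (sum(!manual & !test) + sum(manual & test)) / length(manual)
}

#' Total region number nonuniformity
#'
#' Penalty for producing a different number of connected regions than
#' the manual reference: `TRNU = |R_T - R_o| / R_o` with `R_o` the
#' region count of the manual mask and `R_T` of the test mask
#' (`trnu_def = "abs_rel"`, the adopted form; the argument exists so an
#' alternate definition can be slotted in).
#'
#' @param manual_region_count Region count of the manual mask (>= 1).
#' @param test_region_count Region count of the test mask (>= 0).
#' @param trnu_def Definition identifier; only `"abs_rel"` is
#'   implemented.
#' @return A non-negative number.
#' @export
trnu <- function(manual_region_count, test_region_count,
                 trnu_def = "abs_rel") {
  if (trnu_def != "abs_rel") stop("unknown trnu_def: ", trnu_def)
  if (manual_region_count < 1) {
    stop("undefined metric: manual mask has no regions")
  }
  abs(test_region_count - manual_region_count) / manual_region_count
}

# population variance (divide by N): deterministic small-sample metric
pop_var <- function(x) mean((x - mean(x))^2)

#' Variance nonuniformity
#'
#' Compares the spread of foreground fluorescence between the manual
#' and test segmentations: with `sigma_T` the population variance of
#' the frame over the test foreground and `sigma_M` over the manual
#' foreground, `VNU = |sigma_T - sigma_M| / sigma_M`
#' (`vnu_def = "rel_var"`, the adopted form). An empty test foreground
#' contributes `sigma_T = 0`, giving VNU = 1.
#'
#' @param frame Numeric intensity matrix.
#' @param manual Logical matrix; its foreground must contain at least 2
#'   pixels with non-zero intensity variance.
#' @param test Logical matrix of identical shape.
#' @param vnu_def Definition identifier; only `"rel_var"` is
#'   implemented.
#' @return A non-negative number.
#' @export
vnu <- function(frame, manual, test, vnu_def = "rel_var") {
  if (vnu_def != "rel_var") stop("unknown vnu_def: ", vnu_def)
  if (!identical(dim(manual), dim(test)) ||
      !identical(dim(frame), dim(manual))) {
    stop("frame and mask shapes must all agree")
  }
  fm <- frame[manual]
  if (length(fm) < 2L) stop("undefined metric: manual foreground has < 2 pixels")
  sM <- pop_var(fm)
  if (sM == 0) stop("undefined metric: manual foreground variance is 0")
  ft <- frame[test]
  sT <- if (length(ft)) pop_var(ft) else 0
  abs(sT - sM) / sM
}

#' Evaluate thresholding methods against manual masks on one image
#'
#' Runs each method on the frame, computes ME, TRNU and VNU against
#' each supplied manual reference mask, and averages the metric values
#' over the references (the multi-reviewer convention). Region counts
#' are taken from 8-connected components of the raw thresholded masks.
#'
#' @param frame Numeric matrix in `[0, 1]`.
#' @param manual A logical matrix or list of logical matrices (one per
#'   reviewer).
#' @param methods Character vector of methods to score.
#' @param image_id Identifier recorded in the output rows.
#' @param gamma,ray Passed to [threshold_frame()].
#' @return A data frame with columns `image_id`, `method`, `me`,
#'   `trnu`, `vnu`.
#' @export
evaluate_thresholds <- function(frame, manual,
                                methods = c("otsu", "huang", "ray"),
                                image_id = "image", gamma = 1,
                                ray = ray_params()) {
  if (is.matrix(manual)) manual <- list(manual)
  r_o <- vapply(manual, function(m) max(label_components8(m)), numeric(1))
  rows <- lapply(methods, function(meth) {
    res <- threshold_frame(frame, method = meth, gamma = gamma, ray = ray)
    r_t <- max(label_components8(res$mask))
    vals <- vapply(seq_along(manual), function(k) {
      c(misclassification_error(manual[[k]], res$mask),
        trnu(r_o[k], r_t),
        vnu(frame, manual[[k]], res$mask))
    }, numeric(3))
    data.frame(image_id = image_id, method = meth,
               me = mean(vals[1, ]), trnu = mean(vals[2, ]),
               vnu = mean(vals[3, ]))
  })
  do.call(rbind, rows)
}

# Friedman chi-square from within-block mid-ranks;
# the all-tied design gives 0 by construction
friedman_from_ranks <- function(rank_mat) {
  n <- nrow(rank_mat); k <- ncol(rank_mat)
  Rj <- colSums(rank_mat)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p)
}

#' Rank-based comparison of thresholding methods
#'
#' For each metric (ME, TRNU, VNU) the methods are ranked within each
#' image (rank 1 = lowest, i.e. best; mid-ranks on ties), the Friedman
#' rank-sums test is applied across images, and — only where the
#' Friedman test is significant at `alpha` — pairwise two-sample
#' Wilcoxon rank-sum tests compare each pair of methods.
#'
#' @param rows A data frame as produced by [evaluate_thresholds()]
#'   (possibly row-bound over images): columns `image_id`, `method`,
#'   `me`, `trnu`, `vnu`. Every method must be scored on every image.
#' @param alpha Significance gate for running the pairwise tests.
#' @return An object of class `MetricReport`: `rows` (input augmented
#'   with `rank_me`, `rank_trnu`, `rank_vnu`), `rank_table` (mean rank
#'   per method and metric), `friedman` (statistic and p-value per
#'   metric) and `pairwise` (data frame of pairwise p-values, empty
#'   where the gate was not passed).
#' @export
compare_methods <- function(rows, alpha = 0.05) {
  metrics <- c("me", "trnu", "vnu")
  stopifnot(all(c("image_id", "method", metrics) %in% names(rows)))
  images <- unique(rows$image_id)
  methods <- unique(rows$method)
  tab <- table(rows$image_id, rows$method)
  if (any(tab != 1L)) {
    stop("incomplete design: every method must be scored exactly once per image")
  }
  rows <- rows[order(match(rows$image_id, images),
                     match(rows$method, methods)), , drop = FALSE]
  n <- length(images); k <- length(methods)
  friedman <- data.frame(metric = metrics, statistic = NA_real_,
                         p_value = NA_real_)
  rank_table <- matrix(NA_real_, k, length(metrics),
                       dimnames = list(methods, metrics))
  pairwise <- data.frame(metric = character(0), method_a = character(0),
                         method_b = character(0), p_value = numeric(0))
  for (mi in seq_along(metrics)) {
    m <- metrics[mi]
    vals <- matrix(rows[[m]], n, k, byrow = TRUE)   # images x methods
    rk <- t(apply(vals, 1, rank))                   # mid-ranks on ties
    if (k == 1L) rk <- matrix(rk, n, k)
    rows[[paste0("rank_", m)]] <- as.vector(t(rk))
    rank_table[, mi] <- colMeans(rk)
    fr <- friedman_from_ranks(rk)
    friedman$statistic[mi] <- fr$statistic
    friedman$p_value[mi] <- fr$p_value
    if (!is.na(fr$p_value) && fr$p_value < alpha) {
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        pv <- suppressWarnings(
          stats::wilcox.test(vals[, a], vals[, b], exact = FALSE)$p.value)
        pairwise <- rbind(pairwise, data.frame(
          metric = m, method_a = methods[a], method_b = methods[b],
          p_value = pv))
      }
    }
  }
  structure(list(rows = rows, rank_table = rank_table,
                 friedman = friedman, pairwise = pairwise, alpha = alpha),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat("MetricReport over", length(unique(x$rows$image_id)), "image(s),",
      length(unique(x$rows$method)), "method(s)\n")
  cat("mean ranks (1 = best):\n")
  print(round(x$rank_table, 2))
  cat("Friedman tests:\n")
  print(x$friedman, row.names = FALSE)
  if (nrow(x$pairwise)) {
    cat("pairwise Wilcoxon (where Friedman p <", x$alpha, "):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
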