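#' Gamma adjustment
#'
#' Elementwise power-law intensity adjustment `x^gamma` on `[0, 1]`
#' images. Strictly order-preserving, so it changes which threshold is
#' selected but never the relative ranking of pixels.
#'
#' @param frame Numeric matrix with values in `[0, 1]`.
#' @param gamma Positive exponent; `gamma = 1` is the identity,
#'   `gamma < 1` brightens dim structures.
#' @return Adjusted matrix in `[0, 1]`.
#' @export
gamma_adjust <- function(frame, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a single positive number")
  }
  if (min(frame) < 0 || max(frame) > 1) stop("frame must lie in [0, 1]")
  frame^gamma
}

#' Parameters of the iterative locally-adaptive thresholder
#'
#' @param iterations Iteration cap (the method typically needs on the
#'   order of a thousand iterations at a tight tolerance, far fewer at
#'   the default tolerance).
#' @param power Class-weighting exponent; higher values make the local
#'   threshold more selective towards the dominant class.
#' @param epsilon Termination tolerance on the mean absolute change of
#'   the threshold surface per pixel and iteration.
#' @param window_radius Radius (pixels) of the square local window; the
#'   default 15 px is roughly one nucleus diameter at 20x magnification.
#'   The window must straddle an object and its surround: objects much
#'   larger than the window need internal intensity structure to
#'   segment well.
#' @param min_contrast Minimum local foreground/background class
#'   contrast (on the `[0, 1]` intensity scale) for a neighborhood to
#'   yield foreground at all; windows below it (flat or noise-only
#'   background) are forced to background. Set to 0 to disable the
#'   guard.
#' @return An object of class `RayParams`.
#' @export
ray_params <- function(iterations = 1000L, power = 1, epsilon = 1e-4,
                       window_radius = 15L, min_contrast = 0.05) {
  if (iterations < 1L) stop("iterations must be >= 1")
  if (power <= 0) stop("power must be > 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (window_radius < 1L) stop("window_radius must be >= 1")
  if (min_contrast < 0) stop("min_contrast must be >= 0")
  structure(list(iterations = as.integer(iterations), power = power,
                 epsilon = epsilon, window_radius = as.integer(window_radius),
                 min_contrast = min_contrast),
            class = "RayParams")
}

# --- shared internals -------------------------------------------------

# 256-level quantization of [0,1]: level g in 0..255 with bins
# (g/256, (g+1)/256], so that "level > t" is exactly "value > (t+1)/256"
quantize256 <- function(frame) {
  g <- ceiling(frame * 256) - 1L
  g[g < 0L] <- 0L
  g[g > 255L] <- 255L
  g
}

threshold_result <- function(frame, surface, method, iterations_used = 1L,
                             deltas = numeric(0)) {
  structure(list(mask = frame > surface, surface = surface, method = method,
                 iterations_used = as.integer(iterations_used),
                 deltas = deltas),
            class = "ThresholdResult")
}

#' @export
print.ThresholdResult <- function(x, ...) {
  cat(sprintf("ThresholdResult[%s]: %d/%d px foreground, %d iteration(s)\n",
              x$method, sum(x$mask), length(x$mask), x$iterations_used))
  invisible(x)
}

check_nonconstant <- function(frame) {
  if (length(unique(as.vector(quantize256(frame)))) < 2L) {
    stop("degenerate input: frame has fewer than 2 distinct quantized levels")
  }
}

#' Otsu's global threshold
#'
#' Clustering-based global thresholding: the image histogram (256
#' uniform bins of `[0, 1]`) is split at the level maximizing the
#' between-class variance, equivalently minimizing the weighted
#' within-class variance. Ties are broken towards the smallest
#' maximizing level; foreground is strictly above the threshold.
#'
#' @param frame Numeric matrix in `[0, 1]` with at least two distinct
#'   quantized levels.
#' @return A `ThresholdResult` with fields `mask` (logical matrix),
#'   `surface` (constant matrix of the threshold value), `method` and
#'   `iterations_used`.
#' @export
otsu_threshold <- function(frame) {
  check_nonconstant(frame)
  g <- quantize256(frame)
  h <- tabulate(g + 1L, 256L)
  lev <- 0:255
  n <- length(g)
  cw <- cumsum(h)
  cs <- cumsum(h * lev)
  tot <- cs[256]
  w1 <- cw[1:255]; w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  m1 <- cs[1:255] / w1
  m2 <- (tot - cs[1:255]) / w2
  bcv <- ifelse(valid, w1 * w2 * (m1 - m2)^2, -Inf)
  t_lev <- which.max(bcv) - 1L            # which.max takes the first maximum
  surface <- matrix((t_lev + 1) / 256, nrow(frame), ncol(frame))
  threshold_result(frame, surface, "otsu")
}

#' Huang's fuzzy global threshold
#'
#' Object-attribute thresholding by minimal fuzziness: for a candidate
#' level `t`, each pixel's membership to its class (foreground above
#' `t`, background at or below) is `1 / (1 + |g - m_class| / C)` with
#' `m_class` the class mean gray level and `C` the image gray-level
#' range. The returned threshold minimizes the Shannon-entropy index of
#' fuzziness `sum(-mu log mu - (1-mu) log(1-mu))`; ties break to the
#' smallest level.
#'
#' @inheritParams otsu_threshold
#' @return A `ThresholdResult`; see [otsu_threshold()].
#' @export
huang_threshold <- function(frame) {
  check_nonconstant(frame)
  g <- quantize256(frame)
  h <- tabulate(g + 1L, 256L)
  lev <- 0:255
  C <- max(g) - min(g)
  cw <- cumsum(h)
  cs <- cumsum(h * lev)
  n <- length(g); tot <- cs[256]
  shannon <- function(mu) {
    s <- numeric(length(mu))
    ok <- mu > 0 & mu < 1
    s[ok] <- -mu[ok] * log(mu[ok]) - (1 - mu[ok]) * log(1 - mu[ok])
    s
  }
  best <- Inf; t_best <- NA_integer_
  for (t in 0:254) {
    w1 <- cw[t + 1L]; w2 <- n - w1
    if (w1 == 0 || w2 == 0) next
    m1 <- cs[t + 1L] / w1
    m2 <- (tot - cs[t + 1L]) / w2
    mu <- numeric(256)
    bg <- lev <= t
    mu[bg] <- 1 / (1 + abs(lev[bg] - m1) / C)
    mu[!bg] <- 1 / (1 + abs(lev[!bg] - m2) / C)
    fz <- sum(h * shannon(mu))
    if (fz < best - 1e-12) { best <- fz; t_best <- t }
  }
  if (is.na(t_best)) stop("degenerate input: no candidate level splits the histogram")
  surface <- matrix((t_best + 1) / 256, nrow(frame), ncol(frame))
  threshold_result(frame, surface, "huang")
}

# clamped-window box sum via summed-area table; windows are squares of
# half-width r truncated at the image edge
box_sum <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  S <- apply(x, 2, cumsum)
  if (nr == 1L) S <- matrix(S, 1L, nc)
  S <- t(apply(S, 1, cumsum))
  if (nc == 1L) S <- matrix(S, nr, 1L)
  Sp <- matrix(0, nr + 1, nc + 1)
  Sp[2:(nr + 1), 2:(nc + 1)] <- S
  i <- seq_len(nr); j <- seq_len(nc)
  r1 <- pmax(i - r, 1); r2 <- pmin(i + r, nr)
  c1 <- pmax(j - r, 1); c2 <- pmin(j + r, nc)
  out <- Sp[cbind(rep(r2 + 1, nc), rep(c2 + 1, each = nr))] -
    Sp[cbind(rep(r1, nc), rep(c2 + 1, each = nr))] -
    Sp[cbind(rep(r2 + 1, nc), rep(c1, each = nr))] +
    Sp[cbind(rep(r1, nc), rep(c1, each = nr))]
  matrix(out, nr, nc)
}

box_count <- function(nr, nc, r) box_sum(matrix(1, nr, nc), r)

#' Iterative locally-adaptive threshold
#'
#' Computes a per-pixel threshold surface from windowed class
#' statistics, refined iteratively. The surface is initialized at the
#' midpoint of the local foreground/background class means (classes
#' split at the local window mean). At each iteration the local
#' foreground fraction `f` and class means `m_F`, `m_B` are recomputed
#' under the current surface, the surface is updated to the weighted
#' mean `(w_F m_F + w_B m_B) / (w_F + w_B)` with `w_F = f^power` and
#' `w_B = (1 - f)^power`, and smoothed with a mean filter over the same
#' window. Iteration stops when the mean absolute surface change per
#' pixel drops below `epsilon` or the iteration cap is reached (hitting
#' the cap is not an error; the surface at the cap is returned).
#' Finally, neighborhoods whose class contrast stays below
#' `min_contrast` are forced to background, so flat or noise-only
#' areas do not fragment into spurious foreground.
#'
#' Because the threshold adapts to each neighborhood, nuclei at very
#' different brightness levels are recovered simultaneously — the
#' regime where a single global threshold must sacrifice the dim ones.
#'
#' @inheritParams otsu_threshold
#' @param params A [ray_params()] object.
#' @return A `ThresholdResult`; `surface` is the per-pixel threshold,
#'   `iterations_used` the iterations actually run, and `deltas` the
#'   recorded per-iteration mean absolute surface changes.
#' @export
ray_threshold <- function(frame, params = ray_params()) {
  stopifnot(inherits(params, "RayParams"))
  check_nonconstant(frame)
  r <- params$window_radius
  nr <- nrow(frame); nc <- ncol(frame)
  cnt <- box_count(nr, nc, r)
  sg <- box_sum(frame, r)
  m_all <- sg / cnt
  class_stats <- function(fg) {
    cf <- box_sum(fg + 0, r)
    sf <- box_sum(frame * fg, r)
    mF <- ifelse(cf > 0, sf / cf, m_all)       # empty class: fall back to local mean
    cb <- cnt - cf
    mB <- ifelse(cb > 0, (sg - sf) / cb, m_all)
    list(mF = mF, mB = mB, f = cf / cnt)
  }
  st <- class_stats(frame > m_all)
  surface <- (st$mF + st$mB) / 2
  deltas <- numeric(0)
  used <- params$iterations
  for (k in seq_len(params$iterations)) {
    st <- class_stats(frame > surface)
    wF <- st$f^params$power
    wB <- (1 - st$f)^params$power
    wsum <- wF + wB
    raw <- ifelse(wsum > 0, (wF * st$mF + wB * st$mB) / wsum, m_all)
    new_surface <- box_sum(raw, r) / cnt
    d <- mean(abs(new_surface - surface))
    deltas <- c(deltas, d)
    surface <- new_surface
    if (d < params$epsilon) { used <- k; break }
  }
  # guard against summed-area rounding: exactly-flat neighborhoods must
  # stay background, so bias the surface up by far less than one
  # 16-bit quantization step
  surface <- surface + 1e-9
  # contrast floor: a neighborhood whose class means are closer than
  # min_contrast carries no object/background structure (flat area or
  # pure noise); force it to background instead of splitting the noise
  if (params$min_contrast > 0) {
    st <- class_stats(frame > surface)
    surface[st$mF - st$mB < params$min_contrast] <- 1
  }
  threshold_result(frame, surface, "ray", iterations_used = used,
                   deltas = deltas)
}

#' Threshold a frame by a named method
#'
#' Dispatcher over [otsu_threshold()], [huang_threshold()] and
#' [ray_threshold()], applied after optional [gamma_adjust()].
#'
#' @inheritParams otsu_threshold
#' @param method One of `"otsu"`, `"huang"`, `"ray"`.
#' @param gamma Gamma pre-adjustment exponent.
#' @param ray [ray_params()] used when `method = "ray"`.
#' @return A `ThresholdResult`.
#' @export
threshold_frame <- function(frame, method = c("ray", "otsu", "huang"),
                            gamma = 1, ray = ray_params()) {
  method <- match.arg(method)
  frame <- gamma_adjust(frame, gamma)
  switch(method,
         otsu = otsu_threshold(frame),
         huang = huang_threshold(frame),
         ray = ray_threshold(frame, ray))
}
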