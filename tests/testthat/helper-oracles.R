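# Independent brute-force oracles. These deliberately use the most
# direct (slow) formulation of each definition, so they share no code
# path with the package implementation they check.

# misclassification error by explicit pixel loop
oracle_me <- function(manual, test) {
  agree <- 0L
  for (i in seq_len(nrow(manual))) for (j in seq_len(ncol(manual))) {
    if (manual[i, j] == test[i, j]) agree <- agree + 1L
  }
  1 - agree / length(manual)
}

# population variance written out longhand
oracle_pop_var <- function(x) sum((x - sum(x) / length(x))^2) / length(x)

oracle_vnu <- function(frame, manual, test) {
  sM <- oracle_pop_var(frame[manual])
  sT <- if (any(test)) oracle_pop_var(frame[test]) else 0
  abs(sT - sM) / sM
}

# exhaustive Otsu: between-class variance evaluated per candidate level
# directly from the pixel values (no histogram sharing with the package)
oracle_otsu_level <- function(frame) {
  g <- pmin(pmax(ceiling(frame * 256) - 1, 0), 255)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:254) {
    fg <- g > t
    n1 <- sum(!fg); n2 <- sum(fg)
    if (n1 == 0 || n2 == 0) next
    v <- n1 * n2 * (mean(g[!fg]) - mean(g[fg]))^2
    if (v > best + 1e-9) { best <- v; bt <- t }
  }
  bt
}

# exhaustive Huang: fuzziness index per candidate level from pixel values
oracle_huang_level <- function(frame) {
  g <- pmin(pmax(ceiling(frame * 256) - 1, 0), 255)
  C <- max(g) - min(g)
  S <- function(mu) ifelse(mu <= 0 | mu >= 1, 0,
                           -mu * log(mu) - (1 - mu) * log(1 - mu))
  best <- Inf; bt <- NA_integer_
  for (t in 0:254) {
    fg <- g > t
    if (!any(fg) || !any(!fg)) next
    mu <- numeric(length(g))
    mu[!fg] <- 1 / (1 + abs(g[!fg] - mean(g[!fg])) / C)
    mu[fg] <- 1 / (1 + abs(g[fg] - mean(g[fg])) / C)
    fz <- sum(S(mu))
    if (fz < best - 1e-9) { best <- fz; bt <- t }
  }
  bt
}

# opening by double loop straight from the structuring-element
# definition (i^2 + j^2 <= r^2); out-of-bounds positions are ignored
oracle_opening <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  off <- expand.grid(a = -r:r, b = -r:r)
  off <- off[off$a^2 + off$b^2 <= r^2, ]
  ero <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (k in seq_len(nrow(off))) {
      ii <- i + off$a[k]; jj <- j + off$b[k]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && !mask[ii, jj]) {
        ok <- FALSE; break
      }
    }
    ero[i, j] <- ok && mask[i, j]
  }
  dil <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    hit <- FALSE
    for (k in seq_len(nrow(off))) {
      ii <- i + off$a[k]; jj <- j + off$b[k]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && ero[ii, jj]) {
        hit <- TRUE; break
      }
    }
    dil[i, j] <- hit
  }
  dil
}

# 8-connected labeling by iterative flood fill (explicit stack)
oracle_flood_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {   # column-major like R
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (a in -1:1) for (b in -1:1) {
        ii <- p[1] + a; jj <- p[2] + b
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# optimal frame-to-frame linking by exhaustive recursion: maximize the
# number of links within max_radius, then minimize total squared
# displacement. Returns link[i] = matched current-frame index or 0.
oracle_link <- function(prev, curr, max_radius) {
  n <- nrow(prev); m <- nrow(curr)
  if (n == 0 || m == 0) return(integer(n))
  d2 <- outer(prev[, 1], curr[, 1], "-")^2 +
    outer(prev[, 2], curr[, 2], "-")^2
  best_link <- integer(n); best_k <- -1L; best_cost <- Inf
  link <- integer(n)
  recurse <- function(i, used, k, cost) {
    if (i > n) {
      if (k > best_k || (k == best_k && cost < best_cost - 1e-12)) {
        best_k <<- k; best_cost <<- cost; best_link <<- link
      }
      return(invisible())
    }
    for (j in seq_len(m)) {
      if (!used[j] && d2[i, j] <= max_radius^2) {
        used[j] <- TRUE; link[i] <<- j
        recurse(i + 1L, used, k + 1L, cost + d2[i, j])
        used[j] <- FALSE
      }
    }
    link[i] <<- 0L
    recurse(i + 1L, used, k, cost)
  }
  recurse(1L, rep(FALSE, m), 0L, 0)
  best_link
}

# brute-force square assignment: min total cost over all permutations
oracle_lap_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best) best <- cc
  }
  best
}

# random logical matrix
random_mask <- function(nr, nc, p = 0.5) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# map detected regions to ground-truth cells by nearest centroid;
# returns data frame (region k, truth cell, distance)
match_regions_to_truth <- function(regions, truth_centers) {
  t(vapply(seq_len(nrow(regions)), function(k) {
    d <- sqrt((truth_centers[, 1] - regions$centroid_row[k])^2 +
                (truth_centers[, 2] - regions$centroid_col[k])^2)
    ci <- which.min(d)
    c(region = k, cell = ci, dist = d[ci])
  }, numeric(3)))
}
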