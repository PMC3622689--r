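# Linear assignment by shortest augmenting paths (Jonker-Volgenant
# style, O(n^3)); cost must be square, may contain Inf for forbidden
# pairs but every row needs one finite entry. Returns for each row the
# assigned column.
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)                  # p[j+1] = row assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      free_j <- which(!used[2:(n + 1)])
      cur <- cost[i0, free_j] - u[i0 + 0] - v[free_j + 1]
      upd <- cur < minv[free_j + 1]
      minv[free_j[upd] + 1] <- cur[upd]
      way[free_j[upd] + 1] <- j0
      jmin <- free_j[which.min(minv[free_j + 1])]
      delta <- minv[jmin + 1]
      j1 <- jmin
      isu <- which(used)
      u[p[isu]] <- u[p[isu]] + delta
      v[isu] <- v[isu] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_col <- integer(n)
  for (j in seq_len(n)) assign_col[p[j + 1]] <- j
  assign_col
}

# match detections of two consecutive frames: one-to-one assignment
# maximizing the number of links within max_radius and, among those,
# minimizing total squared displacement (dummy birth/death entries at a
# big-M cost make extra links always preferable)
match_frames <- function(prev, curr, max_radius) {
  n <- nrow(prev); m <- nrow(curr)
  if (n == 0L || m == 0L) return(integer(0))
  d2 <- outer(prev[, 1], curr[, 1], "-")^2 + outer(prev[, 2], curr[, 2], "-")^2
  d2[d2 > max_radius^2] <- Inf
  M <- max_radius^2 * (n + m + 1) + 1
  N <- n + m
  cost <- matrix(0, N, N)
  cost[seq_len(n), seq_len(m)] <- d2
  cost[seq_len(n), m + seq_len(n)] <- Inf
  cost[cbind(seq_len(n), m + seq_len(n))] <- M       # death
  cost[n + seq_len(m), seq_len(m)] <- Inf
  cost[cbind(n + seq_len(m), seq_len(m))] <- M       # birth
  a <- solve_lap(cost)
  link <- integer(n)
  for (i in seq_len(n)) link[i] <- if (a[i] <= m) a[i] else 0L
  link
}

#' Link per-frame detections into cell tracks
#'
#' Between consecutive frames, detections are joined by an optimal
#' one-to-one assignment: among all pairings whose displacement is at
#' most `max_radius` pixels, the assignment maximizes the number of
#' links and minimizes the total squared displacement. Unmatched
#' previous-frame detections terminate their tracks and unmatched
#' current-frame detections start new ones — there is no gap closing,
#' merging or splitting, so frames within a track are strictly
#' consecutive and each detection belongs to exactly one track.
#'
#' @param detections A list with one element per frame; each element a
#'   data frame with columns `cell_id`, `row`, `col` (centroids in
#'   pixels). [regions_to_detections()] builds this from segmentation
#'   output. Empty frames are allowed.
#' @param max_radius Maximum linking displacement in pixels; the
#'   default 10 px matches typical inter-frame nuclear motion at this
#'   magnification and frame interval.
#' @return A data frame of class `cell_tracks` with columns `track_id`,
#'   `frame`, `row`, `col`, `cell_id`, ordered by track then frame.
#' @export
link_tracks <- function(detections, max_radius = 10) {
  stopifnot(max_radius > 0)
  nf <- length(detections)
  det <- lapply(detections, function(d) {
    if (is.null(d) || nrow(d) == 0L) {
      data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0))
    } else d
  })
  track_of <- vector("list", nf)    # per frame: track id of each detection
  next_track <- 1L
  rows <- list()
  add_point <- function(tid, fi, d, k) {
    rows[[length(rows) + 1L]] <<- data.frame(
      track_id = tid, frame = fi, row = d$row[k], col = d$col[k],
      cell_id = d$cell_id[k])
  }
  if (nf >= 1L && nrow(det[[1]])) {
    track_of[[1]] <- seq_len(nrow(det[[1]]))
    next_track <- nrow(det[[1]]) + 1L
    for (k in seq_len(nrow(det[[1]]))) add_point(track_of[[1]][k], 1L, det[[1]], k)
  }
  if (nf >= 2L) for (fi in 2:nf) {
    prev <- det[[fi - 1]]; curr <- det[[fi]]
    m <- nrow(curr)
    track_of[[fi]] <- integer(m)
    link <- match_frames(cbind(prev$row, prev$col),
                         cbind(curr$row, curr$col), max_radius)
    if (length(link)) for (i in seq_along(link)) {
      if (link[i] > 0L) track_of[[fi]][link[i]] <- track_of[[fi - 1]][i]
    }
    if (m) for (k in seq_len(m)) {
      if (track_of[[fi]][k] == 0L) {
        track_of[[fi]][k] <- next_track
        next_track <- next_track + 1L
      }
      add_point(track_of[[fi]][k], fi, curr, k)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(track_id = integer(0), frame = integer(0), row = numeric(0),
               col = numeric(0), cell_id = integer(0))
  }
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cell_tracks", "data.frame")
  out
}

#' Convert per-frame segmentations to detection lists
#'
#' @param regions_list List of `LabeledRegions` (one per frame).
#' @return A list of data frames with `cell_id`, `row`, `col`,
#'   `amplitude` (mean intensity of the first measured channel, or
#'   area if no channel was measured).
#' @export
regions_to_detections <- function(regions_list) {
  lapply(regions_list, function(lr) {
    r <- lr$regions
    amp_col <- grep("^mean_", names(r), value = TRUE)
    data.frame(cell_id = r$id, row = r$centroid_row, col = r$centroid_col,
               amplitude = if (length(amp_col)) r[[amp_col[1]]] else r$area_px)
  })
}

#' Attach per-cell drug concentrations to tracks
#'
#' Joins a [link_tracks()] result with a [cell_concentrations()] series
#' by `(frame, cell_id)`, so each track carries its cell's nuclear drug
#' concentration over time.
#'
#' @param tracks A `cell_tracks` data frame.
#' @param series A `ConcentrationSeries`.
#' @return `tracks` with an added `conc_uM` column.
#' @export
attach_concentrations <- function(tracks, series) {
  stopifnot(inherits(series, "ConcentrationSeries"))
  pc <- series$per_cell
  if (is.null(pc)) stop("series has no per-cell records")
  key_t <- paste(tracks$frame, tracks$cell_id)
  key_s <- paste(pc$frame, pc$cell_id)
  hit <- match(key_t, key_s)
  if (anyNA(hit)) {
    miss <- which(is.na(hit))[1]
    stop(sprintf("no concentration record for frame %d cell %d",
                 tracks$frame[miss], tracks$cell_id[miss]))
  }
  tracks$conc_uM <- pc$conc_uM[hit]
  tracks
}

#' Export/read detections for external linkers
#'
#' Writes per-frame detection records as CSV with columns `frame`,
#' `x`, `y`, `amplitude` in frame-major order (`x` = column, `y` = row,
#' the image-coordinate convention of common particle-tracking tools).
#' `read_detections()` restores the per-frame list losslessly.
#'
#' @param detections As for [link_tracks()] (an `amplitude` column is
#'   carried through if present, else 0).
#' @param path Output CSV path.
#' @return `export_detections` returns `path` invisibly;
#'   `read_detections` returns a detections list.
#' @export
export_detections <- function(detections, path) {
  rows <- lapply(seq_along(detections), function(fi) {
    d <- detections[[fi]]
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    data.frame(frame = fi, x = d$col, y = d$row,
               amplitude = if ("amplitude" %in% names(d)) d$amplitude else 0)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      amplitude = numeric(0))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_detections
#' @param n_frames Total frame count (so trailing empty frames
#'   round-trip); defaults to the largest frame index present.
#' @export
read_detections <- function(path, n_frames = NULL) {
  d <- utils::read.csv(path)
  nf <- if (is.null(n_frames)) {
    if (nrow(d)) max(d$frame) else 0L
  } else n_frames
  lapply(seq_len(nf), function(fi) {
    di <- d[d$frame == fi, , drop = FALSE]
    data.frame(cell_id = seq_len(nrow(di)), row = di$y, col = di$x,
               amplitude = di$amplitude)
  })
}
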