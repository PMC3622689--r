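#' Multi-channel image stack
#'
#' A `ChannelStack` holds a named set of channels, each a list of 2-D
#' numeric frame matrices with intensities normalized to `[0, 1]`. The
#' third axis is either time (a movie) or depth (a Z-stack). All channels
#' must agree in frame count and frame dimensions.
#'
#' Pixel coordinates throughout the package are `(row, col)`, 1-based,
#' matching R matrix indexing; centroids are sub-pixel numerics in the
#' same convention.
#'
#' @param channels Named list; each element is a list of numeric matrices
#'   (one per frame) with values in `[0, 1]`.
#' @param axis One of `"time"` or `"z"`.
#' @param frame_interval_s Seconds between frames (time axis only).
#' @param pixel_size_um Micrometers per pixel.
#' @param bit_depth Integer bit depth of the source data (used for
#'   normalization on write).
#' @return An object of class `ChannelStack`.
#' @export
channel_stack <- function(channels, axis = c("time", "z"),
                          frame_interval_s = 75, pixel_size_um = 1,
                          bit_depth = 16L) {
  axis <- match.arg(axis)
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list of frame lists")
  }
  nf <- vapply(channels, length, integer(1))
  if (length(unique(nf)) != 1L || nf[1] < 1L) {
    stop("all channels must have the same, positive frame count")
  }
  dims <- lapply(channels, function(ch) unique(lapply(ch, dim)))
  d0 <- dims[[1]][[1]]
  if (any(vapply(dims, length, integer(1)) != 1L) ||
      any(vapply(dims, function(d) !identical(d[[1]], d0), logical(1)))) {
    stop("all frames in all channels must share one dimension")
  }
  rng <- range(unlist(lapply(channels, function(ch)
    vapply(ch, range, numeric(2)))))
  if (rng[1] < 0 || rng[2] > 1) {
    stop("pixel values must lie in [0, 1] after normalization")
  }
  if (axis == "time" && frame_interval_s <= 0) {
    stop("frame_interval_s must be > 0 for a time axis")
  }
  structure(list(channels = channels, axis = axis,
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um,
                 bit_depth = as.integer(bit_depth)),
            class = "ChannelStack")
}

#' @export
print.ChannelStack <- function(x, ...) {
  d <- dim(x$channels[[1]][[1]])
  cat(sprintf("ChannelStack: %d channel(s) [%s] x %d frame(s), %dx%d px, axis=%s\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              n_frames(x), d[1], d[2], x$axis))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [channel_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$channels[[1]])

#' Extract one frame of one channel
#' @param stack A [channel_stack()].
#' @param channel Channel name.
#' @param frame Frame index (1-based).
#' @return A numeric matrix.
#' @export
get_frame <- function(stack, channel, frame) {
  if (!channel %in% names(stack$channels)) {
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(names(stack$channels), collapse = ", ")))
  }
  if (frame < 1L || frame > n_frames(stack)) {
    stop(sprintf("frame %d out of range 1..%d", frame, n_frames(stack)))
  }
  stack$channels[[channel]][[frame]]
}

#' Read a multi-page TIFF into a ChannelStack
#'
#' Pages are assumed channel-interleaved in acquisition order: page 1 is
#' frame 1 of `channel_names[1]`, page 2 frame 1 of `channel_names[2]`,
#' and so on. Channel order is taken from the caller, never guessed from
#' metadata. Intensities are normalized to `[0, 1]` by division by
#' `2^bit_depth - 1`.
#'
#' @param path Path to a multi-page TIFF/OME-TIFF.
#' @param channel_names Character vector naming the interleaved channels.
#' @inheritParams channel_stack
#' @return A [channel_stack()].
#' @export
read_stack <- function(path, channel_names, axis = "time",
                       frame_interval_s = 75, pixel_size_um = 1) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  k <- length(channel_names)
  if (length(pages) %% k != 0L) {
    stop(sprintf("page count %d not divisible by channel count %d",
                 length(pages), k))
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first sample if multi-sample
    attributes(p) <- list(dim = dim(p))      # drop TIFF tag attributes
    p
  })
  nf <- length(pages) %/% k
  channels <- stats::setNames(lapply(seq_len(k), function(ci) {
    lapply(seq_len(nf), function(fi) pages[[(fi - 1L) * k + ci]])
  }), channel_names)
  channel_stack(channels, axis = axis, frame_interval_s = frame_interval_s,
                pixel_size_um = pixel_size_um, bit_depth = as.integer(bits))
}

#' Write a ChannelStack to a multi-page TIFF
#'
#' Pages are written channel-interleaved, mirroring [read_stack()].
#' Intensities are quantized onto the stack's `bit_depth` grid, so a
#' round trip preserves values to within `1/(2^bit_depth - 1)`.
#'
#' @param stack A [channel_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  k <- length(stack$channels)
  nf <- n_frames(stack)
  bits <- if (stack$bit_depth > 8L) 16L else 8L
  pages <- vector("list", k * nf)
  for (fi in seq_len(nf)) for (ci in seq_len(k)) {
    pages[[(fi - 1L) * k + ci]] <- stack$channels[[ci]][[fi]]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Binary mask I/O
#'
#' Masks are stored as single-channel PNG (or TIFF) images with
#' foreground = 1. `read_mask(write_mask(m, path))` is bit-exact.
#'
#' @param mask A logical matrix.
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_mask` returns a logical matrix; `write_mask` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 8)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Correct translational drift against the first frame
#'
#' Integer-pixel translation registration: every frame of the reference
#' channel is aligned to frame 1 by maximizing the windowed
#' cross-correlation over integer shifts up to `max_shift` pixels; the
#' same offset is applied to every channel. Edge pixels exposed by a
#' shift are filled with 0. Sub-pixel and rotational motion are out of
#' scope; the intended use is removal of small stage/animal drift.
#'
#' @param stack A [channel_stack()].
#' @param reference_channel Channel used to estimate offsets.
#' @param max_shift Maximum absolute shift searched, in pixels.
#' @return A list with `stack` (registered) and `offsets`, an
#'   `n_frames x 2` matrix of applied `(drow, dcol)` shifts
#'   (frame 1 is `(0, 0)`).
#' @export
register_translation <- function(stack, reference_channel, max_shift = 20L) {
  ref <- stack$channels[[reference_channel]]
  if (is.null(ref)) stop(sprintf("reference channel '%s' not present",
                                 reference_channel))
  nf <- length(ref)
  offsets <- matrix(0L, nf, 2,
                    dimnames = list(NULL, c("drow", "dcol")))
  if (nf == 1L) return(list(stack = stack, offsets = offsets))
  f0 <- ref[[1]]
  if (stats::sd(f0) == 0) {
    stop("registration undefined: reference frame has zero variance")
  }
  for (fi in 2:nf) {
    offsets[fi, ] <- best_translation(f0, ref[[fi]], max_shift)
  }
  out <- stack
  for (ch in names(out$channels)) {
    for (fi in 2:nf) {
      out$channels[[ch]][[fi]] <-
        shift_frame(out$channels[[ch]][[fi]],
                    offsets[fi, 1], offsets[fi, 2])
    }
  }
  list(stack = out, offsets = offsets)
}

# offset (dr, dc) such that shift_frame(moving, dr, dc) best matches fixed;
# exhaustive search over the overlap cross-correlation
best_translation <- function(fixed, moving, max_shift) {
  best <- c(0L, 0L); best_v <- -Inf
  nr <- nrow(fixed); nc <- ncol(fixed)
  for (dr in -max_shift:max_shift) {
    r_f <- max(1, 1 + dr):min(nr, nr + dr)
    r_m <- max(1, 1 - dr):min(nr, nr - dr)
    for (dc in -max_shift:max_shift) {
      c_f <- max(1, 1 + dc):min(nc, nc + dc)
      c_m <- max(1, 1 - dc):min(nc, nc - dc)
      a <- fixed[r_f, c_f]; b <- moving[r_m, c_m]
      v <- sum(a * b) / length(a)
      if (v > best_v + 1e-15) { best_v <- v; best <- c(dr, dc) }
    }
  }
  best
}

# integer shift with zero fill; positive dr moves content down (towards
# larger row indices), positive dc towards larger column indices
shift_frame <- function(frame, dr, dc) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(0, nr, nc)
  r_src <- max(1, 1 - dr):min(nr, nr - dr)
  c_src <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(r_src) && length(c_src)) {
    out[r_src + dr, c_src + dc] <- frame[r_src, c_src]
  }
  out
}
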