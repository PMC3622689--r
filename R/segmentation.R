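#' Segmentation parameters
#'
#' The user-tunable knobs of the per-frame segmentation pipeline:
#' which frame to preview, the gamma of the intensity pre-adjustment,
#' the minimum object size kept, the disk radius of the speckle filter,
#' and the thresholding method with its parameters. In interactive use
#' these are tuned on one preview frame and then applied unchanged to
#' the whole movie.
#'
#' @param frame_index Frame used for previewing/tuning (1-based).
#' @param gamma Gamma pre-adjustment (see [gamma_adjust()]).
#' @param min_object_area Regions smaller than this many pixels are
#'   discarded as non-cells.
#' @param speckle_disk_radius Disk radius of the rough-pass speckle
#'   filter (0 disables it).
#' @param method Thresholding method, `"ray"`, `"otsu"` or `"huang"`.
#' @param ray [ray_params()] for the locally-adaptive method.
#' @param invert If `TRUE`, frames are intensity-inverted (`1 - x`)
#'   before thresholding (for stacks where structures are dark on a
#'   bright background).
#' @return An object of class `SegmentationParams`.
#' @export
segmentation_params <- function(frame_index = 1L, gamma = 1,
                                min_object_area = 40L,
                                speckle_disk_radius = 1L,
                                method = "ray", ray = ray_params(),
                                invert = FALSE) {
  stopifnot(min_object_area >= 0, speckle_disk_radius >= 0)
  structure(list(frame_index = as.integer(frame_index), gamma = gamma,
                 min_object_area = as.integer(min_object_area),
                 speckle_disk_radius = as.integer(speckle_disk_radius),
                 method = method, ray = ray, invert = isTRUE(invert)),
            class = "SegmentationParams")
}

# 8-connected component labeling; labels are consecutive positive
# integers ordered by each component's first pixel in column-major order
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  pos <- rep(NA_integer_, nr * nc)
  pos[idx] <- seq_along(idx)
  ii <- ((idx - 1L) %% nr) + 1L
  jj <- ((idx - 1L) %/% nr) + 1L
  ee <- vector("list", 4)
  dirs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (d in seq_along(dirs)) {
    i2 <- ii + dirs[[d]][1]; j2 <- jj + dirs[[d]][2]
    ok <- i2 >= 1L & i2 <= nr & j2 <= nc
    v2 <- pos[(j2[ok] - 1L) * nr + i2[ok]]
    v1 <- seq_along(idx)[ok]
    keep <- !is.na(v2)
    ee[[d]] <- cbind(v1[keep], v2[keep])
  }
  edges <- do.call(rbind, ee)
  g <- igraph::make_graph(t(edges), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  memb <- match(memb, unique(memb))
  lab[idx] <- memb
  lab
}

# border pixels of each region: member pixels 4-adjacent to a pixel
# outside the region (or to the image edge)
region_borders <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(-1L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  up    <- pad[1:nr, 2:(nc + 1)]
  down  <- pad[3:(nr + 2), 2:(nc + 1)]
  left  <- pad[2:(nr + 1), 1:nc]
  right <- pad[2:(nr + 1), 3:(nc + 2)]
  core > 0L & (up != core | down != core | left != core | right != core)
}

#' Label connected regions and measure them
#'
#' Connected components of a binary mask under 8-connectivity, with
#' per-region area, unweighted centroid, 4-adjacency border pixels, and
#' mean intensity per channel of the supplied stack frame.
#'
#' @param mask Logical matrix (foreground = cell).
#' @param stack Optional [channel_stack()] supplying intensity channels.
#' @param frame_index Frame of `stack` the mask belongs to.
#' @return An object of class `LabeledRegions`: `label_map` (integer
#'   matrix, 0 = background), `regions` (data frame with `id`,
#'   `area_px`, `centroid_row`, `centroid_col` and one `mean_<channel>`
#'   column per channel), and `borders` (list of two-column matrices of
#'   border pixel coordinates per region).
#' @export
label_regions <- function(mask, stack = NULL, frame_index = 1L) {
  stopifnot(is.matrix(mask))
  if (!is.null(stack)) {
    d <- dim(stack$channels[[1]][[1]])
    if (!identical(dim(mask), d)) {
      stop(sprintf("mask is %dx%d but stack frames are %dx%d",
                   nrow(mask), ncol(mask), d[1], d[2]))
    }
  }
  lab <- label_components8(mask)
  n <- max(lab)
  nr <- nrow(mask)
  chans <- if (is.null(stack)) character(0) else names(stack$channels)
  cols <- c("id", "area_px", "centroid_row", "centroid_col",
            if (length(chans)) paste0("mean_", chans))
  if (n == 0L) {
    regions <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    return(structure(list(label_map = lab, regions = regions,
                          borders = list()),
                     class = "LabeledRegions"))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  ii <- ((idx - 1L) %% nr) + 1L
  jj <- ((idx - 1L) %/% nr) + 1L
  area <- tabulate(l, n)
  cr <- as.numeric(tapply(ii, l, mean))
  cc <- as.numeric(tapply(jj, l, mean))
  regions <- data.frame(id = seq_len(n), area_px = area,
                        centroid_row = cr, centroid_col = cc)
  for (ch in chans) {
    fr <- stack$channels[[ch]][[frame_index]]
    regions[[paste0("mean_", ch)]] <- as.numeric(tapply(fr[idx], l, mean))
  }
  bmask <- region_borders(lab)
  bidx <- which(bmask)
  bl <- lab[bidx]
  bi <- ((bidx - 1L) %% nr) + 1L
  bj <- ((bidx - 1L) %/% nr) + 1L
  borders <- lapply(seq_len(n), function(k) {
    sel <- bl == k
    cbind(row = bi[sel], col = bj[sel])
  })
  structure(list(label_map = lab, regions = regions, borders = borders),
            class = "LabeledRegions")
}

#' @export
print.LabeledRegions <- function(x, ...) {
  cat(sprintf("LabeledRegions: %d region(s), %d foreground px\n",
              nrow(x$regions), sum(x$label_map > 0L)))
  invisible(x)
}

#' Remove regions smaller than a minimum area
#'
#' The user-defined high-pass filter that eliminates objects too small
#' to be cells. Surviving labels are renumbered consecutively,
#' preserving their original order.
#'
#' @param labeled A [label_regions()] result.
#' @param min_area Minimum region area in pixels.
#' @return A filtered `LabeledRegions`.
#' @export
size_filter <- function(labeled, min_area) {
  stopifnot(inherits(labeled, "LabeledRegions"), min_area >= 0)
  keep <- labeled$regions$area_px >= min_area
  old <- labeled$regions$id[keep]
  map <- integer(max(labeled$label_map, 1L))
  map[old] <- seq_along(old)
  lab <- labeled$label_map
  pos <- lab > 0L
  lab[pos] <- map[lab[pos]]
  regions <- labeled$regions[keep, , drop = FALSE]
  regions$id <- seq_len(nrow(regions))
  rownames(regions) <- NULL
  structure(list(label_map = lab, regions = regions,
                 borders = labeled$borders[keep]),
            class = "LabeledRegions")
}

#' Segment one frame
#'
#' The full per-frame pipeline: gamma adjustment, thresholding, speckle
#' (rough-pass) filtering, 8-connected labeling, and size filtering.
#' Deterministic for fixed parameters.
#'
#' @param stack A [channel_stack()].
#' @param params A [segmentation_params()] object.
#' @param channel Channel to segment (the nuclear marker).
#' @param frame_index Frame to segment; defaults to
#'   `params$frame_index`.
#' @return A `LabeledRegions` (see [label_regions()]).
#' @export
segment_frame <- function(stack, params = segmentation_params(),
                          channel, frame_index = params$frame_index) {
  fr <- get_frame(stack, channel, frame_index)
  if (params$invert) fr <- 1 - fr
  res <- threshold_frame(fr, method = params$method, gamma = params$gamma,
                         ray = params$ray)
  mask <- speckle_filter(res$mask, params$speckle_disk_radius)
  labeled <- label_regions(mask, stack, frame_index)
  size_filter(labeled, params$min_object_area)
}

#' Segment every frame/slice of a stack
#'
#' Applies [segment_frame()] independently to each frame (time axis) or
#' slice (Z axis) and additionally returns a border projection: a
#' matrix counting, per pixel, in how many slices that pixel is a
#' region border — the summed-outline view of a segmented Z-stack.
#' Slices on which thresholding is degenerate (e.g. empty) yield an
#' empty region list rather than an error.
#'
#' @inheritParams segment_frame
#' @return A list with `frames` (list of `LabeledRegions`) and
#'   `border_projection` (integer matrix).
#' @export
segment_stack <- function(stack, params = segmentation_params(), channel) {
  nf <- n_frames(stack)
  d <- dim(stack$channels[[1]][[1]])
  proj <- matrix(0L, d[1], d[2])
  frames <- vector("list", nf)
  for (fi in seq_len(nf)) {
    frames[[fi]] <- tryCatch(
      segment_frame(stack, params, channel, frame_index = fi),
      error = function(e) {
        if (grepl("degenerate input", conditionMessage(e))) {
          label_regions(matrix(FALSE, d[1], d[2]), stack, fi)
        } else {
          stop(sprintf("frame %d: %s", fi, conditionMessage(e)), call. = FALSE)
        }
      })
    if (nrow(frames[[fi]]$regions)) {
      b <- region_borders(frames[[fi]]$label_map)
      proj <- proj + b
    }
  }
  list(frames = frames, border_projection = proj)
}
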