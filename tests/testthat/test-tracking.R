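test_that("the assignment solver matches brute-force permutation search", {
  set.seed(60)
  for (n in 2:5) for (rep in 1:10) {
    cost <- matrix(runif(n * n), n, n)
    a <- ivpharm:::solve_lap(cost)
    expect_equal(sort(a), seq_len(n))             # a permutation
    expect_equal(sum(cost[cbind(seq_len(n), a)]), oracle_lap_cost(cost),
                 tolerance = 1e-12)
  }
  # with forbidden entries (a finite perfect matching still exists)
  for (rep in 1:10) {
    cost <- matrix(runif(16), 4, 4)
    cost[1, 2] <- Inf; cost[3, 4] <- Inf
    finite <- cost; finite[!is.finite(finite)] <- 1e9
    a <- ivpharm:::solve_lap(cost)
    expect_equal(sum(finite[cbind(1:4, a)]), oracle_lap_cost(finite),
                 tolerance = 1e-6)
  }
})

test_that("a single drifting cell forms one track; a long jump splits it", {
  det <- lapply(0:9, function(fi)
    data.frame(cell_id = 1L, row = 10 + 3 * fi, col = 20))
  tr <- link_tracks(det, max_radius = 10)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 10L)
  expect_equal(tr$frame, 1:10)

  jump <- list(data.frame(cell_id = 1L, row = 10, col = 10),
               data.frame(cell_id = 1L, row = 10, col = 22))   # 12 px
  tr2 <- link_tracks(jump, max_radius = 10)
  expect_equal(length(unique(tr2$track_id)), 2L)
  tr3 <- link_tracks(jump, max_radius = 13)
  expect_equal(length(unique(tr3$track_id)), 1L)
})

test_that("frame-to-frame linking equals exhaustive enumeration", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    prev <- cbind(runif(n, 0, 40), runif(n, 0, 40))
    curr <- cbind(runif(m, 0, 40), runif(m, 0, 40))
    got <- ivpharm:::match_frames(prev, curr, max_radius = 12)
    expect_equal(got, oracle_link(prev, curr, 12),
                 info = sprintf("rep %d", rep))
  }
})

test_that("tracks partition the detections", {
  set.seed(62)
  det <- lapply(1:8, function(fi) {
    n <- sample(0:6, 1)
    data.frame(cell_id = seq_len(n), row = runif(n, 0, 60),
               col = runif(n, 0, 60))
  })
  tr <- link_tracks(det, max_radius = 8)
  expect_equal(nrow(tr), sum(vapply(det, nrow, integer(1))))
  # no detection in two tracks; frames strictly consecutive per track
  expect_false(any(duplicated(tr[, c("frame", "cell_id")])))
  for (id in unique(tr$track_id)) {
    fr <- tr$frame[tr$track_id == id]
    expect_equal(fr, seq(min(fr), max(fr)))
    if (length(fr) > 1) {
      p <- tr[tr$track_id == id, ]
      step <- sqrt(diff(p$row)^2 + diff(p$col)^2)
      expect_true(all(step <= 8 + 1e-9))
    }
  }
})

test_that("track count is non-increasing as the search radius grows", {
  set.seed(63)
  det <- lapply(1:6, function(fi) {
    data.frame(cell_id = 1:4,
               row = c(10, 30, 50, 70) + rnorm(4, 0, 3),
               col = c(10, 30, 50, 70) + rnorm(4, 0, 3))
  })
  counts <- vapply(c(1, 3, 6, 10, 20), function(r)
    length(unique(link_tracks(det, r)$track_id)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("well-separated synthetic movies are tracked with exact identities", {
  spec <- scene_spec(n_cells = 12, min_gap_px = 25, cell_step_sd_px = 1.5,
                     n_frames = 15, seed = 64)
  mv <- generate_movie(spec)
  seg <- segment_stack(mv$stack, segmentation_params(), "nuclear")
  tr <- link_tracks(regions_to_detections(seg$frames), max_radius = 10)
  expect_equal(length(unique(tr$track_id)), 12L)
  # every track follows one ground-truth cell throughout
  for (id in unique(tr$track_id)) {
    p <- tr[tr$track_id == id, ]
    cells <- vapply(seq_len(nrow(p)), function(q) {
      tc <- mv$truth$paths[[p$frame[q]]]
      which.min((tc[, 1] - p$row[q])^2 + (tc[, 2] - p$col[q])^2)
    }, integer(1))
    expect_equal(length(unique(cells)), 1L)
    expect_equal(nrow(p), 15L)
  }
})

test_that("concentrations attach to tracks through (frame, cell) identity", {
  spec <- scene_spec(n_cells = 8, min_gap_px = 25, n_frames = 6, seed = 65)
  mv <- generate_movie(spec)
  cv <- calibration_curve(spec$calibration$slope, spec$calibration$intercept)
  seg <- segment_stack(mv$stack, segmentation_params(), "nuclear")
  ser <- cell_concentrations(seg$frames, mv$stack, "drug", cv)
  tr <- link_tracks(regions_to_detections(seg$frames), 10)
  tr <- attach_concentrations(tr, ser)
  expect_true(all(is.finite(tr$conc_uM)))
  # each track's curve equals the generating cell's truth within noise
  for (id in unique(tr$track_id)[1:3]) {
    p <- tr[tr$track_id == id, ]
    tc <- mv$truth$paths[[p$frame[1]]]
    ci <- which.min((tc[, 1] - p$row[1])^2 + (tc[, 2] - p$col[1])^2)
    truth <- mv$truth$conc[p$frame, ci]
    expect_lt(max(abs(p$conc_uM - truth)), 0.2)
  }
  bad <- tr[1, , drop = FALSE]
  bad$cell_id <- 999L
  expect_error(attach_concentrations(bad, ser), "no concentration record")
})

test_that("single-frame tracks carry a single-point curve", {
  st <- channel_stack(list(nuclear = list(matrix(0.5, 8, 8)),
                           drug = list(matrix(0.2, 8, 8))))
  m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
  lr <- label_regions(m, st, 1)
  ser <- cell_concentrations(list(lr), st, "drug", calibration_curve(10))
  tr <- link_tracks(regions_to_detections(list(lr)), 10)
  tr <- attach_concentrations(tr, ser)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$conc_uM, 2)
})

test_that("detection export round-trips and writes frame-major rows", {
  det <- list(data.frame(cell_id = 1:3, row = c(1, 2, 3) + 0.25,
                         col = c(4, 5, 6) + 0.5, amplitude = c(7, 8, 9)),
              data.frame(cell_id = 1:3, row = c(2, 3, 4), col = c(5, 6, 7),
                         amplitude = c(1, 2, 3)))
  path <- withr::local_tempfile(fileext = ".csv")
  export_detections(det, path)
  raw <- read.csv(path)
  expect_equal(nrow(raw), 6L)
  expect_equal(raw$frame, rep(1:2, each = 3))
  expect_equal(raw$x[1:3], det[[1]]$col)          # x = column convention
  expect_equal(raw$y[1:3], det[[1]]$row)
  back <- read_detections(path)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$row, det[[1]]$row)
  expect_equal(back[[2]]$col, det[[2]]$col)
  expect_equal(back[[1]]$amplitude, det[[1]]$amplitude)

  empty_path <- withr::local_tempfile(fileext = ".csv")
  export_detections(list(), empty_path)
  expect_equal(nrow(read.csv(empty_path)), 0L)
  expect_equal(readLines(empty_path)[1], "\"frame\",\"x\",\"y\",\"amplitude\"")
})
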