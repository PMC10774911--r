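test_that("a single moving bubble yields one track at the prescribed speed", {
  det <- tibble::tibble(frame = 1:20, depth_um = 2000,
                        lateral_um = 500 + (0:19) * (5000 / 48))
  tr <- build_tracks(det, tracker_config())
  expect_equal(length(unique(tr$track)), 1)
  sp <- track_speeds(tr, grid_spec())
  expect_equal(mean(sp$speed_um_s, na.rm = TRUE), 5000, tolerance = 0.01)
})

test_that("well-separated bubbles produce separate tracks, empty input none", {
  det <- dplyr::bind_rows(
    tibble::tibble(frame = 1:15, depth_um = 1000,
                   lateral_um = 500 + (0:14) * 100),
    tibble::tibble(frame = 1:15, depth_um = 4000,
                   lateral_um = 4000 - (0:14) * 100))
  tr <- build_tracks(det, tracker_config())
  expect_equal(length(unique(tr$track)), 2)
  expect_equal(nrow(build_tracks(tibble::tibble(
    frame = integer(), depth_um = numeric(), lateral_um = numeric()))), 0)
})

test_that("no detection is assigned to two tracks in the same frame", {
  set.seed(61)
  det <- dplyr::bind_rows(lapply(1:10, function(f)
    tibble::tibble(frame = f, depth_um = runif(5, 0, 4000),
                   lateral_um = runif(5, 0, 4000))))
  tr <- build_tracks(det, tracker_config(gate = 500, min_length = 1))
  dup <- tr |>
    dplyr::count(.data$frame, .data$depth_um, .data$lateral_um) |>
    dplyr::filter(.data$n > 1)
  expect_equal(nrow(dup), 0)
})

test_that("overlap correction interpolates linear crossings exactly", {
  da <- tibble::tibble(frame = 1:20, depth_um = 1000 + (0:19) * 50,
                       lateral_um = 2000)
  db <- tibble::tibble(frame = 1:20, depth_um = 1950 - (0:19) * 50,
                       lateral_um = 2000)
  merged <- dplyr::bind_rows(da[-10, ], db[-10, ],
                             tibble::tibble(frame = 10, depth_um = 1475,
                                            lateral_um = 2000))
  tr <- build_tracks(merged, tracker_config())
  trc <- correct_overlaps(tr, merged, tracker_config())
  at10 <- dplyr::arrange(trc[trc$frame == 10, ], .data$depth_um)
  expect_equal(nrow(at10), 2)
  expect_true(all(at10$interpolated))
  # cubic interpolation reproduces linear motion exactly
  expect_equal(at10$depth_um, c(1450, 1500), tolerance = 1e-9)
})

test_that("correction leaves scenes without overlap events untouched", {
  det <- dplyr::bind_rows(
    tibble::tibble(frame = 1:10, depth_um = 1000,
                   lateral_um = 500 + (0:9) * 100),
    tibble::tibble(frame = 1:10, depth_um = 4000, lateral_um = 4000))
  tr <- build_tracks(det, tracker_config())
  expect_identical(as.data.frame(correct_overlaps(tr, det,
                                                  tracker_config())),
                   as.data.frame(tr))
})

test_that("a track that is not re-acquired after an overlap is terminated", {
  # fast track A crosses slow track B; B's trace merges into A's detection
  # at frame 9 and B never re-appears
  da <- tibble::tibble(frame = 1:12, depth_um = 1000 + (0:11) * 50,
                       lateral_um = 2000)
  db <- tibble::tibble(frame = 1:8, depth_um = 1430 - (0:7) * 5,
                       lateral_um = 2000)
  merged <- dplyr::bind_rows(da, db)
  tr <- build_tracks(merged, tracker_config(gate = 60))
  trc <- correct_overlaps(tr, merged, tracker_config(gate = 60))
  ends <- trc |>
    dplyr::group_by(.data$track) |>
    dplyr::summarize(last = max(.data$frame), status = .data$status[1])
  expect_true(any(ends$status == "terminated"))
  expect_lte(min(ends$last), 8)
})
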