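test_that("parse/write round trip is the identity on simulated tracks", {
  field <- predict_field(standard_salt_schedule(), grid_spacing_mm = 2)
  tr <- simulate_chemotaxis_tracks(field, n_worms = 3, duration_s = 40,
                                   gap_prob = 0.05, seed = 6)
  attr(tr, "peak_mm") <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  back <- parse_tracks(path)
  expect_equal(back, tr)
})

test_that("unparseable coordinates become undetected frames", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,time_s,x_mm,y_mm",
               "w1,0,0,1.0,2.0",
               "w1,1,0.27,,",
               "w1,2,0.53,3.0,4.0"), path)
  tab <- parse_tracks(path)
  expect_equal(tab$detected, c(TRUE, FALSE, TRUE))
  expect_equal(tab$x_mm, c(1, NA, 3))
})

test_that("malformed track files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x_mm", "w1,0,1.0"), path)
  expect_error(parse_tracks(path), "y_mm")
  writeLines(c("track_id,frame,time_s,x_mm,y_mm",
               "w1,0,0,1,1", "w1,0,0,2,2"), path)
  expect_error(parse_tracks(path), "duplicate")
})

test_that("custom column maps read foreign tracker dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Worm,Frame,X,Y", "a,0,1,2", "a,1,2,3"), path)
  tab <- parse_tracks(path, columns = c(track_id = "Worm", frame = "Frame",
                                        x_mm = "X", y_mm = "Y"),
                      frame_rate = 2)
  expect_equal(tab$time_s, c(0, 0.5))
  expect_equal(tab$x_mm, c(1, 2))
})

test_that("carry-forward imputation reproduces the hand-walked example", {
  tr <- tibble::tibble(frame = c(0L, 3L), time_s = c(0, 3),
                       x_mm = c(0, 3), y_mm = c(0, 0), detected = TRUE)
  imp <- impute_carry_forward(tr, frames = 0:3, frame_rate = 1)
  expect_equal(imp$x_mm, c(0, 0, 0, 3))
  expect_equal(imp$y_mm, rep(0, 4))
  expect_equal(imp$imputed, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("imputation is idempotent, forward-only and terminal-carrying", {
  full <- tibble::tibble(frame = 0:4, time_s = 0:4, x_mm = 1:5,
                         y_mm = 5:1, detected = TRUE)
  expect_equal(impute_carry_forward(full, 0:4)$x_mm, full$x_mm)
  # frames before first detection are excluded, never back-filled
  late <- tibble::tibble(frame = c(2L, 3L), time_s = c(2, 3),
                         x_mm = c(9, 10), y_mm = 0, detected = TRUE)
  imp <- impute_carry_forward(late, frames = 0:5, frame_rate = 1)
  expect_equal(imp$frame, 2:5)
  expect_equal(imp$x_mm, c(9, 10, 10, 10))  # terminal gap carried to end
  # imputed positions only re-use observed points
  expect_true(all(imp$x_mm %in% late$x_mm))
  none <- tibble::tibble(frame = 0:2, time_s = 0:2, x_mm = NA_real_,
                         y_mm = NA_real_, detected = FALSE)
  expect_warning(out <- impute_carry_forward(none, 0:2), "no detected")
  expect_equal(nrow(out), 0)
})

test_that("worm_outcome handles stationary and windowed cases", {
  geom <- assay_geometry()
  still <- stationary_track(12.5 + 7, 0, n_frames = 1575)
  expect_equal(worm_outcome(still, geom)$mean_distance_mm, 7)
  at_peak <- stationary_track(12.5, 0, n_frames = 1575)
  expect_equal(worm_outcome(at_peak, geom)$mean_distance_mm, 0)
  # three-frame window with distances 4, 6, 8 -> mean 6
  geom3 <- assay_geometry(peak_mm = c(0, 0), duration_s = 4,
                          frame_rate = 1, window_s = 3)
  tr <- tibble::tibble(frame = 0:3, time_s = 0:3,
                       x_mm = c(1, 4, 6, 8), y_mm = 0, detected = TRUE)
  expect_equal(worm_outcome(tr, geom3)$mean_distance_mm, 6)
  expect_equal(worm_outcome(tr, geom3)$n_frames_in_window, 3L)
})

test_that("the final-minute window covers 225 frames at 3.75 fps", {
  geom <- assay_geometry()
  tr <- stationary_track(5, 5, n_frames = 1575)
  out <- worm_outcome(tr, geom)
  expect_equal(out$n_frames_in_window, 225L)
})

test_that("a worm lost before the window contributes via carry-forward", {
  geom <- assay_geometry()
  early <- tibble::tibble(frame = 0:99, time_s = (0:99) / 3.75,
                          x_mm = 2.5, y_mm = 0, detected = TRUE)
  out <- worm_outcome(early, geom)
  expect_equal(out$mean_distance_mm, 10)
  expect_equal(out$n_imputed_frames, 225L)
})

test_that("worm_outcome matches the brute-force oracle on random tables", {
  set.seed(101)
  geom <- assay_geometry(peak_mm = c(5, -3), duration_s = 50,
                         frame_rate = 1, window_s = 20)
  for (rep in 1:8) {
    tab <- random_track_table(n_tracks = sample(1:10, 1), n_frames = 50)
    for (id in unique(tab$track_id)) {
      track <- tab[tab$track_id == id, ]
      got <- suppressWarnings(worm_outcome(track, geom))
      want <- oracle_worm_outcome(track, geom)
      if (is.na(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(got$mean_distance_mm, want)
      }
    }
  }
})

test_that("outcomes are invariant to translation and rotation about the peak", {
  set.seed(7)
  geom <- assay_geometry(peak_mm = c(12.5, 0), duration_s = 50,
                         frame_rate = 1, window_s = 20)
  tab <- random_track_table(1, 50)
  base <- suppressWarnings(worm_outcome(tab, geom))$mean_distance_mm
  shift <- c(3.2, -1.7)
  tab_shift <- dplyr::mutate(tab, x_mm = x_mm + shift[1],
                             y_mm = y_mm + shift[2])
  geom_shift <- assay_geometry(peak_mm = c(12.5, 0) + shift,
                               duration_s = 50, frame_rate = 1,
                               window_s = 20)
  expect_equal(
    suppressWarnings(worm_outcome(tab_shift, geom_shift))$mean_distance_mm,
    base)
  th <- 0.83
  rot <- function(x, y, cx, cy) {
    list(x = cx + cos(th) * (x - cx) - sin(th) * (y - cy),
         y = cy + sin(th) * (x - cx) + cos(th) * (y - cy))
  }
  p <- rot(tab$x_mm, tab$y_mm, 12.5, 0)
  tab_rot <- dplyr::mutate(tab, x_mm = p$x, y_mm = p$y)
  expect_equal(
    suppressWarnings(worm_outcome(tab_rot, geom))$mean_distance_mm, base)
})

test_that("plate_summary aggregates worms equally and counts exclusions", {
  geom <- assay_geometry()
  two <- rbind(stationary_track(12.5 + 4, 0, 1575, id = "a"),
               stationary_track(12.5 - 8, 0, 1575, id = "b"))
  ps <- plate_summary(two, geom)
  expect_equal(ps$plate$mean_distance_mm, 6)
  expect_equal(ps$plate$n_worms, 2L)
  ghost <- tibble::tibble(track_id = "ghost", frame = 0:10,
                          time_s = (0:10) / 3.75, x_mm = NA_real_,
                          y_mm = NA_real_, detected = FALSE)
  ps2 <- plate_summary(rbind(two, ghost), geom)
  expect_equal(ps2$plate$n_worms, 2L)
  expect_equal(ps2$plate$n_excluded, 1L)
  expect_warning(empty <- plate_summary(two[0, ], geom), "empty")
  expect_equal(empty$plate$n_worms, 0L)
})
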