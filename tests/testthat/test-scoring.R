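# The constructed traces below are built directly from geometry (not via the
# synthetic module) so the scorers and generator are exercised independently.

lay18 <- item_layout_18()
ctr <- lay18$center

test_that("item 18 walks its decision tree over constructed traces", {
  # clean single-stroke circle just outside the CD edge -> 3
  clean <- make_recording(18, lay18, circle_points(ctr, 6.3, n = 360))
  s <- score_item18(clean)
  expect_equal(s$score, 3)
  expect_true(check_item18_score3(clean))
  # evidence consistency: the stored measures satisfy every score-3 clause
  p <- s$params
  expect_gte(abs(s$evidence$net_sweep_deg), p$theta_complete_deg)
  expect_gte(s$evidence$min_radius_cm, lay18$r_large - p$eps_in_cm)
  expect_lte(s$evidence$max_radius_cm, lay18$r_large + p$band_out_cm)
  expect_equal(s$evidence$n_pauses, 0L)

  # same circle with a 1.2 s stationary pause inserted -> 2
  xy <- circle_points(ctr, 6.3, n = 360)
  pause <- xy[rep(180, 60), ]
  xy2 <- rbind(xy[1:180, ], pause, xy[181:360, ])
  paused <- make_recording(18, lay18, xy2)
  s2 <- score_item18(paused)
  expect_equal(s2$score, 2)
  expect_false(check_item18_score3(paused))
  expect_gte(s2$evidence$n_pauses, 1)

  # trace that dips into the disc but still circles in the annulus -> 2
  r <- rep(6.3, 360); r[100:110] <- 4.0
  a <- (90 + seq(0, 360, length.out = 360)) * pi / 180
  dip <- make_recording(18, lay18, cbind(ctr[1] + r * cos(a), ctr[2] + r * sin(a)))
  expect_equal(score_item18(dip)$score, 2)

  # circumnavigation split over two strokes -> 2, not 3
  half1 <- circle_points(ctr, 6.3, n = 180, sweep_deg = 185)
  half2 <- circle_points(ctr, 6.3, n = 180, sweep_deg = 185, start_deg = 270)
  two <- rbind(
    data.frame(time_ms = seq(0, by = 20, length.out = 180), pointer_id = 0L,
               phase = c("down", rep("move", 178), "up"),
               x = half1[, 1], y = half1[, 2]),
    data.frame(time_ms = seq(4000, by = 20, length.out = 180), pointer_id = 0L,
               phase = c("down", rep("move", 178), "up"),
               x = half2[, 1], y = half2[, 2]))
  rec2s <- trace_recording(18, two, lay18, cm_calibration())
  expect_equal(score_item18(rec2s)$score, 2)

  # small-circle circumnavigation -> 1
  small <- make_recording(18, lay18, circle_points(ctr, 1.7, n = 200))
  s1 <- score_item18(small)
  expect_equal(s1$score, 1)
  expect_lte(s1$evidence$median_radius_cm, lay18$r_small + p$band_small_cm)

  # empty recording -> 0
  empty <- trace_recording(18, data.frame(time_ms = integer(0),
                                          pointer_id = integer(0),
                                          phase = character(0),
                                          x = numeric(0), y = numeric(0)),
                           lay18, cm_calibration())
  expect_equal(score_item18(empty)$score, 0)
  # short scribble near the centre -> 0
  scrib <- make_recording(18, lay18, cbind(ctr[1] + c(0, 0.1, 0.2), ctr[2]))
  expect_equal(score_item18(scrib)$score, 0)
})

test_that("item 18 tie-break: a sample exactly at r_large - eps does not enter", {
  p <- scoring_params()
  r_edge <- lay18$r_large - p$eps_in_cm
  xy <- circle_points(ctr, 6.3, n = 360)
  # one sample exactly on the tolerance boundary
  xy[50, ] <- c(ctr[1] + r_edge * cos(pi), ctr[2] + r_edge * sin(pi))
  rec <- make_recording(18, lay18, xy)
  expect_equal(score_item18(rec)$score, 3)
})

lay19 <- item_layout_19()

sinusoid19 <- function(n_periods, x_from, x_to, n = 400, amp_inset = 0.05) {
  amp <- lay19$height / 2 - amp_inset
  u <- seq(0, 1, length.out = n)
  cbind(x_from + (x_to - x_from) * u,
        lay19$origin[2] + lay19$height / 2 + amp * sin(2 * pi * n_periods * u - pi / 2))
}

test_that("item 19 counts loops as band alternations and walks its tree", {
  x0 <- lay19$origin[1]; x1 <- x0 + lay19$width
  # 5 full periods across the frame, single stroke, no pauses -> 3
  full <- make_recording(19, lay19, sinusoid19(5, x0 + 0.05, x1 - 0.05),
                         input_kind = "stylus")
  s3 <- score_item19(full)
  expect_equal(s3$score, 3)
  expect_equal(s3$evidence$n_loops, count_loops_oracle(full))
  expect_gte(s3$evidence$n_loops, 3)
  expect_false(s3$evidence$exited_frame)

  # two loops then the stroke exits the frame -> 2
  part <- sinusoid19(2.5, x0 + 0.05, x0 + 2, n = 200)
  exit <- cbind(part[200, 1] + seq(0.02, 0.4, length.out = 20),
                seq(part[200, 2], lay19$origin[2] + lay19$height + 1,
                    length.out = 20))
  two <- make_recording(19, lay19, rbind(part, exit), input_kind = "stylus")
  s2 <- score_item19(two)
  expect_equal(s2$score, 2)
  expect_equal(s2$evidence$n_loops, count_loops_oracle(two))
  expect_true(s2$evidence$exited_frame)

  # short flat mark inside the frame: ink but zero alternations -> 1
  mark <- make_recording(19, lay19,
                         cbind(seq(x0 + 1, x0 + 2, length.out = 30),
                               lay19$origin[2] + lay19$height / 2),
                         input_kind = "stylus")
  s1 <- score_item19(mark)
  expect_equal(s1$score, 1)
  expect_equal(s1$evidence$n_loops, 0L)
  expect_equal(count_loops_oracle(mark), 0)

  # no contact -> 0
  empty <- trace_recording(19, data.frame(time_ms = integer(0),
                                          pointer_id = integer(0),
                                          phase = character(0),
                                          x = numeric(0), y = numeric(0)),
                           lay19, cm_calibration(), input_kind = "stylus")
  expect_equal(score_item19(empty)$score, 0)

  # a full series interrupted by a pause is demoted to 2
  xy <- sinusoid19(5, x0 + 0.05, x1 - 0.05)
  still <- xy[rep(200, 40), ]
  pause_rec <- make_recording(19, lay19, rbind(xy[1:200, ], still, xy[201:400, ]),
                              input_kind = "stylus")
  expect_equal(score_item19(pause_rec)$score, 2)

  # finger instead of stylus: warned, still scored
  finger <- suppressWarnings(make_recording(19, lay19,
                                            sinusoid19(5, x0 + 0.05, x1 - 0.05),
                                            input_kind = "finger"))
  expect_warning(sf <- score_item19(finger), "stylus")
  expect_equal(sf$score, 3)
})

lay22 <- item_layout_22()

tap_samples <- function(at, t0, pointer = 0L) {
  data.frame(time_ms = t0 + c(0, 50, 100, 150), pointer_id = pointer,
             phase = c("down", "move", "move", "up"),
             x = at[1] + c(0, 0.005, -0.005, 0), y = at[2] + c(0, 0.005, 0, 0))
}

test_that("item 22 classifies taps, slides and target hits", {
  ctr22 <- lay22$center
  tc <- function(k) c(lay22$targets[[k]]$x, lay22$targets[[k]]$y)
  # centre tap + 8 precise taps -> 3
  rows <- tap_samples(ctr22, 0)
  for (k in 1:8) rows <- rbind(rows, tap_samples(tc(k), 500 * k))
  full <- trace_recording(22, rows, lay22, cm_calibration())
  s3 <- score_item22(full)
  expect_equal(s3$score, 3)
  expect_equal(s3$evidence$n_targets_precise, 8)
  expect_true(s3$evidence$lifted)

  # one tap straddles a target boundary -> 2
  rows2 <- tap_samples(ctr22, 0)
  for (k in 1:8) {
    at <- if (k == 4) tc(4) + c(lay22$targets[[4]]$r, 0) else tc(k)
    rows2 <- rbind(rows2, tap_samples(at, 500 * k))
  }
  imp <- trace_recording(22, rows2, lay22, cm_calibration())
  s2 <- score_item22(imp)
  expect_equal(s2$score, 2)
  expect_equal(s2$evidence$n_targets_precise, 7)
  expect_equal(s2$evidence$n_targets_imprecise, 1)

  # hitting fewer than 8 targets precisely is still 2
  rows7 <- tap_samples(ctr22, 0)
  for (k in 1:7) rows7 <- rbind(rows7, tap_samples(tc(k), 500 * k))
  expect_equal(score_item22(trace_recording(22, rows7, lay22, cm_calibration()))$score, 2)

  # single continuous drag through three targets, never lifting -> 1
  way <- rbind(ctr22, tc(1), tc(2), tc(3))
  n <- 120
  u <- seq(0, 1, length.out = n)
  cum <- c(0, cumsum(sqrt(rowSums(diff(way)^2))))
  cum <- cum / max(cum)
  drag <- cbind(stats::approx(cum, way[, 1], xout = u)$y,
                stats::approx(cum, way[, 2], xout = u)$y)
  slide <- make_recording(22, lay22, drag, times_ms = seq(0, by = 25, length.out = n))
  s1 <- score_item22(slide)
  expect_equal(s1$score, 1)
  expect_false(s1$evidence$lifted)
  expect_gte(s1$evidence$n_targets_slid, 3)

  # nothing meaningful -> 0
  lone <- trace_recording(22, tap_samples(ctr22 + c(0, 2.5), 0), lay22,
                          cm_calibration())
  expect_warning(s0 <- score_item22(lone), "start zone")
  expect_equal(s0$score, 0)
  empty <- trace_recording(22, tap_samples(ctr22, 0)[0, ], lay22, cm_calibration())
  expect_equal(score_item22(empty)$score, 0)
})

test_that("scoring is deterministic and rejects mismatched items", {
  rec <- make_recording(18, lay18, circle_points(ctr, 6.3, n = 100))
  a <- score_item18(rec)
  b <- score_item18(rec)
  expect_identical(a$score, b$score)
  expect_identical(a$evidence, b$evidence)
  expect_error(score_item19(rec), class = "mfm_validation_error")
  expect_error(score_item22(rec), class = "mfm_validation_error")
  expect_equal(score_recording(rec)$score, a$score)
})

test_that("adding a pause to a clean circumnavigation never scores above 2", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(200:400, 1)
    xy <- circle_points(ctr, runif(1, 6.1, 6.6), n = n)
    clean <- make_recording(18, lay18, xy)
    stopifnot(score_item18(clean)$score == 3)
    cut <- sample(50:(n - 50), 1)
    xy2 <- rbind(xy[1:cut, ], xy[rep(cut, 40), ], xy[(cut + 1):n, ])
    expect_lte(score_item18(make_recording(18, lay18, xy2))$score, 2)
  }
})

test_that("score tables collect evidence columns across items", {
  recs <- list(
    a = make_recording(18, lay18, circle_points(ctr, 6.3, n = 120)),
    b = make_recording(19, lay19, sinusoid19(5, lay19$origin[1] + 0.05,
                                             lay19$origin[1] + lay19$width - 0.05),
                       input_kind = "stylus"))
  tab <- score_recordings(recs)
  expect_equal(tab$recording_id, c("a", "b"))
  expect_equal(tab$score, c(3, 3))
  expect_true(is.na(tab$ink_cm[1]) && !is.na(tab$ink_cm[2]))
  expect_true(!is.na(tab$net_sweep_deg[1]) && is.na(tab$net_sweep_deg[2]))
})
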