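test_that("blink detection reports maximal invalid runs", {
  tr <- const_trace(500)
  expect_equal(nrow(detect_blinks(tr)), 0)

  tr1 <- with_gap(tr, 200, 50)  # 50 samples at 250 Hz = 200 ms
  b <- detect_blinks(tr1)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_ms, 200)
  expect_equal(b$start_idx, 200)
  expect_equal(b$end_idx, 249)

  tr2 <- with_gap(with_gap(tr, 100, 10), 300, 20)
  b2 <- detect_blinks(tr2)
  expect_equal(nrow(b2), 2)
  expect_true(all(diff(b2$start_ms) > 0))
})

test_that("blink interpolation bridges gaps with median anchors", {
  tr <- with_gap(const_trace(500), 200, 30)
  b <- detect_blinks(tr)
  fixed <- interpolate_blink(tr, b[1, ])
  expect_equal(fixed$pupil, rep(1000, 500))
  expect_true(all(fixed$valid))

  # ramp between differing medians
  tr2 <- const_trace(500, pupil = 900)
  tr2$pupil[231:500] <- 1000
  tr2 <- with_gap(tr2, 226, 5)
  fixed2 <- interpolate_blink(tr2, detect_blinks(tr2)[1, ])
  expect_equal(fixed2$pupil[226:230], 900 + 100 * (1:5) / 6)
  expect_equal(fixed2$pupil[1:225], rep(900, 225))   # untouched outside gap
  expect_equal(fixed2$pupil[231:500], rep(1000, 270))

  # median anchors shrug off an outlier spike that shifts a mean anchor
  tr3 <- with_gap(const_trace(500), 200, 30)
  tr3$pupil[190] <- 5000
  fixed3 <- interpolate_blink(tr3, detect_blinks(tr3)[1, ])
  expect_equal(fixed3$pupil[200:229], rep(1000, 30))
  mean_anchor <- mean(tr3$pupil[175:199])
  expect_gt(mean_anchor, 1000)  # the mean-anchored alternative would ramp

  # not enough context
  tr4 <- with_gap(const_trace(100), 10, 20)
  expect_error(interpolate_blink(tr4, detect_blinks(tr4)[1, ]), "un-repairable")
})

test_that("trial screening applies the click and blink-duration rules", {
  keep <- function(trial, trace) screen_trial(trial, trace)
  tr <- const_trace(1000)

  s <- keep(correct_trial(), with_gap(tr, 400, 30))  # 120-ms blink
  expect_true(s$keep)
  expect_equal(s$trace$pupil, rep(1000, 1000))        # interpolated

  expect_false(keep(correct_trial(), with_gap(tr, 400, 100))$keep)  # 400 ms
  expect_equal(keep(correct_trial(), with_gap(tr, 400, 100))$reason, "long_blink")
  expect_false(keep(wrong_trial(), tr)$keep)
  expect_equal(keep(wrong_trial(), tr)$reason, "wrong_click")

  # boundary behavior: 296 ms repaired, 300 ms excluded, 304 ms excluded
  expect_true(keep(correct_trial(), with_gap(tr, 400, 74))$keep)
  expect_false(keep(correct_trial(), with_gap(tr, 400, 75))$keep)
  expect_false(keep(correct_trial(), with_gap(tr, 400, 76))$keep)

  # repairable duration but no valid context -> unrepairable
  s4 <- keep(correct_trial(), with_gap(tr, 5, 30))
  expect_false(s4$keep)
  expect_equal(s4$reason, "unrepairable")
})

test_that("participant screening applies the 50% rule", {
  expect_true(screen_participant(rep(TRUE, 62)))
  expect_false(screen_participant(c(rep(FALSE, 31), rep(TRUE, 31))))
  expect_true(screen_participant(c(rep(FALSE, 30), rep(TRUE, 32))))
})

test_that("baselines average the correct windows", {
  tr <- const_trace(1000, pupil = 800)
  expect_equal(compute_baseline(tr, 2000, kind = 1), 800)
  expect_equal(compute_baseline(tr, 400, kind = 2), 800)

  # linear ramp: the mean over [onset-200, onset) is the window midpoint value
  tr2 <- const_trace(1000)
  tr2$pupil <- 500 + 0.5 * tr2$t_ms
  onset <- 2000
  got <- compute_baseline(tr2, onset, kind = 1)
  sel <- tr2$t_ms >= onset - 200 & tr2$t_ms < onset
  expect_equal(sum(sel), 50)  # 200 ms at 250 Hz
  expect_equal(got, mean(500 + 0.5 * tr2$t_ms[sel]))

  expect_error(compute_baseline(with_gap(tr, 460, 20), 2000, kind = 1), "gap")
  expect_error(compute_baseline(tr, -100, kind = 1), "window")
})

test_that("the %ERPD formula is exact and scale invariant", {
  expect_equal(erpd(1000, 1000), 0)
  expect_equal(erpd(1100, 1000), 10)
  expect_equal(erpd(900, 1000), -10)
  set.seed(21)
  o <- runif(50, 500, 1500); b <- runif(50, 500, 1500); c <- runif(50, 0.1, 10)
  expect_equal(erpd(c * o, c * b), erpd(o, b))
  expect_error(erpd(1000, 0), "positive")
})

test_that("epoching yields the 450-sample relative-time window", {
  tr <- const_trace(2000)
  ep <- epoch_trace(tr, 3000)
  expect_equal(nrow(ep), 450)
  expect_equal(ep$time_ms[1], 200)
  expect_true(all(diff(ep$time_ms) == 4))
  expect_lt(max(ep$time_ms), 2000)
  expect_error(epoch_trace(const_trace(100), 300), "truncated")
})

test_that("fixation counting respects the minimum duration", {
  expect_equal(count_fixations(rep("target", 450)), 1)
  expect_equal(count_fixations(rep(c("target", "competitor"), 225)), 0)
  labs <- c(rep("target", 75), rep("competitor", 75), rep("none", 225),
            rep("target", 75))
  expect_equal(count_fixations(labs), 3)  # three 300-ms dwells, none ignored
  expect_equal(count_fixations(character(0)), 0L)
})

test_that("sample and trial TSV dialects round-trip", {
  tr <- with_gap(const_trace(300), 100, 10)
  p <- tempfile(fileext = ".tsv")
  write_ocular_tsv(tr, p)
  back <- read_ocular_tsv(p)
  expect_equal(back$pupil, tr$pupil)
  expect_equal(back$valid, tr$valid)
  expect_equal(back$t_ms, tr$t_ms)

  trials <- tibble::tibble(trial_id = "t01", condition = "target_matching",
                           presentation = "NS", sentence_onset_ms = 500,
                           word_onset_ms = 1300, clicked_role = "target",
                           correct = TRUE)
  p2 <- tempfile(fileext = ".tsv")
  write_trials_tsv(trials, p2)
  expect_equal(read_trials_tsv(p2)$word_onset_ms, 1300)
  unlink(c(p, p2))
})
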