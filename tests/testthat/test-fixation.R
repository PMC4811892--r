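test_that("AOI assignment partitions the screen grid", {
  lay <- aoi_layout()
  cent <- aoi_centroid(lay, c("target", "competitor", "distractor_a",
                              "distractor_b", "center"))
  expect_equal(assign_aoi(cent[, 1], cent[, 2], lay),
               c("target", "competitor", "distractor_a", "distractor_b", "center"))
  expect_equal(assign_aoi(512, 384, lay), "center")
  expect_equal(assign_aoi(-5, -5, lay), "none")
  expect_equal(assign_aoi(512, 10, lay), "none")  # top edge cell: no picture

  set.seed(8)
  x <- runif(500, -100, 1200); y <- runif(500, -100, 900)
  labs <- assign_aoi(x, y, lay)
  expect_length(labs, 500)
  expect_true(all(labs %in% c("target", "competitor", "distractor_a",
                              "distractor_b", "center", "none")))
  # manual quadrant check for the corner cells
  manual <- ifelse(x >= 0 & x < 1024 / 3 & y >= 0 & y < 768 / 3, "target",
            ifelse(x >= 2 * 1024 / 3 & x < 1024 & y >= 0 & y < 768 / 3,
                   "competitor", NA))
  chk <- !is.na(manual)
  expect_equal(labs[chk], manual[chk])

  expect_error(aoi_layout(role_map = c(target = "tl", competitor = "tl",
                                       distractor_a = "bl", distractor_b = "br")),
               "corners")
})

test_that("proportion curves aggregate trials with participant-level CIs", {
  base <- tidyr::crossing(participant = c("p1", "p2"),
                          trial_id = c("t1", "t2"),
                          time_ms = c(200, 204),
                          condition = "target_matching")
  all_target <- dplyr::mutate(base, aoi = "target")
  pc <- proportion_curves(all_target, group = "condition")
  tg <- pc[pc$role == "target", ]
  expect_true(all(tg$prop == 1))
  expect_true(all(tg$ci_high - tg$ci_low == 0))
  expect_true(all(pc$prop[pc$role == "competitor"] == 0))

  half <- dplyr::mutate(base, aoi = ifelse(trial_id == "t1", "target", "competitor"))
  pch <- proportion_curves(half, group = "condition")
  expect_true(all(pch$prop[pch$role %in% c("target", "competitor")] == 0.5))

  # proportions over the four roles can never exceed one
  sums <- stats::aggregate(prop ~ time_ms, data = pch, FUN = sum)
  expect_true(all(sums$prop <= 1 + 1e-12))

  # relabeling the two distractors leaves target/competitor curves unchanged
  swapped <- dplyr::mutate(half, aoi = dplyr::recode(aoi,
    distractor_a = "distractor_b", distractor_b = "distractor_a"))
  pcs <- proportion_curves(swapped, group = "condition")
  expect_equal(pcs[pcs$role == "target", ], pch[pch$role == "target", ])
})

test_that("proportion curves recover a known generating curve within the CI", {
  set.seed(31)
  times <- seq(200, 1996, 16)
  p_true <- 0.1 + 0.7 * stats::plogis((times - 900) / 150)
  rows <- list()
  for (pp in 1:12) {
    for (tr in 1:30) {
      hit <- stats::rbinom(length(times), 1, p_true)
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant = sprintf("p%02d", pp), trial_id = sprintf("p%02d_t%02d", pp, tr),
        time_ms = times, aoi = ifelse(hit == 1, "target", "none"),
        condition = "c1")
    }
  }
  pc <- proportion_curves(dplyr::bind_rows(rows), group = "condition")
  tg <- pc[pc$role == "target", ]
  covered <- mean(p_true >= tg$ci_low & p_true <= tg$ci_high)
  expect_gte(covered, 0.9)
  expect_lt(max(abs(tg$prop - p_true)), 0.08)
})

test_that("crossover detection matches a brute-force oracle", {
  times <- seq(0, 2000, 4)
  tgt <- stats::plogis((times - 800) / 100)
  cmp <- 1 - stats::plogis((times - 800) / 100)
  got <- crossover_time(times, tgt, cmp, persistence_ms = 100)
  expect_lte(abs(got - 800), 4)

  expect_true(is.na(crossover_time(times, tgt, tgt)))
  expect_equal(crossover_time(times, tgt + 2, cmp), times[1])

  brute <- function(time, a, b, persist) {
    step <- stats::median(diff(time)); k <- max(1, ceiling(persist / step))
    for (i in seq_along(time)) {
      win <- i:min(length(time), i + k - 1)
      if (all(a[win] > b[win])) return(time[i])
    }
    NA_real_
  }
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(20:80, 1)
    tm <- seq(0, by = 4, length.out = n)
    a <- cumsum(rnorm(n)); b <- cumsum(rnorm(n))
    for (persist in c(8, 40, 100))
      expect_identical(crossover_time(tm, a, b, persist), brute(tm, a, b, persist))
  }
})

test_that("the display smoother preserves lines and reduces noise", {
  times <- seq(200, 2000, 8)
  expect_equal(smooth_curve(times, rep(0.4, length(times))), rep(0.4, length(times)))
  lin <- 0.1 + 0.0002 * times
  expect_equal(smooth_curve(times, lin), lin, tolerance = 1e-6)

  set.seed(5)
  clean <- 0.5 + 0.3 * sin(times / 300)
  noisy <- clean + rnorm(length(times), sd = 0.08)
  sm <- smooth_curve(times, noisy, span = 0.3)
  expect_lt(mean((sm - clean)^2), mean((noisy - clean)^2))
  expect_error(smooth_curve(times, lin, span = 0), "span")
})
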