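#' Session configuration for the synthetic-data generator
#'
#' Encodes the study conditions a generated session emulates: 62 trials of
#' which 26 are critical, 250-Hz ocular sampling, 95% correct clicks, slow
#' AR(1) pupil noise, Poisson blinks with log-normal durations straddling
#' the 300-ms repair threshold, and a fixation dwell process tuned to about
#' three fixations per 200-2000 ms analysis window.
#'
#' @param n_trials Trials per session (default 62).
#' @param n_critical Critical trials (default 26; must be <= n_trials and
#'   even, split half target-matching / half target-mismatching).
#' @param presentation `"NS"` (natural) or `"DS"` (vocoder-degraded).
#' @param rate Sampling rate in Hz (default 250).
#' @param seed Integer seed; the whole session is deterministic given it.
#' @param noise_sd Pupil noise SD in device units (default 6, about 0.6% of
#'   the default baseline).
#' @param ar_rho AR(1) coefficient of the pupil noise at 250 Hz (default
#'   0.97, slow physiological drift).
#' @param blink_rate Mean blinks per trial (Poisson; default 0.3).
#' @param blink_meanlog,blink_sdlog Log-normal blink-duration parameters in
#'   ms (defaults log(150) and 0.5, putting roughly 8% of blinks at or
#'   beyond 300 ms).
#' @param dwell_mean_ms,dwell_shape Gamma fixation-dwell parameters
#'   (defaults 1500 ms, shape 4).
#' @param pupil_base,pupil_base_sd Participant baseline pupil area and its
#'   between-participant SD in device units (defaults 1000, 80).
#' @param accuracy Probability of clicking the target (default 0.95).
#' @param n_filler_pool Size of the filler inventory fillers are sampled
#'   from (default 40; the session uses n_trials - n_critical of them).
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_trials = 62L, n_critical = 26L,
                           presentation = c("NS", "DS"), rate = 250,
                           seed = 1L, noise_sd = 6, ar_rho = 0.97,
                           blink_rate = 0.3, blink_meanlog = log(150),
                           blink_sdlog = 0.5, dwell_mean_ms = 1500,
                           dwell_shape = 4, pupil_base = 1000,
                           pupil_base_sd = 80, accuracy = 0.95,
                           n_filler_pool = 40L) {
  presentation <- match.arg(presentation)
  if (n_critical > n_trials) stop("n_critical must be <= n_trials", call. = FALSE)
  if (n_critical %% 2L != 0L) stop("n_critical must be even (balanced conditions)", call. = FALSE)
  structure(as.list(environment()), class = "session_config")
}

# fixed trial timing (ms, multiples of the 4-ms sample period):
# cross 500, sentence onset at +500, word onset at +1300, analysis to +3300,
# trial span 3600
.trial_timing <- list(cross_ms = 500, word_lag_ms = 800, post_ms = 2300, span_ms = 3600)

#' Ground truth driving a synthetic session
#'
#' Per condition, the generator's truth consists of (i) activation curves
#' over time for target, competitor, distractors and the central cross,
#' whose normalization gives the AOI occupancy probabilities the gaze
#' process is sampled from, and (ii) a %ERPD template (relative to the
#' session-start baseline) the pupil trace encodes multiplicatively.
#'
#' The target-mismatching condition is the target-matching condition with
#' the target and competitor dynamics delayed by `shift_ms`, so the
#' generated crossover offset between conditions equals `shift_ms` exactly.
#' The `"NS"` preset uses a 120-ms shift and an ERPD bump peaking 1100 ms
#' after word onset; the `"DS"` preset encodes the qualitative signature of
#' vocoded presentation — shallower, delayed competition dynamics with a
#' 240-ms shift, and an elevated, flat session-baseline ERPD — as generator
#' presets, not as claims about any particular dataset.
#'
#' @param preset `"NS"` or `"DS"`.
#' @param shift_ms Condition latency shift in ms (defaults 120 for NS, 240
#'   for DS).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(preset = c("NS", "DS"), shift_ms = NULL) {
  preset <- match.arg(preset)
  if (is.null(shift_ms)) shift_ms <- if (preset == "NS") 120 else 240
  fix <- if (preset == "NS") {
    list(target = list(base = 0.15, gain = 1.6, center = 800, slope = 110),
         competitor = list(base = 0.15, gain = 1.1, rise_center = 380,
                           rise_slope = 100, fall_center = 870, fall_slope = 180),
         distractor_base = 0.15,
         center = list(base = 0.25, gain = 1.0, tau = 500))
  } else {
    list(target = list(base = 0.15, gain = 1.4, center = 950, slope = 220),
         competitor = list(base = 0.15, gain = 0.95, rise_center = 450,
                           rise_slope = 150, fall_center = 1100, fall_slope = 340),
         distractor_base = 0.15,
         center = list(base = 0.25, gain = 1.0, tau = 500))
  }
  erpd <- if (preset == "NS") {
    list(peak_ms = 1100, shape_k = 2.5,
         amp = c(target_matching = 4, target_mismatching = 6, filler = 1.5),
         offset = 0, offset_rise_ms = 300)
  } else {
    list(peak_ms = 1300, shape_k = 2.5,
         amp = c(target_matching = 1.5, target_mismatching = 2, filler = 1),
         offset = 8, offset_rise_ms = 300)
  }
  structure(list(preset = preset, shift_ms = shift_ms, fix = fix, erpd = erpd,
                 drift_pct_per_min = 0), class = "ground_truth")
}

#' AOI activation curves of the ground truth
#'
#' @param truth A [ground_truth()].
#' @param t_rel Time in ms relative to target word onset (vectorized).
#' @param condition `"target_matching"`, `"target_mismatching"` or
#'   `"filler"`.
#' @return Matrix with columns `target`, `competitor`, `distractor_a`,
#'   `distractor_b`, `center`.
#' @export
fixation_activations <- function(truth, t_rel, condition) {
  f <- truth$fix
  shift <- if (condition == "target_mismatching") truth$shift_ms else 0
  ts <- t_rel - shift
  tg <- f$target
  target <- tg$base + tg$gain * stats::plogis((ts - tg$center) / tg$slope)
  cp <- f$competitor
  competitor <- if (condition == "filler") rep(cp$base, length(t_rel)) else
    cp$base + cp$gain * stats::plogis((ts - cp$rise_center) / cp$rise_slope) *
      stats::plogis(-(ts - cp$fall_center) / cp$fall_slope)
  ct <- f$center
  center <- ct$base + ct$gain * exp(-(t_rel + .trial_timing$word_lag_ms) / ct$tau)
  cbind(target = target, competitor = competitor,
        distractor_a = rep(f$distractor_base, length(t_rel)),
        distractor_b = rep(f$distractor_base, length(t_rel)),
        center = center)
}

#' AOI occupancy probabilities of the ground truth
#'
#' Activations normalized to sum to one at every time point.
#'
#' @inheritParams fixation_activations
#' @return Matrix of probabilities (rows sum to 1).
#' @export
truth_probabilities <- function(truth, t_rel, condition) {
  a <- fixation_activations(truth, t_rel, condition)
  a / rowSums(a)
}

#' %ERPD template of the ground truth
#'
#' Percent pupil change relative to the session-start baseline: a gamma-like
#' bump peaking `peak_ms` after word onset, plus (DS preset) a sustained
#' elevation ramping in shortly after sentence onset. Zero before the
#' sentence begins, so the session-start baseline window is unaffected.
#'
#' @inheritParams fixation_activations
#' @return Percent dilation values.
#' @export
erpd_template <- function(truth, t_rel, condition) {
  e <- truth$erpd
  xr <- t_rel / e$peak_ms
  bump <- ifelse(t_rel > 0, e$amp[[condition]] * xr^e$shape_k * exp(e$shape_k * (1 - xr)), 0)
  t_sent <- t_rel + .trial_timing$word_lag_ms  # time since sentence onset
  elev <- if (e$offset > 0)
    e$offset * stats::plogis((t_sent - e$offset_rise_ms) / 60) * as.numeric(t_sent > 0)
  else 0
  bump + elev
}

#' Simulate one trial's ocular trace
#'
#' Gaze: after display onset, a renewal sequence of fixation dwells with
#' gamma durations; at each dwell onset the AOI is drawn from the
#' ground-truth occupancy probabilities evaluated at the dwell midpoint, and
#' gaze sits near that quadrant's centroid. Pupil: participant baseline
#' scaled by (1 + template/100) — so the %ERPD formula recovers the template
#' on a noiseless trace — plus AR(1) noise and Poisson blinks recorded as
#' invalid zero-pupil samples.
#'
#' @param trial One row of the session trial table (needs
#'   `trial_start_ms`, `sentence_onset_ms`, `word_onset_ms`, `condition`).
#' @param truth A [ground_truth()].
#' @param config A [session_config()].
#' @param pupil_base Participant baseline pupil area.
#' @param layout An [aoi_layout()].
#' @return An [ocular_trace()] covering the trial span. Consumes the
#'   caller's RNG stream (seed the session, not the trial).
#' @export
simulate_trial_trace <- function(trial, truth, config, pupil_base = config$pupil_base,
                                 layout = aoi_layout()) {
  v <- sim_trial_core(trial$trial_start_ms, trial$sentence_onset_ms,
                      trial$word_onset_ms, trial$condition, truth, config,
                      pupil_base, layout)
  ocular_trace(v$t_ms, v$x, v$y, v$pupil, v$valid, rate = config$rate)
}

# plain-vector work-horse behind simulate_trial_trace / generate_session
sim_trial_core <- function(t0, sentence_onset, word_onset, condition, truth,
                           config, pupil_base, layout) {
  step <- 1000 / config$rate
  n <- round(.trial_timing$span_ms / step)
  t_ms <- t0 + (seq_len(n) - 1L) * step
  role_names <- c("target", "competitor", "distractor_a", "distractor_b", "center")

  # gaze: forced on the cross until the display + audio onset; afterwards a
  # quantile-coupled dwell process — one latent uniform per fixation dwell,
  # mapped through the time-varying cumulative AOI probabilities — so the
  # occupancy probability at every single sample equals the generating curve
  # exactly while gaze still moves in realistic fixation-length dwells
  roles <- rep("center", n)
  t_end <- t0 + .trial_timing$span_ms
  taus <- numeric(0); tau <- sentence_onset
  while (tau < t_end) {
    taus <- c(taus, tau)
    tau <- tau + max(stats::rgamma(1, shape = config$dwell_shape,
                                   rate = config$dwell_shape / config$dwell_mean_ms),
                     2 * step)
  }
  U <- stats::runif(length(taus))
  post <- t_ms >= sentence_onset
  P <- truth_probabilities(truth, t_ms[post] - word_onset, condition)
  cum2 <- P[, 1] + P[, 2]
  cum3 <- cum2 + P[, 3]
  cum4 <- cum3 + P[, 4]
  u <- U[findInterval(t_ms[post], taus)]
  idx <- 1L + (P[, 1] < u) + (cum2 < u) + (cum3 < u) + (cum4 < u)
  roles[post] <- role_names[idx]
  cent <- aoi_centroid(layout, roles)
  r <- rle(roles)
  jit_x <- rep(stats::rnorm(length(r$lengths), sd = 15), r$lengths)
  jit_y <- rep(stats::rnorm(length(r$lengths), sd = 15), r$lengths)
  x <- cent[, 1] + jit_x + stats::rnorm(n, sd = 2)
  y <- cent[, 2] + jit_y + stats::rnorm(n, sd = 2)

  # pupil: multiplicative template + AR(1) noise
  pct <- erpd_template(truth, t_ms - word_onset, condition)
  pupil <- pupil_base * (1 + pct / 100)
  if (config$noise_sd > 0) {
    innov <- stats::rnorm(n, sd = config$noise_sd * sqrt(1 - config$ar_rho^2))
    innov[1] <- stats::rnorm(1, sd = config$noise_sd)
    pupil <- pupil + as.numeric(stats::filter(innov, config$ar_rho, method = "recursive"))
  }
  valid <- rep(TRUE, n)

  n_blinks <- stats::rpois(1, config$blink_rate)
  for (b in seq_len(n_blinks)) {
    dur <- min(stats::rlnorm(1, config$blink_meanlog, config$blink_sdlog), 800)
    start <- stats::runif(1, sentence_onset + 100, word_onset + 1800)
    sel <- t_ms >= start & t_ms < start + dur
    valid[sel] <- FALSE
    pupil[sel] <- 0
  }
  list(t_ms = t_ms, x = x, y = y, pupil = pupil, valid = valid)
}

#' Generate a complete synthetic session
#'
#' Builds the trial list (critical trials split evenly between the
#' target-matching and target-mismatching conditions, fillers sampled from
#' the 40-item inventory to fill the remaining trials), simulates every
#' trial's trace, and concatenates them into one continuous 250-Hz session
#' recording. Fully deterministic given `config$seed`; the ground truth is
#' stored alongside the data.
#'
#' @param config A [session_config()].
#' @param truth A [ground_truth()] (default: the preset matching
#'   `config$presentation`).
#' @param participant Participant identifier (default `"p01"`).
#' @return A list of class `vw_session`: `trials` (tibble), `trace`
#'   ([ocular_trace()]), `truth`, `config`, `participant`,
#'   `pupil_base`.
#' @export
generate_session <- function(config = session_config(), truth = NULL,
                             participant = "p01") {
  stopifnot(inherits(config, "session_config"))
  if (is.null(truth)) truth <- ground_truth(config$presentation)
  set.seed(config$seed)
  n_fill <- config$n_trials - config$n_critical
  if (n_fill > config$n_filler_pool)
    stop("filler pool too small for the requested session", call. = FALSE)

  cond <- sample(c(rep("target_matching", config$n_critical / 2),
                   rep("target_mismatching", config$n_critical / 2)))
  item <- c(sprintf("pair%02d", seq_len(config$n_critical)),
            sprintf("fill%02d", sort(sample(config$n_filler_pool, n_fill))))
  condition <- c(cond, rep("filler", n_fill))
  ord <- sample(config$n_trials)
  item <- item[ord]; condition <- condition[ord]

  span <- .trial_timing$span_ms
  trial_start <- (seq_len(config$n_trials) - 1L) * span
  trials <- tibble::tibble(
    trial_id = sprintf("t%02d", seq_len(config$n_trials)),
    item_id = item,
    condition = condition,
    presentation = config$presentation,
    trial_start_ms = trial_start,
    sentence_onset_ms = trial_start + .trial_timing$cross_ms,
    word_onset_ms = trial_start + .trial_timing$cross_ms + .trial_timing$word_lag_ms,
    clicked_role = ifelse(stats::runif(config$n_trials) < config$accuracy,
                          "target", "competitor"),
    clicked_ms = NA_real_
  )
  trials$correct <- trials$clicked_role == "target"
  trials$clicked_ms <- trials$word_onset_ms + stats::runif(config$n_trials, 600, 1900)

  pupil_base <- config$pupil_base + stats::rnorm(1, sd = config$pupil_base_sd)
  layout <- aoi_layout()
  segs <- lapply(seq_len(config$n_trials), function(i)
    sim_trial_core(trials$trial_start_ms[i], trials$sentence_onset_ms[i],
                   trials$word_onset_ms[i], trials$condition[i], truth, config,
                   pupil_base, layout))
  trace <- ocular_trace(
    unlist(lapply(segs, `[[`, "t_ms")),
    unlist(lapply(segs, `[[`, "x")),
    unlist(lapply(segs, `[[`, "y")),
    unlist(lapply(segs, `[[`, "pupil")),
    unlist(lapply(segs, `[[`, "valid")),
    rate = config$rate)
  structure(list(trials = trials, trace = trace, truth = truth, config = config,
                 participant = participant, pupil_base = pupil_base),
            class = "vw_session")
}

#' Preprocess a session into screened, epoched, baseline-corrected data
#'
#' Applies the screening rules trial by trial (wrong clicks and blinks at or
#' above 300 ms exclude; shorter blinks are interpolated), computes the
#' session-start baseline (baseline 2) and per-trial pre-word baselines
#' (baseline 1), epochs each kept trial into the analysis window, labels
#' every sample with its AOI, and attaches %ERPD under both baselines.
#'
#' @param session A `vw_session` (or a list with `trials`, `trace`,
#'   `participant`).
#' @param blink_max_ms Blink exclusion threshold (default 300).
#' @param window Analysis window relative to word onset (default
#'   c(200, 2000)).
#' @param layout An [aoi_layout()].
#' @param critical_only Keep only critical trials in the epochs (default
#'   FALSE; fillers are needed for the ERPD contrasts).
#' @return List of class `vw_preprocessed`: `trials` (screening columns
#'   added), `epochs` (long tibble: participant, trial_id, condition,
#'   presentation, time_ms, x, y, pupil, aoi, erpd1, erpd2),
#'   `baseline2`, `participant_keep`, `n_excluded`.
#' @export
preprocess_session <- function(session, blink_max_ms = 300,
                               window = c(200, 2000), layout = aoi_layout(),
                               critical_only = FALSE) {
  trials <- session$trials
  trace <- session$trace
  rate <- trace_rate(trace)
  step <- 1000 / rate
  t_all <- trace$t_ms
  keep <- logical(nrow(trials)); reason <- rep(NA_character_, nrow(trials))
  epochs <- vector("list", nrow(trials))
  baseline2 <- tryCatch(
    compute_baseline(trace, trials$sentence_onset_ms[1], kind = 2),
    error = function(e) NA_real_)
  correct_v <- if (!is.null(trials$correct)) as.logical(trials$correct)
               else trials$clicked_role == "target"
  for (i in seq_len(nrow(trials))) {
    sel <- which(t_all >= trials$trial_start_ms[i] &
                 t_all < trials$trial_start_ms[i] + .trial_timing$span_ms)
    t <- t_all[sel]
    scr <- screen_core(isTRUE(correct_v[i]), trace$pupil[sel], trace$x[sel],
                       trace$y[sel], trace$valid[sel], step,
                       blink_max_ms = blink_max_ms)
    keep[i] <- scr$keep; reason[i] <- scr$reason
    if (!scr$keep) next
    if (critical_only && trials$condition[i] == "filler") next
    rel <- t - trials$word_onset_ms[i]
    esel <- rel >= window[1] & rel < window[2]
    if (sum(esel) != round(diff(window) / step)) {
      keep[i] <- FALSE; reason[i] <- "truncated"; next
    }
    bsel <- rel >= -200 & rel < 0
    if (!any(bsel) || any(scr$pupil[bsel] <= 0)) {
      keep[i] <- FALSE; reason[i] <- "baseline_gap"; next
    }
    b1 <- mean(scr$pupil[bsel])
    ep <- data.frame(
      time_ms = rel[esel], x = scr$x[esel], y = scr$y[esel],
      pupil = scr$pupil[esel], valid = scr$valid[esel]
    )
    ep$aoi <- assign_aoi(ep$x, ep$y, layout)
    ep$erpd1 <- erpd(ep$pupil, b1)
    ep$erpd2 <- if (!is.na(baseline2)) erpd(ep$pupil, baseline2) else NA_real_
    ep$participant <- session$participant
    ep$trial_id <- trials$trial_id[i]
    ep$condition <- trials$condition[i]
    ep$presentation <- trials$presentation[i]
    ep$baseline1 <- b1
    epochs[[i]] <- ep
  }
  trials$keep <- keep
  trials$exclude_reason <- reason
  structure(list(
    trials = trials,
    epochs = tibble::as_tibble(dplyr::bind_rows(epochs)),
    baseline2 = baseline2,
    participant_keep = screen_participant(keep),
    n_excluded = sum(!keep)
  ), class = "vw_preprocessed")
}

#' Simulate a multi-participant experiment
#'
#' Generates and preprocesses one session per participant, with
#' per-participant seeds derived from `seed`.
#'
#' @param n_participants Number of participants.
#' @param preset `"NS"` or `"DS"` ground-truth preset (also sets the
#'   presentation label).
#' @param seed Root seed.
#' @param config_args Named list of [session_config()] overrides.
#' @param window Analysis window for epoching.
#' @param critical_only Drop filler epochs (default TRUE; saves memory when
#'   only the fixation analysis is needed).
#' @return List with `epochs` (pooled long tibble over kept participants)
#'   and `sessions_kept`.
#' @export
simulate_experiment <- function(n_participants, preset = "NS", seed = 1L,
                                config_args = list(), window = c(200, 2000),
                                critical_only = TRUE) {
  offset <- if (preset == "NS") 0L else 500L
  pooled <- vector("list", n_participants)
  kept <- 0L
  for (i in seq_len(n_participants)) {
    args <- utils::modifyList(
      list(presentation = preset, seed = seed * 1000L + offset + i),
      config_args)
    cfg <- do.call(session_config, args)
    ses <- generate_session(cfg, participant = sprintf("%s_p%03d", preset, i))
    pre <- preprocess_session(ses, window = window, critical_only = critical_only)
    if (!pre$participant_keep) next
    kept <- kept + 1L
    pooled[[i]] <- pre$epochs
  }
  list(epochs = dplyr::bind_rows(pooled), sessions_kept = kept)
}

#' Ground-truth crossover time and condition offset
#'
#' Brute-force evaluation of the generating curves on a 1-ms grid: the
#' crossover of the truth's target and competitor occupancy probabilities
#' per condition, and the offset between conditions.
#'
#' @param truth A [ground_truth()].
#' @param window Evaluation window relative to word onset (default
#'   c(200, 2000)).
#' @param persistence_ms Persistence used by [crossover_time()].
#' @return List with `crossover` (named, per condition) and `offset_ms`.
#' @export
true_crossover_offset <- function(truth, window = c(200, 2000), persistence_ms = 100) {
  grid <- seq(window[1], window[2] - 1, by = 1)
  cross <- vapply(c("target_matching", "target_mismatching"), function(cond) {
    p <- truth_probabilities(truth, grid, cond)
    crossover_time(grid, p[, "target"], p[, "competitor"], persistence_ms)
  }, numeric(1))
  list(crossover = cross,
       offset_ms = unname(cross["target_mismatching"] - cross["target_matching"]))
}

#' End-to-end recovery check
#'
#' Runs the full chain — simulate sessions, preprocess, build fixation
#' proportion curves, detect the target/competitor crossover per condition —
#' and compares the recovered condition crossover offset against the
#' generating truth, for one or both presets.
#'
#' @param n_participants Participants per preset.
#' @param seed Root seed.
#' @param presets Character vector of presets to run.
#' @param persistence_ms Crossover persistence window.
#' @param config_args [session_config()] overrides.
#' @return Tibble with one row per preset: true and recovered crossovers
#'   per condition and the true and recovered offsets.
#' @export
end_to_end_check <- function(n_participants = 40L, seed = 1L,
                             presets = c("NS", "DS"), persistence_ms = 100,
                             config_args = list()) {
  rows <- lapply(presets, function(preset) {
    truth <- ground_truth(preset)
    tc <- true_crossover_offset(truth, persistence_ms = persistence_ms)
    exp <- simulate_experiment(n_participants, preset = preset, seed = seed,
                               config_args = config_args)
    curves <- proportion_curves(exp$epochs, group = "condition")
    rec <- vapply(c("target_matching", "target_mismatching"), function(cond) {
      cc <- curves[curves$condition == cond, ]
      tg <- cc[cc$role == "target", ]
      cp <- cc[cc$role == "competitor", ]
      crossover_time(tg$time_ms, tg$prop, cp$prop, persistence_ms)
    }, numeric(1))
    tibble::tibble(
      preset = preset,
      true_cross_match = tc$crossover[["target_matching"]],
      true_cross_mismatch = tc$crossover[["target_mismatching"]],
      true_offset_ms = tc$offset_ms,
      rec_cross_match = rec[["target_matching"]],
      rec_cross_mismatch = rec[["target_mismatching"]],
      rec_offset_ms = rec[["target_mismatching"]] - rec[["target_matching"]],
      sessions = exp$sessions_kept
    )
  })
  dplyr::bind_rows(rows)
}
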