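#' Ocular trace container
#'
#' Sample-level eye-tracker output: time in ms since session start, gaze
#' position in screen pixels, pupil area in device units, and a validity
#' flag (blinks are recorded as invalid samples with zero pupil). Time must
#' advance in constant steps of 1000/rate ms.
#'
#' @param t_ms Sample times in ms, strictly increasing, constant step.
#' @param x,y Gaze coordinates in px.
#' @param pupil Pupil area in device units; >= 0 where valid.
#' @param valid Logical validity flag.
#' @param rate Sampling rate in Hz (default 250).
#' @return A tibble of class `ocular_trace` with attribute `rate`.
#' @export
ocular_trace <- function(t_ms, x, y, pupil, valid = TRUE, rate = 250) {
  n <- length(t_ms)
  valid <- rep_len(valid, n)
  step <- 1000 / rate
  if (n > 1 && max(abs(diff(t_ms) - step)) > 1e-6)
    stop("t_ms must increase in constant steps of 1000/rate ms", call. = FALSE)
  if (any(pupil[valid] < 0)) stop("pupil must be >= 0 where valid", call. = FALSE)
  out <- tibble::tibble(t_ms = t_ms, x = x, y = y, pupil = pupil, valid = valid)
  attr(out, "rate") <- rate
  class(out) <- c("ocular_trace", class(out))
  out
}

trace_rate <- function(trace) {
  r <- attr(trace, "rate")
  if (is.null(r)) r <- 1000 / stats::median(diff(trace$t_ms))
  r
}

#' Detect blinks in an ocular trace
#'
#' A blink is a maximal run of samples that are flagged invalid or have
#' zero pupil area. Duration is the run length times the sample period.
#'
#' @param trace An [ocular_trace()].
#' @return Tibble with one row per blink: `start_ms`, `end_ms`,
#'   `duration_ms`, `start_idx`, `end_idx`, in time order.
#' @export
detect_blinks <- function(trace) {
  step <- 1000 / trace_rate(trace)
  bad <- !trace$valid | trace$pupil <= 0
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    start_ms = trace$t_ms[starts[keep]],
    duration_ms = r$lengths[keep] * step,
    end_ms = start_ms + duration_ms,
    start_idx = starts[keep],
    end_idx = ends[keep]
  )[, c("start_ms", "end_ms", "duration_ms", "start_idx", "end_idx")]
}

# shared repair core: replace samples i0..i1 by the line joining the medians
# of `context` samples on each side; bridge gaze linearly; NULL when the
# context is missing or itself invalid
gap_fill <- function(pupil, x, y, valid, i0, i1, context) {
  n <- length(pupil)
  pre <- seq(i0 - context, i0 - 1L)
  post <- seq(i1 + 1L, i1 + context)
  if (pre[1] < 1L || post[context] > n || any(!valid[pre]) || any(!valid[post]))
    return(NULL)
  g <- i1 - i0 + 1L
  pre_med <- stats::median(pupil[pre]); post_med <- stats::median(pupil[post])
  pupil[i0:i1] <- pre_med + (post_med - pre_med) * seq_len(g) / (g + 1)
  x[i0:i1] <- x[i0 - 1L] + (x[i1 + 1L] - x[i0 - 1L]) * seq_len(g) / (g + 1)
  y[i0:i1] <- y[i0 - 1L] + (y[i1 + 1L] - y[i0 - 1L]) * seq_len(g) / (g + 1)
  valid[i0:i1] <- TRUE
  list(pupil = pupil, x = x, y = y, valid = valid)
}

# screening core on plain vectors; step in ms per sample
screen_core <- function(correct, pupil, x, y, valid, step, blink_max_ms = 300,
                        context = 25L) {
  bad <- !valid | pupil <= 0
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bs <- starts[r$values]; be <- ends[r$values]
  n_blinks <- length(bs)
  if (!correct)
    return(list(keep = FALSE, reason = "wrong_click", n_blinks = n_blinks))
  if (n_blinks > 0 && any((be - bs + 1L) * step >= blink_max_ms))
    return(list(keep = FALSE, reason = "long_blink", n_blinks = n_blinks))
  for (b in seq_len(n_blinks)) {
    rep <- gap_fill(pupil, x, y, valid, bs[b], be[b], context)
    if (is.null(rep))
      return(list(keep = FALSE, reason = "unrepairable", n_blinks = n_blinks))
    pupil <- rep$pupil; x <- rep$x; y <- rep$y; valid <- rep$valid
  }
  list(keep = TRUE, reason = NA_character_, pupil = pupil, x = x, y = y,
       valid = valid, n_blinks = n_blinks)
}

#' Linearly interpolate one blink
#'
#' Replaces the gap with the straight line joining the median of the 25
#' samples recorded before the blink to the median of the 25 samples after
#' it (anchored at the samples adjacent to the gap). Medians make the
#' anchors robust to spikes in the context. Samples outside the gap are
#' untouched; the sample count is conserved.
#'
#' @param trace An [ocular_trace()].
#' @param blink One row of [detect_blinks()] output.
#' @param context Number of context samples on each side (default 25).
#' @return The repaired trace.
#' @export
interpolate_blink <- function(trace, blink, context = 25L) {
  rep <- gap_fill(trace$pupil, trace$x, trace$y, trace$valid,
                  blink$start_idx, blink$end_idx, context)
  if (is.null(rep))
    stop("insufficient valid context samples around blink; trial un-repairable",
         call. = FALSE)
  trace$pupil <- rep$pupil
  trace$x <- rep$x
  trace$y <- rep$y
  trace$valid <- rep$valid
  trace
}

#' Screen one trial
#'
#' A trial is excluded when the participant clicked something other than the
#' target, or when it contains a blink of `blink_max_ms` (300 ms) or longer;
#' an exactly-300-ms blink is excluded (the conservative reading of the
#' repair rule, configurable). Shorter blinks are repaired by
#' [interpolate_blink()]; a short blink without enough valid context also
#' excludes the trial.
#'
#' @param trial One row of a trial table with columns `clicked_role` and the
#'   target role name in `correct` (logical) or `clicked_role == "target"`.
#' @param trace The trial's [ocular_trace()] segment (baseline window
#'   through end of analysis window).
#' @param blink_max_ms Exclusion threshold in ms (default 300).
#' @param context Interpolation context samples (default 25).
#' @return A list: `keep` (logical), `reason` (`NA`, `"wrong_click"`,
#'   `"long_blink"` or `"unrepairable"`), `trace` (repaired when kept),
#'   `n_blinks`.
#' @export
screen_trial <- function(trial, trace, blink_max_ms = 300, context = 25L) {
  correct <- if (!is.null(trial$correct)) isTRUE(as.logical(trial$correct))
             else identical(trial$clicked_role, "target")
  res <- screen_core(correct, trace$pupil, trace$x, trace$y, trace$valid,
                     step = 1000 / trace_rate(trace),
                     blink_max_ms = blink_max_ms, context = context)
  if (res$keep) {
    trace$pupil <- res$pupil
    trace$x <- res$x
    trace$y <- res$y
    trace$valid <- res$valid
  }
  list(keep = res$keep, reason = res$reason, trace = trace, n_blinks = res$n_blinks)
}

#' Screen a participant
#'
#' A participant's session is discarded when the trials excluded by
#' [screen_trial()] amount to at least half of all trials.
#'
#' @param keep Logical vector, one element per trial, TRUE when kept.
#' @param threshold Exclusion fraction (default 0.5).
#' @return TRUE to keep the participant, FALSE to exclude.
#' @export
screen_participant <- function(keep, threshold = 0.5) {
  mean(!keep) < threshold
}

#' Mean pupil size over a half-open time window
#'
#' @param trace An [ocular_trace()].
#' @param start_ms,end_ms Window \[start, end) in session time.
#' @return Mean pupil area over the window.
#' @export
window_mean_pupil <- function(trace, start_ms, end_ms) {
  sel <- trace$t_ms >= start_ms & trace$t_ms < end_ms
  if (!any(sel)) stop("baseline window lies outside the trace", call. = FALSE)
  if (any(!trace$valid[sel] | trace$pupil[sel] <= 0))
    stop("baseline window overlaps an un-repaired gap", call. = FALSE)
  mean(trace$pupil[sel])
}

#' Compute a pupil baseline
#'
#' Baseline 1 is the average pupil size in the 200 ms immediately preceding
#' the target word, computed per trial; it isolates the window of lexical
#' competition. Baseline 2 is the average pupil size in the 200 ms at the
#' very beginning of the experiment (immediately before the first
#' sentence's onset), one value per participant; it anchors dilation to a
#' state not yet affected by the task.
#'
#' @param trace An [ocular_trace()] (for kind 1, the trial's segment or the
#'   session trace; for kind 2, the session trace).
#' @param onset_ms Word onset (kind 1) or first-sentence onset (kind 2) in
#'   session time.
#' @param kind 1 or 2.
#' @param window_ms Baseline window length (default 200).
#' @return Baseline pupil area.
#' @export
compute_baseline <- function(trace, onset_ms, kind = 1, window_ms = 200) {
  if (!kind %in% c(1, 2)) stop("kind must be 1 or 2", call. = FALSE)
  window_mean_pupil(trace, onset_ms - window_ms, onset_ms)
}

#' Event-related pupil dilation in percent
#'
#' %ERPD = (observation - baseline) / baseline * 100. Scale-invariant:
#' multiplying observation and baseline by the same positive constant leaves
#' the result unchanged.
#'
#' @param observation Pupil area (vectorized).
#' @param baseline Baseline pupil area (> 0).
#' @return Percent change from baseline.
#' @export
erpd <- function(observation, baseline) {
  if (any(baseline <= 0)) stop("baseline must be positive", call. = FALSE)
  (observation - baseline) / baseline * 100
}

#' Epoch a trace around a target word onset
#'
#' Extracts the samples with time in \[onset + window\[1\], onset +
#' window\[2\]) and re-expresses time relative to the word onset. At 250 Hz
#' the default 200-2000 ms window yields 450 samples.
#'
#' @param trace An [ocular_trace()].
#' @param onset_ms Target word onset in session time.
#' @param window Analysis window in ms relative to onset (default
#'   c(200, 2000)).
#' @return Tibble with `time_ms` (relative), `x`, `y`, `pupil`, `valid`.
#' @export
epoch_trace <- function(trace, onset_ms, window = c(200, 2000)) {
  step <- 1000 / trace_rate(trace)
  sel <- trace$t_ms >= onset_ms + window[1] & trace$t_ms < onset_ms + window[2]
  expected <- round(diff(window) / step)
  if (sum(sel) != expected)
    stop("trial truncated: expected ", expected, " samples in window, found ",
         sum(sel), call. = FALSE)
  out <- trace[sel, c("x", "y", "pupil", "valid")]
  out$time_ms <- trace$t_ms[sel] - onset_ms
  out[, c("time_ms", "x", "y", "pupil", "valid")]
}

#' Count fixations in an epoch
#'
#' A fixation is a maximal run of samples labelled with the same area of
#' interest whose duration reaches `min_ms`. Runs labelled `"none"` (gaze
#' off all regions) are not counted.
#'
#' @param aoi Character vector of per-sample AOI labels.
#' @param rate Sampling rate in Hz (default 250).
#' @param min_ms Minimum fixation duration in ms (default 80).
#' @param exclude Labels that never count as fixations (default "none").
#' @return Number of fixations.
#' @export
count_fixations <- function(aoi, rate = 250, min_ms = 80, exclude = "none") {
  if (length(aoi) == 0L) return(0L)
  r <- rle(as.character(aoi))
  sum(!(r$values %in% exclude) & r$lengths * 1000 / rate >= min_ms)
}

#' Read / write sample-level and trial-level TSV files
#'
#' The sample dialect has a header line and columns `t_ms`, `x`, `y`,
#' `pupil`, `valid`; the trial dialect has `trial_id`, `condition`,
#' `presentation`, `sentence_onset_ms`, `word_onset_ms`, `clicked_role`,
#' `correct`.
#'
#' @param path TSV path.
#' @param rate Sampling rate recorded with the trace (default 250).
#' @return `read_ocular_tsv`: an [ocular_trace()]; `read_trials_tsv`: a
#'   tibble of trials; the writers return `path` invisibly.
#' @name ocular_io
NULL

#' @rdname ocular_io
#' @param trace An [ocular_trace()] to write.
#' @export
write_ocular_tsv <- function(trace, path) {
  readr::write_tsv(tibble::as_tibble(trace)[, c("t_ms", "x", "y", "pupil", "valid")], path)
  invisible(path)
}

#' @rdname ocular_io
#' @export
read_ocular_tsv <- function(path, rate = 250) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  ocular_trace(d$t_ms, d$x, d$y, d$pupil, as.logical(d$valid), rate = rate)
}

#' @rdname ocular_io
#' @param trials A trial tibble to write.
#' @export
write_trials_tsv <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname ocular_io
#' @export
read_trials_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
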