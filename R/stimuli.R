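#' Sentence token with a splice boundary
#'
#' Wraps an [audio_signal()] together with the time of its splice point:
#' the end of the first syllable of a polysyllabic word, or the end of a
#' monosyllabic word.
#'
#' @param audio An [audio_signal()].
#' @param boundary_ms Splice point in ms; must lie strictly inside the token.
#' @param label One of `"poly_recording_1"`, `"poly_recording_2"`,
#'   `"mono_recording"`, or a free label for synthetic material.
#' @return An object of class `sentence_token`.
#' @export
sentence_token <- function(audio, boundary_ms, label = "token") {
  stopifnot(inherits(audio, "audio_signal"))
  if (!(boundary_ms > 0 && boundary_ms < duration_ms(audio)))
    stop("boundary_ms must lie strictly inside the token", call. = FALSE)
  structure(list(audio = audio, boundary_ms = boundary_ms, label = label),
            class = "sentence_token")
}

nearest_zero_crossing <- function(samples, idx) {
  # index i such that samples[i] and samples[i+1] straddle (or touch) zero,
  # nearest to idx; falls back to idx if none found
  s <- sign(samples)
  cross <- which(s[-length(s)] * s[-1L] <= 0)
  if (length(cross) == 0L) return(idx)
  cross[which.min(abs(cross - idx))]
}

#' Cross-splice two sentence tokens
#'
#' Concatenates the samples of `part1` up to its boundary with the samples
#' of `part2` from its boundary to the end — the manipulation that creates
#' the two durational-cue conditions. Condition 1 (target-matching cues)
#' splices the first part of one polysyllabic recording onto the second part
#' of the other; Condition 2 (target-mismatching cues) splices the first
#' part of the monosyllabic recording onto the same second part. Splicing is
#' sample-exact: no resampling or windowing.
#'
#' @param part1,part2 [sentence_token()] objects at the same rate.
#' @param snap_to_zero Move each cut to the zero crossing nearest the marked
#'   boundary to avoid clicks (default TRUE). With `FALSE` the cut falls
#'   exactly at the boundary sample.
#' @return The spliced [audio_signal()].
#' @export
cross_splice <- function(part1, part2, snap_to_zero = TRUE) {
  stopifnot(inherits(part1, "sentence_token"), inherits(part2, "sentence_token"))
  if (part1$audio$rate != part2$audio$rate)
    stop("sample rates differ; resample before splicing", call. = FALSE)
  r <- part1$audio$rate
  i1 <- round(part1$boundary_ms * r / 1000)
  i2 <- round(part2$boundary_ms * r / 1000)
  if (snap_to_zero) {
    i1 <- nearest_zero_crossing(part1$audio$samples, i1)
    i2 <- nearest_zero_crossing(part2$audio$samples, i2)
  }
  head <- part1$audio$samples[seq_len(i1)]
  tail <- part2$audio$samples[seq(i2 + 1L, length(part2$audio$samples))]
  audio_signal(c(head, tail), r)
}

#' Synthesize a harmonic sentence-like token
#'
#' Synthetic stand-in for a recorded sentence: a harmonic complex at `f0`
#' with a spectral tilt, a raised-cosine onset/offset, a slow amplitude arc,
#' and a low-level noise floor. A boundary is marked at `boundary_ms`
#' (default: 40% of the duration). Deterministic given `seed`.
#'
#' @param duration_ms Token duration in ms.
#' @param f0 Fundamental frequency in Hz (default 150).
#' @param rate Sampling rate in Hz (default 22050).
#' @param tilt_db_oct Spectral tilt in dB per octave applied to harmonic
#'   amplitudes (default -6).
#' @param boundary_ms Marked splice point (default 0.4 * duration).
#' @param noise_level RMS of the added noise floor (default 0.001).
#' @param seed Integer seed for the noise component.
#' @param label Token label.
#' @return A [sentence_token()].
#' @export
synthesize_token <- function(duration_ms, f0 = 150, rate = 22050,
                             tilt_db_oct = -6, boundary_ms = NULL,
                             noise_level = 0.001, seed = 1L, label = "token") {
  stopifnot(duration_ms > 0)
  n <- round(duration_ms * rate / 1000)
  t <- (seq_len(n) - 1L) / rate
  n_harm <- max(1L, floor(min(rate / 2 - 1, 10000) / f0))
  amps <- 10^(tilt_db_oct * log2(seq_len(n_harm)) / 20)
  x <- numeric(n)
  for (h in seq_len(n_harm)) x <- x + amps[h] * sin(2 * pi * h * f0 * t)
  x <- x / max(abs(x))
  # raised-cosine 10-ms edges plus a slow arc peaking mid-token
  edge <- round(0.010 * rate)
  env <- rep(1, n)
  if (n > 2 * edge) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(edge) / edge))
    env[seq_len(edge)] <- ramp
    env[seq(n - edge + 1L, n)] <- rev(ramp)
  }
  env <- env * (0.75 + 0.25 * sin(pi * seq_len(n) / n))
  old <- .Random.seed_save()
  set.seed(seed)
  noise <- stats::rnorm(n, sd = noise_level)
  .Random.seed_restore(old)
  audio <- audio_signal(0.9 * x * env + noise, rate)
  if (is.null(boundary_ms)) boundary_ms <- 0.4 * duration_ms
  sentence_token(audio, boundary_ms, label)
}

# save/restore the global RNG state so seeded helpers do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic stimulus inventory
#'
#' Emulates the durational statistics of the experimental materials:
#' `n_critical` pairs of a polysyllabic target and its initially embedded
#' monosyllabic competitor, where boundary lengthening makes the
#' monosyllabic token longer than the embedded syllable by a difference
#' drawn from a scaled Beta distribution on \[20, 120\] ms with mean 65 ms;
#' plus `n_filler` fillers partitioned into 7 polysyllabic and 33
#' monosyllabic items, of which 20 are competitor-free, 10 have an
#' initial-position embedding and 10 a final-position embedding.
#'
#' @param n_critical Number of critical pairs (default 26).
#' @param n_filler Number of fillers (default 40).
#' @param seed Integer seed.
#' @param diff_range Support of the duration difference in ms (default
#'   c(20, 120)).
#' @param diff_shape Beta shape parameters; the defaults (2.25, 2.75) give
#'   mean 20 + 100 * 2.25/5 = 65 ms on the default range.
#' @param filler_counts Named counts: `poly`, `mono` (syllabic structure,
#'   must sum to `n_filler`) and `none`, `initial`, `final` (embedding
#'   structure, must also sum to `n_filler`).
#' @param syllable_ms_range Range of the embedded-syllable duration in the
#'   polysyllabic token (default c(160, 220) ms).
#' @return A list with tibbles `pairs` (pair_id,
#'   syllable_duration_poly_ms, syllable_duration_mono_ms,
#'   duration_difference_ms) and `fillers` (filler_id, syllabic, embedding),
#'   class `stimulus_inventory`.
#' @export
generate_stimulus_inventory <- function(n_critical = 26L, n_filler = 40L,
                                        seed = 1L,
                                        diff_range = c(20, 120),
                                        diff_shape = c(2.25, 2.75),
                                        filler_counts = c(poly = 7L, mono = 33L,
                                                          none = 20L, initial = 10L,
                                                          final = 10L),
                                        syllable_ms_range = c(160, 220)) {
  if (n_critical < 0 || n_filler < 0) stop("counts must be >= 0", call. = FALSE)
  fc <- filler_counts
  if (fc[["poly"]] + fc[["mono"]] != n_filler ||
      fc[["none"]] + fc[["initial"]] + fc[["final"]] != n_filler)
    stop("filler partition counts are inconsistent with n_filler", call. = FALSE)
  set.seed(seed)
  poly_syll <- stats::runif(n_critical, syllable_ms_range[1], syllable_ms_range[2])
  diff <- diff_range[1] + diff(diff_range) *
    stats::rbeta(n_critical, diff_shape[1], diff_shape[2])
  pairs <- tibble::tibble(
    pair_id = sprintf("pair%02d", seq_len(n_critical)),
    syllable_duration_poly_ms = poly_syll,
    syllable_duration_mono_ms = poly_syll + diff,
    duration_difference_ms = diff
  )
  syllabic <- sample(rep(c("polysyllabic", "monosyllabic"), c(fc[["poly"]], fc[["mono"]])))
  embedding <- sample(rep(c("none", "initial", "final"),
                          c(fc[["none"]], fc[["initial"]], fc[["final"]])))
  fillers <- tibble::tibble(
    filler_id = sprintf("fill%02d", seq_len(n_filler)),
    syllabic = syllabic, embedding = embedding
  )
  structure(list(pairs = pairs, fillers = fillers, seed = seed), class = "stimulus_inventory")
}

#' Build the audio for one critical stimulus
#'
#' Synthesizes the three recordings of a critical pair (two renditions of
#' the polysyllabic sentence, one of the monosyllabic sentence) and
#' cross-splices them into the requested condition. Condition
#' `"target_matching"` combines the first polysyllabic recording up to its
#' first-syllable boundary with the second part of the other polysyllabic
#' recording; `"target_mismatching"` puts the monosyllabic recording's first
#' part (longer by the pair's duration difference) before the same second
#' part. With `presentation = "DS"` the assembled sentence is vocoded.
#'
#' @param pair One row of the inventory `pairs` tibble.
#' @param condition `"target_matching"` or `"target_mismatching"`.
#' @param presentation `"NS"` (natural) or `"DS"` (vocoded).
#' @param rate Sampling rate in Hz (default 22050).
#' @param config [vocoder_config()] used when `presentation = "DS"`.
#' @param seed Seed for token synthesis.
#' @return A list with the assembled [audio_signal()] (`audio`), the boundary
#'   position in ms (`boundary_ms`), condition and presentation labels.
#' @export
build_condition_stimulus <- function(pair, condition = c("target_matching", "target_mismatching"),
                                     presentation = c("NS", "DS"),
                                     rate = 22050, config = vocoder_config(),
                                     seed = 1L) {
  condition <- match.arg(condition)
  presentation <- match.arg(presentation)
  pre_ms <- 600   # neutral sentence context before the critical word
  post_ms <- 500  # continuation after the splice point
  poly_b <- pre_ms + pair$syllable_duration_poly_ms
  mono_b <- pre_ms + pair$syllable_duration_mono_ms
  poly1 <- synthesize_token(poly_b + post_ms, f0 = 150, rate = rate,
                            boundary_ms = poly_b, seed = seed, label = "poly_recording_1")
  poly2 <- synthesize_token(poly_b + post_ms, f0 = 155, rate = rate,
                            boundary_ms = poly_b, seed = seed + 1L, label = "poly_recording_2")
  mono <- synthesize_token(mono_b + post_ms, f0 = 150, rate = rate,
                           boundary_ms = mono_b, seed = seed + 2L, label = "mono_recording")
  first <- switch(condition, target_matching = poly1, target_mismatching = mono)
  audio <- cross_splice(first, poly2)
  if (presentation == "DS") {
    if (rate < 2 * config$f_hi) stop("rate too low to vocode; raise `rate`", call. = FALSE)
    audio <- vocode(audio, config)
  }
  list(audio = audio, boundary_ms = first$boundary_ms,
       condition = condition, presentation = presentation, pair_id = pair$pair_id)
}

#' Write an inventory manifest as TSV
#'
#' @param inventory A `stimulus_inventory`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_inventory_tsv <- function(inventory, path) {
  stopifnot(inherits(inventory, "stimulus_inventory"))
  readr::write_tsv(inventory$pairs, path)
  invisible(path)
}
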