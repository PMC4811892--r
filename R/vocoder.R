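#' Vocoder configuration
#'
#' Settings for the acoustic cochlear-implant simulation: an n-channel
#' sinewave vocoder whose analysis bands cover `f_lo`..`f_hi` Hz with equal
#' basilar-membrane spacing under the Greenwood map. Per band, the temporal
#' envelope is extracted by half-wave rectification followed by a low-pass
#' Butterworth filter (`env_cutoff` Hz, `env_order`), and the band is
#' resynthesized as a sinusoid at the band's center frequency modulated by
#' that envelope.
#'
#' @param n_channels Number of analysis channels (default 8).
#' @param f_lo,f_hi Lower/upper edge of the analysis range in Hz
#'   (defaults 100 and 10000).
#' @param env_cutoff Envelope low-pass cutoff in Hz (default 300).
#' @param env_order Envelope Butterworth order (default 4).
#' @param band_order Overall order of each Butterworth band-pass filter;
#'   must be even (default 4).
#' @param zero_phase Apply filters forward-backward (zero phase) so splice
#'   timing is not shifted; `FALSE` gives causal forward-only filtering.
#' @param center_mode How band center frequencies are defined: midpoint in
#'   Greenwood position (default), or the geometric/arithmetic mean of the
#'   band edges in Hz.
#' @param carrier Carrier type; only `"sinusoid"` is implemented.
#' @return An object of class `vocoder_config`.
#' @export
vocoder_config <- function(n_channels = 8L, f_lo = 100, f_hi = 10000,
                           env_cutoff = 300, env_order = 4L,
                           band_order = 4L, zero_phase = TRUE,
                           center_mode = c("greenwood", "geometric", "arithmetic"),
                           carrier = "sinusoid") {
  center_mode <- match.arg(center_mode)
  carrier <- match.arg(carrier, "sinusoid")
  if (!(f_lo > 0 && f_hi > f_lo)) stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (n_channels < 1L) stop("n_channels must be >= 1", call. = FALSE)
  if (env_cutoff <= 0) stop("env_cutoff must be positive", call. = FALSE)
  if (env_order < 1L) stop("env_order must be >= 1", call. = FALSE)
  if (band_order < 2L || band_order %% 2L != 0L)
    stop("band_order must be an even integer >= 2", call. = FALSE)
  structure(list(n_channels = as.integer(n_channels), f_lo = f_lo, f_hi = f_hi,
                 env_cutoff = env_cutoff, env_order = as.integer(env_order),
                 band_order = as.integer(band_order), zero_phase = zero_phase,
                 center_mode = center_mode, carrier = carrier),
            class = "vocoder_config")
}

#' Design a Greenwood-spaced filterbank
#'
#' Band edges are placed so that their Greenwood positions form an
#' arithmetic sequence from position(f_lo) to position(f_hi): equal spacing
#' along the basilar membrane rather than in Hz. Center frequencies default
#' to the Greenwood midpoint of each band mapped back to Hz.
#'
#' @param config A [vocoder_config()].
#' @param map A [greenwood_map()].
#' @return A list with `edges` (length n+1, Hz) and `centers` (length n, Hz),
#'   class `filterbank`.
#' @export
design_filterbank <- function(config = vocoder_config(), map = greenwood_map()) {
  stopifnot(inherits(config, "vocoder_config"))
  n <- config$n_channels
  pos <- seq(greenwood_position(config$f_lo, map),
             greenwood_position(config$f_hi, map), length.out = n + 1L)
  edges <- greenwood_frequency(pmin(pmax(pos, 0), 1), map)
  # pin endpoints exactly (inverse map is exact up to rounding)
  edges[1] <- config$f_lo
  edges[n + 1L] <- config$f_hi
  centers <- switch(config$center_mode,
    greenwood  = greenwood_frequency((pos[-(n + 1L)] + pos[-1L]) / 2, map),
    geometric  = sqrt(edges[-(n + 1L)] * edges[-1L]),
    arithmetic = (edges[-(n + 1L)] + edges[-1L]) / 2
  )
  structure(list(edges = edges, centers = centers, positions = pos), class = "filterbank")
}

filter_apply <- function(filt, x, zero_phase) {
  if (zero_phase) signal::filtfilt(filt, x) else as.numeric(signal::filter(filt, x))
}

#' Band-pass filter an audio signal
#'
#' Butterworth band-pass of overall order `order` (an order/2 design applied
#' to the band pair, doubling when run zero-phase as forward-backward).
#'
#' @param x An [audio_signal()].
#' @param lo,hi Band edges in Hz; require 0 < lo < hi < rate/2.
#' @param order Overall filter order (even, default 4).
#' @param zero_phase Forward-backward filtering (default TRUE).
#' @return Filtered [audio_signal()] of identical length and rate.
#' @export
bandpass <- function(x, lo, hi, order = 4L, zero_phase = TRUE) {
  stopifnot(inherits(x, "audio_signal"))
  nyq <- x$rate / 2
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= nyq) stop("upper band edge must lie below the Nyquist frequency", call. = FALSE)
  filt <- signal::butter(order %/% 2L, c(lo, hi) / nyq, type = "pass")
  audio_signal(filter_apply(filt, x$samples, zero_phase), x$rate)
}

#' Extract a temporal amplitude envelope
#'
#' Half-wave rectification followed by a low-pass Butterworth filter with
#' unit DC gain, so steady amplitudes pass through unscaled.
#'
#' @param x A band-limited [audio_signal()].
#' @param cutoff Low-pass cutoff in Hz (default 300; must be below Nyquist).
#' @param order Butterworth order (default 4).
#' @param zero_phase Forward-backward filtering (default TRUE).
#' @return Envelope as an [audio_signal()] of identical length.
#' @export
extract_envelope <- function(x, cutoff = 300, order = 4L, zero_phase = TRUE) {
  stopifnot(inherits(x, "audio_signal"))
  if (cutoff >= x$rate / 2) stop("cutoff must lie below the Nyquist frequency", call. = FALSE)
  rectified <- pmax(x$samples, 0)
  filt <- signal::butter(order, cutoff / (x$rate / 2), type = "low")
  audio_signal(filter_apply(filt, rectified, zero_phase), x$rate)
}

min_vocode_samples <- function(config) {
  # forward-backward filtering needs room for the edge transients of the
  # longest filter involved
  12L * (max(config$band_order, config$env_order) + 1L)
}

#' Sinewave-vocode a signal (acoustic CI simulation)
#'
#' Splits the signal into `n_channels` Greenwood-spaced bands, extracts each
#' band's envelope (half-wave rectification + low-pass), and resynthesizes
#' the signal as the sum of sinusoids at the band center frequencies
#' modulated by the envelopes. The output has exactly the sample count and
#' rate of the input, so durational cues are preserved sample-exactly.
#'
#' @param x An [audio_signal()] with rate >= 2 * f_hi (inputs below that are
#'   rejected rather than resampled).
#' @param config A [vocoder_config()].
#' @param map A [greenwood_map()].
#' @return The vocoded [audio_signal()].
#' @export
vocode <- function(x, config = vocoder_config(), map = greenwood_map()) {
  stopifnot(inherits(x, "audio_signal"), inherits(config, "vocoder_config"))
  if (x$rate < 2 * config$f_hi)
    stop("sampling rate ", x$rate, " Hz is below 2*f_hi = ", 2 * config$f_hi,
         " Hz; resample the input first", call. = FALSE)
  n <- length(x$samples)
  if (n < min_vocode_samples(config))
    stop("signal too short for filter warm-up (need >= ",
         min_vocode_samples(config), " samples, got ", n, ")", call. = FALSE)
  fb <- design_filterbank(config, map)
  t <- (seq_len(n) - 1L) / x$rate
  out <- numeric(n)
  for (ch in seq_len(config$n_channels)) {
    band <- bandpass(x, fb$edges[ch], fb$edges[ch + 1L],
                     order = config$band_order, zero_phase = config$zero_phase)
    env <- extract_envelope(band, cutoff = config$env_cutoff,
                            order = config$env_order,
                            zero_phase = config$zero_phase)
    out <- out + env$samples * sin(2 * pi * fb$centers[ch] * t)
  }
  audio_signal(out, x$rate)
}

#' Per-carrier RMS of a vocoded signal
#'
#' Measures, for each filterbank carrier, the RMS of the signal within a
#' narrow band around the carrier frequency. Used to check that vocoded
#' energy concentrates at the carrier set.
#'
#' @param x An [audio_signal()].
#' @param config A [vocoder_config()].
#' @param map A [greenwood_map()].
#' @param rel_width Half-width of the measurement band as a fraction of the
#'   carrier frequency (default 0.04).
#' @return Numeric vector of length `n_channels`.
#' @export
carrier_rms <- function(x, config = vocoder_config(), map = greenwood_map(),
                        rel_width = 0.04) {
  fb <- design_filterbank(config, map)
  n <- length(x$samples)
  spec <- abs(stats::fft(x$samples))[seq_len(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1L) * x$rate / n
  vapply(fb$centers, function(fc) {
    sel <- freqs >= fc * (1 - rel_width) & freqs <= fc * (1 + rel_width)
    sqrt(sum(spec[sel]^2) / n^2)
  }, numeric(1))
}
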