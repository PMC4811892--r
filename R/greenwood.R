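#' Greenwood cochlear frequency-position map
#'
#' The Greenwood function relates relative position along the basilar
#' membrane, x in \[0, 1\] from apex to base, to characteristic frequency:
#' F(x) = A (10^(a x) - k). The defaults are the standard human
#' parameterization (A = 165.4 Hz, a = 2.1 per unit relative length,
#' k = 0.88), which places F(0) at about 20 Hz and F(1) at about 20.7 kHz.
#' The vocoder uses this map to space its analysis bands equally in
#' cochlear place.
#'
#' @param A Scale constant in Hz.
#' @param a Exponent constant per unit relative cochlear position.
#' @param k Dimensionless offset constant.
#' @return An object of class `greenwood_map`.
#' @export
greenwood_map <- function(A = 165.4, a = 2.1, k = 0.88) {
  stopifnot(is.numeric(A), A > 0, is.numeric(a), a > 0, is.numeric(k), k >= 0, k < 1)
  structure(list(A = A, a = a, k = k), class = "greenwood_map")
}

#' Frequency at a relative cochlear position
#'
#' @param x Relative basilar-membrane position(s) in \[0, 1\] (apex to base).
#' @param map A [greenwood_map()].
#' @return Frequency in Hz; strictly increasing in `x`.
#' @export
greenwood_frequency <- function(x, map = greenwood_map()) {
  stopifnot(inherits(map, "greenwood_map"))
  if (any(x < 0 | x > 1)) stop("relative position must lie in [0, 1]", call. = FALSE)
  map$A * (10^(map$a * x) - map$k)
}

#' Relative cochlear position of a frequency
#'
#' Inverse of [greenwood_frequency()]: x = log10(f/A + k) / a. Defined for
#' any f with f/A + k > 0; values outside the physical range simply map
#' outside \[0, 1\].
#'
#' @param f Frequency in Hz.
#' @param map A [greenwood_map()].
#' @return Relative position(s).
#' @export
greenwood_position <- function(f, map = greenwood_map()) {
  stopifnot(inherits(map, "greenwood_map"))
  if (any(f / map$A + map$k <= 0)) stop("frequency outside the domain of the map", call. = FALSE)
  log10(f / map$A + map$k) / map$a
}
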