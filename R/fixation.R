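#' Area-of-interest layout on the 3x3 display grid
#'
#' The screen is divided into three horizontal and three vertical bars; the
#' fixation cross sits in the central quadrant and the four pictures are
#' centered in the four corner quadrants. Each picture role (target,
#' competitor, two distractors) is assigned one corner; pictures are treated
#' as their full quadrant.
#'
#' @param screen_w,screen_h Screen size in px (defaults 1024 x 768).
#' @param role_map Named character vector mapping the four roles to distinct
#'   corners `"tl"`, `"tr"`, `"bl"`, `"br"`.
#' @return An object of class `aoi_layout`.
#' @export
aoi_layout <- function(screen_w = 1024, screen_h = 768,
                       role_map = c(target = "tl", competitor = "tr",
                                    distractor_a = "bl", distractor_b = "br")) {
  corners <- c("tl", "tr", "bl", "br")
  if (!setequal(names(role_map), c("target", "competitor", "distractor_a", "distractor_b")) ||
      !setequal(unname(role_map), corners))
    stop("role_map must assign the four roles to the four distinct corners", call. = FALSE)
  structure(list(screen_w = screen_w, screen_h = screen_h, role_map = role_map),
            class = "aoi_layout")
}

#' Assign gaze samples to areas of interest
#'
#' Grid cells are half-open pixel intervals; corner quadrants map to their
#' assigned role, the central quadrant to `"center"`, the remaining edge
#' cells and off-screen positions to `"none"`. Every on-screen point maps to
#' exactly one label.
#'
#' @param x,y Gaze coordinates in px (vectorized).
#' @param layout An [aoi_layout()].
#' @return Character vector of labels.
#' @export
assign_aoi <- function(x, y, layout = aoi_layout()) {
  stopifnot(inherits(layout, "aoi_layout"))
  col <- findInterval(x, c(0, layout$screen_w / 3, 2 * layout$screen_w / 3, layout$screen_w),
                      rightmost.closed = FALSE)
  row <- findInterval(y, c(0, layout$screen_h / 3, 2 * layout$screen_h / 3, layout$screen_h),
                      rightmost.closed = FALSE)
  on <- col >= 1 & col <= 3 & row >= 1 & row <= 3
  corner <- rep(NA_character_, length(x))
  corner[on & row == 1 & col == 1] <- "tl"
  corner[on & row == 1 & col == 3] <- "tr"
  corner[on & row == 3 & col == 1] <- "bl"
  corner[on & row == 3 & col == 3] <- "br"
  inv_map <- stats::setNames(names(layout$role_map), layout$role_map)
  out <- rep("none", length(x))
  out[!is.na(corner)] <- inv_map[corner[!is.na(corner)]]
  out[on & row == 2 & col == 2] <- "center"
  out
}

#' Pixel centroid of a role's quadrant
#'
#' @param layout An [aoi_layout()].
#' @param role Role name, `"center"`, or a vector of these.
#' @return Two-column matrix of x, y centroids.
#' @export
aoi_centroid <- function(layout, role) {
  corner <- ifelse(role == "center", "cc", layout$role_map[role])
  cx <- c(tl = 1, tr = 5, bl = 1, br = 5, cc = 3)[corner] * layout$screen_w / 6
  cy <- c(tl = 1, tr = 1, bl = 5, br = 5, cc = 3)[corner] * layout$screen_h / 6
  cbind(x = unname(cx), y = unname(cy))
}

#' Fixation-proportion time curves with confidence bands
#'
#' For every time sample and grouping cell, computes the proportion of
#' trials whose gaze is on each role. The displayed proportion is the mean
#' of per-participant proportions, and the 95% confidence band is the
#' normal approximation over participant means (mean +/- 1.96 SE across
#' participants).
#'
#' @param samples Long tibble with columns `participant`, `trial_id`,
#'   `time_ms`, `aoi`, and any grouping columns.
#' @param roles Roles to report (default the four picture roles).
#' @param group Character vector of grouping column names (default
#'   `c("condition", "presentation")`; use `character()` for none).
#' @param conf Confidence level (default 0.95).
#' @return Tidy tibble: group columns, `time_ms`, `role`, `prop`, `ci_low`,
#'   `ci_high`, `n_participants`.
#' @export
proportion_curves <- function(samples,
                              roles = c("target", "competitor", "distractor_a", "distractor_b"),
                              group = c("condition", "presentation"),
                              conf = 0.95) {
  if (nrow(samples) == 0L) stop("no samples in at least one grouping cell", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- dplyr::bind_rows(lapply(roles, function(r) {
    samples |>
      dplyr::mutate(hit = as.integer(.data$aoi == r), role = r)
  }))
  per_part <- out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, "role", "time_ms", "participant")))) |>
    dplyr::summarise(p = mean(.data$hit), .groups = "drop")
  per_part |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group, "role", "time_ms")))) |>
    dplyr::summarise(
      prop = mean(.data$p),
      se = stats::sd(.data$p) / sqrt(dplyr::n()),
      n_participants = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se = ifelse(is.na(.data$se), 0, .data$se),
      ci_low = pmax(0, .data$prop - z * .data$se),
      ci_high = pmin(1, .data$prop + z * .data$se)
    ) |>
    dplyr::select(-"se")
}

#' Target/competitor crossover time
#'
#' The first time at which the target curve exceeds the competitor curve
#' and stays strictly above it for at least `persistence_ms` (or through the
#' end of the series, if less remains) — the point at which, on average, the
#' target has won lexical competition. Returns `NA` when the target never
#' persistently exceeds the competitor (identical curves have no crossover).
#'
#' @param time_ms Shared time base in ms.
#' @param target,competitor Proportion curves on that base.
#' @param persistence_ms Persistence window in ms (default 100).
#' @return Crossover time in ms, or `NA_real_`.
#' @export
crossover_time <- function(time_ms, target, competitor, persistence_ms = 100) {
  stopifnot(length(time_ms) == length(target), length(target) == length(competitor))
  n <- length(time_ms)
  if (n == 0L) return(NA_real_)
  step <- if (n > 1) stats::median(diff(time_ms)) else persistence_ms
  k <- max(1L, ceiling(persistence_ms / step))
  above <- target > competitor
  # forward run length of consecutive TRUE starting at each index
  run <- numeric(n)
  cnt <- 0
  for (i in n:1) { cnt <- if (above[i]) cnt + 1 else 0; run[i] <- cnt }
  ok <- which(run >= pmin(k, n - seq_len(n) + 1L) & above)
  if (length(ok) == 0L) return(NA_real_)
  time_ms[ok[1]]
}

#' Locally weighted display smoother
#'
#' Classical locally weighted linear regression with tricube weights over a
#' `span` fraction of the points (lowess, no robustness iterations). Used
#' only for display; smoothed curves never feed the statistics.
#'
#' @param time_ms Time base.
#' @param value Curve values.
#' @param span Span fraction in (0, 1\] (default 0.5).
#' @return Smoothed values on the same time base.
#' @export
smooth_curve <- function(time_ms, value, span = 0.5) {
  if (!(span > 0 && span <= 1)) stop("span must lie in (0, 1]", call. = FALSE)
  stats::lowess(time_ms, value, f = span, iter = 0)$y
}
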