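# programmatic fixtures: everything is built in code, nothing on disk

const_trace <- function(n = 500, pupil = 1000, rate = 250, x = 512, y = 384) {
  step <- 1000 / rate
  ocular_trace(t_ms = (seq_len(n) - 1) * step, x = rep(x, n), y = rep(y, n),
               pupil = rep(pupil, n), valid = TRUE, rate = rate)
}

with_gap <- function(trace, start_idx, len) {
  idx <- seq(start_idx, start_idx + len - 1L)
  trace$valid[idx] <- FALSE
  trace$pupil[idx] <- 0
  trace
}

correct_trial <- function() list(correct = TRUE, clicked_role = "target")

wrong_trial <- function() list(correct = FALSE, clicked_role = "competitor")

# pure tone as an audio_signal
tone <- function(freq, dur_s = 1, rate = 22050, amp = 1) {
  t <- seq(0, dur_s - 1 / rate, by = 1 / rate)
  audio_signal(amp * sin(2 * pi * freq * t), rate)
}

rms <- function(x) sqrt(mean(x^2))

# growth-curve simulator: participant random coefficients on all basis
# terms, optional condition effects on the intercept and linear term
sim_gca_data <- function(n_part, times = seq(200, 2000, 60),
                         beta0 = 5, bt = c(4, -2, 1),
                         cond_int = 0, cond_slope = 0,
                         re_sd = 1, sigma = 1) {
  order <- length(bt)
  b <- orthogonal_basis(times, order)
  X <- b$basis[match(times, b$times), -1, drop = FALSE]
  out <- vector("list", n_part)
  for (i in seq_len(n_part)) {
    u <- rnorm(order + 1, sd = re_sd)
    rows <- lapply(c("a", "b"), function(cond) {
      bc <- bt + u[-1]
      ic <- beta0 + u[1]
      if (cond == "b") { bc[1] <- bc[1] + cond_slope; ic <- ic + cond_int }
      tibble::tibble(participant = sprintf("p%02d", i), condition = cond,
                     time_ms = times,
                     y = as.numeric(ic + X %*% bc + rnorm(length(times), sd = sigma)))
    })
    out[[i]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}
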