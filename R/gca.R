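#' Orthonormal polynomial basis over a time grid
#'
#' Orthonormalizes the raw powers 1, t, t^2, ... over the observed grid
#' (QR-based, as in `stats::poly`), then prepends a constant column scaled
#' to unit norm, so the Gram matrix of the full basis is the identity. The
#' basis is built over the grid actually analyzed (e.g., 200-1800 ms for
#' fixations, 200-2000 ms for pupil dilation), not a canonical grid.
#'
#' The columns carry the usual growth-curve reading: intercept (area under
#' the curve), overall slope, width of the rise and fall around the
#' inflection (quadratic), steepness of the tails (cubic), and, at order 4,
#' a quartic term.
#'
#' @param times Numeric grid with at least `order + 1` distinct values.
#' @param order Polynomial order (4 for fixation curves, 3 for %ERPD).
#' @return Object of class `poly_basis`: `times` (sorted unique grid),
#'   `basis` (matrix, columns `ot0` ... `ot<order>`), `order`.
#' @export
orthogonal_basis <- function(times, order) {
  tu <- sort(unique(times))
  if (length(tu) < order + 1) stop("need at least order + 1 distinct time points", call. = FALSE)
  P <- stats::poly(tu, degree = order)
  B <- cbind(1 / sqrt(length(tu)), unclass(P)[, seq_len(order), drop = FALSE])
  colnames(B) <- paste0("ot", 0:order)
  structure(list(times = tu, basis = B, order = order), class = "poly_basis")
}

#' Attach basis columns to a data frame
#'
#' Joins the orthonormal basis columns `ot1` ... `ot<order>` (the intercept
#' is carried by the model's own intercept) onto `data` by time.
#'
#' @param data Data frame with a time column.
#' @param time Name of the time column (default `"time_ms"`).
#' @param order Polynomial order.
#' @return `data` with basis columns appended.
#' @export
add_basis_columns <- function(data, time = "time_ms", order = 4L) {
  b <- orthogonal_basis(data[[time]], order)
  idx <- match(data[[time]], b$times)
  for (j in seq_len(order)) data[[paste0("ot", j)]] <- b$basis[idx, j + 1L]
  data
}

# silence the (expected, harmless) boundary-fit chatter of small simulations
muffle_singular <- function(expr) {
  withCallingHandlers(expr, message = function(m) {
    if (grepl("singular|boundary", conditionMessage(m)))
      invokeRestart("muffleMessage")
  })
}

# boundary (singular) random-effect fits are converged fits at the edge of
# the variance parameter space, not optimizer failures
lme4_clean <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4)
  length(msgs) == 0 || all(grepl("singular|boundary", msgs, ignore.case = TRUE))
}

gca_formula <- function(response, order, factors, random, participant) {
  terms <- paste0("ot", seq_len(order))
  fixed <- paste(terms, collapse = " + ")
  if (length(factors) > 0) {
    fac <- paste(factors, collapse = " * ")
    fixed <- sprintf("(%s) * %s", fixed, fac)
  }
  rhs <- fixed
  if (random) rhs <- sprintf("%s + (1 + %s | %s)", rhs, paste(terms, collapse = " + "), participant)
  stats::as.formula(paste(response, "~", rhs))
}

#' Fit a growth-curve model
#'
#' Regresses a time course on orthonormal polynomial terms with, by
#' default, participant random coefficients on every term (fitted by
#' maximum likelihood via `lme4`; the logistic case uses the Laplace
#' approximation to the marginal likelihood). `family = "binomial"` models
#' per-sample binary fixation indicators with a logistic link;
#' `family = "gaussian"` models %ERPD with an identity link. Factors enter
#' interacting with every basis term. With `random = FALSE` the model
#' degenerates to ordinary least squares / plain logistic regression, which
#' is also the oracle the mixed fits are validated against.
#'
#' @param data Data frame with the response, a time column, factor columns,
#'   and a participant column.
#' @param response Name of the response column.
#' @param order Polynomial order (default 4).
#' @param factors Character vector of factor column names (default none).
#' @param family `"gaussian"` or `"binomial"`.
#' @param random Include participant random coefficients (default TRUE).
#' @param participant Name of the participant column (default
#'   `"participant"`).
#' @param time Name of the time column (default `"time_ms"`).
#' @param ... Passed on to `lme4::lmer` / `lme4::glmer`.
#' @return Object of class `gca_fit`: coefficient table, random-effect
#'   standard deviations, log-likelihood, parameter count, convergence
#'   flag, and the underlying model.
#' @export
fit_gca <- function(data, response, order = 4L, factors = character(),
                    family = c("gaussian", "binomial"), random = TRUE,
                    participant = "participant", time = "time_ms", ...) {
  family <- match.arg(family)
  data <- add_basis_columns(as.data.frame(data), time = time, order = order)
  form <- gca_formula(response, order, factors, random, participant)
  converged <- TRUE
  if (random) {
    fit <- muffle_singular(withCallingHandlers(
      if (family == "gaussian")
        lme4::lmer(form, data = data, REML = FALSE, ...)
      else
        lme4::glmer(form, data = data, family = stats::binomial(), ...),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) converged <<- FALSE
        invokeRestart("muffleWarning")
      }))
    if (!lme4_clean(fit)) converged <- FALSE
    co <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    re_sd <- attr(lme4::VarCorr(fit)[[participant]], "stddev")
  } else {
    fit <- if (family == "gaussian") stats::lm(form, data = data)
           else stats::glm(form, data = data, family = stats::binomial())
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    re_sd <- NULL
  }
  ll <- stats::logLik(fit)
  if (!is.finite(as.numeric(ll))) stop("model log-likelihood is not finite", call. = FALSE)
  structure(list(
    coefficients = tibble::tibble(term = names(co), estimate = unname(co), se = unname(se)),
    ranef_sd = re_sd,
    logLik = as.numeric(ll),
    n_params = attr(ll, "df"),
    converged = converged,
    family = family, order = order, factors = factors,
    formula = form, model = fit
  ), class = "gca_fit")
}

#' @export
print.gca_fit <- function(x, ...) {
  cat(sprintf("<gca_fit: order %d, %s link, logLik %.2f, %d params%s>\n",
              x$order, if (x$family == "gaussian") "identity" else "logit",
              x$logLik, x$n_params,
              if (x$converged) "" else ", NOT converged"))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Likelihood-ratio test between nested growth-curve fits
#'
#' chi^2 = 2 (logLik_big - logLik_small), clipped at zero; degrees of
#' freedom are the parameter-count difference; p from the chi-square upper
#' tail. The fits must be nested models of the same data.
#'
#' @param fit_small,fit_big `gca_fit` objects (or anything with `logLik`
#'   and `n_params` fields).
#' @return Tibble row: `chi_sq`, `df`, `p_value`, `model_small`,
#'   `model_big`.
#' @export
lrt_compare <- function(fit_small, fit_big) {
  chi <- max(0, 2 * (fit_big$logLik - fit_small$logLik))
  df <- fit_big$n_params - fit_small$n_params
  p <- if (df > 0) stats::pchisq(chi, df, lower.tail = FALSE) else if (chi == 0) 1 else NA_real_
  tibble::tibble(chi_sq = chi, df = df, p_value = p,
                 model_small = deparse1(fit_small$formula[[3]]),
                 model_big = deparse1(fit_big$formula[[3]]))
}

seq_formula <- function(response, order, blocks, random, participant) {
  terms <- paste0("ot", seq_len(order))
  rhs <- paste(terms, collapse = " + ")
  if (length(blocks) > 0) rhs <- paste(c(rhs, blocks), collapse = " + ")
  if (random) rhs <- sprintf("%s + (1 + %s | %s)", rhs, paste(terms, collapse = " + "), participant)
  stats::as.formula(paste(response, "~", rhs))
}

#' Default model-comparison ladder
#'
#' One block per curve term: the factor's effect on the intercept, then its
#' interaction with the slope, and so on up to `order`. With several
#' factors each block adds the joint factor expansion (main effects and
#' their interaction) for that term.
#'
#' @param order Polynomial order.
#' @param factors Character vector of factor names.
#' @return Character vector of fixed-effect blocks.
#' @export
gca_ladder <- function(order, factors) {
  fac <- paste0("(", paste(factors, collapse = " * "), ")")
  c(fac, paste0("ot", seq_len(order), ":", fac))
}

#' Sequential likelihood-ratio model comparison
#'
#' Starting from the basis-only model (with participant random coefficients
#' on all terms), adds each fixed-effect block of `ladder` in turn and
#' evaluates the change in fit with a likelihood-ratio test — the
#' growth-curve analogue of a sequential ANOVA table.
#'
#' @inheritParams fit_gca
#' @param ladder Character vector of fixed-effect blocks (see
#'   [gca_ladder()]); an empty ladder yields an empty table.
#' @return Tibble with one row per block: `block`, `chi_sq`, `df`,
#'   `p_value`, plus convergence flags of both fits.
#' @export
sequential_comparison <- function(data, response, ladder, order = 4L,
                                  family = c("gaussian", "binomial"),
                                  random = TRUE, participant = "participant",
                                  time = "time_ms", ...) {
  family <- match.arg(family)
  if (length(ladder) == 0L)
    return(tibble::tibble(block = character(), chi_sq = numeric(),
                          df = numeric(), p_value = numeric(), converged = logical()))
  data <- add_basis_columns(as.data.frame(data), time = time, order = order)
  fit_one <- function(blocks) {
    form <- seq_formula(response, order, blocks, random, participant)
    converged <- TRUE
    fit <- muffle_singular(withCallingHandlers(
      if (random) {
        if (family == "gaussian") lme4::lmer(form, data = data, REML = FALSE, ...)
        else lme4::glmer(form, data = data, family = stats::binomial(), ...)
      } else {
        if (family == "gaussian") stats::lm(form, data = data)
        else stats::glm(form, data = data, family = stats::binomial())
      },
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) converged <<- FALSE
        invokeRestart("muffleWarning")
      }))
    if (random && !lme4_clean(fit)) converged <- FALSE
    ll <- stats::logLik(fit)
    list(logLik = as.numeric(ll), n_params = attr(ll, "df"),
         formula = form, converged = converged)
  }
  prev <- fit_one(character())
  rows <- vector("list", length(ladder))
  for (i in seq_along(ladder)) {
    cur <- fit_one(ladder[seq_len(i)])
    lrt <- lrt_compare(prev, cur)
    rows[[i]] <- tibble::tibble(block = ladder[i], chi_sq = lrt$chi_sq,
                                df = lrt$df, p_value = lrt$p_value,
                                converged = prev$converged && cur$converged)
    prev <- cur
  }
  dplyr::bind_rows(rows)
}
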