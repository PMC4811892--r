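test_that("the orthonormal basis has identity Gram matrix and symmetry", {
  b <- orthogonal_basis(seq(200, 1800, 50), 4)
  expect_equal(ncol(b$basis), 5)
  expect_lt(max(abs(crossprod(b$basis) - diag(5))), 1e-10)

  b1 <- orthogonal_basis(seq(-10, 10, 2), 1)
  ramp <- b1$basis[, "ot1"]
  expect_equal(ramp, -rev(ramp))  # odd about the grid center

  expect_error(orthogonal_basis(c(1, 2, 3), 4), "distinct time points")
})

test_that("degenerate limits match OLS and direct-likelihood logistic oracles", {
  set.seed(61)
  times <- seq(200, 2000, 50)
  d <- tibble::tibble(participant = "p1", time_ms = rep(times, 3),
                      y = rnorm(3 * length(times)))
  f <- fit_gca(d, "y", order = 3, family = "gaussian", random = FALSE)
  db <- add_basis_columns(as.data.frame(d), order = 3)
  X <- cbind(1, as.matrix(db[, c("ot1", "ot2", "ot3")]))
  beta_ols <- solve(crossprod(X), crossprod(X, db$y))
  expect_lt(max(abs(f$coefficients$estimate - beta_ols)), 1e-6)

  # logistic: independent oracle by direct optimization of the binomial
  # log-likelihood on the same design
  eta_true <- X %*% c(-0.5, 2, -1, 0.5)
  d$z <- rbinom(nrow(d), 1, stats::plogis(eta_true))
  fl <- fit_gca(d, "z", order = 3, family = "binomial", random = FALSE)
  nll <- function(beta) {
    eta <- X %*% beta
    -sum(d$z * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, 4), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_lt(max(abs(fl$coefficients$estimate - opt$par)), 1e-4)
  expect_lt(abs(fl$logLik - (-opt$value)), 1e-6)
})

test_that("fits are invariant under affine rescaling of the time axis", {
  set.seed(62)
  d <- sim_gca_data(6, cond_int = 1, cond_slope = 1)
  d2 <- dplyr::mutate(d, time_ms = 3 * time_ms + 500)
  f1 <- fit_gca(d, "y", order = 3, factors = "condition", family = "gaussian")
  f2 <- fit_gca(d2, "y", order = 3, factors = "condition", family = "gaussian")
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(abs(f1$coefficients$estimate), abs(f2$coefficients$estimate),
               tolerance = 1e-4)
})

test_that("likelihood-ratio bookkeeping is exact", {
  set.seed(63)
  d <- sim_gca_data(6)
  f <- fit_gca(d, "y", order = 2, family = "gaussian")
  same <- lrt_compare(f, f)
  expect_equal(same$chi_sq, 0)
  expect_equal(same$df, 0)
  expect_equal(same$p_value, 1)

  f0 <- fit_gca(d, "y", order = 2, family = "gaussian")
  f1 <- fit_gca(d, "y", order = 2, factors = "condition", family = "gaussian")
  lrt <- lrt_compare(f0, f1)
  expect_equal(lrt$df, 3)  # condition main effect + 2 basis interactions
  expect_gte(lrt$chi_sq, 0)

  empty <- sequential_comparison(d, "y", character(), order = 2)
  expect_equal(nrow(empty), 0)
  lad <- sequential_comparison(d, "y", gca_ladder(2, "condition"), order = 2)
  expect_equal(nrow(lad), 3)
  expect_equal(lad$df, rep(1, 3))  # one two-level factor term per block
})

test_that("evidence for a true condition effect grows with participants", {
  chi_at <- function(n) {
    mean(vapply(1:3, function(r) {
      d <- sim_gca_data(n, cond_slope = 2)
      f0 <- fit_gca(d, "y", order = 2, family = "gaussian")
      f1 <- fit_gca(d, "y", order = 2, factors = "condition", family = "gaussian")
      lrt_compare(f0, f1)$chi_sq
    }, numeric(1)))
  }
  set.seed(64)
  expect_gt(chi_at(18), chi_at(6))
})

test_that("null condition coefficients stay within two standard errors", {
  set.seed(65)
  times <- seq(200, 2000, 60)
  inside <- replicate(60, {
    d <- sim_gca_data(10, times = times)
    f <- fit_gca(d, "y", order = 2, factors = "condition", family = "gaussian")
    co <- f$coefficients
    sel <- grepl("condition", co$term)
    abs(co$estimate[sel] / co$se[sel]) < 2
  })
  expect_gte(mean(inside), 0.9)
})

test_that("generated condition effects are recovered with the right signs", {
  set.seed(66)
  hits <- replicate(15, {
    d <- sim_gca_data(30, cond_int = 2, cond_slope = 3)
    co <- fit_gca(d, "y", order = 3, factors = "condition",
                  family = "gaussian")$coefficients
    c(co$estimate[co$term == "conditionb"] > 0,
      co$estimate[co$term == "ot1:conditionb"] > 0)
  })
  expect_gte(mean(hits), 0.95)
})
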