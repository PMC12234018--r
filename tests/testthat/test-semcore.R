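test_that("implied moments follow lambda^2 J + diag(resid)", {
  m0 <- implied_moments(list(loading = 0, means = c(0, 0, 0),
                             residual_variances = c(1, 1, 1)))
  expect_equal(m0$cov, diag(3))
  m1 <- implied_moments(list(loading = 1, means = c(0, 0, 0),
                             residual_variances = c(1, 1, 1)))
  expect_equal(m1$cov, matrix(1, 3, 3) + diag(3))
  m2 <- implied_moments(list(loading = 0.8, means = c(0, 0, 0),
                             residual_variances = rep(0.36, 3)))
  expect_equal(diag(m2$cov), rep(1, 3))
  expect_equal(m2$cov[1, 2], 0.64)
  expect_error(implied_moments(list(loading = 1, means = c(0, 0, 0),
                                    residual_variances = c(1, -1, 1))),
               "positive")
})

test_that("FIML log-likelihood matches closed forms at the mode", {
  fit <- list(loading = 0, means = c(0, 0, 0),
              residual_variances = c(1, 1, 1))
  row <- tibble::tibble(z_cognitive = 0, z_depression = 0, z_anxiety = 0)
  expect_equal(fiml_loglik(fit, row,
                           c("z_cognitive", "z_depression", "z_anxiety")),
               -1.5 * log(2 * pi), tolerance = 1e-12)
  row2 <- tibble::tibble(z_cognitive = 0, z_depression = 0,
                         z_anxiety = NA_real_)
  expect_equal(fiml_loglik(fit, row2,
                           c("z_cognitive", "z_depression", "z_anxiety")),
               -log(2 * pi), tolerance = 1e-12)
})

test_that("FIML equals the brute-force multivariate normal oracle", {
  inds <- c("z_cognitive", "z_depression", "z_anxiety")
  # complete data
  dat <- make_triplets(80, seed = 21)
  fit <- list(loading = 0.7, means = c(0.1, -0.2, 0.05),
              residual_variances = c(0.5, 0.4, 0.6))
  mom <- implied_moments(fit)
  expect_equal(fiml_loglik(fit, dat, inds),
               mvn_loglik_oracle(dat, mom$mean, mom$cov),
               tolerance = 1e-10)
  # with missingness: per-row marginalisation
  dat2 <- make_triplets(120, missing_rate = 0.4, seed = 22)
  expect_equal(fiml_loglik(fit, dat2, inds),
               mvn_loglik_oracle(dat2, mom$mean, mom$cov),
               tolerance = 1e-10)
})

test_that("rows with all indicators missing are rejected", {
  dat <- make_triplets(20, seed = 23)
  dat[3, ] <- NA_real_
  expect_error(fit_factor_model(dat), "all indicators missing")
})

test_that("duplicating the data doubles the log-likelihood, not the fit", {
  dat <- make_triplets(300, missing_rate = 0.3, seed = 24)
  f1 <- fit_factor_model(dat)
  f2 <- fit_factor_model(dplyr::bind_rows(dat, dat))
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
  expect_equal(f2$loading, f1$loading, tolerance = 1e-4)
  expect_equal(f2$residual_variances, f1$residual_variances,
               tolerance = 1e-4)
})

test_that("estimates are invariant under row permutation", {
  dat <- make_triplets(250, missing_rate = 0.3, seed = 25)
  perm <- withr::with_seed(1, sample(nrow(dat)))
  f1 <- fit_factor_model(dat)
  f2 <- fit_factor_model(dat[perm, ])
  expect_equal(f1$loading, f2$loading, tolerance = 1e-7)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-7)
})

test_that("the fitted likelihood dominates random parameter probes", {
  dat <- make_triplets(200, missing_rate = 0.35, seed = 26)
  fit <- fit_factor_model(dat)
  withr::with_seed(27, {
    for (i in 1:20) {
      probe <- list(loading = runif(1, 0, 1.5), means = rnorm(3, 0, 0.5),
                    residual_variances = runif(3, 0.1, 2))
      expect_gte(fit$loglik, fiml_loglik(probe, dat) - 1e-8)
    }
  })
})

test_that("the loading is reported on the nonnegative half-line and the
           likelihood is sign-invariant", {
  dat <- make_triplets(400, seed = 28)
  fit <- fit_factor_model(dat)
  expect_gte(fit$loading, 0)
  flip <- fit
  flip$loading <- -fit$loading
  expect_equal(fiml_loglik(flip, dat), fiml_loglik(fit, dat))
})

test_that("parameters are recovered from model-simulated data", {
  dat <- make_triplets(2000, lambda = 0.8, resid = rep(0.36, 3),
                       missing_rate = 0.35, seed = 29)
  fit <- fit_factor_model(dat)
  expect_true(fit$converged)
  expect_lt(abs(fit$loading - 0.8), 0.05)
  expect_true(all(abs(fit$residual_variances - 0.36) < 0.05))

  null <- make_triplets(2000, lambda = 0, resid = c(1, 1, 1), seed = 30)
  fit0 <- fit_factor_model(null)
  expect_lt(abs(fit0$loading), 0.05)
})

test_that("degenerate inputs are refused", {
  dat <- make_triplets(5, seed = 31)
  expect_error(fit_factor_model(dat), "at least 8 rows")
  flat <- tibble::tibble(z_cognitive = rep(1, 20),
                         z_depression = rnorm(20), z_anxiety = rnorm(20))
  expect_error(fit_factor_model(flat), "zero variance")
})

test_that("tidy and glance expose the 7 free parameters and fit summary", {
  dat <- make_triplets(100, seed = 32)
  fit <- fit_factor_model(dat)
  td <- tidy(fit)
  expect_equal(nrow(td), 7)
  gl <- glance(fit)
  expect_equal(gl$n, 100)
  expect_true(gl$converged)
  expect_equal(gl$n_free_params, 7L)
})
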