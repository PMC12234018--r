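# Shared fixtures and the independent multivariate-normal oracle.

# Indicator triplets drawn directly from the one-factor model on the z scale
# (no instrument mapping), for estimation-level tests.
make_triplets <- function(n, lambda = 0.8, resid = c(0.36, 0.36, 0.36),
                          means = c(0, 0, 0), missing_rate = 0, seed = 1) {
  withr::with_seed(seed, {
    eta <- rnorm(n)
    X <- sapply(1:3, function(k) {
      means[k] + lambda * eta + rnorm(n, 0, sqrt(resid[k]))
    })
    if (missing_rate > 0) X[runif(n) < missing_rate, 3] <- NA
    tibble::tibble(z_cognitive = X[, 1], z_depression = X[, 2],
                   z_anxiety = X[, 3])
  })
}

# Brute-force multivariate normal log-density, row by row, marginalising
# each row to its observed entries with base linear algebra. Deliberately
# independent of the package's sufficient-statistic FIML path.
mvn_loglik_oracle <- function(X, mu, Sigma) {
  X <- as.matrix(X)
  total <- 0
  for (i in seq_len(nrow(X))) {
    o <- which(!is.na(X[i, ]))
    k <- length(o)
    d <- X[i, o] - mu[o]
    S <- Sigma[o, o, drop = FALSE]
    total <- total - 0.5 * (k * log(2 * pi) +
                            determinant(S, logarithm = TRUE)$modulus +
                            drop(t(d) %*% solve(S) %*% d))
  }
  as.numeric(total)
}

# Small planted-cutpoint cohort, preprocessed.
make_cohort_data <- function(n = 600, cutpoints = 4,
                             means = c(-1, 1), seed = 1, ...) {
  coh <- generate_cohort(cohort_spec(n_patients = n,
                                     true_cutpoints = cutpoints,
                                     group_latent_means = means,
                                     seed = seed, ...))
  preprocess_cohort(coh)
}

# Hand-built 20-record fixture for the exclusion rules: 14 clean records,
# 3 missing all measures, 2 with Global < 0.5 in residential/PHP care,
# 1 with no core diagnostic indicators.
make_exclusion_fixture <- function() {
  clean <- tibble::tibble(
    id = sprintf("C%02d", 1:14),
    stratum = rep(c("residential", "php", "outpatient"), length.out = 14),
    edeq_global_wo = seq(0.6, 5.8, length.out = 14),
    depression_total = 20, anxiety_total = 8,
    binge_28d = 4, vomit_28d = 5, laxdiur_28d = 0, exercise_28d = 2
  )
  # outpatient record with Global below 0.5 must be retained (rule 2 only
  # applies in residential/PHP care)
  clean$edeq_global_wo[3] <- 0.4
  clean$stratum[3] <- "outpatient"

  all_missing <- tibble::tibble(
    id = sprintf("M%02d", 1:3), stratum = "residential",
    edeq_global_wo = NA_real_, depression_total = NA_real_,
    anxiety_total = NA_real_, binge_28d = NA_real_, vomit_28d = NA_real_,
    laxdiur_28d = NA_real_, exercise_28d = NA_real_
  )
  low_global <- tibble::tibble(
    id = c("L01", "L02"), stratum = c("residential", "php"),
    edeq_global_wo = 0.4, depression_total = 15, anxiety_total = 5,
    binge_28d = 3, vomit_28d = 2, laxdiur_28d = 0, exercise_28d = 1
  )
  no_core <- tibble::tibble(
    id = "N01", stratum = "outpatient", edeq_global_wo = 2.5,
    depression_total = 10, anxiety_total = 4,
    binge_28d = 0, vomit_28d = 0, laxdiur_28d = NA_real_, exercise_28d = 0
  )
  dplyr::bind_rows(clean, all_missing, low_global, no_core)
}
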