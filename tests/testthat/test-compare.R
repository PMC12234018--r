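test_that("Levene statistic behaves at the boundaries and on clear spread
           differences", {
  same <- levene_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # hand ANOVA on absolute deviations: within-SS zero, F unbounded
  diff <- levene_test(c(0, 0, 0, 0, -5, 5, -5, 5),
                      rep(c("a", "b"), each = 4))
  expect_gt(diff$statistic, 100)
  expect_lt(diff$p, 1e-6)
  expect_error(levene_test(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("Levene p-values are approximately uniform under the null", {
  withr::with_seed(71, {
    y <- rnorm(100)
    ps <- sapply(1:500, function(i) {
      g <- sample(rep(c("a", "b"), each = 50))
      levene_test(y, g)$p
    })
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  })
})

test_that("the classical one-way F matches the hand sums-of-squares fixture", {
  res <- severity_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3),
                        welch = "never")
  # two groups: reported as t; t^2 = F = 1.5
  expect_equal(res$statistic^2, 1.5, tolerance = 1e-12)
  expect_equal(res$f_classical, 1.5, tolerance = 1e-12)
  expect_equal(res$partial_eta_sq, 0.2727, tolerance = 1e-3)
  expect_equal(res$partial_eta_sq, 1.5 / 5.5, tolerance = 1e-12)
})

test_that("F equals t-squared for two groups and eta-squared equals the
           group-indicator R-squared", {
  withr::with_seed(72, {
    y <- c(rnorm(20), rnorm(25, 0.8))
    g <- rep(c("a", "b"), c(20, 25))
    res <- severity_anova(y, g, welch = "never")
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(res$f_classical, unname(tt$statistic)^2, tolerance = 1e-10)
    r2 <- summary(stats::lm(y ~ g))$r.squared
    expect_equal(res$partial_eta_sq, r2, tolerance = 1e-10)
  })
})

test_that("Welch F coincides with classical F under exactly equal variances
           and sizes", {
  # exact identity for two groups with identical spread and equal n;
  # for K > 2 the Welch denominator correction differs from 1 even then
  base <- c(-1.2, -0.3, 0, 0.4, 1.1, -0.8, 0.9, -0.1)
  y <- c(base, base + 2)
  g <- rep(c("a", "b"), each = length(base))
  res <- severity_anova(y, g, welch = "never")
  expect_equal(res$f_welch, res$f_classical, tolerance = 1e-10)
  expect_equal(res$p_welch, res$p_classical, tolerance = 1e-10)
})

test_that("a 10-SD shifted group is detected; null F is centered near 1", {
  withr::with_seed(73, {
    y <- c(rnorm(30), rnorm(30), rnorm(30) + 10)
    g <- rep(c("a", "b", "c"), each = 30)
    expect_lt(severity_anova(y, g)$p, 1e-6)
    fs <- sapply(1:50, function(i) {
      severity_anova(rnorm(60), rep(c("a", "b", "c"), 20),
                     welch = "never")$f_classical
    })
    expect_gt(mean(fs), 0.6)
    expect_lt(mean(fs), 1.6)
  })
})

test_that("empty declared groups are refused by name", {
  g <- factor(c("a", "a", "b", "b"), levels = c("a", "b", "c"))
  expect_error(severity_anova(c(1, 2, 3, 4), g), "c")
})

test_that("contrast coefficients sum to zero and are pairwise orthogonal", {
  for (K in 2:6) {
    C <- contrast_coefficients(K)
    expect_equal(nrow(C), K - 1)
    expect_true(all(abs(rowSums(C)) < 1e-12))
    G <- C %*% t(C)
    expect_true(all(abs(G[upper.tri(G)]) < 1e-12))
  }
  expect_equal(contrast_coefficients(5)[1, ], c(4, -1, -1, -1, -1))
  expect_error(contrast_coefficients(1), "at least 2")
})

test_that("contrast estimates match hand-computed pooled-mean differences", {
  withr::with_seed(74, {
    y <- c(0, 0, 0, 1, 1, 1, 2, 2, 2) + rnorm(9, 0, 1e-6)
    g <- factor(rep(1:3, each = 3))
    pc <- planned_contrasts(y, g, welch = "never")
    expect_equal(nrow(pc), 2)
    expect_equal(pc$estimate[1], 0 - mean(c(1, 2)), tolerance = 1e-4)
    expect_equal(pc$estimate[2], 1 - 2, tolerance = 1e-4)
    expect_true(all(vapply(pc$coefficients, sum, numeric(1)) == 0))
  })
})

test_that("under equal n the contrast sums of squares add to the
           between-group SS", {
  withr::with_seed(75, {
    y <- rnorm(40, rep(c(0, 0.5, 1, 3), each = 10))
    g <- factor(rep(1:4, each = 10))
    pc <- planned_contrasts(y, g, welch = "never")
    means <- tapply(y, g, mean)
    vars <- tapply(y, g, var)
    mse <- sum(9 * vars) / 36
    ss_contrasts <- sum(pc$t^2 * mse)
    ssb <- sum(10 * (means - mean(y))^2)
    expect_equal(ss_contrasts, ssb, tolerance = 1e-10)
  })
})

test_that("two equal groups give d near zero", {
  withr::with_seed(76, {
    y <- rnorm(60)
    g <- factor(rep(1:2, 30))
    pc <- planned_contrasts(y, g)
    expect_lt(abs(pc$cohens_d), 0.5)
    expect_gt(pc$p, 0.001)
  })
})

test_that("scheme-defining characteristics are excluded from comparisons", {
  expect_true(exclusion_of_defining_characteristic("dsm5",
                                                   "comp_freq_weekly"))
  expect_false(exclusion_of_defining_characteristic("semtree",
                                                    "z_depression"))
  expect_true(exclusion_of_defining_characteristic("clinical_overvaluation",
                                                   "overvaluation"))
  expect_error(exclusion_of_defining_characteristic("astrology", "anything"),
               "unknown scheme")
})

test_that("variance summaries aggregate eta-squared and form mean ratios", {
  res <- tibble::tibble(
    scheme = c("a", "a", "b", "b"),
    characteristic = c("x", "y", "x", "y"),
    partial_eta_sq = c(0.1, 0.3, 0.05, 0.05)
  )
  vs <- variance_summary(res)
  expect_equal(vs$by_scheme$mean[vs$by_scheme$scheme == "a"], 0.2)
  expect_equal(vs$by_scheme$min[vs$by_scheme$scheme == "a"], 0.1)
  expect_equal(vs$by_scheme$max[vs$by_scheme$scheme == "a"], 0.3)
  ratio <- vs$ratios$ratio[vs$ratios$scheme_a == "a" &
                             vs$ratios$scheme_b == "b"]
  expect_equal(ratio, 4)
  expect_error(variance_summary(res[0, ]), "no comparison results")
})

test_that("compare_schemes runs the full grid and respects exclusions", {
  dat <- make_cohort_data(n = 800, cutpoints = c(1.25, 3.75, 4.75, 5.75),
                          means = c(-1.2, -0.6, 0, 0.6, 1.2), seed = 77)
  asg <- assign_schemes(dat)
  cmp <- compare_schemes(dat, asg)
  expect_s3_class(cmp, "scheme_comparison")
  # the defining characteristic never appears for its scheme
  expect_false(any(cmp$anova$scheme == "dsm5" &
                     cmp$anova$characteristic == "comp_freq_weekly"))
  expect_false(any(cmp$anova$scheme == "semtree" &
                     cmp$anova$characteristic == "overvaluation"))
  expect_true(all(cmp$anova$partial_eta_sq >= 0 &
                    cmp$anova$partial_eta_sq <= 1))
  # strong planted overvaluation structure: semtree explains depression well
  eta <- cmp$anova$partial_eta_sq[cmp$anova$scheme == "semtree" &
                                    cmp$anova$characteristic ==
                                    "z_depression"]
  expect_gt(eta, 0.1)
  vs <- variance_summary(cmp)
  expect_setequal(vs$by_scheme$scheme,
                  c("semtree", "dsm5", "clinical_overvaluation",
                    "purging_count"))
})
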