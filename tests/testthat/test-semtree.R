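test_that("candidate thresholds are midpoints of distinct values, thinned", {
  mids <- severitree:::candidate_thresholds(c(1, 2, 2, 4))
  expect_equal(mids, c(1.5, 3))
  expect_length(severitree:::candidate_thresholds(rep(3, 10)), 0)
  thin <- severitree:::candidate_thresholds(1:101, max_candidates = 10)
  expect_lte(length(thin), 10)
  expect_true(all(thin %in% (1:100 + 0.5)))
})

test_that("the LR statistic is nonnegative and null-calibrated", {
  inds <- c("z_cognitive", "z_depression", "z_anxiety")
  lrs <- sapply(1:50, function(s) {
    dat <- make_triplets(800, missing_rate = 0.35, seed = 400 + s)
    dat$x <- withr::with_seed(500 + s, runif(800))
    evaluate_split(dat, "x", stats::median(dat$x), tree_config(),
                   inds)$lr
  })
  expect_true(all(lrs >= 0))
  # children share the parent distribution: LR is central chi-square(7)
  expect_gt(mean(lrs), 5.0)
  expect_lt(mean(lrs), 9.0)
  expect_gt(stats::median(lrs), 4.0)
  expect_lt(stats::median(lrs), 8.8)
})

test_that("a split separating planted groups is overwhelmingly significant", {
  dat <- make_cohort_data(n = 500, cutpoints = 4, means = c(-1, 1),
                          seed = 41)
  sp <- evaluate_split(dat, "overvaluation", 3.75)
  expect_true(sp$feasible)
  expect_gt(sp$lr, 50)
  expect_lt(sp$p, 1e-6)
  expect_equal(sp$n_left + sp$n_right, nrow(dat))
})

test_that("infeasible candidates are flagged, not fitted", {
  dat <- make_cohort_data(n = 200, seed = 42)
  sp <- evaluate_split(dat, "overvaluation", min(dat$overvaluation) + 0.01)
  expect_false(sp$feasible)
  expect_true(is.na(sp$lr))
})

test_that("fair selection with a single feasible candidate ignores the seed", {
  dat <- make_cohort_data(n = 400, cutpoints = 4, means = c(-1.5, 1.5),
                          seed = 43)
  dat$binary <- as.numeric(dat$overvaluation >= 4)  # one midpoint only
  res <- lapply(c(1, 99, 1234), function(s) {
    set.seed(s)
    fair_split_search(dat, "binary", tree_config())
  })
  expect_equal(res[[1]]$value, res[[2]]$value)
  expect_equal(res[[1]]$value, res[[3]]$value)
  expect_equal(res[[1]]$covariate, "binary")
})

test_that("fair selection recovers a planted overvaluation cutpoint", {
  hits <- 0
  for (s in 1:5) {
    dat <- make_cohort_data(n = 1000, cutpoints = 4, means = c(-1, 1),
                            seed = 600 + s)
    set.seed(s)
    sc <- fair_split_search(dat, c("overvaluation", "comp_freq_28d"))
    if (!is.null(sc) && sc$covariate == "overvaluation" &&
        abs(sc$value - 4) <= 0.25) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("grown trees partition the sample and improve the likelihood", {
  dat <- make_cohort_data(n = 1000, cutpoints = 4, means = c(-1, 1),
                          seed = 45)
  tr <- grow_tree(dat, c("overvaluation", "comp_freq_28d"),
                  tree_config(seed = 8))
  expect_s3_class(tr, "sem_tree")
  expect_gte(tr$n_leaves, 2)
  labels <- assign_leaf(tr, dat)
  expect_false(any(is.na(labels)))          # covariates complete here
  expect_equal(length(labels), nrow(dat))
  expect_equal(sort(unique(labels)), seq_len(tr$n_leaves))
  gl <- glance(tr)
  expect_gt(gl$loglik_leaves, gl$loglik_root)
  # leaf counts sum to the routable rows
  nodes <- severitree:::tree_nodes(tr)
  expect_equal(sum(nodes$n[nodes$is_leaf]), nrow(dat))
})

test_that("identical seed and data give byte-identical serializations", {
  dat <- make_cohort_data(n = 600, cutpoints = 4, means = c(-1, 1),
                          seed = 46)
  t1 <- grow_tree(dat, c("overvaluation", "comp_freq_28d"),
                  tree_config(seed = 5))
  t2 <- grow_tree(dat, c("overvaluation", "comp_freq_28d"),
                  tree_config(seed = 5))
  expect_identical(serialize_tree(t1), serialize_tree(t2))
  t3 <- grow_tree(dat, c("overvaluation", "comp_freq_28d"),
                  tree_config(seed = 6))
  expect_s3_class(t3, "sem_tree")  # different seed still a valid tree
})

test_that("degenerate inputs give a single leaf or an error", {
  dat <- make_cohort_data(n = 200, seed = 47)
  dat$overvaluation <- 3     # no distinct values: no candidates
  dat$comp_freq_28d <- 10
  tr <- grow_tree(dat, c("overvaluation", "comp_freq_28d"),
                  tree_config(seed = 1))
  expect_equal(tr$n_leaves, 1)
  expect_error(grow_tree(dat[0, ], "overvaluation"), "empty")
})

test_that("routing sends the boundary value right and missing to NA", {
  dir <- withr::local_tempdir()
  js <- file.path(dir, "tree.json")
  jsonlite::write_json(list(covariate = "overvaluation", thresholds = 4),
                       js, auto_unbox = TRUE)
  tr <- reference_tree(js)
  dat <- tibble::tibble(overvaluation = c(3.5, 4, NA))
  expect_warning(labs <- assign_leaf(tr, dat), "unassigned")
  expect_equal(labs, c(1L, 2L, NA))
})

test_that("under the null almost no split is retained", {
  retained <- 0
  for (s in 1:20) {
    coh <- generate_cohort(cohort_spec(n_patients = 400,
                                       true_cutpoints = numeric(0),
                                       group_latent_means = 0,
                                       seed = 700 + s))
    dat <- preprocess_cohort(coh)
    tr <- grow_tree(dat, c("overvaluation", "comp_freq_28d"),
                    tree_config(seed = s))
    if (tr$n_leaves > 1) retained <- retained + 1
  }
  expect_lte(retained / 20, 0.25)  # loose gate; the tight one is 200 seeds
})
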