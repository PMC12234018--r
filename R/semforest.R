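#' Forest configuration
#'
#' @param n_trees Number of trees (the analysis design uses 100).
#' @param vars_per_split Covariates drawn uniformly at random as the
#'   candidate set at each node (the analysis design compares one variable
#'   per split).
#' @param resampling `"bootstrap"` (size-n resample with replacement,
#'   out-of-bag rows tracked per tree) or `"none"` (every tree sees the full
#'   sample; useful only for degenerate checks).
#' @param tree_config A [tree_config()]; its `seed` is ignored -- per-tree
#'   seeds are derived from `seed`.
#' @param seed Integer seed making the whole forest reproducible.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 100, vars_per_split = 1,
                          resampling = c("bootstrap", "none"),
                          tree_config = severitree::tree_config(),
                          seed = 1L) {
  if (n_trees < 1) abort("n_trees must be >= 1")
  if (vars_per_split < 1) abort("vars_per_split must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 vars_per_split = as.integer(vars_per_split),
                 resampling = match.arg(resampling),
                 tree_config = tree_config, seed = as.integer(seed)),
            class = "forest_config")
}

#' Grow an SEM forest
#'
#' Grows `n_trees` SEM trees, each on a bootstrap resample of the cohort,
#' with `vars_per_split` covariates drawn uniformly at random as the
#' candidate set at every node. Out-of-bag row indices are stored per tree
#' for permutation importance. Deterministic given the config seed.
#'
#' @inheritParams grow_tree
#' @param config A [forest_config()].
#' @return A `sem_forest`: trees, out-of-bag index lists, per-tree seeds.
#' @export
grow_forest <- function(data, covariates, config = forest_config(),
                        indicators = c("z_cognitive", "z_depression",
                                       "z_anxiety")) {
  if (config$vars_per_split > length(covariates)) {
    abort("vars_per_split exceeds the number of covariates")
  }
  n <- nrow(data)
  set.seed(config$seed)
  tree_seeds <- sample.int(.Machine$integer.max, config$n_trees)

  tcfg <- config$tree_config
  tcfg$seed <- NULL  # per-tree stream is seeded below

  trees <- vector("list", config$n_trees)
  oob <- vector("list", config$n_trees)
  for (i in seq_len(config$n_trees)) {
    set.seed(tree_seeds[i])
    idx <- if (config$resampling == "bootstrap") {
      sample.int(n, n, replace = TRUE)
    } else {
      seq_len(n)
    }
    oob[[i]] <- setdiff(seq_len(n), idx)
    trees[[i]] <- grow_tree(data[idx, , drop = FALSE], covariates, tcfg,
                            indicators,
                            vars_per_split = config$vars_per_split)
  }
  structure(list(trees = trees, oob = oob, tree_seeds = tree_seeds,
                 covariates = covariates, indicators = indicators,
                 config = config, n = n),
            class = "sem_forest")
}

#' @export
print.sem_forest <- function(x, ...) {
  nl <- vapply(x$trees, function(t) t$n_leaves, integer(1))
  cat("<sem_forest>", length(x$trees), "trees on", x$n, "records;",
      "leaves per tree:", paste(range(nl), collapse = "-"), "\n")
  invisible(x)
}

#' Out-of-bag permutation importance
#'
#' For each tree and covariate, the importance contribution is the increase
#' in -2 log-likelihood over the tree's out-of-bag rows when the
#' covariate's values are permuted before routing the rows through the tree
#' (leaf models stay fixed): permuted minus intact summed leaf -2LL,
#' averaged over `n_perm` permutations. The table reports, per covariate,
#' the contributions summed across all trees (mean contribution scaled by
#' the number of trees), in -2 log-likelihood units. A covariate never used
#' at any split of a tree leaves routing unchanged, so its contribution
#' from that tree is exactly zero.
#'
#' @param forest A `sem_forest` grown with out-of-bag tracking.
#' @param data The cohort the forest was grown on.
#' @param n_perm Permutations per tree and covariate.
#' @param seed Seed for the permutations; defaults to the forest seed + 1.
#' @return Tibble `covariate`, `importance`, `rank`, with the per-tree
#'   contribution matrix in attribute `"per_tree"`.
#' @export
variable_importance <- function(forest, data, n_perm = 1, seed = NULL) {
  covs <- forest$covariates
  set.seed(seed %||% (forest$config$seed + 1L))
  per_tree <- matrix(0, nrow = length(forest$trees), ncol = length(covs),
                     dimnames = list(NULL, covs))

  for (i in seq_along(forest$trees)) {
    tree <- forest$trees[[i]]
    oob_idx <- forest$oob[[i]]
    if (length(oob_idx) == 0) next
    od <- data[oob_idx, , drop = FALSE]
    od <- od[complete.cases(od[, covs, drop = FALSE]), , drop = FALSE]
    if (nrow(od) == 0) next

    used <- stats::na.omit(tree_nodes(tree)$covariate)
    base <- tree_neg2ll(tree, od)
    for (cv in sort(covs)) {  # name order: invariant to column order
      if (!cv %in% used) next  # routing unchanged: exact zero
      acc <- 0
      for (r in seq_len(n_perm)) {
        perm <- sample.int(nrow(od))
        pd <- od
        pd[[cv]] <- pd[[cv]][perm]
        acc <- acc + (tree_neg2ll(tree, pd) - base)
      }
      per_tree[i, cv] <- acc / n_perm
    }
  }

  total <- unname(colSums(per_tree))
  out <- tibble::tibble(
    covariate = covs,
    importance = total,
    rank = rank(-total, ties.method = "min")
  )
  attr(out, "per_tree") <- per_tree
  out
}

#' Covariates offered across forest nodes
#'
#' Counts, over every splittable node of every tree, how often each
#' covariate appeared in the node's randomly drawn candidate set.
#'
#' @param forest A `sem_forest`.
#' @return Tibble `covariate`, `times_offered`, `n_nodes`.
#' @export
offered_covariates <- function(forest) {
  offers <- unlist(lapply(forest$trees, function(tr) {
    unlist(tree_nodes(tr)$offered)
  }))
  n_nodes <- sum(vapply(forest$trees, function(tr) nrow(tree_nodes(tr)),
                        numeric(1)))
  counts <- table(factor(offers, levels = forest$covariates))
  tibble::tibble(covariate = forest$covariates,
                 times_offered = as.integer(counts),
                 n_nodes = as.integer(n_nodes))
}

#' @rdname variable_importance
#' @param x A `sem_forest`.
#' @param ... Unused.
#' @export
tidy.sem_forest <- function(x, ...) {
  nl <- vapply(x$trees, function(t) t$n_leaves, integer(1))
  tibble::tibble(tree = seq_along(x$trees), n_leaves = nl,
                 n_oob = lengths(x$oob))
}

#' Plot covariate importances
#'
#' @param object The tibble returned by [variable_importance()].
#' @param ... Unused.
#' @return A ggplot bar chart of importance in -2 log-likelihood units.
#' @export
plot_importance <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$covariate,
                                                  .data$importance),
                               y = .data$importance)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "importance (-2 log-likelihood units)",
                  title = "SEM forest covariate importance")
}
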