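#' Tree-growing configuration
#'
#' @param min_node_size Minimum rows per child node (default 30, on the
#'   order of the smallest severity group the method is expected to
#'   resolve). Must be at least 8 so every node model is estimable.
#' @param alpha Significance level for retaining a split.
#' @param bonferroni Correct the split p-value for the number of covariates
#'   evaluated at the node? The fair criterion already controls the
#'   per-covariate threshold-selection optimism.
#' @param max_candidates Cap on candidate thresholds per covariate and node.
#'   Candidates are midpoints between consecutive distinct observed values;
#'   when a count covariate offers more than `max_candidates` midpoints an
#'   evenly spaced (quantile-like) subset is scanned instead.
#' @param max_depth Maximum number of splits on any root-to-leaf path
#'   (`Inf` for no limit).
#' @param seed Integer seed consumed by [grow_tree()] (the fair criterion's
#'   random halving); `NULL` uses the current RNG state.
#' @param confirm Reference distribution for the deciding confirmation
#'   test: `"bootstrap"` (default) screens with the chi-square(7) test and
#'   then verifies borderline retentions against a parametric bootstrap of
#'   the confirmation statistic under the fitted parent model, which stays
#'   calibrated where the asymptotic chi-square is anticonservative (small
#'   child nodes); `"chisq"` uses the asymptotic reference alone.
#' @param n_boot Parametric-bootstrap replicates for the confirmation test.
#' @return A `tree_config` list.
#' @export
tree_config <- function(min_node_size = 30, alpha = 0.05, bonferroni = TRUE,
                        max_candidates = 24, max_depth = Inf, seed = NULL,
                        confirm = c("bootstrap", "chisq"), n_boot = 59) {
  if (min_node_size < 8) {
    abort("min_node_size must be >= 8 (free parameters + 1)")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  structure(list(min_node_size = min_node_size, alpha = alpha,
                 bonferroni = bonferroni, max_candidates = max_candidates,
                 max_depth = max_depth, seed = seed,
                 confirm = match.arg(confirm), n_boot = n_boot),
            class = "tree_config")
}

# Midpoints between consecutive distinct observed values, thinned to at most
# max_candidates by even index spacing.
candidate_thresholds <- function(x, max_candidates = Inf) {
  ux <- sort(unique(x[!is.na(x)]))
  if (length(ux) < 2) return(numeric(0))
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  if (length(mids) > max_candidates) {
    keep <- unique(round(seq(1, length(mids), length.out = max_candidates)))
    mids <- mids[keep]
  }
  mids
}

#' Evaluate one candidate split
#'
#' Fits the one-factor model separately in the two children defined by
#' `covariate < value` (left) versus `>= value` (right), and on their union,
#' all restricted to rows with a nonmissing covariate. The improvement is
#' the likelihood-ratio statistic `lr = 2 (LL_left + LL_right - LL_parent)`
#' with a chi-square reference on 7 degrees of freedom (both children
#' re-estimate the full parameter vector).
#'
#' @inheritParams fit_factor_model
#' @param covariate Covariate column name.
#' @param value Threshold; the threshold itself routes right.
#' @param config A [tree_config()].
#' @return One-row tibble: `covariate`, `value`, `lr`, `p`, `n_left`,
#'   `n_right`, `feasible`. Candidates leaving a child below
#'   `min_node_size` are returned infeasible with `lr = NA`.
#' @export
evaluate_split <- function(data, covariate, value, config = tree_config(),
                           indicators = c("z_cognitive", "z_depression",
                                          "z_anxiety")) {
  x <- data[[covariate]]
  keep <- !is.na(x)
  left <- keep & x < value
  right <- keep & x >= value
  n_l <- sum(left); n_r <- sum(right)
  if (n_l < config$min_node_size || n_r < config$min_node_size) {
    return(tibble::tibble(covariate = covariate, value = value, lr = NA_real_,
                          p = NA_real_, n_left = n_l, n_right = n_r,
                          feasible = FALSE))
  }
  parent <- fit_factor_model(data[keep, , drop = FALSE], indicators)
  fl <- fit_factor_model(data[left, , drop = FALSE], indicators)
  fr <- fit_factor_model(data[right, , drop = FALSE], indicators)
  lr <- max(0, 2 * (fl$loglik + fr$loglik - parent$loglik))
  tibble::tibble(covariate = covariate, value = value, lr = lr,
                 p = pchisq(lr, df = 7, lower.tail = FALSE),
                 n_left = n_l, n_right = n_r, feasible = TRUE)
}

# Parametric bootstrap of the confirmation-half likelihood-ratio statistic
# under the null that both children share the fitted parent model. Each
# replicate redraws the half's indicator rows from the parent's implied
# normal (keeping every row's missingness mask and split side fixed) and
# refits parent and children. Retention requires the observed statistic to
# be extreme among the replicates at the Bonferroni-adjusted level; the
# loop stops as soon as retention is impossible.
confirm_split_bootstrap <- function(d2, covariate, value, lr_obs, k, config,
                                    indicators) {
  x <- d2[[covariate]]
  keep <- !is.na(x)
  dd <- d2[keep, , drop = FALSE]
  left <- dd[[covariate]] < value
  X <- indicator_matrix(dd, indicators)
  mask <- is.na(X)
  parent <- fit_core(X)
  if (is.null(parent)) return(TRUE)  # cannot simulate; fall back to screen
  theta <- parent$par
  mu <- theta[2:4]
  Sigma <- theta[1]^2 * matrix(1, 3, 3) + diag(exp(theta[5:7]))
  Lc <- chol(Sigma)
  nh <- nrow(X)
  B <- config$n_boot
  # largest exceedance count that still allows k * (1+e)/(B+1) < alpha
  e_max <- ceiling(config$alpha * (B + 1) / k - 1) - 1
  if (e_max < 0) e_max <- 0
  exceed <- 0
  for (b in seq_len(B)) {
    Z <- matrix(rnorm(nh * 3), nh, 3) %*% Lc
    Z <- sweep(Z, 2, mu, "+")
    Z[mask] <- NA
    op <- fit_core(Z, theta)
    ol <- fit_core(Z[left, , drop = FALSE], theta)
    or <- fit_core(Z[!left, , drop = FALSE], theta)
    if (is.null(op) || is.null(ol) || is.null(or)) next
    lr_b <- max(0, 2 * (-ol$value - or$value + op$value))
    if (lr_b >= lr_obs) {
      exceed <- exceed + 1
      if (exceed > e_max) return(FALSE)
    }
  }
  TRUE
}

# Scan many thresholds on one covariate, reusing the previous candidate's
# child estimates as warm starts. `parent_ll` is the fitted log-likelihood
# of the rows with nonmissing covariate. Returns lr per candidate.
scan_thresholds <- function(data, x, candidates, parent_ll, min_child,
                            indicators) {
  lrs <- rep(NA_real_, length(candidates))
  start_l <- start_r <- NULL
  for (i in seq_along(candidates)) {
    v <- candidates[i]
    left <- !is.na(x) & x < v
    right <- !is.na(x) & x >= v
    if (sum(left) < min_child || sum(right) < min_child) next
    fl <- fit_factor_model(data[left, , drop = FALSE], indicators,
                           start = start_l)
    fr <- fit_factor_model(data[right, , drop = FALSE], indicators,
                           start = start_r)
    start_l <- list(loading = fl$loading, means = fl$means,
                    residual_variances = fl$residual_variances)
    start_r <- list(loading = fr$loading, means = fr$means,
                    residual_variances = fr$residual_variances)
    lrs[i] <- max(0, 2 * (fl$loglik + fr$loglik - parent_ll))
  }
  lrs
}

#' Fair split selection at one node
#'
#' Implements the fair criterion, which controls for covariates' differing
#' numbers of response options: (1) the node's rows are randomly halved;
#' (2) in the first half, every candidate threshold of every offered
#' covariate is evaluated and each covariate's best value is kept; (3) each
#' covariate's selected value is then re-evaluated in the second half;
#' (4) the covariate with the largest second-half improvement wins. The
#' retention decision uses the second-half statistic: because its threshold
#' was selected on the independent first half, it is a valid chi-square(7)
#' likelihood-ratio test, Bonferroni-corrected (optionally) for the number
#' of covariates in play. (5) The winning (covariate, value) pair is then
#' re-assessed on the full node sample, whose likelihood-ratio statistic
#' and p-value are the ones reported at the node; deciding on the full
#' node would re-use the selection half and inflate the type-I error.
#'
#' Uses the current RNG state for the halving; seed via [tree_config()] /
#' [grow_tree()] or `set.seed()` for reproducibility.
#'
#' @inheritParams evaluate_split
#' @param covariates Covariate column names offered at this node.
#' @return One-row tibble for the selected split -- `covariate`, `value`,
#'   full-node `lr` and `p`, confirmation-half `lr_confirm` / `p_confirm`,
#'   the Bonferroni-corrected deciding `p_adj`, `n_left`, `n_right`,
#'   `n_covariates` -- or `NULL` when no candidate is feasible or
#'   significant.
#' @export
fair_split_search <- function(data, covariates, config = tree_config(),
                              indicators = c("z_cognitive", "z_depression",
                                             "z_anxiety")) {
  n <- nrow(data)
  if (n < 2 * config$min_node_size) return(NULL)
  # The confirmation-half children must themselves satisfy min_node_size:
  # the chi-square(7) reference for the confirmation test is anticonservative
  # when a 7-parameter child model sees only a handful of rows, and the
  # first-half argmax preferentially proposes extreme thresholds with just
  # such children. Keeping both halves' children at min_node_size keeps the
  # deciding test calibrated.
  min_child <- config$min_node_size

  idx1 <- sample.int(n, floor(n / 2))
  in1 <- rep(FALSE, n); in1[idx1] <- TRUE
  d1 <- data[in1, , drop = FALSE]
  d2 <- data[!in1, , drop = FALSE]

  picks <- list()
  for (cv in covariates) {
    x_all <- data[[cv]]
    x1 <- d1[[cv]]
    x2 <- d2[[cv]]
    cands <- candidate_thresholds(x1, config$max_candidates)
    if (length(cands) == 0) next
    # feasibility: full-node children >= min_node_size, half children
    # large enough to fit the 7-parameter model
    ok <- vapply(cands, function(v) {
      nl <- sum(x_all < v, na.rm = TRUE)
      nr <- sum(x_all >= v, na.rm = TRUE)
      nl >= config$min_node_size && nr >= config$min_node_size &&
        sum(x1 < v, na.rm = TRUE) >= min_child &&
        sum(x1 >= v, na.rm = TRUE) >= min_child &&
        sum(x2 < v, na.rm = TRUE) >= min_child &&
        sum(x2 >= v, na.rm = TRUE) >= min_child
    }, logical(1))
    cands <- cands[ok]
    if (length(cands) == 0) next

    keep1 <- !is.na(x1)
    p1 <- fit_factor_model(d1[keep1, , drop = FALSE], indicators)
    lr1 <- scan_thresholds(d1, x1, cands, p1$loglik, min_child, indicators)
    if (all(is.na(lr1))) next
    best <- cands[which.max(lr1)]

    keep2 <- !is.na(x2)
    p2 <- fit_factor_model(d2[keep2, , drop = FALSE], indicators)
    lr2 <- scan_thresholds(d2, x2, best, p2$loglik, min_child, indicators)
    picks[[cv]] <- list(value = best, lr2 = lr2)
  }
  if (length(picks) == 0) return(NULL)

  lr2s <- vapply(picks, function(p) ifelse(is.na(p$lr2), -Inf, p$lr2),
                 numeric(1))
  if (all(!is.finite(lr2s))) return(NULL)
  winner <- names(picks)[which.max(lr2s)]
  lr_confirm <- lr2s[[winner]]
  p_confirm <- pchisq(lr_confirm, df = 7, lower.tail = FALSE)
  k <- if (config$bonferroni) length(picks) else 1L
  p_adj <- min(1, p_confirm * k)
  if (p_adj >= config$alpha) return(NULL)
  if (config$confirm == "bootstrap" && p_confirm >= 1e-6) {
    # refine the borderline chi-square decision against the parametric
    # bootstrap; statistics far beyond any plausible null quantile
    # (p < 1e-6) are beyond the bootstrap's resolution anyway
    if (!confirm_split_bootstrap(d2, winner, picks[[winner]]$value,
                                 lr_confirm, k, config, indicators)) {
      return(NULL)
    }
  }

  full <- evaluate_split(data, winner, picks[[winner]]$value, config,
                         indicators)
  if (!full$feasible) return(NULL)
  dplyr::mutate(full, lr_confirm = lr_confirm, p_confirm = p_confirm,
                p_adj = p_adj, n_covariates = length(picks),
                feasible = NULL)
}

#' Grow an SEM tree
#'
#' Recursively partitions the cohort on the covariates, retaining at each
#' node the fair-criterion split ([fair_split_search()]) when it is
#' significant, and stopping at `min_node_size`, nonsignificance, or
#' `max_depth`. Rows whose value on a node's chosen covariate is missing
#' contribute to that node's model fit but are not routed further. Leaves
#' are labelled 1..K in ascending threshold order (left-first traversal).
#'
#' @inheritParams fair_split_search
#' @param vars_per_split If non-`NULL` and smaller than the covariate set,
#'   the number of covariates drawn uniformly at random as the candidate
#'   set at each node (used by [grow_forest()]).
#' @return A `sem_tree`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 600,
#'   true_cutpoints = 4, group_latent_means = c(-1, 1), seed = 11))
#' tr <- grow_tree(preprocess_cohort(coh),
#'                 covariates = c("overvaluation", "comp_freq_28d"),
#'                 config = tree_config(seed = 1))
#' tr
#' @export
grow_tree <- function(data, covariates, config = tree_config(),
                      indicators = c("z_cognitive", "z_depression",
                                     "z_anxiety"),
                      vars_per_split = NULL) {
  if (nrow(data) == 0) abort("cannot grow a tree on empty input")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    abort(paste0("covariate(s) not found: ",
                 paste(missing_cov, collapse = ", ")))
  }
  if (!is.null(vars_per_split) && vars_per_split > length(covariates)) {
    abort("vars_per_split exceeds the number of covariates")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  id_counter <- new.env(parent = emptyenv())
  id_counter$next_id <- 1L

  build <- function(d, depth) {
    node <- list(
      id = id_counter$next_id, depth = depth, n = nrow(d),
      fit = fit_factor_model(d, indicators),
      offered = covariates, split = NULL, left = NULL, right = NULL,
      leaf_label = NA_integer_
    )
    id_counter$next_id <- id_counter$next_id + 1L

    if (depth < config$max_depth && nrow(d) >= 2 * config$min_node_size) {
      offered <- covariates
      if (!is.null(vars_per_split) &&
          vars_per_split < length(covariates)) {
        offered <- sample(covariates, vars_per_split)
      }
      node$offered <- offered
      sc <- fair_split_search(d, offered, config, indicators)
      if (!is.null(sc)) {
        x <- d[[sc$covariate]]
        node$split <- sc
        node$left <- build(d[!is.na(x) & x < sc$value, , drop = FALSE],
                           depth + 1L)
        node$right <- build(d[!is.na(x) & x >= sc$value, , drop = FALSE],
                            depth + 1L)
      }
    }
    node
  }

  root <- build(data, 0L)

  label_env <- new.env(parent = emptyenv())
  label_env$k <- 0L
  label <- function(node) {
    if (is.null(node$split)) {
      label_env$k <- label_env$k + 1L
      node$leaf_label <- label_env$k
    } else {
      node$left <- label(node$left)
      node$right <- label(node$right)
    }
    node
  }
  root <- label(root)

  structure(list(root = root, config = config, covariates = covariates,
                 indicators = indicators, n = nrow(data),
                 n_leaves = label_env$k),
            class = "sem_tree")
}

#' Route records to tree leaves
#'
#' Deterministic routing by threshold comparison: strictly below a node's
#' threshold goes left, the threshold itself and above go right. Records
#' missing a covariate used on their path receive `NA` (unassigned); the
#' number of unassigned records is reported via a warning.
#'
#' @param tree A `sem_tree` (or the published-cutpoint reference tree).
#' @param data Data frame with the tree's covariate columns.
#' @return Integer vector of leaf labels (1..K), `NA` for unassigned rows.
#' @export
assign_leaf <- function(tree, data) {
  labels <- rep(NA_integer_, nrow(data))
  route <- function(node, idx) {
    if (length(idx) == 0) return(invisible())
    if (is.null(node$split)) {
      labels[idx] <<- node$leaf_label
      return(invisible())
    }
    x <- data[[node$split$covariate]][idx]
    route(node$left, idx[!is.na(x) & x < node$split$value])
    route(node$right, idx[!is.na(x) & x >= node$split$value])
  }
  route(tree$root, seq_len(nrow(data)))
  n_un <- sum(is.na(labels))
  if (n_un > 0) {
    warn(sprintf("%d record(s) unassigned: missing covariate on path", n_un))
  }
  labels
}

# Flat per-node table; list-columns carry offered covariates.
tree_nodes <- function(tree) {
  rows <- list()
  walk <- function(node) {
    sp <- node$split
    rows[[length(rows) + 1]] <<- tibble::tibble(
      id = node$id, depth = node$depth, n = node$n,
      is_leaf = is.null(sp),
      leaf_label = if (is.null(sp)) node$leaf_label else NA_integer_,
      covariate = if (is.null(sp)) NA_character_ else sp$covariate,
      value = if (is.null(sp)) NA_real_ else sp$value,
      lr = if (is.null(sp)) NA_real_ else sp$lr,
      p = if (is.null(sp)) NA_real_ else sp$p,
      p_adj = if (is.null(sp)) NA_real_ else sp$p_adj,
      loglik = node$fit$loglik,
      offered = list(node$offered)
    )
    if (!is.null(sp)) { walk(node$left); walk(node$right) }
  }
  walk(tree$root)
  dplyr::bind_rows(rows)
}

#' @rdname grow_tree
#' @param x A `sem_tree`.
#' @param ... Unused.
#' @export
tidy.sem_tree <- function(x, ...) {
  nodes <- tree_nodes(x)
  dplyr::select(dplyr::filter(nodes, !.data$is_leaf),
                "id", "depth", "covariate", "value", "lr", "p", "p_adj", "n")
}

#' @rdname grow_tree
#' @export
glance.sem_tree <- function(x, ...) {
  nodes <- tree_nodes(x)
  tibble::tibble(
    n = x$n,
    n_leaves = x$n_leaves,
    n_splits = sum(!nodes$is_leaf),
    loglik_root = x$root$fit$loglik,
    loglik_leaves = sum(nodes$loglik[nodes$is_leaf])
  )
}

#' @export
print.sem_tree <- function(x, ...) {
  cat("<sem_tree>", x$n, "records,", x$n_leaves, "leaf/leaves\n")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$split)) {
      cat(sprintf("%s* leaf %d: n = %d, loglik = %.2f\n", pad,
                  node$leaf_label, node$n, node$fit$loglik))
    } else {
      cat(sprintf("%s%s < %.4g  (LR = %.2f, p = %.3g, n = %d)\n", pad,
                  node$split$covariate, node$split$value, node$split$lr,
                  node$split$p, node$n))
      show(node$left, indent + 1)
      cat(sprintf("%s%s >= %.4g\n", pad, node$split$covariate,
                  node$split$value))
      show(node$right, indent + 1)
    }
  }
  show(x$root, 1)
  invisible(x)
}

#' Serialise a tree to JSON
#'
#' Nodes, thresholds, likelihood-ratio statistics and node model parameters,
#' in a stable layout: identical data and seed give byte-identical output.
#'
#' @param tree A `sem_tree`.
#' @return A JSON string.
#' @export
serialize_tree <- function(tree) {
  strip <- function(node) {
    out <- list(
      id = node$id, depth = node$depth, n = node$n,
      leaf_label = node$leaf_label,
      fit = list(loading = node$fit$loading, means = node$fit$means,
                 residual_variances = node$fit$residual_variances,
                 loglik = node$fit$loglik)
    )
    if (!is.null(node$split)) {
      out$split <- as.list(node$split)
      out$left <- strip(node$left)
      out$right <- strip(node$right)
    }
    out
  }
  as.character(jsonlite::toJSON(
    list(n = tree$n, covariates = tree$covariates, root = strip(tree$root)),
    auto_unbox = TRUE, digits = NA))
}

# Total -2 log-likelihood of `data` routed through the tree and scored with
# each leaf's fitted parameters; unroutable rows are dropped.
tree_neg2ll <- function(tree, data) {
  labels <- suppressWarnings(assign_leaf(tree, data))
  total <- 0
  for (lab in unique(labels[!is.na(labels)])) {
    leaf_fit <- find_leaf_fit(tree$root, lab)
    rows <- data[which(labels == lab), , drop = FALSE]
    total <- total - 2 * fiml_loglik(leaf_fit, rows, tree$indicators)
  }
  total
}

find_leaf_fit <- function(node, label) {
  if (is.null(node$split)) {
    if (identical(node$leaf_label, label)) return(node$fit)
    return(NULL)
  }
  find_leaf_fit(node$left, label) %||% find_leaf_fit(node$right, label)
}

#' Plot an SEM tree's severity intervals
#'
#' Shows, for trees that split on a single covariate, the leaf intervals
#' over that covariate's range with their group labels and sizes.
#'
#' @param object A `sem_tree`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sem_tree <- function(object, ...) {
  nodes <- tree_nodes(object)
  splits <- dplyr::filter(nodes, !.data$is_leaf)
  leaves <- dplyr::filter(nodes, .data$is_leaf)
  if (nrow(splits) == 0 || length(unique(splits$covariate)) > 1) {
    df <- dplyr::mutate(leaves, label = factor(.data$leaf_label))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(x = "severity group (leaf)", y = "n",
                      title = "SEM tree leaves")
    )
  }
  cuts <- sort(splits$value)
  cov <- splits$covariate[1]
  df <- tibble::tibble(
    lo = c(0, cuts), hi = c(cuts, 6),
    label = factor(seq_len(length(cuts) + 1)),
    n = leaves$n[order(leaves$leaf_label)]
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = 0, ymax = .data$n,
                                    fill = .data$label)) +
    ggplot2::labs(x = cov, y = "n", fill = "group",
                  title = "SEM tree severity groups")
}
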