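#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group center (mean by
#' default; `center = "median"` gives the Brown-Forsythe variant), via
#' [car::leveneTest()]. When every deviation is zero (identical spread in
#' all groups) the statistic is 0 with p = 1.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @param center `"mean"` (classical Levene) or `"median"`
#'   (Brown-Forsythe).
#' @return One-row tibble `statistic` (W), `df1`, `df2`, `p`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort(sprintf("group `%s` has fewer than 2 values",
                  names(sizes)[which(sizes < 2)[1]]))
  }
  # perfect fits on the deviation ANOVA (all-zero spread difference) warn
  # inside the F computation; they are legitimate boundary cases here
  lt <- suppressWarnings(
    car::leveneTest(values, groups,
                    center = if (center == "mean") mean else stats::median))
  W <- lt$`F value`[1]
  p <- lt$`Pr(>F)`[1]
  if (is.nan(W)) { W <- 0; p <- 1 }  # zero deviations everywhere
  tibble::tibble(statistic = W, df1 = lt$Df[1], df2 = lt$Df[2], p = p)
}

#' One-way ANOVA across severity groups
#'
#' Classical one-way F with partial eta squared
#' (\eqn{SS_{effect} / (SS_{effect} + SS_{error})}), or the Welch F with
#' Satterthwaite-type denominator degrees of freedom when variances are
#' unequal. With `welch = "auto"` the Welch statistic is reported when
#' Levene's p < 0.05. Both the classical and Welch statistics are always
#' computed and returned. For two groups the comparison reduces to the
#' (Welch) t-test, with Cohen's d and eta squared from
#' \eqn{t^2 / (t^2 + df)}. Missing values are removed pairwise for this
#' characteristic.
#'
#' @inheritParams levene_test
#' @param welch `"auto"` (Levene-gated), `"never"`, or `"always"`.
#' @return One-row tibble: `statistic` (F, or signed t for two groups),
#'   `df1`, `df2`, `p`, `partial_eta_sq`, `welch_used`, `levene_p`,
#'   `cohens_d` (two groups only), the always-computed
#'   `f_classical` / `p_classical` / `f_welch` / `p_welch`, `n_groups`,
#'   `n_total`.
#' @examples
#' severity_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3),
#'                welch = "never")
#' @export
severity_anova <- function(values, groups, welch = c("auto", "never",
                                                     "always")) {
  welch <- match.arg(welch)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- if (is.factor(groups)) groups[ok] else factor(groups[ok])
  empty <- levels(groups)[table(groups) == 0]
  if (length(empty) > 0) {
    abort(sprintf("group `%s` is empty", empty[1]))
  }
  groups <- droplevels(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort(sprintf("group `%s` has fewer than 2 values",
                  names(sizes)[which(sizes < 2)[1]]))
  }
  K <- length(sizes)
  N <- length(values)

  means <- tapply(values, groups, mean)
  ssb <- sum(sizes * (means - mean(values))^2)
  ssw <- sum((values - means[groups])^2)
  f_classical <- (ssb / (K - 1)) / (ssw / (N - K))
  p_classical <- pf(f_classical, K - 1, N - K, lower.tail = FALSE)
  eta <- ssb / (ssb + ssw)

  wt <- oneway.test(values ~ groups, var.equal = FALSE)
  f_welch <- unname(wt$statistic)
  p_welch <- unname(wt$p.value)
  df2_welch <- unname(wt$parameter[2])

  lev <- levene_test(values, groups)
  welch_used <- switch(welch, never = FALSE, always = TRUE,
                       auto = lev$p < 0.05)

  if (K == 2) {
    tt <- t.test(values ~ groups, var.equal = !welch_used)
    pooled_sd <- sqrt(((sizes[1] - 1) * tapply(values, groups, var)[1] +
                       (sizes[2] - 1) * tapply(values, groups, var)[2]) /
                      (N - 2))
    d <- unname((means[1] - means[2]) / pooled_sd)
    stat <- unname(tt$statistic)
    df2 <- unname(tt$parameter)
    p <- unname(tt$p.value)
    eta2 <- stat^2 / (stat^2 + df2)
    return(tibble::tibble(
      statistic = stat, df1 = 1, df2 = df2, p = p, partial_eta_sq = eta2,
      welch_used = welch_used, levene_p = lev$p, cohens_d = d,
      f_classical = f_classical, p_classical = p_classical,
      f_welch = f_welch, p_welch = p_welch,
      n_groups = K, n_total = N))
  }

  tibble::tibble(
    statistic = if (welch_used) f_welch else f_classical,
    df1 = K - 1,
    df2 = if (welch_used) df2_welch else N - K,
    p = if (welch_used) p_welch else p_classical,
    partial_eta_sq = eta,
    welch_used = welch_used, levene_p = lev$p, cohens_d = NA_real_,
    f_classical = f_classical, p_classical = p_classical,
    f_welch = f_welch, p_welch = p_welch,
    n_groups = K, n_total = N)
}

#' Orthogonal lower-vs-higher contrast coefficients
#'
#' The planned family compares each lower severity group with the pool of
#' all higher groups: contrast j assigns +(K - j) to group j, -1 to each of
#' groups j+1..K, and 0 below (for K = 5 the first contrast is
#' proportional to +4, -1, -1, -1, -1, i.e. group 1 versus groups 2--5).
#' Each row sums to zero and the rows are pairwise orthogonal under equal
#' weights; with unequal group sizes the same coefficient vectors are
#' retained (unweighted convention).
#'
#' @param K Number of ordered groups.
#' @return A (K-1) x K coefficient matrix.
#' @export
contrast_coefficients <- function(K) {
  if (K < 2) abort("need at least 2 groups")
  C <- matrix(0, K - 1, K)
  for (j in seq_len(K - 1)) {
    C[j, j] <- K - j
    C[j, (j + 1):K] <- -1
  }
  C
}

#' Planned orthogonal contrasts across ordered severity groups
#'
#' Builds the K-1 lower-vs-higher contrasts ([contrast_coefficients()]) and
#' estimates each as the difference between the lower group's mean and the
#' unweighted mean of the higher groups' means. Standard errors use the
#' omnibus mean-square error with N - K degrees of freedom, or
#' group-specific variances with Satterthwaite degrees of freedom when
#' Welch correction is indicated. Cohen's d divides the contrast estimate
#' by the pooled standard deviation of the two contrasted pools of
#' observations.
#'
#' @inheritParams severity_anova
#' @param groups Ordered group labels (factor order = severity order).
#' @return Tibble with one row per contrast: `contrast`, `estimate`, `se`,
#'   `t`, `df`, `p`, `cohens_d`, `welch_used`, and the coefficient vector
#'   as a list column.
#' @export
planned_contrasts <- function(values, groups, welch = c("auto", "never",
                                                        "always")) {
  welch <- match.arg(welch)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  lev_names <- levels(groups)
  K <- length(lev_names)
  if (K < 2) abort("need at least 2 groups")
  sizes <- as.numeric(table(groups))
  if (any(sizes < 2)) {
    abort(sprintf("group `%s` has fewer than 2 values",
                  lev_names[which(sizes < 2)[1]]))
  }
  N <- length(values)
  means <- as.numeric(tapply(values, groups, mean))
  vars <- as.numeric(tapply(values, groups, var))
  mse <- sum((sizes - 1) * vars) / (N - K)

  welch_used <- switch(welch, never = FALSE, always = TRUE,
                       auto = levene_test(values, groups)$p < 0.05)

  C <- contrast_coefficients(K)
  out <- lapply(seq_len(K - 1), function(j) {
    cc <- C[j, ] / (K - j)  # normalised: estimate = mean_j - mean(higher)
    est <- sum(cc * means)
    if (welch_used) {
      comp <- cc^2 * vars / sizes
      se <- sqrt(sum(comp))
      df <- se^4 / sum(comp^2 / (sizes - 1))
    } else {
      se <- sqrt(mse * sum(cc^2 / sizes))
      df <- N - K
    }
    tstat <- est / se
    lower_idx <- groups == lev_names[j]
    higher_idx <- as.integer(groups) > j
    nA <- sum(lower_idx); nB <- sum(higher_idx)
    sA <- var(values[lower_idx]); sB <- var(values[higher_idx])
    pooled <- sqrt(((nA - 1) * sA + (nB - 1) * sB) / (nA + nB - 2))
    tibble::tibble(
      contrast = sprintf("%s vs %s", lev_names[j],
                         paste(lev_names[(j + 1):K], collapse = "+")),
      coefficients = list(C[j, ]),
      estimate = est, se = se, t = tstat, df = df,
      p = 2 * pt(-abs(tstat), df),
      cohens_d = est / pooled,
      welch_used = welch_used
    )
  })
  dplyr::bind_rows(out)
}

#' Which characteristics define which scheme
#'
#' Characteristics used to define a severity scheme are excluded from that
#' scheme's comparisons (e.g. compensatory frequency is the metric defining
#' the DSM-5 groups).
#'
#' @return Tibble `scheme`, `characteristic`.
#' @export
scheme_exclusions <- function() {
  tibble::tribble(
    ~scheme, ~characteristic,
    "dsm5", "comp_freq_weekly",
    "dsm5", "comp_freq_28d",
    "clinical_overvaluation", "overvaluation",
    "purging_count", "overvaluation",
    "semtree", "overvaluation"
  )
}

#' @rdname scheme_exclusions
#' @param scheme,characteristic Scheme and characteristic names.
#' @param table Exclusion table (rows `scheme`, `characteristic`).
#' @return `exclusion_of_defining_characteristic()`: a logical flag.
#' @export
exclusion_of_defining_characteristic <- function(scheme, characteristic,
                                                 table = scheme_exclusions()) {
  known <- c("semtree", "dsm5", "clinical_overvaluation", "purging_count")
  if (!scheme %in% union(known, table$scheme)) {
    abort(sprintf("unknown scheme `%s`", scheme))
  }
  any(table$scheme == scheme & table$characteristic == characteristic)
}

#' Compare severity schemes on clinical characteristics
#'
#' Runs, for every scheme and every clinical characteristic not used to
#' define that scheme, the (Welch-aware) one-way ANOVA and the planned
#' lower-vs-higher contrasts. Records unassigned under a scheme -- missing
#' labels, patients purging by no method, and DSM-5 subthreshold patients
#' (below one episode/week) -- are dropped from that scheme's comparison;
#' missing characteristic values are removed pairwise.
#'
#' @param data A preprocessed cohort ([preprocess_cohort()]).
#' @param assignments Scheme assignment table ([assign_schemes()]).
#' @param characteristics Characteristic column names to compare on.
#' @param exclusions Scheme-defining exclusion table
#'   ([scheme_exclusions()]).
#' @inheritParams severity_anova
#' @return List of class `scheme_comparison` with tibbles `anova` (one row
#'   per scheme x characteristic) and `contrasts`.
#' @export
compare_schemes <- function(data, assignments,
                            characteristics = c("edeq_global_wo",
                                                "z_depression", "z_anxiety",
                                                "binge_28d",
                                                "comp_freq_weekly",
                                                "overvaluation"),
                            exclusions = scheme_exclusions(),
                            welch = "auto") {
  stopifnot("id" %in% names(assignments))
  merged <- dplyr::inner_join(data, assignments, by = "id",
                              suffix = c("", ".scheme"))
  schemes <- setdiff(names(assignments), "id")
  anovas <- list()
  contrasts <- list()
  for (sc in schemes) {
    g <- merged[[sc]]
    if (sc == "purging_count") g[g == "none"] <- NA
    if (sc == "dsm5") g[g == "subthreshold"] <- NA
    g <- droplevels(factor(g, levels = levels(merged[[sc]]), ordered = TRUE))
    for (ch in characteristics) {
      if (exclusion_of_defining_characteristic(sc, ch, exclusions)) next
      # pairwise deletion can leave a group with <2 usable values
      # (e.g. a sparsely populated extreme severity group); such groups
      # cannot contribute a variance and are dropped from this comparison
      counts <- table(g[!is.na(merged[[ch]])])
      gg <- g
      gg[gg %in% names(counts)[counts < 2]] <- NA
      gg <- droplevels(gg)
      if (length(levels(gg)) < 2) next
      a <- severity_anova(merged[[ch]], gg, welch = welch)
      anovas[[length(anovas) + 1]] <-
        dplyr::bind_cols(tibble::tibble(scheme = sc, characteristic = ch), a)
      pc <- planned_contrasts(merged[[ch]], gg, welch = welch)
      contrasts[[length(contrasts) + 1]] <-
        dplyr::bind_cols(tibble::tibble(scheme = sc, characteristic = ch,
                                        .rows = nrow(pc)), pc)
    }
  }
  structure(list(anova = dplyr::bind_rows(anovas),
                 contrasts = dplyr::bind_rows(contrasts)),
            class = "scheme_comparison")
}

#' @export
print.scheme_comparison <- function(x, ...) {
  cat("<scheme_comparison>\n")
  print(dplyr::select(x$anova, "scheme", "characteristic", "statistic",
                      "df1", "df2", "p", "partial_eta_sq", "welch_used"))
  invisible(x)
}

#' Variance explained per severity scheme
#'
#' Summarises, per scheme, the minimum, maximum and mean of the variance
#' explained (partial eta squared; for two-group schemes the t-derived eta
#' squared) across the compared clinical characteristics, and the pairwise
#' ratios of scheme means.
#'
#' @param results A `scheme_comparison`, or its `anova` tibble.
#' @return List with `by_scheme` (tibble `scheme`, `min`, `max`, `mean`,
#'   `n_characteristics`) and `ratios` (tibble `scheme_a`, `scheme_b`,
#'   `ratio` = mean_a / mean_b).
#' @export
variance_summary <- function(results) {
  if (inherits(results, "scheme_comparison")) results <- results$anova
  if (is.null(results) || nrow(results) == 0) {
    abort("no comparison results to summarise")
  }
  by_scheme <- results |>
    dplyr::group_by(.data$scheme) |>
    dplyr::summarise(min = min(.data$partial_eta_sq),
                     max = max(.data$partial_eta_sq),
                     mean = mean(.data$partial_eta_sq),
                     n_characteristics = dplyr::n(), .groups = "drop")
  pairs <- tidyr::expand_grid(scheme_a = by_scheme$scheme,
                              scheme_b = by_scheme$scheme) |>
    dplyr::filter(.data$scheme_a != .data$scheme_b) |>
    dplyr::mutate(
      ratio = by_scheme$mean[match(.data$scheme_a, by_scheme$scheme)] /
        by_scheme$mean[match(.data$scheme_b, by_scheme$scheme)]
    )
  list(by_scheme = by_scheme, ratios = pairs)
}

#' Plot variance explained by scheme and characteristic
#'
#' @param results A `scheme_comparison` or its `anova` tibble.
#' @return A ggplot.
#' @export
plot_variance_explained <- function(results) {
  if (inherits(results, "scheme_comparison")) results <- results$anova
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$characteristic,
                               y = .data$partial_eta_sq,
                               fill = .data$scheme)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "variance explained (partial eta squared)", x = NULL,
                  title = "Clinical characteristics by severity scheme")
}
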