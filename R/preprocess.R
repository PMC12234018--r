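#' Shape/weight overvaluation composite
#'
#' Arithmetic mean of the two overvaluation items (weight and shape), each on
#' the 0--6 scale. Because it averages two items, the composite takes values
#' on a 0.5-increment grid. If either item is missing the composite is
#' missing: the composite is defined only as a two-item mean.
#'
#' @param item_weight,item_shape Item scores on the 0--6 scale (vectorised).
#' @return Numeric vector of composites in \[0, 6\].
#' @examples
#' overvaluation_composite(4, 6)  # 5
#' overvaluation_composite(5, 6)  # 5.5, a legal 0.5-grid value
#' @export
overvaluation_composite <- function(item_weight, item_shape) {
  check_item_range(item_weight, "item_weight")
  check_item_range(item_shape, "item_shape")
  (item_weight + item_shape) / 2
}

check_item_range <- function(x, name, lo = 0, hi = 6) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    abort(sprintf("`%s` outside the %g-%g scale at position(s) %s",
                  name, lo, hi,
                  paste(head(which(bad), 5), collapse = ", ")))
  }
  invisible(x)
}

#' Compensatory-behavior frequency composite
#'
#' Sum of the 28-day behavior counts (self-induced vomiting,
#' laxative/diuretic use, excessive exercise), with each item capped at
#' `cap` episodes before summing to control outliers. The default cap of 56
#' corresponds to two instances per day over 28 days.
#'
#' @param vomiting,laxative_diuretic,exercise Nonnegative 28-day counts
#'   (vectorised).
#' @param cap Per-item cap applied before summing.
#' @return Nonnegative numeric vector, at most `3 * cap`.
#' @examples
#' compensatory_frequency(70, 10, 0)  # 66: first item capped at 56
#' @export
compensatory_frequency <- function(vomiting, laxative_diuretic, exercise,
                                   cap = 56) {
  counts <- cbind(vomiting, laxative_diuretic, exercise)
  if (any(counts < 0, na.rm = TRUE)) {
    abort("compensatory counts must be nonnegative")
  }
  rowSums(pmin(counts, cap))
}

#' EDE-Q Global score without the overvaluation items
#'
#' Mean of the retained cognitive eating-disorder items, excluding the two
#' overvaluation items so the severity-defining covariate does not overlap
#' the characteristic severity groups are compared on. A patient's score is
#' missing when fewer than `min_present` of the retained items are observed.
#'
#' @param items Numeric matrix or data frame of item scores (rows =
#'   patients, 0--6 scale), or a single patient's numeric vector.
#' @param overvaluation_idx Column indices (or names) of the overvaluation
#'   items to drop; use `integer(0)` if already excluded.
#' @param min_present Minimum fraction of retained items that must be
#'   nonmissing.
#' @return Numeric vector of per-patient means; `NA` where too few items are
#'   present (a warning reports how many patients were affected).
#' @export
edeq_global_without_overvaluation <- function(items,
                                              overvaluation_idx = integer(0),
                                              min_present = 0.5) {
  if (is.vector(items) && is.numeric(items)) items <- rbind(items)
  items <- as.matrix(items)
  check_item_range(items, "items")
  if (length(overvaluation_idx) > 0) {
    items <- items[, -overvaluation_idx_to_int(items, overvaluation_idx),
                   drop = FALSE]
  }
  frac <- rowMeans(!is.na(items))
  out <- rowMeans(items, na.rm = TRUE)
  short <- frac < min_present
  if (any(short)) {
    warn(sprintf(
      "%d patient(s) below the %.0f%% item-presence threshold; score set missing",
      sum(short), 100 * min_present))
    out[short] <- NA_real_
  }
  out[is.nan(out)] <- NA_real_
  unname(out)
}

overvaluation_idx_to_int <- function(items, idx) {
  if (is.character(idx)) match(idx, colnames(items)) else as.integer(idx)
}

#' Apply the study's exclusion rules
#'
#' Removes, in order: (1) records missing all measures; (2) records with an
#' EDE-Q Global score below 0.5 while in residential or PHP treatment (an
#' indicator of invalid responding at those levels of care); (3) records
#' reporting no core diagnostic indicators of bulimia nervosa, or missing
#' all such items. Each rule is a pure predicate of the record, so the
#' retained set does not depend on the order of application; the order only
#' determines which rule a doubly-excludable record is logged under.
#'
#' @param records Cohort records tibble (see [generate_cohort()]).
#' @param core_indicator_cols Columns operationalising the core diagnostic
#'   indicators (binge eating and compensatory behaviors); a record with all
#'   of them zero or missing is excluded under rule 3.
#' @param measure_cols Columns counted as "measures" for rule 1.
#' @param global_threshold Rule-2 threshold on the Global score.
#' @return List with `records` (retained tibble) and `log` (tibble of
#'   `id`, `rule`, `reason` for each exclusion).
#' @export
apply_exclusions <- function(records,
                             core_indicator_cols = c("binge_28d", "vomit_28d",
                                                     "laxdiur_28d",
                                                     "exercise_28d"),
                             measure_cols = c("edeq_global_wo",
                                              "depression_total",
                                              "anxiety_total", "binge_28d",
                                              "vomit_28d", "laxdiur_28d",
                                              "exercise_28d"),
                             global_threshold = 0.5) {
  measure_cols <- intersect(measure_cols, names(records))
  core_indicator_cols <- intersect(core_indicator_cols, names(records))

  all_missing <- rowSums(!is.na(records[, measure_cols, drop = FALSE])) == 0
  low_global <- !is.na(records$edeq_global_wo) &
    records$edeq_global_wo < global_threshold &
    records$stratum %in% c("residential", "php")
  core <- records[, core_indicator_cols, drop = FALSE]
  core_zero <- rowSums(!is.na(core) & core > 0) == 0

  rule <- dplyr::case_when(
    all_missing ~ 1L,
    low_global ~ 2L,
    core_zero ~ 3L,
    .default = NA_integer_
  )
  reasons <- c("missing data on all measures",
               "EDE-Q Global < 0.5 in residential/PHP",
               "no core diagnostic indicators of BN")
  excluded <- !is.na(rule)
  log <- tibble::tibble(
    id = records$id[excluded],
    rule = rule[excluded],
    reason = reasons[rule[excluded]]
  )
  list(records = records[!excluded, , drop = FALSE], log = log)
}

#' Standardise values within level-of-care strata
#'
#' Centers and scales each stratum separately, `(x - mean) / sd` over that
#' stratum's nonmissing values (sample sd, denominator n-1), so that
#' constructs assessed with different instruments across treatment settings
#' share a common scale. Missing values stay missing.
#'
#' @param values Numeric vector.
#' @param strata Stratum label per value.
#' @return Standardised numeric vector.
#' @export
zscore_within_stratum <- function(values, strata) {
  stopifnot(length(values) == length(strata))
  out <- rep(NA_real_, length(values))
  for (s in unique(strata)) {
    i <- which(strata == s)
    v <- values[i]
    obs <- !is.na(v)
    if (sum(obs) < 2) {
      abort(sprintf("stratum `%s` has fewer than 2 nonmissing values", s))
    }
    sdv <- sd(v[obs])
    if (sdv == 0) {
      abort(sprintf("stratum `%s` has zero variance; cannot standardise", s))
    }
    out[i] <- (v - mean(v[obs])) / sdv
  }
  out
}

#' Preprocess a cohort for the severity analysis
#'
#' Applies the exclusion rules, builds the overvaluation composite and the
#' capped compensatory-frequency composite (28-day and weekly), and z-scores
#' the three outcome-model indicators within each level-of-care stratum.
#'
#' @param records Cohort records tibble, or a `bn_cohort`.
#' @param exclusions Apply [apply_exclusions()] first?
#' @param cap Per-item compensatory-count cap.
#' @return Tibble with one row per retained patient: `z_cognitive`,
#'   `z_depression`, `z_anxiety`, `overvaluation`, `comp_freq_28d`,
#'   `comp_freq_weekly`, clinical characteristics, purging flags and any
#'   noise covariates. The exclusion log is attached as attribute
#'   `"exclusion_log"`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 300, seed = 7))
#' dat <- preprocess_cohort(coh)
#' dplyr::glimpse(dat)
#' @export
preprocess_cohort <- function(records, exclusions = TRUE, cap = 56) {
  if (inherits(records, "bn_cohort")) records <- records$records
  log <- tibble::tibble(id = character(), rule = integer(),
                        reason = character())
  if (exclusions) {
    ex <- apply_exclusions(records)
    records <- ex$records
    log <- ex$log
  }
  out <- records |>
    dplyr::mutate(
      overvaluation = overvaluation_composite(.data$ov_item_weight,
                                              .data$ov_item_shape),
      comp_freq_28d = compensatory_frequency(.data$vomit_28d,
                                             .data$laxdiur_28d,
                                             .data$exercise_28d, cap = cap),
      comp_freq_weekly = .data$comp_freq_28d / 4,
      z_cognitive = zscore_within_stratum(.data$edeq_global_wo,
                                          .data$stratum),
      z_depression = zscore_within_stratum(.data$depression_total,
                                           .data$stratum),
      z_anxiety = zscore_within_stratum(.data$anxiety_total, .data$stratum)
    ) |>
    dplyr::relocate("id", "stratum", "z_cognitive", "z_depression",
                    "z_anxiety", "overvaluation", "comp_freq_28d",
                    "comp_freq_weekly")
  attr(out, "exclusion_log") <- log
  out
}

#' @rdname preprocess_cohort
#' @param data A tibble returned by `preprocess_cohort()`.
#' @export
exclusion_log <- function(data) {
  attr(data, "exclusion_log")
}
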