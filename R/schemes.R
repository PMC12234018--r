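#' DSM-5 severity bands from weekly compensatory frequency
#'
#' Bands the average number of compensatory episodes per week into the
#' DSM-5 severity specifiers: mild 1--3, moderate 4--7, severe 8--13,
#' extreme >= 14 episodes/week. Frequencies below one episode per week are
#' flagged `subthreshold` rather than forced into `mild`. Non-integer
#' weekly values (28-day counts divided by 4) are banded by the same
#' half-open intervals \[1,4), \[4,8), \[8,14), \[14,Inf).
#'
#' @param comp_freq_weekly Nonnegative weekly compensatory-episode
#'   frequency (vectorised); 28-day counts should be divided by 4 first.
#' @return Ordered factor `subthreshold < mild < moderate < severe <
#'   extreme`.
#' @examples
#' assign_dsm5(c(3, 5, 14))  # mild, moderate, extreme
#' @export
assign_dsm5 <- function(comp_freq_weekly) {
  if (any(comp_freq_weekly < 0, na.rm = TRUE)) {
    abort("weekly frequency must be nonnegative")
  }
  cut(comp_freq_weekly, breaks = c(-Inf, 1, 4, 8, 14, Inf),
      labels = c("subthreshold", "mild", "moderate", "severe", "extreme"),
      right = FALSE, ordered_result = TRUE)
}

#' Clinically significant shape/weight overvaluation
#'
#' A patient is in the clinical group when either overvaluation item is
#' rated 4 or higher. Missing items give an unassigned (`NA`) result.
#'
#' @inheritParams overvaluation_composite
#' @return Ordered factor `nonclinical < clinical`.
#' @examples
#' assign_clinical_overvaluation(c(4, 3, 6), c(0, 3, 6))
#' @export
assign_clinical_overvaluation <- function(item_weight, item_shape) {
  check_item_range(item_weight, "item_weight")
  check_item_range(item_shape, "item_shape")
  clinical <- pmax(item_weight, item_shape) >= 4
  factor(ifelse(clinical, "clinical", "nonclinical"),
         levels = c("nonclinical", "clinical"), ordered = TRUE)
}

#' Single versus multiple purging methods
#'
#' Counts the purging methods a patient uses (vomiting, laxatives,
#' diuretics -- excessive exercise is not a purging method): one method is
#' `single`, two or more `multiple`, and patients purging by no method are
#' `none` (excluded from this scheme's comparisons).
#'
#' @param vomiting,laxatives,diuretics Logical presence flags (vectorised).
#' @return Factor `none < single < multiple` (ordered).
#' @export
assign_purging_count <- function(vomiting, laxatives, diuretics) {
  k <- rowSums(cbind(vomiting, laxatives, diuretics), na.rm = TRUE)
  factor(dplyr::case_when(k == 0 ~ "none", k == 1 ~ "single",
                          .default = "multiple"),
         levels = c("none", "single", "multiple"), ordered = TRUE)
}

#' Severity group from an SEM tree
#'
#' Delegates to [assign_leaf()]; leaves are labelled 1..K in ascending
#' threshold order, so the label is an ordered severity group.
#'
#' @param tree A `sem_tree` or the [reference_tree()].
#' @param data Data frame with the tree's covariate columns.
#' @return Ordered factor of group labels.
#' @export
assign_semtree <- function(tree, data) {
  labs <- assign_leaf(tree, data)
  factor(labs, levels = sort(unique(stats::na.omit(labs))), ordered = TRUE)
}

#' The published-cutpoint severity tree
#'
#' Reconstructs the five-group severity tree from the published
#' shape/weight-overvaluation cutpoints (1.25, 3.75, 4.75, 5.75), shipped
#' as a thresholds-only JSON fixture. Group 1 is overvaluation < 1.25 and
#' group 5 is overvaluation >= 5.75; each threshold itself routes to the
#' upper group.
#'
#' @param path Optional path to a thresholds JSON (defaults to the fixture
#'   shipped with the package).
#' @return A `sem_tree` with thresholds but no fitted node parameters.
#' @examples
#' rt <- reference_tree()
#' assign_semtree(rt, tibble::tibble(overvaluation = c(0.5, 5, 6)))
#' @export
reference_tree <- function(path = NULL) {
  path <- path %||% system.file("extdata", "published_tree.json",
                                package = "severitree")
  js <- jsonlite::fromJSON(path)
  thresholds <- sort(as.numeric(js$thresholds))
  cov <- js$covariate

  make_chain <- function(i, depth) {
    if (i > length(thresholds)) {
      return(list(id = NA_integer_, depth = depth, n = NA_integer_,
                  fit = NULL, split = NULL, left = NULL, right = NULL,
                  leaf_label = i))
    }
    list(
      id = NA_integer_, depth = depth, n = NA_integer_, fit = NULL,
      split = tibble::tibble(covariate = cov, value = thresholds[i],
                             lr = NA_real_, p = NA_real_),
      left = list(id = NA_integer_, depth = depth + 1L, n = NA_integer_,
                  fit = NULL, split = NULL, left = NULL, right = NULL,
                  leaf_label = i),
      right = make_chain(i + 1L, depth + 1L),
      leaf_label = NA_integer_
    )
  }
  structure(list(root = make_chain(1L, 0L), config = NULL,
                 covariates = cov, indicators = NULL, n = NA_integer_,
                 n_leaves = length(thresholds) + 1L),
            class = "sem_tree")
}

#' Assign every severity scheme at once
#'
#' @param data A preprocessed cohort ([preprocess_cohort()]).
#' @param tree A `sem_tree` for the `semtree` scheme (default: the
#'   published-cutpoint [reference_tree()]).
#' @return Tibble `id`, `semtree`, `dsm5`, `clinical_overvaluation`,
#'   `purging_count`.
#' @export
assign_schemes <- function(data, tree = reference_tree()) {
  tibble::tibble(
    id = data$id,
    semtree = assign_semtree(tree, data),
    dsm5 = assign_dsm5(data$comp_freq_weekly),
    clinical_overvaluation = assign_clinical_overvaluation(
      data$ov_item_weight, data$ov_item_shape),
    purging_count = assign_purging_count(data$purge_vomiting,
                                         data$purge_laxative,
                                         data$purge_diuretic)
  )
}
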