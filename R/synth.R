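#' Specify a synthetic bulimia nervosa cohort
#'
#' A `cohort_spec` captures everything the generator needs to emulate the
#' statistical structure the severity analysis assumes: three indicators
#' driven by one latent severity factor with a shared loading, a
#' shape/weight-overvaluation item pair correlated on the 0--6 grid,
#' subgroup shifts of the latent mean at planted overvaluation cutpoints,
#' overdispersed 28-day compensatory-behavior counts, and anxiety scores
#' missing completely at random.
#'
#' @param n_patients Number of patients to generate.
#' @param true_cutpoints Strictly increasing overvaluation-composite values in
#'   (0, 6) at which the latent severity mean shifts. May be `numeric(0)` for
#'   a structureless (null) cohort.
#' @param group_latent_means Latent severity mean per planted group; length
#'   must be `length(true_cutpoints) + 1`.
#' @param loading Shared factor loading \eqn{\lambda > 0} of the three
#'   indicators on the latent factor (latent variance fixed at 1).
#' @param residual_variances Length-3 positive residual variances of the
#'   cognitive, depression and anxiety indicators.
#' @param item_correlation Target correlation of the latent scores behind the
#'   two overvaluation items, in \[0, 1). Discretisation to the integer grid
#'   attenuates the realised item correlation slightly.
#' @param anxiety_missing_rate MCAR missingness proportion for anxiety,
#'   in \[0, 1).
#' @param comp_behavior_dispersion Negative-binomial parameters for the three
#'   compensatory 28-day count items: a list with `mu` (length-3 means, named
#'   vomiting / laxative_diuretic / exercise) and `size` (dispersion).
#' @param strata_proportions Named proportions over the level-of-care strata
#'   `residential`, `php`, `outpatient`; must sum to 1.
#' @param noise_covariates Number of pure-noise N(0,1) covariates to append.
#' @param item_location,item_scale Location and scale of the latent normal
#'   mapped onto the 0--6 overvaluation item grid.
#' @param seed Integer seed; the same spec always generates the same cohort.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_patients = 1017,
                        true_cutpoints = c(1.25, 3.75, 4.75, 5.75),
                        group_latent_means = c(-1.2, -0.6, 0, 0.6, 1.2),
                        loading = 0.8,
                        residual_variances = c(0.36, 0.36, 0.36),
                        item_correlation = 0.80,
                        anxiety_missing_rate = 0.35,
                        comp_behavior_dispersion = list(
                          mu = c(vomiting = 10, laxative_diuretic = 5,
                                 exercise = 12),
                          size = 0.6
                        ),
                        strata_proportions = c(residential = 0.45, php = 0.35,
                                               outpatient = 0.20),
                        noise_covariates = 0,
                        item_location = 4.8,
                        item_scale = 1.8,
                        seed = 1L) {
  spec <- structure(
    list(
      n_patients = n_patients,
      true_cutpoints = as.numeric(true_cutpoints),
      group_latent_means = as.numeric(group_latent_means),
      loading = loading,
      residual_variances = as.numeric(residual_variances),
      item_correlation = item_correlation,
      anxiety_missing_rate = anxiety_missing_rate,
      comp_behavior_dispersion = comp_behavior_dispersion,
      strata_proportions = strata_proportions,
      noise_covariates = as.integer(noise_covariates),
      item_location = item_location,
      item_scale = item_scale,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, msg) {
    abort(sprintf("invalid cohort_spec: field `%s` %s", field, msg),
          class = "severitree_spec_error")
  }
  with(spec, {
    if (!is.numeric(n_patients) || length(n_patients) != 1 ||
        n_patients < 1 || n_patients != floor(n_patients)) {
      fail("n_patients", "must be a positive integer")
    }
    if (length(true_cutpoints) > 0) {
      if (any(diff(true_cutpoints) <= 0)) {
        fail("true_cutpoints", "must be strictly increasing")
      }
      if (any(true_cutpoints <= 0 | true_cutpoints >= 6)) {
        fail("true_cutpoints", "must lie in (0, 6)")
      }
    }
    if (length(group_latent_means) != length(true_cutpoints) + 1) {
      fail("group_latent_means",
           "must have length length(true_cutpoints) + 1")
    }
    if (!is.numeric(loading) || loading <= 0) {
      fail("loading", "must be a positive real")
    }
    if (length(residual_variances) != 3 || any(residual_variances <= 0)) {
      fail("residual_variances", "must be three positive reals")
    }
    if (item_correlation < 0 || item_correlation >= 1) {
      fail("item_correlation", "must lie in [0, 1)")
    }
    if (anxiety_missing_rate < 0 || anxiety_missing_rate >= 1) {
      fail("anxiety_missing_rate", "must lie in [0, 1)")
    }
    if (!is.list(comp_behavior_dispersion) ||
        length(comp_behavior_dispersion$mu) != 3 ||
        any(comp_behavior_dispersion$mu < 0) ||
        comp_behavior_dispersion$size <= 0) {
      fail("comp_behavior_dispersion",
           "must supply three nonnegative means and a positive size")
    }
    if (!setequal(names(strata_proportions),
                  c("residential", "php", "outpatient")) ||
        abs(sum(strata_proportions) - 1) > 1e-8 ||
        any(strata_proportions < 0)) {
      fail("strata_proportions",
           "must be nonnegative, named residential/php/outpatient, sum to 1")
    }
    if (noise_covariates < 0) fail("noise_covariates", "must be >= 0")
    if (item_scale <= 0) fail("item_scale", "must be positive")
  })
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_patients, "patients,",
      length(x$true_cutpoints), "planted cutpoint(s)",
      if (length(x$true_cutpoints)) paste0("(",
        paste(x$true_cutpoints, collapse = ", "), ")") else "",
      "\n  loading", x$loading, "| anxiety MCAR rate",
      x$anxiety_missing_rate, "| seed", x$seed, "\n")
  invisible(x)
}

# Columns an analysis CSV is allowed to contain (noise_* handled separately).
cohort_columns <- function() {
  c("id", "stratum", "ov_item_weight", "ov_item_shape", "edeq_global_wo",
    "depression_total", "anxiety_total", "vomit_28d", "laxdiur_28d",
    "exercise_28d", "binge_28d", "purge_vomiting", "purge_laxative",
    "purge_diuretic")
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the structure declared in a [cohort_spec()]:
#' the two overvaluation items come from a thresholded bivariate normal on
#' the 0--6 integer grid; each record's planted severity group is the
#' interval of its overvaluation composite among `true_cutpoints`
#' (boundary values fall in the upper group); the latent severity
#' \eqn{\eta \sim N(\mu_{group}, 1)} drives the three indicators as
#' \eqn{\lambda\eta + \epsilon_k}; instrument totals are affine maps of the
#' indicators on stratum-specific scales; anxiety is blanked MCAR.
#'
#' @param spec A [cohort_spec()].
#' @return A `bn_cohort`: list with `records` (tibble, one row per patient),
#'   `truth` (tibble with the planted group, latent score and composite per
#'   record -- kept out of the analysis table to avoid leakage), and `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 200, seed = 42))
#' coh$records
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_patients

  stratum <- sample(names(spec$strata_proportions), n, replace = TRUE,
                    prob = spec$strata_proportions)

  # correlated latent pair -> 0-6 integer items
  rho <- spec$item_correlation
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  to_item <- function(z) {
    pmin(6, pmax(0, round(spec$item_location + spec$item_scale * z)))
  }
  ov_w <- to_item(z1)
  ov_s <- to_item(z2)
  composite <- (ov_w + ov_s) / 2

  group <- findInterval(composite, spec$true_cutpoints) + 1L
  eta <- rnorm(n, mean = spec$group_latent_means[group], sd = 1)

  lam <- spec$loading
  rv <- spec$residual_variances
  ind <- vapply(1:3, function(k) lam * eta + rnorm(n, 0, sqrt(rv[k])),
                numeric(n))

  resphp <- stratum %in% c("residential", "php")
  edeq_global_wo <- 3.5 + 0.9 * ind[, 1]
  depression_total <- ifelse(resphp, 25 + 9 * ind[, 2], 12 + 5 * ind[, 2])
  anxiety_total <- ifelse(resphp, 10 + 3.5 * ind[, 3], 12 + 5 * ind[, 3])
  anxiety_total[runif(n) < spec$anxiety_missing_rate] <- NA_real_

  disp <- spec$comp_behavior_dispersion
  vomit_28d <- rnbinom(n, size = disp$size, mu = disp$mu[[1]])
  laxdiur_28d <- rnbinom(n, size = disp$size, mu = disp$mu[[2]])
  exercise_28d <- rnbinom(n, size = disp$size, mu = disp$mu[[3]])
  binge_28d <- rnbinom(n, size = 0.8, mu = 12)

  # purging-method flags: vomiting tied to its count; the laxative/diuretic
  # count item splits into laxative-only / diuretic-only / both usage
  method <- runif(n)
  lax_present <- laxdiur_28d > 0
  purge_vomiting <- vomit_28d > 0
  purge_laxative <- lax_present & method < 0.85
  purge_diuretic <- lax_present & method >= 0.60

  records <- tibble::tibble(
    id = sprintf("P%05d", seq_len(n)),
    stratum = stratum,
    ov_item_weight = ov_w,
    ov_item_shape = ov_s,
    edeq_global_wo = edeq_global_wo,
    depression_total = depression_total,
    anxiety_total = anxiety_total,
    vomit_28d = vomit_28d,
    laxdiur_28d = laxdiur_28d,
    exercise_28d = exercise_28d,
    binge_28d = binge_28d,
    purge_vomiting = purge_vomiting,
    purge_laxative = purge_laxative,
    purge_diuretic = purge_diuretic
  )
  if (spec$noise_covariates > 0) {
    for (j in seq_len(spec$noise_covariates)) {
      records[[paste0("noise_", j)]] <- rnorm(n)
    }
  }

  truth <- tibble::tibble(
    id = records$id,
    group = group,
    eta = eta,
    composite = composite
  )

  structure(list(records = records, truth = truth, spec = spec),
            class = "bn_cohort")
}

#' @export
print.bn_cohort <- function(x, ...) {
  cat("<bn_cohort>", nrow(x$records), "records,",
      length(unique(x$truth$group)), "planted group(s)\n")
  print(x$records, n = 5)
  invisible(x)
}

#' Write / read a synthetic cohort
#'
#' The analysis records go to a CSV (missing values as empty fields); the
#' planted truth goes to a JSON sidecar so the analysis inputs contain no
#' leakage.
#'
#' @param cohort A `bn_cohort`.
#' @param dir Directory to write into (created if absent).
#' @param stem File stem; writes `<stem>.csv` and `<stem>_truth.json`.
#' @return `write_cohort()` returns the two paths invisibly;
#'   `read_cohort()` returns a `bn_cohort` (with `truth = NULL` when no
#'   sidecar is found).
#' @export
write_cohort <- function(cohort, dir, stem = "cohort") {
  stopifnot(inherits(cohort, "bn_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  truth <- file.path(dir, paste0(stem, "_truth.json"))
  readr::write_csv(cohort$records, csv, na = "")
  jsonlite::write_json(cohort$truth, truth, digits = NA, na = "null")
  invisible(c(records = csv, truth = truth))
}

#' @rdname write_cohort
#' @param path Path to a cohort CSV written by [write_cohort()].
#' @param truth_path Optional path to the truth sidecar; by default the
#'   `<stem>_truth.json` next to `path` is used when present.
#' @export
read_cohort <- function(path, truth_path = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path))
  }
  if (file.size(path) == 0) {
    abort(paste0("cohort file is empty: ", path))
  }
  rec <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(rec) == 0) abort(paste0("cohort file has no records: ", path))
  probs <- readr::problems(rec)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed cohort file %s: first problem at row %d (%s)",
                  path, probs$row[1], probs$expected[1]))
  }
  known <- c(cohort_columns(), grep("^noise_", names(rec), value = TRUE))
  unknown <- setdiff(names(rec), known)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unknown column(s): ",
                paste(unknown, collapse = ", ")))
    rec <- rec[, setdiff(names(rec), unknown)]
  }
  missing_cols <- setdiff(cohort_columns(), names(rec))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (fl in c("purge_vomiting", "purge_laxative", "purge_diuretic")) {
    rec[[fl]] <- as.logical(rec[[fl]])
  }

  if (is.null(truth_path)) {
    cand <- sub("\\.csv$", "_truth.json", path)
    if (file.exists(cand)) truth_path <- cand
  }
  truth <- NULL
  if (!is.null(truth_path)) {
    truth <- tibble::as_tibble(jsonlite::fromJSON(truth_path))
  }
  structure(list(records = rec, truth = truth, spec = NULL),
            class = "bn_cohort")
}
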