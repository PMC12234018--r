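#' One-factor latent severity model, estimated by FIML
#'
#' The latent bulimia nervosa severity model has three manifest indicators
#' (z-scored cognitive eating-disorder, depression, and anxiety symptoms)
#' loading on a single latent factor through one shared loading
#' \eqn{\lambda}, with the latent variance fixed at 1 for identification.
#' The model-implied moments are \eqn{\mu = (m_1, m_2, m_3)} and
#' \eqn{\Sigma = \lambda^2 J + diag(resid_1, resid_2, resid_3)} (J the 3x3
#' all-ones matrix): 7 free parameters. Estimation maximises the
#' full-information maximum likelihood over all rows with at least one
#' observed indicator, so anxiety missingness costs no rows.
#'
#' @param data Data frame containing the indicator columns.
#' @param indicators Names of the three indicator columns, in order
#'   (cognitive, depression, anxiety).
#' @param start Optional starting values, a list with `loading`, `means`,
#'   `residual_variances`. Defaults: loading 0.5, sample means, half sample
#'   variances.
#' @param min_rows Minimum number of rows (default 8, one more than the
#'   free-parameter count).
#' @param control Passed to [stats::optim()] (method `L-BFGS-B`; residual
#'   variances on the log scale; loading bounded below by 0 to resolve the
#'   sign indeterminacy).
#' @return A `factor_fit`: loading, means, residual_variances, loglik, n,
#'   converged, n_free_params.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 400, true_cutpoints = numeric(0),
#'                                    group_latent_means = 0, seed = 3))
#' fit <- fit_factor_model(preprocess_cohort(coh))
#' glance(fit)
#' @export
fit_factor_model <- function(data,
                             indicators = c("z_cognitive", "z_depression",
                                            "z_anxiety"),
                             start = NULL, min_rows = 8, control = list()) {
  X <- indicator_matrix(data, indicators)
  if (nrow(X) < min_rows) {
    abort(sprintf("need at least %d rows to fit the factor model, got %d",
                  min_rows, nrow(X)))
  }
  nobs_per <- colSums(!is.na(X))
  if (any(nobs_per < 2)) {
    abort("each indicator needs at least 2 observed values")
  }
  vars <- apply(X, 2, var, na.rm = TRUE)
  if (any(vars <= 0)) {
    abort(sprintf("indicator `%s` has zero variance",
                  indicators[which(vars <= 0)[1]]))
  }
  theta0 <- if (is.null(start)) NULL else
    c(start$loading, start$means, log(start$residual_variances))
  opt <- fit_core(X, theta0, control)
  if (is.null(opt)) {
    abort("factor model optimisation failed on all starting values")
  }

  new_factor_fit(
    loading = opt$par[1],
    means = unname(opt$par[2:4]),
    residual_variances = unname(exp(opt$par[5:7])),
    loglik = -opt$value,
    n = nrow(X),
    converged = opt$convergence == 0,
    indicators = indicators
  )
}

new_factor_fit <- function(loading, means, residual_variances, loglik, n,
                           converged, indicators = NULL) {
  structure(
    list(loading = loading, means = means,
         residual_variances = residual_variances, loglik = loglik, n = n,
         converged = converged, n_free_params = 7L, indicators = indicators),
    class = "factor_fit"
  )
}

# Optimiser core over an indicator matrix; returns the raw optim result
# (or NULL when every start fails). Deterministic restarts, no RNG.
fit_core <- function(X, theta0 = NULL, control = list()) {
  stats <- make_fiml_stats(X)
  if (is.null(theta0)) {
    vars <- apply(X, 2, var, na.rm = TRUE)
    theta0 <- c(0.5, colMeans(X, na.rm = TRUE), log(pmax(vars / 2, 1e-3)))
  }
  fn <- function(th) fiml_nll_cpp(th, stats)
  gr <- function(th) fiml_nll_grad_cpp(th, stats)
  ctrl <- utils::modifyList(list(factr = 1e7, maxit = 500), control)
  lower <- c(0, rep(-Inf, 3), rep(log(1e-8), 3))

  opt <- NULL
  for (attempt in 0:2) {
    th_try <- theta0
    if (attempt > 0) {            # deterministic jitter, no RNG
      th_try <- theta0 + attempt * c(0.2, 0.1, -0.1, 0.1, 0.3, 0.3, 0.3)
      th_try[1] <- max(th_try[1], 0)
    }
    o <- tryCatch(
      stats::optim(th_try, fn, gr, method = "L-BFGS-B", lower = lower,
                   control = ctrl),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(opt) || o$value < opt$value)) opt <- o
    if (!is.null(opt) && opt$convergence == 0) break
  }
  opt
}

indicator_matrix <- function(data, indicators) {
  missing_cols <- setdiff(indicators, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("indicator column(s) not found: ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(data)[, indicators, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

# Per-missingness-pattern sufficient statistics (n, colsums, crossproduct)
# feeding the compiled FIML objective. Errors on all-missing rows.
make_fiml_stats <- function(X) {
  obs <- !is.na(X)
  none <- rowSums(obs) == 0
  if (any(none)) {
    abort(sprintf("row(s) %s have all indicators missing; exclude upstream",
                  paste(head(which(none), 5), collapse = ", ")))
  }
  code <- obs %*% c(1L, 2L, 4L)
  lapply(sort(unique(as.vector(code))), function(cd) {
    rows <- which(code == cd)
    cols <- which(bitwAnd(cd, c(1L, 2L, 4L)) > 0)
    Xi <- X[rows, cols, drop = FALSE]
    list(obs = as.integer(cols), n = length(rows), s = colSums(Xi),
         C = crossprod(Xi))
  })
}

#' Model-implied moments of a factor fit
#'
#' @param fit A `factor_fit` (or a list with `loading`, `means`,
#'   `residual_variances`).
#' @return List with `mean` (length 3) and `cov` (3x3,
#'   \eqn{\lambda^2 J + diag(resid)}).
#' @examples
#' implied_moments(list(loading = 0.8, means = c(0, 0, 0),
#'                      residual_variances = c(0.36, 0.36, 0.36)))
#' @export
implied_moments <- function(fit) {
  if (any(fit$residual_variances <= 0)) {
    abort("residual variances must be positive")
  }
  list(mean = fit$means,
       cov = fit$loading^2 * matrix(1, 3, 3) + diag(fit$residual_variances))
}

#' FIML log-likelihood of indicator data under a factor fit
#'
#' Sums, over rows, the log-density of each row's observed sub-vector under
#' the corresponding marginal of the model-implied normal: marginalisation
#' is simply selecting the observed entries of \eqn{\mu} and rows/columns of
#' \eqn{\Sigma}. Rows with all three indicators missing are an error; they
#' should have been excluded upstream.
#'
#' @inheritParams fit_factor_model
#' @param fit A `factor_fit` or compatible list.
#' @return The log-likelihood (a scalar).
#' @export
fiml_loglik <- function(fit, data,
                        indicators = fit$indicators %||%
                          c("z_cognitive", "z_depression", "z_anxiety")) {
  implied_moments(fit)  # validates residual variances
  X <- indicator_matrix(data, indicators)
  stats <- make_fiml_stats(X)
  -fiml_nll_cpp(fit_theta(fit), stats)
}

fit_theta <- function(fit) {
  c(fit$loading, fit$means, log(fit$residual_variances))
}

#' @export
print.factor_fit <- function(x, ...) {
  cat("<factor_fit> one-factor model, shared loading, FIML\n")
  cat(sprintf("  loading %.4f | resid (%.4f, %.4f, %.4f)\n", x$loading,
              x$residual_variances[1], x$residual_variances[2],
              x$residual_variances[3]))
  cat(sprintf("  means (%.4f, %.4f, %.4f)\n", x$means[1], x$means[2],
              x$means[3]))
  cat(sprintf("  loglik %.3f on n = %d (%sconverged)\n", x$loglik, x$n,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
logLik.factor_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free_params, nobs = object$n,
            class = "logLik")
}

#' @rdname fit_factor_model
#' @param x A `factor_fit`.
#' @param ... Unused.
#' @export
tidy.factor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("loading", paste0("mean_", 1:3), paste0("resid_", 1:3)),
    estimate = c(x$loading, x$means, x$residual_variances)
  )
}

#' @rdname fit_factor_model
#' @export
glance.factor_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = x$n, converged = x$converged,
                 n_free_params = x$n_free_params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
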