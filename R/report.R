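#' Compute an agreement report
#'
#' Runs the requested agreement coefficients on one set of paired ratings and
#' assembles a JSON-serializable report: the agreement summary, one entry per
#' estimator (kappa, chance agreement, guessing fraction where applicable,
#' model-violation flag), and optional confidence intervals. An estimator
#' whose preconditions fail (e.g. Gwet's AC1 on more than two categories)
#' contributes an error entry without aborting the others.
#'
#' @param ratings a [paired_ratings()] object.
#' @param estimators subset of `c("cohen", "gwet", "ml")`.
#' @param ci `"none"`, `"bootstrap"` (percentile interval per estimator) or
#'   `"normal"` (for the ML estimator: Wald interval for the guessing
#'   fraction plus its Lipschitz and monotone-map transfers to kappa).
#' @param level confidence level.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed; required when `ci = "bootstrap"`.
#' @param clamp passed to [ml_kappa()].
#' @return A list of class `agreement_report` with elements `summary`,
#'   `estimates` and `config`; serialize with [report_json()].
#' @examples
#' x <- paired_ratings(c("+", "+", "-", "+"), c("+", "-", "-", "+"))
#' compute_report(x, ci = "normal")
#' @export
compute_report <- function(ratings, estimators = c("cohen", "gwet", "ml"),
                           ci = c("none", "bootstrap", "normal"),
                           level = 0.95, n_boot = 2000, seed = NULL,
                           clamp = FALSE) {
  stopifnot(inherits(ratings, "paired_ratings"))
  ci <- match.arg(ci)
  estimators <- match.arg(estimators, c("cohen", "gwet", "ml"),
                          several.ok = TRUE)
  if (length(estimators) == 0L) stop("At least one estimator is required.",
                                     call. = FALSE)
  if (ci == "bootstrap" && is.null(seed)) {
    stop("`seed` is required for bootstrap intervals.", call. = FALSE)
  }
  smry <- summarize_agreement(ratings)

  estimates <- lapply(estimators, function(est) {
    fit <- tryCatch(
      switch(est,
             cohen = cohen_kappa(ratings),
             gwet = gwet_kappa(ratings),
             ml = ml_kappa(ratings, clamp = clamp)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(list(estimator = est, error = conditionMessage(fit)))
    }
    out <- list(estimator = est, kappa = fit$kappa, p_chance = fit$p_chance,
                n_categories = fit$n_categories,
                model_violation = fit$model_violation)
    if (!is.na(fit$r_hat)) out$r_hat <- fit$r_hat
    if (ci == "bootstrap") {
      out$interval <- tryCatch(
        interval_fields(bootstrap_ci(ratings, est, n_boot = n_boot,
                                     level = level, seed = seed,
                                     clamp = clamp)),
        error = function(e) list(error = conditionMessage(e)))
    } else if (ci == "normal" && est == "ml") {
      ci_r <- ci_r_normal(min(fit$r_hat, 1), smry$n_cases, level)
      out$interval_r <- interval_fields(ci_r)
      out$interval_lipschitz <- interval_fields(
        ci_kappa_lipschitz(ci_r, fit$n_categories))
      out$interval <- interval_fields(
        ci_kappa_monotone(ci_r, fit$n_categories))
    }
    out
  })
  names(estimates) <- estimators

  structure(
    list(summary = unclass(smry),
         estimates = estimates,
         config = list(estimators = estimators, ci = ci, level = level,
                       n_boot = if (ci == "bootstrap") n_boot else NULL,
                       seed = seed, clamp = clamp,
                       n_dropped = ratings$n_dropped,
                       categories = ratings$categories,
                       package_version = as.character(packageVersion("kappaML")))),
    class = "agreement_report"
  )
}

interval_fields <- function(x) {
  list(point = x$point, lower = x$lower, upper = x$upper, level = x$level,
       method = x$method, degenerate = x$degenerate)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (N = %d, Pa = %.4f)\n",
              x$summary$n_cases, x$summary$p_agree))
  for (e in x$estimates) {
    if (!is.null(e$error)) {
      cat(sprintf("  %-6s ERROR: %s\n", e$estimator, e$error))
    } else {
      cat(sprintf("  %-6s kappa = %.4f  (Pc = %.4f%s)\n", e$estimator,
                  e$kappa, e$p_chance,
                  if (!is.null(e$r_hat)) sprintf(", r = %.4f", e$r_hat) else ""))
      if (!is.null(e$interval) && is.null(e$interval$error)) {
        cat(sprintf("         %.0f%% CI [%.4f, %.4f] (%s)\n",
                    100 * e$interval$level, e$interval$lower,
                    e$interval$upper, e$interval$method))
      }
    }
  }
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report an `agreement_report` from [compute_report()].
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @param pretty pretty-print the JSON.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL, pretty = TRUE) {
  stopifnot(inherits(report, "agreement_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = pretty)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Flatten a report's estimates to a data frame
#'
#' One row per successfully computed estimator, suitable for TSV export.
#'
#' @param report an `agreement_report` from [compute_report()].
#' @return A data frame with columns `estimator`, `kappa`, `p_chance`,
#'   `r_hat`, `n_categories`, `model_violation`, and interval bounds when
#'   present.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  rows <- lapply(report$estimates, function(e) {
    if (!is.null(e$error)) return(NULL)
    data.frame(estimator = e$estimator, kappa = e$kappa,
               p_chance = e$p_chance,
               r_hat = if (is.null(e$r_hat)) NA_real_ else e$r_hat,
               n_categories = e$n_categories,
               model_violation = e$model_violation,
               ci_lower = if (is.null(e$interval$lower)) NA_real_ else e$interval$lower,
               ci_upper = if (is.null(e$interval$upper)) NA_real_ else e$interval$upper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
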