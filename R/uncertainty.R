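#' @rdname interval_estimate
#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%s %.0f%% interval: %.4f [%.4f, %.4f]%s\n", x$method,
              100 * x$level, x$point, x$lower, x$upper,
              if (isTRUE(x$degenerate)) "  (degenerate)" else ""))
  invisible(x)
}

#' Interval estimate container
#'
#' @param point,lower,upper point estimate and interval bounds
#'   (`lower <= point <= upper`).
#' @param level confidence level in `(0, 1)`.
#' @param method label for the construction used.
#' @param degenerate flag for zero-width intervals arising from degenerate
#'   input (e.g. no observed disagreements).
#' @return An object of class `interval_estimate`.
#' @keywords internal
#' @export
interval_estimate <- function(point, lower, upper, level, method,
                              degenerate = FALSE) {
  stopifnot(lower <= point + 1e-12, point <= upper + 1e-12,
            level > 0, level < 1)
  structure(list(point = point, lower = lower, upper = upper, level = level,
                 method = method, degenerate = degenerate),
            class = "interval_estimate")
}

#' Sampling variance of the ML guessing fraction
#'
#' For binary ratings of `N` cases with true guessing fraction `r`, the
#' number of disagreements is binomial with per-case probability `r/2`, and
#' the maximum-likelihood guessing fraction `r_ML = 2 Nd / N` has
#' \deqn{\mathrm{Var}[r_{ML}] = \frac{r\,(2 - r)}{N}.}
#' The variance is 0 at `r = 0` and largest (`1/N`) at `r = 1`.
#'
#' @param r guessing fraction(s) in `[0, 1]` (vectorized).
#' @param n_cases number of rated cases, `N >= 1`.
#' @return `r * (2 - r) / n_cases`.
#' @examples
#' var_r_ml(0.5, 100)  # 0.0075
#' @export
var_r_ml <- function(r, n_cases) {
  if (any(is.na(r)) || any(r < 0 | r > 1)) {
    stop("`r` must lie in [0, 1].", call. = FALSE)
  }
  if (length(n_cases) != 1L || is.na(n_cases) || n_cases < 1) {
    stop("`n_cases` must be a positive count.", call. = FALSE)
  }
  r * (2 - r) / n_cases
}

#' Normal-approximation interval for the guessing fraction
#'
#' Plug-in Wald interval `r_hat +/- z * sqrt(r_hat (2 - r_hat) / N)` based on
#' [var_r_ml()], clipped to `[0, 1]`. The plug-in uses the estimate itself
#' (clipped into `[0, 1]`) since the true `r` is unknown; at `r_hat = 0` the
#' plug-in variance vanishes and the interval degenerates to a point, which
#' is flagged.
#'
#' @param r_hat estimated guessing fraction (typically `r_hat` from
#'   [ml_kappa()]).
#' @param n_cases number of rated cases.
#' @param level confidence level (default 0.95).
#' @return An `interval_estimate` with `method = "normal_r"`.
#' @export
ci_r_normal <- function(r_hat, n_cases, level = 0.95) {
  stopifnot(length(r_hat) == 1L, !is.na(r_hat), level > 0, level < 1)
  r0 <- min(max(r_hat, 0), 1)
  half <- qnorm((1 + level) / 2) * sqrt(var_r_ml(r0, n_cases))
  interval_estimate(r0, max(r0 - half, 0), min(r0 + half, 1), level,
                    "normal_r", degenerate = half == 0)
}

#' Lipschitz-bound interval for kappa
#'
#' The map `f(r) = (1 - r)/(1 - r/n)` from guessing fraction to kappa has
#' derivative bounded by 2 in magnitude on `[0, 1]` (the bound is attained at
#' `r = 1` for `n = 2`). A guessing-fraction interval with centre `r0` and
#' half-width `delta` therefore transfers to the conservative kappa interval
#' `[f(r0) - 2 delta, f(r0) + 2 delta]`, clipped to `[-1, 1]`. It always
#' contains the exact monotone-map interval of [ci_kappa_monotone()].
#'
#' @param r_interval an `interval_estimate` for `r`, e.g. from
#'   [ci_r_normal()].
#' @param n_categories number of categories (default 2, the case for which
#'   the Lipschitz constant 2 is sharp).
#' @return An `interval_estimate` with `method = "lipschitz_kappa"`.
#' @export
ci_kappa_lipschitz <- function(r_interval, n_categories = 2) {
  stopifnot(inherits(r_interval, "interval_estimate"))
  delta <- max(r_interval$point - r_interval$lower,
               r_interval$upper - r_interval$point)
  k0 <- kappa_star_from_r(r_interval$point, n_categories)
  interval_estimate(k0, max(k0 - 2 * delta, -1), min(k0 + 2 * delta, 1),
                    r_interval$level, "lipschitz_kappa",
                    degenerate = delta == 0)
}

#' Monotone-map interval for kappa
#'
#' Exact image of a guessing-fraction interval under the strictly decreasing
#' map `f(r) = (1 - r)/(1 - r/n)`: the kappa interval is
#' `[f(upper_r), f(lower_r)]`. Never wider than the Lipschitz interval of
#' [ci_kappa_lipschitz()].
#'
#' @inheritParams ci_kappa_lipschitz
#' @return An `interval_estimate` with `method = "monotone_kappa"`.
#' @export
ci_kappa_monotone <- function(r_interval, n_categories = 2) {
  stopifnot(inherits(r_interval, "interval_estimate"))
  interval_estimate(kappa_star_from_r(r_interval$point, n_categories),
                    kappa_star_from_r(r_interval$upper, n_categories),
                    kappa_star_from_r(r_interval$lower, n_categories),
                    r_interval$level, "monotone_kappa",
                    degenerate = isTRUE(r_interval$degenerate))
}

#' Percentile-bootstrap interval for an agreement coefficient
#'
#' Resamples cases with replacement, recomputes the chosen coefficient on
#' each replicate, and returns the percentile interval. The resampling stream
#' is seeded per call, so results are deterministic given `seed` and leave
#' the global random-number state untouched. Replicates on which the
#' coefficient is undefined (e.g. degenerate marginals for Cohen's kappa)
#' are dropped from the percentile computation.
#'
#' @param ratings a [paired_ratings()] object with at least 2 cases.
#' @param estimator `"ml"`, `"cohen"` or `"gwet"`.
#' @param n_boot number of bootstrap replicates (default 2000, minimum 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; required, there is no hidden default.
#' @param clamp passed to [ml_kappa()] for the point estimate and applied to
#'   replicates (`r_ML > 1` truncated to 1, i.e. kappa floored at 0).
#' @return An `interval_estimate` with `method = "bootstrap"`. When the input
#'   has no disagreements every resample agrees everywhere, and the
#'   degenerate interval `[1, 1]` is returned with `degenerate = TRUE`.
#' @export
bootstrap_ci <- function(ratings, estimator = c("ml", "cohen", "gwet"),
                         n_boot = 2000, level = 0.95, seed, clamp = FALSE) {
  estimator <- match.arg(estimator)
  if (missing(seed)) stop("`seed` is required for bootstrap_ci().", call. = FALSE)
  if (n_boot < 100) stop("`n_boot` must be at least 100.", call. = FALSE)
  cd <- ratings_codes(ratings)
  if (cd$N < 2L) stop("Bootstrap requires at least 2 cases.", call. = FALSE)
  point <- switch(estimator,
                  ml = ml_kappa(ratings, clamp = clamp),
                  cohen = cohen_kappa(ratings),
                  gwet = gwet_kappa(ratings))$kappa

  reps <- withr::with_seed(seed, {
    idx <- matrix(sample.int(cd$N, cd$N * n_boot, replace = TRUE), nrow = cd$N)
    boot_kappa(cd, idx, estimator, clamp)
  })
  reps <- reps[is.finite(reps)]
  if (length(reps) == 0L) {
    stop("All bootstrap replicates were degenerate for estimator ",
         sQuote(estimator), ".", call. = FALSE)
  }
  qs <- unname(quantile(reps, c((1 - level) / 2, (1 + level) / 2)))
  degenerate <- qs[1L] == qs[2L]
  interval_estimate(point, min(qs[1L], point), max(qs[2L], point), level,
                    "bootstrap", degenerate = degenerate)
}

# vectorized kappa over a matrix of resample indices (columns = replicates)
boot_kappa <- function(cd, idx, estimator, clamp = FALSE) {
  A <- matrix(cd$a[idx], nrow = nrow(idx))
  B <- matrix(cd$b[idx], nrow = nrow(idx))
  p_agree <- colMeans(A == B)
  if (estimator == "ml") {
    n <- cd$n
    r_ml <- (1 - p_agree) * n / (n - 1)
    if (clamp) {
      p_chance <- pmin(r_ml, 1) / n
      p_agree <- ifelse(r_ml > 1, 1 / n, p_agree)
    } else {
      p_chance <- r_ml / n
    }
  } else if (estimator == "gwet") {
    pi_plus <- (colMeans(A == 1L) + colMeans(B == 1L)) / 2
    p_chance <- 2 * pi_plus * (1 - pi_plus)
  } else {
    p_chance <- 0
    for (k in seq_len(cd$n)) {
      p_chance <- p_chance + colMeans(A == k) * colMeans(B == k)
    }
    p_chance[1 - p_chance < 1e-12] <- NA_real_  # degenerate resample
  }
  (p_agree - p_chance) / (1 - p_chance)
}
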