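#' Theoretical kappa implied by a guessing fraction
#'
#' Under the occasional-guessing model a fraction `r` of cases are hard and
#' raters guess them uniformly over `n` categories, so chance agreement is
#' `Pc = r/n`, overall agreement is `Pa = 1 - r(n-1)/n`, and the theoretical
#' chance-corrected agreement is
#' \deqn{\kappa^* = \frac{P_a - P_c}{1 - P_c} = \frac{1 - r}{1 - r/n}.}
#' The map is strictly decreasing in `r`, with `kappa_star_from_r(0, n) = 1`
#' and `kappa_star_from_r(1, n) = 0`.
#'
#' @param r guessing fraction(s) in `[0, 1]` (vectorized).
#' @param n_categories number of categories, an integer `>= 2`.
#' @return `(1 - r) / (1 - r/n)`, a value in `[0, 1]`.
#' @examples
#' kappa_star_from_r(c(0, 0.5, 1), 2)  # 1, 2/3, 0
#' @seealso [r_from_kappa_star()] for the inverse map.
#' @export
kappa_star_from_r <- function(r, n_categories = 2) {
  check_n_categories(n_categories)
  if (any(is.na(r)) || any(r < 0 | r > 1)) {
    stop("`r` must lie in [0, 1].", call. = FALSE)
  }
  (1 - r) / (1 - r / n_categories)
}

#' Guessing fraction implied by a theoretical kappa
#'
#' Inverse of [kappa_star_from_r()]: solves `kappa* = (1 - r)/(1 - r/n)` for
#' the guessing fraction, giving `r = (1 - kappa*)/(1 - kappa*/n)`.
#'
#' @param kappa_star theoretical kappa value(s) in `[0, 1]` (vectorized).
#' @param n_categories number of categories, an integer `>= 2`.
#' @return Guessing fraction(s) in `[0, 1]`.
#' @examples
#' r_from_kappa_star(2 / 3, 2)  # 0.5
#' @export
r_from_kappa_star <- function(kappa_star, n_categories = 2) {
  check_n_categories(n_categories)
  if (any(is.na(kappa_star)) || any(kappa_star < 0 | kappa_star > 1)) {
    stop("`kappa_star` must lie in [0, 1].", call. = FALSE)
  }
  (1 - kappa_star) / (1 - kappa_star / n_categories)
}

#' Variance of a binary rating indicator
#'
#' For a binary classification made with probability `pi_plus` of choosing the
#' "+" category, the indicator variance is `pi_plus * (1 - pi_plus)`. Its
#' maximum, 1/4, is attained at `pi_plus = 1/2` (rating completely at
#' random); Gwet's AC1 estimates the guessing fraction as the ratio of the
#' observed indicator variance to this maximum.
#'
#' @param pi_plus rate(s) in `[0, 1]` at which a category is chosen.
#' @return `pi_plus * (1 - pi_plus)`, in `[0, 1/4]`.
#' @examples
#' rating_variance(0.5)  # 0.25, the maximum
#' @export
rating_variance <- function(pi_plus) {
  if (any(is.na(pi_plus)) || any(pi_plus < 0 | pi_plus > 1)) {
    stop("`pi_plus` must lie in [0, 1].", call. = FALSE)
  }
  pi_plus * (1 - pi_plus)
}

#' Analytic bias of Gwet's chance-agreement estimate
#'
#' Under the binary occasional-guessing model with guessing fraction `r` and
#' easy-case "+" prevalence `q`, the population value of Gwet's
#' chance-agreement formula is `2 pi_plus (1 - pi_plus)` with
#' `pi_plus = r/2 + (1 - r) q`, so it deviates from the model truth `r/2` by
#' \deqn{\Delta P_c = \frac{(1 - r)\,\big(r + 4 q (1 - q) (1 - r)\big)}{2}.}
#' At `q = 0` or `q = 1` (all easy cases in one category) this reduces to the
#' familiar prevalence-free form `r/2 - r^2/2`, which vanishes at
#' `r in {0, 1}` and peaks (1/8) at `r = 1/2`; that form is the default and
#' is a lower bound on the bias for any `q`. The extra term
#' `2 q (1 - q) (1 - r)^2` shows the chance-agreement overestimate grows as
#' the easy-case categories become balanced. In every case the bias is
#' non-negative and vanishes at `r = 1`, which is why AC1 is accurate at low
#' agreement (and, through `Pa -> 1`, at high agreement) but biased in
#' between.
#'
#' @param r guessing fraction(s) in `[0, 1]` (vectorized).
#' @param q easy-case "+" prevalence in `[0, 1]`; the default 0 gives the
#'   prevalence-free bias `r/2 - r^2/2`.
#' @return The chance-agreement bias of Gwet's formula.
#' @examples
#' gwet_bias_delta_pc(c(0, 0.5, 1))  # 0, 0.125, 0
#' gwet_bias_delta_pc(0.5, q = 0.2)  # 0.205: prevalence inflates the bias
#' @export
gwet_bias_delta_pc <- function(r, q = 0) {
  if (any(is.na(r)) || any(r < 0 | r > 1)) {
    stop("`r` must lie in [0, 1].", call. = FALSE)
  }
  if (any(is.na(q)) || any(q < 0 | q > 1)) {
    stop("`q` must lie in [0, 1].", call. = FALSE)
  }
  (1 - r) * (r + 4 * q * (1 - q) * (1 - r)) / 2
}

#' Log-likelihood of the agreement pattern under occasional guessing
#'
#' For `N = Na + Nd` cases of which `Nd` are disagreements, the
#' occasional-guessing model with guessing fraction `r` and `n` categories
#' gives each case disagreement probability `r(n-1)/n`, so
#' \deqn{L(r) = N_d \log\!\big(r\,(n-1)/n\big) +
#'       N_a \log\!\big(1 - r\,(n-1)/n\big).}
#' The maximizer over `r` in `[0, 1]` is the closed form
#' `min(1, (Nd/N) * n/(n-1))`; this surface is exposed so that the closed
#' form can be verified by direct search.
#'
#' @param r guessing fraction(s) in `[0, 1]` (vectorized). `r = 0` with
#'   `Nd > 0` yields `-Inf` by convention rather than an error.
#' @param summary an [summarize_agreement()] result (or any list with
#'   `n_agree` and `n_disagree`).
#' @param n_categories number of categories, an integer `>= 2`.
#' @return Log-likelihood value(s).
#' @export
og_log_likelihood <- function(r, summary, n_categories = 2) {
  check_n_categories(n_categories)
  if (any(is.na(r)) || any(r < 0 | r > 1)) {
    stop("`r` must lie in [0, 1].", call. = FALSE)
  }
  na <- summary$n_agree
  nd <- summary$n_disagree
  p_dis <- r * (n_categories - 1) / n_categories
  ll <- numeric(length(r))
  ll[p_dis == 0] <- if (nd > 0) -Inf else 0
  pos <- p_dis > 0
  ll[pos] <- nd * log(p_dis[pos]) + na * log1p(-p_dis[pos])
  ll
}

# shared constructor for estimator results
kappa_estimate <- function(estimator, kappa, p_chance, summary, n_categories,
                           r_hat = NA_real_, model_violation = FALSE,
                           extra = list()) {
  structure(
    c(list(estimator = estimator, kappa = kappa, p_chance = p_chance,
           r_hat = r_hat, n_categories = n_categories,
           model_violation = model_violation,
           p_agree = summary$p_agree, n_cases = summary$n_cases),
      extra),
    class = "kappa_estimate"
  )
}

#' @export
print.kappa_estimate <- function(x, ...) {
  label <- c(cohen = "Cohen's kappa", gwet = "Gwet's AC1",
             ml = "Maximum-likelihood kappa")[[x$estimator]]
  cat(sprintf("%s: %.4f  (Pa = %.4f, Pc = %.4f, N = %d, n = %d)\n",
              label, x$kappa, x$p_agree, x$p_chance, x$n_cases,
              x$n_categories))
  if (!is.na(x$r_hat)) {
    cat(sprintf("  estimated guessing fraction r = %.4f\n", x$r_hat))
  }
  if (isTRUE(x$model_violation)) {
    cat("  warning: disagreement rate exceeds the model's support (raw r > 1)\n")
  }
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance agreement under Cohen's "always guess" model: each rater is assumed
#' to assign categories at random with their observed marginal rates, so
#' `Pc = sum_k pA_k * pB_k` over categories `k`, and
#' `kappa = (Pa - Pc)/(1 - Pc)`.
#'
#' @param ratings a [paired_ratings()] object (any number of categories).
#' @return A `kappa_estimate` with `estimator = "cohen"`.
#' @examples
#' cohen_kappa(paired_ratings(c("+", "+", "-", "-"), c("+", "+", "-", "-")))
#' @seealso [gwet_kappa()], [ml_kappa()]
#' @export
cohen_kappa <- function(ratings) {
  smry <- summarize_agreement(ratings)
  m <- marginal_rates(ratings)
  p_chance <- sum(m$p_a * m$p_b)
  if (1 - p_chance < 1e-12) {
    stop("Degenerate marginals: both raters use a single identical category, ",
         "so Cohen's chance agreement is 1 and kappa is undefined.",
         call. = FALSE)
  }
  kappa_estimate("cohen", (smry$p_agree - p_chance) / (1 - p_chance),
                 p_chance, smry, length(ratings$categories))
}

#' Gwet's AC1
#'
#' Gwet's agreement coefficient estimates the guessing fraction as the ratio
#' of the observed rating variance to the maximal variance 1/4:
#' `r = pi_plus(1 - pi_plus) / (1/4)`, where `pi_plus` is the two raters'
#' average rate for one category. The implied chance agreement is
#' `Pc = 2 * pi_plus * (1 - pi_plus)` and `kappa = (Pa - Pc)/(1 - Pc)`.
#' Because `2p(1-p)` is symmetric in `p` and `1-p`, either category may serve
#' as "+". Only binary ratings are supported.
#'
#' @param ratings a [paired_ratings()] object with exactly two categories.
#' @return A `kappa_estimate` with `estimator = "gwet"` and an extra
#'   `pi_plus` element.
#' @examples
#' # low-agreement limit: pi_plus = 1/2 and Pa = 1/2 give kappa = 0
#' gwet_kappa(paired_ratings(c("+", "+", "-", "-"), c("+", "-", "+", "-")))
#' @export
gwet_kappa <- function(ratings) {
  if (length(ratings$categories) != 2L) {
    stop("Gwet's AC1 is implemented for binary ratings only; got ",
         length(ratings$categories), " categories.", call. = FALSE)
  }
  smry <- summarize_agreement(ratings)
  m <- marginal_rates(ratings)
  pi_plus <- (m$p_a[1L] + m$p_b[1L]) / 2
  p_chance <- rating_variance(pi_plus) / rating_variance(0.5) / 2
  kappa_estimate("gwet", (smry$p_agree - p_chance) / (1 - p_chance),
                 p_chance, smry, 2L, extra = list(pi_plus = pi_plus))
}

#' Maximum-likelihood kappa under the occasional-guessing model
#'
#' The likelihood of the observed agreement pattern under the
#' occasional-guessing model is maximized at guessing fraction
#' `r_ML = (Nd/N) * n/(n-1)` (twice the disagreement rate when `n = 2`). The
#' implied chance agreement is `Pc = r_ML / n` — for binary ratings simply the
#' observed disagreement rate — and `kappa = (Pa - Pc)/(1 - Pc)`, which
#' algebraically equals `kappa_star_from_r(r_ML, n)`. `E[r_ML] = r`, so the
#' guessing-fraction estimate is unbiased under the model.
#'
#' When the disagreement rate exceeds `(n-1)/n`, the raw `r_ML` exceeds 1,
#' which lies outside the model's support: the raters disagree more often
#' than uniform guessing can explain. By default the raw value is kept and
#' the resulting kappa is negative (the usual below-chance convention), with
#' `model_violation = TRUE` and a warning; `clamp = TRUE` instead truncates to
#' `r_ML = 1`, giving `kappa = 0`.
#'
#' @param ratings a [paired_ratings()] object (any number of categories).
#' @param clamp truncate a raw `r_ML > 1` to the model boundary `r = 1`
#'   (default `FALSE`: report the unclamped estimate).
#' @return A `kappa_estimate` with `estimator = "ml"`, including the guessing
#'   fraction `r_hat` and the `model_violation` flag.
#' @examples
#' x <- paired_ratings(c("+", "+", "-", "+"), c("+", "-", "-", "+"))
#' ml_kappa(x)  # r_ML = 0.5, Pc = 0.25, kappa = 2/3
#' @export
ml_kappa <- function(ratings, clamp = FALSE) {
  smry <- summarize_agreement(ratings)
  n <- length(ratings$categories)
  r_raw <- smry$p_disagree * n / (n - 1)
  violation <- r_raw > 1 + 1e-12
  if (violation) {
    warning("Observed disagreement rate (", signif(smry$p_disagree, 4),
            ") exceeds the occasional-guessing maximum (", (n - 1), "/", n,
            "): raw r_ML = ", signif(r_raw, 4),
            if (clamp) " clamped to 1." else " reported unclamped.",
            call. = FALSE)
  }
  r_hat <- if (violation && clamp) 1 else r_raw
  p_chance <- r_hat / n
  p_agree <- if (violation && clamp) 1 - (n - 1) / n else smry$p_agree
  kappa <- (p_agree - p_chance) / (1 - p_chance)
  kappa_estimate("ml", kappa, p_chance, smry, n, r_hat = r_hat,
                 model_violation = violation)
}

check_n_categories <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 2 || n != round(n)) {
    stop("`n_categories` must be a single integer >= 2.", call. = FALSE)
  }
  invisible(n)
}
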