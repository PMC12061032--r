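#' Parameters of the occasional-guessing model
#'
#' Defines the generative model for paired ratings: each case is hard with
#' probability `r`, in which case both raters independently guess uniformly
#' over the `n` categories (hard cases carry no true label); otherwise the
#' case is easy, its true label is drawn from `q`, and both raters report it.
#'
#' @param r fraction of hard cases, in `[0, 1]`.
#' @param q easy-case category distribution. For `n_categories = 2` a scalar
#'   is accepted and read as the probability of the first ("+") category,
#'   i.e. the distribution `(q, 1 - q)`. For `n_categories > 2` a full
#'   probability vector of length `n` is required (entries in `[0, 1]`,
#'   summing to 1 within `1e-12`).
#' @param n_categories number of categories, an integer `>= 2`.
#' @param labels optional category labels; defaults to `c("+", "-")` for two
#'   categories and `C1, ..., Cn` otherwise.
#' @return An object of class `og_params`.
#' @examples
#' og_params(r = 0.5, q = 0.2)
#' @export
og_params <- function(r, q, n_categories = 2, labels = NULL) {
  check_n_categories(n_categories)
  if (length(r) != 1L || is.na(r) || r < 0 || r > 1) {
    stop("`r` must be a single value in [0, 1].", call. = FALSE)
  }
  if (length(q) == 1L) {
    if (n_categories != 2L) {
      stop("Scalar `q` is only meaningful for 2 categories; supply a length-",
           n_categories, " probability vector.", call. = FALSE)
    }
    q <- c(q, 1 - q)
  }
  if (length(q) != n_categories) {
    stop("`q` must have one entry per category (", n_categories, "), got ",
         length(q), ".", call. = FALSE)
  }
  if (any(is.na(q)) || any(q < 0 | q > 1) || abs(sum(q) - 1) > 1e-12) {
    stop("`q` entries must lie in [0, 1] and sum to 1.", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (n_categories == 2L) c("+", "-") else
      sprintf("C%d", seq_len(n_categories))
  }
  if (length(labels) != n_categories || anyDuplicated(labels)) {
    stop("`labels` must be ", n_categories, " distinct values.", call. = FALSE)
  }
  structure(list(r = r, q = q, n_categories = as.integer(n_categories),
                 labels = as.character(labels)),
            class = "og_params")
}

#' @export
print.og_params <- function(x, ...) {
  cat(sprintf("Occasional-guessing model: r = %.3f, n = %d, q = (%s)\n",
              x$r, x$n_categories, paste(signif(x$q, 4), collapse = ", ")))
  invisible(x)
}

# one dataset from the model, as integer category codes; relies on the
# caller for seeding. Draw order: hardness, hard-case guesses (rater A then
# B), easy-case true labels.
og_draw <- function(r, q, n, n_cases) {
  hard <- runif(n_cases) < r
  n_hard <- sum(hard)
  a <- b <- integer(n_cases)
  if (n_hard > 0L) {
    a[hard] <- sample.int(n, n_hard, replace = TRUE)
    b[hard] <- sample.int(n, n_hard, replace = TRUE)
  }
  if (n_hard < n_cases) {
    truth <- sample.int(n, n_cases - n_hard, replace = TRUE, prob = q)
    a[!hard] <- truth
    b[!hard] <- truth
  }
  list(a = a, b = b)
}

#' Simulate paired ratings from the occasional-guessing model
#'
#' Draws `n_cases` cases: hard cases (probability `r`) are guessed
#' independently and uniformly by both raters; easy cases receive a true
#' label from `q` that both raters report. The generator is seeded per call
#' and restores the global random-number state, so the output is a pure
#' function of `(params, n_cases, seed)`.
#'
#' @param params an [og_params()] object.
#' @param n_cases number of cases to generate, `>= 1`.
#' @param seed integer seed; required.
#' @return A [paired_ratings()] object whose category set is
#'   `params$labels`.
#' @examples
#' x <- simulate_ratings(og_params(0.5, 0.2), n_cases = 100, seed = 1)
#' ml_kappa(x)
#' @export
simulate_ratings <- function(params, n_cases, seed) {
  stopifnot(inherits(params, "og_params"))
  if (missing(seed)) stop("`seed` is required for simulate_ratings().", call. = FALSE)
  if (length(n_cases) != 1L || is.na(n_cases) || n_cases < 1) {
    stop("`n_cases` must be a positive count.", call. = FALSE)
  }
  d <- withr::with_seed(seed,
    og_draw(params$r, params$q, params$n_categories, n_cases))
  paired_ratings(params$labels[d$a], params$labels[d$b],
                 categories = params$labels)
}

#' Model-implied agreement quantities
#'
#' Closed-form population values under the occasional-guessing model:
#' chance agreement `Pc = r/n`, overall agreement `Pa = 1 - r(n-1)/n`,
#' theoretical kappa `kappa* = (1 - r)/(1 - r/n)`, and (binary case) the
#' "+"-rating rate `pi_plus = r/2 + (1 - r) q`.
#'
#' @param params an [og_params()] object.
#' @return An object of class `theoretical_values`: a list with `r`,
#'   `n_categories`, `p_agree`, `p_chance`, `kappa_star` and `pi_plus`
#'   (`NA` unless binary).
#' @examples
#' theoretical_values(og_params(0.5, 0.2))  # Pa = 0.75, Pc = 0.25
#' @export
theoretical_values <- function(params) {
  stopifnot(inherits(params, "og_params"))
  n <- params$n_categories
  r <- params$r
  structure(
    list(r = r, n_categories = n,
         p_agree = 1 - r * (n - 1) / n,
         p_chance = r / n,
         kappa_star = kappa_star_from_r(r, n),
         pi_plus = if (n == 2L) r / 2 + (1 - r) * params$q[1L] else NA_real_),
    class = "theoretical_values"
  )
}

#' @export
print.theoretical_values <- function(x, ...) {
  cat(sprintf("Model values at r = %.3f, n = %d: Pa = %.4f, Pc = %.4f, kappa* = %.4f",
              x$r, x$n_categories, x$p_agree, x$p_chance, x$kappa_star))
  if (!is.na(x$pi_plus)) cat(sprintf(", pi+ = %.4f", x$pi_plus))
  cat("\n")
  invisible(x)
}
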