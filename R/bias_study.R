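#' Monte-Carlo bias sweep over the reliability range
#'
#' For each true reliability value `kappa*` on a grid, converts it to the
#' model guessing fraction `r = (1 - kappa*)/(1 - kappa*/2)`, simulates
#' `replicates` binary datasets of `n_cases` cases from the
#' occasional-guessing model, and records the across-replicate mean and
#' percentile band of Gwet's AC1 and of the maximum-likelihood kappa, along
#' with each estimator's mean chance-agreement estimate and the mean ML
#' guessing fraction. The default configuration (N = 100 cases, q = 0.2,
#' 95% bands, 21 grid points, 1000 replicates) spans the full reliability
#' range at a realistic study size.
#'
#' The ML kappa is left unclamped, so occasional replicates with raw
#' `r_ML > 1` contribute negative kappa values; this keeps the
#' across-replicate mean comparable with the unbiasedness analysis of
#' `E[r_ML] = r`.
#'
#' @param kappa_star_grid true kappa values in `[0, 1]` (sorted internally).
#' @param n_cases cases per simulated dataset.
#' @param replicates simulated datasets per grid point (minimum 100).
#' @param q easy-case "+" prevalence, a scalar in `[0, 1]`.
#' @param seed integer seed; required.
#' @param level band level for the across-replicate percentile interval.
#' @return An object of class `og_sweep`: a list with a per-grid-point
#'   data frame `table` (columns `kappa_star`, `r`, means, band bounds and
#'   mean chance-agreement estimates for both estimators, and `mean_r_ml`)
#'   plus the sweep configuration.
#' @examples
#' sw <- run_sweep(seq(0, 1, length.out = 5), n_cases = 50,
#'                 replicates = 200, q = 0.2, seed = 1)
#' bias_table(sw)
#' @seealso [bias_table()], [plot.og_sweep()]
#' @export
run_sweep <- function(kappa_star_grid = seq(0, 1, length.out = 21),
                      n_cases = 100, replicates = 1000, q = 0.2, seed,
                      level = 0.95) {
  if (missing(seed)) stop("`seed` is required for run_sweep().", call. = FALSE)
  if (any(is.na(kappa_star_grid)) ||
      any(kappa_star_grid < 0 | kappa_star_grid > 1)) {
    stop("`kappa_star_grid` values must lie in [0, 1].", call. = FALSE)
  }
  if (replicates < 100) stop("`replicates` must be at least 100.", call. = FALSE)
  grid <- sort(kappa_star_grid)
  r_grid <- r_from_kappa_star(grid, 2)
  qv <- c(q, 1 - q)
  probs <- c((1 - level) / 2, (1 + level) / 2)

  rows <- withr::with_seed(seed, lapply(seq_along(grid), function(i) {
    r <- r_grid[i]
    nd <- integer(replicates)
    n_plus <- integer(replicates)
    for (j in seq_len(replicates)) {
      d <- og_draw(r, qv, 2L, n_cases)
      nd[j] <- sum(d$a != d$b)
      n_plus[j] <- sum(d$a == 1L) + sum(d$b == 1L)
    }
    p_agree <- 1 - nd / n_cases
    r_ml <- 2 * nd / n_cases
    pc_ml <- nd / n_cases
    k_ml <- (p_agree - pc_ml) / (1 - pc_ml)
    pi_plus <- n_plus / (2 * n_cases)
    pc_gwet <- 2 * pi_plus * (1 - pi_plus)
    k_gwet <- (p_agree - pc_gwet) / (1 - pc_gwet)
    band_ml <- unname(quantile(k_ml, probs))
    band_gwet <- unname(quantile(k_gwet, probs))
    data.frame(kappa_star = grid[i], r = r,
               mean_gwet = mean(k_gwet),
               gwet_lower = band_gwet[1L], gwet_upper = band_gwet[2L],
               mean_ml = mean(k_ml),
               ml_lower = band_ml[1L], ml_upper = band_ml[2L],
               mean_pc_gwet = mean(pc_gwet), mean_pc_ml = mean(pc_ml),
               mean_r_ml = mean(r_ml))
  }))

  structure(list(table = do.call(rbind, rows), n_cases = n_cases,
                 replicates = replicates, q = q, seed = seed, level = level),
            class = "og_sweep")
}

#' @export
print.og_sweep <- function(x, ...) {
  cat(sprintf(
    "Occasional-guessing bias sweep: %d grid points, N = %d, %d replicates, q = %.2f\n",
    nrow(x$table), x$n_cases, x$replicates, x$q))
  print(bias_table(x), digits = 4)
  invisible(x)
}

#' Tabulate estimator bias from a sweep
#'
#' Per grid point: the empirical bias of Gwet's AC1 and of the ML kappa
#' relative to the true `kappa*`; the empirical bias of Gwet's
#' chance-agreement estimate relative to the model truth `r/2`, alongside the
#' prevalence-free closed form `r/2 - r^2/2` (`delta_pc`) and the exact
#' closed form at the sweep's `q` (`delta_pc_q`; see
#' [gwet_bias_delta_pc()]); and the empirical bias of the ML guessing
#' fraction (zero in expectation).
#'
#' @param result an `og_sweep` from [run_sweep()].
#' @return A data frame with one row per grid point.
#' @export
bias_table <- function(result) {
  stopifnot(inherits(result, "og_sweep"))
  tb <- result$table
  data.frame(kappa_star = tb$kappa_star, r = tb$r,
             gwet_bias = tb$mean_gwet - tb$kappa_star,
             gwet_pc_bias = tb$mean_pc_gwet - tb$r / 2,
             delta_pc = gwet_bias_delta_pc(tb$r),
             delta_pc_q = gwet_bias_delta_pc(tb$r, result$q),
             ml_bias = tb$mean_ml - tb$kappa_star,
             r_ml_bias = tb$mean_r_ml - tb$r)
}

#' Four-panel bias figure
#'
#' Plots, against the true `kappa*`: (A) the mean and band of Gwet's AC1,
#' (B) its bias, (C) the mean and band of the ML kappa, (D) its bias. The
#' identity line in (A)/(C) and the zero line in (B)/(D) mark an unbiased
#' estimator.
#'
#' @param x an `og_sweep` from [run_sweep()].
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.og_sweep <- function(x, ...) {
  tb <- x$table
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel_mean <- function(mean, lower, upper, label) {
    graphics::plot(tb$kappa_star, mean, type = "l", ylim = range(lower, upper, 0, 1),
                   xlab = expression(kappa^"*"), ylab = label)
    graphics::lines(tb$kappa_star, lower, lty = 2)
    graphics::lines(tb$kappa_star, upper, lty = 2)
    graphics::abline(0, 1, col = "grey60")
  }
  panel_bias <- function(bias, label) {
    graphics::plot(tb$kappa_star, bias, type = "l",
                   xlab = expression(kappa^"*"), ylab = label)
    graphics::abline(h = 0, col = "grey60")
  }
  panel_mean(tb$mean_gwet, tb$gwet_lower, tb$gwet_upper, "Gwet's AC1")
  panel_bias(tb$mean_gwet - tb$kappa_star, "AC1 bias")
  panel_mean(tb$mean_ml, tb$ml_lower, tb$ml_upper, expression(kappa[ML]))
  panel_bias(tb$mean_ml - tb$kappa_star, expression(kappa[ML] ~ "bias"))
  invisible(x)
}
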