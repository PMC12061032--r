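test_that("the guessing-fraction/kappa maps hit their closed-form values", {
  expect_identical(kappa_star_from_r(0, 2), 1)
  expect_identical(kappa_star_from_r(1, 2), 0)
  expect_equal(kappa_star_from_r(0.5, 2), 2 / 3)
  expect_identical(r_from_kappa_star(1, 2), 0)
  expect_identical(r_from_kappa_star(0, 2), 1)
  expect_equal(r_from_kappa_star(2 / 3, 2), 0.5)
  expect_error(kappa_star_from_r(1.1, 2), "\\[0, 1\\]")
  expect_error(r_from_kappa_star(-0.1, 2), "\\[0, 1\\]")
  expect_error(kappa_star_from_r(0.5, 1), "n_categories")
})

test_that("kappa* is decreasing in r and round-trips through its inverse", {
  r <- seq(0, 1, length.out = 101)
  for (n in c(2, 3, 5)) {
    ks <- kappa_star_from_r(r, n)
    expect_true(all(diff(ks) < 0))
    expect_true(all(ks >= 0 & ks <= 1))
    expect_equal(r_from_kappa_star(ks, n), r, tolerance = 1e-12)
    expect_equal(kappa_star_from_r(r_from_kappa_star(r, n), n), r,
                 tolerance = 1e-12)
  }
})

test_that("Cohen's kappa matches hand-worked and oracle values", {
  expect_equal(cohen_kappa(pattern_ratings(2, 0, 0, 2))$kappa, 1)

  # pA+ = pB+ = 0.75, Pa = 0.5, Pc = 0.625 -> kappa = -1/3
  est <- cohen_kappa(pr(c("+", "+", "+", "-"), c("+", "+", "-", "+")))
  expect_equal(est$p_chance, 0.625)
  expect_equal(est$kappa, -1 / 3)

  # independent oracle: e1071's contingency-table implementation
  set.seed(11)
  for (n in c(2, 4)) {
    labs <- letters[seq_len(n)]
    x <- pr(sample(labs, 60, replace = TRUE), sample(labs, 60, replace = TRUE),
            categories = labs)
    tab <- table(factor(x$ratings_a, labs), factor(x$ratings_b, labs))
    expect_equal(cohen_kappa(x)$kappa, e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
  }

  # two independent uniform raters agree only by chance
  set.seed(12)
  x <- pr(sample(c("+", "-"), 20000, replace = TRUE),
          sample(c("+", "-"), 20000, replace = TRUE))
  expect_lt(abs(cohen_kappa(x)$kappa), 0.03)

  expect_error(cohen_kappa(pr(rep("+", 4), rep("+", 4),
                              categories = c("+", "-"))),
               "Degenerate marginals")
})

test_that("Gwet's AC1 matches its worked limits", {
  # perfect agreement: kappa = 1 regardless of the chance estimate
  expect_equal(gwet_kappa(pattern_ratings(3, 0, 0, 1))$kappa, 1)

  # low-agreement limit: pi+ = 1/2, Pa = 1/2 -> Pc = 1/2, kappa = 0
  est <- gwet_kappa(pr(c("+", "+", "-", "-"), c("+", "-", "+", "-")))
  expect_equal(est$pi_plus, 0.5)
  expect_equal(est$p_chance, 0.5)
  expect_equal(est$kappa, 0)

  # Na = 8, Nd = 2, pi+ = 0.5 -> kappa = (0.8 - 0.5)/0.5 = 0.6
  est <- gwet_kappa(pattern_ratings(4, 1, 1, 4))
  expect_equal(est$kappa, 0.6)

  # symmetric in the category designation: relabel and compare
  x <- pattern_ratings(5, 2, 1, 3)
  flipped <- pr(chartr("+-", "-+", x$ratings_a), chartr("+-", "-+", x$ratings_b))
  expect_equal(gwet_kappa(x)$kappa, gwet_kappa(flipped)$kappa)

  expect_error(gwet_kappa(pr(c("a", "b"), c("b", "c"))), "binary")
})

test_that("the ML kappa equals its closed form and respects its bounds", {
  est <- ml_kappa(pattern_ratings(3, 1, 0, 0))
  expect_equal(est$r_hat, 0.5)
  expect_equal(est$p_chance, 0.25)
  expect_equal(est$kappa, 2 / 3)

  expect_equal(ml_kappa(pattern_ratings(2, 0, 0, 2))$kappa, 1)
  expect_equal(ml_kappa(pattern_ratings(1, 1, 1, 1))$kappa, 0)

  # kappa_ML == kappa_star_from_r(r_ML, n) and 0 < kappa_ML < Pa
  set.seed(21)
  for (i in 1:25) {
    n <- sample(c(2, 3, 5), 1)
    labs <- letters[seq_len(n)]
    N <- sample(5:60, 1)
    a <- sample(labs, N, replace = TRUE)
    b <- ifelse(runif(N) < 0.7, a, sample(labs, N, replace = TRUE))
    x <- pr(a, b, categories = labs)
    est <- suppressWarnings(ml_kappa(x))
    f <- function(r) (1 - r) / (1 - r / n)  # same map, extended past r = 1
    expect_equal(est$kappa, f(est$r_hat), tolerance = 1e-12)
    if (est$r_hat <= 1) {
      expect_equal(est$kappa, kappa_star_from_r(est$r_hat, n),
                   tolerance = 1e-12)
    }
    if (est$r_hat > 0 && est$r_hat < 1) {
      expect_gt(est$kappa, 0)
      expect_lt(est$kappa, summarize_agreement(x)$p_agree)
    }
  }
})

test_that("disagreement beyond the model support is flagged, not hidden", {
  x <- pattern_ratings(1, 2, 1, 0)  # Pd = 0.75 -> raw r_ML = 1.5
  expect_warning(est <- ml_kappa(x), "exceeds")
  expect_true(est$model_violation)
  expect_equal(est$r_hat, 1.5)
  expect_equal(est$kappa, -2)  # (0.25 - 0.75)/(1 - 0.75)

  expect_warning(clamped <- ml_kappa(x, clamp = TRUE), "clamped")
  expect_true(clamped$model_violation)
  expect_equal(clamped$r_hat, 1)
  expect_equal(clamped$kappa, 0)
})

test_that("all three estimators give 1 under perfect, non-degenerate agreement", {
  x <- pattern_ratings(6, 0, 0, 4)
  expect_equal(cohen_kappa(x)$kappa, 1)
  expect_equal(gwet_kappa(x)$kappa, 1)
  expect_equal(ml_kappa(x)$kappa, 1)
})

test_that("the log-likelihood surface peaks at the closed-form maximizer", {
  grid <- seq(1e-4, 1, by = 1e-4)
  for (case in list(c(na = 3, nd = 1, n = 2), c(na = 5, nd = 5, n = 2),
                    c(na = 17, nd = 4, n = 3))) {
    s <- list(n_agree = case[["na"]], n_disagree = case[["nd"]])
    ll <- og_log_likelihood(grid, s, case[["n"]])
    closed <- min(1, case[["nd"]] / (case[["na"]] + case[["nd"]]) *
                    case[["n"]] / (case[["n"]] - 1))
    expect_lt(abs(grid[which.max(ll)] - closed), 1.01e-4)
  }
  # conventions at the boundary
  expect_identical(og_log_likelihood(0, list(n_agree = 3, n_disagree = 1), 2),
                   -Inf)
  expect_identical(og_log_likelihood(0, list(n_agree = 3, n_disagree = 0), 2),
                   0)
  # no disagreements: likelihood is decreasing in r
  ll0 <- og_log_likelihood(grid, list(n_agree = 10, n_disagree = 0), 2)
  expect_true(all(diff(ll0) < 0))
})

test_that("the chance-agreement bias formula matches its construction", {
  expect_equal(gwet_bias_delta_pc(c(0, 0.5, 1)), c(0, 0.125, 0))
  # default (q = 0) is the prevalence-free form r/2 - r^2/2, maximal at 1/2
  r <- seq(0, 1, length.out = 51)
  expect_equal(gwet_bias_delta_pc(r), r / 2 - r^2 / 2)
  expect_equal(r[which.max(gwet_bias_delta_pc(r))], 0.5)
  # general form is exactly 2 pi(1-pi) - r/2 with pi = r/2 + (1-r) q
  set.seed(31)
  for (i in 1:20) {
    rr <- runif(1); qq <- runif(1)
    pi_plus <- rr / 2 + (1 - rr) * qq
    expect_equal(gwet_bias_delta_pc(rr, qq), 2 * pi_plus * (1 - pi_plus) - rr / 2,
                 tolerance = 1e-12)
  }
  # prevalence-free form is exact at q in {0, 1} and a lower bound otherwise
  expect_equal(gwet_bias_delta_pc(r, 0), gwet_bias_delta_pc(r, 1))
  expect_true(all(gwet_bias_delta_pc(r, 0.3) >= gwet_bias_delta_pc(r)))
  expect_error(gwet_bias_delta_pc(1.2), "\\[0, 1\\]")
})

test_that("the maximal rating variance is 1/4 at a balanced rate", {
  p <- seq(0, 1, by = 1e-3)
  v <- rating_variance(p)
  expect_equal(max(v), 0.25)
  expect_equal(p[which.max(v)], 0.5)
  expect_identical(rating_variance(0.5), 0.25)
})
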