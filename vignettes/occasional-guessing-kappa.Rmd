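---
title: "Interrater reliability under the occasional-guessing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interrater reliability under the occasional-guessing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kappaML)
```

## The model

Two raters independently classify `N` cases into `n` mutually exclusive
categories. Every chance-corrected agreement coefficient has the form
`kappa = (Pa - Pc)/(1 - Pc)`, with `Pa` the observed agreement rate and
`Pc` a *model* of how often the raters agree by accident. kappaML is built
around one such model, the **occasional-guessing model**:

* a case is *hard* with probability `r` (0 ≤ r ≤ 1); on hard cases each
  rater independently guesses uniformly over the `n` categories;
* otherwise the case is *easy*: it has a true label, drawn from a category
  distribution `q`, and both raters report it correctly.

The model's population quantities follow directly: hard cases agree with
probability `1/n`, easy cases always, so

* chance agreement `Pc = r/n`,
* total agreement `Pa = 1 - r(n-1)/n`,
* true reliability `kappa* = (Pa - Pc)/(1 - Pc) = (1 - r)/(1 - r/n)`.

`kappa_star_from_r()` and `r_from_kappa_star()` implement this strictly
decreasing map and its inverse, for any `n ≥ 2`; the binary inverse is
`r = (1 - kappa*)/(1 - kappa*/2)`, and the general inverse is the same
algebra with `n` in place of 2.

## Three estimators of `Pc`

**Cohen's kappa** (`cohen_kappa()`) models chance with an *always-guess*
assumption: each rater assigns categories at random at their observed
marginal rates, `Pc = Σ_k pA_k pB_k`. The per-category marginal-product sum
is the standard multi-category form; for two categories it reduces to
`pA+ pB+ + pA- pB-`.

**Gwet's AC1** (`gwet_kappa()`) adopts the occasional-guessing model but
estimates the guessing fraction heuristically, as the ratio of the observed
rating variance to the maximal variance of a random binary rating
(`rating_variance()`; the maximum is 1/4, at a balanced rate):
`r ≈ pi+(1 - pi+)/(1/4)`, hence `Pc = 2 pi+(1 - pi+)` where `pi+` is the two
raters' average rate for one category. Since `2p(1-p)` is symmetric in
`p ↔ 1-p`, no category designation is needed. The construction is inherently
binary and the package deliberately refuses `n > 2` for it rather than
invent an extension.

**The maximum-likelihood kappa** (`ml_kappa()`) estimates `r` by maximizing
the likelihood of the observed agreement indicators. Each case disagrees
with probability `r(n-1)/n`, so with `Nd` disagreements and `Na`
agreements the log-likelihood is

```
L(r) = Nd log(r (n-1)/n) + Na log(1 - r (n-1)/n)
```

(`og_log_likelihood()`; the surface is exported precisely so that the
closed form can be verified against direct grid search, which the test
suite does at step 1e-4). Setting `dL/dr = 0` gives

```
r_ML = (Nd/N) * n/(n-1),      Pc = r_ML/n  =  Nd/(N(n-1)),
```

which for binary ratings is simply: *the chance-agreement probability is
the observed disagreement rate*. Because `Nd` is a binomial count with
per-case probability `r(n-1)/n`, `E[r_ML] = r` exactly — the
guessing-fraction estimate is unbiased under the model at every `N`. The
resulting kappa satisfies the algebraic identity
`kappa_ML = kappa_star_from_r(r_ML, n)` whenever `r_ML ≤ 1`, and
`0 < kappa_ML < Pa` whenever `0 < r_ML < 1`.

### When the data contradict the model

If the disagreement rate exceeds `(n-1)/n`, the raw `r_ML` exceeds 1: the
raters disagree more often than uniform guessing can produce. By default
`ml_kappa()` reports the unclamped value — the kappa then comes out
negative, matching the below-chance convention of the other coefficients —
sets `model_violation = TRUE` and warns. Silently truncating would hide
data that falsify the model; truncation to the boundary (`r = 1`,
`kappa = 0`) is available explicitly via `clamp = TRUE`.

## Why AC1 is biased at intermediate agreement

Under the model the rate of "+" ratings is `pi+ = r/2 + (1 - r) q` (binary
case, `q` = probability that an easy case is truly "+"). Substituting into
AC1's chance formula and subtracting the model truth `r/2` gives the exact
population bias

```
Delta_Pc(r, q) = 2 pi+ (1 - pi+) - r/2
              = (1 - r) (r + 4 q (1 - q) (1 - r)) / 2
              = r/2 - r^2/2 + 2 q (1 - q) (1 - r)^2 .
```

`gwet_bias_delta_pc(r, q)` implements this. Two readings matter:

* With all easy cases in a single category (`q ∈ {0, 1}`) the second term
  vanishes, leaving the prevalence-free form `r/2 - r²/2` — zero at
  `r ∈ {0, 1}` and maximal (1/8) at `r = 1/2`. This simpler form is often
  quoted as *the* AC1 bias and is the function's default (`q = 0`), but it
  is only a lower bound in general.
* For interior `q` the extra term `2q(1-q)(1-r)²` can dominate: at
  `q = 0.2, r = 0.5` the true `Pc` bias is 0.205, not 0.125, and the bias
  is *not* invariant to `q`. The Monte-Carlo acceptance check of the
  prevalence-free form at interior `q` is accordingly expected to fail, and
  the test suite keeps that check at its stated conditions rather than
  quietly substituting the exact formula; the sweep's `bias_table()` reports
  both closed forms (`delta_pc`, `delta_pc_q`) next to the empirical bias.

None of this rescues AC1's kappa at the extremes for the wrong reasons: at
high agreement `Pa → 1` forces `kappa → 1` regardless of `Pc`, and at
`r = 1` the bias term vanishes, which is exactly why AC1 looks accurate at
high and low agreement while being biased in between.

## Variance and confidence intervals

For binary ratings `Nd ~ Binomial(N, r/2)`, so

```
Var[r_ML] = (4/N²) Var[Nd] = r (2 - r) / N
```

(`var_r_ml()`; zero at `r = 0`, maximal `1/N` at `r = 1`). The package
offers three interval constructions on top of it, plus a bootstrap:

1. `ci_r_normal()` — Wald interval for `r`, plugging `r_hat` (clipped into
   `[0, 1]`) into the variance, clipped to `[0, 1]`. At `r_hat = 0` the
   plug-in variance vanishes; the zero-width interval is flagged
   `degenerate` rather than hidden.
2. `ci_kappa_lipschitz()` — the map `f(r) = (1 - r)/(1 - r/n)` has
   `|f'| ≤ 2` on `[0, 1]` (sharp at `r = 1`, `n = 2`), so an `r`-interval of
   half-width `δ` transfers to `[f(r0) - 2δ, f(r0) + 2δ]`, clipped to
   `[-1, 1]`. One notational subtlety was resolved deliberately: the
   transfer is *centred* at `f(r0)` with half-width `2δ`; reading it instead
   as the pair `f(r0 - 2δ), f(r0 + 2δ)` would produce a reversed interval,
   since `f` is decreasing.
3. `ci_kappa_monotone()` — the exact image `[f(upper), f(lower)]` of the
   `r`-interval under the decreasing map. Always contained in the Lipschitz
   interval (the suite checks containment on randomized intervals); it is
   the default kappa interval in `compute_report(ci = "normal")`, with the
   Lipschitz one reported alongside as the conservative classical bound.
4. `bootstrap_ci()` — percentile interval over case-resampled replicates.
   Percentile (rather than BCa or studentized) is the simplest defensible
   choice and is exactly reproducible under the mandatory per-call seed.
   The replicate statistics are computed by a vectorized index-matrix
   sweep; the test suite verifies replicate-for-replicate equality with a
   naive loop through the public estimator functions under the same seed.

The analytic variance is binary-model algebra; no closed form is offered
for `n > 2`, where the bootstrap applies unchanged.

### A finite-sample note on `kappa_ML`

Unbiasedness is a statement about `r_ML`. The kappa itself is the
*nonlinear* image `f(r_ML)`, and `f` is strictly concave, so at finite `N`
the mean of `kappa_ML` sits slightly below `kappa*` (a Jensen gap of order
`1/N`). It is negligible over most of the range but largest at `r = 1`,
where at `N = 100` the expected gap is about −0.02. The bias sweep
therefore asserts exact unbiasedness on `r_ML` and treats the kappa-scale
gap as a documented finite-sample property, not a defect of the estimator.

## The simulator

`simulate_ratings()` draws directly from the generative model:
per case a hardness indicator (probability `r`); hard cases get two
independent uniform guesses — hard cases have *no* true label, which is
consistent with every probability above, and guesses are uniform over all
`n` categories including any would-be truth; easy cases get one label from
`q`, reported by both raters. Scalar `q` with `n = 2` means the
distribution `(q, 1-q)` over `("+", "-")`; for `n > 2` a full probability
vector is required. Each call uses its own seeded stream and restores the
global RNG state, so simulations are pure functions of their arguments.

What the simulator does *not* emulate — and hence what passing tests do not
establish about real ratings: rater-specific or correlated guessing, easy
cases that are occasionally mis-rated, graded case difficulty, more than
two raters, and missingness (the reader drops incomplete cases pairwise and
reports the count). On real data the occasional-guessing model is an
idealization; `model_violation` is the one diagnostic the data themselves
can raise against it.

## The bias sweep

`run_sweep()` walks a grid of true `kappa*` values (default 21 equally
spaced points — a grid density chosen here, not dictated by theory),
converts each to `r`, simulates `replicates` binary datasets of `n_cases`,
and records the mean and central percentile band of AC1 and of the
(unclamped) ML kappa, their mean chance-agreement estimates, and the mean
`r_ML`. The default configuration — `N = 100`, `q = 0.2`, 1000 replicates,
95% bands — represents a realistically sized two-rater agreement study with
unbalanced prevalence. Bands are across-replicate percentiles: the
sweep-level analogue of per-dataset bootstrap intervals, which remain
available through `bootstrap_ci()`. `plot()` renders the four standard
panels (mean vs truth and bias, for each estimator).

## Numerical and interface choices

* All proportions in double precision; exactness assertions in the suite
  use absolute tolerance 1e-12.
* Likelihood-vs-closed-form verification uses grid step 1e-4 on `[0, 1]`;
  agreement is required within one grid step.
* The category set is inferred as the sorted union of observed labels
  unless supplied; supply it explicitly whenever a category can go
  unobserved, because `n` enters the multi-category formulas.
* Monte-Carlo problem sizes in the test suite (e.g. 100,000 replicates at
  `N = 100` for the unbiasedness and variance checks, 1000 outer
  simulations for bootstrap coverage, 20,000 replicates per point for the
  chance-agreement bias) were sized so each claim is resolved at three
  Monte-Carlo standard errors.
* Reports serialize to JSON (`report_json()`) with a flat TSV alternative
  (`report_table()`); the command-line front end in `inst/cli/` is a thin
  wrapper over these functions with YAML config support, command-line flags
  winning on conflict.

## Limitations

Two raters only; AC1 restricted to binary ratings; no weighted or ordinal
agreement, no AC2, no Scott's pi / Fleiss kappa, no tests comparing two
kappas. Hard-case guessing is uniform — nonuniform guessing distributions
are not modeled. The analytic variance (and hence the normal/Lipschitz/
monotone intervals) is binary; multi-category uncertainty goes through the
bootstrap.
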