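---
title: "A mechanistic Markov model of gene-duplicate retention under subfunctionalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic Markov model of gene-duplicate retention under subfunctionalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subfunr)
```

## The model

After a duplication event a genome briefly carries two perfect copies of a
gene. Under the duplication–degeneration–complementation (DDC) view of
regulatory subfunctionalization, each copy has `z` mutable regulatory
regions, null mutations fix neutrally and independently at Poisson rate
`u_r` per regulatory region and `u_c` per coding region, and selection
merely insists that at least one working copy of every sub-function
survives somewhere in the pair. Two fates compete:

* **pseudogenization (P)** — one copy loses all function and is lost; the
  other is preserved;
* **subfunctionalization (S)** — the copies end up with complementary
  regulatory repertoires, so selection retains both forever.

Because a second regulatory hit in the *other* copy immediately triggers
`S`, it suffices to count the null mutations fixed so far while the fate is
undecided. That gives an absorbing continuous-time Markov chain on
`{0, 1, ..., z-1} ∪ {S, P}` whose transient block `Q*` is upper bidiagonal:

* `0 → P` at `2 u_c`, `0 → 1` at `2 z u_r`;
* `i → P` at `u_c`, `i → S` and `i → i+1` each at `(z - i) u_r`, for
  `1 ≤ i ≤ z-2`;
* `z-1 → P` at `u_r + u_c`, `z-1 → S` at `u_r`.

The absorption time is therefore phase-type, and every quantity the package
reports is a closed-form functional of `exp(Q* t)`, the exit-rate columns
`v_S`, `v_P`, and `(Q*)^{-1}`:

* transient occupancy `e_0 exp(Q* t)`, absorption probabilities
  `e_0 (-Q*)^{-1} v_j`, absorption-time moments
  `(-1)^k k! e_0 (Q*)^{-k} 1`;
* hazard and cause-specific hazards of the absorption time
  (`hazard()`, `cause_specific_hazard()`);
* the **pseudogenization rate** `h_P(t)`, the hazard of the defective
  pseudogenization time `T_P` in which subfunctionalized pairs remain in
  the risk set forever (`pseudo_rate()`); it tends to 0 as `t → ∞`
  whenever `u_r > 0`, unlike the cause-specific hazard;
* the survival `P(T_P > t) = 1 - e_0 (exp(Q* t) - I)(Q*)^{-1} v_P`
  (`pseudo_survival()`), which is what binned genome data constrain.

Time is measured in `s`, silent substitutions per silent site; `u_c` and
`u_r` are rates per unit `s`. All rate functions accept
`dimensionless = TRUE` to re-express the model with `u_c = 1` (time in
units of `1/u_c`, the natural scale for shape analysis). `z = 1` is
rejected everywhere: subfunctionalization is then impossible and survival
is exponential with rate `2 (u_c + u_r)` — provided separately as
`exponential_survival()` and recovered automatically in the `u_r = 0`
limit.

## Shape diagnostics

`h_P(t)` is sigmoidal when the inflection (root of its second derivative)
falls in physical time. The derivatives are evaluated exactly from
`d/dt e_0 exp(Q* t) v = e_0 Q* exp(Q* t) v` and the quotient rule — never
by finite differences (finite differences serve only as an independent
oracle in the tests). `gamma_crit(z)` finds, by bisection in
`gamma = u_r/u_c`, the ratio at which the inflection sits exactly at
`t = 0`; below it the curve is visibly sigmoidal, above it the inflection
retreats to negative `t` and the curve looks exponential for `t ≥ 0`.

Expanding `e_0 (Q*)^k v_P` at `t = 0` gives closed forms that the
root-finder reproduces to `1e-9` and the tests pin down:

* `z ≥ 4`: `h_P''(0) = 2 z u_c^3 γ ((z+1) γ − 1)`, so
  `gamma_crit = 1/(z+1)` — e.g. `0.0769` at `z = 12`;
* `z = 3`: `h_P''(0) = 6 u_c^3 γ (2 γ² + 4 γ − 1)`, so
  `gamma_crit = (√6 − 2)/2 ≈ 0.2247`;
* `z = 2`: `h_P''(0) = −4 u_c^3 γ (3γ − 1)(2γ − 1)` is **cubic**, with two
  interior roots `1/3` and `1/2`. `gamma_crit(2)` returns the smaller and
  attaches both as an attribute. For `1/3 < γ < 1` the z = 2 curve keeps a
  positive-time inflection (up to three of them near `γ ≈ 1/3`), so the
  tidy "sigmoidal below, exponential-like above" trichotomy — which the
  package's property tests verify across `z = 3..20` — genuinely does not
  extend to `z = 2`.

`inflection_time()` scans physical time first (log-spaced grid to
`50/u_c`, bisection at each sign change) and only then the negative-`t`
analytic continuation, which reuses the same matrix-exponential expression
without a probabilistic reading. The scan stops on either side once
`|t| · max|diag Q*| > 30`: beyond that the continuation mixes magnitudes
around `e^30` and double-precision cancellation leaves noise, which
early versions of the scan dutifully reported as spurious roots. Within
the trustworthy window the continuation can still hold real extra
structure (at `z = 3`, `γ = gamma_crit`, a second root sits near
`t ≈ −5.6`); classification always concerns the root nearest the origin.

## Fitting binned duplicate counts

The observable is a table of counts `D_i` of duplicate pairs whose ages
fall in bins of width `0.01 s` (about 1.1 Myr in mammals), `s_i = 0.01 i`.
With duplications arising as a Poisson process at mean `beta0` per bin and
surviving independently, each bin is Poisson with mean
`beta(s_i) = beta0 · P(T_P > s_i)`, and the log-likelihood is
`Σ_i [D_i log beta(s_i) − beta(s_i) − lgamma(D_i + 1)]`. Empty bins simply
contribute `−beta(s_i)`.

`fit_mle()` maximizes over `(u_r, u_c, beta0)` for each `z` in `2..20`
(a gene with more than 20 regulatory regions being implausible) and picks
the grid arg-max `z_hat`. Numerical choices:

* log-parameterization of all three continuous parameters (positivity for
  free, and the surface is closer to quadratic);
* Nelder-Mead from 10 multi-starts drawn log-uniformly over
  `[1e-2, 1e2] ×` plausible scales (`1/max(s)` for rates,
  `max(D)` for `beta0`), followed by a BFGS polish of the best start;
  `reltol 1e-12`. The multi-start matters because `γ` and `z` are strongly
  ridge-correlated: many `(z, γ)` pairs imply nearly the same survival
  curve, so per-`z` surfaces are flat and near-ties across `z` are common.
  `fit_mle` therefore reports every `z` within 2 log-units of the maximum,
  and breaks exact ties (within `1e-6`) to the smallest `z`;
* the likelihood evaluates the survival on the whole bin grid at once via
  the eigendecomposition of the triangular `Q*` (an exponential mixture),
  falling back to a dense scaling-and-squaring matrix exponential per time
  point whenever two diagonal entries agree to better than `1e-9`
  relatively (confluent eigenvalues, e.g. `u_r → 0`). The fast path
  matches the exact path to machine precision in the tests.

`profile_interval()` reports `e²` likelihood intervals — parameter values
whose profile log-likelihood stays within 2 of the maximum, asymptotically
95.4% confidence intervals. Endpoints come from bisection on the profile;
the deficit at a reported endpoint is 2 to `1e-6`. The lower `u_r`
endpoint may legitimately hit 0 (the exponential submodel); it is then
reported as 0 with an `at_bound` flag rather than extrapolated.

`fit_with_z_prior()` replaces fixed `z` by a Poisson(`alpha`) truncated to
`[2, 20]` and fits `(alpha, u_r, u_c, beta0)` against the mixture
survival. Its output carries a caveat: the likelihood rewards priors that
concentrate on a single support point (especially the truncation edges),
because the continuous parameters can then specialize to that `z`, so
concentrated fitted weights should not be over-interpreted.

`aic_compare()` embeds exponential (2 parameters) and Weibull (3) survival
curves in the same Poisson-count wrapper. The Weibull optimizer is seeded
at the fitted exponential (`shape = 1` submodel), so its log-likelihood
can never fall below the exponential's. Whether the mechanistic model
should be charged for `z` is genuinely arguable when `z` is selected over
a small grid, so the table carries both accountings (4 and 3 parameters).

## The synthetic-data generator

`simulate_trajectory()` / `simulate_ensemble()` are exact Gillespie
simulations of the chain — exponential holding times at the total exit
rate, next state by normalized rates — and serve as an oracle that is
independent of every matrix-exponential code path: ensemble fate
frequencies, absorption-time moments and CDF (Kolmogorov–Smirnov), and the
pseudogenization-time survival (subfunctionalized pairs held in the risk
set forever) are all checked against the analytic formulas within 3
standard errors at `1e5` replicates.

`simulate_counts()` draws the binned data exactly as the likelihood
assumes: independent Poisson counts with mean `beta0 · P(T_P > s_i)` on
the `0.01 s` grid. It emulates the *generative law* of the genome data,
not its ascertainment quirks: real duplicate tables inherit alignment
filtering, age-estimation error in `s`, rate heterogeneity across loci and
a non-stationary duplication process, none of which are simulated. Passing
recovery tests therefore demonstrate correctness of the inference
machinery under the model, not robustness to those real-data features.

`recovery_experiment()` closes the loop: simulate, refit, profile, tally
coverage. Replicate `r` uses seed `base + r`, so every stochastic result
in the package is bitwise reproducible. Two study conditions are built in
as defaults, mirroring the fitted mammalian genomes: a rat-like truth
(`z = 2, u_c = 3.04, u_r = 0.67, beta0 = 204.04`) with 30 bins, which
reproduces the instability of `z_hat` across replicates (low counts and a
low mutation rate leave little information, and `z_hat` wanders over the
grid while the truth stays inside the `e²` intervals), and a mouse-like
truth (`z = 3, u_c = 20.07, u_r = 3.26, beta0 = 680.84`) with 100 bins,
under which the `e²` intervals cover each continuous parameter in well
over 80% of replicates. Coverage is assessed with `z` held at its true
value (`fix_z = TRUE`): profile intervals for the continuous parameters
are defined under the structural model, and intervals computed at a
mis-selected `z_hat` measure the selection instability (reported
separately) rather than interval calibration.

Problem sizes used by the shipped checks — `1e5` Gillespie paths for the
oracle comparisons, 20 replicates for recovery and model-comparison
experiments, `2e4` paths in the faster unit-level checks — were chosen
once as the smallest sizes at which 3-standard-error bands are
discriminating.

## Numerical edge cases and known limitations

* `u_r = 0` is accepted everywhere (`Q*` stays invertible) and all
  quantities collapse to the exponential special case; the confluent
  eigenvalues route the survival through the dense-exponential fallback.
* Rates deep in the tail are guarded: when the survival denominator drops
  below `1e-300` the evaluation fails loudly instead of returning noise,
  and a non-positive denominator on the negative-`t` continuation is an
  error, never clipped.
* The piecewise-constant hazard approximations take the expected waiting
  time for the i-th mutation as the sojourn `1/|Q*[i-1, i-1]|`; this
  choice only affects the historical approximation, not any exact
  quantity. The uncorrected variant (rate 0 beyond `t_z`) is retained for
  comparison because it encodes the consequential old assumption that
  subfunctionalization happens exactly at the z-th mutation.
* The multi-root behavior of the `z = 2` shape diagnostics (above) means
  `shape_report()`'s regime label and inflection sign can legitimately
  disagree at `z = 2`.
* Everything assumes one shared `(z, u_c, u_r)` across all pairs in a
  genome, a single duplication rate `beta0`, and error-free bin ages; the
  `z`-prior fit relaxes only the first of these, partially.
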