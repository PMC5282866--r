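# subfunr

Mechanistic modeling of what happens to a pair of gene duplicates after a
duplication event, for people who study gene-family evolution from genomic
duplicate-age distributions. Two fates compete under regulatory
subfunctionalization (the DDC scenario): **pseudogenization** — one copy
loses all function and is lost — and **subfunctionalization** — the copies
end up with complementary regulatory repertoires and selection keeps both.
Instead of fitting an off-the-shelf survival curve and interpreting its
parameters loosely, `subfunr` models the mechanism directly and estimates
biologically meaningful quantities: the number of regulatory regions `z`
and the fixation rates of null mutations in coding (`u_c`) and regulatory
(`u_r`) regions, per silent substitution per silent site.

## The model in brief

A duplicate pair with `z` mutable regulatory regions per gene evolves as an
absorbing continuous-time Markov chain on `{0, ..., z-1} ∪ {S, P}`, where
the transient state counts null mutations fixed while the fate is
undecided. The generator's transient block `Q*` is upper bidiagonal, with
exit columns `v_S`, `v_P`:

```
0 → P : 2 u_c          0 → 1 : 2 z u_r
i → P : u_c            i → S, i → i+1 : (z−i) u_r     (1 ≤ i ≤ z−2)
z−1 → P : u_r + u_c    z−1 → S : u_r
```

Absorption times are phase-type, so everything is closed-form in
`exp(Q* t)`: survival `P(T_P > t) = 1 − e₀ (exp(Q* t) − I)(Q*)⁻¹ v_P`,
hazard and cause-specific hazards, absorption probabilities and moments,
and the pseudogenization rate
`h_P(t) = e₀ exp(Q* t) v_P / P(T_P > t)`, whose sigmoidal-versus-
exponential shape (quantified by the critical ratio `gamma_crit(z)` of
`γ = u_r/u_c` and the inflection time) is the model's signature
prediction. Binned genome data — counts `D_i` of duplicate pairs per
`0.01 s` age bin — enter through independent Poisson bins with mean
`β(s_i) = β₀ P(T_P > s_i)`, fitted by maximum likelihood over `z = 2..20`
with `e²` profile-likelihood intervals and AIC comparison against Weibull
and exponential baselines.

## Worked example

```r
library(subfunr)

m <- duplicate_model(z = 3, u_c = 15, u_r = 2.5)
absorption_probabilities(m)
#>   p_S   p_P
#> 0.075 0.925
```

With these rates only 7.5% of pairs ever subfunctionalize; the rest lose a
copy. The shape diagnostics for a slowly-mutating regulatory complement
(`z = 12`, `γ = 0.005`):

```r
shape_report(z = 12, gamma = 0.005)
#> Pseudogenization-rate shape report
#>   z           = 12
#>   gamma       = 0.005
#>   gamma_crit  = 0.07692
#>   inflection  = 2.678 (units 1/u_c)
#>   regime      = sigmoidal-visible
```

`γ` is below the critical ratio for `z = 12`, so the pseudogenization rate
is visibly sigmoidal: flat near `t = 0`, with its change of concavity at
2.68 time units (`1/u_c`). Simulate a genome-like data set and fit it back:

```r
dat <- simulate_counts(m, dup = 300, n_bins = 60, seed = 42)
fit <- fit_mle(dat, z_grid = 2:6, n_starts = 6, seed = 1, intervals = TRUE)
fit
#> Subfunctionalization model fit
#>   z_hat = 3 (near-ties within 2 log-units: 2, 3, 4, 5, 6)
#>   u_r = 2.393, u_c = 14.14 (gamma = 0.1692), beta0 = 296.5
#>   logLik = -186.5068 over 60 bins
#>   e2 likelihood intervals:
#>     u_r   [2.142, 2.671]
#>     u_c   [12.32, 16.22]
#>     beta0 [261.7, 336.5]
```

The true `z = 3` is selected (every `z` on the small grid is a near-tie —
the `γ`–`z` likelihood ridge is a real feature of this model), and each
true parameter lies inside its `e²` interval. The mechanistic fit crushes
the exponential baseline and beats the Weibull here:

```r
aic_compare(dat, fit, seed = 1)
#>                                  model n_par    logLik      AIC delta_AIC rel_likelihood
#> 1     subfunctionalization (z counted)     4 -186.5068 381.0135      2.00   3.678794e-01
#> 2 subfunctionalization (z conditioned)     3 -186.5068 379.0135      0.00   1.000000e+00
#> 3                              weibull     3 -221.2326 448.4651     69.45   8.294189e-16
#> 4                          exponential     2 -450.1079 904.2158    525.20  8.990470e-115
```

A command-line wrapper over the same functions is installed at
`system.file("scripts", "subfun.R", package = "subfunr")` with subcommands
`fit`, `profile`, `compare`, `rates`, `shape`, `gamma-crit`, `simulate`
and `recover`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","subfun.R",package="subfunr"))')" \
  gamma-crit --z 12
```

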