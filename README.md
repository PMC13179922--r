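# ltrcks

Omnibus k-sample Kolmogorov–Smirnov and Cramér–von Mises tests for
left-truncated right-censored (LTRC) survival data, with a bootstrap
approximation of their null distributions, the weighted log-rank family as
directional comparators, and a warp-speed Monte Carlo engine for
calibration and power studies.

## The problem and who this is for

Survival analysts often need to decide whether `k ≥ 2` groups share a
common event-time distribution when subjects enter the study late (left
truncation: a subject with entry time `U` is observed only if `U ≤ X`) and
may leave it early (right censoring: only `Y = min(X, C)` and
`Δ = I[X ≤ C]` are recorded).  The standard tools for this design are rank
tests, which are not omnibus — they can have trivial power against
crossing or non-ordered alternatives.  This package provides consistent
omnibus alternatives.

Each group's event-time distribution is estimated by the product-limit
estimator with inclusive risk sets `r_i = #{U ≤ x_i ≤ Y}` and an optional
`r+1` hole correction,

    F̂_j(t) = 1 − ∏_{x_i ≤ t} (1 − d_i / (r_i + 1)),

the common distribution under H0 by the convex combination
`F̂_n = Σ_j p_j F̂_j` (default `p_j = n_j/n`), and the statistics are

    D_KS  = sup_t Σ_j n_j (F̂_j(t) − F̂_n(t))²
    D_CvM = Σ_j n_j ∫ (F̂_j(t) − F̂_n(t))² dF̂_n(t),

both computed over the pooled uncensored event times.  P-values come from
the *obvious bootstrap* under the null: event times are resampled from the
pooled estimate while each group keeps its own estimated truncation
distribution `Ĝ_j` and residual-censoring distribution `Q̂_j`
(`D = C − U`), and the truncation filter `U ≤ X` is re-applied.

## Worked example

Three synthetic groups shaped like an unemployment-duration study
(n = 246/413/350, roughly 50 % truncation loss, roughly 80 % censoring):

```r
library(ltrcks)
samples <- fixture_unemployment_like(seed = 1)
fit <- ltrcfit(samples)
fit
#> Nonparametric LTRC fit (3 groups, hole-corrected)
#>     group   n events  gamma
#>      none 246     62 0.3632
#>       one 413     84 0.4526
#>  two_plus 350     67 0.3944

ltrc_ktest(samples, B = 199, seed = 7)
#> k-sample omnibus tests for left-truncated right-censored data
#>
#> groups: none, one, two_plus (n = 246, 413, 350), weights = 0.2438, 0.4093, 0.3469
#> evaluation window: [0.1781, 36.67], B = 199 bootstrap resamples
#>
#>   Kolmogorov-Smirnov : D = 7.67776, p = 0.6784
#>   Cramer-von Mises   : D = 3.47983, p = 0.5075

ltrc_rank_test(samples)
#> Log-rank test for LTRC data (p = 0, q = 0)
#>   chi-square = 4.01527 on 2 df, p-value = 0.1343
```

Reading the output: `gamma` is each group's estimated nontruncation
probability `P(U ≤ X)` — here around 0.4, i.e. late entry removes roughly
60 % of the population from view.  `D` is the observed statistic and `p`
the proportion of the `B` bootstrap replicates at least as large; all
three groups were generated from the same distribution, and none of the
tests rejects.

Simulation studies use the fixed scenario catalogue:

```r
warp_speed_study(11, sizes = c(100, 100, 100), M = 2000, seed = 1)$rejection
```

A thin command-line wrapper is installed with the package
(`inst/cli/ltrcks`), with `test`, `simulate` and `fixture` subcommands
over delimited text tables.

## Package layout

* `ltrcfit()` — per-group estimates (event-time, truncation,
  residual-censoring distributions, nontruncation probability) with
  `print`/`summary`/`plot`/`predict`/`simulate` methods; `simulate()` is
  the obvious bootstrap.
* `ltrc_ktest()`, `ks_statistic()`, `cvm_statistic()` — the omnibus tests.
* `ltrc_rank_test()` — the weighted log-rank family (LR, LR^E, LR^M, LR^L).
* `scenario_catalog()`, `simulate_ltrc_sample()`, `theoretical_gamma()`,
  `warp_speed_study()` — the simulation engine.
* `read_ltrc_table()`, `run_test_command()`, `run_simulate_command()` —
  I/O and the engines behind the CLI.

The methods vignette (`vignettes/ltrc-ksample-tests.Rmd`) documents the
estimators, the bootstrap plan, the design choices and known limitations.
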