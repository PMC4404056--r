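# mbetat

Differential expression testing for gene- and isoform-level read count
matrices with **few replicate libraries**, built on a weighted beta-binomial
model of per-library proportions, plus the negative-binomial scenario
simulator and evaluation harness used to benchmark it.

## The problem

With 3–5 replicate libraries per condition, count data suffer a
small-sample *fudge effect*: some features get, by chance, tiny
within-group variances together with a gap between the two groups, so
their t-statistics explode and false discoveries flood the rejection
region. Methods that moderate every statistic by a global constant pay for
the fix with power.

## The method

For a feature with counts `X_i` in libraries of size `N_i`, the per-library
proportion `p_i = X_i / N_i` is modelled as Beta(α, β). Each condition is
summarised by a weighted proportion

```
p̂ = Σ w_i p̂_i,   w_i ∝ (1/(α+β) + 1/N_i)⁻¹
```

with the weights, α+β, and the weighted unbiased variance `V̂*` estimated
jointly by an iterative method-of-moments loop. The working variance is
floored, `V̂ = max(V̂*, V̂#)`, where `V̂#` is an alternative variance built
from pooled counts and the mean library size, so that features whose
replicate proportions coincide never get a vanishing denominator. The test
statistic between conditions A and B is a Welch-style

```
t = (p̂_A − p̂_B) / √(V̂_A + V̂_B),
df = (V̂_A + V̂_B)² / (V̂_A²/(N_A−1) + V̂_B²/(N_B−1))
```

and its key refinement is a per-feature **gap factor** ρ = √(ψ ζ): ψ (the
*polar ratio*) exceeds 1 exactly when the two count ranges are disjoint,
and ζ (a noise-moderated log odds ratio) shrinks as within-condition noise
grows. The reported statistic is `t* = (ρ/ω) t` — inflated for cleanly
separated count sets, shrunken toward zero for overlapping or noisy ones.
The threshold ω is calibrated on simulated null data matched to the
dataset: run the test without shrinkage, take the gap factors of the false
discoveries, pick their 0.85-quantile, and average over several null
datasets. Two-sided p-values come from the t-distribution (or a pooled
bootstrap), with Benjamini–Hochberg or Storey FDR adjustment.

## Worked example

```r
library(mbetat)

sc  <- simulate_scenario(scenario_config(n_features = 2000, A = 100,
                                         P = 0.1, Q = 0.1, R = 3, seed = 7))
cal <- calibrate_omega(sc$counts, S = 5, seed = 8)
res <- mbeta_test(sc$counts, omega = cal)
glance(res)
#> # A tibble: 1 × 7
#>   n_features n_discoveries omega shrink alpha fdr_method p_method
#> 1       1950            50  1.27 TRUE    0.05 BH         t
dplyr::arrange(tidy(res), q_value)[1:3, c("feature", "log_fc", "t", "rho", "t_star", "q_value")]
#>   feature log_fc     t   rho t_star  q_value
#> 1 f01174   -3.89  4.69  3.12  11.5  2.80e-27
#> 2 f00516   -2.77  5.05  2.70  10.7  1.20e-23
#> 3 f00893   -4.07  3.27  4.14  10.6  1.37e-23
evaluate_calls(res, sc$truth)
#> # A tibble: 1 × 8
#>   n_discoveries n_found  n_de true_fdr power index efficiency alpha
#> 1            50      50   200        0  0.25     1       0.25  0.05
```

The simulator planted 200 truly differential features among 1950 retained
ones; at an estimated-FDR cutoff of 0.05 the test reports 50 discoveries,
all of them truly differential (true FDR 0, so the conservativeness index
is 1 and efficiency equals the power, 0.25). The
top features show the gap factor at work: well-separated count sets with
ρ ≈ 3 have their t-statistics roughly tripled.

`autoplot(res)` draws log fold change against `t*` — the diagnostic plot
showing the null features compressed into a narrow band around zero.

A thin command-line wrapper with subcommands `test`, `simulate`,
`calibrate-omega`, `benchmark` and `evaluate` lives in
`inst/scripts/mbeta-cli.R`:

```sh
Rscript inst/scripts/mbeta-cli.R simulate --out sim --n-features 5000 --seed 1
Rscript inst/scripts/mbeta-cli.R test --counts sim/counts.tsv --design sim/design.tsv \
    --out run --omega calibrate --seed 1
```

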