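# popbenefit

Population-level risk–benefit indices for biomarkers and risk factors used
to trigger disease early-detection or preventive intervention.

A biomarker that looks strong by association (a large odds ratio) can still
be a poor basis for intervening on a population: if the disease is rare or
the marker is common, most marker-positive people are false positives, and
every false positive pays the cost of an unnecessary intervention.
`popbenefit` quantifies this trade-off for epidemiologists and biomarker
researchers deciding whether a validated marker is worth deploying — and
whether it is better suited to early detection or to prevention.

## The indices

For a binary marker, the population is the standard 2×2 table of joint
fractions *a* (marker+/diseased), *b* (marker+/healthy), *c*
(marker−/diseased), *d* (marker−/healthy). Given an odds ratio, marker
prevalence and disease prevalence, the package solves the table exactly
(cell *a* is the admissible root of a quadratic), from which follow
sensitivity *a*/(*a*+*c*), specificity *d*/(*b*+*d*), and the population
attributable risk percent

&nbsp;&nbsp;PAR% = (r₁ − r₂)/r₁ × 100, &nbsp; r₁ = a + c, &nbsp; r₂ = c/(c + d).

The central quantity is the *ratio of population benefit* (RPB). Weighing a
gain f₁ per early-detected case against a loss f₂ per falsely intervened
non-case (1 − the quality-of-life utility weight of the intervention),

&nbsp;&nbsp;RPB = (a·f₁ − b·f₂) / (a·f₁ + b·f₂ + c·f₁ + d·f₂),

negative/zero/positive meaning detrimental/neutral/beneficial at the
population level. The prevention variant credits efficacy η only to the
true positives and charges an adverse-effect loss δ to everyone treated:
RPB = (a·η·f₁ − a·δ − b·δ) / (same denominator). Decision-curve net benefit
(NB = a − w·b) and absolute gain with a per-person intervention cost *h*
are computed alongside, and all indices support stratified
(confounder-adjusted) case-weighted averaging.

Continuous markers use an equal-variance binormal model calibrated so the
per-unit log-odds slope equals ln OR (mean shift σ²·ln OR, defaults μ = 0,
σ = 0.5), with threshold policies (fixed sensitivity, fixed specificity,
balanced, explicit), ROC curves, and the integral forms of every index —
closed-form Gaussian tails by default, adaptive quadrature for arbitrary
density pairs and for marker-dependent η(x), δ(x).

A seeded cohort simulator generates individual-level data from any scenario
and plug-in estimators recover all indices empirically.

## Worked example

A marker with 10% prevalence evaluated for breast-cancer intervention
(f₂ = 0.06, disease prevalence 1%):

```r
library(popbenefit)
library(tibble)

tibble(odds_ratio = c(4, 20, 50), marker_prev = 0.10, disease_prev = 0.01) |>
  binary_benefit(f2 = 0.06) |>
  dplyr::select(odds_ratio, sensitivity, specificity, par_percent, rpb, nb)
#> # A tibble: 3 × 6
#>   odds_ratio sensitivity specificity par_percent     rpb       nb
#>        <dbl>       <dbl>       <dbl>       <dbl>   <dbl>    <dbl>
#> 1          4       0.303       0.902        22.5 -0.0402 -0.00279
#> 2         20       0.675       0.906        63.9  0.0167  0.00116
#> 3         50       0.836       0.907        81.8  0.0412  0.00286
```

At OR = 4 the program is net harmful (RPB < 0): the marker would remove
22.5% of disease burden if used preventively on a causal exposure, yet as a
detection trigger the false-positive losses dominate. Only at OR ≥ 20 does
population benefit turn positive, and even then the RPB (~0.02–0.04) is a
small fraction of its prevalence-determined ceiling.

The continuous analogue, thresholding a binormal marker with OR = 50:

```r
tibble(odds_ratio = 50, policy = c("fixed_specificity", "balanced"),
       disease_prev = 0.01) |>
  continuous_benefit(f2 = 0.03, level = 0.95) |>
  dplyr::select(policy, threshold, sensitivity, specificity, par_percent, rpb, nb)
#> # A tibble: 2 × 7
#>   policy            threshold sensitivity specificity par_percent    rpb      nb
#>   <chr>                 <dbl>       <dbl>       <dbl>       <dbl>  <dbl>   <dbl>
#> 1 fixed_specificity     0.822       0.622       0.95         60.0 0.119  0.00474
#> 2 balanced              0.489       0.836       0.836        80.2 0.0879 0.00349
```

Keeping specificity at 95% sacrifices sensitivity (0.62) but yields the
higher RPB (0.119): with a 1%-prevalence disease, controlling false
positives matters more than catching every case.

`benefit_table_binary()` and `benefit_table_continuous()` regenerate the
full reference grids (30 binary and 18 continuous scenarios across three
cancer utility-loss settings); `render_benefit_table()` rounds them to
display precision. `autoplot()` methods plot ROC curves and RPB-vs-OR
profiles. A command-line interface wraps everything
(`inst/cli/popbenefit binary --or 20 --marker-prev 0.10 --disease-prev 0.01
--f2 0.03`, plus `continuous`, `table1`, `table2`, `roc`, `simulate`,
`empirical`).

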