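# qmoments

Estimate a study's sample mean and standard deviation from the quantile
summaries it actually reported.

## The problem

Meta-analysis of continuous outcomes needs each trial's sample mean X̄ and
standard deviation S, but many trials report a median with a range and/or
an interquartile range instead.  Three reporting patterns dominate:

| Scenario | Reported                                   |
|----------|--------------------------------------------|
| C1       | `{a, m, b; n}` — min, median, max          |
| C2       | `{a, q1, m, q3, b; n}` — five-number summary |
| C3       | `{q1, m, q3; n}` — quartiles only          |

`qmoments` converts any of these into mean and SD estimates.  The mean
estimators are weighted quantile averages:

    C1: X̄ ≈ (a + 2m + b) / 4
    C2: X̄ ≈ (a + 2q1 + 2m + 2q3 + b) / 8
    C3: X̄ ≈ (q1 + m + q3) / 3

The SD estimators rescale the reported spread by expected values of
standard-normal order statistics Z₍r:n₎, so that the divisor adapts to the
sample size:

    ξ(n) = 2·E(Z₍n:n₎)        (range → SD)        S ≈ (b − a) / ξ(n)
    η(n) = 2·E(Z₍3Q+1:n₎)     (IQR → SD, n = 4Q+1) S ≈ (q3 − q1) / η(n)
    C2 combined:               S ≈ ½ [ (b − a)/ξ(n) + (q3 − q1)/η(n) ]

`ξ(n)` and `η(n)` are computed exactly by adaptive quadrature of the
order-statistic expectation integral, or by the Blom closed forms
`2·Φ⁻¹((n − 0.375)/(n + 0.25))` and `2·Φ⁻¹((0.75n − 0.125)/(n + 0.25))`.
The classical sample-size-independent rules — Hozo's adaptive range rule,
Bland's five-number formula, and the Cochrane Handbook's `(q3 − q1)/1.35`
— are included as comparators, and a seeded Monte-Carlo framework
measures every estimator's bias.

## Worked example

A trial of 41 patients reports min 10, median 20, max 70:

```r
library(qmoments)
s <- summary_input(41, min = 10, median = 20, max = 70, study_id = "trial-1")
estimate_moments(s)
#>   study_id scenario  n    method mean_est   sd_est
#> 1  trial-1       C1 41 hozo_mean       30       NA
#> 2  trial-1       C1 41  range_sd       NA 13.82054
```

The mean estimate is `(10 + 2·20 + 70)/4 = 30`; the SD estimate divides
the range 60 by `ξ(41) = 4.341`, giving 13.8 — against 15 from the crude
`(b − a)/4` rule, which ignores that wider ranges are expected at n = 41.

With the full five-number summary the combined estimator averages the
range-based and IQR-based values:

```r
s2 <- summary_input(41, min = 0, q1 = 0.4, median = 0.7, q3 = 1.0, max = 1.5)
estimate_moments(s2)$sd_est
#> [1]        NA 0.4029966   # bland_mean row, combined_sd row
```

i.e. `½·(1.5/4.341 + 0.6/1.303) ≈ 0.403`.

How biased are these? Reproduce a bias curve directly:

```r
run_study("normal", list(mean = 5, sd = 1), "C2", n_grid = c(5, 41, 201),
          methods = c("combined_sd", "bland_sd"), reps = 1000, seed = 7)
#> combined_sd stays within ~1% from n = 41 on; bland_sd swings from
#> about -33% at n = 5 to about +24% at n = 201.
```

## Command line

The installed `exec/qmoments` script exposes everything:

```sh
qmoments estimate --in studies.csv --out results.csv --policy recommended
qmoments tables   --which xi --max 50 --mode exact --out xi.csv
qmoments simulate --study c2 --dist lognormal --params location=5,scale=0.25 \
                  --reps 1000 --seed 42 --out sim.csv --plot sim.png
qmoments fixture  --dist normal --params mean=5,sd=1 --scenario C2 \
                  --n 41 --reps 20 --seed 1 --out fixture.csv
```

Input CSVs have header `study_id,n,min,q1,median,q3,max` with blank cells
for unreported values; a YAML file passed as `--config` supplies option
defaults that explicit flags override.

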