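---
title: "Estimating means and standard deviations from quantile summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating means and standard deviations from quantile summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmoments)
```

## The model

Trials that report a median with a range and/or interquartile range force
the meta-analyst to impute the mean and SD.  `qmoments` does this under a
working normality assumption.  Write $X_{(1)} \le \dots \le X_{(n)}$ for
the ordered sample and, for sizes of the form $n = 4Q + 1$, identify the
reported summaries with order statistics: $a = X_{(1)}$,
$q_1 = X_{(Q+1)}$, $m = X_{(2Q+1)}$, $q_3 = X_{(3Q+1)}$, $b = X_{(n)}$.
If $X_i = \mu + \sigma Z_i$ with $Z_i$ standard normal, the symmetry
$E(Z_{(r:n)}) = -E(Z_{(n+1-r:n)})$ gives

$$E(b - a) = 2\sigma E(Z_{(n:n)}) \equiv \sigma\,\xi(n), \qquad
  E(q_3 - q_1) = 2\sigma E(Z_{(3Q+1:n)}) \equiv \sigma\,\eta(n),$$

so dividing the observed spread by the matching constant yields an SD
estimate whose divisor *adapts to the sample size*:

* scenario C1 (`{a, m, b; n}`): $S \approx (b-a)/\xi(n)$;
* scenario C3 (`{q1, m, q3; n}`): $S \approx (q_3-q_1)/\eta(n)$;
* scenario C2 (all five): the average of the two, implemented exactly as
  that average (`sd_c2()` equals `(sd_c1() + sd_c3())/2` identically, a
  property the test suite asserts).

Mean estimators are quantile averages — $(a + 2m + b)/4$,
$(a + 2q_1 + 2m + 2q_3 + b)/8$, $(q_1 + m + q_3)/3$ — each returning
exactly the median for summaries symmetric about it.  The legacy
comparators (Hozo's adaptive range rule with its $n \le 15$ /
$15 < n \le 70$ / $n > 70$ branches, Bland's sample-size-independent
five-number formula, and the Cochrane rule $(q_3-q_1)/1.35$) are provided
for comparison; the first is flagged with a warning on negative minima,
since its derivation assumes non-negative data.

## Computing the constants

`expected_normal_os()` evaluates $E(Z_{(r:n)})$ by adaptive quadrature of

$$E(Z_{(r:n)}) = r\binom{n}{r}\int z\,\phi(z)\,\Phi(z)^{r-1}
  \,(1-\Phi(z))^{n-r}\,dz$$

over $z \in [-12, 12]$.  Two numerical choices matter:

* the powers $\Phi(z)^{r-1}$ and $(1-\Phi(z))^{n-r}$ are computed as
  `exp((r-1)*pnorm(z, log.p = TRUE) + ...)`, since naive powering
  underflows already for moderate $n$;
* the window $|z| \le 12$ truncates less than $10^{-12}$ of the mass for
  any $n$ up to $10^6$ (the maximum's distribution concentrates near
  $\sqrt{2\log n} < 12$), and `integrate()` runs at `rel.tol = 1e-10`,
  comfortably below the 3-decimal precision of the reference tables.

Blom's plotting-position approximation
$E(Z_{(r:n)}) \approx \Phi^{-1}\!\big((r - \alpha)/(n - 2\alpha + 1)\big)$
with the compromise offset $\alpha = 0.375$ provides the closed forms

$$\xi(n) \approx 2\,\Phi^{-1}\!\Big(\frac{n - 0.375}{n + 0.25}\Big), \qquad
  \eta(n) \approx 2\,\Phi^{-1}\!\Big(\frac{0.75n - 0.125}{n + 0.25}\Big).$$

`mode = "auto"` uses exact integration over the tabulated range
($n \le 50$ for $\xi$, $Q \le 50$ for $\eta$) and the closed forms
beyond, which mirrors how the constants are used in practice; exact mode
stays available at any $n$ for verification.

### Accuracy of the Blom closed form

The absolute gap between the Blom extreme-rank value and the exact
integral is *not* monotone in $n$: it shrinks from 0.025 at $n = 2$ to
about $5\times10^{-5}$ near $n = 23$, where the approximation crosses the
exact curve, then grows again to 0.0057 at $n = 50$ (0.26% in relative
terms, i.e. doubled values 4.487 vs 4.498).  For SD estimation this
0.3%-level discrepancy is immaterial — Monte-Carlo noise in any real
study summary dwarfs it — but it does mean the closed form should not be
used to *reproduce* the printed constant tables, and the package's table
reproduction therefore always integrates exactly.  With $\alpha$ re-tuned
per $n$ (0.330 at $n = 2$, rising with $n$) the approximation would be
far closer; the package keeps the standard fixed $\alpha = 0.375$ and
treats `alpha` as a configurable argument.

### Table rounding

Tabulated constants are rounded half away from zero to 3 decimals.  Three
entries of the published reference tables ($\xi$ at $n = 12$, $\eta$ at
$Q = 12$ and $Q = 24$) sit one unit in the last digit above the correctly
rounded exact integrals (e.g. printed 3.259 vs exact 3.25846); the
comparison tests therefore accept a ±0.001 discrepancy as source-table
rounding while requiring exact agreement everywhere else.

## Degenerate inputs and edge semantics

* Ties between adjacent summaries are legal (heavily tied data); only
  strict order inversions are rejected, with the offending pair named.
* All SD estimators return exactly 0 when their driving spread is 0.
* `sd_c1()` requires $n \ge 2$ ($\xi(1) = 0$); IQR-based estimators
  require $n \ge 5$ (quartile order statistics need $Q \ge 1$, which also
  tightens the combined estimator's domain to $n \ge 5$).
* Exact $\eta(n)$ exists only for $n = 4Q + 1$.  `eta_n(..., "exact")`
  rejects other sizes; the higher-level `estimate_moments(mode = "exact")`
  instead falls back silently to the closed form there, because real
  studies do not come on the $4Q+1$ grid.
* Bland's variance formula is algebraically a Cauchy–Schwarz-type
  difference $[4\sum u_i^2 - (\sum u_i)^2]/64$ in the adjacent pair sums
  $u_i \in \{a{+}q_1, q_1{+}m, m{+}q_3, q_3{+}b\}$, hence nonnegative for
  any ordered input; the negative-radicand guard in `sd_c2_bland()` is
  purely defensive.

## The simulation framework

`run_study()` quantifies bias the way such estimators are conventionally
evaluated: draw `reps` samples per sample size, reduce each sample to its
scenario summary using *exact order statistics* (never interpolated
quantiles — interpolation would blur the very identification the
estimators rest on), apply each estimator, and average the signed
relative error

$$\frac{\hat S - S_{\text{sample}}}{S_{\text{sample}}} \times 100\%$$

against the per-replication true *sample* statistic computed from the
whole sample.  Positive averages mean overestimation.

The default study conditions are the conventional ones for this problem:

* distributions — normal(50, 17), log-normal(location 4, scale 0.3),
  beta(9, 4), exponential(rate 10), weibull(2, 35) for scenario C1;
  normal(5, 1) and log-normal(location 5, scale 0.25/0.5/1) for the
  IQR scenarios.  Log-normal location/scale are the mean and SD of the
  underlying normal.
* sample-size grid — $n = 4Q + 1$ for $Q = 1, \dots, 50$ (5 to 201),
  kept uniform across scenarios so methods are compared on a common grid;
  C1-only methods accept any odd $n$ (the sign-crossing checks of the
  fixed range rules go up to $n = 801$).
* 1000 replications per cell, the conventional choice, which puts the
  Monte-Carlo standard error of an average relative error near 0.2–0.4%
  for these distributions.  The test suite uses 300–1000 replications per
  cell so the full suite runs in about a minute.

Seeding: a root seed deterministically spawns one substream per
(distribution, $n$) cell, so any single cell reproduces in isolation and
whole studies are bit-for-bit reproducible (`test-simulation.R` asserts
both).

### What the generator does and does not emulate

Samples are i.i.d. draws whose summaries are exact order statistics.
Real reported summaries additionally carry rounding to the journal's
precision, within-study selection, and quartile conventions that vary by
software — none of which the generator models.  Passing bias tests
therefore validate the estimators *under their own sampling model*; they
do not certify performance on misreported or non-i.i.d. data, and with
strongly skewed populations all normal-theory estimators here are biased
by construction (see below).

## Behaviour worth knowing about

Results the test suite and acceptance script actually compute:

* For normal data the combined C2 estimator is nearly unbiased from
  moderate $n$ on (within 1% at $n \ge 41$).  At the smallest sizes a
  subtlety appears: the truth being the *sample* SD, whose own expectation
  is $c_4(n)\sigma$ ($c_4(5) \approx 0.94$), the ratio acquires a
  positive bias of several percent at $n = 5$ even though the estimator
  is calibrated to $\sigma$.  The same effect caps the C1 estimator's
  small-$n$ accuracy (about +5% at $n = 5$, under 3% from $n = 9$).
* The fixed rules cross zero where $\xi(n)$ passes their divisor:
  $(b-a)/4$ between $n = 20$ and 30 ($\xi(27) \approx 4$), $(b-a)/6$
  between $n = 400$ and 500 (the closed-form divisor reaches 6 at
  $n \approx 463$); below the crossing they underestimate, above it they
  overestimate.
* Bland's formula works only in a window of sample sizes: about −33% at
  $n = 5$, near zero in the 20–40 range, +24% at $n = 201$ for
  normal(5, 1).
* For the very highly skewed log-normal with scale 1, the combined C2
  estimator underestimates the sample SD by roughly 13% at $n = 41$,
  crossing inside 10% only around $n \approx 80$ (about 8% at the grid
  midpoint $n = 101$).  Skewness breaks the symmetry that calibrates
  both constants, and no amount of replication removes that structural
  bias.
* On skewed data the C1 and C3 *mean* estimators err in opposite
  directions (the extreme-value average is dragged into the long tail,
  the quartile average away from it), which is the practical argument for
  preferring quartile-based reporting.

## Design choices that were genuinely open

* **Recommended C1 mean.** Only the SD estimator is improved in C1; the
  recommended policy returns the simplified quantile-average mean
  (`(a + 2m + b)/4`), with the $1/n$-corrected form available via
  `mean_c1_hozo(..., simplified = FALSE)`.
* **Policy `"all"`.** With a full five-number summary, every estimator
  whose inputs are present is applicable, so `"all"` returns
  cross-scenario methods too (3 mean and 8 SD rows) rather than only the
  scenario's native pair.
* **Quartile convention.** Simulated summaries are exact order
  statistics; CLI input data are taken as reported and never recomputed,
  deliberately avoiding the ambiguity among the many interpolated
  quantile definitions.
* **Rounding convention.** Tables round half away from zero, matching
  the printed reference values rather than IEEE round-half-even.
* **CLI as a thin shell.** All subcommand logic lives in exported,
  testable functions; `exec/qmoments` only forwards `commandArgs()` to
  `cli_main()`.

## Limitations

All estimators assume approximate normality; under strong skew they are
structurally biased (see above), and the package deliberately does not
attempt skewness pre-tests or non-normal recalibration.  Pooling itself
(fixed/random effects, heterogeneity) is out of scope — the output is
per-study moment estimates ready for a meta-analysis package.  Variances
of the estimators (needed for inverse-variance weighting of the
imputation uncertainty itself) are not provided.
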