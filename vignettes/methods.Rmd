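---
title: "Median estimation in stratified two-phase sampling: models, theory and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median estimation in stratified two-phase sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(median2ph)
```

## The estimation problem

A finite population of $N$ units carries a study variable $Y$ and a cheaper
auxiliary variable $X$, and is partitioned into $L$ non-overlapping strata of
sizes $N_h$. Sampling is two-phase SRSWOR within each stratum: a first-phase
sample of $m_h$ units records $X$ only; a nested second-phase subsample of
$n_h < m_h$ units records both $Y$ and $X$. The target is the population
median of $Y$, a location summary that stays meaningful under the skewness,
heavy tails and outliers that break mean-based estimators.

The notation follows survey-sampling convention: $M_{yh}, M_{xh}$ are the
stratum population medians, $\hat M_{yh}, \hat M_{xh}$ the second-phase
sample medians, $\acute M_{xh}$ the first-phase sample median of $X$,
$f_{yh}, f_{xh}$ the densities at the medians, $W_h = N_h/N$ the stratum
weights, and

$$\theta_{1h} = \tfrac14\Big(\tfrac{1}{n_h}-\tfrac{1}{N_h}\Big),\quad
  \theta_{2h} = \tfrac14\Big(\tfrac{1}{m_h}-\tfrac{1}{N_h}\Big),\quad
  \theta_{3h} = \theta_{1h}-\theta_{2h}.$$

All first-order theory lives in the relative-error algebra
$e_{0h} = (\hat M_{yh}-M_{yh})/M_{yh}$,
$e_{1h} = (\hat M_{xh}-M_{xh})/M_{xh}$,
$e_{2h} = (\acute M_{xh}-M_{xh})/M_{xh}$, whose second moments involve the
median coefficients $C_{Myh} = 1/(M_{yh} f_{yh}(M_{yh}))$, $C_{Mxh}$
(analogous), the median correlation $\rho_{yxh} = 4P_{11h}-1$ (with
$P_{11h}$ the probability that both variables sit at or below their
medians), and $C_{Myxh} = \rho_{yxh} C_{Myh} C_{Mxh}$.

## The estimator registry

Besides the baseline stratified sample median
$\hat M_{yst} = \sum_h W_h \hat M_{yh}$, the package implements the ratio
estimator, four difference-type estimators D1–D4, the exponential
ratio/product pair, and the transformed double-exponential family

$$\hat E_{st} = \sum_h W_h \hat M_{yh}
 \exp\!\Big[\frac{V_{1h} t_{1h}(\hat M_{xh}-\acute M_{xh})}
   {t_{1h}(\acute M_{xh}+\hat M_{xh})+2t_{2h}}\Big]
 \exp\!\Big[\frac{V_{2h} t_{3h}(\acute M_{xh}-\hat M_{xh})}
   {t_{3h}(\acute M_{xh}+\hat M_{xh})+2t_{4h}}\Big],$$

whose calibration constants $t_{1h},\dots,t_{4h}$ are robust quantile
characteristics of the auxiliary variable. Eight catalogue variants E1–E8
draw these from the quartile deviation, MAD, trimmed mean, mid-range, IQR,
decile mean, skewness, quartile average and the quartile product
(`make_transform()`). Under first-order expansion each exponential term
contributes through a shrink factor
$k_{1h} = t_{1h}M_{xh}/(t_{1h}M_{xh}+t_{2h})$ (and $k_{2h}$ analogously),
and the family's MSE depends on the transforms only through
$\delta_h = k_{1h}-k_{2h}$:

$$\mathrm{MSE}(\hat E_{st}) \cong \sum_h W_h^2 M_{yh}^2\Big[
  \theta_{1h}C_{Myh}^2 + \tfrac14\theta_{3h}C_{Mxh}^2\delta_h^2 +
  \theta_{3h}C_{Myxh}\delta_h\Big].$$

Minimising over $\delta_h$ gives $\delta_h^* = -2C_{Myxh}/C_{Mxh}^2$, at
which the family's MSE equals the minimum MSE of the difference estimator
D1 — an algebraic identity the test suite verifies on a thousand random
moment models.

## Two theory routes: closed forms and a symbolic oracle

Every closed-form bias/MSE expression is paired with an independent check:
`taylor_oracle()` writes the estimator exactly in $(e_0,e_1,e_2)$,
differentiates it symbolically (`stats::deriv3`, so the gradient and Hessian
are exact, not finite differences), and combines them with the error moment
table. Per stratum, with value $g_0$, gradient $g'$ and Hessian $H$ at zero
and moment matrix $S$:

$$\mathrm{Bias}_h = (g_0-M_{yh}) + \tfrac12\mathrm{tr}(HS),\qquad
  \mathrm{MSE}_h = (g_0-M_{yh})^2 + (g_0-M_{yh})\,\mathrm{tr}(HS) + g'^\top S\,g'.$$

The oracle reproduces the closed-form MSEs of the baseline, ratio, D1,
exponential ratio/product and the proposed family to $10^{-10}$ relative
error on randomized moment models. Three published closed forms do **not**
survive this check and are handled explicitly rather than silently trusted:

* **Exponential-product bias.** The exact kernel is
  $C_{Myxh} - C_{Mxh}^2/4$; the published kernel
  ($\tfrac34 C_{Mxh}^2 + C_{Myxh}$) does not match the expansion. The
  package reports the oracle value; the discrepancy is pinned in a
  regression test.
* **Proposed-family bias.** The published quadratic kernel
  $(k_1^2-k_2^2-2k_1k_2)$ matches neither the exact expansion nor the
  obvious symmetric correction, and it fails the basic sanity check of
  vanishing at $k_1=k_2$ (where the estimator *is* the baseline, hence
  exactly unbiased). `theory_proposed(mode = "fidelity")` evaluates the
  published form verbatim; the default `mode = "oracle"` is authoritative.
  The MSE (which uses $(k_1-k_2)^2$; one printing drops the "+") is
  mode-independent.
* **D4's optimum.** Under the second-order truncation D4's MSE is *linear*
  in $d_{7h}$ — its square only enters at fourth order — so "numerically
  optimize the printed objective" has no solution. The package's plug-in
  constants are $d_{6h}=1$ (the published $d_{6h}^{opt}$ is 1 up to
  $O(\theta)$ corrections) with $d_{7h}$ solving first-order bias $=0$,
  the unique choice under which the published minimum-MSE structure
  ($\mathrm{Bias}^2 + \tfrac14\theta_{3h}d_{6h}^2M_{yh}^2C_{Mxh}^2$) is
  coherent. Because D4's deviation at zero error is $O(1)$, its theory MSE
  uses the coherent $\mathrm{Bias}^2 + g'^\top S g'$ form rather than the
  strict truncation (which can go negative there).

D2's published optimum block, once the flattened typesetting is
disambiguated, agrees exactly with the analytic minimum of its MSE
quadratic and with an independent numeric minimisation; D3's constants come
from numeric minimisation of the oracle MSE (Nelder–Mead, three starts,
relative tolerance $10^{-12}$).

The eight superiority conditions against the competitors are evaluated as
direct sign tests of $\mathrm{MSE}_{competitor}-\mathrm{MSE}_{proposed}$
(`superiority_conditions()`); the published rearranged inequalities are
treated as documentation because at least one of them points the wrong way
relative to the difference it rearranges.

## Numerical and convention choices

* **Sample quantiles** use linear interpolation at position $1+p(n-1)$
  (type 7), the common deterministic default; the convention is exposed in
  `sample_quantile()`. Deciles use the same rule at $p=0.1,\dots,0.9$; the
  even-$n$ median is the mean of the central pair; ties get no special
  handling.
* **MAD is unscaled** (no 1.4826 consistency factor), and $\sigma$ and the
  skewness use divide-by-$N$ population formulas.
* **Densities at medians** are Gaussian-kernel estimates with Silverman's
  rule-of-thumb bandwidth evaluated at the sample median
  (`density_at_median()`; bandwidth configurable). On $10^5$ draws the
  estimate is within 5% of the closed-form density for normal, uniform and
  exponential test cases. On 500-unit skewed strata it carries a systematic
  error of a few percent, which is the accuracy limit of any
  theory-vs-simulation comparison below.
* **Ratio orientation.** The package's default ratio estimator multiplies
  by $\acute M_{xh}/\hat M_{xh}$, the orientation consistent with its
  first-order bias/MSE expressions and with the ratio estimator *gaining*
  efficiency under positive correlation; one printing transposes the
  fraction, and `orientation = "as_printed"` reproduces that form.
* **Signed transformation constants.** Variant E4 uses stratum skewness as
  $t_{1h}$, which is negative in the lower stratum of every right-skewed
  population under equal-frequency stratification; transforms therefore
  accept signed constants and flag only (numerically) zero denominators as
  degenerate. The $k\in(0,1]$ guarantee holds for strictly positive inputs.
* **Variant E5's logarithmic shift** is $\log(Q+1)$ (domain-safe; a second
  printing has $\log(Q-1)$, available via `e5_log_shift = "minus1"`).
* **Allocation rounding**: fractional totals are rounded half up; equal
  allocation across strata sends remainders to the lowest-indexed strata;
  any cell violating $n_h < m_h \le N_h$ errors by name.
* **RNG**: replication $u$ of a Monte Carlo run uses a seed derived
  arithmetically from (master seed, $u$), so replications are
  order-independent and results are bit-reproducible from the master seed;
  seeded draws restore the caller's RNG state.

## The synthetic study populations

`population_model()` encodes five auxiliary-variable designs — Cauchy(21, 16),
Uniform(17, 24), Exponential(0.5), Gamma(shape 23, scale 15) and
Log-normal(meanlog 11, sdlog 6) — with $Y=\rho X+e$, $e$ standard normal,
$N=1000$, and nominal $\rho$ of $-0.40$, $0$, $0.60$, $0.68$, $0.57$
respectively. Two readings were fixed once: the gamma pair is
(shape, scale) and the log-normal pair is on the log scale; both are
overridable. $\rho$ is a regression coefficient, not the realised
correlation (the Cauchy case has none), so the moment model records the
realised median correlation instead. Populations are stratified into
$L = 2$ equal-frequency strata on $X$ by default, mirroring the
two-stratum real-data examples; the population is generated once and held
fixed while samples are redrawn.

What the generator does *not* emulate: measurement error in $X$,
nonresponse, strata formed on anything but $X$, heteroscedastic or
non-additive $Y$–$X$ links, and clustered designs. Passing tests therefore
speak to the estimators' sampling behaviour under clean two-phase SRSWOR,
not to robustness against those complications.

**The target parameter.** Every estimator in the registry reduces, under a
census, to the stratified combination $\sum_h W_h M_{yh}$, and the
first-order theory expands about it. Under equal-frequency-on-$X$
stratification of a skewed population this differs from the plain
population median of $Y$ by an $O(1)$ offset that would enter every
estimator's MSE identically and swamp the efficiency comparison. The Monte
Carlo engine therefore measures squared error against
$\sum_h W_h M_{yh}$ by default (`target = "stratified"`), with
`target = "overall"` available when the design-bias question itself is of
interest.

## Problem sizes and what the study found

The shipped tests run the quantile oracle on 500 datasets of sizes 3–200,
the theory identities on 1000 random moment models, the oracle-vs-formula
sweep on 200 moment models, and Monte Carlo studies at $U=5000$
(theory-vs-simulation, gamma, $m_h=150$, $n_h=60$) and $U=2000$
(efficiency ordering, scheme-2 cell (300, 75)); full-fidelity runs at
$U=20{,}000$ are a configuration change. Two empirical findings are worth
stating plainly:

* The baseline's empirical MSE sits within a few percent of the
  $\sum_h \theta_{1h}W_h^2M_{yh}^2C_{Myh}^2$ plug-in (ratio $\approx$ 0.94
  at $U=2000$) — close to, but at $U=5000$ occasionally outside, a strict
  3-Monte-Carlo-SE band, because the kernel plug-in's systematic error does
  not shrink with $U$.
* With the catalogue transforms as published, $k_{1h}>k_{2h}$ in
  essentially every stratum of the positively correlated populations, so
  $\delta_h>0$ while the favourable direction under positive correlation is
  $\delta_h<0$ (note $\delta_h^*<0$ there). First-order theory accordingly
  predicts PRE slightly *below* 100 for E1–E8 on the exponential and gamma
  populations, and the Monte Carlo agrees with the theory (PRE roughly
  72–101 across variants). The package reports what the published
  definitions imply; users wanting the family at its potential should pick
  transforms (or explicit $k$'s) with $\delta_h$ near $\delta_h^*$, where
  the family provably matches optimal-D1 efficiency.

## Known limitations

First-order theory only (no exact finite-sample distributions, no
confidence intervals); no weighted quantiles, Neyman allocation,
with-replacement or multistage designs; variance estimation from a single
sample is out of scope — efficiency statements come from theory or
replication. The real-population fixtures carry published summary
statistics verbatim (including one internal inconsistency, flagged as
`qd_equals_dm`, and an undefined printed column `QR` kept under its
printed name); their unit-level source tables are not redistributed.
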