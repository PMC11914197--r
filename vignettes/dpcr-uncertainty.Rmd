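---
title: "Uncertainty estimation for digital PCR: models, engines and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty estimation for digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcrvar)
```

## The measurement model

A digital PCR reaction splits a sample over $n$ partitions (nominally
20\,000 in this package's defaults) and reads each one as positive
(holding at least one target molecule) or negative. With molecules
landing independently and uniformly, the per-partition copy number is
approximately Poisson with mean $\lambda$, so the probability that a
partition is negative is $e^{-\lambda}$ and

$$\hat\lambda = -\ln\left(1 - \frac{k}{n}\right)$$

estimates the mean copies per partition from the $k$ observed positives.
Every quantity this package handles is a function of such rates:

* absolute quantification: $\hat\lambda$ itself, the concentration
  $\hat\lambda / V_p$, or the loaded copy number
  $\hat\mu = (V_d/V_p)\,\bar{\hat\lambda}$ across replicates;
* copy number variation: the ratio of target to reference rates, from
  separate singleplex reactions (estimated on the log scale, as the mean
  of per-replicate log ratios) or from one duplex reaction (mean of
  per-replicate ratios);
* fractional abundance: $\hat\lambda_A / (\hat\lambda_A + \hat\lambda_B)$
  for mutant vs wild type in duplex;
* DNA integrity: from the four-category counts of a linkage duplex, the
  share of intact molecules
  $1 - \tfrac{(\hat\lambda_A + \hat\lambda_B)/2}
  {(\hat\lambda_A + \hat\lambda_B)/2 + \hat\lambda_{AB}}$.

For integrity the three rates (free A fragments, free B fragments,
intact molecules carrying both targets) are not read off directly; they
are recovered from the four partition categories by inverting the
independence relations $P(A^-) = e^{-(a+c)}$, $P(B^-) = e^{-(b+c)}$,
$P(A^-B^-) = e^{-(a+b+c)}$ (`decompose_linkage()`). Published linkage
assays define the integrity measure in terms of these rates without
fixing a unique estimator from the category counts; this inversion is
the standard linkage estimator and is a design choice of this package. When sampling noise makes the observed double negatives fall
below the independence product, the linked rate is clipped at zero
(anti-linkage is not modelled) and the clipping is recorded on the
result.

## Why variance estimation is the hard part

If partition counts were exactly binomial, the delta method would settle
the matter. Two things break that idealisation. First, replicates are
pipetted separately from a larger volume, so the number of molecules
loaded varies between replicates beyond Poisson sampling. Second,
experimental error sources — pipetting volume error, random loss of
partitions, unequal partition volumes, misclassification at thresholding
— distort the count distribution. The package therefore offers three
engines, selected by the `method` argument of `dpcr_fit()`:

**NonPVar** uses the empirical between-replicate variance
$S^2 = \frac{1}{r-1}\sum_i (\hat\theta_i - \bar\theta)^2$, reports
$S^2/r$ as the variance of the pooled estimate, and builds the interval
from Student-$t$ quantiles with $r-1$ degrees of freedom (at the
$r < 5$ replicate counts typical of dPCR the $t$ correction matters; we
use it for all $r$ since no switch point is well defined). It assumes
nothing about the count distribution, so any error source that acts
between replicates is automatically absorbed — at the price of noisy
variance estimates when $r$ is small. Variances, not standard
deviations, are the reported and benchmarked quantity; no small-sample
SD bias correction is applied.

**BinomVar** is a parametric bootstrap. Pooling replicates gives
$\bar\lambda$ per channel; each replicate's count is resampled $B$ times
(default 1000) from $\mathrm{Binom}(n_i, 1 - e^{-\bar\lambda})$ — the
exact marginal of the count when the loaded molecule number is Poisson —
the quantity of interest is recomputed per draw, and the per-replicate
bootstrap variances are averaged and divided by $r$. Using the pooled
mean rather than each replicate's own rate is deliberate: it shares
strength across replicates and matches the distribution the bootstrap
claims to sample from. Channels are resampled as independent binomials
within a replicate, except for integrity data, where a four-category
multinomial (with probabilities reconstructed from the pooled rates)
preserves the double-positive dependence that independent binomials
would destroy. Draws for which the quantity is undefined — a saturated
count, or a zero where a log or a ratio denominator needs positivity —
are rejected and redrawn, with a hard cap of $100 B$ rejections. When a
seed is supplied, each replicate gets a deterministically derived child
seed, so results are bit-reproducible and invariant to replicate
ordering. Intervals are normal-theory.

**Delta method** gives closed forms where the linearisation is
trustworthy: $\widehat{\mathrm{Var}}(\hat\lambda) = k/[n(n-k)]$ for
absolute quantification, and for the singleplex log-CNV the sum of
per-assay terms $(1 - e^{-\lambda})/(n \lambda^2 e^{-\lambda})$,
composed over replicates as $(\sum_i v_{A,i} + \sum_i v_{B,i})/r^2$.
Ratios on the natural scale linearise poorly, so no delta formulas are
offered for duplex CNV, fractional abundance or integrity — requesting
them is an error that lists the valid engines. The log-CNV interval
back-transforms to the CNV scale by exponentiating its bounds; the
variance itself does not back-transform and is reported on the log
scale only.

```{r fit-example}
counts <- simulate_counts(dpcr_scenario(0.5, n_replicates = 3, seed = 42))
dpcr_fit(counts, qoi = "lambda", method = "nonpvar")
```

### Degenerate inputs and numerical choices

A saturated reaction ($k = n$) has an infinite rate estimate and is an
error by default; `estimate_lambda(..., saturation_correction = TRUE)`
substitutes $k = n - 0.5$ as a documented, off-by-default heuristic. A
zero count yields $\hat\lambda = 0$ exactly; downstream, the delta
variance is 0 and BinomVar degenerates to zero variance when the pooled
rate is itself 0. Volumes default to $V_d = V_p$ (ratio 1), so all
results are per partition unless volumes are supplied — most users work
on that scale. Singleplex CNV requires equal replicate counts by
default (the paired estimator is only defined then); an explicit
`unpaired = TRUE` mode in `qoi_log_cnv_singleplex()` averages over all
target–reference pairs instead.

## The occupancy oracle

The exact distribution of the number of occupied partitions when $m$
molecules fall uniformly on $n$ partitions is

$$P(K = k \mid m, n) = \frac{n!\, S_2(m,k)}{(n-k)!\, n^m},$$

with $S_2$ the Stirling numbers of the second kind. `occupancy_pmf()`
evaluates it in log space throughout: log-gamma for the factorial
ratios, and $\ln S_2$ by the exact recurrence carried in log space up to
$m = 300$ — enough to cover every desk-scale test exactly — switching
above that to the Lambert-W asymptotic
(`log_stirling2_approx()`). One numerical subtlety: the asymptotic
needs $G = -W_0(-v e^{-v})$ with $v = m/k$, and general-purpose
Lambert-W iterations stall when $v \to 1$ (the argument approaches the
branch point $-1/e$). We instead solve the defining equation
$G e^{-G} = v e^{-v}$ on $(0, 1]$ by bracketed root finding on the log
scale, which is stable arbitrarily close to the branch point.

Mixing the exact pmf over a Poisson molecule count reproduces, to
numerical precision, the binomial law
$\mathrm{Binom}(n, 1 - e^{-\mu/n})$ that BinomVar resamples from
(`poisson_mixture_pmf()` vs `binomial_limit_pmf()`); the test suite
verifies this identity to $10^{-10}$ total variation, a numerical proof
of the derivation behind the bootstrap. The conditional (fixed-$m$)
distribution is *not* that binomial — it omits the molecule-sampling
dispersion and keeps a substantial total-variation gap at matched mean
— which is exactly why the two-level model matters.

## What the simulator emulates

`dpcr_scenario()` defines the generative conditions; its defaults are
the study conditions under which the benchmark results are quoted, not
tuning knobs: $\lambda$ from 0.005 to 1.5 copies per partition, 20\,000
nominal partitions, 3 replicates, and four switchable error sources
with conventional magnitudes — pipetting error as a Normal
multiplicative factor with CV 3\% on the loaded mean (truncated at
$-0.99$ so the mean stays positive; a $33\sigma$ event at this CV),
partition loss retaining $\mathrm{Normal}(16000, 2000)$ partitions
(rounded, clamped to $[1, n]$), partition volumes
$\mathrm{LogNormal}(0, 0.1)$ used as multinomial placement weights
(about a 10\% volume CV), and misclassification flipping true positives
with probability 5\% and true negatives with probability 0.01\%,
independently per partition with rates held constant across replicates.

The pipeline order is: pipetting factor on the loaded mean, Poisson
molecule draw, uniform (or volume-weighted) placement over the nominal
partitions, random retention of the surviving partitions, then
per-channel misclassification. Loss is implemented as random removal of
loaded partitions — molecules in lost partitions are discarded — which
keeps the per-partition mean at $\lambda$; drawing the full molecule
count and then cramming it into fewer partitions would inflate the rate
by $n/n^*$ and is not what "partitions lost completely at random"
means. Duplex quantities share one reaction's partitions, volumes,
realised partition count and pipetting draw across channels, so those
errors cancel in within-reaction ratios, as they do on real
instruments; singleplex CNV uses two fully independent reactions.
Integrity scenarios load three molecule species — intact molecules
(mean $\lambda \cdot \mathrm{intactness}$ per partition) flagging both
channels, and free A- and B-fragments (mean
$\lambda(1-\mathrm{intactness})$ each) — so the generative truth of the
integrity measure equals the intactness parameter (default 0.8).

What it does not emulate: fluorescence amplitudes and "rain",
threshold-setting itself, chamber-vs-droplet platform differences, or
between-run effects. Passing benchmarks here therefore says the
engines are correct under the stated error model, not that any real
instrument satisfies that model.

## The benchmark harness and the sizes it runs at

`benchmark_cell()` simulates `n_sims` replicate sets, applies one
engine, and reports empirical coverage of the nominal 95\% interval
against the generative truth, relative bias of the point estimator, and
relative bias of the variance estimator against the empirical variance
of the estimator across runs — the only available referent for the
"true" variance, and the one consistent with how such methods are
evaluated. Coverage for the log-scale CNV is assessed on the log scale
(equivalent by monotonicity). Runs where an engine fails (saturation, a
zero where a log is needed) are counted and reported as a failure rate
and excluded from the denominators; silent exclusion would bias
coverage invisibly. Each grid cell draws from its own deterministically
derived seed stream, so results are independent of execution order.

The package's own evaluation, in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`, runs 1000 simulation runs of 3 replicates per
grid point with $B = 1000$ — a size chosen so the whole evaluation runs
on a single desk machine in minutes. One metric deserves a caveat: the
variance-bias statistic $\overline{\hat V} / \widehat{\mathrm{Var}}_{\mathrm{emp}} - 1$
is an F-type ratio whose Monte-Carlo standard deviation is
$\approx \sqrt{1/n_{\mathrm{sims}} + 2/(n_{\mathrm{sims}}-1)}$, about
5.5\% at 1000 runs and 3.9\% at 2000. The maximum of its absolute value
over many scenario cells is therefore noise-dominated even for a
perfectly unbiased variance estimator; borderline readings (absolute
value in 4–6\%) are re-measured at 2000 runs, and the maximum should be
read with that noise floor in mind.

Expected behaviours the harness reproduces: all three engines are
near-nominal under pure sampling variation; pipetting error collapses
BinomVar and delta coverage at $\lambda = 1$ to roughly 44\% (the
between-replicate variance is about ten times what the binomial model
admits, and $2\Phi(1.96/3.4) - 1 \approx 0.44$) while NonPVar stays
nominal; misclassification biases $\hat\lambda$ itself — at
$\lambda = 1.5$ the closed form
$-\ln\!\big(1 - [(1{-}\mathrm{FNR})(1{-}e^{-\lambda}) +
\mathrm{FPR}\,e^{-\lambda}]\big)/\lambda - 1 \approx -10.7\%$ — so no
variance method can rescue coverage there; volume variation biases
$\hat\lambda$ only mildly ($\approx -0.8\%$ at $\lambda = 1.5$, by
integrating $E[e^{-\lambda V / \bar V}]$ over the volume law).

## Choosing a method

At low concentration ($\lambda \lesssim 0.1$, a convention rather than
a sharp threshold) sampling variability dominates and the parametric
engines (BinomVar; delta where available) give the most precise
variance estimates. At higher concentration in singleplex, pipetting
error does not cancel and NonPVar is the robust choice. In duplex,
shared errors cancel in ratios, so the parametric engines remain good
unless the clusters are poorly separated, in which case
misclassification favours NonPVar. `recommend_method()` encodes this
advisory logic without ever switching methods automatically. Running
several engines and comparing is itself diagnostic: a large
discrepancy flags error sources beyond sampling variability.

## Known limitations

NonPVar with $r = 3$ replicates yields variance estimates with few
degrees of freedom: unbiased but individually noisy, and its $t$
intervals are correspondingly wide. BinomVar inherits every violation
of the Poisson/binomial assumption as anti-conservatism. The
generalised linear mixed model route to dPCR variance estimation is
deliberately out of scope (it exists in external software and covers
only absolute quantification and CNV); so are raw-fluorescence
thresholding, droplet QC, sample-size planning, and multi-reference
CNV integration. Published empirical case-study datasets (CNV panels, mutation
abundance series) are not redistributed here; the simulator's fixture
generator produces synthetic stand-ins for all tests and demos.
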