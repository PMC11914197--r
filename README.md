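# dpcrvar

Uncertainty estimation for digital PCR (dPCR) partition counts.

Digital PCR splits a reaction into thousands of nanoliter partitions and
counts how many turn positive. The mean copies per partition is estimated
by Poisson statistics as

    lambda_hat = -ln(1 - k/n)

from `k` positives out of `n` partitions, and everything of biological
interest — absolute concentration, copy number variation (CNV), mutant
fractional abundance, DNA integrity — is a function of such rates. Point
estimates are the easy part; this package is about their **variance and
confidence intervals**, which the classical binomial model understates as
soon as real error sources (pipetting error, partition loss, unequal
partition volumes, misclassification) come into play. It is written for
dPCR practitioners and method developers who have per-replicate partition
counts and need defensible uncertainty statements.

Three engines are provided behind one fitting interface:

| engine | idea | interval | when |
|---|---|---|---|
| `nonpvar` | empirical between-replicate variance `S² = Σ(θ̂ᵢ − θ̄)²/(r−1)`, variance of the mean `S²/r` | Student-t, r−1 df | robust at high concentration / unmodelled errors; needs r ≥ 2 |
| `binomvar` | parametric bootstrap: resample counts from `Binom(nᵢ, 1 − e^(−λ̄))` with pooled `λ̄`, B = 1000 draws per replicate | normal | precise when the Poisson/binomial model holds |
| `delta` | closed forms `k/[n(n−k)]` for λ and `(1−e^(−λ))/(n λ² e^(−λ))` summed per assay for log-CNV | normal | fast; absolute quantification and singleplex log-CNV only |

The package also ships the exact partition-occupancy distribution
`P(K = k | m, n) = n! S₂(m,k) / [(n−k)! n^m]` (Stirling numbers, with a
Lambert-W asymptotic for large molecule counts) as a correctness oracle, a
generative simulator of the error sources above, and a Monte-Carlo
benchmark harness measuring empirical coverage and bias per
(method × scenario × concentration).

## Worked example

Simulate a three-replicate experiment at 0.5 copies per partition with
20 000 partitions, then fit it with each engine:

```r
library(dpcrvar)
counts <- simulate_counts(dpcr_scenario(0.5, n_replicates = 3, seed = 42))
head(counts)
#>   sample replicate channel positives total
#> 1    sim         1       A      7916 20000
#> 2    sim         2       A      7879 20000
#> 3    sim         3       A      7767 20000

dpcr_fit(counts, qoi = "lambda", method = "nonpvar")
#> dPCR fit: mean copies per partition
#> method: nonpvar  replicates: 3
#> estimate: 0.4987  se: 0.003683
#> 95% CI: [0.4829, 0.5146]

dpcr_fit(counts, qoi = "lambda", method = "binomvar", seed = 1)
#> estimate: 0.4987  se: 0.003297
#> 95% CI: [0.4923, 0.5052]

dpcr_fit(counts, qoi = "lambda", method = "delta")
#> estimate: 0.4987  se: 0.003283
#> 95% CI: [0.4923, 0.5052]
```

All three agree on the point estimate (the true value is 0.5). The
parametric engines (`binomvar`, `delta`) agree closely with each other —
they rest on the same binomial model — while `nonpvar` reads the spread
of the three replicates and widens its interval with the t quantile
(4.30 instead of 1.96 at r = 3). A duplex copy-number ratio works the
same way:

```r
cnv <- simulate_counts(dpcr_scenario(1.0, qoi = "cnv_duplex",
                                     lambda_ref = 0.5, seed = 7))
dpcr_fit(cnv, qoi = "cnv_duplex", method = "binomvar", seed = 2)
#> dPCR fit: copy-number ratio (duplex)
#> estimate: 2.011  se: 0.01693
#> 95% CI: [1.978, 2.044]
```

(True ratio 2.) The fit object supports `coef()`, `vcov()`, `confint()`,
`summary()` (per-replicate variance decomposition) and `plot()`.
`read_counts()`/`write_estimates()` handle the CSV schema
`sample,replicate,channel,positives,total[,vd,vp]`, and
`scripts/dpcr_cli.R` exposes `estimate`, `simulate`, `benchmark`, `pmf`
and `recommend` subcommands for shell use.

The benchmark harness reproduces the known behaviour of the methods,
e.g. under 3% pipetting error the binomial-based intervals collapse
while the nonparametric ones hold:

```r
benchmark_grid(lambdas = c(0.1, 1.0), scenarios = "pipetting",
               methods = c("nonpvar", "delta"), n_sims = 300, seed = 1)
```

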