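# Generative model: distributional correctness against the occupancy
# oracles and closed-form limits of each error source

test_that("simulation is deterministic given the scenario seed", {
  scn <- dpcr_scenario(0.4, errors = "all", seed = 99)
  c1 <- simulate_counts(scn)
  c2 <- simulate_counts(scn)
  expect_identical(c1, c2)

  tf1 <- tempfile(fileext = ".csv"); tf2 <- tempfile(fileext = ".csv")
  generate_fixture_csv(scn, tf1); generate_fixture_csv(scn, tf2)
  expect_identical(readLines(tf1), readLines(tf2))
  unlink(c(tf1, tf2))
})

test_that("degenerate configurations behave as they must", {
  set.seed(1)
  z <- simulate_reaction(dpcr_scenario(0, n_partitions = 5000))
  expect_identical(unname(z$k["A"]), 0L)
  # a certain false-negative rate silences every positive
  f <- simulate_reaction(dpcr_scenario(1, n_partitions = 5000, fnr = 1))
  expect_identical(unname(f$k["A"]), 0L)
  # partition loss varies the realised totals around 16000
  scn <- dpcr_scenario(0.2, errors = "loss")
  tot <- replicate(40, simulate_reaction(scn)$n["A"])
  expect_true(all(tot >= 1 & tot <= 20000))
  expect_gt(length(unique(tot)), 10)
  expect_equal(mean(tot), 16000, tolerance = 0.05)
})

test_that("fixed-m occupancy counts follow the exact pmf (goodness of fit)", {
  set.seed(202)
  m <- 20; n <- 10; nsim <- 50000
  scn <- dpcr_scenario(0, qoi = "lambda", n_partitions = n, fixed_m = m)
  k <- replicate(nsim, simulate_reaction(scn)$k[["A"]])
  p <- occupancy_pmf(0:n, m, n)
  # pool bins with tiny expectation into their neighbour
  keep <- p * nsim >= 5
  obs <- tabulate(k + 1L, n + 1L)
  chi <- sum((obs[keep] - nsim * p[keep])^2 / (nsim * p[keep])) +
    (sum(obs[!keep]) - nsim * sum(p[!keep]))^2 / max(nsim * sum(p[!keep]), 1e-9)
  df <- sum(keep)   # pooled cell adds ~0 information
  expect_gt(stats::pchisq(chi, df), 1e-3)
})

test_that("Poisson-loaded counts follow the binomial marginal (goodness of fit)", {
  set.seed(203)
  n <- 100; mu <- 50; nsim <- 20000
  scn <- dpcr_scenario(mu / n, n_partitions = n)
  k <- replicate(nsim, simulate_reaction(scn)$k[["A"]])
  p <- binomial_limit_pmf(0:n, n, mu)
  keep <- p * nsim >= 5
  obs <- tabulate(k + 1L, n + 1L)
  chi <- sum((obs[keep] - nsim * p[keep])^2 / (nsim * p[keep])) +
    (sum(obs[!keep]) - nsim * sum(p[!keep]))^2 / (nsim * sum(p[!keep]))
  expect_gt(stats::pchisq(chi, sum(keep)), 1e-3)
})

test_that("misclassification shifts the positive fraction by the closed form", {
  set.seed(204)
  lam <- 1; n <- 20000; fnr <- 0.05; fpr <- 1e-4; nsim <- 500
  scn <- dpcr_scenario(lam, n_partitions = n, fnr = fnr, fpr = fpr)
  kk <- replicate(nsim, simulate_reaction(scn)$k[["A"]])
  expected <- (1 - fnr) * (1 - exp(-lam)) + fpr * exp(-lam)
  se <- sd(kk / n) / sqrt(nsim)
  expect_lt(abs(mean(kk / n) - expected), 3 * se + 1e-6)
})

test_that("volume variation drives the negative fraction to E[exp(-lam V/EV)]", {
  set.seed(205)
  lam <- 1.5; n <- 20000; sig <- 0.1; nsim <- 300
  scn <- dpcr_scenario(lam, n_partitions = n, volume_sigma = sig)
  kk <- replicate(nsim, simulate_reaction(scn)$k[["A"]])
  ev <- exp(sig^2 / 2)
  expected <- stats::integrate(function(v)
    exp(-lam * v / ev) * stats::dlnorm(v, 0, sig), 0, Inf)$value
  se <- sd(1 - kk / n) / sqrt(nsim)
  expect_lt(abs(mean(1 - kk / n) - expected), 3 * se + 1e-5)
})

test_that("duplex channels share partitions and integrity modes are coherent", {
  set.seed(206)
  # symmetric duplex: pooled fractional abundance near 1/2
  scn <- dpcr_scenario(0.8, qoi = "fa", fraction = 0.5, n_replicates = 2)
  fhat <- replicate(200, {
    rc <- simulate_reaction(scn)
    la <- estimate_lambda(rc$k[["A"]], rc$n[["A"]])
    lb <- estimate_lambda(rc$k[["B"]], rc$n[["B"]])
    la / (la + lb)
  })
  expect_lt(abs(mean(fhat) - 0.5), 3 * sd(fhat) / sqrt(200))

  # fully fragmented: no intact molecules, double positives only by chance
  s0 <- dpcr_scenario(0.5, qoi = "integrity", intactness = 0)
  counts0 <- simulate_counts(s0)
  est0 <- dpcr_fit(counts0, "integrity", "nonpvar")$estimate
  expect_lt(est0, 0.05)

  # fully intact: integrity estimate near 1
  s1 <- dpcr_scenario(0.5, qoi = "integrity", intactness = 1)
  est1 <- dpcr_fit(simulate_counts(s1), "integrity", "nonpvar")$estimate
  expect_gt(est1, 0.95)
})

test_that("fixture CSV has the schema row count and reads back", {
  scn <- dpcr_scenario(0.6, qoi = "fa", n_replicates = 3, seed = 5)
  tf <- tempfile(fileext = ".csv")
  generate_fixture_csv(scn, tf)
  lines <- readLines(tf)
  expect_length(lines, 7)   # header + 3 replicates x 2 channels
  back <- read_counts(tf)
  expect_s3_class(back, "dpcr_counts")
  expect_equal(nrow(back), 6)
  unlink(tf)
})
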