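# Partition-occupancy distribution: exact, asymptotic and mixture forms

test_that("Stirling numbers match brute-force set-partition counts", {
  expect_equal(stirling2_exact(2, 1), 1)
  expect_equal(stirling2_exact(2, 2), 1)
  expect_equal(stirling2_exact(4, 2), 7)
  expect_equal(stirling2_exact(4, 2), brute_force_stirling2(4, 2))
  for (m in 1:6) for (k in 0:m) {
    expect_equal(stirling2_exact(m, k), brute_force_stirling2(m, k),
                 info = sprintf("S2(%d,%d)", m, k))
  }
  expect_equal(stirling2_exact(9, 9), 1)
  expect_equal(stirling2_exact(3, 5), 0)
  expect_error(stirling2_exact(-1, 0), "non-negative")
  # log-space recurrence agrees with the plain one
  expect_equal(log_stirling2(50, 20), log(stirling2_exact(50, 20)),
               tolerance = 1e-10)
})

test_that("Lambert-W asymptotic tracks the exact log Stirling numbers", {
  expect_equal(log_stirling2_approx(100, 50), log_stirling2(100, 50),
               tolerance = 0.01)
  expect_true(is.finite(log_stirling2_approx(20, 19)))
  # boundary fallbacks
  expect_equal(log_stirling2_approx(7, 7), 0)
  expect_equal(log_stirling2_approx(5, 0), -Inf)
  # relative error of the implied pmf shrinks as m grows
  relerr <- function(m) {
    k <- round(m / 2)
    abs(log_stirling2_approx(m, k) - log_stirling2(m, k)) / abs(log_stirling2(m, k))
  }
  expect_lt(relerr(200), relerr(20))
})

test_that("occupancy pmf matches brute-force enumeration for m, n <= 6", {
  for (m in 1:6) for (n in 1:6) {
    bf <- brute_force_occupancy(m, n)
    expect_equal(occupancy_pmf(0:min(m, n), m, n), unname(c(bf)),
                 tolerance = 1e-12, info = sprintf("m=%d n=%d", m, n))
  }
  # frozen hand-enumerated cases
  expect_equal(occupancy_pmf(1:2, 2, 2), c(0.5, 0.5))
  expect_equal(occupancy_pmf(1, 5, 1), 1)
  expect_equal(occupancy_pmf(1:3, 3, 3), c(3, 18, 6) / 27)
})

test_that("occupancy pmf sums to one and has the inclusion-exclusion mean", {
  for (case in list(c(10, 7), c(80, 60), c(100, 100), c(37, 120))) {
    m <- case[1]; n <- case[2]
    k <- 0:min(m, n)
    p <- occupancy_pmf(k, m, n)
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_equal(sum(k * p), n * (1 - (1 - 1 / n)^m), tolerance = 1e-8)
  }
  # asymptotic branch (m > 300): mass and mean still near exact
  m <- 350; n <- 120; k <- 0:n
  p <- occupancy_pmf(k, m, n)
  expect_equal(sum(p), 1, tolerance = 1e-3)
  expect_equal(sum(k * p), n * (1 - (1 - 1 / n)^m), tolerance = 1e-3)
})

test_that("Poisson mixture of the exact pmf equals the binomial limit", {
  n <- 50; mu <- 10
  k <- 0:n
  mix <- poisson_mixture_pmf(k, n, mu, m_max = 200)
  lim <- binomial_limit_pmf(k, n, mu)
  expect_lt(0.5 * sum(abs(mix - lim)), 1e-10)   # total variation
  expect_lt(attr(mix, "tail_mass"), 1e-10)
  # binomial limit basics
  expect_equal(binomial_limit_pmf(0, 100, 0), 1)
  expect_equal(sum(0:100 * binomial_limit_pmf(0:100, 100, 30)),
               100 * (1 - exp(-0.3)))
})

test_that("mixing over M, not conditioning on it, gives the binomial marginal", {
  # at matched mean load the fixed-m (conditional) pmf keeps a total
  # variation gap from the binomial marginal -- the molecule-sampling
  # dispersion it omits -- while the Poisson mixture matches it exactly
  # at every n
  lam <- 0.5
  for (n in c(10, 40, 160)) {
    k <- 0:n
    m <- round(lam * n)
    tv_fixed <- 0.5 * sum(abs(occupancy_pmf(k, m, n) -
                              binomial_limit_pmf(k, n, m)))
    tv_mixed <- 0.5 * sum(abs(poisson_mixture_pmf(k, n, m) -
                              binomial_limit_pmf(k, n, m)))
    expect_gt(tv_fixed, 0.1)
    expect_lt(tv_mixed, 1e-10)
  }
})
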