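# Quantities of interest built from per-replicate rate estimates

test_that("singleplex log CNV averages paired log ratios", {
  expect_equal(qoi_log_cnv_singleplex(c(0.7, 0.7), c(0.7, 0.7)), 0)
  expect_equal(qoi_log_cnv_singleplex(c(1, 1), c(0.5, 0.5)), log(2))
  expect_equal(qoi_log_cnv_singleplex(c(0.2, 0.8), c(0.4, 0.4)), 0)
  expect_error(qoi_log_cnv_singleplex(c(0, 1), c(1, 1)), "positive")
  expect_error(qoi_log_cnv_singleplex(c(1, 1, 1), c(1, 1)), "unequal")
  # all-pairs mode: 1/(rA rB) sum_ij (ln a_i - ln b_j)
  a <- c(0.9, 1.1, 1.3); b <- c(0.4, 0.6)
  manual <- mean(outer(log(a), log(b), `-`))
  expect_equal(qoi_log_cnv_singleplex(a, b, unpaired = TRUE), manual)
})

test_that("duplex CNV is the mean of per-replicate ratios", {
  expect_equal(qoi_cnv_duplex(c(1, 1), c(1, 1)), 1)
  expect_equal(qoi_cnv_duplex(c(0.8, 0.8), c(0.4, 0.2)), 3)  # ratios 2 and 4
  expect_equal(qoi_cnv_duplex(0.3, 0.1), 3)
  expect_error(qoi_cnv_duplex(c(1, 1), c(1, 0)), "positive")
})

test_that("fractional abundance lies in [0,1] and matches hand values", {
  expect_equal(qoi_fractional_abundance(c(0.4, 0.4), c(0.4, 0.4)), 0.5)
  expect_equal(qoi_fractional_abundance(0.7, 0), 1)
  expect_equal(qoi_fractional_abundance(0.1, 0.3), 0.25)
  expect_error(qoi_fractional_abundance(0, 0), "zero")
  set.seed(42)
  for (i in 1:50) {
    a <- runif(3, 0, 2); b <- runif(3, 0, 2)
    f <- qoi_fractional_abundance(a, b)
    expect_true(f >= 0 && f <= 1)
  }
})

test_that("integrity is bounded and matches hand values", {
  expect_equal(qoi_integrity(0, 0, 0.5), 1)
  expect_equal(qoi_integrity(0.3, 0.5, 0), 0)
  expect_equal(qoi_integrity(1, 1, 1), 0.5)
  expect_error(qoi_integrity(0, 0, 0), "no molecules")
  set.seed(43)
  for (i in 1:50) {
    v <- qoi_integrity(runif(3), runif(3), runif(3))
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("linkage decomposition solves the three-exponential system", {
  # independent channels: double-negative fraction factorises, no linkage
  n <- 1000
  d <- decompose_linkage(360, 240, 240, 160, n)   # f-- = 0.36 = 0.6 * 0.6
  expect_equal(unname(d["lambda_ab"]), 0)
  expect_false(attr(d, "clipped"))

  # fully linked: fA- = fB- = f-- = e^-1  ->  c = 1, a = b = 0
  n <- 1e6
  k_nn <- round(n * exp(-1))
  d <- decompose_linkage(k_nn, 0, 0, n - k_nn, n)
  expect_equal(unname(d["lambda_ab"]), -log(k_nn / n))
  expect_equal(unname(d[c("lambda_a", "lambda_b")]), c(0, 0))

  # mixed case: fA- = fB- = e^-1.5, f-- = e^-2  ->  c = 1, a = b = 0.5
  f_an <- exp(-1.5); f_nn <- exp(-2)
  nn <- round(n * f_nn); a_only <- round(n * (f_an - f_nn))
  d <- decompose_linkage(nn, a_only, a_only, n - nn - 2 * a_only, n)
  expect_equal(unname(d["lambda_ab"]), 1, tolerance = 1e-3)
  expect_equal(unname(d["lambda_a"]), 0.5, tolerance = 1e-3)

  expect_error(decompose_linkage(0, 10, 10, 80, 100), "identifiable")
  expect_error(decompose_linkage(10, 10, 10, 80, 100), "sum to n")
})

test_that("linkage decomposition inverts exactly (round trip to 1e-12)", {
  set.seed(7)
  n <- 1e6
  for (i in 1:20) {
    # build category counts from arbitrary fractions, then invert
    k <- as.vector(rmultinom(1, n, c(4, 1, 1, 2) * runif(4, 0.5, 1.5)))
    d <- decompose_linkage(k[1], k[2], k[3], k[4], n)
    a <- d["lambda_a"]; b <- d["lambda_b"]; cc <- d["lambda_ab"]
    if (attr(d, "clipped")) next  # clipped solutions are not exact inverses
    expect_equal(unname(exp(-(a + cc))), (k[1] + k[3]) / n, tolerance = 1e-12)
    expect_equal(unname(exp(-(b + cc))), (k[1] + k[2]) / n, tolerance = 1e-12)
    expect_equal(unname(exp(-(a + b + cc))), k[1] / n, tolerance = 1e-12)
  }
})

test_that("point estimators are invariant to replicate ordering", {
  set.seed(11)
  counts <- simulate_counts(dpcr_scenario(0.6, qoi = "fa", fraction = 0.3))
  perm <- counts[order(-counts$replicate, counts$channel), ]
  f1 <- dpcr_fit(counts, "fa", "nonpvar")
  f2 <- dpcr_fit(perm, "fa", "nonpvar")
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$var, f2$var)
  a <- c(0.2, 0.9, 0.5); b <- c(0.3, 0.3, 0.4)
  p <- c(3, 1, 2)
  expect_equal(qoi_cnv_duplex(a, b), qoi_cnv_duplex(a[p], b[p]))
  expect_equal(qoi_log_cnv_singleplex(a, b), qoi_log_cnv_singleplex(a[p], b[p]))
  expect_equal(qoi_fractional_abundance(a, b), qoi_fractional_abundance(a[p], b[p]))
})
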