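# NonPVar, BinomVar and normal/t interval machinery

test_that("NonPVar reproduces hand-computed variances and t intervals", {
  r0 <- nonpvar(c(1, 1, 1))
  expect_equal(r0$s2, 0)
  expect_equal(unname(diff(r0$ci)), 0)

  r1 <- nonpvar(c(1, 2))
  expect_equal(r1$s2, 0.5)
  expect_equal(r1$var, 0.25)

  # r = 3: CI half-width = se * t_{2; 0.025} = se * 4.302653
  r2 <- nonpvar(c(0.9, 1.0, 1.1))
  expect_equal(unname(r2$ci[2] - r2$estimate), r2$se * 4.302653, tolerance = 1e-6)
  expect_equal(r2$df, 2)

  expect_error(nonpvar(1), "2 replicates")
  expect_error(nonpvar(c(1, 2), alpha = 1.2), "alpha")
})

test_that("normal CI multiplier and degenerate cases are right", {
  ci <- ci_normal(1, 0.01)
  expect_equal(unname(ci), c(0.9804, 1.0196), tolerance = 1e-4)
  expect_equal(unname(ci_normal(3, 0)), c(3, 3))
  # alpha = 0.3173 makes the multiplier 1 (one-sigma interval)
  ci1 <- ci_normal(0, 1, alpha = 0.3173)
  expect_equal(unname(ci1[2]), 1, tolerance = 1e-4)
  expect_error(ci_normal(1, 0.1, alpha = 0), "alpha")
  expect_error(ci_normal(1, -0.1), "non-negative")
})

test_that("singleplex CNV variance composition matches the closed form", {
  v <- 0.3
  expect_equal(compose_variance_singleplex_cnv(rep(v, 3), rep(v, 3)), 2 * v / 3)
  expect_equal(compose_variance_singleplex_cnv(c(1, 2, 3), c(0, 0, 0)), 6 / 9)
  expect_equal(compose_variance_singleplex_cnv(0.2, 0.5), 0.7)  # r = 1
  expect_error(compose_variance_singleplex_cnv(numeric(0), numeric(0)), "empty")
  expect_error(compose_variance_singleplex_cnv(c(1, 2), 1), "unequal")
})

test_that("BinomVar converges to the delta variance as B grows", {
  # both rest on the same binomial; at B = 10000 they must agree within
  # 3 Monte-Carlo standard errors of a sample variance, sd ~ V sqrt(2/B)
  counts <- make_counts(rbind(A = c(10000, 10000, 10000)), 20000)
  bv <- binomvar(counts, "lambda", B = 10000, seed = 101)
  vd <- delta_var_lambda(10000, 20000) / 3
  mc_se <- vd * sqrt(2 / 10000)
  expect_lt(abs(bv$var - vd), 3 * mc_se)
})

test_that("BinomVar is deterministic given a seed and replicate-order invariant", {
  counts <- make_counts(rbind(A = c(6321, 6400, 6250)), 20000)
  b1 <- binomvar(counts, "lambda", B = 500, seed = 7)
  b2 <- binomvar(counts, "lambda", B = 500, seed = 7)
  expect_identical(b1$var, b2$var)
  expect_identical(b1$ci, b2$ci)
  # reorder replicates: per-replicate child streams keep the result identical
  perm <- make_counts(rbind(A = c(6250, 6321, 6400)), 20000)
  b3 <- binomvar(perm, "lambda", B = 500, seed = 7)
  expect_equal(sort(b3$sigma2_i), sort(b1$sigma2_i))
  expect_equal(b3$estimate, b1$estimate)
})

test_that("degenerate inputs give zero variance, saturated draws are redrawn", {
  # k = 0 everywhere: pooled pi-hat = 0, all bootstrap draws identical
  z <- binomvar(make_counts(rbind(A = c(0, 0, 0)), 20000), "lambda",
                B = 200, seed = 1)
  expect_equal(z$var, 0)
  expect_equal(unname(diff(z$ci)), 0)

  # tiny n with high load: saturated draws certain, must be rejected and
  # redrawn yet still produce a finite variance
  s <- binomvar(make_counts(rbind(A = c(9, 8, 9)), 10), "lambda",
                B = 300, seed = 2)
  expect_true(is.finite(s$var))
  expect_gt(s$rejected_draws, 0)
})

test_that("duplex fractional-abundance bootstrap is symmetric across channels", {
  k <- rbind(A = c(7000, 7100, 6950), B = c(7050, 6990, 7080))
  bv <- binomvar(make_counts(k, 20000), "fa", B = 2000, seed = 5)
  expect_equal(bv$estimate, 0.5, tolerance = 0.01)
  expect_true(bv$var > 0)
})

test_that("engine audit trail exposes the per-replicate decomposition", {
  counts <- make_counts(rbind(A = c(5000, 5100, 5050)), 20000)
  bv <- binomvar(counts, "lambda", B = 500, seed = 3)
  expect_length(bv$sigma2_i, 3)
  expect_equal(bv$s2, mean(bv$sigma2_i))
  expect_equal(bv$var, bv$s2 / 3)
  expect_true(all(bv$sigma2_i >= 0))
  expect_lte(bv$var, bv$s2)
})
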