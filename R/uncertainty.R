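# The three variance / confidence-interval engines: NonPVar, BinomVar and
# the delta method.  All engines report the variance of the *pooled* (mean
# over replicates) estimator, together with the per-replicate variance
# decomposition for audit.

#' Normal-theory confidence interval
#'
#' \eqn{\hat\theta \pm z_{\alpha/2}\,\mathrm{se}}; for \eqn{\alpha = 0.05}
#' the multiplier is 1.959964.
#'
#' @param estimate point estimate.
#' @param se standard error (>= 0).
#' @param alpha significance level in (0, 1); default 0.05.
#' @return Numeric vector \code{c(low, high)}.
#' @export
ci_normal <- function(estimate, se, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (any(se < 0)) stop("se must be non-negative", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  c(low = estimate - z * se, high = estimate + z * se)
}

#' Nonparametric replicate-based variance (NonPVar)
#'
#' Estimates the variance of a pooled dPCR quantity from the empirical
#' spread of its per-replicate estimates: \eqn{S^2 = \frac{1}{r-1}\sum_i
#' (\hat\theta_i - \bar\theta)^2}, variance of the mean \eqn{S^2/r}, and a
#' Student-t confidence interval with \eqn{r - 1} degrees of freedom
#' (preferred over the normal interval at the small replicate numbers
#' typical of dPCR).  No distributional assumption is placed on the counts,
#' which makes the method robust to error sources (e.g. pipetting) that
#' act between replicates.
#'
#' @param estimates numeric vector of per-replicate estimates
#'   \eqn{\hat\theta_i}; at least two replicates are required.
#' @param alpha significance level for the CI; default 0.05.
#' @return A list with \code{estimate} (mean), \code{per_replicate},
#'   \code{s2} (between-replicate variance), \code{var} (variance of the
#'   mean, \eqn{S^2/r}), \code{se}, \code{ci} (t-interval), \code{df} and
#'   \code{alpha}.
#' @export
nonpvar <- function(estimates, alpha = 0.05) {
  r <- length(estimates)
  if (r < 2L)
    stop("NonPVar needs at least 2 replicates to estimate a variance",
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  est <- mean(estimates)
  s2 <- stats::var(estimates)
  v <- s2 / r
  se <- sqrt(v)
  tq <- stats::qt(1 - alpha / 2, df = r - 1)
  list(estimate = est, per_replicate = estimates, s2 = s2, var = v, se = se,
       ci = c(low = est - tq * se, high = est + tq * se),
       df = r - 1, alpha = alpha, method = "nonpvar")
}

#' Compose singleplex CNV variance from per-replicate log-rate variances
#'
#' For a log copy-number ratio estimated from two independent singleplex
#' series with \eqn{r} replicates each, the variance of the pooled
#' estimator is \eqn{(\sum_i v_{A,i} + \sum_i v_{B,i}) / r^2}, where
#' \eqn{v_{\cdot,i}} are per-replicate variances of
#' \eqn{\ln\hat\lambda_i}.
#'
#' @param vars_target,vars_ref equal-length numeric vectors of
#'   per-replicate variances for the target and reference series.
#' @return The variance of the pooled log-CNV estimator.
#' @export
compose_variance_singleplex_cnv <- function(vars_target, vars_ref) {
  if (length(vars_target) == 0L || length(vars_ref) == 0L)
    stop("empty variance list", call. = FALSE)
  if (length(vars_target) != length(vars_ref))
    stop("unequal replicate counts", call. = FALSE)
  r <- length(vars_target)
  (sum(vars_target) + sum(vars_ref)) / r^2
}

# ---- BinomVar ------------------------------------------------------------

# deterministic per-replicate child seed so results do not depend on the
# order in which replicates/channels are visited
.child_seed <- function(seed, i) as.integer((seed + 104729 * i) %% 2147483629L)

# Draw B per-replicate bootstrap values of the QOI for replicate i.
# lam_bar: pooled per-channel means (per-partition scale); for integrity,
# pooled (a, b, c).  Invalid draws (saturated, zero where a log or a ratio
# needs positivity) are redrawn, with a hard cap.
.binomvar_draws <- function(qoi, n_i, lam_bar, B, vd, vp) {
  max_redraws <- 100 * B
  rejected <- 0L
  if (qoi == "integrity") {
    a <- lam_bar["lambda_a"]; b <- lam_bar["lambda_b"]; cc <- lam_bar["lambda_ab"]
    p_nn <- exp(-(a + b + cc))
    p_an <- exp(-(b + cc)) - p_nn   # A+B-
    p_bn <- exp(-(a + cc)) - p_nn   # A-B+
    p_pp <- max(0, 1 - p_nn - p_an - p_bn)
    n <- n_i[1L]
    draw <- function(m) stats::rmultinom(m, n, c(p_nn, p_an, p_bn, p_pp))
    cnt <- draw(B)
    repeat {
      bad <- cnt[1L, ] == 0 | cnt[1L, ] + cnt[3L, ] == 0 | cnt[1L, ] + cnt[2L, ] == 0
      if (!any(bad)) break
      rejected <- rejected + sum(bad)
      if (rejected > max_redraws)
        stop("BinomVar: too many degenerate bootstrap draws", call. = FALSE)
      cnt[, bad] <- draw(sum(bad))
    }
    f_nn <- cnt[1L, ] / n
    f_a_neg <- (cnt[1L, ] + cnt[3L, ]) / n
    f_b_neg <- (cnt[1L, ] + cnt[2L, ]) / n
    c_hat <- pmax(0, log(f_nn / (f_a_neg * f_b_neg)))
    a_hat <- -log(f_a_neg) - c_hat
    b_hat <- -log(f_b_neg) - c_hat
    broken <- (a_hat + b_hat) / 2
    val <- 1 - broken / (broken + c_hat)
    # degenerate draw with no molecules at all: redraw handled above via f checks;
    # a draw with broken + c_hat == 0 can only occur if all counts negative
    val[broken + c_hat == 0] <- NA_real_
    if (anyNA(val)) val[is.na(val)] <- 1  # zero molecules: define integrity as 1
    return(list(values = val, rejected = rejected))
  }

  chs <- rset_channels_for(qoi)
  pi_ch <- 1 - exp(-lam_bar[chs])
  draw_channel <- function(ch, m) stats::rbinom(m, n_i[ch], pi_ch[ch])
  kk <- vapply(chs, function(ch) draw_channel(ch, B), numeric(B))
  kk <- matrix(kk, nrow = B, dimnames = list(NULL, chs))
  needs_pos <- switch(qoi,
                      cnv_singleplex = c("A", "B"),
                      cnv_duplex = "B",
                      character(0))
  repeat {
    bad <- rep(FALSE, nrow(kk))
    for (ch in chs) bad <- bad | kk[, ch] == n_i[ch]      # saturation
    for (ch in needs_pos) bad <- bad | kk[, ch] == 0      # log/ratio undefined
    if (qoi == "fa") bad <- bad | (kk[, "A"] == 0 & kk[, "B"] == 0)
    if (!any(bad)) break
    rejected <- rejected + sum(bad)
    if (rejected > max_redraws)
      stop("BinomVar: too many degenerate bootstrap draws", call. = FALSE)
    for (ch in chs) kk[bad, ch] <- draw_channel(ch, sum(bad))
  }
  lam <- -log1p(-sweep(kk, 2, n_i[chs], "/"))
  val <- switch(qoi,
    lambda = (vd / vp) * lam[, "A"],
    concentration = lam[, "A"] / vp,
    cnv_singleplex = log(lam[, "A"]) - log(lam[, "B"]),
    cnv_duplex = lam[, "A"] / lam[, "B"],
    fa = lam[, "A"] / (lam[, "A"] + lam[, "B"]))
  list(values = val, rejected = rejected)
}

# BinomVar engine on an rset
binomvar_engine <- function(rset, qoi, B = 1000, seed = NULL, alpha = 0.05) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  per_rep <- rset_per_replicate(rset, qoi)       # also validates counts
  r <- ncol(rset$k)
  est <- mean(per_rep)
  lam <- rset_channel_lambdas(rset, qoi)
  lam_bar <- rowMeans(lam)                       # pooled per-channel means
  sigma2 <- numeric(r)
  rejected <- 0L
  for (i in seq_len(r)) {
    if (!is.null(seed)) set.seed(.child_seed(seed, i))
    n_i <- stats::setNames(rset$n[, i], rownames(rset$n))
    dr <- .binomvar_draws(qoi, n_i, lam_bar, B, rset$vd, rset$vp)
    sigma2[i] <- stats::var(dr$values)
    rejected <- rejected + dr$rejected
  }
  s2 <- mean(sigma2)
  v <- s2 / r
  se <- sqrt(v)
  list(estimate = est, per_replicate = per_rep, sigma2_i = sigma2, s2 = s2,
       var = v, se = se, ci = ci_normal(est, se, alpha), alpha = alpha,
       B = B, rejected_draws = rejected, method = "binomvar")
}

#' Parametric binomial bootstrap variance (BinomVar)
#'
#' Estimates the variance of a pooled dPCR quantity by resampling
#' positive-partition counts from the binomial approximation
#' \eqn{K_i \sim \mathrm{Binom}(n_i, \pi)} with
#' \eqn{\pi = 1 - e^{-\bar\lambda}} computed from the pooled mean of the
#' per-replicate rate estimates.  Per replicate \eqn{i}, \code{B} bootstrap
#' counts are drawn per channel (independent binomials per channel; a
#' joint multinomial over the four categories for integrity data so the
#' double-positive dependence is preserved), the quantity is recomputed
#' for each draw, and its sample variance \eqn{\hat\sigma_i^2} taken.  The
#' pooled variance is the average of the \eqn{\hat\sigma_i^2}, the
#' variance of the mean estimator is that average divided by \eqn{r}, and
#' the confidence interval is normal-theory.
#'
#' Degenerate draws for which the quantity is undefined (a saturated
#' count, or a zero count where a log or ratio needs positivity) are
#' rejected and redrawn, with a hard cap of \code{100 * B} rejections.
#'
#' @param counts a counts data frame (columns \code{sample},
#'   \code{replicate}, \code{channel}, \code{positives}, \code{total},
#'   optional \code{vd}, \code{vp}) for a single sample, as read by
#'   [read_counts()] or generated by [simulate_counts()].
#' @param qoi one of \code{"lambda"}, \code{"concentration"},
#'   \code{"cnv_singleplex"}, \code{"cnv_duplex"}, \code{"fa"},
#'   \code{"integrity"}.
#' @param B bootstrap iterations (default 1000).
#' @param seed optional integer; when given, per-replicate streams are
#'   derived deterministically from it so results are bit-reproducible and
#'   independent of replicate ordering.
#' @param alpha significance level; default 0.05.
#' @param sample optional sample id to select from \code{counts}.
#' @return A list with the point estimate, per-replicate estimates, the
#'   per-replicate bootstrap variances \code{sigma2_i}, their average
#'   \code{s2}, the variance \code{var} and \code{se} of the pooled
#'   estimator, the normal CI, and the number of rejected draws.
#' @export
binomvar <- function(counts, qoi = "lambda", B = 1000, seed = NULL,
                     alpha = 0.05, sample = NULL) {
  qoi <- match.arg(qoi, .qoi_labels)
  binomvar_engine(counts_to_rset(counts, sample), qoi, B = B, seed = seed,
                  alpha = alpha)
}

# ---- delta method --------------------------------------------------------

delta_engine <- function(rset, qoi, alpha = 0.05) {
  r <- ncol(rset$k)
  per_rep <- rset_per_replicate(rset, qoi)
  est <- mean(per_rep)
  if (qoi %in% c("lambda", "concentration")) {
    scale <- if (qoi == "lambda") rset$vd / rset$vp else 1 / rset$vp
    vars_i <- delta_var_lambda(rset$k["A", ], rset$n["A", ]) * scale^2
    v <- sum(vars_i) / r^2
  } else if (qoi == "cnv_singleplex") {
    lam <- rset_channel_lambdas(rset, qoi)
    if (any(lam <= 0))
      stop("delta log-CNV variance requires positive lambda estimates",
           call. = FALSE)
    term <- function(l, n) (1 - exp(-l)) / (n * l^2 * exp(-l))
    va <- term(lam["A", ], rset$n["A", ])
    vb <- term(lam["B", ], rset$n["B", ])
    vars_i <- va + vb
    v <- compose_variance_singleplex_cnv(va, vb)
  } else {
    stop("the delta method is not available for qoi '", qoi,
         "'; valid methods: binomvar, nonpvar", call. = FALSE)
  }
  se <- sqrt(v)
  list(estimate = est, per_replicate = per_rep, sigma2_i = vars_i,
       s2 = mean(vars_i), var = v, se = se, ci = ci_normal(est, se, alpha),
       alpha = alpha, method = "delta")
}
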