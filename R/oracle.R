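# Exact and approximate distributions of the number of positive partitions
# when m molecules are randomly partitioned into n equal partitions.  These
# serve as correctness oracles for the simulator and for the binomial
# approximation behind BinomVar.

# numerically stable log(exp(a) + exp(b)), vectorised
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf   # both -Inf
  out
}

# log S2(m, k) for k = 0..m by the recurrence
# S2(m, k) = k S2(m-1, k) + S2(m-1, k-1), carried in log space so it is
# exact (to double rounding) for any m it is asked for; used up to m = 300.
log_stirling2_row <- function(m) {
  row <- 0                                    # m = 0: S2(0,0) = 1
  if (m == 0) return(row)
  for (mm in seq_len(m)) {
    k <- seq_len(mm)
    prev <- c(row, -Inf)                      # S2(mm-1, k) with k = mm -> 0
    row <- c(-Inf, logaddexp(log(k) + prev[k + 1L], prev[k]))
  }
  row
}

#' Stirling numbers of the second kind (exact recurrence)
#'
#' \eqn{S_2(m, k)}, the number of ways to partition \eqn{m} labelled
#' objects into \eqn{k} non-empty subsets, by the recurrence
#' \eqn{S_2(m,k) = k\,S_2(m-1,k) + S_2(m-1,k-1)} with
#' \eqn{S_2(0,0) = 1}.  Values are exact while they fit in a double
#' (below \eqn{2^{53}}); use [log_stirling2()] beyond that.
#'
#' @param m,k non-negative integers; \code{k > m} gives 0.
#' @return \eqn{S_2(m, k)} as a double.
#' @examples
#' stirling2_exact(4, 2)  # 7
#' @export
stirling2_exact <- function(m, k) {
  if (m < 0 || k < 0) stop("m and k must be non-negative", call. = FALSE)
  if (k > m) return(0)
  row <- rep(0, m + 1L); row[1L] <- 1         # S2(0, .)
  if (m > 0) for (mm in seq_len(m)) {
    kk <- seq_len(mm)
    row[kk + 1L] <- kk * row[kk + 1L] + row[kk]
    row[1L] <- 0
  }
  row[k + 1L]
}

#' Log Stirling numbers of the second kind
#'
#' \eqn{\ln S_2(m, k)} via the exact recurrence carried in log space for
#' \eqn{m \le 300}, and the Lambert-W asymptotic
#' ([log_stirling2_approx()]) above.
#'
#' @inheritParams stirling2_exact
#' @return \eqn{\ln S_2(m, k)}; \code{-Inf} when \eqn{S_2 = 0}.
#' @export
log_stirling2 <- function(m, k) {
  if (m < 0 || any(k < 0)) stop("m and k must be non-negative", call. = FALSE)
  if (m <= 300) {
    row <- log_stirling2_row(m)
    out <- rep(-Inf, length(k))
    ok <- k <= m
    out[ok] <- row[k[ok] + 1L]
    return(out)
  }
  vapply(k, function(kk) log_stirling2_approx(m, kk), numeric(1))
}

# G = -W0(-v e^{-v}) for v >= 1: the principal-branch Lambert W value here
# is the unique G in (0, 1] solving G e^{-G} = v e^{-v}.  Solved directly on
# the log scale, which stays stable arbitrarily close to the branch point
# v = 1 (where general-purpose W iterations stall).
lambert_G <- function(v) {
  if (v < 1) stop("v must be >= 1", call. = FALSE)
  if (v == 1) return(1)
  target <- log(v) - v
  f <- function(g) log(g) - g - target
  lo <- v * exp(-v)                       # G > v e^{-v} since e^{-G} < 1
  stats::uniroot(f, c(lo * 0.5, 1), tol = 1e-15)$root
}

#' Lambert-W asymptotic for log Stirling numbers of the second kind
#'
#' The asymptotic approximation
#' \deqn{S_2(m,k) \sim \sqrt{\frac{v-1}{v(1-G)}}
#'   \left(\frac{v-1}{v-G}\right)^{m-k} \frac{k^m}{m^k}\, e^{k(1-G)}
#'   \binom{m}{k},}
#' with \eqn{v = m/k} and \eqn{G = -W_0(-v e^{-v})}, \eqn{W_0} the
#' principal branch of the Lambert W function (computed by solving its
#' defining equation, which is stable near the branch point \eqn{v = 1}).
#' Evaluated in log space;
#' its relative error shrinks as \eqn{m} grows.  The boundary cases
#' \eqn{k = m} (value 1) and \eqn{k = 0} fall back to exact values.
#'
#' @inheritParams stirling2_exact
#' @return Approximate \eqn{\ln S_2(m, k)}.
#' @export
log_stirling2_approx <- function(m, k) {
  if (m < 0 || k < 0) stop("m and k must be non-negative", call. = FALSE)
  if (k > m) return(-Inf)
  if (k == m) return(0)                       # S2(m, m) = 1
  if (k == 0) return(if (m == 0) 0 else -Inf)
  v <- m / k
  G <- lambert_G(v)
  0.5 * log((v - 1) / (v * (1 - G))) +
    (m - k) * log((v - 1) / (v - G)) +
    m * log(k) - k * log(m) + k * (1 - G) +
    lchoose(m, k)
}

#' Exact occupancy distribution of the positive-partition count
#'
#' Probability that exactly \eqn{k} of \eqn{n} equally likely partitions
#' are occupied when \eqn{m} molecules are placed independently and
#' uniformly at random:
#' \deqn{P(K = k \mid m, n) = \frac{n!\, S_2(m,k)}{(n-k)!\, n^m}.}
#' Computed in log space throughout (log-gamma for the factorials, the
#' log-space Stirling recurrence for \eqn{m \le 300} and the Lambert-W
#' asymptotic above), so it does not overflow for large \eqn{m, n}.
#'
#' @param k vector of positive-partition counts, \eqn{0 \le k \le
#'   \min(m, n)} (values outside get probability 0).
#' @param m number of molecules (fixed).
#' @param n number of partitions.
#' @param log logical; return log probabilities.
#' @return Probabilities (or log probabilities) of the same length as
#'   \code{k}.
#' @examples
#' occupancy_pmf(0:2, m = 2, n = 2)  # 0, 1/2, 1/2
#' @export
occupancy_pmf <- function(k, m, n, log = FALSE) {
  if (m < 0 || n < 1) stop("need m >= 0 and n >= 1", call. = FALSE)
  if (any(k != round(k))) stop("k must be integer", call. = FALSE)
  lp <- rep(-Inf, length(k))
  ok <- k >= 0 & k <= pmin(m, n)
  if (m == 0) {
    lp[k == 0] <- 0
  } else if (any(ok)) {
    ls2 <- log_stirling2(m, k[ok])
    lp[ok] <- lgamma(n + 1) - lgamma(n - k[ok] + 1) - m * base::log(n) + ls2
  }
  if (log) lp else exp(lp)
}

#' Binomial limit of the positive-partition distribution
#'
#' When the number of loaded molecules is itself Poisson with mean
#' \eqn{\mu}, the marginal distribution of the positive-partition count is
#' exactly \eqn{\mathrm{Binom}(n, \pi)} with \eqn{\pi = 1 - e^{-\mu/n}}.
#' This is the distribution BinomVar resamples from.
#'
#' @param k vector of counts.
#' @param n number of partitions.
#' @param mu mean number of molecules loaded in the device (>= 0).
#' @param log logical; return log probabilities.
#' @return Binomial probabilities at \code{k}.
#' @export
binomial_limit_pmf <- function(k, n, mu, log = FALSE) {
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  stats::dbinom(k, n, 1 - exp(-mu / n), log = log)
}

#' Poisson-mixture of the exact occupancy distribution
#'
#' Numerical evaluation of
#' \eqn{P(K = k \mid n) = \sum_m P(K = k \mid M = m, n)\,
#' \mathrm{Pois}(m; \mu)}, the molecule-count mixture of the exact
#' occupancy pmf.  Analytically this equals [binomial_limit_pmf()]; the
#' function exists as an independent numerical check of that identity.
#'
#' @inheritParams binomial_limit_pmf
#' @param m_max truncation point of the Poisson sum; default
#'   \eqn{\mu + 12\sqrt{\mu} + 20}, whose tail mass is negligible.
#' @return Probabilities at \code{k}, plus attribute \code{tail_mass}
#'   giving the truncated Poisson tail.
#' @export
poisson_mixture_pmf <- function(k, n, mu, m_max = NULL) {
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  if (is.null(m_max)) m_max <- ceiling(mu + 12 * sqrt(mu) + 20)
  p <- rep(0, length(k))
  for (m in 0:m_max) {
    w <- stats::dpois(m, mu)
    if (w == 0) next
    p <- p + w * occupancy_pmf(k, m, n)
  }
  attr(p, "tail_mass") <- stats::ppois(m_max, mu, lower.tail = FALSE)
  p
}
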