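#' Estimate the mean number of copies per partition
#'
#' The Poisson estimator of the mean number of target molecules per
#' partition, \eqn{\hat\lambda = -\ln(1 - k/n)}, where \eqn{k} is the number
#' of positive partitions and \eqn{n} the total number of partitions.  A
#' partition is negative exactly when it holds no target molecule, so the
#' observed negative fraction \eqn{1 - k/n} estimates \eqn{e^{-\lambda}}.
#'
#' A saturated reaction (\code{k == n}) carries no information about the
#' upper tail of the concentration and yields an infinite estimate; by
#' default this is an error.  The opt-in continuity correction replaces
#' \code{k} with \code{n - 0.5}, which keeps the estimate finite but is a
#' heuristic, not part of the underlying model.
#'
#' @param k integer, number of positive partitions (0 <= k <= n).
#' @param n integer, total number of partitions (n >= 1).
#' @param saturation_correction logical; if \code{TRUE}, a saturated
#'   reaction (\code{k == n}) is handled by substituting \code{n - 0.5} for
#'   \code{k} instead of raising an error.  Default \code{FALSE}.
#' @return The estimate \eqn{\hat\lambda} (copies per partition), a
#'   non-negative number.  Zero exactly when \code{k} is zero.
#' @examples
#' estimate_lambda(12642, 20000)   # ~1 copy per partition
#' estimate_lambda(0, 20000)       # no positives -> 0
#' @seealso [delta_var_lambda()] for its delta-method variance,
#'   [dpcr_fit()] for full estimation with confidence intervals.
#' @export
estimate_lambda <- function(k, n, saturation_correction = FALSE) {
  check_counts(k, n)
  if (any(k == n)) {
    if (!saturation_correction) {
      stop("saturated reaction (k == n): lambda estimate is infinite; ",
           "use saturation_correction = TRUE to substitute k = n - 0.5",
           call. = FALSE)
    }
    k <- ifelse(k == n, n - 0.5, k)
  }
  -log1p(-k / n)
}

# shared validation of (k, n) count pairs
check_counts <- function(k, n) {
  if (length(k) != length(n) && length(k) != 1L && length(n) != 1L)
    stop("k and n lengths differ", call. = FALSE)
  if (any(!is.finite(k)) || any(!is.finite(n)))
    stop("k and n must be finite", call. = FALSE)
  if (any(n < 1))
    stop("n must be >= 1", call. = FALSE)
  if (any(k < 0))
    stop("k must be >= 0", call. = FALSE)
  if (any(k > n))
    stop("k must not exceed n", call. = FALSE)
  if (any(k != round(k)) || any(n != round(n)))
    stop("k and n must be integers", call. = FALSE)
  invisible(TRUE)
}

#' Combine replicate estimates into the mean loaded copy number
#'
#' With \eqn{r} replicates the mean number of target molecules loaded in the
#' device is estimated as \eqn{\hat\mu = (V_d/V_p)\,\frac1r\sum_i
#' \hat\lambda_i}, where \eqn{V_d} is the loaded volume and \eqn{V_p} the
#' partition volume.  When the volumes are not supplied the ratio defaults
#' to 1 and \eqn{\hat\mu} is simply the mean copies-per-partition.
#'
#' @param lambdas numeric vector of per-replicate \eqn{\hat\lambda_i}.
#' @param vd,vp loaded volume and partition volume (same units); both
#'   default to 1 so the result is on the per-partition scale.
#' @return The point estimate \eqn{\hat\mu}.
#' @export
estimate_mu <- function(lambdas, vd = 1, vp = 1) {
  if (length(lambdas) < 1L) stop("at least one replicate required", call. = FALSE)
  if (vd <= 0 || vp <= 0) stop("vd and vp must be positive", call. = FALSE)
  (vd / vp) * mean(lambdas)
}

#' Target concentration per volume unit
#'
#' Converts a copies-per-partition estimate into a concentration,
#' \eqn{\hat\lambda / V_p}.
#'
#' @param lambda estimated mean copies per partition.
#' @param vp partition volume (e.g. in microlitres); must be positive.
#' @return Concentration in copies per unit of \code{vp}.
#' @examples
#' estimate_concentration(1, vp = 0.85e-3)  # ~1176.5 copies/uL
#' @export
estimate_concentration <- function(lambda, vp) {
  if (any(vp <= 0)) stop("vp must be positive", call. = FALSE)
  lambda / vp
}

#' Delta-method variance of the lambda estimator
#'
#' First-order Taylor (delta-method) variance of
#' \eqn{\hat\lambda = -\ln(1-k/n)} under the binomial model for the number
#' of positive partitions: \eqn{\widehat{\mathrm{Var}}(\hat\lambda) =
#' k / [n(n-k)]}, the plug-in of \eqn{\hat\pi = k/n} into
#' \eqn{\pi / (n(1-\pi))}.
#'
#' @inheritParams estimate_lambda
#' @return Estimated variance of \eqn{\hat\lambda}; zero when \code{k} is 0.
#' @examples
#' delta_var_lambda(10000, 20000)  # 2.5e-5
#' @export
delta_var_lambda <- function(k, n) {
  check_counts(k, n)
  if (any(k == n))
    stop("saturated reaction (k == n): delta variance undefined", call. = FALSE)
  k / (n * (n - k))
}

#' Delta-method variance of a log copy-number ratio
#'
#' Variance of \eqn{\ln(\hat\lambda_t/\hat\lambda_r)} from two independent
#' singleplex reactions with \code{n} partitions each:
#' \deqn{\frac{1-e^{-\lambda_t}}{n\,\lambda_t^2 e^{-\lambda_t}} +
#'       \frac{1-e^{-\lambda_r}}{n\,\lambda_r^2 e^{-\lambda_r}}.}
#' A confidence interval on the natural CNV scale is obtained by
#' exponentiating the log-scale bounds.
#'
#' @param lambda_t,lambda_r positive mean copies per partition for target
#'   and reference.
#' @param n total partitions per reaction; \code{n_r} may be given when the
#'   two reactions differ in size.
#' @param n_r partitions of the reference reaction (defaults to \code{n}).
#' @return Estimated variance of the log ratio.
#' @export
delta_var_log_cnv <- function(lambda_t, lambda_r, n, n_r = n) {
  if (any(lambda_t <= 0) || any(lambda_r <= 0))
    stop("lambda values must be positive for the log-scale variance", call. = FALSE)
  if (any(n < 1) || any(n_r < 1)) stop("n must be >= 1", call. = FALSE)
  term <- function(lam, nn) (1 - exp(-lam)) / (nn * lam^2 * exp(-lam))
  term(lambda_t, n) + term(lambda_r, n_r)
}
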