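# Quantities of interest computed from per-replicate lambda estimates.
# Each qoi_* function maps per-replicate rate estimates to the
# per-replicate value of the quantity; pooling is the plain mean over
# replicates, which makes every point estimator invariant to replicate
# ordering.

#' Log copy-number ratio from two singleplex replicate series
#'
#' Paired log-ratio estimator for copy number variation when target and
#' reference are quantified in separate (singleplex) reactions:
#' \eqn{\hat\theta = \frac1r \sum_i (\ln\hat\lambda_{A,i} -
#' \ln\hat\lambda_{B,i})}.  The CNV point estimate on the natural scale is
#' \eqn{e^{\hat\theta}}.
#'
#' Replicates are paired by position.  When the two series have unequal
#' length the default is an error; \code{unpaired = TRUE} opts into the
#' all-pairs form \eqn{\frac{1}{r_A r_B}\sum_i\sum_j \hat\theta_{ij}},
#' which for the log ratio reduces to the difference of the two mean logs.
#'
#' @param lambda_target,lambda_ref positive per-replicate rate estimates
#'   for target (A) and reference (B).
#' @param unpaired logical; allow unequal replicate counts by averaging the
#'   log ratio over all target x reference pairs.
#' @return The log-scale CNV estimate \eqn{\hat\theta}.
#' @export
qoi_log_cnv_singleplex <- function(lambda_target, lambda_ref, unpaired = FALSE) {
  if (any(lambda_target <= 0) || any(lambda_ref <= 0))
    stop("log CNV requires strictly positive lambda estimates", call. = FALSE)
  if (length(lambda_target) != length(lambda_ref)) {
    if (!unpaired)
      stop("unequal replicate counts; set unpaired = TRUE for the all-pairs estimator",
           call. = FALSE)
    return(mean(log(lambda_target)) - mean(log(lambda_ref)))
  }
  mean(log(lambda_target) - log(lambda_ref))
}

#' Copy-number ratio from a duplex reaction
#'
#' Mean over replicates of the per-replicate ratio
#' \eqn{\hat\lambda_{A,i}/\hat\lambda_{B,i}} (mean of ratios, not ratio of
#' means), for duplex assays where target and reference share partitions.
#'
#' @param lambda_target,lambda_ref per-replicate rate estimates; every
#'   reference estimate must be positive.
#' @return The CNV point estimate on the natural scale.
#' @export
qoi_cnv_duplex <- function(lambda_target, lambda_ref) {
  stopifnot(length(lambda_target) == length(lambda_ref))
  if (any(lambda_ref <= 0))
    stop("reference lambda must be positive in every replicate", call. = FALSE)
  mean(lambda_target / lambda_ref)
}

#' Fractional abundance of a mutant allele
#'
#' Mean over replicates of
#' \eqn{\hat F_i = \hat\lambda_{A,i} / (\hat\lambda_{A,i} +
#' \hat\lambda_{B,i})}, the proportion of mutant (A) among mutant plus
#' wild-type (B) molecules in a duplex assay.  Always in \eqn{[0, 1]}.
#'
#' @param lambda_mut,lambda_wt per-replicate rate estimates for mutant and
#'   wild type; their sum must be positive in every replicate.
#' @return The fractional-abundance estimate in \eqn{[0, 1]}.
#' @export
qoi_fractional_abundance <- function(lambda_mut, lambda_wt) {
  stopifnot(length(lambda_mut) == length(lambda_wt))
  tot <- lambda_mut + lambda_wt
  if (any(tot <= 0))
    stop("both channels are zero in at least one replicate", call. = FALSE)
  mean(lambda_mut / tot)
}

#' Decompose four-category duplex counts into linked and unlinked rates
#'
#' For a linkage (DNA integrity) duplex assay the partitions fall in four
#' categories: double negative, A-only positive, B-only positive, and
#' double positive.  Under Poisson loading of three independent molecule
#' species -- free A fragments (rate \eqn{a}), free B fragments (rate
#' \eqn{b}) and intact molecules carrying both targets (rate \eqn{c}) --
#' the negative fractions satisfy
#' \deqn{P(A^-) = e^{-(a+c)},\quad P(B^-) = e^{-(b+c)},\quad
#'       P(A^-B^-) = e^{-(a+b+c)}.}
#' Inverting this system gives
#' \eqn{\hat c = \ln\{f_{--}/(f_{A^-} f_{B^-})\}} (clipped at zero when
#' sampling noise drives the observed double negatives below independence),
#' \eqn{\hat a = -\ln f_{A^-} - \hat c} and \eqn{\hat b = -\ln f_{B^-} -
#' \hat c}.
#'
#' @param n_double_neg,n_a_only,n_b_only,n_double_pos non-negative
#'   partition counts of the four categories; they must sum to \code{n}.
#' @param n total number of partitions.
#' @return A named numeric vector with elements \code{lambda_a}
#'   (unlinked A), \code{lambda_b} (unlinked B) and \code{lambda_ab}
#'   (linked, intact), plus attribute \code{clipped} indicating whether the
#'   linked rate was clipped at zero.
#' @export
decompose_linkage <- function(n_double_neg, n_a_only, n_b_only, n_double_pos, n) {
  cnt <- c(n_double_neg, n_a_only, n_b_only, n_double_pos)
  if (any(cnt < 0)) stop("category counts must be non-negative", call. = FALSE)
  if (sum(cnt) != n) stop("category counts must sum to n", call. = FALSE)
  f_neg_neg <- n_double_neg / n
  f_a_neg <- (n_double_neg + n_b_only) / n   # negative in channel A
  f_b_neg <- (n_double_neg + n_a_only) / n   # negative in channel B
  if (f_neg_neg <= 0)
    stop("no double-negative partitions: rates not identifiable", call. = FALSE)
  if (f_a_neg <= 0 || f_b_neg <= 0)
    stop("saturated channel: rates not identifiable", call. = FALSE)
  c_hat <- log(f_neg_neg / (f_a_neg * f_b_neg))
  clipped <- c_hat < 0
  if (clipped) c_hat <- 0
  out <- c(lambda_a = -log(f_a_neg) - c_hat,
           lambda_b = -log(f_b_neg) - c_hat,
           lambda_ab = c_hat)
  attr(out, "clipped") <- clipped
  out
}

#' DNA integrity from linked and unlinked rates
#'
#' Mean over replicates of the per-replicate integrity
#' \deqn{1 - \frac{(\hat\lambda_{A,i} + \hat\lambda_{B,i})/2}
#'   {(\hat\lambda_{A,i} + \hat\lambda_{B,i})/2 + \hat\lambda_{AB,i}},}
#' where \eqn{\hat\lambda_{A}} and \eqn{\hat\lambda_{B}} are the rates of
#' broken (single-positive) fragments and \eqn{\hat\lambda_{AB}} the rate
#' of intact (double-positive) molecules.  Values near 1 indicate mostly
#' intact DNA.
#'
#' @param lambda_a,lambda_b,lambda_ab per-replicate unlinked and linked
#'   rates, e.g. from [decompose_linkage()].
#' @return The integrity estimate in \eqn{[0, 1]}.
#' @export
qoi_integrity <- function(lambda_a, lambda_b, lambda_ab) {
  stopifnot(length(lambda_a) == length(lambda_b),
            length(lambda_a) == length(lambda_ab))
  broken <- (lambda_a + lambda_b) / 2
  denom <- broken + lambda_ab
  if (any(denom <= 0))
    stop("no molecules detected in at least one replicate", call. = FALSE)
  mean(1 - broken / denom)
}
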