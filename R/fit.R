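#' Fit a dPCR quantity with uncertainty
#'
#' The package's central fitting function.  Takes a counts table (one row
#' per sample, replicate and channel), computes the per-replicate Poisson
#' rate estimates \eqn{\hat\lambda_i = -\ln(1 - k_i/n_i)}, pools them into
#' the requested quantity of interest, and attaches a variance, standard
#' error and confidence interval from one of three engines:
#'
#' \describe{
#'   \item{\code{nonpvar}}{nonparametric between-replicate variance with a
#'     Student-t interval (\eqn{r - 1} df); robust to error sources acting
#'     between replicates, needs \eqn{r \ge 2}.}
#'   \item{\code{binomvar}}{parametric binomial bootstrap resampling
#'     positive counts from \eqn{\mathrm{Binom}(n_i, 1 - e^{-\bar\lambda})};
#'     precise under the Poisson/binomial model, normal interval.}
#'   \item{\code{delta}}{closed-form first-order variance; available for
#'     absolute quantification (\code{lambda}, \code{concentration}) and
#'     singleplex log-CNV only, normal interval.}
#' }
#'
#' The singleplex CNV quantity is estimated on the log scale
#' (\code{qoi = "cnv_singleplex"}); its interval back-transforms to the
#' natural CNV scale by exponentiation, which [summary.dpcr_fit()] prints.
#'
#' @param data a counts data frame with columns \code{sample},
#'   \code{replicate}, \code{channel}, \code{positives}, \code{total} and
#'   optional \code{vd}, \code{vp} (see [read_counts()]), or anything
#'   coercible to one.  Channels required per quantity: \code{"A"} for
#'   absolute quantification; \code{"A"} (target/mutant) and \code{"B"}
#'   (reference/wild-type) for CNV and fractional abundance; categories
#'   \code{"A"} (A-only), \code{"B"} (B-only), \code{"AB"} (double
#'   positive) for integrity.
#' @param qoi quantity of interest: \code{"lambda"} (mean copies per
#'   partition, scaled by \eqn{V_d/V_p} when volumes are supplied),
#'   \code{"concentration"} (copies per volume unit, needs \code{vp}),
#'   \code{"cnv_singleplex"} (log scale), \code{"cnv_duplex"},
#'   \code{"fa"} (fractional abundance) or \code{"integrity"}.
#' @param method \code{"nonpvar"} (default), \code{"binomvar"} or
#'   \code{"delta"}.
#' @param sample which sample to fit when \code{data} holds several.
#' @param B bootstrap iterations for BinomVar.
#' @param alpha significance level of the interval (default 0.05).
#' @param seed optional integer seed making BinomVar bit-reproducible.
#' @return An object of class \code{"dpcr_fit"}: a list with
#'   \code{estimate}, \code{var}, \code{se}, \code{ci}, \code{alpha},
#'   \code{per_replicate}, the variance decomposition of the engine,
#'   \code{qoi}, \code{method}, \code{scale} (\code{"log"} for singleplex
#'   CNV), \code{r} and the matched call.
#' @examples
#' counts <- simulate_counts(dpcr_scenario(0.5, seed = 7))
#' fit <- dpcr_fit(counts, qoi = "lambda", method = "nonpvar")
#' fit
#' confint(fit)
#' @export
dpcr_fit <- function(data, qoi = "lambda",
                     method = c("nonpvar", "binomvar", "delta"),
                     sample = NULL, B = 1000, alpha = 0.05, seed = NULL) {
  qoi <- match.arg(qoi, .qoi_labels)
  method <- match.arg(method)
  if (!inherits(data, "dpcr_counts")) data <- validate_counts(as.data.frame(data))
  rset <- counts_to_rset(data, sample)
  if (method == "nonpvar") {
    res <- nonpvar(rset_per_replicate(rset, qoi), alpha)
  } else if (method == "binomvar") {
    res <- binomvar_engine(rset, qoi, B = B, seed = seed, alpha = alpha)
  } else {
    res <- delta_engine(rset, qoi, alpha)
  }
  structure(c(res,
              list(qoi = qoi, scale = if (qoi == "cnv_singleplex") "log" else "natural",
                   r = ncol(rset$k), rset = rset, call = match.call())),
            class = "dpcr_fit")
}

.qoi_pretty <- c(lambda = "mean copies per partition",
                 concentration = "concentration (copies per volume unit)",
                 cnv_singleplex = "log copy-number ratio (singleplex)",
                 cnv_duplex = "copy-number ratio (duplex)",
                 fa = "fractional abundance",
                 integrity = "DNA integrity")

#' @export
print.dpcr_fit <- function(x, digits = 4, ...) {
  cat("dPCR fit:", .qoi_pretty[[x$qoi]], "\n")
  cat("method:", x$method, if (x$method == "binomvar") sprintf("(B = %d)", x$B),
      " replicates:", x$r, "\n")
  cat(sprintf("estimate: %.*g  se: %.*g\n", digits, x$estimate, digits, x$se))
  cat(sprintf("%d%% CI: [%.*g, %.*g]\n", round(100 * (1 - x$alpha)),
              digits, x$ci[1], digits, x$ci[2]))
  if (x$scale == "log")
    cat(sprintf("CNV (natural scale): %.*g, CI [%.*g, %.*g]\n",
                digits, exp(x$estimate), digits, exp(x$ci[1]),
                digits, exp(x$ci[2])))
  invisible(x)
}

#' @export
summary.dpcr_fit <- function(object, ...) {
  structure(object, class = c("summary.dpcr_fit", class(object)))
}

#' @export
print.summary.dpcr_fit <- function(x, digits = 4, ...) {
  print.dpcr_fit(x, digits = digits)
  cat("\nper-replicate estimates:\n")
  print(signif(x$per_replicate, digits))
  if (!is.null(x$sigma2_i)) {
    cat("per-replicate variances (engine decomposition):\n")
    print(signif(x$sigma2_i, digits))
  }
  cat(sprintf("between-replicate variance S2: %.*g; variance of the mean: %.*g\n",
              digits, x$s2, digits, x$var))
  if (!is.null(x$rejected_draws) && x$rejected_draws > 0)
    cat("bootstrap draws rejected as degenerate:", x$rejected_draws, "\n")
  invisible(x)
}

#' @export
coef.dpcr_fit <- function(object, ...) {
  stats::setNames(object$estimate, object$qoi)
}

#' @export
vcov.dpcr_fit <- function(object, ...) {
  matrix(object$var, 1, 1, dimnames = list(object$qoi, object$qoi))
}

#' @export
confint.dpcr_fit <- function(object, parm, level = 0.95, ...) {
  a <- 1 - level
  q <- if (object$method == "nonpvar") stats::qt(1 - a / 2, df = object$df)
       else stats::qnorm(1 - a / 2)
  ci <- object$estimate + c(-1, 1) * q * object$se
  out <- matrix(ci, 1, 2,
                dimnames = list(object$qoi,
                                paste0(100 * c(a / 2, 1 - a / 2), " %")))
  out
}

#' @export
plot.dpcr_fit <- function(x, ...) {
  r <- x$r
  graphics::plot(seq_len(r), x$per_replicate,
                 xlim = c(0.5, r + 1.5), ylim = range(x$ci, x$per_replicate),
                 xlab = "replicate", ylab = .qoi_pretty[[x$qoi]],
                 pch = 19, xaxt = "n", ...)
  graphics::axis(1, at = c(seq_len(r), r + 1),
                 labels = c(seq_len(r), "pooled"))
  graphics::points(r + 1, x$estimate, pch = 17, col = 2, cex = 1.3)
  graphics::arrows(r + 1, x$ci[1], r + 1, x$ci[2], angle = 90, code = 3,
                   length = 0.06, col = 2)
  invisible(x)
}

#' Estimate a quantity for every sample in a counts table
#'
#' Convenience wrapper fitting [dpcr_fit()] per sample and returning a
#' schema-stable results table (one row per sample), as used by the CLI
#' and for export with [write_estimates()].
#'
#' @inheritParams dpcr_fit
#' @return A \code{data.frame} with columns \code{sample}, \code{qoi},
#'   \code{method}, \code{estimate}, \code{variance}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{alpha}.
#' @export
dpcr_estimate_table <- function(data, qoi = "lambda",
                                method = c("nonpvar", "binomvar", "delta"),
                                B = 1000, alpha = 0.05, seed = NULL) {
  method <- match.arg(method)
  if (!inherits(data, "dpcr_counts")) data <- validate_counts(as.data.frame(data))
  samples <- unique(data$sample)
  rows <- lapply(samples, function(sm) {
    fit <- dpcr_fit(data, qoi = qoi, method = method, sample = sm,
                    B = B, alpha = alpha, seed = seed)
    data.frame(sample = sm, qoi = qoi, method = method,
               estimate = fit$estimate, variance = fit$var, se = fit$se,
               ci_low = fit$ci[1], ci_high = fit$ci[2], alpha = alpha,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
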