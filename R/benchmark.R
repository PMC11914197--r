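# Monte-Carlo evaluation of the variance methods: empirical coverage of
# the nominal 95% CIs, relative bias of the point estimator, and relative
# bias of the variance estimator against the empirical (Monte-Carlo)
# variance of the estimator across runs.

# generative truth of the scenario's quantity of interest
scenario_truth <- function(scn) {
  switch(scn$qoi,
         lambda = scn$lambda,
         concentration = scn$lambda,   # vp = 1 in simulation
         cnv_singleplex = log(scn$lambda / scn$lambda_ref),
         cnv_duplex = scn$lambda / scn$lambda_ref,
         fa = scn$fraction,
         integrity = scn$intactness)
}

.methods <- c("binomvar", "nonpvar", "delta")

apply_method <- function(rset, qoi, method, B, alpha) {
  switch(method,
         nonpvar = nonpvar(rset_per_replicate(rset, qoi), alpha),
         binomvar = binomvar_engine(rset, qoi, B = B, alpha = alpha),
         delta = delta_engine(rset, qoi, alpha))
}

#' Evaluate one (scenario, method) benchmark cell
#'
#' Simulates \code{n_sims} independent replicate sets from the scenario,
#' applies the requested variance method to each, and tallies: the
#' empirical coverage of the nominal \eqn{1-\alpha} confidence intervals
#' against the generative truth, the relative bias of the pooled point
#' estimator, and the relative bias of the variance estimator with respect
#' to the empirical variance of the estimator across runs (the only
#' available referent for the "true" variance).  For the log-scale
#' singleplex CNV, coverage is assessed on the log scale; the
#' back-transformed interval is equivalent by monotonicity.
#'
#' Runs in which the method fails (e.g. a saturated replicate, or a zero
#' count where a log is needed) are counted and reported as a failure
#' rate and excluded from the tallies, rather than silently dropped.
#'
#' @param scenario a [dpcr_scenario()].
#' @param method \code{"binomvar"}, \code{"nonpvar"} or \code{"delta"}
#'   (delta only for \code{lambda}, \code{concentration} and
#'   \code{cnv_singleplex}).
#' @param n_sims number of simulation runs (>= 2).
#' @param seed integer seed for the cell's private stream.
#' @param B bootstrap iterations for BinomVar (default 1000).
#' @param alpha significance level of the CIs (default 0.05).
#' @return A one-row \code{data.frame} with the scenario descriptors and
#'   the metrics \code{coverage}, \code{estimator_rel_bias},
#'   \code{variance_rel_bias}, \code{mean_estimate}, \code{mean_variance},
#'   \code{empirical_variance}, \code{n_ok}, \code{n_failed}.
#' @export
benchmark_cell <- function(scenario, method, n_sims = 1000, seed = NULL,
                           B = 1000, alpha = 0.05) {
  method <- match.arg(method, .methods)
  if (n_sims < 2) stop("n_sims must be >= 2", call. = FALSE)
  if (method == "delta" &&
      !scenario$qoi %in% c("lambda", "concentration", "cnv_singleplex"))
    stop("the delta method is not available for qoi '", scenario$qoi, "'",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  truth <- scenario_truth(scenario)
  est <- vh <- rep(NA_real_, n_sims)
  cov <- rep(NA, n_sims)
  n_failed <- 0L
  for (s in seq_len(n_sims)) {
    res <- tryCatch({
      rs <- simulate_rset(scenario)
      apply_method(rs, scenario$qoi, method, B, alpha)
    }, error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    est[s] <- res$estimate
    vh[s] <- res$var
    cov[s] <- res$ci[1] <= truth && truth <= res$ci[2]
  }
  ok <- !is.na(est)
  emp_var <- stats::var(est[ok])
  data.frame(qoi = scenario$qoi, method = method, lambda_true = scenario$lambda,
             truth = truth, n_sims = n_sims,
             coverage = mean(cov[ok]),
             estimator_rel_bias = (mean(est[ok]) - truth) / truth,
             variance_rel_bias = (mean(vh[ok]) - emp_var) / emp_var,
             mean_estimate = mean(est[ok]), mean_variance = mean(vh[ok]),
             empirical_variance = emp_var,
             n_ok = sum(ok), n_failed = n_failed,
             stringsAsFactors = FALSE)
}

#' Exact binomial acceptance band for empirical coverage
#'
#' The two-sided \code{level} acceptance band for the observed coverage of
#' a CI with nominal coverage \code{nominal} over \code{n_sims} Monte
#' Carlo runs, from exact binomial quantiles.
#'
#' @param n_sims number of Monte Carlo runs.
#' @param nominal nominal coverage probability (default 0.95).
#' @param level band confidence level (default 0.99).
#' @return \code{c(low, high)} as coverage fractions.
#' @export
coverage_band <- function(n_sims, nominal = 0.95, level = 0.99) {
  a <- (1 - level) / 2
  stats::qbinom(c(a, 1 - a), n_sims, nominal) / n_sims
}

#' Run a benchmark grid
#'
#' Evaluates [benchmark_cell()] over the cross product of error-source
#' scenarios, concentrations and methods, with an independent
#' deterministically derived seed stream per cell, so results do not
#' depend on execution order.
#'
#' @param lambdas numeric vector of true concentrations (copies per
#'   partition).
#' @param scenarios character vector of error presets, from
#'   \code{"sampling"}, \code{"pipetting"}, \code{"loss"},
#'   \code{"volume"}, \code{"misclass"}, \code{"all"}.
#' @param methods subset of \code{c("binomvar", "nonpvar", "delta")}.
#' @param qoi quantity of interest passed to [dpcr_scenario()].
#' @param n_sims,B,alpha per-cell settings, see [benchmark_cell()].
#' @param seed root integer seed.
#' @param ... further arguments to [dpcr_scenario()] (e.g.
#'   \code{n_replicates}, \code{intactness}).
#' @return Long-format \code{data.frame}, one row per cell, with a
#'   \code{scenario} column added to the [benchmark_cell()] metrics.
#' @export
benchmark_grid <- function(lambdas, scenarios = "sampling",
                           methods = c("binomvar", "nonpvar", "delta"),
                           qoi = "lambda", n_sims = 1000, seed = 1,
                           B = 1000, alpha = 0.05, ...) {
  out <- list(); idx <- 0L
  for (sc in scenarios) for (lam in lambdas) for (me in methods) {
    idx <- idx + 1L
    scn <- dpcr_scenario(lambda = lam, qoi = qoi,
                         errors = if (sc == "sampling") character() else sc, ...)
    cell <- benchmark_cell(scn, me, n_sims = n_sims,
                           seed = .child_seed(seed, idx), B = B, alpha = alpha)
    cell$scenario <- sc
    out[[idx]] <- cell
  }
  do.call(rbind, out)
}

#' Plot coverage and variance bias of a benchmark grid
#'
#' One panel per error scenario: empirical coverage (solid, left axis)
#' against the nominal level, and relative bias of the variance estimator
#' (dashed, right axis) against zero, as functions of concentration.
#'
#' @param grid a data frame from [benchmark_grid()].
#' @param nominal nominal coverage reference line (default 0.95).
#' @return The grid, invisibly.
#' @export
plot_benchmark <- function(grid, nominal = 0.95) {
  scenarios <- unique(grid$scenario)
  methods <- unique(grid$method)
  cols <- stats::setNames(seq_along(methods) + 1L, methods)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(scenarios)),
                      mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  for (sc in scenarios) {
    g <- grid[grid$scenario == sc, ]
    plot(range(g$lambda_true), c(0, 1), type = "n", log = "x",
         xlab = "copies per partition", ylab = "empirical coverage", main = sc)
    graphics::abline(h = nominal, col = "black")
    for (me in methods) {
      gm <- g[g$method == me, ]
      gm <- gm[order(gm$lambda_true), ]
      graphics::lines(gm$lambda_true, gm$coverage, col = cols[me], lwd = 2)
      graphics::lines(gm$lambda_true,
                      0.5 + gm$variance_rel_bias / 2,  # right-axis scaling
                      col = cols[me], lty = 2)
    }
    graphics::axis(4, at = c(0, 0.25, 0.5, 0.75, 1),
                   labels = c(-100, -50, 0, 50, 100))
    graphics::mtext("variance rel. bias (%)", side = 4, line = 2.5, cex = 0.7)
    graphics::abline(h = 0.5, lty = 2, col = "black")
  }
  graphics::legend("bottomright", legend = methods, col = cols[methods],
                   lwd = 2, bty = "n")
  invisible(grid)
}
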