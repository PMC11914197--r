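# Generative model of dPCR reactions with the common error sources:
# pipetting error on the loaded mean, random partition loss, partition
# volume variation, and end-point misclassification.

#' Define a simulation scenario
#'
#' A scenario bundles the generative configuration of a simulated dPCR
#' experiment: the target concentration, the partition count, which error
#' sources act and with what magnitude, the number of replicates and the
#' quantity of interest.  Defaults for the error magnitudes are the values
#' commonly used to stress-test dPCR uncertainty methods: 3% pipetting CV,
#' partition loss Normal(16000, 2000) out of 20000, log-normal partition
#' volumes with log-scale sd 0.1 (roughly a 10% CV), a 5% false-negative
#' and 0.01% false-positive rate -- each switched off unless requested.
#'
#' @param lambda mean copies per partition of the target (for duplex
#'   quantities this is the total target level; see \code{fraction},
#'   \code{lambda_ref}, \code{intactness}).
#' @param qoi quantity of interest: \code{"lambda"},
#'   \code{"cnv_singleplex"}, \code{"cnv_duplex"}, \code{"fa"} or
#'   \code{"integrity"}.
#' @param errors character vector of error sources to switch on, from
#'   \code{"pipetting"}, \code{"loss"}, \code{"volume"},
#'   \code{"misclass"}; \code{"all"} turns on all four and
#'   \code{"sampling"} (the default, empty) none.  Individual magnitude
#'   arguments below override the preset values.
#' @param n_partitions nominal number of partitions (default 20000).
#' @param pipetting_cv coefficient of variation of the normally
#'   distributed multiplicative pipetting error on the loaded mean.
#' @param partition_loss logical; lose partitions completely at random,
#'   retaining \code{Normal(loss_mean, loss_sd)} of them.
#' @param loss_mean,loss_sd mean and sd of the retained partition count.
#' @param volume_sigma log-scale standard deviation of log-normal
#'   partition volumes (0 = equal volumes).
#' @param fpr,fnr false-positive and false-negative classification rates.
#' @param n_replicates replicates per simulated run (default 3).
#' @param lambda_ref reference-channel mean for CNV quantities (defaults
#'   to \code{lambda}, i.e. true CNV 1, unless given).
#' @param fraction mutant fraction for fractional abundance: channel A
#'   gets \code{fraction * lambda}, channel B the rest.  Default 0.5.
#' @param intactness fraction of intact (linked) molecules for the
#'   integrity quantity; default 0.8.
#' @param fixed_m if non-NULL, the molecule count is fixed at this value
#'   instead of Poisson (single-channel only; pipetting is ignored).
#' @param seed optional integer seed stored with the scenario and used by
#'   [simulate_counts()] / [generate_fixture_csv()].
#' @return A list of class \code{"dpcr_scenario"}.
#' @export
dpcr_scenario <- function(lambda, qoi = "lambda", errors = character(),
                          n_partitions = 20000,
                          pipetting_cv = NULL, partition_loss = NULL,
                          loss_mean = 16000, loss_sd = 2000,
                          volume_sigma = NULL, fpr = NULL, fnr = NULL,
                          n_replicates = 3, lambda_ref = NULL,
                          fraction = 0.5, intactness = 0.8,
                          fixed_m = NULL, seed = NULL) {
  qoi <- match.arg(qoi, .qoi_labels)
  if (length(errors) && "all" %in% errors)
    errors <- c("pipetting", "loss", "volume", "misclass")
  errors <- setdiff(errors, "sampling")
  bad <- setdiff(errors, c("pipetting", "loss", "volume", "misclass"))
  if (length(bad)) stop("unknown error source: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(pipetting_cv)) pipetting_cv <- if ("pipetting" %in% errors) 0.03 else 0
  if (is.null(partition_loss)) partition_loss <- "loss" %in% errors
  if (is.null(volume_sigma)) volume_sigma <- if ("volume" %in% errors) 0.1 else 0
  if (is.null(fpr)) fpr <- if ("misclass" %in% errors) 1e-4 else 0
  if (is.null(fnr)) fnr <- if ("misclass" %in% errors) 0.05 else 0
  stopifnot(lambda >= 0, n_partitions >= 1, pipetting_cv >= 0,
            volume_sigma >= 0, fpr >= 0, fpr <= 1, fnr >= 0, fnr <= 1,
            n_replicates >= 1, fraction >= 0, fraction <= 1,
            intactness >= 0, intactness <= 1)
  if (is.null(lambda_ref)) lambda_ref <- lambda
  structure(list(lambda = lambda, qoi = qoi, n_partitions = n_partitions,
                 pipetting_cv = pipetting_cv, partition_loss = partition_loss,
                 loss_mean = loss_mean, loss_sd = loss_sd,
                 volume_sigma = volume_sigma, fpr = fpr, fnr = fnr,
                 n_replicates = n_replicates, lambda_ref = lambda_ref,
                 fraction = fraction, intactness = intactness,
                 fixed_m = fixed_m, seed = seed),
            class = "dpcr_scenario")
}

#' @export
print.dpcr_scenario <- function(x, ...) {
  cat("dPCR simulation scenario\n")
  cat("  qoi:", x$qoi, " lambda:", x$lambda, " replicates:", x$n_replicates, "\n")
  on <- c(if (x$pipetting_cv > 0) sprintf("pipetting (CV %g)", x$pipetting_cv),
          if (x$partition_loss) sprintf("loss Normal(%g, %g)", x$loss_mean, x$loss_sd),
          if (x$volume_sigma > 0) sprintf("volume LogNormal(0, %g)", x$volume_sigma),
          if (x$fpr > 0 || x$fnr > 0) sprintf("misclass (FPR %g, FNR %g)", x$fpr, x$fnr))
  cat("  error sources:", if (length(on)) paste(on, collapse = "; ")
      else "none (sampling only)", "\n")
  invisible(x)
}

# truncated multiplicative pipetting draw; resampled if 1 + eps <= 0.01
pipetting_factor <- function(cv) {
  if (cv == 0) return(1)
  repeat {
    eps <- stats::rnorm(1, 0, cv)
    if (eps > -0.99) return(1 + eps)
  }
}

# place molecule counts into partitions; returns a logical occupancy
# matrix (n_partitions x species) before loss and misclassification
place_molecules <- function(m_by_species, n, volume_sigma) {
  s <- length(m_by_species)
  pos <- matrix(FALSE, n, s)
  if (volume_sigma > 0) {
    w <- stats::rlnorm(n, 0, volume_sigma)
    for (j in seq_len(s)) if (m_by_species[j] > 0)
      pos[, j] <- stats::rmultinom(1, m_by_species[j], w) > 0L
  } else {
    for (j in seq_len(s)) if (m_by_species[j] > 0)
      pos[, j] <- tabulate(sample.int(n, m_by_species[j], replace = TRUE), n) > 0L
  }
  pos
}

# flip classification per partition per channel
misclassify <- function(pos, fpr, fnr) {
  if (fpr == 0 && fnr == 0) return(pos)
  u <- matrix(stats::runif(length(pos)), nrow(pos), ncol(pos))
  (pos & u >= fnr) | (!pos & u < fpr)
}

# one physical reaction: species means per nominal-partition, shared
# partitions, loss, volumes; returns channel-positivity matrix + realised n
sim_reaction_core <- function(lambda_by_species, scn) {
  n0 <- scn$n_partitions
  if (!is.null(scn$fixed_m)) {
    m <- scn$fixed_m
  } else {
    mu <- lambda_by_species * n0 * pipetting_factor(scn$pipetting_cv)
    m <- stats::rpois(length(mu), mu)
  }
  pos <- place_molecules(m, n0, scn$volume_sigma)
  if (scn$partition_loss) {
    n_keep <- max(1L, min(n0, round(stats::rnorm(1, scn$loss_mean, scn$loss_sd))))
    pos <- pos[sample.int(n0, n_keep), , drop = FALSE]
  }
  list(pos = pos, m = m, n = nrow(pos))
}

#' Simulate one dPCR replicate
#'
#' Runs the generative pipeline for a single replicate of the scenario's
#' quantity of interest: pipetting error on the loaded mean, Poisson
#' molecule sampling, random partitioning (volume-weighted if partition
#' volumes vary), random partition loss, and per-channel misclassification.
#' Duplex quantities (\code{cnv_duplex}, \code{fa}, \code{integrity})
#' share one reaction's partitions, realised partition count and pipetting
#' draw across channels, so those errors cancel in within-reaction ratios;
#' \code{cnv_singleplex} runs two independent reactions.
#'
#' @param scenario a [dpcr_scenario()].
#' @return A list with \code{k} (named positive counts per channel; for
#'   integrity the categories \code{A} = A-only, \code{B} = B-only,
#'   \code{AB} = double positive), \code{n} (named realised partition
#'   totals) and \code{provenance} (realised molecule counts).
#' @export
simulate_reaction <- function(scenario) {
  scn <- scenario
  qoi <- scn$qoi
  if (qoi %in% c("lambda", "concentration")) {
    rc <- sim_reaction_core(scn$lambda, scn)
    pos <- misclassify(rc$pos, scn$fpr, scn$fnr)
    return(list(k = c(A = sum(pos[, 1])), n = c(A = rc$n),
                provenance = list(m = rc$m)))
  }
  if (qoi == "cnv_singleplex") {
    ra <- sim_reaction_core(scn$lambda, scn)
    rb <- sim_reaction_core(scn$lambda_ref, scn)
    pa <- misclassify(ra$pos, scn$fpr, scn$fnr)
    pb <- misclassify(rb$pos, scn$fpr, scn$fnr)
    return(list(k = c(A = sum(pa[, 1]), B = sum(pb[, 1])),
                n = c(A = ra$n, B = rb$n),
                provenance = list(m = c(ra$m, rb$m))))
  }
  if (qoi %in% c("cnv_duplex", "fa")) {
    lam <- if (qoi == "fa")
      c(scn$fraction * scn$lambda, (1 - scn$fraction) * scn$lambda)
    else c(scn$lambda, scn$lambda_ref)
    rc <- sim_reaction_core(lam, scn)
    pos <- misclassify(rc$pos, scn$fpr, scn$fnr)
    return(list(k = c(A = sum(pos[, 1]), B = sum(pos[, 2])),
                n = c(A = rc$n, B = rc$n),
                provenance = list(m = rc$m)))
  }
  # integrity: intact molecules flag both channels; fragments one each
  lam <- c(intact = scn$intactness * scn$lambda,
           fragA = (1 - scn$intactness) * scn$lambda,
           fragB = (1 - scn$intactness) * scn$lambda)
  rc <- sim_reaction_core(lam, scn)
  chanA <- rc$pos[, 1] | rc$pos[, 2]
  chanB <- rc$pos[, 1] | rc$pos[, 3]
  ch <- misclassify(cbind(chanA, chanB), scn$fpr, scn$fnr)
  list(k = c(A = sum(ch[, 1] & !ch[, 2]), B = sum(!ch[, 1] & ch[, 2]),
             AB = sum(ch[, 1] & ch[, 2])),
       n = c(A = rc$n, B = rc$n, AB = rc$n),
       provenance = list(m = rc$m))
}

# simulate a full replicate set as the internal rset structure
simulate_rset <- function(scenario) {
  reps <- lapply(seq_len(scenario$n_replicates),
                 function(i) simulate_reaction(scenario))
  k <- vapply(reps, `[[`, reps[[1]]$k, "k")
  n <- vapply(reps, `[[`, reps[[1]]$n, "n")
  if (is.null(dim(k))) { k <- rbind(A = k); n <- rbind(A = n) }
  new_rset(k, n)
}

#' Simulate a replicate set as a counts table
#'
#' Generates \code{n_replicates} replicates of the scenario and returns
#' them in the standard counts-table schema (columns \code{sample},
#' \code{replicate}, \code{channel}, \code{positives}, \code{total}),
#' ready for [dpcr_fit()] or [write_counts()].
#'
#' @param scenario a [dpcr_scenario()].
#' @param sample sample identifier written in the \code{sample} column.
#' @return A \code{data.frame} in the counts schema.
#' @export
simulate_counts <- function(scenario, sample = "sim") {
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  rs <- simulate_rset(scenario)
  chs <- rownames(rs$k); r <- ncol(rs$k)
  data.frame(sample = sample,
             replicate = rep(seq_len(r), each = length(chs)),
             channel = rep(chs, r),
             positives = as.vector(rs$k),
             total = as.vector(rs$n),
             stringsAsFactors = FALSE)
}

#' Write a simulated fixture CSV
#'
#' Simulates the scenario (deterministically when it carries a seed) and
#' writes the counts in the package's CSV schema.  Useful as a stand-in
#' demo dataset.
#'
#' @param scenario a [dpcr_scenario()].
#' @param path output file path.
#' @param sample sample identifier.
#' @return The path, invisibly.
#' @export
generate_fixture_csv <- function(scenario, path, sample = "sim") {
  counts <- simulate_counts(scenario, sample = sample)
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
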