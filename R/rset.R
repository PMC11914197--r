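# Internal replicate-set representation shared by the fitting interface,
# the variance engines and the benchmark harness.
#
# An rset is a list:
#   k   integer matrix, channels x replicates (positive-partition counts)
#   n   integer matrix, channels x replicates (total partitions; for
#       multi-category integrity data all channels of a replicate share n)
#   vd, vp  loaded and partition volume (default 1)
# Channel rows are named.  QOI requirements:
#   lambda / concentration : one channel ("A")
#   cnv_singleplex, cnv_duplex, fa : channels "A" (target/mutant) and "B"
#   integrity : category counts "A" (A-only pos), "B" (B-only pos),
#               "AB" (double pos); the double-negative count is n - A - B - AB

.qoi_labels <- c("lambda", "concentration", "cnv_singleplex", "cnv_duplex",
                 "fa", "integrity")

new_rset <- function(k, n, vd = 1, vp = 1) {
  k <- as.matrix(k); n <- as.matrix(n)
  stopifnot(all(dim(k) == dim(n)), ncol(k) >= 1)
  if (is.null(rownames(k))) rownames(k) <- LETTERS[seq_len(nrow(k))]
  rownames(n) <- rownames(k)
  check_counts(as.vector(k), as.vector(n))
  if (vd <= 0 || vp <= 0) stop("vd and vp must be positive", call. = FALSE)
  structure(list(k = k, n = n, vd = vd, vp = vp), class = "dpcr_rset")
}

rset_channels_for <- function(qoi) {
  switch(qoi,
         lambda = "A", concentration = "A",
         cnv_singleplex = c("A", "B"), cnv_duplex = c("A", "B"),
         fa = c("A", "B"),
         integrity = c("A", "B", "AB"),
         stop("unknown qoi '", qoi, "'", call. = FALSE))
}

# per-replicate per-channel lambda estimates (per-partition scale).
# For integrity, returns the (a, b, c) decomposition rows instead.
rset_channel_lambdas <- function(rset, qoi) {
  ch <- rset_channels_for(qoi)
  missing <- setdiff(ch, rownames(rset$k))
  if (length(missing))
    stop("counts lack required channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (qoi == "integrity") {
    r <- ncol(rset$k)
    out <- vapply(seq_len(r), function(i) {
      n <- rset$n["A", i]
      ka <- rset$k["A", i]; kb <- rset$k["B", i]; kab <- rset$k["AB", i]
      decompose_linkage(n - ka - kb - kab, ka, kb, kab, n)
    }, numeric(3))
    rownames(out) <- c("lambda_a", "lambda_b", "lambda_ab")
    return(out)
  }
  k <- rset$k[ch, , drop = FALSE]
  n <- rset$n[ch, , drop = FALSE]
  if (any(k == n))
    stop("saturated reaction (k == n): lambda estimate is infinite", call. = FALSE)
  -log1p(-k / n)
}

# per-replicate values of the quantity of interest, on its reporting scale
rset_per_replicate <- function(rset, qoi) {
  lam <- rset_channel_lambdas(rset, qoi)
  switch(qoi,
    lambda = (rset$vd / rset$vp) * lam["A", ],
    concentration = lam["A", ] / rset$vp,
    cnv_singleplex = {
      if (any(lam <= 0))
        stop("log CNV requires strictly positive lambda estimates", call. = FALSE)
      log(lam["A", ]) - log(lam["B", ])
    },
    cnv_duplex = {
      if (any(lam["B", ] <= 0))
        stop("reference lambda must be positive in every replicate", call. = FALSE)
      lam["A", ] / lam["B", ]
    },
    fa = {
      tot <- lam["A", ] + lam["B", ]
      if (any(tot <= 0))
        stop("both channels are zero in at least one replicate", call. = FALSE)
      lam["A", ] / tot
    },
    integrity = {
      broken <- (lam["lambda_a", ] + lam["lambda_b", ]) / 2
      denom <- broken + lam["lambda_ab", ]
      if (any(denom <= 0))
        stop("no molecules detected in at least one replicate", call. = FALSE)
      1 - broken / denom
    })
}

# build an rset for one sample from a validated counts data frame
counts_to_rset <- function(counts, sample = NULL) {
  counts <- as.data.frame(counts)
  if (!is.null(sample)) counts <- counts[counts$sample == sample, , drop = FALSE]
  if (nrow(counts) == 0L) stop("no rows for requested sample", call. = FALSE)
  if (length(unique(counts$sample)) > 1L)
    stop("counts contain several samples; pass `sample = ` to select one",
         call. = FALSE)
  reps <- sort(unique(counts$replicate))
  chs <- sort(unique(counts$channel))
  k <- matrix(NA_real_, length(chs), length(reps), dimnames = list(chs, reps))
  n <- k
  for (row in seq_len(nrow(counts))) {
    i <- match(counts$channel[row], chs); j <- match(counts$replicate[row], reps)
    if (!is.na(k[i, j]))
      stop("duplicate (sample, replicate, channel) row", call. = FALSE)
    k[i, j] <- counts$positives[row]
    n[i, j] <- counts$total[row]
  }
  if (anyNA(k))
    stop("replicates do not share the same channel set", call. = FALSE)
  vd <- if ("vd" %in% names(counts)) unique(counts$vd) else 1
  vp <- if ("vp" %in% names(counts)) unique(counts$vp) else 1
  if (length(vd) != 1L || length(vp) != 1L)
    stop("vd/vp must be constant within a sample", call. = FALSE)
  new_rset(k, n, vd = vd, vp = vp)
}
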