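# Brute-force enumeration oracles, independent of the package's log-space
# implementations.  Only feasible for tiny m, n.

# pmf of the number of occupied partitions by enumerating all n^m equally
# likely placements of m labelled molecules into n labelled partitions
brute_force_occupancy <- function(m, n) {
  if (m == 0) return(c(`0` = 1))
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), m)))
  k <- apply(grid, 1, function(row) length(unique(row)))
  table(factor(k, levels = 0:min(m, n))) / nrow(grid)
}

# Stirling number of the second kind by counting surjections m -> k
# (each set partition into k blocks corresponds to k! surjections)
brute_force_stirling2 <- function(m, k) {
  if (k == 0) return(as.numeric(m == 0))
  if (k > m) return(0)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  surj <- sum(apply(grid, 1, function(row) length(unique(row)) == k))
  surj / factorial(k)
}

# counts data frame for a single sample built from explicit k/n vectors;
# channels is a character vector, k a matrix channels x replicates
make_counts <- function(k, n, channels = rownames(k), sample = "s1",
                        vd = NULL, vp = NULL) {
  k <- as.matrix(k)
  if (is.null(channels)) channels <- LETTERS[seq_len(nrow(k))]
  r <- ncol(k)
  n <- if (length(n) == 1) matrix(n, nrow(k), r) else as.matrix(n)
  df <- data.frame(sample = sample,
                   replicate = rep(seq_len(r), each = nrow(k)),
                   channel = rep(channels, r),
                   positives = as.vector(k), total = as.vector(n),
                   stringsAsFactors = FALSE)
  if (!is.null(vd)) df$vd <- vd
  if (!is.null(vp)) df$vp <- vp
  df
}

# counts whose per-replicate lambda-hat equal given targets (k rounded,
# so recompute the realised lambdas where exactness matters)
counts_for_lambda <- function(lambdas, n = 20000) {
  k <- round(n * (1 - exp(-lambdas)))
  make_counts(rbind(A = k), n)
}
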