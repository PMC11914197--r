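# Reading and writing the counts CSV schema and serialising results.
# Schema: one row per (sample, replicate, channel) with columns
#   sample, replicate, channel, positives, total [, vd, vp]

#' Read a dPCR counts table
#'
#' Reads and validates a CSV of per-replicate, per-channel partition
#' counts.  Required columns: \code{sample}, \code{replicate},
#' \code{channel}, \code{positives}, \code{total}; optional \code{vd}
#' (loaded volume) and \code{vp} (partition volume).  Validation errors
#' name the offending data row.
#'
#' @param path path to a UTF-8 CSV file with a header.
#' @return A \code{data.frame} of class \code{c("dpcr_counts",
#'   "data.frame")}.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_counts(df)
}

#' @rdname read_counts
#' @param counts a data frame in the counts schema (validated in place).
#' @export
validate_counts <- function(counts) {
  req <- c("sample", "replicate", "channel", "positives", "total")
  missing <- setdiff(req, names(counts))
  if (length(missing))
    stop("counts table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("positives", "total")) {
    v <- counts[[col]]
    bad <- which(!is.finite(v) | v != round(v) | v < 0)
    if (length(bad))
      stop("column '", col, "' must hold non-negative integers; first bad row: ",
           bad[1], call. = FALSE)
  }
  bad <- which(counts$total < 1)
  if (length(bad)) stop("total must be >= 1 (row ", bad[1], ")", call. = FALSE)
  bad <- which(counts$positives > counts$total)
  if (length(bad))
    stop("positives exceed total in row ", bad[1], " (", counts$positives[bad[1]],
         " > ", counts$total[bad[1]], ")", call. = FALSE)
  key <- paste(counts$sample, counts$replicate, counts$channel, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (sample, replicate, channel) in row ", dup[1], call. = FALSE)
  for (sm in unique(counts$sample)) {
    sub <- counts[counts$sample == sm, ]
    chs <- tapply(sub$channel, sub$replicate, function(x) paste(sort(x), collapse = ","))
    if (length(unique(chs)) > 1L)
      stop("sample '", sm, "': replicates do not share the same channel set",
           call. = FALSE)
  }
  class(counts) <- unique(c("dpcr_counts", class(counts)))
  counts
}

#' Write a counts table
#'
#' @param counts a counts data frame.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise estimation results
#'
#' Writes a results table (e.g. from [dpcr_estimate_table()]) as CSV or
#' JSON with method provenance retained.
#'
#' @param results a data frame of estimates.
#' @param path output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return The path, invisibly.
#' @export
write_estimates <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Recommend a variance method for an experiment
#'
#' Advisory helper mapping concentration level and experiment type to the
#' variance methods that perform best: at low concentration the
#' parametric methods (BinomVar or delta, where available) are more
#' precise; at high concentration NonPVar is more robust for singleplex,
#' while for duplex/multiplex the parametric methods remain good when
#' partition clusters are well separated (little misclassification).
#' There is no exact threshold separating low from high concentration;
#' \eqn{\lambda < 0.1} copies per partition is a common working
#' convention, and the better the data quality the higher the threshold
#' can be set.
#'
#' @param lambda approximate mean copies per partition.
#' @param experiment \code{"singleplex"} or \code{"duplex"}.
#' @param well_separated logical; are the positive/negative clusters well
#'   separated (i.e. is misclassification negligible)?
#' @return Character vector of recommended method labels, with an
#'   explanatory \code{note} attribute.
#' @export
recommend_method <- function(lambda, experiment = c("singleplex", "duplex"),
                             well_separated = TRUE) {
  experiment <- match.arg(experiment)
  low <- lambda < 0.1
  rec <- if (low) {
    c("binomvar", "delta")
  } else if (experiment == "singleplex") {
    "nonpvar"
  } else if (well_separated) {
    c("binomvar", "delta")
  } else {
    "nonpvar"
  }
  note <- paste("No exact threshold defines low vs high concentration;",
                "lambda < 0.1 copies/partition is a common convention, and",
                "higher-quality data (low pipetting error, accurate",
                "classification) pushes the threshold up. The delta method",
                "applies only to absolute quantification and singleplex CNV.")
  structure(rec, note = note)
}
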