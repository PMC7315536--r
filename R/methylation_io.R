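#' Construct a methylation beta-value matrix
#'
#' A `MethylationMatrix` is a numeric matrix of methylation fractions
#' (beta values) with CpG sites in rows and samples in columns.  Values
#' must lie in \[0, 1\]; `NA` marks a missing measurement.
#'
#' @param values Numeric matrix with CpG row names and sample column names.
#' @return An object of class `MethylationMatrix` (a classed matrix).
#' @export
MethylationMatrix <- function(values) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix needs CpG row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate CpG ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value %g out of [0,1] at CpG '%s', sample '%s'",
                 values[bad[1, 1], bad[1, 2]],
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  structure(values, class = c("MethylationMatrix", "matrix", "array"))
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d CpGs x %d samples (%d missing values)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

# Accept either a MethylationMatrix or a plain named numeric matrix.
as_beta_matrix <- function(x) {
  if (inherits(x, "MethylationMatrix")) return(unclass(x))
  unclass(MethylationMatrix(x))
}

#' Read a beta-value matrix from TSV
#'
#' The default orientation follows the GEO series-matrix convention:
#' rows are CpGs, the first column holds the CpG id, and the remaining
#' header fields are sample ids.  Blank fields and `NA` become missing
#' values.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param samples_in_rows If `TRUE` the file is transposed on read
#'   (rows are samples, columns are CpGs).
#' @return A [MethylationMatrix].
#' @export
read_methylation_matrix <- function(path, samples_in_rows = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("matrix file needs an id column plus data columns: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (samples_in_rows) m <- t(m)
  MethylationMatrix(m)
}

#' Write a beta-value matrix to TSV
#'
#' @param x A [MethylationMatrix] or named numeric matrix.
#' @param path Output path.
#' @param id_column Header name for the CpG id column.
#' @export
write_methylation_matrix <- function(x, path, id_column = "cpg_id") {
  m <- as_beta_matrix(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `age` (years), `study`, and optionally
#' `tissue`.
#'
#' @param path Path to a tab-separated file.
#' @return A data frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

validate_sample_metadata <- function(df) {
  need <- c("sample_id", "age")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$age <- as.numeric(df$age)
  if (any(!is.na(df$age) & df$age < 0)) stop("negative age in metadata")
  if (is.null(df$study)) df$study <- "study1"
  df
}

#' Construct a counted set of per-read methylation patterns
#'
#' One sequenced DNA strand contributes one occurrence of its binary
#' methylation pattern over the ordered CpG sites of an amplicon.
#' Patterns are strings over `{0, 1, .}`: `1` methylated, `0`
#' unmethylated, `.` a missing call.
#'
#' @param sample_id,amplicon_id Identifiers.
#' @param patterns Named integer vector: names are pattern strings of a
#'   common length, values are occurrence counts (>= 1).
#' @return An object of class `ReadPatternSet`.
#' @export
ReadPatternSet <- function(sample_id, amplicon_id, patterns) {
  pats <- names(patterns)
  counts <- as.integer(patterns)
  if (length(patterns) > 0) {
    if (is.null(pats)) stop("patterns must be a named count vector")
    lens <- unique(nchar(pats))
    if (length(lens) > 1)
      stop(sprintf("mixed pattern lengths (%s) within amplicon '%s'",
                   paste(sort(lens), collapse = ", "), amplicon_id))
    if (any(grepl("[^01.]", pats)))
      stop("pattern characters must be one of {0, 1, .}: ",
           pats[grepl("[^01.]", pats)][1])
    if (any(is.na(counts)) || any(counts < 1))
      stop("all pattern counts must be integers >= 1")
    if (anyDuplicated(pats)) {
      agg <- tapply(counts, pats, sum)
      pats <- names(agg)
      counts <- as.integer(agg)
    }
    n_sites <- lens
  } else {
    n_sites <- 0L
  }
  structure(list(sample_id = as.character(sample_id),
                 amplicon_id = as.character(amplicon_id),
                 n_sites = as.integer(n_sites),
                 patterns = stats::setNames(counts, pats)),
            class = "ReadPatternSet")
}

#' @export
print.ReadPatternSet <- function(x, ...) {
  cat(sprintf("ReadPatternSet: sample '%s', amplicon '%s', %d sites, %d patterns, %d reads\n",
              x$sample_id, x$amplicon_id, x$n_sites,
              length(x$patterns), sum(x$patterns)))
  invisible(x)
}

#' Read a per-read pattern table from TSV
#'
#' Expects columns `sample_id`, `amplicon_id`, `pattern`, `count`.
#' Rows are grouped into one [ReadPatternSet] per (sample, amplicon)
#' pair; pattern length must be consistent within each amplicon.
#'
#' @param path Path to a tab-separated file.
#' @return Named list of [ReadPatternSet] objects
#'   (names `"<sample_id>|<amplicon_id>"`).
#' @export
read_pattern_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          colClasses = c(pattern = "character"),
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "amplicon_id", "pattern", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("pattern table is missing column(s): ", paste(miss, collapse = ", "))
  # pattern-length consistency is enforced per amplicon across all samples
  amp_len <- tapply(nchar(df$pattern), df$amplicon_id,
                    function(l) length(unique(l)))
  if (any(amp_len > 1))
    stop("mixed pattern lengths within amplicon '",
         names(amp_len)[amp_len > 1][1], "'")
  key <- paste(df$sample_id, df$amplicon_id, sep = "|")
  out <- lapply(split(seq_len(nrow(df)), key), function(i) {
    ReadPatternSet(df$sample_id[i[1]], df$amplicon_id[i[1]],
                   stats::setNames(df$count[i], df$pattern[i]))
  })
  out
}

#' Write read-pattern sets to TSV
#'
#' @param x A [ReadPatternSet] or list of them.
#' @param path Output path.
#' @export
write_pattern_table <- function(x, path) {
  if (inherits(x, "ReadPatternSet")) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(r) {
    if (length(r$patterns) == 0) return(NULL)
    data.frame(sample_id = r$sample_id, amplicon_id = r$amplicon_id,
               pattern = names(r$patterns),
               count = as.integer(r$patterns),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop rare read patterns
#'
#' Retains only patterns observed at least `min_count` times in the set
#' (inclusive threshold; the per-read analyses downstream consider only
#' sequences seen at least 10 times by default).  Applied per
#' (sample, amplicon) pair.
#'
#' @param rps A [ReadPatternSet].
#' @param min_count Minimum occurrence count to retain (default 10).
#' @return A [ReadPatternSet] with the surviving patterns; may be empty.
#' @export
filter_rare_patterns <- function(rps, min_count = 10) {
  stopifnot(inherits(rps, "ReadPatternSet"), min_count >= 1)
  keep <- rps$patterns >= min_count
  out <- rps
  out$patterns <- rps$patterns[keep]
  out
}

#' Construct duplex droplet classification counts
#'
#' Tallies from a duplex droplet digital PCR reaction: droplets positive
#' only for the methylation probe, only for the non-methylation probe,
#' for both (double positive), or for neither.  Counts must conserve the
#' total.
#'
#' @param assay_id Identifier for the reaction.
#' @param n_total Total droplets (> 0).
#' @param n_meth_only,n_unmeth_only,n_double Category counts.
#' @param n_negative Empty-droplet count; derived if `NULL`.
#' @return An object of class `DropletCounts`.
#' @export
DropletCounts <- function(assay_id, n_total, n_meth_only, n_unmeth_only,
                          n_double, n_negative = NULL) {
  n_total <- as.integer(n_total)
  if (is.na(n_total) || n_total <= 0) stop("n_total must be > 0")
  cats <- c(n_meth_only = as.integer(n_meth_only),
            n_unmeth_only = as.integer(n_unmeth_only),
            n_double = as.integer(n_double))
  if (any(is.na(cats)) || any(cats < 0)) stop("negative droplet category count")
  if (is.null(n_negative) || is.na(n_negative)) {
    n_negative <- n_total - sum(cats)
    if (n_negative < 0)
      stop(sprintf("assay '%s': categories sum to %d > n_total %d",
                   assay_id, sum(cats), n_total))
  } else {
    n_negative <- as.integer(n_negative)
    if (n_negative < 0) stop("negative droplet category count")
    if (sum(cats) + n_negative != n_total)
      stop(sprintf("assay '%s': categories sum to %d, n_total is %d",
                   assay_id, sum(cats) + n_negative, n_total))
  }
  structure(list(assay_id = as.character(assay_id), n_total = n_total,
                 n_meth_only = cats[["n_meth_only"]],
                 n_unmeth_only = cats[["n_unmeth_only"]],
                 n_double = cats[["n_double"]],
                 n_negative = as.integer(n_negative)),
            class = "DropletCounts")
}

#' Read droplet classification counts from CSV or TSV
#'
#' Expects columns `assay_id`, `n_total`, `n_meth_only`, `n_unmeth_only`,
#' `n_double`, and optionally `n_negative` (derived when absent).  The
#' separator is sniffed from the header line (comma or tab).
#'
#' @param path Path to the table.
#' @return List of [DropletCounts], one per row.
#' @export
read_droplet_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("assay_id", "n_total", "n_meth_only", "n_unmeth_only", "n_double")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("droplet table is missing column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    DropletCounts(df$assay_id[i], df$n_total[i], df$n_meth_only[i],
                  df$n_unmeth_only[i], df$n_double[i],
                  if ("n_negative" %in% names(df)) df$n_negative[i] else NULL)
  })
}
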