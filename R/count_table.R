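#' Construct a taxon-by-sample count table
#'
#' The central container of the package: a non-negative integer matrix of
#' read counts (taxa as rows, samples as columns) together with a mapping
#' from each sample to its habitat label. Relative abundances are always
#' derived on the fly, never stored, to avoid double-normalization.
#'
#' @param counts numeric matrix, taxa x samples, with unique row and column
#'   names; all entries must be non-negative integers.
#' @param habitat_of named character vector mapping every sample id (column
#'   name of `counts`) to a non-empty habitat label.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `habitat` (named character vector aligned with the
#'   columns of `counts`).
#' @examples
#' m <- matrix(c(5L, 1L, 0L, 3L), 2, dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' ct <- count_table(m, c(s1 = "water", s2 = "water"))
#' n_taxa(ct)
#' @export
count_table <- function(counts, habitat_of) {
  if (!is.matrix(counts)) msk_stop("'counts' must be a matrix")
  if (is.null(rownames(counts)) && nrow(counts) > 0L)
    msk_stop("'counts' must have taxon row names")
  if (is.null(colnames(counts)) && ncol(counts) > 0L)
    msk_stop("'counts' must have sample column names")
  if (anyDuplicated(rownames(counts)))
    msk_stop("duplicate taxon ids in count table")
  if (anyDuplicated(colnames(counts)))
    msk_stop("duplicate sample ids in count table")
  if (!is.numeric(counts) && length(counts) > 0L)
    msk_stop("counts must be numeric")
  if (length(counts) > 0L) {
    if (anyNA(counts)) msk_stop("counts contain missing values")
    if (any(counts < 0)) msk_stop("counts must be non-negative")
    if (any(counts != round(counts)))
      msk_stop("counts must be integral (no fractional reads)")
  }
  samples <- colnames(counts)
  if (is.null(names(habitat_of)) && length(habitat_of) == length(samples))
    names(habitat_of) <- samples
  missing <- setdiff(samples, names(habitat_of))
  if (length(missing))
    msk_stop("samples without habitat label: ", paste(missing, collapse = ", "))
  hab <- as.character(habitat_of[samples])
  names(hab) <- samples
  if (length(hab) && (anyNA(hab) || any(!nzchar(hab))))
    msk_stop("habitat labels must be non-empty strings")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, habitat = hab), class = "count_table")
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
n_taxa <- function(x) nrow(x$counts)

#' @rdname count_table
#' @export
n_samples <- function(x) ncol(x$counts)

#' @rdname count_table
#' @export
habitats <- function(x) unique(unname(x$habitat))

#' @rdname count_table
#' @param habitat habitat label.
#' @export
samples_in_habitat <- function(x, habitat) {
  if (!habitat %in% x$habitat) msk_stop("unknown habitat: ", habitat)
  names(x$habitat)[x$habitat == habitat]
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", n_taxa(x), "taxa x", n_samples(x), "samples in",
      length(habitats(x)), "habitat(s)\n")
  if (n_samples(x)) {
    tab <- table(x$habitat)
    cat("  samples per habitat:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read and write count tables with sample metadata
#'
#' `read_count_table()` parses a TSV with taxa as rows (first column
#' `taxon_id`) and samples as columns, together with a metadata TSV holding
#' at least `sample_id` and `habitat` columns. Every sample in the count
#' table header must appear in the metadata; counts must be non-negative
#' integers. `write_count_table()` emits the same two files, so that a
#' write/read round trip reproduces counts and habitat mapping exactly.
#'
#' @param path path of the count TSV.
#' @param metadata_path path of the sample metadata TSV.
#' @return `read_count_table()` returns a [count_table]. The metadata data
#'   frame is attached as attribute `"metadata"`.
#' @export
read_count_table <- function(path, metadata_path) {
  raw <- tryCatch(
    read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) msk_stop("malformed count TSV '", path, "': ",
                                 conditionMessage(e)))
  if (ncol(raw) < 1L) msk_stop("count TSV has no columns")
  taxa <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (length(m) && !is.numeric(m))
    msk_stop("count TSV contains non-numeric entries")
  rownames(m) <- taxa
  meta <- read_sample_metadata(metadata_path)
  unknown <- setdiff(colnames(m), meta$sample_id)
  if (length(unknown))
    msk_stop("samples in count table missing from metadata: ",
             paste(unknown, collapse = ", "))
  hab <- setNames(meta$habitat, meta$sample_id)
  ct <- count_table(m, hab[colnames(m)])
  attr(ct, "metadata") <- meta
  ct
}

#' @rdname read_count_table
#' @export
read_sample_metadata <- function(metadata_path) {
  meta <- tryCatch(
    read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) msk_stop("malformed metadata TSV '", metadata_path,
                                 "': ", conditionMessage(e)))
  need <- c("sample_id", "habitat")
  if (!all(need %in% names(meta)))
    msk_stop("metadata must contain columns: ", paste(need, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$habitat <- as.character(meta$habitat)
  if (anyDuplicated(meta$sample_id)) msk_stop("duplicate sample_id in metadata")
  if (anyNA(meta$habitat) || any(!nzchar(meta$habitat)))
    msk_stop("metadata habitat labels must be non-empty")
  meta
}

#' @rdname read_count_table
#' @param x a [count_table] to write.
#' @export
write_count_table <- function(x, path, metadata_path = NULL) {
  df <- data.frame(taxon_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    meta <- attr(x, "metadata")
    if (is.null(meta))
      meta <- data.frame(sample_id = names(x$habitat),
                         habitat = unname(x$habitat),
                         stringsAsFactors = FALSE)
    write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

# restrict a count table to a subset of samples (internal)
ct_keep_samples <- function(x, samples) {
  ct <- count_table(x$counts[, samples, drop = FALSE], x$habitat[samples])
  attr(ct, "metadata") <- attr(x, "metadata")
  ct
}
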