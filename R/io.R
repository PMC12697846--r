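#' Taxon-to-function incidence tables
#'
#' `function_table()` builds a binary incidence container from a long
#' (taxon, function) pair list, collapsing duplicates; `read_function_table()`
#' parses the same structure from a two-column TSV with header
#' `taxon_id<TAB>function_id`. Named function sets (e.g. the carbon,
#' nitrogen, phosphorus and sulfur cycling gene sets) can be attached and
#' must reference known function ids.
#'
#' @param taxon character vector of taxon/genome ids.
#' @param fun character vector of function ids (KO/COG-style), same length.
#' @param sets optional named list of character vectors of function ids.
#' @return An object of class `function_table`: list with `incidence`
#'   (logical matrix, taxa x functions) and `sets` (named list).
#' @export
function_table <- function(taxon, fun, sets = list()) {
  stopifnot(length(taxon) == length(fun))
  taxon <- as.character(taxon); fun <- as.character(fun)
  if (length(taxon) && (anyNA(taxon) || anyNA(fun) ||
                        any(!nzchar(taxon)) || any(!nzchar(fun))))
    msk_stop("malformed (taxon, function) rows")
  taxa <- sort(unique(taxon))
  funs <- sort(unique(fun))
  inc <- matrix(FALSE, length(taxa), length(funs),
                dimnames = list(taxa, funs))
  inc[cbind(match(taxon, taxa), match(fun, funs))] <- TRUE
  ft <- structure(list(incidence = inc, sets = list()),
                  class = "function_table")
  if (length(sets)) ft <- set_function_sets(ft, sets)
  ft
}

#' @rdname function_table
#' @param path two-column TSV path.
#' @export
read_function_table <- function(path) {
  raw <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) msk_stop("malformed function TSV '", path, "': ",
                                 conditionMessage(e)))
  if (nrow(raw) == 0L) {
    warning("empty function table: no annotated taxa", call. = FALSE)
    return(function_table(character(), character()))
  }
  if (ncol(raw) < 2L) msk_stop("function TSV needs two columns")
  if (anyNA(raw[[1L]]) || anyNA(raw[[2L]]))
    msk_stop("malformed row in function TSV")
  function_table(raw[[1L]], raw[[2L]])
}

#' @rdname function_table
#' @param ft a `function_table`.
#' @export
set_function_sets <- function(ft, sets) {
  stopifnot(inherits(ft, "function_table"), is.list(sets))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    msk_stop("function sets must be named")
  for (nm in names(sets)) {
    unknown <- setdiff(sets[[nm]], colnames(ft$incidence))
    if (length(unknown))
      msk_stop("set '", nm, "' references unknown functions: ",
               paste(utils::head(unknown, 5), collapse = ", "))
  }
  ft$sets <- lapply(sets, as.character)
  ft
}

#' @rdname function_table
#' @export
write_function_table <- function(ft, path) {
  idx <- which(ft$incidence, arr.ind = TRUE)
  df <- data.frame(taxon_id = rownames(ft$incidence)[idx[, 1L]],
                   function_id = colnames(ft$incidence)[idx[, 2L]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$taxon_id, df$function_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.function_table <- function(x, ...) {
  cat("function_table:", nrow(x$incidence), "taxa x", ncol(x$incidence),
      "functions;", length(x$sets), "named set(s)\n")
  invisible(x)
}

#' Read phylogenetic trees and sequence sets
#'
#' Thin, validating wrappers over \pkg{ape}. `read_newick()` requires
#' branch lengths (distance-based metrics are meaningless without them);
#' `read_fasta()` returns a named character vector of uppercase sequences
#' and rejects duplicate ids.
#'
#' @param path file path.
#' @return `read_newick()` a `phylo`; `read_fasta()` a named character
#'   vector of sequences.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) msk_stop("could not parse Newick file '", path, "'")
  if (is.null(tree$edge.length))
    msk_stop("tree has no branch lengths; distance-based metrics need them")
  tree
}

#' @rdname read_newick
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  ids <- names(dna)
  if (anyDuplicated(ids))
    msk_stop("duplicate FASTA ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  setNames(seqs, ids)
}

#' @rdname read_newick
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of tips,
#' optionally normalized by the maximum pairwise distance so that all
#' entries lie in \[0, 1\] (the scale used by the functional redundancy
#' index).
#'
#' @param tree a `phylo` with branch lengths.
#' @param normalize divide by the maximum pairwise distance?
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(tree, normalize = TRUE) {
  if (is.null(tree$edge.length)) msk_stop("tree has no branch lengths")
  d <- stats::cophenetic(tree)
  if (normalize) {
    mx <- max(d)
    if (mx > 0) d <- d / mx
  }
  d[sort(rownames(d)), sort(colnames(d)), drop = FALSE]
}
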