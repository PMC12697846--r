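#' Rarefy a count table to even sequencing depth
#'
#' Subsamples each sample's reads without replacement down to a common
#' depth, either a fixed integer or `"per-habitat-min"`, in which case each
#' habitat is rarefied to the minimum column sum among its own samples.
#' Samples whose total count falls below the target depth are dropped with
#' a warning. The draw is seeded and fully reproducible: identical seed,
#' identical output. Zeros never gain reads and no cell ever exceeds its
#' original count.
#'
#' @param table a [count_table].
#' @param depth positive integer target depth, or `"per-habitat-min"`.
#' @param seed integer seed for the subsampling draw.
#' @return A rarefied [count_table]; every retained sample's column sum
#'   equals its target depth.
#' @examples
#' m <- matrix(c(10L, 0L), 2, dimnames = list(c("a", "b"), "s1"))
#' ct <- count_table(m, c(s1 = "water"))
#' rarefy(ct, 5, seed = 1)$counts
#' @export
rarefy <- function(table, depth = "per-habitat-min", seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  totals <- colSums(table$counts)
  if (identical(depth, "per-habitat-min")) {
    target <- vapply(habitats(table), function(h) {
      min(totals[samples_in_habitat(table, h)])
    }, numeric(1))
    target <- target[table$habitat]           # per sample
    names(target) <- names(table$habitat)
  } else {
    if (!is.numeric(depth) || length(depth) != 1L || is.na(depth) ||
        depth <= 0 || depth != round(depth))
      msk_stop("'depth' must be a positive integer or \"per-habitat-min\"")
    target <- setNames(rep(as.numeric(depth), n_samples(table)),
                       colnames(table$counts))
  }
  keep <- totals >= target
  if (!any(keep)) msk_stop("all samples fall below the rarefaction depth")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below rarefaction depth dropped: ",
            paste(names(keep)[!keep], collapse = ", "), call. = FALSE)
  set.seed(seed)
  out <- table$counts[, keep, drop = FALSE]
  for (j in seq_len(ncol(out))) {
    s <- colnames(out)[j]
    d <- target[[s]]
    tot <- totals[[s]]
    if (tot == d) next
    reads <- rep.int(seq_len(nrow(out)), out[, j])
    drawn <- sample(reads, d)
    out[, j] <- tabulate(drawn, nbins = nrow(out))
  }
  ct <- count_table(out, table$habitat[keep])
  attr(ct, "metadata") <- attr(table, "metadata")
  ct
}
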