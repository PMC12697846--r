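#' Per-taxon sample proportions within a habitat
#'
#' For each taxon j detected in habitat H, computes
#' P_ij = n_ij / sum_i n_ij over the samples i of H, i.e. how the taxon's
#' reads are spread across the habitat's communities. These proportions sum
#' to one per detected taxon and feed Levins' niche breadth. Taxa absent
#' from the habitat get `NA` rows (absence is not minimal breadth).
#'
#' @param table a [count_table].
#' @param habitat habitat label with at least one sample.
#' @return numeric matrix, taxa x habitat samples.
#' @export
taxon_sample_proportions <- function(table, habitat) {
  stopifnot(inherits(table, "count_table"))
  s <- samples_in_habitat(table, habitat)
  m <- table$counts[, s, drop = FALSE]
  tot <- rowSums(m)
  p <- m / tot
  p[tot == 0, ] <- NA_real_
  p
}

#' Levins' niche breadth
#'
#' B = 1 / sum(P^2), the inverse Simpson concentration of a taxon's
#' proportional distribution across the N communities of a habitat. A taxon
#' spread evenly over all N samples attains the maximum B = N (generalist
#' within the habitat); one confined to a single sample has B = 1
#' (specialist).
#'
#' @param p numeric vector of proportions summing to 1.
#' @return breadth value in \[1, length(p)\].
#' @examples
#' levins_breadth(c(0.5, 0.25, 0.25)) # 2.6667
#' @export
levins_breadth <- function(p) {
  if (!length(p) || anyNA(p) || all(p == 0))
    msk_stop("breadth undefined for empty or all-zero proportions")
  if (abs(sum(p) - 1) > 1e-8)
    msk_stop("proportions must sum to 1")
  1 / sum(p^2)
}

#' Normalize niche breadths within a habitat
#'
#' Divides each breadth by the maximal breadth among present taxa of the
#' habitat, so the habitat's broadest taxon scores exactly 1 and values are
#' comparable across habitats with different sample numbers.
#'
#' @param B numeric vector of breadths (NA allowed for absent taxa).
#' @return vector of normalized breadths; `NA` entries are preserved.
#' @export
normalize_breadth <- function(B) {
  if (all(is.na(B))) msk_stop("no present taxa: cannot normalize breadth")
  B / max(B, na.rm = TRUE)
}

#' Per-habitat niche and abundance profiles
#'
#' The workhorse summary behind nonnative classification: for every
#' (taxon, habitat) pair it reports mean relative abundance (mean over the
#' habitat's samples of the taxon's per-sample proportion), occupancy
#' (fraction of samples with count >= `presence_threshold`), Levins breadth
#' and within-habitat normalized breadth, and a presence flag. Breadth is
#' `NA` for absent taxa.
#'
#' @param table a [count_table] (normally rarefied first).
#' @param presence_threshold minimum count for a taxon to count as detected
#'   in a sample (default 1 read).
#' @return data frame with one row per taxon x habitat:
#'   `taxon`, `habitat`, `present`, `occupancy`, `mean_rel_abundance`,
#'   `breadth`, `breadth_norm`, `n_samples`.
#' @export
habitat_profiles <- function(table, presence_threshold = 1L) {
  stopifnot(inherits(table, "count_table"))
  presence_threshold <- check_count(presence_threshold, "presence_threshold",
                                    min = 0L)
  out <- lapply(habitats(table), function(h) {
    s <- samples_in_habitat(table, h)
    m <- table$counts[, s, drop = FALSE]
    depth <- colSums(m)
    rel <- sweep(m, 2, pmax(depth, 1L), "/")
    present <- rowSums(m >= presence_threshold) > 0 & rowSums(m) > 0
    p <- m / rowSums(m)
    B <- 1 / rowSums(p^2)
    B[!present] <- NA_real_
    data.frame(taxon = rownames(m),
               habitat = h,
               present = present,
               occupancy = rowMeans(m >= presence_threshold & m > 0),
               mean_rel_abundance = rowMeans(rel),
               breadth = B,
               breadth_norm = if (any(present)) normalize_breadth(B) else B,
               n_samples = length(s),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  res[order(res$taxon, res$habitat), , drop = FALSE]
}

#' Habitat occurrence count of taxa
#'
#' Number of distinct habitats in which a taxon is detected (count >=
#' `presence_threshold` in at least one sample of the habitat), the
#' occurrence level used to stratify microdiversity.
#'
#' @param table a [count_table].
#' @param taxon optional taxon id(s); default all taxa.
#' @param presence_threshold detection floor per sample (default 1).
#' @return named integer vector in \[0, number of habitats\].
#' @export
habitat_occurrence_count <- function(table, taxon = NULL,
                                     presence_threshold = 1L) {
  stopifnot(inherits(table, "count_table"))
  det <- vapply(habitats(table), function(h) {
    m <- table$counts[, samples_in_habitat(table, h), drop = FALSE]
    rowSums(m >= presence_threshold & m > 0) > 0
  }, logical(n_taxa(table)))
  if (n_taxa(table) == 1L) det <- matrix(det, nrow = 1L,
                                         dimnames = list(rownames(table$counts)))
  occ <- setNames(as.integer(rowSums(det)), rownames(table$counts))
  if (is.null(taxon)) return(occ)
  unknown <- setdiff(taxon, names(occ))
  if (length(unknown))
    msk_stop("unknown taxon: ", paste(unknown, collapse = ", "))
  occ[taxon]
}

#' Shannon diversity of a sample
#'
#' H' = -sum p log p over taxa with positive proportion. Natural logarithm
#' by default; the base is configurable.
#'
#' @param counts non-negative numeric vector of taxon counts.
#' @param base logarithm base (default natural).
#' @return Shannon index, a non-negative number.
#' @export
shannon_diversity <- function(counts, base = exp(1)) {
  if (!length(counts) || sum(counts) <= 0)
    msk_stop("Shannon diversity undefined for an empty sample")
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}
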