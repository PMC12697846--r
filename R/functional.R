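#' Functional richness of a community
#'
#' Number of distinct functions (KO/COG-style identifiers) carried by at
#' least one community member with positive abundance. Members without an
#' annotation row are skipped; their number is reported via `message()`.
#'
#' @param abundance named non-negative numeric vector (taxon counts or
#'   relative abundances) describing one sample community.
#' @param ft a [function_table].
#' @return integer count of distinct functions present.
#' @export
functional_richness <- function(abundance, ft) {
  stopifnot(inherits(ft, "function_table"))
  members <- names(abundance)[abundance > 0]
  if (!length(members)) {
    warning("empty community: functional richness 0", call. = FALSE)
    return(0L)
  }
  known <- intersect(members, rownames(ft$incidence))
  skipped <- length(members) - length(known)
  if (skipped > 0)
    message(skipped, " community member(s) lack functional annotations")
  if (!length(known)) return(0L)
  sum(colSums(ft$incidence[known, , drop = FALSE]) > 0)
}

#' Phylogeny-weighted functional redundancy of one function
#'
#' Rao-type quadratic entropy restricted to the carriers of a function:
#' FR(f) = sum over ordered pairs of distinct carriers i, j of
#' p_i p_j d_ij, where p are relative abundances over the WHOLE community
#' (so losing carriers lowers FR rather than renormalizing it away) and
#' d_ij is patristic distance normalized by the tree's maximum pairwise
#' distance. High FR means the function is carried by several abundant,
#' phylogenetically dispersed members and is therefore robust to member
#' loss; FR = 0 whenever at most one carrier is present.
#'
#' @param abundance named non-negative numeric vector for one sample.
#' @param ft a [function_table].
#' @param dist a `phylo` tree (normalized internally via
#'   [patristic_matrix()]) or a precomputed normalized distance matrix.
#' @param fun a function id.
#' @return FR value in \[0, 1\].
#' @export
functional_redundancy <- function(abundance, ft, dist, fun) {
  stopifnot(inherits(ft, "function_table"))
  if (!fun %in% colnames(ft$incidence)) return(0)
  d <- if (inherits(dist, "phylo")) patristic_matrix(dist) else dist
  tot <- sum(abundance)
  if (tot <= 0) return(0)
  p <- abundance / tot
  carriers <- intersect(names(p)[p > 0],
                        rownames(ft$incidence)[ft$incidence[, fun]])
  if (length(carriers) <= 1L) return(0)
  missing <- setdiff(carriers, rownames(d))
  if (length(missing))
    msk_stop("carrier(s) missing from the tree: ",
             paste(missing, collapse = ", "))
  pc <- p[carriers]
  as.numeric(pc %*% d[carriers, carriers] %*% pc)
}

#' Mean functional redundancy over a named function set
#'
#' Arithmetic mean of [functional_redundancy()] over the functions of a
#' named set (e.g. the carbon, nitrogen, phosphorus or sulfur cycling
#' sets). Functions with no carriers in the community contribute 0 and are
#' counted in the denominator.
#'
#' @inheritParams functional_redundancy
#' @param set_name name of a set registered in `ft$sets`.
#' @return mean FR value.
#' @export
cycle_redundancy <- function(abundance, ft, dist, set_name) {
  stopifnot(inherits(ft, "function_table"))
  if (!set_name %in% names(ft$sets))
    msk_stop("unknown function set '", set_name, "'; available: ",
             paste(names(ft$sets), collapse = ", "))
  funs <- ft$sets[[set_name]]
  if (!length(funs)) return(0)
  d <- if (inherits(dist, "phylo")) patristic_matrix(dist) else dist
  mean(vapply(funs, function(f)
    functional_redundancy(abundance, ft, d, f), numeric(1)))
}

#' Functional consequences of targeted versus random removal
#'
#' Recomputes per-sample functional richness and per-set functional
#' redundancy under three scenarios — observed, targeted removal of the
#' habitat's flagged nonnative taxa, and random removal of an equivalent
#' number of taxa (mean over replicates) — and contrasts the scenarios per
#' habitat with paired t-tests, Benjamini-Hochberg adjusted across the
#' habitat x metric x comparison family.
#'
#' @param table a [count_table] (rarefied).
#' @param calls output of [classify_nonnative()].
#' @param ft a [function_table] (sets optional; set metrics are computed
#'   for every registered set).
#' @param tree `phylo` over the table's taxa (or a normalized distance
#'   matrix) for the redundancy index.
#' @param replicates random-removal replicates (default 50).
#' @param seed integer seed.
#' @return list of class `functional_removal_result`: `per_sample` (long
#'   data frame: `sample`, `habitat`, `metric`, `observed`, `targeted`,
#'   `random_mean`) and `stats` (paired tests with `p_adjust`).
#' @export
removal_functional_comparison <- function(table, calls, ft, tree,
                                          replicates = 50L, seed = 1L) {
  stopifnot(inherits(table, "count_table"), inherits(ft, "function_table"))
  replicates <- check_count(replicates, "replicates")
  d <- if (inherits(tree, "phylo")) patristic_matrix(tree) else tree
  metrics <- c("functional_richness",
               if (length(ft$sets)) paste0("FR_", names(ft$sets)))
  fr_one <- function(x) {   # metric vector for one community
    fr <- suppressMessages(suppressWarnings(functional_richness(x, ft)))
    sets <- vapply(names(ft$sets), function(nm)
      cycle_redundancy(x, ft, d, nm), numeric(1))
    c(functional_richness = fr,
      if (length(ft$sets)) setNames(sets, paste0("FR_", names(ft$sets))))
  }
  rows <- list()
  for (h in habitats(table)) {
    s <- samples_in_habitat(table, h)
    m <- table$counts[, s, drop = FALSE]
    pool <- rownames(m)[rowSums(m) > 0]
    fl <- intersect(unique(calls$taxon[calls$habitat == h & calls$nonnative]),
                    pool)
    set.seed(seed + match(h, sort(habitats(table))))
    rem_sets <- lapply(seq_len(replicates), function(r)
      if (length(fl)) sample(pool, length(fl)) else character())
    for (j in seq_along(s)) {
      x <- m[, j]
      obs <- fr_one(x)
      xt <- x; xt[fl] <- 0
      tar <- fr_one(xt)
      acc <- matrix(0, replicates, length(metrics),
                    dimnames = list(NULL, metrics))
      for (r in seq_len(replicates)) {
        xr <- x; xr[rem_sets[[r]]] <- 0
        acc[r, ] <- fr_one(xr)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s[j], habitat = h, metric = metrics,
        observed = unname(obs[metrics]), targeted = unname(tar[metrics]),
        random_mean = unname(colMeans(acc)),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  ps <- do.call(rbind, rows)
  stats <- removal_paired_stats(
    ps, value_cols = c(observed = "observed", targeted = "targeted",
                       random = "random_mean"),
    extra_group = "metric")
  structure(list(per_sample = ps, stats = stats),
            class = "functional_removal_result")
}
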