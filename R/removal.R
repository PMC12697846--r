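#' Per-sample taxonomic richness
#'
#' @param table a [count_table].
#' @return named integer vector: number of taxa with count > 0 per sample.
#' @export
sample_richness <- function(table) {
  stopifnot(inherits(table, "count_table"))
  setNames(as.integer(colSums(table$counts > 0)), colnames(table$counts))
}

#' Targeted removal of flagged nonnative taxa
#'
#' Zeroes the counts of every taxon flagged nonnative in a habitat from all
#' of that habitat's samples, leaving other habitats untouched. Counts of
#' retained taxa are never altered and there is no re-rarefaction:
#' richness comparisons are count-based.
#'
#' @param table a [count_table].
#' @param calls output of [classify_nonnative()] computed on `table` (or a
#'   data frame with `taxon`, `habitat`, `nonnative`).
#' @param habitat optional habitat label(s) to process; default all.
#' @return the modified [count_table].
#' @export
targeted_removal <- function(table, calls, habitat = NULL) {
  stopifnot(inherits(table, "count_table"))
  habitat <- habitat %||% habitats(table)
  out <- table$counts
  for (h in habitat) {
    s <- samples_in_habitat(table, h)
    fl <- unique(calls$taxon[calls$habitat == h & calls$nonnative])
    fl <- intersect(fl, rownames(out))
    if (!length(fl)) {
      warning("no flagged taxa in habitat '", h, "': identity transform",
              call. = FALSE)
      next
    }
    out[fl, s] <- 0L
  }
  ct <- count_table(out, table$habitat)
  attr(ct, "metadata") <- attr(table, "metadata")
  ct
}

#' Random removal of taxa from a habitat's metacommunity
#'
#' Null counterpart of [targeted_removal()]: each replicate removes a
#' uniform random k-subset of the habitat's detected-taxon pool (taxa with
#' at least one read in the habitat) from all its samples. Seeded and
#' reproducible.
#'
#' @param table a [count_table].
#' @param habitat habitat label.
#' @param k number of taxa to remove per replicate; `k = 0` reproduces the
#'   observed communities.
#' @param replicates number of independent random subsets.
#' @param seed integer seed.
#' @return list with `removed` (list of character vectors, one per
#'   replicate) and `richness` (matrix, replicates x habitat samples).
#' @export
random_removal <- function(table, habitat, k, replicates = 100L, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  replicates <- check_count(replicates, "replicates")
  k <- check_count(k, "k", min = 0L)
  s <- samples_in_habitat(table, habitat)
  m <- table$counts[, s, drop = FALSE]
  pool <- rownames(m)[rowSums(m) > 0]
  if (k > length(pool))
    msk_stop("k = ", k, " exceeds the habitat's detected pool (",
             length(pool), " taxa)")
  set.seed(seed)
  removed <- vector("list", replicates)
  rich <- matrix(NA_integer_, replicates, length(s),
                 dimnames = list(NULL, s))
  pres <- m > 0
  for (r in seq_len(replicates)) {
    rem <- if (k) sample(pool, k) else character()
    removed[[r]] <- rem
    keep <- !(rownames(m) %in% rem)
    rich[r, ] <- colSums(pres[keep, , drop = FALSE])
  }
  list(removed = removed, richness = rich)
}

#' Compare observed, targeted-removal and random-removal richness
#'
#' Runs the whole removal experiment per habitat: observed per-sample
#' richness; richness after targeted removal of the habitat's flagged
#' nonnative taxa; and the mean richness over `replicates` random removals
#' of an equivalent number of taxa from the habitat's detected pool.
#' Richness is also normalized by the maximum observed richness within each
#' habitat. Scenario pairs are contrasted with paired t-tests on the
#' normalized richness, with Benjamini-Hochberg adjustment across the whole
#' habitat x comparison family. Habitats with fewer than 3 samples are
#' skipped with a warning; degenerate contrasts (identical vectors) are
#' reported with `NA` statistics and flagged `no_difference`.
#'
#' @param table a [count_table] (rarefied).
#' @param calls output of [classify_nonnative()].
#' @param replicates random-removal replicates (default 100).
#' @param seed integer seed.
#' @return list of class `removal_result`: `per_sample` data frame
#'   (`sample`, `habitat`, `observed`, `targeted`, `random_mean`, plus
#'   `_norm` variants), `stats` data frame (`habitat`, `comparison`,
#'   `mean_a`, `mean_b`, `statistic`, `df`, `p_value`, `p_adjust`,
#'   `no_difference`), and `random_richness` (per-habitat replicate x
#'   sample matrices).
#' @export
compare_removals <- function(table, calls, replicates = 100L, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  per_sample <- list(); random_mats <- list()
  for (h in habitats(table)) {
    s <- samples_in_habitat(table, h)
    m <- table$counts[, s, drop = FALSE]
    obs <- colSums(m > 0)
    fl <- unique(calls$taxon[calls$habitat == h & calls$nonnative])
    fl <- intersect(fl, rownames(m)[rowSums(m) > 0])
    tar <- colSums(m[!(rownames(m) %in% fl), , drop = FALSE] > 0)
    rr <- random_removal(table, h, k = length(fl), replicates = replicates,
                         seed = seed + match(h, sort(habitats(table))))
    random_mats[[h]] <- rr$richness
    per_sample[[h]] <- data.frame(
      sample = s, habitat = h,
      observed = as.integer(obs), targeted = as.integer(tar),
      random_mean = colMeans(rr$richness),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  ps <- do.call(rbind, per_sample)
  mx <- tapply(ps$observed, ps$habitat, max)
  norm <- pmax(as.numeric(mx[ps$habitat]), 1)
  ps$observed_norm <- ps$observed / norm
  ps$targeted_norm <- ps$targeted / norm
  ps$random_mean_norm <- ps$random_mean / norm
  stats <- removal_paired_stats(ps, value_cols = c(observed = "observed_norm",
                                                   targeted = "targeted_norm",
                                                   random = "random_mean_norm"))
  rownames(ps) <- NULL
  structure(list(per_sample = ps, stats = stats,
                 random_richness = random_mats),
            class = "removal_result")
}

# paired t-tests between scenario columns per habitat + BH across the family
removal_paired_stats <- function(ps, value_cols, extra_group = NULL) {
  combos <- list(c("observed", "targeted"),
                 c("observed", "random"),
                 c("targeted", "random"))
  gid <- if (is.null(extra_group)) ps$habitat
         else paste(ps$habitat, ps[[extra_group]], sep = "\r")
  groups <- split(ps, gid)
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    if (nrow(d) < 3L) {
      warning("fewer than 3 samples in group '", g, "': tests skipped",
              call. = FALSE)
      next
    }
    for (cmb in combos) {
      a <- d[[value_cols[[cmb[1L]]]]]
      b <- d[[value_cols[[cmb[2L]]]]]
      if (isTRUE(all.equal(a, b)) || stats::sd(a - b) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, comparison = paste(cmb, collapse = "_vs_"),
          mean_a = mean(a), mean_b = mean(b), statistic = NA_real_,
          df = NA_real_, p_value = NA_real_, no_difference = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      tt <- stats::t.test(a, b, paired = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, comparison = paste(cmb, collapse = "_vs_"),
        mean_a = mean(a), mean_b = mean(b),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value, no_difference = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), comparison = character(),
               mean_a = numeric(), mean_b = numeric(), statistic = numeric(),
               df = numeric(), p_value = numeric(), no_difference = logical())
  out$p_adjust <- p.adjust(out$p_value, method = "BH")
  if (is.null(extra_group)) {
    names(out)[names(out) == "group"] <- "habitat"
  } else {
    parts <- strsplit(out$group, "\r", fixed = TRUE)
    out$habitat <- vapply(parts, `[`, character(1), 1L)
    out[[extra_group]] <- vapply(parts, `[`, character(1), 2L)
    out$group <- NULL
    first <- c("habitat", extra_group)
    out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
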