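#' Classify putative nonnative (taxon, habitat) pairs
#'
#' Applies the dual abundance/niche-breadth rule: a taxon j present in
#' habitat H is flagged putative nonnative in H only when all three hold:
#' \enumerate{
#'   \item its mean relative abundance in H is lower than in some other
#'     habitat where it is present (H is not its best habitat by abundance);
#'   \item its normalized niche breadth in H is lower than in some other
#'     habitat where it is present;
#'   \item its normalized niche breadth in H is lower than the `quantile`
#'     (default: median) of normalized breadths over all present taxa in H.
#' }
#' "Lower than" is strict: ties fail. Taxa detected in a single habitat are
#' exempt (the cross-habitat comparisons are undefined), and a taxon can
#' never be nonnative in its maximum-abundance habitat. The interpretation
#' is source-sink: nonnative pairs are dispersal-derived colonists that
#' persist at low abundance and low within-habitat evenness in sinks.
#'
#' @param profiles output of [habitat_profiles()].
#' @param quantile fraction in (0,1): reference quantile of within-habitat
#'   normalized breadths for criterion 3 (default 0.5).
#' @return A data frame of class `nonnative_calls`, one row per present
#'   (taxon, habitat) pair: `taxon`, `habitat`, `n_habitats_present`,
#'   `crit_abundance`, `crit_breadth_cross`, `crit_breadth_within`,
#'   `nonnative`. Sorted by taxon then habitat, so the result is invariant
#'   to input row order.
#' @export
classify_nonnative <- function(profiles, quantile = 0.5) {
  check_fraction(quantile, "quantile", closed_upper = FALSE)
  need <- c("taxon", "habitat", "present", "mean_rel_abundance", "breadth_norm")
  if (!all(need %in% names(profiles)))
    msk_stop("'profiles' must come from habitat_profiles()")
  pres <- profiles[profiles$present, , drop = FALSE]
  if (nrow(pres) == 0L)
    return(structure(data.frame(taxon = character(), habitat = character(),
                                n_habitats_present = integer(),
                                crit_abundance = logical(),
                                crit_breadth_cross = logical(),
                                crit_breadth_within = logical(),
                                nonnative = logical()),
                     class = c("nonnative_calls", "data.frame")))
  taxa <- sort(unique(pres$taxon))
  habs <- sort(unique(pres$habitat))
  wide <- function(v) {
    m <- matrix(NA_real_, length(taxa), length(habs),
                dimnames = list(taxa, habs))
    m[cbind(match(pres$taxon, taxa), match(pres$habitat, habs))] <- v
    m
  }
  mra <- wide(pres$mean_rel_abundance)
  bn <- wide(pres$breadth_norm)
  nhab <- rowSums(!is.na(mra))
  rmax_mra <- apply(mra, 1L, max, na.rm = TRUE)
  rmax_bn <- apply(bn, 1L, max, na.rm = TRUE)
  # strict "lower than the max over other habitats" is equivalent to
  # "strictly below the row maximum" (ties at the max fail either way)
  crit1 <- sweep(mra, 1L, rmax_mra, "<")
  crit2 <- sweep(bn, 1L, rmax_bn, "<")
  qthr <- vapply(habs, function(h)
    stats::quantile(bn[, h], probs = quantile, na.rm = TRUE, names = FALSE),
    numeric(1))
  crit3 <- sweep(bn, 2L, qthr, "<")
  multi <- nhab >= 2L
  crit1[!multi, ] <- FALSE
  crit2[!multi, ] <- FALSE
  i <- cbind(match(pres$taxon, taxa), match(pres$habitat, habs))
  out <- data.frame(taxon = pres$taxon,
                    habitat = pres$habitat,
                    n_habitats_present = nhab[pres$taxon],
                    crit_abundance = crit1[i],
                    crit_breadth_cross = crit2[i],
                    crit_breadth_within = crit3[i],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$nonnative <- out$crit_abundance & out$crit_breadth_cross &
    out$crit_breadth_within & multi[out$taxon]
  out <- out[order(out$taxon, out$habitat), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("nonnative_calls", "data.frame"))
}

#' Summarize nonnative contributions per habitat and sample
#'
#' Per habitat: the fraction of the habitat's detected metacommunity taxa
#' flagged nonnative there. Per sample: the summed relative abundance of
#' flagged taxa and the fraction of the sample's detected taxa that are
#' flagged (richness share).
#'
#' @param table the [count_table] on which `calls` were computed.
#' @param calls output of [classify_nonnative()].
#' @return list with data frames `per_habitat` (`habitat`, `n_pool`,
#'   `n_flagged`, `flagged_fraction`) and `per_sample` (`sample`, `habitat`,
#'   `flagged_abundance`, `flagged_richness_fraction`).
#' @export
summarize_nonnative <- function(table, calls) {
  stopifnot(inherits(table, "count_table"))
  unknown <- setdiff(calls$taxon, rownames(table$counts))
  if (length(unknown))
    msk_stop("calls reference taxa absent from the count table: ",
             paste(utils::head(unknown, 5), collapse = ", "))
  per_h <- lapply(habitats(table), function(h) {
    s <- samples_in_habitat(table, h)
    m <- table$counts[, s, drop = FALSE]
    pool <- rownames(m)[rowSums(m) > 0]
    fl <- calls$taxon[calls$habitat == h & calls$nonnative]
    data.frame(habitat = h, n_pool = length(pool), n_flagged = length(fl),
               flagged_fraction = if (length(pool)) length(fl) / length(pool) else 0,
               stringsAsFactors = FALSE)
  })
  per_s <- lapply(seq_len(n_samples(table)), function(j) {
    s <- colnames(table$counts)[j]
    h <- table$habitat[[s]]
    x <- table$counts[, j]
    fl <- calls$taxon[calls$habitat == h & calls$nonnative]
    det <- names(x)[x > 0]
    data.frame(sample = s, habitat = h,
               flagged_abundance = if (sum(x)) sum(x[intersect(det, fl)]) / sum(x) else 0,
               flagged_richness_fraction =
                 if (length(det)) length(intersect(det, fl)) / length(det) else 0,
               stringsAsFactors = FALSE)
  })
  list(per_habitat = do.call(rbind, per_h),
       per_sample = do.call(rbind, per_s))
}

#' Score classification against simulator ground truth
#'
#' Confusion-matrix metrics over the evaluable universe: (taxon, habitat)
#' pairs where the taxon is detected in that habitat and in at least two
#' habitats overall. Planted colonist pairs that never got detected in the
#' sink (sequencing dropout) cannot be called and are excluded.
#'
#' @param calls output of [classify_nonnative()].
#' @param truth a `ground_truth` object from [simulate_metacommunity()], or
#'   any list with a `nonnative_pairs` data frame (`taxon`, `habitat`).
#' @return list with `n_eligible`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1` (NA when undefined).
#' @export
evaluate_against_truth <- function(calls, truth) {
  tp_pairs <- truth$nonnative_pairs
  elig <- calls[calls$n_habitats_present >= 2L, , drop = FALSE]
  key <- function(t, h) paste(t, h, sep = "\r")
  truth_keys <- if (nrow(tp_pairs)) key(tp_pairs$taxon, tp_pairs$habitat) else character()
  elig_keys <- key(elig$taxon, elig$habitat)
  actual <- elig_keys %in% truth_keys
  pred <- elig$nonnative
  tp <- sum(pred & actual); fp <- sum(pred & !actual); fn <- sum(!pred & actual)
  if (tp + fp + fn == 0L) {
    message("no positives in either calls or truth: metrics undefined")
    return(list(n_eligible = nrow(elig), tp = 0L, fp = 0L, fn = 0L,
                precision = NA_real_, recall = NA_real_, f1 = NA_real_))
  }
  precision <- if (tp + fp) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(n_eligible = nrow(elig), tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}
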