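#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment with match score 1, mismatch 0 and a
#' linear gap penalty of 1 per gap column; identity is the number of
#' matched columns divided by the total number of alignment columns
#' (terminal gaps included). Among co-optimal alignments the one with the
#' most matches is used; because score and matches both accumulate
#' additively, the pair (score, matches) of that alignment is obtained from
#' a single scalarized dynamic program without traceback, making the value
#' deterministic and symmetric.
#'
#' @param a,b non-empty nucleotide sequences (character scalars).
#' @return identity fraction in \[0, 1\].
#' @examples
#' pairwise_identity("ACGT", "ACGT") # 1
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) msk_stop("empty sequence")
  sa <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  sb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  La <- length(sa); Lb <- length(sb)
  K <- La + Lb + 1          # scalarization: U = K * score + matches
  jj <- seq_len(Lb)
  prev <- -(0:Lb) * K       # row 0: j leading gaps, score -j, 0 matches
  for (i in seq_len(La)) {
    step <- ifelse(sb == sa[i], K + 1, 0)
    cand <- pmax(prev[jj] + step,      # diagonal
                 prev[jj + 1L] - K)    # gap in b (up)
    # left-gap propagation: H[j] = max(cand[j], H[j-1] - K)
    A <- cummax(c(-i * K, cand + K * jj))
    prev <- A - K * (0:Lb)
  }
  U <- prev[Lb + 1L]
  S <- floor(U / K)
  M <- U - K * S
  G <- M - S                           # gap columns (penalty 1 each)
  M / ((La + Lb + G) / 2)
}

# distinct k-mers of a sequence (internal)
seq_kmers <- function(s, w) {
  L <- nchar(s)
  if (L < w) return(character())
  unique(substring(s, seq_len(L - w + 1L), w:L))
}

#' Greedy abundance-sorted OTU clustering
#'
#' Emulates centroid-based greedy clustering at a fixed identity threshold
#' (the `--cluster_size` strategy of common amplicon tools): sequences are
#' processed in decreasing total-abundance order (ties broken by id); each
#' sequence joins the earliest-created centroid with
#' [pairwise_identity()] >= `threshold`, otherwise it founds a new OTU. The
#' result depends only on (abundance, id) order, never on input file
#' order. A shared k-mer prefilter (word size `word_size`) restricts which
#' centroids are aligned against, as in production clustering tools; it is
#' disabled automatically whenever the q-gram bound cannot guarantee
#' filtering is safe (short sequences or low thresholds), in which case
#' every centroid is aligned.
#'
#' @param sequences named character vector of unique ASV sequences.
#' @param abundances named numeric vector of total abundances (same names).
#' @param threshold identity threshold in (0, 1\]; default 0.97.
#' @param word_size k-mer length for the prefilter (default 8); `NULL`
#'   disables the prefilter entirely.
#' @return data frame of class `otu_assignment`: `asv_id`, `otu_id`,
#'   `is_centroid`, `identity_to_centroid`, sorted by `otu_id` then
#'   `asv_id`.
#' @export
greedy_otu_cluster <- function(sequences, abundances,
                               threshold = 0.97, word_size = 8L) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    msk_stop("'threshold' must lie in (0, 1]")
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) msk_stop("sequence ids must be unique")
  if (!all(ids %in% names(abundances)))
    msk_stop("abundances missing for some sequences")
  ord <- order(-abundances[ids], ids)
  ids <- ids[ord]
  n <- length(ids)
  Ls <- nchar(sequences[ids])
  use_filter <- !is.null(word_size)
  if (use_filter) {
    w <- as.integer(word_size)
    # q-gram lemma: >= t-identity over columns C <= La+Lb implies at least
    # (Lmin - w + 1) - w*ceil((1-t)(La+Lb)) shared w-mer occurrences; we
    # require half that many shared distinct w-mers, and fall back to
    # aligning everything when the bound is not positive
    kindex <- new.env(parent = emptyenv())
    km_list <- vector("list", n)
  }
  centroid_ids <- character(); centroid_of <- character(n)
  identity_to <- numeric(n); is_cent <- logical(n)
  names(centroid_of) <- names(identity_to) <- names(is_cent) <- ids
  for (q in seq_len(n)) {
    id <- ids[q]
    sq <- sequences[[id]]
    if (use_filter) km <- seq_kmers(sq, w)
    cands <- seq_along(centroid_ids)
    if (use_filter && length(centroid_ids)) {
      Lmin_all <- pmin(Ls[centroid_ids], nchar(sq))
      bound <- (Lmin_all - w + 1) -
        w * ceiling((1 - threshold) * (Ls[centroid_ids] + nchar(sq)))
      need <- floor(bound / 2)
      if (all(need >= 1)) {
        hits <- unlist(mget(km, envir = kindex, ifnotfound = list(integer())),
                       use.names = FALSE)
        cnt <- tabulate(hits, nbins = length(centroid_ids))
        cands <- which(cnt >= need)
      }
    }
    assigned <- FALSE
    for (ci in cands) {                 # earliest centroid first
      idt <- pairwise_identity(sq, sequences[[centroid_ids[ci]]])
      if (idt >= threshold) {
        centroid_of[id] <- centroid_ids[ci]
        identity_to[id] <- idt
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroid_ids <- c(centroid_ids, id)
      centroid_of[id] <- id
      identity_to[id] <- 1
      is_cent[id] <- TRUE
      if (use_filter) {
        ci <- length(centroid_ids)
        for (k in km) assign(k, c(kindex[[k]] %||% integer(), ci),
                             envir = kindex)
      }
    }
  }
  otu_id <- setNames(paste0("OTU", match(centroid_of, centroid_ids)), ids)
  out <- data.frame(asv_id = ids, otu_id = unname(otu_id),
                    is_centroid = unname(is_cent),
                    identity_to_centroid = unname(identity_to),
                    stringsAsFactors = FALSE)
  out <- out[order(out$otu_id, out$asv_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("otu_assignment", "data.frame"))
}

#' Nearest-taxon distance and closeness
#'
#' For each taxon, the distance to its closest relative in the dataset
#' (patristic distance when a tree is given, or any symmetric distance
#' matrix, e.g. 1 - identity), minus-log-transformed into "closeness":
#' closeness = -log(d_min). Zero distances (identical sequences) are
#' floored to `epsilon`, by default half the smallest positive distance in
#' the dataset, before taking the log.
#'
#' @param dist a `phylo` tree or a symmetric numeric distance matrix with
#'   taxon dimnames.
#' @param log_base base of the logarithm (default natural).
#' @param epsilon floor for zero distances; default half the smallest
#'   positive distance.
#' @return data frame: `taxon`, `nearest_distance` (pre-flooring),
#'   `closeness`.
#' @export
nearest_taxon_closeness <- function(dist, log_base = exp(1), epsilon = NULL) {
  d <- if (inherits(dist, "phylo")) stats::cophenetic(dist) else as.matrix(dist)
  if (nrow(d) < 2L) msk_stop("nearest-taxon distance needs at least 2 taxa")
  if (any(d < 0)) msk_stop("distances must be non-negative")
  diag(d) <- NA
  dmin <- apply(d, 1L, min, na.rm = TRUE)
  pos <- d[!is.na(d) & d > 0]
  if (is.null(epsilon))
    epsilon <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  floored <- pmax(dmin, epsilon)
  data.frame(taxon = rownames(d),
             nearest_distance = unname(dmin),
             closeness = -log(unname(floored), base = log_base),
             stringsAsFactors = FALSE)
}

#' Microdiversity stratified by habitat occurrence level
#'
#' Groups OTUs and ASVs by the number of habitats they occur in and asks
#' whether microdiversity rises with occurrence: per occurrence level it
#' summarizes intra-OTU ASV counts (per OTU; an OTU's level is the maximum
#' over its members) and nearest-taxon closeness (per ASV); runs all
#' pairwise Welch t-tests between levels with Benjamini-Hochberg adjustment
#' and a compact letter display; and reports the Spearman rank correlation
#' between occurrence level and each metric.
#'
#' @param assignment an `otu_assignment` from [greedy_otu_cluster()].
#' @param closeness data frame from [nearest_taxon_closeness()] over the
#'   same ASVs (may be `NULL` to skip the closeness metric).
#' @param occurrence named integer vector: habitat occurrence count per ASV.
#' @return list with `otu_records` (`otu_id`, `n_asvs`, `occurrence`),
#'   `summary` (per metric x level: n, mean, sd, letters), `pairwise`
#'   (tests with `p_adjust`), `spearman` (per metric: rho, p, p_adjust).
#' @export
microdiversity_by_occurrence <- function(assignment, closeness = NULL,
                                         occurrence) {
  miss <- setdiff(assignment$asv_id, names(occurrence))
  if (length(miss))
    msk_stop("occurrence counts missing for: ",
             paste(utils::head(miss, 5), collapse = ", "))
  occ_asv <- occurrence[assignment$asv_id]
  otu_rec <- data.frame(
    otu_id = unique(assignment$otu_id), stringsAsFactors = FALSE)
  sp <- split(seq_len(nrow(assignment)), assignment$otu_id)
  otu_rec$n_asvs <- vapply(sp[otu_rec$otu_id], length, integer(1))
  otu_rec$occurrence <- vapply(sp[otu_rec$otu_id], function(i)
    max(occ_asv[i]), numeric(1))

  metrics <- list(intra_otu_asv_count = data.frame(
    value = otu_rec$n_asvs, level = otu_rec$occurrence))
  if (!is.null(closeness)) {
    cl <- setNames(closeness$closeness, closeness$taxon)[assignment$asv_id]
    metrics$closeness <- data.frame(value = unname(cl),
                                    level = unname(occ_asv))
  }

  summaries <- list(); pw <- list(); sp_rows <- list()
  for (mn in names(metrics)) {
    d <- metrics[[mn]]
    levs <- sort(unique(d$level))
    smry <- data.frame(metric = mn, level = levs,
                       n = vapply(levs, function(l) sum(d$level == l), integer(1)),
                       mean = vapply(levs, function(l) mean(d$value[d$level == l]), numeric(1)),
                       sd = vapply(levs, function(l) sd(d$value[d$level == l]), numeric(1)),
                       stringsAsFactors = FALSE)
    testable <- levs[smry$n >= 2L]
    prs <- if (length(testable) >= 2L) utils::combn(testable, 2L, simplify = FALSE)
           else list()
    tests <- lapply(prs, function(pr) {
      x <- d$value[d$level == pr[1L]]; y <- d$value[d$level == pr[2L]]
      p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
      data.frame(metric = mn, level_a = pr[1L], level_b = pr[2L],
                 p_value = p, stringsAsFactors = FALSE)
    })
    tst <- if (length(tests)) do.call(rbind, tests) else
      data.frame(metric = character(), level_a = numeric(),
                 level_b = numeric(), p_value = numeric())
    tst$p_adjust <- p.adjust(tst$p_value, method = "BH")
    sig <- matrix(FALSE, length(levs), length(levs),
                  dimnames = list(levs, levs))
    if (nrow(tst)) {
      s <- !is.na(tst$p_adjust) & tst$p_adjust < 0.05
      sig[cbind(as.character(tst$level_a), as.character(tst$level_b))[s, ,
                                                                      drop = FALSE]] <- TRUE
      sig <- sig | t(sig)
    }
    smry$letters <- compact_letters(as.character(levs), sig)
    summaries[[mn]] <- smry
    pw[[mn]] <- tst
    ct <- tryCatch(suppressWarnings(
      cor.test(d$level, d$value, method = "spearman")),
      error = function(e) NULL)
    sp_rows[[mn]] <- data.frame(
      metric = mn,
      rho = if (is.null(ct)) NA_real_ else unname(ct$estimate),
      p_value = if (is.null(ct)) NA_real_ else ct$p.value,
      n = nrow(d), stringsAsFactors = FALSE)
  }
  spearman <- do.call(rbind, sp_rows)
  spearman$p_adjust <- p.adjust(spearman$p_value, method = "BH")
  rownames(spearman) <- NULL
  list(otu_records = otu_rec,
       summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(pw, list(make.row.names = FALSE))),
       spearman = spearman)
}

# compact letter display by insert-and-absorb over a significance matrix
compact_letters <- function(levels, sig) {
  n <- length(levels)
  if (!n) return(character())
  cols <- list(rep(TRUE, n))
  prs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  if (nrow(prs)) {
    for (r in seq_len(nrow(prs))) {
      i <- prs[r, 1L]; j <- prs[r, 2L]
      newcols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          newcols <- c(newcols, list(a, b))
        } else newcols <- c(newcols, list(col))
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(newcols))
      for (u in seq_along(newcols)) for (v in seq_along(newcols)) {
        if (u != v && keep[u] && keep[v] &&
            all(newcols[[u]] <= newcols[[v]]) &&
            !identical(newcols[[u]], newcols[[v]]))
          keep[u] <- FALSE
      }
      cols <- unique(newcols[keep])
    }
  }
  ord <- order(vapply(cols, function(c) which(c)[1L], integer(1)))
  cols <- cols[ord]
  vapply(seq_len(n), function(i)
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = ""),
    character(1))
}
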