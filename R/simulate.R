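#' Configuration for the synthetic metacommunity generator
#'
#' Bundles and validates every knob of the simulator. Defaults describe a
#' moderately connected multi-habitat system: 4 habitats with 30 samples
#' each; 250 habitat-exclusive natives per habitat plus 50 regional
#' generalists present everywhere; log-normal(0, sigma^2) abundance
#' weights; each native colonizes each foreign habitat independently with
#' probability `dispersal_rate`, and such colonists appear in a sink
#' sample with probability `colonist_occupancy` at `colonist_abundance_factor`
#' times their home weight; every sample is a multinomial draw of `depth`
#' reads over its present taxa.
#'
#' @param n_habitats number of habitats (>= 2).
#' @param samples_per_habitat samples per habitat.
#' @param natives_per_habitat habitat-exclusive native taxa per habitat.
#' @param regional_generalists taxa native to every habitat.
#' @param native_occupancy per-sample presence probability of a native in
#'   its home habitat.
#' @param generalist_occupancy per-sample presence probability of a
#'   generalist (any habitat).
#' @param dispersal_rate probability m that a native colonizes any given
#'   foreign habitat.
#' @param colonist_occupancy per-sample presence probability of a colonist
#'   in a colonized sink habitat.
#' @param colonist_abundance_factor delta: weight multiplier for colonists
#'   in sinks (0 = colonists carry no reads).
#' @param lognormal_sigma sd of log abundance weights.
#' @param depth reads per sample.
#' @param function_universe total number of function ids.
#' @param functions_per_taxon_mean Poisson mean repertoire size.
#' @param cycle_set_size functions per biogeochemical cycle set (C/N/P/S).
#' @param exclusive_cycle_fraction fraction of each cycle set carried
#'   exclusively by planted colonist taxa.
#' @param variant_rate_per_occurrence Poisson rate of extra sequence
#'   variants per habitat of occurrence.
#' @param seq_length ancestor sequence length (nt).
#' @param seed integer random seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_habitats = 4L,
                              samples_per_habitat = 30L,
                              natives_per_habitat = 250L,
                              regional_generalists = 50L,
                              native_occupancy = 0.6,
                              generalist_occupancy = 0.9,
                              dispersal_rate = 0.15,
                              colonist_occupancy = 0.15,
                              colonist_abundance_factor = 0.05,
                              lognormal_sigma = 2.0,
                              depth = 10000L,
                              function_universe = 2000L,
                              functions_per_taxon_mean = 80,
                              cycle_set_size = 25L,
                              exclusive_cycle_fraction = 0.3,
                              variant_rate_per_occurrence = 0.8,
                              seq_length = 250L,
                              seed = 1L) {
  cfg <- list(
    n_habitats = check_count(n_habitats, "n_habitats", 2L),
    samples_per_habitat = check_count(samples_per_habitat, "samples_per_habitat"),
    natives_per_habitat = check_count(natives_per_habitat, "natives_per_habitat"),
    regional_generalists = check_count(regional_generalists,
                                       "regional_generalists", 0L),
    native_occupancy = native_occupancy,
    generalist_occupancy = generalist_occupancy,
    dispersal_rate = dispersal_rate,
    colonist_occupancy = colonist_occupancy,
    colonist_abundance_factor = colonist_abundance_factor,
    lognormal_sigma = lognormal_sigma,
    depth = check_count(depth, "depth"),
    function_universe = check_count(function_universe, "function_universe"),
    functions_per_taxon_mean = functions_per_taxon_mean,
    cycle_set_size = check_count(cycle_set_size, "cycle_set_size"),
    exclusive_cycle_fraction = exclusive_cycle_fraction,
    variant_rate_per_occurrence = variant_rate_per_occurrence,
    seq_length = check_count(seq_length, "seq_length", 10L),
    seed = as.integer(seed))
  for (f in c("native_occupancy", "generalist_occupancy", "dispersal_rate",
              "colonist_occupancy", "colonist_abundance_factor",
              "exclusive_cycle_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msk_stop("'", f, "' must lie in [0, 1]")
  }
  if (!is.numeric(cfg$lognormal_sigma) || cfg$lognormal_sigma <= 0)
    msk_stop("'lognormal_sigma' must be positive")
  if (cfg$variant_rate_per_occurrence < 0)
    msk_stop("'variant_rate_per_occurrence' must be non-negative")
  if (4L * cfg$cycle_set_size > cfg$function_universe)
    msk_stop("cycle sets exceed the function universe")
  structure(cfg, class = "simulation_config")
}

#' Simulate a multi-habitat metacommunity with planted source-sink structure
#'
#' Generates a [count_table], sample metadata and a `ground_truth` object.
#' Each habitat holds its exclusive natives plus the shared generalists;
#' native weights are log-normal; each native of habitat A becomes a
#' colonist of each other habitat B independently with probability
#' `dispersal_rate`, appearing in B's samples with probability
#' `colonist_occupancy` at `colonist_abundance_factor` times its home
#' weight. Per-sample counts are one multinomial draw of `depth` reads over
#' present-taxon weights, so column sums equal `depth` exactly. Identical
#' seed, identical output. The ground truth records every planted
#' (colonist, sink habitat) pair, each taxon's source habitat and lineage,
#' and each lineage's habitat occurrence count (generalists occupy all
#' habitats and are deliberately never labelled nonnative).
#'
#' @param config a [simulation_config()].
#' @return list with `table` ([count_table]), `metadata` (data frame) and
#'   `truth` (class `ground_truth`: `nonnative_pairs` data frame,
#'   `source_habitat`, `lineage_of`, `occurrence_count`).
#' @export
simulate_metacommunity <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  habs <- sprintf("H%d", seq_len(config$n_habitats))
  natives <- lapply(habs, function(h)
    sprintf("%s_t%04d", h, seq_len(config$natives_per_habitat)))
  names(natives) <- habs
  gens <- if (config$regional_generalists)
    sprintf("gen_t%04d", seq_len(config$regional_generalists)) else character()
  taxa <- c(unlist(natives, use.names = FALSE), gens)

  # habitat-level weight matrix: NA = taxon absent from habitat pool
  W <- matrix(NA_real_, length(taxa), length(habs),
              dimnames = list(taxa, habs))
  O <- matrix(NA_real_, length(taxa), length(habs),
              dimnames = list(taxa, habs))
  home_w <- setNames(rlnorm(length(taxa), 0, config$lognormal_sigma), taxa)
  src <- setNames(rep(NA_character_, length(taxa)), taxa)
  for (h in habs) {
    W[natives[[h]], h] <- home_w[natives[[h]]]
    O[natives[[h]], h] <- config$native_occupancy
    src[natives[[h]]] <- h
  }
  for (g in gens) {
    W[g, ] <- rlnorm(length(habs), 0, config$lognormal_sigma)
    O[g, ] <- config$generalist_occupancy
  }
  # habitat-level colonization of natives into foreign habitats
  pairs <- list()
  for (h in habs) {
    for (b in setdiff(habs, h)) {
      col <- natives[[h]][rbinom(length(natives[[h]]), 1L,
                                 config$dispersal_rate) == 1L]
      if (length(col)) {
        W[col, b] <- home_w[col] * config$colonist_abundance_factor
        O[col, b] <- config$colonist_occupancy
        pairs[[length(pairs) + 1L]] <- data.frame(
          taxon = col, habitat = b, source = h, stringsAsFactors = FALSE)
      }
    }
  }
  nn <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(taxon = character(), habitat = character(),
               source = character(), stringsAsFactors = FALSE)

  samples <- unlist(lapply(habs, function(h)
    sprintf("%s_s%02d", h, seq_len(config$samples_per_habitat))))
  habitat_of <- setNames(rep(habs, each = config$samples_per_habitat), samples)
  counts <- matrix(0L, length(taxa), length(samples),
                   dimnames = list(taxa, samples))
  for (s in samples) {
    h <- habitat_of[[s]]
    pool <- which(!is.na(W[, h]))
    draw_presence <- function() pool[runif(length(pool)) < O[pool, h]]
    present <- draw_presence()
    if (!length(present)) present <- draw_presence()
    if (!length(present))
      msk_stop("sample '", s, "' ended up with zero present taxa; ",
               "occupancy parameters are too sparse")
    w <- W[present, h]
    if (sum(w) > 0)
      counts[present, s] <- rmultinom(1L, config$depth, w)[, 1L]
    else
      counts[present[1L], s] <- config$depth
  }

  # habitat-level occurrence by design; colonist habitats where the taxon
  # can carry no reads (delta = 0 => weight 0) are not counted
  occurrence <- setNames(pmax(1L, as.integer(rowSums(!is.na(W) & W > 0))),
                         taxa)

  truth <- structure(list(
    nonnative_pairs = nn[, c("taxon", "habitat")],
    source_habitat = src,
    lineage_of = setNames(taxa, taxa),
    occurrence_count = occurrence), class = "ground_truth")

  meta <- data.frame(sample_id = samples, habitat = unname(habitat_of),
                     stringsAsFactors = FALSE)
  ct <- count_table(counts, habitat_of)
  attr(ct, "metadata") <- meta
  list(table = ct, metadata = meta, truth = truth)
}

#' Simulate ASV sequences, variants and a phylogeny from ground truth
#'
#' Each lineage receives a random ancestor sequence; it then spawns
#' `1 + Poisson(variant_rate_per_occurrence x occurrence_count)` variant
#' sequences (the first variant being the unmutated ancestor), each
#' carrying 1 to 2% point mutations, so all variants of a lineage stay
#' within one 97%-identity OTU by construction while lineages occupying
#' more habitats accumulate more variants. Two trees are returned: a
#' variant-level tree (lineage coalescent backbone with variants attached
#' at branch lengths proportional to their mutation counts) and the
#' lineage-level backbone itself, useful as the taxon phylogeny for
#' functional redundancy.
#'
#' @param truth a `ground_truth` from [simulate_metacommunity()].
#' @param config the matching [simulation_config()].
#' @param abundance optional named vector of total counts per lineage used
#'   to apportion variant abundances (defaults to equal).
#' @return list with `sequences` (named character), `tree` (`phylo` over
#'   variants), `taxon_tree` (`phylo` over lineages) and `asv_info`
#'   (data frame: `asv_id`, `lineage_id`, `n_mutations`, `abundance`,
#'   `occurrence`).
#' @export
simulate_sequences <- function(truth, config, abundance = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  lineages <- sort(unique(unname(truth$lineage_of)))
  if (length(lineages) < 2L) msk_stop("need at least 2 lineages")
  occ <- truth$occurrence_count[lineages]
  L <- config$seq_length
  bases <- c("A", "C", "G", "T")
  max_mut <- max(1L, floor(0.02 * L))
  lin_tot <- if (is.null(abundance)) setNames(rep(1, length(lineages)), lineages)
             else abundance[lineages]

  seqs <- character(0); info <- list(); sub_nwk <- character(length(lineages))
  names(sub_nwk) <- lineages
  for (k in seq_along(lineages)) {
    lin <- lineages[[k]]
    anc <- sample(bases, L, replace = TRUE)
    nv <- 1L + rpois(1L, config$variant_rate_per_occurrence * occ[[lin]])
    ids <- sprintf("%s_v%d", lin, seq_len(nv))
    muts <- integer(nv)
    vseqs <- character(nv)
    vseqs[1L] <- paste(anc, collapse = "")
    if (nv > 1L) {
      for (v in 2:nv) {
        nm <- sample.int(max_mut, 1L)
        muts[v] <- nm
        pos <- sample.int(L, nm)
        s <- anc
        for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
        vseqs[v] <- paste(s, collapse = "")
      }
    }
    seqs[ids] <- vseqs
    w <- 2^-(seq_len(nv) - 1L)
    info[[k]] <- data.frame(asv_id = ids, lineage_id = lin,
                            n_mutations = muts,
                            abundance = lin_tot[[lin]] * w / sum(w),
                            occurrence = occ[[lin]],
                            stringsAsFactors = FALSE)
    sub_nwk[[lin]] <- paste0(
      "(", paste(sprintf("%s:%.8f", ids, muts / L), collapse = ","), ")")
  }
  backbone <- ape::rcoal(length(lineages), tip.label = lineages)
  backbone$edge.length <- backbone$edge.length /
    max(stats::cophenetic(backbone)) * 1.0
  nwk <- ape::write.tree(backbone)
  # graft each lineage's variant fan onto its backbone tip
  for (lin in lineages)
    nwk <- sub(paste0("([(,])", lin, ":"),
               paste0("\\1", sub_nwk[[lin]], lin, ":"), nwk)
  vtree <- ape::read.tree(text = nwk)
  asv_info <- do.call(rbind, info)
  rownames(asv_info) <- NULL
  list(sequences = seqs, tree = vtree, taxon_tree = backbone,
       asv_info = asv_info)
}

#' Simulate taxon-level function repertoires with planted cycle structure
#'
#' Every taxon carries a Poisson(`functions_per_taxon_mean`) sample of the
#' function universe. Four disjoint cycle sets (C, N, P, S) of
#' `cycle_set_size` functions are reserved at the start of the universe; a
#' fraction `exclusive_cycle_fraction` of each set is carried exclusively
#' by planted colonist (nonnative) taxa, so targeted removal demonstrably
#' erodes cycle-related functional richness and redundancy. Each exclusive
#' function is assigned to several colonists (when any exist) so its
#' redundancy is positive before removal.
#'
#' @param truth a `ground_truth`.
#' @param config the matching [simulation_config()].
#' @return a [function_table] with sets `C`, `N`, `P`, `S`.
#' @export
simulate_function_table <- function(truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  taxa <- names(truth$lineage_of)
  U <- config$function_universe
  funs <- sprintf("F%05d", seq_len(U))
  sz <- config$cycle_set_size
  sets <- list(C = funs[seq_len(sz)],
               N = funs[sz + seq_len(sz)],
               P = funs[2L * sz + seq_len(sz)],
               S = funs[3L * sz + seq_len(sz)])
  n_excl <- floor(config$exclusive_cycle_fraction * sz)
  colonists <- unique(truth$nonnative_pairs$taxon)
  exclusive <- unlist(lapply(sets, function(s)
    if (n_excl) s[seq_len(n_excl)] else character()), use.names = FALSE)
  open_funs <- setdiff(funs, exclusive)

  tx <- character(0); fn <- character(0)
  for (t in taxa) {
    k <- rpois(1L, config$functions_per_taxon_mean)
    k <- min(k, length(open_funs))
    allowed <- if (t %in% colonists) funs else open_funs
    k <- min(k, length(allowed))
    if (k) {
      pick <- sample(allowed, k)
      tx <- c(tx, rep(t, k)); fn <- c(fn, pick)
    }
  }
  # guarantee each exclusive cycle function has a few colonist carriers
  if (length(colonists) && length(exclusive)) {
    for (f in exclusive) {
      carriers <- sample(colonists, min(3L, length(colonists)))
      tx <- c(tx, carriers); fn <- c(fn, rep(f, length(carriers)))
    }
  }
  ft <- function_table(tx, fn)
  # taxa with empty repertoires are absent from the incidence rows; that is
  # fine (functional_richness skips unannotated members with a message)
  set_function_sets(ft, sets)
}
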