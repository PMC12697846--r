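# Independent naive reference implementations used as oracles.
# These deliberately avoid the package's own code paths.

# Levins breadth straight from raw counts of one taxon across samples
naive_levins <- function(counts) {
  p <- counts / sum(counts)
  1 / sum(p^2)
}

# Rao-type functional redundancy by explicit double loop
naive_fr <- function(p, carriers, d) {
  fr <- 0
  for (i in carriers) for (j in carriers)
    if (i != j) fr <- fr + p[[i]] * p[[j]] * d[i, j]
  fr
}

# global alignment identity: explicit (score, matches) lexicographic DP,
# match +1, mismatch 0, linear gap penalty 1 per gap column
naive_identity <- function(a, b) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  la <- length(A); lb <- length(B)
  better <- function(x, y) x[1] > y[1] || (x[1] == y[1] && x[2] > y[2])
  S <- array(0, c(la + 1L, lb + 1L, 2L))
  for (j in seq_len(lb)) S[1L, j + 1L, ] <- c(-j, 0)
  for (i in seq_len(la)) S[i + 1L, 1L, ] <- c(-i, 0)
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    hit <- as.integer(A[i] == B[j])
    cand <- list(S[i, j, ] + c(hit, hit),
                 S[i, j + 1L, ] + c(-1, 0),
                 S[i + 1L, j, ] + c(-1, 0))
    best <- cand[[1L]]
    for (cc in cand[-1L]) if (better(cc, best)) best <- cc
    S[i + 1L, j + 1L, ] <- best
  }
  sc <- S[la + 1L, lb + 1L, 1L]
  m <- S[la + 1L, lb + 1L, 2L]
  gaps <- m - sc
  m / ((la + lb + gaps) / 2)
}

# greedy abundance-ordered clustering using the naive aligner
naive_greedy_cluster <- function(seqs, ab, threshold) {
  ids <- names(seqs)[order(-ab[names(seqs)], names(seqs))]
  centroids <- character()
  assign_to <- setNames(character(length(ids)), ids)
  for (id in ids) {
    hit <- NA_character_
    for (ce in centroids) {
      if (naive_identity(seqs[[id]], seqs[[ce]]) >= threshold) {
        hit <- ce; break
      }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, id)
      assign_to[id] <- id
    } else assign_to[id] <- hit
  }
  assign_to
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# small deterministic toy count table: 2 habitats x 3 samples each
toy_table <- function() {
  m <- matrix(c(
    30L, 20L, 10L,   1L, 0L, 1L,    # t1: abundant in water, trace in gut
    5L,  5L,  5L,    5L, 5L, 5L,    # t2: everywhere, even
    0L,  0L,  0L,   20L, 30L, 10L,  # t3: gut only
    10L, 0L,  0L,    0L, 0L, 0L),   # t4: one water sample only
    nrow = 4L, byrow = TRUE,
    dimnames = list(paste0("t", 1:4),
                    c("w1", "w2", "w3", "g1", "g2", "g3")))
  count_table(m, setNames(c(rep("water", 3), rep("gut", 3)), colnames(m)))
}

small_sim_config <- function(seed = 1L, ...) {
  args <- list(n_habitats = 3L, samples_per_habitat = 8L,
               natives_per_habitat = 30L, regional_generalists = 10L,
               depth = 1000L, function_universe = 300L,
               functions_per_taxon_mean = 30, cycle_set_size = 10L,
               seq_length = 120L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}
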