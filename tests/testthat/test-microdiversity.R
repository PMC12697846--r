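mutate_at <- function(seq, pos) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1L]
  paste(s, collapse = "")
}

test_that("pairwise identity handles exact, mismatch and gap cases", {
  set.seed(61)
  s100 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  expect_equal(pairwise_identity(s100, s100), 1)
  expect_equal(pairwise_identity(s100, mutate_at(s100, c(3, 50, 97))), 0.97)
  # symmetric
  a <- "ACGTACGTAC"; b <- "ACGTTACGTA"
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("identity matches an independent quadratic-time aligner", {
  set.seed(62)
  for (rep in 1:25) {
    la <- sample(5:30, 1); lb <- sample(5:30, 1)
    a <- random_dna(1, la); b <- random_dna(1, lb)
    expect_equal(pairwise_identity(a, b), naive_identity(a, b),
                 tolerance = 1e-12)
    # related pair: mutate/indel a copy
    b2 <- mutate_at(a, sample.int(la, min(3, la)))
    expect_equal(pairwise_identity(a, b2), naive_identity(a, b2),
                 tolerance = 1e-12)
  }
})

test_that("greedy clustering follows the abundance-ordered first-fit rule", {
  set.seed(63)
  base <- random_dna(1, 100)
  a <- base
  b <- mutate_at(base, c(5, 50))          # 0.98 to a
  c_ <- mutate_at(base, seq(3, 93, by = 10))  # 0.90 to a
  seqs <- c(a = a, b = b, c = c_)
  ab <- c(a = 30, b = 20, c = 10)
  res <- greedy_otu_cluster(seqs, ab, threshold = 0.97)
  got <- setNames(res$otu_id, res$asv_id)
  expect_equal(got[["a"]], got[["b"]])
  expect_false(got[["c"]] == got[["a"]])
  expect_true(res$is_centroid[res$asv_id == "a"])
  expect_equal(res$identity_to_centroid[res$asv_id == "b"], 0.98)
  # all sequences identical: one OTU
  same <- setNames(rep(base, 3), c("x", "y", "z"))
  r1 <- greedy_otu_cluster(same, c(x = 1, y = 1, z = 1))
  expect_equal(length(unique(r1$otu_id)), 1L)
  # threshold 1 with distinct sequences: every ASV its own OTU
  r2 <- greedy_otu_cluster(seqs, ab, threshold = 1)
  expect_equal(length(unique(r2$otu_id)), 3L)
  expect_error(greedy_otu_cluster(seqs, ab, threshold = 0), "threshold")
})

test_that("clustering is invariant to input order and satisfies the radius", {
  set.seed(64)
  # 6 lineages x up to 4 variants, lengths ~ 150
  seqs <- character(); ab <- numeric()
  for (l in 1:6) {
    anc <- random_dna(1, 150)
    for (v in 1:sample(1:4, 1)) {
      id <- sprintf("L%d_v%d", l, v)
      seqs[id] <- if (v == 1) anc else mutate_at(anc, sample.int(150, 2))
      ab[id] <- runif(1, 1, 100)
    }
  }
  res <- greedy_otu_cluster(seqs, ab)
  perm <- sample(length(seqs))
  res_perm <- greedy_otu_cluster(seqs[perm], ab)
  expect_equal(res, res_perm)
  # every member within the threshold radius of its centroid (brute check)
  cent <- setNames(res$asv_id[res$is_centroid][
    match(res$otu_id, res$otu_id[res$is_centroid])], res$asv_id)
  for (id in res$asv_id)
    expect_gte(pairwise_identity(seqs[[id]], seqs[[cent[[id]]]]), 0.97)
  # membership equals the naive greedy oracle
  naive <- naive_greedy_cluster(seqs, ab, 0.97)
  got_cent <- setNames(res$asv_id[res$is_centroid][
    match(res$otu_id, res$otu_id[res$is_centroid])], res$asv_id)
  expect_equal(as.list(got_cent[names(naive)]), as.list(naive))
})

test_that("nearest-taxon closeness floors zeros and is antitone in distance", {
  d <- matrix(c(0, 0.1, 0.4,
                0.1, 0, 0.5,
                0.4, 0.5, 0), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  res <- nearest_taxon_closeness(d)
  expect_equal(res$nearest_distance[res$taxon == "a"], 0.1)
  expect_equal(res$closeness[res$taxon == "a"], -log(0.1), tolerance = 1e-12)
  expect_equal(res$closeness[res$taxon == "a"], 2.3026, tolerance = 1e-4)
  # d_min = 1 => closeness 0
  d1 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(nearest_taxon_closeness(d1)$closeness, c(0, 0))
  # zero distance floored to half the smallest positive distance
  dz <- matrix(c(0, 0, 0.02,
                 0, 0, 0.02,
                 0.02, 0.02, 0), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  rz <- nearest_taxon_closeness(dz)
  expect_equal(rz$closeness[rz$taxon == "a"], -log(0.01), tolerance = 1e-12)
  # antitone: larger minimum distance, smaller closeness
  expect_true(all(diff(order(res$nearest_distance)) ==
                    diff(order(-res$closeness))))
  expect_error(nearest_taxon_closeness(d1[1, 1, drop = FALSE]), "at least 2")
  # log base option
  expect_equal(nearest_taxon_closeness(d, log_base = 10)$closeness,
               res$closeness / log(10), tolerance = 1e-12)
  # tree input: patristic distances drive the result
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.2,c:0.3);")
  rt <- nearest_taxon_closeness(tr)
  expect_equal(rt$nearest_distance[rt$taxon == "a"], 0.1)
})

test_that("microdiversity summaries group by occurrence level correctly", {
  # hand-built assignment: 3 OTUs with 1, 2 and 3 members
  asn <- structure(data.frame(
    asv_id = c("a1", "b1", "b2", "c1", "c2", "c3"),
    otu_id = c("OTU1", "OTU2", "OTU2", "OTU3", "OTU3", "OTU3"),
    is_centroid = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    identity_to_centroid = 1, stringsAsFactors = FALSE),
    class = c("otu_assignment", "data.frame"))
  occ <- c(a1 = 1, b1 = 2, b2 = 1, c1 = 3, c2 = 3, c3 = 1)
  md <- microdiversity_by_occurrence(asn, NULL, occ)
  rec <- md$otu_records
  expect_equal(rec$n_asvs[rec$otu_id == "OTU3"], 3L)
  # OTU occurrence is the max over members
  expect_equal(rec$occurrence[rec$otu_id == "OTU2"], 2)
  sm <- md$summary
  expect_equal(sm$mean[sm$level == 3], 3)
  # all-singleton OTUs: counts identically one, no significant differences
  asn1 <- asn; asn1$otu_id <- paste0("OTU", 1:6); asn1$is_centroid <- TRUE
  md1 <- microdiversity_by_occurrence(asn1, NULL, occ)
  expect_true(all(md1$otu_records$n_asvs == 1L))
  expect_true(all(md1$summary$letters == "a"))
  expect_error(microdiversity_by_occurrence(asn, NULL, occ[1:3]), "missing")
})
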