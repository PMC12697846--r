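test_that("simulated metacommunities respect depth, determinism and truth labels", {
  cfg <- small_sim_config(seed = 21L)
  sim <- simulate_metacommunity(cfg)
  expect_true(all(colSums(sim$table$counts) == cfg$depth))
  expect_equal(length(habitats(sim$table)), cfg$n_habitats)
  # identical seed => identical output; different seed differs
  sim2 <- simulate_metacommunity(cfg)
  expect_identical(sim$table$counts, sim2$table$counts)
  expect_identical(sim$truth$nonnative_pairs, sim2$truth$nonnative_pairs)
  expect_false(identical(
    sim$table$counts, simulate_metacommunity(small_sim_config(seed = 22L))$table$counts))
  # truth never labels a taxon nonnative in its own source habitat
  nn <- sim$truth$nonnative_pairs
  expect_true(all(nn$habitat != sim$truth$source_habitat[nn$taxon]))
  expect_true(all(sim$truth$occurrence_count >= 1L &
                    sim$truth$occurrence_count <= cfg$n_habitats))
})

test_that("no dispersal means no nonnative pairs and no shared natives", {
  sim <- simulate_metacommunity(small_sim_config(seed = 4L, dispersal_rate = 0))
  expect_equal(nrow(sim$truth$nonnative_pairs), 0L)
  occ <- habitat_occurrence_count(sim$table)
  natives <- grep("^gen", names(occ), invert = TRUE, value = TRUE)
  expect_true(all(occ[natives] <= 1L))
})

test_that("zero colonist weight removes colonists from the count support", {
  sim <- simulate_metacommunity(
    small_sim_config(seed = 4L, colonist_abundance_factor = 0))
  nn <- sim$truth$nonnative_pairs
  expect_gt(nrow(nn), 0L)
  for (i in seq_len(nrow(nn))) {
    s <- samples_in_habitat(sim$table, nn$habitat[i])
    expect_true(all(sim$table$counts[nn$taxon[i], s] == 0L))
  }
})

test_that("planted colonists are rarer than natives in their sink habitats", {
  sim <- simulate_metacommunity(simulation_config(seed = 42L))
  prof <- habitat_profiles(sim$table)
  nn <- sim$truth$nonnative_pairs
  key <- paste(prof$taxon, prof$habitat)
  nn_rows <- prof[key %in% paste(nn$taxon, nn$habitat) & prof$present, ]
  nat_rows <- prof[prof$present &
                     sim$truth$source_habitat[prof$taxon] == prof$habitat, ]
  nat_rows <- nat_rows[!is.na(nat_rows$mean_rel_abundance), ]
  expect_lt(mean(nn_rows$mean_rel_abundance), mean(nat_rows$mean_rel_abundance))
})

test_that("generalists are detected in essentially every habitat", {
  sim <- simulate_metacommunity(simulation_config(seed = 8L))
  occ <- habitat_occurrence_count(sim$table)
  gens <- grep("^gen", names(occ), value = TRUE)
  expect_gte(mean(occ[gens] == 4L), 0.95)
})

test_that("sequence variants track occurrence and stay within one OTU radius", {
  cfg <- small_sim_config(seed = 13L)
  sim <- simulate_metacommunity(cfg)
  sq <- simulate_sequences(sim$truth, cfg)
  info <- sq$asv_info
  # zero variant rate: exactly one variant per lineage
  cfg0 <- small_sim_config(seed = 13L, variant_rate_per_occurrence = 0)
  sq0 <- simulate_sequences(sim$truth, cfg0)
  expect_true(all(table(sq0$asv_info$lineage_id) == 1L))
  # every variant within 2% of its lineage ancestor (identity >= 0.98)
  some <- info[info$n_mutations > 0, ][1:10, ]
  anc <- setNames(info$asv_id[!duplicated(info$lineage_id)],
                  info$lineage_id[!duplicated(info$lineage_id)])
  for (i in seq_len(nrow(some))) {
    idt <- pairwise_identity(sq$sequences[[some$asv_id[i]]],
                             sq$sequences[[anc[[some$lineage_id[i]]]]])
    expect_gte(idt, 0.98)
    expect_equal(idt, (cfg$seq_length - some$n_mutations[i]) / cfg$seq_length)
  }
  # variant counts rise with habitat occurrence across lineages
  per_lin <- table(info$lineage_id)
  occ <- sim$truth$occurrence_count[names(per_lin)]
  ct <- suppressWarnings(cor.test(as.numeric(per_lin), as.numeric(occ),
                                  method = "spearman"))
  expect_gt(unname(ct$estimate), 0)
  # the variant tree covers all ASVs and has usable branch lengths
  expect_setequal(sq$tree$tip.label, info$asv_id)
  expect_false(is.null(sq$tree$edge.length))
  expect_setequal(sq$taxon_tree$tip.label, names(sim$truth$lineage_of))
})

test_that("function tables plant exclusive cycle functions on colonists only", {
  cfg <- small_sim_config(seed = 5L, exclusive_cycle_fraction = 1)
  sim <- simulate_metacommunity(cfg)
  ft <- simulate_function_table(sim$truth, cfg)
  colonists <- unique(sim$truth$nonnative_pairs$taxon)
  cyc <- unlist(ft$sets, use.names = FALSE)
  carried <- cyc[colSums(ft$incidence[, cyc, drop = FALSE]) > 0]
  for (f in carried) {
    carriers <- rownames(ft$incidence)[ft$incidence[, f]]
    expect_true(all(carriers %in% colonists))
  }
  # with exclusive fraction 1, targeted removal strips all cycle functions
  ab <- setNames(rep(1, nrow(ft$incidence)), rownames(ft$incidence))
  ab[colonists] <- 0
  kept <- names(ab)[ab > 0]
  expect_equal(sum(colSums(ft$incidence[kept, cyc, drop = FALSE]) > 0), 0L)

  # exclusive fraction 0: cycle functions are open to all taxa
  cfg0 <- small_sim_config(seed = 5L, exclusive_cycle_fraction = 0)
  ft0 <- simulate_function_table(sim$truth, cfg0)
  cyc0 <- unlist(ft0$sets, use.names = FALSE)
  carriers0 <- rownames(ft0$incidence)[rowSums(ft0$incidence[, cyc0, drop = FALSE]) > 0]
  expect_gt(length(setdiff(carriers0, colonists)), 0L)

  # default config: at least one cycle function has >= 2 carriers at
  # positive patristic distance, so FR is positive before removal
  ftd <- simulate_function_table(sim$truth, small_sim_config(seed = 5L))
  sq <- simulate_sequences(sim$truth, small_sim_config(seed = 5L))
  d <- patristic_matrix(sq$taxon_tree)
  ab2 <- setNames(rowSums(sim$table$counts), rownames(sim$table$counts))
  frs <- vapply(unlist(ftd$sets, use.names = FALSE), function(f)
    functional_redundancy(ab2, ftd, d, f), numeric(1))
  expect_gt(max(frs), 0)
})

test_that("cycle sets larger than the universe are rejected", {
  expect_error(small_sim_config(function_universe = 30L, cycle_set_size = 10L),
               "exceed")
})
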