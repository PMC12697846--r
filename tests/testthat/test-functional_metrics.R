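# deterministic toy system: 4 taxa on a caterpillar tree, 5 functions
toy_funsys <- function() {
  ft <- function_table(
    taxon = c("t1", "t1", "t2", "t2", "t3", "t4", "t4", "t4"),
    fun = c("f1", "f2", "f1", "f3", "f4", "f2", "f4", "f5"),
    sets = list(C = c("f1", "f2"), N = "f4", P = "f3", S = "f5"))
  tree <- ape::read.tree(
    text = "(((t1:0.1,t2:0.1):0.2,t3:0.3):0.2,t4:0.5);")
  list(ft = ft, tree = tree)
}

test_that("functional richness is the union of present repertoires", {
  sys <- toy_funsys()
  expect_equal(functional_richness(c(t1 = 2, t2 = 3), sys$ft), 3L)  # f1,f2,f3
  expect_equal(functional_richness(c(t1 = 1, t3 = 1, t4 = 1), sys$ft), 4L)
  # identical repertoires add nothing
  ft2 <- function_table(c("a", "a", "b", "b"), c("f1", "f2", "f1", "f2"))
  expect_equal(functional_richness(c(a = 1, b = 1), ft2), 2L)
  # zero-abundance members do not contribute
  expect_equal(functional_richness(c(t1 = 1, t4 = 0), sys$ft), 2L)
  expect_warning(z <- functional_richness(setNames(numeric(), character()),
                                          sys$ft), "empty")
  expect_equal(z, 0L)
  # unannotated members are skipped with a message
  expect_message(functional_richness(c(t1 = 1, zz = 1), sys$ft), "lack")
})

test_that("functional redundancy matches its defining double sum", {
  sys <- toy_funsys()
  d <- patristic_matrix(sys$tree)
  # single carrier => 0
  expect_equal(functional_redundancy(c(t1 = 1, t3 = 1), sys$ft, d, "f2"), 0)
  # two equal-abundance carriers at normalized distance d: FR = 2*0.25*d
  ab <- c(t1 = 1, t2 = 1)
  expect_equal(functional_redundancy(ab, sys$ft, d, "f1"),
               2 * 0.25 * d["t1", "t2"], tolerance = 1e-12)
  # worked value: t1-t2 patristic 0.2, max pairwise = t4 vs t1/t2 = 1.0
  expect_equal(functional_redundancy(ab, sys$ft, d, "f1"), 0.1,
               tolerance = 1e-12)
  expect_error(functional_redundancy(c(t1 = 1, t2 = 1), sys$ft,
                                     ape::drop.tip(sys$tree, "t2"), "f1"),
               "t2")
})

test_that("FR equals the brute-force oracle on random communities", {
  set.seed(41)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    taxa <- paste0("x", seq_len(n))
    # random tree, random incidence, random abundances
    tree <- ape::rcoal(n, tip.label = taxa)
    d <- patristic_matrix(tree)
    carry <- taxa[runif(n) < 0.6]
    ft <- function_table(c(taxa, carry), c(rep("base", n), rep("fX", length(carry))))
    ab <- setNames(rpois(n, 8) + 1, taxa)
    got <- functional_redundancy(ab, ft, d, "fX")
    expect_equal(got, naive_fr(ab / sum(ab), carry, d), tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, 1)
  }
})

test_that("adding a dispersed carrier never decreases FR", {
  sys <- toy_funsys()
  d <- patristic_matrix(sys$tree)
  ft <- function_table(c("t1", "t2", "t4"), rep("g", 3))
  base <- functional_redundancy(c(t1 = 2, t2 = 2), ft, d, "g")
  # rescale existing members proportionally, add t4 with positive abundance
  grown <- functional_redundancy(c(t1 = 2, t2 = 2, t4 = 1), ft, d, "g")
  expect_gte(grown, base - 1e-12)
})

test_that("branch-length scaling cancels under normalization", {
  sys <- toy_funsys()
  ab <- c(t1 = 1, t2 = 2, t3 = 1, t4 = 3)
  fr1 <- functional_redundancy(ab, sys$ft, patristic_matrix(sys$tree), "f4")
  doubled <- sys$tree
  doubled$edge.length <- doubled$edge.length * 2
  expect_equal(functional_redundancy(ab, sys$ft, patristic_matrix(doubled), "f4"),
               fr1, tolerance = 1e-12)
  # without normalization every FR doubles
  raw1 <- functional_redundancy(ab, sys$ft,
                                patristic_matrix(sys$tree, normalize = FALSE), "f4")
  raw2 <- functional_redundancy(ab, sys$ft,
                                patristic_matrix(doubled, normalize = FALSE), "f4")
  expect_equal(raw2, 2 * raw1, tolerance = 1e-12)
})

test_that("cycle redundancy averages over the set, counting carrier-free functions", {
  sys <- toy_funsys()
  d <- patristic_matrix(sys$tree)
  ab <- c(t1 = 1, t2 = 1, t3 = 1, t4 = 1)
  # C = {f1, f2}: mean of the two per-function FR values
  expect_equal(cycle_redundancy(ab, sys$ft, d, "C"),
               mean(c(functional_redundancy(ab, sys$ft, d, "f1"),
                      functional_redundancy(ab, sys$ft, d, "f2"))),
               tolerance = 1e-12)
  # one-function set equals that function's FR
  expect_equal(cycle_redundancy(ab, sys$ft, d, "N"),
               functional_redundancy(ab, sys$ft, d, "f4"), tolerance = 1e-12)
  # set with no carriers present: 0
  expect_equal(cycle_redundancy(c(t1 = 1, t2 = 1), sys$ft, d, "S"), 0)
  expect_error(cycle_redundancy(ab, sys$ft, d, "Z"), "unknown function set")
})

test_that("functional removal comparison: no flags means identical scenarios", {
  sim <- simulate_metacommunity(small_sim_config(seed = 51L))
  cfg <- small_sim_config(seed = 51L)
  ft <- simulate_function_table(sim$truth, cfg)
  sq <- simulate_sequences(sim$truth, cfg)
  none <- data.frame(taxon = character(), habitat = character(),
                     nonnative = logical())
  res <- suppressWarnings(suppressMessages(removal_functional_comparison(
    sim$table, none, ft, sq$taxon_tree, replicates = 3L, seed = 1L)))
  expect_equal(res$per_sample$observed, res$per_sample$targeted)
  expect_equal(res$per_sample$observed, res$per_sample$random_mean)
  expect_true(all(res$stats$no_difference))
})
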