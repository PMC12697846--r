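# metasink

Source–sink analysis of multi-habitat microbiomes: niche breadth,
putative nonnative taxa, removal simulations, functional redundancy and
microdiversity.

## The problem

Connected landscapes — lakes, soils, sediments, plant and animal surfaces
within one ecosystem — continuously exchange microbes. A taxon adapted to
one habitat disperses into others, where it persists at low abundance
without establishing. `metasink` is for microbial ecologists who have a
taxon-by-sample count table spanning several habitats and want to:

* quantify each taxon's **Levins niche breadth** per habitat,

  $$B_j = 1 \Big/ \sum_{i=1}^{N} P_{ij}^2 ,$$

  where $P_{ij}$ is the proportion of taxon $j$'s reads in community
  $i$ of the habitat ($B = N$ for a perfectly even generalist, $B = 1$
  for single-sample occupancy), normalized within each habitat by the
  maximal breadth;
* flag **putative nonnative** (taxon, habitat) pairs by a strict
  three-part rule — lower relative abundance than in other habitats,
  lower normalized breadth than in other habitats, and lower normalized
  breadth than a quantile (default median) of co-occurring taxa;
* measure what those taxa contribute, via **targeted vs. random
  taxon-removal simulations** of taxonomic and functional richness
  (paired t-tests, Benjamini–Hochberg FDR) and a phylogeny-weighted
  **functional redundancy** index
  $\mathrm{FR}(f) = \sum_{i \ne j \in \text{carriers}(f)} p_i p_j d_{ij}$
  over C/N/P/S cycling gene sets;
* test whether cross-habitat taxa carry more **microdiversity**:
  greedy 97%-identity OTU clustering of ASVs, intra-OTU ASV counts,
  nearest-taxon closeness, and their association with habitat occurrence.

A fully seeded synthetic metacommunity generator with planted ground
truth (`simulate_metacommunity()`) makes every stage testable without
external data. See the vignette in `vignettes/` for the model and all
design decisions.

## Worked example

Simulate the default 4-habitat system (30 samples/habitat, 250 natives
per habitat plus 50 generalists, dispersal rate 0.15, colonists at 5% of
their home weight, 10 000 reads/sample), then classify and score against
the planted truth:

```r
library(metasink)
cfg <- simulation_config(seed = 42)
sim <- simulate_metacommunity(cfg)
sim$table
#> count_table: 1050 taxa x 120 samples in 4 habitat(s)
#>   samples per habitat: H1=30, H2=30, H3=30, H4=30

ct       <- rarefy(sim$table, "per-habitat-min", seed = 42)
profiles <- habitat_profiles(ct)
calls    <- classify_nonnative(profiles, quantile = 0.5)
unlist(evaluate_against_truth(calls, sim$truth))
#> n_eligible          tp          fp          fn   precision      recall          f1
#> 787.0000000 308.0000000  33.0000000   0.0000000   0.9032258   1.0000000   0.9491525
```

Of the 787 evaluable (taxon, habitat) pairs, the rule recovers every
detectable planted colonist (recall 1.0) at 90% precision. Per habitat,
roughly a fifth to a quarter of the detected taxon pool is flagged:

```r
summarize_nonnative(ct, calls)$per_habitat
#>   habitat n_pool n_flagged flagged_fraction
#> 1      H1    390       100        0.2564103
#> 2      H2    375        83        0.2213333
#> 3      H3    385        92        0.2389610
#> 4      H4    349        66        0.1891117
```

Removing the flagged taxa costs each sample a measurable slice of its
richness (normalized by the habitat maximum; `mean_a` = observed,
`mean_b` = after targeted removal):

```r
res <- compare_removals(ct, calls, replicates = 100, seed = 42)
subset(res$stats, comparison == "observed_vs_targeted",
       select = c(habitat, mean_a, mean_b, statistic, p_adjust))
#>    habitat    mean_a    mean_b statistic     p_adjust
#> 1       H1 0.9206430 0.8561760  19.46644 4.549609e-18
#> 4       H2 0.9008547 0.8504274  19.37202 4.668969e-18
#> 7       H3 0.9215168 0.8666667  18.30723 1.939674e-17
#> 10      H4 0.9107468 0.8648452  16.43746 3.098706e-16
```

The same interfaces are scriptable from a shell via the installed
wrapper (`system.file("exec", "metasink", package = "metasink")`), with
subcommands `simulate`, `breadth`, `classify`, `removal`, `funcmetrics`
and `microdiv`, each taking `--config`, `--seed` and `--out-dir`;
identical seed and config give byte-identical TSV outputs.

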