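# cryptomotu

Cryptic-diversity analysis of DNA barcodes by multi-method MOTU
delimitation.

A single morphospecies can conceal tens of deeply divergent mitochondrial
lineages. `cryptomotu` implements the full analysis chain used in
continental-scale COI barcode surveys of such *hyper cryptic diversity*:

- **Haplotype collapsing** of aligned barcodes over an analysis window
  (exact-string identity; `H0001`, ... in order of appearance).
- **Kimura two-parameter (K2P) distances** with pairwise deletion,
  `d = -1/2 · ln((1 - 2P - Q)·sqrt(1 - 2Q))` from transition (`P`) and
  transversion (`Q`) proportions, with a minimum-overlap floor and explicit
  handling of saturated (undefined) pairs.
- **Four MOTU delimitation methods**, each returning a `motu_partition`:
  - *ABGD-style*: recursive barcode-gap discovery over a log-spaced ladder
    of prior intraspecific distances (0.001–0.1), reporting the stable
    **primary partition**;
  - *RESL/BIN-style*: single-linkage at 2.2% with a 4.4% isolation rule,
    silhouette-based discontinuity refinement, and 500/300-bp
    sequence-length rules with flagged BIN-equivalent singletons;
  - *PTP*: Poisson tree processes on a non-ultrametric tree — two
    exponential branch-length classes (speciation vs coalescent) with
    rates `λ = n/L`; exact antichain search on small trees, deterministic
    multi-start hill climbing on large ones, plus a Bayesian MCMC variant
    with crown-subtree support;
  - *Lagrue*: sister clades diverging by more than 20% K2P are distinct
    MOTUs — a conservative bound calibrated on reproductive-isolation
    experiments.
- **Diversity statistics**: method concordance and nestedness, within-site
  syntopy, rare-MOTU frequency profiles, great-circle range-size classes
  (narrow < 100 km / broad / widespread > 1000 km), latitudinal bands and
  altitudinal summaries.
- **Chronogram tools**: strict-clock rescaling (default 0.0115
  substitutions/site/My) and lineage-through-time tables/plots.
- **Genetic landscapes**: Delaunay site network, edge-midpoint divergence,
  inverse-distance-weighted surfaces masked to the site hull, with an
  option to exclude highly divergent endemic lineages.
- **A synthetic barcode generator** with known ground truth, calibrated
  through the K2P inverse map, that reproduces the bimodal
  within/between distance structure real datasets show.

Everything is tibble-first and pipe-friendly; trees are `ape::phylo`
objects, distance matrices plain named matrices with `tidy()` methods.

## Worked example

Simulate a 12-lineage barcode dataset at the package's default study
conditions and run the full pipeline:

```r
library(cryptomotu)

sim <- simulate_barcodes(simulation_config(), seed = 42)
sim
#> <barcode_simulation> K=12 lineages, 60 sites, 551 individuals (seed 42)

haps <- collapse_haplotypes(sim$alignment)
m <- k2p_matrix(haps)
m
#> <k2p_dist> 72 haplotypes, 2556 pairs (0 undefined)

report <- run_pipeline(sim, seed = 1)
report
#> <pipeline_report>
#>   551 records -> 72 haplotypes
#>   MOTUs: ABGD=12, RESL=12, PTP=12, LAGRUE=12
#>   concordant MOTUs (ABGD/RESL/PTP): 12
#>   agreement vs truth: ABGD=1, RESL=1, PTP=1, LAGRUE=1
```

The 551 individuals collapse to 72 haplotypes whose 2556 pairwise K2P
distances are bimodal — 180 pairs fall below 0.05 (within-lineage), 2376
above 0.15 (between-lineage), and none in the barcode gap between. All
four delimitation methods therefore recover exactly the 12 simulated
lineages, with chance-corrected agreement (adjusted Rand index) of 1
against the ground truth, and all 12 MOTUs are concordant across methods.

Per-method syntopy — the share of multi-individual sites hosting two or
more MOTUs — reflects the generator's 30% two-lineage site probability:

```r
report$syntopy
#> # A tibble: 4 × 5
#>   method n_sites n_eligible pct_syntopy n_sites_ge_k
#>   <chr>    <int>      <int>       <dbl>        <int>
#> 1 ABGD        60         56        32.1            0
#> 2 RESL        60         56        32.1            0
#> 3 PTP         60         56        32.1            0
#> 4 LAGRUE      60         56        32.1            0
```

Useful building blocks behind the pipeline:

```r
plot_distance_histogram(m)          # bimodal distance distribution
abgd  <- delimit_abgd(m)            # per-prior partitions + primary
resl  <- delimit_resl(m)            # BIN-style clusters
tree  <- nj_tree(m)                 # midpoint-rooted NJ surrogate
ptp   <- delimit_ptp(tree)          # ML Poisson tree processes
lagr  <- delimit_lagrue(tree, m)    # sister-clade 20% rule
ltt   <- ltt_table(rescale_to_time(chronogram))   # needs an ultrametric tree
edges <- delaunay_network(sim$sites)              # genetic landscape
```

Real data enter through `read_barcode_fasta()` (headers `record_id|site_id`
or a record-to-site TSV), `read_site_table()` and `read_tree_newick()`;
`trim_to_window(aln, start, length)` restricts the alignment to the
analysis window before collapsing.

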