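---
title: "Delimiting cryptic diversity from DNA barcodes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting cryptic diversity from DNA barcodes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptomotu)
```

`cryptomotu` implements a complete analysis chain for cryptic-diversity
surveys based on mitochondrial COI barcodes: haplotype collapsing, Kimura
two-parameter (K2P) distances, four complementary MOTU (Molecular
Operational Taxonomic Unit) delimitation methods, concordance and
geography-aware diversity summaries, strict-clock chronogram utilities, and
interpolated genetic-landscape surfaces. This vignette explains the models
behind each stage, the parameters that matter, and the design decisions
taken where the methodological literature leaves choices open.

## The problem

A single morphospecies can hide tens of deeply divergent mitochondrial
lineages — hyper cryptic diversity. Detecting it from barcodes relies on the
*barcode gap*: within-species pairwise distances concentrate near zero
while between-species distances concentrate far higher, leaving a sparsely
populated interval between the two modes. Different delimitation methods
exploit this signal differently, and their disagreement is itself a result:
the spread between a conservative distance-based count and a fine-grained
clustering count brackets the plausible number of species hypotheses.

## Distances

Pairwise distances use the K2P model: with transition proportion $P$ and
transversion proportion $Q$ over the comparable sites of a pair,

$$d = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big).$$

Comparable sites are those where *both* sequences carry an unambiguous
A/C/G/T (pairwise deletion). Pairs with fewer than `min_overlap` comparable
sites (default 300 nt, the same floor used for MOTU assignability of short
sequences) or with a non-positive log argument (saturation) are *undefined*:
they are excluded from histograms and gap detection and carried in the
matrix as `NA`. Datasets mixing full-length and partial barcodes make both
rules necessary; complete deletion would discard most of the alignment.

## The four delimitation methods

**ABGD-style barcode-gap discovery.** For a prior maximum intraspecific
distance $p$, sort the defined pairwise distances and scan consecutive
intervals. The baseline increment $b$ is the 95th percentile of consecutive
differences among distances at or below $p$ ($b = 0$ if there are fewer
than two such distances). A candidate gap must end at or above $p$ and be
wider than $X \cdot \max(b,\, p/10)$ with $X = 1.5$; the widest qualifying
interval wins (ties toward the smaller threshold) and the matrix is split
into single-linkage components at the gap's lower edge. The rule is applied
recursively inside every group until no gap qualifies, then repeated for a
log-spaced ladder of priors (default 10 values from 0.001 to 0.1). The
*primary partition* is the one stable over the longest contiguous run of
priors, ties resolved toward larger priors. Two remarks. First, the
candidate condition is on the *upper* endpoint of the interval: distances
below the prior are presumed intraspecific, so a legitimate gap starts
inside the intraspecific cloud and ends above the prior. Second, at priors
below the dataset's within-group spread there are no intraspecific
distances to calibrate $b$, and the recursion will over-split tight
clusters — the reference method behaves the same way, and it is exactly why
the primary (stability-based) partition, not any single-prior partition, is
the reported answer.

**RESL/BIN-style clustering.** Single-linkage clustering at 2.2%
(`t_intra = 0.022`), then an isolation rule: clusters whose minimum
separation is at or below twice the threshold (`t_isolation = 0.044`) merge
unless the merged set shows an internal discontinuity. Clusters are then
refined: the top cut of each cluster's single-linkage dendrogram is split
off whenever its mean silhouette reaches `silhouette_min = 0.5`, applied
recursively — so a cluster with clear internal partitions splits even when
the separation is below 2.2%, while a high-variation cluster without
discontinuity stays whole. The discontinuity statistic in the reference
implementation is not published; mean silhouette over dendrogram cuts is
the standard discontinuity surrogate and keeps the procedure deterministic
and order-independent. Sequence-length rules mirror registry practice: only
sequences of 500+ called bases found clusters, sequences of 300–499 bases
join the cluster of their nearest full-length neighbour when that distance
is at most `t_intra` and otherwise become flagged "BIN-equivalent"
singleton MOTUs, and anything shorter is rejected with a report.

**Poisson tree processes (PTP).** On a rooted, binary, non-ultrametric
tree in substitutions/site, a delimitation is an antichain of *crown nodes*
covering all tips. Branches strictly inside crown subtrees form the
within-species (coalescent) class, all others the speciation class; each
non-empty class of $n$ branches with total length $L$ contributes
$n\ln(n/L) - n$ at the plug-in MLE rate $\hat\lambda = n/L$ of an
exponential branch-length model. The ML search is exact where feasible — a
dynamic program enumerates every tip-covering antichain when their number
is at most 20 000 (all trees used in oracle comparisons fall in this
range) — and otherwise uses deterministic hill climbing with split and
merge moves from multiple starts: the single-species state, the all-tips
state, and branch-length-threshold seeds (maximal subtrees whose internal
edges all sit at or below each value of a 20-step threshold ladder).
The multiple starts matter: because both rates are global, the likelihood
surface over the antichain lattice is multimodal, and a split-only greedy
walk from the root demonstrably stalls far from the optimum on strongly
structured trees. Likelihood ties (which arise exactly, e.g. on
equal-branch-length trees) resolve toward fewer MOTUs. The Bayesian variant
runs Metropolis–Hastings over delimitations with the same split/merge
moves, Hastings-corrected for the number of moves available in each state;
defaults follow common practice (500 000 iterations, 10% burn-in, three
runs whose modal MOTU counts are compared for convergence; disagreement
beyond 10% warns rather than fails). Support values are post-burn-in
frequencies of each crown subtree. Because a maximum-likelihood tree is
often unavailable, `nj_tree()` provides a midpoint-rooted neighbour-joining
surrogate built from the K2P matrix; this is a documented surrogate, not a
substitute for proper tree inference, and any user Newick is accepted.

**Lagrue sister-clade rule.** Mate-choice experiments place the onset of
pre-zygotic reproductive isolation between roughly 4% K2P (random mating)
and 16% (near-complete isolation); a conservative operational species
bound therefore splits sister clades diverging by more than 20% K2P.
Implementation: post-order agglomeration in which the two child clades of a
node merge only when each is still a single group and their between-clade
distance is at or below the cutoff. The conservative "no merge past a
multi-group child" rule guarantees every MOTU is a clade. The between-clade
summary defaults to the mean over defined pairs (`linkage = "mean"`), with
`"min"` available; the mean is less sensitive to single outlier haplotypes
on clade boundaries.

## Chronograms and diversification

`rescale_to_time()` converts an ultrametric tree in substitutions/site to
My by dividing branch lengths by a strict clock rate, default 0.0115
substitutions/site/My — the conventional arthropod COI rate. Ultrametricity
is checked to a relative tolerance of $10^{-6}$ of tree height.
`ltt_table()` emits the lineage-through-time series: one event per internal
node, counts rising from 2 after the root to the tip count at the present.

## Geography

Site-level summaries run per delimitation method. *Syntopy* is the
percentage of sites holding two or more MOTUs among sites with at least 2
sampled individuals (singleton sites cannot show co-occurrence).
*Rare-MOTU profiles* use sites with more than 10 individuals and at least
two MOTUs: a monomorphic site has no rare MOTU, so it is excluded from the
denominator — the operational reading of "rare MOTU" is the least-frequent
MOTU at a site, and both choices are configurable. *Range classes* use the
maximum great-circle distance (haversine, Earth radius 6371 km) among a
MOTU's sites: narrow below 100 km, broad to 1000 km, widespread beyond.
Latitudinal profiles count a MOTU once per half-open 0.5° band where it
occurs; altitudinal box-plot summaries cover MOTUs present at three or more
sites.

The genetic landscape connects sites by planar Delaunay triangulation on
(lon, lat), places each edge's mean cross-site K2P divergence
(individual-weighted by default) at the edge midpoint, and interpolates the
midpoints onto a lattice by inverse-distance weighting with exponent 2,
masking cells outside the sites' convex hull. IDW over all midpoints
replaces the TIN rendering step of GIS pipelines: it is single-pass,
deterministic, and preserves the two properties the maps rely on — exact
values at midpoints and surface values bounded by the input extremes.
Treating longitude/latitude as Euclidean is standard in landscape-genetics
software and acceptable for a visualisation surface at continental extent;
it is a documented limitation, not a geodetic claim.

## The synthetic generator

`simulate_barcodes()` produces data with the statistical structure the
analysis assumes, plus full ground truth. A uniform-random root sequence
spawns `n_lineages` founders by sprinkling a fixed number of substitutions
under a two-rate kernel (transition:transversion hit ratio
`ts_tv_ratio = 4`); the count is calibrated through the K2P inverse map — a
per-site Markov chain over relative states with a Poisson number of hits —
so the expected pairwise founder divergence equals `target_between`
(default 0.22). Each founder then spawns a haplotype pool (default 6,
founder included) at expected pairwise divergence `target_within` (default
0.02). The defaults reproduce the bimodal distance distribution of real
hyper-cryptic datasets: a small within mode near 0.02–0.03, a dominant
between mode near 0.22, and an essentially empty gap between 0.08 and 0.15.
Geography is block-contiguous: lineages occupy consecutive longitude
blocks, emulating endemism, and a site hosts a second, block-adjacent
lineage with probability `syntopy_prob` (default 0.3), so syntopy and
landscape hotspots concentrate at block borders. Per-site sample sizes are
overdispersed (negative binomial, mean 10, minimum 1). All randomness
derives from one seed; identical seeds give byte-identical output.

What the generator does *not* emulate: among-site rate heterogeneity,
codon structure, saturation beyond the K2P model, within-lineage
population structure, migration, or recombination. Tests passing on this
generator therefore demonstrate that the pipeline recovers the structure it
is designed to detect — clean deep splits with shallow internal diversity —
not that it resolves the harder regimes (incomplete barcode gaps,
ring-like continua) where delimitation methods genuinely disagree.

Fixed-count substitution sprinkling (rather than Poisson counts per
branch) keeps realized divergences concentrated at their targets. Even so,
realized founder-pair distances vary around 0.22; at the default
conditions a rare seed can place one sister-lineage pair's mean divergence
marginally below the 0.20 Lagrue cutoff, or make an over-split ABGD ladder
run longest, which is the honest behaviour of those rules near their
decision boundaries.

## Parameter recovery

At the default study conditions (12 lineages, 60 sites, 530-nt barcodes,
within 0.02 / between 0.22), all four methods — ABGD primary, RESL, PTP-ML
on the NJ surrogate, and Lagrue — recover the simulated lineages exactly,
with chance-corrected agreement (adjusted Rand index) of 1.0 against
truth:

```{r recovery, eval = FALSE}
sim <- simulate_barcodes(simulation_config(), seed = 42)
report <- run_pipeline(sim, seed = 1)
report$motu_counts
report$truth
```

The test suite asserts this end to end, checks the component algorithms
against independent oracles (brute-force union-find for single-linkage
components, exhaustive antichain enumeration for PTP, brute-force set
intersection for concordance, `ape::dist.dna` and `geosphere` for the
closed forms), and verifies the monotonicity and conservation laws the
statistics obey (MOTU counts non-increasing in thresholds, syntopy
non-increasing under nested coarsening, histogram totals conserving pair
counts, IDW surfaces bounded by their inputs).

## Numerical choices and problem sizes

Tolerances: likelihood ties and hill-climb acceptance use $10^{-12}$;
exact-search tie grouping uses $10^{-9}$; ultrametricity uses a relative
$10^{-6}$. Degenerate inputs error early with typed conditions
(`cm_*` classes) naming the offending records, sites or labels. Test and
example problem sizes (tens of sites, a dozen lineages, hundreds of
individuals) are chosen so the whole suite exercises every code path in
seconds while remaining statistically meaningful; every algorithm scales to
continental datasets (hundreds of sites, hundreds of haplotypes) in
minutes, with the K2P matrix computed by dense indicator-matrix products
rather than per-pair loops.

## Known limitations

- The RESL discontinuity surrogate (silhouette over dendrogram cuts) is a
  reasoned stand-in for an unpublished registry algorithm; identity with
  registry BIN assignments is not claimed.
- PTP beyond the exact-search regime is a deterministic heuristic; a
  better optimum than its multi-start hill climb cannot be ruled out.
- The Bayesian PTP sampler uses the profile (plug-in MLE) likelihood
  rather than integrating over rates; support values are comparative, not
  calibrated posterior probabilities.
- Landscape interpolation is planar and visual; no geodetic or
  statistical interpolation guarantees are implied.
- The Lagrue rule inherits the uncertainty of its reproductive-isolation
  calibration; its 0.20 default is deliberately conservative.
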