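---
title: "Methods: diversity, core partitioning and phylogenetic null models for mat communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, core partitioning and phylogenetic null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Hypersaline microbial mats pack thousands of amplicon sequence variants
(ASVs) into centimetres of space. Their community structure is typically a
tiny core of high-read-count taxa present at every site, carrying most of
the sequencing reads, sitting on a very long tail of rare taxa (each under
1% relative abundance) with patchy spatial occupancy. Two questions drive
the analysis this package implements for a ~10-sample transect across such
a mat:

1. **Partition structure.** How small is the shared core, how much of the
   read mass does it carry, and how do rare and abundant subcommunities
   differ in richness and phylogenetic diversity?
2. **Assembly process.** Are the taxa of a sample (or of its rare/abundant
   subcommunities) phylogenetically *clustered* — more closely related than
   a random draw of equally many taxa — which is the classic signature of
   environmental filtering, or *overdispersed*, or indistinguishable from
   chance?

`rarephylo` provides the full chain: seeded rarefaction, alpha/beta
diversity with UPGMA clustering, Mantel tests against transect geography,
shared-core intersection counts, rare/abundant partitioning, Faith's PD and
PSC, and a randomization null model producing standardized effect sizes.

## Metrics

**Faith's Phylogenetic Diversity (PD)** of a taxon set is the total branch
length of the minimal subtree connecting the set, here extended to the tree
root by default (`include_root = TRUE`). The root convention matters: PD of
a single taxon is then its root-to-tip distance rather than zero, and PD
values are only comparable across tools under a fixed convention. The
common amplicon toolchains include the root, so that is the default; the
flag is recorded in the metric's arguments rather than hidden.

**Phylogenetic Species Clustering (PSC)** starts from the phylogenetic
correlation matrix: \(V_{ij}\) is the branch length shared by the
root-to-tip paths of taxa *i* and *j* (the depth of their most recent
common ancestor along the tree), and
\(C_{ij} = V_{ij} / \sqrt{V_{ii} V_{jj}}\). Then

\[\mathrm{PSC} = 1 - \frac{1}{n}\sum_i \max_{j \neq i} C_{ij}.\]

PSC near 0 means every taxon has a very close relative in the set
(clustering); a star phylogeny gives exactly 1. The correlation form makes
no ultrametricity assumption, which matters because amplicon trees
(FastTree on short reads) are not ultrametric. Both metrics are
presence-based: the taxon set of a sample is its ASVs with nonzero count.

Internally both metrics are linear-algebraic operations on a sparse
tip-by-edge incidence matrix built once per tree (`phylo_edge_index()`);
for trees up to a few thousand tips the full tip correlation matrix is
cached, which is what makes 1,000-replicate null distributions cheap.

## Rare/abundant partitioning

Two rules, matching the two scales on which "rare biosphere" is used:

* **Per-site quartile rule** (`quartile_partition()`): for each sample, the
  first and third quartiles of its *nonzero* read counts (low to high)
  define thresholds; rare = counts ≤ Q1, abundant = counts ≥ Q3, ties
  included on both sides. Quartiles use the nearest-rank estimator so the
  thresholds are observed integer read counts; an interpolating (type 7)
  estimator is available behind a flag for sensitivity analysis — on
  integer count data the two differ by at most the gap between adjacent
  order statistics. Zero counts are excluded because an absent ASV is not
  part of a site's abundance distribution. Q1 = Q3 (e.g. all counts equal)
  is flagged degenerate rather than silently producing overlapping sets.
  `balance_partition()` optionally equalizes the two set sizes by seeded
  subsampling of the larger, for comparisons at an equivalent ASV number
  per site.
* **Whole-table relative abundance** (`relabund_partition()`): a unit (ASV
  or, via a taxonomy table, genus) is abundant when it carries more than
  `threshold_pct` (default 1%) of all reads in the table.

## The richness null model and nmdPSC

The null model randomizes each sample independently: the multiset of its
nonzero counts is reassigned to a uniformly random subset of the full ASV
pool of the same size. This conserves, per sample, richness, total reads
and the count multiset — "total sample diversity" — while destroying taxon
identity, which is exactly what a phylogenetic clustering test must
randomize. For each sample the observed metric is compared with
`n_replicates` (default 1,000) null values:

\[\mathrm{SES} = \frac{\mathrm{obs} - \overline{\mathrm{null}}}{\mathrm{sd}(\mathrm{null})}\]

with SES < −2 labelled *clustered*, > +2 *overdispersed*, boundary values
and everything between *null*. When PD/PSC are evaluated on rare/abundant
subcommunities, the quartile rule is **re-derived inside every replicate**
from the randomized matrix, keeping the null internally consistent.

A frozen variant (`freeze_subsets = TRUE`) mirrors the alternative workflow
of handing the null model pre-built rare and abundant matrices: the
observed partition is frozen, each subset's counts form their own community
matrix, and the randomization pool is restricted to that subset's ASV union
across samples. Holding the observed taxon *sets* literally fixed is not
offered: PD and PSC depend only on the set, so that "null" has zero
variance and SES is undefined; `ses_metric()` detects any such degenerate
null (sd = 0) and returns a flagged, non-fatal row labelled `null`.

Small subsets can also make the metric undefined (PSC needs ≥ 2 taxa on
the tree); those replicates contribute `NA` and are excluded from the null
moments. ASVs missing from the tree are dropped from the metrics with a
logged count but stay in the randomization pool, so tree/table mismatch
does not distort the null.

## The synthetic-data generator

`simulate_communities()` emulates the mat's structure; its defaults *are*
the study conditions the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 10 | sites along the 1.5-m transect |
| `n_taxa` | 1,000 | ASV pool size (scaled from the study's thousands) |
| `depth` | 100,000 | reads per sample (scaled similarly) |
| `core_size` | 3% of taxa | abundant shared core |
| `core_read_fraction` | 0.725 | expected read share of the core |
| `abundance_shape` | 1.5 | lognormal sigma of the rare tail |
| `occupancy_rare` | 0.35 | per-sample occurrence probability of a rare ASV |
| `abundant_placement` | random | `clade` plants phylogenetic clustering |

Mechanism: core ASVs get lognormal (sigma 0.5) weights fixed across samples
— the core is the stable dominant community; rare ASVs get lognormal
(sigma `abundance_shape`) weights and occur in each sample independently
with probability `occupancy_rare`; per sample the core block is normalized
to `core_read_fraction`; counts are one multinomial draw per sample at
`depth` reads after reserving one read per core ASV, which makes per-sample
totals exact and guarantees the core is present everywhere. With
`occupancy_rare = 0.35` a rare ASV is in all ten samples with probability
\(0.35^{10} \approx 3\times10^{-5}\), so the realized all-sample core is
essentially the planted one — a ~3% core carrying ~72.5% of reads, the
structure observed in the mat. The tree is a pure-birth (Yule) simulation.

`abundant_placement = "clade"` draws the core from the smallest clade
containing at least `core_size` of the community's tips, giving the
null-model tests a dataset whose abundant subcommunity is clustered by
construction.

What the generator does **not** emulate: taxonomic composition, sequencing
noise and chimeras, spatial autocorrelation along the transect (samples are
exchangeable, so Mantel r is expected to be ~0 on synthetic data), and
abundance correlations within the rare tail. Tests passing on synthetic
data therefore validate the *computations* and the recoverability of
planted structure, not any biological claim about real mats.

## Validation experiments and problem sizes

The experiments the test suite and `scripts/acceptance.R` run, with the
sizes chosen to keep each at desk scale:

* **Metric oracles.** PD and PSC agree to 1e-9 with brute-force
  path-enumeration implementations (independent code paths built on
  `ape::nodepath`) on 100 random 8-tip non-ultrametric trees, alongside
  hand-computed cherry/star examples; `picante`'s `pd` and `psc` are
  cross-checked on a simulated community.
* **Null calibration.** 200 samples that are themselves richness-null
  draws are scored with 1,000-replicate SES: the SES distribution must be
  centred (|mean| < 0.15), unit-spread (sd in [0.8, 1.25]) and rarely
  beyond ±2 (≤ 10%).
* **Parameter recovery.** 25 datasets (10 samples, 300 taxa, 20,000 reads)
  with clade-placed cores of 30 taxa. The core is sized to the expected Q3
  set (~richness/4) deliberately: the recovery target is a *clustered
  abundant subcommunity*, and with a much smaller clustered core the
  abundant quartile would be dominated by scattered tail taxa and carry no
  planted signal to recover. Success = the sample-median abundant-subset
  PSC SES below −2; required in ≥ 80% of datasets, and rare-subset PD must
  exceed abundant-subset PD in every dataset.
* **Exhaustive Mantel.** On 4-label matrices the test enumerates all 24
  joint permutations, and the reported p must equal the directly
  enumerated value; with larger label sets the usual
  \((1 + \#\{r_\pi \ge r\})/(n_{\mathrm{perm}}+1)\) estimate is used. The
  switch is automatic whenever \(n! \le n_{\mathrm{perm}}\).

## Numerical and design choices

* Counts stay integers until a ratio is computed; rarefaction is a single
  seeded multivariate-hypergeometric draw per sample (subsampling without
  replacement), and samples below the target depth are an error by default
  (droppable by flag).
* The Shannon log base is an explicit recorded parameter (base 2 and base
  e are both in common toolchain use); `pipeline_config()` presets pair
  base 2 with the 760,000-read rarefaction depth and base e with the
  164,820-read depth.
* The Mantel test is one-sided (greater), Pearson by default with Spearman
  as an option.
* UPGMA uses average-linkage `hclust`; merge heights are half the average
  between-cluster distance, so two samples at distance *d* merge at height
  *d*/2. Tie handling is `hclust`'s deterministic rule, so identical input
  always yields identical trees.
* Every stochastic function takes an explicit seed; `run_pipeline()`
  derives fixed per-stage substreams (seed + 1 rarefaction, + 2 Mantel,
  + 3 whole-sample SES, + 4 subset SES) so a single config seed makes the
  whole bundle byte-reproducible.
* Orientation of community tables is auto-detected against the tree's tip
  labels (overridable), and trailing non-numeric taxonomy columns are split
  off rather than coerced.

## Known limitations

* The null model is the richness null only; swap-type and
  frequency-preserving nulls are out of scope, as are other phylogenetic
  community metrics (MPD/MNTD, UniFrac) and ordination.
* PSC on very small subsets (2–3 taxa) is noisy and its null can be
  near-degenerate; results carry the replicate count and degenerate flag
  so such rows are identifiable.
* The generator's independence assumptions (rare occupancy independent
  across samples and taxa) make synthetic Mantel tests uninformative by
  design; geographic structure must come from real data.
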