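---
title: "Models and methods behind xenocensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xenocensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models, the decision rules, the
tunable parameters and the deliberate simplifications in `xenocensus`. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## 1. The species-tagged hybrid namespace

All computation starts from counts over a *hybrid* gene namespace: the
union of a human and a pig gene panel, each display name prefixed by its
genome tag (`hg38-`, `ss11-`). The same symbol may legitimately appear
once per species (`hg38-CD19` and `ss11-CD19` are distinct features). The
species tag is parsed as the prefix before the first hyphen; features
without a recognizable tag are a hard error, because every downstream
statistic partitions counts by species.

## 2. Species assignment

Two independent classifiers are implemented, mirroring the two ways a
mixed-species experiment can be read.

**Majority transcript species.** Per barcode, transcripts are summed by
species; purity is the majority fraction and the call is the argmax
(`tie` on exact equality — a tied cell cannot be "associated with a
single species" and is excluded from the single-species transcript
numerator). The transcript-level summary reports the fraction of all
transcripts belonging to their cell's majority species, and the fraction
of cells whose purity strictly exceeds 0.90. Both comparisons are strict
because the underlying rules are phrased as strict inequalities
(">90%"). Zero-count barcodes have undefined purity; they are flagged
and excluded from summaries rather than silently dropped.

**Modified-reference gene ratio.** A pure sample of species A mapped
against species B's panel reveals B genes that attract cross-mapped reads
through sequence homology. Any B gene with a *summed* count above 3
across the whole sample is removed from B's reference. Summation over the
sample (rather than per cell) is deliberate: the calibration input is a
bulk-like pure library, and a per-cell rule would scale with cell number.
The boundary is strict — 3 cross-mapped counts retain a gene, 4 remove
it. Cells are then classified by the ratio r of genes detected (count at
least 1) under each species' modified reference: porcine if r < 0.75,
human if r > 1.33, ambiguous between them. Detection counts rather than
summed counts make the ratio robust to library size. Degenerate
denominators follow the rule's limits: no pig genes with human genes
present gives r = +Inf (human); the mirror case gives r = 0 (porcine);
no genes at all is ambiguous and flagged unassignable.

Concordance between the two classifiers is the agreement fraction over
barcodes that both call unambiguously, with the full 3x3 confusion matrix
retained; it is symmetric in its arguments.

**Cross-mapping diagnostics.** For a cluster with an assigned species,
the report gives the fraction of its reads on opposite-species genes and
ranks the offending genes by count. Because "how many genes carry the
leak" depends on an inclusion criterion the analyst must choose, the
report exposes two: all opposite-species genes with nonzero counts, and
the minimal top set explaining 90% of the leaked counts
(`cum_cutoff`, configurable).

## 3. Census

QC follows the standard droplet workflow with every threshold strict:
cells with fewer than 200 or more than 3000 unique features, more than
12% mitochondrial expression, or a doublet score above 0.3 are removed,
then genes expressed in fewer than 5 retained cells. A single-nucleus
profile (`qc_thresholds(profile = "snrna")`: feature cap 2500,
mitochondrial cap 15%) is provided as a configuration variant rather than
a separate module. Doublet scores are consumed as an input column — the
workflow names a cutoff, not a detection algorithm, so the generator
supplies a calibrated stand-in score.

Normalization is `log(1 + 10000 * count / cell_total)`; it preserves
sparsity, within-cell rank order, and is invariant to scaling a cell's
counts. Variable genes are ranked by the coefficient of variation of the
*log-normalized* values (variable features are computed after
log-normalization in this workflow), descending, ties broken by gene
name; genes with zero mean sort last. Embedding centers and scales the
variable genes (values clipped at +/-10 — a standard guard against a
single cell dominating a component), takes 30 principal components,
builds a k-nearest-neighbor graph (k = 20), weights edges by the Jaccard
overlap of neighbor sets including self (pruned below 1/15), and
optimizes modularity with Louvain at resolution 0.8. k, resolution, the
clip value and the prune threshold are not dictated by the workflow being
emulated; the defaults are the common single-cell toolchain values and
all are exposed. Clustering is deterministic given the seed.

Markers use a one-vs-rest Wilcoxon rank-sum test per gene (normal
approximation with tie and continuity corrections, verified in the test
suite against `stats::wilcox.test`), BH-adjusted within cluster, with the
log fold-change computed on the de-logged scale with a pseudocount of 1.

## 4. M1/M2 polarization scoring

The module score of a gene set is the per-cell mean expression of the set
minus the mean of control genes drawn from the same average-expression
strata: all genes are cut into `n_bins = 24` equal-frequency bins by
their data-wide average, and `n_ctrl = 100` controls are sampled (with
replacement, seeded) from each set gene's bin. The defaults follow the
common implementation of this scoring method; neither value is dictated
by the emulated workflow, and both are configurable. Two properties are
tested: a set whose genes track their bins' averages scores ~0, and
adding a constant to every gene of every cell leaves scores unchanged.

Scoring is species-stratified: each species' cells are scored against
its own tagged gene lists within its own gene space, because the two
species' gene spaces are disjoint under the hybrid namespace and a
cross-species bin would pair genes with structurally zero counts.
Scores are computed over *all* cells of a species (so the expression bins
span the full census) and the M2-vs-M1 comparison is then read off the
macrophage subset: per group, mean scores, the fraction of cells with
score(M2) > score(M1), and a Wilcoxon signed-rank test of the difference.

The shipped M1/M2 lists are canonical polarization markers from the
macrophage literature (the study this workflow emulates used a custom
list that is not reprinted in the available text); any two-column
(set, gene) file can replace them.

## 5. Spatial census

The expected cell density is the arithmetic mean of manually counted
nuclei in a sample of capture spots — a deliberately simple estimator
(`estimate_cells_per_spot()`).

Reference signatures are per-type means of library-size-normalized
expression (target 10,000), flagged low-confidence under 10 cells. This
is a deterministic surrogate for regression-based signature estimation.

Deconvolution is a declared surrogate for the Bayesian
cell-abundance model used in the emulated workflow (whose detection
efficiency hyperparameter, training schedule and posterior summaries are
out of scope): per spot, the normalized count vector over the genes
shared with the signatures — mitochondrial genes removed first — is
regressed on the signature rows by non-negative least squares
(`pracma::lsqnonneg`; tests verify it against an exhaustive active-set
solve), and coefficients are rescaled to sum to the expected cells per
spot. The outputs are *relative composition scaled to a density*, not
posterior cell counts, and are labeled surrogate throughout. Non-
negativity, objective monotonicity and gene-permutation invariance are
tested invariants.

For cell types too depleted to contribute signatures (human T and B
cells under effective depletion therapy), presence is imputed per spot
from individual tagged markers (`hg38-CD3E`, `ss11-CD19`, `hg38-CD19` by
convention) with a count threshold of 1; absent markers are reported,
not fatal.

## 6. The synthetic barnyard generator

Because the emulated study's sequencing data are not public, validation
rests on a generator whose draws have complete ground truth.

**Expression model.** Each species panel carries lognormal baseline
weights (meanlog 0, sdlog 1). Cell types boost program blocks over
baseline; a cell's counts are a multinomial draw over its species panel
with a lognormal library size (meanlog log(5000), sdlog 0.35, floored at
50) and per-gene gamma multipliers (mean 1, variance 0.3), giving
negative-binomial marginals. The macrophage program in both species
encodes the alternatively activated phenotype: marker block 8-fold up,
M2 block 4-fold up, M1 block 2-fold *down* — matching a population whose
anti-inflammatory signature is elevated while pro-inflammatory genes are
diminished. The first ten canonical M1 and M2 markers double as the
planted polarization blocks, and CD3E/CD19 lead the T/B blocks so
marker imputation is exercised end to end.

Baseline weights are drawn from a separate `program_seed` (fixed by
default) rather than the dataset seed: the baselines are the "organism",
and a dissociated reference and a spatial section of the same tissue must
share them for signature transfer to be meaningful. The dataset `seed`
controls all sampling noise.

**Contamination channels.** (1) *Homolog cross-mapping*: configurable
pairs link positional partners across species; each read on a pair
member moves to its partner with probability `cross_map_prob`
(default 0.02). Reassignment is count-conserving by construction.
(2) *Soup*: after cross-mapping, a binomial `soup_fraction` share
(default 0.02) of each cell's counts is replaced by draws from the
pooled profile of all drawn cells (the library-size-weighted mean
profile); per-cell totals are conserved exactly and the realized
fraction is recorded in the truth table. (3) *Doublets*: a
`doublet_rate` fraction (default 0.05) of barcodes is the sum of two
independently drawn cells; truth records the species of the
larger-library member (also the species a majority-transcript call
converges to) and both member types. True doublets score 1 on the
doublet axis, singlets |N(0, 0.1)| clipped to [0, 1]. (4) *Dying cells*:
5% of cells have their mitochondrial share pinned at 20% (healthy: 4%),
so the 12% QC rule has both pass and fail cases.

Defaults (2,000 cells, even species mix, the rates above) are the
reference conditions of the validation suite. Panel size (300 genes per
species), library scale and dispersion were chosen once as a desk-scale
compromise that keeps per-gene counts in a realistic range; the methods'
problem sizes in the tests and acceptance script (2,000-cell censuses,
500-cell calibration samples, 30-spot sections, 10-cells-per-spot
densities) are the package's own choices for a reproducible desk run.

**Visium-like sections.** Spots draw cells per type from a given
abundance matrix — Poisson around the expectation by default, or exactly
the given integers (`sampling = "exact"`) for controlled mixtures — and
sum their profiles; cross-mapping and soup apply, doublets do not (spots
are already mixtures). The realized per-spot type counts are returned as
the truth abundance.

**What the generator does not emulate.** Read-level errors, UMI
collisions, sequence-level homology (cross-mapping is a per-pair
probability, not an alignment model), batch effects, spatial
autocorrelation of expression within a section, and empty droplets.
Passing tests therefore demonstrate correctness of the decision rules
and estimators under a faithful statistical caricature, not performance
on real libraries.

## 7. Numerical choices and degenerate inputs

- All decision boundaries are strict inequalities, matching their
  verbatim phrasing; boundary cases are pinned by tests.
- HVG ties break lexicographically by gene name; zero-mean genes sort
  last (CV undefined).
- Zero-total cells: an error in normalization (QC should have removed
  them), flagged-and-excluded in species profiles.
- Empty calibration sample for the removal rule: all genes retained,
  with a warning.
- All-zero spots deconvolve to all-zero abundance rows.
- Clustering with fewer cells than requested components reduces the
  rank with a warning; singleton clusters are skipped by the marker
  stage with a warning.
- The full pipeline (`run_pipeline()`) is bit-reproducible given its
  configuration, and logs per-stage parameters and sizes in a
  provenance record.

## 8. Known limitations

- The NNLS surrogate shares only the objective's spirit with the
  Bayesian deconvolution model it stands in for; absolute abundances
  depend on the supplied cells-per-spot scale and should be read as
  composition.
- The gene-ratio method's accuracy depends on how many genes the removal
  rule deletes; with aggressive homology (large `cross_map_prob` in
  calibration samples) the modified panels shrink and ambiguous calls
  grow. This mirrors the real trade-off.
- Homolog cross-mapping is simulated but not *corrected*; counts are
  analyzed as contaminated, as in the emulated workflow.
- The generator's truth species for a cross-species doublet is a
  convention (larger library wins); any accuracy computed over doublets
  inherits it.
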