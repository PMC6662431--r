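---
title: "Marker-gene community profiling with rpS3profiler: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene community profiling with rpS3profiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpS3profiler)
```

# The profiling model

Assembly-based marker profiling treats each de-replicated ribosomal
protein S3 (rpS3) sequence cluster as an organism unit and the read
coverage of the scaffold carrying its representative gene as a proxy for
that organism's relative abundance. The model rests on three
assumptions: rpS3 is single-copy, so coverage is not inflated by
paralogs; a 99%-identity protein cluster groups assemblies of the same
population across samples; and read mapping depth on a few kbp of
sequence around the gene is proportional to the population's DNA
fraction in the extract.

The pipeline therefore has two halves. The *profiling* half turns raw
artifacts (HMM hit tables, a marker alignment, scaffolds, read
alignments) into a cluster-by-site abundance matrix; the *ecology* half
turns that matrix into dissimilarities, ordinations and
environment-association statistics.

# Stage-by-stage procedure and parameters

## Hit screening

Per-domain tabular HMM hits are filtered by a per-model minimum bit
score (user-supplied, since sensible cutoffs differ between custom and
PFAM models) and a global e-value ceiling (default `1e-5`). Score
cutoffs are minima, so the comparison is `>=`; taxonomy assignment from
best-hit tables instead uses a strict `<` on the e-value, keeping the
single highest-bit-score qualifying hit per query (ties fall to the
lower e-value, then the earlier row; ranking by e-value is available via
`rankBy`). Two qualifying hits on one scaffold stay separate genes —
clustering decides redundancy later.

## Alignment QC

Marker proteins arrive aligned (externally, e.g. with MAFFT, together
with a set of reference sequences that anchor the model; reference ids
carry a configurable prefix, default `REF|`). Columns whose gap fraction
strictly exceeds `maxGapFraction = 0.95` are removed; a column exactly
at the threshold stays. Sequence removal then uses a retention
threshold `T = floor(retentionFraction * N)` with
`retentionFraction = 0.5` and `N` the non-gap count of the longest
*non-reference* row: rows with fewer than `T` non-gap positions are
dropped. Reading the "50% of overall non-gap positions" rule against
the longest non-reference sequence is the only arithmetic that
reproduces the canonical worked pair (a 206-residue core giving
threshold 103, removing a 102-residue fragment and keeping a 103-residue
one); an alternative reading — 50% of the retained column count —
coincides only when the longest sequence spans every retained column,
and is deliberately not used. References are exempt from removal (they
are scaffolding, not observations) and are dropped before clustering.
Gap characters are `-` and `.`.

## Identity and clustering

The external clustering tool this stage emulates does not document its
internal identity definition, so the package fixes its own,
deterministic one: a global alignment with free end gaps under unit
scoring (match +1, mismatch 0, gap −1 — the scores only steer the
alignment), with identity = matches over the alignment columns between
the first and last aligned pair (terminal gaps excluded) and coverage =
aligned span over sequence length. This gives substring matches
identity 1 with partial target coverage, which is what the coverage
constraints are for. Tie-breaking in the dynamic program (diagonal over
up over left; corner-preferring end cell) is fixed so results are
reproducible. The implementation is a small C++ dynamic program; tests
cross-check it against an independent overlap aligner within the ±0.5%
slack we allow for alternative optimal paths.

Greedy clustering processes sequences in decreasing length order (ties
by input order), so every centroid is the longest member of its cluster
and hence also its representative. Defaults: identity `>= 0.99`, query
coverage `>= 1`, target coverage `>= 0.5`. With `exhaustive = TRUE`
(the analogue of unlimited accept/reject scanning) a sequence joins the
best-identity qualifying centroid, ties to the earlier-created one.
Lowering the identity threshold can only merge clusters, never split
them — a property the tests assert on random inputs.

## Coverage, breadth and the calibrated cutoff

Representative scaffolds are trimmed to `flankBp = 2000` bp around the
gene; if the window would be shorter than `minScaffoldBp = 1000` bp the
whole scaffold is used, and scaffolds of 1 kbp or less are excluded
outright. Depth is counted from primary, mapped SAM records using only
reference-consuming match operations (`M`, `=`, `X`); deletions consume
reference but add no depth; secondary and supplementary records are
skipped, and no mapping-quality filter is applied. Coordinates are
1-based inclusive throughout, matching both SAM and gene-caller
conventions. Average coverage is `sum(depth)/L`, breadth is the
fraction of window positions with depth at least 1.

Every cluster is genuinely present in at least the sample its scaffold
was assembled from, so a breadth cutoff should never eliminate a
cluster; cross-sample detections below the cutoff are treated as false
positives. The calibration scans the grid 0.10 to 1.00 in steps of
0.01 (a two-decimal grid, the natural resolution for a two-decimal
cutoff) and returns the **maximal** cutoff at which every cluster still
retains a record with breadth at or above it. Because retention is
monotone non-increasing in the cutoff, "the lowest cutoff that retains
all clusters" is operationally this maximal retaining value — the
literal lowest grid value always retains everything, so the maximal
reading is the only self-consistent one; we state it prominently rather
than silently assuming it. Records exactly at the cutoff are kept
(`>=`); coverage of failing records is set to zero but their breadth is
preserved for reporting.

## Normalization and replicate averaging

Sequencing effort differs between libraries, so each sample column is
scaled by `bp_max / bp_sample` — the deepest library has factor exactly
1 and within-column rank order is conserved. Replicate DNA extractions
are then averaged per site with zeros counted (a zeroed, cutoff-failed
detection is evidence of absence at that threshold, and the averaging is
unconditional), after normalization so replicates enter on a common
scale.

## Dissimilarity, ordination and environment selection

Bray–Curtis is `sum|x−y| / sum(x+y)` over clusters; an all-zero sample
pair has no defined value and is reported as 0 with a warning.
Unweighted UniFrac is branch length unique to either sample over branch
length covered by either; weighted UniFrac is
`sum_b l_b |p_A(b) − p_B(b)|` with `p` the descendant
relative-abundance fraction, and the normalized variant (the default,
matching common usage of the reference implementations) divides by the
pair's maximum attainable value `sum_j depth_j (p_A(j) + p_B(j))`.
PCoA reports all eigenvalues, negative ones included, rather than
silently dropping them. NMDS minimizes Kruskal stress-1 over monotone
regression, taking the best of `nStarts` initializations; the first
start is the metric PCoA configuration and the rest are seeded random
configurations, so identical input and seed give identical output, and
perfectly embeddable distances reach numerically zero stress.

BIOENV standardizes each environmental variable to zero mean and unit
variance, excludes constants with a warning, and exhaustively scores
every non-empty subset up to `maxSubsetSize` by correlating the
Euclidean distances on the subset with the community dissimilarity over
the lower triangle. Exhaustive enumeration is the default at the
problem sizes this package targets (tens of variables, subset sizes up
to ~5); the stepwise best-first shortcut recommended for very large
variable sets is out of scope here. Pearson correlation is the default
with Spearman available — the source analyses report both conventions
in different places, so the choice is surfaced as a parameter rather
than resolved silently.

The Mantel test permutes the row/column labels of the second matrix and
uses the add-one convention `p = (1 + #{r_perm >= r_obs})/(1 + n_perm)`
(default 999 permutations), so p is never exactly zero and a statistic
above all permuted values gives exactly `1/(n_perm + 1)`. Permutations
are uniform over all relabelings; with a dozen or more samples the
chance of re-drawing the identity is negligible, which is what makes the
self-test value of 0.001 exact in practice. Covariate statistics are a
plain Pearson test plus ordinary least squares of abundance on the
covariate.

# The synthetic transect generator

`simulateTransect()` emulates the sampling design of a hillslope
transect study: positions along a slope with decreasing distance to a
river, several coring depths per position, two replicate DNA extractions
per sampled site and a third at one designated site. The defaults — 5
positions, depths 5/30/90/200 cm, 40 taxa, giving 20 sites and 41
samples — mirror a realistic campaign of that shape. Per-taxon
log-abundance is linear in standardized depth and distance plus
site-level and replicate-level lognormal noise (defaults 0.3 and 0.1),
softmax-normalized per sample; a designated group (default 6 taxa,
labelled as candidate phyla) receives a strong positive depth response
(+2 per depth z-unit) so a depth-trending guild exists by construction.

`emitGenomesAndTree()` controls sequence identity exactly rather than
estimating it: all markers descend from one ancestor by seeded point
substitution, with between-taxon identity capped at 0.97 (verified
all-pairs at generation) and within-taxon duplicate copies within one
substitution (identity ≥ 0.995), each on its own scaffold as if
assembled independently. A sub-5% minority of taxa carries an 11-residue
C-terminal insert so that, after the bundled gapless stacking aligner
pads the alignment, the insert columns exceed the 95% gap threshold and
trimming restores the shared 206-residue core — exercising the column
rule realistically. Truncated stubs exercise the retention rule.
Scaffolds are i.i.d. uniform nucleotides outside the embedded gene (a
seeded reverse translation of the marker).

`emitReadsSam()` places single-end 150 bp reads uniformly on each
taxon's primary scaffold with Poisson counts at an expected depth
proportional to true abundance (community mean 20x at size factor 1;
per-sample size factors uniform in 0.7–1 so depth normalization has
work to do). In its origin sample a taxon's expected depth is floored
at 2x, reflecting that its scaffold was assembled there — the same
presence assumption the breadth calibration relies on. Pairing, quality
strings, sequencing error, assembly artifacts and chimeras are *not*
modelled: passing tests show the quantification and statistics are
correct on clean alignments, not that any upstream mapper or assembler
behaves well on real soil data.

`emitGeochem()` makes the driving variables deterministic functions of
the latent community gradient: the site-level Bray–Curtis configuration
is embedded in `k` principal-coordinate dimensions, rotated by an
orthogonal variance-equalizing (Givens) rotation — distances are
untouched but every variable gets the same scale, so BIOENV's internal
z-scoring does not distort the geometry — standardized, and perturbed
with Gaussian noise expressed as a fraction of the unit signal
(default 0.1). The remaining variables are independent standard
normals. With this construction, noise-free recovery of the full
driving subset with correlation above 0.99 holds by design, and
recovery of the subset survives 10% noise; a naive construction that
mixes the raw depth/distance gradients directly gives correlations
around 0.85 and fails to make the full subset optimal under
standardization.

# Numerical choices and degenerate inputs

* Grid arithmetic for the breadth cutoff rounds grid values to 10
  decimals to avoid floating-point drift in `seq()`.
* `breadth = 0` if and only if `average_coverage = 0` holds by
  construction and is asserted in tests.
* A cluster with no positive-breadth record violates the presence
  assumption and raises an error naming the cluster, as does a grid
  whose lowest value already loses a cluster.
* Empty alignments, all-reference alignments, empty sequences, gapped
  input to the aligner, duplicate sequence ids, unknown models,
  constant covariates and mismatched distance-matrix labels all raise
  immediate, named errors rather than propagating silently.
* All-zero distance matrices ordinate to all-zero coordinates; PCoA
  pads dropped axes with zeros instead of changing its output shape.
* Permutation p-values never reach 0 (add-one convention); seeded NMDS
  and Mantel runs are bit-reproducible.

# Problem sizes used in the tests

The test-suite and the acceptance script run the generator at its
default design (20 sites / 41 samples / 40 taxa / 20x depth) for the
end-to-end recovery checks, and smaller seeded instances (12 sites / 25
samples / 12 taxa) for per-stage tests. Oracle-equivalence checks use
regions up to ~9 kbp against brute-force depth arrays, up to 30
sequences against an all-pairs greedy reference, 8-leaf random trees
against a per-branch UniFrac summation, and up to 5 environmental
variables against exhaustive BIOENV enumeration. The scaled clustering
stress test collapses ~150 near-identical copies into 60 mutually
<99%-identical ancestor clusters; the construction (not just the
outcome) is verified by an explicit all-pairs identity check.

# Known limitations

* The identity definition, while deterministic and documented, is not
  guaranteed to match any particular external clustering tool
  bit-for-bit; agreement is expected within ~0.5% identity.
* Exhaustive BIOENV scales as `2^v` in the variable count; beyond ~40
  variables with subsets of 4 it becomes the dominant cost.
* Coverage reading assumes plain single-file SAM per sample; BAM/CRAM
  and indexed access are out of scope, though the reader is isolated
  behind `readSam()` for later extension.
* The generator's clean-alignment assumption means mapping ambiguity
  between near-identical duplicate scaffolds — a real phenomenon when
  multiple assemblies of one population are mapped jointly — is not
  represented; the pipeline sidesteps it by quantifying representative
  scaffolds only.
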