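---
title: "Methods: circadian cluster discovery and clock-TF set mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian cluster discovery and clock-TF set mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Liver transcription is strongly circadian. Given a short replicated
time course — six sampling occasions at zeitgeber times 0, 2, 4, 8, 16
and 24 h with three animals each — `clockmine` asks two questions:

1. Which transcripts vary over the day, and in which coherent temporal
   patterns?
2. Which transcription factors (TFs), and which *combinations* of clock
   TFs, plausibly drive each pattern?

The pipeline chains five stages: an ANOVA/positive-FDR differential
filter, consensus clustering with trivial-cluster removal, a
rhythmicity test based on Fisher's exact g statistic, promoter
remodelling into binding-site lists with phylogenetic footprinting, and
combinatorial clock-TF set mining scored by hypergeometric enrichment
against a GC-matched background.

# Stage models and assumptions

## Differential filter

Each probeset is tested with a one-way fixed-effects ANOVA across the
six sampling occasions. The 0 h and 24 h samples share a clock phase
but are distinct occasions and are kept as separate groups; a transcript
flat in time but different between day 0 and day 1 is thereby still
detected. p-values are converted to Storey q-values (positive false
discovery rate). Defaults are p < 0.001 and q < 0.01 — deliberately
strict for an 18-chip design, and known to sacrifice sensitivity for
specificity.

The Storey estimator uses
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$ on the grid
$\lambda \in \{0.05, 0.10, \ldots, 0.95\}$, choosing $\lambda$ by the
bootstrap (100 resamples): minimise the bootstrap mean squared error of
$\hat\pi_0(\lambda)$ around the plug-in minimum. $\hat\pi_0$ is clamped
to $(0, 1]$ (floor $1/m$ to keep q-values positive). q-values are the
usual step-up transform
$q(p_{(i)}) = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. The smoother
variant of the estimator is not implemented; the bootstrap is used
everywhere a q-value appears.

Probesets with zero within-group variance everywhere are assigned
p = 1: with no error variance there is no usable evidence, and on
continuous expression data the case indicates a degenerate input rather
than a perfect signal.

## Consensus clustering

Profiles are replicate-averaged per occasion and z-scored, giving one
six-point vector per probeset. For row-standardised vectors, squared
Euclidean distance is proportional to one minus Pearson correlation, so
k-means on these vectors is correlation-distance partitioning around
random centroids. The consensus matrix averages pairwise co-membership
over 200 such base partitions with k drawn uniformly from 2–8 and
random initial centroids. Clusters are read off by average-linkage
hierarchical clustering of 1 − consensus; the number of clusters is
chosen to maximise the mean silhouette width on that dissimilarity
(rows are processed in lexicographic probeset order so dendrogram ties
break deterministically).

Trivial-cluster removal tests each cluster's coherence — mean pairwise
correlation of member profiles — against a permutation null. Two points
matter here:

* The consensus entry itself cannot be the null statistic: each null
  draw would need its own 200-partition consensus, which is orders of
  magnitude more work than the test itself. Coherence orders clusters
  the same way and is computable in microseconds.
* The null must include the selection step. Clusters are found by
  optimising on the data, so comparing a found cluster against
  re-permutations of only its own members is anti-conservative — on
  fully permuted data that naive null still "confirms" the spurious
  clusters the clusterer carved out of noise. Each null draw therefore
  permutes every profile's timepoints independently, re-partitions the
  permuted data into the same number of clusters (one k-means run), and
  records the best cluster coherence. A cluster's p-value is the
  fraction of null maxima at least as large as its observed coherence;
  the default cut is p < 0.001 with at least 999 draws, and the p-value
  is the plain null fraction (it can be exactly 0), so the cut is
  attainable.

## Rhythmicity

Fisher's exact g-test asks whether a single periodogram ordinate
dominates the spectrum: $g = \max_k I(f_k) / \sum_k I(f_k)$, with the
exact null
$P(G > g) = \sum_{j=1}^{\lfloor 1/g \rfloor} (-1)^{j-1}\binom{m}{j}(1-jg)^{m-1}$
for white Gaussian noise. At the support minimum $g = 1/m$ the p-value
is exactly 1.

Because only one day was sampled, the three replicates at each occasion
are first redistributed over three consecutive cycles: a uniformly
random permutation sends exactly one replicate to each of t, t + 24 and
t + 48 h, turning 6 × 3 observations into one 18-point series spanning
72 h while preserving the value multiset. The sampling pattern is
uneven (0, 2, 4, 8, 16, 24), so the default test computes least-squares
spectral ordinates (the regression sum of squares of a centred
cosine/sine pair) at the harmonic frequencies k/72 h⁻¹ for periods from
72 h down to 6 h (m = 12), takes the g ratio, and calibrates it by
permuting values over the fixed time stamps:
p = (1 + #{g* ≥ g}) / (1 + n_perm). The closed-form test (`exact_grid`)
is also provided for evenly gridded series: values are averaged onto a
2 h grid, gaps filled by linear interpolation, and the classical
periodogram ordinates feed the exact formula. The permutation route is
the default because the closed-form null assumes independent ordinates,
which uneven spacing breaks. Whether to average replicates before
testing was an open choice; the 18-point redistributed series is tested
directly, which matches the replicate-redistribution construction.
q < 0.01 (Storey, as above) is the pass criterion.

## Promoter remodelling and footprinting

Promoters default to 500 bp upstream + 100 bp downstream of the TSS,
the binding-site-dense proximal window. Scanning is information
weighted: with frequency matrix $f(b, j)$ (pseudocount applied, columns
renormalised) and information content $I(j)$, a window scores
$\sum_j I(j) f(b_j, j) / \sum_j I(j) \max_b f(b, j)$ — 1.0 for the
consensus. The *core* similarity restricts this to the four consecutive
highest-information positions and gates the scan at 0.75; the full
matrix similarity must exceed a per-matrix threshold. Ambiguity codes
contribute zero. Both strands are scanned, and each promoter becomes a
position-sorted, deduplicated site list.

Per-matrix thresholds are calibrated, not fixed: the smallest threshold
giving at most 0.3 hits/kb (both strands) on background sequence. This
mirrors the "optimised" per-matrix thresholds of commercial scanners
while keeping the procedure self-contained.

Conserved regions are found by seed-and-extend on exact 8-mers: every
shared 8-mer defines an ungapped diagonal; along each diagonal, a
reference position is conserved in one ortholog if a 20 bp window
covering it reaches 70% identity. A position is conserved overall if
enough orthologs support it. The operation default is 2 supporting
orthologs (the weakest usable evidence); the pipeline default is a
4-of-6 majority, which at the synthetic divergence level below cleanly
separates planted conserved blocks (100% recovered) from background
(~28% covered). Genes with fewer than three orthologous promoters are
skipped. Footprinting keeps hits overlapping a conserved interval by at
least half their length (a hit exactly half inside is kept), and a TF
family is reported as a cluster regulator if it has a conserved hit on
at least 70% of the cluster's genes (inclusive threshold, computed over
genes, not promoters).

## Clock-TF sets

Clock-controlled TF candidates are genes that are differentially
expressed, annotated as TFs, and carry a CLOCK:BMAL1 E-box hit on any
of their promoters. The mining universe is the literature clock
families (CLOCK:BMAL1, PARF, RORA) plus the families of identified
ccTFs. Presence is gene-level and physical (any promoter, conservation
not required — footprinting feeds the regulator report, while set
mining follows the plain promoter scan); a configuration switch can
restrict mining to conserved hits.

Frequent sets are mined level-wise (breadth-first): singletons at
support ≥ 0.7, then candidate (k+1)-sets joined from frequent k-sets
and pruned by antimonotonicity, with support the fraction of genes
carrying *every* member. Each set A is scored by the hypergeometric
upper tail $P(X \ge n)$ with B background genes, b background carriers,
N foreground genes and n foreground carriers. The tail, not the point
mass, is the implemented contract: the quantity is an
over-representation p-value, and a point mass alone is not monotone in
enrichment. The scoring population is the background united with the
foreground, which guarantees the count invariants (n ≤ b, N ≤ B)
whatever background the caller supplies. Storey q-values are computed
per call — per cluster in the pipeline, matching the per-pattern
reports; the alternative (pooling across clusters) is a caller choice.
Significance defaults are p < 0.05 and q < 0.10; non-significant
records are reported with a flag, and overlapping sets are all kept by
default (a maximal-only filter exists).

The background is GC-matched: per-gene mean promoter GC is binned at
width 0.05, the foreground histogram sets target proportions, and
background genes are sampled per bin without replacement (deficits
filled from the remaining pool with a warning). This blocks
composition-driven enrichment of GC-rich motifs.

# The synthetic-data generator

Simulated inputs emulate the study conditions and carry ground truth:

* **Expression**: four rhythmic clusters of 153/64/52/83 probesets (the
  sizes of the four reported patterns) peaking at ZT0/4/8/16, a 24 h
  cosine of amplitude 1.0 with Gaussian replicate noise (sd 0.25) on a
  log-like scale (baselines N(7, 1)), inside 2000 total probesets —
  the chip scaled down ~15× so simulation studies run in seconds.
  At this amplitude/noise the planted effect is strong, as the paper's
  selected clusters are; recovery tests therefore probe the pipeline's
  wiring, not marginal detection power.
* **Promoters**: 600 bp reference promoters at GC 0.55 with four 60 bp
  conserved blocks; six orthologous promoters derived by point
  substitutions at 2% inside blocks and 50% outside. The high outside
  divergence is a deliberate calibration: at the 20 bp / 70% identity
  criterion, realistic mammalian-style 15% divergence leaves the whole
  promoter "conserved" and footprinting filters nothing, so the
  generator widens the contrast until conservation detection is
  non-trivial but reliable (blocks fully recovered, ~28% background
  coverage at the 4-of-6 majority).
* **Planted regulation**: family sites (PWM consensus, random strand)
  are inserted inside conserved blocks at configured per-family rates.
  Planting is *comonotone* — one uniform draw per gene is compared
  against every family's rate — so marginal rates are honoured and the
  planted families are frequent *as a set* (joint support = smallest
  rate). Independent planting at 0.8 would give a three-family set
  joint support ≈ 0.51, below the 0.7 mining level, and no set-level
  signal to recover. TF-annotated genes additionally receive a
  CLOCK:BMAL1 site, making them ccTF candidates.
* **PWM library**: twelve synthetic family matrices of length 8–14
  (consensus weights 0.85–0.97 per position), including a palindromic
  CACGTG-core CLOCK:BMAL1 matrix, the nine clock families used in the
  analyses, and two decoys (GATA, SORY) for false-positive checks.

What the generator does **not** emulate: probe-level microarray
artefacts, correlated noise between probesets, realistic phylogenetic
tree structure (substitutions are iid per branch-less ortholog),
insertions/deletions, cooperative or overlapping binding sites, and
dependence of binding on chromatin. Passing recovery tests therefore
demonstrates the pipeline's statistical wiring under its own model, not
performance on real arrays or real promoters.

# Numerical choices

* All stochastic steps take explicit seeds; the pipeline derives
  per-stage seeds from a master seed. Rerunning a configuration
  reproduces outputs byte-for-byte.
* `fisher_g_pvalue` returns exactly 1 at g ≤ 1/m and clamps the
  alternating sum to [0, 1]; terms with 1 − jg < 0 are dropped.
* Permutation p-values use the (1 + exceedances)/(1 + draws) estimator
  except the trivial-cluster p, which uses the plain fraction so the
  spec's p < 0.001 cut is reachable at 999 draws.
* Threshold comparisons at the study's cuts are strict (<), support
  and conservation thresholds inclusive (≥), matching the stated
  boundary conventions ("common threshold 70%" includes 7/10).
* Coordinates are 0-based half-open internally and in BED output.
* k-means degeneracies (duplicate random centres, empty clusters) are
  retried with fresh centres and fall back to a random-start run.
* Constant series, all-N sequences and empty site lists all take
  defined degenerate paths (p = 1, empty lists) rather than errors.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic
data at the scales chosen for the package's own validation studies:
the faithful expression preset (2000 probesets, 352 planted rhythmic),
500-series type-I calibration at 499 permutations, 50-seed footprint
recovery on 50-gene clusters, 50 + 50 faithful/null end-to-end set
discovery simulations with 40 foreground and 200 pool genes, and a
full hypergeometric enumeration sweep to B = 12. These sizes give
Monte-Carlo error small enough for the stated bands while keeping a
complete run in minutes on one CPU.

# Known limitations

* The consensus base learner is k-means on z-scored profiles; base
  partitioners with non-convex cluster shapes are not provided, though
  the learner is a single function boundary to swap.
* The g-test's closed form is only exact for evenly spaced,
  uncorrelated ordinates; for the 18-point redistributed design the
  permutation route is the honest default, at ~500× the cost.
* Conservation is ungapped: indel-rich promoters would fragment
  diagonals and under-call conserved regions.
* GC matching controls composition at the promoter level only;
  dinucleotide (CpG) structure is not matched.
* The mining universe is family-level; within-family matrix
  heterogeneity is collapsed to the family label supplied by the PWM
  library.
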