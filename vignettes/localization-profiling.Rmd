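---
title: "Methods: subcellular localization profiling in motile ciliated cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subcellular localization profiling in motile ciliated cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

`ciliamap` quantifies where a candidate protein sits inside motile
ciliated epithelial cells. The input is one multichannel image stack per
tissue-microarray core: five reference marker channels that each outline
one subcellular compartment — ciliary axoneme (CL), transition zone (TZ),
rootlet (RL), cytoplasm (CYTO), nucleus (NUC) — plus the candidate
channel, DAPI, and an autofluorescence page. The central assumption is
**marker-anchored colocalization**: the candidate's intensity measured
inside each marker-derived region of interest (ROI) is proportional to
the candidate's abundance in that compartment. The pipeline makes no
attempt at cell-instance segmentation; the ROI of a compartment is simply
the brightest multi-Otsu class of its marker channel, pooled over the
whole core.

The stages, and the quantity each produces:

| stage | operation | output |
|---|---|---|
| conversion | per-channel min–max rescale to 8-bit | intensities in 0–255 |
| segmentation | 3-level multi-Otsu, brightest class | one boolean ROI per marker |
| profiling | masked mean/max/min/area of candidate | 5 rows per passing core |
| aggregation | median over cores, min–max per protein | proteins × (5 compartments × tissues) matrix in [0, 1] |
| clustering | Euclidean, complete linkage, fixed-k cut | dendrograms + cluster ids |
| annotation | hypergeometric over-representation, FE scores | per-cluster GO terms, rich factors |

# Numerical choices

**8-bit conversion.** Interactive image tools convert using whatever
display range is active, which is irreproducible in batch. We fix the
linear map of the observed `[min, max]` onto `[0, 255]` with
round-half-up (`floor(x + 0.5)`); a constant image maps to all zeros.
Segmentation and ROI statistics both use converted intensities, since
conversion precedes segmentation in the workflow.

**Multi-Otsu.** Histograms use 256 unit-width bins on the 8-bit range, no
smoothing. The threshold pair `(t1, t2)` partitions intensities into
`{x < t1}`, `{t1 <= x < t2}`, `{x >= t2}` and maximizes the between-class
variance over every pair for which all three classes have positive mass;
ties are broken by the lexicographically smallest pair, so the result is
deterministic. The implementation evaluates all ~32k admissible pairs
from cumulative moments; the test suite checks it bit-for-bit against an
independent exhaustive search that evaluates the defining formula
directly.

**Segmentation failure.** The term is given a concrete definition: a
channel with fewer than three distinct intensity values (a three-class
partition is undefined) or an empty brightest-class mask. Either verdict
excludes the whole core from measurement — failed cores contribute no
rows, which downstream medians therefore never see. ROIs of different
markers may overlap; each marker is segmented independently and no mutual
exclusion is imposed.

**Aggregation.** "Median per ROI, protein and tissue" is computed as the
median over cores of the per-core ROI *mean* (one mean per core per ROI),
not a pooled-pixel median; even core counts use the mean of the two
central values. Min–max scaling is applied once per protein over its full
compartment × tissue profile (each protein occupies one slide, so
per-protein and per-slide coincide); scaling per tissue instead would
erase the cross-tissue comparisons the heatmap is meant to show. A
constant profile maps to all zeros. A (protein, tissue) cell whose cores
were all excluded is flagged missing — never imputed, never silently
zero — and rows containing missing values are dropped from clustering
with a warning.

**Clustering.** Euclidean distance with complete linkage, the default of
the standard heatmap packages, for both rows and columns. The row
dendrogram is cut at fixed k (default 7); a height cut is also exposed,
but fixed k is the default because it makes the cluster count an explicit
parameter rather than an emergent one. Cluster ids are renumbered by
dendrogram leaf order so labels are stable across runs.

**Enrichment.** The hypergeometric upper tail is summed in log space
(log-binomials + log-sum-exp) for stability at large universes. The
universe defaults to all annotated input candidates: a self-contained
choice that requires no live GO or organism database and makes the test
a comparison of the cluster against the studied candidate set. The
p < 0.05 cutoff is applied to *raw* p-values; a Benjamini–Hochberg option
exists but is off by default, and this ambiguity (raw vs adjusted) is a
known interpretive fork. Top terms are ranked by associated-protein count
k, ties by smaller p, then lexical term id.

**Candidate selection.** nTPM ≥ 0.1 (inclusive) and antibody reliability
in {Enhanced, Supported, Approved}; the funnel stops at the computational
stages — manual curation of staining patterns is out of scope.

# The synthetic generator

`generate_study()` emulates the study design: five tissues (nasopharynx,
bronchus, fallopian tube, endometrium, cervix), three patients per
tissue, duplicate cores — six cores per tissue — and one stack per
candidate protein per core. Each 96×96 (configurable, ≥ 64×64) cell
template renders cilia as an apical band of thin vertical strips, the TZ
as a 2–3 px line beneath it, rootlets as short strips below that, and a
cell body split into elliptical nuclei and cytoplasm; exact shapes are
free parameters, the load-bearing properties being that the three ciliary
masks are disjoint and every compartment is non-empty. A candidate's
ground truth is a 5-weight vector summing to 1 (optionally overridden per
tissue to emulate tissue-variable proteins); its channel has expected
intensity `background + amplitude × weight(compartment)` on each
compartment mask.

Noise defaults were chosen once as a plausible mid-contrast acquisition:
background 20, amplitude 180 (so full signal reaches 200 of 255), additive
Gaussian σ = 8 on the 8-bit scale, optional Poisson shot noise off, all
stored at 16 bits (value × 257) so the 8-bit conversion stage does real
work. Marker channels carry a half-amplitude one-pixel rim around the
mask, giving noiseless marker images exactly three intensity levels —
which is why, at σ = 0, the multi-Otsu brightest class recovers the
ground-truth mask *exactly*, a property the tests assert. "Failed" cores
are emulated by setting one marker channel constant, which triggers the
degenerate-histogram exclusion rule deterministically.

What the generator does **not** emulate: optics (PSF, chromatic shift),
registration error between staining cycles, stripping artifacts,
non-ciliated cell populations, or intensity calibration drift. Passing
tests therefore demonstrate that the algorithmic chain is correct and
self-consistent under the stated noise model — not that the pipeline is
robust to every real acquisition artifact.

# Problem sizes and verification

The test suite and the acceptance script use: the default study at 20
candidates × 5 tissues × 6 cores (600 stacks, ~25 s end to end on one
CPU) for dominant-compartment recovery, noisy and noiseless; 12
candidates from three localization archetypes for clustering recovery
(adjusted Rand index vs the archetype labels, via `mclust`); 1,000
seeded random 256-bin histograms for multi-Otsu oracle equivalence; and
every hypergeometric parameter set with N ≤ 30 (87,295 sets) against
brute-force pmf summation. Determinism is checked by re-running with the
same seed and comparing outputs byte-for-byte.

# Known limitations

* ROI statistics pool all pixels of a compartment across the core; a
  candidate expressed in a non-ciliated cell type that happens to overlap
  a marker ROI would be attributed to that compartment.
* Min–max scaling makes profiles relative per protein: the matrix
  supports *pattern* comparisons, not absolute abundance comparisons
  between proteins.
* The fixed-k cut requires choosing k; no gap statistic or stability
  analysis is provided.
* GO enrichment against the candidate-set universe answers "which terms
  distinguish this cluster within the studied set", which is narrower
  than a genome-wide over-representation claim, and no GO-graph ancestor
  propagation is performed.
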