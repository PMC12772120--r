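# ciliamap

Quantitative subcellular localization profiling of candidate proteins in
motile ciliated epithelium from multiplex immunofluorescence (mIHC) image
stacks.

## The problem

Motile ciliated cells line the airways and parts of the female
reproductive tract; defects in their ciliary machinery cause disease such
as primary ciliary dyskinesia. Iterative multiplex immunohistochemistry
can co-stain one *candidate* protein per slide alongside a fixed
five-antibody panel that outlines five subcellular compartments of the
ciliated cell — the ciliary axoneme (CL), the transition zone (TZ), the
rootlet (RL), the cytoplasm (CYTO) and the nucleus (NUC) — across tissue
microarray (TMA) cores from several tissues. `ciliamap` turns those
per-core image stacks into a localization map:

1. **Segmentation** — each channel is converted to 8-bit (min–max linear
   rescale, round-half-up); DAPI and autofluorescence pages are discarded;
   each marker channel is segmented by three-level multi-Otsu
   thresholding, maximizing the between-class variance
   σ²_B = Σ_c ω_c (μ_c − μ)² over all threshold pairs (t₁, t₂), keeping
   only the brightest class (intensity ≥ t₂) as the compartment ROI. A
   core whose markers cannot be segmented is excluded (QC verdict).
2. **Profiling** — mean / max / min candidate intensity and area are
   measured inside each of the five ROIs per core.
3. **Aggregation** — medians over QC-passing cores per (protein, tissue,
   compartment), then min–max scaling per protein across its full
   compartment × tissue profile, x′ = (x − min)/(max − min) ∈ [0, 1].
4. **Clustering** — hierarchical clustering (Euclidean distance, complete
   linkage) of proteins and of compartment–tissue columns, with a fixed-k
   cut (default k = 7) and a clustered heatmap.
5. **Annotation** — per-cluster GO over-representation using the
   hypergeometric upper tail p = Σ_{i≥k} C(K,i)·C(N−K,n−i)/C(N,n) with
   rich factor RF = k/K, top-3 terms per category ranked by associated
   protein count; plus HUPO Function Evidence (FE1–5) score summaries and
   the nTPM/antibody-reliability candidate-selection funnel.

A seeded synthetic TMA generator (`generate_study`) draws image stacks
with known ground-truth compartment geometry and localization weights, so
the whole pipeline is testable end to end without any external images.

## Worked example

```r
library(ciliamap)

run <- run_pipeline(pipeline_config(n_proteins = 10, k = 5, seed = 42))
print(run)
#> Subcellular localization profiling run
#>   cores processed : 300 (300 passed QC, 0 excluded)
#>   proteins        : 10
#>   expression matrix: 10 x 25 (min-max scaled medians)
#>   row clusters (k=5): sizes 2, 2, 2, 2, 2
summary(run)
#> Apparent dominant compartment (argmax of normalized profile):
#>   CL CYTO  NUC   RL   TZ
#>    2    2    2    2    2
```

Ten simulated candidates (two per dominant compartment) are processed
through segmentation, aggregation and clustering: all 300 synthetic cores
pass QC, the 10 × 25 normalized matrix clusters into the five expected
localization groups, and each protein's profile peaks in its true
compartment.

The FE-score summary on the bundled synthetic score table (187 proteins,
marginals matching the reference study) reports the headline functional
annotation gap:

```r
fe <- read.delim(system.file("extdata", "fe_scores_synthetic.tsv", package = "ciliamap"))
fe_distribution(fe)[c("fe1_percent", "fe2to5_percent")]
#> $fe1_percent   27      # at least one known molecular function
#> $fe2to5_percent 73     # poorly or partially characterized
```

A command-line wrapper is installed at `exec/ciliamap` with `simulate`,
`run` and `select` subcommands.

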