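# geitad

Genome-scale modeling of **g**enetic–**e**pigenetic **i**nteractions
within **TAD**s.

In genetically diverse populations, local genotype and chromatin
accessibility shape gene expression jointly, not just additively: the
effect of an open-chromatin peak can depend on the allele present at a
nearby variant, and vice versa. geitad implements an analysis pipeline
for detecting and characterising these non-additive interactions at
genome scale, and for relating them to three-dimensional genome structure
(topologically associating domains, TADs). It is aimed at groups with
paired genotype / RNA-seq / ATAC-seq panels — e.g. outbred mouse or human
cohorts — and at methodologists who want a fully synthetic, ground-truthed
testbed for interaction scans.

## The model

For a *trio* (gene, variant, peak) the package fits

    y = b0 + b1*x1 + b2*x2 + b3*x1*x2 + e

with `y` log2 TPM expression, `x1` the allele dosage (0/1/2), `x2` the
TMM-scale peak intensity. Terms are selected by backward AIC with
marginality; the interaction is tested with a partial F-test against the
additive null (`b3 = 0`); raw p-values are Bonferroni-adjusted over the
scan family with a default cutoff of adjusted p < 1e-7. Downstream
modules localise significant interactions relative to TADs (membership,
loop distance, enrichment odds ratios, capture windows, search-efficiency
profiles), classify coefficient sign patterns (synergy vs
redundancy/interference), scan sequences for transcription-factor motifs
with exact score p-values, and validate genotype-predicted CTCF binding
against replicate ChIP intensities across inbred strains.

A synthetic-data generator (`generate_genome()`, `plant_models()`,
`plant_ctcf_world()`) produces fully self-contained inputs with planted
ground truth, so every statistical claim the pipeline makes can be
checked against a known answer.

## Worked example

```r
library(geitad)

# a synthetic study: 2 chromosomes, 176 samples, planted model classes
cfg <- sim_config(chrom_lengths = c(chr1 = 60e6, chr2 = 60e6),
                  n_genes = 150, n_markers = 250, n_peaks = 350)
ds  <- generate_genome(cfg, seed = 42)
ds  <- plant_models(ds, truth_spec(class_props = c(interacting = 0.4,
                                                   additive = 0.2,
                                                   null = 0.4),
                                   b3_range = c(0.6, 1.2),
                                   intra_tad_prob = 0.9), seed = 43)

# TAD-constrained scan: every variant/peak within one TAD of each TSS
scan <- run_scan(ds, scan_plan("tad_constrained"))
scan
#> Genotype-by-accessibility scan (tad_constrained)
#>   fitted trios: 7268 (family size 7268); skipped 0 monomorphic,
#>   0 zero-variance; 0 collinear
#>   significant (adj. p < 1e-07): 44
#>   model classes:
#>      additive     atac_only genotype_only   interacting          null
#>           202           856           970          1305          3935

# where do the significant interactions sit relative to TADs?
enr <- boundary_window_enrichment(scan, ds$genes, ds$peaks, ds$tads)
enr
#> Intra-TAD enrichment of significant interacting models
#>           interacting other
#> intra_tad          28  2148
#> extra_tad           0  2669
#> odds ratio = 70.82 (Haldane-Anscombe corrected), Fisher p = 1.677e-10
#> 2423 boundary-proximal pairs (excluded from the default table)
```

The scan object is a classed S3 result: `summary(scan)` tabulates model
classes and unique genes/variants/peaks, `significant_models(scan,
"interacting")` extracts the hit table, and single trios fitted with
`fit_trio()` carry `coef()`, `summary()`, `predict()`, `residuals()`,
`simulate()` and `plot()` methods. (Counts above are what this exact
seeded example prints; the odds ratio says intra-TAD candidate pairs are
overwhelmingly more likely to be significant interactions, as planted.)

## Package layout

- `R/fit-trio.R` — trio OLS, backward AIC selection, classification,
  Bonferroni; the `trio_fit` S3 class.
- `R/scan.R` — scan plans, random and TAD-constrained drivers, the
  `gei_scan` class, truth-trio driver.
- `R/synthetic-data.R` — genome/TAD/feature simulation and model
  planting with a truth ledger.
- `R/tad-geometry.R` — TAD membership, loop distance, standardised
  coordinates, enrichment, capture windows, search profiles.
- `R/effect-taxonomy.R` — sign-pattern classification and magnitude
  summaries.
- `R/motif.R` — PWM container, exact-p-value scanning, SNP-in-motif
  density, peak annotation, effector subsets.
- `R/ctcf.R` — ChIP peak matrices, consensus calling, variance,
  genotype-binding association, subset rates, the planted CTCF world.
- `R/io.R` — BED/TSV/FASTA/PWM/JSON readers and writers.
- `vignettes/geitad-methods.Rmd` — the methods vignette: model,
  assumptions, tunables, generator scope, design decisions, limitations.
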