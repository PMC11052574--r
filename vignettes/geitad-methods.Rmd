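---
title: "Modeling genetic-epigenetic interactions within TADs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling genetic-epigenetic interactions within TADs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geitad)
```

## The model

Gene expression in a genetically diverse population varies with both local
genotype and local chromatin state, and these two factors need not act
independently. geitad models the expression of one gene as a function of
one genetic variant and one open-chromatin (ATAC) peak — a *trio* — with a
non-additive interaction term:

$$y_i = \beta_0 + \beta_1 x_{1i} + \beta_2 x_{2i} + \beta_3 x_{1i} x_{2i} + \varepsilon_i$$

where $y_i$ is log2 TPM expression in sample $i$, $x_1 \in \{0, 1, 2\}$ is
the dosage of the non-reference allele at a marker (heterozygotes are the
mid-point by construction), $x_2 \ge 0$ is the TMM-normalised peak
intensity, and $\varepsilon_i$ is i.i.d. Gaussian noise. The model assumes
a biallelic marker (multi-allelic markers are excluded upstream), no
kinship/batch covariates, and homoscedastic residuals.

Two devices decide what a trio "is":

* **Term selection.** Backward elimination from the full model using
  $AIC = n\,\ln(RSS/n) + 2k$ with $k$ the number of estimated
  coefficients. Marginality is enforced (the product term is dropped
  before either main effect) and ties within $10^{-12}$ are broken
  deterministically (interaction first, then $x_2$), so results are
  reproducible to the bit. The retained set maps to a model class:
  interacting, additive, genotype-only, ATAC-only, or null.
* **Interaction test.** A partial F-test of the full model against the
  additive null ($\beta_3 = 0$), $F = (RSS_0 - RSS_1)/(RSS_1/(n-4))$ on
  $(1, n-4)$ degrees of freedom. Raw p-values are Bonferroni-multiplied by
  the number of *attempted* fits in the scan batch (degenerate trios that
  were skipped are excluded from the family, and the skip counts are
  reported so a stricter family can be applied); the significance cutoff
  defaults to adjusted $p < 10^{-7}$.

Selection and testing are computed unconditionally for every trio; a
model is reported "significant interacting" when it both retains the
interaction term and clears the adjusted-p cutoff. Whether the original
analysis applied the F-test before or after selection is not determinable
from its description; computing both unconditionally reproduces their
joint use without ordering assumptions.

### Numerical choices

OLS is solved by QR (`lm.fit`); the test suite checks it against an
explicit normal-equations solve to $10^{-8}$ relative error. For the AIC
the RSS is floored at $10^{-12}\max(1, \sum y_i^2)$ so that numerically
perfect fits (noise-free synthetic data) rank by the parameter penalty
rather than by round-off noise in an RSS of order $10^{-29}$. A trio with
constant genotype or constant intensity raises a typed condition and is
skipped; a rank-deficient design (product column collinear with the main
effects) is emitted flagged, with the F statistic undefined.

## Scan modes

`run_scan()` supports two enumeration strategies. *Random mode* samples
distinct same-chromosome gene-variant-peak trios uniformly (seeded),
mirroring an exploratory genome-wide subset. *TAD mode* enumerates, for
every gene, all variants and peaks whose anchor (variant locus, peak
midpoint, gene TSS — strand-aware) lies in the gene's TAD or inter-TAD
region, or the region immediately up- or downstream of it. This "one TAD
either side" window is the deterministic search space implied by a
TAD-bounded view of local regulation.

## TAD geometry

TADs are intervals (0-based half-open, as all coordinates in the package);
the gaps between them are first-class *inter-TAD regions*. On top of
membership the package computes:

* **Loop distance** — a TAD behaves as a loop whose two boundaries are
  joined, so the distance between two intra-TAD positions is
  $\min(|a-b|, L - |a-b|)$, maximised at $L/2$ halfway around the loop.
  Standardised coordinates divide by $L$ and keep the linear-sequence
  sign, giving gene-centred profiles on $[-1/2, 1/2]$.
* **Intra-TAD enrichment** — a 2x2 table over the scanned gene-peak
  pairs (intra-TAD vs not x significant-interacting vs not) with the
  sample odds ratio $(ad)/(bc)$ and a two-sided Fisher exact p. Because
  the original construction of this table is not fully specified, the
  package documents its own: pairs are the unit, peaks within 200 kb of a
  TAD boundary are tagged boundary-proximal and excluded from the default
  table (both versions are returned). An empty cell triggers the
  Haldane-Anscombe 0.5 correction, flagged.
* **Capture window** — the smallest TSS-relative upstream/downstream
  distances containing a fraction $q$ (default 0.95) of significant
  interacting models. Marginal type-1 quantiles of the per-model
  most-upstream and most-downstream element offsets are used, yielding an
  asymmetric (upstream, downstream) pair; joint bivariate coverage rules
  were rejected as underdetermined — many windows satisfy them. Fewer than 20 models refuse with an error
  (the quantile is unstable).
* **Search-efficiency profiles** — per distance bin from the TSS, the
  percentage of peaks participating in significant interactions and the
  peak density, comparing a linear-sequence search with a TAD-limited
  search.

## Effect-sign taxonomy

For significant interacting models the signs of
$(\beta_1, \beta_2, \beta_3)$ classify the regulatory logic: all equal is
*synergy*; main effects agreeing but opposed by the interaction is
*redundancy/interference*; disagreeing main effects are *mixed*; a model
whose retained set lacks a required term is *incomplete*. Coefficients
within $10^{-12}$ of zero take sign zero and force the mixed label with a
flag — OLS on floating-point data produces exact zeros only in degenerate
constructions, so this tolerance is effectively a guard. Magnitude
summaries report how often $|\beta_3|$ exceeds $|\beta_2|$, $|\beta_1|$,
or both, and how often the ATAC main effect is negative; they are computed
over significant interacting models by default (a flag widens to all
significant models).

## Motif scanning

`scan_pwm()` scores every window on both strands with
$\log_2 P(w \mid \text{PWM}) / P(w \mid \text{background})$ (probabilities
floored at $10^{-4}$, the usual pseudocount, so zero entries stay finite).
Score p-values are exact for a discretised score: per-position scores are
rounded onto a 1000-bin integer grid (configurable) and the distribution
of total scores over all $4^L$ windows under the background is obtained by
position-wise convolution; the p-value of a window is the exact tail
probability of its discretised score. This guarantees validity — the
fraction of background windows at $p \le \alpha$ cannot exceed $\alpha$ —
which the suite verifies both against exhaustive enumeration at $L = 6$
and empirically on simulated background. The background defaults to
uniform; windows containing N are skipped; a window and its reverse
complement score identically on opposite strands by construction.

SNP density within motif hits is tabulated by strand-aware offset, and the
*negative effector* subset is defined as peaks carrying at least 10
significant interacting models of which at least half have $\beta_2 < 0$
(peaks clearing the count bar but not the sign bar form the positive
complement). Peak-to-annotation overlap uses the midpoint rule — a peak
counts for a category when its midpoint falls in any category interval —
because partial-overlap semantics are ambiguous for wide peaks, and the
midpoint rule is unambiguous and order-free.

## CTCF binding validation

Replicate ChIP intensities across inbred strains validate
genotype-predicted binding. A peak is *consensus* when detected (fold
enrichment above a floor, default 1) in at least two samples of at least
one strain; the per-peak count of strains meeting that same rule gives the
strain-sharing distribution. Per-peak intensity variance (n−1
denominator) summarises differential binding. Genotype-intensity
association uses Welch's two-sample t-test by default: the source
analysis names a paired Student's test, but allele groups spanning
different strains have no natural pairing, so the unpaired
unequal-variance test is the defensible default (a `var_equal` switch
recovers pooled-variance Student). Groups with fewer than two samples per
allele are flagged untestable rather than tested. Subset significance
rates compare the fraction of associations at $p < 0.05$ across
model-defined peak subsets; the *dense region* subset uses the TAD as its
region unit — peaks whose TAD holds more significant models than the
genome-wide mean — since the region unit was otherwise unspecified.

## What the synthetic generator emulates — and what it does not

`generate_genome()` tiles chromosomes with log-normal TADs (mean 1.1 Mb,
matching the field's canonical average) separated by optional exponential
gaps, places genes/markers/peaks uniformly, draws dosages per marker from
binomial(2, f) with f uniform on [0.2, 0.8] (the balanced allele
frequencies of an outbred panel), and draws peak intensities from a
per-peak log-normal (meanlog 1, sdlog 0.5). The default sample count is
176. Residual expression noise defaults to 0.5 log2 TPM. The intensity
distribution and residual scale are not published quantities for the real
data; both are exposed in the config and were fixed once at values a
practitioner would call realistic.

`plant_models()` assigns each gene a true model class, chooses its causal
marker and peak (inside the gene's TAD with configurable probability —
an error if intra-TAD placement is forced for a gene whose TAD holds no
candidates), draws coefficients with the class's zero pattern, and fills
expression from the generative formula, recording everything in a truth
ledger. `plant_ctcf_world()` builds background sequences with embedded
motif-consensus instances, injects biallelic SNPs into a configurable
fraction of sites (of which a configurable fraction actually modulate
binding — silent SNPs keep the association null calibrated), and
simulates replicate fold enrichments with a four-strain,
three-replicate, two-dropped-samples design (10 columns).

Deliberately **not** emulated: linkage disequilibrium between markers
(independent markers by default; the scan treats markers as given),
founder haplotype mosaics, read-level data, nested/hierarchical TADs, and
peak-calling artefacts. Passing tests on this generator therefore
demonstrate the pipeline's statistical correctness — calibration under
the null, recovery of planted effects, exactness of geometric and
combinatorial computations — not robustness to LD-confounded causal
inference, which no trio-at-a-time method can settle.

## Problem sizes and verification

The test suite verifies the OLS/F path against a normal-equations oracle
on 1,000 trios at n = 176, backward selection against exhaustive submodel
search on 500 trios, null calibration on a 100,000-trio all-null scan
(zero significant models; uniform raw p by Kolmogorov-Smirnov), planted
interaction recovery (≥95% classified interacting and significant at
$|\beta_3| \ge 0.5$, $\sigma = 0.3$; Wald interval coverage within 3% of
nominal), exact PWM p-values at motif length 6, and the ChIP consensus,
Welch, null-calibration and subset-ordering properties. These sizes keep
the full suite in the low minutes on one core while leaving binomial
sampling error well inside the asserted bands.

`scripts/acceptance.R` reruns the whole pipeline at comparable sizes from
a single seed and writes its headline numbers as JSON; the README
describes how to run it.

## Known limitations

* Bonferroni is deliberately conservative at genome scale; no FDR
  alternative is wired in because the downstream geometry consumes a hard
  significance set.
* The enrichment odds ratio depends on the documented table construction;
  other constructions (e.g. peak-level rather than pair-level units) give
  different numerators and are not comparable one-to-one.
* Welch's test with two or three replicates per strain has low power;
  subset *orderings* are stable in simulation long before individual
  rates are.
* The PWM p-value is exact only for the discretised score; with 1,000
  bins the discretisation error is far below any threshold used here.
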