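---
title: "Methods: single-cell analysis of checkpoint-blockade response with somatic-variant tumor identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell analysis of checkpoint-blockade response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbscl)
```

## The scientific setting

`icbscl` implements the computational analysis of a pre-clinical
single-cell study of combined PD-1/CTLA-4 immune checkpoint blockade
(ICB) in a clonal mouse model of invasive urothelial carcinoma.  The
study design it targets has three conditions — untreated control, ICB,
and ICB after CD4+ T-cell depletion (`ICBdT`) — with five biological
replicates each, profiled by droplet scRNA-seq, alongside bulk tumor and
matched-normal exome sequencing.  The analytic chain is:

1. **Somatic variants** — consensus-filter candidate calls and summarize
   the VAF distribution to establish clonality.
2. **Cell QC** — remove high-mitochondrial cells, top-UMI doublets,
   low-feature cells, then cells whose reference-based typing was
   rejected ("pruned"); filter lowly expressed genes.
3. **Tumor calling** — classify each cell as somatic-variant-containing
   from per-cell ref/alt allele counts at known variant sites.
4. **Subtyping** — basal/luminal marker rule plus cluster propagation,
   and a per-cell differentiation score.
5. **Differential expression** — Wilcoxon rank-sum per cell type per
   condition pair, BH correction, Seurat-convention fold changes.
6. **Gene-set screening** — hypergeometric overrepresentation, preranked
   GSEA, and a "sum of fold changes" metric, assembled into cell-type ×
   comparison matrices focused on the hallmark IFN-γ response set.

Because the study's raw data are not deposited, every stage is exercised
against a bundled synthetic-data generator with known ground truth.  A
green test establishes correctness of the *operations* on data shaped
like the study's — not a reproduction of the study's headline numbers.

## The statistical machinery

### Variant filtering and clonality

A candidate call is kept iff it is supported by ≥ 2 callers, normal and
tumor coverage are each **strictly** above 30 reads, normal VAF is
strictly below 5% and tumor VAF strictly above 5%.  All comparisons are
strict because the source criteria are phrased with ">" and "<";
boundary records (coverage = 30, VAF = 5%) are rejected.  Rejections are
counted per criterion independently, so one record can contribute to
several counts.  VAF columns may arrive as fractions or percentages; the
scale is auto-detected (max > 1.5 ⇒ percent) and logged.

The clonality summary reports the median tumor VAF (mean of the central
pair for even n), a binned histogram, the count of variants at VAF
exactly 1 (tolerance 1e-9), and the chromosome composition of that
subpopulation — in the motivating study the VAF = 1 variants concentrate
on the hemizygous X and a chr12 copy-loss region.  Mutation burden is
`n / target_size_mb`; the denominator is deliberately a parameter
because the appropriate target size (exome vs genome) is a property of
the capture design, not of this package.

### The QC cascade

* mitochondrial filter: `mito_pct > cutoff` (default 12.5, strict; the
  boundary convention is configurable because the source is silent on
  it);
* doublet filter: within each (replicate, condition) group of n cells,
  the `k = round(0.009 × n)` highest-UMI cells (half-up rounding, ties
  at rank k broken by lexicographic cell id so the flag set is
  deterministic and permutation-invariant).  A `per_1000` option scales
  the rate by group size, mirroring the per-1000-cells phrasing of the
  droplet chemistry's doublet model; the flat rate is the default
  because that is what the published filter applied;
* low-feature filter: `gene_count < cutoff`, strict.  The numeric cutoff
  is a config value; deriving it (via reference-based typing failures)
  is out of scope.

The union of the three QC flags is removed first; pruned cells are
removed second and counted separately, so either ordering can be
audited.  Genes are then kept only if, in **every** replicate, at least
2 cells support them with ≥ 2 UMIs.

### Tumor-cell classification

A variant position qualifies in a cell iff `ref + alt > 20`, `alt > 5`
and `alt / (ref + alt) > 0.10` (all strict); a cell is
variant-positive iff ≥ 2 positions qualify.  Coverage is the sum of
counted ref and alt reads at the position in that cell, matching the
semantics of allele-counting tools that assign reads to barcodes.
Cells with no covered position are negative (not missing); an
`n_covered_positions` column supports sensitivity analyses.  Lowering
any threshold can only add positives (tested monotonicity).

### Subtyping and the differentiation proxy

The marker rule is detection-based on the raw UMI layer: Krt5 > 0 and
Psca = 0 ⇒ basal; Psca > 0 and Krt5 = 0 ⇒ luminal; double-positive and
double-negative cells are unassigned (the source rule is silent on
double-positives; leaving them unassigned is the conservative reading).
Cluster propagation assigns each cluster the majority label of its
marker-labelled seeds; ties and seedless clusters stay unassigned, and
marker-labelled cells are never relabelled.

The differentiation score is `1 − stemness`, where stemness is a
**deliberately simplified proxy** for the published CytoTRACE score: per
gene, the Pearson correlation with per-cell detected-gene counts is
computed on the log-normalized layer; the mean expression of the 200
most-correlated genes is rank-transformed to [0, 1].  The full published
algorithm adds similarity-graph smoothing, which is not reproduced; only
the core gene-counts signature and the `1 − score` convention are.
Scores are therefore comparable within a data set, not across data sets.

### Differential expression

Normalization is `ln(1 + count × 10^4 / cell_total)`.  The rank-sum p
uses the normal approximation with tie correction and continuity
correction — numerically identical to `wilcox.test(exact = FALSE,
correct = TRUE)` — because that is the approximation the field's tools
apply at scRNA-seq group sizes.  At very small groups the approximation
deviates from exact enumeration by up to 0.031 (worst case at n = 4 vs
4, at p ≈ 0.34; below p = 0.2 the deviation is < 0.007).  The fold
change copies the Seurat convention
`log2(mean(expm1 a) + 1) − log2(mean(expm1 b) + 1)` because downstream
metrics (GSEA ranking, sum of fold changes) consume exactly that
statistic.  BH adjustment is the standard step-up with cumulative
minimum.  DE genes are selected with strict cuts (`p_adj < 0.05`,
`|log2FC| > 0.26` by default; the stricter `> 1.58` regime used for
subtype contrasts is the same operation with a different parameter), and
an exclusion list supports "unique to treatment" subtractions.  No
minimum-detection prefilter is applied by default because the source
pipeline states none.

### Gene-set statistics

* **ORA**: upper-tail hypergeometric `P(X ≥ k)` with the detected-gene
  universe as the population; q-values are BH across tested sets.
* **Preranked GSEA**: the weighted running sum gains
  `|score|^w / Σ_hits |score|^w` at members and loses `1/(N − N_hits)`
  at non-members; ES is the signed extremum.  The null permutes set
  membership (the preranked convention — phenotype permutation is not
  possible without per-sample labels).  NES divides ES by the mean
  |null ES| of matching sign, following the published normalization.
  The permutation p counts **all** null ES values at least as extreme in
  absolute value, `(1 + #{|ES_null| ≥ |ES|})/(n_perm + 1)`: a
  sign-restricted count over the same denominator would make the p-value
  a non-uniform mixture; the two-sided count keeps it exchangeable, so p
  is uniform on its achievable grid under a random set (a tested
  property) and bounded below by `1/(n_perm + 1)`.
* **Sum of fold changes**: the sum of `avg_log2fc` over every detected
  set gene, with no significance filter — a cheap signed, magnitude-aware
  screen.  Positive values mean the set skews up in the first condition
  of the comparison.  It is additive over disjoint sets and negates
  exactly under comparison reversal.

## What the synthetic generator emulates

The generator (`sim_config()`, `simulate_variant_table()`,
`simulate_counts()`, `simulate_allele_counts()`) encodes the study
design as its defaults: 5 replicates × 3 conditions, a 15-type cell
mixture with planted markers, clonal tumor VAFs (clipped normal, mean
0.5, sd 0.08) with a 1.6% VAF = 1 subpopulation placed on chrX with
probability 0.708, and the IFN-γ response set planted ×2 up under ICB in
endothelial cells, neutrophils and luminal tumor cells and ×0.5 down in
macrophages and monocytes — the qualitative pattern the motivating study
reports.  Default scale is 500 cells/sample (7,500 cells), 2,000 genes,
1,000 variants: large enough for every tested property, small enough for
a laptop.

Counts are negative-binomial (dispersion 2) with log-normal gene means
and a log-normal per-cell library factor (sd 0.3), so the top-UMI
doublet rule has genuine signal.  Planted QC failures: high
mitochondrial percentages (uniform 15–60%), 2.5× library inflation for
doublets, 0.08× expression for low-feature cells.  Receptor status is
planted with 80% detection sensitivity in the true lineage and 5% of
detections relocated onto out-of-lineage cells, so receptor/label
concordance lands near 95% — a symmetric flip model would instead be
dominated by false positives from the large out-of-lineage population
and sit near 70%, which contradicts the concordance the design intends.

Stemness is planted as transcriptome **breadth**, not depth: a program
of 30% of the background genes (means floored at 0.3 so they sit above
the detection limit) is scaled by `0.1 + 2.4 × s` with per-cell stemness
`s ~ Beta(5, 2)` for basal and `Beta(2, 5)` for luminal cells.  A
uniform per-cell scaling would be removed by library-size normalization
and carry no recoverable signal; breadth survives normalization, which
is exactly the empirical signature the gene-counts proxy exploits.
Likewise, planted DE effects live on expressed genes: a 2× effect on a
gene with mean 0.01 UMIs is unrecoverable at any sample size.

Allele counts model the variant-coverage process as: each variant
covered in each cell with probability 0.02, depth Poisson(30), alt reads
binomial at the true VAF in tumor cells and at an error rate of 0.002 in
normal cells.  The Poisson depth is an assumption (the source does not
state the depth distribution); `ref + alt` equals the simulated depth at
every covered position by construction.

**What it does not emulate**: ambient RNA, doublet transcriptome mixing
(doublets are only deep libraries), batch effects, read-level error
profiles, and real clustering structure (cluster labels mirror cell
types, with tumor cells split by true subtype).  Tests that pass on this
world certify the operations' logic, not robustness to those artifacts.

## Numerical choices and degenerate inputs

* Median of an even-length VAF list = mean of the central pair.
* VAF = 1 matching uses a 1e-9 tolerance on the fraction scale.
* Zero-coverage allele positions never qualify (no division by zero).
* An empty variant table, empty universe, empty gene list, a gene set
  spanning the entire ranking, constant per-cell gene counts, and cells
  with zero totals are all defined errors, not NaNs.
* Doublet rounding is half-up (`floor(rate × n + 0.5)`); groups smaller
  than `1/(2 × rate)` therefore flag nothing.
* `k = 0` overlap gives ORA p = 1 by construction of the upper tail.
* DE comparisons with < 3 cells per group are skipped and logged, and
  screening matrices mark them `NA` rather than 0.

## Design choices where the design was open

* **Boundary strictness** everywhere follows the printed inequalities;
  each is configurable because inclusive readings cannot be excluded.
* **Coverage clauses**: separate normal/tumor thresholds are
  implemented (the Methods formulation) rather than the looser "total
  coverage" phrasing that appears once in the Results.
* **Marker pair**: Krt5/Psca (the Methods rule); the display-oriented
  Krt14 alternative is reachable by passing different marker vectors.
* **Mutation-burden denominator**: exposed, never hard-coded; 2,500 Mb
  is only the pipeline default.
* **Pruned-cell ordering**: QC union first, pruned second, each counted
  separately.
* **GSEA p-value convention**: two-sided over all permutations (see
  above) with sign-matched NES normalization.

## Known limitations

* The differentiation proxy is not CytoTRACE; rankings agree with the
  planted program (Spearman > 0.8 in the tested world) but absolute
  values are not comparable to published CytoTRACE scores.
* The Wilcoxon p is an approximation; below ~8 cells per group its
  worst-case deviation from the exact null reaches 0.03.
* The VCF reader covers the AD/DP two-sample dialect only; the TSV
  dialect is the first-class input format.
* No multi-set GSEA FDR machinery: per-set permutation p plus BH across
  sets stands in for it at desk scale.

## End-to-end use

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "run1", seed = 1)
run_pipeline(cfg)  # simulate -> variants -> qc -> tumor-call ->
                   # subtype -> de -> enrich; manifest.json records
                   # parameters, seed and input checksums
```

Each stage writes plain files (TSV/MTX/JSON) so any stage can be re-run
from cached upstream outputs byte-identically; `inst/cli/icb-scl`
exposes the same stages as a command line.
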