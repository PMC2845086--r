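---
title: "Cross-tissue enrichment of transcriptional programs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue enrichment of transcriptional programs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossgsea)
```

## The question the pipeline answers

Do the genes that distinguish a genetic subtype of leukemia from the other
subtypes look like the genes that distinguish one normal tissue or cell
population from the rest of its panel? `crossgsea` formalises that question
as a two-stage computation:

1. **Signature construction.** From a reference expression panel (tissues,
   sorted hematopoietic populations, tumor types), derive for each group a
   pair of directed gene sets — the genes up- and downregulated in that
   group relative to the remaining samples.
2. **Cross-dataset enrichment.** In a second, independent dataset with its
   own grouping (leukemia genetic subtypes such as *ETV6/RUNX1*, HeH,
   *TCF3/PBX1*), rank all genes by each subtype's one-vs-rest differential
   statistic and test every reference gene set for enrichment at either end
   of that ranking. The result is a subtype × gene-set matrix of normalized
   enrichment scores, masked to the cells that survive a permutation FDR.

A positive score for a `*_UP` set means the subtype's upregulated genes are
enriched for that tissue's upregulated program; a positive score for a
`*_DN` set means the subtype upregulates what the tissue downregulates.
Both stages work on log2-scale expression matrices with sample group
labels, read from GCT 1.2 / CLS / plain TSV, with gene sets in GMT.

## Preprocessing

Reference panels pass through the chain
`floor_values() |> mean_center() |> variation_filter()`:

* **Intensity floor** (`floor_linear = 10`): linear intensities below 10
  are raised to 10 (`log2(10)` ≈ 3.32 on the log2 scale). Intensities in
  that range are dominated by array background, and flooring stops
  background ratios from producing spurious t statistics. The floor is
  interpreted on the *linear* scale: flooring log2 values at 10 would mean
  intensity 1024 and erase most of the data. The matrix carries an explicit
  scale tag (`expr_matrix(..., scale=)`); the scale is declared, never
  sniffed, precisely because this step depends on it.
* **Mean-centering**: each gene is expressed as deviation from its own
  across-sample mean.
* **Variation filter** (`sd_min = 0.5`, sample SD with n−1 denominator):
  genes whose across-sample SD falls below 0.5 log2 units carry no usable
  contrast and are removed; genes at exactly 0.5 are kept. The *test*
  (leukemia) dataset is deliberately **not** variation-filtered — the gene
  universe the enrichment walks must stay complete — so the pipeline
  applies the filter per dataset, not globally.

Probe-level matrices are first reduced to gene symbols with
`collapse_probes()`: probes hitting multiple genomic loci are removed, then
each gene keeps the whole row of its probe with the highest mean expression
(the dominant collapse convention; an element-wise maximum is available via
`mode = "max_element"`). Replicate hybridizations are averaged with
`aggregate_samples()` before signature construction when the panel was run
in duplicate.

## Signature construction

For each reference group, `contrast_statistics()` computes a per-gene
two-sample t of the group against all remaining samples. The default is the
**Welch** (unequal-variance) statistic with Welch–Satterthwaite degrees of
freedom: only group means and within-group variances enter it, it is robust
to the unbalanced one-vs-rest design, and a pooled-variance variant remains
available (`var_equal = TRUE`) for sensitivity checks. Per-group variances
are floored at 10⁻⁶ (log2 units²) so constant rows give t = 0 rather than
NaN; the floor only touches pathological inputs.

P-values are adjusted by Benjamini–Hochberg (`fdr_adjust()`), the default
meaning of "FDR" for microarray-era gene lists. `build_gene_sets()` keeps
genes with q ≤ 1% and, when many more pass, truncates to the 300 genes of
largest |t| per direction — truncation is deterministic, with |t| ties at
the boundary broken by gene symbol. The surviving list is split by sign of
t into `<group>_UP` and `<group>_DN` sets; the direction lives in the name
suffix and the source group in the GMT description field, which keeps the
collection plain standard GMT. The cap is applied per direction because the
sets are emitted per direction; a combined-list cap is available
(`cap_scope = "combined"`). Finally `filter_by_size()` drops sets with
≤ 15 or ≥ 500 members (after intersection with the test dataset's gene
universe, when one is supplied) and logs each exclusion with its size.

Whether a 1% FDR cut refers to BH-adjusted values or some other estimator
is genuinely open for this kind of pipeline; BH was chosen as the
conventional reading and is isolated behind `fdr_adjust()` so the choice is
one function.

## The enrichment engine

`rank_genes()` orders all genes by descending one-vs-rest t. Ties are
broken by gene symbol, ascending for positive scores and descending for
negative ones, so relabeling the two sides negates the statistic *and*
exactly reverses the list — determinism across platforms without breaking
the swap symmetry.

`enrichment_score()` walks the ranked list with a Kolmogorov–Smirnov-style
running sum: at a gene-set hit it rises by `|score|^p / Σ_hits |score|^p`,
at a miss it falls by `1/(N − n_set)`, so the walk always terminates at
zero. The enrichment score (ES) is the signed extremum of maximum absolute
deviation, bounded in [−1, 1]; the **leading edge** (core enrichment genes)
are the hits at or before a positive extremum, or at or after a negative
one. Two weight exponents are supported: `weight = 1` (hits weighted by
|score|; the default, matching the GSEA software tradition) and
`weight = 0` (the unweighted, classic KS form). The unweighted description
and the weighted software default are both defensible readings of how such
analyses were run; the duality is surfaced in configuration rather than
resolved by assumption. If every hit score is exactly zero the weighted
increment degenerates and the walk falls back to equal hit weights.

`permutation_null()` builds the null by **phenotype permutation**: sample
labels are reshuffled with the target group size preserved, all genes are
re-ranked with the same metric, and every set's ES is recomputed — gene–gene
correlation is preserved under the null, which gene-tag shuffling would
destroy. The default is 2000 permutations; when fewer distinct label
assignments exist than requested (e.g. C(4,2) = 6), all assignments are
enumerated instead. Permutations are drawn in a private RNG stream derived
from the root seed and the target label, so results are independent of set
iteration order and identical seeds give bitwise-identical null arrays.

`normalize_and_test()` divides the observed ES by the mean magnitude of
same-sign permuted ES, giving the **NES**; the nominal p is the add-one
estimator `(1 + #{same-sign null at least as extreme}) / (1 + #same-sign
null)`, never exactly zero at finite permutations. A set with no same-sign
nulls reports a missing NES (with a warning) rather than a sign hack.
`fdr_q()` estimates the FDR of each enrichment from the null NES pooled
across sets (each permutation ES normalised by its own set's same-sign
mean): for positive NES\*, q = (fraction of pooled positive null NES ≥
NES\*) / (fraction of observed positive NES ≥ NES\*), clipped at 1,
mirrored for negative scores, and made monotone in |NES| by a running
minimum from the least extreme set inward. Cells with q ≤ 0.25 are called
significant — an enrichment expected to be real three times out of four,
the conventional exploratory threshold for this method.

## The cross-enrichment matrix

`run_matrix()` repeats `run_gsea()` for every subtype with at least two
samples and assembles the long table behind the subtype × set grid.
`export_matrix()` writes four artifacts: the masked grid (NES printed only
for significant cells, as enrichment figures conventionally show), the
complete table (every ES/NES/p/q — always retained for auditability;
masking is an export concern only), per-cell leading-edge gene lists, and a
YAML manifest of all parameters and seeds. FDR is estimated within each
subtype's run by default, mirroring per-phenotype invocations of the
original tooling; `global_fdr = TRUE` pools across the whole grid instead.
Neither mode is claimed to be the historical intent; both exist because the
choice is not recoverable from published descriptions.

## The synthetic study and what it can show

`synthetic_design()` / `generate_datasets()` stand in for the microarray
accessions a real run would use. The generator plants group-specific
up/down modules on a shared gene universe: each value is
`baseline_g ± effect + N(0, noise_sd)`, with per-gene baselines
N(7, 1) log2 units drawn once and shared between the two datasets (decouple
them to emulate platform shift). Defaults — the package's standing study
conditions — are: 5000 genes; five reference tissue groups of 10 samples;
three leukemia-like subtypes (*ETV6/RUNX1*, HeH, *TCF3/PBX1*) of 12
samples; 100-gene modules; effect 1.5 log2 units (≈ 2.8-fold); noise SD
1.0; and one planted overlap in which the first subtype's up-module shares
`floor(0.5 × 100) = 50` genes with the first tissue's up-module (overlap
rounding is floor, for determinism). Group sizes of ~10–12 and ~1.5-log2
subtype effects are typical of the microarray panels this pipeline
addresses; module size 100 matches the "top ~100 genes per program" scale
of such signatures. Non-overlap modules are drawn disjoint from every
module of the other dataset so unplanted cells are true nulls.

The generator emulates exactly the structure the analysis assumes —
additive group shifts, i.i.d. Gaussian log2 noise, exchangeable samples
within groups. It does **not** emulate batch effects, intensity-dependent
variance, probe saturation, correlated gene modules beyond the planted
ones, or missing values. Passing tests therefore certify the *inferential
machinery* (scores, permutation null, FDR, determinism), not robustness to
real microarray artifacts; `add_probe_layer()` adds a minimal probe-level
wrapper only so the collapse step is exercised.

One property of the one-vs-rest design is worth knowing when reading
results: genes planted in subtype A's up-module sit in the "rest" of every
other subtype's contrast, so a gene set overlapping A's module tends to
show *negative* enrichment in the other subtypes. That is a real feature
of one-vs-rest contrasts, not a false positive, and the package's own
validation treats such coupled cells separately from true null cells.

## Numerical and testing choices

* Problem sizes in the test-suite experiments — 800–1200-gene universes for
  calibration fixtures, 500 permutations and 20 replicate end-to-end runs,
  200 calibration replicates — were chosen as the smallest sizes at which
  the binomial tolerances quoted in the tests are meaningful.
* Exact-recovery validation of the builder uses noise SD 0.3 with the
  standard effect 1.5 (five noise SDs) and runs the documented
  floor→center→filter chain first: at any noise level the BH step admits on
  the order of 1% false members among discoveries, and it is the variation
  filter — part of the pipeline, not of the test — that removes the null
  genes which would otherwise make exact set equality a coin flip.
* The running sum is validated against an independently coded brute-force
  walk (and, for the weighted form, against an external implementation) to
  1e-10; conservation (walk ends at 0) to 1e-9.
* Extremum ties: with the unweighted form the running sum can tie exactly
  at opposite-sign extrema (the increments are rationals). The extremum is
  defined as the earliest position whose |S| is within one ulp (relative
  1e-12) of the maximum, which also makes the choice independent of
  floating-point summation order.
* Seeds: a single root seed; per-(target, stream) seeds are derived
  deterministically and kept below 2³¹ − 1. All generator and permutation
  code restores the caller's RNG state.

## Known limitations

* Only the t statistic is implemented as a ranking metric
  (signal-to-noise and other multi-class metrics are out of scope), and
  only phenotype permutation (no gene-tag permutation, no preranked mode).
* BH is the only gene-level FDR for signature construction; moderated
  (empirical-Bayes) t statistics are deliberately not offered.
* The permutation FDR is the pooled-null estimator; with very few sets per
  run it is noisy, which is inherent to the method rather than to this
  implementation.
* gcRMA/quantile normalization and CEL-file handling are out of scope:
  inputs are assumed to be already-normalized log2 matrices.
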