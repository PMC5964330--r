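---
title: "Calling promoter chromatin states and testing their transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling promoter chromatin states and testing their transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromstates)
```

# The problem

Post-mitotic neurons must keep alternative fate programs off for a lifetime.
One layer of that stability is the combinatorial deposition of histone
modifications at promoters: the permissive H3K4me3 (K4), the
Polycomb-associated H3K27me3 (K27) and the heterochromatin-associated
H3K9me3 (K9). With low-input native ChIP-seq it is possible to profile all
three marks in a few thousand sorted nuclei — for example midbrain
dopaminergic neurons, raphe serotonergic neurons and embryonic neural
progenitors — and couple the resulting promoter *chromatin states* to
matched expression data. `chromstates` implements that analysis as a tested,
reusable pipeline, from window counts to state-transition enrichment,
together with a simulator that provides ground truth for every stage.

# Mark calling at TSS regions

## Model

For each gene we define a promoter region of `2 * half_width` bp (default
20 kb) centered on the TSS, clipped and flagged at chromosome ends. Regions
are tiled with mark-specific sliding windows: 150 bp every 50 bp for the
punctate K4 signal (398 windows per full region), 1000 bp every 100 bp for
the broad K27 and K9 domains (191 windows). Reads enter as 5′ positions with
strand; each is extended to a 170-bp fragment and increments every window its
fragment overlaps by at least one bp. All coordinates are 0-based half-open;
BED inputs conform as-is, and the annotation TSS is documented as 0-based
(the TSS convention of any particular annotation source is data, not logic).

Two filters remove uninformative windows before testing:

* **minimum count** — the summed count over all ChIP and input samples of the
  contrast must be at least 20 (inclusive);
* **global background** — the per-bp window rate must exceed the median rate
  of disjoint 10-kb genome bins by strictly more than log2 fold-change 2.
  The median was chosen as the background summary because it is robust to
  the minority of bins that contain truly enriched regions; a pseudo-count of
  0.5 is added to both counts so zero windows are well-defined. The two
  filters are independent masks and therefore commute.

Composition bias between samples is corrected with TMM factors computed on
the same 10-kb bins (unweighted trimmed mean of M values, 30 % trim on M,
5 % on A, reference column by upper quartile; factors are rescaled to
geometric mean 1 and multiply the library sizes). Genome-wide bin totals are
also used as the library sizes, which matters for designs without replicates:
with one sample per group the group effect is otherwise confounded with any
depth normalization computed on the windows themselves.

Each surviving window is tested ChIP vs input with a negative-binomial GLM
with group term and log effective library size offsets. With residual degrees
of freedom the dispersion is estimated with empirical-Bayes shrinkage toward
a mean trend and the test is the quasi-likelihood F-test (edgeR's machinery);
with a single sample per group — a realistic situation when replicates are
pooled for coverage — the model is fit at a fixed dispersion of 0.05 and a
likelihood-ratio chi-square test is used, and every such row is flagged
`lrt_fixed_disp` in the output. The contract we verify is *calibration*, not
numeric identity with any particular implementation: under a simulated null
(equal NB means, 3 vs 3 samples, 2000 windows) the fraction of p < 0.05 must
sit inside the 99 % binomial interval around 0.05, and the test suite checks
exactly that.

Window p-values are combined per gene with the Simes rule
`min_i m p_(i) / i`, which is valid under the positive dependence typical of
overlapping windows, and genes are corrected with Benjamini–Hochberg. A gene
is *marked* when FDR < 0.05, strictly. Genes whose windows were all filtered
are reported as untested and treated as unmarked — they stay in the universe,
because dropping them would bias every downstream enrichment. A window that
falls inside two genes' overlapping regions contributes to both genes.

## Designs with and without replicates

Pooling replicates increases coverage for rare populations but removes the
residual degrees of freedom the QL test needs. The package supports both: the
replicated path is preferred whenever both groups have two or more samples,
and results carry a per-row `method` flag so mixed analyses stay auditable.
The fixed fallback dispersion (0.05) is a typical ChIP-seq value; it is a
configuration field, not a constant.

# Chromatin states, abundances and profiles

The three binary calls map bijectively onto 8 states. Compound labels order
the marks K4, K9, K27 — `"K4/K9/K27"`, `"K9/K27"` — and the canonical level
order (K27, K4, K4/K27, K4/K9, K4/K9/K27, K9, K9/K27, None) makes output
tables diff-stable. `state_to_marks()` inverts the mapping, which the tests
use to verify the truth table exhaustively.

`state_abundance()` reports per-state counts and fractions (summing to 1).
`average_profile()` averages 10-bp binned, RPKM-scaled coverage per state,
reversing minus-strand genes so profiles read 5′→3′; orientation is
switchable since some pipelines deliberately keep genomic orientation. A
state with no member genes yields NA, never zeros, so empty states cannot
masquerade as unmarked signal. RPKM here is the track-style definition:
reads per kilobase of bin per million retained reads.

# Transition enrichment

Two cell types define a 64-cell transition matrix over an explicit gene
universe — universe membership is always an argument, never inferred, because
published analyses differ in whether untested or unexpressed genes are kept.
Genes missing from an assignment are counted as `None` with a warning.

Enrichment of a gene set in a transition (or a single state) uses the
standard disjoint 2×2 table — set vs complement, in-category vs not. The
"set vs all genes" phrasing common in figure legends does not give a valid
Fisher table because the rows overlap; the disjoint construction is what the
test actually requires. We report the raw cross-product odds ratio, applying
the Haldane–Anscombe +0.5 correction only when a zero cell occurs (flagged);
the p-value is the exact two-sided Fisher probability and is unaffected by
the correction. BH correction is applied within one comparison's family (64
transitions, or 8 states); separate gene sets (up vs down) are corrected
separately, matching per-figure reporting. The degenerate case set = universe
returns OR 1 and p 1, because the complement is empty and there is no
contrast. Fisher p-values are computed from hypergeometric point
probabilities (the same rule as `stats::fisher.test`, asserted equal in the
tests) so that a 64-test comparison costs ~2 ms and null calibration with
10,000 random gene sets is feasible in the suite.

`proportion_summary()` reports per-category counts with one-decimal
percentages of the set — the "n = 93, 34.2 %" bookkeeping form used in the
literature — and the acceptance tests reproduce seven reference percentages
exactly from their component counts.

# Expression integration

RPKM follows its definition exactly (`count * 1e9 / (length * lib_size)`),
and a gene is *silent* when log2(mean RPKM + 1) < 1 — equivalently mean
RPKM < 1; the tests assert the two forms agree. Per-state expression is
summarized with box statistics and a two-sided Wilcoxon rank-sum test of the
member genes against all others (exact for small groups, verified against
full rank enumeration up to group size 8).

Single-nucleus QC removes nuclei more than k = 3 MADs *below* the median
(one-sided, strict) on log library size and log detected genes; the MAD uses
the 1.4826 consistency constant, making the rule scale-equivariant. The
highly-variable-gene decomposition fits a loess trend of total variance vs
mean; the fitted value is the technical component, the excess is biological,
and a gene is an HVG when its total variance significantly exceeds
(technical + 0.5) under a scaled chi-square with n−1 degrees of freedom, at
BH FDR ≤ 0.05. The default span is 0.3: spans as small as 0.03 are
appropriate for transcriptome-scale inputs (tens of thousands of genes) but
leave too few local points below a few thousand, so the small value is an
argument rather than the default. HVG pair correlations use Spearman's rho
with a permutation p of the standard add-one form, reproducible under a seed.

The TRAP regulated-gene selection combines three sets: capture-fraction DE
genes, unbound-fraction DE genes, and capture-enriched genes. The selection
sentence in common protocol descriptions is grammatically ambiguous — does
"not enriched" qualify the subtracted unbound genes, or gate the final set?
Both readings are implemented: the default `gate_final` rule is
`(trap_de \ ub_de) ∩ trap_enriched`; the alternative `subtract_filtered` is
`trap_de \ (ub_de \ trap_enriched)`. We do not assert which reading any
particular study used; the rule is recorded in the output.

# The simulator

The generator emulates the structure of a low-input ChIP-seq + nuclear
RNA-seq study: per mark, one pooled ChIP sample against three input
replicates; NB counts with variance μ + φμ², φ = 0.05 (a typical ChIP-seq
dispersion); an input rate of 0.02 reads/bp (≈20 reads per broad window);
8-fold enrichment for a present mark. Enrichment geometry follows the
observed mark behavior: K4 is a TSS-centered Gaussian (sd 500 bp); K27 is
TSS-centered (sd 2000 bp) in K27 and K4/K27 but covers the whole 20-kb
region when co-occurring with K9; K9 is broad and attenuated to half its
log-fold when K4 is present. Profiles are parametric rather than learned —
sufficient for the state caller to face the qualitative geometry it must
distinguish, which is all the recovery tests require.

Expression is normal on the log2(RPKM + 1) scale around state-specific means
ordered K4 > K4/K27 > other K4-containing ≈ K27 > K9-containing/None.
Regulated gene sets are drawn by weighted sampling without replacement; when
the weights partition genes into two groups (the usual planted-odds-ratio
design) the weighted-group count is drawn from the exact Fisher noncentral
hypergeometric distribution, so the planted odds ratio is the actual odds of
the sampling process rather than an approximation. The single-nucleus
generator spreads inlier depths uniformly in log over a bounded range
(20,000–200,000 reads) with heavy-tailed gene abundances so the number of
detected genes tracks depth smoothly, and plants outliers at 500 reads —
a clean-separation regime in which the 3-MAD filter provably isolates the
planted outliers (98 nuclei → 89 passing, on every seed tested).

What passing tests on these simulations do **not** show: robustness to
mappability and GC bias, to copy-number differences between samples, to
fragment-length misspecification, or to enrichment shapes outside the
parametric family above. Real analyses should inspect the per-window output
and the coverage profiles rather than trust the state labels blindly.

# Numerical choices and degenerate inputs

* Pseudo-count 0.5 on both rates in every fold-change computation.
* Strict inequalities where the conventional thresholds are strict: background
  log2FC > 2, mark FDR < 0.05, silent log2(RPKM+1) < 1, QC "more than
  3 MADs below".
* All-zero windows: p = 1, logFC = 0, never NA.
* An all-zero background is an error (degenerate input), not a silent pass.
* MAD 0 on a QC metric: every nucleus passes that metric, with a warning.
* Constant genes in correlation analysis are skipped and flagged.
* Ties in the TMM trimming are resolved by the two-sided rank rule, so tied
  M values share a fate.

# Problem sizes used by the tests

The suite and the acceptance script run at deliberately small scale — 150
genes for end-to-end state recovery, 2000 windows for null calibration,
10,000 random gene sets for the enrichment FDR check, 50 replicates for the
planted odds-ratio recovery — sizes at which every statistical contract can
be checked in a couple of minutes while remaining far above the regime where
the asymptotics would be in doubt.

# Session

```{r}
sessionInfo()
```
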