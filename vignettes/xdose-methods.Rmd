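---
title: "Models and methods behind xdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

xdose analyses X-linked gene expression in XX/X0 systems: whether the
single male X is transcriptionally compensated relative to the two
female copies, whether it is silenced beyond the two-fold copy-number
expectation in the male germline (meiotic sex chromosome inactivation,
MSCI), and the chromatin and tissue-specificity correlates of both. This
vignette documents the models, conventions and numerical choices behind
every stage, and what the bundled synthetic-data generator does and does
not emulate.

# The quantities

All expression comparisons are built on the per-gene log2 ratio of
male to female mean expression, computed on RPKM within a
tissue × stage group:

* complete dosage compensation: X ratios match autosomal ratios (≈ 0);
* no compensation: X ratios at −1 (one copy against two);
* MSCI: X ratios *below* −1 — copy-number loss alone cannot push the
  ratio past −1, so a significant deviation below it implies active
  silencing.

The ratio of means (average RPKM per sex first, then the ratio), not
the mean of per-replicate ratios, is used throughout; genes with a zero
mean in either sex are excluded from ratio analyses rather than
rescued with a pseudo-count (a pseudo-count option exists, off by
default, because it biases ratios for lowly expressed genes in a
direction that depends on expression level).

# Synthetic study generator

## Count model

Counts are negative binomial with variance `mu + phi * mu^2` and a
single common dispersion `phi` (default 0.05, a typical RNA-seq
replicate-level value). The expected count of gene *g* in sample *j* is

```
mu_gj = baseline_g / 2 * factor_g * bias_g * tissue_g * depth_j
```

* `baseline_g` — log-normal (sdlog 1), rescaled so that a nominal
  sample sums to `mean_library_size` reads (default 2e6). The shape is
  arbitrary but fixed; the heavy tail matters because it makes TMM
  trimming non-trivial.
* `factor_g` — X copy number times regulation: autosomes 2 in both
  sexes; female X 2 (or 2 × 0.5 under `female_downregulation`); male X
  1 (`none`), 2 (`complete_upregulation`), or
  `(1 − g) * 2 + g * 2 * residual` under `msci_mixture`.
* `bias_g` — a `sex_bias_fold` (default 4) multiplier in the biased sex
  for the `sex_biased_fraction` of genes (half male-, half
  female-biased).
* `tissue_g` — tissue-specific genes (a configurable fraction) keep
  full expression in one home tissue and drop to
  `tissue_specific_leak` (default 0.1) elsewhere.
* `depth_j` — per-sample relative depth, log-normal with sdlog 0.2, so
  normalization is always exercised.

The MSCI regime is a *tissue-level mixture*, not a per-cell model: a
bulk gonad sample is a fraction `g` of meiotic germ cells whose X
retains only `residual` of its per-copy activity, plus `1 − g` of
fully compensated somatic cells. This matches bulk RNA-seq designs; it
cannot represent cell-to-cell heterogeneity, and conclusions about
individual cells do not follow from it.

The germ-fraction defaults used in the analysis scripts (0 at the
first nymphal stage, 0.8 at the fourth when meiosis I dominates the
gonad, 0.6 in adults where accessory somatic tissue is larger) are
illustrative settings for a hemimetabolous insect design, not measured
values.

## Coverage model

DNA coverage is Poisson per window, with the rate halved on the X for
male libraries (hemizygosity). ChIP/input pairs share one tiling;
input is Poisson everywhere and ChIP is Poisson with a
`chip_x_enrichment`-fold rate on X windows — a chromosome-wide mark,
deliberately without peak structure. Mapped-read counts are derived
from the simulated depths assuming 100 bp reads.

## What the generator does not emulate

Read-level artifacts (mappability, GC bias, PCR duplicates),
positional structure along chromosomes (every gene on a scaffold is
exchangeable), annotation errors, batch effects, and per-cell
expression variation. Passing tests therefore validate the statistical
machinery and its conventions — not robustness to these real-data
complications.

# Stage-by-stage conventions

## X identification

Tracks are normalized to depth per million mapped reads; the
per-window statistic is `log2((m + p)/(f + p))`. Scaffold medians
below −0.5 are called X-linked, above −0.25 autosomal, anything else
(including exact threshold hits and scaffolds with fewer than 5 usable
windows) ambiguous. The thresholds are midpoints between the expected
−1 and 0 and are configurable; real analyses of this kind are often
decided visually, so the defaults are deliberately generous.

The pseudo-count `p` and the minimum-depth filter are *relative*
constants (fractions of the genome-wide mean depth; defaults 0.01 and
0). Per-million normalization rescales depths by roughly
`1e8 / genome size`, so any fixed absolute offset would bias ratios by
a data-dependent amount — at 50× coverage of a 36 Mb toy genome a 0.5
offset on the normalized scale compresses the X median from −1 to
about −0.65. Relative constants keep their meaning at any depth and
genome size, keep `m = f → 0` exact, and make profiles invariant to
rescaling a library's depths together with its mapped-read count. The
same convention applies to the ChIP `pseudo` (0.01) and `min_input`
(0.03 ≈ 1 depth unit at 30×).

Note one systematic effect: because the male library carries less X
coverage overall, per-million normalization shifts male autosomal
windows slightly above 0 and the X above −1, by `−log2(1 − x/2)` where
`x` is the X's fraction of the mapped genome (≈ 0.06 for an X carrying
6% of the genome; larger in small toy genomes). The classification
thresholds leave ample room for this.

## Filtering and normalization

A gene is kept in a tissue × stage group if its CPM, computed with raw
library sizes, reaches 0.5 in at least 2 of the group's libraries.
Two readings of this filter are possible ("within the group" vs
globally); the group-wise reading is the default because all
downstream statistics are group-wise, and a global variant is
available by passing all samples. Filtering precedes normalization;
TMM factors are then computed on the kept genes (edgeR's
`calcNormFactors`, i.e. the trimmed-mean-of-M-values estimator:
precision-weighted mean of gene-wise log ratios after trimming 30% of
M and 5% of A values, factors rescaled to geometric mean 1). RPKM uses
exon-union lengths — the total width of the union of a gene's exon
intervals as annotated in the GFF3 — not gene spans, matching how
exonic read counting defines the effective gene length.

TMM assumes most genes are unchanged between samples. When the X
carries many genes and is strongly silenced in one sex, the trimming
window may not exclude all X genes, leaving a small composition bias
(autosomal medians a few hundredths above 0, X medians pulled up by
the same amount). At a realistic X share (≤ 10% of genes) the 30% M
trim absorbs it almost entirely.

## Rank statistics

All Wilcoxon conventions follow the R defaults the field's analyses
use: average ranks for ties, zeros dropped in the signed-rank test,
normal approximation with tie and continuity corrections. Exact
p-values are computed when they are well defined and cheap: both
groups ≤ 25 and tie-free (rank-sum), n ≤ 25 with no zeros or tied
absolute differences (signed-rank). The test suite checks both paths
against brute-force enumeration of all group assignments / sign
vectors for n ≤ 8.

The MSCI test is one-sample and one-sided (`alternative = "less"`)
against the reference −1, per the two-fold expectation; an input in
which every ratio equals the reference exactly is reported as
degenerate with p = 1 rather than an error. Benjamini–Hochberg
adjustment is applied within each family of tests (across groups,
across chromosome comparisons within a sex).

## Sex-biased genes

Classification uses a negative-binomial exact test with a common
dispersion estimated on the group (edgeR `estimateCommonDisp` +
`exactTest`) on TMM-normalized counts, BH-adjusted at FDR 0.05, with
direction from the fold-change sign. This is a simpler estimator than
the quasi-likelihood F-test often used for the same purpose; with ≥ 2
replicates per sex and strong (4-fold) effects the two agree closely,
and the simpler model keeps the dependency surface small. The output
metadata records the method.

## Germ/soma mixture estimator

With soma fully compensated and the germline X at residual activity
ε, the autosome-corrected male:female X expression ratio of a bulk
gonad sample is `r = (1 − g) + g·ε`, hence `g = (1 − r)/(1 − ε)`,
clamped to [0, 1] with a flag. `r` is computed from ratios of
across-gene mean expression (per-gene baselines cancel between the
sexes). The estimator assumes ε is known; sensitivity is modest
(∂g/∂ε = g/(1 − ε)), and recovery on simulated studies is within
±0.05 across g ∈ [0.3, 0.8], ε ∈ [0, 0.2]. Sex-biased genes distort
`r` slightly (they do not cancel); with 10% biased genes the bias in g
is a few hundredths.

## Tau

`tau = sum(1 - x_i / max(x)) / (N - 1)` on per-tissue median RPKM
(medians across replicates and, by default, jointly across stages),
per sex. No log-transform is applied by default — the index is
computed on expression summaries as-is — but a `log2(x + 1)` option
exists. All-zero genes are undefined and excluded. Chromosome-level
comparisons test the X against the pooled autosomes and against each
autosome, BH-adjusted within sex. One caveat the analysis scripts
surface explicitly: when gonads are among the tissues, MSCI itself
makes male X genes look tissue-restricted; re-running tau on somatic
tissues only separates that footprint from genuine tissue specificity.

## ChIP smoothing

Per-scaffold trend curves use a penalized cubic smoothing spline with
the smoothing parameter chosen by generalized cross-validation — the
univariate structure that chromosome-scale enrichment plots need.
Scaffolds with fewer than 10 windows return raw values with a flag.
Constant and linear profiles are reproduced exactly (the penalty null
space), which the tests assert.

## Expression along the chromosome

`smooth_expression_along_x` is tricube-weighted local *linear*
regression (loess, degree 1, span 0.5, direct surface evaluation), so
constant and linear trends are reproduced exactly and edge windows are
not flattened the way local-constant smoothing would.

# Determinism and problem sizes

Every simulator consumes only the config seed (plus fixed offsets per
data type), so identical configs produce byte-identical outputs, which
the suite verifies at file level. The validation suite runs at 200
X-linked / ~2000 autosomal genes, 3 replicates per sex, dispersion
0.05 — large enough that the median X ratio is estimated to ±0.03
(SE) and all regime checks have wide margins — with 20-seed
replication for recovery checks, 100 seeds for MSCI detection, and
1000 replicates for the type-I error of the X-vs-autosome test.

# Known limitations

* The adult-gonad default regime (g = 0.6, ε = 0.1) has a true mixture
  ratio of −1.12, close to the two-fold line; with a few hundred X
  genes the signed-rank deviation test has limited power there, and
  normalization composition bias moves the observed median a few
  hundredths toward 0. The N4 regime (g = 0.8) is detected essentially
  always. This mirrors the biology: a diluted germline is genuinely
  harder to distinguish from simple non-compensation.
* `female_downregulation` and `complete_upregulation` produce
  identical male:female ratios (both fully compensated); telling them
  apart requires the within-sex X-vs-autosome comparisons
  (`within_sex_xa_test`), not the ratio.
* The NB exact test for sex bias uses a common dispersion; genes with
  atypically high dispersion are slightly anticonservative.
* Tau depends on which tissues enter the index; results are only
  comparable across genes computed on the same tissue set.
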