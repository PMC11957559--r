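# xdose

Chromosome-level analysis of **dosage compensation** and **meiotic sex
chromosome inactivation (MSCI)** for species with XX/X0 sex determination,
written for researchers analysing RNA-seq, DNA-seq and ChIP-seq data from
male/female study designs (and for anyone who wants a fully synthetic,
ground-truthed testbed for such analyses).

In an X0 system males carry a single X. Without regulatory compensation,
X-linked expression in males is expected at half the female level:

```
log2(M/F) = 0    on autosomes, and on the X under complete compensation
log2(M/F) = -1   on the X without compensation (one copy vs two)
log2(M/F) < -1   on the X when it is actively silenced (MSCI)
```

The package implements the full analysis chain around these quantities:

- **X identification** from male vs female DNA coverage: per-window
  log2(M/F) depth ratios (depth per million mapped reads), scaffold
  medians classified against thresholds midway between the hemizygous
  (−1) and autosomal (0) expectations.
- **Expression normalization**: CPM filtering (≥ 0.5 CPM in ≥ 2
  libraries, per tissue × stage group), TMM factors (trimmed mean of
  M-values), CPM and RPKM on exon-union gene lengths from GFF3.
- **Dosage-compensation statistics**: per-gene log2 ratios of sex-mean
  RPKM, Mann–Whitney X-vs-autosome tests, a one-sided Wilcoxon
  signed-rank test of X ratios against −1 (silencing *beyond* the
  two-fold copy-number loss — the MSCI signature), Benjamini–Hochberg
  FDR control, and NB exact-test sex-biased gene classification.
- **Germ/soma mixture estimator**: bulk gonad expression modelled as
  `r = (1 − g) + g·ε` (g = germ-cell fraction, ε = residual X activity
  in germ cells), inverted to estimate g from the autosome-corrected
  male:female X expression ratio.
- **Tau tissue specificity**: τ = Σ(1 − xᵢ/x_max)/(N − 1) per gene and
  sex, with chromosome-level rank-sum comparisons.
- **ChIP/input profiling**: windowed log2 enrichment of a silencing
  histone mark (e.g. H3K9me3), per-scaffold smoothing splines, and an
  X-vs-autosome enrichment test.
- **Synthetic studies**: a negative-binomial generator with a hemizygous
  male X, configurable compensation regimes (`complete_upregulation`,
  `none`, `female_downregulation`, `msci_mixture`), sex-biased and
  tissue-specific genes, Poisson DNA/ChIP coverage — with full ground
  truth, so every stage is testable end to end.

## Worked example

Simulate one study with compensated brain and meiotic gonads (germ
fraction 0.8, 10% residual X activity), then run the whole pipeline:

```r
library(xdose)

cfg <- sim_config(
  n_scaffolds = 12, x_scaffold = 3,
  genes_per_scaffold = c(182, 182, 200, rep(182, 9)),
  groups = data.frame(
    sex = c("M", "F", "M", "F"),
    tissue = c("brain", "brain", "gonad", "gonad"),
    stage = "N4", n_replicates = 3,
    dc_mode = c("complete_upregulation", "complete_upregulation",
                "msci_mixture", "msci_mixture"),
    germ_fraction = c(0, 0, 0.8, 0.8)),
  residual_x_activity = 0.1, seed = 1)

report <- run_study(cfg)
report
```

```
<study_report> seed 1 | stages: sexlink, expression, dc, tau, chip 
  X called: scaffold_3 
  per-group median X log2(M:F):
    brain/N4: +0.052 (autosomes +0.005, p_adj 0.17)
    gonad/N4: -1.740 (autosomes +0.067, p_adj 5.3e-85)
  ChIP X enrichment: 1.96-fold (p 5.3e-187)
```

Reading the output: coverage correctly calls scaffold 3 as the X; brain
X expression matches autosomes (median log2 ratio ≈ 0, complete
compensation), while the gonadal X sits at −1.74 — far below the −1
expected from losing one copy, the MSCI signature (here the mixture
model predicts log2(0.28) ≈ −1.84 before normalization-composition
effects). The ChIP stage recovers the simulated 2-fold enrichment of
the silencing mark on the X.

## The analysis workflow

`analysis/` contains numbered drivers that run a complete study over
on-disk files (GFF3 / TSV / bedGraph), writing tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R      # inputs + ground truth
Rscript analysis/02_identify_x.R          # coverage-based X call
Rscript analysis/03_dosage_compensation.R # per-group DC/MSCI statistics
Rscript analysis/04_tissue_specificity.R  # tau, all-tissue and soma-only
Rscript analysis/05_chip_enrichment.R     # windowed ChIP/input profile
```

To analyse real data, point the same functions (`read_gff3`,
`read_counts`, `read_bedgraph`, `filter_low_expression`, `tmm_factors`,
`rpkm_matrix`, `log2_sex_ratio`, `xa_ratio_test`, `msci_test`,
`tau_table`, `enrichment_profile`, ...) at your own files; the drivers
are templates.

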