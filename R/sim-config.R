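#' Configuration for a synthetic X0/XX expression study
#'
#' Bundles every knob of the synthetic-data generator: the genome layout
#' (scaffolds, one of which is the X), the sampling design (sex x tissue x
#' stage groups with replicates), the count model (negative binomial with a
#' common dispersion and log-normally varying library sizes), and the
#' male-X regulatory regime.
#'
#' @param n_scaffolds Number of scaffolds (chromosomes). Default 12, the
#'   karyotype the generator emulates (11 autosomes + 1 X).
#' @param scaffold_lengths Integer vector of scaffold lengths in bp. Defaults
#'   to lengths decreasing from 12 Mb so that scaffold rank is informative.
#' @param x_scaffold Index of the scaffold designated as the X. Default 3
#'   (the X is the third-largest chromosome in the emulated karyotype).
#' @param genes_per_scaffold Number of genes placed on each scaffold
#'   (recycled to `n_scaffolds`).
#' @param gene_length_range Length-2 numeric, bp range for exon-union lengths.
#' @param groups Data frame with columns `sex` ("M"/"F"), `tissue`, `stage`,
#'   `n_replicates`, and optionally `dc_mode` / `germ_fraction` overriding the
#'   global regime for that group (male gonads under meiosis vs soma).
#' @param mean_library_size Expected library size in reads.
#' @param dispersion Negative-binomial dispersion phi (variance mu + phi mu^2).
#' @param dc_mode One of `"complete_upregulation"`, `"none"`,
#'   `"female_downregulation"`, `"msci_mixture"`.
#' @param germ_fraction Germ-cell fraction g in `[0, 1]` (msci_mixture only):
#'   the bulk gonad sample is modelled as g meiotic germ cells (X silenced
#'   down to `residual_x_activity`) plus 1 - g somatic cells (X compensated).
#' @param residual_x_activity Residual per-copy X activity in germ cells,
#'   in `[0, 1]`.
#' @param sex_biased_fraction Fraction of genes given a sex-biased effect.
#' @param sex_bias_fold Fold-change applied to sex-biased genes.
#' @param tissue_specific_fraction Fraction of genes expressed mainly in one
#'   tissue.
#' @param tissue_specific_leak Relative expression of a tissue-specific gene
#'   outside its home tissue.
#' @param chip_x_enrichment Fold enrichment of ChIP over input on X windows.
#' @param seed Integer seed; all simulators are deterministic given the config.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_scaffolds = 4, genes_per_scaffold = 50, seed = 1)
#' cfg$x_scaffold
sim_config <- function(n_scaffolds = 12,
                       scaffold_lengths = NULL,
                       x_scaffold = 3,
                       genes_per_scaffold = 100,
                       gene_length_range = c(500, 5000),
                       groups = default_groups(),
                       mean_library_size = 2e6,
                       dispersion = 0.05,
                       dc_mode = c("complete_upregulation", "none",
                                   "female_downregulation", "msci_mixture"),
                       germ_fraction = 0.8,
                       residual_x_activity = 0.1,
                       sex_biased_fraction = 0.1,
                       sex_bias_fold = 4,
                       tissue_specific_fraction = 0.1,
                       tissue_specific_leak = 0.1,
                       chip_x_enrichment = 2,
                       seed = 1L) {
  dc_mode <- match.arg(dc_mode)
  if (is.null(scaffold_lengths)) {
    # decreasing sizes; scaffold 3 "third largest" stays meaningful
    scaffold_lengths <- as.integer(round(seq(12e6, 4e6,
                                             length.out = n_scaffolds)))
  }
  if (length(scaffold_lengths) != n_scaffolds)
    stop("scaffold_lengths must have length n_scaffolds")
  if (any(scaffold_lengths <= 0)) stop("scaffold_lengths must all be > 0")
  if (!(x_scaffold %in% seq_len(n_scaffolds)))
    stop("x_scaffold must index a scaffold")
  genes_per_scaffold <- rep_len(as.integer(genes_per_scaffold), n_scaffolds)
  stopifnot(length(gene_length_range) == 2L,
            gene_length_range[1] > 0,
            gene_length_range[2] >= gene_length_range[1])
  groups <- as.data.frame(groups)
  req <- c("sex", "tissue", "stage", "n_replicates")
  if (!all(req %in% names(groups)))
    stop("groups needs columns sex, tissue, stage, n_replicates")
  if (nrow(groups) == 0L) stop("groups must not be empty")
  if (!all(groups$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (any(groups$n_replicates < 1)) stop("n_replicates must be >= 1")
  for (p in c(germ_fraction, residual_x_activity, sex_biased_fraction,
              tissue_specific_fraction, tissue_specific_leak))
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (chip_x_enrichment <= 0) stop("chip_x_enrichment must be > 0")
  if (mean_library_size <= 0) stop("mean_library_size must be > 0")

  structure(list(
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_lengths = stats::setNames(as.numeric(scaffold_lengths),
                                       scaffold_names(n_scaffolds)),
    x_scaffold = as.integer(x_scaffold),
    genes_per_scaffold = genes_per_scaffold,
    gene_length_range = as.numeric(gene_length_range),
    groups = groups,
    mean_library_size = mean_library_size,
    dispersion = dispersion,
    dc_mode = dc_mode,
    germ_fraction = germ_fraction,
    residual_x_activity = residual_x_activity,
    sex_biased_fraction = sex_biased_fraction,
    sex_bias_fold = sex_bias_fold,
    tissue_specific_fraction = tissue_specific_fraction,
    tissue_specific_leak = tissue_specific_leak,
    chip_x_enrichment = chip_x_enrichment,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default sampling design for a synthetic study
#'
#' One male and one female group per tissue (brain and reproductive tract)
#' at three stages (N1, N4, adult), three replicates each. Gonad groups at
#' N4 and adult default to the MSCI mixture regime in `run_study()`-style
#' full designs; `sim_config()` itself applies a single global regime unless
#' a `dc_mode` column is present here.
#'
#' @return Data frame with columns sex, tissue, stage, n_replicates.
#' @export
default_groups <- function() {
  expand.grid(sex = c("M", "F"),
              tissue = "brain",
              stage = "adult",
              n_replicates = 3,
              stringsAsFactors = FALSE)
}

scaffold_names <- function(n) sprintf("scaffold_%d", seq_len(n))

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_scaffolds, "scaffolds; X =",
      names(x$scaffold_lengths)[x$x_scaffold], "\n")
  cat("  regime:", x$dc_mode,
      if (x$dc_mode == "msci_mixture")
        sprintf("(g = %.2f, residual = %.2f)",
                x$germ_fraction, x$residual_x_activity) else "", "\n")
  cat("  groups:", nrow(x$groups), "| dispersion:", x$dispersion,
      "| seed:", x$seed, "\n")
  invisible(x)
}
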