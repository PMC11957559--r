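# Shared study configurations: 200 X-linked genes vs ~2000 autosomal
# genes (the X carries ~9% of genes, near its share in a 12-chromosome
# karyotype), 3 replicates per sex, NB dispersion 0.05.

dc_sim_config <- function(dc_mode, seed, g = 0.8, res = 0.1,
                          n_reps = 3, dispersion = 0.05) {
  sim_config(n_scaffolds = 12, x_scaffold = 3,
             genes_per_scaffold = c(182, 182, 200, rep(182, 9)),
             groups = data.frame(sex = c("M", "F"), tissue = "gonad",
                                 stage = "N4", n_replicates = n_reps),
             dispersion = dispersion, dc_mode = dc_mode,
             germ_fraction = g, residual_x_activity = res,
             sex_biased_fraction = 0, tissue_specific_fraction = 0,
             seed = seed)
}

# simulate -> filter -> TMM -> RPKM -> sex means -> log2 ratios
run_dc_study <- function(cfg) {
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  keep <- filter_low_expression(sim$counts)
  nf <- tmm_factors(sim$counts, keep)
  rp <- rpkm_matrix(sim$counts, ann, keep, norm_factors = nf)
  mm <- mean_by_sex(rp, sim$sheet)
  lr <- log2_sex_ratio(mm)
  isx <- stats::setNames(ann$genes$is_x, ann$genes$gene_id)
  ok <- !lr$excluded
  list(annotation = ann, sim = sim, means = mm, ratios = lr,
       x_vals = lr$log2_mf[ok & isx[lr$gene_id]],
       auto_vals = lr$log2_mf[ok & !isx[lr$gene_id]],
       rpkm = rp)
}

# autosome-corrected linear-scale relative male X expression
relative_x_expression <- function(study) {
  isx <- stats::setNames(study$annotation$genes$is_x,
                         study$annotation$genes$gene_id)[study$means$gene_id]
  m <- study$means
  (mean(m$mean_M[isx]) / mean(m$mean_F[isx])) /
    (mean(m$mean_M[!isx]) / mean(m$mean_F[!isx]))
}

tiny_config <- function(seed = 1, ...) {
  sim_config(n_scaffolds = 3, x_scaffold = 2,
             genes_per_scaffold = 40,
             scaffold_lengths = c(2e6, 1.5e6, 1e6),
             groups = data.frame(sex = c("M", "F"), tissue = "brain",
                                 stage = "adult", n_replicates = 3),
             seed = seed, ...)
}

# minimal two-scaffold annotation for direct statistical tests
two_scaffold_ann <- function(n_x, n_auto) {
  ids <- c(sprintf("x%03d", seq_len(n_x)), sprintf("a%03d", seq_len(n_auto)))
  genes <- data.frame(
    gene_id = ids,
    scaffold = rep(c("chrX", "chr1"), c(n_x, n_auto)),
    strand = "+",
    start = c(seq_len(n_x) * 1000, seq_len(n_auto) * 1000),
    end = c(seq_len(n_x) * 1000 + 500, seq_len(n_auto) * 1000 + 500),
    exon_union_length = 500)
  exons <- genes[, c("gene_id", "scaffold", "strand", "start", "end")]
  gene_annotation(genes, exons,
                  c(chrX = (n_x + 1) * 1000 + 500,
                    chr1 = (n_auto + 1) * 1000 + 500),
                  x_scaffold = "chrX")
}
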