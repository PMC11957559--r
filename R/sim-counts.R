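#' Simulate an RNA-seq count study with known ground truth
#'
#' Draws negative-binomial counts (variance mu + phi mu^2, common phi) for
#' every gene in `annotation` and every replicate of every configured group.
#' The expected count for gene g in sample j is
#'
#'   mu_gj = baseline_g / 2 * regulation_factor * bias * tissue_effect * d_j
#'
#' where `d_j` is the sample's relative sequencing depth (library sizes vary
#' log-normally, sdlog 0.2) and the regulation factor encodes X copy number
#' and the compensation regime:
#' autosomes carry factor 2 in both sexes; the female X carries 2
#' (or 2 x 0.5 under `female_downregulation`); the male X carries 1 under
#' `none`, 2 under `complete_upregulation`, 1 under `female_downregulation`
#' (a single uncompensated copy, matched by the downregulated female X), and
#' `(1 - g) * 2 + g * 2 * residual_x_activity` under `msci_mixture` — a bulk
#' germ/soma mixture in which the somatic compartment is fully compensated
#' and the germline X is silenced down to its residual activity.
#'
#' A `dc_mode` (and `germ_fraction`) column in `config$groups` overrides the
#' global regime per group, so one study can combine compensated soma with
#' meiotic gonads.
#'
#' @param config A [sim_config()].
#' @param annotation A [gene_annotation()], typically from
#'   [simulate_annotation()] with the same config.
#' @return List with `counts` (a [count_matrix()]), `sheet` (a
#'   [sample_sheet()]), and `truth` (ground-truth labels: the true X
#'   scaffold, per-gene baseline means, sex-bias and tissue labels, and the
#'   regime and germ fraction applied to each group).
#' @export
#' @examples
#' cfg <- sim_config(n_scaffolds = 3, genes_per_scaffold = 20, seed = 2)
#' sim <- simulate_counts(cfg, simulate_annotation(cfg))
#' dim(sim$counts$counts)
simulate_counts <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "gene_annotation"))
  genes <- annotation$genes
  ng <- nrow(genes)
  set.seed(config$seed + 1L)

  baseline <- stats::rlnorm(ng, meanlog = 4, sdlog = 1)
  # rescale so a fully autosomal-like sample at nominal depth sums to the
  # configured library size; lognormal shape (sdlog 1) is preserved
  baseline <- baseline / sum(baseline) * config$mean_library_size
  names(baseline) <- genes$gene_id

  tissues <- unique(config$groups$tissue)
  # sex-bias labels: MB and FB in equal shares of sex_biased_fraction
  lab <- rep("unbiased", ng)
  n_sb <- round(config$sex_biased_fraction * ng)
  if (n_sb > 0) {
    idx <- sample.int(ng, n_sb)
    lab[idx] <- sample(c("MB", "FB"), n_sb, replace = TRUE)
  }
  tis_lab <- rep("broad", ng)
  n_ts <- round(config$tissue_specific_fraction * ng)
  if (n_ts > 0 && length(tissues) >= 1) {
    idx <- sample.int(ng, n_ts)
    tis_lab[idx] <- sample(tissues, n_ts, replace = TRUE)
  }

  grp <- config$groups
  grp$dc_mode <- if ("dc_mode" %in% names(grp)) as.character(grp$dc_mode)
                 else config$dc_mode
  grp$dc_mode[is.na(grp$dc_mode)] <- config$dc_mode
  grp$germ_fraction <- if ("germ_fraction" %in% names(grp))
                         as.numeric(grp$germ_fraction)
                       else config$germ_fraction
  grp$germ_fraction[is.na(grp$germ_fraction)] <- config$germ_fraction

  sheet_rows <- list(); cols <- list(); k <- 0L
  is_x <- genes$is_x
  x_male_factor <- function(mode, g) {
    switch(mode,
           complete_upregulation = 2,
           none                  = 1,
           female_downregulation = 1,
           msci_mixture = (1 - g) * 2 + g * 2 * config$residual_x_activity,
           stop("unknown dc_mode: ", mode))
  }
  for (i in seq_len(nrow(grp))) {
    mode <- grp$dc_mode[i]; g <- grp$germ_fraction[i]
    sex <- grp$sex[i]
    fac <- rep(2, ng)
    if (sex == "M") fac[is_x] <- x_male_factor(mode, g)
    if (sex == "F" && mode == "female_downregulation") fac[is_x] <- 2 * 0.5
    bias <- rep(1, ng)
    if (sex == "M") bias[lab == "MB"] <- config$sex_bias_fold
    if (sex == "F") bias[lab == "FB"] <- config$sex_bias_fold
    tfac <- ifelse(tis_lab == "broad" | tis_lab == grp$tissue[i],
                   1, config$tissue_specific_leak)
    for (r in seq_len(grp$n_replicates[i])) {
      k <- k + 1L
      d <- stats::rlnorm(1, meanlog = log(config$mean_library_size),
                         sdlog = 0.2) / config$mean_library_size
      mu <- baseline / 2 * fac * bias * tfac * d
      cnt <- stats::rnbinom(ng, mu = mu, size = 1 / config$dispersion)
      id <- sprintf("%s_%s_%s_r%d", sex, grp$tissue[i], grp$stage[i], r)
      sheet_rows[[k]] <- data.frame(sample_id = id, sex = sex,
                                    tissue = grp$tissue[i],
                                    stage = grp$stage[i], replicate = r,
                                    stringsAsFactors = FALSE)
      cols[[k]] <- cnt
    }
  }
  counts <- do.call(cbind, cols)
  sheet <- sample_sheet(do.call(rbind, sheet_rows))
  dimnames(counts) <- list(genes$gene_id, sheet$sample_id)

  truth <- list(
    true_x_scaffold = annotation$x_scaffold,
    baseline_means = baseline,
    sex_bias = stats::setNames(lab, genes$gene_id),
    tissue_label = stats::setNames(tis_lab, genes$gene_id),
    group_regimes = grp[, c("sex", "tissue", "stage", "dc_mode",
                            "germ_fraction")]
  )
  list(counts = count_matrix(counts), sheet = sheet, truth = truth)
}
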