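#' Run a full synthetic dosage-compensation study
#'
#' End-to-end driver: simulates a study from `config` (annotation, counts,
#' male/female DNA coverage, ChIP/input pair), identifies the X from
#' coverage, then runs per-group expression filtering, TMM normalization,
#' RPKM, log2 M:F ratios, the X-vs-autosome rank-sum test (BH-adjusted
#' across groups), the signed-rank test against the two-fold reduction,
#' sex-biased gene counts, genome-wide Tau comparisons (when >= 2 tissues
#' are configured), and the ChIP enrichment profile. Any stage can be
#' disabled. Given the same config, outputs are identical between runs.
#'
#' @param config A [sim_config()]. Per-group `dc_mode` / `germ_fraction`
#'   columns in `config$groups` let soma and gonad groups follow different
#'   regimes in one study.
#' @param outdir Optional directory; when given, every table is written as
#'   a TSV with a deterministic name and the report metadata as JSON.
#' @param stages Character vector of enabled stages, any of
#'   `"sexlink"`, `"expression"`, `"dc"`, `"tau"`, `"chip"`.
#' @param dna_window,dna_depth DNA coverage windowing/depth
#'   (see [simulate_dna_coverage()]).
#' @param chip_window,chip_depth ChIP windowing/depth
#'   (see [simulate_chip_pair()]).
#' @return A `study_report` list: `meta` (config hash, seed, thresholds),
#'   `scaffold_report`, `group_stats` (one row per tissue x stage group),
#'   `msci` (per gonad-like group), `sex_bias`, `tau_tests`, `chip`.
#' @export
run_study <- function(config, outdir = NULL,
                      stages = c("sexlink", "expression", "dc", "tau",
                                 "chip"),
                      dna_window = 100000, dna_depth = 50,
                      chip_window = 30000, chip_depth = 30) {
  stopifnot(inherits(config, "sim_config"))
  bad <- setdiff(stages, c("sexlink", "expression", "dc", "tau", "chip"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("dc" %in% stages && !"expression" %in% stages)
    stop("the dc stage requires the expression stage")

  report <- list(meta = list(
    config_hash = config_hash(config),
    seed = config$seed,
    dc_mode = config$dc_mode,
    stages = stages,
    package_version = as.character(utils::packageVersion("xdose")),
    thresholds = list(min_cpm = 0.5, min_libraries = 2,
                      x_max = -0.5, auto_min = -0.25,
                      msci_reference = -1, alpha = 0.05)))
  class(report) <- "study_report"
  if (!length(stages)) {
    if (!is.null(outdir)) write_study_report(report, outdir)
    return(report)
  }

  ann <- simulate_annotation(config)

  if ("sexlink" %in% stages) {
    male <- normalize_track(simulate_dna_coverage(config, "M", dna_window,
                                                  dna_depth))
    female <- normalize_track(simulate_dna_coverage(config, "F", dna_window,
                                                    dna_depth))
    ratios <- coverage_log2_ratio(male, female)
    report$scaffold_report <- classify_scaffolds(ratios)
    called_x <- report$scaffold_report$scaffold[
      report$scaffold_report$classification == "X-linked"]
    report$meta$x_called <- if (length(called_x) == 1) called_x
                            else NA_character_
    if (length(called_x) == 1) ann <- set_x_scaffold(ann, called_x)
  }

  if (any(c("expression", "dc", "tau") %in% stages)) {
    sim <- simulate_counts(config, ann)
    cm <- sim$counts; sheet <- sim$sheet
    report$meta$n_genes_simulated <- nrow(cm$counts)
    grp_keys <- unique(sheet[, c("tissue", "stage")])
    rpkm_store <- list()
    rows <- list(); msci_rows <- list(); bias <- list()
    for (i in seq_len(nrow(grp_keys))) {
      ti <- grp_keys$tissue[i]; st <- grp_keys$stage[i]
      ids <- group_samples(sheet, ti, st)
      keep <- filter_low_expression(cm, ids)
      nf <- tmm_factors(cm, keep, ids)
      rp <- rpkm_matrix(cm, ann, keep, ids, nf)
      rpkm_store[[paste(ti, st, sep = ".")]] <- rp
      if (!"dc" %in% stages) next
      mm <- mean_by_sex(rp, sheet)
      lr <- log2_sex_ratio(mm)
      xa <- xa_ratio_test(lr, ann)
      rows[[length(rows) + 1]] <- data.frame(
        tissue = ti, stage = st, n_kept = length(keep),
        n_x = xa$n_x, n_auto = xa$n_auto,
        median_x_log2_mf = xa$median_x,
        median_auto_log2_mf = xa$median_auto,
        U = xa$U, p = xa$p, stringsAsFactors = FALSE)
      is_x <- stats::setNames(ann$genes$is_x, ann$genes$gene_id)
      xvals <- lr$log2_mf[!lr$excluded & is_x[lr$gene_id]]
      if (length(xvals) >= 6) {
        mt <- msci_test(xvals)
        msci_rows[[length(msci_rows) + 1]] <- data.frame(
          tissue = ti, stage = st, n = mt$n, V = mt$V, p = mt$p,
          median_x_log2_mf = mt$median, degenerate = mt$degenerate,
          stringsAsFactors = FALSE)
      }
      sexes <- table(sheet$sex[sheet$sample_id %in% ids])
      if (all(c("M", "F") %in% names(sexes)) && all(sexes >= 2)) {
        sb <- sex_biased_genes(cm, sheet, ti, st)
        sb$counts$tissue <- ti; sb$counts$stage <- st
        bias[[length(bias) + 1]] <- sb$counts
      }
    }
    if (length(rows)) {
      gs <- do.call(rbind, rows)
      gs$p_adj <- bh_adjust(gs$p)
      report$group_stats <- gs
    }
    if (length(msci_rows)) {
      ms <- do.call(rbind, msci_rows)
      ms$p_adj <- bh_adjust(ms$p)
      report$msci <- ms
    }
    if (length(bias)) report$sex_bias <- do.call(rbind, bias)

    if ("tau" %in% stages && length(unique(sheet$tissue)) >= 2) {
      # tau needs one expression value per gene over all groups: use RPKM
      # on the union of kept genes, normalized over all samples jointly
      keep_all <- filter_low_expression(cm)
      nf_all <- tmm_factors(cm, keep_all)
      rp_all <- rpkm_matrix(cm, ann, keep_all, norm_factors = nf_all)
      tt <- tau_table(rp_all, sheet)
      report$tau_tests <- rbind(
        cbind(sex = "M", tau_chromosome_tests(tt, ann, "M")),
        cbind(sex = "F", tau_chromosome_tests(tt, ann, "F")))
      report$tau_medians <- data.frame(
        median_tau_M_x = stats::median(tt$tau_M[is_x_gene(tt, ann)],
                                       na.rm = TRUE),
        median_tau_M_auto = stats::median(tt$tau_M[!is_x_gene(tt, ann)],
                                          na.rm = TRUE),
        median_tau_F_x = stats::median(tt$tau_F[is_x_gene(tt, ann)],
                                       na.rm = TRUE),
        median_tau_F_auto = stats::median(tt$tau_F[!is_x_gene(tt, ann)],
                                          na.rm = TRUE))
    }
  }

  if ("chip" %in% stages) {
    pair <- simulate_chip_pair(config, chip_window, chip_depth)
    prof <- enrichment_profile(pair$chip, pair$input)
    xname <- if (!is.null(report$meta$x_called) &&
                 !is.na(report$meta$x_called)) report$meta$x_called
             else names(config$scaffold_lengths)[config$x_scaffold]
    xt <- x_enrichment_test(prof, xname)
    report$chip <- data.frame(
      x_scaffold = xname, n_x_windows = xt$n_x,
      n_auto_windows = xt$n_auto, median_diff = xt$median_diff,
      fold = xt$fold, U = xt$U, p = xt$p, stringsAsFactors = FALSE)
  }

  if (!is.null(outdir)) write_study_report(report, outdir)
  report
}

is_x_gene <- function(tt, ann) {
  stats::setNames(ann$genes$is_x, ann$genes$gene_id)[tt$gene_id]
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a study report as a TSV bundle plus JSON metadata
#'
#' @param report A `study_report` from [run_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$meta, file.path(outdir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in setdiff(names(report), "meta")) {
    x <- report[[nm]]
    if (is.data.frame(x))
      utils::write.table(format(x, digits = 6, trim = TRUE),
                         file.path(outdir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed", x$meta$seed, "| stages:",
      paste(x$meta$stages, collapse = ", "), "\n")
  if (!is.null(x$scaffold_report))
    cat("  X called:", x$meta$x_called, "\n")
  if (!is.null(x$group_stats)) {
    cat("  per-group median X log2(M:F):\n")
    g <- x$group_stats
    for (i in seq_len(nrow(g)))
      cat(sprintf("    %s/%s: %+.3f (autosomes %+.3f, p_adj %.2g)\n",
                  g$tissue[i], g$stage[i], g$median_x_log2_mf[i],
                  g$median_auto_log2_mf[i], g$p_adj[i]))
  }
  if (!is.null(x$chip))
    cat(sprintf("  ChIP X enrichment: %.2f-fold (p %.2g)\n",
                x$chip$fold, x$chip$p))
  invisible(x)
}
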