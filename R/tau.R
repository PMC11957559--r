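#' Tau tissue-specificity index
#'
#' tau = sum_i (1 - x_i / max_j x_j) / (N - 1) over N per-tissue expression
#' summaries: 0 for a gene expressed equally in every tissue, 1 for a gene
#' expressed in a single tissue. Scale-invariant; undefined (NA) when all
#' values are zero.
#'
#' @param x Non-negative per-tissue expression values (length >= 2).
#' @param log_transform Apply log2(x + 1) before the index (off by
#'   default; the index is usually computed on raw expression summaries).
#' @return Tau in `[0, 1]`, or `NA` for an all-zero gene.
#' @export
#' @examples
#' tau(c(1, 0.5, 0.5, 0.5))  # 0.5
#' tau(c(7, 0, 0, 0))        # 1
tau <- function(x, log_transform = FALSE) {
  if (length(x) < 2) stop("tau needs >= 2 tissues")
  if (any(is.na(x)) || any(x < 0)) stop("expression values must be >= 0")
  if (log_transform) x <- log2(x + 1)
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Per-gene Tau table from expression data
#'
#' For each sex, summarizes expression per tissue as the median across all
#' replicates (and stages, jointly) of that sex x tissue, then computes
#' Tau per gene. Genes with zero expression in every tissue for a sex are
#' excluded for that sex (NA, flagged).
#'
#' @param expr Expression matrix (genes x samples), typically RPKM.
#' @param sheet [sample_sheet()] covering the columns of `expr`.
#' @param tissues Tissues to use (default: all in the sheet). Tau needs at
#'   least 2.
#' @param stages Stages to pool (default: all).
#' @param log_transform Passed to [tau()].
#' @return Data frame of class `tau_table`: `gene_id`, `tau_M`, `tau_F`,
#'   `n_tissues`; attribute `tissues`.
#' @export
tau_table <- function(expr, sheet, tissues = unique(sheet$tissue),
                      stages = unique(sheet$stage), log_transform = FALSE) {
  if (length(tissues) < 2) stop("need >= 2 tissues for tau")
  sheet <- sheet[match(colnames(expr), sheet$sample_id), , drop = FALSE]
  out <- data.frame(gene_id = rownames(expr), stringsAsFactors = FALSE)
  for (s in c("M", "F")) {
    med <- sapply(tissues, function(ti) {
      cols <- sheet$sample_id[sheet$sex == s & sheet$tissue == ti &
                                sheet$stage %in% stages]
      if (!length(cols)) stop("no ", s, " samples for tissue ", ti)
      apply(expr[, cols, drop = FALSE], 1, stats::median)
    })
    out[[paste0("tau_", s)]] <- apply(med, 1, tau,
                                      log_transform = log_transform)
  }
  out$n_tissues <- length(tissues)
  attr(out, "tissues") <- tissues
  class(out) <- c("tau_table", "data.frame")
  out
}

#' Chromosome-level comparisons of tissue specificity
#'
#' Within one sex, rank-sum tests of Tau on the X versus the pooled
#' autosomes and versus each autosome separately, BH-adjusted within the
#' sex. A higher X median indicates X-linked genes are more
#' tissue-restricted in their expression than autosomal genes.
#'
#' @param tt A [tau_table()].
#' @param annotation A [gene_annotation()] with the X assigned.
#' @param sex `"M"` or `"F"`.
#' @param min_genes Minimum genes per scaffold for a comparison.
#' @return Data frame: `group1`, `group2`, `n1`, `n2`, `median1`,
#'   `median2`, `U`, `p`, `p_adj`.
#' @export
tau_chromosome_tests <- function(tt, annotation, sex = c("M", "F"),
                                 min_genes = 2) {
  sex <- match.arg(sex)
  stopifnot(inherits(annotation, "gene_annotation"))
  if (is.na(annotation$x_scaffold)) stop("X scaffold unassigned")
  vals <- tt[[paste0("tau_", sex)]]
  scaf <- stats::setNames(annotation$genes$scaffold,
                          annotation$genes$gene_id)[tt$gene_id]
  ok <- !is.na(vals) & !is.na(scaf)
  vals <- vals[ok]; scaf <- scaf[ok]
  xname <- annotation$x_scaffold
  xv <- vals[scaf == xname]
  if (length(xv) < min_genes) stop("too few X genes with tau")
  autosomes <- setdiff(names(annotation$scaffold_lengths), xname)
  rows <- list()
  av_all <- vals[scaf != xname]
  rs <- rank_sum_test(xv, av_all)
  rows[[1]] <- data.frame(group1 = xname, group2 = "autosomes",
                          n1 = length(xv), n2 = length(av_all),
                          median1 = stats::median(xv),
                          median2 = stats::median(av_all),
                          U = rs$U, p = rs$p, stringsAsFactors = FALSE)
  for (a in autosomes) {
    av <- vals[scaf == a]
    if (length(av) < min_genes) {
      warning("scaffold ", a, " has < ", min_genes, " genes with tau; ",
              "skipped")
      next
    }
    rs <- rank_sum_test(xv, av)
    rows[[length(rows) + 1]] <-
      data.frame(group1 = xname, group2 = a, n1 = length(xv),
                 n2 = length(av), median1 = stats::median(xv),
                 median2 = stats::median(av), U = rs$U, p = rs$p,
                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res
}
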