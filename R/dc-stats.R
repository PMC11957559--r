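#' Per-gene log2 male:female expression ratio
#'
#' log2(mean_M / mean_F) for genes with both sex means > 0; genes with a
#' zero mean in either sex are flagged `excluded` and carry no ratio (no
#' pseudo-count by default — a pseudo-count can be supplied to rescue them).
#' Under complete dosage compensation the X ratio matches the autosomal
#' ratio (~0); without compensation the hemizygous X sits at -1; values
#' below -1 indicate silencing beyond the two-fold copy-number expectation.
#'
#' @param means Data frame from [mean_by_sex()].
#' @param pseudo Optional pseudo-count added to both means (default 0 = off).
#' @return Data frame `gene_id`, `log2_mf`, `excluded`.
#' @export
log2_sex_ratio <- function(means, pseudo = 0) {
  m <- means$mean_M + pseudo
  f <- means$mean_F + pseudo
  excl <- !(m > 0 & f > 0)
  data.frame(gene_id = means$gene_id,
             log2_mf = ifelse(excl, NA_real_, log2(m / f)),
             excluded = excl,
             stringsAsFactors = FALSE)
}

# internal: rank-sum wrapper with the exact-vs-approximate policy used
# throughout: exact enumeration when both groups are small and tie-free,
# otherwise normal approximation with tie correction and continuity
# correction (the R convention).
rank_sum_test <- function(x, y, exact_max = 25) {
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' X-versus-autosome test on log2 male:female ratios
#'
#' Two-sided Mann-Whitney rank-sum test comparing X-linked against
#' autosomal per-gene log2 M:F ratios within one tissue x stage group. A
#' shift of the X distribution below the autosomal one indicates
#' incomplete compensation (or silencing).
#'
#' @param ratios Output of [log2_sex_ratio()].
#' @param annotation A [gene_annotation()] with the X scaffold assigned.
#' @return List: `n_x`, `n_auto`, `median_x`, `median_auto`, `U`, `p`,
#'   `exact`.
#' @export
xa_ratio_test <- function(ratios, annotation) {
  v <- split_xa(ratios$log2_mf[!ratios$excluded],
                ratios$gene_id[!ratios$excluded], annotation)
  if (length(v$x) < 2 || length(v$auto) < 2)
    stop("need >= 2 genes with ratios in each class (X: ", length(v$x),
         ", autosomes: ", length(v$auto), ")")
  rs <- rank_sum_test(v$x, v$auto)
  list(n_x = length(v$x), n_auto = length(v$auto),
       median_x = stats::median(v$x), median_auto = stats::median(v$auto),
       U = rs$U, p = rs$p, exact = rs$exact)
}

#' Within-sex X-versus-autosome expression test
#'
#' Rank-sum test of X-linked vs autosomal mean expression (e.g. RPKM)
#' within a single sex: detects whether X-linked genes are expressed at
#' lower levels than autosomal genes in that sex.
#'
#' @param means Data frame from [mean_by_sex()].
#' @param annotation A [gene_annotation()] with the X scaffold assigned.
#' @param sex `"M"` or `"F"`.
#' @return List as in [xa_ratio_test()].
#' @export
within_sex_xa_test <- function(means, annotation, sex = c("M", "F")) {
  sex <- match.arg(sex)
  vals <- if (sex == "M") means$mean_M else means$mean_F
  v <- split_xa(vals, means$gene_id, annotation)
  if (length(v$x) < 2 || length(v$auto) < 2)
    stop("need >= 2 genes in each class")
  rs <- rank_sum_test(v$x, v$auto)
  list(sex = sex, n_x = length(v$x), n_auto = length(v$auto),
       median_x = stats::median(v$x), median_auto = stats::median(v$auto),
       U = rs$U, p = rs$p, exact = rs$exact)
}

split_xa <- function(values, gene_ids, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (is.na(annotation$x_scaffold))
    stop("annotation has no X scaffold assigned (see set_x_scaffold)")
  is_x <- stats::setNames(annotation$genes$is_x,
                          annotation$genes$gene_id)[gene_ids]
  if (anyNA(is_x)) stop("gene ids absent from annotation")
  list(x = values[is_x], auto = values[!is_x])
}

#' Test for X silencing beyond the two-fold hemizygous expectation (MSCI)
#'
#' One-sample Wilcoxon signed-rank test of X-linked log2 M:F ratios against
#' the reference -1 (the ratio expected from a single uncompensated X
#' copy), one-sided alternative "less": rejection means X expression in
#' males is reduced beyond what losing one copy explains — the signature
#' of meiotic sex chromosome inactivation. Zero differences are dropped
#' and ties receive average ranks; the p-value is exact for small
#' (n <= 25) zero- and tie-free samples and otherwise uses the normal
#' approximation with continuity correction.
#'
#' @param x_log2_mf Numeric vector of X-linked log2 M:F ratios.
#' @param reference Reference log2 ratio (default -1).
#' @param min_genes Minimum ratios required (default 6).
#' @return List of class `msci_test`: `n`, `V`, `p`, `median`, `reference`,
#'   `degenerate` (TRUE when every ratio equals the reference; then p = 1).
#' @export
msci_test <- function(x_log2_mf, reference = -1, min_genes = 6) {
  x <- x_log2_mf[!is.na(x_log2_mf)]
  if (length(x) < min_genes)
    stop("need >= ", min_genes, " X-linked ratios, got ", length(x))
  d <- x - reference
  if (all(d == 0)) {
    res <- list(n = length(x), V = 0, p = 1,
                median = stats::median(x), reference = reference,
                degenerate = TRUE)
    class(res) <- "msci_test"
    return(res)
  }
  use_exact <- length(d) <= 25 && !any(d == 0) &&
    !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, mu = reference, alternative = "less",
                       exact = use_exact, correct = TRUE))
  res <- list(n = length(x), V = unname(wt$statistic), p = wt$p.value,
              median = stats::median(x), reference = reference,
              degenerate = FALSE, exact = use_exact)
  class(res) <- "msci_test"
  res
}

#' @export
print.msci_test <- function(x, ...) {
  cat("Wilcoxon signed rank test vs two-fold reduction (log2 ratio ",
      x$reference, ")\n", sep = "")
  cat("  n =", x$n, " V =", x$V, " p =", format.pval(x$p), "\n")
  cat("  median log2(M:F) =", round(x$median, 3),
      if (x$degenerate) "(degenerate: all at reference)" else "", "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: sorted p-values are multiplied by
#' m/rank, monotonicity is enforced from the largest down, and values are
#' capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify sex-biased genes in a group
#'
#' Negative-binomial two-group comparison of male vs female counts on the
#' TMM-normalized matrix: common dispersion estimated on the group, exact
#' NB test per gene, BH adjustment; genes with adjusted p < `alpha` are
#' male- or female-biased by the sign of the fold change. Reports the
#' MB / FB / SB / T bookkeeping with percentages of expressed genes.
#'
#' @param cm A [count_matrix()].
#' @param sheet A [sample_sheet()].
#' @param tissue,stage Group selector.
#' @param alpha FDR threshold (default 0.05).
#' @param min_cpm,min_libraries Expression filter, as in
#'   [filter_low_expression()].
#' @return List: `labels` (named vector, "MB"/"FB"/"unbiased"), `table`
#'   (per-gene logFC, p, p_adj), `counts` (MB, FB, SB, T with percentages),
#'   `method` metadata.
#' @export
sex_biased_genes <- function(cm, sheet, tissue, stage, alpha = 0.05,
                             min_cpm = 0.5, min_libraries = 2) {
  ids <- group_samples(sheet, tissue, stage)
  sub <- sheet[match(ids, sheet$sample_id), , drop = FALSE]
  for (s in c("M", "F"))
    if (sum(sub$sex == s) < 2)
      stop("need >= 2 replicates per sex in ", tissue, "/", stage)
  keep <- filter_low_expression(cm, ids, min_cpm, min_libraries)
  y <- edgeR::DGEList(counts = cm$counts[keep, ids, drop = FALSE],
                      group = factor(sub$sex, levels = c("F", "M")))
  y <- edgeR::calcNormFactors(y, method = "TMM")
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y, pair = c("F", "M"))   # logFC > 0 = male-biased
  tab <- et$table
  tab$p_adj <- bh_adjust(tab$PValue)
  lab <- rep("unbiased", nrow(tab))
  lab[tab$p_adj < alpha & tab$logFC > 0] <- "MB"
  lab[tab$p_adj < alpha & tab$logFC < 0] <- "FB"
  names(lab) <- rownames(tab)
  n_mb <- sum(lab == "MB"); n_fb <- sum(lab == "FB"); n_t <- length(lab)
  counts <- data.frame(
    category = c("MB", "FB", "SB", "T"),
    n = c(n_mb, n_fb, n_mb + n_fb, n_t),
    percent = round(c(n_mb, n_fb, n_mb + n_fb, n_t) / n_t * 100, 1))
  list(labels = lab,
       table = data.frame(gene_id = rownames(tab), logFC = tab$logFC,
                          p = tab$PValue, p_adj = tab$p_adj,
                          label = lab, stringsAsFactors = FALSE),
       counts = counts,
       method = paste("NB exact test, common dispersion (edgeR),",
                      "TMM-normalized; BH FDR <", alpha))
}

#' Estimate the germ-cell fraction of a gonad sample
#'
#' Inverts the germ/soma mixture model for bulk gonad expression. With
#' relative X expression r = (male X mean / female X mean) divided by the
#' same male:female ratio on autosomes, a mixture of a fraction g of germ
#' cells (X silenced down to residual activity eps) and 1 - g of fully
#' compensated somatic cells gives r = (1 - g) + g * eps, hence
#' g = (1 - r) / (1 - eps).
#'
#' @param r Linear-scale relative X expression (autosome-corrected
#'   male:female X ratio).
#' @param residual Residual per-copy X activity eps in `[0, 1)`.
#' @return List: `g` (clamped to `[0, 1]`), `clamped` flag, `r`, `residual`.
#' @export
estimate_germline_fraction <- function(r, residual = 0) {
  if (residual < 0 || residual >= 1) stop("residual must lie in [0, 1)")
  g <- (1 - r) / (1 - residual)
  clamped <- g < 0 || g > 1
  list(g = min(1, max(0, g)), clamped = clamped, r = r, residual = residual)
}

#' Smooth expression along a chromosome
#'
#' Tricube-weighted local linear regression (loess, degree 1) of per-gene
#' log2 expression against gene midpoint position, to visualize whether
#' expression changes are uniform along the chromosome or regional.
#'
#' @param position Gene positions (bp).
#' @param values Per-gene expression values (e.g. log2 RPKM or log2 M:F).
#' @param span Loess span (default 0.5).
#' @param eval_at Positions at which to evaluate (default the input
#'   positions, sorted).
#' @return Data frame `position`, `smoothed`.
#' @export
smooth_expression_along_x <- function(position, values, span = 0.5,
                                      eval_at = sort(position)) {
  ok <- !is.na(position) & !is.na(values)
  if (sum(ok) < 10) stop("need >= 10 genes to smooth")
  d <- data.frame(pos = position[ok], y = values[ok])
  fit <- stats::loess(y ~ pos, data = d, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  data.frame(position = eval_at,
             smoothed = unname(stats::predict(fit,
                                              newdata = data.frame(pos = eval_at))))
}
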