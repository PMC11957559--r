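#' Filter lowly expressed genes within a group
#'
#' Keeps a gene if its CPM (computed with raw library sizes, before any
#' between-sample normalization) reaches `min_cpm` in at least
#' `min_libraries` of the group's samples. Filtering precedes TMM
#' normalization, mirroring the standard edgeR workflow.
#'
#' @param cm A [count_matrix()].
#' @param samples Character vector of sample ids forming the group
#'   (default: all samples).
#' @param min_cpm CPM threshold (default 0.5).
#' @param min_libraries Minimum number of libraries reaching it (default 2).
#' @return Character vector of kept gene ids.
#' @export
filter_low_expression <- function(cm, samples = colnames(cm$counts),
                                  min_cpm = 0.5, min_libraries = 2) {
  stopifnot(inherits(cm, "count_matrix"))
  miss <- setdiff(samples, colnames(cm$counts))
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  if (length(samples) < min_libraries)
    stop("group has ", length(samples), " samples, fewer than min_libraries")
  m <- cm$counts[, samples, drop = FALSE]
  raw_cpm <- t(t(m) / cm$lib_sizes[samples]) * 1e6
  keep <- rowSums(raw_cpm >= min_cpm) >= min_libraries
  rownames(m)[keep]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors (Robinson & Oshlack) on the filtered
#' gene set, computed with edgeR's `calcNormFactors`: the reference sample
#' is the one whose upper-quartile count fraction is closest to the mean;
#' per-sample factors are precision-weighted means of gene-wise log ratios
#' (M) after trimming the 30% most extreme M and 5% most extreme abundance
#' (A) values; factors are rescaled to geometric mean 1.
#'
#' @param cm A [count_matrix()].
#' @param genes Gene ids to use (typically [filter_low_expression()]
#'   output). Default: all genes.
#' @param samples Sample ids (default all).
#' @return Named numeric vector of normalization factors (geometric mean 1).
#' @export
tmm_factors <- function(cm, genes = rownames(cm$counts),
                        samples = colnames(cm$counts)) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(samples) < 2) stop("TMM needs >= 2 samples")
  m <- cm$counts[genes, samples, drop = FALSE]
  # library sizes stay those of the full (unfiltered) matrix
  f <- edgeR::calcNormFactors(m, lib.size = cm$lib_sizes[samples],
                              method = "TMM")
  stats::setNames(f, samples)
}

#' Counts per million
#'
#' CPM = count x 1e6 / (library size x normalization factor). Library sizes
#' are the raw column sums of the full matrix; the effective library size
#' is their product with the TMM factor.
#'
#' @param cm A [count_matrix()].
#' @param genes,samples Subsets to return (defaults: all).
#' @param norm_factors Per-sample factors; default the ones stored in `cm`.
#' @return Numeric matrix of CPM values with attribute `provenance = "cpm"`.
#' @export
cpm_matrix <- function(cm, genes = rownames(cm$counts),
                       samples = colnames(cm$counts),
                       norm_factors = cm$norm_factors[samples]) {
  stopifnot(inherits(cm, "count_matrix"))
  eff <- cm$lib_sizes[samples] * norm_factors
  if (any(eff <= 0)) stop("effective library sizes must be > 0")
  out <- t(t(cm$counts[genes, samples, drop = FALSE]) / eff) * 1e6
  attr(out, "provenance") <- "cpm"
  out
}

#' Reads per kilobase per million (RPKM)
#'
#' CPM further divided by the gene's exon-union length in kb.
#'
#' @inheritParams cpm_matrix
#' @param annotation A [gene_annotation()] supplying exon-union lengths.
#' @return Numeric matrix of RPKM values, attribute `provenance = "rpkm"`.
#' @export
rpkm_matrix <- function(cm, annotation, genes = rownames(cm$counts),
                        samples = colnames(cm$counts),
                        norm_factors = cm$norm_factors[samples]) {
  stopifnot(inherits(annotation, "gene_annotation"))
  len <- stats::setNames(annotation$genes$exon_union_length,
                         annotation$genes$gene_id)[genes]
  if (anyNA(len))
    stop("no exon-union length for gene(s): ",
         paste(utils::head(genes[is.na(len)], 5), collapse = ", "))
  out <- cpm_matrix(cm, genes, samples, norm_factors) / (len / 1e3)
  attr(out, "provenance") <- "rpkm"
  out
}

#' Per-gene mean expression by sex
#'
#' Arithmetic mean across replicates within each sex (the `rowMeans`
#' convention: average expression first, then take ratios).
#'
#' @param expr Expression matrix (genes x samples), e.g. [rpkm_matrix()].
#' @param sheet A [sample_sheet()] covering the columns of `expr`.
#' @return Data frame `gene_id`, `mean_M`, `mean_F`.
#' @export
mean_by_sex <- function(expr, sheet) {
  sheet <- sheet[match(colnames(expr), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("samples missing from sheet")
  for (s in c("M", "F"))
    if (!any(sheet$sex == s)) stop("no ", s, " samples in group")
  data.frame(
    gene_id = rownames(expr),
    mean_M = rowMeans(expr[, sheet$sex == "M", drop = FALSE]),
    mean_F = rowMeans(expr[, sheet$sex == "F", drop = FALSE]),
    stringsAsFactors = FALSE)
}
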