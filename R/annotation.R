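#' Gene annotation container
#'
#' Light S3 container pairing a per-gene table with the per-exon intervals it
#' was derived from. Coordinates follow the GFF3 convention: 1-based,
#' inclusive. `exon_union_length` is the total length of the union of a
#' gene's exon intervals — the gene length used for RPKM.
#'
#' @param genes Data frame with columns `gene_id`, `scaffold`, `strand`,
#'   `start`, `end`, `exon_union_length`.
#' @param exons Data frame with columns `gene_id`, `scaffold`, `strand`,
#'   `start`, `end` (one row per exon).
#' @param scaffold_lengths Named numeric vector of scaffold lengths (bp).
#' @param x_scaffold Character scalar naming the X-linked scaffold, or `NA`
#'   if not yet classified (see [classify_scaffolds()]).
#'
#' @return Object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons, scaffold_lengths, x_scaffold = NA) {
  stopifnot(is.data.frame(genes), is.data.frame(exons))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  if (any(genes$exon_union_length <= 0))
    stop("exon_union_length must be > 0 for every gene")
  bad <- genes$end > scaffold_lengths[genes$scaffold] | genes$start < 1
  if (any(bad))
    stop("genes outside scaffold bounds: ",
         paste(genes$gene_id[bad], collapse = ", "))
  genes$is_x <- !is.na(x_scaffold) & genes$scaffold == x_scaffold
  structure(list(genes = genes, exons = exons,
                 scaffold_lengths = scaffold_lengths,
                 x_scaffold = x_scaffold),
            class = "gene_annotation")
}

#' Assign the X scaffold on an annotation
#'
#' @param annotation A [gene_annotation()].
#' @param x_scaffold Scaffold name to mark as X-linked.
#' @return The annotation with `is_x` flags updated.
#' @export
set_x_scaffold <- function(annotation, x_scaffold) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (!x_scaffold %in% names(annotation$scaffold_lengths))
    stop("unknown scaffold: ", x_scaffold)
  annotation$x_scaffold <- x_scaffold
  annotation$genes$is_x <- annotation$genes$scaffold == x_scaffold
  annotation
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation>", nrow(x$genes), "genes on",
      length(x$scaffold_lengths), "scaffolds; X =",
      if (is.na(x$x_scaffold)) "unassigned" else x$x_scaffold, "\n")
  invisible(x)
}

#' Simulate a gene annotation
#'
#' Places `genes_per_scaffold[i]` non-overlapping genes on each scaffold.
#' Each gene has two exons whose union length is drawn uniformly from
#' `gene_length_range`; an intron gap separates them so that exon-union
#' length and gene span differ, exercising the RPKM length convention.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [gene_annotation()] with the configured X scaffold assigned.
#' @export
#' @examples
#' ann <- simulate_annotation(sim_config(n_scaffolds = 2,
#'                                       genes_per_scaffold = 10, seed = 7))
#' nrow(ann$genes)
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  scafs <- names(config$scaffold_lengths)
  genes_list <- vector("list", length(scafs))
  exons_list <- vector("list", length(scafs))
  for (i in seq_along(scafs)) {
    n <- config$genes_per_scaffold[i]
    L <- config$scaffold_lengths[i]
    len <- round(stats::runif(n, config$gene_length_range[1],
                              config$gene_length_range[2]))
    gap <- round(stats::runif(n, 50, 500))       # intron between the 2 exons
    span <- len + gap
    if (sum(span) > L)
      stop("scaffold ", scafs[i], ": requested gene footprint (",
           sum(span), " bp) exceeds scaffold length (", L, " bp)")
    # lay genes left to right, spreading leftover space uniformly
    slack <- L - sum(span)
    spacing <- if (n > 1) diff(c(0, sort(round(stats::runif(n, 0, slack)))))
               else round(stats::runif(1, 0, slack))
    start <- cumsum(c(1, span[-n])) + cumsum(spacing)
    end <- start + span - 1
    strand <- sample(c("+", "-"), n, replace = TRUE)
    id <- sprintf("%s_g%04d", scafs[i], seq_len(n))
    l1 <- pmax(1, round(len / 2))
    l2 <- len - l1
    # second exon may be empty when len == 1; keep both >= 1 by construction
    l2 <- pmax(1, l2); l1 <- len - l2
    genes_list[[i]] <- data.frame(
      gene_id = id, scaffold = scafs[i], strand = strand,
      start = start, end = end,
      exon_union_length = len, stringsAsFactors = FALSE)
    exons_list[[i]] <- data.frame(
      gene_id = rep(id, 2L), scaffold = scafs[i],
      strand = rep(strand, 2L),
      start = c(start, start + l1 + gap),
      end = c(start + l1 - 1, end),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes_list)
  exons <- do.call(rbind, exons_list)
  exons <- exons[order(exons$scaffold, exons$start), , drop = FALSE]
  rownames(genes) <- rownames(exons) <- NULL
  gene_annotation(genes, exons, config$scaffold_lengths,
                  x_scaffold = scafs[config$x_scaffold])
}
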