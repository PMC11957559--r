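#' Read a GFF3 gene annotation
#'
#' Parses gene and exon features (via rtracklayer) into a
#' [gene_annotation()]. The gene length recorded for RPKM is the
#' exon-union length: the total width of the union of each gene's exon
#' intervals (GFF3 coordinates are 1-based inclusive). Genes without any
#' exon feature fall back to their gene-span length, with a warning.
#' Scaffold lengths are taken from `##sequence-region` directives when
#' present, otherwise from the right-most feature per scaffold.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_annotation()] (X scaffold unassigned).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- grep("^[^#]", lines)
  if (length(body)) {
    flds <- strsplit(lines[body], "\t", fixed = TRUE)
    bad <- vapply(flds, function(f)
      length(f) >= 5 && suppressWarnings(
        isTRUE(as.numeric(f[5]) < as.numeric(f[4]))), logical(1))
    if (any(bad))
      stop("malformed GFF3 (end < start) at line ", body[which(bad)[1]],
           ": ", lines[body[which(bad)[1]]])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  is_gene <- meta$type == "gene"
  is_exon <- meta$type == "exon"
  if (!any(is_gene)) stop("no gene features in ", path)
  g <- gr[is_gene]
  ids <- as.character(S4Vectors::mcols(g)$ID)
  if (anyNA(ids)) stop("gene feature without ID attribute")
  genes <- data.frame(
    gene_id = ids,
    scaffold = as.character(GenomicRanges::seqnames(g)),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(g))),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene id in ", path, ": ",
         genes$gene_id[duplicated(genes$gene_id)][1])

  ex <- gr[is_exon]
  parent <- as.character(S4Vectors::mcols(ex)$Parent)
  exons <- data.frame(
    gene_id = parent,
    scaffold = as.character(GenomicRanges::seqnames(ex)),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(ex))),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE)

  union_len <- vapply(split(IRanges::IRanges(exons$start, exons$end),
                            exons$gene_id),
                      function(ir) sum(IRanges::width(IRanges::reduce(ir))),
                      numeric(1))
  genes$exon_union_length <- unname(union_len[genes$gene_id])
  no_exon <- is.na(genes$exon_union_length)
  if (any(no_exon)) {
    warning(sum(no_exon), " gene(s) without exons; using gene-span length")
    genes$exon_union_length[no_exon] <-
      genes$end[no_exon] - genes$start[no_exon] + 1
  }

  sl <- scaffold_lengths_from_gff(lines, genes)
  gene_annotation(genes, exons, sl)
}

scaffold_lengths_from_gff <- function(lines, genes) {
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "\\s+")
    sl <- vapply(parts, function(p) as.numeric(p[4]), numeric(1))
    names(sl) <- vapply(parts, function(p) p[2], character(1))
    if (all(unique(genes$scaffold) %in% names(sl))) return(sl)
  }
  tapply(genes$end, genes$scaffold, max)
}

#' Write a gene annotation as GFF3
#'
#' Emits `##sequence-region` directives, one `gene` line per gene and its
#' `exon` children (Parent attribute), 1-based inclusive coordinates.
#'
#' @param annotation A [gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  sl <- annotation$scaffold_lengths
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", names(sl), as.integer(sl)))
  g <- annotation$genes
  gene_lines <- sprintf("%s\txdose\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        g$scaffold, g$start, g$end, g$strand, g$gene_id)
  e <- annotation$exons
  e <- e[order(match(e$gene_id, g$gene_id), e$start), , drop = FALSE]
  exon_lines <- sprintf("%s\txdose\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                        e$scaffold, e$start, e$end, e$strand, e$gene_id)
  # interleave exons after their gene so the file reads hierarchically
  ord <- order(c(match(g$gene_id, g$gene_id), match(e$gene_id, g$gene_id) +
                   0.5))
  writeLines(c(hdr, c(gene_lines, exon_lines)[ord]), path)
  invisible(path)
}

#' Read a gene x sample count table
#'
#' Tab-separated, header row with `gene_id` then one column per sample.
#' Columns are matched against the sample sheet and reordered to sheet
#' order; sheet samples missing from the table, non-integer or negative
#' cells are errors.
#'
#' @param path Path to the TSV.
#' @param sheet A [sample_sheet()].
#' @return A [count_matrix()] with columns in sheet order.
#' @export
read_counts <- function(path, sheet) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  miss <- setdiff(sheet$sample_id, names(df))
  if (length(miss)) stop("count table missing sample column(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(df[, sheet$sample_id, drop = FALSE])
  rownames(m) <- df$gene_id
  if (any(m != round(m))) stop("non-integer count cell")
  count_matrix(m)
}

#' Write a count matrix as TSV
#' @param cm A [count_matrix()] (or plain matrix with dimnames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else cm
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet TSV
#' @param path Path to the TSV (columns sample_id, sex, tissue, stage,
#'   replicate).
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_sheet
#' @param sheet A [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph into a windowed coverage track
#'
#' bedGraph intervals (0-based half-open) are averaged into the supplied
#' windows with length weighting; bases not covered by any interval count
#' as depth 0. Intervals extending past the scaffold end implied by the
#' windows are an error.
#'
#' @param path Path to a bedGraph file.
#' @param windows Window data frame from [make_windows()].
#' @param library_mapped_reads Mapped-read count of the library (bedGraph
#'   itself does not carry it).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, windows, library_mapped_reads = NA) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    value = S4Vectors::mcols(gr)$score,
                    stringsAsFactors = FALSE)
  ends <- tapply(windows$end, windows$scaffold, max)
  known <- cov$scaffold %in% names(ends)
  if (!all(known)) stop("bedGraph scaffold not in windows: ",
                        cov$scaffold[!known][1])
  over <- cov$end > ends[cov$scaffold]
  if (any(over)) stop("bedGraph interval beyond scaffold end: ",
                      cov$scaffold[over][1], ":", cov$start[over][1], "-",
                      cov$end[over][1])
  wgr <- GenomicRanges::GRanges(windows$scaffold,
                                IRanges::IRanges(windows$start + 1L,
                                                 windows$end))
  cgr <- GenomicRanges::GRanges(cov$scaffold,
                                IRanges::IRanges(cov$start + 1L, cov$end))
  hits <- GenomicRanges::findOverlaps(wgr, cgr)
  ov <- IRanges::pintersect(wgr[S4Vectors::queryHits(hits)],
                            cgr[S4Vectors::subjectHits(hits)])
  contrib <- IRanges::width(ov) * cov$value[S4Vectors::subjectHits(hits)]
  tot <- rep(0, nrow(windows))
  agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
  tot[as.integer(names(agg))] <- agg
  w <- windows
  w$mean_depth <- tot / (w$end - w$start)
  coverage_track(w, library_mapped_reads = library_mapped_reads)
}

#' Write a coverage track as bedGraph
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  w <- track$windows
  writeLines(sprintf("%s\t%d\t%d\t%s", w$scaffold, as.integer(w$start),
                     as.integer(w$end), formatC(w$mean_depth, digits = 6,
                                                format = "g")), path)
  invisible(path)
}

#' Write the simulation ground truth as a JSON sidecar
#' @param truth The `truth` element of [simulate_counts()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a complete simulated study to disk
#'
#' Convenience wrapper producing every on-disk artifact of a synthetic
#' study: GFF3 annotation, count-matrix TSV, sample sheet TSV, male and
#' female DNA-coverage bedGraphs, ChIP and input bedGraphs, and the
#' ground-truth JSON sidecar.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param dna_window,dna_depth,chip_window,chip_depth Coverage settings,
#'   see [simulate_dna_coverage()] and [simulate_chip_pair()].
#' @return Named character vector of the files written, invisibly.
#' @export
simulate_study_files <- function(config, dir, dna_window = 100000,
                                 dna_depth = 50, chip_window = 30000,
                                 chip_depth = 30) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(config)
  sim <- simulate_counts(config, ann)
  pair <- simulate_chip_pair(config, chip_window, chip_depth)
  dna_m <- simulate_dna_coverage(config, "M", dna_window, dna_depth)
  dna_f <- simulate_dna_coverage(config, "F", dna_window, dna_depth)
  p <- function(f) file.path(dir, f)
  write_gff3(ann, p("annotation.gff3"))
  write_counts(sim$counts, p("counts.tsv"))
  write_sample_sheet(sim$sheet, p("samples.tsv"))
  write_bedgraph(dna_m, p("dna_male.bedgraph"))
  write_bedgraph(dna_f, p("dna_female.bedgraph"))
  write_bedgraph(pair$chip, p("chip.bedgraph"))
  write_bedgraph(pair$input, p("input.bedgraph"))
  write_ground_truth(sim$truth, p("ground_truth.json"))
  # bedGraph carries no library metadata; record mapped reads alongside
  libs <- data.frame(
    library = c("dna_male", "dna_female", "chip", "input"),
    mapped_reads = c(dna_m$library_mapped_reads,
                     dna_f$library_mapped_reads,
                     pair$chip$library_mapped_reads,
                     pair$input$library_mapped_reads))
  utils::write.table(libs, p("libraries.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(annotation = p("annotation.gff3"), counts = p("counts.tsv"),
             samples = p("samples.tsv"), dna_male = p("dna_male.bedgraph"),
             dna_female = p("dna_female.bedgraph"),
             chip = p("chip.bedgraph"), input = p("input.bedgraph"),
             truth = p("ground_truth.json"), libraries = p("libraries.tsv"))
  invisible(files)
}
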