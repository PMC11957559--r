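#' Sample sheet
#'
#' Per-sample metadata defining the analysis groups: sex, tissue,
#' developmental stage, replicate. A group is a tissue x stage combination;
#' all filtering, normalization and statistics run within groups.
#'
#' @param df Data frame with columns `sample_id`, `sex` ("M"/"F"), `tissue`,
#'   `stage`, `replicate`.
#' @return A validated `sample_sheet` data frame.
#' @export
sample_sheet <- function(df) {
  df <- as.data.frame(df)
  req <- c("sample_id", "sex", "tissue", "stage", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  key <- interaction(df$sex, df$tissue, df$stage, df$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop("(sex, tissue, stage, replicate) must be unique")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Raw count matrix with library sizes and normalization factors
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param norm_factors Per-sample multipliers (default 1); their geometric
#'   mean is 1 after TMM normalization.
#' @return Object of class `count_matrix`: list with `counts`, `lib_sizes`
#'   (column sums of the raw matrix), `norm_factors`.
#' @export
count_matrix <- function(counts, norm_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene and sample dimnames")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "double"   # large libraries overflow int sums
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  if (length(norm_factors) != ncol(counts))
    stop("norm_factors length must match sample count")
  structure(list(counts = counts,
                 lib_sizes = colSums(counts),
                 norm_factors = stats::setNames(norm_factors,
                                                colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix>", nrow(x$counts), "genes x", ncol(x$counts),
      "samples; median library", format(stats::median(x$lib_sizes),
                                        big.mark = ","), "\n")
  invisible(x)
}

#' Windowed coverage track
#'
#' Per-window mean sequencing depth over a shared genome tiling, plus the
#' library's mapped-read count for between-library normalization. Window
#' coordinates are 0-based half-open (BED/bedGraph convention).
#'
#' @param windows Data frame with columns `scaffold`, `start`, `end`,
#'   `mean_depth`, and logical `partial` flagging truncated terminal windows.
#' @param library_mapped_reads Total mapped reads in the library.
#' @param normalized Logical; `TRUE` once depths are per million mapped reads.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(windows, library_mapped_reads,
                           normalized = FALSE) {
  req <- c("scaffold", "start", "end", "mean_depth")
  miss <- setdiff(req, names(windows))
  if (length(miss)) stop("windows missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(windows$mean_depth < 0)) stop("mean_depth must be >= 0")
  if (any(windows$end <= windows$start)) stop("windows must have end > start")
  if (!"partial" %in% names(windows)) windows$partial <- FALSE
  o <- order(windows$scaffold, windows$start)
  windows <- windows[o, , drop = FALSE]
  rownames(windows) <- NULL
  by_scaf <- split(windows, windows$scaffold)
  for (w in by_scaf) {
    if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)]))
      stop("overlapping windows on ", w$scaffold[1])
  }
  structure(list(windows = windows,
                 library_mapped_reads = library_mapped_reads,
                 normalized = normalized),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track>", nrow(x$windows), "windows on",
      length(unique(x$windows$scaffold)), "scaffolds;",
      if (x$normalized) "normalized (per-million)" else "raw depth", "\n")
  invisible(x)
}

# internal: shared group key used throughout
group_key <- function(sheet) paste(sheet$tissue, sheet$stage, sep = ".")

# internal: samples of one tissue x stage group
group_samples <- function(sheet, tissue, stage) {
  sheet$sample_id[sheet$tissue == tissue & sheet$stage == stage]
}
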