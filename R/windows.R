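#' Tile scaffolds into consecutive windows
#'
#' Non-overlapping windows of `window` bp covering each scaffold completely;
#' the final window of a scaffold is truncated at the scaffold end and
#' flagged `partial`. Coordinates are 0-based half-open.
#'
#' @param scaffold_lengths Named numeric vector of scaffold lengths (bp).
#' @param window Window size in bp (> 0).
#' @return Data frame with columns `scaffold`, `start`, `end`, `partial`.
#' @export
#' @examples
#' make_windows(c(chr1 = 250000), 100000)
make_windows <- function(scaffold_lengths, window) {
  if (window <= 0) stop("window must be > 0")
  if (is.null(names(scaffold_lengths))) stop("scaffold_lengths must be named")
  tiles <- GenomicRanges::tileGenome(scaffold_lengths,
                                     tilewidth = window,
                                     cut.last.tile.in.chrom = TRUE)
  df <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(tiles)),
    start = GenomicRanges::start(tiles) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(tiles),
    stringsAsFactors = FALSE)
  df$partial <- (df$end - df$start) < window
  df
}

#' Simulate a DNA-seq coverage track
#'
#' Per-window mean depth drawn as Poisson(lambda); on the X scaffold of a
#' male library the rate is halved (X0 males are hemizygous, so male X
#' coverage is expected at half the female level). Deterministic given the
#' config seed and sex.
#'
#' @param config A [sim_config()].
#' @param sex `"M"` or `"F"`.
#' @param window Window size in bp.
#' @param depth Autosomal Poisson depth lambda (reads/bp scale).
#' @return A [coverage_track()] (raw depth units).
#' @export
simulate_dna_coverage <- function(config, sex = c("M", "F"),
                                  window = 100000, depth = 50) {
  stopifnot(inherits(config, "sim_config"))
  sex <- match.arg(sex)
  if (window <= 0) stop("window must be > 0")
  set.seed(config$seed + 100L + (sex == "M"))
  w <- make_windows(config$scaffold_lengths, window)
  xname <- names(config$scaffold_lengths)[config$x_scaffold]
  lam <- ifelse(sex == "M" & w$scaffold == xname, depth / 2, depth)
  w$mean_depth <- stats::rpois(nrow(w), lam)
  mapped <- round(sum(w$mean_depth * (w$end - w$start)) / 100)  # 100 bp reads
  coverage_track(w, library_mapped_reads = mapped)
}

#' Simulate a matched ChIP / input coverage pair
#'
#' Input depth is Poisson(lambda) in every window; ChIP depth is
#' Poisson(lambda x chip_x_enrichment) on X windows and Poisson(lambda)
#' elsewhere, emulating a chromosome-wide heterochromatin mark (H3K9me3)
#' concentrated on the silenced X. Both tracks share the same tiling.
#'
#' @param config A [sim_config()] (uses `chip_x_enrichment` and `seed`).
#' @param window Window size in bp (30 kb by default).
#' @param depth Input Poisson depth lambda.
#' @return List with elements `chip` and `input`, both [coverage_track()]s.
#' @export
simulate_chip_pair <- function(config, window = 30000, depth = 30) {
  stopifnot(inherits(config, "sim_config"))
  if (config$chip_x_enrichment <= 0) stop("chip_x_enrichment must be > 0")
  set.seed(config$seed + 200L)
  w <- make_windows(config$scaffold_lengths, window)
  xname <- names(config$scaffold_lengths)[config$x_scaffold]
  lam_chip <- ifelse(w$scaffold == xname,
                     depth * config$chip_x_enrichment, depth)
  chip <- w; input <- w
  chip$mean_depth <- stats::rpois(nrow(w), lam_chip)
  input$mean_depth <- stats::rpois(nrow(w), depth)
  mk <- function(win) coverage_track(
    win, library_mapped_reads = round(sum(win$mean_depth *
                                            (win$end - win$start)) / 100))
  list(chip = mk(chip), input = mk(input))
}
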