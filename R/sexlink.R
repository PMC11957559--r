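#' Normalize a coverage track to depth per million mapped reads
#'
#' Scales every window's mean depth by `library_mapped_reads / 1e6` so that
#' libraries of different sequencing depth are comparable. Tracks carry a
#' `normalized` flag; normalizing twice is an error.
#'
#' @param track A [coverage_track()] with `library_mapped_reads` set.
#' @return The normalized [coverage_track()].
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (isTRUE(track$normalized)) stop("track is already normalized")
  mr <- track$library_mapped_reads
  if (is.na(mr) || mr <= 0) stop("library_mapped_reads must be > 0")
  track$windows$mean_depth <- track$windows$mean_depth / (mr / 1e6)
  track$normalized <- TRUE
  track
}

#' Per-window log2 male:female coverage ratio
#'
#' For each shared window, log2((m + pseudo) / (f + pseudo)) on normalized
#' depths. Windows whose female depth is below `min_depth` are excluded
#' (low female coverage makes the ratio unstable); the number excluded is
#' recorded in the `n_excluded` attribute. Expected values: 0 on autosomes,
#' -1 on the X of an X0 male.
#'
#' `pseudo` and `min_depth` are relative: `pseudo` is a fraction of the
#' geometric mean of the two tracks' genome-wide mean depths, `min_depth`
#' a fraction of the female track's mean depth. Because per-million
#' normalization rescales depths by an amount that depends on library and
#' genome size, a fixed absolute offset would bias ratios by an
#' arbitrary, data-dependent amount; relative constants keep the same
#' meaning at any depth and make the ratio invariant to rescaling a
#' library's depths together with its mapped-read count. The same offset
#' is added on both sides, so m = f still gives ratio 0 exactly. The
#' default 0.01 corresponds to ~0.5 depth units at 50x coverage.
#'
#' @param male,female Normalized [coverage_track()]s on identical windows.
#' @param pseudo Depth offset added to both numerator and denominator, as
#'   a fraction of mean coverage.
#' @param min_depth Minimum female depth for a window to enter, as a
#'   fraction of mean female coverage.
#' @return Data frame `scaffold`, `start`, `end`, `log2_mf`, with attribute
#'   `n_excluded`.
#' @export
coverage_log2_ratio <- function(male, female, pseudo = 0.01,
                                min_depth = 0) {
  stopifnot(inherits(male, "coverage_track"),
            inherits(female, "coverage_track"))
  if (!isTRUE(male$normalized) || !isTRUE(female$normalized))
    stop("both tracks must be normalized (see normalize_track)")
  mw <- male$windows; fw <- female$windows
  if (nrow(mw) != nrow(fw) ||
      !all(mw$scaffold == fw$scaffold & mw$start == fw$start &
             mw$end == fw$end))
    stop("male and female tracks must share an identical window set")
  pseudo_n <- pseudo * sqrt(mean(mw$mean_depth) * mean(fw$mean_depth))
  keep <- fw$mean_depth >= min_depth * mean(fw$mean_depth)
  out <- data.frame(scaffold = mw$scaffold[keep], start = mw$start[keep],
                    end = mw$end[keep],
                    log2_mf = log2((mw$mean_depth[keep] + pseudo_n) /
                                     (fw$mean_depth[keep] + pseudo_n)),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Classify scaffolds as X-linked or autosomal from coverage ratios
#'
#' Scaffold medians of the per-window log2 male:female ratio are compared
#' against two thresholds: median < `x_max` (default -0.5) is X-linked,
#' median > `auto_min` (default -0.25) autosomal, anything in between (or
#' exactly on a threshold, or with fewer than `min_windows` windows) is
#' ambiguous. The defaults are the midpoints between the hemizygous
#' expectation (-1) and the autosomal expectation (0).
#'
#' @param ratios Output of [coverage_log2_ratio()].
#' @param min_windows Minimum windows for a confident call.
#' @param x_max Strict upper bound on the median for an X-linked call.
#' @param auto_min Strict lower bound for an autosomal call.
#' @return Data frame of class `scaffold_coverage_report`: `scaffold`,
#'   `n_windows`, `median_log2_mf`, `classification`, `reason`.
#' @export
classify_scaffolds <- function(ratios, min_windows = 5,
                               x_max = -0.5, auto_min = -0.25) {
  stopifnot(x_max <= auto_min)
  sc <- split(ratios$log2_mf, ratios$scaffold)
  res <- data.frame(
    scaffold = names(sc),
    n_windows = vapply(sc, length, integer(1)),
    median_log2_mf = vapply(sc, stats::median, numeric(1)),
    stringsAsFactors = FALSE)
  cls <- rep("ambiguous", nrow(res))
  reason <- rep("", nrow(res))
  ok <- res$n_windows >= min_windows
  reason[!ok] <- sprintf("only %d windows (< %d)", res$n_windows[!ok],
                         min_windows)
  cls[ok & res$median_log2_mf < x_max] <- "X-linked"
  cls[ok & res$median_log2_mf > auto_min] <- "autosomal"
  mid <- ok & cls == "ambiguous"
  reason[mid] <- sprintf("median %.3f between thresholds [%g, %g]",
                         res$median_log2_mf[mid], x_max, auto_min)
  res$classification <- cls
  res$reason <- reason
  rownames(res) <- NULL
  class(res) <- c("scaffold_coverage_report", "data.frame")
  res
}
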