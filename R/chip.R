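#' Windowed ChIP/input enrichment profile
#'
#' Both tracks are scaled to depth per million mapped reads (unless already
#' normalized), then each window gets
#' log2((chip + pseudo) / (input + pseudo)). Windows whose input depth
#' falls below `min_input` are excluded (enrichment over a near-empty
#' input is meaningless); the count of exclusions is recorded.
#'
#' As in [coverage_log2_ratio()], `pseudo` and `min_input` are relative:
#' `pseudo` is a fraction of the geometric mean of the two tracks'
#' genome-wide mean depths, `min_input` a fraction of the input track's
#' mean depth. Relative constants keep their meaning at any sequencing
#' depth and leave the profile invariant to rescaling one library's
#' depths together with its mapped-read count. The defaults correspond to
#' ~0.3 and ~1 depth units at 30x input coverage.
#'
#' @param chip,input [coverage_track()]s on identical windows, each with
#'   `library_mapped_reads`.
#' @param pseudo Pseudo-depth added to both, as a fraction of mean
#'   coverage.
#' @param min_input Minimum input depth per window, as a fraction of mean
#'   input coverage.
#' @return Data frame of class `enrichment_profile`: `scaffold`, `start`,
#'   `end`, `log2_chip_input`; attribute `n_excluded`.
#' @export
enrichment_profile <- function(chip, input, pseudo = 0.01,
                               min_input = 0.03) {
  stopifnot(inherits(chip, "coverage_track"),
            inherits(input, "coverage_track"))
  if (!isTRUE(chip$normalized)) chip <- normalize_track(chip)
  if (!isTRUE(input$normalized)) input <- normalize_track(input)
  cw <- chip$windows; iw <- input$windows
  if (nrow(cw) != nrow(iw) ||
      !all(cw$scaffold == iw$scaffold & cw$start == iw$start &
             cw$end == iw$end))
    stop("chip and input tracks must share an identical tiling")
  pseudo_n <- pseudo * sqrt(mean(cw$mean_depth) * mean(iw$mean_depth))
  keep <- iw$mean_depth >= min_input * mean(iw$mean_depth)
  out <- data.frame(scaffold = cw$scaffold[keep], start = cw$start[keep],
                    end = cw$end[keep],
                    log2_chip_input = log2((cw$mean_depth[keep] + pseudo_n) /
                                             (iw$mean_depth[keep] + pseudo_n)),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Smooth an enrichment profile along one scaffold
#'
#' Penalized cubic smoothing spline (smoothing parameter chosen by
#' generalized cross-validation) of the window log2 ratios against window
#' midpoints, evaluated at the midpoints — the per-scaffold trend curves
#' drawn over chromosome-scale enrichment plots. Scaffolds with fewer than
#' `min_windows` windows return the raw values with a flag.
#'
#' @param profile An [enrichment_profile()].
#' @param scaffold Scaffold name to smooth.
#' @param min_windows Minimum windows for spline fitting (default 10).
#' @return Data frame `midpoint`, `smoothed`; attribute
#'   `smoothed = TRUE/FALSE`.
#' @export
smooth_profile <- function(profile, scaffold, min_windows = 10) {
  w <- profile[profile$scaffold == scaffold, , drop = FALSE]
  if (!nrow(w)) stop("no windows on scaffold ", scaffold)
  mid <- (w$start + w$end) / 2
  if (nrow(w) < min_windows) {
    out <- data.frame(midpoint = mid, smoothed = w$log2_chip_input)
    attr(out, "smoothed") <- FALSE
    return(out)
  }
  fit <- stats::smooth.spline(mid, w$log2_chip_input, cv = FALSE)
  out <- data.frame(midpoint = mid,
                    smoothed = stats::predict(fit, mid)$y)
  attr(out, "smoothed") <- TRUE
  out
}

#' Test chromosome-scale X enrichment
#'
#' Difference of window-level medians (X minus autosomes) of the log2
#' ChIP/input ratio, with a two-sided rank-sum p-value. De-logging the
#' difference estimates the fold enrichment of the mark on the X.
#'
#' @param profile An [enrichment_profile()].
#' @param x_scaffold Name of the X scaffold.
#' @param min_windows Minimum windows required in each class (default 5).
#' @return List: `n_x`, `n_auto`, `median_x`, `median_auto`,
#'   `median_diff`, `fold` (2^median_diff), `U`, `p`.
#' @export
x_enrichment_test <- function(profile, x_scaffold, min_windows = 5) {
  if (!x_scaffold %in% profile$scaffold)
    stop("no windows on ", x_scaffold)
  xv <- profile$log2_chip_input[profile$scaffold == x_scaffold]
  av <- profile$log2_chip_input[profile$scaffold != x_scaffold]
  if (length(xv) < min_windows || length(av) < min_windows)
    stop("need >= ", min_windows, " windows per class (X: ", length(xv),
         ", autosomes: ", length(av), ")")
  rs <- rank_sum_test(xv, av)
  md <- stats::median(xv) - stats::median(av)
  list(n_x = length(xv), n_auto = length(av),
       median_x = stats::median(xv), median_auto = stats::median(av),
       median_diff = md, fold = 2^md, U = rs$U, p = rs$p)
}
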