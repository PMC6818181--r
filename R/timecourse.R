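#' Segment means of an activation time course
#'
#' Averages a gene-by-timepoint matrix within consecutive, equal-sized
#' blocks of timepoints (default six segments of three points from an
#' 18-point series). A 19-point series is reduced to 18 by dropping the
#' time-zero point — it precedes activation — unless `drop_first = FALSE`,
#' in which case the last point is dropped instead.
#'
#' @param tc Numeric matrix, genes in rows, timepoints in columns (column
#'   order = time order).
#' @param panel Optional character vector restricting to these genes (all
#'   must be present).
#' @param n_segments Number of consecutive blocks (default 6).
#' @param drop_first Which end to trim when one point is surplus.
#' @return Gene-by-segment matrix of means, columns `T0`, `T1`, ...
#' @export
segment_means <- function(tc, panel = NULL, n_segments = 6, drop_first = TRUE) {
  tc <- as.matrix(tc)
  if (!is.null(panel)) {
    absent <- setdiff(panel, rownames(tc))
    if (length(absent))
      stop_validation(sprintf("panel genes absent from time course: %s",
                              paste(absent, collapse = ", ")))
    tc <- tc[panel, , drop = FALSE]
  }
  nt <- ncol(tc)
  if (nt %% n_segments == 1) {
    message(sprintf("segment_means: dropping the %s of %d timepoints",
                    if (drop_first) "first" else "last", nt))
    tc <- if (drop_first) tc[, -1, drop = FALSE] else tc[, -nt, drop = FALSE]
    nt <- nt - 1L
  }
  if (nt %% n_segments != 0)
    stop_validation(sprintf("%d timepoints not divisible into %d segments", nt, n_segments))
  width <- nt %/% n_segments
  seg <- rep(seq_len(n_segments), each = width)
  out <- t(apply(tc, 1, function(v) tapply(v, seg, mean)))
  colnames(out) <- paste0("T", seq_len(n_segments) - 1)
  out
}

#' Classify the trend of a segment-mean trajectory
#'
#' Labels a trajectory `rising` when the Spearman correlation of segment
#' means with segment index is at least 0.8, `falling` when at most -0.8,
#' `peak_then_decline` when the maximum sits at an interior segment with
#' both flanks monotone (non-decreasing up to the peak, non-increasing
#' after), and `flat` otherwise. The thresholds are package-defined
#' operationalizations of verbal trend descriptions.
#'
#' @param seg_means Numeric vector of segment means (length >= 3), or a
#'   matrix from [segment_means()] (one classification per row).
#' @param rho_cut Spearman threshold (default 0.8).
#' @return Character label(s).
#' @export
trend_classification <- function(seg_means, rho_cut = 0.8) {
  if (is.matrix(seg_means))
    return(vapply(seq_len(nrow(seg_means)),
                  function(i) trend_classification(seg_means[i, ], rho_cut),
                  character(1)))
  v <- as.numeric(seg_means)
  k <- length(v)
  if (k < 3) stop_validation("need at least 3 segments to classify a trend")
  if (stats::sd(v) == 0) return("flat")
  rho <- suppressWarnings(stats::cor(seq_len(k), v, method = "spearman"))
  if (!is.na(rho)) {
    if (rho >= rho_cut) return("rising")
    if (rho <= -rho_cut) return("falling")
  }
  peak <- which.max(v)
  if (peak > 1 && peak < k &&
      !is.unsorted(v[1:peak]) && !is.unsorted(rev(v[peak:k])))
    return("peak_then_decline")
  "flat"
}
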