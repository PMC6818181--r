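#' Find the expressed/not-expressed threshold from a bimodal distribution
#'
#' Pooled log2 expression values across all genes and samples of a dataset
#' typically form a bimodal distribution: a low peak of non-expressed genes
#' and a high peak of expressed genes. The threshold is the lowest point of
#' the valley between the two peaks; genes at or below it are treated as not
#' expressed.
#'
#' Density estimation is Gaussian KDE with Silverman's rule-of-thumb
#' bandwidth (`bw.nrd0`), evaluated on a 512-point grid spanning the data
#' range. The two dominant modes are the two highest local maxima of the
#' estimated density among those reaching at least `min_peak_frac` of the
#' global maximum (guarding against reading a tail ripple of a unimodal
#' density as a second mode); the threshold is the grid minimum strictly
#' between them.
#'
#' @param x An `ExpressionMatrix` (all values pooled) or a numeric vector of
#'   at least 200 pooled log2 values.
#' @param min_peak_frac Minimum height of a candidate mode, as a fraction of
#'   the density maximum (default 0.05).
#' @return An `ExpressionThreshold` list: `threshold`, `peaks` (the two mode
#'   locations, ascending), `bandwidth`, and the density `grid`
#'   (`x`/`y` vectors).
#' @section Errors: If no interior valley exists (a unimodal density), a
#'   condition of class `NoValleyError` is signalled; callers may then supply
#'   a manual threshold to [mark_expressed()].
#' @export
find_expression_threshold <- function(x, min_peak_frac = 0.05) {
  v <- if (inherits(x, "ExpressionMatrix")) as.vector(x$values) else as.numeric(x)
  if (length(v) < 200)
    stop_validation("need at least 200 pooled values to estimate the valley")
  d <- stats::density(v, bw = "nrd0", n = 512)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  peaks <- which(is_max & y >= min_peak_frac * max(y))
  if (length(peaks) < 2)
    stop_no_valley("density has fewer than two modes; supply a manual threshold")
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  between <- (top2[1] + 1):(top2[2] - 1)
  if (!length(between))
    stop_no_valley("no interior point between the two modes")
  valley <- between[which.min(y[between])]
  structure(list(
    threshold = d$x[valley],
    peaks = d$x[top2],
    bandwidth = d$bw,
    grid = list(x = d$x, y = d$y)
  ), class = "ExpressionThreshold")
}

#' Flag expressed genes per group
#'
#' A gene counts as expressed in a group when its median log2 expression in
#' that group exceeds the threshold; the dataset-level flag is "expressed in
#' at least one group". Genes not expressed in either group are excluded from
#' differential testing.
#'
#' @param em An `ExpressionMatrix`.
#' @param threshold An `ExpressionThreshold` or a single numeric log2 value
#'   (manual threshold).
#' @return Data frame with columns `gene`, `expressed_case`,
#'   `expressed_control`, `expressed` (either group).
#' @export
mark_expressed <- function(em, threshold) {
  thr <- if (inherits(threshold, "ExpressionThreshold")) threshold$threshold
         else as.numeric(threshold)
  case_med <- apply(em$values[, em$groups == "case", drop = FALSE], 1, stats::median)
  ctrl_med <- apply(em$values[, em$groups == "control", drop = FALSE], 1, stats::median)
  data.frame(gene = em$gene_ids,
             expressed_case = case_med > thr,
             expressed_control = ctrl_med > thr,
             expressed = case_med > thr | ctrl_med > thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Collapse probes to genes
#'
#' For a microarray-style matrix keyed by probe ids, retains for each gene
#' the probe with the highest mean expression across all samples; ties are
#' broken by the lexicographically smallest probe id. Probes absent from the
#' map are dropped, with the count reported via `message()`.
#'
#' @param em An `ExpressionMatrix` whose rows are probes.
#' @param probe_to_gene Named character vector, `names` = probe ids,
#'   values = gene symbols.
#' @return An `ExpressionMatrix` with one row per gene; each retained row is
#'   bit-identical to the winning probe's row.
#' @export
collapse_probes <- function(em, probe_to_gene) {
  probes <- em$gene_ids
  mapped <- probes %in% names(probe_to_gene)
  if (any(!mapped))
    message(sprintf("collapse_probes: dropping %d probe(s) absent from the map",
                    sum(!mapped)))
  probes <- probes[mapped]
  if (!length(probes)) stop_validation("no probes left after applying the map")
  gene <- unname(probe_to_gene[probes])
  means <- rowMeans(em$values[probes, , drop = FALSE])
  # highest mean wins; ties go to the lexicographically smallest probe id
  ord <- order(gene, -means, probes, method = "radix")
  keep <- probes[ord][!duplicated(gene[ord])]
  out <- em$values[keep, , drop = FALSE]
  rownames(out) <- unname(probe_to_gene[keep])
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_matrix(out, em$groups, platform = em$platform, paired = em$paired)
}

#' Convert between linear and log2 expression scales
#'
#' Values are stored on the log2 scale throughout; operations that need
#' linear expression (fold-change ratios, the PDHB/PKM flux proxy) de-log
#' explicitly. `log2p1` applies the conventional pseudocount-1 transform for
#' raw FPKM input.
#'
#' @param x Numeric vector or matrix.
#' @return Transformed values.
#' @export
delog2 <- function(x) 2^x

#' @rdname delog2
#' @export
log2p1 <- function(x) {
  if (any(x < 0)) stop_validation("linear expression must be non-negative")
  log2(x + 1)
}
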