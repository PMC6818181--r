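#' Differential expression by Wilcoxon tests with BH control
#'
#' Tests each expressed gene for a case-vs-control expression difference. The
#' default is the unpaired Wilcoxon rank-sum (Mann-Whitney) test; when the
#' matrix declares a matched design (`paired = TRUE`) the signed-rank test is
#' used instead. P-values are exact where `stats::wilcox.test` provides an
#' exact distribution (small samples, no ties) and use the tie-corrected
#' normal approximation otherwise. False discovery rate is controlled by
#' Benjamini-Hochberg across the tested genes of the dataset.
#'
#' Fold change is computed on the log2 scale as the difference of group
#' means, so `FC = 2^(mean_case - mean_control)` (a ratio of geometric means
#' on the linear scale); `fc_method = "linear_means"` instead uses the ratio
#' of arithmetic linear means for sensitivity analysis. Calls use the
#' two-tier thresholds: a differential call (`deg_call`) requires
#' `FC > 1.3` (or `< 1/1.3`) with `q < 0.01`; the coarser heat-map call
#' (`heatmap_call`) requires only `|log2FC| > 0.6`.
#'
#' @param em An `ExpressionMatrix` with both groups non-empty.
#' @param expressed Optional output of [mark_expressed()]; genes with
#'   `expressed = FALSE` are excluded from testing (their p/q are `NA` and
#'   calls are `unchanged`/`not_expressed`). Default: all genes tested.
#' @param fc_method `"log2_means"` (default) or `"linear_means"`.
#' @param fc_cut Linear fold-change threshold for `deg_call` (default 1.3).
#' @param fdr_cut FDR threshold for `deg_call` (default 0.01).
#' @param log2fc_cut `|log2FC|` threshold for `heatmap_call` (default 0.6).
#' @return A `DifferentialResult` data frame with one row per gene: `gene`,
#'   `mean_case`, `mean_control` (log2), `log2FC`, `FC`, `p_value`,
#'   `q_value`, `deg_call`, `heatmap_call`, `expressed`.
#' @export
differential_expression <- function(em, expressed = NULL,
                                    fc_method = c("log2_means", "linear_means"),
                                    fc_cut = 1.3, fdr_cut = 0.01,
                                    log2fc_cut = 0.6) {
  fc_method <- match.arg(fc_method)
  case <- em$values[, em$groups == "case", drop = FALSE]
  ctrl <- em$values[, em$groups == "control", drop = FALSE]
  if (!ncol(case) || !ncol(ctrl))
    stop_validation("both groups must be non-empty")
  if (em$paired && ncol(case) != ncol(ctrl))
    stop_validation("paired design requires equal group sizes")
  is_exp <- if (is.null(expressed)) rep(TRUE, nrow(em$values))
            else expressed$expressed[match(em$gene_ids, expressed$gene)]

  mean_case <- rowMeans(case)
  mean_ctrl <- rowMeans(ctrl)
  log2fc <- if (fc_method == "log2_means") mean_case - mean_ctrl
            else log2(rowMeans(delog2(case)) / rowMeans(delog2(ctrl)))
  p <- rep(NA_real_, nrow(em$values))
  for (i in which(is_exp)) {
    x <- case[i, ]; y <- ctrl[i, ]
    if (all(x == y[1]) && all(y == y[1])) { p[i] <- 1; next }  # degenerate: no signal
    p[i] <- suppressWarnings(
      stats::wilcox.test(x, y, paired = em$paired, exact = NULL)$p.value)
  }
  q <- rep(NA_real_, length(p))
  q[is_exp] <- stats::p.adjust(p[is_exp], method = "BH")
  fc <- 2^log2fc
  deg <- ifelse(!is_exp | is.na(q), "unchanged",
         ifelse(fc > fc_cut & q < fdr_cut, "up",
         ifelse(fc < 1 / fc_cut & q < fdr_cut, "down", "unchanged")))
  hm <- ifelse(!is_exp, "not_expressed",
        ifelse(log2fc > log2fc_cut, "up",
        ifelse(log2fc < -log2fc_cut, "down", "unchanged")))
  structure(data.frame(
    gene = em$gene_ids, mean_case = mean_case, mean_control = mean_ctrl,
    log2FC = log2fc, FC = fc, p_value = p, q_value = q,
    deg_call = deg, heatmap_call = hm, expressed = is_exp,
    row.names = NULL, stringsAsFactors = FALSE
  ), class = c("DifferentialResult", "data.frame"))
}

#' Categorical heat-map calls for a transporter panel
#'
#' Maps each panel gene to its coarse differential category in this dataset,
#' using the `|log2FC| > 0.6` tier: `up`, `down`, `unchanged`, or
#' `not_expressed`; panel genes absent from the matrix are recorded as
#' `missing`.
#'
#' @param results A `DifferentialResult` from [differential_expression()].
#' @param panel A `TransporterPanel` from [load_default_panel()] (or any data
#'   frame with `symbol` and `role` columns); only included genes are used.
#' @return Data frame with columns `symbol`, `family`, `role`, `call`.
#' @export
categorize_for_heatmap <- function(results, panel) {
  pan <- panel[panel$included, , drop = FALSE]
  idx <- match(pan$symbol, results$gene)
  call <- ifelse(is.na(idx), "missing", results$heatmap_call[idx])
  data.frame(symbol = pan$symbol, family = pan$family, role = pan$role,
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}
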