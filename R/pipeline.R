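#' Configure the full analysis pipeline
#'
#' Collects every tunable threshold with the printed defaults used
#' throughout: Warburg fold-change gate 2, differential-call fold change
#' 1.3, heat-map log2 fold change 0.6, FDR 0.01, correlation significance
#' 0.01, and the 75% PC1+PC2 variance gate.
#'
#' @param warburg_fc Fold-change gate of the Warburg classifier.
#' @param deg_fc,deg_fdr Differential-call thresholds.
#' @param heatmap_log2fc Heat-map tier threshold on `|log2FC|`.
#' @param corr_p Significance level for Fenton/correlation calls.
#' @param variance_gate PC1+PC2 variance fraction for PC regression.
#' @param manual_threshold Optional log2 expression threshold used when the
#'   pooled density has no detectable valley.
#' @param seed Integer seed echoed into the report (the pipeline itself is
#'   deterministic; the seed documents upstream simulation).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(warburg_fc = 2, deg_fc = 1.3, deg_fdr = 0.01,
                            heatmap_log2fc = 0.6, corr_p = 0.01,
                            variance_gate = 0.75, manual_threshold = NULL,
                            seed = 1) {
  stopifnot(warburg_fc > 0, deg_fc > 0, deg_fdr > 0, heatmap_log2fc > 0,
            corr_p > 0, variance_gate > 0, variance_gate < 1)
  structure(list(warburg_fc = warburg_fc, deg_fc = deg_fc, deg_fdr = deg_fdr,
                 heatmap_log2fc = heatmap_log2fc, corr_p = corr_p,
                 variance_gate = variance_gate,
                 manual_threshold = manual_threshold, seed = seed),
            class = "PipelineConfig")
}

#' Run the full case/control analysis
#'
#' Executes the stages in fixed order: expressed-gene thresholding (valley
#' of the pooled bimodal density, or the configured manual threshold when no
#' valley exists), Wilcoxon differential expression with BH control,
#' transporter-panel heat-map calls and acidification score, the
#' two-criterion Warburg classifier, and the Fenton-reaction criterion. Each
#' stage's parameters and filter counts are echoed into the report, so every
#' number is traceable; timestamps are excluded, making re-runs on identical
#' input byte-identical.
#'
#' @param em An `ExpressionMatrix`.
#' @param cfg A `PipelineConfig`.
#' @param panel A `TransporterPanel` (default [load_default_panel()]).
#' @param fenton_cfg A `FentonMarkerConfig` (default markers).
#' @param dataset_id Label echoed into the report.
#' @return An `AnalysisReport` list with elements `dataset`, `parameters`,
#'   `threshold`, `counts`, `differential` (the full table),
#'   `heatmap_calls`, `acidification`, `warburg`, `fenton`.
#' @export
run_pipeline <- function(em, cfg = pipeline_config(),
                         panel = load_default_panel(),
                         fenton_cfg = fenton_marker_config(),
                         dataset_id = "dataset") {
  thr <- tryCatch(find_expression_threshold(em),
                  NoValleyError = function(e) {
                    if (is.null(cfg$manual_threshold)) stop(e)
                    structure(list(threshold = cfg$manual_threshold,
                                   peaks = NULL, bandwidth = NA,
                                   grid = NULL),
                              class = "ExpressionThreshold")
                  })
  expressed <- mark_expressed(em, thr)
  de <- differential_expression(em, expressed = expressed,
                                fc_cut = cfg$deg_fc, fdr_cut = cfg$deg_fdr,
                                log2fc_cut = cfg$heatmap_log2fc)
  acid <- acidification_summary(de, panel)
  wv <- classify_warburg(em, fc_cut = cfg$warburg_fc)
  fen <- assess_fenton(em, fenton_cfg, threshold = cfg$corr_p)
  list(
    dataset = dataset_id,
    parameters = unclass(cfg),
    threshold = thr$threshold,
    counts = list(
      genes = nrow(em$values),
      samples = ncol(em$values),
      genes_expressed = sum(expressed$expressed),
      genes_tested = sum(!is.na(de$p_value)),
      deg_up = sum(de$deg_call == "up"),
      deg_down = sum(de$deg_call == "down"),
      panel_missing = acid$n_missing,
      ratio_samples_excluded = wv$n_ratio_excluded
    ),
    differential = de,
    heatmap_calls = acid$calls,
    acidification = list(score = acid$score, verdict = acid$verdict),
    warburg = unclass(wv),
    fenton = list(r = fen$r, p_value = fen$p_value, predicted = fen$predicted,
                  superoxide_included = fen$superoxide_included)
  )
}
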