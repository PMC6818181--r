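#' Load the curated pH-transporter panel
#'
#' The panel encodes the plasma-membrane transporters whose expression
#' direction reports on intracellular acidification: Cl-/HCO3- exchangers and
#' the plasma-membrane V-ATPase subunits as acid loaders; Na+/HCO3-
#' cotransporters, Na+/H+ exchangers and the outward Cl- exchanger SLC26A9
#' as acid extruders; and the monocarboxylate (lactic acid) transporters
#' SLC16A1/SLC16A3 kept as a separate class because they are proton-gradient
#' driven and argue nothing about net acidification. Family members excluded
#' from analysis (ambiguous localization, no expression, single-tissue
#' expression, non-bicarbonate function) are retained in the table with their
#' exclusion reason.
#'
#' ATP6V0B and ATP6V0C are carried as one plasma-membrane V-ATPase signal
#' duplicated over two symbols; datasets reporting only one of them lose no
#' information.
#'
#' The panel ships as an editable TSV
#' (`system.file("extdata", "transporter_panel.tsv", package = "warburgph")`),
#' so roles can be amended without touching code.
#'
#' @param path Optional path to an alternative panel TSV with columns
#'   `symbol`, `family`, `role`, `included`, `exclusion_reason`.
#' @return A `TransporterPanel` data frame.
#' @export
load_default_panel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "transporter_panel.tsv", package = "warburgph")
  pan <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE, fill = TRUE,
                           na.strings = character())
  need <- c("symbol", "family", "role", "included", "exclusion_reason")
  if (!all(need %in% names(pan)))
    stop_format("panel table must have columns symbol, family, role, included, exclusion_reason")
  pan$included <- as.logical(pan$included)
  if (!all(pan$role %in% c("acid_loader", "acid_extruder", "lactate_exporter")))
    stop_validation("unknown transporter role in panel")
  structure(pan, class = c("TransporterPanel", "data.frame"))
}

#' Net acidification direction of a dataset
#'
#' A transparent integer surrogate for the transporter heat-map pattern:
#' counting coarse calls over the panel,
#' `score = (loaders up + extruders down) - (loaders down + extruders up)`.
#' A positive score (cancer-like: loaders induced, extruders repressed) is
#' read as net intracellular acidification by the transporters; a negative
#' score (proliferating-normal-like) as alkalinization. Lactate exporters
#' never enter the score: being driven by the proton gradient they cannot set
#' its direction.
#'
#' @param results A `DifferentialResult`.
#' @param panel A `TransporterPanel`.
#' @return List with `score` (integer), `verdict` (`"acidifying"`,
#'   `"alkalinizing"`, `"neutral"`), the per-gene call table, and counts of
#'   missing panel genes.
#' @export
acidification_summary <- function(results, panel) {
  calls <- categorize_for_heatmap(results, panel)
  scored <- calls[calls$role %in% c("acid_loader", "acid_extruder"), , drop = FALSE]
  if (all(scored$call == "missing"))
    stop_validation("no panel gene present in the expression matrix")
  loader <- scored$role == "acid_loader"
  score <- sum(loader & scored$call == "up") +
           sum(!loader & scored$call == "down") -
           sum(loader & scored$call == "down") -
           sum(!loader & scored$call == "up")
  list(
    score = as.integer(score),
    verdict = if (score > 0) "acidifying" else if (score < 0) "alkalinizing" else "neutral",
    calls = calls,
    n_missing = sum(calls$call == "missing")
  )
}
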