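#' Default proteasome (PSM) gene list
#'
#' Curated 26S proteasome subunit symbols (PSMA1-7, PSMB1-7, PSMC1-6,
#' PSMD1-14) used as the default hydroxyl-radical-side proxy: proteasome
#' induction reports on the protein damage inflicted by Fenton-produced
#' hydroxyl radicals.
#'
#' @return Character vector of gene symbols.
#' @export
psm_genes <- function() {
  c(sprintf("PSMA%d", 1:7), sprintf("PSMB%d", 1:7),
    sprintf("PSMC%d", 1:6), sprintf("PSMD%d", 1:14))
}

#' Configure marker gene sets for the Fenton-reaction criterion
#'
#' The criterion asks whether the two sides of the iron-catalyzed
#' Haber-Weiss reaction (superoxide + H2O2 -> hydroxyl radical + hydroxide +
#' O2, with Fe2+ as catalyst) co-vary across samples. Each chemical quantity
#' is proxied by a marker gene set: proteasome genes for the hydroxyl-radical
#' (product) side; thioredoxins and glutamate-cysteine ligase subunits
#' (`TXN`, `TXN2`, `GCLC`, `GCLM`) for H2O2; transferrin receptors (`TFRC`,
#' `TFR2`) for iron uptake. No default exists for a superoxide proxy — it is
#' generated largely by cells outside the sampled tissue — so it must be
#' supplied explicitly if used.
#'
#' @param oh_proxy,h2o2_proxy,iron_proxy `GeneSet`s (defaults as above).
#' @param superoxide_proxy Optional `GeneSet`; no default.
#' @return A `FentonMarkerConfig` list. Sets must be pairwise disjoint.
#' @export
fenton_marker_config <- function(
    oh_proxy = gene_set("oh_proxy", psm_genes()),
    h2o2_proxy = gene_set("h2o2_proxy", c("TXN", "TXN2", "GCLC", "GCLM")),
    iron_proxy = gene_set("iron_proxy", c("TFRC", "TFR2")),
    superoxide_proxy = NULL) {
  sets <- list(oh = oh_proxy, h2o2 = h2o2_proxy, iron = iron_proxy)
  if (!is.null(superoxide_proxy)) sets$superoxide <- superoxide_proxy
  members <- unlist(lapply(sets, function(s) s$members))
  if (anyDuplicated(members))
    stop_validation("Fenton marker sets must be pairwise disjoint")
  structure(list(oh_proxy = oh_proxy, h2o2_proxy = h2o2_proxy,
                 iron_proxy = iron_proxy, superoxide_proxy = superoxide_proxy),
            class = "FentonMarkerConfig")
}

# oriented, standardized PC1 score of a gene submatrix: genes are z-scored
# across samples first, PC1 sign fixed to correlate positively with the
# per-sample mean of the standardized genes
.oriented_pc1 <- function(sub) {
  keep <- apply(sub, 1, stats::sd) > 0
  sub <- sub[keep, , drop = FALSE]
  if (!nrow(sub)) stop_validation("all proxy genes have zero variance")
  z <- t(scale(t(sub)))
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  s <- pc$x[, 1]
  ms <- colMeans(z)
  if (stats::sd(s) > 0 && stats::sd(ms) > 0 && stats::cor(s, ms) < 0) s <- -s
  s
}

#' Test for a cytosolic Fenton-reaction signature
#'
#' Scores each sample on the product side (oriented, standardized PC1 of the
#' hydroxyl-radical proxy set) and the substrate side (oriented PC1 of the
#' pooled H2O2, iron and — if supplied — superoxide proxy sets), then calls
#' the reaction present when the two scores correlate positively and
#' significantly (Pearson, two-sided p below `threshold`).
#'
#' @param em An `ExpressionMatrix` with at least 10 samples.
#' @param cfg A `FentonMarkerConfig`.
#' @param threshold Significance level (default 0.01).
#' @return A `FentonVerdict` list: `lhs_score`, `rhs_score` (per sample),
#'   `r`, `p_value`, `predicted`, and `superoxide_included`.
#' @export
assess_fenton <- function(em, cfg = fenton_marker_config(), threshold = 0.01) {
  if (ncol(em$values) < 10) stop_validation("need at least 10 samples")
  rhs_sub <- gene_submatrix(em, cfg$oh_proxy$members)
  if (nrow(rhs_sub) < 2) stop_validation("too few oh_proxy genes present")
  substrate <- c(cfg$h2o2_proxy$members, cfg$iron_proxy$members)
  sox <- !is.null(cfg$superoxide_proxy)
  if (sox) substrate <- c(substrate, cfg$superoxide_proxy$members)
  lhs_sub <- gene_submatrix(em, substrate)
  if (nrow(lhs_sub) < 2) stop_validation("too few substrate-side genes present")
  rhs <- .oriented_pc1(rhs_sub)
  lhs <- .oriented_pc1(lhs_sub)
  ct <- suppressWarnings(stats::cor.test(lhs, rhs, method = "pearson"))
  r <- unname(ct$estimate)
  structure(list(
    lhs_score = lhs, rhs_score = rhs, r = r, p_value = ct$p.value,
    predicted = isTRUE(r > 0 && ct$p.value < threshold),
    superoxide_included = sox
  ), class = "FentonVerdict")
}

#' Couple transporter expression to the Fenton product proxy
#'
#' For every included panel gene present in the matrix, the Pearson
#' correlation between its expression and the oriented PC1 score of the
#' hydroxyl-radical proxy set, partitioned by transporter role. In a
#' cancer-like Fenton-driven dataset, acid loaders correlate positively and
#' acid extruders negatively with this score.
#'
#' @inheritParams assess_fenton
#' @param panel A `TransporterPanel`.
#' @return Data frame: `symbol`, `role`, `r`, `p_value`; panel genes shared
#'   with the proxy sets are rejected, absent genes are reported via
#'   `message()` and omitted.
#' @export
fenton_transporter_coupling <- function(em, panel, cfg = fenton_marker_config()) {
  proxy_genes <- c(cfg$oh_proxy$members, cfg$h2o2_proxy$members,
                   cfg$iron_proxy$members,
                   if (!is.null(cfg$superoxide_proxy)) cfg$superoxide_proxy$members)
  pan <- panel[panel$included, , drop = FALSE]
  clash <- intersect(pan$symbol, proxy_genes)
  if (length(clash))
    stop_validation(sprintf("panel gene(s) inside a proxy set: %s",
                            paste(clash, collapse = ", ")))
  score <- .oriented_pc1(gene_submatrix(em, cfg$oh_proxy$members))
  present <- pan$symbol %in% em$gene_ids
  if (any(!present))
    message(sprintf("fenton_transporter_coupling: %d panel gene(s) absent", sum(!present)))
  pan <- pan[present, , drop = FALSE]
  res <- lapply(pan$symbol, function(g) {
    ct <- suppressWarnings(stats::cor.test(em$values[g, ], score))
    data.frame(symbol = g, r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$role <- pan$role
  out[order(out$role, out$symbol), c("symbol", "role", "r", "p_value")]
}
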