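#!/usr/bin/env Rscript
# Gene-set correlation analyses: the Fenton-reaction criterion per
# archetype, the coupling of transporter expression to the proteasome
# proxy, a principal-curve correlation between the product and substrate
# proxy sets, and a PC-regression of PKM on the proteasome set. Outputs:
# results/fenton_verdicts.json, results/fenton_coupling_<type>.tsv.
suppressMessages(library(warburgph))

read_archetype <- function(ty) {
  groups <- utils::read.table(sprintf("results/data/%s_groups.tsv", ty),
                              header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  read_expression_matrix(sprintf("results/data/%s_expr.tsv", ty),
                         setNames(groups$group, groups$sample))
}

panel <- load_default_panel()
cfg <- fenton_marker_config()
substrate <- gene_set("substrate", c(cfg$h2o2_proxy$members, cfg$iron_proxy$members))
out <- list()
for (ty in c("cancer", "npc", "null")) {
  em <- read_archetype(ty)
  fen <- assess_fenton(em, cfg)
  curve <- set_vs_set_correlation(cfg$oh_proxy, substrate, em)
  pcr <- gene_vs_set_correlation("PKM", cfg$oh_proxy, em, variance_gate = 0.1)
  coup <- suppressMessages(fenton_transporter_coupling(em, panel, cfg))
  utils::write.table(coup, sprintf("results/fenton_coupling_%s.tsv", ty),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out[[ty]] <- list(fenton = list(r = fen$r, p = fen$p_value, predicted = fen$predicted),
                    curve_pcc = curve$pcc, curve_p = curve$p_value,
                    pkm_vs_psm = list(method = pcr$method,
                                      r_squared = pcr$r_squared, p = pcr$p_value))
  cat(sprintf("%s: Fenton %s (r=%.2f, p=%.2g); curve PCC=%.2f; PKM~PSM R2=%.2f; loader median r=%.2f\n",
              ty, if (fen$predicted) "predicted" else "not predicted",
              fen$r, fen$p_value, curve$pcc, pcr$r_squared,
              median(coup$r[coup$role == "acid_loader"])))
}
write_report(out, "results/fenton_verdicts.json")
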