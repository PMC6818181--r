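#!/usr/bin/env Rscript
# Transporter-panel heat-map calls, the acidification score, and the
# two-criterion Warburg classifier for each archetype. The categorical
# heat-map matrix (panel gene x dataset) goes to results/heatmap_calls.tsv,
# verdicts to results/warburg_verdicts.json.
suppressMessages(library(warburgph))

read_archetype <- function(ty) {
  groups <- utils::read.table(sprintf("results/data/%s_groups.tsv", ty),
                              header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  read_expression_matrix(sprintf("results/data/%s_expr.tsv", ty),
                         setNames(groups$group, groups$sample))
}

panel <- load_default_panel()
heat <- NULL
verdicts <- list()
for (ty in c("cancer", "npc", "null")) {
  em <- read_archetype(ty)
  de <- differential_expression(em, expressed = mark_expressed(em, find_expression_threshold(em)))
  acid <- acidification_summary(de, panel)
  wv <- classify_warburg(em)
  col <- setNames(acid$calls$call, acid$calls$symbol)
  heat <- if (is.null(heat)) data.frame(symbol = names(col), role = acid$calls$role,
                                        ty = unname(col), stringsAsFactors = FALSE)
          else cbind(heat, ty = unname(col[heat$symbol]))
  names(heat)[names(heat) == "ty"] <- ty
  verdicts[[ty]] <- list(acidification = acid$verdict, score = acid$score,
                         warburg = unclass(wv))
  cat(sprintf("%s: acidification score %+d (%s); Warburg %s (FC LDHA %.2f, SLC16A1 %.2f; PDHB/PKM %.3f vs %.3f)\n",
              ty, acid$score, acid$verdict,
              if (wv$verdict) "PRESENT" else "absent",
              wv$fc_LDHA, wv$fc_SLC16A1, wv$ratio_case, wv$ratio_control))
}
utils::write.table(heat, "results/heatmap_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_report(verdicts, "results/warburg_verdicts.json")
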