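#!/usr/bin/env Rscript
# Generate the three synthetic study archetypes — a cancer-like dataset
# (Warburg fold changes, acid loaders up / extruders down, a proteasome-
# substrate latent link), an NPC-like dataset (same Warburg fold changes,
# loaders down, no Fenton link) and a structure-free null — and write them
# as TSV expression matrices with group maps under results/data/.
suppressMessages(library(warburgph))

seed <- 101
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

for (ty in c("cancer", "npc", "null")) {
  sim <- simulate_dataset(warburg_demo_spec(ty, seed = seed))
  em <- sim$matrix
  write_expression_matrix(em, sprintf("results/data/%s_expr.tsv", ty))
  utils::write.table(
    data.frame(sample = em$sample_ids, group = em$groups),
    sprintf("results/data/%s_groups.tsv", ty),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d genes x %d samples, %d planted fold changes, %d latent link(s)\n",
              ty, nrow(em$values), ncol(em$values),
              sum(sim$truth$planted_fc != 1), length(sim$truth$latent_links)))
}
cat("wrote expression matrices and group maps to results/data/\n")
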