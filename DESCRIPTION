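Package: warburgph
Title: Warburg-Effect Classification and Intracellular pH Energetics from Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to distinguish the Warburg effect in cancer tissues from
    that in normal proliferating cells using bulk expression data: bimodal
    expressed-gene thresholding, Wilcoxon differential expression with
    Benjamini-Hochberg control, a curated pH-transporter panel with an
    acidification score, a two-criterion Warburg classifier based on lactate
    dehydrogenase / monocarboxylate transporter fold changes and the
    PDHB/PKM flux proxy, gene-set correlation via principal-component
    regression, hypergeometric overlap and principal-curve projection, a
    Fenton-reaction correlation criterion, and a closed-form proton budget
    for intracellular pH shifts. Includes a synthetic-data generator with
    planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
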