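#!/usr/bin/env Rscript
# The closed-form proton budget: protons (= respiratory ATPs) needed to
# raise intracellular pH from 6.8 to 7.4 in a 100 um^3 cell with buffering
# coefficient 2e5, the equivalent fraction of the genome's nucleotide-
# synthesis ATP cost, and the per-pathway proton ledger.
suppressMessages(library(warburgph))

spec <- ph_shift_spec()
budget <- protons_for_ph_shift(spec)
frac <- genome_fraction_equivalent(budget$protons, spec)
cat(sprintf("pH %.1f -> %.1f in %g um^3 (buffer %g): %.4g protons (%.3g ATPs)\n",
            spec$pH_start, spec$pH_end, spec$volume, spec$buffer_coefficient,
            budget$protons, budget$atp_equivalent))
cat(sprintf("equivalent to synthesizing %.2f%% of the genome (%g nt x %g ATP/nt)\n",
            100 * frac, spec$genome_nucleotides, spec$atp_per_nucleotide))
cat(sprintf("ledger: glycolytic ATP consumed nets %+d H+; respiratory ATP consumed nets %+d H+\n",
            net_protons("glycolysis_synthesis", 1),
            net_protons("respiration_synthesis", 1)))
dir.create("results", showWarnings = FALSE)
write_report(list(spec = unclass(spec), protons = budget$protons,
                  atp_equivalent = budget$atp_equivalent,
                  genome_fraction = frac,
                  ledger = proton_ledger()),
             "results/proton_budget.json")
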