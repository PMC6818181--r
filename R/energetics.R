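#' Proton stoichiometry of ATP pathways
#'
#' The bookkeeping behind the pH argument: respiration-based ATP synthesis
#' (`ADP3- + HPO4^2- -> ATP4- + OH-`) consumes one proton per ATP;
#' glycolytic ATP synthesis (`glucose + 2 ADP3- + 2 HPO4^2- -> 2 lactate +
#' 2 ATP4-`) is pH neutral and yields one lactate per ATP; hydrolysis of any
#' ATP (`ATP4- + H2O -> ADP3- + HPO4^2- + H+`) releases one proton. Hence a
#' glycolytic ATP nets +1 H+ once consumed, while a respiratory ATP nets 0 —
#' the stoichiometric basis for reading continuous glycolysis as an
#' intracellular acidification program.
#'
#' @return Data frame of ledger entries: `reaction`, `protons_consumed`,
#'   `protons_released`, `lactate_per_atp`, `atp_per_glucose` (36 for
#'   respiration, 2 for glycolysis, NA for hydrolysis).
#' @export
proton_ledger <- function() {
  data.frame(
    reaction = c("respiration_synthesis", "glycolysis_synthesis", "atp_hydrolysis"),
    protons_consumed = c(1L, 0L, 0L),
    protons_released = c(0L, 0L, 1L),
    lactate_per_atp = c(0L, 1L, 0L),
    atp_per_glucose = c(36L, 2L, NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Net protons released by ATP synthesis (and optional hydrolysis)
#'
#' @param pathway `"respiration_synthesis"` or `"glycolysis_synthesis"`.
#' @param n_atp Number of ATPs (>= 0).
#' @param include_hydrolysis If `TRUE`, adds the +1 H+ per ATP released when
#'   each synthesized ATP is consumed.
#' @return Net protons released (integer-valued; negative = net consumption).
#'   Glycolysis with hydrolysis gives `+n_atp`; respiration with hydrolysis
#'   gives `0`; respiration synthesis alone gives `-n_atp`.
#' @export
net_protons <- function(pathway, n_atp, include_hydrolysis = TRUE) {
  if (n_atp < 0) stop_validation("n_atp must be non-negative")
  led <- proton_ledger()
  if (!pathway %in% c("respiration_synthesis", "glycolysis_synthesis"))
    stop_validation(sprintf("unknown pathway '%s'", pathway))
  row <- led[led$reaction == pathway, ]
  net_per_atp <- row$protons_released - row$protons_consumed
  if (include_hydrolysis) {
    hyd <- led[led$reaction == "atp_hydrolysis", ]
    net_per_atp <- net_per_atp + hyd$protons_released - hyd$protons_consumed
  }
  net_per_atp * n_atp
}

#' Specify an intracellular pH shift
#'
#' Fixes the constants of the closed-form proton budget. The buffering
#' coefficient is the dimensionless multiplier converting the change in free
#' proton concentration to the total protons that must move against the
#' cytosolic buffer in this pH range; the Avogadro constant is kept at the
#' conventional 6.02e23 so printed values reproduce exactly.
#'
#' @param pH_start,pH_end pH values in (0, 14); defaults 6.8 -> 7.4, the
#'   shift from a resting epithelial cytosol to the proliferation-permissive
#'   level.
#' @param volume Cell volume in cubic micrometres (default 100, a typical
#'   human cell).
#' @param buffer_coefficient Dimensionless buffering multiplier (default
#'   2e5).
#' @param avogadro Particles per mole (default 6.02e23).
#' @param atp_per_nucleotide ATPs to synthesize one nucleotide (default 5).
#' @param genome_nucleotides Nucleotides in the genome (default 6e9).
#' @return A `PhShiftSpec` list.
#' @export
ph_shift_spec <- function(pH_start = 6.8, pH_end = 7.4, volume = 100,
                          buffer_coefficient = 2e5, avogadro = 6.02e23,
                          atp_per_nucleotide = 5, genome_nucleotides = 6e9) {
  if (pH_start <= 0 || pH_start >= 14 || pH_end <= 0 || pH_end >= 14)
    stop_validation("pH values must lie in (0, 14)")
  if (volume <= 0) stop_validation("volume must be positive")
  if (buffer_coefficient <= 0) stop_validation("buffer_coefficient must be positive")
  structure(list(pH_start = pH_start, pH_end = pH_end, volume = volume,
                 buffer_coefficient = buffer_coefficient, avogadro = avogadro,
                 atp_per_nucleotide = atp_per_nucleotide,
                 genome_nucleotides = genome_nucleotides),
            class = "PhShiftSpec")
}

#' Protons required for an intracellular pH shift
#'
#' Closed form: `(10^-pH_start - 10^-pH_end) [mol/L] * volume [um^3] * 1e-15
#' [L/um^3] * buffer_coefficient * avogadro`. With the defaults (6.8 -> 7.4,
#' 100 um^3, buffer 2e5) this is about 1.43e9 protons. Since respiration
#' consumes one proton per ATP synthesized, the equivalent count of
#' respiratory ATPs that must accumulate equals the proton count.
#'
#' @param spec A `PhShiftSpec`.
#' @return List: `protons` (negative when `pH_end < pH_start`, i.e. an
#'   acidifying shift), `atp_equivalent`, `direction`
#'   (`"alkalinizing"`/`"acidifying"`/`"none"`).
#' @export
protons_for_ph_shift <- function(spec) {
  protons <- (10^(-spec$pH_start) - 10^(-spec$pH_end)) *
    spec$volume * 1e-15 * spec$buffer_coefficient * spec$avogadro
  list(protons = protons,
       atp_equivalent = protons,
       direction = if (protons > 0) "alkalinizing"
                   else if (protons < 0) "acidifying" else "none")
}

#' pH-shift cost as a fraction of the genome's synthesis budget
#'
#' Expresses a proton (= respiratory ATP) count as the fraction of the ATP
#' cost of synthesizing the full genome (`genome_nucleotides *
#' atp_per_nucleotide`, 3e10 ATPs with the defaults). The default pH shift
#' costs about 4.8% of a genome — i.e. the ATP needed to synthesize roughly
#' 143/3000 of the DNA.
#'
#' @param protons Non-negative proton/ATP count.
#' @param spec A `PhShiftSpec`.
#' @return The fraction (0.0477... for 1.43e9 protons under the defaults).
#' @export
genome_fraction_equivalent <- function(protons, spec = ph_shift_spec()) {
  if (protons < 0) stop_validation("protons must be non-negative")
  protons / (spec$genome_nucleotides * spec$atp_per_nucleotide)
}
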