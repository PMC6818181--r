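#' Specify a synthetic expression dataset
#'
#' Defines the statistical structure the downstream analysis assumes: a
#' two-component Gaussian mixture of log2 expression (non-expressed vs.
#' expressed genes), planted case-vs-control fold changes on named genes, and
#' latent-factor correlation links between gene groups. The generated data
#' carry full ground truth, so every stage of the pipeline can be validated
#' against planted structure.
#'
#' The defaults fix the study conditions used throughout the package's
#' validation suite: 2000 genes, 50 case and 50 control samples, a 30%
#' non-expressed fraction, mixture modes N(0, 1) and N(6, 1) on the log2
#' scale, and per-gene sample noise with standard deviation 1.
#'
#' @param n_genes Total number of genes.
#' @param n_case,n_control Group sizes.
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @param nonexpressed_fraction Proportion of genes drawn from the low mode.
#' @param mode_low,mode_high Numeric `c(mean, sd)` of the non-expressed and
#'   expressed log2 peaks. The low mean must be below the high mean.
#' @param noise_sd Per-sample within-gene standard deviation (log2 units).
#' @param planted_fc Named numeric vector of linear fold changes (case vs
#'   control, > 0) planted as additive log2 shifts on case samples. Named
#'   genes are forced into the expressed mode.
#' @param latent_links List of links, each `list(set_a =, set_b =, rho =)`
#'   with character member vectors and `rho` in \[-1, 1\]: genes in the two
#'   sets share a per-sample Gaussian factor so that the expected Pearson
#'   correlation between any gene of `set_a` and any gene of `set_b` is
#'   `rho`. A gene may belong to at most one link (contradictory overlapping
#'   links are rejected).
#' @param gene_ids Optional gene names; defaults to the genes named in
#'   `planted_fc`/`latent_links` padded with `gene_0001`, ... Named genes must
#'   be covered.
#' @param timecourse Optional list for [simulate_timecourse()]:
#'   `n_timepoints` (default 19), `interval_min` (default 20), `trends`
#'   (named character, values `rising`, `falling` or `peak_then_decline`),
#'   `amplitude` (log2 units, default 2), `noise_sd` (default 0.25).
#' @return A `SimulationSpec` list.
#' @export
simulation_spec <- function(n_genes = 2000, n_case = 50, n_control = 50,
                            seed = 1, nonexpressed_fraction = 0.3,
                            mode_low = c(mean = 0, sd = 1),
                            mode_high = c(mean = 6, sd = 1),
                            noise_sd = 1,
                            planted_fc = numeric(),
                            latent_links = list(),
                            gene_ids = NULL,
                            timecourse = NULL) {
  if (mode_low[[1]] >= mode_high[[1]])
    stop_validation("mode_low mean must be below mode_high mean (bimodality)")
  if (length(planted_fc) && (is.null(names(planted_fc)) || any(planted_fc <= 0)))
    stop_validation("planted_fc must be a named vector of positive linear fold changes")
  link_genes <- character()
  for (lk in latent_links) {
    if (!all(c("set_a", "set_b", "rho") %in% names(lk)))
      stop_validation("each latent link needs set_a, set_b and rho")
    if (abs(lk$rho) > 1) stop_validation("|rho| must be <= 1")
    g <- c(lk$set_a, lk$set_b)
    if (anyDuplicated(g))
      stop_validation("set_a and set_b of a latent link must be disjoint")
    if (any(g %in% link_genes))
      stop_validation("a gene may belong to at most one latent link")
    link_genes <- c(link_genes, g)
  }
  named <- unique(c(names(planted_fc), link_genes))
  if (is.null(gene_ids)) {
    n_fill <- n_genes - length(named)
    if (n_fill < 0) stop_validation("n_genes smaller than the number of named genes")
    gene_ids <- c(named, sprintf("gene_%04d", seq_len(n_fill)))
  } else {
    if (length(gene_ids) != n_genes || anyDuplicated(gene_ids))
      stop_validation("gene_ids must be n_genes unique names")
    if (!all(named %in% gene_ids))
      stop_validation("all genes named in planted_fc/latent_links must be in gene_ids")
  }
  if (!is.null(timecourse)) {
    tc <- utils::modifyList(list(n_timepoints = 19, interval_min = 20,
                                 trends = character(), amplitude = 2,
                                 noise_sd = 0.25), timecourse)
    if (tc$n_timepoints < 6)
      stop_validation("a time course needs at least 6 timepoints")
    if (length(tc$trends) &&
        !all(tc$trends %in% c("rising", "falling", "peak_then_decline")))
      stop_validation("trends must be rising, falling or peak_then_decline")
    timecourse <- tc
  }
  structure(list(
    n_genes = n_genes, n_case = n_case, n_control = n_control, seed = seed,
    nonexpressed_fraction = nonexpressed_fraction,
    mode_low = mode_low, mode_high = mode_high, noise_sd = noise_sd,
    planted_fc = planted_fc, latent_links = latent_links,
    gene_ids = gene_ids, timecourse = timecourse
  ), class = "SimulationSpec")
}

#' Generate a synthetic case/control expression dataset
#'
#' Draws per-gene baselines from the two-mode mixture, adds shared latent
#' factors for linked gene groups, independent Gaussian noise elsewhere, and
#' plants fold changes as additive log2 shifts on case samples. Genes named
#' in `planted_fc` or a latent link are always expressed so the planted
#' structure is observable.
#'
#' @param spec A `SimulationSpec` from [simulation_spec()].
#' @return List with `matrix` (an [expression_matrix()]) and `truth`, a record
#'   of the planted structure: per-gene baseline means, expressed flags,
#'   `planted_fc`, and `latent_links`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  ns <- spec$n_case + spec$n_control
  genes <- spec$gene_ids
  groups <- c(rep("case", spec$n_case), rep("control", spec$n_control))
  named <- unique(c(names(spec$planted_fc),
                    unlist(lapply(spec$latent_links, function(l) c(l$set_a, l$set_b)))))
  expressed <- stats::runif(ng) >= spec$nonexpressed_fraction
  names(expressed) <- genes
  expressed[named] <- TRUE
  mu <- ifelse(expressed,
               stats::rnorm(ng, spec$mode_high[[1]], spec$mode_high[[2]]),
               stats::rnorm(ng, spec$mode_low[[1]], spec$mode_low[[2]]))
  names(mu) <- genes

  vals <- matrix(stats::rnorm(ng * ns, sd = spec$noise_sd), ng, ns,
                 dimnames = list(genes, sprintf("s%03d", seq_len(ns))))
  # shared latent factor per link: x = mu + sd*(sqrt|rho| z +- sqrt(1-|rho|) eps)
  # gives cross-set correlation rho (sign carried by set_b's loading)
  for (lk in spec$latent_links) {
    if (lk$rho == 0) next
    z <- stats::rnorm(ns)
    a <- sqrt(abs(lk$rho))
    b <- sqrt(1 - abs(lk$rho))
    load <- c(rep(a, length(lk$set_a)), rep(sign(lk$rho) * a, length(lk$set_b)))
    g <- c(lk$set_a, lk$set_b)
    vals[g, ] <- spec$noise_sd *
      (outer(load, z) + b * matrix(stats::rnorm(length(g) * ns), length(g), ns))
  }
  vals <- vals + mu
  if (length(spec$planted_fc)) {
    shift <- log2(spec$planted_fc)
    vals[names(shift), groups == "case"] <-
      vals[names(shift), groups == "case", drop = FALSE] + shift
  }
  list(
    matrix = expression_matrix(vals, groups, platform = "rnaseq_fpkm_log2"),
    truth = list(mu = mu, expressed = expressed,
                 planted_fc = spec$planted_fc, latent_links = spec$latent_links)
  )
}

#' Generate a synthetic activation time course
#'
#' Emulates a dense activation time series (default 19 points at 20-minute
#' intervals, matching a T-cell activation design) with per-gene trend shapes:
#' `rising` and `falling` are linear in time; `peak_then_decline` is a smooth
#' interior-peaked bump (half-sine), so that in the noiseless limit segment
#' means are strictly monotone on each flank.
#'
#' @param spec A `SimulationSpec` with a non-`NULL` `timecourse` component.
#' @return Numeric matrix, genes in rows, timepoints in columns; column names
#'   are times in minutes from activation.
#' @export
simulate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  tc <- spec$timecourse
  if (is.null(tc)) stop_validation("spec has no timecourse component")
  set.seed(spec$seed)
  nt <- tc$n_timepoints
  tfrac <- seq(0, 1, length.out = nt)
  genes <- names(tc$trends)
  shape <- function(trend) switch(
    trend,
    rising            = tc$amplitude * tfrac,
    falling           = tc$amplitude * (1 - tfrac),
    peak_then_decline = tc$amplitude * sin(pi * tfrac)
  )
  vals <- t(vapply(tc$trends, function(tr)
    shape(tr) + stats::rnorm(nt, sd = tc$noise_sd), numeric(nt)))
  dimnames(vals) <- list(genes, as.character(tc$interval_min * (seq_len(nt) - 1)))
  vals
}

#' Preset simulation specs for the three study archetypes
#'
#' Convenience builders for end-to-end demonstrations and validation:
#' \describe{
#'   \item{cancer}{lactate dehydrogenase and exporter genes up > 2-fold,
#'     PDHB/PKM halved, acid loaders planted up (2.5x) and acid extruders
#'     down (0.4x), and a latent link (rho = 0.8) between the proteasome
#'     proxy and the H2O2/iron substrate proxies — a Fenton-driven,
#'     acidifying, Warburg-positive profile. ATP6V0B/ATP6V0C are planted
#'     identically, as one plasma-membrane V-ATPase signal.}
#'   \item{npc}{the same Warburg fold changes but acid loaders planted down
#'     (0.4x), extruders untouched, and no Fenton link — an alkalinizing
#'     Warburg-positive profile typical of activated normal proliferating
#'     cells.}
#'   \item{null}{all marker genes present, nothing planted.}
#' }
#'
#' @param type `"cancer"`, `"npc"` or `"null"`.
#' @param seed Integer seed.
#' @param n_case,n_control Group sizes (default 50/50).
#' @param n_genes Total genes (default 2000).
#' @return A `SimulationSpec`.
#' @export
warburg_demo_spec <- function(type = c("cancer", "npc", "null"), seed = 1,
                              n_case = 50, n_control = 50, n_genes = 2000) {
  type <- match.arg(type)
  loaders <- c("SLC4A1AP", "SLC4A2", "SLC4A3", "SLC26A6", "ATP6V0B", "ATP6V0C")
  extruders <- c("SLC4A4", "SLC4A9", "SLC9A2", "SLC9A3", "SLC9A4", "SLC9A9", "SLC26A9")
  markers <- c(LDHA = 1, LDHB = 1, SLC16A1 = 1, SLC16A3 = 1, PKM = 1, PDHB = 1)
  substrate <- c("TXN", "TXN2", "GCLC", "GCLM", "TFRC", "TFR2")
  # without a latent link the Fenton marker genes must still be present and
  # expressed, so plant them neutrally (FC = 1)
  neutral <- stats::setNames(rep(1, length(substrate) + length(psm_genes())),
                             c(substrate, psm_genes()))
  fc <- switch(type,
    cancer = c(markers[c("LDHB", "SLC16A3", "PKM")],
               c(LDHA = 4, SLC16A1 = 3, PDHB = 0.5),
               stats::setNames(rep(2.5, length(loaders)), loaders),
               stats::setNames(rep(0.4, length(extruders)), extruders)),
    npc = c(markers[c("LDHB", "SLC16A3", "PKM")],
            c(LDHA = 4, SLC16A1 = 3, PDHB = 0.5),
            stats::setNames(rep(0.4, length(loaders)), loaders),
            stats::setNames(rep(1, length(extruders)), extruders),
            neutral),
    null = c(markers,
             stats::setNames(rep(1, length(loaders)), loaders),
             stats::setNames(rep(1, length(extruders)), extruders),
             neutral))
  links <- if (type == "cancer")
    list(list(set_a = psm_genes(), set_b = substrate, rho = 0.8))
  else list()
  simulation_spec(n_genes = n_genes, n_case = n_case, n_control = n_control,
                  seed = seed, planted_fc = fc, latent_links = links)
}
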