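#' Simulation configuration
#'
#' Collects every tunable constant of the model with its standard default:
#' edge survival probability `p_thresh = 0.95`, functional compatibility
#' threshold `c_thresh = 0.55`, seeding multiplier 4500 (each locality is
#' seeded with `4500 * u` random species, `u` its natural-land fraction),
#' adaptation lottery `p_adp = 0.001` and factor `C_adp = 0.01`, linear
#' land-use response (`S_LUC = 0`) with full body-size bias (`V_LUC = 0`),
#' a 100-step burn-in with webs rebuilt every 10 steps, and yearly
#' dispersal. The taxon counts default to the relative vertebrate diversity
#' the species factory emulates.
#'
#' @param p_thresh survival probability at niche tolerance edges, (0.5, 1).
#' @param c_thresh functional compatibility threshold for links.
#' @param seed_multiplier species seeded per locality per unit land fraction.
#' @param counts_per_taxon named counts for the species pool.
#' @param trait_pairs Monte-Carlo pairs for trait-matrix normalization.
#' @param burn_in_steps dispersal-only steps before forcing starts.
#' @param rebuild_every web rebuild period (in burn-in steps).
#' @param p_adp yearly per-species probability of a niche shift.
#' @param C_adp adaptation factor scaling the shift length.
#' @param S_LUC land-use response shape in `[-1, 1]`.
#' @param V_LUC land-use body-size-bias relaxation in `[0, 1]`.
#' @param years simulated years after burn-in.
#' @param replicates number of replicate simulations.
#' @param dispersal,adaptation master switches for the two processes.
#' @param min_ratio_records minimum interaction records per taxon pair
#'   before the pooled ratio distribution is used.
#' @param p_immune extinction probabilities at or below this value never
#'   trigger climate mortality (also the persistence filter at seeding).
#' @return a validated `coexsim_config` list.
#' @export
sim_config <- function(p_thresh = 0.95, c_thresh = 0.55,
                       seed_multiplier = 4500,
                       counts_per_taxon = c(mammal = 5513, bird = 10425,
                                            reptile = 10038, amphibian = 7302),
                       trait_pairs = 1e6,
                       burn_in_steps = 100, rebuild_every = 10,
                       p_adp = 0.001, C_adp = 0.01,
                       S_LUC = 0, V_LUC = 0,
                       years = 80, replicates = 100,
                       dispersal = TRUE, adaptation = TRUE,
                       min_ratio_records = 20, p_immune = 0.05) {
  cfg <- list(p_thresh = p_thresh, c_thresh = c_thresh,
              seed_multiplier = seed_multiplier,
              counts_per_taxon = counts_per_taxon,
              trait_pairs = trait_pairs,
              burn_in_steps = burn_in_steps, rebuild_every = rebuild_every,
              p_adp = p_adp, C_adp = C_adp, S_LUC = S_LUC, V_LUC = V_LUC,
              years = years, replicates = replicates,
              dispersal = dispersal, adaptation = adaptation,
              min_ratio_records = min_ratio_records, p_immune = p_immune)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(p_thresh > 0.5 && p_thresh < 1))
      stop("p_thresh must be in (0.5, 1)")
    if (!(c_thresh > 0 && c_thresh < 1))
      stop("c_thresh must be in (0, 1)")
    if (S_LUC < -1 || S_LUC > 1) stop("S_LUC must be in [-1, 1]")
    if (V_LUC < 0 || V_LUC > 1) stop("V_LUC must be in [0, 1]")
    if (p_adp < 0 || p_adp > 1) stop("p_adp must be in [0, 1]")
    if (C_adp < 0) stop("C_adp must be >= 0")
    if (seed_multiplier < 0) stop("seed_multiplier must be >= 0")
    if (burn_in_steps < 0 || rebuild_every < 1)
      stop("invalid burn-in settings")
    if (years < 0 || replicates < 1) stop("invalid horizon settings")
    if (is.null(names(counts_per_taxon)) ||
        !all(names(counts_per_taxon) %in% TAXA))
      stop("counts_per_taxon must be named over the four taxa")
  })
  structure(cfg, class = "coexsim_config")
}

#' Read a configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are an error.
#' `counts_per_taxon` may be given as a mapping from taxon to count.
#'
#' @param path YAML file.
#' @return a `coexsim_config`.
#' @export
sim_config_from_file <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$counts_per_taxon))
    vals$counts_per_taxon <- unlist(vals$counts_per_taxon)
  do.call(sim_config, vals)
}

#' Desk-scale configuration profile
#'
#' The defaults of [sim_config()] describe a planetary-scale experiment.
#' This profile keeps every model constant at its standard value but scales
#' the problem down to sizes a single CPU handles in minutes: a small pool
#' (150 species per taxon), 60 seeded species per fully natural cell, a
#' reduced trait-normalization sample, and a multi-decade horizon on a small
#' lattice. Used throughout the package's tests and worked examples.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return a `coexsim_config`.
#' @export
desk_config <- function(...) {
  defaults <- list(seed_multiplier = 60,
                   counts_per_taxon = c(mammal = 150, bird = 150,
                                        reptile = 150, amphibian = 150),
                   trait_pairs = 1e5, years = 40, replicates = 20)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
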