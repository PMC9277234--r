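#' Simulation configuration for a synthetic symbiosis study
#'
#' Bundles every knob of the synthetic-data generator: panel size and
#' population structure, planted pleiotropic architecture, replicate design
#' of the single-strain experiments, and the pooled multi-strain experiment.
#' Defaults give a structured 100-strain, 5000-site panel that runs through
#' the whole pipeline in well under a minute.
#'
#' @param n_strains Number of strains in the panel.
#' @param n_sites Number of biallelic sites.
#' @param n_subpops Number of subpopulations (population structure).
#' @param fst Differentiation between subpopulations, strictly in (0, 1).
#' @param gene_size_mean Mean gene length in sites (geometric tiling).
#' @param n_concordant_pairs,n_discordant_pairs Number of planted pleiotropic
#'   variants whose two trait effects share sign (concordant) or differ in
#'   sign (discordant).
#' @param pair_category Category of planted pairs: `"symbiotic"` pairs one
#'   rhizobium with one plant fitness proxy, `"rhizobium"` pairs two rhizobium
#'   proxies, `"both"` alternates.
#' @param effect_size Magnitude of each planted allelic effect, in trait
#'   standard-deviation units.
#' @param h2_polygenic Strain-level polygenic fraction of (polygenic +
#'   single-replicate residual) variance, in [0, 1).
#' @param noise_sd Residual standard deviation per replicate, trait units.
#' @param n_racks Number of greenhouse racks (nuisance factor).
#' @param rack_sd Standard deviation of the rack effects (drawn once).
#' @param reps_per_strain Replicate plants per strain per host line.
#' @param n_pools Pooled nodule samples per host line in the multi-strain
#'   experiment.
#' @param mean_depth Mean sequencing depth per site per pool (Poisson).
#' @param selection_gradient Strength of selection on the relative-fitness
#'   breeding value; strain fitness is `w = exp(gradient * standardized bv)`.
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param host_specific Fraction of planted pairs private to a single host
#'   line (alternating hosts); 0 means both hosts share the architecture.
#' @param init_frequencies Initial pool composition: `"equal"` or
#'   `"dirichlet"` (mildly perturbed around equal).
#' @param seed Integer seed; identical configs (including seed) reproduce
#'   byte-identical outputs.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_strains = 40, n_sites = 500, seed = 1)
#' cfg$fst
#' @export
sim_config <- function(n_strains = 100,
                       n_sites = 5000,
                       n_subpops = 3,
                       fst = 0.3,
                       gene_size_mean = 10,
                       n_concordant_pairs = 10,
                       n_discordant_pairs = 10,
                       pair_category = c("symbiotic", "rhizobium", "both"),
                       effect_size = 0.8,
                       h2_polygenic = 0.3,
                       noise_sd = 1,
                       n_racks = 4,
                       rack_sd = 1,
                       reps_per_strain = 4,
                       n_pools = 6,
                       mean_depth = 100,
                       selection_gradient = 0.5,
                       missing_rate = 0.02,
                       host_specific = 0,
                       init_frequencies = c("equal", "dirichlet"),
                       seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains), n_sites = as.integer(n_sites),
    n_subpops = as.integer(n_subpops), fst = fst,
    gene_size_mean = gene_size_mean,
    n_concordant_pairs = as.integer(n_concordant_pairs),
    n_discordant_pairs = as.integer(n_discordant_pairs),
    pair_category = match.arg(pair_category),
    effect_size = effect_size, h2_polygenic = h2_polygenic,
    noise_sd = noise_sd, n_racks = as.integer(n_racks), rack_sd = rack_sd,
    reps_per_strain = as.integer(reps_per_strain),
    n_pools = as.integer(n_pools), mean_depth = mean_depth,
    selection_gradient = selection_gradient, missing_rate = missing_rate,
    host_specific = host_specific,
    init_frequencies = match.arg(init_frequencies),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_strains < 2L) abort("need at least 2 strains", class = "symbio_config_error")
  if (cfg$n_subpops > cfg$n_strains)
    abort("n_subpops cannot exceed n_strains", class = "symbio_config_error")
  if (!(cfg$fst > 0 && cfg$fst < 1))
    abort("fst must be strictly inside (0, 1)", class = "symbio_config_error")
  if (!(cfg$h2_polygenic >= 0 && cfg$h2_polygenic < 1))
    abort("h2_polygenic must be in [0, 1)", class = "symbio_config_error")
  n_causal <- cfg$n_concordant_pairs + cfg$n_discordant_pairs
  if (n_causal > cfg$n_sites)
    abort("more causal pairs than sites", class = "symbio_config_error")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    abort("missing_rate must be in [0, 1)", class = "symbio_config_error")
  if (cfg$n_racks < 1L || cfg$reps_per_strain < 1L || cfg$n_pools < 1L)
    abort("n_racks, reps_per_strain and n_pools must be positive",
          class = "symbio_config_error")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_strains, " strains x ", x$n_sites, " sites, ",
      x$n_subpops, " subpops (Fst ", x$fst, ")\n",
      "  planted pairs: ", x$n_concordant_pairs, " concordant + ",
      x$n_discordant_pairs, " discordant (", x$pair_category, ")\n",
      "  seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Derive a stage-specific RNG seed from the master seed, staying < 2^31.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}
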