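#' Simulate single-strain replicate phenotypes with planted pleiotropy
#'
#' Builds, for each host line, strain-level genetic values for the five
#' fitness proxies (shoot biomass, leaf chlorophyll A, nodule number, nodule
#' weight, and the latent relative-fitness breeding value used by the
#' multi-strain simulator), then emits replicate-level measurements for the
#' four single-strain proxies. Each planted "pair" is a single pleiotropic
#' variant with effects on two proxies: same-sign for concordant pairs
#' (fitness alignment), opposite-sign for discordant pairs (conflict).
#' Symbiotic pairs couple a rhizobium proxy with a plant proxy; rhizobium
#' pairs couple two rhizobium proxies. On top of the planted effects each
#' trait receives a polygenic term with covariance proportional to the
#' kinship matrix (scaled by `h2_polygenic`), a rack effect, and i.i.d.
#' residual noise.
#'
#' @param panel A [genotype_panel()] from [simulate_genotypes()].
#' @param cfg The same [sim_config()] used to build the panel.
#' @return A list with `phenotypes` (long tibble: `strain_id`, `host`,
#'   `rack`, `trait`, `value`) and `truth` (a `truth_ledger`: planted effects,
#'   rack effects, per-host strain genetic values and fitness multipliers).
#' @examples
#' cfg <- sim_config(n_strains = 30, n_sites = 300, seed = 2)
#' sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
#' dplyr::count(sim$phenotypes, host, trait)
#' @export
simulate_phenotypes <- function(panel, cfg) {
  validate_sim_config(cfg)
  stopifnot(inherits(panel, "genotype_panel"))
  set.seed(stage_seed(cfg$seed, 23L))
  S <- nrow(panel$geno)
  G <- if (!is.null(panel$geno_complete)) panel$geno_complete else
    impute_genotypes(panel$geno)

  causal <- draw_causal_architecture(panel, cfg)

  # polygenic draws share the kinship of the panel (same matrix the LMM uses)
  K <- compute_kinship(panel)
  ev <- attr(K, "eigen")
  Lh <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), S)
  sigma_g <- cfg$noise_sd * sqrt(cfg$h2_polygenic / (1 - cfg$h2_polygenic))

  rack_levels <- paste0("rack", LETTERS[seq_len(cfg$n_racks)])
  rack_effects <- setNames(rnorm(cfg$n_racks, 0, cfg$rack_sd), rack_levels)

  gvals <- list(); fitness <- list(); reps <- list()
  for (h in HOST_LINES) {
    gv <- matrix(0, S, length(ALL_TRAITS),
                 dimnames = list(panel$strains$strain_id, ALL_TRAITS))
    ch <- causal[causal$host %in% c(h, "both"), ]
    for (i in seq_len(nrow(ch))) {
      j <- match(ch$site_id[i], panel$sites$site_id)
      x <- G[, j]
      gv[, ch$trait1[i]] <- gv[, ch$trait1[i]] + ch$beta1[i] * x
      gv[, ch$trait2[i]] <- gv[, ch$trait2[i]] + ch$beta2[i] * x
    }
    poly <- Lh %*% matrix(rnorm(S * length(ALL_TRAITS)), S) * sigma_g
    gv <- gv + poly
    gvals[[h]] <- as_tibble(gv) %>%
      mutate(strain_id = panel$strains$strain_id, host = h, .before = 1)

    # multi-strain fitness: exponential of the standardized relative-fitness
    # breeding value, scaled by the selection gradient
    bv <- gv[, "relative_fitness"]
    bv_std <- if (sd(bv) > 0) (bv - mean(bv)) / sd(bv) else bv * 0
    fitness[[h]] <- tibble(strain_id = panel$strains$strain_id, host = h,
                           breeding_value = unname(bv_std),
                           w = exp(cfg$selection_gradient * unname(bv_std)))

    n_rep <- cfg$reps_per_strain
    rack <- sample(rack_levels, S * n_rep, replace = TRUE)
    base <- tibble(
      strain_id = rep(panel$strains$strain_id, each = n_rep),
      host = h, rack = rack
    )
    for (tr in SINGLE_STRAIN_TRAITS) {
      base[[tr]] <- gv[rep(seq_len(S), each = n_rep), tr] +
        rack_effects[rack] + rnorm(S * n_rep, 0, cfg$noise_sd)
    }
    reps[[h]] <- tidyr::pivot_longer(base, dplyr::all_of(SINGLE_STRAIN_TRAITS),
                                     names_to = "trait", values_to = "value")
  }

  truth <- structure(list(
    causal = causal,
    rack_effects = rack_effects,
    genetic_values = bind_rows(gvals),
    fitness = bind_rows(fitness),
    pools = NULL
  ), class = "truth_ledger")
  list(phenotypes = bind_rows(reps), truth = truth)
}

# Sample the planted pleiotropic architecture: one variant per pair, two
# signed effects whose sign relation encodes the concordant/discordant label.
draw_causal_architecture <- function(panel, cfg) {
  n_pairs <- cfg$n_concordant_pairs + cfg$n_discordant_pairs
  if (n_pairs == 0L) {
    return(tibble(pair_id = integer(), site_id = character(),
                  label = character(), category = character(),
                  host = character(), trait1 = character(),
                  trait2 = character(), beta1 = double(), beta2 = double()))
  }
  ss <- site_summary(panel)
  eligible <- which(!is.na(ss$maf) & ss$maf >= 0.1)
  if (length(eligible) < n_pairs)
    eligible <- order(-ss$maf)[seq_len(min(nrow(ss), n_pairs * 2L))]
  sites <- sample(eligible, n_pairs)
  label <- c(rep("concordant", cfg$n_concordant_pairs),
             rep("discordant", cfg$n_discordant_pairs))
  category <- switch(cfg$pair_category,
    symbiotic = rep("symbiotic", n_pairs),
    rhizobium = rep("rhizobium", n_pairs),
    both = rep_len(c("symbiotic", "rhizobium"), n_pairs))
  host <- rep("both", n_pairs)
  if (cfg$host_specific > 0) {
    n_priv <- round(cfg$host_specific * n_pairs)
    if (n_priv > 0)
      host[seq_len(n_priv)] <- rep_len(HOST_LINES, n_priv)
  }
  t1 <- t2 <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    if (category[i] == "symbiotic") {
      t1[i] <- sample(RHIZOBIUM_TRAITS, 1L)
      t2[i] <- sample(PLANT_TRAITS, 1L)
    } else {
      tt <- sample(RHIZOBIUM_TRAITS, 2L)
      t1[i] <- tt[1L]; t2[i] <- tt[2L]
    }
  }
  s1 <- sample(c(-1, 1), n_pairs, replace = TRUE)
  s2 <- ifelse(label == "concordant", s1, -s1)
  tibble(pair_id = seq_len(n_pairs), site_id = ss$site_id[sites],
         label = label, category = category, host = host,
         trait1 = t1, trait2 = t2,
         beta1 = s1 * cfg$effect_size, beta2 = s2 * cfg$effect_size)
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat("<truth_ledger> ", nrow(x$causal), " planted pleiotropic variants (",
      sum(x$causal$label == "concordant"), " concordant, ",
      sum(x$causal$label == "discordant"), " discordant)\n", sep = "")
  if (!is.null(x$pools))
    cat("  pool frequencies recorded for ",
        length(unique(x$pools$pool_id)), " pools\n", sep = "")
  invisible(x)
}
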