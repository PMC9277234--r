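#' Simulate the multi-strain pooled sequencing experiment
#'
#' Implements the select-and-resequence design: all strains are inoculated
#' together, selection acts multiplicatively on initial frequencies
#' (`f_end proportional to f_init * w`, renormalized, with
#' `w = exp(selection_gradient * standardized breeding value)` from the truth
#' ledger), and each pooled nodule sample is sequenced with per-site depth
#' `Poisson(mean_depth)` and alternate-read count
#' `Binomial(depth, (G' f)_site)` where `G` is the complete genotype matrix.
#'
#' @param panel A [genotype_panel()] from [simulate_genotypes()].
#' @param truth The `truth_ledger` from [simulate_phenotypes()].
#' @param cfg The shared [sim_config()]; `n_pools` pools are generated per
#'   host line.
#' @param f_init Optional initial frequency vector over strains (defaults to
#'   the config's `init_frequencies` policy). Must be non-negative and sum
#'   to 1.
#' @return A list: `pools` (long tibble of per-site [PoolObservation] rows:
#'   `pool_id`, `host`, `timepoint`, `site_id`, `replicon`, `pos`, `depth`,
#'   `alt_count`), `initial` (tibble `strain_id`, `f_init`), and `truth`
#'   updated with the realized end frequencies per pool.
#' @examples
#' cfg <- sim_config(n_strains = 20, n_sites = 200, seed = 3)
#' panel <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(panel, cfg)
#' pools <- simulate_pools(panel, sim$truth, cfg)
#' head(pools$pools)
#' @export
simulate_pools <- function(panel, truth, cfg, f_init = NULL) {
  validate_sim_config(cfg)
  stopifnot(inherits(panel, "genotype_panel"), inherits(truth, "truth_ledger"))
  set.seed(stage_seed(cfg$seed, 37L))
  S <- nrow(panel$geno); L <- ncol(panel$geno)
  G <- if (!is.null(panel$geno_complete)) panel$geno_complete else
    impute_genotypes(panel$geno)

  if (is.null(f_init)) {
    f_init <- if (cfg$init_frequencies == "equal") rep(1 / S, S) else {
      d <- rgamma(S, shape = 50, rate = 1)  # mild Dirichlet(50) perturbation
      d / sum(d)
    }
  }
  check_simplex(f_init, what = "f_init")

  obs <- list(); pool_truth <- list()
  for (h in HOST_LINES) {
    w <- truth$fitness$w[truth$fitness$host == h]
    f_end <- f_init * w
    f_end <- f_end / sum(f_end)
    p_site <- as.numeric(crossprod(G, f_end))   # expected alt fraction per site
    p_site <- pmin(pmax(p_site, 0), 1)
    for (k in seq_len(cfg$n_pools)) {
      pid <- sprintf("%s_pool%02d", h, k)
      depth <- rpois(L, cfg$mean_depth)
      alt <- rbinom(L, depth, p_site)
      obs[[pid]] <- tibble(
        pool_id = pid, host = h, timepoint = "final",
        site_id = panel$sites$site_id, replicon = panel$sites$replicon,
        pos = panel$sites$pos, depth = depth, alt_count = alt
      )
      pool_truth[[pid]] <- tibble(pool_id = pid, host = h,
                                  strain_id = panel$strains$strain_id,
                                  f_init = f_init, f_end = f_end)
    }
  }
  truth$pools <- bind_rows(pool_truth)
  list(pools = bind_rows(obs),
       initial = tibble(strain_id = panel$strains$strain_id, f_init = f_init),
       truth = truth)
}

check_simplex <- function(f, tol = 1e-9, what = "frequency vector") {
  if (any(!is.finite(f)) || any(f < 0) || abs(sum(f) - 1) > tol)
    abort(paste0(what, " must be non-negative and sum to 1"),
          class = "symbio_data_error")
  invisible(f)
}
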