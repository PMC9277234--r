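#' Simulate a structured haploid strain panel
#'
#' Draws a strains-by-sites haploid genotype matrix under the
#' Balding-Nichols model of population structure: each site has an ancestral
#' allele frequency `p ~ Uniform(0.05, 0.95)` and each subpopulation draws
#' its own frequency from `Beta(p (1 - Fst) / Fst, (1 - p)(1 - Fst) / Fst)`,
#' so `fst` controls differentiation. Sites are assigned to the three
#' replicons of the rhizobium genome (chromosome, pSymA, pSymB,
#' proportionally to their physical sizes) and tiled into contiguous,
#' non-overlapping genes with geometric lengths. A configurable fraction of
#' calls is masked as missing; the complete matrix is kept internally so the
#' pooled-sequencing simulator can draw reads from true genotypes.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_panel()] whose `strains` tibble carries `subpop` and
#'   whose `sites` tibble carries `gene_id`; the unmasked matrix is stored as
#'   the `geno_complete` element.
#' @examples
#' panel <- simulate_genotypes(sim_config(n_strains = 30, n_sites = 200, seed = 7))
#' panel
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, 11L))
  S <- cfg$n_strains; L <- cfg$n_sites; P <- cfg$n_subpops

  subpop <- rep_len(paste0("pop", seq_len(P)), S)
  p_anc <- runif(L, 0.05, 0.95)
  # Balding-Nichols: Beta with mean p_anc and variance fst * p(1-p)
  shape_scale <- (1 - cfg$fst) / cfg$fst
  p_sub <- matrix(rbeta(P * L, rep(p_anc, each = P) * shape_scale,
                        rep(1 - p_anc, each = P) * shape_scale),
                  nrow = P)
  pop_idx <- match(subpop, paste0("pop", seq_len(P)))
  geno <- matrix(rbinom(S * L, 1L, p_sub[pop_idx, ]), nrow = S)

  # replicon assignment proportional to physical size, contiguous blocks
  n_per <- diff(round(c(0, cumsum(REPLICON_WEIGHTS) / sum(REPLICON_WEIGHTS)) * L))
  replicon <- rep(REPLICONS, times = n_per)
  pos <- unlist(lapply(n_per, function(k) seq_len(k) * 10L), use.names = FALSE)

  # tile sites into contiguous genes with geometric lengths (mean gene_size_mean)
  gene_id <- character(L)
  for (r in REPLICONS) {
    idx <- which(replicon == r)
    lens <- integer(0)
    while (sum(lens) < length(idx))
      lens <- c(lens, rgeom(32L, 1 / cfg$gene_size_mean) + 1L)
    gene <- rep(seq_along(lens), times = lens)[seq_along(idx)]
    gene_id[idx] <- sprintf("%s_g%04d", r, gene)
  }

  sites <- tibble(
    site_id = sprintf("%s:%d", replicon, pos),
    replicon = replicon, pos = pos, gene_id = gene_id
  )
  strains <- tibble(strain_id = sprintf("strain%03d", seq_len(S)),
                    subpop = subpop)

  masked <- geno
  if (cfg$missing_rate > 0) {
    miss <- which(runif(S * L) < cfg$missing_rate)
    masked[miss] <- NA_integer_
  }
  panel <- genotype_panel(masked, strains, sites)
  complete <- geno
  dimnames(complete) <- dimnames(panel$geno)
  panel$geno_complete <- complete
  panel
}
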