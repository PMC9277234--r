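# Harmonic-number constants shared by the neutrality statistics.
harmonic <- function(n, power = 1) sum(1 / seq_len(n - 1)^power)

# Tajima (1989) variance constants for D.
tajima_constants <- function(n) {
  a1 <- harmonic(n); a2 <- harmonic(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Fu & Li (1993) constants for the outgroup-free (starred) statistics,
# with the corrected variance terms.
fu_li_constants <- function(n) {
  an <- harmonic(n); bn <- harmonic(n, 2)
  an1 <- an + 1 / n
  cn <- if (n > 2) 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2)) else 1
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  v_dstar <- ((n / (n - 1))^2 * bn + an^2 * dn -
                2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  u_dstar <- (n / (n - 1)) * (an - n / (n - 1)) - v_dstar
  v_fstar <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
                (2 * (n - 1) * an) / n^2 - 8 * bn / n) / (an^2 + bn)
  u_fstar <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
                (3 * n * (n - 1))) / an - v_fstar
  list(an = an, u_dstar = u_dstar, v_dstar = v_dstar,
       u_fstar = u_fstar, v_fstar = v_fstar)
}

#' Per-gene diversity and neutrality statistics
#'
#' For one gene interval of the panel, computes segregating sites `S`,
#' nucleotide diversity `pi` (mean pairwise differences, reported both in
#' total and per site), Watterson's `theta_W = S / a_n`, Tajima's `D`
#' (scaled `pi - theta_W`, Tajima 1989 constants), and the outgroup-free
#' Fu & Li `D*` and `F*` (singleton-based, Fu & Li 1993). Missing data are
#' handled by restricting the gene to strains with complete genotypes over
#' its sites (complete-case rule); genes with fewer than `min_n` complete
#' strains are skipped. A monomorphic gene has `pi = theta_W = 0` and its
#' `D`-type statistics are recorded as missing, never zero; when `S > 0` but
#' the numerator is exactly zero (e.g. two sequences, where `pi` and
#' `theta_W` coincide algebraically), Tajima's `D` is 0.
#'
#' @param panel A [genotype_panel()].
#' @param gene_id Gene to analyse (must appear in `panel$sites$gene_id`),
#'   or use `site_idx` to pass explicit column indices.
#' @param site_idx Optional integer site indices overriding `gene_id`.
#' @param min_n Minimum number of complete-case strains (default 4, the
#'   smallest sample for stable `D`).
#' @return One-row tibble: `gene_id`, `replicon`, `n_seq`, `n_sites`, `S`,
#'   `singletons`, `pi_total`, `pi_per_site`, `theta_w_total`,
#'   `theta_w_per_site`, `tajima_d`, `fu_li_dstar`, `fu_li_fstar`; or `NULL`
#'   (with a message attribute) if the gene was skipped.
#' @examples
#' panel <- simulate_genotypes(sim_config(n_strains = 12, n_sites = 100, seed = 9))
#' gene_neutrality_stats(panel, panel$sites$gene_id[[1]])
#' @export
gene_neutrality_stats <- function(panel, gene_id = NULL, site_idx = NULL,
                                  min_n = 4L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(site_idx)) {
    site_idx <- which(panel$sites$gene_id == gene_id)
    if (!length(site_idx))
      abort("gene not found in panel annotation", class = "symbio_data_error")
  }
  g <- panel$geno[, site_idx, drop = FALSE]
  keep <- complete.cases(g)
  n <- sum(keep)
  if (n < min_n) return(NULL)
  g <- g[keep, , drop = FALSE]
  replicon <- panel$sites$replicon[site_idx[1]]
  gid <- gene_id %||% paste0("sites:", site_idx[1], "-", site_idx[length(site_idx)])

  ca <- colSums(g)                      # alternate-allele counts
  seg <- ca > 0L & ca < n
  S <- sum(seg)
  L <- length(site_idx)
  if (S == 0L) {
    return(tibble(gene_id = gid, replicon = replicon, n_seq = n, n_sites = L,
                  S = 0L, singletons = 0L, pi_total = 0, pi_per_site = 0,
                  theta_w_total = 0, theta_w_per_site = 0,
                  tajima_d = NA_real_, fu_li_dstar = NA_real_,
                  fu_li_fstar = NA_real_))
  }
  cs <- ca[seg]
  pi_total <- sum(2 * cs * (n - cs)) / (n * (n - 1))
  singles <- sum(cs == 1L | cs == (n - 1L))

  tc <- tajima_constants(n)
  theta_w <- S / tc$a1
  var_d <- tc$e1 * S + tc$e2 * S * (S - 1)
  num_d <- pi_total - theta_w
  tajima_d <- if (abs(num_d) < 1e-14) 0 else if (var_d > 0)
    num_d / sqrt(var_d) else NA_real_

  fl <- fu_li_constants(n)
  eta <- S   # biallelic sites: one mutation each
  vd <- fl$u_dstar * eta + fl$v_dstar * eta^2
  dstar <- if (isTRUE(is.finite(vd) && vd > 0))
    ((n / (n - 1)) * eta - fl$an * singles) / sqrt(vd) else NA_real_
  vf <- fl$u_fstar * eta + fl$v_fstar * eta^2
  fstar <- if (isTRUE(is.finite(vf) && vf > 0))
    (pi_total - ((n - 1) / n) * singles) / sqrt(vf) else NA_real_
  if (n == 2L) tajima_d <- 0   # pi and theta_W coincide identically at n = 2

  tibble(gene_id = gid, replicon = replicon, n_seq = n, n_sites = L,
         S = S, singletons = singles, pi_total = pi_total,
         pi_per_site = pi_total / L, theta_w_total = theta_w,
         theta_w_per_site = theta_w / L, tajima_d = tajima_d,
         fu_li_dstar = dstar, fu_li_fstar = fstar)
}

#' Neutrality statistics for every gene in a panel
#'
#' @param panel A [genotype_panel()] whose sites carry `gene_id`.
#' @param gene_ids Genes to analyse (default: all annotated genes).
#' @param min_n Complete-case minimum passed to [gene_neutrality_stats()].
#' @return Row-bound tibble of per-gene statistics; skipped genes (too few
#'   complete strains) are absent and counted in attribute `n_skipped`.
#' @export
gene_stats_table <- function(panel, gene_ids = NULL, min_n = 4L) {
  if (is.null(gene_ids)) gene_ids <- unique(panel$sites$gene_id)
  gene_ids <- gene_ids[!is.na(gene_ids)]
  res <- purrr::map(gene_ids, function(g)
    gene_neutrality_stats(panel, g, min_n = min_n))
  skipped <- sum(vapply(res, is.null, logical(1)))
  out <- bind_rows(res)
  attr(out, "n_skipped") <- skipped
  out
}

#' Compare a focal gene category against the null pool of significant genes
#'
#' Formalizes the focal-category-versus-distribution comparison: the null
#' pool is all genes containing GWAS-significant variants; the focal mean of
#' a statistic is compared with means of `reps` random subsets of the same
#' size drawn without replacement from the null pool. The empirical
#' two-tailed p-value is
#' `(1 + #\{|null mean - grand mean| >= |focal mean - grand mean|\}) / (reps + 1)`,
#' flagged significant at `p < 0.1`.
#'
#' @param stats Per-gene statistics tibble from [gene_stats_table()].
#' @param focal_ids Gene ids of the focal category (subset of `null_ids`).
#' @param null_ids Gene ids of the null pool.
#' @param statistic Column of `stats` to compare (e.g. `"tajima_d"`).
#' @param reps Number of resampled subsets (default 1000).
#' @param seed Integer seed.
#' @return One-row tibble of class `category_comparison`: `statistic`,
#'   `n_focal`, `n_null`, `focal_mean`, `null_mean`, `p_value`,
#'   `significant`, plus a list-column `null_distribution`.
#' @export
category_comparison <- function(stats, focal_ids, null_ids, statistic,
                                reps = 1000L, seed = 1L) {
  focal_ids <- unique(focal_ids); null_ids <- unique(null_ids)
  if (!length(focal_ids))
    abort("empty focal category", class = "symbio_data_error")
  if (!all(focal_ids %in% null_ids))
    abort("focal gene ids must be a subset of the null pool",
          class = "symbio_data_error")
  vals <- stats[[statistic]][match(null_ids, stats$gene_id)]
  names(vals) <- null_ids
  focal_vals <- vals[focal_ids]
  if (all(is.na(focal_vals)))
    abort("statistic is missing for every focal gene",
          class = "symbio_data_error")
  focal_mean <- mean(focal_vals, na.rm = TRUE)
  grand_mean <- mean(vals, na.rm = TRUE)
  k <- length(focal_ids)
  set.seed(seed)
  null_means <- vapply(seq_len(reps), function(i)
    mean(vals[sample.int(length(vals), k)], na.rm = TRUE), numeric(1))
  p <- (1 + sum(abs(null_means - grand_mean) >=
                  abs(focal_mean - grand_mean), na.rm = TRUE)) / (reps + 1)
  out <- tibble(statistic = statistic, n_focal = k, n_null = length(null_ids),
                focal_mean = focal_mean, null_mean = grand_mean,
                p_value = p, significant = p < 0.1,
                null_distribution = list(null_means))
  class(out) <- c("category_comparison", class(out))
  out
}

#' Run the full category-versus-null comparison grid
#'
#' One comparison per statistic per pleiotropy category (concordant /
#' discordant crossed with symbiotic / rhizobium), mirroring the
#' selection-signature panel of the analysis.
#'
#' @param stats Per-gene statistics tibble.
#' @param gene_categories Tibble with `gene_id`, `label`
#'   (concordant/discordant), `pair_category` (symbiotic/rhizobium); e.g.
#'   built from [classify_pleiotropy()] pair labels via [assign_genes()].
#' @param null_ids Null pool: all genes containing significant variants.
#' @param statistics Statistic columns to test.
#' @param reps,seed Passed to [category_comparison()].
#' @return Row-bound comparison tibble with `label` and `pair_category`
#'   columns.
#' @export
category_comparison_grid <- function(stats, gene_categories, null_ids,
                                     statistics = c("pi_per_site", "tajima_d",
                                                    "fu_li_dstar", "fu_li_fstar"),
                                     reps = 1000L, seed = 1L) {
  combos <- gene_categories %>%
    distinct(.data$label, .data$pair_category)
  out <- list()
  for (i in seq_len(nrow(combos))) {
    lab <- combos$label[i]; pc <- combos$pair_category[i]
    ids <- gene_categories %>%
      filter(.data$label == lab, .data$pair_category == pc) %>%
      pull(.data$gene_id)
    ids <- intersect(unique(ids), null_ids)
    if (!length(ids)) next
    for (stt in statistics) {
      cc <- category_comparison(stats, ids, null_ids, stt,
                                reps = reps, seed = seed)
      cc$label <- lab; cc$pair_category <- pc
      out[[paste(lab, pc, stt)]] <- cc
    }
  }
  bind_rows(out) %>% select(-"null_distribution")
}
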