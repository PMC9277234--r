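#' Rack-corrected estimated marginal strain means
#'
#' Fits the additive fixed-effect model `value ~ strain + rack` by least
#' squares for one trait on one host line and returns each strain's
#' estimated marginal mean (EMM): the model prediction averaged over rack
#' levels with equal weight, i.e. the strain mean corrected for the
#' greenhouse rack a replicate happened to sit on. With a single rack level
#' or a perfectly balanced design the EMM reduces to the raw strain mean.
#'
#' @param phenotypes Long replicate tibble with columns `strain_id`, `host`,
#'   `rack`, `trait`, `value`.
#' @param trait Trait name to analyse.
#' @param host Host line to analyse (never pooled across hosts).
#' @return Tibble: `strain_id`, `host`, `trait`, `emmean`, `se`, `n_reps`.
#' @examples
#' reps <- tibble::tibble(
#'   strain_id = rep(c("s1", "s2"), each = 4), host = "DZA",
#'   rack = rep(c("rackA", "rackB"), 4), trait = "shoot_biomass",
#'   value = c(1, 1.2, 0.9, 1.1, 2, 2.2, 1.9, 2.1))
#' estimated_marginal_means(reps, "shoot_biomass", "DZA")
#' @export
estimated_marginal_means <- function(phenotypes, trait, host) {
  dat <- phenotypes %>%
    filter(.data$trait == !!trait, .data$host == !!host, !is.na(.data$value)) %>%
    mutate(strain_id = factor(.data$strain_id), rack = factor(.data$rack))
  if (nrow(dat) == 0L)
    abort("no replicates for this trait/host", class = "symbio_data_error")
  if (nlevels(dat$strain_id) < 2L)
    abort("need at least 2 strains", class = "symbio_data_error")

  if (nlevels(dat$rack) > 1L) {
    fit <- lm(value ~ strain_id + rack, data = dat)
    if (anyNA(coef(fit)))
      warn("rack confounded with strain: model is rank-deficient, EMMs use the pseudo-inverse fit",
           class = "symbio_rank_warning")
    em <- as.data.frame(emmeans::emmeans(fit, "strain_id"))
  } else {
    fit <- lm(value ~ strain_id, data = dat)
    em <- as.data.frame(emmeans::emmeans(fit, "strain_id"))
  }
  nrep <- dat %>% dplyr::count(.data$strain_id, name = "n_reps")
  tibble(strain_id = as.character(em$strain_id), host = host, trait = trait,
         emmean = em$emmean, se = em$SE) %>%
    left_join(nrep %>% mutate(strain_id = as.character(.data$strain_id)),
              by = "strain_id")
}

#' EMMs for every trait-by-host combination present
#'
#' @param phenotypes Long replicate tibble (see
#'   [estimated_marginal_means()]).
#' @return Tibble of stacked per-strain EMMs for every `(trait, host)`
#'   combination observed in the data.
#' @export
strain_means_table <- function(phenotypes) {
  combos <- phenotypes %>% distinct(.data$trait, .data$host)
  purrr::pmap_dfr(combos, function(trait, host)
    estimated_marginal_means(phenotypes, trait, host))
}

#' Pairwise phenotypic correlation between two strain-mean vectors
#'
#' Inner-joins two per-strain summary tables on strain id and reports the
#' Pearson correlation, its two-sided p-value from the regression slope test
#' (`lm(y ~ x)`), and the conventional significance stars.
#'
#' @param emms_x,emms_y Tibbles with `strain_id` and a value column (the
#'   column named by `value_col`, default `emmean`).
#' @param host Host line label carried into the report.
#' @param value_col Name of the value column in both tables.
#' @return One-row tibble: `trait_x`, `trait_y`, `host`, `r`, `p_value`,
#'   `n_strains`, `stars`.
#' @export
pairwise_correlation <- function(emms_x, emms_y, host,
                                 value_col = "emmean") {
  joined <- inner_join(
    emms_x %>% select("strain_id", x = dplyr::all_of(value_col)),
    emms_y %>% select("strain_id", y = dplyr::all_of(value_col)),
    by = "strain_id")
  if (nrow(joined) < 3L)
    abort("need at least 3 strains shared between the two tables",
          class = "symbio_data_error")
  if (sd(joined$x) == 0 || sd(joined$y) == 0)
    abort("zero variance: correlation undefined", class = "symbio_data_error")
  fit <- lm(y ~ x, data = joined)
  sl <- summary(fit)$coefficients["x", ]
  r <- sign(sl[["Estimate"]]) * sqrt(summary(fit)$r.squared)
  p <- sl[["Pr(>|t|)"]]
  tibble(
    trait_x = attr(emms_x, "trait") %||% unique(emms_x[["trait"]]) %||% "x",
    trait_y = attr(emms_y, "trait") %||% unique(emms_y[["trait"]]) %||% "y",
    host = host, r = unname(r), p_value = unname(p),
    n_strains = nrow(joined), stars = star_label(p))
}

star_label <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "ns")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' All pairwise trait correlations per host
#'
#' Builds the full correlation grid over the five fitness proxies:
#' single-strain proxies enter as rack-corrected EMMs, multi-strain relative
#' fitness (when supplied) as the per-strain median log2 fold-change across
#' pools.
#'
#' @param means Stacked EMM tibble from [strain_means_table()].
#' @param relative_fitness Optional tibble `strain_id`, `host`,
#'   `median_log2_fc` from [relative_fitness()]; joined in as trait
#'   `relative_fitness`.
#' @return Tibble with one row per unordered trait pair per host.
#' @export
correlation_grid <- function(means, relative_fitness = NULL) {
  vals <- means %>% select("strain_id", "host", "trait", value = "emmean")
  if (!is.null(relative_fitness)) {
    vals <- bind_rows(vals, relative_fitness %>%
      transmute(strain_id = .data$strain_id, host = .data$host, trait = "relative_fitness",
                value = .data$median_log2_fc))
  }
  out <- list()
  for (h in unique(vals$host)) {
    traits <- sort(unique(vals$trait[vals$host == h]))
    for (i in seq_along(traits)) for (j in seq_len(i - 1L)) {
      tx <- traits[j]; ty <- traits[i]
      ex <- vals %>% filter(.data$host == h, .data$trait == tx) %>%
        select("strain_id", emmean = "value")
      ey <- vals %>% filter(.data$host == h, .data$trait == ty) %>%
        select("strain_id", emmean = "value")
      rep <- pairwise_correlation(ex, ey, h)
      rep$trait_x <- tx; rep$trait_y <- ty
      out[[paste(h, tx, ty)]] <- rep
    }
  }
  bind_rows(out)
}
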