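#' Classify significant variants into pleiotropy categories
#'
#' A variant is pleiotropic when it is significant for two or more fitness
#' proxies on the same host line. Variants significant for two or more
#' rhizobium proxies (nodule number, nodule weight, relative fitness) carry
#' *rhizobium fitness pleiotropy*; variants significant for at least one
#' rhizobium AND one plant proxy (shoot biomass, chlorophyll A) carry
#' *symbiotic pleiotropy*; a variant can carry both. For every pair of
#' traits in a variant's significant set the two effect signs are compared:
#' same sign (`+,+` or `-,-`) is *concordant* (fitness alignment), opposite
#' sign is *discordant* (conflict). Sign labels use the standardized-trait
#' betas so scale differences between proxies cannot flip interpretations.
#'
#' @param runs Named list of annotated `symbio_assoc` tibbles for one host
#'   (each with a `significant` column, e.g. from
#'   [annotate_significance()]), or a single row-bound tibble.
#' @param host Host line the runs belong to.
#' @return A list with `records` (one row per pleiotropic variant:
#'   `site_id`, `host`, `traits` (comma-joined significant set),
#'   `n_traits`, `category`) and `pair_labels` (one row per variant per
#'   trait pair: `site_id`, `host`, `trait_x`, `trait_y`, `beta_x`,
#'   `beta_y`, `sign_pattern`, `label`, `pair_category`).
#' @examples
#' a <- tibble::tibble(site_id = "chromosome:10", trait = "nodule_weight",
#'   host = "DZA", beta = 0.3, significant = TRUE)
#' b <- tibble::tibble(site_id = "chromosome:10", trait = "shoot_biomass",
#'   host = "DZA", beta = 0.2, significant = TRUE)
#' classify_pleiotropy(list(a, b), "DZA")$records
#' @export
classify_pleiotropy <- function(runs, host) {
  sig <- if (is.data.frame(runs)) runs else bind_rows(runs)
  sig <- sig %>% filter(.data$host == !!host, .data$significant)
  if (nrow(sig) == 0L) {
    return(list(
      records = tibble(site_id = character(), host = character(),
                       traits = character(), n_traits = integer(),
                       category = character()),
      pair_labels = tibble(site_id = character(), host = character(),
                           trait_x = character(), trait_y = character(),
                           beta_x = double(), beta_y = double(),
                           sign_pattern = character(), label = character(),
                           pair_category = character())))
  }
  if (any(sig$beta == 0))
    abort("significant variant with beta exactly 0: sign undefined",
          class = "symbio_classification_error")

  by_site <- sig %>%
    group_by(.data$site_id) %>%
    summarise(traits = list(sort(unique(.data$trait))), .groups = "drop") %>%
    mutate(n_traits = lengths(.data$traits)) %>%
    filter(.data$n_traits >= 2L)
  if (nrow(by_site) == 0L)
    return(classify_pleiotropy(sig[0, ], host))

  categorize <- function(tr) {
    n_rhiz <- sum(tr %in% RHIZOBIUM_TRAITS)
    n_plant <- sum(tr %in% PLANT_TRAITS)
    rhiz <- n_rhiz >= 2L
    symb <- n_rhiz >= 1L && n_plant >= 1L
    if (rhiz && symb) "both"
    else if (rhiz) "rhizobium_fitness_pleiotropy"
    else if (symb) "symbiotic_pleiotropy"
    else NA_character_  # >= 2 plant proxies only: not a pleiotropy category
  }
  records <- by_site %>%
    mutate(category = purrr::map_chr(.data$traits, categorize),
           traits = purrr::map_chr(.data$traits, paste, collapse = ","),
           host = host) %>%
    filter(!is.na(.data$category)) %>%
    select("site_id", "host", "traits", "n_traits", "category")

  beta_of <- sig %>% distinct(.data$site_id, .data$trait, .keep_all = TRUE)
  pair_labels <- by_site %>%
    filter(.data$site_id %in% records$site_id) %>%
    purrr::pmap_dfr(function(site_id, traits, n_traits) {
      combs <- utils::combn(traits, 2L)
      purrr::map_dfr(seq_len(ncol(combs)), function(k) {
        tx <- combs[1L, k]; ty <- combs[2L, k]
        bx <- beta_of$beta[beta_of$site_id == site_id & beta_of$trait == tx]
        by <- beta_of$beta[beta_of$site_id == site_id & beta_of$trait == ty]
        tibble(site_id = site_id, host = host, trait_x = tx, trait_y = ty,
               beta_x = bx, beta_y = by,
               sign_pattern = paste0(ifelse(bx > 0, "+", "-"), ",",
                                     ifelse(by > 0, "+", "-")),
               label = ifelse(bx * by > 0, "concordant", "discordant"),
               pair_category = pair_trait_category(tx, ty))
      })
    })
  list(records = records, pair_labels = pair_labels)
}

pair_trait_category <- function(tx, ty) {
  rx <- tx %in% RHIZOBIUM_TRAITS; ry <- ty %in% RHIZOBIUM_TRAITS
  if (rx && ry) "rhizobium" else if (rx || ry) "symbiotic" else "plant"
}

#' Concordance summary for one trait pair
#'
#' Counts concordant and discordant pleiotropic variants for a trait pair on
#' one host, with percentages computed against the union of variants
#' significant for either trait of the pair (the denominator used in the
#' per-pair panels).
#'
#' @param pleio Output of [classify_pleiotropy()].
#' @param runs The same annotated runs the records were built from (used
#'   for the union denominator).
#' @param trait_x,trait_y The trait pair.
#' @param host Host line.
#' @return One-row tibble: `trait_x`, `trait_y`, `host`, `n_concordant`,
#'   `n_discordant`, `n_pleiotropic`, `n_significant_union`,
#'   `pct_concordant`, `pct_discordant`.
#' @export
concordance_summary <- function(pleio, runs, trait_x, trait_y, host) {
  sig <- if (is.data.frame(runs)) runs else bind_rows(runs)
  union_sites <- sig %>%
    filter(.data$host == !!host, .data$significant,
           .data$trait %in% c(trait_x, trait_y)) %>%
    pull(.data$site_id) %>% unique()
  pl <- pleio$pair_labels %>%
    filter(.data$host == !!host,
           (.data$trait_x == !!trait_x & .data$trait_y == !!trait_y) |
             (.data$trait_x == !!trait_y & .data$trait_y == !!trait_x))
  n_con <- sum(pl$label == "concordant")
  n_dis <- sum(pl$label == "discordant")
  denom <- length(union_sites)
  tibble(trait_x = trait_x, trait_y = trait_y, host = host,
         n_concordant = n_con, n_discordant = n_dis,
         n_pleiotropic = n_con + n_dis, n_significant_union = denom,
         pct_concordant = if (denom > 0) 100 * n_con / denom else 0,
         pct_discordant = if (denom > 0) 100 * n_dis / denom else 0)
}

#' Host overlap of pleiotropic variants
#'
#' Tallies variants pleiotropic on one host only versus shared between the
#' two host lines, overall and per pleiotropy category.
#'
#' @param records_dza,records_a17 `records` tibbles from
#'   [classify_pleiotropy()] for the two hosts (same site universe).
#' @return A list: `overall` (one-row tibble `n_dza_only`, `n_a17_only`,
#'   `n_shared`, `n_total`) and `by_category` (per-category breakdown).
#' @export
host_overlap <- function(records_dza, records_a17) {
  sd_ <- unique(records_dza$site_id)
  sa <- unique(records_a17$site_id)
  overall <- tibble(
    n_dza_only = length(setdiff(sd_, sa)),
    n_a17_only = length(setdiff(sa, sd_)),
    n_shared = length(intersect(sd_, sa)),
    n_total = length(union(sd_, sa)))
  cats <- union(records_dza$category, records_a17$category)
  by_category <- purrr::map_dfr(cats, function(cc) {
    d <- records_dza$site_id[records_dza$category == cc]
    a <- records_a17$site_id[records_a17$category == cc]
    tibble(category = cc,
           n_dza_only = length(setdiff(d, a)),
           n_a17_only = length(setdiff(a, d)),
           n_shared = length(intersect(d, a)),
           n_total = length(union(d, a)))
  })
  list(overall = overall, by_category = by_category)
}

#' Roll pleiotropic variants up to genes
#'
#' Maps each pleiotropic variant to the gene whose annotation interval
#' contains it (1-based, inclusive); intergenic variants get `NA` and are
#' excluded from selection scans.
#'
#' @param records `records` tibble from [classify_pleiotropy()] (any tibble
#'   with `site_id`).
#' @param sites Site tibble with `site_id`, `replicon`, `pos`.
#' @param genes Gene tibble with `gene_id`, `replicon`, `start`, `end`.
#' @return The records with `gene_id` joined on.
#' @export
assign_genes <- function(records, sites, genes) {
  pos_tbl <- sites %>% select("site_id", "replicon", "pos")
  rec <- records %>% left_join(pos_tbl, by = "site_id")
  rec$gene_id <- purrr::map2_chr(rec$replicon, rec$pos, function(r, p) {
    hit <- genes$gene_id[genes$replicon == r & genes$start <= p & genes$end >= p]
    if (length(hit)) hit[[1]] else NA_character_
  })
  rec
}
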