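mk_run <- function(site, trait, beta, sig = TRUE, host = "DZA") {
  tibble::tibble(site_id = site, trait = trait, host = host, beta = beta,
                 significant = sig)
}

test_that("category and sign labels follow the definitions", {
  runs <- dplyr::bind_rows(
    mk_run("c:10", "nodule_weight", 0.3),
    mk_run("c:10", "shoot_biomass", 0.2),
    mk_run("c:20", "nodule_number", 0.3),
    mk_run("c:20", "relative_fitness", -0.2),
    mk_run("c:30", "shoot_biomass", 0.5))
  pl <- classify_pleiotropy(runs, "DZA")
  rec <- pl$records
  expect_setequal(rec$site_id, c("c:10", "c:20"))
  expect_identical(rec$category[rec$site_id == "c:10"],
                   "symbiotic_pleiotropy")
  expect_identical(rec$category[rec$site_id == "c:20"],
                   "rhizobium_fitness_pleiotropy")
  lab <- pl$pair_labels
  expect_identical(lab$label[lab$site_id == "c:10"], "concordant")
  expect_identical(lab$sign_pattern[lab$site_id == "c:10"], "+,+")
  expect_identical(lab$label[lab$site_id == "c:20"], "discordant")
  # single-trait variant never appears
  expect_false("c:30" %in% rec$site_id)
})

test_that("a variant significant for three traits yields one label per pair", {
  runs <- dplyr::bind_rows(
    mk_run("c:10", "nodule_weight", 0.3),
    mk_run("c:10", "nodule_number", -0.1),
    mk_run("c:10", "shoot_biomass", 0.2))
  pl <- classify_pleiotropy(runs, "DZA")
  expect_identical(nrow(pl$pair_labels), 3L)
  expect_identical(pl$records$category, "both")
})

test_that("zero betas cannot be signed", {
  runs <- dplyr::bind_rows(
    mk_run("c:10", "nodule_weight", 0),
    mk_run("c:10", "shoot_biomass", 0.2))
  expect_error(classify_pleiotropy(runs, "DZA"),
               class = "symbio_classification_error")
})

test_that("labels are invariant under a simultaneous allele-coding flip", {
  set.seed(31)
  traits <- c("nodule_weight", "shoot_biomass")
  runs <- dplyr::bind_rows(lapply(1:20, function(i)
    dplyr::bind_rows(
      mk_run(paste0("c:", i), traits[1], rnorm(1)),
      mk_run(paste0("c:", i), traits[2], rnorm(1)))))
  runs$beta[runs$beta == 0] <- 0.1
  l1 <- classify_pleiotropy(runs, "DZA")$pair_labels
  runs2 <- dplyr::mutate(runs, beta = -beta)
  l2 <- classify_pleiotropy(runs2, "DZA")$pair_labels
  expect_identical(l1$label, l2$label)
})

test_that("records stay consistent with the per-trait significant sets", {
  set.seed(32)
  sites <- paste0("c:", 1:30)
  runs <- dplyr::bind_rows(lapply(c("nodule_weight", "nodule_number",
                                    "shoot_biomass"), function(tr)
    mk_run(sample(sites, 12), tr, rnorm(12))))
  pl <- classify_pleiotropy(runs, "DZA")
  for (i in seq_len(nrow(pl$records))) {
    traits_i <- strsplit(pl$records$traits[i], ",")[[1]]
    for (tr in traits_i)
      expect_true(any(runs$site_id == pl$records$site_id[i] &
                        runs$trait == tr & runs$significant))
  }
})

test_that("concordance summaries count against the pair union", {
  runs <- dplyr::bind_rows(
    mk_run("c:10", "nodule_weight", 0.3),
    mk_run("c:10", "shoot_biomass", 0.2),
    mk_run("c:20", "nodule_weight", -0.4),
    mk_run("c:20", "shoot_biomass", 0.1),
    mk_run("c:30", "nodule_weight", 0.2),   # significant for one trait only
    mk_run("c:40", "shoot_biomass", 0.2))
  pl <- classify_pleiotropy(runs, "DZA")
  cs <- concordance_summary(pl, runs, "nodule_weight", "shoot_biomass", "DZA")
  expect_identical(cs$n_concordant, 1L)
  expect_identical(cs$n_discordant, 1L)
  expect_identical(cs$n_significant_union, 4L)
  expect_equal(cs$pct_concordant, 25)
  expect_equal(cs$pct_discordant, 25)
  # empty case
  cs0 <- concordance_summary(pl, runs, "chlorophyll_a", "nodule_number",
                             "DZA")
  expect_identical(cs0$n_pleiotropic, 0L)
  expect_equal(cs0$pct_concordant, 0)
})

test_that("host overlap handles identical, disjoint and partial sets", {
  recs <- function(ids) tibble::tibble(
    site_id = ids, host = "x", traits = "a,b", n_traits = 2L,
    category = "symbiotic_pleiotropy")
  same <- host_overlap(recs(c("a", "b", "c")), recs(c("a", "b", "c")))
  expect_identical(same$overall$n_shared, 3L)
  expect_identical(same$overall$n_dza_only, 0L)
  disj <- host_overlap(recs(c("a", "b")), recs(c("c", "d")))
  expect_identical(disj$overall$n_shared, 0L)
  expect_identical(disj$overall$n_total, 4L)
  part <- host_overlap(recs(c("a", "b", "c")), recs(c("b", "c", "d")))
  expect_identical(part$overall$n_shared, 2L)
  expect_identical(part$overall$n_dza_only, 1L)
  expect_identical(part$overall$n_a17_only, 1L)
})

test_that("variants map to containing genes, intergenic ones to NA", {
  sites <- tibble::tibble(site_id = c("c:15", "c:25", "c:99"),
                          replicon = "chromosome", pos = c(15L, 25L, 99L))
  genes <- tibble::tibble(gene_id = c("g1", "g2"), replicon = "chromosome",
                          start = c(10L, 20L), end = c(19L, 30L))
  rec <- assign_genes(tibble::tibble(site_id = sites$site_id), sites, genes)
  expect_identical(rec$gene_id, c("g1", "g2", NA_character_))
})

test_that("host-specific planted architecture yields the designed host overlap", {
  cfg <- sim_config(n_strains = 40, n_sites = 400, n_concordant_pairs = 10,
                    n_discordant_pairs = 10, host_specific = 0.5, seed = 33)
  sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  ca <- sim$truth$causal
  expect_identical(sum(ca$host == "both"), 10L)
  expect_identical(sum(ca$host %in% c("DZA", "A17")), 10L)
  # classify from the planted truth itself (each causal variant significant
  # for its two traits on its host(s)): overlap must match the design
  mk <- function(h) {
    cah <- dplyr::filter(ca, host %in% c(h, "both"))
    dplyr::bind_rows(
      tibble::tibble(site_id = cah$site_id, trait = cah$trait1, host = h,
                     beta = cah$beta1, significant = TRUE),
      tibble::tibble(site_id = cah$site_id, trait = cah$trait2, host = h,
                     beta = cah$beta2, significant = TRUE))
  }
  ov <- host_overlap(classify_pleiotropy(mk("DZA"), "DZA")$records,
                     classify_pleiotropy(mk("A17"), "A17")$records)
  expect_identical(ov$overall$n_shared, 10L)
  expect_identical(ov$overall$n_dza_only, 5L)
  expect_identical(ov$overall$n_a17_only, 5L)
})
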