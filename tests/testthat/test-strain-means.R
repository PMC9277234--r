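balanced_reps <- function(truth, racks, reps_per_rack = 2, rack_fx = NULL,
                          noise = 0, seed = 1) {
  set.seed(seed)
  if (is.null(rack_fx)) rack_fx <- setNames(rep(0, length(racks)), racks)
  grid <- expand.grid(strain_id = names(truth), rack = racks,
                      rep = seq_len(reps_per_rack),
                      stringsAsFactors = FALSE)
  tibble::tibble(strain_id = grid$strain_id, host = "DZA", rack = grid$rack,
                 trait = "shoot_biomass",
                 value = truth[grid$strain_id] + rack_fx[grid$rack] +
                   rnorm(nrow(grid), 0, noise))
}

test_that("balanced designs give EMM equal to the raw strain mean", {
  truth <- c(s1 = 1, s2 = 3, s3 = -2)
  reps <- balanced_reps(truth, c("rackA", "rackB"), rack_fx = c(rackA = 5,
                                                                rackB = -5),
                        noise = 0.2, seed = 2)
  emm <- estimated_marginal_means(reps, "shoot_biomass", "DZA")
  raw <- tapply(reps$value, reps$strain_id, mean)
  expect_equal(emm$emmean, as.vector(raw[emm$strain_id]), tolerance = 1e-10)
})

test_that("a single rack level degenerates to the raw strain mean", {
  truth <- c(s1 = 0.5, s2 = 2)
  reps <- balanced_reps(truth, "rackA", reps_per_rack = 3, noise = 0.3,
                        seed = 3)
  emm <- estimated_marginal_means(reps, "shoot_biomass", "DZA")
  raw <- tapply(reps$value, reps$strain_id, mean)
  expect_equal(emm$emmean, as.vector(raw[emm$strain_id]), tolerance = 1e-10)
})

test_that("EMMs remove a known rack effect from an unbalanced design", {
  set.seed(4)
  truth <- setNames(rnorm(40), sprintf("s%02d", 1:40))
  # unbalanced: each replicate lands in a random rack; rackB shifted +2
  reps <- purrr::map_dfr(names(truth), function(s) {
    racks <- sample(c("rackA", "rackB"), 5, replace = TRUE)
    tibble::tibble(strain_id = s, host = "DZA", rack = racks,
                   trait = "shoot_biomass",
                   value = truth[s] + ifelse(racks == "rackB", 2, 0) +
                     rnorm(5, 0, 0.1))
  })
  emm <- estimated_marginal_means(reps, "shoot_biomass", "DZA")
  # EMMs sit at the balanced rack average (+1 here); strain contrasts recover
  # the truth with small bias
  centred <- emm$emmean - mean(emm$emmean)
  expect_lt(max(abs(centred - (truth[emm$strain_id] - mean(truth)))), 0.15)
  expect_lt(mean(abs(centred - (truth[emm$strain_id] - mean(truth)))), 0.05)
})

test_that("EMMs are invariant to replicate row order and rack-level shifts", {
  truth <- c(s1 = 1, s2 = -1, s3 = 0.5, s4 = 2)
  reps <- balanced_reps(truth, c("rackA", "rackB"), noise = 0.5, seed = 5)
  emm1 <- estimated_marginal_means(reps, "shoot_biomass", "DZA")
  emm2 <- estimated_marginal_means(reps[sample(nrow(reps)), ],
                                   "shoot_biomass", "DZA")
  expect_equal(emm1$emmean[order(emm1$strain_id)],
               emm2$emmean[order(emm2$strain_id)], tolerance = 1e-10)
  # adding a constant to one rack shifts all EMMs equally
  shifted <- dplyr::mutate(reps,
    value = value + ifelse(rack == "rackB", 7, 0))
  emm3 <- estimated_marginal_means(shifted, "shoot_biomass", "DZA")
  d1 <- diff(emm1$emmean[order(emm1$strain_id)])
  d3 <- diff(emm3$emmean[order(emm3$strain_id)])
  expect_equal(d1, d3, tolerance = 1e-10)
})

test_that("perfect and near-perfect correlations are reported with stars", {
  x <- tibble::tibble(strain_id = sprintf("s%02d", 1:20),
                      emmean = seq(-1, 1, length.out = 20))
  y2 <- dplyr::mutate(x, emmean = 2 * emmean)
  expect_equal(suppressWarnings(pairwise_correlation(x, y2, "DZA"))$r, 1,
               tolerance = 1e-12)
  set.seed(6)
  yneg <- dplyr::mutate(x, emmean = -emmean + rnorm(20, 0, 0.05))
  rep <- pairwise_correlation(x, yneg, "DZA")
  expect_lt(rep$r, -0.9)
  expect_identical(rep$stars, "***")
  # symmetry
  expect_equal(pairwise_correlation(x, yneg, "DZA")$r,
               pairwise_correlation(yneg, x, "DZA")$r, tolerance = 1e-12)
})

test_that("degenerate correlation inputs error", {
  x <- tibble::tibble(strain_id = c("s1", "s2", "s3"), emmean = c(1, 1, 1))
  y <- tibble::tibble(strain_id = c("s1", "s2", "s3"), emmean = c(1, 2, 3))
  expect_error(pairwise_correlation(x, y, "DZA"),
               class = "symbio_data_error")
  expect_error(pairwise_correlation(y[1:2, ], y[1:2, ], "DZA"),
               class = "symbio_data_error")
})

test_that("the slope test has calibrated type-I error at n = 89", {
  set.seed(7)
  n_sim <- 600
  hits <- 0
  for (i in seq_len(n_sim)) {
    x <- tibble::tibble(strain_id = sprintf("s%02d", 1:89),
                        emmean = rnorm(89))
    y <- dplyr::mutate(x, emmean = rnorm(89))
    if (pairwise_correlation(x, y, "DZA")$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / n_sim, 0.02)
  expect_lt(hits / n_sim, 0.08)
})

test_that("star labels follow the conventional thresholds", {
  expect_identical(symbiopleio:::star_label(c(0.2, 0.04, 0.009, 0.0009)),
                   c("ns", "*", "**", "***"))
})

test_that("a strain confined to one rack triggers a rank warning but still gets an EMM", {
  set.seed(8)
  reps <- dplyr::bind_rows(
    tibble::tibble(strain_id = "s1", host = "DZA", rack = "rackA",
                   trait = "shoot_biomass", value = rnorm(3, 1)),
    tibble::tibble(strain_id = "s2", host = "DZA", rack = "rackB",
                   trait = "shoot_biomass", value = rnorm(3, 2)))
  expect_warning(
    emm <- estimated_marginal_means(reps, "shoot_biomass", "DZA"),
    class = "symbio_rank_warning")
  expect_identical(nrow(emm), 2L)
  expect_true(all(is.finite(emm$emmean)))
})
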