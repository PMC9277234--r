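test_that("a single-strain panel always reconstructs to frequency one", {
  G <- matrix(c(0L, 1L, 1L, 0L), nrow = 1)
  panel <- make_panel(G)
  obs <- tibble::tibble(site_id = panel$sites$site_id,
                        depth = c(100L, 100L, 50L, 80L),
                        alt_count = c(30L, 70L, 10L, 0L))
  est <- reconstruct_frequencies(obs, panel, maf_min = 0)
  expect_equal(unname(est$f[[1]]), 1)
})

test_that("one informative site resolves a two-strain mixture", {
  G <- rbind(c(0L, 1L, 0L), c(1L, 1L, 0L))  # strains differ at site 1 only
  panel <- make_panel(G)
  obs <- tibble::tibble(site_id = panel$sites$site_id,
                        depth = c(10000L, 10000L, 10000L),
                        alt_count = c(3000L, 10000L, 0L))
  est <- reconstruct_frequencies(obs, panel, maf_min = 0)
  expect_equal(unname(est$f[[1]]), c(0.7, 0.3), tolerance = 1e-5)
})

test_that("noiseless counts are recovered exactly with full-rank genotypes", {
  set.seed(11)
  S <- 10; L <- 300
  G <- matrix(rbinom(S * L, 1L, runif(S * L, 0.2, 0.8)), S, L)
  panel <- make_panel(G)
  f_true <- as.numeric(rgamma(S, 3)); f_true <- f_true / sum(f_true)
  depth <- rep(1000, L)
  p <- as.numeric(crossprod(G, f_true))
  obs <- tibble::tibble(site_id = panel$sites$site_id, depth = depth,
                        alt_count = depth * p)
  est <- reconstruct_frequencies(obs, panel, maf_min = 0, tol = 1e-10)
  expect_lt(max(abs(est$f[[1]] - f_true)), 1e-6)
  expect_lt(est$residual, 1e-12)
})

test_that("the projected-gradient objective never increases", {
  set.seed(12)
  S <- 15; L <- 100
  G <- matrix(rbinom(S * L, 1L, 0.5), S, L)
  panel <- make_panel(G)
  depth <- rpois(L, 200)
  f <- rep(1 / S, S)
  alt <- rbinom(L, depth, pmin(pmax(as.numeric(crossprod(G, f)), 0), 1))
  obs <- tibble::tibble(site_id = panel$sites$site_id, depth = depth,
                        alt_count = alt)
  est <- reconstruct_frequencies(obs, panel, trace = TRUE)
  tr <- attr(est, "objective_trace")
  expect_gt(length(tr), 2)
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("simplex projection returns the closest simplex point", {
  v <- c(0.8, 0.6, -0.4)
  p <- project_simplex(v)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_equal(p, c(0.6, 0.4, 0), tolerance = 1e-12)
  expect_equal(project_simplex(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5),
               tolerance = 1e-12)
})

test_that("alignment and depth errors are raised", {
  G <- rbind(c(0L, 1L), c(1L, 0L))
  panel <- make_panel(G)
  expect_error(reconstruct_frequencies(
    tibble::tibble(site_id = c("nope:1", "nope:2"), depth = c(10L, 10L),
                   alt_count = c(1L, 2L)), panel),
    class = "symbio_data_error")
  expect_error(reconstruct_frequencies(
    tibble::tibble(site_id = panel$sites$site_id, depth = c(0L, 0L),
                   alt_count = c(0L, 0L)), panel, maf_min = 0),
    class = "symbio_no_information")
  expect_error(reconstruct_frequencies(
    tibble::tibble(site_id = panel$sites$site_id, depth = c(5L, 5L),
                   alt_count = c(6L, 0L)), panel),
    class = "symbio_data_error")
})

test_that("reconstruction recovers simulated pool composition", {
  cfg <- sim_config(n_strains = 20, n_sites = 400, mean_depth = 500,
                    missing_rate = 0, n_pools = 1, seed = 13)
  panel <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(panel, cfg)
  pl <- simulate_pools(panel, sim$truth, cfg)
  est <- reconstruct_frequencies(
    dplyr::filter(pl$pools, pool_id == "DZA_pool01"), panel)
  truth <- dplyr::filter(pl$truth$pools, pool_id == "DZA_pool01")
  rmse <- sqrt(mean((est$f[[1]][truth$strain_id] - truth$f_end)^2))
  expect_lt(rmse, 0.05)
  expect_true(est$converged)
})

test_that("fold-change identities hold", {
  f0 <- c(s1 = 0.5, s2 = 0.3, s3 = 0.2)
  est <- tibble::tibble(pool_id = "p1", host = "DZA", f = list(f0))
  class(est) <- c("strain_freq_estimate", class(est))
  rf <- relative_fitness(est, f0, pseudo = 0.01)
  expect_true(all(rf$per_pool$fold_change == 1))
  expect_true(all(rf$per_strain$median_log2_fc == 0))

  est2 <- tibble::tibble(pool_id = "p1", host = "DZA",
                         f = list(c(s1 = 0.02, s2 = 0.98)))
  class(est2) <- c("strain_freq_estimate", class(est2))
  rf2 <- relative_fitness(est2, c(s1 = 0.01, s2 = 0.99), pseudo = 0)
  expect_equal(rf2$per_pool$fold_change[1], 2, tolerance = 1e-12)
})

test_that("zero frequency with zero pseudo is flagged and log2 missing", {
  est <- tibble::tibble(pool_id = "p1", host = "DZA",
                        f = list(c(s1 = 0, s2 = 1)))
  class(est) <- c("strain_freq_estimate", class(est))
  expect_warning(
    rf <- relative_fitness(est, c(s1 = 0.5, s2 = 0.5), pseudo = 0),
    class = "symbio_zero_frequency_warning")
  expect_identical(rf$per_pool$fold_change[1], 0)
  expect_true(is.na(rf$per_pool$log2_fold_change[1]))
})

test_that("estimates are invariant to a common rescaling of depths", {
  set.seed(14)
  S <- 8; L <- 120
  G <- matrix(rbinom(S * L, 1L, 0.5), S, L)
  panel <- make_panel(G)
  depth <- rpois(L, 100) + 1L
  f <- as.numeric(rgamma(S, 2)); f <- f / sum(f)
  alt <- depth * as.numeric(crossprod(G, f))
  obs1 <- tibble::tibble(site_id = panel$sites$site_id, depth = depth,
                         alt_count = alt)
  obs2 <- dplyr::mutate(obs1, depth = depth * 10, alt_count = alt_count * 10)
  e1 <- reconstruct_frequencies(obs1, panel, maf_min = 0, tol = 1e-10)
  e2 <- reconstruct_frequencies(obs2, panel, maf_min = 0, tol = 1e-10)
  expect_equal(e1$f[[1]], e2$f[[1]], tolerance = 1e-6)
})
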