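test_that("variant filter applies MAF and missingness thresholds exactly", {
  # 100 strains; site 1 has a single alternate allele (MAF 0.01)
  G <- matrix(0L, 100, 4)
  G[1, 1] <- 1L
  G[1:30, 2] <- 1L
  G[1:50, 3] <- 1L; G[1:30, 3] <- NA_integer_  # 30% missing
  G[1:2, 4] <- 1L
  panel <- make_panel(G)
  f <- filter_variants(panel, maf_min = 0.05, miss_max = 0.2)
  expect_false("chromosome:10" %in% f$sites$site_id)   # MAF too low
  expect_true("chromosome:20" %in% f$sites$site_id)
  expect_false("chromosome:30" %in% f$sites$site_id)   # too much missing
  expect_false("chromosome:40" %in% f$sites$site_id)   # MAF 0.02
  # no-op bounds keep everything
  expect_identical(ncol(filter_variants(panel, 0, 1)$geno), 4L)
  expect_error(filter_variants(panel, 0.5, 0),
               class = "symbio_empty_panel")
})

test_that("filter counts match a brute-force recount", {
  cfg <- sim_config(n_strains = 50, n_sites = 800, missing_rate = 0.05,
                    seed = 17)
  panel <- simulate_genotypes(cfg)
  f <- filter_variants(panel, maf_min = 0.1, miss_max = 0.06)
  # independent recount with explicit loops
  keep <- 0L
  for (j in seq_len(ncol(panel$geno))) {
    x <- panel$geno[, j]
    miss <- sum(is.na(x)) / length(x)
    af <- mean(x, na.rm = TRUE)
    maf <- min(af, 1 - af)
    if (!is.nan(maf) && maf >= 0.1 && miss <= 0.06) keep <- keep + 1L
  }
  expect_identical(unname(attr(f, "filter_counts")["n_kept"]), keep)
  expect_identical(ncol(f$geno), as.integer(keep))
})

test_that("kinship reflects duplication, independence, and relabeling", {
  set.seed(18)
  # duplicated strains have identical rows
  G <- matrix(rbinom(10 * 50, 1L, 0.5), 10, 50)
  G[2, ] <- G[1, ]
  K <- compute_kinship(make_panel(G))
  expect_equal(K[1, ], K[2, ], tolerance = 1e-12)

  # i.i.d. Bernoulli(0.5) sites: diagonal near 0.25, off-diagonal near 0
  G2 <- matrix(rbinom(50 * 20000, 1L, 0.5), 50, 20000)
  K2 <- compute_kinship(make_panel(G2))
  expect_equal(mean(diag(K2)), 0.25, tolerance = 0.02)
  expect_lt(abs(mean(K2[upper.tri(K2)])), 0.01)

  # permuting strains permutes the kinship
  perm <- sample(10)
  Kp <- compute_kinship(subset_panel_for_test(make_panel(G), perm))
  expect_equal(unclass(Kp)[, ], unclass(K)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("with identity kinship the scan reduces to ordinary least squares", {
  set.seed(19)
  S <- 40; L <- 60
  G <- matrix(rbinom(S * L, 1L, 0.4), S, L)
  panel <- make_panel(G)
  y <- rnorm(S) + 0.5 * G[, 7]
  KI <- diag(S); dimnames(KI) <- list(panel$strains$strain_id,
                                      panel$strains$strain_id)
  res <- lmm_association(setNames(y, panel$strains$strain_id), panel, KI,
                         standardize = FALSE, lambda = 1)
  for (j in c(1, 7, 33)) {
    ols <- summary(lm(y ~ G[, j]))$coefficients
    expect_equal(res$beta[j], ols[2, 1], tolerance = 1e-8)
    expect_equal(res$se[j], ols[2, 2], tolerance = 1e-8)
    expect_equal(res$p_wald[j], ols[2, 4], tolerance = 1e-8)
  }
})

test_that("the scan matches an explicit-inverse GLS oracle at frozen lambda", {
  set.seed(20)
  G <- matrix(rbinom(40 * 100, 1L, 0.5), 40, 100)
  G[, colSums(G) %in% c(0L, 40L)] <- 1L * (seq_len(40) <= 20)  # keep polymorphic
  panel <- make_panel(G)
  K <- compute_kinship(panel)
  y <- rnorm(40)
  lambda <- 1.7
  res <- lmm_association(setNames(y, panel$strains$strain_id), panel, K,
                         standardize = FALSE, lambda = lambda)
  oracle <- gls_oracle(y, symbiopleio:::impute_genotypes(panel$geno),
                       unclass(K)[, ], lambda)
  expect_equal(res$beta, unname(oracle[, "beta"]), tolerance = 1e-8)
  expect_equal(res$se, unname(oracle[, "se"]), tolerance = 1e-8)
  expect_equal(res$p_wald, unname(oracle[, "p"]), tolerance = 1e-8)
})

test_that("beta flips sign exactly under allele recoding", {
  set.seed(21)
  cfg <- sim_config(n_strains = 30, n_sites = 50, missing_rate = 0, seed = 21)
  panel <- simulate_genotypes(cfg)
  y <- setNames(rnorm(30), panel$strains$strain_id)
  res1 <- lmm_association(y, panel, lambda = 0.5)
  flipped <- panel
  flipped$geno <- 1L - panel$geno
  res2 <- lmm_association(y, flipped, compute_kinship(panel), lambda = 0.5)
  expect_equal(res1$beta, -res2$beta, tolerance = 1e-10)
  expect_equal(res1$p_wald, res2$p_wald, tolerance = 1e-10)
})

test_that("results are invariant to site and strain order", {
  cfg <- sim_config(n_strains = 25, n_sites = 80, seed = 22)
  panel <- simulate_genotypes(cfg)
  y <- setNames(rnorm(25), panel$strains$strain_id)
  res <- lmm_association(y, panel)
  sperm <- sample(25); jperm <- sample(80)
  panel2 <- subset_panel_for_test(panel, sperm, jperm)
  res2 <- lmm_association(y[sperm], panel2)
  m <- match(res$site_id, res2$site_id)
  expect_equal(res$beta, res2$beta[m], tolerance = 1e-10)
  expect_equal(res$p_wald, res2$p_wald[m], tolerance = 1e-10)
})

test_that("standard errors shrink as 1 / sqrt(n strains)", {
  med_se <- vapply(c(50L, 200L), function(S) {
    set.seed(S)
    G <- matrix(rbinom(S * 200, 1L, 0.5), S, 200)
    panel <- make_panel(G)
    y <- setNames(rnorm(S), panel$strains$strain_id)
    median(lmm_association(y, panel, lambda = 0)$se)
  }, numeric(1))
  expect_equal(med_se[1] / med_se[2], 2, tolerance = 0.25)
})

test_that("degenerate trait vectors are rejected", {
  cfg <- sim_config(n_strains = 10, n_sites = 30, seed = 23)
  panel <- simulate_genotypes(cfg)
  y <- setNames(rep(1, 10), panel$strains$strain_id)
  expect_error(lmm_association(y, panel), class = "symbio_data_error")
  y2 <- setNames(c(NA, rnorm(9)), panel$strains$strain_id)
  expect_error(lmm_association(y2, panel), class = "symbio_data_error")
})
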