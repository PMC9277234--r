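#' Filter variants on minor allele frequency and missingness
#'
#' Keeps sites with panel minor allele frequency at least `maf_min` (over
#' non-missing calls) and missing fraction at most `miss_max`. The raw
#' genotype matrix is untouched; mean-imputation of the survivors happens
#' inside the association machinery only.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min Minimum minor allele frequency, in `[0, 0.5]`.
#' @param miss_max Maximum missing fraction, in `[0, 1]`.
#' @return The filtered [genotype_panel()] with attribute `filter_counts`
#'   (`n_in`, `n_kept`, `n_removed`).
#' @examples
#' panel <- simulate_genotypes(sim_config(n_strains = 30, n_sites = 300, seed = 4))
#' filtered <- filter_variants(panel, maf_min = 0.05, miss_max = 0.1)
#' attr(filtered, "filter_counts")
#' @export
filter_variants <- function(panel, maf_min = 0.05, miss_max = 0.2) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  ss <- site_summary(panel)
  keep <- !is.na(ss$maf) & ss$maf >= maf_min & ss$missing_frac <= miss_max
  if (!any(keep))
    abort("all sites removed by the filter", class = "symbio_empty_panel")
  out <- subset_panel(panel, sites = which(keep))
  if (!is.null(panel$geno_complete))
    out$geno_complete <- panel$geno_complete[, keep, drop = FALSE]
  attr(out, "filter_counts") <- c(n_in = nrow(ss), n_kept = sum(keep),
                                  n_removed = sum(!keep))
  out
}

#' Centered kinship matrix
#'
#' Computes the strain-by-strain relatedness matrix `K = Xc Xc' / L` over
#' the panel's sites, where `Xc` is the genotype matrix with each site
#' column centered on its mean (missing calls mean-imputed, i.e. centered to
#' zero). This is the standard "centered" kinship of mixed-model GWAS and is
#' what absorbs population structure in [lmm_association()]. The
#' eigendecomposition is cached as an attribute.
#'
#' @param panel A [genotype_panel()].
#' @return An S-by-S symmetric matrix of class `kinship_matrix` with
#'   attribute `eigen` (the cached eigendecomposition).
#' @export
compute_kinship <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- impute_genotypes(panel$geno)
  if (nrow(X) < 2L) abort("need at least 2 strains", class = "symbio_data_error")
  Xc <- sweep(X, 2L, colMeans(X))
  poly <- colSums(Xc != 0) > 0L
  if (!any(poly)) abort("no polymorphic sites", class = "symbio_data_error")
  K <- tcrossprod(Xc) / ncol(X)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(X), rownames(X))
  attr(K, "eigen") <- eigen(K, symmetric = TRUE)
  class(K) <- c("kinship_matrix", class(K))
  K
}

# Restricted log-likelihood of the null (intercept-only) model as a function
# of lambda = sigma_g^2 / sigma_e^2, in the eigenbasis of K.
reml_loglik <- function(lambda, d, Xr, yr) {
  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xr, w * Xr)
  XtWy <- crossprod(Xr, w * yr)
  beta <- solve(XtWX, XtWy)
  rss <- sum(w * (yr - Xr %*% beta)^2)
  nq <- length(yr) - ncol(Xr)
  -0.5 * (sum(log(v)) + determinant(XtWX, logarithm = TRUE)$modulus +
            nq * log(rss / nq))
}

# REML estimate of lambda on the null model: log-grid scan then Brent
# refinement within the bracketing interval.
estimate_lambda <- function(d, Xr, yr, grid = 10^seq(-5, 5, by = 0.25)) {
  ll <- vapply(grid, reml_loglik, numeric(1), d = d, Xr = Xr, yr = yr)
  i <- which.max(ll)
  boundary <- i == 1L || i == length(grid)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(function(lg) reml_loglik(10^lg, d, Xr, yr),
                  lower = log10(lo), upper = log10(hi), maximum = TRUE,
                  tol = 1e-6)
  list(lambda = 10^opt$maximum, boundary = boundary)
}

#' Kinship-corrected linear mixed-model association scan
#'
#' Fits, for every site, the univariate linear mixed model
#' `y = a + x b + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`. The variance ratio
#' `lambda = sigma_g^2 / sigma_e^2` is estimated once per trait by REML on
#' the null (intercept-only) model via eigen-rotation and one-dimensional
#' optimization; each site's allelic effect `beta`, its standard error and a
#' Wald p-value (t reference, n - 2 df) then come from generalized least
#' squares in the rotated basis. With `K = I` the scan reduces exactly to
#' ordinary least squares. Missing genotypes are mean-imputed for testing
#' only. The trait is standardized to unit variance by default so betas are
#' comparable across fitness proxies; raw-scale betas are also emitted.
#'
#' @param y Named per-strain trait vector (one value per strain, e.g. EMMs),
#'   or a tibble with `strain_id` and `value`.
#' @param panel A (filtered) [genotype_panel()].
#' @param K A [compute_kinship()] matrix (defaults to computing it from
#'   `panel`).
#' @param trait,host Labels carried into the result.
#' @param standardize Standardize `y` to unit variance before testing
#'   (default `TRUE`).
#' @param lambda Optional fixed variance ratio; skips REML (used for
#'   diagnostics and oracle checks).
#' @return A tibble of class `symbio_assoc`, one row per site: `site_id`,
#'   `replicon`, `pos`, `trait`, `host`, `maf`, `n_strains`, `beta`, `se`,
#'   `p_wald`, `beta_raw`, `se_raw`, with attributes `lambda`, `sigma_g2`,
#'   `sigma_e2`, `lambda_boundary`.
#' @examples
#' cfg <- sim_config(n_strains = 40, n_sites = 300, seed = 6)
#' panel <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(panel, cfg)
#' emm <- estimated_marginal_means(sim$phenotypes, "nodule_weight", "DZA")
#' y <- setNames(emm$emmean, emm$strain_id)
#' res <- lmm_association(y, panel, trait = "nodule_weight", host = "DZA")
#' head(tidy(res))
#' @export
lmm_association <- function(y, panel, K = NULL, trait = "trait",
                            host = "host", standardize = TRUE,
                            lambda = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.data.frame(y)) y <- setNames(y$value, y$strain_id)
  if (!is.null(names(y))) {
    keep <- panel$strains$strain_id %in% names(y)
    if (!all(keep)) panel <- subset_panel(panel, strains = which(keep))
    y <- y[panel$strains$strain_id]
  }
  if (any(!is.finite(y)))
    abort("trait vector contains non-finite values", class = "symbio_data_error")
  n <- length(y)
  if (n != nrow(panel$geno))
    abort("trait vector does not align with panel strains",
          class = "symbio_data_error")
  if (sd(y) == 0)
    abort("trait has zero variance", class = "symbio_data_error")
  if (is.null(K)) K <- compute_kinship(panel)
  if (!is.null(rownames(K)) &&
      !identical(rownames(K), panel$strains$strain_id)) {
    idx <- match(panel$strains$strain_id, rownames(K))
    if (anyNA(idx))
      abort("kinship matrix does not cover all panel strains",
            class = "symbio_data_error")
    K <- unclass(K)[idx, idx]
  }
  stopifnot(nrow(K) == n)

  y_sd <- sd(y)
  ys <- if (standardize) (y - mean(y)) / y_sd else y

  ev <- attr(K, "eigen")
  if (is.null(ev)) ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
  U <- ev$vectors
  d <- pmax(ev$values, 0)

  yr <- as.numeric(crossprod(U, ys))
  one_r <- as.numeric(crossprod(U, rep(1, n)))

  boundary <- FALSE
  if (is.null(lambda)) {
    est <- estimate_lambda(d, matrix(one_r, ncol = 1), yr)
    lambda <- est$lambda
    boundary <- est$boundary
    if (boundary)
      warn("REML variance ratio at grid boundary", class = "symbio_lambda_boundary")
  }
  w <- 1 / (lambda * d + 1)

  X <- impute_genotypes(panel$geno)
  Xr <- crossprod(U, X)                  # rotated genotypes, n x L

  # per-site weighted 2x2 GLS, fully vectorized over sites
  sw <- sum(w * one_r^2)
  swy <- sum(w * one_r * yr)
  syy <- sum(w * yr^2)
  a1x <- as.numeric(crossprod(Xr, w * one_r))
  axx <- as.numeric(crossprod(Xr^2, w))
  bxy <- as.numeric(crossprod(Xr, w * yr))
  det <- sw * axx - a1x^2
  det[det <= 1e-10 * sw * axx] <- NA_real_   # monomorphic / collinear site
  beta <- (sw * bxy - a1x * swy) / det
  alpha <- (axx * swy - a1x * bxy) / det
  rss <- syy - alpha * swy - beta * bxy
  rss[rss < 0] <- 0
  df <- n - 2L
  sigma2 <- rss / df
  se <- sqrt(sigma2 * sw / det)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)

  ss <- site_summary(panel)
  sigma_e2 <- {
    # null-model residual variance at the REML lambda, for reporting
    XtWX <- sum(w * one_r^2); b0 <- sum(w * one_r * yr) / XtWX
    sum(w * (yr - one_r * b0)^2) / (n - 1L)
  }
  out <- tibble(
    site_id = ss$site_id, replicon = ss$replicon, pos = ss$pos,
    trait = trait, host = host, maf = ss$maf, n_strains = n,
    beta = beta, se = se, p_wald = p,
    beta_raw = if (standardize) beta * y_sd else beta,
    se_raw = if (standardize) se * y_sd else se
  )
  attr(out, "lambda") <- lambda
  attr(out, "sigma_e2") <- sigma_e2
  attr(out, "sigma_g2") <- lambda * sigma_e2
  attr(out, "lambda_boundary") <- boundary
  attr(out, "standardized") <- standardize
  class(out) <- c("symbio_assoc", class(out))
  out
}

#' Orchestrate the full set of trait-by-host association scans
#'
#' Runs one mixed-model scan per fitness proxy per host line (the
#' "5 proxies x 2 hosts = 10 runs" layout): the four single-strain proxies
#' enter as rack-corrected EMMs and the multi-strain proxy as the per-strain
#' median log2 fold-change.
#'
#' @param means Stacked EMM tibble from [strain_means_table()].
#' @param panel A filtered [genotype_panel()].
#' @param relative_fitness Optional `per_strain` tibble from
#'   [relative_fitness()].
#' @param K Optional precomputed kinship (defaults to `compute_kinship(panel)`).
#' @return Named list of `symbio_assoc` tibbles keyed `"trait|host"`.
#' @export
gwas_all_runs <- function(means, panel, relative_fitness = NULL, K = NULL) {
  if (is.null(K)) K <- compute_kinship(panel)
  vals <- means %>% select("strain_id", "host", "trait", value = "emmean")
  if (!is.null(relative_fitness)) {
    vals <- bind_rows(vals, relative_fitness %>%
      transmute(strain_id = .data$strain_id, host = .data$host, trait = "relative_fitness",
                value = .data$median_log2_fc))
  }
  combos <- vals %>% distinct(.data$trait, .data$host)
  runs <- purrr::pmap(combos, function(trait, host) {
    v <- vals %>% filter(.data$trait == !!trait, .data$host == !!host)
    y <- setNames(v$value, v$strain_id)
    y <- y[!is.na(y)]
    lmm_association(y, panel, K, trait = trait, host = host)
  })
  names(runs) <- paste(combos$trait, combos$host, sep = "|")
  runs
}
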