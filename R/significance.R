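#' Permutation-based family-wise significance threshold
#'
#' Calibrates a per-run significance threshold by permuting the trait vector
#' across strains (breaking the genotype-phenotype link while preserving the
#' panel's LD and the kinship spectrum), rerunning the mixed-model scan, and
#' recording the maximum `|beta|` (and minimum Wald p) of each permutation.
#' The threshold at level `alpha` is the `ceiling((1 - alpha) * B)`-th order
#' statistic of the null maxima; a variant is declared significant when its
#' observed `|beta|` is at or above the threshold. Both the `|beta|`- and
#' p-based null statistics are recorded so either convention can be audited.
#'
#' @param y Named per-strain trait vector (or tibble with `strain_id`,
#'   `value`).
#' @param panel A filtered [genotype_panel()].
#' @param K Kinship matrix (defaults to `compute_kinship(panel)`).
#' @param B Number of permutations (at least 100).
#' @param alpha Family-wise level in (0, 1).
#' @param seed Integer seed for the permutations.
#' @param refit_lambda Re-estimate the REML variance ratio for every
#'   permuted trait (default `TRUE`); `FALSE` reuses the observed trait's
#'   ratio.
#' @param standardize Passed through to the scan (default `TRUE`).
#' @return A list of class `permutation_null`: `B`, `alpha`, `seed`,
#'   `threshold_beta`, `threshold_p`, `null_max_beta` (length-B vector),
#'   `null_min_p`.
#' @examples
#' cfg <- sim_config(n_strains = 40, n_sites = 200, seed = 8)
#' panel <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(panel, cfg)
#' emm <- estimated_marginal_means(sim$phenotypes, "nodule_weight", "DZA")
#' pn <- permutation_threshold(setNames(emm$emmean, emm$strain_id),
#'                             panel, B = 100, seed = 1)
#' pn$threshold_beta
#' @export
permutation_threshold <- function(y, panel, K = NULL, B = 1000L,
                                  alpha = 0.05, seed = 1L,
                                  refit_lambda = TRUE, standardize = TRUE) {
  B <- as.integer(B)
  if (B < 100L) abort("B must be at least 100", class = "symbio_config_error")
  if (!(alpha > 0 && alpha <= 1))
    abort("alpha must be in (0, 1]", class = "symbio_config_error")
  if (is.data.frame(y)) y <- setNames(y$value, y$strain_id)
  if (!is.null(names(y))) {
    keep <- panel$strains$strain_id %in% names(y)
    if (!all(keep)) panel <- subset_panel(panel, strains = which(keep))
    y <- y[panel$strains$strain_id]
  }
  n <- length(y)
  if (is.null(K)) K <- compute_kinship(panel)
  if (!is.null(rownames(K)) &&
      !identical(rownames(K), panel$strains$strain_id)) {
    idx <- match(panel$strains$strain_id, rownames(K))
    K <- unclass(K)[idx, idx]
  }
  ev <- attr(K, "eigen")
  if (is.null(ev)) ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
  U <- ev$vectors
  d <- pmax(ev$values, 0)

  ys <- if (standardize) (y - mean(y)) / sd(y) else y
  one_r <- as.numeric(crossprod(U, rep(1, n)))
  X <- impute_genotypes(panel$geno)
  Xr <- crossprod(U, X)
  Xr2 <- Xr^2
  Xrt <- t(Xr)

  lambda_obs <- estimate_lambda(d, matrix(one_r, ncol = 1),
                                as.numeric(crossprod(U, ys)))$lambda

  scan_stats <- function(yr, lambda) {
    w <- 1 / (lambda * d + 1)
    sw <- sum(w * one_r^2)
    swy <- sum(w * one_r * yr)
    syy <- sum(w * yr^2)
    a1x <- as.numeric(Xrt %*% (w * one_r))
    axx <- as.numeric(crossprod(Xr2, w))
    bxy <- as.numeric(Xrt %*% (w * yr))
    det <- sw * axx - a1x^2
    det[det <= 1e-10 * sw * axx] <- NA_real_
    beta <- (sw * bxy - a1x * swy) / det
    alpha_hat <- (axx * swy - a1x * bxy) / det
    rss <- pmax(syy - alpha_hat * swy - beta * bxy, 0)
    se <- sqrt(rss / (n - 2L) * sw / det)
    tstat <- abs(beta / se)
    list(max_beta = max(abs(beta), na.rm = TRUE),
         min_p = 2 * pt(-max(tstat, na.rm = TRUE), n - 2L))
  }

  set.seed(seed)
  null_max_beta <- numeric(B)
  null_min_p <- numeric(B)
  for (b in seq_len(B)) {
    yp <- ys[sample.int(n)]
    yr <- as.numeric(crossprod(U, yp))
    lam <- if (refit_lambda)
      estimate_lambda(d, matrix(one_r, ncol = 1), yr)$lambda else lambda_obs
    st <- scan_stats(yr, lam)
    null_max_beta[b] <- st$max_beta
    null_min_p[b] <- st$min_p
  }
  k <- ceiling((1 - alpha) * B)
  structure(list(
    B = B, alpha = alpha, seed = seed,
    threshold_beta = sort(null_max_beta)[max(k, 1L)],
    threshold_p = sort(null_min_p, decreasing = TRUE)[max(k, 1L)],
    null_max_beta = null_max_beta, null_min_p = null_min_p,
    lambda_obs = lambda_obs
  ), class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null> B = ", x$B, ", alpha = ", x$alpha,
      "; |beta| threshold = ", signif(x$threshold_beta, 4),
      ", p threshold = ", signif(x$threshold_p, 4), "\n", sep = "")
  invisible(x)
}

#' Annotate an association scan with permutation significance
#'
#' @param assoc A `symbio_assoc` tibble from [lmm_association()].
#' @param null A `permutation_null` from [permutation_threshold()].
#' @return The association tibble with a logical `significant` column
#'   (`|beta| >= threshold_beta`).
#' @export
annotate_significance <- function(assoc, null) {
  stopifnot(inherits(null, "permutation_null"))
  mutate(assoc, significant = abs(.data$beta) >= null$threshold_beta)
}
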