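#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an association scan
#'
#' @param x A `symbio_assoc` tibble from [lmm_association()].
#' @param ... Unused.
#' @return A plain tibble with one row per site (`term` = site id,
#'   `estimate` = beta, `std.error`, `p.value`, plus the scan metadata
#'   columns).
#' @export
#' @exportS3Method generics::tidy
tidy.symbio_assoc <- function(x, ...) {
  as_tibble(x) %>%
    rename(term = "site_id", estimate = "beta", std.error = "se",
           p.value = "p_wald")
}

#' Scan-level summary of an association run
#'
#' @param x A `symbio_assoc` tibble.
#' @param ... Unused.
#' @return One-row tibble: `trait`, `host`, `n_strains`, `n_sites`,
#'   `lambda` (REML variance ratio), `sigma_g2`, `sigma_e2`,
#'   `lambda_boundary`, `inflation` (median chi-square ratio).
#' @export
#' @exportS3Method generics::glance
glance.symbio_assoc <- function(x, ...) {
  tibble(trait = x$trait[[1]], host = x$host[[1]],
         n_strains = x$n_strains[[1]], n_sites = nrow(x),
         lambda = attr(x, "lambda"), sigma_g2 = attr(x, "sigma_g2"),
         sigma_e2 = attr(x, "sigma_e2"),
         lambda_boundary = isTRUE(attr(x, "lambda_boundary")),
         inflation = inflation_factor(x$p_wald))
}

#' Genomic-control inflation factor
#'
#' Median chi-square statistic of the p-values divided by the median of the
#' 1-df chi-square distribution; 1 for a calibrated scan, > 1 under
#' uncorrected structure confounding.
#'
#' @param p Vector of two-sided p-values.
#' @return The inflation factor (scalar).
#' @export
inflation_factor <- function(p) {
  p <- p[is.finite(p) & p > 0 & p <= 1]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Tidy a permutation null
#'
#' @param x A `permutation_null` from [permutation_threshold()].
#' @param ... Unused.
#' @return Tibble of the per-permutation null maxima.
#' @export
#' @exportS3Method generics::tidy
tidy.permutation_null <- function(x, ...) {
  tibble(permutation = seq_len(x$B), max_abs_beta = x$null_max_beta,
         min_p = x$null_min_p)
}

#' @rdname tidy.permutation_null
#' @export
#' @exportS3Method generics::glance
glance.permutation_null <- function(x, ...) {
  tibble(B = x$B, alpha = x$alpha, seed = x$seed,
         threshold_beta = x$threshold_beta, threshold_p = x$threshold_p)
}

#' Tidy a frequency-reconstruction estimate
#'
#' @param x A `strain_freq_estimate`.
#' @param ... Unused.
#' @return Long tibble: `pool_id`, `strain_id`, `frequency`.
#' @export
#' @exportS3Method generics::tidy
tidy.strain_freq_estimate <- function(x, ...) {
  pid <- if ("pool_id" %in% names(x)) x$pool_id else
    sprintf("pool%02d", seq_len(nrow(x)))
  purrr::map2_dfr(pid, x$f, function(p, f)
    tibble(pool_id = p, strain_id = names(f), frequency = unname(f)))
}

#' @rdname tidy.strain_freq_estimate
#' @export
#' @exportS3Method generics::glance
glance.strain_freq_estimate <- function(x, ...) {
  as_tibble(x) %>% select(-"f")
}
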