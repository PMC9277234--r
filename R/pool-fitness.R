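#' Reconstruct strain frequencies from pooled allele counts
#'
#' Given the known haploid genotypes of the panel, estimates the strain
#' composition of one pooled nodule sample by depth-weighted constrained
#' least squares on the probability simplex:
#' \deqn{\min_{f \ge 0,\ \sum f = 1} \sum_{sites} d_j \left(a_j/d_j - (G^T f)_j\right)^2}
#' where \eqn{d_j} is read depth, \eqn{a_j} the alternate-read count and
#' \eqn{G} the strains-by-sites 0/1 matrix. The problem is convex and solved
#' by projected gradient descent (Euclidean projection onto the simplex,
#' backtracking line search, monotone objective) to a gradient-mapping norm
#' below `tol` or `max_iter` iterations. Sites with any missing genotype in
#' the panel are dropped (and counted), as are panel-monomorphic or
#' low-information sites (panel minor allele frequency below `maf_min`) and
#' zero-depth sites.
#'
#' @param obs Tibble of pool observations for a single pool: `site_id`,
#'   `depth`, `alt_count` (extra columns ignored).
#' @param panel A [genotype_panel()]; sites are matched on `site_id`.
#' @param maf_min Panel minor-allele-frequency cutoff for sites used
#'   (default 0.05).
#' @param tol Convergence tolerance on the gradient-mapping norm.
#' @param max_iter Iteration cap.
#' @param trace If `TRUE`, attach the per-iteration objective values as
#'   attribute `objective_trace` (diagnostic; the objective is monotone
#'   non-increasing).
#' @return A one-row tibble of class `strain_freq_estimate`: `pool_id` (if
#'   present in `obs`), `n_sites_used`, `n_sites_dropped_missing`,
#'   `residual` (weighted mean squared error), `converged`, `iterations`,
#'   and a list-column `f` holding the named frequency vector.
#' @examples
#' cfg <- sim_config(n_strains = 10, n_sites = 200, missing_rate = 0, seed = 5)
#' panel <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(panel, cfg)
#' pl <- simulate_pools(panel, sim$truth, cfg)
#' est <- reconstruct_frequencies(dplyr::filter(pl$pools,
#'   pool_id == "DZA_pool01"), panel)
#' est$residual
#' @export
reconstruct_frequencies <- function(obs, panel, maf_min = 0.05,
                                    tol = 1e-8, max_iter = 10000L,
                                    trace = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  m <- match(obs$site_id, panel$sites$site_id)
  if (anyNA(m))
    abort("pool sites do not align with panel sites", class = "symbio_data_error")
  if (any(obs$alt_count > obs$depth) || any(obs$depth < 0))
    abort("alt_count must lie in [0, depth]", class = "symbio_data_error")

  G <- panel$geno[, m, drop = FALSE]            # strains x sites
  complete <- colSums(is.na(G)) == 0L
  n_missing_dropped <- sum(!complete)
  ss <- site_summary(panel)[m, ]
  informative <- !is.na(ss$maf) & ss$maf >= maf_min
  use <- complete & informative & obs$depth > 0
  if (!any(use))
    abort("no usable sites with positive depth", class = "symbio_no_information")

  Gu <- t(G[, use, drop = FALSE])               # sites x strains
  storage.mode(Gu) <- "double"
  d <- as.numeric(obs$depth[use])
  y <- obs$alt_count[use] / d
  S <- ncol(Gu)

  if (S == 1L) {
    res <- sum(d * (y - Gu[, 1])^2) / sum(d)
    out <- tibble(n_sites_used = sum(use),
                  n_sites_dropped_missing = n_missing_dropped,
                  residual = res, converged = TRUE, iterations = 0L,
                  f = list(setNames(1, panel$strains$strain_id)))
    if ("pool_id" %in% names(obs))
      out <- mutate(out, pool_id = obs$pool_id[[1]], .before = 1)
    class(out) <- c("strain_freq_estimate", class(out))
    return(out)
  }

  # objective 0.5 * sum d (y - G f)^2 ; gradient -G' D (y - G f)
  dG <- d * Gu
  GtDy <- crossprod(dG, y)                       # S vector
  A <- crossprod(Gu, dG)                         # G' D G, S x S
  fobj <- function(f) {
    r <- y - as.numeric(Gu %*% f)
    0.5 * sum(d * r * r)
  }
  grad <- function(f) as.numeric(A %*% f) - as.numeric(GtDy)

  f <- rep(1 / S, S)
  step <- 1 / max(sum(abs(A)) / S, 1e-12)        # conservative initial step
  obj <- fobj(f)
  obj_trace <- if (trace) obj else NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- grad(f)
    repeat {
      f_new <- project_simplex(f - step * g)
      obj_new <- fobj(f_new)
      # sufficient decrease; the objective never increases across iterations
      if (obj_new <= obj + sum(g * (f_new - f)) +
            sum((f_new - f)^2) / (2 * step) + 1e-15) break
      step <- step / 2
      if (step < 1e-18) break
    }
    gmap <- sqrt(sum((f - f_new)^2)) / step
    f <- f_new; obj <- obj_new
    if (trace) obj_trace <- c(obj_trace, obj)
    step <- min(step * 1.5, 1e6)
    if (gmap < tol) { converged <- TRUE; break }
  }

  out <- tibble(n_sites_used = sum(use),
                n_sites_dropped_missing = n_missing_dropped,
                residual = 2 * obj / sum(d), converged = converged,
                iterations = it,
                f = list(setNames(f, panel$strains$strain_id)))
  if ("pool_id" %in% names(obs))
    out <- mutate(out, pool_id = obs$pool_id[[1]], .before = 1)
  if (trace) attr(out, "objective_trace") <- obj_trace
  attr(out, "median_depth") <- median(d)
  class(out) <- c("strain_freq_estimate", class(out))
  out
}

#' Euclidean projection onto the probability simplex
#'
#' @param v Numeric vector.
#' @return The closest point to `v` (in Euclidean norm) with non-negative
#'   entries summing to 1.
#' @export
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Reconstruct frequencies for every pool in a long observation table
#'
#' @param pools Long tibble of pool observations (multiple `pool_id`s).
#' @param panel A [genotype_panel()].
#' @param ... Passed to [reconstruct_frequencies()].
#' @return Row-bound `strain_freq_estimate` tibble, one row per pool,
#'   carrying each pool's `host` when present.
#' @export
reconstruct_all_pools <- function(pools, panel, ...) {
  out <- split(pools, pools$pool_id) |>
    purrr::map(function(d) {
      est <- reconstruct_frequencies(d, panel, ...)
      if ("host" %in% names(d)) est$host <- d$host[[1]]
      est
    }) |>
    bind_rows()
  attr(out, "median_depth") <- median(pools$depth[pools$depth > 0])
  class(out) <- c("strain_freq_estimate", class(out))
  out
}

#' Relative fitness as fold-change in reconstructed strain frequency
#'
#' Converts per-pool final frequency estimates into the multi-strain
#' relative-fitness proxy: per pool,
#' `fold_change = (f_final + pseudo) / (f_initial_mean + pseudo)`, summarised
#' per strain as the median across pools of the same host line. The log2
#' fold-change is also emitted (the scale used as the GWAS trait). A zero
#' final frequency with `pseudo = 0` yields fold-change 0 and a missing
#' log2 value, with a warning.
#'
#' @param estimates `strain_freq_estimate` tibble from
#'   [reconstruct_all_pools()] (or a single estimate), with `host` column.
#' @param initial_mean Named initial mean frequency vector over strains (a
#'   simplex).
#' @param pseudo Pseudo-frequency added to numerator and denominator;
#'   `NULL` (default) uses `1 / (2 * median per-site depth)` via the
#'   `median_depth` attribute when available, else `1e-6`.
#' @return A list of tibbles: `per_pool` (`pool_id`, `host`, `strain_id`,
#'   `f_final`, `fold_change`, `log2_fold_change`) and `per_strain`
#'   (`strain_id`, `host`, `median_fold_change`, `median_log2_fc`,
#'   `n_pools`).
#' @export
relative_fitness <- function(estimates, initial_mean, pseudo = NULL) {
  check_simplex(initial_mean, what = "initial_mean")
  if (is.null(pseudo)) {
    md <- attr(estimates, "median_depth")
    pseudo <- if (!is.null(md)) 1 / (2 * md) else 1e-6
  }
  if (pseudo < 0) abort("pseudo must be >= 0", class = "symbio_config_error")
  if (!"host" %in% names(estimates)) estimates$host <- "pooled"

  per_pool <- purrr::pmap_dfr(
    list(estimates$pool_id, estimates$host, estimates$f),
    function(pid, host, f) {
      f <- f[names(initial_mean)]
      fc <- (f + pseudo) / (initial_mean + pseudo)
      l2 <- ifelse(fc > 0, log2(fc), NA_real_)
      if (any(fc == 0))
        warn("zero final frequency with pseudo = 0: log2 fold-change undefined, recorded as missing",
             class = "symbio_zero_frequency_warning")
      tibble(pool_id = pid, host = host, strain_id = names(initial_mean),
             f_final = unname(f), fold_change = unname(fc),
             log2_fold_change = unname(l2))
    })
  per_strain <- per_pool %>%
    group_by(.data$strain_id, .data$host) %>%
    summarise(median_fold_change = median(.data$fold_change),
              median_log2_fc = median(.data$log2_fold_change, na.rm = TRUE),
              n_pools = dplyr::n(), .groups = "drop")
  list(per_pool = per_pool, per_strain = per_strain)
}
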