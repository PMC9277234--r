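#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_histogram geom_abline labs facet_wrap theme_minimal
#'   scale_colour_manual
#' @export
ggplot2::autoplot

#' Manhattan-style plot of an association scan
#'
#' @param object A `symbio_assoc` tibble.
#' @param threshold Optional `|beta|` significance threshold drawn as a
#'   horizontal line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.symbio_assoc <- function(object, threshold = NULL, ...) {
  df <- as_tibble(object) %>%
    mutate(index = dplyr::row_number())
  p <- ggplot(df, aes(x = .data$index, y = abs(.data$beta),
                      colour = .data$replicon)) +
    geom_point(size = 0.6) +
    labs(x = "site", y = "|allelic effect size|",
         title = paste(object$trait[[1]], "on", object$host[[1]])) +
    theme_minimal()
  if (!is.null(threshold))
    p <- p + geom_hline(yintercept = threshold, linetype = "dashed")
  p
}

#' Effect-size grid for a trait pair (alignment vs conflict quadrants)
#'
#' Scatter of allelic effect sizes for two fitness proxies on one host,
#' highlighting pleiotropic variants (significant for both). Points in the
#' same-sign quadrants represent concordant effects (fitness alignment);
#' opposite-sign quadrants represent discordant effects (conflict).
#'
#' @param assoc_x,assoc_y Annotated association tibbles (with `significant`)
#'   for the two traits on the same host.
#' @return A ggplot.
#' @export
plot_effect_grid <- function(assoc_x, assoc_y) {
  df <- inner_join(
    as_tibble(assoc_x) %>% select("site_id", beta_x = "beta",
                                  sig_x = "significant"),
    as_tibble(assoc_y) %>% select("site_id", beta_y = "beta",
                                  sig_y = "significant"),
    by = "site_id") %>%
    mutate(status = dplyr::case_when(
      .data$sig_x & .data$sig_y ~ "pleiotropic",
      .data$sig_x | .data$sig_y ~ "single-trait",
      TRUE ~ "not significant"))
  ggplot(df, aes(.data$beta_x, .data$beta_y, colour = .data$status)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_vline(xintercept = 0, colour = "grey70") +
    scale_colour_manual(values = c(`pleiotropic` = "black",
                                   `single-trait` = "orange",
                                   `not significant` = "grey80")) +
    labs(x = paste(assoc_x$trait[[1]], "effect size"),
         y = paste(assoc_y$trait[[1]], "effect size")) +
    theme_minimal()
}

#' Null-distribution plot for a category comparison
#'
#' Histogram of resampled null means with the focal category mean as a
#' vertical line (solid when significant at p < 0.1, dashed otherwise).
#'
#' @param object A `category_comparison` row (with `null_distribution`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.category_comparison <- function(object, ...) {
  df <- tibble(null_mean = object$null_distribution[[1]])
  ggplot(df, aes(.data$null_mean)) +
    geom_histogram(bins = 40, fill = "grey80", colour = "grey50") +
    geom_vline(xintercept = object$focal_mean,
               linetype = if (object$significant) "solid" else "dashed",
               colour = "orange", linewidth = 1) +
    labs(x = object$statistic, y = "resampled null count",
         title = sprintf("focal mean %.3f, p = %.3g",
                         object$focal_mean, object$p_value)) +
    theme_minimal()
}

#' Phenotypic correlation scatter for a trait pair
#'
#' @param emms_x,emms_y Per-strain summary tibbles (as in
#'   [pairwise_correlation()]).
#' @param host Host line label.
#' @return A ggplot with the fitted regression line and the Pearson r label.
#' @export
plot_correlation <- function(emms_x, emms_y, host) {
  rep <- pairwise_correlation(emms_x, emms_y, host)
  df <- inner_join(emms_x %>% select("strain_id", x = "emmean"),
                   emms_y %>% select("strain_id", y = "emmean"),
                   by = "strain_id")
  ggplot(df, aes(.data$x, .data$y)) +
    geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "orange") +
    labs(x = rep$trait_x, y = rep$trait_y,
         title = sprintf("%s: r = %.2f %s", host, rep$r, rep$stars)) +
    theme_minimal()
}
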