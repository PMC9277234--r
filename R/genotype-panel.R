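#' Construct a genotype panel
#'
#' A genotype panel holds a haploid biallelic genotype matrix (strains in
#' rows, sites in columns, entries 0/1/`NA`) together with strain and site
#' metadata tibbles. Rhizobia are haploid, so each call is a single allele.
#'
#' @param geno Integer matrix, strains x sites, entries in `{0, 1, NA}`.
#' @param strains Tibble with at least `strain_id`; optionally `subpop`.
#' @param sites Tibble with `site_id`, `replicon`, `pos` (1-based) and
#'   optionally `gene_id`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, strains, sites) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  strains <- as_tibble(strains)
  sites <- as_tibble(sites)
  stopifnot(nrow(geno) == nrow(strains), ncol(geno) == nrow(sites),
            all(c("site_id", "replicon", "pos") %in% names(sites)),
            "strain_id" %in% names(strains))
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    abort("genotypes must be haploid 0/1 or missing", class = "symbio_data_error")
  rownames(geno) <- strains$strain_id
  colnames(geno) <- sites$site_id
  structure(list(geno = geno, strains = strains, sites = sites),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$geno), " strains x ", ncol(x$geno),
      " sites on ", length(unique(x$sites$replicon)), " replicon(s); ",
      sprintf("%.2f%%", 100 * mean(is.na(x$geno))), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

#' Per-site allele summaries of a panel
#'
#' @param panel A [genotype_panel()].
#' @return A tibble with one row per site: `site_id`, `replicon`, `pos`,
#'   alternate-allele frequency `alt_freq`, minor-allele frequency `maf`, and
#'   `missing_frac`, all computed over non-missing calls.
#' @export
site_summary <- function(panel) {
  g <- panel$geno
  nm <- colSums(!is.na(g))
  af <- ifelse(nm > 0, colMeans(g, na.rm = TRUE), NA_real_)
  panel$sites %>%
    mutate(alt_freq = unname(af),
           maf = pmin(.data$alt_freq, 1 - .data$alt_freq),
           missing_frac = unname(colSums(is.na(g)) / nrow(g)))
}

# Subset a panel by site index (logical or integer) and/or strain index.
subset_panel <- function(panel, sites = NULL, strains = NULL) {
  g <- panel$geno
  st <- panel$strains
  si <- panel$sites
  if (!is.null(strains)) {
    g <- g[strains, , drop = FALSE]
    st <- st[strains, , drop = FALSE]
  }
  if (!is.null(sites)) {
    g <- g[, sites, drop = FALSE]
    si <- si[sites, , drop = FALSE]
  }
  genotype_panel(g, st, si)
}

# Mean-impute missing genotypes (association only; raw panel untouched).
impute_genotypes <- function(geno) {
  mu <- colMeans(geno, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(geno))
  if (length(idx)) {
    out <- matrix(as.numeric(geno), nrow(geno), ncol(geno),
                  dimnames = dimnames(geno))
    out[idx] <- mu[((idx - 1L) %/% nrow(geno)) + 1L]
    out
  } else {
    storage.mode(geno) <- "double"
    geno
  }
}
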