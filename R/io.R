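#' Write a genotype panel as a haploid VCF
#'
#' Plain-text VCFv4.2 with one sample column per strain and haploid GT
#' calls (`0`, `1`, or `.` for missing). Deterministic output: no
#' timestamps, fixed column order.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  g <- panel$geno
  s <- panel$sites
  gt <- matrix(as.character(t(g)), nrow = ncol(g))   # sites x strains
  gt[is.na(gt)] <- "."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=symbiopleio",
    paste0("##contig=<ID=", unique(s$replicon), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$strains$strain_id), collapse = "\t"))
  body <- paste(s$replicon, s$pos, s$site_id, "A", "T", ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a haploid VCF into a genotype panel
#'
#' Uses vcfR to parse the file; haploid GT fields (`0`/`1`/`.`) become
#' 0/1/`NA`. Diploid-style calls are rejected.
#'
#' @param path VCF path.
#' @param genes Optional gene tibble (from [read_gff3_genes()]) used to
#'   annotate sites with `gene_id`.
#' @return A [genotype_panel()].
#' @export
read_panel_vcf <- function(path, genes = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("[/|]", gt[!is.na(gt)])))
    abort("expected haploid GT calls", class = "symbio_data_error")
  geno <- t(matrix(suppressWarnings(as.integer(gt)), nrow = nrow(gt),
                   dimnames = dimnames(gt)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sites <- tibble(site_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                   paste0(fix$CHROM, ":", fix$POS), fix$ID),
                  replicon = fix$CHROM, pos = as.integer(fix$POS))
  if (!is.null(genes)) {
    sites$gene_id <- purrr::map2_chr(sites$replicon, sites$pos, function(r, p) {
      hit <- genes$gene_id[genes$replicon == r & genes$start <= p &
                             genes$end >= p]
      if (length(hit)) hit[[1]] else NA_character_
    })
  }
  genotype_panel(geno, tibble(strain_id = rownames(geno)), sites)
}

#' Write gene annotations as GFF3
#'
#' 1-based inclusive intervals, `gene` features only; deterministic output.
#'
#' @param genes Tibble with `gene_id`, `replicon`, `start`, `end`.
#' @param path Output path (`.gff3`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(genes$replicon, "symbiopleio", "gene", genes$start,
                   genes$end, ".", "+", ".",
                   paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' @param path GFF3 path.
#' @return Tibble: `gene_id`, `replicon`, `start`, `end`.
#' @export
read_gff3_genes <- function(path) {
  if (!requireNamespace("ape", quietly = TRUE))
    abort("reading GFF3 requires the ape package")
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", ]
  tibble(gene_id = sub("^ID=([^;]+).*$", "\\1", g$attributes),
         replicon = as.character(g$seqid),
         start = as.integer(g$start), end = as.integer(g$end))
}

# Gene intervals implied by a simulated panel's site tiling: each gene spans
# its first to last site position (1-based, inclusive).
panel_gene_table <- function(panel) {
  panel$sites %>%
    filter(!is.na(.data$gene_id)) %>%
    group_by(gene_id = .data$gene_id, replicon = .data$replicon) %>%
    summarise(start = min(.data$pos), end = max(.data$pos), .groups = "drop") %>%
    arrange(.data$replicon, .data$start)
}

#' Write / read the long phenotype table
#'
#' CSV in long format: `strain_id`, `host`, `rack`, `trait`, `value`.
#' @param phenotypes Long tibble.
#' @param path CSV path.
#' @return `path` / the tibble.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    strain_id = "c", host = "c", rack = "c",
                    trait = "c", value = "d"))
}

#' Write / read pooled allele counts
#'
#' TSV with one row per site per pool: `pool_id`, `host`, `timepoint`,
#' `site_id`, `replicon`, `pos`, `depth`, `alt_count`.
#' @param pools Long tibble of pool observations.
#' @param path TSV path.
#' @return `path` / the tibble.
#' @export
write_pools_tsv <- function(pools, path) {
  readr::write_tsv(pools, path)
  invisible(path)
}

#' @rdname write_pools_tsv
#' @export
read_pools_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Serialize / restore the truth ledger as JSON
#'
#' @param truth A `truth_ledger`.
#' @param path JSON path.
#' @return `path` / the restored `truth_ledger`.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(causal = truth$causal,
              rack_effects = as.list(truth$rack_effects),
              genetic_values = truth$genetic_values,
              fitness = truth$fitness, pools = truth$pools)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    causal = as_tibble(obj$causal),
    rack_effects = unlist(obj$rack_effects),
    genetic_values = as_tibble(obj$genetic_values),
    fitness = as_tibble(obj$fitness),
    pools = if (!is.null(obj$pools)) as_tibble(obj$pools) else NULL
  ), class = "truth_ledger")
}
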