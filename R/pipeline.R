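#' Pipeline run configuration
#'
#' Bundles the simulation block with per-stage analysis parameters and the
#' output directory. Every stochastic stage derives an explicit seed from
#' the simulation seed, and the config is echoed to the run manifest so a
#' run can be reproduced from its outputs alone.
#'
#' @param sim A [sim_config()] (the synthetic study), or `NULL` when inputs
#'   are pre-existing files in `out_dir`.
#' @param out_dir Output directory (created if missing).
#' @param maf_min,miss_max Variant-filter thresholds for
#'   [filter_variants()].
#' @param B,alpha Permutation count and family-wise level for
#'   [permutation_threshold()].
#' @param selection_reps Resampling count for [category_comparison()].
#' @param hosts Host lines to analyse.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), out_dir = tempfile("symbiorun"),
                       maf_min = 0.05, miss_max = 0.2, B = 1000L,
                       alpha = 0.05, selection_reps = 1000L,
                       hosts = c("DZA", "A17")) {
  cfg <- list(sim = sim, out_dir = out_dir, maf_min = maf_min,
              miss_max = miss_max, B = as.integer(B), alpha = alpha,
              selection_reps = as.integer(selection_reps), hosts = hosts)
  class(cfg) <- "run_config"
  cfg
}

run_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

pipeline_log <- function(stage, msg, quiet = FALSE) {
  if (!quiet) message("[", stage, "] ", msg)
}

# ---- stage functions: each reads declared input files, writes output files

#' Pipeline stages
#'
#' Each stage reads its declared input artifacts from the run directory and
#' writes its outputs there, so stages only communicate through files.
#' `run_pipeline()` sequences them with freshness-based skipping.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress progress messages.
#' @return The paths written, invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(cfg, quiet = FALSE) {
  sim <- cfg$sim
  pipeline_log("simulate", "generating synthetic study", quiet)
  panel <- simulate_genotypes(sim)
  ph <- simulate_phenotypes(panel, sim)
  pl <- simulate_pools(panel, ph$truth, sim)
  write_panel_vcf(panel, run_path(cfg, "panel.vcf"))
  write_gff3(panel_gene_table(panel), run_path(cfg, "genes.gff3"))
  write_phenotypes_csv(ph$phenotypes, run_path(cfg, "phenotypes.csv"))
  write_pools_tsv(pl$pools, run_path(cfg, "pools.tsv"))
  readr::write_tsv(pl$initial, run_path(cfg, "initial_frequencies.tsv"))
  write_truth_json(pl$truth, run_path(cfg, "truth.json"))
  yaml::write_yaml(unclass(sim), run_path(cfg, "config.yaml"))
  invisible(run_path(cfg, c("panel.vcf", "genes.gff3", "phenotypes.csv",
                            "pools.tsv", "initial_frequencies.tsv",
                            "truth.json", "config.yaml")))
}

#' @rdname pipeline_stages
#' @export
stage_means <- function(cfg, quiet = FALSE) {
  pipeline_log("means", "estimated marginal means + correlations", quiet)
  ph <- read_phenotypes_csv(run_path(cfg, "phenotypes.csv"))
  means <- strain_means_table(ph)
  readr::write_tsv(means, run_path(cfg, "emms.tsv"))
  rf_path <- run_path(cfg, "relative_fitness.tsv")
  rf <- if (file.exists(rf_path)) readr::read_tsv(rf_path,
                                                  show_col_types = FALSE)
  corr <- correlation_grid(means, relative_fitness = rf)
  readr::write_tsv(corr, run_path(cfg, "correlations.tsv"))
  invisible(run_path(cfg, c("emms.tsv", "correlations.tsv")))
}

#' @rdname pipeline_stages
#' @export
stage_poolfit <- function(cfg, quiet = FALSE) {
  pipeline_log("poolfit", "reconstructing pool frequencies", quiet)
  panel <- read_panel_vcf(run_path(cfg, "panel.vcf"))
  pools <- read_pools_tsv(run_path(cfg, "pools.tsv"))
  init <- readr::read_tsv(run_path(cfg, "initial_frequencies.tsv"),
                          show_col_types = FALSE)
  est <- reconstruct_all_pools(pools, panel)
  freq <- purrr::pmap_dfr(list(est$pool_id, est$host, est$f),
    function(pid, h, f) tibble(pool_id = pid, host = h,
                               strain_id = names(f), frequency = unname(f)))
  readr::write_tsv(freq, run_path(cfg, "pool_frequencies.tsv"))
  rf <- relative_fitness(est, setNames(init$f_init, init$strain_id))
  readr::write_tsv(rf$per_strain, run_path(cfg, "relative_fitness.tsv"))
  readr::write_tsv(rf$per_pool, run_path(cfg, "relative_fitness_per_pool.tsv"))
  diag <- est %>% select("pool_id", "host", "n_sites_used",
                         "n_sites_dropped_missing", "residual", "converged",
                         "iterations")
  readr::write_tsv(diag, run_path(cfg, "reconstruction_diagnostics.tsv"))
  invisible(run_path(cfg, c("pool_frequencies.tsv", "relative_fitness.tsv",
                            "relative_fitness_per_pool.tsv",
                            "reconstruction_diagnostics.tsv")))
}

read_filtered_panel <- function(cfg) {
  genes <- read_gff3_genes(run_path(cfg, "genes.gff3"))
  panel <- read_panel_vcf(run_path(cfg, "panel.vcf"), genes = genes)
  filter_variants(panel, cfg$maf_min, cfg$miss_max)
}

assoc_path <- function(cfg, trait, host)
  run_path(cfg, sprintf("assoc_%s_%s.tsv", trait, host))

#' @rdname pipeline_stages
#' @export
stage_gwas <- function(cfg, quiet = FALSE) {
  pipeline_log("gwas", "mixed-model association scans", quiet)
  panel <- read_filtered_panel(cfg)
  means <- readr::read_tsv(run_path(cfg, "emms.tsv"), show_col_types = FALSE)
  rf <- readr::read_tsv(run_path(cfg, "relative_fitness.tsv"),
                        show_col_types = FALSE)
  runs <- gwas_all_runs(means, panel, relative_fitness = rf)
  paths <- character()
  for (nm in names(runs)) {
    r <- runs[[nm]]
    p <- assoc_path(cfg, r$trait[[1]], r$host[[1]])
    readr::write_tsv(
      mutate(as_tibble(r), lambda_hat = attr(r, "lambda")), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname pipeline_stages
#' @export
stage_permute <- function(cfg, quiet = FALSE) {
  pipeline_log("permute", paste0("permutation thresholds (B = ", cfg$B, ")"),
               quiet)
  panel <- read_filtered_panel(cfg)
  means <- readr::read_tsv(run_path(cfg, "emms.tsv"), show_col_types = FALSE)
  rf <- readr::read_tsv(run_path(cfg, "relative_fitness.tsv"),
                        show_col_types = FALSE)
  vals <- means %>% select("strain_id", "host", "trait", value = "emmean") %>%
    bind_rows(rf %>% transmute(strain_id = .data$strain_id, host = .data$host,
                               trait = "relative_fitness",
                               value = .data$median_log2_fc))
  K <- compute_kinship(panel)
  combos <- vals %>% distinct(.data$trait, .data$host)
  thresholds <- list(); paths <- character()
  for (i in seq_len(nrow(combos))) {
    tr <- combos$trait[i]; h <- combos$host[i]
    v <- vals %>% filter(.data$trait == tr, .data$host == h)
    y <- setNames(v$value, v$strain_id); y <- y[!is.na(y)]
    sd_seed <- stage_seed(cfg$sim$seed, 100L + i)
    pn <- permutation_threshold(y, panel, K, B = cfg$B, alpha = cfg$alpha,
                                seed = sd_seed)
    thresholds[[paste(tr, h, sep = "|")]] <- list(
      trait = tr, host = h, B = pn$B, alpha = pn$alpha, seed = pn$seed,
      threshold_beta = pn$threshold_beta, threshold_p = pn$threshold_p)
    ap <- assoc_path(cfg, tr, h)
    assoc <- readr::read_tsv(ap, show_col_types = FALSE)
    assoc$significant <- abs(assoc$beta) >= pn$threshold_beta
    sp <- run_path(cfg, sprintf("assoc_sig_%s_%s.tsv", tr, h))
    readr::write_tsv(assoc, sp)
    paths <- c(paths, sp)
  }
  jsonlite::write_json(thresholds, run_path(cfg, "thresholds.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(c(run_path(cfg, "thresholds.json"), paths))
}

read_annotated_runs <- function(cfg) {
  files <- list.files(cfg$out_dir, pattern = "^assoc_sig_.*\\.tsv$",
                      full.names = TRUE)
  purrr::map(sort(files), readr::read_tsv, show_col_types = FALSE)
}

#' @rdname pipeline_stages
#' @export
stage_pleiotropy <- function(cfg, quiet = FALSE) {
  pipeline_log("pleiotropy", "classifying pleiotropic variants", quiet)
  runs <- read_annotated_runs(cfg)
  genes <- read_gff3_genes(run_path(cfg, "genes.gff3"))
  sig <- bind_rows(runs)
  pleio <- purrr::map(cfg$hosts, function(h) classify_pleiotropy(sig, h))
  names(pleio) <- cfg$hosts
  records <- bind_rows(purrr::map(pleio, "records"))
  pair_labels <- bind_rows(purrr::map(pleio, "pair_labels"))
  readr::write_tsv(records, run_path(cfg, "pleiotropy_records.tsv"))
  readr::write_tsv(pair_labels, run_path(cfg, "pleiotropy_pair_labels.tsv"))

  summaries <- list()
  for (h in cfg$hosts) {
    pairs <- pair_labels %>% filter(.data$host == h) %>%
      distinct(.data$trait_x, .data$trait_y)
    for (i in seq_len(nrow(pairs)))
      summaries[[paste(h, i)]] <- concordance_summary(
        pleio[[h]], sig, pairs$trait_x[i], pairs$trait_y[i], h)
  }
  readr::write_tsv(bind_rows(summaries), run_path(cfg, "concordance_summary.tsv"))

  ov <- host_overlap(pleio[[cfg$hosts[1]]]$records,
                     pleio[[cfg$hosts[min(2, length(cfg$hosts))]]]$records)
  jsonlite::write_json(list(overall = ov$overall, by_category = ov$by_category),
                       run_path(cfg, "host_overlap.json"),
                       digits = NA, auto_unbox = TRUE)

  sites <- sig %>% distinct(.data$site_id, .data$replicon, .data$pos)
  rollup <- assign_genes(bind_rows(
    pair_labels %>% select("site_id", "host", "label",
                           pair_category = "pair_category")), sites, genes) %>%
    filter(!is.na(.data$gene_id)) %>%
    distinct(.data$gene_id, .data$host, .data$label, .data$pair_category)
  readr::write_tsv(rollup, run_path(cfg, "gene_rollup.tsv"))
  invisible(run_path(cfg, c("pleiotropy_records.tsv",
                            "pleiotropy_pair_labels.tsv",
                            "concordance_summary.tsv", "host_overlap.json",
                            "gene_rollup.tsv")))
}

#' @rdname pipeline_stages
#' @export
stage_selection <- function(cfg, quiet = FALSE) {
  pipeline_log("selection", "gene diversity / neutrality statistics", quiet)
  panel <- read_filtered_panel(cfg)
  genes <- read_gff3_genes(run_path(cfg, "genes.gff3"))
  rollup <- readr::read_tsv(run_path(cfg, "gene_rollup.tsv"),
                            show_col_types = FALSE)
  runs <- read_annotated_runs(cfg)
  sig <- bind_rows(runs) %>% filter(.data$significant)
  sig_sites <- sig %>% distinct(.data$site_id, .data$replicon, .data$pos)
  sig_genes <- assign_genes(sig_sites %>% select("site_id"),
                            sig_sites, genes) %>%
    filter(!is.na(.data$gene_id)) %>% pull(.data$gene_id) %>% unique()

  stats <- gene_stats_table(panel)
  readr::write_tsv(stats, run_path(cfg, "gene_stats.tsv"))

  null_ids <- intersect(sig_genes, stats$gene_id)
  comp <- if (length(null_ids) >= 2 && nrow(rollup) > 0) {
    category_comparison_grid(
      stats, rollup %>% select("gene_id", "label", "pair_category"),
      null_ids, reps = cfg$selection_reps,
      seed = stage_seed(cfg$sim$seed, 211L))
  } else tibble()
  jsonlite::write_json(comp, run_path(cfg, "category_comparison.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(run_path(cfg, c("gene_stats.tsv", "category_comparison.json")))
}

# declared file dependencies of each stage, for freshness-based skipping
PIPELINE_STAGES <- list(
  simulate = list(fn = stage_simulate, inputs = character(),
                  outputs = c("panel.vcf", "genes.gff3", "phenotypes.csv",
                              "pools.tsv", "initial_frequencies.tsv",
                              "truth.json", "config.yaml")),
  poolfit = list(fn = stage_poolfit,
                 inputs = c("panel.vcf", "pools.tsv",
                            "initial_frequencies.tsv"),
                 outputs = c("pool_frequencies.tsv", "relative_fitness.tsv",
                             "relative_fitness_per_pool.tsv",
                             "reconstruction_diagnostics.tsv")),
  means = list(fn = stage_means,
               inputs = c("phenotypes.csv", "relative_fitness.tsv"),
               outputs = c("emms.tsv", "correlations.tsv")),
  gwas = list(fn = stage_gwas,
              inputs = c("panel.vcf", "genes.gff3", "emms.tsv",
                         "relative_fitness.tsv"),
              outputs = NULL),   # computed from cfg at run time
  permute = list(fn = stage_permute,
                 inputs = c("panel.vcf", "genes.gff3", "emms.tsv",
                            "relative_fitness.tsv"),
                 outputs = c("thresholds.json")),
  pleiotropy = list(fn = stage_pleiotropy,
                    inputs = c("genes.gff3", "thresholds.json"),
                    outputs = c("pleiotropy_records.tsv",
                                "pleiotropy_pair_labels.tsv",
                                "concordance_summary.tsv",
                                "host_overlap.json", "gene_rollup.tsv")),
  selection = list(fn = stage_selection,
                   inputs = c("panel.vcf", "genes.gff3", "gene_rollup.tsv"),
                   outputs = c("gene_stats.tsv", "category_comparison.json"))
)

#' Run the full analysis pipeline
#'
#' Executes simulate, poolfit, means, gwas, permute, pleiotropy and
#' selection in dependency order, communicating only through file artifacts
#' in `cfg$out_dir`. A stage is skipped when all its outputs exist and are
#' newer than all its inputs (idempotent re-run). Writes `manifest.json`
#' (config echo, seeds, artifact checksums — deterministic for a fixed
#' config) and `timings.json` (wall-clock per stage).
#'
#' @param cfg A [run_config()].
#' @param force Rerun every stage regardless of freshness.
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(cfg, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$sim))
    abort("run_pipeline currently requires a simulation block",
          class = "symbio_config_error")
  validate_sim_config(cfg$sim)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  timings <- list()
  for (nm in names(PIPELINE_STAGES)) {
    st <- PIPELINE_STAGES[[nm]]
    outs <- if (nm == "gwas") gwas_output_names(cfg) else st$outputs
    out_paths <- run_path(cfg, outs)
    in_paths <- run_path(cfg, st$inputs)
    fresh <- length(outs) > 0 && all(file.exists(out_paths)) &&
      (length(in_paths) == 0 ||
         min(file.mtime(out_paths)) >= max(file.mtime(in_paths)))
    if (!force && fresh) {
      pipeline_log(nm, "outputs up to date, skipping", quiet)
      next
    }
    t0 <- proc.time()[["elapsed"]]
    tryCatch(st$fn(cfg, quiet = quiet), error = function(e) {
      abort(paste0("stage '", nm, "' failed: ", conditionMessage(e)),
            class = "symbio_stage_error", parent = e)
    })
    timings[[nm]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  artifacts <- sort(setdiff(list.files(cfg$out_dir),
                            c("manifest.json", "timings.json")))
  checksums <- as.list(tools::md5sum(file.path(cfg$out_dir, artifacts)))
  names(checksums) <- artifacts
  manifest <- list(
    package = "symbiopleio",
    config = run_config_echo(cfg),
    artifacts = checksums)
  jsonlite::write_json(manifest, run_path(cfg, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(timings, run_path(cfg, "timings.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

gwas_output_names <- function(cfg) {
  traits <- c(SINGLE_STRAIN_TRAITS, "relative_fitness")
  as.character(t(outer(traits, cfg$hosts, function(tr, h)
    sprintf("assoc_%s_%s.tsv", tr, h))))
}

run_config_echo <- function(cfg) {
  list(sim = unclass(cfg$sim), maf_min = cfg$maf_min,
       miss_max = cfg$miss_max, B = cfg$B, alpha = cfg$alpha,
       selection_reps = cfg$selection_reps, hosts = cfg$hosts)
}

#' Rebuild a run configuration from a written manifest
#'
#' @param path Path to a `manifest.json` written by [run_pipeline()].
#' @param out_dir Output directory to attach (defaults to the manifest's
#'   directory).
#' @return A [run_config()] equal (up to `out_dir`) to the one that
#'   produced the manifest.
#' @export
run_config_from_manifest <- function(path, out_dir = dirname(path)) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  simc <- m$config$sim
  sim <- do.call(sim_config, simc[!vapply(simc, is.null, logical(1))])
  run_config(sim = sim, out_dir = out_dir, maf_min = m$config$maf_min,
             miss_max = m$config$miss_max, B = m$config$B,
             alpha = m$config$alpha,
             selection_reps = m$config$selection_reps,
             hosts = m$config$hosts)
}
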