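#' Pipeline configuration
#'
#' Bundles every stage setting of the end-to-end analysis. Defaults are the
#' study's stated settings: curation threshold 1000 reads, family-level
#' collapse, rarefaction to 1110 reads with 10 replicates, grouping
#' variables site/order/family/genus/FFG, 999 permutations, BH q-threshold
#' 0.05, and 4 MCMC chains of 2000 iterations with 1000 warmup. All stage
#' seeds are derived deterministically from the single master seed.
#'
#' @param metadata Path to the metadata TSV.
#' @param counts Path to the count table (TSV or BIOM-style JSON).
#' @param count_format `"tsv"` or `"biom-json"`.
#' @param output_dir Directory for stage artifacts and the report.
#' @param min_reads,collapse_rank,rarefy_depth,rarefy_replicates Curation
#'   and rarefaction settings.
#' @param group_vars Metadata variables tested for group differences.
#' @param n_permutations Permutations for PERMANOVA/PERMDISP.
#' @param q_threshold BH threshold for the indicator screen.
#' @param chains,iterations,warmup MCMC settings per model.
#' @param fixed_factors Models to fit: `"none"` is the intercept-only
#'   variance-partition model; the others fix one factor each.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(metadata, counts, count_format = "tsv",
                            output_dir = tempfile("streamgut_run_"),
                            min_reads = 1000, collapse_rank = "family",
                            rarefy_depth = 1110, rarefy_replicates = 10,
                            group_vars = c("site", "order", "family",
                                           "genus", "ffg"),
                            n_permutations = 999, q_threshold = 0.05,
                            chains = 4, iterations = 2000, warmup = 1000,
                            fixed_factors = c("none", "family", "genus",
                                              "ffg", "site"),
                            seed = 1) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

# deterministic per-stage seed derivation from the master seed
pipeline_seed <- function(seed, stage) {
  offset <- c(rarefy = 1000L, nmds = 2000L, permanova = 3000L,
              permdisp = 4000L, model = 5000L)
  (as.integer(seed) + offset[[stage]]) %% .Machine$integer.max
}

group_labels <- function(metadata, var) {
  if (var == "genus") genus_levels(metadata) else metadata[[var]]
}

#' Run the full analysis pipeline
#'
#' Executes curation, family-level collapse, replicated rarefaction, alpha
#' diversity with Kruskal-Wallis group tests, replicate-averaged
#' Bray-Curtis, NMDS, PERMANOVA and PERMDISP per grouping variable, the
#' Kruskal-Wallis indicator screen with BH control, and the hierarchical
#' Beta regressions (intercept-only plus single-fixed-factor variants) with
#' WAIC comparison, Bayesian R-squared, variance partitioning and
#' convergence diagnostics. Every stage artifact is written under
#' `config$output_dir` and the machine-readable report as `report.json`.
#' The report contains no timestamps, so identical config and seed give an
#' identical report.
#'
#' @param config A [pipeline_config()].
#' @return The report, invisibly, as a list of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  stage <- function(name, expr) {
    message("[streamgut] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  md <- stage("read_metadata", read_metadata(config$metadata))
  tbl <- stage("read_counts",
               read_count_table(config$counts, config$count_format))
  md_summary <- summarize_metadata(md)

  curated <- stage("curate", curate_table(tbl, config$min_reads))
  removal <- attr(curated, "removal")
  fam <- stage("collapse", collapse_to_rank(curated, config$collapse_rank))
  rar <- stage("rarefy", rarefy(fam, depth = config$rarefy_depth,
                                replicates = config$rarefy_replicates,
                                seed = pipeline_seed(config$seed, "rarefy")))
  kept_md <- md[md$sample_id %in% sample_ids(rar$replicates[[1]]), ]

  alpha_reps <- lapply(rar$replicates, alpha_diversity)
  alpha_mean <- aggregate_alpha(alpha_reps)
  alpha_tests <- stage("alpha_tests",
                       alpha_group_tests(alpha_mean, kept_md,
                                         config$group_vars))

  dm_reps <- lapply(rar$replicates, bray_curtis)
  dm <- aggregate_distance(dm_reps)$mean
  ord <- stage("nmds", nmds(dm, k = 2,
                            seed = pipeline_seed(config$seed, "nmds")))

  per_var <- function(fun, seed_stage) {
    res <- list()
    for (v in config$group_vars) {
      g <- group_labels(kept_md, v)[match(rownames(dm), kept_md$sample_id)]
      res[[v]] <- tryCatch(
        suppressWarnings(fun(dm, g,
                             n_permutations = config$n_permutations,
                             seed = pipeline_seed(config$seed, seed_stage))),
        error = function(e) list(error = conditionMessage(e)))
    }
    res
  }
  permanova_res <- stage("permanova", per_var(permanova, "permanova"))
  permdisp_res <- stage("permdisp", per_var(permdisp, "permdisp"))

  ffg_groups <- kept_md$ffg[match(sample_ids(rar$replicates[[1]]),
                                  kept_md$sample_id)]
  indicators <- stage("indicators",
                      indicator_kw(rar$replicates[[1]], ffg_groups,
                                   config$q_threshold))

  obs <- stage("pair_observations", build_pair_observations(dm, kept_md))
  fits <- list()
  for (i in seq_along(config$fixed_factors)) {
    fx <- config$fixed_factors[i]
    fits[[fx]] <- stage(paste0("fit_", fx),
                        sample_posterior(obs, model_spec(fx),
                                         chains = config$chains,
                                         iterations = config$iterations,
                                         warmup = config$warmup,
                                         seed = pipeline_seed(config$seed,
                                                              "model") + i))
  }
  comparison <- stage("compare_models", compare_models(fits, obs))
  diag_tab <- do.call(rbind, lapply(names(fits), function(nm) {
    d <- diagnostics(fits[[nm]])
    d$model <- nm
    d
  }))
  vpart <- if ("none" %in% names(fits)) {
    variance_partition(fits[["none"]])
  } else {
    NULL
  }

  # ---- artifacts -----------------------------------------------------------
  utils::write.table(alpha_mean, out("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(alpha_tests, out("alpha_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_distance_matrix(dm, out("bray_curtis_mean.tsv"))
  utils::write.table(
    data.frame(sample_id = rownames(ord$points), ord$points),
    out("nmds_coordinates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(indicators$tests, out("indicator_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comparison, out("model_comparison.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  strip_perm <- function(r) {
    if (!is.null(r$error)) return(r)
    r$permuted <- NULL
    r$group_sizes <- as.list(r$group_sizes)
    unclass(r)
  }
  report <- list(
    package_version = as.character(utils::packageVersion("streamgut")),
    config = unclass(config),
    metadata_summary = unclass(md_summary),
    curation = removal,
    rarefaction = list(depth = rar$depth,
                       replicates = length(rar$replicates),
                       dropped_samples = rar$dropped_samples),
    alpha_tests = alpha_tests,
    nmds = list(stress = ord$stress, converged = ord$converged),
    permanova = lapply(permanova_res, strip_perm),
    permdisp = lapply(permdisp_res, strip_perm),
    indicators = list(n_tested = nrow(indicators$tests),
                      significant = indicators$significant,
                      q_threshold = indicators$q_threshold),
    model_comparison = comparison,
    variance_partition = if (!is.null(vpart)) {
      list(summary = vpart$summary, pr_largest = as.list(vpart$pr_largest))
    },
    diagnostics = list(max_rhat = max(diag_tab$rhat, na.rm = TRUE),
                       min_ess = min(diag_tab$ess, na.rm = TRUE),
                       all_below_1.1 = all(diag_tab$rhat < 1.1, na.rm = TRUE))
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       force = TRUE)
  report$fits <- fits
  report$distance_matrix <- dm
  class(report) <- "pipeline_report"
  invisible(report)
}

#' Write a complete synthetic input bundle
#'
#' Generates metadata, an ASV count table with taxonomy, and the generator
#' ground truth at one of two scales, and writes them (plus a ready-to-run
#' pipeline YAML config) into a directory. `"paper-like"` mirrors the
#' emulated survey design (10 sites, 41 samples, 5 FFGs); `"small"` is a
#' 12-sample bundle sized for fast end-to-end runs.
#'
#' @param dir Output directory.
#' @param scale `"small"` or `"paper-like"`.
#' @param seed Integer seed.
#' @return Named list of written paths, invisibly.
#' @export
make_fixture <- function(dir, scale = c("small", "paper-like"), seed = 1) {
  scale <- match.arg(scale)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- if (scale == "small") {
    sim_config(n_sites = 3, samples_per_site = 4, n_asvs = 60,
               n_orders = 3, n_families = 6, n_genera = 8, n_ffgs = 3,
               n_taxa_families = 12, depth_log_mean = 8.2,
               depth_log_sd = 0.3, seed = seed)
  } else {
    sim_config(seed = seed)
  }
  md <- generate_metadata(cfg)
  gen <- generate_counts(md, cfg)
  paths <- list(metadata = file.path(dir, "metadata.tsv"),
                counts = file.path(dir, "counts.tsv"),
                taxonomy = file.path(dir, "taxonomy.tsv"),
                truth = file.path(dir, "truth.json"),
                config = file.path(dir, "config.yaml"))
  write_metadata(md, paths$metadata)
  write_count_table(gen$table, paths$counts, format = "tsv")
  write_taxonomy(gen$table$taxonomy, paths$taxonomy)
  jsonlite::write_json(
    list(config = unclass(gen$truth$config),
         depth = gen$truth$depth, baseline = gen$truth$baseline,
         effects = lapply(gen$truth$effects, function(m) {
           list(levels = rownames(m), matrix = m)
         })),
    paths$truth, auto_unbox = TRUE, digits = NA)
  run_cfg <- list(metadata = paths$metadata, counts = paths$counts,
                  output_dir = file.path(dir, "results"), seed = seed)
  if (scale == "small") {
    run_cfg <- c(run_cfg, list(rarefy_depth = 1000, rarefy_replicates = 5,
                               n_permutations = 199, chains = 2,
                               iterations = 500, warmup = 250))
  }
  yaml::write_yaml(run_cfg, paths$config)
  invisible(paths)
}
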