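# Pipeline orchestration: configured, logged, reproducible end-to-end run
# (simulate/load -> preprocess -> contrasts -> concordance -> enrichment ->
# integration) with plain-file handoff between stages.

default_config <- function() {
  list(seed = 1L,
       out_dir = "senemeth_run",
       simulate = NULL,
       input = NULL,
       normalize = TRUE,
       paired = FALSE,
       thresholds = list(delta = 0.20, concordance = 0.15, p = 0.01,
                         detection_alpha = 0.01, max_fail_fraction = 0,
                         present_fraction = 0.5,
                         bins = c(0, 0.25, 0.75, 1)))
}

check_range <- function(errors, value, key, lo, hi, lo_open = TRUE) {
  ok <- is.numeric(value) && length(value) == 1 && is.finite(value) &&
    (if (lo_open) value > lo else value >= lo) && value <= hi
  if (!ok)
    errors <- c(errors, sprintf("%s: must be a number in %s%g, %g]",
                                key, if (lo_open) "(" else "[", lo, hi))
  errors
}

#' Build and range-check a pipeline configuration
#'
#' Merges user settings over the documented defaults and validates every
#' threshold. Unknown keys are rejected (misspelled options must not be
#' silently ignored). Exactly one of `simulate` (simulation parameters for
#' [simulation_params()]) or `input` (paths to `beta`, `design`,
#' `annotation`, `gene_sets`, optionally `expression`, `pyro` files) must
#' be present.
#'
#' @param config named list of settings (see [default_config] fields:
#'   `seed`, `out_dir`, `simulate`, `input`, `normalize`, `paired`,
#'   `thresholds`).
#' @return validated config list of class `pipeline_config`, fully
#'   defaulted; errors list every violation with its key path.
#' @export
pipeline_config <- function(config = list()) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  errors <- if (length(unknown) > 0)
    sprintf("unknown key(s): %s", paste(unknown, collapse = ", "))
  else character(0)
  cfg <- utils::modifyList(base, config[intersect(names(config), names(base))])
  if (!is.null(config$thresholds)) {
    unknown_t <- setdiff(names(config$thresholds), names(base$thresholds))
    if (length(unknown_t) > 0)
      errors <- c(errors, sprintf("thresholds: unknown key(s): %s",
                                  paste(unknown_t, collapse = ", ")))
  }
  th <- cfg$thresholds
  errors <- check_range(errors, th$delta, "thresholds.delta", 0, 1)
  errors <- check_range(errors, th$concordance, "thresholds.concordance", 0, 1)
  if (!is.null(th$p))
    errors <- check_range(errors, th$p, "thresholds.p", 0, 1)
  errors <- check_range(errors, th$detection_alpha,
                        "thresholds.detection_alpha", 0, 1)
  errors <- check_range(errors, th$max_fail_fraction,
                        "thresholds.max_fail_fraction", 0, 1, lo_open = FALSE)
  errors <- check_range(errors, th$present_fraction,
                        "thresholds.present_fraction", 0, 1, lo_open = FALSE)
  if (!is.numeric(th$bins) || length(th$bins) < 2 || any(diff(th$bins) <= 0))
    errors <- c(errors, "thresholds.bins: must be strictly increasing edges")
  if (is.null(cfg$simulate) && is.null(cfg$input))
    errors <- c(errors, "config: provide either 'simulate' or 'input'")
  if (!is.null(cfg$simulate) && !is.null(cfg$input))
    errors <- c(errors, "config: 'simulate' and 'input' are exclusive")
  if (!is.null(cfg$input)) {
    for (k in c("beta", "design", "annotation", "gene_sets")) {
      if (is.null(cfg$input[[k]]))
        errors <- c(errors, sprintf("input.%s: required path missing", k))
    }
  }
  if (!is_count(cfg$seed %||% NA))
    errors <- c(errors, "seed: must be a positive integer")
  if (length(errors) > 0)
    stopf("invalid pipeline configuration:\n  - %s",
          paste(errors, collapse = "\n  - "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration file
#'
#' Reads a JSON configuration file, merges it over the defaults, and
#' range-checks it via [pipeline_config()].
#'
#' @param path JSON file path.
#' @return a validated `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stopf("cannot parse config: %s",
                                            conditionMessage(e)))
  if (length(cfg) == 0) cfg <- list()
  pipeline_config(cfg)
}

#' Write the fully-resolved effective configuration
#'
#' @param config a `pipeline_config`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

pipeline_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Sequences simulate/load, preprocessing, the culture and aging contrasts,
#' cross-contrast concordance, gene-set/band enrichment and
#' methylation-expression integration, writing every stage's tables under
#' `config$out_dir` and returning a run report with the headline numbers.
#' Deterministic for a fixed seed and inputs.
#'
#' @param config a `pipeline_config` (see [pipeline_config()]).
#' @param quiet suppress progress messages.
#' @return a list of class `run_report`: per-stage record counts, DM counts
#'   per direction and contrast, shared-DM count, concordance statistics,
#'   enrichment table sizes, the config echo, package version and
#'   timestamps.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds

  if (!is.null(config$simulate)) {
    pipeline_log(quiet, "stage simulate: generating synthetic study")
    params <- do.call(simulation_params, as.list(config$simulate))
    gen_ann <- generate_annotation(params, config$seed)
    study <- generate_methylation_study(params, config$seed)
    beta_raw <- study$beta
    design <- study$design
    annotation <- gen_ann$annotation
    sets <- gen_ann$gene_sets
    expr <- generate_expression(beta_raw, annotation,
                                slope = params$expression_slope,
                                intercept = params$expression_intercept,
                                noise_sd = params$expression_noise_sd,
                                seed = config$seed)
    dm_islands <- study$truth$cpg_id[
      study$truth$label_culture != "null" &
        !is.na(annotation$island_id[match(study$truth$cpg_id,
                                          annotation$cpg_id)])]
    pyro <- if (length(dm_islands) >= 1) {
      generate_pyro_profiles(beta_raw, annotation,
                             target_cpgs = utils::head(dm_islands, 6),
                             seed = config$seed)
    }
    write_beta_tsv(beta_raw, file.path(out, "beta_raw.tsv"))
    write_design_tsv(design, file.path(out, "design.tsv"))
    write_annotation_tsv(annotation, file.path(out, "annotation.tsv"))
    write_gmt(sets, file.path(out, "gene_sets.gmt"))
    write_truth_tsv(study$truth, file.path(out, "truth.tsv"))
    write_expression_tsv(expr, file.path(out, "expression.tsv"))
    if (!is.null(pyro)) write_pyro_csv(pyro, file.path(out, "pyro.csv"))
  } else {
    pipeline_log(quiet, "stage load: reading inputs")
    beta_raw <- read_beta_tsv(config$input$beta)
    design <- read_design_tsv(config$input$design)
    annotation <- read_annotation_tsv(config$input$annotation)
    sets <- read_gmt(config$input$gene_sets)
    expr <- if (!is.null(config$input$expression))
      read_expression_tsv(config$input$expression)
    pyro <- if (!is.null(config$input$pyro))
      read_pyro_csv(config$input$pyro)
  }

  pipeline_log(quiet, "stage preprocess: %d CpGs x %d samples",
               nrow(beta_raw), ncol(beta_raw))
  n_in <- nrow(beta_raw)
  beta <- if (isTRUE(config$normalize)) quantile_normalize(beta_raw)
          else beta_raw
  n_excluded <- length(attr(beta, "excluded_cpgs") %||% character(0))
  write_beta_tsv(beta, file.path(out, "beta_normalized.tsv"))

  pipeline_log(quiet, "stage diffmeth: culture and aging contrasts")
  res_culture <- classify_dm(
    contrast_stats(beta, design, culture_contrast(paired = config$paired)),
    th$delta, th$p)
  res_aging <- classify_dm(contrast_stats(beta, design, aging_contrast()),
                           th$delta, th$p)
  utils::write.table(res_culture, file.path(out, "contrast_culture.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res_aging, file.path(out, "contrast_aging.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dm_counts <- list(
    culture = c(hyper = sum(res_culture$dm_label == "hyper"),
                hypo = sum(res_culture$dm_label == "hypo")),
    aging = c(hyper = sum(res_aging$dm_label == "hyper"),
              hypo = sum(res_aging$dm_label == "hypo")))
  dm_cpgs <- res_culture$cpg_id[res_culture$dm_label != "unchanged"]
  if (length(dm_cpgs) >= 2) {
    cl <- hierarchical_cluster(beta[dm_cpgs, , drop = FALSE], "cpgs")
    writeLines(cl$labels, file.path(out, "cluster_order_culture_dm.txt"))
  }

  pipeline_log(quiet, "stage concordance")
  joined <- join_contrasts(res_culture, res_aging)
  shared <- select_shared_dm(joined, th$concordance)
  conc <- if (nrow(shared) >= 2) concordance_stats(shared)
  utils::write.table(joined, file.path(out, "joined_deltas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  subgroup <- subgroup_dm_counts(beta, design, culture_contrast(),
                                 delta_threshold = th$delta,
                                 p_threshold = th$p)
  if (!is.null(conc)) {
    jsonlite::write_json(
      list(n_selected = conc$n_selected, pearson_r = conc$pearson_r,
           sign_table = conc$sign_table, chi2 = conc$chi2,
           chi2_p = conc$chi2_p,
           subgroup_counts = as.list(subgroup$counts),
           subgroup_relative_difference_pct =
             subgroup$relative_difference_pct),
      file.path(out, "concordance.json"), auto_unbox = TRUE, digits = NA)
  }

  pipeline_log(quiet, "stage enrichment")
  universe <- unique(annotation$gene_symbol[
    !is.na(annotation$gene_symbol) &
      annotation$cpg_id %in% rownames(beta)])
  bands <- band_sets(annotation)
  enr <- list()
  for (contrast in c("culture", "aging")) {
    res <- if (contrast == "culture") res_culture else res_aging
    for (dir in c("hyper", "hypo")) {
      genes <- genes_from_cpgs(res, annotation, dir)
      genes <- intersect(genes, universe)
      for (coll_name in c("functional", "bands")) {
        coll <- if (coll_name == "functional") sets else bands
        tag <- sprintf("%s_%s_%s", contrast, dir, coll_name)
        if (length(genes) > 0 && length(coll) > 0) {
          enr[[tag]] <- overrepresentation(genes, coll, universe,
                                           direction = tag)
          utils::write.table(enr[[tag]],
                             file.path(out, sprintf("enrichment_%s.tsv", tag)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
  }

  integration <- NULL
  if (!is.null(expr)) {
    pipeline_log(quiet, "stage integration")
    kept <- present_filter(expr, th$present_fraction)
    mapping <- match_by_symbol(annotation, expr, probes = kept)
    integration <- list(n_probes_present = length(kept),
                        n_linked_cpgs = nrow(mapping$cpg_gene))
    if (nrow(mapping$cpg_gene) > 0) {
      bins <- methylation_expression_summary(beta, mapping, th$bins)
      utils::write.table(bins, file.path(out, "expression_by_methylation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ge <- mapping$gene_expression
      early <- design$sample_id[design$passage_group == "early"]
      late <- design$sample_id[design$passage_group == "late"]
      early <- intersect(early, colnames(ge))
      late <- intersect(late, colnames(ge))
      if (length(early) > 0 && length(late) > 0) {
        ratio <- rowMeans(ge[, late, drop = FALSE]) -
          rowMeans(ge[, early, drop = FALSE])
        dve <- delta_vs_expression(res_culture, ratio, mapping)
        utils::write.table(dve$pairs,
                           file.path(out, "delta_vs_expression_culture.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        integration$delta_expression_correlation <- dve$correlation
      }
      integration$bins <- bins
    }
    if (!is.null(pyro)) {
      plat <- compare_platforms(beta, pyro, design, culture_contrast())
      utils::write.table(plat$per_cpg, file.path(out, "platforms.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      integration$platform_delta_correlation <- plat$delta_correlation
      integration$platform_offset <- mean(plat$per_cpg$offset)
    }
  }

  report <- list(
    package_version = as.character(utils::packageVersion("senemeth")),
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    config = unclass(config),
    counts = list(cpgs_in = n_in,
                  cpgs_excluded_normalization = n_excluded,
                  cpgs_tested = nrow(beta),
                  dm = dm_counts,
                  n_shared_selected = nrow(shared),
                  enrichment_tables = lengths(lapply(enr, nrow))),
    concordance = if (!is.null(conc))
      list(pearson_r = conc$pearson_r, chi2 = conc$chi2,
           chi2_p = conc$chi2_p),
    subgroup = list(counts = as.list(subgroup$counts),
                    relative_difference_pct =
                      subgroup$relative_difference_pct),
    integration = integration)
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  pipeline_log(quiet, "pipeline finished: %d CpGs tested, DM culture %d/%d, aging %d/%d",
               nrow(beta), dm_counts$culture["hyper"],
               dm_counts$culture["hypo"], dm_counts$aging["hyper"],
               dm_counts$aging["hypo"])
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  cat(sprintf("  CpGs tested: %d (of %d)\n", x$counts$cpgs_tested,
              x$counts$cpgs_in))
  cat(sprintf("  DM culture: %d hyper / %d hypo\n",
              x$counts$dm$culture["hyper"], x$counts$dm$culture["hypo"]))
  cat(sprintf("  DM aging:   %d hyper / %d hypo\n",
              x$counts$dm$aging["hyper"], x$counts$dm$aging["hypo"]))
  cat(sprintf("  shared DM selected: %d\n", x$counts$n_shared_selected))
  if (!is.null(x$concordance))
    cat(sprintf("  concordance: R = %.3f, chi2 = %.2f (p = %.3g)\n",
                x$concordance$pearson_r, x$concordance$chi2,
                x$concordance$chi2_p))
  invisible(x)
}
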