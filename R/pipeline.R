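#' End-to-end run configuration
#'
#' Exactly one of `input_dir` (persisted cohort: three matrices, clinical
#' table, annotation TSV, as written by [write_cohort()] /
#' [write_annotations()]) or `synthetic` (a [synthetic_config()]) must be
#' supplied. Can also be loaded from a YAML file via `config_path`.
#'
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param input_dir directory of persisted inputs, or `NULL`.
#' @param preprocess a [preprocess_config()].
#' @param scheme a [split_scheme()] (its `base_seed` is overridden by
#'   `seed`).
#' @param grid an [rf_grid()] or `NULL` for the default grid.
#' @param panel_sizes candidate panel sizes.
#' @param bootstrap_B bootstrap replicates.
#' @param permutation_P label permutations.
#' @param alpha FDR significance level used throughout.
#' @param n_pathways pathways in the synthetic annotation database.
#' @param seed global seed; stage seeds are derived from it by fixed
#'   offsets.
#' @param outdir output directory, or `NULL` to skip persistence.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(), input_dir = NULL,
                       preprocess = preprocess_config(),
                       scheme = split_scheme(), grid = NULL,
                       panel_sizes = 1:10, bootstrap_B = 1000L,
                       permutation_P = 1000L, alpha = 0.05,
                       n_pathways = 40L, seed = 1L, outdir = NULL) {
  if (!is.null(synthetic) && !is.null(input_dir))
    stopf("supply exactly one of `synthetic` and `input_dir`")
  if (is.null(synthetic) && is.null(input_dir))
    stopf("supply one of `synthetic` and `input_dir`")
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 preprocess = preprocess, scheme = scheme, grid = grid,
                 panel_sizes = panel_sizes, bootstrap_B = as.integer(bootstrap_B),
                 permutation_P = as.integer(permutation_P), alpha = alpha,
                 n_pathways = as.integer(n_pathways), seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized top-level keys mirror the [run_config()] arguments; the
#' `synthetic` and `preprocess` blocks hold the corresponding
#' constructors' arguments.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's value.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic) && !is.null(y$input_dir))
    stopf("config may not contain both `synthetic` and `input_dir`")
  syn <- if (!is.null(y$synthetic)) do.call(synthetic_config, y$synthetic)
         else if (is.null(y$input_dir)) synthetic_config() else NULL
  pp <- if (!is.null(y$preprocess)) do.call(preprocess_config, y$preprocess)
        else preprocess_config()
  sch <- if (!is.null(y$scheme)) do.call(split_scheme, y$scheme) else split_scheme()
  run_config(synthetic = syn, input_dir = y$input_dir, preprocess = pp,
             scheme = sch,
             panel_sizes = y$panel_sizes %||% 1:10,
             bootstrap_B = y$bootstrap_B %||% 1000L,
             permutation_P = y$permutation_P %||% 1000L,
             alpha = y$alpha %||% 0.05,
             n_pathways = y$n_pathways %||% 40L,
             seed = seed %||% y$seed %||% 1L,
             outdir = y$outdir)
}

load_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- derive_seed(config$seed, 1L)
    cohort <- generate_cohort(syn)
    universe <- cohort$datasets |>
      lapply(function(d) d$metabolite_meta$kegg_id) |>
      unlist(use.names = FALSE)
    universe <- unique(universe[!is.na(universe)])
    planted <- unique(cohort$truth$effect_kegg_ids)
    cohort$annotations <- generate_pathway_db(config$n_pathways, universe,
                                              planted,
                                              seed = derive_seed(config$seed, 2L))
    cohort
  } else {
    dsets <- c("polar", "nonpolar_pos", "nonpolar_neg")
    datasets <- lapply(stats::setNames(dsets, dsets), function(d)
      read_abundance_matrix(file.path(config$input_dir, d)))
    list(datasets = datasets,
         clinical = utils::read.delim(file.path(config$input_dir, "clinical.tsv")),
         annotations = load_annotations(file.path(config$input_dir,
                                                  "annotations.tsv")),
         truth = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, per-dataset preprocessing, dataset merging,
#' per-metabolite logistic association with BH-FDR, random forest panel
#' discovery on the significant metabolites, clinical and integrated
#' model comparison, pathway enrichment of the significant metabolites,
#' and a permutation test of the final panel. Rerunning with the same
#' configuration and seed reproduces every number.
#'
#' @param config a [run_config()].
#' @return A `run_report` list: `ledger`, `associations`, `significant`,
#'   `panel` (discovery result), `models` (comparison table), `tableone`,
#'   `enrichment`, `permutation`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_inputs(config)

  pre <- lapply(inputs$datasets, preprocess_dataset, config = config$preprocess)
  ledger <- do.call(rbind, lapply(names(pre), function(d)
    cbind(dataset = d, pre[[d]]$ledger)))
  merged <- merge_datasets(lapply(pre, `[[`, "matrix"))

  labels <- merged$sample_meta$label
  assoc <- fit_metabolite_logistic(merged, labels)
  sig <- assoc$metabolite[!is.na(assoc$fdr_p) & assoc$fdr_p < config$alpha]
  screen <- sig
  if (length(screen) < 2L) {
    ## degenerate screen: fall back to the top metabolites by p value so
    ## downstream stages remain runnable (logged; significant set still
    ## reported as-is)
    ord <- order(assoc$p_value)
    screen <- assoc$metabolite[ord][seq_len(min(10L, nrow(assoc)))]
    log_msg("screen: < 2 significant metabolites; using top %d by p value",
            length(screen))
  }

  X <- merged$values[, screen, drop = FALSE]
  scheme <- config$scheme
  scheme$base_seed <- derive_seed(config$seed, 3L)
  panel <- discover_panels(X, labels, scheme = scheme, grid = config$grid,
                           sizes = config$panel_sizes[config$panel_sizes <= ncol(X)],
                           B = config$bootstrap_B)

  specs <- list(spec_1a(), spec_1b(), spec_1c(panel$final$members))
  models <- compare_models(specs, inputs$clinical, merged)
  tab1 <- summarize_tableone(inputs$clinical)

  ids <- merged$metabolite_meta
  input_ids <- ids$kegg_id[ids$metabolite %in% sig & !is.na(ids$kegg_id)]
  universe <- unique(c(ids$kegg_id[!is.na(ids$kegg_id)],
                       unlist(inputs$annotations$compounds, use.names = FALSE)))
  enr <- if (length(input_ids) >= 1L)
    fisher_enrichment(input_ids, universe, inputs$annotations, config$alpha)
  else NULL

  perm <- permutation_test(X[, panel$final$members, drop = FALSE], labels,
                           cv_auc_metric(folds = 5L, model = "rf",
                                         seed = derive_seed(config$seed, 4L)),
                           P = config$permutation_P,
                           seed = derive_seed(config$seed, 5L))

  report <- list(ledger = ledger, associations = assoc, significant = sig,
                 panel = panel, models = models$table, model_fits = models$fits,
                 tableone = tab1, enrichment = enr, permutation = perm,
                 truth = inputs$truth,
                 provenance = list(seed = config$seed,
                                   alpha = config$alpha,
                                   bootstrap_B = config$bootstrap_B,
                                   permutation_P = config$permutation_P))
  class(report) <- "run_report"
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  significant metabolites: %d\n", length(x$significant)))
  cat(sprintf("  final panel (%d): %s\n", x$panel$final$size,
              paste(x$panel$final$members, collapse = ", ")))
  cat(sprintf("  test AUC %.3f | bootstrap AUC %.3f (SD %.3f) | panel logistic AUC %.3f\n",
              x$panel$final$test_auc_mean, x$panel$final$boot_auc_mean,
              x$panel$final$boot_auc_sd, x$panel$panel_roc$auc))
  cat(sprintf("  permutation p = %.4g\n", x$permutation$p_value))
  invisible(x)
}

write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  utils::write.table(report$associations, file.path(outdir, "associations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cand <- report$panel$candidates
  cand$members <- vapply(cand$members, paste, "", collapse = ";")
  cand$iterations <- vapply(cand$iterations, paste, "", collapse = ";")
  utils::write.table(cand, file.path(outdir, "panel_candidates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$models, file.path(outdir, "model_comparison.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$tableone, file.path(outdir, "tableone.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$enrichment))
    utils::write.table(report$enrichment, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(c("# permutation null metric values",
               format(report$permutation$null, digits = 10)),
             file.path(outdir, "permutation_null.txt"))
  summary <- list(seed = report$provenance$seed,
                  n_significant = length(report$significant),
                  final_panel = report$panel$final$members,
                  bootstrap_auc_mean = report$panel$final$boot_auc_mean,
                  bootstrap_auc_sd = report$panel$final$boot_auc_sd,
                  test_auc_mean = report$panel$final$test_auc_mean,
                  panel_logistic_auc = report$panel$panel_roc$auc,
                  permutation_p = report$permutation$p_value)
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
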