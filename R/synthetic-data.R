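#' Configuration for the synthetic nested case-control cohort
#'
#' Defaults emulate the study conditions of a 50-case / 50-control nested
#' first-trimester cohort profiled in three LC-MS acquisitions (polar,
#' non-polar positive mode, non-polar negative mode; 651 metabolites in
#' total), with pooled-QC injections, batch structure, limit-of-detection
#' (left-censoring) plus completely-at-random missingness, and a set of
#' metabolites carrying a true case-control shift on the log scale.
#'
#' @param n_cases,n_controls biological sample counts per arm.
#' @param n_metabolites named integer vector: metabolites per dataset
#'   (`polar`, `nonpolar_pos`, `nonpolar_neg`).
#' @param n_batches number of acquisition batches; samples are assigned
#'   round-robin so batches are balanced with respect to the label.
#' @param n_qc_injections pooled-QC injections per dataset.
#' @param effect_set_size number of metabolites with a true case-control
#'   shift; `strong_subset_size` of them form the planted "panel" with shift
#'   `strong_shift` (in units of the metabolite's log-scale SD); the rest
#'   draw shifts uniformly from `effect_log_mean_shift`.
#' @param strong_subset_size size of the planted strong panel.
#' @param effect_log_mean_shift length-2 range of standardized shift
#'   magnitudes for non-strong effect metabolites.
#' @param strong_shift standardized shift of the strong panel metabolites.
#' @param batch_additive_sd,batch_scale_sd SDs of the per-batch,
#'   per-metabolite additive offsets and log multiplicative scale
#'   distortions on the log-abundance scale.
#' @param mcar_rate completely-at-random missingness fraction.
#' @param mnar_quantile left-censoring quantile: values below this quantile
#'   of each metabolite's biological distribution are set missing
#'   (limit-of-detection dropout).
#' @param tech_cv_range range of per-metabolite technical CVs for QC rows;
#'   the default straddles the 20% RSD filter threshold.
#' @param clinical_params list of per-arm moments for the clinical table;
#'   see [default_clinical_params()].
#' @param seed integer seed; identical config + seed gives identical output.
#'
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_cases = 50L, n_controls = 50L,
                             n_metabolites = c(polar = 151L, nonpolar_pos = 300L,
                                               nonpolar_neg = 200L),
                             n_batches = 3L, n_qc_injections = 10L,
                             effect_set_size = 49L, strong_subset_size = 8L,
                             effect_log_mean_shift = c(0.4, 1.1),
                             strong_shift = 1.0,
                             batch_additive_sd = 0.3, batch_scale_sd = 0.1,
                             mcar_rate = 0.02, mnar_quantile = 0.05,
                             tech_cv_range = c(0.05, 0.40),
                             clinical_params = default_clinical_params(),
                             seed = 1L) {
  n_cases <- assert_count(n_cases, "n_cases")
  n_controls <- assert_count(n_controls, "n_controls")
  n_batches <- assert_count(n_batches, "n_batches")
  n_qc_injections <- assert_count(n_qc_injections, "n_qc_injections")
  assert_fraction(mcar_rate, "mcar_rate")
  assert_fraction(mnar_quantile, "mnar_quantile")
  if (length(n_metabolites) != 3L || is.null(names(n_metabolites)))
    stopf("`n_metabolites` must be a named length-3 vector")
  if (any(n_metabolites < 1)) stopf("metabolite counts must be positive")
  p_total <- sum(n_metabolites)
  if (effect_set_size > p_total)
    stopf("effect_set_size (%d) exceeds total metabolite count (%d)",
          effect_set_size, p_total)
  if (strong_subset_size > effect_set_size)
    stopf("strong_subset_size must not exceed effect_set_size")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_metabolites = n_metabolites, n_batches = n_batches,
                 n_qc_injections = n_qc_injections,
                 effect_set_size = as.integer(effect_set_size),
                 strong_subset_size = as.integer(strong_subset_size),
                 effect_log_mean_shift = effect_log_mean_shift,
                 strong_shift = strong_shift,
                 batch_additive_sd = batch_additive_sd,
                 batch_scale_sd = batch_scale_sd,
                 mcar_rate = mcar_rate, mnar_quantile = mnar_quantile,
                 tech_cv_range = tech_cv_range,
                 clinical_params = clinical_params,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default clinical covariate moments for the synthetic cohort
#'
#' Per-arm means/SDs and proportions for the clinical table: maternal age,
#' gestational age at inclusion, pre-pregnancy weight and BMI, waist
#' circumference, blood pressures, fasting glucose and venous HbA1c in
#' early pregnancy, OGTT glucose values and follow-up HbA1c at the
#' diagnostic visit, family history of type 2 diabetes, socioeconomic
#' class and nulliparity. Each element is `c(control, case)` for means or
#' proportions, with a matching `*_sd` entry for continuous variables.
#'
#' @return Named list of calibration moments.
#' @export
default_clinical_params <- function() {
  list(
    age = c(26, 27), age_sd = c(2.4, 2.6),
    gest_age = c(10, 10.5), gest_age_sd = c(3.1, 3.1),
    weight = c(55.3, 56.4), weight_sd = c(7.6, 8.6),
    bmi = c(22.8, 23.8), bmi_sd = c(2.1, 2.9),
    waist = c(82, 85), waist_sd = c(7.5, 8.2),
    sbp = c(101, 104), sbp_sd = c(10.4, 10),
    dbp = c(66, 68), dbp_sd = c(8, 7.5),
    fpg = c(83, 83), fpg_sd = c(5.2, 3.9),
    hba1c = c(5.02, 5.02), hba1c_sd = c(0.3, 0.3),
    ogtt_fasting = c(80.5, 85), ogtt_fasting_sd = c(5.7, 6.5),
    ogtt_1h = c(129, 179), ogtt_1h_sd = c(23.3, 28.7),
    ogtt_2h = c(112, 148), ogtt_2h_sd = c(16.8, 28.6),
    hba1c_followup = c(4.76, 4.92), hba1c_followup_sd = c(0.3, 0.3),
    family_history = c(0.40, 0.54),
    ses_lower = c(0.08, 0.20), ses_middle = c(0.64, 0.56),
    nulliparous = c(1.00, 0.68)
  )
}

lipid_classes <- c("PC", "PE", "PS", "PG", "SM", "TAG", "DAG", "LPC", "HexCer")
polar_stems <- c("Serine", "Glycine", "Alanine", "Leucine", "Valine", "Proline",
                 "Threonine", "Glutamate", "Citrate", "Lactate", "Pyruvate",
                 "Pantothenic_acid", "Choline", "Betaine", "Carnitine",
                 "Creatinine", "Uric_acid", "Hypoxanthine", "Taurine", "Urea")

make_metabolite_meta <- function(dataset, p, id_offset) {
  idx <- id_offset + seq_len(p)           # globally unique name index
  if (dataset == "polar") {
    nm <- paste0(rep_len(polar_stems, p), "_", idx)
    cls <- rep("polar metabolite", p)
  } else {
    cls <- sample(lipid_classes, p, replace = TRUE)
    c1 <- sample(c(14, 16, 18, 20, 22), p, replace = TRUE)
    d1 <- sample(0:3, p, replace = TRUE)
    c2 <- sample(c(14, 16, 18, 20, 22), p, replace = TRUE)
    d2 <- sample(0:6, p, replace = TRUE)
    nm <- sprintf("%s(%d:%d/%d:%d)_%d", cls, c1, d1, c2, d2, idx)
  }
  ## ~70% of metabolites carry a (synthetic) KEGG-style compound ID
  has_id <- stats::runif(p) < 0.7
  kegg <- ifelse(has_id, sprintf("C%05d", id_offset + seq_len(p)), NA_character_)
  data.frame(metabolite = nm, dataset = dataset, class = cls,
             kegg_id = kegg, stringsAsFactors = FALSE)
}

#' Generate a synthetic nested case-control metabolomics cohort
#'
#' Produces three [abundance_matrix] objects (one per acquisition dataset),
#' a clinical table, and a ground-truth list for recovery testing.
#' Abundances are log-normal per metabolite; case-control effects are
#' additive on the log scale in units of the metabolite's log-SD; batches
#' add per-batch/per-metabolite location and scale distortions; biological
#' values below each metabolite's `mnar_quantile` are censored to missing
#' and the remainder is thinned completely at random at `mcar_rate`.
#' Pooled-QC rows are the pooled mean of the biological samples perturbed
#' with a per-metabolite technical CV drawn from `tech_cv_range`.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `datasets` (named list of three
#'   `abundance_matrix`), `clinical` (data.frame), and `truth` (list with
#'   `effect_metabolites`, `strong_metabolites`, `true_log_shift`,
#'   `true_tech_cv`, `true_batch_offsets`, `clinical_effects`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_bio <- config$n_cases + config$n_controls
  ## interleave arms so round-robin batch assignment is label-balanced
  label <- c(rep(c(1L, 0L), min(config$n_cases, config$n_controls)),
             rep(1L, max(0L, config$n_cases - config$n_controls)),
             rep(0L, max(0L, config$n_controls - config$n_cases)))
  sample_id <- sprintf("S%03d", seq_len(n_bio))
  batch_id <- sprintf("B%d", ((seq_len(n_bio) - 1L) %% config$n_batches) + 1L)

  p_each <- config$n_metabolites
  metab_meta <- list()
  offset <- 0L
  for (d in names(p_each)) {
    metab_meta[[d]] <- make_metabolite_meta(d, p_each[[d]], offset)
    offset <- offset + as.integer(p_each[[d]])
  }
  all_names <- unlist(lapply(metab_meta, `[[`, "metabolite"), use.names = FALSE)
  p_total <- length(all_names)

  effect_idx <- sample.int(p_total, config$effect_set_size)
  strong_idx <- effect_idx[seq_len(config$strong_subset_size)]
  shift <- numeric(p_total)
  shift[effect_idx] <- stats::runif(config$effect_set_size,
                                    config$effect_log_mean_shift[1],
                                    config$effect_log_mean_shift[2])
  shift[strong_idx] <- config$strong_shift
  ## effect metabolites always carry a compound ID so pathway recovery has
  ## a well-defined planted set
  meta_all <- do.call(rbind, metab_meta)
  meta_all$kegg_id[effect_idx] <- sprintf("C%05d", 90000L + seq_along(effect_idx))

  datasets <- list()
  col_at <- 0L
  truth_cv <- stats::setNames(numeric(p_total), all_names)
  batch_offsets <- list()
  for (d in names(p_each)) {
    p <- as.integer(p_each[[d]])
    cols <- col_at + seq_len(p)
    mu <- stats::runif(p, log(1e4), log(1e6))
    sdlog <- stats::runif(p, 0.3, 0.8)
    beta <- shift[cols]                       # standardized log-scale shift
    gamma <- matrix(stats::rnorm(config$n_batches * p, 0, config$batch_additive_sd),
                    config$n_batches, p)
    ldelta <- matrix(stats::rnorm(config$n_batches * p, 0, config$batch_scale_sd),
                     config$n_batches, p)
    bidx <- ((seq_len(n_bio) - 1L) %% config$n_batches) + 1L
    eps <- matrix(stats::rnorm(n_bio * p), n_bio, p)
    lx <- sweep(eps * exp(ldelta[bidx, , drop = FALSE]), 2, sdlog, `*`)
    lx <- sweep(lx, 2, mu, `+`) + gamma[bidx, , drop = FALSE] +
      outer(label, beta * sdlog)
    x <- exp(lx)

    ## pooled-QC injections: pooled mean perturbed with technical CV
    cv <- stats::runif(p, config$tech_cv_range[1], config$tech_cv_range[2])
    truth_cv[cols] <- cv
    pool <- colMeans(x)
    slog <- sqrt(log(1 + cv^2))
    zq <- matrix(stats::rnorm(config$n_qc_injections * p), config$n_qc_injections, p)
    qc <- sweep(exp(sweep(sweep(zq, 2, slog, `*`), 2, slog^2 / 2, `-`)), 2, pool, `*`)

    ## MNAR left-censoring below the per-metabolite quantile, then MCAR
    thr <- apply(x, 2, stats::quantile, probs = config$mnar_quantile)
    x[sweep(x, 2, thr, `<`)] <- NA
    x[!is.na(x) & matrix(stats::runif(n_bio * p) < config$mcar_rate, n_bio, p)] <- NA

    vals <- rbind(x, qc)
    colnames(vals) <- metab_meta[[d]]$metabolite
    smeta <- data.frame(
      sample_id = c(sample_id, sprintf("QC_%s_%02d", d, seq_len(config$n_qc_injections))),
      batch_id = c(batch_id, sprintf("B%d", ((seq_len(config$n_qc_injections) - 1L) %%
                                               config$n_batches) + 1L)),
      is_qc = c(rep(FALSE, n_bio), rep(TRUE, config$n_qc_injections)),
      label = c(label, rep(NA_integer_, config$n_qc_injections)),
      stringsAsFactors = FALSE)
    mm <- meta_all[cols, , drop = FALSE]
    rownames(mm) <- NULL
    datasets[[d]] <- abundance_matrix(vals, smeta, mm)
    batch_offsets[[d]] <- gamma
    col_at <- col_at + p
  }

  clinical <- generate_clinical(sample_id, label, config$clinical_params)
  truth <- list(
    effect_metabolites = all_names[effect_idx],
    strong_metabolites = all_names[strong_idx],
    true_log_shift = stats::setNames(shift[effect_idx], all_names[effect_idx]),
    effect_kegg_ids = meta_all$kegg_id[effect_idx],
    true_tech_cv = truth_cv,
    true_batch_offsets = batch_offsets,
    clinical_effects = list(family_history = config$clinical_params$family_history)
  )
  list(datasets = datasets, clinical = clinical, truth = truth)
}

generate_clinical <- function(sample_id, label, cp) {
  n <- length(label)
  arm <- label + 1L                 # 1 = control, 2 = case
  rnorm2 <- function(m, s) stats::rnorm(n, m[arm], s[arm])
  rbin2 <- function(p) as.integer(stats::runif(n) < p[arm])
  ## group-matched variables: cases reuse the control draws (permuted and
  ## rescaled to the case arm's moments), so the realized group difference
  ## equals the configured mean difference without sampling noise --
  ## emulating the matched case-control selection of the study design
  rmatched <- function(m, s) {
    x <- numeric(n)
    ctrl <- label == 0L
    x[ctrl] <- stats::rnorm(sum(ctrl), m[1], s[1])
    src <- sample(x[ctrl], sum(!ctrl), replace = sum(!ctrl) > sum(ctrl))
    z <- (src - mean(src)) / max(stats::sd(src), 1e-8)
    x[!ctrl] <- m[2] + s[2] * z
    x
  }
  weight <- rnorm2(cp$weight, cp$weight_sd)
  bmi <- rmatched(cp$bmi, cp$bmi_sd)
  height_cm <- sqrt(weight / pmax(bmi, 10)) * 100
  waist <- rnorm2(cp$waist, cp$waist_sd)
  u <- stats::runif(n)
  ses <- ifelse(u < cp$ses_lower[arm], "lower",
                ifelse(u < cp$ses_lower[arm] + cp$ses_middle[arm], "middle", "upper"))
  data.frame(
    sample_id = sample_id,
    age = rmatched(cp$age, cp$age_sd),
    gest_age = rnorm2(cp$gest_age, cp$gest_age_sd),
    weight = weight, bmi = bmi,
    waist = waist, whtr = waist / height_cm,
    sbp = rnorm2(cp$sbp, cp$sbp_sd), dbp = rnorm2(cp$dbp, cp$dbp_sd),
    fpg = rnorm2(cp$fpg, cp$fpg_sd),
    hba1c = rnorm2(cp$hba1c, cp$hba1c_sd),
    ogtt_fasting = rnorm2(cp$ogtt_fasting, cp$ogtt_fasting_sd),
    ogtt_1h = rnorm2(cp$ogtt_1h, cp$ogtt_1h_sd),
    ogtt_2h = rnorm2(cp$ogtt_2h, cp$ogtt_2h_sd),
    hba1c_followup = rnorm2(cp$hba1c_followup, cp$hba1c_followup_sd),
    family_history = rbin2(cp$family_history),
    ses = ses,
    nulliparous = rbin2(cp$nulliparous),
    label = label,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic pathway annotation database
#'
#' Builds a local KEGG-style pathway table: one pathway is guaranteed to
#' contain the planted compound set (so enrichment recovery is well
#' defined); the remaining pathways sample the universe uniformly.
#'
#' @param n_pathways number of pathways.
#' @param universe character vector of compound IDs.
#' @param planted_pathway compound IDs of the planted pathway (subset of
#'   `universe`); may be `NULL` for a fully random database.
#' @param seed integer seed.
#' @param size_range member-count range for random pathways.
#' @return data.frame with columns `pathway_id`, `pathway_name`, `compounds`
#'   (list column of member IDs).
#' @export
generate_pathway_db <- function(n_pathways, universe, planted_pathway = NULL,
                                seed = 1L, size_range = c(5L, 30L)) {
  if (length(universe) == 0) stopf("`universe` must be non-empty")
  n_pathways <- assert_count(n_pathways, "n_pathways")
  if (!is.null(planted_pathway) && !all(planted_pathway %in% universe))
    stopf("`planted_pathway` must be a subset of `universe`")
  set.seed(seed)
  ids <- sprintf("map%05d", seq_len(n_pathways))
  compounds <- vector("list", n_pathways)
  start <- 1L
  if (!is.null(planted_pathway) && length(planted_pathway)) {
    compounds[[1L]] <- unique(planted_pathway)
    start <- 2L
  }
  if (start <= n_pathways) {
    for (i in start:n_pathways) {
      sz <- min(length(universe),
                sample(seq(size_range[1], size_range[2]), 1L))
      compounds[[i]] <- sample(universe, max(1L, sz))
    }
  }
  data.frame(pathway_id = ids,
             pathway_name = paste0("Synthetic pathway ", seq_len(n_pathways)),
             compounds = I(compounds),
             stringsAsFactors = FALSE)
}

#' Persist a synthetic cohort as delimited text
#'
#' Writes each dataset with [write_abundance_matrix()], the clinical table
#' as TSV and the ground truth as JSON under `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (d in names(cohort$datasets))
    write_abundance_matrix(cohort$datasets[[d]], file.path(dir, d))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
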