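#' Preprocessing configuration
#'
#' @param rsd_threshold percent RSD above which a metabolite's biological
#'   values are nulled (default 20; metabolites at exactly the threshold
#'   are retained).
#' @param max_missing_fraction metabolites with a strictly greater missing
#'   fraction among biological samples are dropped (default 0.40).
#' @param log_offset offset inside the log transform, `ln(x + offset)`.
#' @param scale standardize to zero mean / unit variance after correction.
#' @param combat_enabled apply empirical-Bayes batch correction.
#' @param combat_protect_label include the case/control label as a
#'   protected covariate during batch correction so true group differences
#'   are not absorbed into the batch estimates.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(rsd_threshold = 20, max_missing_fraction = 0.40,
                              log_offset = 1, scale = TRUE,
                              combat_enabled = TRUE,
                              combat_protect_label = TRUE) {
  if (rsd_threshold <= 0 || rsd_threshold > 100)
    stopf("`rsd_threshold` must be in (0, 100]")
  assert_fraction(max_missing_fraction, "max_missing_fraction", allow_one = FALSE)
  structure(list(rsd_threshold = rsd_threshold,
                 max_missing_fraction = max_missing_fraction,
                 log_offset = log_offset, scale = scale,
                 combat_enabled = combat_enabled,
                 combat_protect_label = combat_protect_label),
            class = "preprocess_config")
}

#' Per-metabolite relative standard deviation from pooled-QC injections
#'
#' RSD is `100 * sd / mean` over the non-missing QC values of each
#' metabolite (sample SD, n-1 denominator). A zero QC mean yields `Inf`
#' so the metabolite always fails the downstream filter.
#'
#' @param matrix an [abundance_matrix] containing at least two QC-flagged
#'   samples.
#' @return A `qc_report` list with `rsd` (named numeric, percent) and a
#'   placeholder stage ledger.
#' @export
compute_rsd <- function(matrix) {
  qc <- matrix$values[matrix$sample_meta$is_qc, , drop = FALSE]
  if (nrow(qc) < 2L) stopf("compute_rsd requires >= 2 QC samples, found %d", nrow(qc))
  m <- apply(qc, 2, mean, na.rm = TRUE)
  s <- apply(qc, 2, stats::sd, na.rm = TRUE)
  rsd <- ifelse(m == 0, Inf, 100 * s / m)
  structure(list(rsd = stats::setNames(rsd, colnames(qc)),
                 n_qc = nrow(qc)),
            class = "qc_report")
}

#' Null metabolites failing the QC RSD filter
#'
#' Metabolites whose pooled-QC RSD exceeds `threshold` percent have all
#' biological values replaced with missing; metabolites at or below the
#' threshold pass unchanged. QC rows are dropped from the output, which
#' therefore contains biological samples only.
#'
#' @param matrix an [abundance_matrix].
#' @param qc a `qc_report` from [compute_rsd()] covering all metabolites.
#' @param threshold RSD threshold in percent, in (0, 100].
#' @return An `abundance_matrix` of biological samples with failing
#'   metabolites nulled; attribute `nulled` lists their names.
#' @export
apply_rsd_filter <- function(matrix, qc, threshold = 20) {
  if (threshold <= 0 || threshold > 100) stopf("`threshold` must be in (0, 100]")
  if (!all(colnames(matrix$values) %in% names(qc$rsd)))
    stopf("QC report does not cover all metabolites")
  rsd <- qc$rsd[colnames(matrix$values)]
  fail <- rsd > threshold          # strictly greater: exactly 20% is retained
  out <- biological_samples(matrix)
  out$values[, fail] <- NA_real_
  attr(out, "nulled") <- colnames(out$values)[fail]
  log_msg("RSD filter: %d/%d metabolites nulled at %.4g%%",
          sum(fail), length(fail), threshold)
  out
}

#' Drop metabolites with excessive missingness
#'
#' Metabolites whose missing fraction among biological samples is strictly
#' greater than `max_missing_fraction` are removed.
#'
#' @param matrix an [abundance_matrix] (biological samples).
#' @param max_missing_fraction threshold fraction in \[0, 1).
#' @return An `abundance_matrix`; attribute `dropped` lists removed names.
#' @export
filter_missingness <- function(matrix, max_missing_fraction = 0.40) {
  bio <- !matrix$sample_meta$is_qc
  frac <- colMeans(is.na(matrix$values[bio, , drop = FALSE]))
  drop <- frac > max_missing_fraction
  out <- am_subset(matrix, metabolites = !drop)
  attr(out, "dropped") <- colnames(matrix$values)[drop]
  log_msg("missingness filter: %d/%d metabolites dropped at > %.0f%%",
          sum(drop), length(drop), 100 * max_missing_fraction)
  out
}

#' Half-minimum imputation
#'
#' Replaces each missing cell of metabolite j with half the minimum
#' observed value of metabolite j (a limit-of-detection surrogate).
#' Observed cells are untouched.
#'
#' @param matrix an [abundance_matrix]; every metabolite must have at
#'   least one observed value.
#' @return An `abundance_matrix` with no missing cells.
#' @export
impute_half_min <- function(matrix) {
  v <- matrix$values
  nmiss <- colSums(is.na(v))
  if (any(nmiss == nrow(v)))
    stopf("all-missing metabolite(s) must be removed before imputation: %s",
          paste(colnames(v)[nmiss == nrow(v)], collapse = ", "))
  mins <- suppressWarnings(apply(v, 2, min, na.rm = TRUE))
  if (any(mins == 0 & nmiss > 0))
    warning("observed minimum is 0 for some metabolites; imputing 0")
  for (j in which(nmiss > 0)) v[is.na(v[, j]), j] <- mins[j] / 2
  out <- matrix
  out$values <- v
  out
}

#' Log transform, `x -> ln(x + offset)`
#'
#' @param matrix an [abundance_matrix] with no negative values.
#' @param offset added before the log (default 1, so zeros map to zero).
#' @return An `abundance_matrix` on the log scale.
#' @export
log1p_transform <- function(matrix, offset = 1) {
  if (any(matrix$values < 0, na.rm = TRUE))
    stopf("log transform requires nonnegative values")
  abundance_matrix_transformed(log(matrix$values + offset),
                               matrix$sample_meta, matrix$metabolite_meta)
}

#' Empirical-Bayes batch correction
#'
#' Parametric empirical-Bayes location/scale adjustment per metabolite
#' (ComBat): each feature is standardized against a feature-wise model,
#' per-batch location and scale parameters are estimated and shrunk via
#' parametric priors (normal for location, inverse-gamma for scale), and
#' adjusted values are returned. With `protect_label = TRUE` the
#' case/control label enters the model as a protected covariate so genuine
#' group differences are not removed. A single batch is a no-op.
#'
#' @param matrix an [abundance_matrix] on the log scale with a batch label
#'   for every sample and at least two samples per batch.
#' @param protect_label protect the case/control label (default `TRUE`).
#' @return An `abundance_matrix` with the same dimensions.
#' @export
combat_correct <- function(matrix, protect_label = TRUE) {
  batch <- matrix$sample_meta$batch_id
  if (anyNA(batch)) stopf("missing batch label")
  tab <- table(batch)
  if (length(tab) == 1L) {
    log_msg("single batch: batch correction is a no-op")
    return(matrix)
  }
  if (any(tab < 2L))
    stopf("every batch needs >= 2 samples (batch %s has %d)",
          names(tab)[which.min(tab)], min(tab))
  mod <- NULL
  if (protect_label) {
    lab <- matrix$sample_meta$label
    if (!anyNA(lab) && length(unique(lab)) > 1L)
      mod <- stats::model.matrix(~ factor(lab))
  }
  dat <- t(matrix$values)                       # features x samples
  keep <- apply(dat, 1, stats::sd) > 0
  adj <- dat
  if (any(keep)) {
    corrected <- suppressMessages(
      sva::ComBat(dat[keep, , drop = FALSE], batch = factor(batch), mod = mod,
                  par.prior = TRUE, prior.plots = FALSE))
    adj[keep, ] <- corrected
  }
  abundance_matrix_transformed(t(adj), matrix$sample_meta, matrix$metabolite_meta)
}

#' Standardize metabolites to zero mean and unit variance
#'
#' Sample-SD (n-1) convention. Constant metabolites cannot be scaled and
#' are dropped with a warning.
#'
#' @param matrix an [abundance_matrix] with no missing values.
#' @return An `abundance_matrix` of z-scored metabolites.
#' @export
standardize_metabolites <- function(matrix) {
  if (anyNA(matrix$values)) stopf("standardization requires complete data")
  s <- apply(matrix$values, 2, stats::sd)
  if (any(s == 0)) {
    warning(sprintf("dropping %d constant metabolite(s)", sum(s == 0)))
    matrix <- am_subset(matrix, metabolites = s > 0)
    s <- s[s > 0]
  }
  z <- scale(matrix$values)
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  abundance_matrix_transformed(z, matrix$sample_meta, matrix$metabolite_meta)
}

#' Principal component analysis of a standardized matrix
#'
#' @param matrix a standardized [abundance_matrix].
#' @param n_components number of components to retain (default
#'   `min(n - 1, p)`).
#' @param rank_component component whose absolute loadings rank the
#'   metabolites (default 1).
#' @return A `pca_result` list: `scores`, `loadings`, `explained_variance`
#'   (fractions), `ranking` (metabolites by descending |loading|).
#' @export
run_pca <- function(matrix, n_components = NULL, rank_component = 1L) {
  n <- nrow(matrix$values); p <- ncol(matrix$values)
  kmax <- min(n - 1L, p)
  k <- n_components %||% kmax
  if (k > kmax) stopf("cannot extract %d components from %d x %d data", k, n, p)
  pc <- stats::prcomp(matrix$values, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  ld <- pc$rotation[, seq_len(k), drop = FALSE]
  ranking <- rownames(ld)[order(-abs(ld[, rank_component]), rownames(ld))]
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = ld,
                 explained_variance = ev[seq_len(k)],
                 ranking = ranking),
            class = "pca_result")
}

#' Merge the three acquisition datasets into one matrix
#'
#' Inner join on `(batch_id, sample_id)`; metabolite columns are
#' concatenated and names colliding across datasets are disambiguated with
#' a dataset-of-origin suffix.
#'
#' @param ... two or more preprocessed [abundance_matrix] objects.
#' @return An `abundance_matrix` whose sample set is the ID intersection.
#' @export
merge_datasets <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1]]) && !inherits(mats[[1]], "abundance_matrix"))
    mats <- mats[[1]]
  stopifnot(length(mats) >= 2L)
  keys <- lapply(mats, function(m) paste(m$sample_meta$batch_id,
                                         m$sample_meta$sample_id, sep = "\r"))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) stopf("no samples shared across datasets")
  lost <- length(unique(unlist(keys))) - length(common)
  if (lost > 0) log_msg("merge: %d sample(s) absent from some dataset excluded", lost)
  nm <- unlist(lapply(mats, function(m) colnames(m$values)), use.names = FALSE)
  dup <- nm[duplicated(nm)]
  vals <- list(); metas <- list()
  for (m in mats) {
    idx <- match(common, paste(m$sample_meta$batch_id, m$sample_meta$sample_id,
                               sep = "\r"))
    v <- m$values[idx, , drop = FALSE]
    mm <- m$metabolite_meta
    clash <- colnames(v) %in% dup
    if (any(clash)) {
      colnames(v)[clash] <- paste0(colnames(v)[clash], ".", mm$dataset[clash])
      mm$metabolite[clash] <- colnames(v)[clash]
    }
    vals[[length(vals) + 1L]] <- v
    metas[[length(metas) + 1L]] <- mm
  }
  smeta <- mats[[1]]$sample_meta[match(common, keys[[1]]), , drop = FALSE]
  abundance_matrix_transformed(do.call(cbind, vals), smeta, do.call(rbind, metas))
}

#' Run the full per-dataset preprocessing chain
#'
#' Fixed stage order: RSD filter, missingness filter, half-minimum
#' imputation, log transform, batch correction, standardization. A count
#' ledger (input = nulled-by-RSD + dropped-by-missingness + retained) is
#' attached and asserted.
#'
#' @param matrix a raw [abundance_matrix] with QC rows.
#' @param config a [preprocess_config()].
#' @return list with `matrix` (processed, biological samples only),
#'   `qc_report`, and `ledger` (one-row data.frame of stage counts).
#' @export
preprocess_dataset <- function(matrix, config = preprocess_config()) {
  p_in <- ncol(matrix$values)
  qc <- compute_rsd(matrix)
  m <- apply_rsd_filter(matrix, qc, config$rsd_threshold)
  nulled <- attr(m, "nulled")
  m <- filter_missingness(m, config$max_missing_fraction)
  dropped <- setdiff(attr(m, "dropped"), nulled)
  m <- impute_half_min(m)
  m <- log1p_transform(m, config$log_offset)
  if (config$combat_enabled) m <- combat_correct(m, config$combat_protect_label)
  p_before_scale <- ncol(m$values)
  if (config$scale) m <- suppressWarnings(standardize_metabolites(m))
  ledger <- data.frame(metabolites_in = p_in,
                       nulled_by_rsd = length(nulled),
                       dropped_by_missingness = length(dropped),
                       dropped_constant = p_before_scale - ncol(m$values),
                       retained = ncol(m$values))
  stopifnot(ledger$metabolites_in ==
              ledger$nulled_by_rsd + ledger$dropped_by_missingness +
                ledger$dropped_constant + ledger$retained)
  list(matrix = m, qc_report = qc, ledger = ledger)
}
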