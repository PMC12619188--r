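#' Clinical prediction model specification
#'
#' Standard specifications: model "1a" uses maternal age, pre-pregnancy
#' BMI, family history of diabetes and venous HbA1c; "1b" substitutes
#' waist-to-height ratio for BMI; "1c" adds the selected metabolite panel
#' to the 1b covariates. Covariate lists are fully overridable.
#'
#' @param name model name.
#' @param covariates clinical covariate column names.
#' @param panel metabolite panel member names (required for the
#'   integrated model).
#' @return A `model_spec` list.
#' @export
model_spec <- function(name, covariates, panel = NULL) {
  structure(list(name = name, covariates = covariates, panel = panel),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
spec_1a <- function() model_spec("1a", c("age", "bmi", "family_history", "hba1c"))

#' @rdname model_spec
#' @export
spec_1b <- function() model_spec("1b", c("age", "whtr", "family_history", "hba1c"))

#' @rdname model_spec
#' @export
spec_1c <- function(panel) {
  if (is.null(panel) || !length(panel))
    stopf("the integrated model requires a metabolite panel")
  model_spec("1c", c("age", "whtr", "family_history", "hba1c"), panel)
}

#' Fit a logistic risk model and summarize its ROC
#'
#' Logistic regression of the outcome on the spec's clinical covariates
#' (plus the metabolite panel for the integrated model), on complete
#' cases; in-sample (apparent) ROC with a DeLong 95% CI.
#'
#' @param clinical data.frame with the covariates, `sample_id` and
#'   `label`.
#' @param spec a [model_spec()].
#' @param metabolites optional standardized [abundance_matrix] or numeric
#'   matrix with rownames = sample IDs, providing panel columns.
#' @return list: `fit` (glm), `roc` ([roc_summary()]), `coefficients`,
#'   `n` (complete cases used), `sample_ids`.
#' @export
fit_risk_model <- function(clinical, spec, metabolites = NULL) {
  df <- clinical[, c("sample_id", "label", spec$covariates), drop = FALSE]
  if (!is.null(spec$panel)) {
    if (is.null(metabolites)) stopf("spec `%s` needs a metabolite matrix", spec$name)
    vals <- if (inherits(metabolites, "abundance_matrix"))
      biological_samples(metabolites)$values else metabolites
    miss <- setdiff(spec$panel, colnames(vals))
    if (length(miss)) stopf("panel members absent from matrix: %s",
                            paste(miss, collapse = ", "))
    idx <- match(df$sample_id, rownames(vals))
    pm <- vals[idx, spec$panel, drop = FALSE]
    colnames(pm) <- make.names(colnames(pm))
    df <- cbind(df, pm)
  }
  cc <- stats::complete.cases(df)
  if (sum(!cc)) log_msg("model %s: %d incomplete row(s) dropped", spec$name, sum(!cc))
  df <- df[cc, , drop = FALSE]
  fit <- stats::glm(label ~ ., data = df[, setdiff(names(df), "sample_id")],
                    family = stats::binomial())
  roc <- roc_summary(stats::fitted(fit), df$label)
  list(fit = fit, roc = roc, coefficients = stats::coef(fit),
       n = nrow(df), sample_ids = df$sample_id)
}

#' Compare prediction models on an identical sample set
#'
#' Restricts all models to the complete-case intersection across every
#' spec's covariates (and the panel), fits each, and tabulates AUC with
#' DeLong CIs.
#'
#' @param specs list of [model_spec()] objects.
#' @param clinical clinical data.frame.
#' @param metabolites metabolite matrix for specs with panels.
#' @return list: `table` (data.frame `model`, `auc`, `ci_low`, `ci_high`,
#'   `n`), `fits` (named list), `sample_ids` (the shared sample set).
#' @export
compare_models <- function(specs, clinical, metabolites = NULL) {
  all_cov <- unique(unlist(lapply(specs, `[[`, "covariates")))
  df <- clinical[, c("sample_id", "label", all_cov), drop = FALSE]
  cc <- stats::complete.cases(df)
  panels <- unique(unlist(lapply(specs, `[[`, "panel")))
  if (length(panels)) {
    vals <- if (inherits(metabolites, "abundance_matrix"))
      biological_samples(metabolites)$values else metabolites
    cc <- cc & clinical$sample_id %in% rownames(vals)
  }
  shared <- clinical$sample_id[cc]
  if (!length(shared)) stopf("complete-case intersection is empty")
  clin <- clinical[clinical$sample_id %in% shared, , drop = FALSE]
  fits <- lapply(specs, function(s) fit_risk_model(clin, s, metabolites))
  names(fits) <- vapply(specs, `[[`, "", "name")
  stopifnot(all(vapply(fits, function(f) identical(sort(f$sample_ids), sort(shared)),
                       TRUE)))
  tab <- data.frame(model = names(fits),
                    auc = vapply(fits, function(f) f$roc$auc, 0),
                    ci_low = vapply(fits, function(f) f$roc$ci[["low"]], 0),
                    ci_high = vapply(fits, function(f) f$roc$ci[["high"]], 0),
                    n = vapply(fits, `[[`, 0L, "n"),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, fits = fits, sample_ids = shared)
}

#' Cohort characteristics summary ("table one")
#'
#' Continuous variables are summarized as mean and SD per group with a
#' two-sample t-test; categorical variables as n (%) per level with a
#' chi-square test, or Fisher's exact test when any expected cell count
#' falls below 5.
#'
#' @param clinical data.frame.
#' @param group name of the binary/categorical grouping column (default
#'   `"label"`).
#' @param variables columns to summarize (default: all except
#'   `sample_id` and the group).
#' @return data.frame: `variable`, `level`, one `mean`/`sd`/`n`/`pct`
#'   block per group, `p_value`, `test`.
#' @export
summarize_tableone <- function(clinical, group = "label", variables = NULL) {
  g <- factor(clinical[[group]])
  if (any(table(g) == 0L) || nlevels(g) < 2L) stopf("each group must be non-empty")
  variables <- variables %||% setdiff(names(clinical), c("sample_id", group))
  blank_row <- function(v, level, test, p) {
    row <- data.frame(variable = v, level = level, test = test, p_value = p,
                      stringsAsFactors = FALSE)
    for (lev in levels(g)) {
      row[[paste0("mean_", lev)]] <- NA_real_
      row[[paste0("sd_", lev)]] <- NA_real_
      row[[paste0("n_", lev)]] <- NA_integer_
      row[[paste0("pct_", lev)]] <- NA_real_
    }
    row
  }
  rows <- list()
  for (v in variables) {
    x <- clinical[[v]]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      p <- if (nlevels(g) == 2L) stats::t.test(x ~ g)$p.value
           else stats::anova(stats::lm(x ~ g))[["Pr(>F)"]][1]
      row <- blank_row(v, NA_character_, "t", p)
      for (lev in levels(g)) {
        row[[paste0("mean_", lev)]] <- mean(x[g == lev])
        row[[paste0("sd_", lev)]] <- stats::sd(x[g == lev])
      }
      rows[[length(rows) + 1L]] <- row
    } else {
      x <- factor(x)
      tab <- table(x, g)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use_fisher <- any(expected < 5)
      p <- if (use_fisher) stats::fisher.test(tab)$p.value
           else stats::chisq.test(tab, correct = FALSE)$p.value
      for (lev_x in levels(x)) {
        row <- blank_row(v, lev_x, if (use_fisher) "fisher" else "chisq", p)
        for (lev in levels(g)) {
          n <- sum(x == lev_x & g == lev)
          row[[paste0("n_", lev)]] <- n
          row[[paste0("pct_", lev)]] <- 100 * n / sum(g == lev)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
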