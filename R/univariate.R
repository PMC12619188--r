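## Fast Wald logistic fit via IRLS (stats::glm.fit). Returns coefficient
## vector, SEs, convergence and separation flags. Used per metabolite; the
## formula interface of glm() is too slow for the null-calibration suites
## (1e5 fits). Agreement with stats::glm is asserted in the test suite.
logistic_wald <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  ok <- TRUE
  vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) {ok <<- FALSE; NULL})
  se <- if (ok) sqrt(diag(vc)) else rep(NA_real_, ncol(X))
  mu <- fit$fitted.values
  separated <- any(mu > 1 - 1e-8 | mu < 1e-8) && max(abs(fit$coefficients)) > 10
  list(coef = fit$coefficients, se = se,
       converged = fit$converged && ok && !separated)
}

#' Per-metabolite logistic association with the outcome
#'
#' Fits one maximum-likelihood logistic regression per metabolite
#' (outcome ~ metabolite \[+ covariates\]) and reports the Wald estimate
#' (log-odds per 1 SD of the standardized metabolite), SE, symmetric 95%
#' CI, two-sided p value, BH-FDR adjusted p across metabolites, and the
#' odds ratio `exp(estimate)`. Non-converged or separated fits are
#' flagged `converged = FALSE` and excluded from the FDR ranking;
#' constant metabolites are skipped.
#'
#' @param matrix an [abundance_matrix] of standardized metabolites
#'   (biological samples), or a plain numeric matrix.
#' @param labels binary outcome (1 = case); taken from the sample
#'   metadata when `NULL`.
#' @param covariates optional data.frame of adjustment covariates (e.g.
#'   parity for the sensitivity analysis).
#' @return data.frame with one row per metabolite: `metabolite`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `p_value`, `fdr_p`,
#'   `odds_ratio`, `converged`.
#' @export
fit_metabolite_logistic <- function(matrix, labels = NULL, covariates = NULL) {
  vals <- if (inherits(matrix, "abundance_matrix")) {
    if (is.null(labels)) labels <- matrix$sample_meta$label[!matrix$sample_meta$is_qc]
    biological_samples(matrix)$values
  } else matrix
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stopf("labels must contain both classes")
  if (length(y) != nrow(vals)) stopf("labels length does not match sample count")
  covm <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  p <- ncol(vals)
  est <- se <- pv <- rep(NA_real_, p)
  conv <- rep(FALSE, p)
  zc <- stats::qnorm(0.975)
  for (j in seq_len(p)) {
    xj <- vals[, j]
    if (stats::sd(xj) == 0) next                      # constant: skipped
    X <- cbind(1, xj, covm)
    f <- logistic_wald(X, y)
    est[j] <- f$coef[2]; se[j] <- f$se[2]
    conv[j] <- f$converged && is.finite(f$se[2])
    if (conv[j]) pv[j] <- 2 * stats::pnorm(-abs(est[j] / se[j]))
  }
  fdr <- rep(NA_real_, p)
  fdr[conv] <- adjust_bh(pv[conv])
  data.frame(metabolite = colnames(vals),
             estimate = est, se = se,
             ci_low = est - zc * se, ci_high = est + zc * se,
             p_value = pv, fdr_p = fdr,
             odds_ratio = exp(est), converged = conv,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps `stats::p.adjust(method = "BH")` with input validation; adjusted
#' values are monotone-enforced, capped at 1, and returned in input order.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @return FDR-adjusted p values.
#' @export
adjust_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Volcano-plot data table
#'
#' Classifies each association as `positive` (OR > 1 and FDR p below
#' `alpha`), `negative` (OR < 1 and FDR p below `alpha`) or `ns`. The
#' threshold is strict: FDR p exactly at `alpha` is not significant.
#'
#' @param records data.frame from [fit_metabolite_logistic()].
#' @param alpha FDR significance level (default 0.05).
#' @return data.frame: `metabolite`, `odds_ratio`, `neglog10_fdr`,
#'   `class`.
#' @export
volcano_table <- function(records, alpha = 0.05) {
  sig <- !is.na(records$fdr_p) & records$fdr_p < alpha
  cls <- ifelse(sig & records$odds_ratio > 1, "positive",
                ifelse(sig & records$odds_ratio < 1, "negative", "ns"))
  data.frame(metabolite = records$metabolite,
             odds_ratio = records$odds_ratio,
             neglog10_fdr = -log10(records$fdr_p),
             class = cls, stringsAsFactors = FALSE)
}

#' Metabolite associations with continuous clinical variables
#'
#' For each (metabolite, clinical variable) pair, fits the ordinary least
#' squares regression `variable ~ metabolite`, applies BH-FDR within each
#' variable, and assigns a direction: `up`/`down` by the slope sign when
#' the FDR p is below `alpha`, `no-change` otherwise. This is the data
#' layer behind circular association heatmaps.
#'
#' @param matrix an [abundance_matrix] of standardized metabolites or a
#'   numeric matrix (biological samples).
#' @param clinical data.frame of clinical variables, rows aligned with
#'   samples.
#' @param variables character vector of clinical column names (default:
#'   the seven glycemic-outcome variables).
#' @param alpha FDR level (default 0.05).
#' @return data.frame: `metabolite`, `variable`, `effect` (OLS slope),
#'   `p_value`, `fdr_p`, `direction`.
#' @export
clinical_variable_associations <- function(matrix, clinical,
                                           variables = c("hba1c_followup",
                                                         "ogtt_fasting", "ogtt_1h",
                                                         "ogtt_2h", "hba1c",
                                                         "fpg", "bmi"),
                                           alpha = 0.05) {
  vals <- if (inherits(matrix, "abundance_matrix")) biological_samples(matrix)$values else matrix
  n <- nrow(vals)
  out <- list()
  for (v in variables) {
    yv <- clinical[[v]]
    if (is.null(yv)) stopf("clinical variable `%s` not found", v)
    if (stats::sd(yv) == 0) stopf("clinical variable `%s` is constant", v)
    ## simple OLS slope + t test, vectorized over metabolites
    xc <- sweep(vals, 2, colMeans(vals))
    yc <- yv - mean(yv)
    sxx <- colSums(xc^2)
    b <- colSums(xc * yc) / sxx
    res <- outer(yc, rep(1, ncol(vals))) - sweep(xc, 2, b, `*`)
    s2 <- colSums(res^2) / (n - 2)
    tstat <- b / sqrt(s2 / sxx)
    pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
    fdr <- adjust_bh(pv)
    out[[v]] <- data.frame(metabolite = colnames(vals), variable = v,
                           effect = b, p_value = pv, fdr_p = fdr,
                           direction = ifelse(fdr < alpha,
                                              ifelse(b > 0, "up", "down"),
                                              "no-change"),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
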