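test_that("RSD is sample-SD over QC mean, with degenerate cases handled", {
  vals <- matrix(runif(12, 50, 100), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  qc <- rbind(c(10, 8, 0), c(10, 10, 0), c(10, 12, 0))
  m <- tiny_matrix(vals, n_qc = 3, qc_values = qc)
  rep <- compute_rsd(m)
  expect_equal(unname(rep$rsd["a"]), 0)          # zero variance
  expect_equal(unname(rep$rsd["b"]), 20.0)       # sd 2, mean 10
  expect_equal(unname(rep$rsd["c"]), Inf)        # zero mean
  expect_error(compute_rsd(tiny_matrix(vals, n_qc = 1)), ">= 2 QC")
})

test_that("RSD filter nulls strictly above threshold and drops QC rows", {
  vals <- matrix(runif(20, 50, 100), 5, 4,
                 dimnames = list(NULL, c("keep20", "null25", "keepLow", "null20.01")))
  qc <- sapply(c(0.20, 0.25, 0.05, 0.2001), function(cv) 100 + c(-1, 0, 1) * cv * 100)
  colnames(qc) <- colnames(vals)
  m <- tiny_matrix(vals, n_qc = 3, qc_values = qc)
  rep <- compute_rsd(m)
  expect_equal(unname(round(rep$rsd, 2)), c(20, 25, 5, 20.01))
  out <- suppressMessages(apply_rsd_filter(m, rep, threshold = 20))
  expect_false(any(out$sample_meta$is_qc))
  expect_equal(out$values[, "keep20"], vals[, "keep20"], ignore_attr = TRUE)
  expect_equal(out$values[, "keepLow"], vals[, "keepLow"], ignore_attr = TRUE)
  expect_true(all(is.na(out$values[, "null25"])))
  expect_true(all(is.na(out$values[, "null20.01"])))
  expect_error(apply_rsd_filter(m, rep, threshold = 0), "\\(0, 100\\]")
})

test_that("missingness filter uses a strict 40% boundary", {
  vals <- matrix(runif(300, 1, 10), 100, 3,
                 dimnames = list(NULL, c("at40", "at41", "full")))
  vals[1:40, "at40"] <- NA
  vals[1:41, "at41"] <- NA
  m <- tiny_matrix(vals)
  out <- suppressMessages(filter_missingness(m, 0.40))
  expect_setequal(colnames(out$values), c("at40", "full"))
  expect_equal(attr(out, "dropped"), "at41")
})

test_that("half-minimum imputation fills exactly min/2 and only the gaps", {
  vals <- matrix(c(4, 8, NA, 12,
                   5, 5, 5, 5,
                   0, NA, 3, 6), 4, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  m <- tiny_matrix(vals)
  out <- suppressWarnings(impute_half_min(m))
  expect_equal(out$values[3, "a"], 2.0, ignore_attr = TRUE)   # min 4 -> 2
  expect_equal(out$values[c(1, 2, 4), "a"], vals[c(1, 2, 4), "a"], ignore_attr = TRUE)
  expect_equal(out$values[1:4, "b"], vals[, "b"], ignore_attr = TRUE)
  expect_equal(out$values[2, "c"], 0, ignore_attr = TRUE)     # min 0 -> 0
  expect_warning(impute_half_min(m), "minimum is 0")
  allna <- vals; allna[, "a"] <- NA
  expect_error(impute_half_min(tiny_matrix(allna)), "all-missing")
})

test_that("log transform maps 0 to 0 and rejects negatives", {
  vals <- matrix(c(0, exp(1) - 1, 10), 3, 1, dimnames = list(NULL, "m"))
  out <- log1p_transform(tiny_matrix(vals, n_qc = 2))
  expect_equal(out$values[1:3, 1], c(0, 1, log(11)), ignore_attr = TRUE)
  neg <- tiny_matrix(vals, n_qc = 2)
  neg$values[1, 1] <- -1
  expect_error(log1p_transform(neg), "nonnegative")
})

test_that("batch correction is identity for a single batch", {
  set.seed(1)
  vals <- matrix(rnorm(200, 10), 20, 10, dimnames = list(NULL, paste0("m", 1:10)))
  meta <- data.frame(sample_id = sprintf("S%02d", 1:20), batch_id = "B1",
                     is_qc = FALSE, label = rep_len(0:1, 20))
  m <- abundance_matrix(vals, meta)
  out <- suppressMessages(combat_correct(m))
  expect_equal(out$values, m$values, tolerance = 1e-8)
})

test_that("batch correction removes additive batch offsets", {
  set.seed(2)
  n <- 500; p <- 40
  offs <- rnorm(p, 0, 2)
  vals <- rbind(matrix(rnorm(n * p, 10), n, p),
                sweep(matrix(rnorm(n * p, 10), n, p), 2, offs, `+`))
  colnames(vals) <- paste0("m", 1:p)
  meta <- data.frame(sample_id = sprintf("S%04d", 1:(2 * n)),
                     batch_id = rep(c("B1", "B2"), each = n),
                     is_qc = FALSE, label = rep_len(0:1, 2 * n))
  out <- suppressMessages(combat_correct(abundance_matrix(vals, meta),
                                         protect_label = FALSE))
  gap <- abs(colMeans(out$values[1:n, ]) - colMeans(out$values[n + 1:n, ]))
  expect_lt(max(gap), 0.05)
  ## and with equal variances + large n the corrected batch means agree with
  ## simple per-batch mean-centering (to the pooled mean)
  pooled <- colMeans(vals)
  expect_lt(max(abs(colMeans(out$values[1:n, ]) - pooled)), 1e-2)
  expect_lt(max(abs(colMeans(out$values[n + 1:n, ]) - pooled)), 1e-2)
})

test_that("protected labels survive correction under partial confounding", {
  set.seed(3)
  n <- 120; p <- 15
  ## batch composition 80/20 vs 20/80 cases: strong but not perfect confounding
  label <- c(rep(1, 48), rep(0, 12), rep(1, 12), rep(0, 48))
  batch <- rep(c("B1", "B2"), each = 60)
  shift <- 1.0
  vals <- matrix(rnorm(n * p, 10), n, p, dimnames = list(NULL, paste0("m", 1:p)))
  vals[, 1] <- vals[, 1] + shift * label
  vals[batch == "B2", ] <- vals[batch == "B2", ] + 1.5
  meta <- data.frame(sample_id = sprintf("S%03d", 1:n), batch_id = batch,
                     is_qc = FALSE, label = label)
  out <- suppressMessages(combat_correct(abundance_matrix(vals, meta),
                                         protect_label = TRUE))
  eff <- mean(out$values[label == 1, 1]) - mean(out$values[label == 0, 1])
  expect_lt(abs(eff - shift) / shift, 0.2)
})

test_that("standardization hits machine-zero means and drops constants", {
  set.seed(4)
  vals <- matrix(rnorm(60, 5), 20, 3, dimnames = list(NULL, c("a", "b", "const")))
  vals[, "const"] <- 7
  m <- tiny_matrix(vals, n_qc = 0)
  expect_warning(standardize_metabolites(m), "constant")
  out <- suppressWarnings(standardize_metabolites(m))
  expect_equal(colnames(out$values), c("a", "b"))
  expect_true(all(abs(colMeans(out$values)) < 1e-10))
  expect_equal(unname(apply(out$values, 2, sd)), c(1, 1))
  ## two-sample column: values +/- 1/sqrt(2) under the n-1 convention
  two <- tiny_matrix(matrix(c(3, 5), 2, 1, dimnames = list(NULL, "x")), n_qc = 0)
  expect_equal(unname(standardize_metabolites(two)$values[, 1]),
               c(-1, 1) / sqrt(2))
})

test_that("PCA explains rank-1 data with one component and ranks by |loading|", {
  set.seed(5)
  t <- rnorm(30)
  vals <- outer(t, c(2, -1, 0.5))
  colnames(vals) <- c("hi", "mid", "lo")
  m <- tiny_matrix(vals, n_qc = 0)
  pc <- run_pca(m, n_components = 2)
  expect_gt(pc$explained_variance[1], 0.999)
  expect_equal(pc$ranking[1], "hi")
  ## ranking invariant to a global sign flip
  pc2 <- run_pca(tiny_matrix(-vals, n_qc = 0), n_components = 2)
  expect_equal(pc$ranking, pc2$ranking)
  expect_error(run_pca(m, n_components = 10), "components")
})

test_that("dataset merge inner-joins on batch+sample and disambiguates names", {
  mk <- function(ids, nm, dataset) {
    vals <- matrix(seq_along(ids), length(ids), 1, dimnames = list(NULL, nm))
    meta <- data.frame(sample_id = ids, batch_id = "B1", is_qc = FALSE,
                       label = rep_len(0:1, length(ids)))
    mm <- data.frame(metabolite = nm, dataset = dataset)
    abundance_matrix(vals, meta, mm)
  }
  a <- mk(sprintf("S%02d", 1:10), "shared", "polar")
  b <- mk(sprintf("S%02d", 1:10), "shared", "nonpolar_pos")
  c3 <- mk(sprintf("S%02d", 2:10), "only", "nonpolar_neg")
  merged <- suppressMessages(merge_datasets(a, b, c3))
  expect_equal(nrow(merged$values), 9L)       # inner join loses S01
  expect_setequal(colnames(merged$values),
                  c("shared.polar", "shared.nonpolar_pos", "only"))
  expect_error(merge_datasets(a, mk("X99", "z", "polar")), "no samples shared")
})

test_that("filters are monotone in their thresholds and idempotent on clean data", {
  co <- generate_cohort(synthetic_config(
    n_cases = 15L, n_controls = 15L,
    n_metabolites = c(polar = 40L, nonpolar_pos = 40L, nonpolar_neg = 40L),
    effect_set_size = 5L, strong_subset_size = 2L, seed = 6))
  m <- co$datasets$polar
  rep <- compute_rsd(m)
  retained <- sapply(c(10, 20, 30), function(thr) {
    out <- suppressMessages(apply_rsd_filter(m, rep, thr))
    sum(colSums(!is.na(out$values)) > 0)
  })
  expect_true(all(diff(retained) >= 0))
  kept <- sapply(c(0.1, 0.4, 0.8), function(mx)
    ncol(suppressMessages(filter_missingness(m, mx))$values))
  expect_true(all(diff(kept) >= 0))
  clean <- suppressMessages(filter_missingness(m, 0.4))
  again <- suppressMessages(filter_missingness(clean, 0.4))
  expect_identical(clean$values, again$values)
})

test_that("the preprocessing ledger is conserved", {
  co <- generate_cohort(synthetic_config(
    n_cases = 15L, n_controls = 15L,
    n_metabolites = c(polar = 50L, nonpolar_pos = 50L, nonpolar_neg = 50L),
    effect_set_size = 5L, strong_subset_size = 2L, seed = 7))
  for (d in co$datasets) {
    res <- suppressMessages(preprocess_dataset(d))
    l <- res$ledger
    expect_equal(l$metabolites_in,
                 l$nulled_by_rsd + l$dropped_by_missingness +
                   l$dropped_constant + l$retained)
    expect_equal(ncol(res$matrix$values), l$retained)
    expect_false(any(res$matrix$sample_meta$is_qc))
    expect_true(all(abs(colMeans(res$matrix$values)) < 1e-10))
  }
})
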