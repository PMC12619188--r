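#' Stratified train/test split scheme
#'
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.7, i.e. 70/30 splits).
#' @param n_iterations number of repeated stratified splits (default 10).
#' @param inner_folds stratified cross-validation folds for tuning within
#'   the training subset (default 10).
#' @param base_seed seed from which per-iteration seeds are derived.
#' @return A `split_scheme` list.
#' @export
split_scheme <- function(train_fraction = 0.7, n_iterations = 10L,
                         inner_folds = 10L, base_seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("`train_fraction` must be in (0, 1)")
  if (inner_folds < 2L) stopf("`inner_folds` must be >= 2")
  structure(list(train_fraction = train_fraction,
                 n_iterations = as.integer(n_iterations),
                 inner_folds = as.integer(inner_folds),
                 base_seed = as.integer(base_seed)),
            class = "split_scheme")
}

#' Random forest hyperparameter grid
#'
#' Default candidates: `mtry` in `{floor(sqrt(p)), floor(p/3), floor(p/2)}`
#' and `ntree` in `{250, 500, 1000}`.
#'
#' @param mtry,ntree candidate vectors (all >= 1; `mtry` is capped at the
#'   feature count when fitting).
#' @param p feature count used to build the default `mtry` set.
#' @return data.frame of grid points (`mtry`, `ntree`).
#' @export
rf_grid <- function(mtry = NULL, ntree = c(250L, 500L, 1000L), p = NULL) {
  if (is.null(mtry)) {
    if (is.null(p)) stopf("supply `mtry` or `p`")
    mtry <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), floor(p / 2))))
  }
  if (any(mtry < 1) || any(ntree < 1)) stopf("grid candidates must be >= 1")
  expand.grid(mtry = sort(unique(as.integer(mtry))),
              ntree = sort(unique(as.integer(ntree))))
}

#' Stratified train/test indices for one iteration
#'
#' Splits each class as close to `train_fraction` as integer rounding
#' allows; deterministic given `base_seed + iteration`.
#'
#' @param labels binary labels.
#' @param scheme a [split_scheme()].
#' @param iteration iteration index (1-based).
#' @return list with integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, scheme, iteration = 1L) {
  y <- as.integer(labels)
  if (any(table(y) < 2L)) stopf("each class needs >= 2 members")
  set.seed(derive_seed(scheme$base_seed, iteration))
  train <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    k <- round(scheme$train_fraction * length(idx))
    k <- min(max(k, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, k))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

rf_fit <- function(X, y, mtry, ntree, seed, importance = "none") {
  ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                 num.trees = ntree, mtry = min(mtry, ncol(X)),
                 probability = TRUE, importance = importance,
                 num.threads = 1L, seed = seed, verbose = FALSE)
}

rf_score <- function(fit, X) {
  predict(fit, X, num.threads = 1L, verbose = FALSE)$predictions[, "1"]
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune a random forest by inner stratified cross-validation
#'
#' Grid search over (`mtry`, `ntree`) maximizing mean inner-CV AUC,
#' computed exclusively within the training data; the forest is then
#' refit on the full training subset with the chosen hyperparameters.
#' Ties take the first grid point in (`mtry`, `ntree`) order.
#'
#' @param X training feature matrix.
#' @param y training binary labels.
#' @param grid data.frame from [rf_grid()].
#' @param inner_folds stratified CV folds (default 10).
#' @param seed integer seed (controls fold assignment and forest RNG).
#' @param importance importance measure for the refit forest
#'   (`"permutation"`, the default, or `"impurity"`).
#' @return list: `fit` (ranger object), `mtry`, `ntree`, `cv_auc` (vector
#'   over grid points), `best` (row index).
#' @export
tune_random_forest <- function(X, y, grid, inner_folds = 10L, seed = 1L,
                               importance = "permutation") {
  if (nrow(grid) == 0L) stopf("empty hyperparameter grid")
  y <- as.integer(y)
  set.seed(derive_seed(seed, 7L))
  fold <- stratified_folds(y, inner_folds)
  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2L) { aucs[f] <- NA; next }
      fit <- rf_fit(X[tr, , drop = FALSE], y[tr], grid$mtry[g], grid$ntree[g],
                    seed = derive_seed(seed, 100L * g + f))
      aucs[f] <- auc_score(rf_score(fit, X[!tr, , drop = FALSE]), y[!tr])
    }
    cv_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cv_auc)          # ties: first grid point
  fit <- rf_fit(X, y, grid$mtry[best], grid$ntree[best],
                seed = derive_seed(seed, 9999L), importance = importance)
  list(fit = fit, mtry = grid$mtry[best], ntree = grid$ntree[best],
       cv_auc = cv_auc, best = best)
}

#' Rank features by forest importance
#'
#' Descending importance; ties are broken by metabolite name order.
#'
#' @param fit a ranger forest fitted with an importance measure.
#' @return data.frame `metabolite`, `importance`, sorted.
#' @export
rank_features <- function(fit) {
  imp <- ranger::importance(fit)
  ord <- order(-imp, names(imp))
  data.frame(metabolite = names(imp)[ord], importance = unname(imp)[ord],
             stringsAsFactors = FALSE)
}

#' Enumerate candidate panels from per-iteration rankings
#'
#' For each iteration's ranking and each size k, the top-k features form
#' one candidate panel; candidates with identical member sets are merged
#' across iterations.
#'
#' @param rankings list of character vectors (one ranking per iteration).
#' @param sizes panel sizes (default 1:10).
#' @return data.frame: `key` (sorted members, "|"-joined), `size`,
#'   `members` (list column), `iterations` (list column of iteration
#'   indices that proposed the panel).
#' @export
enumerate_panels <- function(rankings, sizes = 1:10) {
  if (!is.list(rankings)) rankings <- list(rankings)
  pmax_feat <- min(lengths(rankings))
  if (max(sizes) > pmax_feat)
    stopf("panel size %d exceeds feature count %d", max(sizes), pmax_feat)
  seen <- list()
  for (it in seq_along(rankings)) {
    for (k in sizes) {
      members <- rankings[[it]][seq_len(k)]
      key <- paste(sort(members), collapse = "|")
      if (is.null(seen[[key]])) {
        seen[[key]] <- list(key = key, size = k, members = members,
                            iterations = it)
      } else {
        seen[[key]]$iterations <- c(seen[[key]]$iterations, it)
      }
    }
  }
  data.frame(key = vapply(seen, `[[`, "", "key"),
             size = vapply(seen, function(s) as.integer(s$size), 0L),
             members = I(unname(lapply(seen, `[[`, "members"))),
             iterations = I(unname(lapply(seen, `[[`, "iterations"))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Evaluate a panel on a held-out test set
#'
#' Fits the forest on the training subset only and applies the
#' Youden-optimal threshold of the *training* ROC to the test scores.
#'
#' @param X feature matrix (all samples).
#' @param y binary labels.
#' @param panel character vector of member metabolites.
#' @param train,test disjoint index vectors.
#' @param mtry,ntree forest hyperparameters.
#' @param seed integer seed.
#' @return Named numeric vector: `auc`, `sensitivity`, `specificity`,
#'   `f1`, `accuracy`.
#' @export
evaluate_on_test <- function(X, y, panel, train, test,
                             mtry = max(1L, floor(sqrt(length(panel)))),
                             ntree = 500L, seed = 1L) {
  if (length(intersect(train, test))) stopf("train and test must be disjoint")
  y <- as.integer(y)
  if (length(unique(y[test])) < 2L) stopf("test set contains a single class")
  fit <- rf_fit(X[train, panel, drop = FALSE], y[train], mtry, ntree, seed)
  thr <- youden_threshold(rf_score(fit, X[train, panel, drop = FALSE]), y[train])
  sc <- rf_score(fit, X[test, panel, drop = FALSE])
  cm <- classification_metrics(sc, y[test], thr)
  c(auc = auc_score(sc, y[test]), cm[c("sensitivity", "specificity", "f1", "accuracy")])
}

#' Bootstrap validation of a panel
#'
#' B stratified resamples with replacement; the forest is refit on each
#' resample and evaluated on the out-of-resample samples, with
#' sensitivity/specificity/accuracy/F1 taken at the Youden-optimal
#' threshold of that resample's out-of-resample ROC. Replicates whose
#' out-of-resample set lacks a class are redrawn (counted and logged).
#'
#' The B refits are realized as blocks of trees inside larger ranger
#' forests sharing one resample per block (via ranger's `inbag`
#' interface), which is numerically equivalent to fitting B separate
#' forests and an order of magnitude cheaper than B separate calls.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param panel character vector of member metabolites.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param mtry,ntree forest hyperparameters for the refits.
#' @return list: `mean` and `sd` (named vectors over `auc`, `sensitivity`,
#'   `specificity`, `accuracy`, `f1`), `B`, `n_redrawn`.
#' @export
bootstrap_validate <- function(X, y, panel, B = 1000L, seed = 1L,
                               mtry = max(1L, floor(sqrt(length(panel)))),
                               ntree = 100L) {
  if (!all(panel %in% colnames(X))) stopf("panel members missing from data")
  y <- as.integer(y)
  n <- length(y)
  Xp <- X[, panel, drop = FALSE]
  idx1 <- which(y == 1L); idx0 <- which(y == 0L)
  set.seed(derive_seed(seed, 11L))
  met <- matrix(NA_real_, B, 5,
                dimnames = list(NULL, c("auc", "sensitivity", "specificity",
                                        "accuracy", "f1")))
  redrawn <- 0L
  counts <- matrix(0L, n, B)
  for (b in seq_len(B)) {
    repeat {
      boot <- c(sample(idx1, length(idx1), replace = TRUE),
                sample(idx0, length(idx0), replace = TRUE))
      cnt <- tabulate(boot, n)
      oob <- cnt == 0L
      if (sum(oob) >= 2L && length(unique(y[oob])) == 2L) break
      redrawn <- redrawn + 1L
    }
    counts[, b] <- cnt
  }
  chunk_b <- max(1L, 20000L %/% ntree)          # bound forest size / memory
  yf <- factor(y, levels = c(0, 1))
  for (b0 in seq(1L, B, by = chunk_b)) {
    bs <- b0:min(b0 + chunk_b - 1L, B)
    inbag <- rep(lapply(bs, function(b) counts[, b]), each = ntree)
    fit <- ranger::ranger(x = Xp, y = yf, num.trees = length(bs) * ntree,
                          inbag = inbag, probability = TRUE,
                          mtry = min(mtry, ncol(Xp)), num.threads = 1L,
                          seed = derive_seed(seed, 20000L + b0),
                          verbose = FALSE)
    pr <- predict(fit, Xp, predict.all = TRUE, num.threads = 1L,
                  verbose = FALSE)$predictions[, 2L, ]
    for (i in seq_along(bs)) {
      oob <- counts[, bs[i]] == 0L
      sc <- rowMeans(pr[oob, (i - 1L) * ntree + seq_len(ntree), drop = FALSE])
      thr <- youden_threshold(sc, y[oob])
      cm <- classification_metrics(sc, y[oob], thr)
      met[bs[i], ] <- c(auc_score(sc, y[oob]),
                        cm[c("sensitivity", "specificity", "accuracy", "f1")])
    }
  }
  if (redrawn > 0) log_msg("bootstrap: %d degenerate replicate(s) redrawn", redrawn)
  sds <- apply(met, 2, stats::sd)
  if (B == 1L) {
    warning("B = 1: bootstrap SDs reported as 0")
    sds[] <- 0
  }
  list(mean = colMeans(met), sd = sds, B = B, n_redrawn = redrawn)
}

#' Select the final panel by bootstrap stability, then AUC
#'
#' Within each panel size, the candidate with the lowest bootstrap AUC-SD
#' is flagged as most stable (SD ties: higher bootstrap mean AUC, then
#' member-name order); among the flagged candidates, the one with the
#' highest bootstrap mean AUC is returned (AUC ties: smaller panel, then
#' member-name order).
#'
#' @param evaluations data.frame of candidate evaluations with columns
#'   `key`, `size`, `boot_auc_mean`, `boot_auc_sd`.
#' @return The input data.frame with logical columns `stable` and `final`
#'   added; attribute `final_key` gives the selected panel key.
#' @export
select_final_panel <- function(evaluations) {
  if (nrow(evaluations) == 0L) stopf("no panel evaluations supplied")
  ev <- evaluations
  ev$stable <- FALSE
  for (k in unique(ev$size)) {
    i <- which(ev$size == k)
    o <- i[order(ev$boot_auc_sd[i], -ev$boot_auc_mean[i], ev$key[i])]
    ev$stable[o[1L]] <- TRUE
  }
  cand <- which(ev$stable)
  o <- cand[order(-ev$boot_auc_mean[cand], ev$size[cand], ev$key[cand])]
  ev$final <- FALSE
  ev$final[o[1L]] <- TRUE
  attr(ev, "final_key") <- ev$key[o[1L]]
  ev
}

#' Random forest panel discovery with bootstrap stability selection
#'
#' The full discovery procedure: over `n_iterations` stratified 70/30
#' splits, tune a forest by inner stratified CV on the training subset,
#' rank features by importance, and form top-k candidate panels for
#' k in `sizes`; pool candidates across iterations (duplicates merged),
#' evaluate each candidate on the iteration test sets where it was
#' proposed, bootstrap-validate every candidate on the full cohort, flag
#' the most stable candidate per size (lowest bootstrap AUC-SD), and
#' select the final panel as the flagged candidate with the highest
#' bootstrap mean AUC. A logistic model on the final panel over the full
#' cohort provides the headline ROC with DeLong CI.
#'
#' @param X standardized feature matrix (biological samples).
#' @param y binary labels.
#' @param scheme a [split_scheme()].
#' @param grid an [rf_grid()]; defaults to the standard grid for `ncol(X)`.
#' @param sizes candidate panel sizes (default 1:10, capped at `ncol(X)`).
#' @param B bootstrap replicates per candidate (default 1000).
#' @param boot_ntree trees per bootstrap refit.
#' @param importance importance measure for ranking.
#' @return list: `candidates` (evaluation table with bootstrap metrics and
#'   selection flags), `final` (members, bootstrap metrics, mean test
#'   metrics), `test_metrics` (per iteration x panel), `rankings`,
#'   `tuning` (chosen hyperparameters per iteration), `panel_roc`
#'   (logistic [roc_summary()] on the final panel).
#' @export
discover_panels <- function(X, y, scheme = split_scheme(), grid = NULL,
                            sizes = 1:10, B = 1000L, boot_ntree = 100L,
                            importance = "permutation") {
  y <- as.integer(y)
  p <- ncol(X)
  sizes <- sizes[sizes <= p]
  if (!length(sizes)) stopf("no feasible panel sizes for %d features", p)
  if (is.null(grid)) grid <- rf_grid(p = p)
  rankings <- vector("list", scheme$n_iterations)
  tuning <- vector("list", scheme$n_iterations)
  splits <- vector("list", scheme$n_iterations)
  for (it in seq_len(scheme$n_iterations)) {
    sp <- stratified_split(y, scheme, it)
    tn <- tune_random_forest(X[sp$train, , drop = FALSE], y[sp$train], grid,
                             scheme$inner_folds,
                             seed = derive_seed(scheme$base_seed, 50L + it),
                             importance = importance)
    rankings[[it]] <- rank_features(tn$fit)$metabolite
    tuning[[it]] <- data.frame(iteration = it, mtry = tn$mtry, ntree = tn$ntree)
    splits[[it]] <- sp
  }
  cand <- enumerate_panels(rankings, sizes)

  ## per-iteration test metrics for each candidate, on the iterations that
  ## proposed it
  test_rows <- list()
  for (i in seq_len(nrow(cand))) {
    for (it in cand$iterations[[i]]) {
      sp <- splits[[it]]
      hp <- tuning[[it]]
      m <- evaluate_on_test(X, y, cand$members[[i]], sp$train, sp$test,
                            mtry = min(hp$mtry, length(cand$members[[i]])),
                            ntree = hp$ntree,
                            seed = derive_seed(scheme$base_seed, 300L * it + i))
      test_rows[[length(test_rows) + 1L]] <-
        data.frame(key = cand$key[i], iteration = it, t(m))
    }
  }
  test_metrics <- do.call(rbind, test_rows)

  boot <- lapply(seq_len(nrow(cand)), function(i)
    bootstrap_validate(X, y, cand$members[[i]], B = B,
                       seed = derive_seed(scheme$base_seed, 700L + i),
                       ntree = boot_ntree))
  for (m in c("auc", "sensitivity", "specificity", "accuracy", "f1")) {
    cand[[paste0("boot_", m, "_mean")]] <- vapply(boot, function(b) b$mean[[m]], 0)
    cand[[paste0("boot_", m, "_sd")]] <- vapply(boot, function(b) b$sd[[m]], 0)
  }
  cand$test_auc_mean <- vapply(cand$key, function(k)
    mean(test_metrics$auc[test_metrics$key == k]), 0)
  cand <- select_final_panel(cand)

  fk <- attr(cand, "final_key")
  fi <- which(cand$key == fk)
  members <- cand$members[[fi]]
  glm_fit <- stats::glm(y ~ ., data = data.frame(y = y, X[, members, drop = FALSE]),
                        family = stats::binomial())
  panel_roc <- roc_summary(stats::fitted(glm_fit), y)
  list(candidates = cand,
       final = list(members = members, size = cand$size[fi],
                    boot_auc_mean = cand$boot_auc_mean[fi],
                    boot_auc_sd = cand$boot_auc_sd[fi],
                    boot_sensitivity_mean = cand$boot_sensitivity_mean[fi],
                    boot_specificity_mean = cand$boot_specificity_mean[fi],
                    boot_accuracy_mean = cand$boot_accuracy_mean[fi],
                    test_auc_mean = cand$test_auc_mean[fi]),
       test_metrics = test_metrics, rankings = rankings,
       tuning = do.call(rbind, tuning), panel_roc = panel_roc)
}

#' Permutation test of classifier performance
#'
#' Shuffles the outcome labels `P` times, recomputes the full modeling
#' metric for each permutation, and reports the add-one empirical p value
#' `(1 + #[null >= observed]) / (1 + P)`, which is never exactly zero.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param metric_fun function `(X, y) -> numeric` implementing the whole
#'   modeling pipeline (tuning included) and returning the performance
#'   metric; see [cv_auc_metric()] for a standard choice.
#' @param P number of permutations (default 1000).
#' @param seed integer seed.
#' @return list: `observed`, `null` (length-P numeric), `p_value`, `P`.
#' @export
permutation_test <- function(X, y, metric_fun, P = 1000L, seed = 1L) {
  if (P < 1L) stopf("P must be >= 1")
  y <- as.integer(y)
  observed <- metric_fun(X, y)
  null <- numeric(P)
  for (i in seq_len(P)) {
    set.seed(derive_seed(seed, 40000L + i))
    null[i] <- metric_fun(X, sample(y))
  }
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (1 + P), P = as.integer(P))
}

#' Cross-validated AUC metric factory
#'
#' Builds a `(X, y) -> AUC` function for [permutation_test()]: stratified
#' k-fold cross-validation with either a fixed-hyperparameter random
#' forest or a logistic model refit in every fold.
#'
#' @param folds number of stratified folds (default 5).
#' @param model `"rf"` or `"glm"`.
#' @param ntree,mtry forest hyperparameters when `model = "rf"`.
#' @param seed integer seed controlling fold assignment.
#' @return A function of `(X, y)` returning the pooled CV AUC.
#' @export
cv_auc_metric <- function(folds = 5L, model = c("rf", "glm"), ntree = 100L,
                          mtry = NULL, seed = 1L) {
  model <- match.arg(model)
  force(folds); force(ntree); force(mtry); force(seed)
  function(X, y) {
    y <- as.integer(y)
    set.seed(derive_seed(seed, 13L))
    fold <- stratified_folds(y, folds)
    sc <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (model == "rf") {
        fit <- rf_fit(X[tr, , drop = FALSE], y[tr],
                      mtry %||% max(1L, floor(sqrt(ncol(X)))), ntree,
                      seed = derive_seed(seed, 500L + f))
        sc[!tr] <- rf_score(fit, X[!tr, , drop = FALSE])
      } else {
        fit <- logistic_wald(cbind(1, X[tr, , drop = FALSE]), y[tr])
        sc[!tr] <- cbind(1, X[!tr, , drop = FALSE]) %*% fit$coef
      }
    }
    auc_score(sc, y)
  }
}
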