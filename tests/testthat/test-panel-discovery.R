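test_that("stratified splits respect class proportions and determinism", {
  y <- rep(c(1L, 0L), each = 50)
  sch <- split_scheme(train_fraction = 0.7, base_seed = 3)
  sp <- stratified_split(y, sch, iteration = 2)
  expect_equal(sum(y[sp$train] == 1), 35L)
  expect_equal(sum(y[sp$train] == 0), 35L)
  expect_equal(sum(y[sp$test] == 1), 15L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, stratified_split(y, sch, iteration = 2))
  expect_false(identical(sp, stratified_split(y, sch, iteration = 3)))
  ## 4 samples at fraction 0.5: forced 1+1 / 1+1
  sp2 <- stratified_split(c(1L, 1L, 0L, 0L), split_scheme(0.5, base_seed = 1))
  expect_equal(sum(c(1L, 1L, 0L, 0L)[sp2$train]), 1L)
  expect_length(sp2$train, 2L)
  expect_error(stratified_split(c(1L, 0L, 0L), sch), ">= 2 members")
})

test_that("rank AUC equals brute-force pair counting, and pROC agrees", {
  set.seed(1)
  for (i in 1:30) {
    n <- sample(6:30, 1)
    y <- c(1L, 0L, rbinom(n - 2, 1, 0.5))
    s <- sample(round(rnorm(n), 1))       # rounded: forces ties
    expect_equal(auc_score(s, y), auc_oracle(s, y))
  }
  y <- rep(c(1L, 0L), each = 20)
  s <- rnorm(40)
  expect_equal(auc_score(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                              direction = "<", quiet = TRUE))))
  ## antisymmetry under label swap
  expect_equal(auc_score(s, 1L - y), 1 - auc_score(s, y))
})

test_that("forest tuning maximizes inner-CV AUC within the training data", {
  sim <- signal_matrix(n1 = 35, n0 = 35, p = 12, n_signal = 4, shift = 1.2,
                       seed = 2)
  grid <- rf_grid(mtry = c(2L, 6L), ntree = c(50L, 100L))
  tn <- tune_random_forest(sim$X, sim$y, grid, inner_folds = 5, seed = 4)
  expect_equal(tn$cv_auc[tn$best], max(tn$cv_auc))
  expect_true(tn$mtry %in% grid$mtry && tn$ntree %in% grid$ntree)
  one <- tune_random_forest(sim$X, sim$y, rf_grid(mtry = 3L, ntree = 50L),
                            inner_folds = 5, seed = 4)
  expect_equal(c(one$mtry, one$ntree), c(3L, 50L))
  expect_error(tune_random_forest(sim$X, sim$y, data.frame()), "empty")
})

test_that("a label-duplicating feature dominates the importance ranking", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 80
    y <- rep(c(1L, 0L), each = 40)
    X <- cbind(oracle = y + rnorm(n, 0, 0.05),
               matrix(rnorm(n * 9), n, 9, dimnames = list(NULL, paste0("n", 1:9))))
    fit <- tune_random_forest(X, y, rf_grid(mtry = 3L, ntree = 100L),
                              inner_folds = 3, seed = s)$fit
    if (rank_features(fit)$metabolite[1] == "oracle") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("panel enumeration applies the top-k rule and merges duplicates", {
  panels <- enumerate_panels(list(c("A", "B", "C")), sizes = 1:2)
  expect_equal(panels$members, list("A", c("A", "B")), ignore_attr = TRUE)
  dup <- enumerate_panels(list(c("A", "B", "C"), c("B", "A", "C")), sizes = 1:2)
  ## {A}, {A,B} from both rankings (merged), {B} from the second
  expect_equal(nrow(dup), 3L)
  expect_equal(sort(vapply(dup$iterations, length, 0L)), c(1L, 1L, 2L))
  singles <- enumerate_panels(list(c("A", "B")), sizes = 1)
  expect_equal(unlist(singles$members), "A")
  expect_error(enumerate_panels(list(c("A", "B")), sizes = 1:5), "exceeds")
})

test_that("final-panel selection follows lowest-SD-then-highest-AUC with ties", {
  ev <- data.frame(key = c("a", "b", "c", "d", "e"),
                   size = c(3L, 3L, 5L, 5L, 1L),
                   boot_auc_mean = c(0.90, 0.85, 0.88, 0.92, 0.70),
                   boot_auc_sd = c(0.02, 0.05, 0.03, 0.03, 0.01))
  out <- select_final_panel(ev)
  ## size 3: "a" (lowest SD); size 5: SD tie -> "d" (higher AUC); size 1: "e"
  expect_setequal(out$key[out$stable], c("a", "d", "e"))
  expect_equal(attr(out, "final_key"), "d")   # highest AUC among stable
  ## across-size mean-AUC tie: smaller panel wins
  tie <- data.frame(key = c("x", "y"), size = c(2L, 4L),
                    boot_auc_mean = c(0.9, 0.9), boot_auc_sd = c(0.01, 0.01))
  expect_equal(attr(select_final_panel(tie), "final_key"), "x")
  expect_error(select_final_panel(ev[0, ]), "no panel")
})

test_that("test-set evaluation is train-only with sensible edge behavior", {
  sim <- signal_matrix(n1 = 30, n0 = 30, p = 6, n_signal = 6, shift = 4,
                       seed = 5)
  sp <- stratified_split(sim$y, split_scheme(base_seed = 6))
  m <- evaluate_on_test(sim$X, sim$y, colnames(sim$X), sp$train, sp$test,
                        seed = 7)
  expect_equal(unname(m["auc"]), 1)             # near-separable panel
  expect_error(evaluate_on_test(sim$X, sim$y, colnames(sim$X), 1:40, 30:60),
               "disjoint")
  expect_error(evaluate_on_test(sim$X, sim$y, colnames(sim$X),
                                which(sim$y == 1), which(sim$y == 0)[1:5] ,
                                ), "single class")
})

test_that("constant scores give AUC 0.5 and well-defined threshold metrics", {
  y <- rep(c(1L, 0L), each = 10)
  s <- rep(0.5, 20)
  expect_equal(auc_score(s, y), 0.5)
  cm <- classification_metrics(s, y, youden_threshold(s, y))
  expect_false(any(is.na(cm)))
  expect_true(cm["f1"] >= 0 && cm["f1"] <= 1)
})

test_that("bootstrap validation: separable panel, null panel, degenerate B", {
  ## perfectly separating panel: AUC 1 with zero spread
  y <- rep(c(1L, 0L), each = 25)
  Xsep <- cbind(sep = ifelse(y == 1, 5, -5) + rnorm(50, 0, 0.01))
  b <- bootstrap_validate(Xsep, y, "sep", B = 30, seed = 1, ntree = 25)
  expect_equal(unname(b$mean["auc"]), 1)
  expect_equal(unname(b$sd["auc"]), 0)
  ## pure-noise panel centers on 0.5
  set.seed(2)
  Xn <- matrix(rnorm(100 * 3), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  yn <- rep(c(1L, 0L), each = 50)
  bn <- bootstrap_validate(Xn, yn, c("a", "b", "c"), B = 100, seed = 3,
                           ntree = 25)
  expect_lt(abs(bn$mean["auc"] - 0.5), 0.1)
  ## B = 1 reports SD 0 with a warning
  expect_warning(b1 <- bootstrap_validate(Xn, yn, "a", B = 1, seed = 4,
                                          ntree = 10), "B = 1")
  expect_equal(unname(b1$sd["auc"]), 0)
  expect_error(bootstrap_validate(Xn, yn, "zzz", B = 5), "missing")
})

test_that("permuting test labels cannot change a train-only fitted model", {
  sim <- signal_matrix(n1 = 25, n0 = 25, p = 5, n_signal = 2, seed = 8)
  sp <- stratified_split(sim$y, split_scheme(base_seed = 9))
  y2 <- sim$y
  set.seed(10)
  y2[sp$test] <- sample(y2[sp$test])
  fit1 <- tune_random_forest(sim$X[sp$train, ], sim$y[sp$train],
                             rf_grid(mtry = 2L, ntree = 50L), 3, seed = 11)
  fit2 <- tune_random_forest(sim$X[sp$train, ], y2[sp$train],
                             rf_grid(mtry = 2L, ntree = 50L), 3, seed = 11)
  expect_identical(rank_features(fit1$fit), rank_features(fit2$fit))
  expect_identical(metabogdm:::rf_score(fit1$fit, sim$X),
                   metabogdm:::rf_score(fit2$fit, sim$X))
})

test_that("permutation p follows the add-one convention", {
  ## metric that always beats its nulls
  sentinel <- local({first <- TRUE; function(X, y) {
    if (first) {first <<- FALSE; return(2)}
    runif(1)
  }})
  pt <- permutation_test(matrix(rnorm(20), 10), rep(c(1L, 0L), 5),
                         sentinel, P = 1000, seed = 1)
  expect_equal(pt$p_value, 1 / 1001)
  expect_length(pt$null, 1000L)
  expect_error(permutation_test(matrix(rnorm(20), 10), rep(c(1L, 0L), 5),
                                sentinel, P = 0), "P must be")
})

test_that("full discovery recovers a strongly planted panel end to end", {
  sim <- signal_matrix(n1 = 30, n0 = 30, p = 25, n_signal = 4, shift = 1.6,
                       seed = 12)
  res <- suppressMessages(discover_panels(
    sim$X, sim$y, scheme = split_scheme(n_iterations = 4, inner_folds = 3,
                                        base_seed = 13),
    grid = rf_grid(mtry = 5L, ntree = 100L), sizes = 1:6, B = 60,
    boot_ntree = 25))
  expect_gte(sum(sim$signal %in% res$final$members), 3L)
  expect_true(all(c("stable", "final") %in% names(res$candidates)))
  expect_equal(sum(res$candidates$final), 1L)
  ## one stable flag per represented size
  expect_equal(sum(res$candidates$stable),
               length(unique(res$candidates$size)))
  expect_gt(res$panel_roc$auc, 0.8)
  ## deterministic under identical seeds
  res2 <- suppressMessages(discover_panels(
    sim$X, sim$y, scheme = split_scheme(n_iterations = 4, inner_folds = 3,
                                        base_seed = 13),
    grid = rf_grid(mtry = 5L, ntree = 100L), sizes = 1:6, B = 60,
    boot_ntree = 25))
  expect_identical(res$final, res2$final)
})
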