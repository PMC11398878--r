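als_hc_design <- function(...) {
  args <- list(cohort_sizes = c(ALS = 119L, HC = 150L),
               haemolysis_rate = 0, outlier_rate = 0,
               invalid_sample_count = 0L)
  args[names(list(...))] <- list(...)
  do.call(synthetic_design, args)
}

dcq_features <- function(seed, design = als_hc_design()) {
  sm <- sim_matrix(design, seed)
  dcq <- normalize_dcq(sm$matrix)
  list(x = dcq$values, labels = sm$groups[rownames(dcq$values)])
}

test_that("stratified split honours the ceiling rule and the seed", {
  ids <- sprintf("S%03d", 1:269)
  labels <- rep(c("ALS", "HC"), c(119, 150))
  plan <- stratified_split(ids, labels, 0.8, seed = 375)
  expect_length(plan$train, 216)   # ceil(0.8 * 269)
  expect_length(plan$test, 53)
  expect_length(intersect(plan$train, plan$test), 0)
  # stratification: train class counts by largest remainder
  expect_equal(sum(labels[match(plan$train, ids)] == "ALS"), 96)
  expect_equal(sum(labels[match(plan$train, ids)] == "HC"), 120)
  plan2 <- stratified_split(ids, labels, 0.8, seed = 375)
  expect_identical(plan, plan2)
  plan3 <- stratified_split(ids, labels, 0.8, seed = 101)
  expect_false(identical(plan$train, plan3$train))
})

test_that("a balanced 10-sample split at one half stays stratified", {
  ids <- letters[1:10]
  labels <- rep(c("ALS", "HC"), 5)
  plan <- stratified_split(ids, labels, 0.5, seed = 1)
  expect_length(plan$train, 5)
  counts <- table(labels[match(plan$train, ids)])
  expect_true(all(counts %in% c(2, 3)))
  expect_error(stratified_split(c("a", "b", "c"), c("ALS", "ALS", "HC"),
                                0.5, 1), "stratification")
})

test_that("confusion metrics follow their definitions and report NA, never 0", {
  perfect <- confusion_metrics(2, 0, 2, 0)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 100)

  m <- confusion_metrics(9, 2, 8, 1)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_equal(m$ppv, 100 * 9 / 11, tolerance = 1e-6)
  expect_equal(m$npv, 100 * 8 / 9, tolerance = 1e-6)
  expect_equal(m$accuracy, 85)

  deg <- confusion_metrics(0, 0, 5, 5)
  expect_equal(deg$sensitivity, 0)
  expect_true(is.na(deg$ppv))
  # accuracy recomputable from the stored counts
  expect_equal(deg$accuracy, 100 * (deg$tp + deg$tn) /
                 (deg$tp + deg$fp + deg$tn + deg$fn))
})

test_that("rank AUC matches exhaustive pair counting and is monotone-invariant", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.6, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, auc_pairs_oracle(scores, labels))
  # strictly monotone transforms leave the AUC unchanged
  expect_equal(roc_auc(exp(scores), labels)$auc, r$auc)
  expect_equal(roc_auc(10 * scores - 3, labels)$auc, r$auc)

  perfect <- roc_auc(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  flat <- roc_auc(rep(1, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(flat$auc, 0.5)
  expect_true(flat$degenerate)

  set.seed(201)
  null <- roc_auc(rnorm(2000), rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(null$auc - 0.5), 0.05)

  # cross-check against an established ROC implementation
  set.seed(211)
  s <- rnorm(60)
  l <- s + rnorm(60) > 0
  expect_equal(roc_auc(s, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("logistic design separates well-separated clouds and keeps its books", {
  f <- dcq_features(202)
  rep <- run_design_logistic(f$x, f$labels, seed = 375)
  expect_equal(rep$df_null, 215)       # 216 training samples - 1
  expect_equal(rep$df_residual, 207)   # minus 8 coefficients
  expect_gt(rep$metrics$sensitivity, 95)
  expect_gt(rep$metrics$specificity, 95)
  expect_gt(rep$auc, 0.9)
  m <- rep$metrics
  expect_equal(m$tp + m$fp + m$tn + m$fn, 53)
})

test_that("logistic coefficients are reported when the MLE exists", {
  # noisier cohorts: classes overlap, so the fit cannot separate
  noisy <- als_hc_design(sigma_target = 2 * synthetic_design()$sigma_target)
  f <- dcq_features(211, noisy)
  rep <- run_design_logistic(f$x, f$labels, seed = 375)
  expect_false(rep$separation_flag)
  expect_equal(rownames(rep$coefficients)[1], "(Intercept)")
  expect_equal(nrow(rep$coefficients), 9)
  expect_equal(colnames(rep$coefficients),
               c("estimate", "std_error", "z", "p"))
  expect_equal(rep$df_null - rep$df_residual, 8)
  expect_true(rep$null_deviance > rep$residual_deviance)
  expect_length(rep$deviance_residuals, 5)
})

test_that("label permutation drives the logistic AUC to chance", {
  f <- dcq_features(203)
  set.seed(204)
  aucs <- vapply(1:10, function(i) {
    pl <- stats::setNames(sample(f$labels), names(f$labels))
    run_design_logistic(f$x, pl, seed = 375)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("forest design is deterministic and reports Gini importances", {
  f <- dcq_features(205)
  a <- run_design_forest(f$x, f$labels, seed = 375, ntree = 200)
  b <- run_design_forest(f$x, f$labels, seed = 375, ntree = 200)
  expect_identical(a$features, b$features)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$importance, b$importance)
  expect_true(all(a$importance >= 0))
  expect_gt(a$metrics$accuracy, 85)
})

test_that("iterative removal discards uninformative features", {
  set.seed(206)
  drops_null <- vapply(1:10, function(i) {
    n <- 160
    x <- cbind(matrix(rnorm(n * 6), n, 6) +
                 outer(rep(c(1.6, 0), each = n / 2), rep(1, 6)),
               matrix(rnorm(n * 2), n, 2))
    colnames(x) <- c(paste0("sig", 1:6), paste0("null", 1:2))
    rownames(x) <- paste0("S", 1:n)
    labels <- stats::setNames(rep(c("ALS", "HC"), each = n / 2),
                              rownames(x))
    rep <- run_design_forest(x, labels, seed = 300 + i, ntree = 150)
    any(!paste0("null", 1:2) %in% rep$features)
  }, logical(1))
  expect_gte(mean(drops_null), 0.8)
})

test_that("noise features earn low importance relative to signal features", {
  set.seed(207)
  n <- 200
  x <- cbind(sig = rnorm(n) + rep(c(2, 0), each = n / 2),
             n1 = rnorm(n), n2 = rnorm(n))
  rownames(x) <- paste0("S", 1:n)
  labels <- stats::setNames(rep(c("ALS", "HC"), each = n / 2), rownames(x))
  rep <- run_design_forest(x, labels, seed = 1, iterative_removal = FALSE,
                           ntree = 200)
  expect_gt(rep$importance[["sig"]], 2 * max(rep$importance[c("n1", "n2")]))
})

test_that("cross-cohort design aligns features and absorbs global batch shifts", {
  train <- dcq_features(208, als_hc_design(cohort_sizes = c(ALS = 50L,
                                                            HC = 50L)))
  test <- dcq_features(209)
  rep <- run_design_cross_cohort(train$x, train$labels, test$x, test$labels,
                                 seed = 101, ntree = 200)
  expect_gt(rep$metrics$accuracy, 80)
  expect_gt(rep$auc, 0.9)

  # a +1-cycle shift on every target (references included) cancels in dCq;
  # base Cqs lowered so no well grazes the 40-cycle ceiling in either run
  d <- als_hc_design(base_cq = synthetic_design()$base_cq - 4)
  shifted_d <- als_hc_design(base_cq = synthetic_design()$base_cq - 3)
  plain <- dcq_features(210, d)
  shifted <- dcq_features(210, shifted_d)
  expect_equal(shifted$x, plain$x, tolerance = 1e-10)

  # disjoint feature sets are an alignment error
  x2 <- test$x
  colnames(x2) <- paste0("other_", seq_len(ncol(x2)))
  expect_error(run_design_cross_cohort(train$x, train$labels, x2,
                                       test$labels, seed = 101),
               "alignment")
})
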