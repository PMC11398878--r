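#' @title Diagnostic classifier designs
#' @description Three classification designs on normalized dCq features:
#'   logistic regression with an 80/20 split, random forest with a 79/21
#'   split and iterative low-importance feature removal, and a random forest
#'   trained on one cohort and tested on an independent one. Metric panel:
#'   confusion matrix, sensitivity/specificity/PPV/NPV/accuracy/F1 (as
#'   percentages) and ROC AUC via the rank formulation.
#' @name diagnostic_classifier
NULL

#' Stratified train/test split
#'
#' Deterministic for a fixed seed. Train size is the smallest integer >=
#' fraction * n; it is apportioned across classes by largest remainder so the
#' split stays stratified.
#'
#' @param sample_ids character vector.
#' @param labels class labels, same length; both classes need >= 2 members.
#' @param fraction train fraction in (0, 1).
#' @param seed integer seed.
#' @return Object of class `split_plan`: list with `train`, `test` (sample
#'   ids), `fraction`, `seed`.
#' @export
stratified_split <- function(sample_ids, labels, fraction, seed) {
  stopifnot(length(sample_ids) == length(labels),
            fraction > 0, fraction < 1)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("stratification error: class(es) with < 2 members: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  n <- length(sample_ids)
  n_train <- ceiling(fraction * n)
  # largest-remainder apportionment of n_train across classes
  quota <- fraction * as.numeric(tab)
  base <- floor(quota)
  rem <- quota - base
  left <- n_train - sum(base)
  if (left > 0L) {
    add <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1L
  }
  base <- pmin(base, as.numeric(tab))  # never exceed class size
  set.seed(as.integer(seed))
  train <- character(0)
  for (i in seq_along(tab)) {
    ids <- sample_ids[labels == names(tab)[i]]
    train <- c(train, sample(ids, base[i]))
  }
  structure(list(train = sort(train),
                 test = sort(setdiff(sample_ids, train)),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' Confusion-matrix metric panel
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return Named list of percentages: sensitivity, specificity, ppv, npv,
#'   accuracy, f1, plus the counts. A metric with a zero denominator is NA
#'   (not applicable), never 0.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  ppv <- rate(tp, tp + fp)
  npv <- rate(tn, tn + fn)
  acc <- rate(tp + tn, tp + fp + tn + fn)
  f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_
  else 2 * ppv * sens / (ppv + sens)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       accuracy = acc, f1 = f1)
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' AUC = P(score of a random positive > score of a random negative), with
#' ties contributing 1/2; computed from mid-ranks. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric predictor (higher = more positive).
#' @param labels logical or two-level vector; TRUE / second level = positive.
#' @return List with `auc`, `curve` (data.frame fpr/tpr, one point per
#'   distinct threshold) and `degenerate` (TRUE when scores are constant,
#'   where AUC is 0.5 by convention).
#' @export
roc_auc <- function(scores, labels) {
  pos <- as.logical(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  np <- sum(pos); nn <- sum(!pos)
  degenerate <- length(unique(scores)) == 1L
  r <- rank(scores)
  auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    fpr = c(0, vapply(thr, function(s) sum(scores >= s & !pos) / nn,
                      numeric(1))),
    tpr = c(0, vapply(thr, function(s) sum(scores >= s & pos) / np,
                      numeric(1))))
  list(auc = auc, curve = curve, degenerate = degenerate)
}

classifier_report <- function(design, seed, split, features, truth, pred,
                              scores, extra = list()) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  metrics <- confusion_metrics(tp, fp, tn, fn)
  roc <- roc_auc(scores, truth)
  structure(c(list(design = design, seed = seed, split = split,
                   features = features, metrics = metrics,
                   auc = roc$auc, roc_curve = roc$curve), extra),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("%s: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%, ",
                     "acc %.1f%%, AUC %.3f (%d features)\n"),
              x$design, m$sensitivity, m$specificity, m$ppv, m$npv,
              m$accuracy, x$auc, length(x$features)))
  invisible(x)
}

prepare_xy <- function(dcq_features, labels, positive) {
  x <- as.matrix(dcq_features)
  keep <- stats::complete.cases(x) & !is.na(labels)
  x <- x[keep, , drop = FALSE]
  y <- labels[keep] == positive
  list(x = x, y = y)
}

#' Logistic-regression design (80/20 split)
#'
#' Maximum-likelihood logistic fit of disease status on all fingerprint dCq
#' features over a stratified random train split; coefficient table with
#' estimate/SE/z/p, null and residual deviance with df, and the metric panel
#' plus ROC AUC on the held-out test samples (classification threshold 0.5).
#'
#' @param dcq_features matrix/data.frame samples x features (rownames =
#'   sample ids).
#' @param labels named or aligned vector of cohort labels.
#' @param positive label treated as the positive (disease) class.
#' @param fraction train fraction; default 0.8.
#' @param seed split seed; default 375.
#' @param roc_on "test" (default) or "all": observations used for the ROC.
#' @return A `classifier_report` with `coefficients`, `null_deviance`,
#'   `df_null`, `residual_deviance`, `df_residual`, `aic`,
#'   `deviance_residuals` (5-number summary) and `separation_flag`.
#' @export
run_design_logistic <- function(dcq_features, labels, positive = "ALS",
                                fraction = 0.8, seed = 375,
                                roc_on = c("test", "all")) {
  roc_on <- match.arg(roc_on)
  d <- prepare_xy(dcq_features, labels, positive)
  ids <- rownames(d$x)
  plan <- stratified_split(ids, d$y, fraction, seed)
  tr <- ids %in% plan$train
  df_tr <- data.frame(y = d$y[tr], d$x[tr, , drop = FALSE],
                      check.names = FALSE)
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df_tr, family = stats::binomial(),
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      # extreme fitted probabilities alone are expected with strong markers
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  # separation: IWLS failed, or coefficients diverging towards infinity
  # (beyond ~15 log-odds per dCq cycle the MLE does not exist in practice)
  separation <- !fit$converged || max(abs(stats::coef(fit))) > 15
  coefs <- summary(fit)$coefficients
  colnames(coefs) <- c("estimate", "std_error", "z", "p")
  newdata <- data.frame(d$x[!tr, , drop = FALSE], check.names = FALSE)
  prob_test <- stats::predict(fit, newdata = newdata, type = "response")
  pred <- prob_test >= 0.5
  scores <- if (roc_on == "all")
    stats::predict(fit, newdata = data.frame(d$x, check.names = FALSE),
                   type = "response") else prob_test
  roc_truth <- if (roc_on == "all") d$y else d$y[!tr]
  rep <- classifier_report(
    design = "logistic_80_20", seed = seed, split = plan,
    features = colnames(d$x), truth = d$y[!tr], pred = pred,
    scores = prob_test,
    extra = list(
      coefficients = coefs,
      null_deviance = fit$null.deviance, df_null = fit$df.null,
      residual_deviance = fit$deviance, df_residual = fit$df.residual,
      aic = fit$aic,
      fisher_iterations = fit$iter,
      deviance_residuals = stats::quantile(stats::residuals(fit,
                                                            type = "deviance"),
                                           c(0, 0.25, 0.5, 0.75, 1)),
      separation_flag = separation))
  if (roc_on == "all") {
    roc <- roc_auc(scores, roc_truth)
    rep$auc <- roc$auc
    rep$roc_curve <- roc$curve
  }
  if (separation) rep$coefficients <- NULL  # withheld: not at an MLE
  rep
}

forest_fit <- function(x, y, ntree) {
  if (length(unique(y)) < 2L)
    stop("degenerate training fold: a single class present")
  randomForest::randomForest(x = x, y = factor(y), ntree = ntree)
}

forest_eval <- function(fit, x_test, y_test) {
  pred <- stats::predict(fit, x_test) == "TRUE"
  mean(pred == y_test)
}

# Iterative removal: drop the lowest-Gini feature one at a time, tracking
# test accuracy; keep the subset with the best accuracy (ties -> fewer
# features, i.e. the later subset).
forest_iterative <- function(x_tr, y_tr, x_te, y_te, ntree) {
  feats <- colnames(x_tr)
  best <- list(features = feats, accuracy = -Inf)
  cur <- feats
  while (length(cur) >= 2L) {
    fit <- forest_fit(x_tr[, cur, drop = FALSE], y_tr, ntree)
    acc <- forest_eval(fit, x_te[, cur, drop = FALSE], y_te)
    if (acc >= best$accuracy) best <- list(features = cur, accuracy = acc)
    imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
    cur <- setdiff(cur, names(which.min(imp)))
  }
  best$features
}

#' Random-forest design (79/21 split, iterative feature removal)
#'
#' Random forest on a stratified random split; mean-decrease-in-Gini
#' importances are reported, and with `iterative_removal` the
#' lowest-importance feature is dropped one at a time, keeping the subset
#' with the best test accuracy (ties favour fewer features).
#'
#' @inheritParams run_design_logistic
#' @param fraction train fraction; default 0.79.
#' @param iterative_removal logical; default TRUE.
#' @param ntree ensemble size; default 500.
#' @return A `classifier_report` with `importance` (named numeric, mean
#'   decrease in Gini of the final model).
#' @export
run_design_forest <- function(dcq_features, labels, positive = "ALS",
                              fraction = 0.79, seed = 375,
                              iterative_removal = TRUE, ntree = 500) {
  d <- prepare_xy(dcq_features, labels, positive)
  ids <- rownames(d$x)
  plan <- stratified_split(ids, d$y, fraction, seed)
  tr <- ids %in% plan$train
  x_tr <- d$x[tr, , drop = FALSE]; y_tr <- d$y[tr]
  x_te <- d$x[!tr, , drop = FALSE]; y_te <- d$y[!tr]
  if (ncol(x_tr) < 2L) stop("need >= 2 features")
  set.seed(as.integer(seed))
  feats <- colnames(x_tr)
  if (iterative_removal)
    feats <- forest_iterative(x_tr, y_tr, x_te, y_te, ntree)
  fit <- forest_fit(x_tr[, feats, drop = FALSE], y_tr, ntree)
  prob <- stats::predict(fit, x_te[, feats, drop = FALSE],
                         type = "prob")[, "TRUE"]
  pred <- stats::predict(fit, x_te[, feats, drop = FALSE]) == "TRUE"
  classifier_report(
    design = "forest_79_21", seed = seed, split = plan, features = feats,
    truth = y_te, pred = pred, scores = prob,
    extra = list(importance =
                   randomForest::importance(fit)[, "MeanDecreaseGini"],
                 ntree = ntree))
}

#' Cross-cohort random-forest design
#'
#' Random forest trained wholly on one cohort's dCq features and evaluated
#' wholly on an independent cohort; no re-splitting. Features are aligned by
#' miRNA name; an empty intersection is an error.
#'
#' @param train_dcq,test_dcq matrices samples x features.
#' @param train_labels,test_labels cohort labels aligned with the rows.
#' @param positive positive-class label; default "ALS".
#' @param seed forest seed; default 101.
#' @inheritParams run_design_forest
#' @return A `classifier_report` (design `forest_cross_cohort`).
#' @export
run_design_cross_cohort <- function(train_dcq, train_labels,
                                    test_dcq, test_labels,
                                    positive = "ALS", seed = 101,
                                    iterative_removal = TRUE, ntree = 500) {
  common <- intersect(colnames(train_dcq), colnames(test_dcq))
  if (length(common) == 0L)
    stop("alignment error: no shared features between cohorts")
  dtr <- prepare_xy(train_dcq[, common, drop = FALSE], train_labels, positive)
  dte <- prepare_xy(test_dcq[, common, drop = FALSE], test_labels, positive)
  set.seed(as.integer(seed))
  feats <- common
  if (iterative_removal && length(common) >= 2L)
    feats <- forest_iterative(dtr$x, dtr$y, dte$x, dte$y, ntree)
  fit <- forest_fit(dtr$x[, feats, drop = FALSE], dtr$y, ntree)
  prob <- stats::predict(fit, dte$x[, feats, drop = FALSE],
                         type = "prob")[, "TRUE"]
  pred <- stats::predict(fit, dte$x[, feats, drop = FALSE]) == "TRUE"
  classifier_report(
    design = "forest_cross_cohort", seed = seed, split = NULL,
    features = feats, truth = dte$y, pred = pred, scores = prob,
    extra = list(importance =
                   randomForest::importance(fit)[, "MeanDecreaseGini"],
                 ntree = ntree))
}
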