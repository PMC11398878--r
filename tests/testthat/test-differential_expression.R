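fake_dcq <- function(values, refs = c("r1", "r2")) {
  structure(list(values = values, refs = refs,
                 excluded_samples = character(0)),
            class = "dcq_table")
}

test_that("ddCq and fold change follow the Livak definitions", {
  values <- matrix(c(2, 1, 3, 2), ncol = 1,
                   dimnames = list(paste0("S", 1:4), "t"))
  g <- stats::setNames(c("ALS", "ALS", "HC", "HC"), rownames(values))
  expr <- ddcq_fold_change(fake_dcq(values), g, control = "HC")
  # control mean dcq = 2.5
  expect_equal(unname(expr$control_baseline[["t"]]), 2.5)
  expect_equal(unname(expr$ddcq[, "t"]), c(-0.5, -1.5, 0.5, -0.5))
  expect_equal(unname(expr$fold_change[, "t"]), 2^c(0.5, 1.5, -0.5, 0.5))
  # ddcq 0 -> fold change 1; -1 -> 2; 1 -> 0.5
  expect_equal(2^-0, 1)
  expect_equal(unname(expr$fold_change["S2", "t"]) /
                 unname(expr$fold_change["S1", "t"]), 2)
})

test_that("control fold changes have geometric mean exactly one", {
  set.seed(101)
  for (i in 1:5) {
    n <- 30
    values <- matrix(rnorm(n * 3, 2, 1), n, 3,
                     dimnames = list(paste0("S", 1:n), c("a", "b", "c")))
    g <- stats::setNames(sample(c("ALS", "HC"), n, replace = TRUE),
                         rownames(values))
    g[1:4] <- "HC"  # control never empty
    expr <- ddcq_fold_change(fake_dcq(values), g, control = "HC")
    for (t in c("a", "b", "c")) {
      ctrl_fc <- expr$fold_change[g == "HC", t]
      expect_equal(exp(mean(log(ctrl_fc))), 1, tolerance = 1e-10)
      expect_equal(mean(expr$ddcq[g == "HC", t]), 0, tolerance = 1e-10)
    }
  }
})

test_that("an empty control cohort is an error", {
  values <- matrix(1:4, ncol = 1, dimnames = list(paste0("S", 1:4), "t"))
  g <- stats::setNames(rep("ALS", 4), rownames(values))
  expect_error(ddcq_fold_change(fake_dcq(values), g, control = "HC"),
               "control")
})

make_expr <- function(fc_matrix, groups) {
  structure(list(
    ddcq = -log2(fc_matrix), fold_change = fc_matrix,
    outlier_mask = matrix(FALSE, nrow(fc_matrix), ncol(fc_matrix),
                          dimnames = dimnames(fc_matrix)),
    invalid_samples = character(0),
    control_baseline = stats::setNames(rep(0, ncol(fc_matrix)),
                                       colnames(fc_matrix)),
    groups = groups, control = "HC", excluded_targets = character(0)),
    class = "expression_table")
}

test_that("single extreme cells are masked and the sample retained", {
  set.seed(102)
  n <- 400  # large enough that one displaced cell barely moves pooled SD
  fc <- matrix(2^rnorm(n * 4, 0, 0.3), n, 4,
               dimnames = list(paste0("S", 1:n), c("a", "b", "c", "d")))
  g <- stats::setNames(rep(c("ALS", "HC"), each = n / 2), rownames(fc))
  m <- mean(fc[, "a"]); s <- sd(fc[, "a"])
  fc["S5", "a"] <- m + 5 * s
  expr <- mask_outliers(make_expr(fc, g))
  expect_true(expr$outlier_mask["S5", "a"])
  expect_false("S5" %in% expr$invalid_samples)
  expect_equal(sum(expr$outlier_mask), 1L)
})

test_that("samples with half their fingerprint cells extreme are invalidated", {
  set.seed(103)
  n <- 30
  fc <- matrix(2^rnorm(n * 8, 0, 0.2), n, 8,
               dimnames = list(paste0("S", 1:n), paste0("t", 1:8)))
  g <- stats::setNames(rep(c("ALS", "HC"), each = n / 2), rownames(fc))
  for (t in paste0("t", 1:5))  # 5 of 8 >= 50%
    fc["S9", t] <- mean(fc[, t]) + 8 * sd(fc[, t])
  expr <- mask_outliers(make_expr(fc, g))
  expect_identical(expr$invalid_samples, "S9")
  expect_true(all(expr$outlier_mask["S9", ]))
})

test_that("a clean low-noise run produces no masks and no invalid samples", {
  d <- small_design(sigma_sample = 0.3, sigma_target = 0.1,
                    sigma_noise = 0.02)
  sm <- sim_matrix(d, 104)
  expr <- mask_outliers(ddcq_fold_change(normalize_dcq(sm$matrix),
                                         sm$groups))
  expect_equal(sum(expr$outlier_mask), 0L)
  expect_identical(expr$invalid_samples, character(0))
})

test_that("zero-SD targets mask nothing", {
  fc <- matrix(1, 10, 1, dimnames = list(paste0("S", 1:10), "t"))
  g <- stats::setNames(rep(c("ALS", "HC"), each = 5), rownames(fc))
  expr <- mask_outliers(make_expr(fc, g))
  expect_equal(sum(expr$outlier_mask), 0L)
})

test_that("fold regulation is signed, reciprocal and bounded away from zero", {
  expect_equal(fold_regulation(ratio = 1), 1)
  expect_equal(fold_regulation(ratio = 0.5), -2)
  expect_equal(fold_regulation(ratio = 1 / 7.38), -7.38)
  set.seed(105)
  for (r in exp(runif(20, log(1.01), log(50)))) {
    expect_equal(fold_regulation(ratio = r),
                 -fold_regulation(ratio = 1 / r), tolerance = 1e-12)
    expect_gte(abs(fold_regulation(ratio = r)), 1)
    expect_gte(abs(fold_regulation(ratio = 1 / r)), 1)
  }
  expect_true(is.na(fold_regulation(ratio = 0)))
})

test_that("Kruskal-Wallis matches the rank-formula oracle and handles ties", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  g <- rep(c("A", "B", "C", "D"), each = 3)
  fc <- matrix(vals, ncol = 1, dimnames = list(paste0("S", 1:12), "t"))
  expr <- make_expr(fc, stats::setNames(g, rownames(fc)))
  kw <- kruskal_wallis(expr)
  expect_equal(kw$H, kw_h_oracle(vals, g), tolerance = 1e-12)
  expect_equal(kw$df, 3L)

  const <- make_expr(matrix(5, 12, 1,
                            dimnames = list(paste0("S", 1:12), "t")),
                     stats::setNames(g, paste0("S", 1:12)))
  kwc <- kruskal_wallis(const)
  expect_equal(kwc$H, 0)
  expect_equal(kwc$p_kw, 1)
})

test_that("chi-square p approximates the exhaustive permutation p", {
  # strong-effect fixture: both p-values are small and close
  vals <- c(1, 2, 3, 14, 15, 16, 27, 28)
  g <- c("A", "A", "A", "B", "B", "B", "C", "C")
  fc <- matrix(vals, ncol = 1, dimnames = list(paste0("S", 1:8), "t"))
  expr <- make_expr(fc, stats::setNames(g, rownames(fc)))
  p_chisq <- kruskal_wallis(expr)$p_kw
  h_obs <- kw_h_oracle(vals, g)
  set.seed(106)
  perm <- replicate(2000, kw_h_oracle(vals, sample(g)))
  p_perm <- mean(perm >= h_obs - 1e-9)
  expect_lt(abs(p_chisq - p_perm), 0.05)
})

test_that("Mann-Whitney agrees with enumeration and normal-theory oracles", {
  g2 <- function(x, y) {
    fc <- matrix(c(x, y), ncol = 1,
                 dimnames = list(paste0("S", seq_along(c(x, y))), "t"))
    make_expr(fc, stats::setNames(rep(c("ALS", "HC"), c(length(x),
                                                        length(y))),
                                  rownames(fc)))
  }
  # {1,2,3} vs {4,5,6}: U = 0, exact two-tailed p = 0.1
  r <- mann_whitney_posthoc(g2(c(1, 2, 3), c(4, 5, 6)),
                            pairs = list(c("ALS", "HC")), gate_kw = FALSE)
  expect_equal(r$U, 0)
  expect_equal(r$p_mw, 0.1)
  expect_equal(r$p_mw, mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)))
  expect_match(r$method, "exact")

  # identical groups: |Z| ~ 0, p ~ 1
  same <- mann_whitney_posthoc(g2(c(1, 2, 3), c(1, 2, 3)),
                               pairs = list(c("ALS", "HC")), gate_kw = FALSE)
  expect_lt(same$Z, 1e-9)
  expect_equal(same$p_mw, 1)

  # |Z| is symmetric in the group order
  a <- mann_whitney_posthoc(g2(c(1, 5, 7, 9), c(2, 3, 4, 8)),
                            pairs = list(c("ALS", "HC")), gate_kw = FALSE)
  b <- mann_whitney_posthoc(g2(c(2, 3, 4, 8), c(1, 5, 7, 9)),
                            pairs = list(c("ALS", "HC")), gate_kw = FALSE)
  expect_equal(a$Z, b$Z)

  # tie-corrected normal approximation matches wilcox.test(correct = FALSE)
  set.seed(107)
  x <- round(rnorm(15, 10, 2), 1)
  y <- round(rnorm(12, 11, 2), 1)
  y[1] <- x[1]  # force a tie
  r2 <- mann_whitney_posthoc(g2(x, y), pairs = list(c("ALS", "HC")),
                             gate_kw = FALSE)
  w <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE,
                                           exact = FALSE))
  expect_equal(r2$U, unname(w$statistic))
  expect_equal(r2$p_mw, w$p.value, tolerance = 1e-10)
})

test_that("post hoc tests are gated on the Kruskal-Wallis result", {
  set.seed(108)
  n <- 24
  null_fc <- matrix(2^rnorm(n, 0, 0.5), ncol = 1,
                    dimnames = list(paste0("S", 1:n), "null_t"))
  g <- stats::setNames(rep(c("ALS", "HC", "PD"), each = n / 3),
                       rownames(null_fc))
  expr <- make_expr(null_fc, g)
  gated <- mann_whitney_posthoc(expr, pairs = list(c("ALS", "HC")),
                                gate_kw = TRUE)
  ungated <- mann_whitney_posthoc(expr, pairs = list(c("ALS", "HC")),
                                  gate_kw = FALSE)
  expect_equal(nrow(ungated), 1L)
  expect_true(nrow(gated) %in% c(0L, 1L))
  if (kruskal_wallis(expr)$p_kw >= 0.05) expect_equal(nrow(gated), 0L)
})

test_that("compare_groups assembles the statistics-table surfaces", {
  d <- small_design(cohort_sizes = c(ALS = 10L, HC = 12L, PD = 6L, PLS = 6L))
  sm <- sim_matrix(d, 109)
  expr <- mask_outliers(ddcq_fold_change(normalize_dcq(sm$matrix),
                                         sm$groups))
  gc <- compare_groups(expr, gate_kw = FALSE)
  expect_s3_class(gc$kw, "data.frame")
  expect_true(all(gc$kw$H >= 0, na.rm = TRUE))
  expect_true(all(gc$mw$p_mw >= 0 & gc$mw$p_mw <= 1))
  expect_true(all(abs(gc$fold_regulation$fold_regulation) >= 1,
                  na.rm = TRUE))
  expect_setequal(gc$medians$target, fingerprint_targets())
})
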