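#' @title Relative quantification and group comparison
#' @description Livak 2^-ddCq fold changes against a control cohort,
#'   4-SD extreme-outlier masking with the >= 50% invalid-sample rule,
#'   signed fold regulation, and Kruskal-Wallis + Mann-Whitney group
#'   comparison on fold changes.
#' @name differential_expression
NULL

#' ddCq and fold change against a control cohort
#'
#' ddcq(s, t) = dcq(s, t) - mean over control samples of dcq(., t);
#' fold_change = 2^-ddcq. By construction the control group's mean ddcq is 0
#' per target and the geometric mean of its fold changes is exactly 1.
#'
#' @param dcq a [normalize_dcq()] result.
#' @param groups named character vector sample_id -> cohort.
#' @param control control cohort label (default "HC").
#' @return Object of class `expression_table`: list with `ddcq` and
#'   `fold_change` matrices, `outlier_mask` (all FALSE until
#'   [mask_outliers()]), `invalid_samples`, `control_baseline` (per-target
#'   mean control dcq), `groups`, `excluded_targets`.
#' @export
ddcq_fold_change <- function(dcq, groups, control = "HC") {
  stopifnot(inherits(dcq, "dcq_table"))
  v <- dcq$values
  g <- groups[rownames(v)]
  ctrl <- v[g == control & !is.na(g), , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("control cohort ", control, " is empty")
  baseline <- colMeans(ctrl, na.rm = TRUE)
  excluded <- colnames(v)[is.nan(baseline)]
  if (length(excluded) > 0L) {
    v <- v[, !colnames(v) %in% excluded, drop = FALSE]
    baseline <- baseline[!names(baseline) %in% excluded]
  }
  ddcq <- sweep(v, 2L, baseline)
  structure(list(ddcq = ddcq, fold_change = 2^(-ddcq),
                 outlier_mask = matrix(FALSE, nrow(ddcq), ncol(ddcq),
                                       dimnames = dimnames(ddcq)),
                 invalid_samples = character(0),
                 control_baseline = baseline,
                 groups = g, control = control,
                 excluded_targets = excluded),
            class = "expression_table")
}

#' Mask extreme outliers and invalidate compromised samples
#'
#' Single pass, on the fold-change scale: per target, the mean and SD are
#' pooled over all unmasked samples of all cohorts; cells with
#' |fold_change - mean| > sd_mult * SD are masked. Samples whose masked
#' fraction over the fingerprint targets reaches `invalid_frac` are removed
#' entirely (all their cells masked) and listed in `invalid_samples`. No
#' re-iteration after masking, so one extreme batch cannot cascade into
#' removing ordinary samples.
#'
#' @param expr an [ddcq_fold_change()] result.
#' @param sd_mult SD multiplier; default 4.
#' @param invalid_frac masked-fraction threshold for whole-sample removal;
#'   default 0.5.
#' @return The `expression_table` with `outlier_mask` and `invalid_samples`
#'   filled in, plus `n_masked_cells` (extreme cells outside invalid
#'   samples).
#' @export
mask_outliers <- function(expr, sd_mult = 4, invalid_frac = 0.5) {
  stopifnot(inherits(expr, "expression_table"))
  fc <- expr$fold_change
  mask <- expr$outlier_mask
  for (t in colnames(fc)) {
    v <- fc[, t]
    ok <- !is.na(v)
    if (sum(ok) < 3L) next
    m <- mean(v[ok]); s <- stats::sd(v[ok])
    if (!is.finite(s) || s == 0) next  # degenerate zero-SD target: nothing masked
    mask[ok, t] <- abs(v[ok] - m) > sd_mult * s
  }
  # invalid fraction computed over cells with data only
  has <- !is.na(fc)
  frac <- ifelse(rowSums(has) > 0L, rowSums(mask & has) / rowSums(has), 0)
  invalid <- rownames(fc)[frac >= invalid_frac]
  n_masked_cells <- sum(mask[!rownames(fc) %in% invalid, , drop = FALSE])
  mask[invalid, ] <- TRUE
  expr$outlier_mask <- mask
  expr$invalid_samples <- invalid
  expr$n_masked_cells <- n_masked_cells
  expr
}

#' Signed fold regulation
#'
#' ratio = mean fold change of the numerator cohort over that of the
#' denominator cohort; fold regulation equals the ratio when >= 1 and
#' -1/ratio otherwise, so |FR| >= 1 always and FR(r) = -FR(1/r).
#'
#' @param group_means named numeric vector (or single ratio via `ratio=`).
#' @param numerator,denominator cohort labels.
#' @param ratio optionally, the ratio directly (overrides group_means).
#' @return Signed fold regulation (numeric).
#' @export
fold_regulation <- function(group_means = NULL, numerator = "ALS",
                            denominator = "HC", ratio = NULL) {
  if (is.null(ratio)) {
    if (!numerator %in% names(group_means) ||
        !denominator %in% names(group_means))
      return(NA_real_)
    num <- group_means[[numerator]]
    den <- group_means[[denominator]]
    if (is.na(num) || is.na(den) || num <= 0 || den <= 0)
      return(NA_real_)
    ratio <- num / den
  }
  if (is.na(ratio) || ratio <= 0) return(NA_real_)
  if (ratio >= 1) ratio else -1 / ratio
}

masked_values <- function(expr, target) {
  v <- expr$fold_change[, target]
  v[expr$outlier_mask[, target]] <- NA
  v
}

#' Kruskal-Wallis test per target
#'
#' Rank-based H with tie correction (via [stats::kruskal.test]) on fold
#' changes, all cohorts; p from chi-square with (groups - 1) df. Masked
#' cells and invalid samples are excluded.
#'
#' @param expr an `expression_table` (after [mask_outliers()] or not).
#' @return data.frame per target: H, df, p_kw, n, plus attribute
#'   `critical_value` (chi-square critical value at p = 0.001).
#' @export
kruskal_wallis <- function(expr) {
  stopifnot(inherits(expr, "expression_table"))
  g <- expr$groups
  out <- lapply(colnames(expr$fold_change), function(t) {
    v <- masked_values(expr, t)
    ok <- !is.na(v) & !is.na(g)
    gt <- g[ok]
    if (length(unique(gt)) < 2L)
      return(data.frame(target = t, H = NA_real_, df = NA_integer_,
                        p_kw = NA_real_, n = sum(ok),
                        note = "fewer than 2 groups with data",
                        stringsAsFactors = FALSE))
    if (length(unique(v[ok])) == 1L)  # all ties: tie-corrected H is 0
      return(data.frame(target = t, H = 0, df = length(unique(gt)) - 1L,
                        p_kw = 1, n = sum(ok), note = "constant values",
                        stringsAsFactors = FALSE))
    kt <- stats::kruskal.test(v[ok], factor(gt))
    data.frame(target = t, H = unname(kt$statistic),
               df = unname(kt$parameter), p_kw = kt$p.value, n = sum(ok),
               note = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  dfs <- res$df[!is.na(res$df)]
  if (length(dfs) > 0L)
    attr(res, "critical_value") <- stats::qchisq(0.999, df = dfs[1L])
  res
}

# Mann-Whitney U, tie-corrected Z (no continuity correction), two-tailed p.
# For total n <= 8 without ties (too small for the normal approximation)
# the exact distribution is used instead.
mw_u_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  N <- m + n
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  mu <- m * n / 2
  sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  method <- "normal approximation (tie-corrected, no continuity correction)"
  if (N <= 8L && tie_term == 0) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    method <- "exact enumeration (small n)"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = U, Z = abs(z), p = min(p, 1), method = method)
}

#' Mann-Whitney post hoc comparisons per target
#'
#' Two-tailed Mann-Whitney tests on fold changes for the requested cohort
#' pairs; U, |Z| (tie-corrected normal approximation without continuity
#' correction) and p are reported. By default pairs are only tested for
#' targets whose Kruskal-Wallis null was rejected (gating configurable).
#'
#' @param expr an `expression_table`.
#' @param pairs list of length-2 character vectors of cohort labels; default
#'   ALS vs HC, ALS vs PLS, ALS vs PD.
#' @param gate_kw logical; when TRUE (default) only targets with
#'   KW p < `alpha` are tested.
#' @param alpha gating level, default 0.05.
#' @return data.frame: target, group1, group2, U, Z (absolute), p_mw, method.
#' @export
mann_whitney_posthoc <- function(expr,
                                 pairs = list(c("ALS", "HC"),
                                              c("ALS", "PLS"),
                                              c("ALS", "PD")),
                                 gate_kw = TRUE, alpha = 0.05) {
  stopifnot(inherits(expr, "expression_table"))
  g <- expr$groups
  targets <- colnames(expr$fold_change)
  if (gate_kw) {
    kw <- kruskal_wallis(expr)
    targets <- kw$target[!is.na(kw$p_kw) & kw$p_kw < alpha]
  }
  rows <- list()
  for (t in targets) {
    v <- masked_values(expr, t)
    for (pr in pairs) {
      x <- v[!is.na(v) & g == pr[1L] & !is.na(g)]
      y <- v[!is.na(v) & g == pr[2L] & !is.na(g)]
      if (length(x) == 0L || length(y) == 0L) next
      res <- mw_u_test(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        target = t, group1 = pr[1L], group2 = pr[2L],
        U = res$U, Z = res$Z, p_mw = res$p, method = res$method,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(target = character(0), group1 = character(0),
                      group2 = character(0), U = numeric(0), Z = numeric(0),
                      p_mw = numeric(0), method = character(0)))
  do.call(rbind, rows)
}

#' Full group comparison (statistics table shape)
#'
#' Per target: Kruskal-Wallis H and p over all cohorts, Mann-Whitney |Z| and
#' p for the standard pairs, group medians of fold change, and signed fold
#' regulation from group means (medians are reported alongside; regulation
#' direction labels follow the sign).
#'
#' @param expr an `expression_table`.
#' @param comparisons list of c(numerator, denominator) cohort pairs for fold
#'   regulation; default ALS/HC, PD/ALS, PLS/ALS.
#' @inheritParams mann_whitney_posthoc
#' @return Object of class `group_comparison`: list with `kw`, `mw`,
#'   `medians`, `fold_regulation` data.frames.
#' @export
compare_groups <- function(expr,
                           comparisons = list(c("ALS", "HC"),
                                              c("PD", "ALS"),
                                              c("PLS", "ALS")),
                           gate_kw = TRUE, alpha = 0.05) {
  stopifnot(inherits(expr, "expression_table"))
  g <- expr$groups
  kw <- kruskal_wallis(expr)
  mw <- mann_whitney_posthoc(expr, gate_kw = gate_kw, alpha = alpha)
  cohorts <- sort(unique(g[!is.na(g)]))
  med <- t(sapply(colnames(expr$fold_change), function(t) {
    v <- masked_values(expr, t)
    vapply(cohorts, function(cc) stats::median(v[g == cc & !is.na(g)],
                                               na.rm = TRUE), numeric(1))
  }))
  means <- t(sapply(colnames(expr$fold_change), function(t) {
    v <- masked_values(expr, t)
    vapply(cohorts, function(cc) mean(v[g == cc & !is.na(g)], na.rm = TRUE),
           numeric(1))
  }))
  fr <- do.call(rbind, lapply(colnames(expr$fold_change), function(t) {
    rows <- lapply(comparisons, function(pr) {
      frv <- fold_regulation(means[t, ], numerator = pr[1L],
                             denominator = pr[2L])
      data.frame(target = t, numerator = pr[1L], denominator = pr[2L],
                 fold_regulation = frv,
                 regulation = ifelse(is.na(frv), NA_character_,
                                     ifelse(frv >= 1, "Up-regulated",
                                            "Down-regulated")),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  structure(list(kw = kw, mw = mw,
                 medians = data.frame(target = rownames(med), med,
                                      row.names = NULL,
                                      stringsAsFactors = FALSE),
                 group_means = data.frame(target = rownames(means), means,
                                          row.names = NULL,
                                          stringsAsFactors = FALSE),
                 fold_regulation = fr),
            class = "group_comparison")
}
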