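#' @title Reference validation and dCq normalization
#' @description Model-based reference stability (variance-components
#'   decomposition in the manner of NormFinder, Andersen et al. 2004),
#'   pairwise variation of normalization factors (Vandesompele et al. 2002),
#'   and normalized dCq computation against the geometric mean of the
#'   reference miRNAs.
#' @name reference_normalization
NULL

#' Model-based reference stability
#'
#' Works on the log2-expression scale x = -Cq (amplification efficiency 2
#' assumed). Per candidate i and cohort j the sample effect (mean over all
#' candidates of a sample's x) is removed, then:
#' \itemize{
#'   \item intra-group variance s2_ij: residual variance of candidate i in
#'     group j after two-way (candidate x sample) centering, rescaled by
#'     1/(1 - 1/I) to undo the candidate-centering shrinkage;
#'   \item inter-group bias b_ij: the candidate-by-group interaction, i.e.
#'     candidate i's deviation in group j beyond its overall deviation.
#' }
#' The stability value is mean_j ( |b_ij| + sqrt(s2_ij / n_j) ): systematic
#' group bias plus the standard error of the candidate's group level. Lower
#' is more stable. The Bayesian shrinkage of the original NormFinder software
#' is not applied.
#'
#' @param matrix a `cq_matrix`.
#' @param groups named character vector sample_id -> cohort.
#' @param candidates candidate target names (>= 2).
#' @return Object of class `stability_table`: data.frame with per-candidate
#'   `stability`, mean absolute inter-group bias and mean intra-group
#'   variance, ranked ascending by stability. With a single group, falls back
#'   to ranking by plain SD with a warning.
#' @export
normfinder_stability <- function(matrix, groups, candidates) {
  stopifnot(inherits(matrix, "cq_matrix"))
  miss <- setdiff(candidates, colnames(matrix$values))
  if (length(miss) > 0L)
    stop("candidate(s) absent from matrix: ", paste(miss, collapse = ", "))
  if (length(candidates) < 2L) stop("need >= 2 candidates")
  x <- -matrix$values[, candidates, drop = FALSE]  # log2 expression
  x <- x[stats::complete.cases(x), , drop = FALSE]
  g <- groups[rownames(x)]
  tab <- table(g)
  usable <- names(tab)[tab >= 2L]
  if (length(usable) < 2L) {
    warning("fewer than 2 groups with >= 2 samples: ranking by SD only")
    s <- apply(x, 2L, stats::sd)
    out <- data.frame(target = candidates, stability = s,
                      mean_abs_bias = NA_real_, mean_intra_var = s^2,
                      stringsAsFactors = FALSE)
    out <- out[order(out$stability), ]
    rownames(out) <- NULL
    class(out) <- c("stability_table", "data.frame")
    return(out)
  }
  x <- x[g %in% usable, , drop = FALSE]
  g <- g[g %in% usable]
  I <- length(candidates)
  # remove per-sample effect
  z <- x - rowMeans(x)
  grand <- colMeans(z)  # overall candidate deviations
  bias <- matrix(NA_real_, I, length(usable),
                 dimnames = list(candidates, usable))
  intra <- bias
  for (j in usable) {
    zj <- z[g == j, , drop = FALSE]
    nj <- nrow(zj)
    mj <- colMeans(zj)
    bias[, j] <- mj - grand
    resid <- sweep(zj, 2L, mj)
    v <- colSums(resid^2) / (nj - 1)
    intra[, j] <- if (I > 1) v / (1 - 1 / I) else v
  }
  nj <- as.numeric(tab[usable])
  se <- sweep(sqrt(intra), 2L, sqrt(nj), "/")
  stability <- rowMeans(abs(bias) + se)
  out <- data.frame(target = candidates, stability = stability,
                    mean_abs_bias = rowMeans(abs(bias)),
                    mean_intra_var = rowMeans(intra),
                    stringsAsFactors = FALSE)
  out <- out[order(out$stability), ]
  rownames(out) <- NULL
  attr(out, "bias") <- bias
  attr(out, "intra_var") <- intra
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Pairwise variation of normalization factors
#'
#' NF_n per sample is the arithmetic mean Cq of the best n candidates
#' (equivalently the log2 geometric mean of their linear expressions). V[n]
#' is the SD over samples of NF_n - NF_(n+1), in cycle (log2-ratio) units.
#' V[3] < threshold (default 0.15) means a fourth reference adds nothing.
#'
#' @param matrix a `cq_matrix`.
#' @param ranked candidate targets, best first (e.g. a
#'   [normfinder_stability()] ranking).
#' @param threshold pass threshold applied to V[3]; default 0.15.
#' @return Object of class `pairwise_variation`: list with `V` (named numeric
#'   V1, V2, ...), `pass_3_4` (logical, NA with a truncation note when fewer
#'   than 4 candidates), `n_samples` (pairwise-complete count per V entry)
#'   and `note`.
#' @export
pairwise_variation <- function(matrix, ranked, threshold = 0.15) {
  stopifnot(inherits(matrix, "cq_matrix"))
  miss <- setdiff(ranked, colnames(matrix$values))
  if (length(miss) > 0L)
    stop("candidate(s) absent from matrix: ", paste(miss, collapse = ", "))
  k <- length(ranked)
  if (k < 2L) stop("need >= 2 ranked candidates")
  x <- matrix$values[, ranked, drop = FALSE]
  V <- numeric(k - 1L)
  n_used <- integer(k - 1L)
  for (n in seq_len(k - 1L)) {
    nf_n <- rowMeans(x[, seq_len(n), drop = FALSE])
    nf_n1 <- rowMeans(x[, seq_len(n + 1L), drop = FALSE])
    d <- nf_n - nf_n1
    d <- d[!is.na(d)]
    n_used[n] <- length(d)
    V[n] <- stats::sd(d)
  }
  names(V) <- paste0("V", seq_len(k - 1L))
  note <- ""
  if (k >= 4L) {
    pass <- V[["V3"]] < threshold
  } else {
    pass <- NA
    note <- sprintf("series truncated at V%d: only %d candidates; V3/4 not evaluable",
                    k - 1L, k)
  }
  structure(list(V = V, pass_3_4 = pass, threshold = threshold,
                 n_samples = n_used, note = note),
            class = "pairwise_variation")
}

#' Normalized dCq per sample and fingerprint target
#'
#' dcq(s, t) = Cq(s, t) - mean over references r of Cq(s, r): subtracting the
#' arithmetic mean Cq of the references is the log2 form of dividing by the
#' geometric mean of their linear expressions. Lower dcq = higher relative
#' expression. A cell is absent if the target Cq or any reference Cq is
#' missing; samples with all references missing are excluded and reported.
#'
#' @param matrix a `cq_matrix` (normally IPC-calibrated).
#' @param refs reference target names; default [reference_targets()].
#' @param targets targets to normalize; default the fingerprint panel.
#' @return Object of class `dcq_table`: list with `values` (matrix samples x
#'   targets of dcq, cycles), `refs`, `excluded_samples`.
#' @export
normalize_dcq <- function(matrix, refs = reference_targets(),
                          targets = fingerprint_targets()) {
  stopifnot(inherits(matrix, "cq_matrix"))
  miss <- setdiff(c(refs, targets), colnames(matrix$values))
  if (length(miss) > 0L)
    stop("target(s) absent from matrix: ", paste(miss, collapse = ", "))
  refm <- matrix$values[, refs, drop = FALSE]
  any_ref_missing <- rowSums(is.na(refm)) > 0L
  ref_mean <- rowMeans(refm)  # NA if any reference missing
  dcq <- matrix$values[, targets, drop = FALSE] - ref_mean
  excluded <- rownames(refm)[rowSums(!is.na(refm)) == 0L]
  structure(list(values = dcq, refs = refs,
                 excluded_samples = excluded,
                 any_ref_missing = any_ref_missing),
            class = "dcq_table")
}
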