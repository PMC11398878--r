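# Small designs and independent oracles used across the suite.

# compact 2-plate design, moderate noise
small_design <- function(...) {
  args <- list(
    cohort_sizes = c(ALS = 8L, HC = 10L, PD = 4L, PLS = 4L),
    sigma_sample = 0.8, sigma_noise = 0.1,
    haemolysis_rate = 0, outlier_rate = 0, invalid_sample_count = 0L,
    samples_per_plate = 14L)
  args[names(list(...))] <- list(...)
  do.call(synthetic_design, args)
}

# noise-free design: every Cq equals its expected value
quiet_design <- function(...) {
  small_design(sigma_sample = 0, sigma_target = 0, sigma_noise = 0,
               plate_offsets = 0,
               effect_log2fc = 0 * default_effect_log2fc_fixture(), ...)
}

default_effect_log2fc_fixture <- function() {
  d <- synthetic_design()
  d$effect_log2fc
}

sim_matrix <- function(design, seed, calibrate = TRUE) {
  sim <- simulate_run(design, seed)
  m <- build_cq_matrix(sim$run)
  if (calibrate) m <- apply_calibration(m, ipc_factors(sim$run))
  list(sim = sim, matrix = m,
       groups = stats::setNames(sim$run$metadata$cohort,
                                sim$run$metadata$sample_id))
}

# --- independent oracles -------------------------------------------------

# Kruskal-Wallis H by the textbook rank formula with tie correction
kw_h_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * (mean(x) - (N + 1) / 2)^2))
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# exact two-tailed Mann-Whitney p by full enumeration of group assignments
mw_exact_oracle <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  combos <- utils::combn(n, m)
  mu <- m * (n - m) / 2
  us <- apply(combos, 2L, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  })
  # two-tailed: as extreme or more, by distance from the mean U
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# AUC by exhaustive positive/negative pair counting
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# NormFinder-style stability via an lm()-based variance-component route:
# per group, two-way fit x ~ candidate + sample; per-candidate residual
# variance rescaled by 1/(1 - 1/I); bias from group-level candidate means.
normfinder_oracle <- function(values, groups, candidates) {
  x <- -values[, candidates, drop = FALSE]
  I <- length(candidates)
  g <- groups[rownames(x)]
  z <- x - rowMeans(x)
  grand <- colMeans(z)
  gl <- sort(unique(g))
  per_group <- lapply(gl, function(j) {
    zj <- z[g == j, , drop = FALSE]
    nj <- nrow(zj)
    long <- data.frame(
      v = as.vector(zj),
      cand = factor(rep(candidates, each = nj), levels = candidates),
      samp = factor(rep(rownames(zj), times = I)))
    fit <- stats::lm(v ~ cand + samp, data = long)
    res <- matrix(stats::residuals(fit), nrow = nj,
                  dimnames = list(rownames(zj), candidates))
    list(bias = colMeans(zj) - grand,
         var = colSums(res^2) / (nj - 1) / (1 - 1 / I),
         n = nj)
  })
  st <- sapply(candidates, function(cand) {
    mean(vapply(per_group, function(pg)
      abs(pg$bias[[cand]]) + sqrt(pg$var[[cand]] / pg$n), numeric(1)))
  })
  st
}

# all distinct arrangements of a multiset of group labels
combinat_perms <- function(labels) {
  tab <- table(labels)
  n <- length(labels)
  place <- function(slots, remaining) {
    if (length(remaining) == 0L) return(list(slots))
    lab <- names(remaining)[1L]
    k <- remaining[[1L]]
    free <- which(is.na(slots))
    out <- list()
    for (idx in utils::combn(length(free), k, simplify = FALSE)) {
      s2 <- slots
      s2[free[idx]] <- lab
      out <- c(out, place(s2, remaining[-1L]))
    }
    out
  }
  place(rep(NA_character_, n), as.list(tab))
}

# pairwise variation directly from normalization-factor log ratios
pairwise_variation_oracle <- function(values, ranked) {
  k <- length(ranked)
  vapply(seq_len(k - 1L), function(n) {
    nf_a <- apply(values[, ranked[seq_len(n)], drop = FALSE], 1L, mean)
    nf_b <- apply(values[, ranked[seq_len(n + 1L)], drop = FALSE], 1L, mean)
    stats::sd(nf_a - nf_b, na.rm = TRUE)
  }, numeric(1))
}
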