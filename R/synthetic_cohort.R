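#' @title Synthetic cohort generator
#' @description Plate-structured Cq data with known ground truth: Gaussian
#'   noise on the cycle (log2-expression) scale, cohort effects on the
#'   fingerprint targets, plate offsets, spike-ins, IPC triplicates, NTC
#'   wells, and optional haemolysis / extreme-outlier / invalid-sample
#'   corruption.
#' @name synthetic_cohort
NULL

default_base_cq <- function() {
  c("miR-10b-5p" = 33.5, "miR-4454" = 31.0, "miR-199a-3p" = 32.5,
    "miR-151a-3p" = 31.5, "miR-151a-5p" = 32.0, "miR-199a-5p" = 34.5,
    "miR-146a-5p" = 30.8, "miR-29b-3p" = 33.8,
    "miR-126-5p" = 30.0,
    "miR-142-3p" = 30.5, "miR-451a" = 25.0, "miR-23a-3p" = 29.0,
    "miR-30c-5p" = 30.0, "miR-103a-3p" = 29.5, "miR-191-5p" = 28.5,
    "UniSp2" = 19.0, "UniSp4" = 26.0, "UniSp5" = 33.0,
    "UniSp6" = 19.0, "cel-miR-39-3p" = 21.0)
}

default_sigma_target <- function() {
  # per-target biological SD (cycles). Strongly dysregulated miRNAs vary
  # more across patients; references are the most stable by construction.
  c("miR-10b-5p" = 0.9, "miR-4454" = 0.9, "miR-199a-3p" = 0.75,
    "miR-151a-3p" = 0.80, "miR-151a-5p" = 1.00, "miR-199a-5p" = 1.00,
    "miR-146a-5p" = 0.5, "miR-29b-3p" = 0.5,
    "miR-126-5p" = 0.30,
    "miR-142-3p" = 1.0, "miR-451a" = 1.0, "miR-23a-3p" = 1.0,
    "miR-30c-5p" = 1.0, "miR-103a-3p" = 1.0, "miR-191-5p" = 1.0)
}

default_effect_log2fc <- function() {
  # ALS vs HC log2 fold changes implied by the fingerprint's fold
  # regulations: FR >= 1 -> log2(FR); FR <= -1 -> -log2(-FR)
  fr <- c("miR-10b-5p" = -7.38, "miR-4454" = -2.55, "miR-199a-3p" = 2.03,
          "miR-151a-3p" = 2.09, "miR-151a-5p" = 1.77, "miR-199a-5p" = 2.54,
          "miR-146a-5p" = 1.57, "miR-29b-3p" = -1.35)
  l2 <- fr
  l2[fr >= 1] <- log2(fr[fr >= 1])
  l2[fr <= -1] <- -log2(-fr[fr <= -1])
  eff <- matrix(0, nrow = length(l2), ncol = 4L,
                dimnames = list(names(fr), cohort_levels()))
  eff[, "ALS"] <- l2
  eff
}

#' Describe a synthetic study design
#'
#' Defaults emulate the study conditions: cohort sizes ALS 119 / HC 150 /
#' PD 20 / PLS 42; ALS-vs-HC effects on the eight fingerprint miRNAs equal to
#' the published fold regulations converted to log2; three stable reference
#' miRNAs; six endogenous signal miRNAs; extraction and RT spike-ins; IPC
#' triplicates per plate with plate-level Cq offsets.
#'
#' @param cohort_sizes named integer vector, cohorts ALS/PLS/PD/HC.
#' @param effect_log2fc numeric matrix targets x cohorts of log2 fold changes
#'   vs HC on the expression scale (a +1 effect lowers Cq by one cycle).
#'   Reference targets outside the fingerprint must have zero effect.
#' @param ref_targets reference miRNA names.
#' @param base_cq named numeric vector: mean Cq of each target in HC.
#' @param sigma_sample SD (cycles) of the global per-sample shift (pipetting,
#'   input amount); cancels in dCq.
#' @param sigma_target SD (cycles) of per-sample-per-target biological
#'   variation, the dominant noise on the dCq scale: either a single value
#'   for all targets or a named vector (unnamed targets fall back to the
#'   median of the vector).
#' @param sigma_noise SD (cycles) of per-well technical replicate noise.
#' @param plate_offsets numeric vector of plate Cq shifts, recycled over
#'   plates.
#' @param ipc_base Cq of the inter-plate calibrator assay.
#' @param haemolysis_rate fraction of samples with erythrocyte contamination.
#' @param haemolysis_shift Cq decrease applied to miR-451a in contaminated
#'   samples.
#' @param outlier_rate fraction of (sample, fingerprint-target) cells
#'   displaced to extreme values by [corrupt_run()].
#' @param outlier_sd_displace displacement size for corrupted cells, in
#'   pooled SDs of the target's clean fold-change distribution; default 8
#'   (comfortably beyond the 4-SD masking rule even after the injected cells
#'   inflate the pooled SD).
#' @param invalid_sample_count samples in which >= 50% of fingerprint targets
#'   are displaced, making the whole sample invalid downstream.
#' @param samples_per_plate plate capacity (samples assigned round-robin in
#'   blocks of this size).
#' @return Object of class `synthetic_design` (a validated list).
#' @export
synthetic_design <- function(cohort_sizes = c(ALS = 119L, HC = 150L,
                                              PD = 20L, PLS = 42L),
                             effect_log2fc = default_effect_log2fc(),
                             ref_targets = reference_targets(),
                             base_cq = default_base_cq(),
                             sigma_sample = 1.5,
                             sigma_target = default_sigma_target(),
                             sigma_noise = 0.25,
                             plate_offsets = c(0, 0.4, -0.3, 0.2),
                             ipc_base = 25.0,
                             haemolysis_rate = 0.02,
                             haemolysis_shift = 5.0,
                             outlier_rate = 0.002,
                             outlier_sd_displace = 8.0,
                             invalid_sample_count = 3L,
                             samples_per_plate = 96L) {
  stopifnot(all(cohort_sizes >= 0), all(names(cohort_sizes) %in% cohort_levels()))
  if (sigma_sample < 0 || any(sigma_target < 0) || sigma_noise < 0)
    stop("noise SDs must be >= 0")
  if (haemolysis_rate < 0 || haemolysis_rate > 1 ||
      outlier_rate < 0 || outlier_rate > 1)
    stop("rates must lie in [0, 1]")
  if (!all(rownames(effect_log2fc) %in% names(base_cq)))
    stop("effect targets missing from base_cq")
  non_fp_refs <- setdiff(ref_targets, rownames(effect_log2fc))
  if (!all(non_fp_refs %in% names(base_cq)))
    stop("reference targets missing from base_cq")
  if (samples_per_plate < 1L) stop("samples_per_plate must be >= 1")
  structure(list(cohort_sizes = cohort_sizes,
                 effect_log2fc = effect_log2fc,
                 ref_targets = ref_targets, base_cq = base_cq,
                 sigma_sample = sigma_sample, sigma_target = sigma_target,
                 sigma_noise = sigma_noise, plate_offsets = plate_offsets,
                 ipc_base = ipc_base,
                 haemolysis_rate = haemolysis_rate,
                 haemolysis_shift = haemolysis_shift,
                 outlier_rate = outlier_rate,
                 outlier_sd_displace = outlier_sd_displace,
                 invalid_sample_count = as.integer(invalid_sample_count),
                 samples_per_plate = as.integer(samples_per_plate)),
            class = "synthetic_design")
}

#' Simulate a plate-structured qPCR run
#'
#' Generative model on the cycle scale:
#' \deqn{Cq(s, t, w) = base_t - effect_{t, cohort(s)} + u_s + b_{s,t} +
#'   plate_{p(s)} + \epsilon_w}
#' with u ~ N(0, sigma_sample^2), b ~ N(0, sigma_target^2) and
#' epsilon ~ N(0, sigma_noise^2). Lower Cq encodes higher expression.
#' Spike-ins get base + plate offset + technical noise; every plate carries
#' IPC triplicates and NTC triplicates (Cq absent). Each (sample, target)
#' is measured in duplicate wells.
#'
#' @param design a [synthetic_design()].
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @return List with elements `run` ([run_data]) and `truth` (list: per-target
#'   per-cohort true log2 fold change, plate assignment, empty corruption
#'   slots filled in by [corrupt_run()]).
#' @export
simulate_run <- function(design, seed) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(as.integer(seed))
  sizes <- design$cohort_sizes
  n <- sum(sizes)
  cohorts <- rep(names(sizes), sizes)
  sample_ids <- sprintf("S%03d", seq_len(n))
  n_plates <- ceiling(n / design$samples_per_plate)
  plate_ids <- sprintf("P%02d", seq_len(n_plates))
  plate_of <- plate_ids[ceiling(seq_len(n) / design$samples_per_plate)]
  offsets <- stats::setNames(
    rep_len(design$plate_offsets, n_plates), plate_ids)

  metadata <- data.frame(
    sample_id = sample_ids, cohort = cohorts,
    sex = sample(c("M", "F"), n, replace = TRUE),
    age_group = sample(c("40-49", "50-59", "60-69", "70-79"), n,
                       replace = TRUE),
    batch = plate_of, stringsAsFactors = FALSE)

  targets <- names(design$base_cq)
  eff <- design$effect_log2fc
  sp <- unlist(spikein_targets(), use.names = FALSE)
  is_spike <- targets %in% sp
  nt <- length(targets)

  u <- stats::rnorm(n, 0, design$sigma_sample)
  st <- design$sigma_target
  sigma_t <- if (is.null(names(st))) rep_len(st, nt) else {
    out <- st[targets]
    out[is.na(out)] <- stats::median(st)
    unname(out)
  }
  b <- matrix(stats::rnorm(n * nt, 0, rep(sigma_t, each = n)), n, nt,
              dimnames = list(sample_ids, targets))
  b[, is_spike] <- 0  # spike-ins added post-lysis: no biological variation

  # expected Cq per sample x target before well noise
  effect_of <- matrix(0, n, nt, dimnames = list(sample_ids, targets))
  common <- intersect(rownames(eff), targets)
  effect_of[, common] <- t(eff[common, cohorts, drop = FALSE])
  mu <- matrix(design$base_cq, n, nt, byrow = TRUE) - effect_of + b +
    offsets[plate_of]
  mu[, !is_spike] <- mu[, !is_spike] + u  # fixed-quantity spike-ins skip the
  # per-sample input shift; endogenous targets carry it

  n_rep <- 2L
  cq <- as.vector(mu)  # column-major: sample varies fastest within target
  well_rows <- data.frame(
    plate_id = rep(plate_of, times = nt * n_rep),
    role = "sample",
    sample_id = rep(sample_ids, times = nt * n_rep),
    target = rep(rep(targets, each = n), times = n_rep),
    cq = rep(cq, times = n_rep) +
      stats::rnorm(n * nt * n_rep, 0, design$sigma_noise),
    melt_pass = TRUE, stringsAsFactors = FALSE)

  ipc <- data.frame(
    plate_id = rep(plate_ids, each = 3L), role = "ipc",
    sample_id = NA_character_, target = "IPC",
    cq = design$ipc_base + rep(offsets, each = 3L) +
      stats::rnorm(3L * n_plates, 0, design$sigma_noise),
    melt_pass = TRUE, stringsAsFactors = FALSE)
  ntc <- data.frame(
    plate_id = rep(plate_ids, each = 3L), role = "ntc",
    sample_id = NA_character_, target = "NTC",
    cq = NA_real_, melt_pass = NA, stringsAsFactors = FALSE)

  wells <- rbind(well_rows, ipc, ntc)
  wells$cq <- ifelse(is.na(wells$cq), NA_real_, pmin(wells$cq, 40))
  wells$cq <- ifelse(!is.na(wells$cq) & wells$cq <= 0, 0.01, wells$cq)
  # unique well ids within each plate
  wells <- wells[order(wells$plate_id), ]
  wells$well <- unlist(lapply(split(seq_len(nrow(wells)), wells$plate_id),
                              function(i) sprintf("W%04d", seq_along(i))),
                       use.names = FALSE)
  wells <- wells[, plate_columns()]

  roles <- default_target_roles()
  run <- run_data(wells, metadata, roles)

  truth <- list(
    true_log2fc = eff,
    plate_of = stats::setNames(plate_of, sample_ids),
    plate_offsets = offsets,
    haemolysed = character(0),
    outlier_cells = data.frame(sample_id = character(0),
                               target = character(0),
                               stringsAsFactors = FALSE),
    invalid_samples = character(0),
    seed = as.integer(seed))
  list(run = run, truth = truth)
}

#' Inject haemolysis, extreme outliers and invalid samples
#'
#' Applies three corruptions to a simulated run, updating ground truth:
#' haemolysed samples get their miR-451a Cq decreased by `haemolysis_shift`;
#' a fraction `outlier_rate` of (sample, fingerprint target) cells is
#' displaced to extreme fold changes, and for `invalid_sample_count` chosen
#' samples more than half of the fingerprint targets are displaced, making
#' the whole sample invalid downstream.
#'
#' Displacement is defined on the fold-change scale: the cell's Cq is set so
#' that its eventual 2^-ddCq equals the target's clean pooled mean plus
#' `outlier_sd_displace` pooled SDs (computed by running normalization and
#' relative quantification on the clean run). Only fingerprint targets
#' outside the reference set are displaced, so a corrupted cell never drags
#' its sample's reference mean and the remaining cells stay intact.
#'
#' @param sim list from [simulate_run()] (elements `run`, `truth`).
#' @param design the [synthetic_design()] used to simulate.
#' @param seed integer seed for the corruption draws.
#' @param control control cohort for the internal ddCq baseline; default
#'   "HC" (falls back to the first cohort present).
#' @return List with updated `run` and `truth`.
#' @export
corrupt_run <- function(sim, design, seed, control = "HC") {
  stopifnot(inherits(design, "synthetic_design"))
  run <- sim$run
  truth <- sim$truth
  set.seed(as.integer(seed))
  samples <- run$metadata$sample_id
  n <- length(samples)
  if (design$invalid_sample_count > n)
    stop("invalid_sample_count exceeds number of samples")
  wells <- run$wells
  fp <- intersect(fingerprint_targets(), unique(wells$target))
  displaceable <- setdiff(fp, design$ref_targets)

  n_haem <- round(design$haemolysis_rate * n)
  haem <- if (n_haem > 0L) sample(samples, n_haem) else character(0)
  if (length(haem) > 0L) {
    idx <- wells$role == "sample" & wells$sample_id %in% haem &
      wells$target == haemolysis_pair()[["erythrocyte"]]
    wells$cq[idx] <- pmax(wells$cq[idx] - design$haemolysis_shift, 0.01)
  }

  invalid <- if (design$invalid_sample_count > 0L)
    sample(setdiff(samples, haem), design$invalid_sample_count)
  else character(0)

  cells <- expand.grid(sample_id = setdiff(samples, invalid),
                       target = displaceable, stringsAsFactors = FALSE)
  n_out <- round(design$outlier_rate * n * length(fp))
  out_cells <- if (n_out > 0L) cells[sample(nrow(cells), n_out), ]
  else cells[0, ]
  n_disp <- min(floor(length(fp) / 2) + 1L, length(displaceable))
  for (s in invalid) {
    disp <- sample(displaceable, n_disp)
    out_cells <- rbind(out_cells,
                       data.frame(sample_id = s, target = disp,
                                  stringsAsFactors = FALSE))
  }

  if (nrow(out_cells) > 0L) {
    # clean fold-change distribution per target, from the uncorrupted run
    groups <- stats::setNames(run$metadata$cohort, run$metadata$sample_id)
    ctrl <- if (control %in% groups) control else groups[[1L]]
    cqm <- build_cq_matrix(sim$run)
    dcq <- normalize_dcq(cqm, refs = design$ref_targets,
                         targets = displaceable)
    expr <- ddcq_fold_change(dcq, groups, control = ctrl)
    ref_mean <- rowMeans(cqm$values[, design$ref_targets, drop = FALSE])
    for (i in seq_len(nrow(out_cells))) {
      s <- out_cells$sample_id[i]; t <- out_cells$target[i]
      fc_clean <- expr$fold_change[, t]
      fc_star <- mean(fc_clean, na.rm = TRUE) +
        design$outlier_sd_displace * stats::sd(fc_clean, na.rm = TRUE)
      cq_star <- expr$control_baseline[[t]] - log2(fc_star) + ref_mean[[s]]
      hit <- wells$role == "sample" & wells$sample_id == s &
        wells$target == t
      wells$cq[hit] <- max(cq_star, 0.01)
    }
  }

  truth$haemolysed <- sort(haem)
  truth$outlier_cells <- out_cells[order(out_cells$sample_id,
                                         out_cells$target), ]
  rownames(truth$outlier_cells) <- NULL
  truth$invalid_samples <- sort(invalid)
  list(run = run_data(wells, run$metadata, run$target_roles), truth = truth)
}
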