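#' @title Pipeline orchestration and report surfaces
#' @description Config-driven end-to-end runs: simulate or load -> QC ->
#'   inter-plate calibration -> reference validation -> dCq -> 2^-ddCq ->
#'   outlier filtering -> group statistics -> classifier designs, with all
#'   report tables and a manifest capturing every default and seed.
#' @name cli_report
NULL

#' Pipeline configuration
#'
#' All defaults equal the study's stated values: haemolysis threshold 7,
#' IQR multiplier 1.5, outlier SD multiplier 4, invalid fraction 0.5,
#' pairwise-variation threshold 0.15, split fractions 0.8 / 0.79, seeds
#' 375 / 101.
#'
#' @param design a [synthetic_design()] to simulate, or NULL when loading
#'   from files.
#' @param plate_paths,metadata_path input CSVs (used when `design` is NULL).
#' @param seed simulation seed (also salts the independent training cohort).
#' @param corrupt logical: inject haemolysis/outliers/invalid samples into a
#'   simulated run; default TRUE.
#' @param haemolysis_threshold,iqr_k,sd_mult,invalid_frac,v_threshold QC and
#'   filtering parameters.
#' @param calibration_mode "grand_mean" or a plate id to centre to.
#' @param refs reference miRNAs; control control cohort.
#' @param gate_kw gate Mann-Whitney tests on the Kruskal-Wallis result.
#' @param logistic_fraction,logistic_seed,forest_fraction,forest_seed,
#'   cross_seed,ntree classifier settings.
#' @param run_classifiers logical; default TRUE.
#' @return Object of class `pipeline_config` (validated list).
#' @export
pipeline_config <- function(design = synthetic_design(),
                            plate_paths = NULL, metadata_path = NULL,
                            seed = 375, corrupt = TRUE,
                            haemolysis_threshold = 7, iqr_k = 1.5,
                            sd_mult = 4, invalid_frac = 0.5,
                            v_threshold = 0.15,
                            calibration_mode = "grand_mean",
                            refs = reference_targets(), control = "HC",
                            gate_kw = TRUE,
                            logistic_fraction = 0.8, logistic_seed = 375,
                            forest_fraction = 0.79, forest_seed = 375,
                            cross_seed = 101, ntree = 500,
                            run_classifiers = TRUE) {
  if (is.null(design) && (is.null(plate_paths) || is.null(metadata_path)))
    stop("either a synthetic design or input paths must be given")
  if (invalid_frac < 0 || invalid_frac > 1)
    stop("config validation error: invalid_frac must lie in [0, 1]")
  if (sd_mult <= 0) stop("config validation error: sd_mult must be > 0")
  if (v_threshold <= 0) stop("config validation error: v_threshold must be > 0")
  if (logistic_fraction <= 0 || logistic_fraction >= 1 ||
      forest_fraction <= 0 || forest_fraction >= 1)
    stop("config validation error: split fractions must lie in (0, 1)")
  if (haemolysis_threshold <= 0 || iqr_k <= 0)
    stop("config validation error: QC thresholds must be > 0")
  structure(list(design = design, plate_paths = plate_paths,
                 metadata_path = metadata_path, seed = as.integer(seed),
                 corrupt = corrupt,
                 haemolysis_threshold = haemolysis_threshold, iqr_k = iqr_k,
                 sd_mult = sd_mult, invalid_frac = invalid_frac,
                 v_threshold = v_threshold,
                 calibration_mode = calibration_mode,
                 refs = refs, control = control, gate_kw = gate_kw,
                 logistic_fraction = logistic_fraction,
                 logistic_seed = as.integer(logistic_seed),
                 forest_fraction = forest_fraction,
                 forest_seed = as.integer(forest_seed),
                 cross_seed = as.integer(cross_seed), ntree = ntree,
                 run_classifiers = run_classifiers),
            class = "pipeline_config")
}

# independent 50/50 ALS+HC cohort used as the cross-cohort training set
independent_design <- function(design, n_als = 50L, n_hc = 50L) {
  synthetic_design(
    cohort_sizes = c(ALS = n_als, HC = n_hc),
    effect_log2fc = design$effect_log2fc,
    ref_targets = design$ref_targets, base_cq = design$base_cq + 0.5,
    sigma_sample = design$sigma_sample, sigma_target = design$sigma_target,
    sigma_noise = design$sigma_noise,
    plate_offsets = rev(design$plate_offsets),
    ipc_base = design$ipc_base,
    haemolysis_rate = 0, outlier_rate = 0, invalid_sample_count = 0L,
    samples_per_plate = design$samples_per_plate)
}

#' Run the full pipeline
#'
#' Executes simulate/load -> calibrate -> QC -> reference validation ->
#' normalize -> quantify -> filter -> group statistics -> classifiers, and
#' returns every report surface: fold-regulation table, statistics table,
#' coefficient and importance tables, metric panel, ROC points and a
#' manifest with config and seeds. Any stage failure is reported with the
#' failing stage named.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `report_bundle` (list of report surfaces).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  if (!is.null(config$design)) {
    sim <- stage("simulate", simulate_run(config$design, config$seed))
    if (config$corrupt)
      sim <- stage("simulate", corrupt_run(sim, config$design,
                                           config$seed + 1L))
    run <- sim$run
    truth <- sim$truth
  } else {
    run <- stage("load", load_run(config$plate_paths, config$metadata_path))
  }
  groups <- stats::setNames(run$metadata$cohort, run$metadata$sample_id)

  factors <- stage("calibrate", ipc_factors(
    run, reference_plate = if (identical(config$calibration_mode,
                                         "grand_mean")) NULL
    else config$calibration_mode))
  cqm <- stage("build_matrix", build_cq_matrix(run))
  cqm <- stage("calibrate", apply_calibration(cqm, factors))
  qc <- stage("qc", run_qc(cqm, run,
                           haemolysis_threshold = config$haemolysis_threshold,
                           iqr_k = config$iqr_k))

  candidates <- unique(c(config$refs, fingerprint_targets()))
  stability <- stage("reference_validation",
                     normfinder_stability(cqm, groups, candidates))
  pv <- stage("reference_validation",
              pairwise_variation(cqm, stability$target,
                                 threshold = config$v_threshold))

  dcq <- stage("normalize", normalize_dcq(cqm, refs = config$refs))
  expr <- stage("quantify", ddcq_fold_change(dcq, groups,
                                             control = config$control))
  expr <- stage("filter", mask_outliers(expr, sd_mult = config$sd_mult,
                                        invalid_frac = config$invalid_frac))
  comparison <- stage("stats", compare_groups(expr, gate_kw = config$gate_kw))

  classifiers <- NULL
  if (config$run_classifiers) {
    # classifiers run on all ALS + control observations, without removing
    # outliers or invalid samples (the filtering applies to the group
    # statistics only)
    keep <- groups[rownames(dcq$values)] %in% c("ALS", config$control)
    feats <- dcq$values[keep, , drop = FALSE]
    labs <- groups[rownames(feats)]
    logistic <- stage("classify",
                      run_design_logistic(feats, labs,
                                          fraction = config$logistic_fraction,
                                          seed = config$logistic_seed))
    forest <- stage("classify",
                    run_design_forest(feats, labs,
                                      fraction = config$forest_fraction,
                                      seed = config$forest_seed,
                                      ntree = config$ntree))
    cross <- NULL
    if (!is.null(config$design)) {
      cross <- stage("classify", {
        idesign <- independent_design(config$design)
        isim <- simulate_run(idesign, config$seed + 1000L)
        icqm <- apply_calibration(build_cq_matrix(isim$run),
                                  ipc_factors(isim$run))
        idcq <- normalize_dcq(icqm, refs = config$refs)
        ilabs <- stats::setNames(isim$run$metadata$cohort,
                                 isim$run$metadata$sample_id)
        run_design_cross_cohort(idcq$values,
                                ilabs[rownames(idcq$values)],
                                feats, labs, seed = config$cross_seed,
                                ntree = config$ntree)
      })
    }
    classifiers <- list(logistic = logistic, forest = forest, cross = cross)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("evmirna")),
    seed = config$seed,
    config = config[!names(config) %in% "design"],
    design_summary = if (!is.null(config$design)) list(
      cohort_sizes = as.list(config$design$cohort_sizes),
      sigma_sample = config$design$sigma_sample,
      sigma_target = config$design$sigma_target,
      sigma_noise = config$design$sigma_noise) else NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  structure(list(run = run, truth = truth, qc = qc, factors = factors,
                 stability = stability, pairwise_variation = pv,
                 cq_matrix = cqm, dcq = dcq, expression = expr,
                 comparison = comparison, classifiers = classifiers,
                 manifest = manifest),
            class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' Emits the report surfaces as TSV/JSON: fold regulation,
#' group statistics, reference stability and pairwise variation, QC report,
#' classifier metric panel, coefficient/importance tables, ROC points and
#' the manifest.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    path
  }
  files <- c(
    tsv(bundle$comparison$fold_regulation, "fold_regulation.tsv"),
    tsv(merge(bundle$comparison$kw, bundle$comparison$mw, by = "target",
              all = TRUE), "group_statistics.tsv"),
    tsv(as.data.frame(bundle$stability), "reference_stability.tsv"),
    tsv(data.frame(pair = names(bundle$pairwise_variation$V),
                   V = unname(bundle$pairwise_variation$V)),
        "pairwise_variation.tsv"),
    tsv(as.data.frame(bundle$qc), "qc_report.tsv"))
  if (!is.null(bundle$classifiers)) {
    panel <- do.call(rbind, lapply(
      Filter(Negate(is.null), bundle$classifiers), function(r)
        data.frame(design = r$design, as.data.frame(r$metrics),
                   auc = r$auc, n_features = length(r$features))))
    files <- c(files, tsv(panel, "classifier_metrics.tsv"))
    lg <- bundle$classifiers$logistic
    if (!is.null(lg$coefficients))
      files <- c(files, tsv(data.frame(term = rownames(lg$coefficients),
                                       lg$coefficients, row.names = NULL),
                            "logistic_coefficients.tsv"))
    if (!is.null(bundle$classifiers$forest$importance))
      files <- c(files, tsv(
        data.frame(target = names(bundle$classifiers$forest$importance),
                   mean_decrease_gini =
                     unname(bundle$classifiers$forest$importance)),
        "forest_importance.tsv"))
    files <- c(files, tsv(lg$roc_curve, "roc_points.tsv"))
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(c(files, manifest_path))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("evmirna report bundle\n")
  print(x$run)
  cat(" invalid samples:",
      if (length(x$expression$invalid_samples) == 0L) "none"
      else paste(x$expression$invalid_samples, collapse = ", "), "\n")
  cat(" KW H range:",
      paste(round(range(x$comparison$kw$H, na.rm = TRUE), 1),
            collapse = " - "), "\n")
  if (!is.null(x$classifiers)) {
    for (r in Filter(Negate(is.null), x$classifiers)) print(r)
  }
  invisible(x)
}
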