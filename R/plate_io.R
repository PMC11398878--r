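#' @title Plate-level qPCR input/output
#' @description Read and write long-format plate CSVs and sample metadata,
#'   validate them into a `run_data` object, and collapse replicate wells
#'   into a samples x targets Cq matrix.
#' @name plate_io
NULL

plate_columns <- function() {
  c("plate_id", "well", "role", "sample_id", "target", "cq", "melt_pass")
}

#' Construct a run_data object from its components
#'
#' @param wells data.frame with columns plate_id, well, role, sample_id,
#'   target, cq, melt_pass. `cq` is NA when no amplification occurred within
#'   40 cycles; present values must be finite, positive and <= 40.
#' @param metadata data.frame with columns sample_id, cohort and optionally
#'   sex, age_group, batch.
#' @param target_roles named character vector mapping every target appearing
#'   in `wells` to a role.
#' @return An object of class `run_data`.
#' @export
run_data <- function(wells, metadata, target_roles) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  validate_wells(wells)
  validate_metadata(metadata)
  miss_meta <- setdiff(unique(wells$sample_id[wells$role == "sample"]),
                       metadata$sample_id)
  if (length(miss_meta) > 0L)
    stop("samples present on plates but absent from metadata: ",
         paste(miss_meta, collapse = ", "))
  unknown <- setdiff(unique(wells$target), names(target_roles))
  if (length(unknown) > 0L)
    stop("targets without an assigned role: ", paste(unknown, collapse = ", "))
  bad_role <- setdiff(unique(target_roles), target_role_levels())
  if (length(bad_role) > 0L)
    stop("unknown target roles: ", paste(bad_role, collapse = ", "))
  structure(list(wells = wells, metadata = metadata,
                 target_roles = target_roles),
            class = "run_data")
}

validate_wells <- function(wells) {
  miss <- setdiff(plate_columns(), names(wells))
  if (length(miss) > 0L)
    stop("plate table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  dup <- duplicated(wells[, c("plate_id", "well")])
  if (any(dup))
    stop("duplicate (plate, well) entries: ",
         paste(utils::head(paste(wells$plate_id[dup], wells$well[dup],
                                 sep = "/"), 5L), collapse = ", "))
  if (!all(wells$role %in% c("sample", "ipc", "ntc")))
    stop("well role must be one of sample, ipc, ntc")
  if (any(wells$role == "ntc" & !is.na(wells$sample_id)))
    stop("no-template control wells must not carry a sample_id")
  if (any(wells$role == "sample" & is.na(wells$sample_id)))
    stop("sample wells must carry a sample_id")
  cq <- wells$cq
  ok <- is.na(cq) | (is.finite(cq) & cq > 0 & cq <= 40)
  if (!all(ok))
    stop("Cq values must be finite, in (0, 40], or absent; offending wells: ",
         paste(utils::head(wells$well[!ok], 5L), collapse = ", "))
  invisible(wells)
}

validate_metadata <- function(metadata) {
  miss <- setdiff(c("sample_id", "cohort"), names(metadata))
  if (length(miss) > 0L)
    stop("metadata format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(metadata$cohort), cohort_levels())
  if (length(bad) > 0L)
    stop("cohort label(s) outside {",
         paste(cohort_levels(), collapse = ", "), "}: ",
         paste(bad, collapse = ", "))
  invisible(metadata)
}

#' Load a qPCR run from plate CSVs and a metadata CSV
#'
#' Plate files are long-format CSVs with columns plate_id, well, role,
#' sample_id, target, cq, melt_pass. A `cq` cell that is empty or the literal
#' string "Undetermined" becomes the absent sentinel (NA), never 40.
#'
#' @param plate_paths character vector of plate CSV paths.
#' @param metadata_path path to the sample metadata CSV.
#' @param target_roles named character vector assigning a role to every
#'   target; defaults to [default_target_roles()]. Unknown targets are
#'   rejected.
#' @return A validated [run_data] object.
#' @export
load_run <- function(plate_paths, metadata_path,
                     target_roles = default_target_roles()) {
  for (p in c(plate_paths, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)
  plates <- lapply(plate_paths, function(p) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE,
                          colClasses = "character")
    miss <- setdiff(plate_columns(), names(df))
    if (length(miss) > 0L)
      stop("plate file ", p, ": missing column(s) ",
           paste(miss, collapse = ", "))
    df
  })
  wells <- do.call(rbind, plates)
  cq <- trimws(wells$cq)
  cq[cq %in% c("", "Undetermined", "NA")] <- NA_character_
  wells$cq <- as.numeric(cq)
  mp <- trimws(wells$melt_pass)
  wells$melt_pass <- ifelse(mp %in% c("", "NA"), NA,
                            toupper(mp) %in% c("TRUE", "T", "1"))
  wells$sample_id[trimws(wells$sample_id) == ""] <- NA_character_
  metadata <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  run_data(wells, metadata, target_roles)
}

#' Write a run to plate CSVs and a metadata CSV
#'
#' Inverse of [load_run()]: one CSV per plate plus `metadata.csv`, in the
#' dialect that [load_run()] reads back (absent Cq written as "Undetermined").
#'
#' @param run a [run_data] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with `plate_paths` and `metadata_path`.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "run_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plate_ids <- unique(run$wells$plate_id)
  plate_paths <- character(0)
  for (pid in plate_ids) {
    sub <- run$wells[run$wells$plate_id == pid, plate_columns()]
    sub$cq <- ifelse(is.na(sub$cq), "Undetermined",
                     format(sub$cq, digits = 15, trim = TRUE,
                            scientific = FALSE))
    path <- file.path(dir, paste0("plate_", pid, ".csv"))
    utils::write.csv(sub, path, row.names = FALSE, na = "")
    plate_paths <- c(plate_paths, path)
  }
  metadata_path <- file.path(dir, "metadata.csv")
  utils::write.csv(run$metadata, metadata_path, row.names = FALSE, na = "")
  invisible(list(plate_paths = plate_paths, metadata_path = metadata_path))
}

#' Collapse replicate wells into a samples x targets Cq matrix
#'
#' Replicate wells of the same (sample, target) are averaged (arithmetic mean
#' of present Cqs, equivalent to the geometric mean in linear expression
#' space). Cells whose wells are all absent stay missing. IPC, NTC and
#' spike-in wells are excluded from the grid; only targets with role
#' fingerprint, reference, signal_qc or haemolysis enter it.
#'
#' @param run a [run_data] object.
#' @param discordance_threshold replicate Cq range (cycles) above which a
#'   (sample, target) cell is flagged in the discordance report. Default 1.0.
#' @return An object of class `cq_matrix`: list with `values` (numeric matrix
#'   samples x targets, NA = missing), `plate_of` (named character),
#'   `discordance` (data.frame sample_id/target/spread), and `notes`
#'   (data.frame of single-replicate cells).
#' @export
build_cq_matrix <- function(run, discordance_threshold = 1.0) {
  stopifnot(inherits(run, "run_data"))
  keep_targets <- names(run$target_roles)[run$target_roles %in% grid_roles()]
  w <- run$wells[run$wells$role == "sample" &
                 run$wells$target %in% keep_targets, ]
  if (nrow(w) == 0L) stop("no sample wells with grid-role targets")
  sample_ids <- run$metadata$sample_id[run$metadata$sample_id %in%
                                         unique(w$sample_id)]
  targets <- keep_targets
  sf <- factor(w$sample_id, levels = sample_ids)
  tf <- factor(w$target, levels = targets)
  mean_narm <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  values <- tapply(w$cq, list(sf, tf), mean_narm)
  values <- matrix(unlist(values), nrow = length(sample_ids),
                   ncol = length(targets),
                   dimnames = list(sample_ids, targets))
  spread <- tapply(w$cq, list(sf, tf), function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else diff(range(x))
  })
  spread <- matrix(unlist(spread), nrow = length(sample_ids),
                   dimnames = list(sample_ids, targets))
  disc_idx <- which(!is.na(spread) & spread > discordance_threshold,
                    arr.ind = TRUE)
  discordance <- data.frame(
    sample_id = sample_ids[disc_idx[, 1L]],
    target = targets[disc_idx[, 2L]],
    spread = spread[disc_idx],
    stringsAsFactors = FALSE)
  n_present <- tapply(!is.na(w$cq), list(sf, tf), sum)
  n_present <- matrix(unlist(n_present), nrow = length(sample_ids),
                      dimnames = list(sample_ids, targets))
  single_idx <- which(!is.na(n_present) & n_present == 1L, arr.ind = TRUE)
  notes <- data.frame(
    sample_id = sample_ids[single_idx[, 1L]],
    target = targets[single_idx[, 2L]],
    note = rep("single-replicate", nrow(single_idx)),
    stringsAsFactors = FALSE)
  plate_of <- tapply(w$plate_id, sf, function(x) x[1L])
  plate_of <- stats::setNames(as.character(plate_of), sample_ids)
  structure(list(values = values, plate_of = plate_of,
                 discordance = discordance, notes = notes),
            class = "cq_matrix")
}

#' @export
print.run_data <- function(x, ...) {
  cat("qPCR run:", length(unique(x$wells$plate_id)), "plate(s),",
      nrow(x$wells), "wells,",
      nrow(x$metadata), "samples (",
      paste(names(table(x$metadata$cohort)),
            table(x$metadata$cohort), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat("Cq matrix:", nrow(x$values), "samples x", ncol(x$values), "targets;",
      sum(is.na(x$values)), "missing cells;",
      nrow(x$discordance), "discordant replicate cells\n")
  invisible(x)
}
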