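#' @title Inter-plate calibration
#' @description Mean-centre plate-level Cq shifts using the inter-plate
#'   calibrator (IPC) wells run in triplicate on every plate, so samples run
#'   months apart are comparable.
#' @name plate_calibration
NULL

#' Compute IPC correction factors
#'
#' For each plate p, m_p is the mean of its IPC Cqs; the reference level L is
#' the mean of the m_p (grand-mean mode, default) or the m_p of a chosen
#' reference plate; the plate correction is L - m_p, added to every Cq of
#' that plate.
#'
#' @param run a [run_data] object; every plate needs at least one IPC well
#'   with a present Cq.
#' @param reference_plate optional plate id to centre to instead of the
#'   grand mean.
#' @return Object of class `plate_factors`: list with `correction` (named
#'   numeric, cycles), `reference_level` (cycles) and `plate_means`.
#' @export
ipc_factors <- function(run, reference_plate = NULL) {
  stopifnot(inherits(run, "run_data"))
  ipc <- run$wells[run$wells$role == "ipc" & run$wells$target != "NTC", ]
  plates <- unique(run$wells$plate_id)
  m <- vapply(plates, function(p) {
    v <- ipc$cq[ipc$plate_id == p]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      stop("calibration error: plate ", p, " has no usable IPC wells")
    mean(v)
  }, numeric(1))
  L <- if (is.null(reference_plate)) mean(m) else {
    if (!reference_plate %in% plates)
      stop("calibration error: unknown reference plate ", reference_plate)
    m[[reference_plate]]
  }
  structure(list(correction = L - m, reference_level = L, plate_means = m),
            class = "plate_factors")
}

#' Apply IPC correction factors to a Cq matrix
#'
#' Adds each sample's plate correction to all its Cq values. Missing cells
#' stay missing. Within-sample Cq differences (dCq) are unchanged because a
#' sample's wells share one plate.
#'
#' @param matrix a [build_cq_matrix()] result.
#' @param factors a [ipc_factors()] result covering every plate in `matrix`.
#' @return A `cq_matrix` with corrected values.
#' @export
apply_calibration <- function(matrix, factors) {
  stopifnot(inherits(matrix, "cq_matrix"), inherits(factors, "plate_factors"))
  plates <- matrix$plate_of[rownames(matrix$values)]
  unknown <- setdiff(unique(plates), names(factors$correction))
  if (length(unknown) > 0L)
    stop("calibration error: no factor for plate(s) ",
         paste(unknown, collapse = ", "))
  matrix$values <- matrix$values + factors$correction[plates]
  matrix$calibrated <- TRUE
  matrix
}

#' @export
print.plate_factors <- function(x, ...) {
  cat("IPC calibration: reference level", round(x$reference_level, 3),
      "cycles\n")
  print(round(x$correction, 3))
  invisible(x)
}
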