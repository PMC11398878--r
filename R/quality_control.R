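#' @title Sample-level quality control
#' @description Spike-in monitoring, endogenous signal check, and the
#'   haemolysis dCq (miR-23a-3p minus miR-451a) with inclusive flagging at
#'   7 cycles and an IQR-based context check.
#' @name quality_control
NULL

#' Haemolysis delta Cq
#'
#' miR-23a-3p is stable in plasma while miR-451a is erythrocyte-specific, so
#' `Cq(miR-23a-3p) - Cq(miR-451a)` grows with red-cell contamination. Values
#' at or above the threshold (default 7 cycles) are flagged.
#'
#' @param cq_23a Cq of miR-23a-3p (cycles, <= 40).
#' @param cq_451a Cq of miR-451a (cycles, <= 40).
#' @param threshold flag threshold in cycles; the flag is inclusive (>=).
#' @return List with `delta` (cycles), `flagged` (logical) and `status`
#'   ("ok" or "indeterminate" when either Cq is absent; an indeterminate
#'   result is never silently passed).
#' @export
haemolysis_delta <- function(cq_23a, cq_451a, threshold = 7) {
  if (is.na(cq_23a) || is.na(cq_451a))
    return(list(delta = NA_real_, flagged = NA, status = "indeterminate"))
  stopifnot(cq_23a <= 40, cq_451a <= 40)
  delta <- cq_23a - cq_451a
  list(delta = delta, flagged = delta >= threshold, status = "ok")
}

#' Quartiles, IQR and Tukey fences
#'
#' Quartiles use linear interpolation of the empirical distribution
#' (`stats::quantile` type 7).
#'
#' @param values numeric vector, at least 4 finite values.
#' @param k interquartile multiplier (default 1.5).
#' @return Named list: q1, q3, iqr, lower_fence, upper_fence.
#' @export
iqr_fences <- function(values, k = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 4L)
    stop("insufficient data: need >= 4 finite values for IQR fences")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  list(q1 = q[1L], q3 = q[2L], iqr = iqr,
       lower_fence = q[1L] - k * iqr, upper_fence = q[2L] + k * iqr)
}

#' Per-sample quality-control report
#'
#' Evaluates extraction spike-ins (UniSp2/4/5) and RT spike-ins (UniSp6,
#' cel-miR-39-3p) against acceptance windows, computes the mean Cq over the
#' six endogenous signal miRNAs, and the haemolysis delta with its flag.
#' Haemolysis-flagged samples whose fingerprint Cqs stay inside the
#' IQR fences (computed over all fingerprint Cq values of the run) are
#' retained with a note, not dropped.
#'
#' @param matrix a [build_cq_matrix()] result (calibrated or not).
#' @param run the [run_data] the matrix came from (for spike-in wells).
#' @param haemolysis_threshold cycles; default 7.
#' @param iqr_k interquartile multiplier; default 1.5.
#' @param spikein_sd_mult half-width of the spike-in acceptance window in run
#'   SDs around the run mean; default 2.
#' @param low_signal_cq signal-mean Cq above which a sample is flagged
#'   low_signal; default 35 cycles.
#' @return Object of class `qc_report`: data.frame (one row per sample) with
#'   spike-in Cqs, `signal_mean`, `haemolysis_delta`, flag columns and a
#'   `note` column; attributes `iqr_context` (list from [iqr_fences()]) and
#'   `spikein_windows`.
#' @export
run_qc <- function(matrix, run, haemolysis_threshold = 7, iqr_k = 1.5,
                   spikein_sd_mult = 2, low_signal_cq = 35) {
  stopifnot(inherits(matrix, "cq_matrix"), inherits(run, "run_data"))
  samples <- rownames(matrix$values)
  pair <- haemolysis_pair()
  sig_t <- signal_qc_targets()
  miss <- setdiff(c(sig_t, unname(pair)), colnames(matrix$values))
  if (length(miss) > 0L)
    stop("QC configuration error: target(s) missing from the run: ",
         paste(miss, collapse = ", "))

  sp <- unlist(spikein_targets(), use.names = FALSE)
  spw <- run$wells[run$wells$role == "sample" & run$wells$target %in% sp, ]
  miss_sp <- setdiff(sp, unique(spw$target))
  if (length(miss_sp) > 0L)
    stop("QC configuration error: spike-in(s) missing from the run: ",
         paste(miss_sp, collapse = ", "))
  spike_cq <- sapply(sp, function(t) {
    w <- spw[spw$target == t, ]
    v <- tapply(w$cq, factor(w$sample_id, levels = samples),
                function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    as.numeric(v)
  })
  rownames(spike_cq) <- samples
  windows <- apply(spike_cq, 2L, function(v) {
    m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
    c(lower = m - spikein_sd_mult * s, upper = m + spikein_sd_mult * s)
  })
  spike_fail <- rowSums(
    sweep(spike_cq, 2L, windows["lower", ], "<") |
      sweep(spike_cq, 2L, windows["upper", ], ">"), na.rm = TRUE) > 0

  signal_mean <- rowMeans(matrix$values[, sig_t, drop = FALSE], na.rm = TRUE)

  hd <- lapply(samples, function(s)
    haemolysis_delta(matrix$values[s, pair[["stable"]]],
                     matrix$values[s, pair[["erythrocyte"]]],
                     threshold = haemolysis_threshold))
  delta <- vapply(hd, `[[`, numeric(1), "delta")
  haem_flag <- vapply(hd, function(x) isTRUE(x$flagged), logical(1))
  indeterminate <- vapply(hd, function(x) x$status == "indeterminate",
                          logical(1))

  fp <- intersect(fingerprint_targets(), colnames(matrix$values))
  ctx <- iqr_fences(as.vector(matrix$values[, fp, drop = FALSE]), k = iqr_k)
  in_fences <- apply(matrix$values[, fp, drop = FALSE], 1L, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || all(v >= ctx$lower_fence & v <= ctx$upper_fence)
  })

  note <- ifelse(haem_flag & in_fences,
                 "haemolysis-flagged; fingerprint Cqs within IQR fences; retained",
                 ifelse(haem_flag, "haemolysis-flagged; fingerprint Cqs outside IQR fences",
                        ifelse(indeterminate, "haemolysis indeterminate", "")))

  report <- data.frame(
    sample_id = samples, spike_cq, signal_mean = signal_mean,
    haemolysis_delta = delta,
    haemolysis_flag = haem_flag,
    spikein_fail = as.logical(spike_fail),
    low_signal = signal_mean > low_signal_cq,
    within_iqr_fences = in_fences,
    note = note, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  attr(report, "iqr_context") <- ctx
  attr(report, "spikein_windows") <- windows
  class(report) <- c("qc_report", "data.frame")
  report
}
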