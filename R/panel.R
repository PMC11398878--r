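#' The eight-miRNA ALS fingerprint panel
#'
#' Names of the eight fingerprint miRNAs measured in plasma neural-enriched
#' extracellular vesicles. Two of them (miR-146a-5p, miR-29b-3p) also belong
#' to the default reference set used for normalization; this overlap is
#' deliberate and mirrors the assay design.
#'
#' @return Character vector of length 8.
#' @export
fingerprint_targets <- function() {
  c("miR-10b-5p", "miR-4454", "miR-199a-3p", "miR-151a-3p",
    "miR-151a-5p", "miR-199a-5p", "miR-146a-5p", "miR-29b-3p")
}

#' Default reference miRNAs for normalization
#'
#' @return Character vector of length 3.
#' @export
reference_targets <- function() {
  c("miR-146a-5p", "miR-29b-3p", "miR-126-5p")
}

#' The six endogenous signal-QC miRNAs
#'
#' Mean Cq over these six miRNAs measures how much amplifiable cDNA a sample
#' yielded. Two of them (miR-23a-3p, miR-451a) double as the haemolysis
#' marker pair.
#'
#' @return Character vector of length 6.
#' @export
signal_qc_targets <- function() {
  c("miR-142-3p", "miR-451a", "miR-23a-3p", "miR-30c-5p",
    "miR-103a-3p", "miR-191-5p")
}

#' Haemolysis marker pair
#' @return Named character vector with elements `stable` (miR-23a-3p) and
#'   `erythrocyte` (miR-451a).
#' @export
haemolysis_pair <- function() {
  c(stable = "miR-23a-3p", erythrocyte = "miR-451a")
}

#' Spike-in assay names
#' @return Named list with `extraction` (UniSp2/4/5) and `rt`
#'   (UniSp6, cel-miR-39-3p) components.
#' @export
spikein_targets <- function() {
  list(extraction = c("UniSp2", "UniSp4", "UniSp5"),
       rt = c("UniSp6", "cel-miR-39-3p"))
}

#' Valid cohort labels
#' @return Character vector: ALS, PLS, PD, HC.
#' @export
cohort_levels <- function() c("ALS", "PLS", "PD", "HC")

#' Default target-role map for the assay panel
#'
#' Maps every assay of the panel to its role. The haemolysis pair carries
#' role `haemolysis`; together with the four `signal_qc` assays they form
#' the six endogenous signal miRNAs. Reference role is assigned only to the
#' reference miRNA that is not part of the fingerprint.
#'
#' @return Named character vector target -> role, roles drawn from
#'   fingerprint, reference, signal_qc, haemolysis, spikein_extraction,
#'   spikein_rt, ipc.
#' @export
default_target_roles <- function() {
  fp <- fingerprint_targets()
  sq <- setdiff(signal_qc_targets(), haemolysis_pair())
  sp <- spikein_targets()
  roles <- c(
    stats::setNames(rep("fingerprint", length(fp)), fp),
    stats::setNames("reference", "miR-126-5p"),
    stats::setNames(rep("signal_qc", length(sq)), sq),
    stats::setNames(rep("haemolysis", 2L), unname(haemolysis_pair())),
    stats::setNames(rep("spikein_extraction", 3L), sp$extraction),
    stats::setNames(rep("spikein_rt", 2L), sp$rt),
    stats::setNames("ipc", "IPC"),
    stats::setNames("ipc", "NTC")  # no-template pseudo-target, never gridded
  )
  roles
}

target_role_levels <- function() {
  c("fingerprint", "reference", "signal_qc", "haemolysis",
    "spikein_extraction", "spikein_rt", "ipc")
}

# roles whose targets enter the sample x target Cq grid
grid_roles <- function() c("fingerprint", "reference", "signal_qc", "haemolysis")
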