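# Relative copy number from qPCR Ct triplicates under the delta-Ct = 0 =>
# diploid calibration, and concordance with predicted CNV types.

#' Estimate relative copy number from Ct triplicates
#'
#' For each measurement, `dCt = mean(Ct_target) - mean(Ct_reference)` and
#' `CN = 2 * 2^(-dCt)`, so a delta-Ct of zero is calibrated to the diploid
#' state and every unit of delta-Ct halves the copy number. The standard
#' deviation of CN is propagated in quadrature from the triplicate standard
#' errors: `sd(dCt) = sqrt(sd_t^2/3 + sd_r^2/3)` and
#' `sd(CN) = CN * ln(2) * sd(dCt)`. Measurements whose raw triplicate
#' standard deviation exceeds `sd_threshold` cycles (target or reference) are
#' flagged unreliable.
#'
#' @param measurements Data frame from [read_qpcr()] (columns `sample_id`,
#'   `assay_id`, `ct_t1..3`, `ct_r1..3`, optional `predicted_type`).
#' @param sd_threshold Maximum acceptable triplicate SD in cycles
#'   (default 0.5).
#' @return Data frame with `delta_ct`, `copy_number`, `cn_sd`, `reliable`
#'   appended.
#' @export
estimate_copy_number <- function(measurements, sd_threshold = 0.5) {
  req <- c(paste0("ct_t", 1:3), paste0("ct_r", 1:3))
  if (!all(req %in% names(measurements))) {
    stop("estimate_copy_number: missing Ct columns")
  }
  ct_t <- as.matrix(measurements[, paste0("ct_t", 1:3)])
  ct_r <- as.matrix(measurements[, paste0("ct_r", 1:3)])
  if (anyNA(ct_t) || anyNA(ct_r)) stop("estimate_copy_number: incomplete triplicate")
  if (any(!is.finite(ct_t)) || any(!is.finite(ct_r)) || any(ct_t <= 0) || any(ct_r <= 0)) {
    stop("estimate_copy_number: Ct values must be finite and positive")
  }
  mt <- rowMeans(ct_t); mr <- rowMeans(ct_r)
  sdt <- apply(ct_t, 1, stats::sd); sdr <- apply(ct_r, 1, stats::sd)
  dct <- mt - mr
  cn <- 2 * 2^(-dct)
  sd_dct <- sqrt(sdt^2 / 3 + sdr^2 / 3)
  out <- as.data.frame(measurements)
  out$delta_ct <- dct
  out$copy_number <- cn
  out$cn_sd <- cn * log(2) * sd_dct
  out$reliable <- sdt <= sd_threshold & sdr <= sd_threshold
  out
}

#' Concordance of qPCR copy number with predicted CNV type
#'
#' A predicted loss is confirmed when the estimated copy number falls below
#' `loss_max`; a predicted gain when it exceeds `gain_min`. Unreliable
#' measurements get the verdict `unreliable` and are excluded from
#' confirmation counts.
#'
#' @param estimates Output of [estimate_copy_number()] with a
#'   `predicted_type` column.
#' @param loss_max Copy number below which a predicted loss is confirmed
#'   (default 1.5).
#' @param gain_min Copy number above which a predicted gain is confirmed
#'   (default 2.5).
#' @return `estimates` with a `verdict` column (`confirmed`,
#'   `not_confirmed`, `unreliable`); attribute `counts` tabulates verdicts.
#' @export
qpcr_concordance <- function(estimates, loss_max = 1.5, gain_min = 2.5) {
  if (!"predicted_type" %in% names(estimates)) {
    stop("qpcr_concordance: predicted_type column required")
  }
  if (!"copy_number" %in% names(estimates)) {
    stop("qpcr_concordance: run estimate_copy_number() first")
  }
  verdict <- rep(NA_character_, nrow(estimates))
  known <- !is.na(estimates$predicted_type)
  cn <- estimates$copy_number
  verdict[known & estimates$predicted_type == "loss"] <-
    ifelse(cn[known & estimates$predicted_type == "loss"] < loss_max,
           "confirmed", "not_confirmed")
  verdict[known & estimates$predicted_type == "gain"] <-
    ifelse(cn[known & estimates$predicted_type == "gain"] > gain_min,
           "confirmed", "not_confirmed")
  verdict[!estimates$reliable] <- "unreliable"
  out <- estimates
  out$verdict <- verdict
  attr(out, "counts") <- table(factor(verdict, levels = c("confirmed", "not_confirmed", "unreliable")))
  out
}
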