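#' Quick-SOFA score
#'
#' The qSOFA score is the sum of three binary bedside criteria, each
#' contributing one point: Glasgow Coma Scale at or below 13, systolic
#' blood pressure at or below 100 mmHg, and respiratory rate at or above
#' 22 breaths/min. All three boundaries are inclusive. A score of 2 or
#' more flags elevated risk of poor outcome.
#'
#' @param gcs Glasgow Coma Scale, integer in 3..15.
#' @param sbp Systolic blood pressure, mmHg (> 0).
#' @param rr Respiratory rate, breaths/min (>= 0).
#' @return Integer score in 0..3. Vectorised over its arguments.
#' @examples
#' qsofa_score(gcs = 15, sbp = 120, rr = 12) # 0
#' qsofa_score(gcs = 13, sbp = 100, rr = 22) # 3, all boundaries inclusive
#' @export
qsofa_score <- function(gcs, sbp, rr) {
  if (any(!is.finite(gcs)) || any(gcs < 3) || any(gcs > 15) ||
      any(gcs != round(gcs))) {
    stop("gcs must be an integer in 3..15", call. = FALSE)
  }
  if (any(!is.finite(sbp)) || any(sbp <= 0)) {
    stop("sbp must be positive", call. = FALSE)
  }
  if (any(!is.finite(rr)) || any(rr < 0)) {
    stop("rr must be non-negative", call. = FALSE)
  }
  as.integer((gcs <= 13) + (sbp <= 100) + (rr >= 22))
}

#' Label an instance from its qSOFA score at t6
#'
#' The prediction task is whether a patient whose qSOFA equals 1 at t0
#' deteriorates to a score of 2 or 3 after the six-hour prediction gap.
#' Deterioration is the positive class (+1); a score below 2 at t6 is the
#' negative class (-1).
#'
#' @param score_t6 Integer qSOFA score at t6, in 0..3.
#' @return `+1` or `-1`. Vectorised.
#' @export
label_instance <- function(score_t6) {
  if (any(!score_t6 %in% 0:3)) {
    stop("score_t6 must be in 0..3", call. = FALSE)
  }
  ifelse(score_t6 >= 2, 1L, -1L)
}

#' Build a patient instance from a raw record
#'
#' Assembles one classifiable instance: the regular-space ECG segment
#' ending at t0, the privileged ECG segment ending at t6, the EHR
#' timeline, and the outcome label derived from the qSOFA inputs at t6.
#' Records are screened, never silently dropped: an unusable record
#' yields a rejection with a reason code.
#'
#' @param record A list with elements `patient_id`, `ecg_t0`
#'   ([ecg_segment] at anchor `t0`), `ecg_t6` ([ecg_segment] at `t6`),
#'   `ehr` (list of [ehr_observation]), `qsofa_t0` (score at prediction
#'   time; must equal 1), and `qsofa_inputs_t6` (list with `gcs`, `sbp`,
#'   `rr` at the outcome time).
#' @param noise_threshold Segments with at least this fraction of noisy
#'   subwindows are rejected (default 0.5).
#' @param filter Logical; band-pass filter both segments before storing
#'   them (default `TRUE`).
#' @return A `patient_instance` (fields `patient_id`, `ecg_t0`, `ecg_t6`,
#'   `ehr`, `qsofa_t0`, `score_t6`, `label`), or a `instance_rejection`
#'   with a `reason` in `missing_regular_ecg`, `missing_privileged_ecg`,
#'   `missing_ehr`, `qsofa_t0_not_one`, `noise`.
#' @export
build_instance <- function(record, noise_threshold = 0.5, filter = TRUE) {
  reject <- function(reason) {
    structure(list(patient_id = record$patient_id, reason = reason),
              class = "instance_rejection")
  }
  if (is.null(record$ecg_t0)) return(reject("missing_regular_ecg"))
  if (is.null(record$ecg_t6)) return(reject("missing_privileged_ecg"))
  if (is.null(record$ehr) || !length(record$ehr)) {
    return(reject("missing_ehr"))
  }
  stopifnot(inherits(record$ecg_t0, "ecg_segment"),
            inherits(record$ecg_t6, "ecg_segment"))
  if (record$ecg_t0$anchor != "t0" || record$ecg_t6$anchor != "t6") {
    stop("segments must be anchored at t0 and t6 respectively",
         call. = FALSE)
  }
  if (is.null(record$qsofa_t0) || record$qsofa_t0 != 1) {
    return(reject("qsofa_t0_not_one"))
  }
  ecg_t0 <- if (filter) bandpass_filter(record$ecg_t0) else record$ecg_t0
  ecg_t6 <- if (filter) bandpass_filter(record$ecg_t6) else record$ecg_t6
  if (noise_fraction(ecg_t0) >= noise_threshold ||
      noise_fraction(ecg_t6) >= noise_threshold) {
    return(reject("noise"))
  }
  q6 <- record$qsofa_inputs_t6
  score_t6 <- qsofa_score(q6$gcs, q6$sbp, q6$rr)
  structure(list(
    patient_id = record$patient_id,
    ecg_t0 = ecg_t0,
    ecg_t6 = ecg_t6,
    ehr = record$ehr,
    qsofa_t0 = 1L,
    score_t6 = score_t6,
    label = label_instance(score_t6)
  ), class = "patient_instance")
}

#' @export
print.patient_instance <- function(x, ...) {
  cat("Patient instance", x$patient_id,
      "| qSOFA(t0) = 1, qSOFA(t6) =", x$score_t6,
      "| label =", x$label, "\n")
  invisible(x)
}
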