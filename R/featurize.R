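#' Compute all feature vectors of a patient instance
#'
#' Runs the regular-space featurisation (ECG tensor flattening and EHR
#' lookback assembly) and the three privileged-space feature sets
#' (taut-string ECG, statistical ECG, EHR at t6) for one
#' `patient_instance`.
#'
#' @param instance A `patient_instance` from [build_instance()].
#' @param ehr_config An `ehr_encoding_config`.
#' @param epsilons Taut-string tube schedule.
#' @return A list with `ecg` (60), `ehr` (115), `pi_ts` (30), `pi_sf`
#'   (7), `pi_ehr` (23), `y` and `patient_id`.
#' @export
featurize_instance <- function(instance, ehr_config = load_ehr_config(),
                               epsilons = default_epsilons()) {
  stopifnot(inherits(instance, "patient_instance"))
  reg <- regular_ecg_features(instance$ecg_t0, epsilons)
  priv <- privileged_ecg_features(instance$ecg_t6, epsilons)
  offs <- vapply(instance$ehr, `[[`, numeric(1), "time_offset")
  t6_obs <- instance$ehr[[which(offs == 6)[1]]]
  list(
    ecg = reg$vector,
    ehr = assemble_regular_ehr(instance$ehr[offs != 6], ehr_config),
    pi_ts = priv$ts_vector,
    pi_sf = priv$sf,
    pi_ehr = assemble_privileged_ehr(t6_obs, ehr_config),
    y = instance$label,
    patient_id = instance$patient_id
  )
}

#' Stack per-instance features into a LUPI dataset
#'
#' @param features List of per-instance feature lists from
#'   [featurize_instance()].
#' @return An object of class `lupi_dataset`: feature matrices `X_ecg`
#'   (n x 60), `X_ehr` (n x 115), `Xstar_ts` (n x 30), `Xstar_sf`
#'   (n x 7), `Xstar_ehr` (n x 23), labels `y` and `patient_id`.
#' @export
as_lupi_dataset <- function(features) {
  stack <- function(field) {
    do.call(rbind, lapply(features, `[[`, field))
  }
  structure(list(
    X_ecg = stack("ecg"),
    X_ehr = stack("ehr"),
    Xstar_ts = stack("pi_ts"),
    Xstar_sf = stack("pi_sf"),
    Xstar_ehr = stack("pi_ehr"),
    y = as.integer(vapply(features, `[[`, numeric(1), "y")),
    patient_id = vapply(features, `[[`, character(1), "patient_id")
  ), class = "lupi_dataset")
}

#' @export
print.lupi_dataset <- function(x, ...) {
  cat("LUPI dataset:", length(x$y), "instances,",
      length(unique(x$patient_id)), "patients,",
      sum(x$y > 0), "positive\n")
  invisible(x)
}

# select the regular-space design matrix for an experiment arm
regular_matrix <- function(data, regular = c("ecg", "ehr", "ecg_ehr")) {
  regular <- match.arg(regular)
  switch(regular,
         ecg = data$X_ecg,
         ehr = data$X_ehr,
         ecg_ehr = cbind(data$X_ecg, data$X_ehr))
}

# select the privileged design matrix for a PI type ("none" -> NULL)
privileged_matrix <- function(data,
                              pi_type = c("none", "ts_ecg", "sf_ecg", "ehr")) {
  pi_type <- match.arg(pi_type)
  switch(pi_type,
         none = NULL,
         ts_ecg = data$Xstar_ts,
         sf_ecg = data$Xstar_sf,
         ehr = data$Xstar_ehr)
}
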