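# Shared small synthetic cohorts, generated once per test run.
# Short (non-600 s) ECG records are built directly where a full
# 10-minute instance is not required.

.cohort_cache <- new.env(parent = emptyenv())

tiny_cohort <- function(n = 24, seed = 401, ...) {
  key <- paste0("c", n, "_", seed, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(
      cohort_config(n_patients = n, seed = seed, ...))
  }
  .cohort_cache[[key]]
}

# a complete raw record suitable for build_instance
make_record <- function(patient_id = "P1", seed = 7, positive = TRUE) {
  set.seed(seed)
  sepsislupi:::generate_patient_record(patient_id,
                                       if (positive) 1L else -1L,
                                       cohort_config(seed = seed))
}

# small featurised dataset without any ECG pipeline (fast): random
# features with a planted linear signal, patient-wise structure
toy_dataset <- function(n = 40, d = 6, seed = 11, signal = 1.5) {
  set.seed(seed)
  y <- rep(c(-1, 1), length.out = n)
  X <- matrix(rnorm(n * d), n) + signal * y %o% c(rep(1, 2), rep(0, d - 2))
  Xstar <- matrix(y, n, 2) + matrix(rnorm(n * 2, sd = 0.1), n)
  structure(list(
    X_ecg = X, X_ehr = X, Xstar_ts = Xstar, Xstar_sf = Xstar,
    Xstar_ehr = Xstar, y = y,
    patient_id = sprintf("P%03d", seq_len(n))
  ), class = "lupi_dataset")
}
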