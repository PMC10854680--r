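#' Synthetic cohort configuration
#'
#' Study conditions for the synthetic ICU cohort generator. The default
#' shape mirrors the smaller, critically ill cohort of the prediction
#' task (106 instances, 59 positive); `n_patients = 453` with
#' `positive_fraction = 144/453` gives the broader-cohort shape.
#'
#' @param n_patients Number of patients (>= 4); with
#'   `multi_instance_fraction = 0` this is also the instance count.
#' @param positive_fraction Fraction of instances whose generating class
#'   is deterioration, in (0, 1).
#' @param ecg_effect Class separation planted in the ECG generating
#'   parameters (beat-interval jitter and noise amplitude), >= 0;
#'   0 removes all ECG signal.
#' @param ehr_effect Class separation planted in vital-sign drift and
#'   lab/infusion severity, >= 0.
#' @param pi_informativeness Probability in `[0, 1]` that the t6
#'   physiology is drawn consistently with the generating class; at 1
#'   the qSOFA outcome equals the generating class, at 0 the outcome is
#'   independent of every feature (a null cohort).
#' @param noise_sd Baseline additive ECG noise, mV.
#' @param multi_instance_fraction Fraction of patients contributing a
#'   second, independently generated instance (default 0).
#' @param seed Integer seed; cohorts are reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 106, positive_fraction = 59 / 106,
                          ecg_effect = 0.3, ehr_effect = 0.3,
                          pi_informativeness = 1, noise_sd = 0.05,
                          multi_instance_fraction = 0, seed = 1) {
  stopifnot(n_patients >= 4,
            positive_fraction > 0, positive_fraction < 1,
            ecg_effect >= 0, ehr_effect >= 0,
            pi_informativeness >= 0, pi_informativeness <= 1,
            noise_sd >= 0,
            multi_instance_fraction >= 0, multi_instance_fraction < 1)
  structure(list(n_patients = as.integer(n_patients),
                 positive_fraction = positive_fraction,
                 ecg_effect = ecg_effect, ehr_effect = ehr_effect,
                 pi_informativeness = pi_informativeness,
                 noise_sd = noise_sd,
                 multi_instance_fraction = multi_instance_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic single-lead ECG segment
#'
#' A periodic QRS-like pulse train: Gaussian R-wave bumps (about 1 mV)
#' with a smaller T-wave, beat-interval jitter, slow baseline wander and
#' additive white noise. This emulates the morphology statistics the
#' taut-string features respond to; it is not a physiological ECG model.
#'
#' @param hr Mean heart rate in bpm (30..220).
#' @param noise_sd White-noise standard deviation, mV.
#' @param duration_s Segment duration in seconds (default 600).
#' @param rate Sampling rate (default 240).
#' @param jitter_sd Relative standard deviation of beat intervals.
#' @param wander_amp Baseline wander amplitude, mV.
#' @param anchor Timeline anchor of the produced [ecg_segment].
#' @return An [ecg_segment].
#' @export
generate_ecg_segment <- function(hr, noise_sd = 0.05, duration_s = 600,
                                 rate = 240, jitter_sd = 0.02,
                                 wander_amp = 0.1, anchor = "t0") {
  if (!is.finite(hr) || hr < 30 || hr > 220) {
    stop("hr must be in 30..220 bpm", call. = FALSE)
  }
  n <- as.integer(round(duration_s * rate))
  mean_rr <- 60 / hr
  n_beats <- ceiling(duration_s / mean_rr) + 3
  rr <- mean_rr * pmax(0.4, 1 + stats::rnorm(n_beats, sd = jitter_sd))
  beat_t <- cumsum(rr)
  beat_t <- beat_t[beat_t < duration_s]
  # impulse train convolved with Gaussian wave templates (beat times are
  # rounded to the sample grid; jitter is far above one sample period)
  bump_train <- function(centres_s, amp, sigma_s) {
    imp <- numeric(n)
    c0 <- round(centres_s * rate) + 1
    c0 <- c0[c0 >= 1 & c0 <= n]
    imp[c0] <- amp
    half <- ceiling(4 * sigma_s * rate)
    tmpl <- exp(-((-half:half) / rate)^2 / (2 * sigma_s^2))
    out <- stats::convolve(imp, rev(tmpl), type = "open")
    out[(half + 1):(half + n)]
  }
  x <- bump_train(beat_t, 1.0, 0.012) +              # R wave
    bump_train(beat_t + 0.25 * mean_rr, 0.2, 0.05)   # T wave
  tt <- (seq_len(n) - 1) / rate
  phase <- stats::runif(1, 0, 2 * pi)
  x <- x + wander_amp * sin(2 * pi * 0.25 * tt + phase)
  if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
  ecg_segment(x, anchor = anchor, sampling_rate = rate,
              duration = duration_s)
}

# draw qSOFA inputs with exactly `k` criteria met; the criterion mix is
# random but respects the printed boundary inequalities
draw_qsofa_inputs <- function(k) {
  gcs <- 15L
  sbp <- stats::runif(1, 110, 140)
  rr <- stats::runif(1, 12, 20)
  which_crit <- sample(c("sbp", "rr", "gcs"), size = k)
  if ("sbp" %in% which_crit) sbp <- stats::runif(1, 80, 100)
  if ("rr" %in% which_crit) rr <- stats::runif(1, 22, 32)
  if ("gcs" %in% which_crit) gcs <- sample(8:13, 1)
  list(gcs = gcs, sbp = sbp, rr = rr)
}

#' Generate a synthetic EHR timeline for one instance
#'
#' Vital signs follow a random walk over the lookback grid whose drift
#' depends on the generating class scaled by `ehr_effect`; the t0 vitals
#' are constrained so that qSOFA(t0) = 1; the t6 qSOFA inputs are drawn
#' consistently with the generating class with probability
#' `pi_informativeness` (and with a coin flip otherwise); labs and
#' infusions come from class-conditional severity distributions.
#'
#' @param true_class `+1` (deteriorating) or `-1`.
#' @param cfg A [cohort_config].
#' @return A list with `observations` (six [ehr_observation]s at
#'   -16..0 and +6 h), `qsofa_inputs_t0` and `qsofa_inputs_t6`.
#' @export
generate_ehr_timeline <- function(true_class, cfg) {
  stopifnot(true_class %in% c(-1, 1))
  pos <- as.numeric(true_class > 0)
  eff <- cfg$ehr_effect * pos
  # per-lookback drift of (temp, spo2, hr, map, rr) for deteriorating class
  drift <- c(0.15, -0.5, 2.5, -2.0, 0.8) * eff
  base <- c(temperature = stats::rnorm(1, 37, 0.4),
            spo2 = min(100, stats::rnorm(1, 97, 1.5)),
            heart_rate = stats::rnorm(1, 82, 9),
            mean_arterial_pressure = stats::rnorm(1, 88, 9),
            respiratory_rate = stats::rnorm(1, 16, 2.5))
  vit <- matrix(NA_real_, 5, 5,
                dimnames = list(NULL, EHR_VITALS))
  vit[1, ] <- base
  for (i in 2:5) {
    vit[i, ] <- vit[i - 1, ] + drift +
      stats::rnorm(5, sd = c(0.15, 0.8, 3, 3, 1.2))
  }
  q0 <- draw_qsofa_inputs(1)
  # t0 vitals agree with the qSOFA inputs that define the anchor
  vit[5, "respiratory_rate"] <- q0$rr
  vit[5, "mean_arterial_pressure"] <- q0$sbp * 0.7 + stats::rnorm(1, 8, 2)
  consistent <- stats::runif(1) < cfg$pi_informativeness ||
    stats::runif(1) < 0.5
  target_pos <- if (consistent) pos else 1 - pos
  q6 <- draw_qsofa_inputs(if (target_pos > 0) sample(2:3, 1, prob = c(.8, .2))
                          else sample(0:1, 1, prob = c(.4, .6)))
  lab_presence <- c(0.4, 0.4, 0.5, 0.6, 0.8, 0.9)
  severity_shift <- c(0, 0, 0, 0, 0.5, 1) # grows towards t6 for positives
  draw_labs <- function(step) {
    if (stats::runif(1) > lab_presence[step]) return(list())
    s <- 1 + eff * severity_shift[step]
    list(creatinine = stats::rlnorm(1, log(0.9 * s), 0.3),
         glucose = stats::rnorm(1, 110 * sqrt(s), 25),
         lactate = stats::rlnorm(1, log(1.2 * s), 0.4),
         wbc = stats::rnorm(1, 9 * s, 2.5),
         platelet_count = stats::rnorm(1, 230 / s, 50),
         hemoglobin = stats::rnorm(1, 12.5 / sqrt(s), 1.2),
         hematocrit = stats::rnorm(1, 38 / sqrt(s), 3),
         inr = stats::rlnorm(1, log(1.1 * sqrt(s)), 0.15),
         potassium = stats::rnorm(1, 4.1, 0.4),
         sodium = stats::rnorm(1, 139, 3))
  }
  draw_infusions <- function(step) {
    p <- 0.08 + 0.25 * eff * severity_shift[step]
    agents <- EHR_INFUSIONS[stats::runif(7) < p / 7 * c(2, 2, 3, 1, 1, 5, 2)]
    if (!length(agents)) return(list())
    doses <- list(dobutamine = stats::runif(1, 2, 12),
                  dopamine = stats::runif(1, 2, 18),
                  epinephrine = stats::runif(1, 0.02, 0.3),
                  isoproterenol = stats::runif(1, 1, 6),
                  milrinone = stats::runif(1, 0.1, 0.6),
                  norepinephrine = stats::runif(1, 0.02, 0.4),
                  vasopressin = stats::runif(1, 0.01, 0.05))
    doses[agents]
  }
  obs <- vector("list", 6)
  for (i in 1:5) {
    obs[[i]] <- ehr_observation(
      time_offset = EHR_LOOKBACKS[i],
      vitals = as.list(vit[i, ]),
      urine_output = max(0, stats::rnorm(1, 60 - 15 * eff * (i / 5), 15)),
      labs = draw_labs(i),
      infusions = draw_infusions(i))
  }
  vit6 <- vit[5, ] + drift + stats::rnorm(5, sd = c(0.15, 0.8, 3, 3, 1.2))
  vit6["respiratory_rate"] <- q6$rr
  vit6["mean_arterial_pressure"] <- q6$sbp * 0.7 + stats::rnorm(1, 8, 2)
  obs[[6]] <- ehr_observation(
    time_offset = 6,
    vitals = as.list(vit6),
    urine_output = max(0, stats::rnorm(1, 60 - 25 * eff, 15)),
    labs = draw_labs(6),
    infusions = draw_infusions(6))
  list(observations = obs, qsofa_inputs_t0 = q0, qsofa_inputs_t6 = q6)
}

generate_patient_record <- function(patient_id, true_class, cfg,
                                    duration_s = 600) {
  pos <- as.numeric(true_class > 0)
  hr <- stats::rnorm(1, 82 + 8 * cfg$ehr_effect * pos, 8)
  hr <- min(180, max(45, hr))
  # ECG class signal: deterioration raises beat-interval variability and
  # broadband noise, more strongly in the privileged (t6) window.
  # Patients carry individual lognormal factors so that classes overlap:
  # the class shift competes with realistic between-patient spread.
  indiv_noise <- exp(stats::rnorm(1, 0, 0.35))
  indiv_jit <- exp(stats::rnorm(1, 0, 0.25))
  jit0 <- 0.02 * indiv_jit * (1 + cfg$ecg_effect * pos)
  jit6 <- 0.02 * indiv_jit * (1 + 1.5 * cfg$ecg_effect * pos)
  nsd0 <- cfg$noise_sd * indiv_noise * (1 + cfg$ecg_effect * pos)
  nsd6 <- cfg$noise_sd * indiv_noise * (1 + 1.5 * cfg$ecg_effect * pos)
  tl <- generate_ehr_timeline(true_class, cfg)
  list(patient_id = patient_id,
       ecg_t0 = generate_ecg_segment(hr, nsd0, duration_s,
                                     jitter_sd = jit0, anchor = "t0"),
       ecg_t6 = generate_ecg_segment(hr + 6 * pos * cfg$ehr_effect, nsd6,
                                     duration_s, jitter_sd = jit6,
                                     anchor = "t6"),
       ehr = tl$observations,
       qsofa_t0 = 1L,
       qsofa_inputs_t6 = tl$qsofa_inputs_t6,
       true_class = true_class,
       gen_params = list(hr = hr, jitter_t0 = jit0, jitter_t6 = jit6,
                         noise_t0 = nsd0, noise_t6 = nsd6))
}

#' Generate a synthetic patient cohort
#'
#' Draws the configured number of patients, builds each instance through
#' [build_instance()] (so labels always come from the qSOFA scoring of
#' the generated t6 physiology, never from the generating class
#' directly), and featurises every accepted instance. Rejected records
#' (e.g. a noisy segment) are redrawn so the cohort size is exact.
#'
#' @param cfg A [cohort_config].
#' @param ehr_config An `ehr_encoding_config` for featurisation.
#' @param keep_signals Keep the raw ECG segments on each instance
#'   (memory-heavy for large cohorts; default `FALSE`).
#' @param duration_s ECG segment duration (default 600 s).
#' @param progress Print one line per 25 patients to stderr.
#' @return An object of class `synthetic_cohort`: `data` (a
#'   `lupi_dataset`), `true_class`, `gen_params`, `config`, and, when
#'   `keep_signals = TRUE`, the full `instances`.
#' @export
generate_cohort <- function(cfg = cohort_config(),
                            ehr_config = load_ehr_config(),
                            keep_signals = FALSE, duration_s = 600,
                            progress = FALSE) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n_multi <- round(cfg$multi_instance_fraction * cfg$n_patients)
  instance_patients <- c(seq_len(cfg$n_patients),
                         if (n_multi > 0) seq_len(n_multi))
  feats <- vector("list", length(instance_patients))
  instances <- if (keep_signals) vector("list", length(instance_patients))
  true_class <- integer(length(instance_patients))
  gen_params <- vector("list", length(instance_patients))
  for (k in seq_along(instance_patients)) {
    pid <- sprintf("P%04d", instance_patients[k])
    inst <- NULL
    for (attempt in 1:5) {
      tc <- if (stats::runif(1) < cfg$positive_fraction) 1L else -1L
      rec <- generate_patient_record(pid, tc, cfg, duration_s)
      cand <- build_instance(rec)
      if (inherits(cand, "patient_instance")) {
        inst <- cand
        break
      }
    }
    if (is.null(inst)) {
      stop("could not generate an acceptable record for ", pid,
           call. = FALSE)
    }
    feats[[k]] <- featurize_instance(inst, ehr_config)
    true_class[k] <- tc
    gen_params[[k]] <- c(rec$gen_params,
                         list(qsofa_inputs_t6 = rec$qsofa_inputs_t6,
                              score_t6 = inst$score_t6))
    if (keep_signals) instances[[k]] <- inst
    if (progress && k %% 25 == 0) {
      message("generated ", k, "/", length(instance_patients), " instances")
    }
  }
  structure(list(
    data = as_lupi_dataset(feats),
    true_class = true_class,
    gen_params = gen_params,
    config = cfg,
    instances = instances
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$data$y), "instances,",
      sum(x$data$y > 0), "positive (seed", x$config$seed, ")\n")
  invisible(x)
}
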