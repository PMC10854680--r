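# canonical feature orderings; every assembled vector follows these
EHR_VITALS <- c("temperature", "spo2", "heart_rate",
                "mean_arterial_pressure", "respiratory_rate")
EHR_LABS <- c("creatinine", "glucose", "hematocrit", "hemoglobin", "inr",
              "lactate", "platelet_count", "potassium", "sodium", "wbc")
EHR_INFUSIONS <- c("dobutamine", "dopamine", "epinephrine", "isoproterenol",
                   "milrinone", "norepinephrine", "vasopressin")
EHR_LOOKBACKS <- c(-16, -12, -8, -4, 0)
EHR_OFFSETS <- c(EHR_LOOKBACKS, 6)

#' Load an ordinal EHR encoding configuration
#'
#' Reads the YAML threshold configuration used by [encode_labs()] and
#' [encode_infusions()]. Without a path the packaged default is used;
#' its cut points are clinically plausible synthetic values, not a
#' canonical published encoding.
#'
#' @param path Optional path to a YAML file with `labs`, `infusions` and
#'   `vital_defaults` blocks.
#' @return A validated configuration list of class `ehr_encoding_config`.
#' @export
load_ehr_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ehr_encoding_default.yaml",
                        package = "sepsislupi")
  }
  cfg <- yaml::read_yaml(path)
  validate_ehr_config(cfg)
}

validate_ehr_config <- function(cfg) {
  if (!all(c("labs", "infusions", "vital_defaults") %in% names(cfg))) {
    stop("encoding config needs labs, infusions and vital_defaults blocks",
         call. = FALSE)
  }
  missing_labs <- setdiff(EHR_LABS, names(cfg$labs))
  if (length(missing_labs)) {
    stop("config lacks lab thresholds for: ",
         paste(missing_labs, collapse = ", "), call. = FALSE)
  }
  for (lab in EHR_LABS) {
    spec <- cfg$labs[[lab]]
    th <- as.numeric(spec$thresholds)
    dir <- spec$direction
    if (length(th) != 3 || !dir %in% c("high", "low")) {
      stop("lab '", lab, "': need 3 thresholds and direction high/low",
           call. = FALSE)
    }
    ordered <- if (dir == "high") all(diff(th) > 0) else all(diff(th) < 0)
    if (!ordered) {
      stop("lab '", lab, "': thresholds must be strictly ordered",
           call. = FALSE)
    }
  }
  missing_inf <- setdiff(EHR_INFUSIONS, names(cfg$infusions))
  if (length(missing_inf)) {
    stop("config lacks infusion thresholds for: ",
         paste(missing_inf, collapse = ", "), call. = FALSE)
  }
  for (drug in EHR_INFUSIONS) {
    th <- as.numeric(cfg$infusions[[drug]]$thresholds)
    if (length(th) != 2 || any(diff(th) <= 0)) {
      stop("infusion '", drug, "': need 2 strictly increasing thresholds",
           call. = FALSE)
    }
  }
  if (!all(c(EHR_VITALS, "urine_output") %in% names(cfg$vital_defaults))) {
    stop("vital_defaults must cover the five vitals and urine_output",
         call. = FALSE)
  }
  structure(cfg, class = "ehr_encoding_config")
}

#' A single timestamped EHR observation
#'
#' @param time_offset Hours relative to t0; one of -16, -12, -8, -4, 0, 6.
#' @param vitals Named list/vector of any of temperature (degrees C),
#'   spo2 (%), heart_rate (bpm), mean_arterial_pressure (mmHg),
#'   respiratory_rate (breaths/min). Missing entries are allowed.
#' @param urine_output Hourly urine output in mL/h, or `NA`.
#' @param labs Named list of raw lab values (subset of the ten encoded
#'   labs); absent labs encode to 0.
#' @param infusions Named list of raw infusion doses (subset of the seven
#'   encoded agents); absent agents encode to 0.
#' @return An object of class `ehr_observation`.
#' @export
ehr_observation <- function(time_offset, vitals = list(), urine_output = NA,
                            labs = list(), infusions = list()) {
  if (!time_offset %in% EHR_OFFSETS) {
    stop("time_offset must be one of ",
         paste(EHR_OFFSETS, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(vitals), EHR_VITALS)
  if (length(unknown)) {
    stop("unknown vitals: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(setdiff(names(labs), EHR_LABS))) {
    stop("unknown labs: ",
         paste(setdiff(names(labs), EHR_LABS), collapse = ", "),
         call. = FALSE)
  }
  if (length(setdiff(names(infusions), EHR_INFUSIONS))) {
    stop("unknown infusions: ",
         paste(setdiff(names(infusions), EHR_INFUSIONS), collapse = ", "),
         call. = FALSE)
  }
  structure(list(time_offset = time_offset, vitals = vitals,
                 urine_output = urine_output, labs = labs,
                 infusions = infusions),
            class = "ehr_observation")
}

bin_severity <- function(value, thresholds, direction = "high") {
  if (is.null(value) || is.na(value)) return(0L)
  crossed <- if (direction == "high") sum(value >= thresholds)
             else sum(value <= thresholds)
  1L + as.integer(crossed)
}

#' Ordinal encoding of raw lab values
#'
#' Maps each of the ten labs to a severity in 1..4 via the configured
#' threshold list; a lab with nothing logged encodes to 0.
#'
#' @param labs Named list/vector of raw values (missing entries allowed).
#' @param config An `ehr_encoding_config` from [load_ehr_config()].
#' @return Named integer vector of length 10 in canonical lab order.
#' @export
encode_labs <- function(labs, config = load_ehr_config()) {
  config <- validate_ehr_config(config)
  out <- vapply(EHR_LABS, function(lab) {
    spec <- config$labs[[lab]]
    v <- if (lab %in% names(labs)) labs[[lab]] else NA
    bin_severity(v, as.numeric(spec$thresholds), spec$direction)
  }, integer(1))
  out
}

#' Ordinal encoding of cardiovascular infusion doses
#'
#' Maps each of the seven vasoactive/inotropic agents to a dose severity
#' in 1..3; an agent that is not running encodes to 0.
#'
#' @inheritParams encode_labs
#' @param infusions Named list/vector of raw doses.
#' @return Named integer vector of length 7 in canonical agent order.
#' @export
encode_infusions <- function(infusions, config = load_ehr_config()) {
  config <- validate_ehr_config(config)
  vapply(EHR_INFUSIONS, function(drug) {
    v <- if (drug %in% names(infusions)) infusions[[drug]] else NA
    bin_severity(v, as.numeric(config$infusions[[drug]]$thresholds), "high")
  }, integer(1))
}

# one 23-value block: 5 vitals + urine + 10 lab ordinals + 7 infusion ordinals
ehr_block <- function(obs, config) {
  vit <- vapply(EHR_VITALS, function(v) {
    val <- if (!is.null(obs) && v %in% names(obs$vitals)) obs$vitals[[v]] else NA
    as.numeric(val)
  }, numeric(1))
  urine <- if (!is.null(obs)) as.numeric(obs$urine_output) else NA_real_
  labs <- if (!is.null(obs)) encode_labs(obs$labs, config)
          else stats::setNames(rep(0L, 10), EHR_LABS)
  inf <- if (!is.null(obs)) encode_infusions(obs$infusions, config)
         else stats::setNames(rep(0L, 7), EHR_INFUSIONS)
  c(vit, urine_output = urine, labs, inf)
}

ehr_block_names <- function(prefix) {
  paste(prefix, c(EHR_VITALS, "urine_output", EHR_LABS, EHR_INFUSIONS),
        sep = "_")
}

#' Assemble the regular-space EHR feature vector
#'
#' Concatenates one 23-value block per lookback time (t-16, t-12, t-8,
#' t-4, t0, in time order) into the 115-value regular-space vector.
#' Missing numeric vitals/urine are filled by last observation carried
#' forward across lookbacks and, failing that, by the population default
#' from the configuration; labs and infusions never carry forward (an
#' absent value means nothing was logged and encodes to 0).
#'
#' @param observations List of [ehr_observation] objects covering any
#'   subset of the five lookback offsets (an observation at +6 h is
#'   ignored here). At most one observation per offset.
#' @param config An `ehr_encoding_config`.
#' @return Named numeric vector of length 115.
#' @export
assemble_regular_ehr <- function(observations, config = load_ehr_config()) {
  config <- validate_ehr_config(config)
  offs <- vapply(observations, function(o) {
    if (!inherits(o, "ehr_observation")) {
      stop("observations must be ehr_observation objects", call. = FALSE)
    }
    o$time_offset
  }, numeric(1))
  if (anyDuplicated(offs)) {
    stop("at most one observation per time offset", call. = FALSE)
  }
  blocks <- lapply(EHR_LOOKBACKS, function(tt) {
    idx <- which(offs == tt)
    obs <- if (length(idx)) observations[[idx]] else NULL
    ehr_block(obs, config)
  })
  mat <- do.call(rbind, blocks) # 5 x 23, rows in time order
  # LOCF over the six numeric columns (vitals + urine), then defaults
  defaults <- unlist(config$vital_defaults[c(EHR_VITALS, "urine_output")])
  for (j in 1:6) {
    col <- mat[, j]
    for (i in seq_along(col)) {
      if (is.na(col[i])) col[i] <- if (i > 1) col[i - 1] else NA
    }
    col[is.na(col)] <- defaults[j]
    mat[, j] <- col
  }
  vec <- as.numeric(t(mat))
  names(vec) <- unlist(lapply(EHR_LOOKBACKS, function(tt) {
    ehr_block_names(sprintf("t%+d", tt))
  }))
  vec
}

#' Assemble the privileged-space EHR feature vector
#'
#' The same 23-value block as in the regular space, taken from the single
#' observation in the ten minutes ending at t6. Missing numeric values
#' fall back to the configured population defaults; absent labs and
#' infusions encode to 0.
#'
#' @param observation An [ehr_observation] with `time_offset = 6`.
#' @param config An `ehr_encoding_config`.
#' @return Named numeric vector of length 23.
#' @export
assemble_privileged_ehr <- function(observation,
                                    config = load_ehr_config()) {
  config <- validate_ehr_config(config)
  if (!inherits(observation, "ehr_observation") ||
      observation$time_offset != 6) {
    stop("privileged EHR features need a single observation at +6 h",
         call. = FALSE)
  }
  block <- ehr_block(observation, config)
  defaults <- unlist(config$vital_defaults[c(EHR_VITALS, "urine_output")])
  block[1:6][is.na(block[1:6])] <- defaults[is.na(block[1:6])]
  names(block) <- ehr_block_names("t+6")
  block
}
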