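cfg <- load_ehr_config()

# exhaustive linear-scan binning, independent of bin_severity's arithmetic
brute_bin <- function(value, thresholds, direction) {
  if (is.na(value)) return(0L)
  sev <- 1L
  for (t in thresholds) {
    hit <- if (direction == "high") value >= t else value <= t
    if (hit) sev <- sev + 1L
  }
  sev
}

test_that("lab encoding maps absent to 0 and bins to 1..4", {
  zeros <- encode_labs(list(), cfg)
  expect_equal(unname(zeros), rep(0L, 10))
  expect_named(zeros, sepsislupi:::EHR_LABS)

  # below the first threshold of an increasing config -> severity 1
  expect_equal(unname(encode_labs(list(lactate = 0.5), cfg)["lactate"]), 1L)
  expect_equal(unname(encode_labs(list(lactate = 100), cfg)["lactate"]), 4L)
})

test_that("random lab panels agree with brute-force binning", {
  set.seed(51)
  for (k in 1:40) {
    labs <- list(creatinine = runif(1, 0.2, 6), glucose = runif(1, 40, 400),
                 hematocrit = runif(1, 15, 55), hemoglobin = runif(1, 4, 18),
                 inr = runif(1, 0.8, 5), lactate = runif(1, 0.3, 15),
                 platelet_count = runif(1, 5, 450),
                 potassium = runif(1, 2.5, 8), sodium = runif(1, 120, 165),
                 wbc = runif(1, 1, 40))
    drop <- sample(names(labs), sample(0:5, 1))
    labs[drop] <- NULL
    enc <- encode_labs(labs, cfg)
    for (lab in sepsislupi:::EHR_LABS) {
      spec <- cfg$labs[[lab]]
      v <- if (lab %in% names(labs)) labs[[lab]] else NA
      expect_identical(unname(enc[lab]),
                       brute_bin(v, as.numeric(spec$thresholds),
                                 spec$direction))
    }
  }
})

test_that("infusion encoding maps absent to 0 and doses to 1..3", {
  expect_equal(unname(encode_infusions(list(), cfg)), rep(0L, 7))
  expect_equal(
    unname(encode_infusions(list(norepinephrine = 10), cfg)["norepinephrine"]),
    3L)
  set.seed(52)
  for (k in 1:20) {
    doses <- list(dopamine = runif(1, 0, 30),
                  vasopressin = runif(1, 0, 0.1))
    enc <- encode_infusions(doses, cfg)
    for (drug in names(doses)) {
      expect_identical(unname(enc[drug]),
                       brute_bin(doses[[drug]],
                                 as.numeric(cfg$infusions[[drug]]$thresholds),
                                 "high"))
    }
    expect_true(all(enc >= 0 & enc <= 3))
  }
})

test_that("encoders are monotone under an increasing-severity config", {
  set.seed(53)
  for (k in 1:25) {
    v1 <- runif(1, 0, 20)
    v2 <- v1 + runif(1, 0, 10)
    e1 <- encode_labs(list(lactate = v1), cfg)["lactate"]
    e2 <- encode_labs(list(lactate = v2), cfg)["lactate"]
    expect_gte(e2, e1)
    d1 <- encode_infusions(list(dopamine = v1), cfg)["dopamine"]
    d2 <- encode_infusions(list(dopamine = v2), cfg)["dopamine"]
    expect_gte(d2, d1)
  }
})

test_that("malformed configs are rejected", {
  bad <- unclass(cfg)
  bad$labs$lactate$thresholds <- c(4, 2, 8)
  expect_error(encode_labs(list(), bad), "strictly ordered")
  bad2 <- unclass(cfg)
  bad2$labs$lactate <- NULL
  expect_error(encode_labs(list(), bad2), "lactate")
})

full_obs <- function(tt, seed = 1) {
  set.seed(seed + round(100 * tt))
  ehr_observation(
    time_offset = tt,
    vitals = list(temperature = 37, spo2 = 97, heart_rate = 80 + tt,
                  mean_arterial_pressure = 85, respiratory_rate = 16),
    urine_output = 55,
    labs = list(lactate = 1.5, sodium = 141),
    infusions = list(norepinephrine = 0.1))
}

test_that("regular EHR assembly yields 115 values matching its blocks", {
  obs <- lapply(c(-16, -12, -8, -4, 0), full_obs)
  vec <- assemble_regular_ehr(obs, cfg)
  expect_length(vec, 115)
  # block-by-block oracle
  for (i in seq_along(obs)) {
    block <- vec[(23 * (i - 1) + 1):(23 * i)]
    expect_equal(unname(block[3]), 80 + obs[[i]]$time_offset) # heart rate
    expect_equal(unname(block[7:16]), unname(encode_labs(obs[[i]]$labs, cfg)))
    expect_equal(unname(block[17:23]),
                 unname(encode_infusions(obs[[i]]$infusions, cfg)))
  }
  # deterministic and idempotent
  expect_identical(vec, assemble_regular_ehr(obs, cfg))
})

test_that("missing values follow LOCF then population defaults", {
  # vitals observed only at t-16 carry forward to all five blocks
  first <- ehr_observation(-16, vitals = list(heart_rate = 99),
                           urine_output = 40)
  vec <- assemble_regular_ehr(list(first), cfg)
  hr_positions <- seq(3, 115, by = 23)
  expect_equal(unname(vec[hr_positions]), rep(99, 5))
  urine_positions <- seq(6, 115, by = 23)
  expect_equal(unname(vec[urine_positions]), rep(40, 5))
  # a vital never observed falls back to the configured default
  temp_positions <- seq(1, 115, by = 23)
  expect_equal(unname(vec[temp_positions]),
               rep(cfg$vital_defaults$temperature, 5))
  # labs never observed stay 0 in all 50 lab positions
  lab_positions <- as.vector(vapply(0:4, function(b) 23 * b + 7:16,
                                    numeric(10)))
  expect_true(all(vec[lab_positions] == 0))
})

test_that("privileged EHR assembly yields the 23-value t6 block", {
  obs6 <- full_obs(6)
  vec <- assemble_privileged_ehr(obs6, cfg)
  expect_length(vec, 23)
  expect_equal(unname(vec[7:16]), unname(encode_labs(obs6$labs, cfg)))
  empty6 <- ehr_observation(6)
  v2 <- assemble_privileged_ehr(empty6, cfg)
  expect_true(all(v2[7:23] == 0)) # 17 ordinal positions
  expect_error(assemble_privileged_ehr(full_obs(0), cfg), "\\+6")
})

test_that("unknown time offsets and duplicates are input errors", {
  expect_error(ehr_observation(3), "time_offset")
  expect_error(ehr_observation(0, vitals = list(pulse = 70)), "unknown")
  obs <- list(full_obs(0), full_obs(0))
  expect_error(assemble_regular_ehr(obs, cfg), "one observation")
})
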