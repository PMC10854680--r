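test_that("patient-wise splits partition instances at the stated fractions", {
  pid <- sprintf("P%03d", 1:100)
  y <- rep(c(-1, 1), 50)
  idx <- patient_wise_split(pid, y, iteration_seed = 1)
  expect_length(idx$train, 64)
  expect_length(idx$validation, 16)
  expect_length(idx$test, 20)
  expect_setequal(c(idx$train, idx$validation, idx$test), 1:100)
  expect_equal(anyDuplicated(c(idx$train, idx$validation, idx$test)), 0)
})

test_that("all instances of a patient land in the same set", {
  pid <- c("A", "A", sprintf("P%02d", 1:28))
  y <- rep(c(1, -1), 15)
  for (s in 1:5) {
    idx <- patient_wise_split(pid, y, iteration_seed = s)
    in_set <- vapply(idx, function(ii) any(c(1, 2) %in% ii), logical(1))
    expect_equal(sum(in_set), 1) # both instances of patient A together
    sets <- vapply(idx, function(ii) all(c(1, 2) %in% ii) ||
                     !any(c(1, 2) %in% ii), logical(1))
    expect_true(all(sets))
  }
  expect_error(patient_wise_split(c("A", "B"), c(1, -1), 1), "3 distinct")
  expect_error(patient_wise_split(pid, rep(1, 30), 1), "both classes")
})

test_that("metrics match hand-computed and brute-force values", {
  m <- compute_metrics(c(1, -1, 1, -1), c(1, -1, 1, -1))
  expect_equal(unname(m), c(1, 1, 1, 1, 1))

  # pair-counting oracle: 3 of 4 discordant-free pairs
  m2 <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, -1, 1, -1))
  expect_equal(unname(m2["auroc"]), 0.75)

  m3 <- compute_metrics(c(-2, -1, -3), c(1, -1, 1))
  expect_equal(unname(m3["sensitivity"]), 0)
  expect_equal(unname(m3["specificity"]), 1)
  expect_equal(unname(m3["f1"]), 0)

  expect_error(compute_metrics(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank AUROC and step AUPRC agree with independent references", {
  skip_if_not_installed("pROC")
  set.seed(111)
  for (k in 1:10) {
    n <- 40
    y <- sample(c(-1, 1), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- rnorm(n) + 0.8 * y
    s[sample(n, 5)] <- s[sample(n, 5)] # leave ties possible
    m <- compute_metrics(s, y)
    ref <- suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
    expect_equal(unname(m["auroc"]), as.numeric(ref), tolerance = 1e-10)
    # brute-force pair counting
    pos <- s[y == 1]; neg <- s[y == -1]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(unname(m["auroc"]), mean(pairs), tolerance = 1e-12)
  }
})

test_that("grid search returns the argmax and breaks ties deterministically", {
  dat <- toy_dataset(n = 36, seed = 112)
  idx <- patient_wise_split(dat$patient_id, dat$y, 3)
  X <- dat$X_ecg
  g <- grid_search(X[idx$train, ], NULL, dat$y[idx$train],
                   X[idx$validation, ], dat$y[idx$validation],
                   box_constraints = 2, kernel_scales = 1.5)
  expect_equal(g$C, 2)
  expect_equal(g$scale, 1.5)

  Cs <- c(0.5, 5); ss <- c(1, 3)
  g2 <- grid_search(X[idx$train, ], NULL, dat$y[idx$train],
                    X[idx$validation, ], dat$y[idx$validation],
                    box_constraints = Cs, kernel_scales = ss)
  # exhaustive oracle re-evaluation
  best <- NULL
  for (C in Cs) for (s in ss) {
    model <- fit_svm_baseline(X[idx$train, ], dat$y[idx$train], C, s)
    a <- compute_metrics(decision_scores(model, X[idx$validation, ]),
                         dat$y[idx$validation])["auroc"]
    if (is.null(best) || a > best$a + 1e-12) best <- list(C = C, s = s, a = a)
  }
  expect_equal(g2$C, best$C)
  expect_equal(g2$scale, best$s)
  expect_equal(g2$auroc, as.numeric(best$a))
})

test_that("experiments are deterministic and leakage-free", {
  dat <- toy_dataset(n = 40, seed = 113)
  cfg <- experiment_config(regular = "ecg", pi_types = c("none", "ts_ecg"),
                           n_iterations = 2, box_constraints = c(1, 10),
                           scale_factors = c(1, 2), seed = 9)
  r1 <- run_experiment(dat, cfg)
  r2 <- run_experiment(dat, cfg)
  expect_identical(r1$per_iteration, r2$per_iteration)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_metrics_report(r1, d1)
  write_metrics_report(r2, d2)
  expect_identical(readLines(file.path(d1, "metrics_long.csv")),
                   readLines(file.path(d2, "metrics_long.csv")))
  expect_identical(
    unname(tools::md5sum(file.path(d1, "summary_ecg.csv"))),
    unname(tools::md5sum(file.path(d2, "summary_ecg.csv"))))

  # hyperparameter selection must not depend on test-set features:
  # perturb the features of iteration-1 test rows only
  idx <- patient_wise_split(dat$patient_id, dat$y, cfg$seed * 10000L + 1)
  dat2 <- dat
  dat2$X_ecg[idx$test, ] <- dat2$X_ecg[idx$test, ] + 100
  dat2$Xstar_ts[idx$test, ] <- dat2$Xstar_ts[idx$test, ] + 100
  r3 <- run_experiment(dat2, experiment_config(
    regular = "ecg", pi_types = c("none", "ts_ecg"), n_iterations = 1,
    box_constraints = c(1, 10), scale_factors = c(1, 2), seed = 9))
  sel1 <- unique(r1$per_iteration[r1$per_iteration$iteration == 1,
                                  c("pi_type", "C", "scale")])
  sel3 <- unique(r3$per_iteration[, c("pi_type", "C", "scale")])
  expect_equal(sel1, sel3, ignore_attr = TRUE)
})

test_that("reports carry all arms with metrics bounded in [0, 1]", {
  dat <- toy_dataset(n = 36, seed = 114)
  cfg <- experiment_config(regular = "ecg",
                           pi_types = c("none", "ts_ecg", "sf_ecg", "ehr"),
                           n_iterations = 3, box_constraints = 1,
                           scale_factors = 1, seed = 4)
  r <- run_experiment(dat, cfg)
  expect_equal(sort(unique(r$per_iteration$pi_type)),
               sort(c("none", "ts_ecg", "sf_ecg", "ehr")))
  expect_true(all(r$per_iteration$value >= 0 & r$per_iteration$value <= 1))
  expect_equal(nrow(r$summary), 4)
  tab <- format_report_table(r)
  expect_match(tab$auroc[1], "^\\d\\.\\d{2} \\(\\d\\.\\d{2}\\)$")
  for (m in c("f1", "auroc")) {
    v <- r$per_iteration$value[r$per_iteration$metric == m &
                                 r$per_iteration$pi_type == "none"]
    expect_gte(r$summary[[paste0(m, "_mean")]][1], min(v))
    expect_lte(r$summary[[paste0(m, "_mean")]][1], max(v))
  }
})
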