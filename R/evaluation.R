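#' Patient-wise train/validation/test split
#'
#' Splits instances at the patient level so that no patient appears in
#' more than one of the three sets: 20% of patients to test, 20% of the
#' remaining training patients to validation (fractions configurable).
#' The split is redrawn (deterministically) until every set contains
#' both classes, since AUROC is undefined on a single-class set.
#'
#' @param patient_id Character vector, one entry per instance.
#' @param y Labels in `{-1, +1}` per instance.
#' @param iteration_seed Integer seed for this split.
#' @param test_fraction Fraction of patients held out for testing.
#' @param validation_fraction Fraction of the training patients reserved
#'   for validation.
#' @return List of integer index vectors `train`, `validation`, `test`
#'   (a partition of `seq_along(y)`).
#' @export
patient_wise_split <- function(patient_id, y, iteration_seed,
                               test_fraction = 0.2,
                               validation_fraction = 0.2) {
  stopifnot(length(patient_id) == length(y),
            test_fraction > 0, test_fraction < 1,
            validation_fraction > 0, validation_fraction < 1)
  patients <- unique(patient_id)
  if (length(patients) < 3) {
    stop("need at least 3 distinct patients to split", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  for (attempt in 0:99) {
    set.seed(iteration_seed + attempt * 100003L)
    perm <- sample(patients)
    n_test <- max(1L, round(test_fraction * length(patients)))
    n_val <- max(1L, round(validation_fraction *
                             (length(patients) - n_test)))
    test_p <- perm[seq_len(n_test)]
    val_p <- perm[n_test + seq_len(n_val)]
    train_p <- perm[-(seq_len(n_test + n_val))]
    idx <- list(train = which(patient_id %in% train_p),
                validation = which(patient_id %in% val_p),
                test = which(patient_id %in% test_p))
    if (length(unique(y[idx$train])) == 2 &&
        length(unique(y[idx$validation])) == 2 &&
        length(unique(y[idx$test])) == 2) {
      return(idx)
    }
  }
  stop("could not produce a class-balanced patient-wise split",
       call. = FALSE)
}

#' Classification metrics of raw decision scores
#'
#' F1 score, sensitivity and specificity from thresholding the scores at
#' `threshold` (positive class = deterioration, predicted when the score
#' is strictly positive at the default threshold 0); AUROC by the
#' rank-sum (trapezoidal) method with tie averaging; AUPRC by step
#' interpolation of the precision-recall curve.
#'
#' @param scores Numeric decision scores.
#' @param labels Labels in `{-1, +1}`; both classes required.
#' @param threshold Decision threshold (default 0).
#' @return Named numeric vector `f1`, `sensitivity`, `specificity`,
#'   `auroc`, `auprc`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1)) || length(unique(labels)) < 2) {
    stop("labels must contain both classes coded -1/+1", call. = FALSE)
  }
  pred <- ifelse(scores > threshold, 1, -1)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == -1)
  fn <- sum(pred == -1 & labels == 1)
  tn <- sum(pred == -1 & labels == -1)
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  npos <- sum(labels == 1)
  nneg <- sum(labels == -1)
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  # precision-recall: walk score thresholds from high to low, collapsing
  # tied scores, and accumulate precision * delta-recall
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  l_sorted <- labels[ord]
  cum_tp <- cumsum(l_sorted == 1)
  cum_fp <- cumsum(l_sorted == -1)
  keep <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  cum_tp <- cum_tp[keep]
  cum_fp <- cum_fp[keep]
  recall <- cum_tp / npos
  precision <- cum_tp / (cum_tp + cum_fp)
  auprc <- sum(diff(c(0, recall)) * precision)
  c(f1 = f1, sensitivity = sens, specificity = spec,
    auroc = auroc, auprc = auprc)
}

# z-score columns by training statistics; constant columns pass through
standardizer <- function(X_train) {
  mu <- colMeans(X_train)
  sd_ <- apply(X_train, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  function(X) sweep(sweep(X, 2, mu), 2, sd_, "/")
}

fit_arm <- function(X, Xstar, y, C, scale, gamma, nu, privileged_scale) {
  if (is.null(Xstar)) {
    fit_svm_baseline(X, y, C = C, scale = scale)
  } else {
    fit_svmplus(X, Xstar, y,
                svmplus_hyperparams(C = C, gamma = gamma, nu = nu,
                                    regular_scale = scale,
                                    privileged_scale = privileged_scale))
  }
}

#' Grid search on validation AUROC
#'
#' Exhaustively evaluates every (box constraint, kernel scale) candidate
#' by fitting on the training rows and scoring validation AUROC. Ties
#' are broken towards the smaller box constraint, then the smaller
#' scale, making the search deterministic.
#'
#' @param X,Xstar,y Training design matrices (privileged `Xstar` may be
#'   `NULL` for the baseline SVM) and labels.
#' @param Xval,yval Validation design matrix and labels.
#' @param box_constraints,kernel_scales Positive candidate vectors.
#' @param gamma,nu,privileged_scale SVM+ parameters held fixed during
#'   the search.
#' @return List with `C`, `scale` and the attained validation `auroc`.
#' @export
grid_search <- function(X, Xstar, y, Xval, yval,
                        box_constraints, kernel_scales,
                        gamma = 1, nu = 0.5, privileged_scale = NULL) {
  stopifnot(length(box_constraints) > 0, all(box_constraints > 0),
            length(kernel_scales) > 0, all(kernel_scales > 0))
  best <- NULL
  for (C in sort(box_constraints)) {
    for (s in sort(kernel_scales)) {
      model <- fit_arm(X, Xstar, y, C, s, gamma, nu, privileged_scale)
      auroc <- compute_metrics(decision_scores(model, Xval), yval)["auroc"]
      if (is.null(best) || auroc > best$auroc + 1e-12) {
        best <- list(C = C, scale = s, auroc = as.numeric(auroc))
      }
    }
  }
  best
}

#' Experiment configuration for the repeated holdout protocol
#'
#' @param regular Regular-space design: `"ecg"` (60 taut-string
#'   features), `"ehr"` (115 lookback features) or `"ecg_ehr"` (both).
#' @param pi_types Privileged-information arms to run; `"none"` is the
#'   baseline SVM, the others are SVM+ with taut-string ECG, statistical
#'   ECG, or t6 EHR privileged features.
#' @param n_iterations Number of repeated patient-wise splits.
#' @param box_constraints Candidate box constraints for the grid search.
#' @param scale_factors Candidate kernel scales, as multiples of
#'   `sqrt(d)` of the regular design.
#' @param gamma,nu SVM+ parameters (fixed; not part of the grid).
#' @param test_fraction,validation_fraction Split fractions.
#' @param seed Master seed; iteration seeds derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(regular = c("ecg", "ehr", "ecg_ehr"),
                              pi_types = c("none", "ts_ecg", "sf_ecg",
                                           "ehr"),
                              n_iterations = 100,
                              box_constraints = c(0.1, 1, 10, 100),
                              scale_factors = c(0.5, 1, 2, 4),
                              gamma = 1, nu = 0.5,
                              test_fraction = 0.2,
                              validation_fraction = 0.2,
                              seed = 1) {
  regular <- match.arg(regular)
  pi_types <- match.arg(pi_types, several.ok = TRUE)
  structure(list(regular = regular, pi_types = pi_types,
                 n_iterations = as.integer(n_iterations),
                 box_constraints = box_constraints,
                 scale_factors = scale_factors,
                 gamma = gamma, nu = nu,
                 test_fraction = test_fraction,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the repeated patient-wise holdout experiment
#'
#' For each iteration: draw a patient-disjoint train/validation/test
#' split, standardise features by training statistics, grid-search the
#' box constraint and kernel scale on validation AUROC, refit on
#' train + validation with the selected values, and compute test
#' metrics. The baseline SVM never sees privileged features; SVM+ uses
#' them at training time only. A failing iteration aborts the run.
#'
#' @param data A `lupi_dataset`.
#' @param config An [experiment_config].
#' @param progress Emit one line per iteration to stderr.
#' @return An object of class `metrics_report`: `per_iteration` (long
#'   data frame: iteration, pi_type, metric, value), `summary` (one row
#'   per PI type with mean and sd per metric), `config`.
#' @export
run_experiment <- function(data, config = experiment_config(),
                           progress = FALSE) {
  stopifnot(inherits(data, "lupi_dataset"),
            inherits(config, "experiment_config"))
  X_all <- regular_matrix(data, config$regular)
  d <- ncol(X_all)
  rows <- list()
  for (iter in seq_len(config$n_iterations)) {
    iter_seed <- config$seed * 10000L + iter
    idx <- patient_wise_split(data$patient_id, data$y, iter_seed,
                              config$test_fraction,
                              config$validation_fraction)
    for (pi_type in config$pi_types) {
      Xs_all <- privileged_matrix(data, pi_type)
      zx <- standardizer(X_all[idx$train, , drop = FALSE])
      Xtr <- zx(X_all[idx$train, , drop = FALSE])
      Xva <- zx(X_all[idx$validation, , drop = FALSE])
      Xstar_tr <- NULL
      pscale <- NULL
      if (!is.null(Xs_all)) {
        zs <- standardizer(Xs_all[idx$train, , drop = FALSE])
        Xstar_tr <- zs(Xs_all[idx$train, , drop = FALSE])
        pscale <- sqrt(ncol(Xstar_tr))
      }
      best <- grid_search(Xtr, Xstar_tr, data$y[idx$train], Xva,
                          data$y[idx$validation],
                          config$box_constraints,
                          config$scale_factors * sqrt(d),
                          gamma = config$gamma, nu = config$nu,
                          privileged_scale = pscale)
      # refit on train + validation with the selected hyperparameters
      fit_idx <- c(idx$train, idx$validation)
      zx2 <- standardizer(X_all[fit_idx, , drop = FALSE])
      Xfit <- zx2(X_all[fit_idx, , drop = FALSE])
      Xtest <- zx2(X_all[idx$test, , drop = FALSE])
      Xstar_fit <- NULL
      if (!is.null(Xs_all)) {
        zs2 <- standardizer(Xs_all[fit_idx, , drop = FALSE])
        Xstar_fit <- zs2(Xs_all[fit_idx, , drop = FALSE])
      }
      model <- fit_arm(Xfit, Xstar_fit, data$y[fit_idx],
                       best$C, best$scale, config$gamma, config$nu,
                       pscale)
      m <- compute_metrics(decision_scores(model, Xtest),
                           data$y[idx$test])
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = iter, pi_type = pi_type,
        metric = names(m), value = as.numeric(m),
        C = best$C, scale = best$scale,
        stringsAsFactors = FALSE)
    }
    if (progress) {
      message("iteration ", iter, "/", config$n_iterations, " done")
    }
  }
  per_iteration <- do.call(rbind, rows)
  summary_df <- metrics_summary(per_iteration, config$pi_types)
  structure(list(per_iteration = per_iteration, summary = summary_df,
                 config = config),
            class = "metrics_report")
}

metrics_summary <- function(per_iteration, pi_order) {
  metrics <- c("f1", "sensitivity", "specificity", "auroc", "auprc")
  out <- lapply(pi_order, function(pt) {
    sub <- per_iteration[per_iteration$pi_type == pt, ]
    row <- data.frame(pi_type = pt, stringsAsFactors = FALSE)
    for (m in metrics) {
      v <- sub$value[sub$metric == m]
      row[[paste0(m, "_mean")]] <- mean(v)
      row[[paste0(m, "_sd")]] <- stats::sd(v)
    }
    row
  })
  do.call(rbind, out)
}

#' Format a metrics report like the result tables of the study design
#'
#' One row per PI type, each cell `mean (sd)` over iterations.
#'
#' @param report A `metrics_report`.
#' @param digits Rounding digits (default 2).
#' @return A character data frame.
#' @export
format_report_table <- function(report, digits = 2) {
  s <- report$summary
  cell <- function(m) {
    sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
            s[[paste0(m, "_mean")]], s[[paste0(m, "_sd")]])
  }
  data.frame(pi_type = s$pi_type,
             f1 = cell("f1"), sensitivity = cell("sensitivity"),
             specificity = cell("specificity"), auroc = cell("auroc"),
             auprc = cell("auprc"), stringsAsFactors = FALSE)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Repeated holdout report | regular space:", x$config$regular,
      "|", x$config$n_iterations, "iterations\n")
  print(format_report_table(x), row.names = FALSE)
  invisible(x)
}

#' Write a metrics report to CSV files
#'
#' Writes `metrics_long.csv` (iteration, pi_type, metric, value, chosen
#' hyperparameters) and `summary_<regular>.csv` (the formatted table).
#' Output is byte-reproducible for a fixed master seed.
#'
#' @param report A `metrics_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long_path <- file.path(dir, "metrics_long.csv")
  utils::write.csv(report$per_iteration, long_path, row.names = FALSE)
  tab_path <- file.path(dir,
                        paste0("summary_", report$config$regular, ".csv"))
  utils::write.csv(format_report_table(report), tab_path,
                   row.names = FALSE)
  invisible(dir)
}
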