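#' Discrete signal container
#'
#' Bundles a sampled real-valued signal with its sampling rate. Lead-II ECG
#' in this package is sampled at 240 Hz, but any finite signal of length
#' two or more is accepted.
#'
#' @param samples Numeric vector of finite samples, length >= 2.
#' @param sampling_rate Samples per second (default 240).
#' @return An object of class `discrete_signal`.
#' @export
discrete_signal <- function(samples, sampling_rate = 240) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) {
    stop("a discrete signal needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar", call. = FALSE)
  }
  structure(list(samples = samples, sampling_rate = sampling_rate),
            class = "discrete_signal")
}

as_discrete_signal <- function(x, sampling_rate = 240) {
  if (inherits(x, "discrete_signal")) return(x)
  discrete_signal(x, sampling_rate)
}

#' Taut-string estimate of a signal inside an epsilon-tube
#'
#' Computes the unique piecewise-linear estimate `g` of a signal `f` such
#' that `max |f - g| <= epsilon` and the sum of squared first differences
#' of `g` is minimal over the tube. Geometrically `g` is the shortest path
#' ("taut string") through the corridor of vertical gates
#' `[f_i - epsilon, f_i + epsilon]`; subtracting it from `f` yields a
#' noise estimate. Both endpoints are free inside their gates. When the
#' whole tube admits a horizontal line the forced constant estimate is
#' returned, with the tie broken towards the middle of the feasible band.
#'
#' @param f A [discrete_signal] or plain numeric vector (length >= 2).
#' @param epsilon Positive tube half-width, in signal units.
#' @return An object of class `taut_string_estimate` with components
#'   `estimate` (the taut string `g`), `noise` (`f - g`), `knots`
#'   (1-based indices of slope-change points, including both endpoints),
#'   `epsilon`, and `signal` (the input samples).
#' @examples
#' est <- taut_string_estimate(c(0, 2, 0, 2, 0), epsilon = 0.5)
#' est$estimate
#' @export
taut_string_estimate <- function(f, epsilon) {
  sig <- as_discrete_signal(f)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("epsilon must be a positive finite scalar", call. = FALSE)
  }
  res <- .taut_string_tube(sig$samples, epsilon)
  structure(list(
    estimate = res$estimate,
    noise = sig$samples - res$estimate,
    knots = res$knots,
    epsilon = epsilon,
    signal = sig$samples
  ), class = "taut_string_estimate")
}

#' @export
print.taut_string_estimate <- function(x, ...) {
  cat("Taut-string estimate: n =", length(x$estimate),
      " epsilon =", format(x$epsilon),
      " knots =", length(x$knots), "\n")
  invisible(x)
}

# slope-change tolerance used to merge numerically collinear pieces
TS_SLOPE_TOL <- 1e-9

# maximal linear pieces of the estimate: consecutive knot segments whose
# slopes differ by more than the tolerance
ts_segment_slopes <- function(est) {
  g <- est$estimate
  kx <- est$knots
  if (length(kx) < 2) return(numeric(0))
  slopes <- (g[kx[-1]] - g[kx[-length(kx)]]) / diff(kx)
  keep <- c(TRUE, abs(diff(slopes)) > TS_SLOPE_TOL)
  slopes[keep]
}

#' Six taut-string features of an estimate
#'
#' Summarises a [taut_string_estimate] by the number of maximal line
#' segments, the number of inflection segments (interior slope-change
#' points where the slope sign flips from rising to falling or vice
#' versa; near-zero slopes carry no sign), the total variation
#' (sum of absolute first differences) of the noise and of the denoised
#' signal, and the power (mean squared amplitude) of the denoised signal
#' and of the noise.
#'
#' @param est A [taut_string_estimate].
#' @return A named numeric vector of length 6 in the order
#'   `n_line_segments`, `n_inflection_segments`, `tv_noise`,
#'   `tv_denoised`, `power_denoised`, `power_noise`.
#' @export
ts_features <- function(est) {
  if (!inherits(est, "taut_string_estimate")) {
    stop("est must be a taut_string_estimate", call. = FALSE)
  }
  g <- est$estimate
  r <- est$noise
  slopes <- ts_segment_slopes(est)
  n_seg <- max(1L, length(slopes))
  sgn <- sign(slopes)
  sgn[abs(slopes) <= TS_SLOPE_TOL] <- 0
  n_infl <- if (length(sgn) >= 2) sum(sgn[-1] * sgn[-length(sgn)] < 0) else 0L
  c(
    n_line_segments = n_seg,
    n_inflection_segments = as.integer(n_infl),
    tv_noise = sum(abs(diff(r))),
    tv_denoised = sum(abs(diff(g))),
    power_denoised = mean(g^2),
    power_noise = mean(r^2)
  )
}

#' Default taut-string epsilon schedule
#'
#' The five tube half-widths used to build the ECG feature tensor.
#'
#' @return Numeric vector of length 5.
#' @export
default_epsilons <- function() {
  c(0.0100, 0.1575, 0.3050, 0.4525, 0.6000)
}

#' Bank of taut-string features over an epsilon schedule
#'
#' Runs [taut_string_estimate] and [ts_features] once per tube half-width
#' and stacks the results.
#'
#' @param f A [discrete_signal] or numeric vector.
#' @param epsilons Strictly positive numeric vector of tube half-widths;
#'   defaults to [default_epsilons()].
#' @return A numeric matrix with one row per epsilon (in input order) and
#'   the six feature columns of [ts_features()]; row names carry the
#'   epsilon values.
#' @export
ts_feature_bank <- function(f, epsilons = default_epsilons()) {
  if (length(epsilons) < 1 || !all(is.finite(epsilons)) ||
      any(epsilons <= 0)) {
    stop("epsilons must be a non-empty vector of positive reals",
         call. = FALSE)
  }
  sig <- as_discrete_signal(f)
  bank <- t(vapply(
    epsilons,
    function(eps) ts_features(taut_string_estimate(sig, eps)),
    numeric(6)
  ))
  rownames(bank) <- format(epsilons)
  bank
}

#' Read a sampled signal from CSV
#'
#' Accepts either a single-column file of samples or a two-column
#' (time, value) file; the sampling rate is taken from the time column
#' when present, otherwise from `sampling_rate`.
#'
#' @param path CSV file with a header row.
#' @param sampling_rate Fallback sampling rate (default 240).
#' @return A [discrete_signal].
#' @export
read_signal_csv <- function(path, sampling_rate = 240) {
  df <- utils::read.csv(path)
  if (ncol(df) >= 2) {
    dt <- diff(df[[1]])
    if (length(dt) && all(dt > 0)) sampling_rate <- 1 / stats::median(dt)
    discrete_signal(df[[2]], sampling_rate)
  } else {
    discrete_signal(df[[1]], sampling_rate)
  }
}

#' Write a taut-string feature bank as CSV
#'
#' @param bank Matrix returned by [ts_feature_bank()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ts_features_csv <- function(bank, path) {
  df <- data.frame(epsilon = rownames(bank), bank, row.names = NULL,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
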