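#' ECG segment container
#'
#' A 10-minute strip of single-lead ECG anchored at one of the two
#' timeline points of the prediction task: `t0` (prediction time, regular
#' space) or `t6` (outcome time six hours later, privileged space).
#'
#' @param samples Numeric vector of ECG samples (millivolts).
#' @param anchor `"t0"` or `"t6"`; the point the segment ends at.
#' @param sampling_rate Samples per second (default 240).
#' @param duration Expected duration in seconds (default 600). The sample
#'   count must match `duration * sampling_rate` within one sample.
#' @return An object of class `ecg_segment`.
#' @export
ecg_segment <- function(samples, anchor = c("t0", "t6"),
                        sampling_rate = 240, duration = 600) {
  anchor <- match.arg(anchor)
  samples <- as.numeric(samples)
  if (abs(length(samples) - duration * sampling_rate) > 1) {
    stop(sprintf(
      "segment length %d does not match duration %g s at %g Hz",
      length(samples), duration, sampling_rate), call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all ECG samples must be finite", call. = FALSE)
  }
  structure(list(samples = samples, anchor = anchor,
                 sampling_rate = sampling_rate, duration = duration),
            class = "ecg_segment")
}

#' Band-pass filter an ECG segment
#'
#' Applies a second-order Butterworth band-pass filter with cutoff
#' frequencies 0.5 and 40 Hz, forward and backward (zero phase), so that
#' QRS morphology is not phase-distorted. Output length equals input
#' length.
#'
#' @param seg An [ecg_segment].
#' @param low,high Cutoff frequencies in Hz.
#' @param order Butterworth prototype order (default 2).
#' @return The filtered [ecg_segment].
#' @export
bandpass_filter <- function(seg, low = 0.5, high = 40, order = 2) {
  stopifnot(inherits(seg, "ecg_segment"))
  if (seg$sampling_rate <= 2 * high) {
    stop("sampling rate must exceed twice the upper cutoff", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (seg$sampling_rate / 2),
                       type = "pass")
  out <- signal::filtfilt(bf, seg$samples)
  seg$samples <- as.numeric(out)
  seg$filtered <- TRUE
  seg
}

#' Split a 10-minute segment into two 5-minute windows
#'
#' @param seg An [ecg_segment] of 600 s duration.
#' @return A list of two numeric vectors: the earlier and the later
#'   5-minute window, contiguous and non-overlapping; their concatenation
#'   reproduces the input.
#' @export
segment_windows <- function(seg) {
  stopifnot(inherits(seg, "ecg_segment"))
  n <- length(seg$samples)
  expected <- seg$duration * seg$sampling_rate
  if (seg$duration != 600 || abs(n - expected) > 1) {
    stop("segment_windows expects a full 10-minute segment", call. = FALSE)
  }
  half <- n %/% 2
  list(seg$samples[seq_len(half)], seg$samples[(half + 1):n])
}

#' Regular-space ECG feature tensor (2 windows x 5 epsilons x 6 features)
#'
#' Splits a filtered `t0` segment into its two 5-minute windows and runs
#' the taut-string feature bank on each, giving the 2 x 5 x 6 tensor with
#' modes (window, epsilon, feature) and its deterministic flattening
#' (window-major, then epsilon, then feature).
#'
#' @param seg A filtered [ecg_segment] with anchor `t0`.
#' @param epsilons Tube half-width schedule; defaults to
#'   [default_epsilons()].
#' @return A list with `tensor` (array `2 x 5 x 6`) and `vector`
#'   (named numeric of length 60).
#' @export
regular_ecg_features <- function(seg, epsilons = default_epsilons()) {
  stopifnot(inherits(seg, "ecg_segment"))
  if (seg$anchor != "t0") {
    stop("regular-space features are computed on the t0 segment",
         call. = FALSE)
  }
  wins <- segment_windows(seg)
  banks <- lapply(wins, ts_feature_bank, epsilons = epsilons)
  tensor <- array(NA_real_, dim = c(2, length(epsilons), 6),
                  dimnames = list(window = c("w1", "w2"),
                                  epsilon = format(epsilons),
                                  feature = colnames(banks[[1]])))
  tensor[1, , ] <- banks[[1]]
  tensor[2, , ] <- banks[[2]]
  # flattening: window-major, then epsilon, then feature (feature fastest)
  vec <- c(as.numeric(t(banks[[1]])), as.numeric(t(banks[[2]])))
  grid <- expand.grid(feature = colnames(banks[[1]]),
                      epsilon = format(epsilons), window = c("w1", "w2"),
                      stringsAsFactors = FALSE)
  names(vec) <- paste(grid$window, grid$epsilon, grid$feature, sep = "_")
  list(tensor = tensor, vector = vec)
}

#' Statistical summary features of a signal window
#'
#' Computes the seven statistical features used in the privileged space:
#' mean, median, variance (1/n normalisation), Pearson kurtosis
#' (standardised fourth moment; 3 for a Gaussian), skewness (standardised
#' third moment), Shannon entropy of a 64-bin equal-width histogram (in
#' nats, empty bins contribute zero), and the mean absolute value of the
#' unnormalised discrete Fourier transform. A zero-variance window has
#' kurtosis, skewness and entropy defined as 0.
#'
#' @param window Numeric vector, length >= 2.
#' @param bins Histogram bins for the entropy estimate (default 64).
#' @return Named numeric vector of length 7.
#' @export
statistical_features <- function(window, bins = 64) {
  x <- as.numeric(window)
  if (length(x) < 2 || !all(is.finite(x))) {
    stop("window must be a finite numeric vector of length >= 2",
         call. = FALSE)
  }
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v > 0) {
    sk <- mean((x - m)^3) / v^1.5
    ku <- mean((x - m)^4) / v^2
    breaks <- seq(min(x), max(x), length.out = bins + 1)
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE), nbins = bins)
    p <- counts[counts > 0] / n
    ent <- -sum(p * log(p))
  } else {
    sk <- 0
    ku <- 0
    ent <- 0
  }
  c(mean = m, median = stats::median(x), variance = v, kurtosis = ku,
    skewness = sk, shannon_entropy = ent,
    mean_abs_fft = mean(Mod(stats::fft(x))))
}

#' Privileged-space ECG features of the t6 segment
#'
#' Taut-string feature bank over the unwindowed 10-minute privileged
#' segment (5 epsilons x 6 features) plus the seven statistical summary
#' features of the same segment.
#'
#' @param seg A filtered [ecg_segment] with anchor `t6`.
#' @param epsilons Tube half-width schedule.
#' @return A list with `ts` (5 x 6 matrix), `ts_vector` (length 30,
#'   epsilon-major), and `sf` (length-7 named vector).
#' @export
privileged_ecg_features <- function(seg, epsilons = default_epsilons()) {
  stopifnot(inherits(seg, "ecg_segment"))
  if (seg$anchor != "t6") {
    stop("privileged-space features are computed on the t6 segment",
         call. = FALSE)
  }
  bank <- ts_feature_bank(seg$samples, epsilons)
  vec <- as.numeric(t(bank))
  names(vec) <- as.vector(outer(colnames(bank), format(epsilons),
                                function(f, e) paste(e, f, sep = "_")))
  list(ts = bank, ts_vector = vec, sf = statistical_features(seg$samples))
}

#' Fraction of noisy 10-second subwindows in a segment
#'
#' Screens an ECG segment with a configurable quality rule: a subwindow
#' is flagged as noise when it is a flat line, when it clips against an
#' amplitude rail, or when its amplitude leaves the physiologic range.
#' Instances whose segments are 50% or more noise are rejected upstream
#' (see [build_instance()]).
#'
#' @param seg An [ecg_segment].
#' @param subwindow_s Subwindow length in seconds (default 10).
#' @param flat_tol Peak-to-peak amplitude (mV) below which a subwindow
#'   counts as flat.
#' @param rail_frac Fraction of samples sitting exactly at the subwindow
#'   extreme beyond which clipping is assumed.
#' @param amp_limit Absolute amplitude limit in mV.
#' @return The fraction of flagged subwindows, in `[0, 1]`.
#' @export
noise_fraction <- function(seg, subwindow_s = 10, flat_tol = 1e-4,
                           rail_frac = 0.05, amp_limit = 6) {
  stopifnot(inherits(seg, "ecg_segment"))
  x <- seg$samples
  wlen <- max(2L, as.integer(round(subwindow_s * seg$sampling_rate)))
  nwin <- max(1L, length(x) %/% wlen)
  flagged <- vapply(seq_len(nwin), function(w) {
    sub <- x[((w - 1) * wlen + 1):min(w * wlen, length(x))]
    rng <- range(sub)
    flat <- (rng[2] - rng[1]) < flat_tol
    clipped <- (rng[2] - rng[1]) >= flat_tol &&
      (mean(sub >= rng[2] - 1e-12) > rail_frac ||
         mean(sub <= rng[1] + 1e-12) > rail_frac)
    out_of_range <- max(abs(rng)) > amp_limit
    flat || clipped || out_of_range
  }, logical(1))
  mean(flagged)
}
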