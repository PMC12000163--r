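#' Detector trace container
#'
#' A sampled photodetector signal from a particle counter: each particle
#' transit produces a short pulse over baseline noise.
#'
#' @param samples Numeric vector of signal samples (arbitrary units, finite).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @return An object of class `counter_trace` with fields `samples`,
#'   `sampling_rate`, `duration`.
#' @export
counter_trace <- function(samples, sampling_rate) {
  stop_if_not_positive(sampling_rate = sampling_rate)
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite numeric values", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 duration = length(samples) / sampling_rate),
            class = "counter_trace")
}

#' @export
print.counter_trace <- function(x, ...) {
  cat(sprintf("<counter_trace> %d samples @ %g Hz (%.3g s)\n",
              length(x$samples), x$sampling_rate, x$duration))
  invisible(x)
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' (`signal::filtfilt`), giving a flat passband and zero phase shift so
#' peak times are not displaced. The 100 Hz default removes high-frequency
#' detector noise while passing millisecond-scale transit pulses.
#'
#' @param trace A [counter_trace()].
#' @param cutoff Cut-off frequency in Hz, must be below the Nyquist
#'   frequency (default 100 Hz).
#' @param order Filter order (default 4).
#' @return A filtered [counter_trace()].
#' @export
lowpass <- function(trace, cutoff = 100, order = 4) {
  stopifnot(inherits(trace, "counter_trace"))
  stop_if_not_positive(cutoff = cutoff)
  nyquist <- trace$sampling_rate / 2
  if (cutoff >= nyquist)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, nyquist), call. = FALSE)
  bf <- signal::butter(order, cutoff / nyquist, type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # zero-initial-condition forward/backward passes
  x <- trace$samples
  n <- length(x)
  pad <- min(3L * ceiling(trace$sampling_rate / cutoff), n - 1L)
  filtered <- if (pad >= 1) {
    xp <- c(2 * x[1] - x[(pad + 1):2],
            x,
            2 * x[n] - x[(n - 1):(n - pad)])
    signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
  } else {
    signal::filtfilt(bf, x)
  }
  counter_trace(filtered, trace$sampling_rate)
}

#' Detect transit peaks in a trace
#'
#' Local maxima exceeding `baseline + threshold_sigmas * sigma`, where the
#' baseline is the sample median and `sigma` the median absolute deviation
#' (robust to the peaks themselves). Maxima closer than `min_separation`
#' are merged, keeping the highest (refractory rule against double-counting
#' a single transit).
#'
#' @param trace A [counter_trace()], normally low-pass filtered first.
#' @param threshold_sigmas Detection threshold in robust noise SDs
#'   (default 5).
#' @param min_separation Minimum event spacing in seconds (default 1 ms).
#' @return Numeric vector of event times in seconds (sample-centre
#'   convention).
#' @export
detect_peaks <- function(trace, threshold_sigmas = 5, min_separation = 1e-3) {
  stopifnot(inherits(trace, "counter_trace"))
  x <- trace$samples
  n <- length(x)
  if (n < 3) return(numeric(0))
  baseline <- stats::median(x)
  sigma <- stats::mad(x)
  if (sigma == 0) sigma <- stats::sd(x)
  thr <- baseline + threshold_sigmas * sigma
  core <- x[2:(n - 1)]
  is_max <- core > x[1:(n - 2)] & core >= x[3:n] & core > thr
  idx <- which(is_max) + 1L
  if (!length(idx)) return(numeric(0))
  min_gap <- min_separation * trace$sampling_rate
  # greedy suppression: accept peaks by descending height
  ord <- idx[order(x[idx], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_gap))
      accepted <- c(accepted, i)
  }
  sort(accepted - 0.5) / trace$sampling_rate
}

#' Bin event times into fixed-width counts
#'
#' Counts events per consecutive right-open bin `[k w, (k+1) w)`. Events on
#' a bin edge belong to the bin starting there.
#'
#' @param events Event times in seconds (>= 0).
#' @param bin_width Bin width in seconds (default 1 s).
#' @param t_max Optional end time; bins extend to cover it (zero-count
#'   trailing bins included).
#' @return Integer vector of counts per bin.
#' @export
bin_counts <- function(events, bin_width = 1, t_max = NULL) {
  stop_if_not_positive(bin_width = bin_width)
  if (length(events) && (any(!is.finite(events)) || any(events < 0)))
    stop("`events` must be finite and >= 0", call. = FALSE)
  end <- max(c(events, t_max, 0))
  n_bins <- max(1L, ceiling(end / bin_width - 1e-9))
  if (!length(events)) return(integer(n_bins))
  bins <- floor(events / bin_width) + 1L
  bins <- pmin(bins, n_bins)
  tabulate(bins, nbins = n_bins)
}

#' Normalize and smooth a throughput count series
#'
#' Converts per-bin event counts into an effective concentration ratio
#' estimate: per-bin rates are (optionally) corrected for counting dead
#' time, divided by the mean raw rate over the initial window (the measured
#' "initial value"), and smoothed with a centred moving average (shrinking
#' symmetrically at the edges).
#'
#' The dead-time correction is the standard nonparalyzable-counter form
#' `lambda = m / (1 - m tau)` for observed rate `m`. Event trains whose
#' pulses pass a low-pass filter acquire a resolution limit of a few
#' milliseconds: transits closer than that merge into one detected peak, so
#' the observed rate under-counts proportionally to the rate itself, which
#' would otherwise bias the normalized curve (and the half-life) upward.
#'
#' @param counts Event counts per bin (from [bin_counts()]).
#' @param bin_width Bin width in seconds (default 1 s).
#' @param initial_window Length of the normalization window in seconds
#'   (default 20 s).
#' @param smooth_window Moving-average window in bins (default 21).
#' @param dead_time Counting dead time in seconds (default 0 = no
#'   correction). [analyze_trace()] can estimate it from the event train.
#' @return A [concentration_curve()] with source `"measured"`; times are
#'   bin centres.
#' @export
normalize_and_smooth <- function(counts, bin_width = 1, initial_window = 20,
                                 smooth_window = 21, dead_time = 0) {
  if (!length(counts))
    stop("`counts` must be non-empty", call. = FALSE)
  stop_if_not_positive(bin_width = bin_width, initial_window = initial_window)
  rate <- counts / bin_width
  if (dead_time > 0)
    rate <- rate / pmax(1 - rate * dead_time, 0.2)
  n0 <- max(1L, min(length(rate), ceiling(initial_window / bin_width)))
  base <- mean(rate[seq_len(n0)])
  if (!is.finite(base) || base <= 0)
    stop("zero initial rate; cannot normalize", call. = FALSE)
  sm <- moving_average(rate, smooth_window)
  centers <- (seq_along(counts) - 0.5) * bin_width
  concentration_curve(centers, sm / base, source = "measured",
                      meta = list(bin_width = bin_width,
                                  initial_window = initial_window,
                                  smooth_window = smooth_window,
                                  dead_time = dead_time))
}

#' Full trace-to-half-life pipeline
#'
#' Chains [lowpass()], [detect_peaks()], [bin_counts()],
#' [normalize_and_smooth()] and [half_life_from_curve()]: the complete
#' particle-counter data-analysis path from a raw detector trace to the
#' measured concentration half-life. Deterministic given the trace.
#'
#' @param trace A raw [counter_trace()].
#' @param cutoff Low-pass cut-off in Hz.
#' @param threshold_sigmas,min_separation Peak detection parameters.
#' @param bin_width,initial_window,smooth_window Throughput-curve
#'   parameters.
#' @param dead_time Counting dead time in seconds for the pile-up
#'   correction: a number, `0` (off), or `"auto"` (default) to estimate it
#'   from the inter-event gap distribution of the early trace (see
#'   [estimate_dead_time()]).
#' @return List with `t_half` (s, `NA` if no crossing), the `curve`, the
#'   `events`, per-bin `counts` and the `dead_time` used.
#' @export
analyze_trace <- function(trace, cutoff = 100, threshold_sigmas = 5,
                          min_separation = 1e-3, bin_width = 1,
                          initial_window = 20, smooth_window = 21,
                          dead_time = "auto") {
  filtered <- lowpass(trace, cutoff)
  events <- detect_peaks(filtered, threshold_sigmas, min_separation)
  if (identical(dead_time, "auto"))
    dead_time <- estimate_dead_time(events)
  counts <- bin_counts(events, bin_width, t_max = trace$duration)
  curve <- normalize_and_smooth(counts, bin_width, initial_window,
                                smooth_window, dead_time = dead_time)
  list(t_half = half_life_from_curve(curve), curve = curve,
       events = events, counts = counts, dead_time = dead_time)
}

#' Estimate the effective counting dead time of an event train
#'
#' For a Poisson train observed through a counter with (soft) dead time
#' `tau`, the inter-event gaps are approximately `tau` plus an exponential
#' with the true rate `lambda`: their mean is `tau + 1/lambda`, while the
#' excess of gaps above any threshold is still exponential with mean
#' `1/lambda` (memorylessness). The estimator therefore takes
#' `1/lambda_hat` from the mean excess over the median gap and returns
#' `tau_hat = mean(gap) - 1/lambda_hat`, clamped at 0. Only the earliest
#' `n_gaps` gaps are used so the rate is approximately constant over the
#' fitting window.
#'
#' Because the event rate drifts over a sedimentation trace while the dead
#' time is a constant of the detection chain, the gaps are split into
#' blocks of `block` consecutive gaps (locally constant rate), the shift is
#' estimated per block, and the median across blocks is returned.
#'
#' @param events Sorted event times in seconds.
#' @param block Gaps per estimation block (default 400).
#' @return Estimated dead time in seconds (0 when fewer than 100 events).
#' @export
estimate_dead_time <- function(events, block = 400) {
  if (length(events) < 100) return(0)
  g <- diff(events)
  blocks <- split(g, (seq_along(g) - 1) %/% block)
  blocks <- blocks[vapply(blocks, length, integer(1)) >= 50]
  est <- vapply(blocks, function(gb) {
    med <- stats::median(gb)
    tail_mean <- mean(gb[gb > med]) - med
    mean(gb) - tail_mean
  }, numeric(1))
  max(stats::median(est), 0)
}
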