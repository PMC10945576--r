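#' Specification of the spontaneous (unstimulated) dynamics
#'
#' Describes the resting behaviour of every channel: instantaneous angular
#' frequency and instantaneous amplitude each follow a stationary AR(1)
#' process that is squashed into a closed range, the phase is the running sum
#' of the frequency series, and the observed signal is
#' `a * sin(phi) + noise`. Channels and trials are sampled independently, so
#' resting channel time series are asymptotically uncorrelated.
#'
#' @param ar_freq,ar_amp AR(1) coefficients of the frequency and amplitude
#'   processes; must lie strictly inside (-1, 1) for stationarity.
#' @param freq_range Closed interval (length-2 numeric, radians/sample) that
#'   the instantaneous angular frequency is confined to. Must lie within
#'   (0, pi]. The ordinary frequency in Hz is `fs * f / (2 * pi)`.
#' @param amp_range Closed interval (signal units) for the instantaneous
#'   amplitude; the lower bound must be non-negative (amplitude is a
#'   magnitude).
#' @param innov_sd_freq,innov_sd_amp Innovation standard deviations of the
#'   two AR(1) processes. Their scale is absorbed by the range squash
#'   ([constrain_to_range()]), so the default of 1 is a pure convention.
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise.
#' @param fs Sampling frequency in Hz.
#' @param n_channels,n_times,n_trials Number of channels, time points per
#'   trial, and trials.
#'
#' @return An object of class `spontaneous_spec` (a validated list).
#' @seealso [sample_resting()], [sim_config()]
#' @export
#' @examples
#' spec <- spontaneous_spec(n_trials = 4, n_times = 100, n_channels = 2)
#' rest <- sample_resting(spec, seed = 1)
#' dim(rest$signal)
spontaneous_spec <- function(ar_freq = 0.99, ar_amp = 0.99,
                             freq_range = c(0.01, 0.25 * pi),
                             amp_range = c(0.5, 1.5),
                             innov_sd_freq = 1, innov_sd_amp = 1,
                             noise_sd = 0.5, fs = 250,
                             n_channels = 32, n_times = 250, n_trials = 250) {
  spec <- list(
    ar_freq = ar_freq, ar_amp = ar_amp,
    freq_range = as.numeric(freq_range), amp_range = as.numeric(amp_range),
    innov_sd_freq = innov_sd_freq, innov_sd_amp = innov_sd_amp,
    noise_sd = noise_sd, fs = fs,
    n_channels = as.integer(n_channels), n_times = as.integer(n_times),
    n_trials = as.integer(n_trials)
  )
  problems <- character()
  if (abs(ar_freq) >= 1) problems <- c(problems, "`ar_freq` must satisfy |ar_freq| < 1")
  if (abs(ar_amp) >= 1) problems <- c(problems, "`ar_amp` must satisfy |ar_amp| < 1")
  if (length(spec$freq_range) != 2 || spec$freq_range[1] >= spec$freq_range[2] ||
      spec$freq_range[1] <= 0 || spec$freq_range[2] > pi) {
    problems <- c(problems, "`freq_range` must be an increasing interval within (0, pi]")
  }
  if (length(spec$amp_range) != 2 || spec$amp_range[1] > spec$amp_range[2] ||
      spec$amp_range[1] < 0) {
    problems <- c(problems, "`amp_range` must be non-decreasing with lower bound >= 0")
  }
  if (innov_sd_freq < 0 || innov_sd_amp < 0 || noise_sd < 0) {
    problems <- c(problems, "innovation and noise standard deviations must be >= 0")
  }
  if (fs <= 0) problems <- c(problems, "`fs` must be positive")
  if (spec$n_channels < 1 || spec$n_times < 1 || spec$n_trials < 1) {
    problems <- c(problems, "`n_channels`, `n_times`, `n_trials` must be >= 1")
  }
  if (length(problems)) {
    stop("invalid spontaneous_spec:\n", paste0("- ", problems, collapse = "\n"),
         call. = FALSE)
  }
  structure(spec, class = "spontaneous_spec")
}

#' @export
print.spontaneous_spec <- function(x, ...) {
  cat("<spontaneous_spec>\n")
  cat(sprintf("  trials x times x channels: %d x %d x %d (fs = %g Hz)\n",
              x$n_trials, x$n_times, x$n_channels, x$fs))
  cat(sprintf("  freq AR(1) b = %.3g in [%.4g, %.4g] rad/sample (%.2g-%.2g Hz)\n",
              x$ar_freq, x$freq_range[1], x$freq_range[2],
              x$fs * x$freq_range[1] / (2 * pi), x$fs * x$freq_range[2] / (2 * pi)))
  cat(sprintf("  amp  AR(1) b = %.3g in [%.3g, %.3g]; noise sd = %.3g\n",
              x$ar_amp, x$amp_range[1], x$amp_range[2], x$noise_sd))
  invisible(x)
}

#' Sample a stationary AR(1) process
#'
#' `x[1] = e[1]`, `x[t] = b * x[t-1] + e[t]` with Gaussian innovations
#' `e[t] ~ N(0, sigma^2)`. Several independent series can be drawn at once;
#' the recursion is vectorised across series.
#'
#' @param b AR(1) coefficient, `|b| < 1`.
#' @param sigma Innovation standard deviation (>= 0).
#' @param n Series length (>= 1).
#' @param n_series Number of independent series.
#' @return A numeric vector of length `n` if `n_series == 1`, otherwise an
#'   `n x n_series` matrix.
#' @export
#' @examples
#' set.seed(1)
#' x <- sample_ar1(0.9, 1, 1000)
#' stats::cor(x[-1], x[-length(x)])  # close to 0.9
sample_ar1 <- function(b, sigma, n, n_series = 1) {
  if (abs(b) >= 1) {
    stop("non-stationary AR coefficient: |b| must be < 1, got ", b, call. = FALSE)
  }
  stopifnot(sigma >= 0, n >= 1, n_series >= 1)
  e <- matrix(stats::rnorm(n * n_series, 0, sigma), n, n_series)
  if (b != 0 && n > 1) {
    for (t in 2:n) e[t, ] <- b * e[t - 1, ] + e[t, ]
  }
  if (n_series == 1) drop(e) else e
}

#' Confine a series to a closed range by a monotone affine squash
#'
#' Centres the input, scales it by its (analytic or empirical) standard
#' deviation, passes it through a logistic sigmoid, and maps the result
#' affinely onto `[range[1], range[2]]`. The map is deterministic, monotone
#' (rank-preserving), and keeps every output strictly inside the range
#' without the clipping artefacts of truncation. An input equal to `center`
#' maps to the midpoint of the range.
#'
#' For a stationary AR(1) input with coefficient `b` and innovation sd
#' `sigma`, pass `center = 0` and `scale = sigma / sqrt(1 - b^2)` (the
#' analytic marginal sd) so the squash is a fixed, data-independent map.
#'
#' @param x Numeric vector or matrix.
#' @param range Length-2 numeric, `range[1] <= range[2]`.
#' @param center,scale Location and scale used to standardise `x` before the
#'   sigmoid. Defaults are the empirical mean and sd of `x`.
#' @return Object of the same shape as `x`, with every value in `range`.
#' @export
#' @examples
#' z <- constrain_to_range(rnorm(1000), c(0.01, 0.25 * pi), center = 0, scale = 1)
#' range(z)
constrain_to_range <- function(x, range, center = mean(x), scale = stats::sd(as.numeric(x))) {
  range <- as.numeric(range)
  if (length(range) != 2 || range[1] > range[2]) {
    stop("`range` must be a non-decreasing length-2 interval", call. = FALSE)
  }
  if (range[1] == range[2]) {
    warning("degenerate range (lower == upper): returning a constant series")
    out <- x
    out[] <- range[1]
    return(out)
  }
  if (!is.finite(scale) || scale <= 0) scale <- 1
  z <- (x - center) / scale
  out <- x
  out[] <- range[1] + (range[2] - range[1]) * stats::plogis(z)
  out
}

#' Integrate an instantaneous-frequency series into a phase series
#'
#' The phase starts at 0 and accumulates the angular-frequency increments:
#' `phi[t] = phi[t-1] + f[t]`. The phase is kept unwrapped (monotone when f
#' is positive); use [wrap_phase()] for a wrapped view.
#'
#' @param f Numeric vector (or `n x m` matrix of series in columns) of
#'   angular frequencies in radians/sample.
#' @return Unwrapped phase of the same shape, starting at 0.
#' @export
#' @examples
#' integrate_phase(rep(0.1, 11))[11]  # 1.0
integrate_phase <- function(f) {
  if (!all(is.finite(f))) stop("frequency series must be finite", call. = FALSE)
  if (is.matrix(f)) {
    apply(f, 2, function(col) cumsum(col) - col[1])
  } else {
    cumsum(f) - f[1]
  }
}

#' Wrap phases to [-pi, pi)
#'
#' @param phi Numeric vector/array of phases in radians.
#' @return Phases wrapped into `[-pi, pi)`.
#' @export
wrap_phase <- function(phi) {
  ((phi + pi) %% (2 * pi)) - pi
}

#' Build the resting signal from its components
#'
#' `x[t] = a[t] * sin(phi[t]) + eps[t]` with i.i.d. Gaussian measurement
#' noise of standard deviation `noise_sd`.
#'
#' @param a Amplitude series (vector or matrix).
#' @param phi Unwrapped phase series, same shape as `a`.
#' @param noise_sd Measurement-noise standard deviation.
#' @return Signal of the same shape.
#' @export
resting_signal <- function(a, phi, noise_sd = 0) {
  if (length(a) != length(phi)) {
    stop("amplitude and phase series have mismatched lengths", call. = FALSE)
  }
  stopifnot(noise_sd >= 0)
  x <- a * sin(phi)
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
  x
}

# One trial of resting components, T x C matrices, drawn from the current
# RNG state in a fixed order (freq innovations, amp innovations, noise).
# The fixed order is what guarantees that adding stimulation effects on top
# leaves the resting draw untouched for the same per-trial seed.
.sample_resting_trial <- function(spec) {
  Tt <- spec$n_times
  C <- spec$n_channels
  f_raw <- sample_ar1(spec$ar_freq, spec$innov_sd_freq, Tt, C)
  a_raw <- sample_ar1(spec$ar_amp, spec$innov_sd_amp, Tt, C)
  eps <- matrix(stats::rnorm(Tt * C, 0, spec$noise_sd), Tt, C)
  f_sd <- spec$innov_sd_freq / sqrt(1 - spec$ar_freq^2)
  a_sd <- spec$innov_sd_amp / sqrt(1 - spec$ar_amp^2)
  f <- constrain_to_range(matrix(f_raw, Tt, C), spec$freq_range, center = 0, scale = f_sd)
  a <- constrain_to_range(matrix(a_raw, Tt, C), spec$amp_range, center = 0, scale = a_sd)
  list(f = f, a = a, eps = eps)
}

.trial_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Sample resting (unstimulated) components and signal for many trials
#'
#' Draws, independently per trial and channel, the AR(1) instantaneous
#' frequency and amplitude (squashed into their configured ranges), the
#' integrated phase, and the noisy resting signal.
#'
#' @param spec A [spontaneous_spec()].
#' @param seed Integer master seed; each trial uses its own derived stream so
#'   results are reproducible trial-by-trial.
#' @return A list of class `resting_components` with arrays
#'   `freq`, `amp`, `phase`, `signal`, each `n_trials x n_times x n_channels`.
#' @export
sample_resting <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "spontaneous_spec"))
  seeds <- .trial_seeds(seed, spec$n_trials)
  dims <- c(spec$n_trials, spec$n_times, spec$n_channels)
  freq <- amp <- phase <- signal <- array(NA_real_, dims)
  for (i in seq_len(spec$n_trials)) {
    set.seed(seeds[i])
    comp <- .sample_resting_trial(spec)
    phi <- integrate_phase(comp$f)
    freq[i, , ] <- comp$f
    amp[i, , ] <- comp$a
    phase[i, , ] <- phi
    signal[i, , ] <- comp$a * sin(phi) + comp$eps
  }
  structure(list(freq = freq, amp = amp, phase = phase, signal = signal,
                 spec = spec, seed = seed),
            class = "resting_components")
}
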