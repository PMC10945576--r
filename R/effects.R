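#' Polar gradient between a target phase and the ongoing phase
#'
#' The signed angular difference `target - phi`, wrapped into `[-pi, pi)`,
#' i.e. the shortest rotation that takes the ongoing phase onto the target.
#'
#' @param target Target phase(s), radians.
#' @param phi Ongoing phase(s), radians (wrapped or unwrapped).
#' @return Gradient(s) in `[-pi, pi)`; `phi + polar_gradient(target, phi)`
#'   is congruent to `target` modulo `2*pi`.
#' @export
#' @examples
#' polar_gradient(3 * pi / 2, 0)  # -pi/2: wraps the long way round
polar_gradient <- function(target, phi) {
  wrap_phase(target - phi)
}

# inverse of A(kappa) = I1(kappa)/I0(kappa): standard series/rational
# approximation (Fisher 1993), accurate to ~1e-3 which is far below the
# sampling noise of any phase draw.
.kappa_from_resultant <- function(r) {
  if (r >= 1) return(Inf)
  if (r < 0) r <- 0
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Map a circular standard deviation to a von Mises concentration
#'
#' Uses circular-variance matching: the concentration `kappa` is chosen so
#' the mean resultant length of the von Mises distribution equals
#' `exp(-sd^2 / 2)` (the resultant length of a wrapped normal with linear sd
#' `sd`). `sd = 0` maps to `Inf` (a point mass).
#'
#' @param sd Circular standard deviation in radians (>= 0).
#' @return Concentration parameter `kappa`.
#' @export
vm_concentration <- function(sd) {
  stopifnot(sd >= 0)
  if (sd == 0) return(Inf)
  .kappa_from_resultant(exp(-sd^2 / 2))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = Inf` returns the mean exactly;
#' very small `kappa` falls back to the circular uniform.
#'
#' @param n Number of draws.
#' @param mu Circular mean, radians.
#' @param kappa Concentration (>= 0, may be `Inf`).
#' @return `n` phases in `[-pi, pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(wrap_phase(mu), n))
  if (kappa < 1e-7) return(wrap_phase(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu
        break
      }
    }
  }
  wrap_phase(out)
}

#' Sample a trial-level target phase
#'
#' The target phase a channel resets towards is redrawn every trial from a
#' von Mises distribution centred on the condition's mean target phase, with
#' spread given as a circular standard deviation (see [vm_concentration()]).
#'
#' @param mean Condition mean target phase, radians.
#' @param sd Circular standard deviation, radians; 0 returns `mean` exactly.
#' @param n Number of draws.
#' @return `n` phases in `[-pi, pi)`.
#' @export
sample_target_phase <- function(mean, sd, n = 1) {
  rvonmises(n, mean, vm_concentration(sd))
}

#' Per-trial channel activation mask
#'
#' Each stimulus-relevant channel responds in a given trial with probability
#' `theta` (independently across trials and channels); non-relevant channels
#' never respond.
#'
#' @param n_channels Total number of channels.
#' @param relevant Integer indices of the relevant channels.
#' @param theta Activation probability, scalar or one value per relevant
#'   channel, in `[0, 1]`.
#' @param n_trials Number of trials.
#' @return `n_trials x n_channels` logical matrix.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_activations(32, 1:32, 1 / 6, 1000))  # ~ 1/6
sample_activations <- function(n_channels, relevant, theta, n_trials) {
  stopifnot(all(theta >= 0), all(theta <= 1),
            all(relevant >= 1), all(relevant <= n_channels))
  theta <- rep_len(theta, length(relevant))
  mask <- matrix(FALSE, n_trials, n_channels)
  if (length(relevant)) {
    u <- matrix(stats::runif(n_trials * length(relevant)), n_trials)
    mask[, relevant] <- sweep(u, 2, theta, "<")
  }
  mask
}

#' One step of the phase-reset / frequency-entrainment dynamics
#'
#' Before `tmax` the ongoing phase is pulled towards the trial's target
#' phase along the polar gradient, with the pull strength given by the gate:
#' `phi_t = phi_{t-1} + (1 - g) * f_rest + g * grad`. From `tmax` onwards
#' the reset is over and the phase entrains towards the target frequency:
#' `phi_t = phi_{t-1} + g * f_k + (1 - g) * f_rest`.
#'
#' @param phi_prev Previous (unwrapped) phase.
#' @param f_rest Resting angular-frequency increment at this step.
#' @param g Gate value in `[0, 1]`.
#' @param target Trial target phase (radians).
#' @param entrain_freq Target (entrainment) angular frequency.
#' @param past_tmax Logical: has the gate peak been passed?
#' @return Next unwrapped phase value.
#' @export
phase_reset_entrain <- function(phi_prev, f_rest, g, target, entrain_freq,
                                past_tmax) {
  stopifnot(g >= 0, g <= 1)
  if (past_tmax) {
    phi_prev + g * entrain_freq + (1 - g) * f_rest
  } else {
    phi_prev + (1 - g) * f_rest + g * polar_gradient(target, phi_prev)
  }
}

# Full-trial phase series under phase reset + entrainment.
# f: resting freq increments (length T); g: gate (length T);
# tmax_pos: 1-based index of the gate peak. Only the gate support needs the
# sequential recursion; outside it the phase follows the resting cumsum.
.phase_with_reset <- function(f, g, tmax_pos, target, entrain_freq) {
  Tt <- length(f)
  phi <- integrate_phase(f)
  idx <- which(g > 0)
  if (!length(idx)) return(phi)
  i0 <- max(min(idx), 2L)
  i1 <- max(idx)
  for (t in i0:i1) {
    phi[t] <- phase_reset_entrain(phi[t - 1], f[t], g[t], target,
                                  entrain_freq, past_tmax = t > tmax_pos)
  }
  if (i1 < Tt) {
    later <- (i1 + 1):Tt
    phi[later] <- phi[i1] + cumsum(f[later])
  }
  phi
}

#' Additive damped oscillatory response
#'
#' A sinusoid with condition-specific amplitude, frequency and phase, damped
#' by the response gate: `y = g * alpha * sin(omega * t_rel + gamma)`.
#' `t_rel` counts samples since stimulus onset, so `gamma` is the phase of
#' the additive oscillation at onset (the condition code).
#'
#' @param g Gate values in `[0, 1]`.
#' @param alpha Oscillation amplitude (>= 0).
#' @param omega Angular frequency, radians/sample.
#' @param gamma Phase at stimulus onset, radians.
#' @param t_rel Samples since onset, same length as `g`.
#' @return Additive response, zero wherever the gate is zero.
#' @export
additive_oscillation <- function(g, alpha, omega, gamma, t_rel) {
  stopifnot(all(g >= 0), all(g <= 1), alpha >= 0, length(g) == length(t_rel))
  g * alpha * sin(omega * t_rel + gamma)
}

#' Gate-timed amplitude modulation
#'
#' Scales the ongoing amplitude by `(1 + g * m)`: at the gate peak the
#' amplitude is increased by a factor `1 + m` (e.g. `m = 0.1` is a 10%
#' increment at `tmax`; `m = 4` a fivefold increase).
#'
#' @param a_rest Resting amplitude series.
#' @param g Gate values in `[0, 1]`, same length.
#' @param m Proportional increment, `m > -1` so amplitude stays positive.
#' @return Modulated amplitude series.
#' @export
amplitude_modulation <- function(a_rest, g, m) {
  stopifnot(m > -1, length(a_rest) == length(g))
  (1 + g * m) * a_rest
}

#' Additive slow (non-oscillatory) response
#'
#' A gate-scaled constant: `z = g * s`, where the per-trial, per-channel
#' level `s` is drawn once from `N(mean, sd^2)` (condition-specific mean).
#' Driven by a slower gate than the oscillatory effects, this produces the
#' ramping, long-lived component of the evoked response.
#'
#' @param g Gate values in `[0, 1]`.
#' @param s Trial/channel response level (scalar).
#' @return Slow response series.
#' @export
additive_slow <- function(g, s) {
  stopifnot(all(g >= 0), all(g <= 1), length(s) == 1)
  g * s
}
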