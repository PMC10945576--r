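#' Stimulus-effect constructors
#'
#' Each constructor describes one of the four response mechanisms for all
#' conditions at once; per-condition parameters are given as vectors (one
#' entry per condition, recycled if scalar).
#'
#' @param target_mean Mean target phase per condition, radians (the phase
#'   the ongoing oscillation is reset towards).
#' @param target_sd Circular standard deviation of the trial-level target
#'   phase, radians.
#' @param entrain_freq Entrainment angular frequency per condition
#'   (radians/sample, in (0, pi]); a per-channel override can be supplied
#'   via `channel_freq` in [sim_config()].
#' @return A list describing the effect, for the `effects` argument of
#'   [sim_config()].
#' @name effects-config
NULL

#' @rdname effects-config
#' @export
effect_phase_reset <- function(target_mean = c(0, pi), target_sd = 0.1,
                               entrain_freq = 0.15) {
  structure(list(kind = "phase_reset", target_mean = target_mean,
                 target_sd = target_sd, entrain_freq = entrain_freq),
            class = "sim_effect")
}

#' @rdname effects-config
#' @param amplitude Additive-oscillation amplitude per condition (>= 0).
#' @param freq Additive-oscillation angular frequency per condition.
#' @param phase Additive-oscillation phase code per condition, radians.
#' @param phase_ref Where the phase code is anchored: `"onset"` (default)
#'   makes `phase` the phase of the sinusoid at stimulus onset; `"tmax"`
#'   anchors it at the gate peak, so that channels with different
#'   frequencies and latencies all attain the condition phase at their own
#'   response maximum (needed to give the oscillatory code a well-defined
#'   in-/anti-phase relation to the slow response).
#' @export
effect_additive_osc <- function(amplitude = 1, freq = 0.15,
                                phase = c(0, pi),
                                phase_ref = c("onset", "tmax")) {
  phase_ref <- match.arg(phase_ref)
  structure(list(kind = "additive_osc", amplitude = amplitude, freq = freq,
                 phase = phase, phase_ref = phase_ref),
            class = "sim_effect")
}

#' @rdname effects-config
#' @param m Proportional amplitude increment per condition (`m > -1`);
#'   `m = 0.1` increases the ongoing amplitude by 10% at the gate peak.
#' @export
effect_amp_mod <- function(m = 0.5) {
  structure(list(kind = "amp_mod", m = m), class = "sim_effect")
}

#' @rdname effects-config
#' @param mean Mean slow-response level per condition (signal units).
#' @param sd Standard deviation of the per-trial/channel slow level.
#' @param shape [response_shape()] timing the slow response; defaults to a
#'   slow gate that ramps up in ~100 ms and vanishes around 800 ms at
#'   250 Hz.
#' @export
effect_slow <- function(mean = c(0.25, -0.25), sd = 0.1,
                        shape = response_shape(delta1 = 0, delta2 = 25,
                                               delta3 = 175)) {
  structure(list(kind = "slow", mean = mean, sd = sd, shape = shape),
            class = "sim_effect")
}

#' Full simulation configuration
#'
#' Bundles the spontaneous dynamics, the channel model (which channels are
#' stimulus relevant and how often they respond), the response-function
#' shape shared by the oscillatory effects, and any combination of the four
#' stimulation effects.
#'
#' Defaults reproduce the reference study conditions: 250 trials of 250
#' samples at 250 Hz over 32 channels, endogenous angular frequency in
#' [0.01, 0.25*pi] (0.4-10 Hz), all channels relevant with activation
#' probability 1/6.
#'
#' @param spontaneous A [spontaneous_spec()]. Its `n_trials`, `n_times`,
#'   `n_channels`, `fs` fields define the dataset geometry.
#' @param n_conditions Number of stimulus conditions (>= 2).
#' @param tau Stimulus-onset sample index (0-based) within the epoch.
#' @param relevant Indices of stimulus-relevant channels (default: all).
#' @param theta Activation probability per relevant channel (scalar or
#'   vector), in `[0, 1]`.
#' @param shape [response_shape()] timing the oscillatory effects.
#' @param channel_latency Optional per-channel additional latency (samples)
#'   added to `shape$delta1` — latency diversity across channels.
#' @param channel_freq Optional per-channel effect angular frequency
#'   (radians/sample) overriding the per-condition entrainment/oscillation
#'   frequency — frequency diversity across channels.
#' @param in_phase_fraction Fraction of relevant channels whose oscillatory
#'   condition code is aligned ("in phase") with the slow-response condition
#'   code; the remaining channels use the condition-swapped oscillatory
#'   parameters ("anti-phase"). Only meaningful with 2 conditions.
#' @param effects List of effect descriptions built with
#'   [effect_phase_reset()], [effect_additive_osc()], [effect_amp_mod()],
#'   [effect_slow()]. May be empty (resting data only).
#' @return Object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(
#'   spontaneous = spontaneous_spec(n_trials = 20, n_times = 100,
#'                                  n_channels = 4),
#'   effects = list(effect_additive_osc(), effect_slow())
#' )
#' ds <- sample_dataset(cfg, seed = 1)
sim_config <- function(spontaneous = spontaneous_spec(),
                       n_conditions = 2,
                       tau = 0,
                       relevant = seq_len(spontaneous$n_channels),
                       theta = 1 / 6,
                       shape = response_shape(),
                       channel_latency = NULL,
                       channel_freq = NULL,
                       in_phase_fraction = 1,
                       effects = list()) {
  cfg <- structure(list(
    spontaneous = spontaneous, n_conditions = as.integer(n_conditions),
    tau = tau, relevant = as.integer(relevant), theta = theta,
    shape = shape, channel_latency = channel_latency,
    channel_freq = channel_freq, in_phase_fraction = in_phase_fraction,
    effects = effects
  ), class = "sim_config")
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every field and reports all problems at once (one line per
#' offending field), rather than stopping at the first.
#'
#' @param config A [sim_config()].
#' @return `config`, invisibly, if valid; otherwise an error naming each
#'   invalid field.
#' @export
validate_config <- function(config) {
  p <- character()
  sp <- config$spontaneous
  if (!inherits(sp, "spontaneous_spec")) p <- c(p, "spontaneous: must be a spontaneous_spec")
  C <- sp$n_channels
  if (config$n_conditions < 2) p <- c(p, "n_conditions: must be >= 2")
  if (config$tau < 0 || config$tau >= sp$n_times) {
    p <- c(p, "tau: must satisfy 0 <= tau < n_times")
  }
  if (length(config$relevant) &&
      (any(config$relevant < 1) || any(config$relevant > C) ||
       anyDuplicated(config$relevant))) {
    p <- c(p, "relevant: channel indices must be unique and in 1..n_channels")
  }
  if (any(config$theta < 0) || any(config$theta > 1)) {
    p <- c(p, "theta: activation probabilities must lie in [0, 1]")
  }
  if (!inherits(config$shape, "response_shape")) {
    p <- c(p, "shape: must be a response_shape")
  }
  if (!is.null(config$channel_latency) &&
      (length(config$channel_latency) != C || any(config$channel_latency < 0))) {
    p <- c(p, "channel_latency: needs one non-negative value per channel")
  }
  if (!is.null(config$channel_freq) &&
      (length(config$channel_freq) != C ||
       any(config$channel_freq <= 0) || any(config$channel_freq > pi))) {
    p <- c(p, "channel_freq: needs one value per channel, within (0, pi]")
  }
  if (config$in_phase_fraction < 0 || config$in_phase_fraction > 1) {
    p <- c(p, "in_phase_fraction: must lie in [0, 1]")
  }
  if (config$in_phase_fraction < 1 && config$n_conditions != 2) {
    p <- c(p, "in_phase_fraction: anti-phase coding requires exactly 2 conditions")
  }
  kinds <- vapply(config$effects, function(e) e$kind %||% "", "")
  if (length(config$effects) &&
      (!all(vapply(config$effects, inherits, TRUE, "sim_effect")) ||
       anyDuplicated(kinds))) {
    p <- c(p, "effects: must be a list of distinct sim_effect objects")
  }
  K <- config$n_conditions
  for (e in config$effects) {
    if (!inherits(e, "sim_effect")) next
    if (e$kind == "phase_reset") {
      if (any(e$target_sd < 0)) p <- c(p, "phase_reset$target_sd: must be >= 0")
      if (any(e$entrain_freq <= 0) || any(e$entrain_freq > pi)) {
        p <- c(p, "phase_reset$entrain_freq: must lie in (0, pi]")
      }
    } else if (e$kind == "additive_osc") {
      if (any(e$amplitude < 0)) p <- c(p, "additive_osc$amplitude: must be >= 0")
      if (any(e$freq <= 0) || any(e$freq > pi)) {
        p <- c(p, "additive_osc$freq: must lie in (0, pi]")
      }
    } else if (e$kind == "amp_mod") {
      if (any(e$m <= -1)) p <- c(p, "amp_mod$m: must be > -1")
    } else if (e$kind == "slow") {
      if (any(e$sd < 0)) p <- c(p, "slow$sd: must be >= 0")
      if (!inherits(e$shape, "response_shape")) {
        p <- c(p, "slow$shape: must be a response_shape")
      }
    }
  }
  if (length(p)) {
    stop("invalid sim_config:\n", paste0("- ", p, collapse = "\n"), call. = FALSE)
  }
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  sp <- x$spontaneous
  cat("<sim_config>\n")
  cat(sprintf("  %d trials x %d times x %d channels @ %g Hz, %d conditions, tau = %g\n",
              sp$n_trials, sp$n_times, sp$n_channels, sp$fs,
              x$n_conditions, x$tau))
  cat(sprintf("  relevant channels: %d, theta = %s\n", length(x$relevant),
              paste(signif(unique(x$theta), 3), collapse = "/")))
  kinds <- vapply(x$effects, `[[`, "", "kind")
  cat("  effects:", if (length(kinds)) paste(kinds, collapse = ", ") else "none", "\n")
  invisible(x)
}

.get_effect <- function(config, kind) {
  for (e in config$effects) if (e$kind == kind) return(e)
  NULL
}

# per-condition parameter, recycled; possibly channel-overridden
.par_k <- function(x, k, K) rep_len(x, K)[k]

# Simulate one trial of condition k from the current RNG state.
# Returns T x C signal plus (optionally) components.
.simulate_trial <- function(config, k, components = FALSE) {
  sp <- config$spontaneous
  Tt <- sp$n_times
  C <- sp$n_channels
  K <- config$n_conditions
  tt <- 0:(Tt - 1)

  rest <- .sample_resting_trial(config$spontaneous)
  phi <- integrate_phase(rest$f)

  e_pr <- .get_effect(config, "phase_reset")
  e_ao <- .get_effect(config, "additive_osc")
  e_am <- .get_effect(config, "amp_mod")
  e_sl <- .get_effect(config, "slow")
  any_effect <- !is.null(e_pr) || !is.null(e_ao) || !is.null(e_am) || !is.null(e_sl)

  a <- rest$a
  y <- matrix(0, Tt, C)
  z <- matrix(0, Tt, C)

  if (any_effect && length(config$relevant)) {
    active <- drop(sample_activations(C, config$relevant, config$theta, 1))
    d1 <- jitter_latency(config$shape, C)
    if (!is.null(config$channel_latency)) d1 <- d1 + round(config$channel_latency)
    d1_slow <- if (!is.null(e_sl)) jitter_latency(e_sl$shape, C) else NULL
    targets <- if (!is.null(e_pr)) {
      vapply(seq_len(K), function(kk) {
        sample_target_phase(.par_k(e_pr$target_mean, kk, K),
                            .par_k(e_pr$target_sd, kk, K))
      }, 0)
    } else NULL
    s_slow <- if (!is.null(e_sl)) {
      stats::rnorm(C, .par_k(e_sl$mean, k, K), .par_k(e_sl$sd, k, K))
    } else NULL

    # anti-phase channels use the condition-swapped oscillatory code
    k_osc <- rep(k, C)
    if (config$in_phase_fraction < 1 && length(config$relevant)) {
      n_in <- round(config$in_phase_fraction * length(config$relevant))
      anti <- config$relevant[seq_along(config$relevant) > n_in]
      k_osc[anti] <- 3 - k  # swap between conditions 1 and 2
    }

    for (j in which(active)) {
      kj <- k_osc[j]
      g <- response_gate(config$shape, tt, config$tau, delta1 = d1[j])
      if (!is.null(e_pr)) {
        fk <- if (!is.null(config$channel_freq)) config$channel_freq[j] else
          .par_k(e_pr$entrain_freq, kj, K)
        tmax_pos <- d1[j] + config$shape$delta2 + config$tau + 1
        phi[, j] <- .phase_with_reset(rest$f[, j], g, tmax_pos,
                                      targets[kj], fk)
      }
      if (!is.null(e_am)) {
        a[, j] <- amplitude_modulation(rest$a[, j], g, .par_k(e_am$m, k, K))
      }
      if (!is.null(e_ao)) {
        wj <- if (!is.null(config$channel_freq)) config$channel_freq[j] else
          .par_k(e_ao$freq, kj, K)
        gam <- .par_k(e_ao$phase, kj, K)
        t_rel <- tt - config$tau
        if ((e_ao$phase_ref %||% "onset") == "tmax") {
          t_rel <- t_rel - (d1[j] + config$shape$delta2)
        }
        y[, j] <- additive_oscillation(g, .par_k(e_ao$amplitude, kj, K), wj,
                                       gam, t_rel)
      }
      if (!is.null(e_sl)) {
        g_slow <- response_gate(e_sl$shape, tt, config$tau, delta1 = d1_slow[j])
        z[, j] <- additive_slow(g_slow, s_slow[j])
      }
    }
  }
  x <- a * sin(phi) + z + y + rest$eps
  if (components) {
    list(x = x, freq = rest$f, amp = a, phase = phi, slow = z, osc = y,
         noise = rest$eps)
  } else {
    list(x = x)
  }
}

#' Simulate a single trial with all its components
#'
#' Convenience wrapper around the per-trial pipeline, returning the sampled
#' signal together with its constitutive components (phase, frequency,
#' amplitude, slow and oscillatory responses) for inspection or plotting.
#'
#' @param config A [sim_config()].
#' @param condition Condition index of the trial.
#' @param seed Integer seed.
#' @return List with `n_times x n_channels` matrices `x`, `freq`, `amp`,
#'   `phase`, `slow`, `osc`, `noise`.
#' @export
simulate_trial <- function(config, condition = 1, seed = 1L) {
  validate_config(config)
  stopifnot(condition >= 1, condition <= config$n_conditions)
  set.seed(seed)
  .simulate_trial(config, condition, components = TRUE)
}

#' Sample a full epoched dataset
#'
#' Assigns balanced, shuffled condition labels, then runs the per-trial
#' pipeline (resting components, channel activations, latency jitter,
#' stimulation effects, composition) with one derived RNG stream per trial,
#' so the result is bit-reproducible given the master seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return Object of class `epoched_data`: a list with `data`
#'   (`n_trials x n_times x n_channels` array), `labels` (integer condition
#'   per trial), `tau`, `fs`, `seed`, and a config `provenance` hash.
#' @export
#' @examples
#' cfg <- sim_config(spontaneous_spec(n_trials = 10, n_times = 50,
#'                                    n_channels = 3))
#' ds <- sample_dataset(cfg, seed = 7)
#' dim(ds$data)
sample_dataset <- function(config, seed = 1L) {
  validate_config(config)
  sp <- config$spontaneous
  seeds <- .trial_seeds(seed, sp$n_trials)
  labels <- sample(rep_len(seq_len(config$n_conditions), sp$n_trials))
  data <- array(NA_real_, c(sp$n_trials, sp$n_times, sp$n_channels))
  for (i in seq_len(sp$n_trials)) {
    set.seed(seeds[i])
    data[i, , ] <- .simulate_trial(config, labels[i])$x
  }
  structure(list(data = data, labels = labels, tau = config$tau, fs = sp$fs,
                 seed = seed, config = config,
                 provenance = config_hash(config)),
            class = "epoched_data")
}

#' Hash a simulation configuration for provenance tracking
#'
#' The hash is taken over the configuration's canonical YAML serialisation
#' (15 significant digits), so a configuration written with
#' [write_config()] and read back hashes identically, while any edit to a
#' hyperparameter changes the hash.
#'
#' @param config A [sim_config()].
#' @return Character hash of the configuration's canonical serialisation.
#' @export
config_hash <- function(config) {
  rlang::hash(yaml::as.yaml(.config_to_list(config), precision = 15))
}

#' @export
print.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_data> %d trials x %d times x %d channels @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  conditions: %s (tau = %g, seed = %d)\n",
              paste(table(x$labels), collapse = "/"), x$tau, x$seed))
  invisible(x)
}
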