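#' Parametrise the temporal response function G(t; tau)
#'
#' Every stimulation effect is timed by an asymmetric gate that is zero
#' until `delta1` samples after stimulus onset `tau`, rises to 1 over
#' `delta2` samples, peaks at `tmax = delta1 + delta2 + tau`, falls back to
#' zero over `delta3` samples, and is zero afterwards. Each side is, by
#' default, a normalised logarithmic curve
#' `G(t) = 1 - log(1 + (d / T_side)^zeta)` where `d` is the distance to
#' `tmax` in samples and the scale `T_side` is solved from the boundary
#' constraints (exactly 0 at the window edge, exactly 1 at `tmax`). Either
#' side may instead use a faster-decaying Gaussian-kernel ("exponential")
#' piece, normalised by the same two boundary constraints.
#'
#' @param delta1 Response latency in samples (>= 0).
#' @param delta2 Rise duration in samples (>= 1).
#' @param delta3 Fall duration in samples (>= 1).
#' @param zeta1,zeta2 Shape exponents of the rising and falling pieces
#'   (defaults 2 and 4).
#' @param left,right Family of the rising/falling piece: `"log"` (default)
#'   or `"exp"`.
#' @param jitter_sd Upper bound of the per-trial Uniform(0, jitter_sd)
#'   latency jitter, in samples (0 disables jitter).
#' @param jitter_mode `"absolute"`: one jitter draw per trial shared by all
#'   channels; `"relative"`: an independent draw per channel per trial.
#' @return Object of class `response_shape`.
#' @seealso [response_gate()], [jitter_latency()]
#' @export
#' @examples
#' sh <- response_shape(delta1 = 5, delta2 = 10, delta3 = 20)
#' g <- response_gate(sh, t = 0:40)
#' g[5 + 10 + 1]  # value at tmax is exactly 1
response_shape <- function(delta1 = 0, delta2 = 15, delta3 = 23,
                           zeta1 = 2, zeta2 = 4,
                           left = c("log", "exp"), right = c("log", "exp"),
                           jitter_sd = 0,
                           jitter_mode = c("absolute", "relative")) {
  left <- match.arg(left)
  right <- match.arg(right)
  jitter_mode <- match.arg(jitter_mode)
  stopifnot(delta1 >= 0, delta2 >= 1, delta3 >= 1,
            zeta1 > 0, zeta2 > 0, jitter_sd >= 0)
  structure(list(delta1 = delta1, delta2 = delta2, delta3 = delta3,
                 zeta1 = zeta1, zeta2 = zeta2,
                 left = left, right = right,
                 jitter_sd = jitter_sd, jitter_mode = jitter_mode),
            class = "response_shape")
}

#' @export
print.response_shape <- function(x, ...) {
  cat(sprintf(
    "<response_shape> delta1=%g delta2=%g delta3=%g (tmax = delta1+delta2+tau); zeta=(%g, %g); sides=(%s, %s); jitter U(0,%g) %s\n",
    x$delta1, x$delta2, x$delta3, x$zeta1, x$zeta2, x$left, x$right,
    x$jitter_sd, x$jitter_mode))
  invisible(x)
}

#' Normalisation constants of the response function
#'
#' Each logarithmic piece `-log(1 + (d / T)^zeta) + C` is pinned by two
#' constraints: value 1 at `tmax` (distance 0) and value 0 at its window
#' edge (distance `delta2` on the left, `delta3` on the right). The first
#' gives `C = 1`; the second gives `T = delta / (e - 1)^(1/zeta)`.
#' For an exponential piece, the Gaussian kernel
#' `exp(-0.5 d^2 C3 / C4)` uses `C3 = 1` and `C4 = (delta/3)^2` (the window
#' edge sits three kernel widths from the peak) and is then renormalised to
#' satisfy the same two boundary constraints exactly.
#'
#' @param shape A [response_shape()].
#' @return Named list with `C1`, `C2`, `T1`, `T2` (and `C3`, `C4` per
#'   exponential side, named `C3_left`/`C4_left`, `C3_right`/`C4_right`).
#' @export
normalisation_constants <- function(shape) {
  stopifnot(inherits(shape, "response_shape"))
  out <- list(
    C1 = 1, C2 = 1,
    T1 = shape$delta2 / (exp(1) - 1)^(1 / shape$zeta1),
    T2 = shape$delta3 / (exp(1) - 1)^(1 / shape$zeta2)
  )
  if (shape$left == "exp") {
    out$C3_left <- 1
    out$C4_left <- (shape$delta2 / 3)^2
  }
  if (shape$right == "exp") {
    out$C3_right <- 1
    out$C4_right <- (shape$delta3 / 3)^2
  }
  out
}

# one piece of the gate as a function of distance d >= 0 from tmax
.gate_piece <- function(d, width, zeta, kind) {
  if (kind == "log") {
    Tn <- width / (exp(1) - 1)^(1 / zeta)
    1 - log(1 + (d / Tn)^zeta)
  } else {
    s2 <- (width / 3)^2
    raw <- exp(-0.5 * d^2 / s2)
    edge <- exp(-0.5 * width^2 / s2)
    (raw - edge) / (1 - edge)
  }
}

#' Evaluate the response function
#'
#' @param shape A [response_shape()].
#' @param t Integer (or numeric) time indices, in samples from trial start
#'   (0-based: `t = 0` is the first sample).
#' @param tau Stimulus-onset sample index (same convention).
#' @param delta1 Effective latency, defaulting to `shape$delta1`; pass the
#'   output of [jitter_latency()] to evaluate a jittered gate.
#' @return Gate values in `[0, 1]`, same length as `t`. Zero outside the
#'   support `[delta1 + tau, delta1 + delta2 + delta3 + tau]`, exactly 1 at
#'   `tmax = delta1 + delta2 + tau`.
#' @export
#' @examples
#' sh <- response_shape(delta1 = 5, delta2 = 10, delta3 = 20)
#' max(response_gate(sh, 0:60)) # 1 at t = 15
response_gate <- function(shape, t, tau = 0, delta1 = shape$delta1) {
  stopifnot(inherits(shape, "response_shape"))
  tmax <- delta1 + shape$delta2 + tau
  g <- numeric(length(t))
  il <- t >= (delta1 + tau) & t <= tmax
  ir <- t > tmax & t <= (tmax + shape$delta3)
  if (any(il)) {
    g[il] <- .gate_piece(tmax - t[il], shape$delta2, shape$zeta1, shape$left)
  }
  if (any(ir)) {
    g[ir] <- .gate_piece(t[ir] - tmax, shape$delta3, shape$zeta2, shape$right)
  }
  pmin(pmax(g, 0), 1)
}

#' Evaluate one side of the gate at tmax (for both-sided peak checks)
#'
#' Returns the value of the requested piece at the changing point `tmax`,
#' computed through that piece's own normalisation (not short-circuited), so
#' that the two-sided peak constraint `G(tmax) = 1` can be verified piece by
#' piece.
#'
#' @inheritParams response_gate
#' @param side `"left"` or `"right"`.
#' @return Scalar gate value.
#' @export
response_gate_at_peak <- function(shape, side = c("left", "right"), tau = 0,
                                  delta1 = shape$delta1) {
  side <- match.arg(side)
  if (side == "left") {
    .gate_piece(0, shape$delta2, shape$zeta1, shape$left)
  } else {
    .gate_piece(0, shape$delta3, shape$zeta2, shape$right)
  }
}

#' Draw per-trial (and optionally per-channel) latency jitter
#'
#' Adds a `Uniform(0, jitter_sd)` draw to the base latency `delta1`. In
#' `"absolute"` mode a single draw is shared by every channel of the trial;
#' in `"relative"` mode each channel receives an independent draw. Effective
#' latencies are rounded to the nearest sample because the gate is evaluated
#' on the integer sample grid.
#'
#' @param shape A [response_shape()].
#' @param n_channels Number of channels.
#' @return Integer-valued numeric vector of length `n_channels` of effective
#'   latencies (samples).
#' @export
jitter_latency <- function(shape, n_channels) {
  stopifnot(inherits(shape, "response_shape"), n_channels >= 1)
  if (shape$jitter_sd == 0) {
    return(rep(round(shape$delta1), n_channels))
  }
  u <- if (shape$jitter_mode == "absolute") {
    rep(stats::runif(1, 0, shape$jitter_sd), n_channels)
  } else {
    stats::runif(n_channels, 0, shape$jitter_sd)
  }
  round(shape$delta1 + u)
}
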