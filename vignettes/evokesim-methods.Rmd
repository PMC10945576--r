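---
title: "Simulating evoked electrophysiological responses: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating evoked electrophysiological responses: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evokesim)
```

## Why a generative model

Time-resolved decoding of M/EEG data yields temporal generalisation
matrices (TGMs) with recurring signatures — a sharp early diagonal,
late-trial broadening, vertical and horizontal bands of above-chance
generalisation, sometimes periodic ("chequer") structure. These signatures
are observations about *accuracy*, not about the signal: many different
signal-level mechanisms could in principle produce them. `evokesim`
generates multichannel epoched data in which the mechanism is known and
configurable, so that running the very same decoding pipeline on simulated
and real data lets one reason backwards from TGM signatures to candidate
mechanisms.

## The resting state

Each channel, in each trial, is an amplitude-modulated sinusoid with
drifting instantaneous (angular) frequency:

$$x_t = a_t \sin\varphi_t + \epsilon_t, \qquad
  \varphi_t = \varphi_{t-1} + f_t,\quad \varphi_0 = 0 .$$

Both $f_t$ and $a_t$ follow stationary AR(1) processes,
$u_t = b\,u_{t-1} + e_t$, squashed into closed ranges $r_f$ and $r_a$.
Defaults: $r_f = [0.01, 0.25\pi]$ radians/sample (0.4–10 Hz at 250 Hz),
$r_a = [0.5, 1.5]$ signal units, AR coefficients $b_f = b_a = 0.99$
(slowly wandering dynamics), innovation SDs 1, measurement noise SD 0.5.
The AR coefficients, amplitude range and noise SD are not pinned down by
the modelled phenomena and were chosen once as values that produce
realistic-looking chaotic oscillations with order-one signal-to-noise;
the innovation SDs are pure conventions because the squash renormalises
scale.

**The range squash.** How the AR series is confined to its range is a
design choice. We use an affine squash: the series is standardised by its
*analytic* stationary moments (mean 0, SD $\sigma/\sqrt{1-b^2}$) and passed
through a logistic sigmoid onto $[\text{lo}, \text{hi}]$. The map is
smooth, monotone (rank-preserving), stationary, and avoids the boundary
pile-up that truncation or clipping would create. Its midpoint is the AR
mean, so the constrained frequency hovers around the middle of $r_f$.

**Trial-start coherence.** Because $\varphi_0 = 0$ by definition, the
resting phase is *coherent across trials near the trial start* and only
mixes (through the spread of accumulated frequencies) after a few hundred
milliseconds. This is a property of the model, not a bug, but it matters
for interpretation: any effect that scales the ongoing oscillation early in
the trial (e.g. an amplitude modulation peaking at 64 ms) inherits a
phase-locked mean and becomes linearly decodable even though it carries "no
phase effect". Statements of the form "amplitude modulation without a phase
effect is not decodable" hold in this model only once the resting phase has
decohered; the test suite therefore places such controls $\geq 0.4$ s into
the trial.

## The response function

Every effect is timed by a gate $G(t;\tau) \in [0,1]$: zero before
$\delta_1 + \tau$, rising over $\delta_2$ samples, equal to 1 at
$t_{\max} = \delta_1 + \delta_2 + \tau$, falling over $\delta_3$ samples,
zero afterwards. Each side is
$1 - \log\!\big(1 + (d/T)^{\varsigma}\big)$ in the distance $d$ to
$t_{\max}$, with $T$ solved per side from the two boundary constraints
(exactly 0 at the window edge, exactly 1 at $t_{\max}$):
$T = \delta/(e-1)^{1/\varsigma}$, and both additive constants equal 1. The
published piecewise conditions carry "−1" sample offsets whose literal
reading is inconsistent (the onset appears twice in the final condition);
fixing the function by its boundary constraints on the closed support
$[\delta_1+\tau,\ \delta_1+\delta_2+\delta_3+\tau]$ reproduces the stated
bounds and the stated meaning of $\delta_3$. Shape exponents default to
$\varsigma_1 = 2$, $\varsigma_2 = 4$. A faster-decaying Gaussian-kernel
("exponential") side is available; its kernel width is set to a third of
the window (so the edge sits three kernel widths from the peak) and the
kernel is renormalised to meet the same two boundary constraints exactly.

Latency jitter adds a $\mathrm{Uniform}(0, \sigma_{\delta_1})$ draw to the
base latency — one shared draw per trial ("absolute") or an independent
draw per channel ("relative") — rounded to the nearest sample because the
gate is evaluated on the integer sample grid. Per-channel deterministic
latency offsets (`channel_latency`) implement latency *diversity* across
channels, which is distinct from jitter.

## The four effects

* **Phase reset + entrainment.** Before $t_{\max}$ the phase update blends
  the resting increment with the polar gradient to a trial-specific target
  phase (von Mises around the condition mean; the SD→concentration map
  matches resultant lengths, $A(\kappa) = e^{-\sigma_\varphi^2/2}$). The
  gradient pull continues until $t_{\max}$, after which the update blends
  the resting increment with a target (entrainment) frequency. With a gate
  that reaches 1 and zero target spread, every trial's phase equals the
  target exactly at $t_{\max}$.
* **Additive oscillation.** A gate-damped sinusoid with condition-specific
  amplitude, frequency and phase. By default its phase code is anchored at
  stimulus onset (`phase_ref = "onset"`), which gives the code its natural
  reading as "phase at onset". For experiments that manipulate the phase
  *relation* between the oscillation and the slow response, the code can be
  anchored at the gate peak (`phase_ref = "tmax"`): with diverse
  frequencies and latencies the oscillation's sign at the response peak is
  otherwise channel-dependent, and "in-phase versus anti-phase" would be
  ill-defined.
* **Amplitude modulation.** $a_t = (1 + g_t m)\,a^{rest}_t$: a 10%
  increment at the peak for $m = 0.1$, fivefold for $m = 4$.
* **Additive slow response.** $z_t = g_t s$, with $s$ drawn once per trial
  and channel from $N(\bar z_k, \sigma_z)$. Drawing once (rather than per
  time point) is what makes this component *slow*: a scaled gate, not
  noise. Its own gate defaults to a ~100 ms rise and a decay vanishing
  around 800 ms.

Channels are stimulus-relevant or not; relevant channels respond per trial
with probability $\theta$ (Bernoulli, independent across trials and
channels). Non-responding channels emit exactly their resting signal: with
equal seeds, their samples are bit-identical to a no-effect run, because
the per-trial RNG draws the resting components first and in a fixed order.

With two conditions, `in_phase_fraction` splits the relevant channels into
a group whose oscillatory condition code is aligned with the slow-response
code and a group using the condition-swapped oscillatory parameters
("anti-phase"), operationalising the sign convention
$\mathrm{sign}(\gamma_1-\gamma_2) = \mathrm{sign}(\bar z_1-\bar z_2)$.

## Decoding

One linear discriminant per training time point, on the raw channel values
at that sample (no window), standardised with training-fold statistics
only. The pooled covariance is shrunk towards the scaled identity with a
Ledoit–Wolf-style analytic intensity, which keeps 32-channel fits stable in
small folds; with shrinkage forced to zero the decoder reproduces a
reference LDA implementation exactly (tested). Folds are stratified by
condition; the default is 10-fold, the number of folds being unstated in
the modelled analyses. Accuracy is the proportion correct over held-out
trials (two balanced classes, chance 0.5), and entry $(t, t')$ of the TGM
averages it over folds for training time $t$ and testing time $t'$. A
deliberate-leakage variant (resubstitution) exists purely as a regression
control: it must inflate accuracy on null data, and does.

## TGM features

* `t_star`: earliest maximiser of the diagonal.
* `vertical_slice`: row `t_star` of the TGM (the generalisation profile of
  the best decoder).
* `late_width`: the longest contiguous run of diagonal accuracy above
  chance + 0.05 within the last 40% of the trial. "Broadening" is described
  but never quantified in the modelled analyses; run length above a fixed
  offset is the simplest monotone operationalisation. The 0.05 offset is
  roughly two binomial SEs at the default reduced scale.
* `row_periodicity`: rows are mean-detrended, the periodogram is averaged
  over rows, and the statistic is the largest non-DC peak as a fraction of
  total power, together with its frequency. An injected row sinusoid is
  recovered to ±1 frequency bin (tested).

## Study scales and the experiments

Full scale follows the reference conditions: 250 trials × 250 samples
(1 s at 250 Hz) × 32 channels, all relevant, $\theta = 1/6$, endogenous
frequency 0.01–0.25π rad/sample. The chance-level null (all effects
disabled) runs at full scale. The contrast experiments run at a reduced
scale — 100 trials × 125 samples (1 s at 125 Hz) × 16 channels, effect
frequencies 0.1–0.2 rad/sample, latencies 0–160 ms — chosen so each
experiment completes in seconds while keeping the contrasts far above
their noise floors; the vignette's numbers and the tests use exactly these
scales.

Design notes per experiment:

* **Periodicity contrast (uniform vs diverse frequencies/latencies).** The
  rise/fall durations of the oscillatory response are not printed for this
  comparison in the modelled analyses. With the sweep-optimum fall
  (0.09 s) the oscillatory support is shorter than one oscillation period
  and *no* configuration can express periodic revisitation. The contrast
  therefore uses a long fall (0.64 s), under which the uniform
  configuration shows the expected chequer (dominant row-spectrum peak at
  the response frequency) and the diverse configuration suppresses it.
* **Broadening.** Slow-response condition difference
  $|\bar z_1 - \bar z_2| \in \{0, 0.5, 1\}$; the late-trial run length
  grows (weakly but monotonically at this scale) with the difference.
* **Coupling.** With the oscillation's condition code anchored at the gate
  peak, all-channels-in-phase yields a higher vertical-slice mean than
  all-channels-anti-phase: decoders trained at the accuracy peak weight
  channels by a mixture of the oscillatory and slow codes, which generalise
  constructively only when aligned.
* **Amplitude modulation.** Under the model's equations the modulation
  scales the *ongoing* oscillation. In an additive-oscillation
  configuration the ongoing oscillation is not stimulus-locked, so
  increasing $m$ adds condition-unspecific variance and decoding weakens —
  we measured exactly that. The enhancement experiment therefore applies
  the modulation to a phase-reset configuration, where the ongoing
  oscillation *is* the stimulus-locked component: features are present at
  $m = 0$ and grow monotonically to $m = 4$.
* **Shape-sweep recovery.** The $(\delta_2, \delta_3)$ sweep correlates
  10-run-average TGMs against a reference. As a correctness check the
  reference is itself simulated at a known truth; with sparse activations
  ($\theta = 1/6$) at reduced scale the correlation surface is noise-flat,
  so the recovery experiments use deterministic activations
  ($\theta = 1$), under which the argmax cell lands exactly on the truth
  for multiple distinct truths on a 5×5 grid. Default sweep grids of
  0.02–0.12 s cover the plausible rise/fall range.

## What the simulations do and do not show

The generator emulates: chaotic single-oscillation resting dynamics per
channel, asymptotically uncorrelated channels, probabilistic sparse
activations, latency/frequency diversity, cross-frequency coupling between
a slow component and the oscillatory response, and trial-level response
variability (latency jitter, target-phase noise, per-trial slow levels).
It does not emulate: correlated sensor noise or volume conduction (channel
mixing), multiple coexisting endogenous frequencies per channel,
non-sinusoidal (phase-asymmetric) waveforms, or coupled-oscillator
interactions between sources. Passing the simulated contrasts shows the
decoding signatures are *producible* by these mechanisms, not that real
data arise from them; conversely the fitted $(\delta_2,\delta_3)$ from the
sweep inherit all of the fixed hyperparameters of the configuration being
swept.

## Numerical details

* Determinism: one RNG stream per trial, derived from the master seed;
  datasets are bit-reproducible given a seed, and non-responding channels
  are bit-identical between effect and no-effect runs.
* Phases are stored unwrapped (integration-friendly); wrapping to
  $[-\pi,\pi)$ happens only at comparisons, and the polar gradient is the
  wrapped difference.
* $\sigma_\varphi = 0$ short-circuits the von Mises draw to the exact mean;
  tiny concentrations fall back to the circular uniform.
* Degenerate ranges (lo = hi) constrain to a constant with a warning; a
  flat TGM breaks the `t_star` tie to the earliest time with a message;
  zero-variance TGMs make correlation an explicit error.
* Covariance singularities (e.g. duplicated channels) are absorbed by the
  analytic shrinkage, with a small ridge as a final fallback.
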