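---
title: "Simulating spike-train variability: the model behind spikevar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating spike-train variability: the model behind spikevar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikevar)
```

## The generative model

`spikevar` simulates the spiking of a single cortical unit across repeated
trials of a reaching-style task. Each trial lasts `duration` ms (default
1000) and has a deterministic instantaneous firing-rate profile
$\lambda(t)$ in spikes/s: either constant, or a *task-epoch* profile that
sits at a baseline, ramps linearly to a peak starting at the target-onset
time, and stays at the peak. Trial-to-trial variability beyond Poisson
point noise is injected as a single Gaussian rate offset per trial,

$$\lambda_i(t) = \max\{0,\; \lambda(t) + \eta_i\}, \qquad
  \eta_i \sim \mathcal N(0, \sigma^2),$$

constant over the trial. Spikes are then drawn from an inhomogeneous
Poisson process with intensity $\lambda_i(t)$ by thinning: candidates from
a homogeneous process at the ceiling rate $\lambda_{\max}$, each accepted
with probability $\lambda_i(t)/\lambda_{\max}$. Thinning is exact for any
bounded intensity and trivially verifiable, which is why it is used rather
than time-rescaling inversion. With $\sigma = 0$ the process is *pure*
Poisson; with $\sigma > 0$ it is a doubly stochastic (Cox) process — the
"noisy Poisson" case.

Two modelling choices deserve comment.

* **Additive offset, not multiplicative gain.** With a per-trial additive
  offset of fixed variance, the spike-count Fano factor over a window of
  $w$ seconds is $1 + \sigma^2 w/\lambda$, which *decreases* as the rate
  $\lambda$ rises — the inverse variability–rate relation seen in motor
  and premotor cortex. A multiplicative gain ($\lambda_i = g_i\lambda$)
  would predict the opposite trend, so it is not the default; the
  `noise_spec()` abstraction is the extension point if gain noise is ever
  wanted.
* **Clipping at zero.** Rates are intensities and cannot be negative, so
  realized trial rates are clipped at zero (`clip_at_zero = TRUE` by
  default). Clipping matters once $\sigma$ is comparable to the rate: for
  $\lambda = 20$, $\sigma = 10$ spikes/s it raises the mean rate by ~0.4%
  and shrinks the offset variance from 100 to ≈ 96 (spikes/s)²; the tests
  use the closed-form clipped-normal moments as the oracle wherever this
  bias is visible (e.g. the full-window Fano is ≈ 5.8 rather than the
  unclipped 6).

## From spikes to rates: the SDF

Analyses are peri-event: `align_trials()` re-expresses spike times
relative to an event (target onset by default), and statistics are
computed on the aligned window. Each spike is replaced by a unit-area
Gaussian kernel of SD $\sigma_k$ = 30 ms — the conventional width for
reaching-task data — and the kernel sum, scaled to spikes/s, is the
per-trial spike density function. Numerically, spikes are binned to the
nearest point of a `dt` = 1 ms grid and convolved (FFT) with the discrete
kernel; the kernel is truncated at $\pm 5\sigma_k$ and renormalized so its
discrete area is exactly 1. The SDF is computed on a window padded by
$5\sigma_k$ on each side and then cropped, so spikes just outside the
analysis window contribute their kernel mass and no per-point edge
renormalization is needed. On such padded interior windows total SDF mass
matches the spike count to well under 0.5%; on the *full* trial window the
outermost ~$\sigma_k$ of the trial genuinely loses mass (there are no
spikes beyond the trial to compensate), which is an edge property of the
data, not of the estimator. Halving `dt` changes downstream NV by less
than 1%, so the 1 ms default is not a resolution bottleneck.

## The normalized variance and its calibration

The variability statistic is the regularized variance-to-mean ratio of the
SDF across trials,

$$NV(t) = \frac{k\,\varepsilon + \mathrm{Var}(SDF(t))}
               {k\,\varepsilon' + \mathrm{Mean}(SDF(t))},
  \qquad k = 0.1,\; \varepsilon = \varepsilon' = 0.01,$$

with the unbiased ($n-1$) variance. The regularizers keep the ratio
defined for silent data (all-empty trials give exactly 1).

A subtlety: for *counts* a Poisson process has variance = mean, but the
SDF is a smoothed process, and by Campbell's theorem a homogeneous Poisson
process smoothed with a unit-area kernel has
$\mathrm{Var}(SDF) = c\cdot\mathrm{Mean}(SDF)$ with

$$c = 1000\, dt \sum_j k_j^2 \;\approx\; \frac{1000}{2\sigma_k\sqrt{\pi}}
  \;=\; 9.40 \text{ spikes/s for } \sigma_k = 30 \text{ ms}.$$

The raw ratio of a smoothed Poisson process is therefore $c$, not 1. To
honor the Poisson-unity reference point while keeping the statistic's
literal form available, `nv_series()` ships three explicit modes:
`raw_eq1` (no correction), `calibrated` (default; the variance is divided
by `c` = `kernel_correction()`, so pure Poisson input has expectation 1
and additive rate noise gives $1 + \sigma^2/(c\lambda)$), and
`count_fano()`, a sliding-window count Fano factor with the same
regularizers, which needs no correction and acts as the independent
oracle — at the kernel's effective window $w_\mathrm{eff} =
2\sigma_k\sqrt{\pi} \approx 106$ ms it agrees with the calibrated NV to
within a few percent (10% is the tested bound). The correction is applied
to the variance *before* the $k\varepsilon$ regularizer is added, so the
two modes coincide exactly in the regularizer-only limit. Whether
variance-to-mean traces in the literature were implicitly calibrated is
rarely stated; keeping the modes explicit makes the choice visible instead
of baked in.

## Rate-level binning and pooling

`rate_level_nv()` relates variability to activity: time bins are assigned
by their normalized mean rate (fraction of the maximum of the trial-mean
SDF) into the levels 0.8–1.0, 0.5–0.8 and below 0.5 — the level edges are
read as fractions of the maximum — and NV samples are summarized per
level. Empty levels are reported with `n = 0` rather than dropped.
`pool_nv()` averages NV series across simulated units (pointwise mean and
standard error), mirroring how experimental variability is pooled across
neurons and movement directions.

Under the additive-offset model the expected per-level NV is
$1 + \sigma^2_\mathrm{eff}/(c\,\lambda_\mathrm{level})$, so level means
decrease as the level rate rises. A caution on power: with a task-epoch
profile (5 → 45 spikes/s, onset 400 ms, rise 200 ms, $\sigma = 5$, 500
trials) the expected top/mid/low level means are ≈ 1.07 / 1.09 / 1.32, but
the mid level occupies only the narrow slice of the ramp crossing 0.5–0.8
of maximum — roughly one kernel correlation length — so a *single*
500-trial run orders the mid and top levels correctly only ~70% of the
time, while low vs high is essentially always correct. Averaging the level
means over ~20 replicate units (as the pooled analyses do) resolves the
ordering reliably. The 200 ms linear ramp itself is a choice: motor and
premotor preparatory rate buildups are typically one to a few hundred ms,
and no canonical functional form exists, so a linear ramp of configurable
duration is used.

## Default parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_trials` | 100 | — | typical per-condition trial count; reference condition for all unity checks |
| `duration` | 1000 | ms | one trial of the reference simulation |
| baseline rate | 20 (constant), 5 (task epoch) | spikes/s | cortical baseline range |
| peak rate | 45 | spikes/s | strong preparatory response |
| `target_onset`, `rise_time` | 400, 200 | ms | onset mid-trial; ramp of typical preparatory duration |
| noise `sigma` | 10 (constant fixture), 5 (task epoch) | spikes/s | at $\lambda=20$, $\sigma=10$ gives full-window Fano ≈ 6, far enough from 1 to make the NV > 1 dichotomy unambiguous at 100 trials |
| kernel `sigma` | 30 | ms | standard SDF width for reach data |
| kernel `dt`, truncation | 1, 5 | ms, $\sigma_k$ | ms-resolution spiking; truncation below 1e-6 of mass |
| `k`, `eps`, `eps_prime` | 0.1, 0.01, 0.01 | — | regularizers of the NV statistic |

## Determinism

One root seed drives everything: `simulate_trialset()` derives per-trial
seeds as the first `n_trials` draws of `sample.int(2^31 - 1)` from the
root stream, then re-seeds per trial before drawing the offset and the
spikes. Trial *i* is therefore bit-reproducible regardless of how many
trials follow it, and the whole file workflow (spike tables, sidecars,
analysis tables) is byte-identical under a fixed seed; run logs record a
configuration fingerprint.

## What the simulations do and do not show

The generator reproduces the statistical skeleton of peri-event cortical
variability: Poisson point noise, slow trial-to-trial excitability
changes, a stimulus-locked rate increase, and the resulting NV decline
with rising rate. It deliberately omits refractoriness and spike-history
effects, latency jitter of the onset response, direction tuning,
correlations between simultaneously recorded units, and nonstationarities
across the session. Passing tests therefore validate the statistics and
their calibration on a known ground truth — they do not certify that real
cortical NV declines are *only* rate effects, and applying the pipeline to
real data inherits all the usual caveats of those omissions. Problem sizes
in the test suite (100–2000 trials, 100-seed replicate sweeps) are chosen
so Monte-Carlo bounds are tight at three standard errors while the whole
suite stays fast.
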