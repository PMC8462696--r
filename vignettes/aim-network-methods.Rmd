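---
title: "Attentional inhibitory modulation: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentional inhibitory modulation: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The circuit

`aimnet` simulates a cortical circuit in which selective auditory
attention is implemented as *disinhibition*. Each spatial or spectral
channel contains four neurons: a bottom-up input unit (IC), an excitatory
relay (E), a lateral-inhibition interneuron (I), and a second inhibitory
neuron (I2) that represents top-down control. A cortical readout neuron
(C) integrates the E population. Within a channel, IC drives E, E drives
I, and I2 inhibits both I and E; across channels, I inhibits the E
neurons of *other* channels. With every I2 tonically active the I layer
is clamped and the readout integrates all channels (monitor mode).
Silencing one channel's I2 releases that channel's E and I; the released
I then suppresses all competing channels — attention manifests largely
as *suppression*, with focal facilitation at the attended channel.

All five populations are leaky integrate-and-fire neurons,

$$C\,\frac{dV}{dt} = g_{leak}(E_{leak} - V) - i_{syn} + i_{app},$$

with a spike-and-reset rule (`V > V_thresh` records a spike and sets `V`
to `V_reset`; there is no refractory period) and double-exponential
conductance synapses

$$g(t) = g_{syn}\,\big(e^{-t/\tau_D} - e^{-t/\tau_R}\big)\,u(t),
\qquad i_{syn} = g(t)\,(V - E_{syn}),$$

with the inhibitory preset $\tau_R = 1$ ms, $\tau_D = 10$ ms,
$E_{syn} = -80$ mV and the excitatory preset $\tau_R = 0.4$ ms,
$\tau_D = 2$ ms, $E_{syn} = 0$ mV. Kernels superpose linearly across
presynaptic spikes and are *not* peak-normalised: `g_syn` multiplies the
raw kernel, whose peak (≈0.54 excitatory, ≈0.70 inhibitory) depends on
the time constants. Units are mV, nA, µS, nF and ms throughout, so
`tau_m = C/g_leak` is 10 ms at the default `C = 1` nF,
`g_leak = 0.1` µS.

Cellular defaults (`cell_params()`): `E_leak` −70 mV, `V_thresh` −55 mV,
`V_reset` −75 mV, `V_spike` +50 mV (cosmetic, shown in voltage traces
only), `i_app` 0 nA, noise 0. Per-simulation conductances and tonic
currents come from `aim_table2()`, which packages one column per
protocol; for the spectral builds it also carries the connectivity
kernels: a Gaussian excitatory convergence (width `sigma_EC`, peak
`g_EC`) and a thresholded inverted-Gaussian lateral inhibition that is
exactly zero within `2*sigma_IE` of the source channel and rises to
`g_IE` beyond. We read the duplicated strength row of the
parameter table as `g_EC` and `g_IE` (both 1), and we use the literal
thresholded form of the inhibition kernel — zero inside the dead zone,
`1 − exp(−d²/2σ²)` outside — because the monaural-attention protocol
requires strong inhibition immediately beyond the dead-zone edge (the
two talkers' fundamental-frequency channels are a single grid step
apart).

## Integration scheme

The simulator advances all populations on a fixed step (default
`dt = 0.01` ms at the API level; the packaged protocols use 0.05 ms,
eight steps per excitatory rise time). Synaptic gating is carried by two
per-connection decay traces whose difference reproduces the
double-exponential exactly on the step grid; spikes emitted at step *n*
enter the traces at the end of step *n* and affect currents from step
*n*+1.

The membrane equation is integrated with **exponential Euler**
(conductances held constant within a step),

$$V \leftarrow V_\infty + (V - V_\infty)\,e^{-g_{tot}\,dt/C},$$

rather than forward Euler. This is a deliberate numerical choice: with
spike-and-reset and no refractory period, a strongly driven population
fires near once per step, and the summed inhibitory conductance it
delivers reaches hundreds of µS — the effective membrane time constant
`C/g_tot` then drops far below any affordable `dt`, where forward Euler
oscillates and produces spurious spikes in neurons that should be
clamped silent. Exponential Euler is unconditionally stable, exact for
constant drive (the subthreshold step response matches the RC closed
form to machine precision), and confines the potential to the span of
the reversal potentials, which is also a stated invariant of the model.
The unit-level `membrane_step()` exposes the plain forward-Euler update
for didactic use and closed-form testing.

A consequence of spike-and-reset without refractoriness is worth
stating plainly: a single input spike through a µS-scale synapse re-fires
its target for as long as the kernel exceeds the ~0.03 µS re-firing
threshold (≈8 ms), so the "relay" configuration *amplifies* — one input
spike yields on the order of ten output spikes, and strongly driven
cells saturate near one spike per step. The qualitative circuit logic
(inhibition gating saturated relays) survives; absolute rates are
therefore reported as what they are, and the companion calibration
property (tonically active I silences E exactly) holds. A one-to-one
rate relay would require either a refractory period or non-superposing
synapses; neither is part of this model, and the relay calibration is
the one place where that is visible.

## The subcortical front end

Stimuli are generated in-process: seeded white Gaussian noise, pure
tones, and harmonic-complex "speech surrogate" tokens — a harmonic
series at a fundamental `f0` with a glottal-like −6 dB/oct source
rolloff, three formant resonances (defaults 500/1500/2500 Hz;
concurrent talkers use different sets, as different voices and
utterances do), random harmonic phases, and a full-depth syllabic
envelope (squared raised sine at a rate drawn from 3–5 Hz, giving
burst–gap alternation like running speech). The surrogates reproduce
the properties the segregation analyses need — a well-defined f0 and a
sparse, speech-like envelope — without lexical content; the
conventional fundamentals are 115 Hz ("male") and 220 Hz ("female").
The source rolloff matters: without it the fundamental region carries
no energy and the f0-channel analyses are vacuous; the envelope
sparsity matters because time–frequency tiles containing both talkers
carry composite binaural cues that match no spatial channel.

Spatialisation uses parametric binaural cues instead of measured HRTFs:
the spherical-head (Woodworth) interaural time difference
`ITD = (r/c)(θ + sin θ)` with r = 8.75 cm (656 µs at ±90°), and a
frequency-dependent interaural level difference `ILD = 5√(f/kHz)·θ/90°`
dB, applied as an exact fractional delay and a zero-phase level shelf
in the frequency domain. The ILD is linear in azimuth so that
neighbouring directions near the poles remain resolvable, where a
sin-law would compress them onto nearly identical levels. A hook accepts measured
HRTF impulse-response pairs where cue fidelity matters.

The periphery is a 4th-order gammatone filterbank on 64 centre
frequencies spaced uniformly on the ERB-number scale from 200 to
8000 Hz, applied by FFT convolution with the analytic impulse response
and peak-normalised at each centre frequency; envelopes are half-wave
rectified and low-passed at 150 Hz (2nd-order Butterworth). The
midbrain stage assigns each 20 ms time-frequency tile to the spatial
channel whose preferred cue best matches the tile's observed cue, *and
drops the tile if the match is worse than half the cue distance to the
winning channel's nearest neighbour*. Fine-structure ITD
(cross-correlation lag) is used below 750 Hz — the highest frequency at
which the lag is unambiguous given the maximum head delay — and ILD
(envelope energy ratio) above. The matching tolerance implements the
tile-matching semantics of the midbrain stage: tiles dominated by one
source match their channel; tiles where two talkers mix into a
composite cue match no channel. Masks are winner-take-all, so per-tile
mask mass never exceeds 1.

Masked envelopes drive inhomogeneous Poisson spike trains
(`encode_ic()`): each IC unit is an ensemble-rate proxy, with rate
`rate_scale · (env/env_ref)^compress` clipped at `max_rate`. Protocols
that bypass spatial hearing present the input dichotically (single
spatial channel, no masks). For the azimuth-tuning protocol the
64-channel input is collapsed to one Poisson train per spatial channel
whose rate profile is the summed rate across frequency channels, so the
expected collapsed count equals the total input count.

## Operating points

The parameter table fixes conductances and tonic currents but
not the input rate scale; the model only expresses the described
behaviours in particular drive regimes, which the packaged configs pin:

* *Spatial tuning* (`run_lee`): `rate_scale = 60` sp/s per frequency
  channel (≈1 kHz collapsed). The attended channel's tonically released
  I neuron (~118 sp/s, ≈3 µS mean conductance) can veto this drive, so
  attending sharpens; at several-fold higher drive bottom-up input wins
  and attention has no effect.
* *Spectral tuning* (`run_atiani`, `run_fritz`): `rate_scale = 800`
  sp/s. The E population sits just below the threshold imposed by its
  tonic I2 inhibition, so firing is intermittent rather than saturated
  and tuning curves are graded. The far-target variant needs the target
  at least `2*sigma_IE` from the best frequency (packaged: 5 kHz); the
  hotspot protocol needs it *inside* the dead zone (packaged: 1.2 kHz)
  so that the E→E route and the best-frequency response are not
  annihilated by the released I neuron.
* *Cocktail party* (`run_cocktail_spatial`, `run_separation_sweep`):
  `rate_scale = 800` sp/s; each filterbank channel is an independent
  lane of the 5- or 7-channel spatial circuit with its own readout.
  Correlations are 2-D Pearson coefficients between per-channel rate
  matrices (5 ms window) of the mixture run and single-talker reference
  runs with independent Poisson draws.
* *Monaural F0* (`run_monaural_f0`): `rate_scale = 1200` sp/s with
  compressive exponent 0.4, the regime in which passive activity is
  time-shared across several channels rather than winner-take-all.
  f0-channel spike counts are measured on the E population: the
  per-channel cortical convergence (`sigma_EC` = 0.05 kHz) is wider
  than the ~20 Hz channel spacing at the low edge of the ERB grid and
  cannot resolve the two talkers' channels.

Every protocol prepends a 20 ms settling period (tonic populations reach
steady state in 2–3 membrane time constants) and analyses spikes after
it; stimuli are followed by a 30–40 ms tail so synaptic decays are
captured. Repeat counts default to n = 20 with a `fast` mode at n = 5.
Probe sets are the full grids (17 azimuths; all 64 tone frequencies).

## What the tests do and do not show

The synthetic front end reproduces cue geometry, spectral structure and
envelope dynamics, not the acoustics of real rooms or real speech:
reverberation, microphone noise, natural prosody and lexical content are
absent, and the segregation stage sees exactly the cue model that
spatialised the stimuli. Passing protocols therefore demonstrate the
circuit-level claims — disinhibition-gated sharpening, suppression,
hotspot emergence, monitor/select/switch behaviour, spatial release from
masking — under idealised inputs, and say nothing quantitative about
performance on natural recordings.

Three behaviours the model is meant to show are *not* reproduced, for reasons the
package documents rather than hides (all trace to the superposing
synapse plus the absence of refractoriness, which make strongly driven
populations saturate, and to hard winner-take-all tile masks):

* the "relayed and combined with a similar firing rate" calibration —
  the relay configuration amplifies instead (see above);
* the monaural percent-change pattern relative to passive — the passive
  state carries no spikes in the two f0 channels under winner-take-all
  competition, so a percent change from passive is undefined there,
  even though the attentional boost/suppression pattern itself is
  clean and complete;
* the monotone rise of the attended-talker correlation with talker
  separation — with one scalar cue per tile, tiles containing both
  talkers fall to intermediate channels, so the attended channel's
  *completeness* falls as the talkers separate, and on a Pearson
  metric losing own-talker tiles costs more than excluding
  other-talker tiles gains; the monitor control declines identically,
  identifying this as a density artifact of the metric rather than a
  failure of selection (which is robust: the attended talker wins the
  correlation comparison in 100% of repeats).

An alternative reading of the synaptic equation (gating by time since
the *most recent* presynaptic spike only, which caps every synapse at
its single-kernel peak) would bound conductances and soften both
effects; it is noted as a limitation and a candidate source of the
divergence, but the conventional superposition reading is implemented
throughout.

## Reproducibility

All randomness flows from a single integer seed per protocol through a
deterministic sub-seed map (stimulus seeds, Poisson encoding seeds,
collapse seeds are all derived); two runs with the same config are
bit-identical, and each result carries a manifest (config snapshot,
seed, package version) sufficient to re-execute it. Simulations with
noise amplitude 0 consume no randomness at all.
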