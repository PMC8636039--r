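---
title: "From neural masses to BCI classifiers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From neural masses to BCI classifiers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`simbci` implements a complete simulation-to-application chain for
electroencephalography: a three-population neural mass model of the
postsynaptic membrane potential, an equivalent-dipole three-shell forward
model producing multichannel scalp EEG, a conditional GAN that converts the
simulated signals into "practical" labelled EEG, and the common-spatial-
pattern (CSP) classification pipeline that measures whether the converted
signals improve classifier training when real data are scarce.  This
vignette explains the models, their parameters, and every place where the
design was genuinely open.

## 1. The neural mass model

Each spectral band is produced by one Wendling-type population: four coupled
second-order synaptic blocks describing pyramidal cells, excitatory
interneurons, slow (dendritic) and fast (somatic) inhibitory interneurons.
With state variables $y_0 \dots y_3$ (postsynaptic potentials, mV),

$$
\begin{aligned}
\ddot y_0 &= A a\,S(C_2 y_1 - C_4 y_2 - C_7 y_3) - 2a\dot y_0 - a^2 y_0\\
\ddot y_1 &= A a\,\big(S(C_1 y_0) + P(t)/C_2\big) - 2a\dot y_1 - a^2 y_1\\
\ddot y_2 &= B b\,S(C_3 y_0) - 2b\dot y_2 - b^2 y_2\\
\ddot y_3 &= G g\,S(C_5 y_0 - C_6 y_2) - 2g\dot y_3 - g^2 y_3
\end{aligned}
$$

with the firing-rate sigmoid $S(v) = 2e_0/(1+e^{r(s_0-v)})$ and the
population output $V(t) = C_2 y_1 - C_4 y_2 - C_7 y_3$ (the summed pyramidal
input, the conventional observable for this model family).  Shared
constants: $C_1{=}135$, $C_2{=}C_7{=}108$, $C_3{=}C_4{=}33.75$, $C_5{=}40.5$,
$C_6{=}13.5$, $e_0{=}2.5\,\mathrm{s^{-1}}$, $s_0{=}6$ mV, $r{=}0.56$.

Two modelling points deserve emphasis, because both are required for the
intended band-tuned behaviour to emerge at all:

* **Units of $r$.**  The slope is interpreted as $0.56\ \mathrm{mV^{-1}}$,
  consistent with $s_0$ in millivolts and with the classical literature; a
  literal per-volt reading makes the sigmoid essentially linear and kills
  every feedback loop.
* **The fast-inhibition input.**  The fast somatic interneurons receive the
  slow interneurons' *postsynaptic potential*, $C_5y_0 - C_6y_2$ — the
  original five-state Wendling wiring condensed into four states (the slow
  PSP at the fast cells obeys the same dynamics as $y_2$, so no extra state
  is needed).  A nested-sigmoid reading, in which $C_6$ multiplies a firing
  *rate* bounded by $2e_0 = 5\ \mathrm{s^{-1}}$, injects up to
  $\sim 67$ mV of inhibition, silences the fast loop, and leaves all three
  parameter sets overdamped with spectral peaks at 1–2 Hz.  We verified this
  by both direct simulation and linearization before adopting the PSP
  wiring.

### Band tuning, bistability and ignition

Per-band gains and rates (`nmm_band_defaults()`):

| band | A (mV) | B (mV) | G (mV) | a (1/s) | b (1/s) | g (1/s) |
|------|-----|-----|----|-----|----|-----|
| low (4–12 Hz) | 2.7 | 3.2 | 27 | 40 | 20 | 300 |
| medium (12–30 Hz) | 5.2 | 4.5 | 43 | 85 | 30 | 350 |
| high (>30 Hz) | 5.6 | 3.8 | 75 | 110 | 40 | 400 |

The exogenous drive is Gaussian, mean 60 s⁻¹ and variance 100, sampled once
per integration step and held constant within the four Runge–Kutta stage
evaluations (this avoids committing to a stochastic-integration order and
keeps runs bit-reproducible).  Integration is fixed-step RK4 at
$\Delta t = 1$ ms, matching the 1000 Hz recording rate; the first 2 s are
discarded as burn-in from the all-zero initial state.

The high-band parameter set is *bistable* under this drive: a stable
$\sim$33.5 Hz gamma limit cycle coexists with a quiescent fixed point, and
the zero state lies in the quiescent basin.  `integrate_population()`
therefore adds a deterministic +150 s⁻¹ "ignition" drive during the first
0.5 s of the (discarded) burn-in, which selects the active attractor for
every band.  Without it the high population never leaves its fixed point
and no gamma peak exists; with it the three bands peak at roughly 7–8 Hz,
20–22 Hz and 33.5 Hz under Welch estimation (2-s Hann segments, 50%
overlap — chosen as a stable default; the band placement is insensitive to
the exact estimator).

Richardson comparison on noise-free input confirms 4th-order convergence,
with the caveat that the asymptotic regime requires
$\Delta t \lesssim 0.5$ ms (the fastest rate constant is
$g = 350\text{–}400\ \mathrm{s^{-1}}$, so at 1 ms steps the error ratio
overshoots 16); the order test therefore runs at
$\Delta t = 0.5\,\mathrm{ms} \to 0.125$ ms.

## 2. The volume conductor

The mixed source is attached to an equivalent current dipole and propagated
through an isotropic three-shell head.  Two forward engines share one
contract:

* `analytic_three_sphere_potential()` — Legendre-series solution for
  concentric spheres (radii 0.087/0.092/0.100 m; conductivities
  0.33/0.0042/0.33 S/m, the classical 1:1/80:1 ratio; both configurable).
  The per-degree radial systems are solved with row/column equilibration
  (raw powers of the radii are numerically singular by degree ~40), and the
  series is truncated adaptively at $10^{-9}$ relative increment.  The
  homogeneous limit reproduces the classical insulated-sphere closed form
  to $10^{-9}$, and the primary-source expansion was validated termwise
  against the exact free-medium dipole potential.
* `bem_leadfield()` — centroid-collocation boundary element method on
  procedurally generated icosphere meshes (1280 triangles per surface at
  the default subdivision), van Oosterom–Strackee solid angles, deflation
  of the singular constant mode, and inverse-distance electrode
  interpolation from the three nearest scalp elements.  Median relative
  electrode-potential error against the analytic oracle is ~2.8% over
  random dipoles up to 0.7 eccentricity, so the isolated-skull correction
  was not needed at this mesh density.

Class dipoles are radial and placed at template coordinates — frontal
(0, 0.06, 0.05) m for both brow expressions, and mirrored motor-cortex
positions (∓0.04, 0.01, 0.06) m for the smirks (contralateral control) —
since only regions, not coordinates, are prescribed by the paradigm.  The
30-channel 10–20 montage is generated on the scalp sphere from idealized
18°-step angles; CPz is the recording reference (that channel is
identically zero before sensor noise), AFz the ground.

## 3. The synthetic recording protocol

`generate_recordings()` emulates the experiment the package targets: 8
subjects × 4 microexpression classes (raise-brow, furrow-brow, left-smirk,
right-smirk) × 4 sessions × 6 trials, 3 s countdown + 4 s task + 2 s rest,
30 channels at 1000 Hz.  Only the task segment is synthesized; countdown and
rest are zero-padded at EDF export for timing fidelity.

The stated world of the generator:

* **Class structure.**  Each class has a dipole (above) and a population
  weight triple; the shipped weights are the reference band-energy fractions
  (raise-brow 0.1190/0.3332/0.5478, furrow-brow 0.0845/0.0487/0.0357,
  left-smirk 0.0887/0.0574/0.0467, right-smirk 0.0996/0.0550/0.0509).
  Population outputs are standardized to unit variance and mixed with
  $\sqrt{w_k}$ scaling so the weights are interpretable as band-*energy*
  fractions; because the populations' linewidths straddle the band edges,
  the mixing energies are additionally calibrated against the realized
  band-confinement matrix of each trial's population outputs, which makes
  the configured weights recoverable from the data to within a few percent
  (the parameter-recovery invariant).
* **Amplitude.**  One calibration per subject sets the global RMS to a
  nominal 10 µV; relative class amplitudes are preserved (they carry class
  information, as they would in real recordings).
* **Noise.**  Sensor noise is a half-white, half-$1/f$ mixture, spatially
  independent, at a global floor of `amplitude_uV * 10^(-SNR/20)`.  A
  *global* floor matters: deriving the noise from per-trial signal power
  would leak class identity into the noise level and fake separability at
  arbitrarily low SNR (we observed exactly that failure mode and removed
  it).
* **Subject variability.**  Multiplicative jitter (default ±10%, uniform)
  on the nine band gains and the three weights.
* **Determinism.**  Every trial/channel/band derives its own seed from the
  scenario seed through a fixed integer chain; identical configuration and
  seed give identical datasets.

What a green test on this world does *not* establish: realism of facial-EMG
contamination, ocular artifacts, inter-session nonstationarity beyond fresh
noise/NMM realizations, or any claim about the authors' subjects.

## 4. The conditional GAN converter

The generator maps a whole simulated trial (timestamps × channels, scaled
per channel to (−1, 1) by min–max over the simulated set) plus a one-hot
class label to a converted trial: the label is embedded by a dense layer to
one extra channel, followed by five same-padding stride-1 1-D convolutions
(filters 64/52/42/36/channels, kernels 64/32/16/6/2, LeakyReLU 0.2, final
tanh).  The discriminator judges 100-ms windows (valid-padding convolutions
16/8/4/2 with kernels 32/16/8/4, flatten, dropout 0.4, sigmoid), also
label-conditioned.  Training alternates one RMSprop step for the
discriminator (64 real windows, target 1, plus 64 windows sliced at random
offsets from converted trials, target 0) and one for the stacked
generator→slicer→discriminator (target 1), with binary cross-entropy,
learning rates 0.0008/0.0004, clip value 1.0, decay 10⁻⁸, 200 iterations.
All passes are explicit matrix code over compiled im2col/GEMM kernels and
were verified against finite differences.

Open points resolved here: LeakyReLU slope 0.2; discriminator padding
"valid"; batch 64; fake windows drawn at uniformly random offsets from a
small set of trials per iteration (`trials_per_iter`); the stray duplicated
optimizer rows in the published discriminator table are read as
discriminator lr 0.0008 / stacked lr 0.0004 with a sigmoid output.
`convert()` inverts the min–max normalization of the real templates and, by
default, additionally matches each channel's pooled RMS to the template
session (the tanh head habitually under-uses its range at these iteration
counts, which otherwise inflates amplitudes ~3×).

## 5. The classification pipeline

All signals are linearly detrended and band-passed 2–55 Hz with a
zero-phase 4th-order Butterworth cascade (second-order sections; the exact
DC nulls of the sections are supplemented by removing the tiny
edge-transient residual mean).  Trials are sliced into non-overlapping
100-ms windows; one-vs-rest CSP (per-window trace-normalized covariances,
ridge 10⁻⁶·trace, m = 3 pairs) yields 24 log-variance features; classifiers
are nearest-neighbor (k = 1 and 10), a CART tree, LDA, linear and
Gaussian-kernel SVMs (pegasos), bagged trees and a random-subspace KNN
ensemble — the usual BCI toolbox families, with defaults recorded in the
report.  Validation is stratified 5-fold; testing uses the held-out
sessions 2–4; `compare_conditions()` reports signed per-classifier deltas
(augmented − real-only, improvement positive) and an equal-variance
two-sample t-test over the pooled validation+test accuracies.

## 6. The augmentation result, honestly

On the low-template scenario (one template session, −5 dB SNR, 8-channel
desk-scale montage) the augmented-vs-real comparison is *negative* in this
package's world: across seeds, training steps (200–1600), and mixing
settings, adding converter output at 1:1 window ratio costs roughly 3–6
accuracy points on average.  The converted trials do carry class structure
(training on them alone gives 25–48% transfer accuracy against a 25%
chance level), but their residual bias — distorted spatial covariance and
class-conditional amplitudes — outweighs any variance reduction, because a
single template session already supplies 240 windows for a 24-dimensional
feature space.  This is a known failure mode of GAN-based augmentation:
converted samples share the converter's feature bias, so classifiers
overfit to it.  The corresponding acceptance assertion is deliberately left
failing rather than weakened, and the class-balance half of the check
(recall spread under augmentation within 10 points of real-only) passes.

## 7. Numerical and testing notes

* Determinism: every stochastic routine takes or derives an explicit seed;
  RNG state is restored after internal use.
* Welch PSD: one-sided, Hann, mean-detrended segments; 2-s segments by
  default (0.5 Hz resolution), 4-s where fine peak ordering matters.
* Degenerate inputs: constant windows floor their variance at 10⁻¹² before
  the log; zero-moment dipoles, non-nested meshes, open or flipped surfaces,
  missing montage channels and sub-Nyquist band edges are hard errors.
* Desk scaling in the acceptance suite: the GAN criteria run on an
  8-channel montage subset with 1-s task segments and 2–4 trials per
  iteration; the BEM oracle runs at the stated 1280-triangle meshes; the
  heavy augmentation sweep uses 10 seeds.  Budgets: the full suite runs in
  roughly a quarter hour on one CPU.
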