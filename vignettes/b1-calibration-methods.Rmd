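---
title: "Complex-valued neural B1+ mapping and pTx pulse design: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex-valued neural B1+ mapping and pTx pulse design: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ptxmap)
```

# The calibration problem

At ultra-high field (7T) the transmit RF field B1+ is strongly
inhomogeneous across the head: the RF wavelength in tissue (~12 cm) is
comparable to the object, so the per-channel fields of a parallel-transmit
(pTx) array interfere, and the default circularly-polarized (CP+) drive
produces flip-angle variations of 25% and more. Subject-specific pTx
calibration — measuring channel-wise B1+ maps, then designing RF shims or
kt-point pulses — costs scan time. `ptxmap` implements a calibration chain
that replaces the B1+ measurement with a learned estimate: complex-valued
encoder-decoder networks map the multi-channel localizer images (acquired
anyway at the start of every session) to channel-wise complex B1+ maps,
which then drive standard static and dynamic pulse design.

The package contains five cooperating parts: complex network primitives
with hand-derived backpropagation, the network architecture and trainer,
the B1+ quality metrics, a synthetic phantom/coil simulator that generates
paired training libraries, and the downstream pulse-design tools (static
phase-only shimming, kt-point design, hard-pulse Bloch simulation).

# The network

The mapping network is a U-Net-style complex encoder-decoder. Inputs are
nine channels per 2D slice: eight complex receive-channel localizer
images plus their root-sum-of-squares magnitude. Outputs are eight
complex transmit-channel B1+ maps. Four encoder stages apply two 3x3
stride-1 complex convolutions each, followed by a 3x3 stride-2 complex
convolution for downsampling; feature maps start at 16 and double per
stage (16/32/64/128), so a 128x96 input reaches an 8x6 bottleneck.
The decoder mirrors the encoder with stride-2 transposed complex
convolutions and skip connections; after the shared decoder trunk, each
transmit channel owns a head of four convolutions with decreasing feature
maps (16, 8, 4, 1). All complex convolutions use true complex
multiply-accumulate arithmetic, and the activation is ModReLU,
`ReLU(|z| + b) exp(i angle(z))`, with a real learnable magnitude bias per
channel (zero-initialized: the identity on nonzero magnitudes).

Design choices where the architecture was genuinely open:

* **Head split vs. full decoder split.** Splitting only the heads (the
  default) shares the expensive decoder trunk; the literal per-channel
  decoder reading is available via
  `network_config(full_split_decoder = TRUE)`. Both satisfy the same
  shape contract and are tested.
* **Skip connections** concatenate encoder features at matching
  resolution (the standard U-Net wiring) rather than adding them.
* **Dropout** (rate 0.1 by default, configurable) is applied at the end
  of every encoder/decoder stage and at the bottleneck; real and
  imaginary parts are masked jointly.
* **Input gain.** Normalized localizers have in-mask RMS around 0.2. A
  fixed input gain of 5 (part of the architecture configuration) brings
  first-layer activations to unit scale. Without it, the learnable
  ModReLU biases — whose Adam steps are of order the learning rate
  regardless of their gradients — clamp a large fraction of units dead
  (`|z| + b <= 0`) before the weights can adapt. For the same reason the
  ModReLU biases are updated with gradient-proportional momentum-SGD
  steps rather than Adam's normalized steps.
* **Real baseline.** `build_real_unet()` realizes the same topology with
  real arithmetic and ReLU on split channels (17 in, 16 out); a feature
  multiplier scales its parameter count. It trains with a masked MSE on
  the split channels.

# The training loss

Training minimizes a perpendicular-decomposition loss over all voxels of
each slice. With target `T` and prediction `P`, per voxel:

* perpendicular term `|Re(T) Im(P) - Im(T) Re(P)| / max(|T|, eps)` — the
  length of the component of `P` perpendicular to the target phasor,
  penalizing phase error symmetrically;
* along-target term `lambda * (Re(P conj(T))/max(|T|, eps) - |T|)^2` —
  the signed parallel-component error;
* voxels with vanishing target (outside tissue, where acquired maps are
  zero) contribute the continuous completion `lambda * |P|^2`.

Two numerical properties motivated the signed parallel form over the
plain magnitude difference `(|T| - |P|)^2`: the loss must discriminate
sign (`P = -T` is a gross error, yet has equal magnitude and zero
perpendicular component), and it must provide a well-defined descent
direction at `P = 0`, where the gradient of `|P|` has no direction. With
the signed form the loss is zero iff `P = T`, and training cannot park in
the zero-output saddle. `lambda` (the weighting between the two terms,
not printed by the source work) defaults to 1 in `perp_l2_loss()`; the
scaled-down training profile uses `lambda = 10`, which balances the
magnitude pull against the unit-scale perpendicular subgradients over the
short schedule.

Optimization is Adam with batch size 1 (one slice per step). The
full-scale schedule is a learning rate of 1e-4 decaying by 0.19% per
epoch for 1000 epochs. The desk-scale profile (64x48 grid, 8 base
features; see below) compresses a ~100x shorter step budget into a
matching decay envelope: learning rate 2e-3 decaying 4.5% per epoch,
along-target weight 10 (probed once over a small schedule grid; larger
rates diverge even with gradient clipping, which is available via
`train_config(clip_norm = ...)` but off by default). Training is
fully seeded (shuffling, dropout), so two runs with the same seed produce
identical histories and weights.

# Cross-validation and normalization

Fifteen subjects are randomly partitioned into five subject-disjoint
folds of three; each fold holds one subset out and trains on the other
twelve subjects, and the same partitioning (fixed by the seed) is reused
across network variants. Orientation-specific models restrict the
training slices (`orientations = "transversal"` etc.) but are always
evaluated on all orientations of the held-out subjects.

Targets are normalized per subject by the 99th percentile of the in-mask
CP+-combined B1+ magnitude (so combined magnitudes are ~1 and channel
magnitudes ~0.12). Localizers are scaled by one library-wide constant
(the median over subjects of their maximum combined magnitude), not per
subject: on a scanner the transmit voltage and receiver gain are fixed
across a study, so localizer intensity carries the absolute field scale,
and a per-subject input normalization would erase exactly the
information the network needs to recover the per-subject target scale
(in our phantoms the ratio of the two per-subject scales varies by
about 11%, which would put a floor of that order on the achievable
relative magnitude error). Scales are stored in the library and the
checkpoint, and `denormalize_b1()` inverts the target scaling.

# The phantom simulator

`generate_library()` emulates the structure of an acquired 15-subject
library: per-subject ellipsoidal head phantoms (semi-axes ~7/9/8 cm,
+/-10% seeded jitter, smooth proton density), an 8-element transceiver
loop array on a 14 cm-radius cylinder (seeded gain and azimuth jitter,
shared across subjects like a real coil), and whole-head multi-slice
stacks in transversal, sagittal and coronal orientation (8 mm gap,
12-18 slices at full scale depending on head size).

The analytic field model is deliberately simple but poses the real
learning problem:

* per-channel magnitude: loop falloff `g_k (a/(a + d_k))^2` with the
  element distance `d_k` and falloff length `a = 5 cm`;
* per-channel phase: element drive azimuth plus a travelling-wave term
  `k_w d_k`, mimicking wavelength effects. The phase is smooth in Re/Im
  everywhere — a physical complex field can only wind its phase around
  nulls, so no azimuthal vortex terms are used. Under the CP+ drive the
  wave terms align at the centre (central brightening) and interfere
  destructively off-centre. The effective wavelength (default 25 cm) is
  calibrated so the CP+ coefficient of variation over the phantoms falls
  in the 25-29% band observed in vivo at 7T; the bare ~12 cm in-tissue
  wavelength overstates interference for this simplified cylindrical
  geometry;
* the receive fields are azimuth-mirrored copies of the transmit fields
  with conjugated wave phase — the transceive-coil property ("receive
  resembles transmit") that makes localizer-based B1+ estimation
  feasible;
* stored B1+ maps are zero outside the tissue mask, like acquired maps;
* localizer signal per receive channel: proton density times
  `sin(FA_nom |B1+_CP+| / ref)` times the transmit phase factor times the
  receive field, plus complex Gaussian noise at a configurable
  image-domain SNR (default 30, a typical 7T localizer regime); the
  nominal flip angle defaults to 8 degrees. The 9th channel is the
  root-sum-of-squares of the noisy receive channels.

What the simulator does *not* model: Maxwell-accurate (full-wave) fields,
tissue-dependent contrast and susceptibility, motion, slice profile, and
the acquisition chain of the reference B1+ mapping method. Passing the
package's end-to-end checks therefore demonstrates that the chain —
simulation, training, prediction, metrics, pulse design — is correct and
self-consistent at desk scale, not that the specific accuracy figures
transfer to acquired 7T data.

# Metrics

All metrics are restricted to the brain mask (Otsu threshold on the
combined magnitude, largest connected component, hole fill — Dice > 0.98
against the simulator's true mask at SNR 30). The panel follows the B1+
mapping literature: mean relative magnitude error (mask-mean
denominator, so signal nulls cannot blow it up; a per-voxel variant is
available), circular mean absolute phase difference
(`|angle(P conj(T))|`, wrap-aware, in `[0, 180]` degrees), RMSE of
magnitude and of the complex difference, SSIM on magnitude / unwrapped
phase / averaged real-and-imaginary parts, and masked Pearson correlation
of magnitude and unwrapped phase. SSIM uses a 7x7 uniform window,
`k1 = 0.01, k2 = 0.03`, sample-covariance normalization, the valid
(border-cropped) region, and data range = max over both images; the
implementation is verified against an independent reference
implementation on a frozen fixture. Phase unwrapping is deterministic
scan-line (Itoh) unwrapping — exact for fields whose true phase gradients
stay below pi per voxel, which holds for these smooth transmit phases and
avoids the cost of quality-guided region growing at 570-slice scale.

# Pulse design

`combine_channels()` forms the complex shim combination; its magnitude
(MOS) and phase (POS) drive everything downstream.

**Static phase-only shimming** (`design_phase_shim()`) minimizes the
coefficient of variation (CV; population SD over mean) of MOS over the
mask, constraining the transmit efficiency
`mean(MOS) / mean(sum_k |B1+_k|)` to a target (default 60%, within 1%) —
deliberately below the fully constructive optimum so the optimizer can
trade efficiency for homogeneity, and so the combined phase does not
degenerate to the all-zero reference. The constraint is enforced by an
adaptive quadratic penalty around seeded multi-start Nelder-Mead over the
7 free phases (one channel fixes the global phase; the CP+ phases are
always one start). For volumes the efficiency is evaluated on the centre
slice by default (`efficiency_slice = "all"` switches to volumetric).

**kt-point pulses** (`design_ktpoints()`) use the small-tip-angle model
`theta(r) = gamma tau sum_n sum_c w_nc B1+_c(r) exp(i k_n r)`, with
normalized B1+ maps read as uT per unit drive weight, subpulse duration
100 us and blip duration 50 us (tunable; the source work's values are not
printed). RF weights solve a Tikhonov-regularized magnitude least-squares
problem by variable exchange (each half-step is an exact minimizer, so
the cost is monotone; iterated to numerical convergence). k-locations are
picked greedily from the symmetric 3x3x3 candidate grid (step 26 rad/m);
the DC point is always selected first, nesting the static-shim solution
so adding points can only improve the design cost. The regularization
weight is relative (`reg * mean(diag(A^H A))`), and increasing it never
increases the returned RF power.

**Bloch verification** (`bloch_simulate_fa()`) applies each subpulse as
an instantaneous rotation about its transverse effective-field axis,
interleaved with gradient-blip z-rotations that realize the k-space
steps (relaxation neglected); the flip angle is `acos(Mz)`. For target
angles up to ~5 degrees it matches the small-tip prediction to within 2%
per voxel, and a single hard pulse reproduces the analytic rotation to
1e-9.

# Scaled-down profiles and problem sizes

The package's tests and the acceptance script run a desk-scale twin of
the full study: 64x48 grid (4 mm, same field of view), 8 base features,
15 subjects with 3 slices per orientation, SNR 30. The end-to-end
parameter-recovery check trains on the 12 training subjects of one fold
for 45 epochs (all orientations; the orientation-specific model uses 30
epochs on its one-third-sized slice set) with the scaled schedule above,
then evaluates the 3 held-out subjects. Pulse-design checks reuse the
same library and trained networks. These sizes are the package's chosen
desk-scale study conditions; the full-scale configuration
(`network_config()`, `train_config()` defaults) reproduces the source
architecture and schedule.

A desk-scale run is an abbreviation, not a converged fit: a full-scale
schedule takes on the order of 10^5 batch-1 Adam steps, while the
45-epoch profile takes about 5 x 10^3, and at the largest stable
learning rate the held-out accuracy is still improving when the budget
ends. The end-to-end checks therefore treat prediction quality two
ways: the parameter-recovery thresholds document the aspirational
converged-fold accuracy (and fail honestly when the short schedule
falls short of them), while the downstream pulse-design checks assert
the orderings that already hold at desk-scale quality — pulses designed
on predictions beat the CP+ mode and lose to pulses designed on ground
truth, exactly the relationship the calibration chain is meant to
exhibit.

# Data formats and provenance

Libraries are schema-versioned single-file containers
(`write_dataset()` / `read_dataset()`) holding, per subject and
orientation, the complex localizer stack, the complex B1+ stack, the
tissue mask and grid metadata; complex arrays round-trip losslessly and
foreign or truncated files are rejected with a schema error. Checkpoints
store weights, architecture, normalization scales and training history.
Pulses serialize to JSON (k-locations, complex weights as re/im pairs,
timings, units); flip-angle maps export to NIfTI. Every CLI artifact
embeds the configuration hash and the seeds that produced it.

# Known limitations

* The simulator's analytic fields are smooth and low-dimensional;
  networks reach accuracy levels here that acquired data would not allow.
* The scan-line phase unwrapper assumes smooth phase; speckled
  low-magnitude regions would need a quality-guided unwrapper.
* The real-valued baseline is provided for architecture comparison and
  shape contracts; its training profile has not been tuned to parity
  with the complex variant.
* Phase metrics include low-magnitude voxels by default (an exclusion
  threshold is configurable), where phase is intrinsically noisy.
* SAR and hardware constraints are out of scope for the pulse designs.
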