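---
title: "Methods: the virtual rig and its analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the virtual rig and its analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyrig)
```

`flyrig` re-creates, entirely in software, the computational core of a
low-cost Raspberry Pi + Arduino neurogenetics rig: its camera conventions,
its Peltier--thermistor temperature loop, its LED-ring stimulus scheduler,
and the image analyses used with it on five standard preparations (bead
fields for resolution measurement, a crawling GCaMP larva, a tethered fly
showing the proboscis extension reflex, a tethered larval zebrafish, and a
multi-fly arena). Because no hardware or animals are involved, every
analysis can be validated against the exact ground truth of a synthetic
scene generator. This vignette explains the models, the defaults, and the
design decisions; it states nothing that the package's tests and
acceptance script do not themselves compute.

## Conventions

Pixel coordinates are 0-based, row-major, origin at the top-left;
rectangular ROIs are half-open. 8-bit values are produced by rounding
half-up and clamping to [0, 255]. Stacks carry their frame rate, pixel
size and start time; frame timestamps are implied as `t0 + k / rate`. The
primary interchange format is uncompressed multi-page TIFF with a JSON
sidecar for acquisition metadata, because TIFF tags for frame rate and
pixel size are dialect-ridden; 8-bit round trips are bit-identical.

## The camera model

The emulated sensor acquires 2592 × 1944 RGB frames; spatial binning
trades resolution for rate with the pairing ×1 → 15 Hz, ×2 → 42 Hz
(1296 × 972), ×4 → 90 Hz, and the effective pixel size is about 1 µm at
peak zoom, scaled by the binning factor. Binning is modelled as a block
mean with half-up rounding; the true on-GPU averaging rule of the camera
pipeline is not published, so the block mean is a documented stand-in.
Temporal downsampling defaults to block averaging rather than decimation:
it improves SNR and reproduces the ~100 ms frame spacing conventional for
the kymograph analyses (decimation is available behind `method =
"decimate"`). Greyscale conversion is the unweighted RGB mean (no
weighting is conventional for these quantitative pipelines; luminance
weights are available via the `weights` argument). Bayer mosaicing is not
simulated — all analyses operate on demosaiced output.

The sensor noise model is analytic intensity `I` in [0, 1] → Poisson shot
noise with mean `photon_scale * I` → conversion to grey (255 at `I = 1`) →
additive Gaussian read noise → quantisation. The default
`photon_scale = 500` gives photon SNR ≈ 20 at typical spot intensities
(`sqrt(0.8 × 500)`), matching a bright but realistic fluorescence
preparation; `photon_scale = Inf` with zero read noise yields the exact
analytic render, which the tests exploit as a noiseless oracle.

## Synthetic scenes and their ground truth

Each generator returns a stack plus a truth object, and is deterministic
given (config, seed). Scenes are rendered directly at the binned output
geometry for speed.

**Beads.** Sub-resolution point sources rendered as pixel-integrated 2D
isotropic Gaussians (default σ = 5.4 µm at 1 µm pixels, the instrument's
measured resolution), rejection-placed at ≥ 6σ separation. Truth records
exact centres and σ.

**Crawling larva.** The calcium signal of a peristaltic wave is a raised
cosine of half-width 0.25 body lengths travelling tail-to-head at
3000 µm/s along a 3 mm body, one wave per 1.5 s, with the body advancing
200 µm per completed wave. These values are free parameters of the scene
(published recordings show the qualitative pattern but not calibrated
amplitudes); they were chosen once as typical of a second-instar larva
crawling at one wave per 1–2 s and are not tuned thereafter. Only the
green channel carries the wave (a GCaMP indicator); red and blue show a
dim static body. The default frame rate, 10.5 Hz, corresponds to 42 Hz
acquisition downsampled ×4 in time, the standard analysis convention.

**PER fly.** A fixed fly whose proboscis-tip region brightens with 0.1 s
latency during each red-LED stimulus interval of a compiled protocol. A
uniform 10-grey-level illumination artefact covers the whole frame during
stimulation, so the background-over-time subtraction step is genuinely
exercised; an artefact-only control (`extend = FALSE`) must come out flat
after that subtraction, and does.

**Tethered fish.** Fin responses are modelled at ROI level (mean
brightness bursts), not as fin kinematics, because that is precisely what
the downstream analysis measures. A stimulus elicits a bilateral
oscillatory burst (0.8 s, 0.1 s latency) if and only if its duration
reaches `threshold_s = 0.5` — the empirical reliability boundary for
whole-field blue-light ChR2 activation, where ~150 ms stimuli reliably
fail. The transition is modelled as sharp because the data characterise
only the two regimes, not the crossover. The stimulus light artefact
defaults to zero here (an excitation filter is assumed in place); it can
be enabled via `artefact_grey`.

**Arena flies.** Dark ellipses on a light background performing
velocity-persistent reflecting random walks with pairwise repulsion below
a minimum separation (default four blob diameters, the regime in which a
greedy tracker should be exact). Truth holds per-frame centroids with
persistent identities.

## Fluorescence analyses

**Background subtraction** offers three estimators because "background"
is under-specified in common practice: per-pixel minimum projection
(default; static arena under a moving bright object), per-pixel temporal
median (structure present most of the time), and per-frame spatial median
("background over time" — removes a uniform common-mode stimulus artefact
exactly, the standard treatment for PER recordings).

**Running-average time differential.** Output frame *t* is frame *t*
minus the mean of its `k = 4` predecessors; the first `k` frames are
dropped, values are signed floats, and `t0` advances by `k/rate`. The
implementation is tested for exact float equality against a naive
double-loop oracle, plus closed forms (a linear ramp gives a constant
`(k+1)/2`-step output; a height-A step decays A, 3A/4, 2A/4, A/4, 0; the
telescoped sum matches an explicit weighting).

**Kymograph.** The space–time map averages each frame across the short
body axis; orienting the long axis along image rows is the caller's
responsibility (no automatic registration — the generator renders the
larva vertically). Travelling waves appear as diagonal ridges.

**Wave detection** thresholds the positive differential at 0.3 of the map
maximum and keeps 8-connected components spanning ≥ 0.5 of the position
axis — defaults chosen to reject noise and partial ridges, since the
original analyses identified waves by eye. Speed is the least-squares
slope through the per-frame intensity-weighted ridge centroids, which is
robust to ridge thickness. Across ten seeds of the default larva scene
the detector recovers the exact wave count and speeds within 10%.

**PSF estimation** detects local maxima above background + 5 noise s.d.,
rejects saturated or crowded spots (closer than 6 σ-guess), and fits each
with a pixel-integrated 2D Gaussian by Levenberg–Marquardt
(`minpack.lm`). The summary statistic is the **median** per-bead σ,
robust to occasional mis-detections. Recovery bias is under 5% for σ
between 2 and 8 px at photon SNR ≥ 10, and under 1% per bead in the
noiseless limit.

## Behavioural analyses

**Event detection** uses a median baseline and a MAD-derived sigma
(threshold = baseline + 3σ by default), a minimum duration of 100 ms and
a merge gap of 100 ms — stated as configuration, not constants. On a
noiseless trace the MAD is zero and any elevation is an event, which is
the intended behaviour for synthetic square waves.

**Larval length** automates what is classically a manual head-to-tail
measurement: Otsu threshold, largest component, Zhang–Suen thinning, and
the longest geodesic path through the 8-connected skeleton — so a bent
body is measured along its arc, not its chord (a semicircular-arc fixture
must read πr, not 2r). Two corrections matter numerically: the geodesic
is measured along a stride-5 subsampled polyline of the path (the raw
8-connected chain zigzags on curves and reads several percent long), and
the local body radius at both path ends is added back (thinning erodes
about half a body width from each end; without this a straight rod reads
~8% short). The contraction summary samples the length trace at t = −1,
+0.5 and +5 s around a flash by nearest sample and reports fractional
contraction `1 − len(0.5)/len(−1)` and recovery `len(5)/len(−1)`.

**Fin bouts** are attributed per stimulus when either fin trace shows an
event onset within a 1 s response window (the recordings show prompt
responses but state no window; 1 s comfortably covers the 0.1 s
generator latency without reaching the next trial).

**Tracking** is greedy global-nearest-neighbour linking under a maximum
jump, not Hungarian assignment: at the separations the arena generator
maintains (≥ 4 blob diameters) greedy linking is provably adequate, far
simpler to verify, and achieves zero identity switches in the tests.
Unmatched tracks are closed, so a jump beyond `max_jump_px` splits a
track rather than teleporting it.

## The thermal loop

The plant is a two-node lumped model — the Peltier surface and the
sink/fan beneath it. The Peltier pumps `u · Q_max` watts from sink to
surface (cooling derated by `eta_asym = 0.7`, reflecting the lower
efficiency of thermoelectric cooling); conduction couples the nodes
antisymmetrically, and each leaks to ambient. The published description
of the rig gives loop *performance*, not physics, so the default
constants (`C_surf = 20`, `C_sink = 200` J/°C, `k_surf_sink = 0.8`,
`k_surf_amb = 0.15`, `k_sink_amb_fan = 5` W/°C, `Q_max = 30` W) were
calibrated once, from the steady-state algebra, so that the weaker
(cooling) direction still attains a ≥ 20 °C offset from a 19 °C ambient
and initial ramps exceed 1 °C/s; they are committed as constants and not
revisited. Integration is explicit Euler at 10 ms (the stability bound
for these constants is ~21 s, so the scheme is deeply stable; halving the
step changes an open-loop response by well under 0.05 °C).

The firmware's control law is not published; the default is bang-bang
with a ±0.25 °C hysteresis band — robust and tuning-free, and entirely
sufficient for sub-degree holds given the plant's per-control-period
excursion of at most `Q_max/C_surf × 0.1 s = 0.15 °C`. A clamped PI
controller is provided for comparison. The thermistor is a 10 kΩ NTC
beta model (β = 3950 K, 10 kΩ divider, 10-bit ADC — typical values; the
actual part is a hardware detail not printed anywhere) with 0.1 °C
Gaussian sensor noise added before quantisation. The loop logs setpoint,
reading and drive at 2 Hz, the rig's serial logging rate.

On the reference 20-minute schedule (15/35 °C alternating every 5
minutes, ambient 19 °C) the simulated loop holds every epoch with
s.d. ≈ 0.23 °C, ramps at ≈ 1.1 °C/s on average, and attains ±21.5 °C at
full drive — reproducing the three published performance figures, which
the test suite asserts as a regression.

## The stimulus scheduler and serial protocol

Protocols compile to integer-microsecond event logs with no accumulated
drift (timestamps are computed from closed-form arithmetic, not summed;
they are stored as doubles, exact for integers far beyond any protocol
length, because R's 32-bit integers would overflow within ~36 minutes of
microseconds). Execution runs on a virtual clock: correctness is about
event ordering and spacing, not wall-time fidelity. The ASCII serial
grammar (`RING r g b`, `PELT SET <°C×10>`, `SERVO id pos`, `LOG ON|OFF`)
is a documented stand-in, not a wire-compatible clone of any firmware;
setpoints travel as fixed-point ×10 integers to avoid float parsing on
the wire. The 8×8 LED matrix exists as a channel but renders no spatial
patterns (out of scope).

## Problem sizes, determinism and limitations

The test suite and acceptance script use deliberately small scenes — a
256² bead field, an 80×240 larva arena at 10.5 Hz for 5–8 s, 96² PER
frames, a 200² arena for 3–5 s, and a single 20-minute thermal run —
sizes at which every statistical check is already stable across seeds.
All randomness flows through explicit integer seeds; identical seeds give
byte-identical stacks, truths and logs.

What passing these tests does *not* show: the generators idealise real
recordings. There is no motion blur, no body-axis curvature requiring
registration, no photobleaching, no uneven illumination, no Bayer
artefacts, and the fish bout threshold is sharp rather than probabilistic.
The analyses are therefore validated as *algorithms*; their performance
on real video depends on conditions the simulator does not emulate.
Absolute fluorescence scales are arbitrary throughout (unnormalised
brightness, no ΔF/F pipeline), and the thermal model collapses the 4×4 cm
plate to a single node, so spatial gradients across the surface are out
of scope.
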