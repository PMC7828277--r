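---
title: "Simulating chronic drift in nerve-cuff recordings and comparing classifier update strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating chronic drift in nerve-cuff recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cuffdrift)
```

## The problem

A multi-contact nerve cuff (here 7 rings x 8 contacts = 56 channels around
a rat sciatic nerve) records compound action potentials (CAPs) whose
spatiotemporal signature — the 56 x 100 matrix of channels by time samples
around a CAP peak — identifies which neural pathway (tibial, peroneal or
sural) fired. A classifier trained at implant time degrades as the
interface changes chronically: fibrotic encapsulation tissue grows between
the nerve and the cuff, and the cuff can rotate around the nerve. This
package simulates both perturbations end to end and compares three ways of
keeping the classifier useful over time:

1. **baseline calibration** — train once at implant time, never update
   (the control);
2. **periodic recalibration** — supervised warm-start retraining on newly
   labelled data at every time point;
3. **self-learning** — retraining on the classifier's own high-confidence
   predictions (pseudo-labels at >= 95% softmax confidence), with no new
   manual labels.

Everything is synthetic; there is no external data. The package is the
computation behind the numbered drivers in `analysis/`.

## Volume conductor

The leadfield maps a unit source current at position $j$ inside the nerve
to the potential at contact $i$. We do not solve a finite-element model;
the gain is an analytic composite of two terms.

**Straight-ray layered kernel.** The local term is the point-source kernel
$1 / (4\pi\,\sigma_{\mathrm{eff}}\,d)$ with $d$ the source-contact
distance and $\sigma_{\mathrm{eff}}$ the length-weighted harmonic-mean
conductivity along the straight segment between them. The segment is split
at its intersections with the nested cylindrical boundaries (endoneurium,
perineurium shell, epineurium, and the annulus between epineurium and
cuff, divided at the encapsulation/saline boundary). The anisotropic
endoneurium contributes
$\sigma_{\parallel}\cos^2\alpha + \sigma_{\perp}\sin^2\alpha$ for a ray at
angle $\alpha$ to the nerve axis. Conductivities (S/m): endoneurium
radial $8.26\times10^{-2}$, longitudinal $5.71\times10^{-1}$; perineurium
$2.10\times10^{-3}$ (0.065 mm shell); epineurium $8.26\times10^{-2}$;
encapsulation $6.59\times10^{-2}$; saline $2.00\times10^{-1}$; cuff
$10^{-7}$.

**Cuff confinement.** An insulating cuff squeezes the far-field return
current into the conductive cross-section, which adds a
quasi-one-dimensional component along the axis: a tent profile
$z_<\,(L - z_>)/L$ between the source and contact axial positions
(cuff length $L$ = 23 mm, grounded ends), divided by the axial conductance
$\sum_k \sigma_k A_k$ of the cross-section. The annulus conductivity in
that sum is the area-weighted mix of encapsulation and saline, so the term
is where encapsulation changes the *shape* of signatures, not just their
scale — without it the encapsulation perturbation is almost entirely a
uniform gain factor that per-dataset normalization cancels, and no
realistic drift occurs. The term is gated by the insulation contrast
$1 - \sigma_{\mathrm{cuff}}/\sigma_{\mathrm{saline}}$, so in a homogeneous
medium the composite reduces exactly to $1/(4\pi\sigma r)$. It has no
tunable constants; geometry and the conductivities above determine it.
`compute_leadfield(confinement = FALSE)` gives the pure ray kernel.

Two exact properties anchor the implementation: a 45 degree cuff rotation
(360/8 contacts) is precisely a ring-wise channel permutation of the
leadfield, and gain magnitudes are nondecreasing in the encapsulation fill
(both summands are monotone).

**Fascicle layout.** The three fascicles are clustered and adjacent
(tibial 0.28 mm @ 90 deg, r = 0.35 mm; peroneal 0.42 mm @ 215 deg,
r = 0.25 mm; sural 0.52 mm @ 285 deg, r = 0.15 mm; epineurium 0.70 mm),
as in a sciatic cross-section at cuff level where the nerve has not yet
branched. Adjacency matters scientifically: with fascicles spread evenly
around the cross-section the three classes are so separable that macro F1
saturates at 1.0 even at -5 dB and no drift is observable; the clustered
layout reproduces the regime in which the update-strategy comparison is
meaningful. The layout is configurable and not derived from imaging data.

## CAP simulation

Nodes of Ranvier are placed at equal arc length along spline-interpolated
fiber trajectories: spacing 1.70 mm and conduction velocity 94.86 m/s for
A-alpha fibers (tibial, peroneal), 1.16 mm and 64.72 m/s for A-beta
(sural). Each pathway has a bank of 20 trajectories at distinct radial
offsets inside its fascicle (a deterministic sunflower pattern with a
gentle helical wiggle), emulating CAPs initiated at different locations;
the count is configurable. All nodes share one source template — a Ricker
wavelet (width parameter 0.1 ms, half-support 0.8 ms), charge balanced by
construction — time-shifted by arc length over velocity. This stands in
for a biophysical membrane model; since all fibers of a pathway fire in
perfect synchrony here, only the waveform's scale and propagation matter
downstream.

Recordings are tripole referenced (the instantaneous mean of the 16
outer-ring contacts is subtracted from every channel; referencing twice is
an error, never silent) and clipped to 100 samples (3.333 ms at 30 kHz)
centered on the global magnitude peak of the referenced signal, ties going
to the earliest sample and lowest channel. The peak sits at sample 50: 49
samples before, 50 after.

A per-pathway time series holds 10,000 CAPs in 53.333 s at study scale
(the desk default scales both together, keeping the 187.5 CAP/s density).
Onsets are drawn uniformly with a minimum separation of one clip, so
events never overlap; the firing-time distribution is a modeling choice —
no firing-rate structure is intended. White Gaussian noise is calibrated
against the mean squared value of the whole series, pooled across
channels, silence included: $\sigma^2 = P_{\mathrm{signal}} /
10^{\mathrm{SNR}/10}$ at SNR $\in \{-5, -10, -15\}$ dB. Pooling across
channels (rather than per channel) is a deliberate choice. Because events
do not overlap, noising the full series and then windowing is identical in
distribution to adding windowed noise with the same $\sigma$; the dataset
path uses the latter with $\sigma$ computed analytically from clip
energies, and the full-series path is kept and tested for fidelity.

## Datasets

Signatures are extracted at the peaks of the *clean* series (detection
from noisy data is intentionally bypassed), normalized per dataset by the
single global maximum magnitude (so the maximum becomes exactly 1; the
constant is stored so amplitude growth across time points stays
inspectable), and split into 5 stratified folds — at study scale, 30,000
signatures per time point, folds of 6000 with 2000 per class.
Normalization is per time point; whether a single global constant across
time points was intended is ambiguous, and the per-time-point reading was
chosen and flagged here.

Datasets at different fills or rotations are generated with identical
seeds and banks, so signatures correspond one-to-one in order; linear
interpolation between corresponding time points
(`interpolate_datasets`, exact at the endpoints) supplies the intermediate
time points for the training-frequency analysis. Interpolation acts on the
noisy signatures as built.

## Classifier

`dual_cnn` is a dual-branch convolutional network: each branch consumes
one channel ordering of the same signature — "spatial emphasis"
(ring-major rows) and "temporal emphasis" (longitudinal, slot-major
rows) — through two convolution (3 x 3) + ReLU + 2 x 2 average-pooling
stages (8 then 16 filters by default), and the concatenated branch
features feed a 3-way softmax. Branches share topology, not weights
(untied weights were chosen where the description is ambiguous).
Convolution is implemented natively (im2col + explicit backpropagation;
gradients are verified against finite differences in the test suite), and
the filter counts default small for single-CPU training; everything is
config-exposed. `linear_baseline` is softmax regression on the flattened
signature (3 x 5601 parameters). Both train with mini-batch Adam under
seeded shuffling, support warm starts (training always continues from the
passed-in parameters; zero epochs is the identity), and are
interchangeable everywhere downstream. Confidence is the maximum softmax
probability; argmax ties break toward the lowest class index (tibial <
peroneal < sural). There is no early stopping.

## Update strategies

All strategies consume identical datasets, folds and per-fold initial
weights (every stage seed derives from one master seed and a stage label),
so trajectory differences are attributable to the update rule alone.
Evaluation is 5-fold cross-validated macro F1 (mean over classes of
$2PR/(P+R)$, a class scoring 0 when $P + R = 0$), always against true
labels on the held-out fold.

Self-learning predicts the new time point's four training folds with the
previous classifier, keeps samples at confidence >= 0.95 with their
pseudo-labels (true labels discarded), and warm-start retrains on that
subset only — no replay of earlier data (a config flag enables replay, off
by default). A run stops at the first time point where any class's
self-labelled count falls below 200; the rule is applied per fold to the
self-labelled training pool (the stated "validation set" is read as this
pool, the set the rule can actually observe without labels), and the
run-level stop is the earliest over folds.

The slope analysis starts at ET1 from two initial levels sharing the Base
lineage — HP (one supervised step) and LP (one self-learning step) — and
runs self-learning to ET2 at frequency multipliers 1, 2, 4, 8 (inserting
m - 1 interpolated time points). Each cell reports the strategy's
ET1-to-ET2 slope minus that of a control frozen at ET1; positive means the
updates slowed the decline. "Time" is sequence position; there is no
calendar timescale. At -5 dB, where the classifier is near ceiling and
pseudo-labels are almost pure, LP can tie or marginally exceed HP; the
HP > LP gap belongs to noisier regimes.

## Problem sizes and numerical choices

The default profile runs 1000 CAPs per class per time point (3000 per
dataset, folds of 600) with the linear classifier; `full_profile()`
selects the study-scale 10,000 per class and the CNN. The series used for
SNR fidelity checks is 1000 events (5.33 s) at the study's event density.
Tolerances asserted in the tests: homogeneous leadfield limit $10^{-12}$
relative; rotation equivariance $10^{-10}$; template charge balance
$10^{-9}$ relative (half-support 8 width parameters keeps the truncated
tail below that); per-channel CAP integral $10^{-6}$ relative; measured
SNR within 0.1 dB; peak-lag error under one sample at 30 kHz — the lag law
is exact for the localized ray kernel and is checked with
`confinement = FALSE`, since the confinement far field deliberately
spreads energy across rings. Degenerate inputs error loudly: sources
outside the epineurium, zero-length paths, infeasible event packing,
all-zero datasets, double referencing, missing classes in training data.

## What the generator does and does not emulate

It emulates: geometry- and conductivity-dependent multi-contact gains
under encapsulation and rotation; constant-velocity propagation over
discrete nodes; tripole referencing; calibrated stationary Gaussian noise;
intra-class variability through source-position banks; paired drift
(identical noise draws across time points of a sequence, which makes
strategy comparisons low-variance). It does not emulate: membrane
biophysics or firing-rate structure; electrode impedance changes,
artifacts, or non-stationary noise; nerve branching; encapsulation outside
the cuff; independent re-recording noise at each time point. Passing tests
therefore certify the pipeline's arithmetic and the direction of its
drift effects under this model, not field performance on in vivo
recordings; the encapsulation-driven F1 decline here is in particular far
gentler than an MRI-derived finite-element model produces, while the
rotation-driven decline is strong in both.

## Reproducibility

Every stochastic stage derives its seed from the master seed and a stage
label (`derive_seed`), all seeds stay below $2^{31}$, and two runs of
`run_full_study()` with one master seed write identical result tables.
Artifacts are plain CSV/JSON; configurations round-trip through YAML at
full double precision and are fingerprinted (excluding the output path)
in the run manifest.
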