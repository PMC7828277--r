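# cuffdrift

Chronic changes at a peripheral-nerve interface — fibrotic encapsulation
tissue growing between the nerve and a recording cuff, and rotation of the
cuff around the nerve — slowly change what the electrodes see, so a
classifier calibrated at implant time loses accuracy. `cuffdrift`
simulates this problem end to end for a 56-contact (7 rings x 8 contacts)
nerve cuff on a rat sciatic nerve and compares three classifier update
strategies over simulated time. It is aimed at neural-interface
researchers who want a controlled, fully synthetic testbed for decoder
recalibration schemes.

## What it computes

**Signal model.** A compound action potential (CAP) travelling along a
pathway is a set of point current sources at the nodes of Ranvier
(spacing 1.70 mm, velocity 94.86 m/s for A-alpha fibers of the tibial and
peroneal pathways; 1.16 mm, 64.72 m/s for A-beta sural fibers), each
injecting a shared charge-balanced waveform delayed by arc length over
velocity. Contact potentials come from an analytic leadfield: the
point-source kernel

$$L_{ij} = \frac{1}{4\pi\,\sigma_{\mathrm{eff}}(i,j)\; d(i,j)}$$

with $\sigma_{\mathrm{eff}}$ the harmonic-mean conductivity along the
straight source-contact ray through the layered nerve (anisotropic
endoneurium, perineurium, epineurium, encapsulation/saline annulus), plus
a parameter-free insulating-cuff confinement term (a quasi-1D tent
potential scaled by the axial conductance of the cross-section) through
which encapsulation changes signature shape. Recordings are
tripole-referenced, cut into 56 x 100 signatures (3.333 ms at 30 kHz, CAP
peak at sample 50), noised with white Gaussian noise calibrated on
whole-series power (SNR -5/-10/-15 dB), normalized to [-1, 1], and split
into 5 stratified folds.

**Strategies.** On a sequence of time points (encapsulation fills 0, 1/3,
2/3, 1 = Base..ET3, or rotations 0..45 degrees in 5 degree steps), macro
F1 is tracked for: baseline calibration (train once), periodic
recalibration (supervised warm-start retraining), and self-learning
(warm-start retraining on the classifier's own predictions at >= 95%
confidence, halting when any class yields fewer than 200 self-labelled
samples). A slope analysis compares self-learning against a frozen
control between ET1 and ET2 across training frequencies (1x, 2x, 4x, 8x
via linearly interpolated intermediate datasets) and two initial
performance levels. Classifiers: a dual-branch CNN (spatial- and
temporal-emphasis channel orderings) and a fast linear softmax baseline,
interchangeable everywhere.

## Worked example

```r
library(cuffdrift)

# a reduced configuration: 8 source trajectories per pathway and
# 150 CAPs per class per time point (folds of 90); the self-labelling
# floor is scaled with the training pool (120 per class available)
cfg <- default_config(master_seed = 42)
cfg$pathway$n_traj <- 8L
cfg$n_per_class <- 150L

seqd <- build_timepoint_sequence(cfg, "encapsulation", snr_db = -5)

hyper <- list(epochs = 20L)
states <- train_base_states(seqd, "linear_baseline", seed = 42, hyper = hyper)
baseline  <- run_baseline_calibration(seqd, base_states = states)
periodic  <- run_periodic_recalibration(seqd, base_states = states)
selflearn <- run_self_learning(seqd, base_states = states, seed = 42,
                               min_per_class = 25L)
print(baseline)
print(periodic)
```

which prints

```
<strategy_run> baseline_calibration on encapsulation @ -5 dB
 timepoint        f1
      Base 0.9024665
       ET1 0.8980676
       ET2 0.8915190
       ET3 0.8894909
<strategy_run> periodic_recalibration on encapsulation @ -5 dB
 timepoint        f1
      Base 0.9024665
       ET1 0.9046441
       ET2 0.8985075
       ET3 0.8941348
```

The static classifier declines monotonically as encapsulation grows
(0.902 to 0.889 mean macro F1), while supervised recalibration stays
above it at every later time point. In this run self-learning matches
periodic recalibration exactly: at -5 dB every training-pool sample
cleared the 95% confidence threshold with a correct pseudo-label, so both
strategies trained on identical data — the strategies separate at lower
SNRs, where pseudo-labels err and the self-labelled pool shrinks.

The full study is driven by the numbered scripts in `analysis/`
(01 model and leadfields, 02 simulated recordings, 03 encapsulation
strategies, 04 rotation strategies, 05 training-frequency/initial-
performance slope analysis); each writes tidy CSVs under `results/`.

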