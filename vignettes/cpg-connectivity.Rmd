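---
title: "Inferring CPG network coupling from rhythmic burst recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring CPG network coupling from rhythmic burst recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(cpgnet)
```

## The problem

Walking insects coordinate their legs through central pattern generators
(CPGs): segmental circuits in the pro-, meso- and metathoracic ganglia that
produce rhythmic motoneuron bursts even when all sensory feedback is removed
(deafferented preparations activated with the muscarinic agonist
pilocarpine). Extracellular nerve recordings then show slow bursting at
roughly 0.1–0.5 Hz per hemisegment. The scientific question is which ganglia
are coupled to which, in which direction, and how strongly — inferred purely
from the simultaneous multichannel rhythms.

`cpgnet` implements two complementary analyses:

1. **Phase connectivity (PC)** — an undirected, descriptive measure.
   Each channel is reduced to an instantaneous phase; channel pairs whose
   phase difference stays constant long enough are declared coupled, and the
   fraction of recording time spent coupled is the coupling likelihood.
2. **Spectral model comparison ("DCM-lite")** — a directed, model-based
   measure. A linear stochastic oscillator network `z' = (A + uB) z` is
   fitted to empirical cross-spectral densities; candidate coupling
   architectures are compared through approximate log model evidence.

A seeded synthetic-data generator provides ground-truth networks so that
every stage is testable without animal data.

## Phase extraction

Preprocessed nerve signals (DC-removed, rectified, smoothed, downsampled to
200 Hz, and re-centred to zero mean) are turned into phases via the analytic
signal `X = X_r + i X_i`, with `X_i` the Hilbert transform of `X_r`. Burst
onsets are the counter-clockwise crossings of a Poincaré section — a fixed
ray from the origin of the complex plane. Design choices that matter:

* **Section placement.** Any fixed ray gives a consistent reference phase;
  the default is the positive real axis (`section_angle = 0`), configurable.
  Onsets therefore sit at a constant *phase lag* relative to, say, the burst
  envelope edge; only consistency matters for phase analysis.
* **Debouncing.** A crossing only counts after the trajectory has advanced
  at least half a revolution since the previous onset. Residual carrier
  ripple or noise can wiggle the trajectory back and forth across the
  section; requiring net angular progress rejects these without any
  amplitude threshold.
* **Small-unit filtering.** Prothoracic recordings often contain tonic
  small-amplitude units that produce their own small loops around the
  origin and hence spurious onsets. Onset amplitudes (peak `|X|` of the
  revolution each onset starts) are split by 1-D k-means with k = 2,
  deterministically initialised at the extremes, and only the
  large-centroid cluster is kept. If the centroid ratio small/large exceeds
  0.6 the two "clusters" are one population: nothing is filtered and a
  warning is raised. This auto-detects recordings that need no filtering.
* **Phase interpolation.** Phase is piecewise linear between onsets
  (`2*pi*k` at the k-th onset), unwrapped, `NA` outside the onset span. The
  units are radians; divide by `2*pi` for cycles.

## Phase-connectivity criteria

For a channel pair, the mean resultant vector (phase-locking value)
`R = |mean(exp(i (phi1 - phi2)))|` is computed in a gliding 15 s window
(step 1 s). A coupled interval requires

1. windowed `R > 0.8` sustained for at least 50 s (about ten cycles), and
2. whole-interval `R > 0.3`, which rejects slow drifts whose windowed R
   stays high while the phase difference wanders over full turns.

Both thresholds were calibrated manually in the original analyses; they are
arguments, not constants. Candidate intervals span the outer edges of the
first and last qualifying window; because this expansion can bridge two
runs separated by less than a window, overlapping candidates are merged
before the criteria are applied, keeping accepted intervals disjoint.
The **coupling likelihood** is the summed length of accepted intervals
divided by total recording time; recordings with no coupling count as zero.
PC is undirected, so pair order is irrelevant. Group differences between
connection classes (e.g. meso-meso vs meso-meta) use Welch two-sample
t-tests on per-animal likelihoods; p-values are reported raw, without
multiplicity correction, and flagged as such in reports.

## The spectral model

Each node (hemisegmental CPG) is a stochastically driven damped oscillator:

$$\ddot z_i = -\omega_i^2 z_i - \gamma_i \dot z_i + \sum_j A_{ij} z_j + w_i(t),$$

which keeps the coupled system `z' = (A + uB) z` linear and gives a closed
form for the one-sided cross-spectral density,
`S(f) = 2 G H(f) Q H(f)^H G' + s_obs I` with `H(f) = (i 2 pi f I - M)^{-1}`.
This node model deliberately replaces convolution-based neural mass models:
it preserves exactly the quantities of interest — masked coupling strengths
`A`, condition changes `B`, and evidence-based architecture comparison —
while remaining closed-form and desk-scale.

Empirical CSDs are Welch estimates (Hann taper, half-overlapping demeaned
segments, one-sided density scaling) on a 0.05–2 Hz band covering the ~5 s
cycles and first harmonics. Fitting maximises a Gaussian log joint with the
**Whittle (complex-Wishart) likelihood**
`-K [log det S_mod(f) + tr(S_mod(f)^{-1} S_emp(f))]` summed over
frequencies, `K` the segment count. An entry-wise Gaussian approximation
(variance `S_ii S_jj / K`) is available as an option; the Wishart form uses
the full correlation structure of the averaged periodogram and recovers
coupling parameters measurably better at realistic recording lengths, which
is why it is the default.

Parameters are log-transformed (damping, frequency, noise levels, coupling
strengths) with Gaussian priors. Coupling strengths are `sign * exp(theta)`
with one global sign per architecture (excitatory or inhibitory variants;
mixtures are excluded), so a connection assumed present never vanishes:
the prior centres allowed connections on a genuine default strength
(0.4 of the default damping, i.e. 0.2 in absolute units) with a log-scale
SD of 0.5. This is the
mechanism behind evidence-based architecture discrimination: a model with a
superfluous connection cannot silently zero it out, fits uncoupled data
worse, and loses evidence — while a missing necessary connection loses fit
quality directly. Multi-start quasi-Newton optimisation (default 8 seeded
starts, best joint value kept, ties to the first found) handles the
non-convex landscape; in practice the optimum has been unimodal in all
simulation checks, so tests use fewer starts.

The log model evidence is the Laplace approximation
`log p(y | theta_hat) + log p(theta_hat) + d/2 log(2 pi) + 1/2 log det
Sigma_post`, with the posterior covariance from the numerical Hessian
(eigenvalues floored for safety). Bayesian model selection uses equal model
priors: posterior probabilities are the softmax of log evidences, which for
two models is exactly `1 / (1 + exp(-log B))` with `log B` the log Bayes
factor; relative log evidences are displayed against the least probable
model.

### Model spaces

Two-segment space (4 nodes): (1) fully connected; (2) contralateral
intrasegmental + ipsilateral intersegmental ("eight-shaped"); (3)
intrasegmental + diagonal cross; (4) ipsilateral intersegmental only; (5)
diagonal cross only; (6) intrasegmental only; (7) fully unconnected. The
three-segment space builds on the two-segment winner: (1) union of the
winning subnetworks; (2) + pro-meta diagonal crosses; (3) + bidirectional
ipsilateral pro-meta; (4) + unidirectional ipsilateral meta-to-pro. The
published figures describing the middle architectures leave some edge sets
ambiguous; the sets above follow the accompanying results narrative, and
`fit_model()` accepts an explicit adjacency mask wherever a different space
is wanted.

### Condition changes

For connected/cut-connective designs the two conditions are fitted jointly:
condition 1 uses `A`, condition 2 uses `A + B`, with every connection free
to change (`mask_B = mask_A`, change priors centred on "no change" with a
log-scale SD of 2 — wide enough that a genuinely removed pathway can drop
by an order of magnitude without undue prior cost). Per-connection changes
are reported as `100 ((A+B)/A - 1)` percent; absolute changes above 70 %
are flagged reliable. Because connections never vanish exactly, a
surgically removed pathway shows up as a large flagged decrease rather than
a literal zero. Two tables are produced: per directed edge, and with the
two directions of each connection combined before the percent change is
computed. The combined (per-side) table is the primary summary, matching
the left-right symmetry convention used for strength reporting; individual
directions between spectrally similar nodes are weakly identified, so their
separate changes scatter more.

### Strength summaries

Under the left-right symmetry assumption, each directed connection is
averaged with its mirror image (L and R swapped at both endpoints) within
each fit. Normalisation is per fit: either the maximum symmetrised strength
becomes 1 (boxplot convention) or strengths are divided by a named
reference class such as meso-meso. Fitted strengths have no absolute
physical scale — only normalised comparisons are meaningful.

## The synthetic-data generator

Ground truth is a network of weakly coupled phase oscillators,
`dphi_i = [2 pi f_i + sum_j K_ij sin(phi_j - phi_i)] dt + sigma dW`,
integrated by Euler–Maruyama at 1000 Hz. The sinusoidal coupling is a
standard weak-coupling surrogate with analytically checkable lock states;
the analysis stages never assume this functional form (the spectral stage
fits a *linear* model to these decidedly non-linear data). Channels are
rendered as a 30 Hz carrier gated by a rectangular envelope covering the
first 40 % of each cycle (duty 0.4), with lognormal per-burst amplitude
jitter (SD 0.1), optional Poisson small-unit contamination (half-sine
kernels of 50 ms), and additive Gaussian noise. Defaults: 0.2 Hz cycles,
burst amplitude 1, observation noise SD 0.02, phase noise 0.1 rad/sqrt(s).
The 1000 Hz raw rate makes the downsample-to-200 Hz step of preprocessing
non-trivial.

What the generator emulates: rhythmic antagonist bursting, weak directed
coupling, slow phase wandering, small-unit contamination, the
connected-versus-cut-connective design (intersegmental entries zeroed, with
optional compensatory rescaling of intrasegmental coupling). What it does
not: spike shapes, motor-unit statistics, nonstationary episode structure,
conduction delays. Tests passing on generated data therefore demonstrate
correctness of the analysis machinery under known ground truth, not
biological validity on real recordings.

In fixtures that probe estimation accuracy the node frequencies are set
slightly heterogeneous (e.g. 0.17–0.25 Hz across hemisegments). Real
segmental rhythms differ slightly in intrinsic frequency; exactly identical
frequencies are a degenerate special case in which uncoupled channels stay
accidentally phase-aligned for long stretches and directed couplings become
poorly identifiable. Heterogeneity is the realistic, better-posed condition.

## Numerical choices

* Preprocessing: order is DC-remove, rectify, smooth (0.05 s moving
  average), anti-alias low-pass at 0.8x the target Nyquist, decimate,
  re-centre. The final mean re-subtraction is what makes the analytic
  trajectory encircle the origin.
* Hilbert edge artifacts: 0.25 s at each end are excluded from onset
  detection.
* k-means on amplitudes: min/max initialisation makes it deterministic;
  degeneracy ratio 0.6 declares "no small units present".
* Welch defaults: 60 s segments for full recordings; an epoch of length L
  uses L/4 segments. The fitted frequency grid is capped at 80 points.
* Stability: parameter vectors whose drift matrix has eigenvalues with
  non-negative real part are rejected with a large penalty during
  optimisation and an explicit error elsewhere.
* Laplace Hessians are symmetrised and eigenvalue-floored; optimiser
  non-convergence from every start raises an error rather than returning a
  silent fallback.
* Problem sizes used by the test-suite simulation studies: 100–600 s
  recordings for phase-connectivity checks; 600 s / 30 s segments for
  parameter and model recovery (10 seeds); 4000 s for the closed-form
  versus Welch cross-spectrum equivalence check (2 nodes, damping 1.2).
  These sizes were chosen so each check is decisive at desk scale.

## Worked example

```{r example, eval = FALSE}
net <- make_architecture_network(2, strengths = list(intra = 0.5, inter = 0.3))
rec <- simulate_recording(net, simulation_params(duration = 300, seed = 1))
prep <- preprocess(rec)

# undirected phase connectivity
pc <- pc_report(prep)
dplyr::select(pc, class, likelihood, n_intervals)

# directed spectral model comparison over the two-segment space
csd <- empirical_csd(prep, seg_len = 60)
fits <- lapply(1:7, function(id) fit_model(csd, id, n_starts = 2, seed = id))
bms(fits)
```

## Known limitations

* The spectral stage assumes second-order stationarity within an epoch;
  strongly episodic recordings should be pre-screened (e.g. with the PC
  stage, mirroring the "biased-interval" workflow) before fitting.
* Evidence differences between nested architectures hinge on the prior
  strength scale of allowed connections; the default is calibrated for
  rhythms near 0.2 Hz with damping of order 0.25–0.5 s^-1 and should be
  revisited for very different systems.
* Directed strengths between structurally symmetric nodes with identical
  spectra are weakly identified at short recording lengths; expect
  per-direction scatter even when symmetrised averages are stable.
* PC cannot express directionality, and its thresholds (0.8 / 50 s / 0.3)
  are calibration choices inherited from the original manual tuning.
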