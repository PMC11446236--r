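---
title: "Methods: smFRET trace processing and state-occupancy decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smFRET trace processing and state-occupancy decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfretr)
```

## Scope and model

`smfretr` quantifies conformational state occupancy from two-channel
(donor/acceptor) single-molecule FRET recordings of membrane receptors,
as used to compare GluN1 conformations across NMDA receptor GluN2
subtypes and ligand conditions. The package covers everything downstream
of spot extraction: channel correction, automated trace selection,
per-movie display histograms averaged across replicate movies, a
fixed-mean trimodal Gaussian occupancy decomposition, and the Förster
conversion between inter-residue distance and expected efficiency. It
also contains a full trace simulator, because the statistical claims the
pipeline makes (occupancy recovery, selection behavior) are only testable
against traces with known ground truth.

The physical picture is a hidden-state one. A receptor occupies one of a
few conformational states; each state *k* has an ideal efficiency
$\mu_k \in [0,1]$, a width $w_k$ that lumps all conformational motion
faster than the 10 frames/s acquisition into a per-frame Gaussian jitter,
an equilibrium occupancy $\pi_k$, and a mean dwell time in frames.
Measured efficiency per frame is $E_t = I_A/(I_A + I_D)$ on corrected
channels. The trimodal decomposition then reads occupancies off the
ensemble histogram as area shares of Gaussian components with fixed
means (0.3, 0.5, 0.7).

## The simulator and what it does (not) emulate

`simulate_movie()` draws receptors, assigns each of the two labeling
sites a donor or acceptor independently with probability 1/2 (so half the
receptors are the FRET-competent donor/acceptor species; donor/donor and
acceptor/acceptor receptors are counted but not rendered), and renders
each DA receptor from a Markov state path.

**State path.** The chain runs at frame resolution: from state *i* it
exits each frame with probability $1/d_i$ ($d_i$ = mean dwell in frames)
and on exit draws a destination (self allowed) with weights
$\pi_j / d_j$, renormalized. This construction was chosen because its
stationary distribution is *exactly* $\pi$ for any dwell vector — the
property the whole recovery analysis rests on — and because for equal
dwell times (the default) it reduces to drawing destinations in
proportion to occupancy. The initial state is drawn from $\pi$, so paths
are stationary from the first frame. The price is that the realized mean
dwell in state *i* is $d_i/(1 - w_i)$, slightly longer than $d_i$; with
the default occupancy structures the inflation is below 15% and
irrelevant to everything measured downstream. The published experiments
give no dwell times (sub-100 ms transitions are unresolved at 10
frames/s), so the default is 20 frames (2 s): long enough for clear
state segments, short enough that a trace visits several states.

**Photophysics.** Per frame, the ideal efficiency is
$e_t = \mathrm{clamp}(\mu_{s_t} + w_{s_t}\,\varepsilon_t,\ 0,\ 1)$ with
standard-normal $\varepsilon_t$. Each fluorophore photobleaches in a
single step with a geometric (memoryless) per-frame hazard; defaults are
mean 600 frames (donor) and 400 frames (acceptor) so that most traces
survive the >50-frame lifetime filter while still showing their bleach
steps within an 800-frame recording. Before either bleach the channels
carry

$$I_D = T(1-e_t) + b + \eta_D, \qquad
  I_A = \tfrac{1}{\gamma_A}\bigl(T e_t + \chi\, T(1-e_t)\bigr) + b + \eta_A,$$

with total intensity $T$, background $b$, crosstalk $\chi = 0.15$, and
acceptor gain $\gamma_A = 1.2$ — the inverse of the correction stage, so
that correction recovers $e_t$ exactly when noise is zero (a tested
invariant, ≤ 1e-9 per frame). After the acceptor bleaches the donor
dequenches to the full $T$ and the acceptor channel carries only donor
bleed-through; after the donor bleaches both channels are background.
Noise is additive Gaussian per channel (read-noise-dominated sCMOS
regime), default 10% of $T$. The simulator does not emulate image
formation, diffusion, blinking, spectral fluctuations, or non-geometric
bleaching; conclusions from passing tests are about the trace-level
statistics, not about raw-movie artifacts.

**Condition library.** `condition_model()` packages one state model per
receptor subtype × probe site (NTD-W56 or LBD-D677) × ligand condition.
Peak positions are the published values (e.g. GluN2D NTD apo-like: main
peak ~0.18, minor ~0.60). The publications describe occupancies only as
major/minor, so the library uses 0.80/0.20 for two-state conditions and
1.0 for single peaks, with two documented exceptions chosen from the
qualitative descriptions: GluN2C NTD apo-like uses 0.60/0.40
(its low-FRET peak is "larger" but the compact peak remains substantial,
and its splayed occupancy sits strictly between GluN2A/B and GluN2D),
and minor skew states elsewhere carry 0.15. These weights are declared
approximations, not measured ground truth, and every model can be
overridden via `state_model()`.

## Trace correction and selection

`correct_trace()` scales both channels first
($I_D' = g_D I_D$, default $g_D = 1$; acceptor by $\gamma_A = 1.2$) and
then subtracts donor bleed-through
($I_A' = \gamma_A I_A - \chi I_D'$). The order matters and is fixed:
it is the standard gamma/crosstalk pipeline and the exact inverse of the
simulator.

`detect_bleach_step()` finds bleaching by binary segmentation on the
mean-shift least-squares cost. A candidate split is pursued when the
segment-mean change exceeds the threshold, and counted as a bleaching
step only when it is a *drop* larger than three times the robust noise
scale, taken as 1.4826 × the median absolute deviation of the first
differences. Upward steps — donor dequenching — are located but never
counted. Degenerate inputs behave predictably: a constant trace yields
no step; in noise-free traces the scale collapses and any clean drop is
found exactly (verified against an exhaustive change-point search). Two
consequences of this rule are worth knowing. First, the MAD of first
differences overestimates the per-frame noise s.d. by up to $\sqrt{2}$,
which makes the detector conservative. Second, at the default 10%
channel noise, an acceptor drop from a mid-FRET level sits *below* the
threshold, so acceptor bleaching in low-FRET traces often goes
undetected until the donor bleaches; the lifetime filter absorbs most of
the damage, but roughly 5% of pooled histogram frames can be
post-acceptor-bleach. This is a property of the thresholded detector at
that noise level, documented rather than hidden.

`select_traces()` applies the selection rules as explicit thresholds:
at most one accepted bleach step per channel and at least one channel
bleaching within the recording (single-molecule evidence); FRET lifetime
(frames with $E > 0.125$ before the first bleach) strictly greater than
50; coefficient of variation of total intensity over pre-bleach frames
≤ 0.20 ("constant total fluorescence"); and Pearson donor–acceptor
correlation over pre-bleach frames ≤ −0.2 (global anti-correlation).
The lifetime threshold is the published setting; the CV and correlation
cutoffs replace manual curation and were fixed once at values that pass
clean simulated traces with margin while rejecting constructed defects —
reproducibility requires numbers, and both are configurable. Selection
is monotone: loosening any threshold never shrinks the passing set
(tested).

## Histograms, quartiles, occupancies

`trace_histogram()` pools the first 50 valid frames of each selected
trace — the deterministic display-histogram convention — and bins at
width 0.02 over $[-0.1, 1.1]$, a range that accommodates noise
excursions outside $[0,1]$ without clipping; each valid frame is one
count. `average_histograms()` treats movies as equal-weight technical
replicates and reports the elementwise mean and s.d./√n SEM.
`quartile_summary()` walks each movie's bins in increasing FRET and
takes the center of the first bin whose cumulative fraction *strictly*
exceeds 0.25/0.50/0.75, then averages across movies; the strictness
matters at exact ties and is pinned by a dedicated test.

`fit_trimodal()` fits
$\sum_{i=1}^{3} A_i \exp\!\bigl(-(x-\mu_i)^2/(2\sigma_i^2)\bigr)$ with
$\mu = (0.3, 0.5, 0.7)$ fixed to the (bin center, ensemble mean) pairs,
by bounded Levenberg–Marquardt: $A_i \ge 0$,
$\sigma_i \in [0.005, 0.5]$ (no degenerate spikes, no component wide
enough to swallow the axis), initialization $A_i = 0.05$,
$\sigma_i = 0.01$, convergence at relative cost change < 1e-10 or 1000
iterations. **A single shared width is the default.** This was a genuine
design fork: with realistic channel noise the effective component width
is ~0.09–0.11 while the means are 0.2 apart, and with independent widths
the global least-squares optimum is degenerate — one broadened middle
component absorbs most of the distribution (this is a property of the
objective, reproduced identically by an independent optimizer, not an
optimizer artifact). The shared-width model matches the single width
symbol of the published component formula and is well conditioned;
`shared_sigma = FALSE` restores fully independent widths.
`component_occupancies()` integrates each component and their sum on the
histogram grid by composite Simpson's rule (trapezoid-correcting the
last interval when the interval count is odd) and reports percent area
shares; they agree with the analytic $A_i\sigma_i$ shares to < 0.1
point and always sum to 100 within 1e-6.

**What occupancy recovery can and cannot do.** The end-to-end harness
`occupancy_recovery_report()` (simulate → select → histogram → fit →
occupancies) recovers a three-state model placed *on* the fixed means
to a few points at 300 traces × 4 movies. When state means are displaced
from the fixed means by ~0.03 (e.g. a low state at 0.33) the fixed-mean
decomposition acquires a systematic bias of roughly 6–9 points at the
default noise level, because mass centered off a fixed mean must be
explained by neighboring components; no amount of data removes it. Users
comparing occupancies across conditions should treat the decomposition
as a consistent *relative* measure — the use it is put to here — rather
than an unbiased per-state estimator. For states well below the fixed
basis (the ~0.2 "splayed" NTD peak), `histogram_mass_below()` provides a
direct low-FRET mass measure; it is what reproduces the published
splayed-occupancy ordering GluN2A ≈ GluN2B < GluN2C < GluN2D in the
packaged apo-like NTD models.

## Distances and expected FRET

`fret_from_distance()` and `distance_from_fret()` implement
$E = 1/(1 + (r/R_0)^6)$ and its exact inverse with the AF555/AF647
Förster radius $R_0 = 51$ Å as default, so $E(51\,\text{Å}) = 0.5$ by
definition. `residue_pair_distance()` measures the Euclidean distance
between two named atoms in a PDB file (β-carbons by default, the
convention when dye-linker geometry is not modeled; alternate locations
resolve to the highest-occupancy record unless an error policy is set).
Orientation-factor and accessible-volume dye modeling are deliberately
out of scope: the conversion is the bare point-to-point estimate, useful
for ranking structural classes, and expected to differ from measured
efficiencies in absolute terms.

## Numerical and interface choices

* All randomness flows from one user seed, expanded deterministically
  per movie and per trace; simulation outputs are bit-identical across
  runs with equal seeds (tested).
* Trace files are plain tab-separated text with a key–value header and
  `>trace_id` blocks; intensities are written with 17 significant
  digits so read(write(x)) round-trips exactly.
* Run configurations are YAML with sections `simulate`, `qc`,
  `histogram`, `fit`, `forster`; unknown keys are rejected by name and
  every run log records the fully resolved configuration and seed.
* Problem sizes used in the validation suite (e.g. 150–300 traces × 4
  movies, 400–800 frames) were chosen as the smallest sets at which the
  relevant statistics are stable; all fixtures are generated in code.

## Known limitations

* Occupancy decomposition is biased for states displaced from the fixed
  means (quantified above) and blind to states outside ~[0.2, 0.8].
* The step detector's fixed 3× robust-scale rule misses small bleach
  drops at high noise; traces selected despite an undetected acceptor
  bleach contribute a small low-E contamination to display histograms.
* Dwell-time inference, hidden-Markov state assignment, and transition
  density analysis are out of scope, as is anything upstream of
  extracted traces.
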