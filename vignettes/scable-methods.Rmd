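---
title: "Passive cable modeling and synapse mapping: models, conventions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive cable modeling and synapse mapping: models, conventions, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scable)
```

## The model

`scable` treats a neuron as a passive electrical tree. A morphology is a
rooted tree of 3D nodes with radii; `compartmentalize()` turns it into a
chain-of-cylinders circuit: the soma is a single isopotential spherical
compartment of membrane area $\pi d^2$, dendrites are cylinders of length at
most `max_compartment_length` (default 1 µm). Each compartment carries a
leak conductance $g_m = A/R_m$ toward $E_\mathrm{leak}$ and a capacitance
$C = A\,C_m$; neighbours are coupled by the axial conductance of the
half-cylinders between their centers, $R_\mathrm{axial} = 4 R_i \Delta x /
(\pi d^2)$ per cylinder. The membrane equation per compartment is

$$C_i \frac{dV_i}{dt} = -g_{m,i}(V_i - E_\mathrm{leak})
  + \sum_{j \sim i} g_{ij}(V_j - V_i) - g_{\mathrm{syn},i}(t)(V_i - E_\mathrm{rev}) + I_{\mathrm{inj},i}(t).$$

Synapses are conductances, not currents: the unnormalized difference of two
exponentials
$g(t) = G_\mathrm{max}\,(e^{-t/\tau_1} - e^{-t/\tau_0})$ with rise
$\tau_0$, decay $\tau_1$. Because the synaptic current is
$g(t)\,(V_\mathrm{local} - E_\mathrm{rev})$, a large conductance on a
high-impedance dendrite depolarizes its own compartment and reduces its
driving force — the mechanism behind every sublinearity this package
measures. Two quantal parameter presets are built in
(`quantal_conductance()`): immature
($\tau_0 = 0.073$, $\tau_1 = 0.26$ ms, $G_\mathrm{max} = 0.004$ µS; peak
0.00175 µS, half-width 0.36 ms) and adult
($\tau_0 = 0.072$, $\tau_1 = 0.24$ ms, $G_\mathrm{max} = 0.0032$ µS; peak
0.00133 µS, half-width 0.341 ms).

Assumptions: uniform passive properties; no active conductances, NMDA
receptor kinetics, or gap junctions; the soma is a point (its size is
irrelevant under an ideal clamp, and enters only through its area
otherwise); dendritic diameter is piecewise constant per reconstruction
edge.

### Default parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| $C_m$ | 0.9 | µF/cm² | specific membrane capacitance |
| $R_m$ | 20,000 | Ω·cm² | specific membrane resistance ($\tau_m$ = 18 ms) |
| $R_i$ | 150 (100–200) | Ω·cm | axial resistivity; its physiological value is uncertain, so protocols accept the full range |
| $E_\mathrm{leak}$ | −70 | mV | leak reversal; equal to the −70 mV holding potential so rest equals hold |
| $E_\mathrm{rev}$ | 0 | mV | AMPA-receptor reversal |
| `dt` | 0.005 | ms | integration step for clamp-current protocols (0.01 ms for the slower EPSP protocols) |
| `max_compartment_length` | 1 | µm | spatial resolution |

Internally the unit system is µm, ms, mV, µS, nF, nA; the conventional
units above are converted at the boundary.

## Numerics

The integrator is a Crank–Nicolson scheme on the tree, implemented as a
backward-Euler half-step with midpoint coefficients followed by
extrapolation; the first full step is plain backward Euler to damp any
inconsistent initial transient. Each step solves one symmetric tree system
by Hines-ordered elimination (children eliminated into parents in reverse
topological order, then forward substitution), so a step costs O(number of
compartments). Synaptic conductances enter the matrix diagonal, keeping the
per-step system linear and the scheme unconditionally stable for
arbitrarily fast conductances.

The ideal voltage clamp is a Dirichlet condition at the soma node; the
clamp current is the sum of the axial, leak and local synaptic currents at
that node. An optional `series_resistance` (MΩ) instead couples the soma to
the command potential through the pipette, as in a real recording.
Divergence (non-finite or implausibly large voltages) raises an error
advising a smaller `dt`.

Accuracy anchors (all enforced by tests): halving `dt` and the compartment
length changes the filtered qEPSC peak by <0.5%; steady-state profiles
match the sealed-cable closed form $\cosh((L-x)/\lambda)/\cosh(L/\lambda)$
within 1%; with the synapse at the clamped soma the clamp current equals
$g(t)(V_\mathrm{hold}-E_\mathrm{rev})$ to machine accuracy; a dense
`deSolve` integration of the same ODEs agrees to <0.1% of peak.

## Measurement conventions

Event statistics follow standard electrophysiology practice: baseline is
the mean over 1 ms preceding the onset; amplitude is the deviation of the
mean over a 100 µs window centered on the peak; rise time is 10–90% with
linear interpolation; half-width is the width at half amplitude; the
weighted decay constant is $\tau_\mathrm{decay} = \int_{t_\mathrm{peak}}^{t_\infty} I\,dt / I_\mathrm{peak}$,
with $t_\infty$ the first post-peak baseline crossing, else the end of a
10 ms window (noisy tails otherwise make the integral ill-defined). The
100 µs peak window biases the measured amplitude of very fast events
slightly downward relative to the instantaneous peak, which in turn widens
the measured half-width by ~2% and shortens the measured rise by ~5% for
the immature conductance waveform; the analytic `biexp_peak()` /
`biexp_half_width()` values are free of this bias. For the same reason the
10–90% rise time of a waveform measured on a sampled grid exceeds the
continuous-waveform value by a few percent; the package therefore anchors
tests to peaks and half-widths, not sampled rise times.

Event detection is a boxcar-smoothed (0.1 ms) robust-SD threshold with a
minimum above-threshold run of 0.2 ms and a 2 ms dead time. A bare
one-sample 4-SD crossing would false-trigger many times per 10 s of white
noise at 50 kHz sampling; the run requirement brings the false-positive
rate below one per 10 s while detecting essentially all events at
signal-to-noise 10. Population kinetics are measured on the onset-aligned
mean waveform (`average_event_waveform()`): per-event threshold crossings
on noisy traces are biased (noise perturbs the 10/90/50% crossings), while
the aligned average recovers rise and half-width to well under 5% at
signal-to-noise 10.

## Protocols

`qepsc_distance_sweep()` places the synapse at the dendritic compartment
whose center path distance (from the soma center) is nearest the requested
distance, ties going distal, and runs one clamp simulation per distance;
distance 0 is the somatic reference. `simulate_ppr()` applies two
conductances at one site, the second scaled by 2.25 at a 20 ms interval,
and measures the second amplitude from the decayed tail baseline; at an
ideally clamped soma the readout is linear, so the somatic ratio equals
2.25 exactly. `quantal_io_curve()` scales a unit conductance to a quanta
count under current clamp and compares the somatic EPSP peak against the
linear extrapolation of a 0.1-quantum reference response;
`dendritic_sublinearity()` is one minus the ratio of the per-quantum
normalized dendritic to somatic responses. `synthesize_mean_mepsc()` forms
the pointwise weighted average of aligned qEPSC traces, weighting each
distance bin (10 µm bins, bin-center representative distances, the soma as
its own bin) by the relative frequency of synapses there, emulating
miniature events arising with equal probability at every synapse; a list of
per-dendrite sweeps is averaged after weighting (pooled mode).

### Why the filtering ratios depend on the clamp model

Under the default ideal clamp, the idealized immature cell (8 µm soma, one
unbranched 90 µm × 0.47 µm dendrite, $R_i$ 150 Ω·cm) attenuates the
45 µm qEPSC by ≈61% with a rise ≈2.5× and half-width ≈2.1× the somatic
values. An independent linearized frequency-domain calculation (killed-end
transfer function applied to the conductance spectrum) gives the same
kinetic ratios and a 50% amplitude ratio before driving-force saturation,
confirming these are properties of the model rather than of the solver.
Experimentally reported filtering ratios for comparable configurations are
smaller (≈48%/195%/180%); a non-ideal clamp brings the simulation toward
them, because pipette series resistance attenuates and slows the fast
somatic event much more than the already-filtered dendritic one. The
`series_resistance` argument exposes this: at 16 MΩ (a typical
uncompensated whole-cell value) the same comparison yields ≈58%/208%/201%.
The package's default remains the ideal clamp — it is the cleaner, fully
specified boundary condition — and the acceptance script reports the
ideal-clamp values.

The sublinearity comparison uses the three-dendrite idealized cell (9 µm
soma) and quanta {1, 5, 10, 20}. On very small cells the somatic reference
site itself saturates at the largest conductances, so the sublinearity
index can plateau or dip by a few tenths of a percent at 20 quanta on a
single-dendrite model; the larger three-dendrite cell buffers the soma and
the index is monotone there.

## Synapse mapping

Candidate spots (position, per-axis diameter, peak intensity, optional
soma-channel intensity) are filtered with strict inequalities: all three
diameters must exceed the PSF (default 0.3, 0.3, 1.1 µm) — a spot exactly
at the PSF is rejected — and the peak intensity must exceed the background
mean plus three background SDs. The per-axis reading of the size rule is
the conservative choice where a single sub-resolution axis disqualifies a
spot. Somatic puncta additionally require a soma-channel intensity above
half the stack maximum. Skeletons are resampled at 100 nm along each
branch (samples at step multiples from the branch start, plus the exact
branch end); path distances are measured from the soma surface, with bins
half-open `[lo, hi)`. A punctum is assigned to the nearest resampled
sample within the search radius `local radius + 0.2 µm` and inherits its
path distance. Densities are reported both per micrometre
(count/(segments × 0.1 µm)) and per segment, which differ only by the
resampling step.

## The synthetic generators

The generators provide ground truth for every analysis stage, encoding the
developmental contrasts as presets: the adult preset grows longer arbors
(mean tip path 95 vs 65 µm), branches more (rate 0.015/µm to order 3 vs
0.012/µm to order 2), keeps the primary-dendrite count at 5, and thins
diameters (0.41 vs 0.47 µm); puncta are a homogeneous Poisson process along
arclength (0.7/µm) with radial jitter bounded inside the assignment search
radius, plus 20% sub-threshold decoys to exercise the filters; event trains
are Poisson (1.37 vs 1.14 Hz) with amplitudes around 48 vs 24 pA, kinetics
matching recorded miniature events (rise constants 0.17 vs 0.26 ms, decay
0.75 vs 1.45 ms), and white Gaussian noise at signal-to-noise 10. Every
generator is a deterministic function of its configuration, seed included.

What the generators deliberately do not emulate: correlated (pink)
recording noise, event-rate bursting, spatially clustered synapses,
diameter taper along dendrites, 3D image formation, and detection artifacts
of commercial spot-finding software. Passing the closure tests therefore
shows that the analysis stages invert the stated generative model, not that
they are robust to every pathology of real recordings.

## Problem sizes

The test-suite and acceptance computations use: 1 µm compartments and
dt = 0.005 ms for clamp-current protocols (91–271 compartments, 8–28 ms of
simulated time), dt = 0.01 ms and 15 ms for EPSP protocols, 40 trees per
stage for the generator contrast checks, 90 s of synthetic recording at
50 kHz (≈540 events) for parameter recovery, and 100 Monte-Carlo repeats
for the diameter estimator. These sizes were chosen to keep every
stochastic check comfortably inside its tolerance while the whole suite
runs in a few minutes.

## Known limitations

* Purely passive: no voltage-gated channels, so predictions apply to
  subthreshold signals only.
* The soma is a single isopotential compartment; somatic geometry enters
  only through its area.
* Diameter estimation from line profiles assumes an isolated, roughly
  Gaussian peak; crossing structures violate it.
* `assign_puncta()` is an exact all-pairs search — appropriate for up to
  ~10^4 puncta × 10^5 skeleton samples; larger problems would want a
  spatial index.
* The branched idealized-cell variants split the mother dendrite at equal
  length fractions with daughters running to the same tip distance; this is
  one reasonable convention, and branch geometry is otherwise
  unconstrained.
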