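---
title: "Modelling entorhinal synapse loss in a DG-CA3-CA1 microcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling entorhinal synapse loss in a DG-CA3-CA1 microcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hippoflow` simulates a 21-cell model of the hippocampal trisynaptic
pathway, degrades its entorhinal input in stages, and quantifies the
consequences with burst statistics, nonlinear (delay-embedding) complexity
measures and directed information flow.  This vignette documents the model,
its assumptions, the tunable parameters, and the design decisions that were
genuinely open — including where we deliberately departed from the obvious
construction and why.

## The circuit model

**Cells.** The dentate gyrus contains four granule cells, two basket cells
and one mossy cell; CA3 and CA1 each contain four pyramidal cells, two
basket cells and one O-LM cell (21 cells in total; the granule and
pyramidal cells are the "principal" population over which all region-level
statistics are averaged).  Every cell has the same simplified morphology: a
16-compartment passive tree — soma, one axonal compartment, and a single
apical cable of seven proximal plus seven distal dendritic compartments.
Compartments follow conductance-based leaky dynamics with axial coupling;
a spike is a threshold-crossing event at the soma followed by a reset and
an absolute refractory period.  There are no active dendritic channels:
the model is built for circuit-level questions (burst structure,
information routing), not for pharmacology or detailed electrogenesis.

Integration uses exponential-Euler steps (`dt` = 0.1 ms), which is exact
for a compartment with piecewise-constant conductances and therefore stable
for the stiff synaptic decays; the single-compartment step response matches
the analytic RC charging curve to machine-level accuracy (this is a test).

**Synapses.** AMPA, NMDA and GABA-A receptors are difference-of-exponential
conductances; NMDA is additionally gated by a Jahr–Stevens-style sigmoidal
magnesium block `1/(1 + [Mg]/3.57 exp(-0.062 V))`.  Wiring follows the
trisynaptic template: EC2 ("perforant path") onto granule- and CA3
pyramidal-cell distal dendrites and, weakly, onto DG/CA3 basket cells;
mossy fibers from granule cells onto CA3 pyramidal cells, CA3 baskets and
the mossy cell; the mossy cell back onto granule cells and DG baskets;
Schaffer collaterals from CA3 onto CA1 pyramidal cells and CA1 baskets;
EC3 ("temporoammonic") input onto CA1 distal dendrites; basket cells onto
local principal somata; O-LM cells onto local distal dendrites, excited by
their local pyramidal cells; and a septal GABAergic drive onto all
interneurons.  Topology lives in code; every quantitative constant lives in
one versioned YAML file (`inst/extdata/default-network.yaml`).

**Drives.** EC2 and EC3 are inhomogeneous Poisson sources whose rate is a
theta envelope (8 Hz, depth 1) multiplied by a gamma carrier (40 Hz, depth
0.5), one independent train per synaptic contact; the two layers are locked
in antiphase, so strong EC2 input coincides with weak EC3 input.  The
septum is a deterministic theta-locked burst generator, the standard
reading of rhythmic septal disinhibition.  Drive trains are generated for
every drive synapse *whether or not it is active*, so deleting synapses
never reshuffles the input realisation of the survivors — deletion effects
are never confounded with resampling noise.

**LTP.** Plasticity is potentiation-only (no depression term), restricted
to excitatory synapses onto principal cells: each presynaptic arrival
within 20 ms at or before a postsynaptic spike adds
`learning_rate * (1 - w/weight_ceiling)`, a soft-bounded Hebbian rule.
Defaults (`learning_rate` 5e-4, ceiling 1.15) keep the potentiation a slow
modulation rather than a bifurcation: with interneuron-targeted synapses
plastic, or with a generous ceiling, runaway potentiation of the
excitation–inhibition balance destabilises the circuit — we observed both
failure modes during calibration and they motivated the restriction.

## The degeneration model

Degeneration inactivates EC2-pathway synapses cumulatively at fractions
0.09, 0.18, 0.26 and 0.35 (`round` half-up of `fraction × N_target`); the
synapses removed at a lower fraction are always a subset of those removed
at a higher one, the total synapse count never changes, and nothing outside
the EC2 pathways is ever touched.  The default order is the synapse-table
order; the builder lays the 40 EC2 contacts down in rounds — contact 1 of
every target cell, then contact 2, and so on, alternating DG and CA3
targets — so deletion thins every cell's entorhinal drive in lockstep, the
diffuse-denervation regime of early degeneration.  A seeded-random order is
available for sensitivity runs.

Two design points deserve emphasis:

* **AMPA-only EC2 contacts.**  Each principal target receives four
  identical AMPA contacts (on four distal compartments), baskets two.
  Identical contacts make every deletion step remove the same physical
  quantum of drive.  An earlier construction with AMPA+NMDA contact pairs
  made alternate deletion rounds strong (AMPA) and nearly inert (NMDA),
  producing spurious plateaus between adjacent deletion levels.  NMDA
  receptors and their voltage gating remain at the mossy-fiber, Schaffer,
  EC3 and local-excitation synapses.
* **Feedback-dominated interneurons.**  The EC2→basket conductance is
  deliberately small; baskets are driven mainly by collaterals of the local
  principal cells (and the mossy cell in DG).  Because the paper's lesion
  also removes EC2 synapses on interneurons, a strongly EC2-driven basket
  population would make deletion *disinhibitory*, and intermediate levels
  could then fire more than the control.  With feedback-dominated
  interneurons, inhibition tracks principal activity and scales down with
  it, which keeps all four burst statistics monotone in the deletion
  fraction.

## Calibration of the defaults

The membrane, synaptic and drive constants are not taken from any published
table (the upstream literature leaves them to cited prior work); they were
calibrated, once, so that the *control* circuit satisfies the study's
qualitative fixed points, and then frozen:

* principal cells burst once per theta cycle with ~5–9 spikes per burst,
  so that mean burst duration plus mean inter-burst interval closes one
  125 ms theta cycle within 20%;
* the circuit is *saturated* in the control: the EC2 drive is high-rate
  (120 spikes/s per contact) with proportionally small unitary
  conductances, so threshold crossings are reliable and the per-cycle burst
  pattern is nearly stereotyped.  Deletion then moves cells from the
  saturated into the marginal regime where Poisson fluctuations decide
  whether a cycle bursts at all — the mechanism behind both the monotone
  burst decline and the chaos transition below;
* cells are electrotonically compact (axial coupling 8 mS/cm², space
  constant of several compartments), because with a leakier cable the
  distal entorhinal input could not drive the soma at biophysically
  sensible conductances.

Defaults: 16 s simulated time (128 theta cycles), burst criterion
ISI ≤ quarter theta period with a 2-spike minimum, burst-offset-to-onset
IBI convention (which makes duration + IBI ≈ one cycle for theta-locked
trains), aggregation over principal cells with missing values excluded.

## Complexity analysis

All estimators are generic and validated on benchmarks with known
properties (`logistic_map`, `henon_map`, `lorenz_series`,
`coupled_binary_processes`, `theta_poisson_trains`): the Rosenstein
exponent recovers ln 2 on the fully chaotic logistic map and a negative
value in its period-2 regime, the correlation dimension recovers 2 on
planar noise, ~1.2 on the Hénon attractor and 1 on a limit cycle, FNN
selects 2/2/3 for sine/Hénon/Lorenz, and the plug-in transfer entropy
matches enumeration-exact values to 0.01 bits at n = 10⁶.

Estimator conventions: AMI uses 16 equal-width bins and returns the first
local minimum of a lightly smoothed curve (the raw histogram-AMI of a
noiseless periodic signal carries binning ripple; a structureless series,
AMI < 0.05 bits everywhere, returns delay 1); FNN uses the Kennel
criteria (rtol 15, atol 2, 1% threshold) with a guard that near-exact
duplicate neighbours — unavoidable on periodic orbits — are not counted as
false unless the next coordinate genuinely differs; the correlation sum is
a full pairwise count with a Theiler window, with the scaling region chosen
as the longest contiguous radius window whose local slopes stay within 10%
of their median; recurrence plots fix the radius as the distance quantile
that achieves a 10% recurrence rate (nudged off exact distance plateaus),
and the diagonal-line entropy (base 2, lines ≥ 2) censors border-truncated
lines, which removes the spurious length spread that a strictly periodic
signal inherits from the plot border.

**The analysis signal.**  Region-level complexity can be computed on two
signals: the averaged z-scored somatic voltage (`region_voltage`) and the
binned multiunit spike-count series of the region's principal cells
(`region_activity`; 5 ms bins, counts clipped at 2).  The correlation
dimension and recurrence entropy default to the voltage signal, whose
continuous amplitudes suit distance-based estimators.  The Lyapunov
exponent defaults to the count series, for a structural reason worth
stating plainly: for *any* stationary stochastic continuous signal the mean
log nearest-neighbour divergence is non-decreasing (nearest neighbours
start below the typical cycle-to-cycle variability and relax up to it), so
a voltage-based Rosenstein slope cannot distinguish a noisy limit cycle
from weak chaos by sign — it is positive for both.  The quantised count
series does not have this defect: in a stereotyped theta-locked network
most same-phase patterns coincide exactly, the tracked *distinct*-pattern
pairs relax back toward the common cycle (distances are floored at half a
count quantum, the resolution of the measurement), and the slope over the
first theta period (fit window bins 3–15, Theiler window one period,
planar embedding with delay 5 bins) is genuinely negative.  A
cycle-skipping degenerate network produces diverging patterns and a
positive slope.  Under the shipped defaults the median exponent over ten
seeds is ≤ 0 for the control and > 0 at every deletion level — the
regression test that guards the calibration.

## Information flow

Spike counts of each region's principal cells are binned at 10 ms and
clipped to the alphabet {0, 1, 2, ≥3}, which bounds the plug-in bias at
achievable sample sizes; entropy, mutual information and transfer entropy
(histories k = l = 1) are plug-in estimates in bits, with no bias
correction by default.  Transfer entropy is computed for both directions of
DG↔CA3 and CA3↔CA1, and pathology values are normalised per seed as
percent of the same-seed control.  In the control, flow along the
anatomical directions exceeds the reverse directions.

## What the synthetic data do and do not show

Every quantitative claim in the package is made about this synthetic
circuit under its calibrated defaults.  The generator reproduces the
qualitative signatures reported for hippocampal degeneration — monotone
loss of spikes, spikes per burst and burst duration, rising inter-burst
interval, a stable-to-divergent transition of the regional dynamics, and
direction-resolved information flow — but it does not emulate cell death,
synaptic compensation, cholinergic modulation, morphological detail or
inter-animal variability.  Passing tests therefore validate the estimators
and the implemented mechanism, not clinical quantities; absolute spike
counts and entropy values depend on the calibrated operating point and the
simulated duration.

## Known limitations

* Threshold-reset somata cannot express depolarisation block or
  intrinsic bursting; burst structure is inherited from the drive envelope,
  refractoriness and inhibition.
* Aggregated isolated-DG statistics can be non-monotone at high deletion
  (fully denervated cells drop out of per-cell means, leaving healthier
  survivors); the cumulative DG-CA3-CA1 and CA3-CA1 regions are monotone.
* The Lyapunov sign criterion is a property of the *median over seeds*;
  individual seeds scatter by ±0.02 per bin around it.
* The plug-in information estimators are biased upward at small n; with
  the default 10 ms bins and 16 s runs the bias is well below the effects
  of interest (the independence tests bound it at 0.01 bits at n = 10⁵).

## Problem sizes

Default analyses use 16 s of simulated time per run (160 000 integration
steps, ~3 100 activity bins after transient discard), ten replicate seeds
per deletion level, reference budgets of 2 000–2 500 points for the O(n²)
neighbour searches, and up to 4 000 embedded points for correlation sums
and recurrence plots.
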