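---
title: "Models and methods behind msngain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msngain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msngain)
```

`msngain` studies how the balance of synaptic excitation and inhibition sets
the firing output of striatal D1 medium spiny neurons (D1-MSNs), and how a
loss of the neuronal glutamate transporter EAAC1 (gene *Slc1a1*) shifts that
balance. The package covers the full chain: dendritic morphology in and out
of SWC files, a multicompartment conductance-based cell model, calibration
of synaptic conductances against miniature postsynaptic currents (mPSCs),
input–output mapping under randomized excitatory/inhibitory input ensembles,
and the arithmetic that attributes GABA supply to neuronal uptake, glial
uptake and de novo synthesis. This vignette explains the models, the
parameters that matter, and the design decisions, in that order.

## The cell model

The membrane follows the standard branched cable equation. A morphology
(`read_swc()`, `synthesize_morphology()`) is discretized into compartments no
longer than `max_seg_length_um` (default 20 µm); each compartment carries a
membrane capacitance and a leak conductance proportional to its frustum
surface area, and neighbouring compartments are coupled by axial conductances
computed from the axial resistivity (150 Ω·cm). The soma is treated as an
equivalent-area cylinder of length and diameter $2r$, so a spherical soma of
radius $r$ keeps its $4\pi r^2$ area.

Seven voltage-gated channel populations are placed exactly as the source
model prescribes: sodium (2.4 S/cm²) confined to a 50 µm × 0.5 µm axon
initial segment (AIS, appended automatically when the morphology has no
axon), and Ca~V~1.2 (6.7·10⁻⁶), Ca~V~1.3 (1.0·10⁻⁴), K~AS~ (4.0·10⁻⁵),
K~DR~ (5.0·10⁻³), K~IR~ (1.0·10⁻⁴) and K~RP~ (2.0·10⁻⁴ S/cm²) on soma and
dendrites.

**Gating kinetics are stand-ins.** The channel *types* and *densities* are
published; their rate equations are not (they live in a simulator-specific
deposit). The package therefore ships a generic Hodgkin–Huxley gate library
(`gate_spec()`): Boltzmann steady states and either constant or bell-shaped
voltage-dependent time constants. The default parameters were tuned once,
behaviourally, so that the assembled wild-type cell shows the canonical
D1-MSN phenotype: resting potential near −89 mV dominated by the inward
rectifier, input resistance near 300 MΩ, delayed spike onset, rheobase
around 25–40 pA, and a monotone frequency–current curve over sustained
(500 ms) 10–80 pA somatic steps without depolarization block. They are data,
not code — pass modified `channel_spec()`s to `discretize()` to substitute
measured kinetics.

Two tuning choices deserve explanation:

* **Sodium inactivation is steep** (half-voltage −57 mV, slope 4 mV). With
  all sodium channels in the AIS and only ~0.01–0.03 µS of axial coupling to
  the soma, a shallow inactivation curve leaves a window conductance that is
  large compared with the AIS leak, and the cell latches into a depolarized
  plateau after its first spike. The steep curve removes the window current
  while leaving enough availability near threshold for repetitive firing.
* **K~RP~ acts as a subthreshold brake** (half-activation −45 mV, τ = 15 ms).
  It holds the interspike voltage near −50 mV under strong drive, which is
  what protects the cell from depolarization block across the input range
  used in the firing-surface experiments.

Reversal potentials default to +50 mV (Na), −90 mV (K), +120 mV (Ca, ohmic,
no GHK), 0 mV (AMPA/NMDA) and −70 mV (GABA~A~); the leak reversal is −80 mV
with a leak density of 6·10⁻⁶ S/cm². All are config-overridable.

## Numerics

`integrate_model()` advances the system with an implicit θ-method — backward
Euler by default (θ = 1, unconditionally stable against synaptic-event
discontinuities), Crank–Nicolson optionally (θ = ½). Each step performs one
Hines-ordered elimination on the tree (children always follow parents in the
compartment table, so a single sweep solves the branched linear system).
Gating variables advance between voltage solves with Rush–Larsen exponential
updates, evaluated through precomputed voltage lookup tables (0.05 mV
resolution over −150…+80 mV). Synapses are dual-exponential conductances
driven by two event-incremented exponential state variables; events between
grid points snap to the next grid time. Units are mV, ms, nA and µS
internally; user-facing currents are pA. The default step is 0.025 ms.
Everything is deterministic: identical inputs give bitwise-identical traces,
and all stochastic generators (placements, trains, morphologies, synthetic
traces) are seed-deterministic with the global RNG state restored afterwards.

Spikes are counted as upward crossings of −10 mV separated by at least 2 ms,
*recorded at the distal AIS compartment* (`spike_record_site()`). The source
model does not state its spike criterion. With sodium confined to the AIS,
the somatic action potential is an attenuated copy of the axonal one
(peaking between −10 and 0 mV at rest, lower still under heavy synaptic
shunt), whereas the AIS spike reaches +40 mV regardless of load — and the
axon is what carries the cell's output.

## Miniature-PSC calibration

`simulate_mpsc()` mirrors the experimental procedure: the synapse is placed
at a random dendritic location (uniform per unit length), the somatic
voltage is clamped (−70 mV for AMPA, +40 mV for NMDA and GABA~A~, matching
the recording conditions), the clamp current is recorded, and the mean over
`n_iterations` randomized placements is summarized by its amplitude, 20–80%
rise time, 50%-decay time t₅₀, and a mono-exponential decay fit
$A_1 e^{-t/\tau_1}$. During this measurement the voltage-gated channels are
removed (`passive = TRUE`), emulating the caesium-based internal solution
and channel blockers used in the recordings; without this, potassium
currents at +40 mV dwarf the synaptic signal. Series resistance is not
modelled.

`match_psc()` then adjusts the peak conductance and decay constant so the
simulated mean mPSC hits a target amplitude and t₅₀ (default tolerance 2%).
Because the somatic amplitude is nearly proportional to `gpeak` under clamp
and t₅₀ is monotone in `tau_decay`, the search alternates a fixed-point
amplitude rescale with a bracketed secant update of the decay constant and
typically converges within 10–20 simulations.

Genotype targets (`genotype_targets()`): the AMPA amplitudes are measured
values (15.0 pA wild type, 19.3 pA knockout at −70 mV), and the NMDA
amplitudes follow from them as amplitude × NMDA/AMPA ratio × driving-force
ratio (15.0 · 0.68 · 40/70 = 5.8 pA; 19.3 · 0.57 · 40/70 = 6.3 pA). The
kinetic targets and the GABA amplitudes are *representative defaults* chosen
by this package (the measured values are shown only graphically in the
source figures): GABA 40 pA/t₅₀ 8 ms in the wild type versus 32 pA/6 ms in
the knockout — smaller and faster, the reported direction — and excitatory
kinetics identical between genotypes (t₅₀ 4.5 ms). The 4.5 ms value respects
a physical floor: averaging over random locations on the large knockout
arbor, dendritic cable filtering alone broadens the somatic mPSC to
t₅₀ ≳ 4.2 ms, so faster targets are unattainable on that morphology.

## Input–output mapping

`run_io_grid()` drives the calibrated cell with `n_exc` excitatory
(co-localized AMPA+NMDA) and `n_inh` GABA~A~ inputs placed randomly along
the dendrites. Per iteration, each input's activation rate is an independent
draw from a normal distribution truncated at zero (SD = 20% of the nominal
rate by default), and events follow a homogeneous Poisson process (regular
trains with jitter are available). Iteration seeds derive deterministically
from `base_seed` and the cell/iteration indices, so whole grids are
reproducible. For these current-clamp trials the NMDA conductance carries
the standard sigmoidal magnesium block at 1 mM: the clamp calibration is
magnesium-free like the recordings it imitates, but an unblocked NMDA
conductance at in-vivo-like rates drives the cell into depolarization block
across most of the grid, so physiological magnesium is the defensible
default for the functional simulations (`nmda_mg_mM = 0` restores the
unblocked case).

Input counts: the wild-type cell receives 100 excitatory and 100 inhibitory
inputs. `build_genotype_model()` scales the *excitatory* count with total
dendritic length (≈200 on the twofold-larger knockout arbor), reflecting the
knockout's higher miniature-EPSC frequency and synapse count; with equal
counts the knockout's doubled membrane load would mask its stronger
excitatory and weaker inhibitory quanta and invert the reported
hyperexcitability. Explicit `n_exc`/`n_inh` arguments override this.

Firing surfaces are summarized three ways: iso-firing contours
(`extract_contours()`, marching squares with points snapped to exact linear
interpolation along grid edges); threshold-linear or 4-parameter-logistic
input–output fits (`fit_io_curve()`), where the offset is the input-rate
threshold (or half-activation) and the gain the slope; and classified
comparisons (`compare_io()`): raising the offset is subtractive, lowering
the gain divisive.

## GABA-source decomposition

A broad-spectrum transporter antagonist removes all glutamate-uptake-derived
GABA; in the knockout only glial uptake remains. `decompose_gaba_sources()`
turns a pair of percent reductions into the three-way attribution
(neuronal = WT − KO reduction, glial = KO reduction, de novo = 100 − WT
reduction), which closes to 100% by construction. A knockout reduction that
exceeds the wild-type one raises an error rather than clamping — a negative
neuronal share means the decomposition's premise failed and should be
surfaced. `decomposition_from_amplitudes()` accepts raw before/after
amplitude pairs and is scale-invariant.

## The synthetic generators

`synthesize_morphology()` grows binary-branching dendritic trees from a
spherical soma: branch lengths are truncated-normal draws, each completed
branch bifurcates with probability `p_branch` up to `max_depth`, and growth
stops when the target total length is reached (trees outside the stated
tolerance are regrown; the same seed always yields the same tree). The
genotype presets encode the reported direction of the anatomy contrast —
wild type ≈2000 µm total dendritic length with 4 primaries, knockout
≈4000 µm with 5 primaries, more branching and a larger radial extent. They
emulate the *statistics* that matter for the electrical model (length,
branching, spatial extent); they do not reproduce tortuosity, spine
geometry, or the true anatomical distributions, so tests passing on them
show internal consistency of the pipeline, not anatomical fidelity.

`generate_event_trace()` builds continuous mPSC recordings (Poisson events,
lognormal amplitudes — mPSC amplitude distributions are right-skewed —
linear event summation, additive Gaussian noise) and returns the generating
event times and amplitudes, so every downstream metric is validated as
recovery against known truth. `generate_genotype_dataset()` draws per-cell
summary tables with lognormal between-cell variability for two-group
comparisons.

## Problem sizes and tolerances

The test suite and the acceptance script run everything at reduced scale,
as the package's own default study conditions for desk-top reproduction:
4×4 excitation×inhibition grids (0–20 Hz excitation, 0–40 Hz inhibition),
10 iterations per cell, 2 s trials at dt = 0.025 ms; calibration with 10–20
randomized placements per evaluation; oracle comparisons over ≥100 random
instances; recovery studies over 100 seeds. Full-scale runs (100
iterations, wider grids) use the same functions with larger arguments.
Key tolerances: passive analytic limits 1%, membrane-area conservation 1%,
calibration targets 2%, mono-exponential recovery 5% median at SNR ≥ 10,
gain/offset recovery 10% under noise.

## Known limitations

* Channel kinetics are behaviourally tuned surrogates, not fits to
  voltage-clamp families; quantitative firing rates should be read as
  model-relative, and only the directions of genotype contrasts are claimed.
* The genotype contrast in firing is reproduced as an ordering (knockout
  iso-firing contours at lower excitatory rates), not as the exact published
  surfaces, which are figure-only.
* No calcium dynamics, GHK fluxes, stochastic gating, temperature
  dependence, tonic GABA current (verified similar between genotypes), or
  synaptic short-term plasticity.
* Coverage area uses the convex hull of the xy-projected dendritic nodes as
  a reproducible surrogate for the published polar-plot shading, whose exact
  construction is not specified.
* Sholl analysis defaults to 3D Euclidean distances with a 2D-projection
  switch; whether the published analysis used 2D or 3D distances is not
  stated.
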