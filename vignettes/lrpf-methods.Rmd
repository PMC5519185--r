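---
title: "Linear-response path following: model, toy system and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-response path following: model, toy system and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrpath)
```

This vignette is the package's own account of the science it implements:
the biasing scheme, the synthetic two-state transporter it is validated
on, the numerical choices, and what the validation does and does not
demonstrate.

## The linear-response biasing scheme

A transporter's alternating-access transition — outward-facing (OF) form
to inward-facing (IF) form — is separated from the starting basin by a
free-energy barrier that plain simulation will not cross on any
accessible time scale. The scheme implemented here accelerates the
transition with a *biasing force field* derived from the protein's own
equilibrium fluctuations.

From an unbiased segment, `estimate_covariance()` builds the mean
structure $\langle \mathbf r\rangle$ and the $3N\times 3N$ positional
covariance $C$ of the sites, after iterative rigid-body superposition of
every frame onto the running mean (two passes). Linear response theory
gives the mean conformational change under a small external force
$\mathbf f$:

$$\Delta\langle \mathbf r\rangle = \beta\, C\, \mathbf f,
  \qquad \beta = 1/k_BT .$$

The force $\mathbf f$ is *perturbative*: sparse, applied only at motif
sites, and chosen from functional reasoning rather than from knowledge
of the target structure. Two designs are provided:

* **Outward push** (`design_outward_push`): at each chosen site, a unit
  force from the sites' centroid toward the site, projected onto the
  plane normal to the channel axis. Applied to the matrix-side acidic
  motif sites it models the electrostatic kick those residues receive
  from a bound substrate, and opens the matrix gate.
* **Pair contraction** (`design_pair_contraction`): equal-and-opposite
  forces shrinking chosen inter-domain pairs, modeling salt-bridge
  formation across the cytoplasmic gate.

The *biasing* field returned by `build_bias()` is parallel to
$\Delta\langle\mathbf r\rangle$ at every site and rescaled so that the
largest per-site force norm equals `f_max`. It is applied to **all**
protein sites, constant throughout a biased segment.

Because the real conformational change is strongly nonlinear, the
procedure iterates (`run_lrpf`): cycle $k$ runs a biased segment, then an
unbiased relaxation segment; the relaxation segment provides the next
mean structure and covariance; the perturbation directions are refreshed
from the new mean (the perturbed *sites* stay fixed — they are
identities, not positions); and a new bias field is built. A cycle-0
unbiased bootstrap supplies the first covariance, so the first bias is
estimated before any force has been applied. Monitors — declarative
specs of metric, selection, comparator and threshold, evaluated on each
relaxation segment's mean structure — terminate the run; the first
monitor in configuration order that fires wins, which keeps termination
deterministic. A plateau comparator (least-squares slope of the last
five cycle values below a tolerance) is available for runs without a
known target.

Assumptions worth stating: the covariance is estimated in the current
basin, so the prediction is only trustworthy for displacements of the
order of the basin's own fluctuations — hence the iteration; the bias is
constant within a segment (no ramping — segment-internal scheduling is
deliberately not modeled); and bias magnitude is capped per site rather
than in total, so the strongest local force is bounded regardless of
system size or covariance conditioning.

## The toy transporter

`toy_transporter_spec()` defines the synthetic system every higher-level
claim is tested on. Geometry: `n_domains = 3` domains, each contributing
an "even" and an "odd" helix — six straight rods of
`sites_per_helix = 8` beads (48 sites), length 16 model units, arranged
with exact three-fold symmetry about $z$ (the membrane normal). Each rod
is a rigid body whose two states are related by a pivot: even helices
carry the cytoplasmic gate bead at their top, odd helices carry the
matrix gate bead (also tagged `acidic`, the motif analog) at their
bottom.

Gate ring radii define the two states:

| gate | OF | IF |
|------|----|----|
| cytoplasmic (`gate_cyt`) | 13 | 9 |
| matrix (`gate_mat`) | 6 | 10 |

The cytoplasmic values are adopted from the channel gyration radii
reported for the carrier transition this toy emulates (open $\sim$13 Å,
closed $\sim$9 Å); the matrix radii mirror them so that
$r_\mathrm{cyt}+r_\mathrm{mat}$ is the same in both states. That sum
rule is load-bearing: the distance between a cytoplasmic gate bead and
the diametrically opposite matrix gate bead is then *state-invariant*,
and the corresponding long-range springs (picked up automatically by the
invariant-pair scan, below) couple the two gates into a single concerted
seesaw — closing one side forces the other open, which is the essence of
alternating access. The full-site RMSD between the reference states is
2.40 model units.

### The double-basin potential

`build_double_basin_spec()` splits all site pairs into

* a **scaffold**: pairs whose OF and IF distances differ by less than
  `invariant_tol = 0.5`, held by one stiff elastic network
  (`enm_spring = 3`) anchored at the mean distance — these are the
  constraints of the fold itself, taken at any range so the seesaw
  pairs are included; and
* **transition pairs**: pairs within `enm_cutoff = 14` of either
  reference whose distance changes, entering a double-basin term with
  one network anchored at each reference, mixed smoothly:

$$E = -\frac{1}{\beta_\mathrm{mix}}
      \ln\!\left(e^{-\beta_\mathrm{mix}(V_\mathrm{OF}+\Delta V)}
               + e^{-\beta_\mathrm{mix} V_\mathrm{IF}}\right),$$

with `beta_mix = 0.5` per kT. Two quantities are calibrated jointly:
the transition-pair spring constant is rescaled by bisection until the
barrier along the 101-point linear OF–IF interpolation path equals
`barrier_height = 12` kT (achieved to 1%), and the basin offset
$\Delta V$ is iterated until the two basins' harmonic free energies —
minimum energy plus the entropic $\tfrac{1}{2}k_BT\log\det H$ over
internal modes — agree to 0.25 kT. The offset matters: the IF geometry
happens to give a stiffer vibrational spectrum, so with $\Delta V = 0$
the IF basin is about 4 kT entropically shallower and a system parked
there occasionally escapes back on long continuations. Splitting scaffold
from transition pairs decouples the two jobs a single network cannot do
at once: the scaffold keeps the fold rigid (basin RMSD fluctuations of
$\sim$0.6, peaking near 1.1), while the calibrated soft transition
springs place the barrier. The 12 kT barrier makes spontaneous crossing
astronomically unlikely on desk-scale runs — the property that motivates
biasing in the first place — yet a single well-aimed biased segment
crosses it.

### Tracers

`add_tracers()` appends soft repulsive particles (quartic truncated
cores, $E = \varepsilon(1-(r/\sigma)^2)^2$ for $r<\sigma$,
$\varepsilon = 40$ kT) initialized above the cytoplasmic gate. Gate
beads carry wide cores ($\sigma = 10.5$ cytoplasmic, $8$ matrix and the
matrix packing layer, versus $2$ for plain beads), so a gate ring
narrower than its core diameter occludes the channel: in OF the matrix
vestibule is sealed and tracers fill the open cytoplasmic funnel; in IF
the cytoplasmic side excludes them. A flat-bottom cylindrical wall keeps
tracers near the protein.

Occupancy contrasts are measured with the protein position-restrained
to the reference state, the standard solvent-equilibration setup: an
occupancy map characterizes one conformational state at a time. This is
not a cosmetic choice. The same soft transition mode that lets LRPF
drive the transition also lets thermal fluctuations breathe the gate
rings by a unit or more, and during such excursions a nominally closed
gate transiently admits a tracer, which then stays trapped in the
vestibule; a frozen-protein control shows perfect open/closed contrast
while the unrestrained toy shows a washed-out one. The restrained
protocol reproduces the qualitative water-occupancy signature of the
transition (occupancy-grid maps, 0.3 contour); it does not attempt
water's hydrogen-bonded structure, electrostatics, or lipids.

## Engine and numerical choices

* **Integrator**: BAOAB splitting of Langevin dynamics — the most
  accurate standard discretization for configurational averages at
  moderate step size. Defaults `dt = 0.005`, `friction = 1`,
  `temperature = 1` (all model units, $k_B = 1$); the constructor
  rejects `dt * friction >= 0.5`. Validated against the analytic
  stationary variance $kT/k$ and equipartition in the test suite.
* **RNG**: one `mt19937_64` stream per segment, seeded from
  `(global seed, cycle, segment)` via `lrpf_segment_seed()`. Identical
  seeds give bit-identical trajectories, and an LRPF run with
  `f_max = 0` reproduces the corresponding unbiased segments frame for
  frame — the null-bias contract tested in the suite.
* **Forces**: every term implements energy and analytic gradient
  (checked against central differences to $10^{-6}$), including the
  targeted-RMSD restraint, whose gradient passes through the optimal
  Kabsch superposition. Internal terms exert zero net force.
* **Neighbor handling**: the tracer repulsion uses a brute-force pair
  loop. At the toy's sizes (48 protein beads, tens of tracers) this is
  faster than maintaining cell lists; the loop lives in C++.
* **Superposition**: Kabsch with SVD and reflection correction
  (determinant always $+1$); degenerate (collinear) inputs are refused.
  An independent quaternion-eigenvalue oracle in the tests agrees to
  $10^{-8}$ on random point sets.
* **Covariance**: shrinkage toward the diagonal with
  $\lambda = 0.05$ by default, because a $3N\times 3N$ covariance from
  a few thousand frames is rank-deficient; mild shrinkage stabilizes
  the matrix–vector product without distorting well-sampled directions.
  Rigid-body motion is removed by two passes of superposition onto the
  running mean before moments are taken.
* **Occupancy grids**: voxel membership is half-open per axis, so no
  face is double-counted and occupancies are exact rational counts.

## Validation design, problem sizes, and what it shows

The fluctuation–dissipation checks run on small harmonic networks (5–6
sites) built stiff enough (tethers $k=4$, springs $k=6$, pair distances
$\ge 3$ at $kT = 1$) that the harmonic approximation is genuinely valid;
on looser networks the anharmonic shift of the thermal mean is
comparable to the response signal and would test the network, not the
estimator. `verify_response()` therefore also differences perturbed
against unperturbed companion runs at equal seeds, which cancels both
shared sampling noise and any residual anharmonic mean shift — this
paired design is what makes the test sharp at modest run lengths.
Covariance accuracy is measured on $5\times 10^4$ sampled frames
(Frobenius error against $kT\,K^{-1}$ typically 3–5%).

The transition benchmark uses the default toy exactly as generated:
10 LRPF seeds (biased segments of 3000 steps, relaxation segments of
6000, `f_max = 2.5`, at most 40 cycles, in practice 1–3), 10 unbiased
control runs of matched total step count, and, for every successful
run, an unbiased continuation of ten times the biased duration. Basin
residence is judged the same way the protocol itself judges success:
the RMSD of a segment-mean structure to the relevant reference against
a 1.5 model-unit threshold (the references are 2.40 apart; each basin's
mean sits within $\sim$0.5 of its reference). Instantaneous
frame-by-frame RMSD stays below the threshold in these runs too, but
the windowed mean is the defined monitor. These sizes keep the entire
suite and the acceptance script at a few minutes on one CPU.

Passing all of this shows that the machinery is correct and that the
covariance-derived bias can drive a genuinely two-state, barrier-locked
system across in a handful of cycles while unbiased dynamics never
crosses. It does not show that the method finds *the* physical pathway
of any real transporter: the toy's landscape is a designed double basin,
its solvent is a soft-core fluid, and electrostatics, lipids, side-chain
packing and substrate chemistry are all absent. On real systems the
relaxation segments must be long enough to re-equilibrate the local
basin ("sufficiently long" is system-dependent), the perturbation design
encodes real mechanistic hypotheses, and success is not guaranteed —
among several independent runs, some may stall, which is why seeds,
monitors and complete per-cycle records are first-class outputs here.

## Known limitations

* The linear path used for barrier calibration is a diagnostic, not a
  minimum-energy path; the dynamical barrier can differ from the
  calibrated value.
* Monitors are evaluated once per cycle (on the relaxation mean), so
  termination granularity is one cycle.
* The bias cap `f_max` is not auto-tuned; the default (2.5 model force
  units) is calibrated to the toy and should be re-examined for any
  other system, as should segment lengths.
* `verify_response()` assumes the supplied force terms really are the
  system that produced the covariance model; it cannot detect a
  mismatch.
* PDB output abuses the B-factor column for per-site bias magnitudes —
  convenient for visualization, nonstandard semantically.
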