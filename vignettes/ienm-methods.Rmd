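---
title: "Interpolated elastic network models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpolated elastic network models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ienm)
```

This vignette documents the models implemented by `ienm`, the numerical
choices behind them, and what the synthetic test systems do and do not
demonstrate. The motivating application is the gating transition of
pentameric ligand-gated ion channels (pLGICs), where two crystal structures
— a closed-channel and an open-channel conformation — bracket a large
collective rearrangement whose *order of events* (which loops and helices
move early, which late) is the scientific question.

## The elastic network model

A protein is reduced to its C-alpha trace. Atoms $i$ and $j$ interact
through a Hookean spring whenever their distance $d^0_{ij}$ in the
reference structure is below a cutoff $R_c$:

$$E_\mathrm{ENM}(\mathbf{x}) = \sum_{d^0_{ij} < R_c} \frac{k_{ij}}{2}
\left(d_{ij} - d^0_{ij}\right)^2 .$$

Defaults follow common practice for C-alpha networks of this kind:
$R_c = 10$ Å, $k_{ij} = 10$ for chemically bonded (sequential, same-chain)
pairs and $k_{ij} = 1$ otherwise. Force constants are in arbitrary model
units; they fix the energy scale only, so everything geometric downstream
(pathways, crossover values, pore radii) is unit-free. Two deliberate
choices:

* **Bonded springs survive the cutoff.** A sequential pair beyond $R_c$
  keeps its spring: the bonded term expresses chain connectivity, not a
  distance criterion, and severing the backbone is never meaningful here.
* **No mass weighting.** All C-alpha pseudo-atoms carry unit mass,
  matching the potential's form; eigenvalues are reported in model units.

Normal mode analysis diagonalises the analytic Hessian at the reference.
The Hessian is assembled sparsely (each spring touches only its two 3×3
diagonal and two off-diagonal blocks). Six eigenvalues vanish for the
rigid translations/rotations — five for exactly collinear point sets,
which `normal_modes()` detects by the rank of the centred coordinates.
A network is accepted as well-constrained only if the first non-rigid
eigenvalue exceeds the largest rigid one by a factor $10^6$; otherwise the
error distinguishes a *disconnected* network (named components) from a
connected but *underconstrained* one (floppy mechanisms). Eigenvector
signs are fixed by making the first non-negligible coordinate positive, so
results are reproducible across LAPACK builds.

Two eigensolver routes are provided and cross-checked in the tests: a
dense `eigen()` route (default up to $3N \le 1200$) and a shift-invert
subspace iteration on the sparse Hessian, factorised once with a sparse
Cholesky decomposition, for larger systems. The iteration is deterministic
(fixed congruential start block, no RNG state touched) and terminates on
explicit eigenpair residuals so that eigenvectors, not only eigenvalues,
are converged; near-degenerate doublets (every helical fixture has them)
are compared subspace-wise in the tests.

The similarity between a mode $\mathbf{v}_m$ and an observed displacement
$\Delta\mathbf{x}$ (end conformation superposed on the begin conformation)
is the overlap $|\mathbf{v}_m \cdot \Delta\mathbf{x}| /
\|\Delta\mathbf{x}\|$; the cumulative overlap over the lowest $M$ modes
aggregates in quadrature and reaches 1 on a complete non-rigid basis when
the displacement carries no rigid component. `cutoff_scan()` exposes the
standard diagnostic of scanning $R_c$ (default grid 8–16 Å in 1 Å steps)
for the cutoff that maximises cumulative overlap for a given transition;
no particular optimum is asserted.

## The interpolated double-well pathway

Given begin and end structures and a residue-level alignment between them
(from DALI or any structural aligner — this package ingests alignments, it
does not compute them), two single-well ENMs $E_1$ and $E_2$ are anchored
at the two conformations. Any double-well potential $g(E_1, E_2)$ with
these two minima has its saddle points on the curve traced by the minima
of the *linearly interpolated* potential

$$E_\lambda(\mathbf{x}) = \lambda E_1(\mathbf{x}) +
(1-\lambda) E_2(\mathbf{x}) + E_\mathrm{coll}(\mathbf{x}),
\qquad \lambda: 1 \to 0,$$

independent of the functional form of $g$ — the central property that
makes the pathway well defined without choosing a mixing rule. Solving
$\nabla E_\lambda = 0$ along a descending $\lambda$ schedule, warm-starting
each solve from the previous solution, traces a minimum-energy path from
the begin well to the end well. The tests verify the form-independence
operationally: re-solving with a different (coarser) $\lambda$ schedule
reproduces the same conformations at matching $\lambda$ to well below the
sampling resolution.

**Collision term.** $E_\mathrm{coll}$ penalises steric clashes between
non-bonded residues. It is implemented as a smooth one-sided quadratic,

$$E_\mathrm{coll} = \sum_{\mathrm{non\text{-}bonded}\ i<j}
\frac{k_\mathrm{coll}}{2}\,(d_{ij} - d_c)^2\,\Theta(d_c - d_{ij}),$$

with $k_\mathrm{coll} = 10$ and $d_c$ the minimal non-bonded C-alpha
distance over both endpoint conformations (computed automatically; about
3 Å for compact protein structures). Each pair's contribution vanishes
continuously at $d_{ij} = d_c$, and both endpoints are exactly
collision-free by the definition of $d_c$. For transitions without severe
steric conflict the term contributes little to the resulting path; it is a
guard, not a driver.

**Alignment gaps.** Residues of the begin structure without an aligned
partner have no end-state coordinates. They participate fully in $E_1$; in
$E_2$ they keep only their bonded springs, with rest lengths copied from
the begin conformation, so the chain stays intact while no fictitious
non-bonded geometry is imposed. A consequence worth knowing: the end well
then has flat directions for those residues, so the $\lambda = 0$ endpoint
is defined up to motion in that flat manifold; the aligned subnetwork
still pins the aligned residues (the tests compare the final conformation
to the target modulo a rigid fit for exactly this reason).

**Solver.** Each $\lambda$ solve is a damped Newton iteration: the sparse
linear system uses the analytic Hessian plus an adaptive Levenberg-style
diagonal shift (starting at $10^{-8}$ of the maximum diagonal, increased
a hundredfold whenever a step fails, relaxed after success), which also
regularises the rigid-body null space. Steps are accepted on energy
descent — the interpolated problem is a minimisation at fixed $\lambda$,
and the energy is the reliable merit function where bonded-only regions
make the landscape non-convex. Convergence is declared at a gradient
max-norm of $10^{-8}$ (model units/Å), or within a factor 10 of it when
floating-point precision admits no further descent; the residuals stored
with the pathway are always re-evaluated ones. After each solve the
conformation is re-superposed onto the begin structure (all atoms) to
remove rigid drift. The whole sweep is deterministic.

**Schedule and sampling.** The default schedule is 201 uniform $\lambda$
steps with adaptive bisection wherever consecutive solutions jump by more
than `max_step` (default twice the sampling increment); bisection makes
the sampled path insensitive to the initial grid density, which is why a
moderate default suffices — the schedule-refinement test checks exactly
this. The converged sweep is then subsampled so consecutive retained
conformations are at least the sampling increment (default 0.1 Å RMSD)
apart, with begin and end always retained. The number of intermediate
conformations is therefore a settings-dependent quantity, not a property
of the transition.

## Quantifying the order of events

The fractional progress of a conformation is its arc-length position:
cumulative RMSD between consecutive conformations, divided by the total.
For each residue, the *crossover conformation* is the first pathway point
at which its C-alpha is equidistant from its begin and end positions; the
residue is assigned the fractional progress of that point (linearly
interpolated between the bracketing conformations). Early-moving residues
have low crossover values. Choices:

* **Displacement floor, 0.5 Å (default).** Residues whose begin-to-end
  displacement is below the floor have no meaningful crossover; they are
  reported as `NA` and excluded from motif means. The floor is a visible
  knob (`floor` argument) and is reported with results.
* **First crossing.** If the distance difference changes sign several
  times, the first crossing is used — the conservative "begins moving"
  reading; single crossings are the norm on smooth pathways.
* **Frame.** Distances are measured in the pathway's own frame, which the
  solver keeps superposed on the begin structure — consistent with how the
  pathway was constructed.

Motif averages (arithmetic mean of defined crossover values over member
residues, across all chains in scope) summarise the order of events for
named structural elements; the package ships the residue ranges of the
ELIC pentamer's key elements (`elic_motifs()`: binding loops A/B/C,
interface loops 2/7/9, helices M1–M4, the M2–M3 linker; extracellular
domain residues ≤ 200, transmembrane domain from 201, following the M1
range — configurable by supplying other motif tables). For five-fold
symmetric assemblies the mean over all chains equals the per-chain value
in exact arithmetic; averaging over all chains and checking the
inter-chain spread is the package's convention.

Experimental Φ values from rate-equilibrium free-energy-relationship
analysis of receptor mutants order events from the kinetics side: high Φ
means early motion. `order_correlation()` computes the Pearson correlation
between motif-average crossover and $1-\Phi$; `achr_phi_motifs()` ships
the motif-level Φ summaries commonly quoted for the muscle-type receptor
alpha subunit (loops A/B/C ≈ 0.93, loops 2/7 ≈ 0.75, M2 ≈ 0.65,
M4 ≈ 0.54, M3 ≈ 0.32), and finer per-residue tables can be supplied as
TSV.

## Perturbation analysis

To ask which interactions dictate the order of events, selected non-bonded
springs are switched off and the pathway re-solved. Masks are generated
from two rules — same-chain (`intra`) or cross-chain (`inter`) pairs
between two residue-number selections — which cover the standard
experiments: severing all intra-subunit contacts between the extracellular
and transmembrane domains, severing only those mediated by one interface
loop, or severing the inter-subunit contacts between adjacent
extracellular domains. Masks apply to both wells by default
(`mask_wells = "both"`); one-well masking is available since the
literature is not explicit on this point, and the no-op mask reproduces
the unperturbed pathway bit for bit. Bonded springs are never severed,
whatever the mask; a mask matching a bonded pair is reported and ignored.
A mask that disconnects the network surfaces as the normal-mode layer's
disconnected-network error, naming the components.

## Pore radius profiling

The channel pore is profiled directly from the C-alpha trace: each atom
carries a fixed 3 Å radius, and at each station along the pore axis the
pore radius is the largest probe sphere, centred anywhere in the
perpendicular plane, that overlaps no atom sphere. The in-plane centre
optimisation is deterministic — a coarse 0.5 Å grid scan within
`max_offset` (default 5 Å) of the axis, followed by pattern-search
refinement (tolerance 0.01 Å) from several well-separated top candidates
and from the previous station's centre — rather than the Monte Carlo
wobble of HOLE-style tools; the clearance landscape is piecewise smooth
and multi-modal, and the multi-start makes the deterministic search match
a brute-force 0.05 Å grid on random cage systems. Stations where even the
optimal probe overlaps are clamped to radius 0 and flagged occluded;
stations with no reachable atom are capped at `max_radius`. The automatic
axis is the smallest principal component of the chain centroids — exact
for ring-like assemblies — and requires at least three chains (two
centroids leave the perpendicular direction undetermined); any explicit
axis can be supplied.

## The synthetic two-state systems

`make_two_state()` generates small assemblies with known motional order so
the full workflow runs and is checkable without downloads. Backbones are
idealised C-alpha helices (rise 1.5 Å, 100° twist, helix radius 2.3 Å):
the ENM needs plausible neighbour distances, not chemistry.

* **`c5-barrel`** — five identical chains on a ring, end state expanded
  radially by 2 Å. The ring radius default of 8 Å is chosen so that both
  endpoint networks are rigid at the 10 Å cutoff (larger rings leave too
  few inter-chain contacts in the expanded state, producing floppy
  mechanisms) while the pore stays open (minimal radius
  $8 - 2.3 - 3 = 2.7$ Å against 3 Å atom spheres). Exercises symmetry
  preservation: both endpoints are exactly five-fold symmetric and any
  faithful pathway must stay so.
* **`two-phase-chain`** — one chain; an early segment moves 3 Å, a late
  segment 6 Å. The default split (80 % early) makes the two phases of the
  constructed reference path equal in arc length, so the early group
  crosses at fractional progress 0.25 and the late group at 0.75 — the
  recovery target for the crossover machinery.
* **`hinge-dimer`** — a long static stalk and a short arm rotating about
  a hinge. Because a least-squares fit of the end state onto the begin
  state necessarily redistributes some arm motion into the stalk, the
  generator superposes the end state itself and derives the truth groups
  from the superposed displacement field (static < 0.4 Å, moving > 1 Å).

What these systems do **not** emulate: side chains, solvent, membrane,
realistic contact-density heterogeneity, sequence effects, or asymmetric
fluctuations. Tests passing on them demonstrate the numerics (saddle
residuals, symmetry preservation, oracle agreement, order recovery), not
biological accuracy on real channels; for real structures the workflow is
the same with PDB files and an external alignment as inputs, via the
functions or the `inst/cli/ienm.R` driver.

Problem sizes used throughout the tests and the acceptance script — 40 to
70 residues per system, 101-step schedules, 0.1 Å sampling — are chosen to
be proportionate to these fixtures; all quantities they compute are
settings-stable at these sizes (the schedule-independence and oracle tests
are exactly the evidence).

## Known limitations

* Energies are in arbitrary model units; no free-energy barrier or rate
  information is produced or implied.
* The pathway is a single minimum-energy curve: a frictionless,
  single-barrier idealisation with no metastable intermediates and no
  symmetry breaking; stochastic, asymmetric excursions seen in molecular
  dynamics are outside the model.
* Crossover analysis needs the begin-to-end displacement to exceed the
  floor; nearly static residues are genuinely unordered by this measure.
* Pore profiles against C-alpha spheres approximate the physical lumen;
  hydration and side-chain packing are not modelled.
* With alignment gaps, the end well's flat directions make the
  $\lambda = 0$ endpoint unique only up to motion of the unaligned
  residues along their bonded constraints.
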