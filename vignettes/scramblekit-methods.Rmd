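---
title: "Methods: scrambling detection, the flip-flop CV, and WHAM in scramblekit"
author: "scramblekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scrambling detection, the flip-flop CV, and WHAM in scramblekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scramblekit quantifies lipid scrambling — the passage of lipids between the
two leaflets of a membrane bilayer, catalysed by scramblase proteins whose
hydrophilic groove lets the lipid headgroup cross the hydrophobic core in
"credit-card" fashion. The package provides the full analysis chain used to
characterise such activity in molecular simulations: leaflet assignment and
event counting, a cylinder-based flip-flop collective variable, umbrella
window bookkeeping, WHAM free-energy reconstruction with barrier reporting,
and protein-centered density/RMSD mapping. A synthetic membrane simulator
with known ground truth validates every stage end to end.

Units are fixed package-wide: nm, ns, kJ/mol, K; the membrane normal is +z.

## Leaflet assignment and scrambling counting

Each lipid is represented by its phosphate particle ("PO4" in coarse-grained
systems, "P" atomistically). At each analysis snapshot (every 10 ns by
default) the membrane center is the mean phosphate z after the bilayer has
been made z-connected under periodic boundaries: phosphate coordinates are
wrapped into the box, the largest cyclic gap in their sorted z values is
located, and coordinates below the gap are lifted by one box length before
averaging. This handles a bilayer straddling the periodic z boundary without
assuming the membrane sits near the box center, and the center is recomputed
per snapshot so slow drift is harmless.

A lipid is "upper" iff its (connected-image) phosphate z exceeds the center.
A phosphate exactly at the center keeps its previous label — a measure-zero
state that would otherwise produce spurious transitions. No hysteresis
deadband is applied by default: the pure sign rule at 10 ns snapshots matches
the reference analysis; an optional deadband can be emulated by the caller
but is deliberately not wired in.

Two observables are emitted because they answer different questions. The
instantaneous *scrambled count* (lipids currently opposite their first
observed leaflet) is what published scrambling traces plot — it can decrease
when a lipid returns. The *cumulative event count* increments on every label
change between consecutive snapshots and divides by the observation span to
give the rate in events per microsecond, with a block-bootstrap confidence
interval over per-snapshot event increments. A lipid that flips and returns
contributes two events but ends unscrambled.

One degenerate configuration is worth documenting: if every phosphate ends up
in the same leaflet, the midplane is undefined (all phosphates tie with the
mean) and the sticky tie rule freezes the labels. No bilayer with realistic
lipid numbers reaches this state; the synthetic oracle schedules keep both
leaflets populated.

## The cylinder collective variable

The flip-flop CV is the oriented z-distance between the tracked phosphate
and the *local* membrane center of mass: membrane particles whose xy
minimum-image distance from the target is at most the cylinder radius R
(2.0 nm for plain bilayers, 3.0 nm for protein systems, matching the pull
geometry those simulations used). A local reference tolerates membrane
bending and drift that would contaminate a global-center CV; as R grows the
two coincide, which the test suite checks as a limit identity.

The local center is unweighted by default because coarse-grained beads are
effectively equal-mass; a `masses` argument enables mass weighting for
atomistic systems, where pull codes default to it. Which particles count as
"membrane" is the caller's selection — all lipid particles, not phosphates
only, is the recommended choice and what the analysis scripts use.

Bias potentials combine a harmonic umbrella on the CV, U = k/2 (xi - c)^2,
with an optional flat-bottom xy restraint that is zero inside the reference
distance d0 and harmonic outside (defaults d0 = 2.5 nm,
k = 500 kJ/mol/nm^2 — the published restraint that confines the pulled
lipid to the scrambling pathway without biasing the interior). Window seed
frames are picked from a pulling trace as the frame with CV nearest each
requested center (earliest on ties); a spacing scheme generates centers
dense near the midplane (0.03 nm core / 0.1 nm surface by default).
Umbrella sample files are two-column (time, CV) text with `#`/`@` comments
tolerated, and the first 10 ns of each window are discarded as equilibration
by default.

## WHAM

`wham_solve()` iterates the standard self-consistent equations on a binned
CV axis (default bin width 0.05 nm — finer than the tightest window
spacing):

$$P(b) = \frac{\sum_i n_i(b)}{\sum_i N_i \exp[(f_i - U_i(\xi_b))/k_BT]},
\qquad
f_i = -k_BT \ln \sum_b P(b) \exp[-U_i(\xi_b)/k_BT].$$

Direct iteration alone can need $10^5$+ sweeps when adjacent windows overlap
weakly, so the offsets are first obtained by BFGS on the equivalent convex
negative log-likelihood (with analytic gradient) and then polished by direct
iteration until the offsets move by less than $10^{-8}$ kJ/mol — tight
enough that discretisation, not iteration, dominates the error. Failure to
reach the tolerance within the iteration cap is an error carrying the
residual, never a silent result.

Two numerical choices matter in practice. First, the histogram spans the
*windowed* CV range (outermost umbrella centers), not the sample range: bins
beyond the last window are reweighted from a single window's tail, and their
noisy free energies would corrupt the min-zero alignment of the profile.
Samples outside the range are discarded with the window counts reduced
accordingly, never clamped into edge bins. Second, windows enter WHAM as
plain (center, k, samples) triples — samples from replica-exchange-enhanced
windows are treated as ordinary samples under their own window's bias, which
is how pooled window sets are conventionally fed to WHAM; demultiplexing is
out of scope.

The free-energy profile is F = -kBT ln P, shifted so its global minimum is
zero (profiles conventionally start near zero in the bulk leaflet, and the
shift makes the barrier simply the global maximum). Bins without support are
masked, not extrapolated. The reported error estimate is the profile
asymmetry, max over xi of |F(xi) - F(-xi)|/2: a flip-flop profile in a
symmetric bilayer should be mirror-symmetric, so residual asymmetry bounds
the sampling error from below. A seeded Bayesian-style window bootstrap
could tighten this but the asymmetry heuristic is what the headline numbers
quote, so it is the default. When the two pulling directions give separate,
hysteresis-free profiles, both are reported and `profile_mean()` provides
the labeled pointwise mean. Barrier reductions are
(ref - barrier)/ref x 100; the published barrier pairs (62, 7), (83, 15),
(92, 16) kJ/mol give 88.7%, 81.9% and 82.6%.

## Density and RMSD mapping

Frames are superposed onto a reference by least-squares rigid fit (Kabsch,
proper rotations only — reflections are excluded to preserve chirality;
collinear fit sets are rejected as non-unique). RMSD can be reported over a
different selection than the fit — e.g. fit on the full backbone, report on
the cavity helices (residues 1-31, 74-100, 117-151, 182-207, 216-247 in the
reference protein) — which is how loop motion is separated from helix
stability.

Number densities are accumulated on a regular voxel grid (default spacing
0.1 nm, resolving the coarse-grained bead scale without huge grids), one
snapshot every 10 ns, after optional alignment. The stored density is
counts/(frames x voxel volume) in nm^-3, so
sum(density x voxel volume) equals the mean in-bounds particle count per
frame exactly; out-of-bounds particles are counted and reported, never
silently dropped. Grids export to plain-text OpenDX (z fastest, full double
precision) and round-trip exactly through `read_dx()`. All frames are
aligned to one explicit reference; pooling replicas is the caller's
decision, made visible by the shared reference.

## The synthetic membrane generator

The generator is a toy sampler, not a physical membrane model. Each lipid's
phosphate evolves independently by overdamped Langevin dynamics in a
symmetric quartic double-well U(z) = B(1 - (z/z0)^2)^2 — the simplest
smooth form with minima at the leaflet positions +/-z0 and barrier B at the
midplane; the reference free-energy profiles constrain only barrier heights,
not shapes, so the quartic is a modelling choice, documented as such.
Defaults: z0 = 2.0 nm (a POPC phosphate half-thickness, consistent with
pulling start distances of 2.1-2.3 nm), T = 310 K (kBT = 2.5775 kJ/mol),
D = 0.1 nm^2/ns and dt = 0.01 ns. D and dt are chosen for desk-scale event
statistics, not physical fidelity: absolute synthetic rates cannot be
calibrated to published per-microsecond rates because attempt prefactors are
not reported, so only barrier-driven *relative* behaviour is meaningful
(and is tested: flip counts decrease strictly over barriers 5, 10,
20 kJ/mol). The timestep must satisfy dt |U'| D / kBT < 0.1 z0, checked at
construction, and any step larger than z0 aborts the run with advice to
reduce dt.

A scenario may add a cylindrical "groove": within radius Rg of a protein
axis the local barrier drops to the groove value, blended by a cosine ramp
over 0.25 nm so U is continuous in xy; an optional Gaussian gate bump on the
groove path reproduces the secondary peak that a hydrophobic gate leaves in
a free-energy profile. xy motion is free diffusion under periodic
boundaries — the groove lowers the crossing barrier where the lipid happens
to be but exerts no lateral force, keeping the generator trivially
analysable.

What the generator emulates: leaflet-resolved phosphate kinetics with a
tunable barrier, planted ground-truth events, Boltzmann-exact umbrella
samples (drawn by inverse-CDF lookup on a trapezoidal grid — a plain
cumulative-sum staircase would shift every sample by half a grid step,
which WHAM reads as a spurious ~0.5 kJ/mol/nm tilt across the profile; the
test suite cross-checks against an independent Metropolis chain). What it
does not emulate: lipid-lipid interactions, membrane undulations and
thinning, solvent, pressure coupling, or realistic diffusion anisotropy.
Passing tests therefore demonstrate the correctness of the *analysis* under
known ground truth, not force-field realism.

Determinism: a scenario seed fixes the whole trajectory bit for bit. Noise
is drawn from one seeded stream in fully vectorised per-step blocks across
lipids, which is reproducible without per-lipid stream bookkeeping.

## Scale of the packaged checks

The packaged validation uses problem sizes a laptop handles in minutes:
67 windows x 20,000 exact samples for the plain-bilayer barrier (ground
truth 62 kJ/mol), 44 windows for the groove barrier (7 kJ/mol), a
290-lipid, 10 microsecond zero-scrambling control at the 62 kJ/mol barrier,
1000-fold randomized oracles for the event counter and the geometry kernels,
and 2 microsecond runs for the Kramers barrier scan. Recovered barriers land
within statistical noise of the construction (typically 0.2-0.3 kJ/mol RMS
across the profile against a 0.5 kJ/mol acceptance band).

## Known limitations

- No XTC/TRR reader: binary trajectories must be converted to the package's
  documented text container; GRO/PDB structures are read natively.
- Orthorhombic boxes only; triclinic input errors out explicitly.
- The WHAM error bar is the asymmetry heuristic, a lower-bound-style
  estimate; it does not replace block-averaged convergence analysis.
- The groove model has no lateral force and no lipid crowding, so in-groove
  residence statistics are diffusive, not interacting.
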