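---
title: "Barrier screening by constrained adiabatic mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barrier screening by constrained adiabatic mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiamap)
```

## The model

`adiamap` estimates the reaction barrier of the nucleophilic-attack step in
a serine-hydrolase-type active site: the catalytic serine O~γ~ attacks the
substrate carbonyl carbon, converting the enzyme–substrate complex (ES)
into the tetrahedral intermediate (TI). The nucleophile–electrophile
distance d(O~γ~–C) serves as the reaction coordinate.

Instead of a saddle-point search — which on truncated protein models of
10^2^–10^3^ residues is expensive and frequently fails to stay on the
relevant part of the surface — the barrier is bracketed by *adiabatic
mapping*: the reaction coordinate is stepped through a series of
intermediate values and, at each value, every other degree of freedom is
relaxed. Concretely:

1. **Interpolation.** With identical atom ordering in the two optimized end
   points, interior frame $i$ of $n$ divisions places every atom at
   $r_i = r_\mathrm{ES} + \tfrac{i}{n}\,(r_\mathrm{TI} - r_\mathrm{ES})$.
   Per-frame displacement of every atom is constant; an atom whose end-point
   positions differ by 2.2 Å moves 0.22 Å per frame at $n = 10$.
2. **Constraint.** In each interior frame both reaction-coordinate atoms are
   frozen in Cartesian space. Freezing the pair fixes their distance, and
   per-coordinate freeze flags are the native constraint mechanism of the
   target engine — no Lagrange machinery required. The first and last frames
   carry no reaction-coordinate constraint (they are the free end points).
3. **Relaxation.** Every frame is optimized independently; there is no
   cross-frame state, so frames parallelize trivially and execution order
   cannot change the profile.
4. **Re-evaluation.** Linear-scaling localized-orbital (MOZYME-style) SCF
   accumulates orbital-truncation error over an optimization, so the
   optimization energy drifts relative to a conventional SCF. Each optimized
   geometry is therefore re-evaluated as a conventional single point, and
   profiles carry the channels separately (`mozyme`,
   `mozyme_reorthogonalized`, `conventional_sp`). `drift_report()` exposes
   the per-frame difference and its correlation with SCF cycle count.
5. **Barrier.** `extract_barrier()` takes the highest profile point and
   subtracts the lowest point *before* it. This is deliberately not
   "energy of frame 0": a variant profile can dip below its initial state
   when a lower local minimum becomes accessible a few frames in, and the
   rule must not reward that dip with a negative barrier reference.
6. **Verification.** The frame at the maximum approximates the transition
   state. Its character is verified by partial Hessian vibrational analysis
   (PHVA) over the reactive core with constraints released: a genuine saddle
   shows exactly one imaginary frequency.

### Assumptions

* The path between ES and TI is well approximated by relaxation around a
  linearly interpolated backbone of geometries; reactions with strongly
  curved minimum-energy paths or discrete conformational gating will be
  described poorly.
* The ES model is derived from the optimized TI (substrate swapped for its
  planar pose, proton transferred back). This biases the ES towards the TI
  basin and thus tends to *underestimate* absolute barriers; for screening,
  where only differences between variants matter, the bias largely cancels.
* Protonation states and the planar substrate pose are curated inputs, not
  predictions made here.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `es_distance` | 3.5 | Å | separation of O~γ~/C in the modeled ES complex; relaxed ES geometries cluster near this value |
| `ti_distance` | 1.5 | Å | a formed C–O single bond in the TI |
| `n_divisions` | 10 | – | resolves the profile at ~0.2 Å of reaction coordinate per frame |
| `nddo_cutoff` | 15 | Å | NDDO interaction cutoff of the linear-scaling engine; grid 9/12/15 supported for convergence studies |
| `gradient_convergence` | 0.5 | kcal/(mol Å) | engine optimization criterion; stricter values lower profiles monotonically on a fixed surface |
| PHVA `step` | 0.01 | Å | central-difference displacement; exact for surfaces quadratic in the Cartesians, auditable by step-doubling |
| `n_imaginary` `threshold` | 10 | cm^-1^ | separates numerical zero modes from reactive modes (see below) |

The `M(C<cutoff>, G<gcc>)` notation labels an engine configuration, e.g.
`M(C15, G0.5)`; profile labels are `"<method>//M(C..., G...)"`, read as
"single-point method on geometries optimized with that configuration".
`convergence_report()` orders configurations from loose to strict and flags
whether extracted barriers decrease monotonically — the expected signature
when approaching the converged estimate from above.

## The surrogate surface and the toy system

The semiempirical engine itself is out of scope; the backend contract is a
function returning energy and analytic gradient. For development and
testing, `surrogate_params()` defines a smooth analytic stand-in surface:

* harmonic bonds $\tfrac{k}{2}(d - d_0)^2$ over a reference topology
  ($k = 300$ kcal/(mol Å²), typical of single-bond stretches), and
* one double-well term along the reaction-coordinate pair,
  $V(d) = A\,(d-d_1)^2(d-d_2)^2 / \left(\tfrac{d_2-d_1}{2}\right)^4$,
  which vanishes at both well distances and equals $A$ exactly at their
  midpoint — so the analytic barrier between the wells is $A$.

`make_toy_system()` builds a deterministic toy model around this surface: an
8-residue glycine-like chain (4 backbone atoms each, plus O~γ~ on the
middle, serine-like residue), a 4-atom pseudo-substrate, the transferable
proton, and 2 single-atom waters — 40 atoms. Conditions are fixed at
`es_distance` 3.5 Å, `ti_distance` 1.5 Å, $A = 10$ kcal/mol; the ES
substrate pose is the TI pose rotated 25° about the electrophile, so the
interior frames genuinely need relaxation (interpolating a rotation
compresses internal distances). A small seeded coordinate jitter
(σ = 0.05 Å) avoids accidental symmetry; the same seed reproduces the
structure byte-for-byte.

What the toy system does *not* emulate: a rugged landscape with many local
minima (the surrogate is single-basin per frame), hydrogen-bond network
rearrangements, charge–charge interactions, and SCF behavior (drift is
modeled as data, not generated by the surrogate). Passing the end-to-end
recovery test therefore demonstrates the *pipeline arithmetic* — frame
generation, constraint handling, optimizer correctness, profile assembly,
barrier extraction — not the accuracy of any electronic-structure method on
real enzymes.

## Numerical choices

* **Optimizer.** Frames are minimized by a quasi-Newton descent with line
  search (L-BFGS-B), with frozen coordinates held by equality bounds — they
  are bit-identical before and after, not merely "small-displacement".
  Termination is on the maximum unconstrained gradient component
  ≤ `gradient_convergence`, matching the engine's GNORM semantics; an
  iteration cap returns a `converged = FALSE` result rather than throwing.
  The optimizer is deterministic, so tightening the criterion can only
  extend the same descent trajectory, never raise the final energy.
* **Tie-breaks.** When two frames share the maximal energy, the lowest index
  wins (determinism); failed frames are excluded from extraction with a
  warning rather than aborting a whole screening run.
* **PHVA zero modes.** A weakly anchored subset (the substrate is bonded
  only internally) has rigid-body-like modes at numerically zero frequency.
  At a geometry converged only to a finite gradient criterion, residual
  forces lend those modes a few cm^-1^ of curvature of either sign, so the
  raw sign rule can miscount. `n_imaginary()` therefore applies a 10 cm^-1^
  magnitude threshold — an order of magnitude below any reactive imaginary
  mode of interest (the toy saddle mode is ~172i cm^-1^) and an order of
  magnitude above the observed numerical zeros. The raw per-mode sign rule
  (λ < 0) is still stored on the result.
* **Frame numbering.** A path of $n$ divisions yields frames
  $0 \ldots n{+}1$: frame $n$ coincides geometrically with the TI but is
  still constrained, frame $n{+}1$ is the unconstrained TI. This keeps
  "divide the displacement by $n$" exact while giving both end points an
  unconstrained relaxation, and it makes the two TI-geometry frames a
  built-in consistency check (their relaxed energies should agree).
* **Degenerate inputs.** ES = TI interpolates to identical frames; a flat
  profile extracts a zero barrier with reference = maximum; empty
  selections, missing residues, atom-count mismatches and out-of-range
  fragment charges are hard errors naming the offending key.
* **Capping geometry.** Cut C-termini become –CHO by adding one hydrogen at
  1.09 Å (a standard C–H bond) along the removed C–N bond direction when
  the full structure is available, else along the sp² completion at the
  carbonyl carbon. Break N-termini are annotated neutral without adding
  atoms: the engine input needs the charge, not a modeled proton. The
  transferred ES proton sits 0.97 Å (O–H bond) from O~γ~ along the
  O~γ~→C direction. These are geometric conventions — the subsequent
  optimization owns the exact positions.

## Design decisions

* **PDB v3.3 fixed-column I/O is implemented in the package** with strict
  error contracts (line-numbered parse errors, duplicate-serial rejection,
  altLoc other than blank/`A` refused) because fragment files carry a
  machine-readable `REMARK 6 FORMAL_CHARGE` line and round-trip guarantees
  at 3-decimal precision are part of the fragment-assembly contract. The
  writer is cross-checked against an independent reader (`bio3d`) in the
  test suite.
* **Fragment libraries are directories**: one single-residue PDB per
  fragment named `<key><resname>.pdb` plus a JSON manifest holding order,
  charges and role flags. Ordering and charge must be machine-readable;
  a manifest is the simplest format that survives manual editing.
* **Selection radius is any-atom-to-any-atom**: a residue enters the model
  if any of its atoms is within the radius of any atom of the center
  residue — the most inclusive reading, erring towards keeping active-site
  environment.
* **Job generation is byte-reproducible** (fixed keyword order, fixed
  formats), so generated inputs can be diffed and cached; the cutoff
  keyword spelling is a dialect knob since engine versions differ.
* **The command line** exposes the file-to-file stages (`fragmentize`,
  `assemble`, `interpolate`, `jobs`, `analyze`, plus `demo` for the
  surrogate end-to-end run). Stages that need a live backend in-process
  (endpoint preparation against an engine, mapping runs, PHVA) are R API
  calls; wrapping them in shell flags would duplicate the API without
  adding capability.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
fixtures: the 40-atom toy system with 4–12 interpolation divisions,
1000-profile barrier-extraction sweeps, 100-point-set superposition checks
against a rotational-search oracle, and 15–48-dimensional partial Hessians.
The complete suite finishes in well under a minute on one core.

## Known limitations

* Linear interpolation assumes a reasonably direct path; no IRC following
  or path refinement is attempted, and no saddle refinement beyond PHVA.
* Absolute barriers inherit the ES-from-TI construction bias; use relative
  barriers between variants.
* No thermochemistry: profiles are electronic energies, not corrected for
  zero-point energy.
* Protonation, substrate posing and mutant side-chain fragment geometry are
  upstream curation steps.
* The localized-orbital drift analysis consumes engine-reported SCF cycle
  counts; the surrogate does not generate drift itself.
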