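# adiamap

Adiabatic mapping and barrier screening for enzyme variant models.

## The problem

Ranking enzyme variants by predicted activity needs a reaction-barrier
estimate per variant that is cheap enough to run for a whole mutant library,
yet grounded in an electronic-structure description of the bond being
formed. For serine-hydrolase-type chemistry the rate-limiting step of
interest is nucleophilic attack: the catalytic serine O<sub>γ</sub> adds to
the substrate carbonyl carbon, taking the system from the enzyme–substrate
complex (ES) to the tetrahedral intermediate (TI). Saddle-point searches on
systems of thousands of atoms are expensive and unreliable, so `adiamap`
estimates the barrier by **constrained adiabatic mapping**:

1. Build a truncated active-site model (all residues within a radius of the
   catalytic residue, single backbone gaps filled, cut C-termini capped as
   –CHO, crystal waters kept) and annotate per-residue formal charges.
2. Prepare the two end points: the optimized TI, and an ES model derived
   from it by swapping in the planar substrate at
   d(O<sub>γ</sub>–C) = 3.5 Å and transferring the catalytic proton back.
3. Linearly interpolate all atomic coordinates between ES and TI in
   `n` divisions: interior frame `i` places every atom at
   `r_ES + i (r_TI − r_ES)/n`.
4. Optimize every frame independently with the reaction-coordinate atom
   pair (O<sub>γ</sub>, C) held fixed — fixing both atoms fixes their
   distance — using a linear-scaling semiempirical engine
   (PM6/MOZYME-style, configuration `M(C<cutoff>, G<gcc>)`), then
   re-evaluate each optimized geometry with a conventional single point,
   because localized-orbital optimization energies drift.
5. The barrier is the highest point of the single-point profile minus the
   lowest point *before* it; transition-state character at the maximum is
   verified by partial Hessian vibrational analysis (PHVA): exactly one
   imaginary frequency.

Variants are assembled combinatorially from a **fragment library** (one PDB
file per residue plus a JSON manifest): substituting the fragment at a
position by a mutated side-chain fragment yields the variant structure, with
serial renumbering and charge re-summation handled automatically. Surface
side chains prone to spurious rearrangement can be frozen by residue list.

The external engine is behind a narrow contract: `adiamap` writes
MOPAC-dialect input files bit-reproducibly, parses output files, and ships a
deterministic analytic surrogate surface (harmonic bonds + a double-well
along the reaction coordinate with known barrier `A`) so the entire
pipeline runs and is testable without any external binary.

## Worked example

```r
library(adiamap)

toy <- make_toy_system(seed = 1)        # chain + substrate + surrogate surface
backend <- surrogate_backend(toy$params, toy$full)

frames  <- interpolate_path(toy$endpoints, n_divisions = 10)
profile <- run_mapping(frames,
                       backend_config(gradient_convergence = 0.05),
                       backend_config(localized_orbitals = FALSE,
                                      single_point = TRUE),
                       backend)
round(profile_energies(profile), 3)
#>      0      1      2      3      4      5      6      7      8      9     10     11
#>  0.000  1.296  4.096  7.056  9.216 10.000  9.216  7.056  4.096  1.296  0.000  0.000
extract_barrier(profile)
#> <barrier_estimate> 10.00 kcal/mol (frame 5 relative to frame 0, conventional_sp)
```

The twelve numbers are the conventional single-point energies of frames
0–11 (kcal/mol, relative to the ES well): frame 0 is the relaxed ES, frame
11 the relaxed TI, and the maximum at frame 5 — the reaction-coordinate
midpoint — recovers the surrogate's analytic 10 kcal/mol barrier. PHVA at
that frame (constraints released, reactive core as the atom subset) finds
exactly one imaginary mode:

```r
top <- profile$frames[[6]]$structure
top$frozen <- integer()
core <- with(top$atoms, serial[(resname == "SUB" & name != "HG") | name == "OG"])
frequencies(compute_partial_hessian(top, core, backend))
#> <vibrational_result> 15 modes, 1 imaginary
#>   imaginary: 172.1i cm^-1
```

A thin command-line front end covers the file-to-file stages:

```sh
adiamap fragmentize wt.pdb lib/ --substrate A900
adiamap assemble lib/ variant.pdb --sub A2=ala_fragment.pdb
adiamap jobs es.pdb ti.pdb jobdir/ --nucleophile 17 --electrophile 33
adiamap demo --seed 1
```

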