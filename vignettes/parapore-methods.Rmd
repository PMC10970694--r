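---
title: "Methods: pore, interface and ion-transport statistics in parapore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore, interface and ion-transport statistics in parapore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parapore)
```

## Scope and coordinate conventions

`parapore` analyses trajectories of paracellular ion-channel models:
oligomeric assemblies (claudin pore scaffolds being the motivating case)
whose conduction pathway runs *between* two membranes, parallel to them.
Throughout the package the pore axis is **+x** and the membrane normal is
z; all lengths are in Ångström and frame times in ns. Frames must be
uniformly spaced in time (tolerance 10⁻⁶ ns): every statistic below weights
frames equally, so a non-uniform stride would silently bias time averages,
and the constructor therefore rejects it.

Structures and multi-model trajectories are read and written as standard
PDB via `bio3d`; a plain-text frame table (`frame,time_ns,atom_id,x,y,z`,
six decimals, bit-exact round trip) is provided for ion-only trajectories.
Van der Waals radii come from a Bondi-style element table (C 1.70, N 1.55,
O 1.52, S/P 1.80, H 1.20 Å, monatomic ions by element; unknown elements
fall back to 1.70 Å with a warning). Formal charges are residue-level:
Arg/Lys +1, Asp/Glu −1, His neutral (the assumed simulation pH), ions by
species. These tables only need to be internally consistent: no result in
the package depends on the absolute radius scale, only on differences.

## The synthetic generator as ground truth

Real claudin-assembly trajectories are large, unpublished, and carry no
known truth. The generator therefore emulates exactly the statistical
structure the transport analysis assumes, nothing more:

* `build_toy_pore()` places scaffold pseudo-atoms of radius *a* on a
  cylindrical shell of radius R + a, so the free lumen has radius R. The
  angular count defaults to ⌈2π(R+a)/a⌉ and construction fails if
  surface-to-surface gaps exceed *a* — no probe of radius *a* can escape
  radially. Four single-atom "BNK" residues at x = 0 mark the bottleneck
  tetrad; eight "ENT" residues with Cα atoms at the two pore mouths mark
  the cuboid corners, mirroring the marker tetrads of the real assemblies.
* `simulate_ion_walk()` starts ions uniformly inside the cylinder and
  advances x by drift(species) + N(0, σ), y/z by N(0, σ), with a reflecting
  wall at radial distance R and reinjection (period L + 10) at
  x = ±(L/2 + 5). Reinjection rather than hard walls keeps a steady-state
  flux and a stationary mean ion count; wrap events are recorded so
  displacement always uses unwrapped coordinates. All randomness comes from
  one generator, seeded once, in a documented draw order (initial axial,
  radial, angular positions in topology order, then one x/y/z noise triple
  per ion per step) — runs are bit-reproducible.

Charge selectivity is modelled purely as species-dependent drift,
mobility × voltage, with no electrostatics, water or forces. The
`"anion-selective"` preset gives Cl⁻ a mobility of 0.25 Å/frame/V and Na⁺
zero; `"symmetric"` gives both species the same mobility. The preset
conditions — lumen radius 5 Å, length 40 Å, 20 ions per species, 400
frames, step noise σ = 0.3 Å/frame, voltages ±0.4/±0.8/±1.4 V — were fixed
once as a scale at which ion transits are frequent but diffusion still
dominates a single step, and are used unchanged by the test-suite and the
acceptance script. What passing tests on this generator shows is that the
*statistics* are implemented correctly (crossing logic, filtering,
summation, regression); it deliberately cannot show that a force field, a
membrane model, or sampling of a real simulation are adequate, and carries
none of the periodic-boundary leak pathways that complicate real
paracellular-channel setups.

## Contact maps

The closest-atoms distance between two residues is the minimum over all
atom pairs; hydrogens participate if present (the atom subset used by the
original analyses of such maps is unreported, and the synthetic fixtures
are heavy-atom-only, so results here are insensitive to the choice). A map
entry is a single flat mean over (frame × interface) samples rather than a
mean of interface means — identical when every interface contributes every
frame, which holds by construction for the intended balanced interface
groups; the choice is documented because it matters for ragged groups.
Contact classification is strictly `mean distance < threshold` with a 5 Å
default. The default analysis window everywhere is the trailing half of
the trajectory (`"last:0.5"` syntax), the usual equilibrated-production
convention.

## Interface metrics

**Hydrogen bonds.** The criterion is an explicit parameter object because
commercial analysis suites do not document theirs. Defaults: donor–acceptor
N···O ≤ 3.5 Å, and either D–H···A ≥ 120° (explicit hydrogens) or a
C(=O)···N acceptor-side angle ≥ 100° in heavy-atom-only mode — the common
literature criterion. Counts are over backbone amide/carbonyl pairs across
two segments, both directions.

**Persistence counts.** A pair of selections "interacts" in a frame iff
the minimum distance between their atoms is ≤ 4 Å (the same cutoff used
for ion contacts); a pair is *counted* iff its fraction of interacting
frames strictly exceeds 0.35. `charged_group_atoms()` supplies the
side-chain charged-group heavy atoms (Arg NH1/NH2/NE, Lys NZ, Asp OD1/OD2,
Glu OE1/OE2), optionally plus backbone O/N where a criterion admits
main-chain contacts.

**SASA.** Shrake–Rupley quadrature on a deterministic Fibonacci-sphere
lattice (default 960 points; below 16 the quadrature is meaningless and
rejected): per atom, area = (exposed points / total) × 4π(r + probe)², with
probe 1.4 Å and *all* topology atoms occluding regardless of the reporting
selection. Per-residue areas are additionally normalized by the
side-chain heavy-atom count — hydrogens are excluded from the divisor
because typical inputs are heavy-atom models. Validation uses the exact
two-sphere spherical-cap closed form and an independent 10⁵-point
quadrature; 960 points reproduce both within 2 %.

**RMSD.** Kabsch/SVD least-squares superposition (with the determinant
sign fix for improper rotations) precedes the deviation sum unless
disabled; fewer than three atoms cannot define a superposition and raise
an error. The implementation is cross-checked in the tests against
`bio3d`'s independent fitting routine.

## Pore diameter profile

At each axial station the package maximizes, over candidate centres in the
perpendicular plane within a lateral search bound, the clearance
min(|c − atom| − r_vdW): a coarse grid (default 0.25 Å) followed by
Nelder–Mead polish from the best grid point (deterministic start,
converged well below the 0.01 Å reporting precision). This differs from
the classic HOLE program's connected Monte-Carlo walk deliberately: for
near-straight paracellular pores whose axis is known, independent
per-station maximization is simpler, deterministic, and equally accurate,
at the cost of not following a curved pathway (out of scope). Negative
maxima are reported as-is with a `blocked` flag rather than clamped, so a
collapsed station is visible. Per-station spread over frames is the
population SD of the per-frame diameters. Ions and water should be passed
through `exclude`. On an ideal toy cylinder the recovered profile is flat
to < 0.05 Å and matches the analytic lumen diameter to < 0.1 Å; a
constriction ring is localized at its station. The validation profiles use
a 1 Å station spacing and an 8 Å search bound — toy lumens are ≤ 5 Å wide,
so a wider search adds nothing; the exported defaults (0.5 Å, 15 Å) suit
real assemblies.

## Ion transport statistics

The permeation pipeline mirrors how transport must be quantified when no
transmembrane flux plane exists:

1. **Crossing plane.** The bottleneck tetrad's centre of geometry is
   evaluated *per frame* (it may drift); "centre of mass" is implemented
   unweighted because the tetrads are symmetric and atom masses are nearly
   uniform — mass weighting is an option flag.
2. **Cuboid filter.** Bounds are per-axis min/max of the window-averaged
   positions of the eight entrance Cα atoms. Membership is inclusive in x
   and strict in y/z. An ion is pore-passing iff consecutive frames change
   the sign of x − x_centre with the ion inside the cuboid at both frames.
   Whether the original protocol required in-cuboid residence for the whole
   transit or only at the crossing is unreported; both are available
   (`strict_transit`), defaulting to crossing-time membership.
3. **One record per ion.** Only the first crossing is kept: the
   displacement formula sums each selected ion's full-window increments,
   so multiple crossings must not duplicate ions.
4. **Displacement.** D = Σᵢ Σₜ (xᵢ(t+1) − xᵢ(t)) over unwrapped
   coordinates — wrap bookkeeping from the generator, or minimum-image
   continuity when frames carry a box. The double sum telescopes exactly
   to Σᵢ (x_end − x_start), an identity the tests assert at machine
   precision on random trajectories; it is kept as the double sum because
   windowing and stride-invariance are then manifest.
5. **Selectivity.** Per species, ordinary least squares of D against
   voltage across runs; slope, its standard error, and R² are reported.
   The zero-selectivity control is judged by the slope gap in units of the
   combined standard error.

Mean ion number uses strict cuboid membership; contact-time profiles use a
strict < 4 Å minimum-distance criterion per residue per subunit, averaged
over subunits, reported as percentages of window frames.

Because the trajectory stride of typical inputs is unknown, every
time-like quantity is defined per frame (fractions or per-frame sums), not
in absolute time. A walk of T saved frames takes T − 1 steps; the drift
expectation used for validation is therefore N·μ·(T−1), which the 4σ√(NT)
acceptance band absorbs.

## Charge fingerprint

Net pore charge = Σ over non-shielded lining residues of formal charge ×
multiplicity. Multiplicity defaults to 4: a tetrameric pore scaffold
contributes each lining residue four times, and residues donated by the
interlocked loops of neighbouring subunits also occur four times per pore.
Shielded residues — lysine/glutamate pairs persistently neutralized by
salt bridges — are excluded from the sum (for the built-in claudin-10
linings the shielded pair is charge-neutral, so exclusion is a matter of
bookkeeping, not of the total). The built-in linings give +8 for
claudin-10a and −12 for claudin-10b, matching the opposite ion occupancy
and selectivity of the two isoforms.

## Numerical choices and degenerate inputs

* Selections resolving to zero atoms warn and flag rather than error, so
  exploratory configs fail softly; operations that cannot proceed without
  atoms (SASA, RMSD) then raise their own errors.
* Equality-adjacent boundaries are all explicit: contacts are strict `<`,
  persistence is strict `>`, contact time is strict `<`, cuboid y/z are
  strict, x inclusive.
* The profiler evaluates clearance in blocks (bounded memory) and prunes
  atoms axially further than search bound + max radius + 5 Å from a
  station, which cannot change any reported radius below that bound.
* PDB altLoc codes other than ''/'A' are dropped with a warning; duplicate
  (chain, residue, atom-name) triples are rejected outright.
* The test-suite and acceptance problem sizes (20-ion/400–1000-frame
  walks, 31–41 profile stations, 960-point quadratures) were chosen so the
  whole validation recomputes in about two minutes on one core while
  keeping every statistical band at 4–5σ.

## Known limitations

* The generator validates statistics, not physics: no electrostatics,
  solvent, or membrane, and its reinjection removes the very
  periodic-boundary leak currents that make real paracellular transport
  hard to quantify.
* The profiler assumes a straight, known axis; curved-pathway searching is
  out of scope.
* Hydrogen-bond and "electrostatic interaction" definitions are
  literature-standard defaults, not reverse-engineered from any particular
  analysis suite; absolute counts should be compared only within one
  criterion.
* Binary trajectory formats (DCD/XTC) and MD-engine topology formats are
  not read; convert to multi-model PDB or the frame table first.
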