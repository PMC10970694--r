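# parapore

Trajectory analysis for **paracellular ion channels** — the pores that
tight-junction proteins such as claudins form *between* epithelial cells,
running parallel to the two membranes rather than through one. Claudin-10a
and claudin-10b assemblies are the motivating system: channels with nearly
identical architecture whose differing pore-lining residues produce opposite
charge selectivity (anion- vs cation-conductive).

The package is aimed at people running molecular-dynamics simulations of
such assemblies who need the analysis layer: interface fingerprints,
pore-geometry profiles, and — because a paracellular pore has no
membrane-spanning flux plane — bespoke permeation statistics based on
counting and displacing ions through the pore interior rather than
computing a transmembrane current.

## What it computes

With the pore axis along *x*:

* **Residue contact maps** — entry (i, j) is the closest-atoms distance
  between residues i and j, averaged over equivalent subunit interfaces and
  a trajectory window; contacts classified at a strict d < 5 Å.
* **Interface metrics** — backbone hydrogen-bond counts (N···O ≤ 3.5 Å with
  a carbonyl-angle check, or D–H···A ≥ 120° with explicit hydrogens), named
  atom-pair distance series, counts of electrostatic pairs persisting in
  > 35 % of frames, Shrake–Rupley solvent-accessible surface area
  (normalized per side-chain heavy atom), and Kabsch-superposed backbone
  RMSD.
* **Pore diameter profile** — at stations along the axis, the diameter
  2·max<sub>c</sub> min<sub>atoms</sub>(|c − x<sub>atom</sub>| − r<sub>vdW</sub>)
  of the maximal inscribed sphere, in the spirit of the HOLE program but as
  an independent deterministic per-station maximisation.
* **Ion transport statistics** — ions count as pore-passing only if they
  cross the *x*-plane of the bottleneck-tetrad centre of mass while inside
  a cuboid bounded by the entrance-residue Cα positions; for the selected
  ions the total displacement

  D = Σ<sub>i=1..N</sub> Σ<sub>t</sub> ( x<sub>i</sub>(t+1) − x<sub>i</sub>(t) )

  is accumulated per species, along with the mean number of ions inside the
  cuboid and per-residue ion contact times (< 4 Å to ≥ 1 ion). Runs at
  several applied voltages feed an ordinary least-squares fit of D against
  voltage; the slope per species is the charge-selectivity readout.
* **Pore net-charge fingerprint** — formal charges of the pore-lining
  residues × their multiplicity around the pore, shielded residues
  excluded. Built-in linings for claudin-10a (+8) and -10b (−12).
* **Synthetic ground truth** — a toy cylindrical pore scaffold with
  bottleneck ("BNK") and entrance ("ENT") marker tetrads, plus a seeded
  drift–diffusion ion walk with species- and voltage-dependent drift, so
  every statistic can be validated against known parameters.

## Worked example

Selectivity of a synthetic anion-selective pore, six voltages:

```r
library(parapore)

volts <- c(-1.4, -0.8, -0.4, 0.4, 0.8, 1.4)
runs <- lapply(seq_along(volts), function(i)
  measure_transport(simulate_transport("anion-selective", volts[i], seed = 10 + i)))
selectivity_regression(runs)
#> selectivity regression (12 points ):
#>  species slope_A_per_V  slope_se intercept_A   r_squared n_points
#>       CL  1967.3461584 40.233210   -3.856557 0.998329902        6
#>       NA     0.9771828  9.398112   -3.505494 0.002695493        6
```

Only the Cl⁻ displacement responds to voltage (slope ≈ 1967 Å/V, R² ≈ 1;
the generator's ground truth is 20 ions × 399 steps × 0.25 Å/frame/V =
1995 Å/V), while Na⁺ shows no trend — the signature of an anion-selective
pore. A single run shows the underlying numbers:

```r
res <- measure_transport(simulate_transport("anion-selective", -1.4, seed = 11))
res
#> transport result at -1.4 V:
#>  species total_displacement_A n_selected_ions mean_ions_in_cuboid
#>       CL         -2772.438032              20             15.8925
#>       NA            -3.996507               2             18.1400
```

All 20 Cl⁻ ions pass the bottleneck and accumulate −2772 Å of axial
displacement at −1.4 V; the two Na⁺ ions that happen to diffuse across
contribute essentially nothing. Pore geometry of a constricted toy pore:

```r
pore <- build_toy_pore(3.5, 60, 1.5, constriction = list(x = 10, pore_radius = 2.5))
pore_profile(trajectory(pore$topology, list(pore$frame)),
             pore_axis_spec(-15, 15, station_spacing = 1, search_radius = 8))
#> pore profile: 31 stations; minimal mean diameter 5 A at station 10 A
```

And the charge fingerprint: `pore_net_charge(cldn10_pore_lining("CLDN10a"))`
returns `8`; `"CLDN10b"` returns `-12`.

A command-line wrapper over the same functions is installed at
`inst/cli/parapore.R` (subcommands `synth`, `displace`, `selectivity`,
`charge`, `profile`, `contacts`, `hbonds`, `pairdist`, `sasa`, `rmsd`);
every run writes a JSON manifest with parameters, input hashes and the
package version.

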