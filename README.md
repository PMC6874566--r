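# hookjoint

Geometric analysis of supercoiled helical polymer assemblies, built around
the bacterial flagellar hook.

The hook is a short tubular polymer of the protein FlgE that acts as a
molecular universal joint: it bends easily while resisting twist, so the
rotary motor's torque is transmitted smoothly to the off-axis filament. In
the native supercoiled state the hook's 11 protofilaments are cyclically
compressed on the inside of the bend and extended on the outside, and each
of the 11 subunit positions around the circumference takes a slightly
different conformation. `hookjoint` turns atomic coordinates of such an
assembly into quantitative geometry:

* **Lattice indexing** — 1-start ordering of subunits, the −5/6/11-start
  neighbour maps, protofilament assignment and the extended/compressed
  numbering convention (extended protofilament = 1).
* **Spacing profiles** — per-residue axial Cα distances along each
  protofilament, per-domain means, and the elastic-bending consistency
  check: under pure bending, spacings follow
  `d(r, φ) = d0 (1 − κ r cos(φ − φ0))`, symmetric about the straight-form
  spacing `d0 = 45.6 Å`.
* **Rigid-domain motions** — Kabsch superposition, per-domain residual
  tilts and axial shifts after superposing the inner D0–Dc domain, and
  subunit length extension between conformers.
* **Supercoil estimation** — discrete curvature/torsion of the tube
  centerline, a least-squares circular-helix fit, and a bending-lattice
  model refinement; pitch `P = 2π|τ|/(κ²+τ²)`, radius
  `R = κ/(κ²+τ²)`, left-handed ⇔ τ < 0. A fitted segment can be
  screw-extended to a full supercoil pitch.
* **Contacts** — residue pairs across the −5/6/11-start interfaces,
  classified constant (present in all 11 protofilament contexts) versus
  switching, with per-residue neighbour-distance variability and the
  mesh-layer (D1) triangle-gap metric.
* **Synthetic generator** — coarse-grained straight and supercoiled
  11-protofilament assemblies with three radial layers and full ground
  truth (lattice bookkeeping, closed-form expected spacings, hinge
  fixtures, seeded noise), so every estimator is validated by parameter
  recovery.

## A worked example

Generate the study-condition synthetic supercoil (26 subunits, 11
protofilaments, left-handed supercoil of pitch 1290 Å and radius 165 Å)
and analyze it end to end:

```r
library(hookjoint)
spec <- synthetic_spec()              # study conditions
g <- generate_supercoiled(spec)
smry <- analyze(hook_config(g$assembly, domains = g$truth$domains, seed = 1))
smry
#> hook analysis summary
#>   subunits: 26  protofilaments: 11  conformation classes: 11
#>   axial spacing: min 37.2 A (pf 7), max 53.8 A (pf 1), d0 45.6 A
#>   supercoil: left-handed, pitch 129.1 nm, diameter 33.1 nm
#>   conformer 7 -> 1: D0c tilt 0.0 deg shift -0.0 A; D1 tilt 1.5 deg shift -0.2 A;
#>     D2 tilt 4.3 deg shift -0.3 A; length extension 4.1 A
```

The assembly's 26 chains index onto 11 protofilaments with 11 conformation
classes; the most compressed protofilament (id 7, 37.2 Å minimum axial
spacing) sits opposite the most extended one (id 1, 53.8 Å), their
per-layer means straddle `d0` symmetrically (elastic bending), and the
left-handed supercoil is recovered at 129.1 nm pitch and 33.1 nm diameter
from the short segment. The same chain runs on a deposited coordinate file
via `analyze(hook_config("model.pdb"))`, or from a shell through
`inst/cli/hookjoint.R`. `recover()` repeats the analysis over 20
randomized ground truths and tabulates recovery errors.

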