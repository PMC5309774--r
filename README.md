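# stalkmech

Quantitative comparative structural analysis of large-scale RNA domain
motion, built around the ribosomal L1 stalk — the mobile arm of the large
subunit (23S rRNA helices H76–H78 plus protein L1) that escorts deacylated
tRNA out of the ribosome during translocation. The package is for
structural biologists who want to measure, from deposited coordinate
models, *how far* a tethered RNA domain moves, *about which axis*, and
*where along the RNA* the motion originates.

## What it computes

Given two conformers superposed on a static core, the motion of a mobile
domain is reduced to a single screw (Euler–Rodrigues) axis. From the 3×3
rotation matrix **R** and translation **T** of the mobile-domain fit:

- rotation angle: Θ = arccos((tr **R** − 1) / 2)
- axis direction: **u** ∝ (R₃₂−R₂₃, R₁₃−R₃₁, R₂₁−R₁₂)
- axis point: the minimum-norm solution of (**I** − **R**) **p** = **T**⊥
- pitch: **T** · **u**

Around this core the package provides:

- Kabsch least-squares superposition with iterative refinement of the
  static core (residues with ensemble backbone RMSD < 0.8 Å);
- helical-axis tracing from local base-pair step screws, deviation
  profiles against a reference conformer, and inflection (hinge)
  localization by curvature analysis with segmented-fit refinement;
- contact maps with A-minor minor-groove classification, curated
  intersubunit-bridge catalogs (B9, B7a, the H68 network), and
  base-stacking overlap areas from projected ring polygons;
- a four-state classifier (open / intermediate 2 / intermediate 1 /
  closed) and a manifest-driven pipeline producing per-structure records
  and group summary tables;
- a synthetic-structure generator (ideal A-form duplexes, hinged helices,
  two-domain systems with imposed screw motions and Gaussian noise) so
  that every stage is verifiable by parameter recovery, with no
  downloads.

## Worked example

```r
library(stalkmech)

# a two-domain system: static helix + mobile helix rotated 26.5 degrees
# about a known axis, 0.2 A coordinate noise
sys <- makeTwoDomainSystem(angle = 26.5, noiseSigma = 0.2, seed = 101)
ax <- domainRotation(sys$moved, sys$reference, sys$staticSel, sys$mobileSel)
ax
#> ScrewAxis: angle 26.522 deg, pitch -0.017 A [ok]
#>   direction: 0 0.0125 0.9999
#>   origin:    -0.008 0.22 25.824
classifyState(screwAngle(ax))
#> [1] closed
#> Levels: open intermediate2 intermediate1 closed
```

The imposed 26.5° rotation is recovered to 0.02° under noise, the axis
direction matches the imposed (0, 0, 1) to ~0.01, and the rotation falls
in the closed class — the stalk position of hybrid-state ribosomes.

```r
# hinge localization: a 20-bp duplex bent 30 degrees at step 12
straight <- makeAformHelix(20)
hinged <- makeHingedHelix(20, hingeStep = 12, bendAngle = 30,
                          noiseSigma = 0.2, seed = 102)
ref  <- traceHelicalAxis(straight, straight@metadata$basePairs)
prof <- deviationProfile(traceHelicalAxis(hinged, hinged@metadata$basePairs), ref)
findInflections(prof)
#>   label prominence
#> 1    12   1.727962
```

The deviation profile of the bent helix against the straight reference
inflects exactly at the imposed hinge step.

For real structures, `runDataset()` drives the same measurements over a
manifest of coordinate files (see `?runDataset` and `?readManifest`), and
`inst/scripts/stalkmech.R` wraps the common operations for shell use.

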