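---
title: "Measuring RNA domain motion: models and methods in stalkmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring RNA domain motion: models and methods in stalkmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stalkmech)
```

## The problem

The L1 stalk of the large ribosomal subunit swings through tens of
Angstroms as deacylated tRNA leaves the ribosome, and it does so as an
essentially rigid body hinged at well-defined points in its rRNA. Given a
set of deposited coordinate models of ribosomes trapped in different
functional states, we want three things: the magnitude and axis of the
stalk's motion in each conformer relative to a reference, the residue
positions where the motion originates, and the contacts the stalk makes
and breaks along the way. None of these are exotic quantities, but
getting them reproducibly requires a chain of careful geometric steps,
each of which this package implements and tests in isolation.

## Rigid-body model and the screw decomposition

Every comparison is made in a common frame defined by superposing
structures on a *static core* — the set of residues whose backbone moves
less than a threshold across the ensemble. Superposition is the standard
least-squares (Kabsch) fit over paired atoms; it performs no outlier
rejection of its own, so the fit is a deterministic function of the
selection. Rejection lives in one place only, `refineStaticCore()`,
which iterates: fit all structures to the first on the current core,
recompute each residue's ensemble backbone RMSD, drop residues at or
above the threshold, repeat to stability. Two implementation details
matter for robustness. First, every residue of the initial selection is
re-evaluated each cycle, so residues displaced only by an early
compromise fit re-enter the core once the fit anchors on truly static
regions. Second, when a poor compromise fit pushes more than half the
residues over the threshold at once, the core shrinks by at most a
quarter per cycle instead of collapsing. The threshold default is 0.8 Å,
the operational definition of "static" used in the analysis this package
supports; the backbone atom set is the sugar-phosphate chain
(P, OP1, OP2, O5', C5', C4', C3', O3'), chosen because base atoms are
frequently unmodeled at medium resolution.

Domain motion between two conformers is reduced to a screw: after the
static-core fit, the residual transform of the mobile selection is
decomposed into a rotation angle about a single axis plus a translation
(pitch) along it. The angle comes from the trace of the rotation matrix,
the direction from its skew part, and the axis point from the
minimum-norm solution of $(I - R)\,p = T_\perp$ — that system is rank 2,
so "the" origin is a choice; we report the point on the axis closest to
the mobile domain's centroid, which is deterministic and physically
readable. Two degeneracies are handled explicitly: below an angle floor
(default 0.25°) the direction is numerically meaningless and the result
is flagged `undefined-axis` with the angle still returned; within 0.25°
of a half-turn the skew part vanishes and the direction is recovered
from the symmetric part of the rotation (eigenvector route), flagged
`near-180`. The decomposition is validated two ways: a round trip
through `screwTransform()` must reproduce the transform, and an
independently written quaternion implementation in the test suite must
agree to 10⁻⁶ over a thousand random screws.

Angles are reported in degrees in [0, 180]; handedness is carried by the
direction vector, so a motion and its inverse have the same angle and
opposite directions.

## Helical-axis tracing and hinge localization

To localize *where* motion originates we trace the helical axis of the
stalk's duplex regions and ask where the traced axis of a moved
conformer departs from the reference conformer's. The tracer works on a
base-pair table (shipped for H75/H76 in E. coli numbering, overridable)
and uses a local screw construction: within each window of three
consecutive base pairs, the rigid transform that advances the first two
pairs onto the last two is a one-helical-step screw whose axis is the
local helix axis. Window fits use the sugar-phosphate backbone plus C1'
atoms of the window's residues — base atoms are excluded because
consecutive residues of unlike type have no atomic correspondence. Each
pair's axis point is the projection of its C1'–C1' midpoint onto the
axis of the *best-fitting* covering window (smallest fit RMSD). That
selection rule is the load-bearing choice: a window that straddles a
hinge is not related by any single rigid step, its fit RMSD betrays
that, and excluding it keeps hinge artifacts out of the trace. Interior
axis points are then smoothed with a three-point average, which leaves
an ideal straight helix exactly on its cylinder axis (the construction
is exact in the noiseless case) while damping coordinate noise.

A deviation profile is the per-pair distance between axis points of two
traces sharing residue labels, computed after both structures are in the
common core frame. Inflections are found in two stages: candidates are
local maxima of the second difference of the moving-average-smoothed
profile (lag equal to the smoothing window, rescaled near the ends),
filtered by topographic prominence; candidate positions are then refined
by a segmented piecewise-linear least-squares fit of the whole profile —
flat first segment, one slope change per candidate — by coordinate
descent of each breakpoint over its feasible interval. The second
difference alone localizes strong bends well but is biased by one to two
steps for gentle bends near the profile ends; the segmented fit removes
that bias. Defaults: smoothing window 3, minimum prominence 0.4 Å. These
were calibrated once against the package's own synthetic-hinge recovery
requirement (bends of 10–40° at known steps, 0.2 Å coordinate noise,
localization within ±1 step in at least 95% of replicates) and are
exposed as arguments; the acceptance script recomputes the recovery rate
on every run.

## Contacts and stacking

Contact maps enumerate heavy-atom pairs between two selections within a
cutoff. The cutoff default is 4.0 Å — a conventional heavy-atom contact
distance, configurable since no single value is canonical. A contact is
classed `minor_groove` when a nucleotide-side atom lies on the
minor-groove face (O2' plus N1/C2/N3 for purines, O2 for pyrimidines),
the atom set implicated in A-minor packing. Curated catalogs (the
transient bridge B9 between the stalk head and the small subunit, bridge
B7a, and the minor-groove network around H68) are shipped as YAML with
symbolic chain keys bound per structure at evaluation time; catalog
entries whose chains or residues are unmodeled are reported as
"absent residue" rather than erroring, because protein L1 and tRNA are
genuinely absent from several deposited models.

Stacking between base-pair planes is quantified as the area of
intersection of the two pairs' ring-atom convex hulls projected onto the
mean plane of the first pair, with the interplanar distance and the
angle between plane normals reported alongside. This is a deterministic,
parameter-free proxy for the visual overlap of stacked bases; it is not
a van-der-Waals surface calculation, and it is documented as such.

## The synthetic generator: what it does and does not emulate

All quantitative guarantees in the test suite rest on generated
structures with known ground truth. The generator builds idealized
A-form-like duplexes: C1' atoms on a 9.4 Å orbit, 2.81 Å rise and 32.7°
twist per pair, an intra-pair C1'–C1' span of 10.4 Å, a simplified
backbone and planar ring atoms on a rigid per-residue template. Three
constructions cover the pipeline: straight duplexes (whose true axis is
known exactly), hinged duplexes (distal segment rotated by a known angle
about a known pivot), and two-domain systems mimicking the stalk
architecture — a static helix with a mobile helix tethered
perpendicular, moved by a known screw. Noise is isotropic Gaussian per
coordinate, applied after the motion, independently per conformer, and
fully seeded: fixed seeds give byte-identical fixtures.

What this does *not* emulate: sugar pucker, sequence-dependent geometry,
groove asymmetry beyond the template, disorder, or resolution-dependent
coordinate error correlations. Passing the synthetic tests therefore
demonstrates that the geometry pipeline is correct and noise-stable at
realistic coordinate-error scales; it does not by itself demonstrate
agreement with published measurements on real ribosome structures. The
test blocks and manifest machinery for that comparison are included and
run whenever a local directory of the relevant PDB entries is provided;
they are the only parts of the suite that need external data.

## State classification and the dataset pipeline

Stalk rotations cluster by the tRNA binding state of the ribosome, and
the four-state classifier simply thresholds the rotation angle. The
default boundaries (9.2°, 17.4°, 23.45°) are midpoints between adjacent
group means of the four stalk positions (4.0°, 14.4°, 20.4°, 26.5°) —
the simplest deterministic rule consistent with the clustering, and
configurable. Intervals are left-closed: a rotation exactly at a
boundary belongs to the more-rotated state. `runDataset()` applies the
whole chain (read, renumber, core-superpose, screw-decompose, measure
the head-marker displacement, classify) over a manifest, skipping
failing entries with recorded reasons; only a failing reference entry
aborts. Structures deposited with a numbering convention other than the
E. coli scheme used by all selection presets must carry an explicit
renumbering map in the manifest — the package never guesses residue
correspondences.

The 30S body/head rotation columns of the full published summary are
not computed by default: they require small-subunit domain selections
that are not part of this package's curated configuration. The same
screw machinery applies once a user supplies those selections.

## Numerical choices and degenerate inputs

- Superposition requires at least 3 paired, non-collinear atoms; the
  rotation is forced proper (determinant +1) in the SVD step.
- Altloc resolution keeps the highest occupancy, ties broken
  alphabetically; hetero records are dropped unless requested.
- `closestApproach` breaks distance ties by atom-identity order and
  excludes identical atoms when selections overlap.
- Convex-polygon clipping (Sutherland–Hodgman) treats points within
  10⁻¹² of an edge as inside; overlap areas are exact for the projected
  hulls.
- Test problem sizes: 20-bp helices for tracing, 8+12-bp two-domain
  systems, 500-point clouds for the noise floor, 1000 random screws for
  the round trip, and 112 hinge replicates over the bend/position grid —
  sizes at which every Monte-Carlo bound in the suite is comfortably
  resolved while the whole suite stays quick.

## Known limitations

Axis tracing assumes a duplex with at least four consecutive base pairs
and A-form-like geometry; profiles across unpaired linkers carry no axis
points there (labels jump, as across the 2091–2092 linker in the shipped
stalk pairing). The stacking overlap is a projection-area proxy. The
static-core refinement measures deviation against the first structure
(anchor-based, not all-pairs) for determinism and linear cost, so a
pathological anchor could bias the core; using a well-ordered reference
structure as the first entry is the intended usage.
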