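---
title: "Simulating crowded cryo-electron tomograms with multi-ball models"
author: "tomopack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating crowded cryo-electron tomograms with multi-ball models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tomopack)
```

## The problem

Analysis methods for cryo-electron tomography (particle picking,
segmentation, subtomogram classification) are hard to benchmark because
real tomograms come without ground truth. A simulator that packs known
structures into a crowded pseudo-cell and renders them into a noisy
density volume provides labelled data: every particle's identity,
position, orientation and extent is known by construction. `tomopack`
implements such a simulator end to end, with one deliberate twist: both
rigid macromolecules and deformable ultrastructures (filaments,
membranes) are represented in a single bead-model formalism, so they can
be packed together by one force field.

## Multi-ball coarse graining

A macromolecule with $n$ atoms is reduced to
$k = \max(3, \lceil n/5000 \rceil)$ balls: one ball per 5000 atoms, with
a floor of three so that the ball centers always span two linearly
independent vectors — the minimum needed to read off a rigid rotation
later. Atoms are partitioned by k-means on their coordinates (seeded
Lloyd iteration: initial centers drawn from the atoms, nearest-center
assignment iterated to a fixed point with a 300-iteration cap; an
emptied cluster is re-seeded at the atom farthest from its current
center, which guarantees termination with non-empty clusters). Each
ball is placed at its cluster centroid; its radius is the distance to
the farthest member atom, so the balls jointly cover every atom; its
mass is 5000 atom units.

Rigidity and deformability are encoded purely in the topology:

* **rigid**: all $\binom{k}{2}$ ball pairs are bonded, with equilibrium
  lengths equal to the initial center distances. A fully connected graph
  of stiff springs admits no shape change without bond-length change,
  so no explicit angle terms are needed (an optional angle stiffness for
  rigid bodies is exposed but defaults to off).
* **filament**: a chain of $m$ balls bonded consecutively (end balls
  have one bond, inner balls two), with angle terms on all interior
  triples at zero stiffness — inextensible but freely bendable.
* **membrane**: an $m \times n$ grid with bonds to the four axial and
  four diagonal neighbours (corners have degree 3, non-corner edge
  balls 5, interior balls 8), plus zero-stiffness straight-through
  angle terms along rows and columns.

Default deformable ball diameters are 40 (filament) and 80 (membrane),
matching the stated structure scales; bead spacing defaults to the ball
diameter so the chain/mesh starts with touching, non-overlapping beads.
The spacing choice is ours — only the diameters are stated — and
touching beads avoid both initial overlap and gaps in the rendered
density.

## Units

All internal lengths live in one consistent unit, documented as
1 unit = 1 Å. The source parameterisation mixes nm and Å incoherently
(switch distance "600 nm" next to 20–65 Å ball radii); we therefore
read every printed numeral as an internal unit: field radius 300,
switch 600, cutoff 610, boxes 1200 and 500 for the "120 nm" and "50 nm"
scenes, rendering at 10-unit voxels (1 nm) with a 40-unit (4 nm)
resolution kernel. Every value is config-overridable.

## The packing force field

Per ball $i$, the force is
$F_i = F_i^{b} + F_i^{nb} + F_i^{ext}$:

* **external (centripetal) field**: magnitude $10\,\lVert x_i\rVert$
  inside radius 300, saturating at 3000 outside, always pointing at the
  scene center; zero at the center and continuous at the boundary
  ($10 \times 300 = 3000$). This is what drives crowding.
* **bonds**: $U = k_b (r - r_0)^2$ with $k_b = 2000$.
* **angles**: $U = k_\theta (\theta - \theta_0)^2$, vertex at the middle
  ball of the triple; $k_\theta = 0$ for deformable kinds. (The angle
  vertex convention in the source text is ambiguous — it writes both
  bond vectors from the first ball — but for straight-chain triples
  with $k_\theta = 0$ both readings coincide; we use the standard
  middle-vertex convention.)
* **Lennard-Jones**:
  $U = \varepsilon\left[(R_{min}/r)^{12} - 2 (R_{min}/r)^{6}\right]$,
  tapered linearly to zero between the switch distance $S = 600$ and
  cutoff $C = 610$. The pair parameter $R_{min}$ is not stated in the
  source; we set $R_{min}(i,j) = r_i + r_j$ (the well sits exactly at
  ball contact) and $\varepsilon = 1$, since the term's stated purpose
  is only to prevent overlap. Electrostatics are deliberately absent
  (all charges zero).

Non-bonded exclusions: directly bonded pairs are excluded from the LJ
sum — which covers every intra-rigid pair, since rigid structures are
fully bonded — while non-bonded intra-filament and intra-membrane pairs
do interact, preventing self-penetration during curling. Neighbour
search uses cell lists with cell edge equal to the cutoff; a test pins
its exact equivalence to the all-pairs sum.

## Integration, stability, and substeps

The printed update is first order and velocity-free: $a = F/m$,
$v = a\,\delta t$, $\Delta x = v\,\delta t$, with $m = 5000$ and
$\delta t = 1$; no velocity is carried between steps. We keep this
update as the outer step, but a straightforward linearisation shows it
is unstable for multi-bonded balls at the default stiffness: a bonded
pair's separation error is multiplied by $1 - 4 k_b/m = -0.6$ per step
(stable), but the breathing mode of a fully connected 3-ball structure
is multiplied by $1 - 6 k_b/m = -1.4$, so any perturbation grows
exponentially and a scene of rigid multi-ball models explodes within a
few dozen steps. Each outer step is therefore evaluated as $n$
fractional substeps of $\delta t/\sqrt{n}$, with
$n = \lceil 2\,\delta t^2 \kappa_{max}/m \rceil$ chosen from the
stiffest ball's total incident bond stiffness
$\kappa_i = \sum_{\text{bonds at } i} 2 k_b$ (a Gershgorin bound on the
bonded Hessian). Two properties make this the minimal intervention:
for a constant force the substeps telescope to exactly the printed
$(F/m)\,\delta t^2$ per outer step — a free ball outside the saturation
radius still moves exactly $3000/5000 = 0.6$ units per step — and
`packStep(..., nSub = 1)` remains the verbatim printed update.

Packing stops at a step cap or when the mean per-ball displacement over
a trailing 50-step window falls below $10^{-3}$ units/step (the source
gives no stop rule; the tolerance is config-overridable).

Initial placement draws uniform random positions for each structure's
bounding sphere inside the box and uniform random orientations (via
random unit quaternions, uniform over rotations rather than uniform
Euler angles), rejecting overlapping bounding spheres; instances are
placed largest-first with whole-scene restarts, which keeps rejection
sampling workable in the crowded 500-unit five-structure scene.

## Pose ground truth

A structure's position is the arithmetic mean of its ball centers. Its
displacement vector is recorded as *initial minus final* — the printed
convention, which points opposite to the prose describing it; a
`fromInitial` flag flips the sign for the geometric reading. For rigid
structures the rotation is extracted from the first three ball centers
(guaranteed non-collinear by the coarse-graining contract): first the
minimal rotation taking direction $A_0B_0$ to $A_1B_1$, then the
residual spin about the $A_1B_1$ axis fixed by the image of $A_0C_0$.
The result is decomposed as ZYZ Euler angles,
$R = R_z(\alpha) R_y(\beta) R_z(\gamma)$ with $\beta \in [0, \pi]$; at
gimbal lock ($\beta = 0$ or $\pi$) we set $\gamma = 0$ and fold the
spin into $\alpha$, so matrices always round-trip even where the angle
triple is not unique. Deformable structures are annotated with zero
rotation — they are rendered in their final shape, so orientation is
meaningless for them. Each structure's truth row also records its final
bounding radius (centroid-to-ball distance plus ball radius), the
radius used by the picking evaluation.

## Rendering and noise

Each ball contributes an isotropic Gaussian of FWHM equal to the target
resolution (default 40 units = 4 nm at 1 nm voxels), truncated at
$3\sigma$ and normalised so the ball's integrated density equals its
mass exactly (mass conservation is a validity invariant). Volumes are
stored as R arrays with `dim = c(nx, ny, nz)`, x fastest — the same
layout MRC uses on disk — and the world coordinate of voxel
$(i, j, k)$'s center is `origin + (i - 1/2, j - 1/2, k - 1/2) *
voxelSize`.

Scene maps render rigid structures from a per-structure reference map
(rasterized in the initial pose about its centroid), rotated by the
extracted rotation and translated to the final centroid via trilinear
resampling; reference maps are rendered at half the scene voxel size
(`refOversample = 2`), which keeps the dual-path discrepancy (rotate
map vs. rotate balls then rasterize) below 2% relative RMS. Deformable
structures are rasterized directly from their final ball positions.

Noise is zero-mean i.i.d. Gaussian with variance
$\mathrm{Var}(\text{signal})/\mathrm{SNR}$ — i.e. SNR is defined as the
variance ratio, the common convention for simulated cryo-ET; this
definition matters when quoting SNR 1000/200 tomograms and is measured
back by `measureSNR()` as $\mathrm{Var}(clean)/\mathrm{Var}(noisy -
clean)$. No missing wedge or CTF is modelled, deliberately: only
random noise is added.

## DoG picking and evaluation

The picker blurs the tomogram with two Gaussians ($\sigma_2 =
1.1\,\sigma_1$, sigmas in voxels) and subtracts. We use the standard
separable 3D Gaussian filter with replicate-edge padding (a constant
volume transforms to exactly zero); only relative DoG values matter for
peak ranking, so the 1D normalisation constant quoted in the source is
immaterial. Local maxima are detected over the 26-neighbourhood; exact
plateaus keep their lexicographically smallest voxel, so "strict
maximum with a deterministic tie-break" is realised consistently.
Peaks below $T = m + t\,(M - m)/20$ are discarded, where $M$ and $m$
are the extreme peak values and $t = 5$ by default; an optional top-K
mode keeps the K strongest peaks, the protocol used when the pick count
is fixed to the particle count. Matching against truth is greedy
one-to-one in increasing peak-to-center distance, counting a true
positive when the matched peak lies within the particle's bounding
radius (a permissive any-peak-within-radius flag exists for sensitivity
analysis). When pick and truth counts are equal, precision, recall and
F-score coincide — an identity the tests assert.

## Synthetic structure generators

Because the pipeline must run self-contained, `synthAtomCloud()`
samples atom clouds of four shapes — globular (isotropic Gaussian), rod
(uniform cylinder, aspect 5), planar (thin slab), dumbbell (two
displaced Gaussians) — at 4000 to 16000 atoms and 120 to 160 unit
extents, mimicking the stated macromolecule size range (overall sizes
60–250, concentrated at 120–160). These fixtures exercise every code
path (cluster counts from the floor of 3 up, anisotropic shapes for the
volume-saving comparison, non-collinear centers for pose extraction).
They do not reproduce real protein density texture, secondary
structure, or compositional abundance — so a passing picking test on
blob fixtures demonstrates the pipeline's correctness, not picking
performance on realistic density; that is what the replication path
with deposited structures is for.

## What the desk-scale experiments show

The test suite packs a five-structure scene (500-unit box, 2000 steps,
16 balls): rigid internal distances drift below 1% and all
inter-structure centroid distances shrink. Single-structure deformation
runs place a 9-ball filament or a 5x5 membrane tangentially at
r = 200 and pack 2000 steps in a 1200-unit box. The filament behaves as
advertised: bonds stay within 0.2% of equilibrium while the end-to-end
distance drops by more than a third (it wraps around the field center).

The membrane does **not** reproduce the expected "deforms less"
contrast at these parameters, and we report that honestly rather than
tuning around it. With zero angle stiffness the mesh has no bending
resistance of its own; its only shape memory is bond chord-shortening,
and the saturated 3000-unit field is strong enough to pay the ~5% bond
strain that unlocks full crumpling. Since the membrane also spans a
larger footprint (corner-to-corner 452 vs. 320), it catches larger
force differentials and ends more collapsed than the filament. The
expected contrast does appear in the early, quasi-static regime (at
400 steps the membrane's spans have dropped ~0.3% against the
filament's 1.8%, with membrane bonds within 0.4%), but in that regime
the filament has not yet curled past the 5% end-to-end threshold, so no
single run length shows both behaviours at once. The corresponding
acceptance check is left failing by design, with this analysis as its
record.

## Numerical choices and degenerate inputs

* k-means determinism: same cloud and seed give identical structures.
* Degenerate clouds whose ball centers are collinear are rejected at
  coarse-graining time (pose extraction would be ill-posed).
* Coincident ball centers make bond/LJ force directions undefined and
  raise errors naming the offending pair.
* The LJ taper is linear in $[S, C)$; forces use the product rule, so
  analytic force equals the numeric gradient within each smooth piece.
* Antiparallel vectors in `rotationBetweenVectors()` use a
  deterministic perpendicular axis (smallest-index basis vector,
  orthogonalised).
* MRC I/O writes mode-2 float32 little-endian with the documented
  header layout; reads validate the magic, mode, axis order and size
  and refuse truncated files.

## Problem sizes

The suite and the acceptance script run desk-scale replicas: five
structures (16 balls) for packing, 9/25-ball deformables, 61-cube and
64-cube volumes, 200000 Monte-Carlo points for the union volume, and
1000 random rigid motions for pose recovery. The 400-particle, 20-type
replication in a 1200-unit box is supported by the same code paths
(`defaultConfig()` plus deposited structure files) but is a
multi-hour, download-dependent run and is not part of the test suite.

## Known limitations

* No thermostats, Brownian noise, periodic boundaries, or solvent; the
  dynamics is a deterministic quasi-static packing scheme, not
  physical MD.
* Deformable membranes lack bending stiffness (by construction,
  $k_\theta = 0$), with the crumpling consequence described above.
* Rendering ignores atomic detail below the ball scale; an all-atom
  rendering option for rigid types would sharpen the maps but is not
  required by the pipeline contract.
* SNR is a variance-ratio definition; other conventions (power ratio in
  Fourier bands, contrast-based) would shift the nominal SNR labels.
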