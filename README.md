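# tomopack

Simulation of crowded cryo-electron tomograms with ground-truth
annotation, for benchmarking tomogram analysis methods (particle
picking, segmentation) that cannot be evaluated on real data for lack
of labels.

`tomopack` is aimed at computational structural biologists who need
labelled 3D density volumes. It packs **rigid macromolecules** and
**deformable ultrastructures** (filaments, membranes) in one unified
bead-model formalism:

* A macromolecule of *n* atoms is coarse-grained by k-means into
  *k* = max(3, ⌈*n*/5000⌉) balls — each ball at a cluster centroid,
  radius equal to the farthest member atom, mass 5000 — and made rigid
  by fully connecting the balls with stiff harmonic bonds
  (*U* = *k*<sub>b</sub>(*r* − *r*<sub>0</sub>)², *k*<sub>b</sub> = 2000).
* Filaments are bead chains, membranes are 8-connected bead meshes;
  their bonds are equally stiff (inextensible) but their angle terms
  have zero stiffness (*U* = *k*<sub>θ</sub>(θ − θ<sub>0</sub>)²,
  *k*<sub>θ</sub> = 0), so they bend freely.
* Structures are packed toward the scene center by a centripetal field
  (magnitude 10·‖x‖ inside radius 300, saturating at 3000), with a
  switched Lennard-Jones term
  (*R*<sub>min</sub> = *r*<sub>i</sub> + *r*<sub>j</sub>, taper between
  *S* = 600 and *C* = 610) preventing overlap. The integrator is the
  first-order update Δx = (*F*/*m*)·δt², evaluated on fractional
  substeps for numerical stability.
* Packed scenes are rendered at 4 nm resolution on 1 nm voxels (Gaussian
  kernels conserving each ball's mass), Gaussian noise is added at a
  requested SNR (variance ratio), and a per-structure ground-truth table
  is emitted: centroid, displacement, ZYZ Euler angles
  (R = R<sub>z</sub>(α)R<sub>y</sub>(β)R<sub>z</sub>(γ), recovered from
  two internal vectors), and bounding radius. Deformable structures are
  rendered in their final shape with zero rotation.
* A reference-free **Difference-of-Gaussian picker**
  (σ₂ = 1.1 σ₁, threshold *T* = *m* + *t*(*M* − *m*)/20, *t* = 5) and
  its precision/recall/F-score evaluation against the ground truth close
  the loop.

All lengths are in internal units (1 unit = 1 Å). Everything runs
self-contained: synthetic atom-cloud generators stand in for deposited
structures, and real PDB files can be substituted via `readPdbAtoms()`.

## Worked example

Pack five synthetic macromolecules into a 500-unit box, render a
tomogram at SNR 200, and score DoG picking against the emitted truth:

```r
library(tomopack)

cloud <- synthAtomCloud("dumbbell", 12000, extent = 150, seed = 7)
st <- coarseGrain(cloud, seed = 7)
st
#> BallStructure 'synthetic-dumbbell' (rigid): 3 balls, 3 bonds, 0 angles
#>   radii 77.1-81.7, total mass 15000

lib <- fixtureStructureLibrary(5, seed = 1)
scene <- placeStructures(lib, counts = 1, box = 500, seed = 1)
traj <- runPacking(scene, maxSteps = 2000, snapshotEvery = 500)
packed <- setPositions(scene, finalFrame(traj))

gt <- groundTruth(packed)
round(gt[, c("x", "y", "z", "alphaDeg", "betaDeg", "gammaDeg", "radius")], 1)
#>       x     y     z alphaDeg betaDeg gammaDeg radius
#> 1  30.4  31.9  38.1    119.9    52.7   -108.3   95.7
#> 2  45.4 -39.0 -22.2    152.0    85.3   -141.3  117.6
#> 3  16.4  26.3 -22.4   -151.5    36.0     74.0   74.3
#> 4 -18.0 -45.6  55.0    160.2    39.8    129.9  135.7
#> 5 -54.1  22.3 -38.6    142.7    14.0    178.3  136.9

tomo <- addNoise(composeSceneMap(packed), snr = 200, seed = 1)
tomo
#> DensityVolume 63x63x63, voxel 10, origin (-310.959, -310.959, -310.959)

picks <- pickParticles(tomo, sigma1 = 4, topK = nrow(gt))
evaluatePicking(picks, gt)
#> PickScore: TP 2 FP 0 FN 3 | precision 1.0000 recall 0.4000 F 0.5714
```

The five structures squeeze from dispersed starting poses into a tight
cluster around the origin (the truth centroids above all lie within
~70 units of it), each annotated with the ZYZ rotation it underwent and
the bounding radius used by the picking evaluation. In the crowded
200-SNR tomogram the picker recovers 2 of the 5 particles at σ₁ = 4 —
crowding makes reference-free picking hard, which is exactly what this
kind of simulation is meant to expose.

The same pipeline, end to end with artifact files (MRC volumes,
CSV/JSON truth, multi-model PDB trajectory, picking report, config
echo, log):

```r
res <- runPipeline(defaultConfig("mixed-scene", seed = 1), "run1")
```

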