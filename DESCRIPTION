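Package: tomopack
Title: Crowded Cryo-Electron Tomogram Simulation with Multi-Ball Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A unified simulator for crowded cryo-electron tomograms.
    Rigid macromolecules are coarse-grained into multi-ball models by
    k-means clustering of their atomic coordinates; deformable filaments
    and membranes are built as bead chains and bead meshes with stiff
    bonds and free angles. Structures are packed toward the scene centre
    under a bespoke force field (harmonic bonds, angle terms, switched
    Lennard-Jones, centripetal external field) with a first-order
    integrator. Packed scenes are rendered into density volumes at a
    stated resolution and voxel size, Gaussian noise is added at a
    requested signal-to-noise ratio, and per-structure ground truth
    (centroid, displacement, ZYZ Euler orientation, bounding radius) is
    emitted. A reference-free Difference-of-Gaussian particle picker and
    its precision/recall/F-score evaluation against the ground truth are
    included, along with MRC volume I/O and synthetic-structure
    generators so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'structures.R'
    'dynamics.R'
    'pose.R'
    'volume.R'
    'fixtures.R'
    'io.R'
    'picking.R'
    'pipeline.R'
    'tomopack-package.R'
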