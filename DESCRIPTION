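Package: ctsurf
Title: Contour-Based 3D Surface Reconstruction of CT Volumes with
    Priority-Driven Mesh Simplification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs closed triangle surfaces from computed-tomography
    (CT) style labeled volumes or per-slice contour polygons of hollow
    organs such as the bladder. Voxels are classified into a tri-state
    field (outside / on / inside the slice contours), a modified
    marching-cubes pass places surface vertices at cell-edge midpoints
    (snapping to grid points labeled "on"), vertex normals are estimated
    by central differences, and the mesh is simplified by greedy edge
    collapse ranked by a weighted priority of flatness, triangle shape
    quality and edge length. Includes synthetic bladder-wall phantoms
    with ground truth, mesh I/O (STL/PLY/OBJ), mesh diagnostics, and
    confusion-matrix / ROC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'constructors.R'
    'casetable.R'
    'ctsurf-package.R'
    'diagnostics.R'
    'field.R'
    'io.R'
    'meshkit.R'
    'phantom.R'
    'simplify.R'
    'surface.R'
    'pipeline.R'
    'zzz.R'
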