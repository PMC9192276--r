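#' @include AllClasses.R
NULL

#' Voxel spacing of a gridded object
#' @param x A [VoxelGrid-class] or [TriStateField-class].
#' @return Numeric length-3 spacing in mm.
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' World origin of a gridded object
#' @param x A [VoxelGrid-class] or [TriStateField-class].
#' @return Numeric length-3 world coordinate (mm) of voxel `(1, 1, 1)`.
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' Grid dimensions of a gridded object
#' @param x A [VoxelGrid-class] or [TriStateField-class].
#' @return Integer length-3 number of voxels along each axis.
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' Sample values of a VoxelGrid
#' @param x A [VoxelGrid-class].
#' @return The 3D numeric array of samples.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Tri-state labels of a field
#' @param x A [TriStateField-class].
#' @return The 3D integer array with values in \{-1, 0, 1\}.
#' @export
setGeneric("fieldLabels", function(x) standardGeneric("fieldLabels"))

#' Vertex coordinates of a mesh
#' @param x A [TriMesh-class].
#' @return n x 3 numeric matrix of vertex positions (mm).
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' Face index triples of a mesh
#' @param x A [TriMesh-class].
#' @return m x 3 integer matrix of 1-based vertex indices.
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' Per-vertex unit normals of a mesh
#' @param x A [TriMesh-class].
#' @return n x 3 matrix of unit normals, or a 0 x 3 matrix when unset.
#' @export
setGeneric("meshNormals", function(x) standardGeneric("meshNormals"))
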