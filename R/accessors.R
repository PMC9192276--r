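#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn gridSpacing spacing of a scalar volume
#' @export
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)

#' @describeIn gridSpacing spacing of a tri-state field
#' @export
setMethod("gridSpacing", "TriStateField", function(x) x@spacing)

#' @describeIn gridOrigin origin of a scalar volume
#' @export
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)

#' @describeIn gridOrigin origin of a tri-state field
#' @export
setMethod("gridOrigin", "TriStateField", function(x) x@origin)

#' @describeIn gridDims dimensions of a scalar volume
#' @export
setMethod("gridDims", "VoxelGrid", function(x) dim(x@values))

#' @describeIn gridDims dimensions of a tri-state field
#' @export
setMethod("gridDims", "TriStateField", function(x) dim(x@labels))

#' @describeIn gridValues sample array
#' @export
setMethod("gridValues", "VoxelGrid", function(x) x@values)

#' @describeIn fieldLabels label array
#' @export
setMethod("fieldLabels", "TriStateField", function(x) x@labels)

#' @describeIn meshVertices vertex matrix
#' @export
setMethod("meshVertices", "TriMesh", function(x) x@vertices)

#' @describeIn meshFaces face matrix
#' @export
setMethod("meshFaces", "TriMesh", function(x) x@faces)

#' @describeIn meshNormals normal matrix
#' @export
setMethod("meshNormals", "TriMesh", function(x) x@normals)

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat("VoxelGrid:", paste(d, collapse = " x "), "voxels\n")
  cat("  spacing (mm):", paste(format(object@spacing), collapse = ", "), "\n")
  cat("  origin (mm): ", paste(format(object@origin), collapse = ", "), "\n")
  cat("  value range: ", paste(format(range(object@values)), collapse = " .. "),
      "\n")
  invisible(NULL)
})

setMethod("show", "TriStateField", function(object) {
  d <- dim(object@labels)
  tab <- tabulate(factor(object@labels, levels = c(-1L, 0L, 1L)), 3L)
  cat("TriStateField:", paste(d, collapse = " x "), "voxels\n")
  cat("  spacing (mm):", paste(format(object@spacing), collapse = ", "), "\n")
  cat(sprintf("  labels: %d outside (-1), %d on (0), %d inside (+1)\n",
              tab[1L], tab[2L], tab[3L]))
  invisible(NULL)
})

setMethod("show", "ContourSet", function(object) {
  np <- sum(vapply(object@slices, function(s) length(s$polygons), integer(1)))
  cat(sprintf("ContourSet: %d polygon(s) on %d slice(s), slice axis %d\n",
              np, length(object@slices), object@sliceAxis))
  invisible(NULL)
})

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (nrow(object@normals) > 0L) ", with vertex normals" else ""))
  invisible(NULL)
})

setMethod("show", "Phantom", function(object) {
  cat("Phantom:", object@description, "\n")
  cat(sprintf("  volume: %.4g mm^3%s\n", object@analyticVolume,
              if (object@approximate) " (approximate)" else ""))
  cat(sprintf("  area:   %.4g mm^2%s\n", object@analyticArea,
              if (object@approximate) " (approximate)" else ""))
  invisible(NULL)
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (A = TP, B = TN, C = FP, D = FN):\n")
  cat(sprintf("  A = %d, B = %d, C = %d, D = %d\n",
              object@A, object@B, object@C, object@D))
  invisible(NULL)
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d operating points, AUC = %.4f\n",
              length(object@thresholds), object@auc))
  invisible(NULL)
})

setMethod("show", "SimplifyConfig", function(object) {
  tgt <- if (!is.na(object@targetFaces)) {
    sprintf("%d faces", object@targetFaces)
  } else sprintf("%.3g of input faces", object@targetRatio)
  cat(sprintf("SimplifyConfig: Ct = %g, Cx = %g, Cg = %g; target %s\n",
              object@ct, object@cx, object@cg, tgt))
  invisible(NULL)
})

setMethod("show", "EdgeRecord", function(object) {
  cat(sprintf("EdgeRecord (%d, %d): T = %.4g, X = %.4g, G = %.4g, Y = %.4g\n",
              object@edge[1L], object@edge[2L],
              object@T, object@X, object@G, object@Y))
  invisible(NULL)
})
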