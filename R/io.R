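#' @include constructors.R
NULL

#' Write a volume or tri-state field to NIfTI
#'
#' Samples are stored as the image array; spacing and origin are recorded
#' in the sform (scale-plus-translation, sform code 2), which round-trips
#' exactly through [readVolume()].
#'
#' @param x A [VoxelGrid-class] or [TriStateField-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "VoxelGrid")) {
    arr <- x@values
  } else if (is(x, "TriStateField")) {
    arr <- x@labels
  } else stopf("'x' must be a VoxelGrid or TriStateField")
  img <- RNifti::asNifti(arr)
  m <- diag(c(x@spacing, 1))
  m[1:3, 4L] <- x@origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume or tri-state field from NIfTI
#'
#' Spacing and origin are recovered from the sform when set (column norms
#' and translation), falling back to the pixdim with a zero origin.
#'
#' @param path Input `.nii` / `.nii.gz` path.
#' @param as `"grid"` for a [VoxelGrid-class] (default) or `"field"` for
#'   a [TriStateField-class] (values must then be -1, 0 or 1).
#' @return A [VoxelGrid-class] or [TriStateField-class].
#' @export
readVolume <- function(path, as = c("grid", "field")) {
  as <- match.arg(as)
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  img <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(img)
  if (h$sform_code > 0L) {
    m <- rbind(h$srow_x, h$srow_y, h$srow_z)
    spacing <- sqrt(colSums(m[, 1:3]^2))
    origin <- m[, 4L]
  } else {
    spacing <- RNifti::pixdim(img)
    origin <- c(0, 0, 0)
  }
  arr <- array(as.vector(img), dim(img))
  if (as == "grid") voxelGrid(arr, spacing, origin)
  else triStateField(arr, spacing, origin)
}

#' Write a contour set to JSON
#'
#' The file layout is `{"slice_axis": <int>, "slices": [{"index": <int>,
#' "polygons": [[[x, y], ...], ...]}, ...]}`. Axis and slice indices are
#' stored 0-based in the file (language-neutral exchange convention) and
#' converted to R's 1-based indexing by [readContours()].
#'
#' @param contours A [ContourSet-class].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
writeContours <- function(contours, path) {
  if (!is(contours, "ContourSet")) stopf("'contours' must be a ContourSet")
  obj <- list(
    slice_axis = contours@sliceAxis - 1L,
    slices = lapply(contours@slices, function(sl) {
      list(index = sl$index - 1L,
           polygons = lapply(sl$polygons, function(p) {
             lapply(seq_len(nrow(p)), function(i) c(p[i, 1L], p[i, 2L]))
           }))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour set from JSON
#'
#' @param path Input `.json` path in the layout written by
#'   [writeContours()].
#' @return A [ContourSet-class].
#' @export
readContours <- function(path) {
  if (!file.exists(path)) stopf("contour file not found: %s", path)
  obj <- jsonlite::read_json(path)
  if (is.null(obj$slice_axis) || is.null(obj$slices))
    stopf("contour JSON parse error: missing 'slice_axis' or 'slices'")
  slices <- lapply(obj$slices, function(sl) {
    polys <- lapply(sl$polygons, function(p) {
      m <- matrix(unlist(p), ncol = 2L, byrow = TRUE)
      storage.mode(m) <- "double"
      m
    })
    list(index = as.integer(sl$index) + 1L, polygons = polys)
  })
  contourSet(slices, as.integer(obj$slice_axis) + 1L)
}
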