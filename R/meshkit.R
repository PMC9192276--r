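#' @include constructors.R
NULL

# unique undirected edges of a mesh, with incidence counts
meshEdges <- function(faces) {
  if (nrow(faces) == 0L) {
    return(list(edges = matrix(integer(0), 0L, 2L), count = integer(0)))
  }
  a <- c(faces[, 1L], faces[, 2L], faces[, 3L])
  b <- c(faces[, 2L], faces[, 3L], faces[, 1L])
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  cnt <- table(key)
  edges <- cbind(lo[first], hi[first])
  list(edges = edges, count = as.integer(cnt[key[first]]))
}

#' Diagnostic statistics of a triangle mesh
#'
#' Counts vertices, unique undirected edges and faces; reports the Euler
#' characteristic V - E + F, whether the mesh is watertight (every edge
#' bordered by exactly two faces), the total surface area, and the signed
#' enclosed volume computed as the sum of signed tetrahedra against the
#' origin (1/6 sum of det[v1 v2 v3] per face; positive for outward-wound
#' closed surfaces, meaningful only when watertight).
#'
#' @param mesh A [TriMesh-class].
#' @return A list with entries `nVertices`, `nEdges`, `nFaces`,
#'   `eulerCharacteristic`, `watertight`, `surfaceArea`, `enclosedVolume`.
#' @examples
#' oct <- triMesh(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
#'                      c(0, 0, 1), c(0, 0, -1)) * 0.5,
#'                rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
#'                      c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6)))
#' meshStats(oct)$enclosedVolume   # 1/6
#' @export
meshStats <- function(mesh) {
  if (!is(mesh, "TriMesh")) stopf("'mesh' must be a TriMesh")
  f <- mesh@faces
  v <- mesh@vertices
  if (nrow(f) == 0L) {
    return(list(nVertices = nrow(v), nEdges = 0L, nFaces = 0L,
                eulerCharacteristic = nrow(v), watertight = FALSE,
                surfaceArea = 0, enclosedVolume = 0))
  }
  ed <- meshEdges(f)
  fn <- faceNormalsRaw(mesh)
  area <- sum(sqrt(rowSums(fn^2))) / 2
  v1 <- v[f[, 1L], , drop = FALSE]
  v2 <- v[f[, 2L], , drop = FALSE]
  v3 <- v[f[, 3L], , drop = FALSE]
  vol <- sum(v1[, 1L] * (v2[, 2L] * v3[, 3L] - v2[, 3L] * v3[, 2L]) -
             v1[, 2L] * (v2[, 1L] * v3[, 3L] - v2[, 3L] * v3[, 1L]) +
             v1[, 3L] * (v2[, 1L] * v3[, 2L] - v2[, 2L] * v3[, 1L])) / 6
  list(
    nVertices = nrow(v),
    nEdges = nrow(ed$edges),
    nFaces = nrow(f),
    eulerCharacteristic = nrow(v) - nrow(ed$edges) + nrow(f),
    watertight = all(ed$count == 2L),
    surfaceArea = area,
    enclosedVolume = vol
  )
}

meshFormatFromPath <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("stl", "ply", "obj"))
    stopf("unsupported mesh format '%s' (use .stl, .ply or .obj)", ext)
  ext
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' STL is written binary little-endian (80-byte header, face count, then
#' 50 bytes per triangle: normal, three vertices, attribute word); PLY as
#' ascii with `x y z` vertex properties and `vertex_indices` face lists;
#' OBJ as ascii `v`/`f` lines with 1-based indices. The format is chosen
#' from the file extension unless `format` is given.
#'
#' @param mesh A [TriMesh-class] with outward-oriented faces.
#' @param path Output file path.
#' @param format One of `"stl"`, `"ply"`, `"obj"`; default from extension.
#' @return `path`, invisibly.
#' @seealso [readMesh()]
#' @export
writeMesh <- function(mesh, path, format = NULL) {
  if (!is(mesh, "TriMesh")) stopf("'mesh' must be a TriMesh")
  format <- if (is.null(format)) meshFormatFromPath(path) else
    match.arg(tolower(format), c("stl", "ply", "obj"))
  switch(format,
    stl = writeStlBinary(mesh, path),
    ply = writePlyAscii(mesh, path),
    obj = writeObj(mesh, path)
  )
  invisible(path)
}

writeStlBinary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "ctsurf binary STL"))[1:80]
  writeBin(header, con)
  nf <- nrow(mesh@faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  if (nf == 0L) return(invisible(NULL))
  fn <- faceNormalsRaw(mesh)
  len <- sqrt(rowSums(fn^2))
  fn <- fn / ifelse(len > 0, len, 1)
  v <- mesh@vertices
  f <- mesh@faces
  # 12 floats per triangle: normal, v1, v2, v3
  flo <- t(cbind(fn, v[f[, 1L], , drop = FALSE], v[f[, 2L], , drop = FALSE],
                 v[f[, 3L], , drop = FALSE]))
  fraw <- writeBin(as.numeric(flo), raw(), size = 4L, endian = "little")
  rec <- matrix(as.raw(0L), 50L, nf)
  rec[1:48, ] <- matrix(fraw, 48L, nf)
  writeBin(as.vector(rec), con)
  invisible(NULL)
}

writePlyAscii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment ctsurf",
    sprintf("element vertex %d", nrow(mesh@vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(mesh@faces)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  if (nrow(mesh@vertices) > 0L) {
    writeLines(paste(mesh@vertices[, 1L], mesh@vertices[, 2L],
                     mesh@vertices[, 3L]), con)
  }
  if (nrow(mesh@faces) > 0L) {
    f0 <- mesh@faces - 1L
    writeLines(paste(3L, f0[, 1L], f0[, 2L], f0[, 3L]), con)
  }
  invisible(NULL)
}

writeObj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(mesh@vertices) > 0L) {
    writeLines(paste("v", mesh@vertices[, 1L], mesh@vertices[, 2L],
                     mesh@vertices[, 3L]), con)
  }
  if (nrow(mesh@faces) > 0L) {
    writeLines(paste("f", mesh@faces[, 1L], mesh@faces[, 2L],
                     mesh@faces[, 3L]), con)
  }
  invisible(NULL)
}

#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Binary and ascii STL are supported (vertices repeated per facet are
#' welded back by exact coordinate identity); ascii PLY with triangular
#' faces; OBJ `v`/`f` lines (`f` entries may carry `/vt/vn` suffixes).
#' Malformed content raises a parse error naming the offending line or
#' byte offset.
#'
#' @param path Input file path.
#' @param format One of `"stl"`, `"ply"`, `"obj"`; default from extension.
#' @return A [TriMesh-class].
#' @seealso [writeMesh()]
#' @export
readMesh <- function(path, format = NULL) {
  format <- if (is.null(format)) meshFormatFromPath(path) else
    match.arg(tolower(format), c("stl", "ply", "obj"))
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  switch(format,
    stl = readStl(path),
    ply = readPlyAscii(path),
    obj = readObj(path)
  )
}

readStl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(sz, 80L))
  if (length(head) < 80L) {
    # could still be a tiny ascii file
    txt <- rawToChar(head)
    if (grepl("^\\s*solid", txt)) {
      close(con); on.exit(NULL)
      return(readStlAscii(path))
    }
    stopf("STL parse error at offset 0: file too short (%d bytes)", sz)
  }
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(nf)
  if (is.na(nf) || expected != sz) {
    if (grepl("^\\s*solid", rawToChar(head))) {
      close(con); on.exit(NULL)
      return(readStlAscii(path))
    }
    stopf("STL parse error at offset 80: facet count %s inconsistent with file size %d",
          nf, sz)
  }
  if (nf == 0L) return(triMesh(NULL, NULL))
  rec <- readBin(con, "raw", n = 50L * nf)
  rec <- matrix(rec, 50L, nf)
  flo <- readBin(as.vector(rec[1:48, ]), "numeric", n = 12L * nf, size = 4L,
                 endian = "little")
  flo <- matrix(flo, 12L, nf)
  verts <- matrix(as.vector(flo[4:12, ]), ncol = 3L, byrow = TRUE)
  weldVertices(verts)
}

readStlAscii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) %% 3L != 0L)
    stopf("STL parse error at line %d: vertex count not a multiple of 3",
          if (length(vl)) vl[length(vl)] else 1L)
  if (length(vl) == 0L) return(triMesh(NULL, NULL))
  parts <- strsplit(trimws(lines[vl]), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad)) stopf("STL parse error at line %d: malformed vertex", vl[bad[1L]])
  verts <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3L,
                  byrow = TRUE)
  if (anyNA(verts)) stopf("STL parse error: non-numeric vertex coordinate")
  weldVertices(verts)
}

# triangle soup (3 consecutive rows per face) -> indexed mesh, welding
# exactly equal coordinates
weldVertices <- function(verts) {
  key <- paste(verts[, 1L], verts[, 2L], verts[, 3L])
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  triMesh(verts[uk, , drop = FALSE], matrix(idx, ncol = 3L, byrow = TRUE))
}

readPlyAscii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || lines[1L] != "ply")
    stopf("PLY parse error at line 1: missing 'ply' magic")
  endH <- match("end_header", lines)
  if (is.na(endH)) stopf("PLY parse error: missing 'end_header'")
  header <- lines[seq_len(endH)]
  if (!any(grepl("^format ascii", header)))
    stopf("PLY parse error: only ascii PLY is supported")
  nv <- as.integer(sub("^element vertex (\\d+).*", "\\1",
                       grep("^element vertex", header, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face (\\d+).*", "\\1",
                       grep("^element face", header, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf))
    stopf("PLY parse error: missing vertex/face element declarations")
  body <- lines[-(seq_len(endH))]
  if (length(body) < nv + nf)
    stopf("PLY parse error at line %d: expected %d data lines",
          length(lines), nv + nf)
  verts <- if (nv > 0L) {
    m <- do.call(rbind, strsplit(trimws(body[seq_len(nv)]), "\\s+"))
    v <- matrix(as.numeric(m[, 1:3]), ncol = 3L)
    if (anyNA(v)) stopf("PLY parse error: non-numeric vertex coordinate")
    v
  } else matrix(numeric(0), 0L, 3L)
  faces <- NULL
  if (nf > 0L) {
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    for (i in seq_along(fl)) {
      n <- as.integer(fl[[i]][1L])
      if (is.na(n) || n != 3L)
        stopf("PLY parse error at line %d: only triangular faces are supported",
              endH + nv + i)
    }
    faces <- matrix(as.integer(unlist(lapply(fl, `[`, 2:4))), ncol = 3L,
                    byrow = TRUE) + 1L
  }
  triMesh(verts, faces)
}

readObj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines)
  fl <- grep("^f\\s", lines)
  verts <- if (length(vl)) {
    parts <- strsplit(trimws(lines[vl]), "\\s+")
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3L,
                byrow = TRUE)
    if (anyNA(m)) stopf("OBJ parse error at line %d: malformed vertex", vl[1L])
    m
  } else matrix(numeric(0), 0L, 3L)
  faces <- NULL
  if (length(fl)) {
    parts <- strsplit(trimws(lines[fl]), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) != 4L)
    if (length(bad))
      stopf("OBJ parse error at line %d: only triangular faces are supported",
            fl[bad[1L]])
    ids <- lapply(parts, function(p) as.integer(sub("/.*$", "", p[2:4])))
    faces <- matrix(unlist(ids), ncol = 3L, byrow = TRUE)
    if (anyNA(faces))
      stopf("OBJ parse error at line %d: malformed face index", fl[1L])
  }
  triMesh(verts, faces)
}
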