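# STL triangle-mesh input/output.
#
# Specimen scans arrive as STL surface meshes (binary or ASCII), coordinates
# in millimetres. STL stores one vertex triple per facet with no shared
# topology, so duplicate vertices are merged on load (tolerance 1e-6 mm) to
# recover connectivity for watertightness checks and contour chaining.

STL_MERGE_TOL <- 1e-6

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param source_format `"binary-stl"`, `"ascii-stl"` or `"generated"`.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `source_format`.
#' @export
triangle_mesh <- function(vertices, faces, source_format = "generated") {
  vertices <- unname(as.matrix(vertices))
  faces <- unname(as.matrix(faces))
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z)")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) < 4L) stop("mesh must have at least 4 faces")
  if (!all(is.finite(vertices))) stop("all vertex coordinates must be finite")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  structure(
    list(vertices = vertices, faces = faces, source_format = source_format),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "<triangle_mesh> %d vertices, %d faces (%s)\n",
    nrow(x$vertices), nrow(x$faces), x$source_format
  ))
  invisible(x)
}

# Merge vertices that coincide within `tol` by snapping to a tol-sized grid.
merge_vertices <- function(vertices, faces, tol = STL_MERGE_TOL) {
  key <- paste(
    round(vertices[, 1] / tol),
    round(vertices[, 2] / tol),
    round(vertices[, 3] / tol)
  )
  first <- !duplicated(key)
  remap <- match(key, key[first])
  new_vertices <- vertices[first, , drop = FALSE]
  new_faces <- matrix(remap[faces], ncol = 3L)
  degenerate <- new_faces[, 1] == new_faces[, 2] |
    new_faces[, 2] == new_faces[, 3] |
    new_faces[, 1] == new_faces[, 3]
  list(vertices = new_vertices, faces = new_faces[!degenerate, , drop = FALSE])
}

#' Read an STL file
#'
#' Auto-detects the binary and ASCII STL dialects. Binary files are
#' recognised by their 84-byte preamble and declared facet count matching the
#' file size; anything starting with `solid` and containing `facet` parses as
#' ASCII. Duplicate vertices within 1e-6 mm are merged.
#'
#' @param path path to an `.stl` file.
#' @return a [triangle_mesh()].
#' @export
load_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  size <- file.info(path)$size
  if (size == 0) stop("empty mesh: file '", path, "' has no triangles")
  if (size >= 84) {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    invisible(readBin(con, "raw", 80L))
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!is.na(n) && n > 0 && size == 84 + 50 * as.numeric(n)) {
      return(read_stl_binary_facets(con, n, path))
    }
    close(con)
    on.exit()
  }
  head_raw <- readBin(path, "raw", min(size, 512))
  printable <- head_raw >= as.raw(32) & head_raw <= as.raw(126)
  head_txt <- rawToChar(head_raw[printable | head_raw %in% as.raw(c(9, 10, 13))])
  if (grepl("^\\s*solid", head_txt)) {
    return(read_stl_ascii(path))
  }
  # A binary header not matching its declared size is a truncated file.
  if (size >= 84) {
    con2 <- file(path, "rb")
    on.exit(close(con2), add = TRUE)
    invisible(readBin(con2, "raw", 80L))
    n2 <- readBin(con2, "integer", 1L, size = 4L, endian = "little")
    stop(sprintf(
      "STL format error in '%s': binary header declares %d facets (expects %.0f bytes) but file has %.0f bytes; truncation at byte offset %.0f",
      path, n2, 84 + 50 * as.numeric(n2), as.numeric(size), as.numeric(size)
    ))
  }
  stop(sprintf(
    "STL format error in '%s': not ASCII ('solid' keyword missing) and too short for binary (84 bytes needed, %.0f present); failure at byte offset %.0f",
    path, as.numeric(size), as.numeric(size)
  ))
}

read_stl_binary_facets <- function(con, n, path) {
  # each 50-byte record: normal(3 floats) + 3 vertices (9 floats) + uint16
  raw_all <- readBin(con, "raw", 50L * n)
  if (length(raw_all) < 50L * n) {
    stop(sprintf(
      "STL format error in '%s': truncated at byte offset %.0f",
      path, 84 + length(raw_all)
    ))
  }
  idx <- rep(seq(0L, n - 1L) * 50L, each = 48L) + rep(1:48, n)
  floats <- readBin(raw_all[idx], "numeric", n * 12L, size = 4L,
                    endian = "little")
  m <- matrix(floats, ncol = 12L, byrow = TRUE)
  verts <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                 m[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * n), ncol = 3L)))
  verts <- verts[ord, , drop = FALSE]
  faces <- matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE)
  mv <- merge_vertices(verts, faces)
  triangle_mesh(mv$vertices, mv$faces, source_format = "binary-stl")
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L) {
    stop("empty mesh: ASCII STL '", path, "' contains no facets")
  }
  if (length(vlines) %% 3L != 0L) {
    stop(sprintf(
      "STL format error in '%s': %d vertex lines is not a multiple of 3 (truncated facet near line %d)",
      path, length(vlines), utils::tail(grep("^\\s*vertex\\s", lines), 1)
    ))
  }
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(f) {
    as.numeric(f[2:4])
  })
  verts <- do.call(rbind, nums)
  if (anyNA(verts)) stop("STL format error in '", path,
                         "': non-numeric vertex coordinate")
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  mv <- merge_vertices(verts, faces)
  triangle_mesh(mv$vertices, mv$faces, source_format = "ascii-stl")
}

#' Write a mesh as binary STL
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl_binary <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  header <- charToRaw(sprintf("%-80s", "tendonmech binary STL"))[1:80]
  writeBin(header, con)
  n <- nrow(mesh$faces)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  v <- mesh$vertices
  f <- mesh$faces
  for (i in seq_len(n)) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    nrm <- cross3(p2 - p1, p3 - p1)
    len <- sqrt(sum(nrm^2))
    if (len > 0) nrm <- nrm / len
    writeBin(as.numeric(c(nrm, p1, p2, p3)), con, size = 4L,
             endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Write a mesh as ASCII STL
#'
#' @inheritParams write_stl_binary
#' @return `path`, invisibly.
#' @export
write_stl_ascii <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  out <- character(2L + 7L * nrow(f))
  out[1] <- "solid tendonmech"
  k <- 2L
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    nrm <- cross3(p2 - p1, p3 - p1)
    len <- sqrt(sum(nrm^2))
    if (len > 0) nrm <- nrm / len
    out[k] <- sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3])
    out[k + 1L] <- "    outer loop"
    out[k + 2L] <- sprintf("      vertex %.9g %.9g %.9g", p1[1], p1[2], p1[3])
    out[k + 3L] <- sprintf("      vertex %.9g %.9g %.9g", p2[1], p2[2], p2[3])
    out[k + 4L] <- sprintf("      vertex %.9g %.9g %.9g", p3[1], p3[2], p3[3])
    out[k + 5L] <- "    endloop"
    out[k + 6L] <- "  endfacet"
    k <- k + 7L
  }
  out[k] <- "endsolid tendonmech"
  writeLines(out, path)
  invisible(path)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
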