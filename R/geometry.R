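# Cross-sectional-area profiling by plane slicing.
#
# The specimen CSA used as the stress denominator is the average of many
# plane sections through the surface scan: 300 slices spaced 0.1 mm,
# +/-150 on either side of the volume centroid. Each section is obtained by
# intersecting the slicing plane with every triangle, chaining the resulting
# segments into closed contours and summing shoelace areas, so multi-lobed
# sections contribute additively.

#' Volume centroid of a closed triangle mesh
#'
#' Decomposes the enclosed solid into signed tetrahedra against the origin.
#' For meshes that are not watertight (an edge not shared by exactly two
#' faces) the signed-volume centroid is undefined; the area-weighted surface
#' centroid is returned instead with a warning.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric length-3 centroid (mm).
#' @export
volume_centroid <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!is_watertight(mesh)) {
    warning("mesh is not watertight; falling back to area-weighted surface centroid")
    return(surface_centroid(mesh))
  }
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cx <- p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]
  cy <- p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]
  cz <- p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1]
  vol6 <- p1[, 1] * cx + p1[, 2] * cy + p1[, 3] * cz  # 6 * signed volume
  total <- sum(vol6) / 6
  if (abs(total) < 1e-9) {
    stop("degenerate mesh: |signed volume| < 1e-9 mm^3; ",
         "consider the vertex or surface centroid instead")
  }
  centers <- (p1 + p2 + p3) / 4  # tetrahedron centroid with 4th vertex at origin
  colSums(centers * vol6) / 6 / total
}

# Area-weighted centroid of the triangulated surface.
surface_centroid <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  centers <- (p1 + p2 + p3) / 3
  colSums(centers * area) / sum(area)
}

#' Is every mesh edge shared by exactly two faces?
#'
#' @param mesh a [triangle_mesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  key <- paste(pmin(a, b), pmax(a, b))
  all(table(key) == 2L)
}

#' Choose the slicing axis for a specimen mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param mode `"largest-extent"` (coordinate axis of the largest bounding-box
#'   extent; the default matches scans acquired with the specimen mounted
#'   vertically), `"principal"` (dominant second-moment axis of the vertex
#'   cloud, for tilted scans) or `"fixed-z"`.
#' @return unit length-3 vector. Ties break toward +z, then +y, then +x.
#' @export
slicing_axis <- function(mesh, mode = c("largest-extent", "principal", "fixed-z")) {
  mode <- match.arg(mode)
  if (mode == "fixed-z") return(c(0, 0, 1))
  v <- mesh$vertices
  if (mode == "largest-extent") {
    ext <- apply(v, 2, function(x) diff(range(x)))
    # tie-break toward +z then +y then +x: scan in order z, y, x
    pick <- c(3L, 2L, 1L)[which.max(ext[c(3L, 2L, 1L)])]
    axis <- c(0, 0, 0)
    axis[pick] <- 1
    return(axis)
  }
  centered <- sweep(v, 2, colMeans(v))
  ev <- eigen(crossprod(centered), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  # orient deterministically: positive along its largest |component|,
  # preferring z then y then x on ties
  comp <- abs(axis)
  pick <- c(3L, 2L, 1L)[which.max(comp[c(3L, 2L, 1L)])]
  if (axis[pick] < 0) axis <- -axis
  axis / sqrt(sum(axis^2))
}

#' Planar cross-section of a mesh
#'
#' Intersects the plane orthogonal to `axis` at axial coordinate `position`
#' with every triangle, chains the segments into closed contours and sums
#' the absolute shoelace areas. Segment endpoints are shared intersection
#' points on mesh edges, so chaining is exact after vertex merging; chains
#' that do not close are dropped from the area with a warning.
#'
#' @param mesh a [triangle_mesh()].
#' @param axis unit length-3 slicing direction.
#' @param position axial coordinate of the plane (mm), measured as
#'   `vertex . axis`.
#' @return an object of class `cross_section`: list with `axial_position`,
#'   `contours` (list of n-by-2 matrices of in-plane mm coordinates) and
#'   `area` (mm^2). A plane that misses the mesh yields zero contours and
#'   area 0.
#' @export
cross_section <- function(mesh, axis, position) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) stop("axis must be a unit vector")
  basis <- plane_basis(axis)
  d <- as.numeric(mesh$vertices %*% axis) - position
  section_from_distances(mesh, d, basis, position)
}

# Two in-plane unit vectors orthogonal to axis.
plane_basis <- function(axis) {
  ref <- c(1, 0, 0)
  if (abs(axis[1]) > 0.9) ref <- c(0, 1, 0)
  u <- cross3(axis, ref)
  u <- u / sqrt(sum(u^2))
  w <- cross3(axis, u)
  list(u = u, w = w)
}

# Core slicing given precomputed signed vertex distances `d` to the plane.
section_from_distances <- function(mesh, d, basis, position) {
  # snap vertices lying exactly in the plane slightly to one side so every
  # crossing is a clean two-edge crossing
  d[abs(d) < 1e-12] <- 1e-12
  f <- mesh$faces
  d1 <- d[f[, 1]]; d2 <- d[f[, 2]]; d3 <- d[f[, 3]]
  lo <- pmin(d1, d2, d3)
  hi <- pmax(d1, d2, d3)
  hit <- which(lo < 0 & hi > 0)
  if (length(hit) == 0L) {
    return(structure(
      list(axial_position = position, contours = list(), area = 0),
      class = "cross_section"
    ))
  }
  v <- mesh$vertices
  # crossing edges of hit triangles, keyed by sorted vertex pair so both
  # adjacent triangles reference the identical intersection point (exact
  # chaining, no tolerance matching needed after vertex merge)
  fh <- f[hit, , drop = FALSE]
  ea_all <- cbind(fh[, 1], fh[, 2], fh[, 3])
  eb_all <- cbind(fh[, 2], fh[, 3], fh[, 1])
  crossing <- d[ea_all] * d[eb_all] < 0
  dim(crossing) <- dim(ea_all)
  face_of <- row(ea_all)[crossing]
  ia <- pmin(ea_all[crossing], eb_all[crossing])
  ib <- pmax(ea_all[crossing], eb_all[crossing])
  ord <- order(face_of)
  face_of <- face_of[ord]
  ia <- ia[ord]
  ib <- ib[ord]
  # drop faces without exactly two crossing edges (cannot occur after the
  # distance clamp, kept as a guard)
  cnt <- tabulate(face_of, nbins = nrow(fh))
  ok <- cnt[face_of] == 2L
  face_of <- face_of[ok]; ia <- ia[ok]; ib <- ib[ok]
  key <- paste(ia, ib)
  keep <- !duplicated(key)
  key_u <- key[keep]
  ea <- ia[keep]
  eb <- ib[keep]
  t_frac <- d[ea] / (d[ea] - d[eb])
  pts <- v[ea, , drop = FALSE] + t_frac * (v[eb, , drop = FALSE] - v[ea, , drop = FALSE])
  px <- as.numeric(pts %*% basis$u)
  py <- as.numeric(pts %*% basis$w)
  # segments: consecutive pairs (each face contributes its two edges)
  node <- match(key, key_u)
  seg <- cbind(node[c(TRUE, FALSE)], node[c(FALSE, TRUE)])
  contours <- chain_segments(seg, length(key_u))
  closed <- Filter(function(cc) cc$closed, contours)
  if (length(closed) < length(contours)) {
    warning(sprintf("%d open contour chain(s) discarded from section at %.3f mm",
                    length(contours) - length(closed), position))
  }
  polys <- lapply(closed, function(cc) cbind(px[cc$nodes], py[cc$nodes]))
  polys <- Filter(function(p) nrow(p) >= 3L, polys)
  area <- sum(vapply(polys, shoelace_area, numeric(1)))
  structure(
    list(axial_position = position, contours = polys, area = area),
    class = "cross_section"
  )
}

# Chain segments (rows of node-index pairs) into node cycles/paths.
chain_segments <- function(seg, n_nodes) {
  if (is.null(seg) || nrow(seg) == 0L) return(list())
  n_seg <- nrow(seg)
  # up to two incident segments per node (manifold sections)
  s1 <- integer(n_nodes)
  s2 <- integer(n_nodes)
  for (s in seq_len(n_seg)) {
    a <- seg[s, 1]; b <- seg[s, 2]
    if (s1[a] == 0L) s1[a] <- s else s2[a] <- s
    if (s1[b] == 0L) s1[b] <- s else s2[b] <- s
  }
  used <- logical(n_seg)
  out <- list()
  for (s0 in seq_len(n_seg)) {
    if (used[s0]) next
    used[s0] <- TRUE
    start <- seg[s0, 1]
    nodes <- integer(n_seg + 1L)
    nodes[1L] <- start
    nodes[2L] <- seg[s0, 2]
    len <- 2L
    repeat {
      cur <- nodes[len]
      s <- s1[cur]
      if (s == 0L || used[s]) s <- s2[cur]
      if (s == 0L || used[s]) break
      used[s] <- TRUE
      len <- len + 1L
      nodes[len] <- if (seg[s, 1] == cur) seg[s, 2] else seg[s, 1]
    }
    nodes <- nodes[seq_len(len)]
    closed <- nodes[len] == start && len > 3L
    if (closed) nodes <- nodes[-len]
    out[[length(out) + 1L]] <- list(nodes = nodes, closed = closed)
  }
  out
}

#' Shoelace area of a closed planar polygon
#'
#' @param poly n-by-2 matrix of vertices in order.
#' @return absolute enclosed area.
#' @export
shoelace_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Cross-sectional-area profile of a specimen
#'
#' Slices the mesh symmetrically about its volume centroid: positions are
#' `centroid +/- k * spacing` for `k = 1..n_slices/2`, i.e. 300 sections in a
#' 30 mm window with the defaults, the centroid plane itself excluded.
#' Slices where the plane misses the specimen are excluded from the summary
#' statistics (averaging zeros would bias the stress denominator downward);
#' more than half empty raises a short-specimen error.
#'
#' @param mesh a [triangle_mesh()].
#' @param axis unit slicing direction; default [slicing_axis()] in
#'   largest-extent mode.
#' @param n_slices even number of sections (default 300).
#' @param spacing slice spacing in mm (default 0.1).
#' @return object of class `csa_profile`: `slice_positions` (mm, increasing),
#'   `areas` (mm^2, `NA` where the plane missed), `n_requested`, `n_valid`,
#'   `mean`, `median`, `std` (over valid slices only).
#' @export
csa_profile <- function(mesh, axis = NULL, n_slices = 300L, spacing = 0.1) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (n_slices %% 2L != 0L) stop("n_slices must be even")
  if (spacing <= 0) stop("spacing must be positive")
  if (is.null(axis)) axis <- slicing_axis(mesh, "largest-extent")
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) stop("axis must be a unit vector")
  centroid <- volume_centroid(mesh)
  c_ax <- sum(centroid * axis)
  k <- seq_len(n_slices %/% 2L)
  positions <- sort(c(c_ax - k * spacing, c_ax + k * spacing))
  basis <- plane_basis(axis)
  dall <- as.numeric(mesh$vertices %*% axis)
  areas <- vapply(positions, function(p) {
    cs <- section_from_distances(mesh, dall - p, basis, p)
    if (length(cs$contours) == 0L) NA_real_ else cs$area
  }, numeric(1))
  n_valid <- sum(!is.na(areas))
  if (n_valid < 0.5 * n_slices) {
    stop(sprintf(
      "short specimen: only %d of %d slices intersect the mesh (slicing window %.1f mm)",
      n_valid, n_slices, n_slices * spacing
    ))
  }
  valid <- areas[!is.na(areas)]
  structure(
    list(
      slice_positions = positions, areas = areas,
      n_requested = as.integer(n_slices), n_valid = as.integer(n_valid),
      mean = mean(valid), median = stats::median(valid), std = sd_or_na(valid),
      spacing = spacing, axis = axis, centroid = centroid
    ),
    class = "csa_profile"
  )
}

#' @export
print.csa_profile <- function(x, ...) {
  cat(sprintf(
    "<csa_profile> %d/%d valid slices; mean %.3f mm^2, median %.3f mm^2, sd %.3f mm^2\n",
    x$n_valid, x$n_requested, x$mean, x$median, x$std
  ))
  invisible(x)
}

#' Write a CSA profile as CSV plus JSON summary
#'
#' @param profile a [csa_profile()] result.
#' @param prefix output path prefix; writes `<prefix>.csv` (columns
#'   `position_mm`, `area_mm2`) and `<prefix>.json`.
#' @return named character vector of the two paths, invisibly.
#' @export
write_csa_profile <- function(profile, prefix) {
  stopifnot(inherits(profile, "csa_profile"))
  csv_path <- paste0(prefix, ".csv")
  json_path <- paste0(prefix, ".json")
  df <- data.frame(position_mm = profile$slice_positions,
                   area_mm2 = profile$areas)
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(n_requested = profile$n_requested, n_valid = profile$n_valid,
         mean_mm2 = profile$mean, median_mm2 = profile$median,
         std_mm2 = profile$std),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv = csv_path, json = json_path))
}
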