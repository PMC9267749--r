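# Fixture builders and independent oracles used across the test files.
# All meshes are generated in code; nothing binary ships with the package.

# Extrude a CCW 2D polygon along z with end caps; optionally a per-ring
# scale factor (linear taper etc.). Returns a watertight triangle_mesh.
extrude_polygon <- function(poly, z0, z1, n_z = 2L, ring_scale = NULL,
                            center = c(0, 0), cap_apex = NULL) {
  n <- nrow(poly)
  z <- seq(z0, z1, length.out = n_z)
  if (is.null(ring_scale)) ring_scale <- rep(1, n_z)
  rings <- lapply(seq_len(n_z), function(iz) {
    cbind(center[1] + poly[, 1] * ring_scale[iz],
          center[2] + poly[, 2] * ring_scale[iz], z[iz])
  })
  verts <- do.call(rbind, rings)
  # cap apexes at the ring vertex means (valid fan for star-shaped sections)
  apex0 <- if (is.null(cap_apex)) colMeans(rings[[1L]]) else c(cap_apex, z0)
  apex1 <- if (is.null(cap_apex)) colMeans(rings[[n_z]]) else c(cap_apex, z1)
  verts <- rbind(verts, apex0, apex1)
  bot <- nrow(verts) - 1L
  top <- nrow(verts)
  j <- seq_len(n)
  jn <- c(seq_len(n)[-1], 1L)
  faces <- list()
  for (iz in seq_len(n_z - 1L)) {
    o1 <- (iz - 1L) * n
    o2 <- iz * n
    faces[[length(faces) + 1L]] <- cbind(o1 + j, o1 + jn, o2 + j)
    faces[[length(faces) + 1L]] <- cbind(o1 + jn, o2 + jn, o2 + j)
  }
  faces[[length(faces) + 1L]] <- cbind(j, bot, jn)
  o <- (n_z - 1L) * n
  faces[[length(faces) + 1L]] <- cbind(o + j, o + jn, top)
  triangle_mesh(verts, do.call(rbind, faces))
}

circle_poly <- function(radius, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(radius * cos(th), radius * sin(th))
}

rect_poly <- function(w, h) {
  cbind(c(-w / 2, w / 2, w / 2, -w / 2), c(-h / 2, -h / 2, h / 2, h / 2))
}

cylinder_mesh <- function(radius, length_mm, n = 256L, center = c(0, 0),
                          z0 = 0) {
  extrude_polygon(circle_poly(radius, n), z0, z0 + length_mm, center = center)
}

cuboid_mesh <- function(xlim, ylim, zlim) {
  w <- diff(xlim)
  h <- diff(ylim)
  extrude_polygon(rect_poly(w, h), zlim[1], zlim[2],
                  center = c(mean(xlim), mean(ylim)))
}

# Linearly tapered circular frustum, radius r0 at z0 to r1 at z1.
frustum_mesh <- function(r0, r1, z0, z1, n = 128L, n_z = 121L) {
  z <- seq(z0, z1, length.out = n_z)
  scale <- (r0 + (r1 - r0) * (z - z0) / (z1 - z0)) / r0
  extrude_polygon(circle_poly(r0, n), z0, z1, n_z = n_z, ring_scale = scale)
}

# UV-sphere tessellation centred at `center`.
sphere_mesh <- function(radius = 1, center = c(0, 0, 0), n_lat = 32L,
                        n_lon = 48L) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2L)
  lat <- lat[-c(1L, n_lat + 2L)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  verts <- do.call(rbind, lapply(lat, function(la) {
    cbind(radius * cos(la) * cos(lon), radius * cos(la) * sin(lon),
          radius * sin(la))
  }))
  verts <- rbind(verts, c(0, 0, -radius), c(0, 0, radius))
  verts <- sweep(verts, 2, center, "+")
  south <- nrow(verts) - 1L
  north <- nrow(verts)
  j <- seq_len(n_lon)
  jn <- c(j[-1], 1L)
  faces <- list(cbind(j, south, jn))
  for (ir in seq_len(n_lat - 1L)) {
    o1 <- (ir - 1L) * n_lon
    o2 <- ir * n_lon
    faces[[length(faces) + 1L]] <- cbind(o1 + j, o1 + jn, o2 + j)
    faces[[length(faces) + 1L]] <- cbind(o1 + jn, o2 + jn, o2 + j)
  }
  o <- (n_lat - 1L) * n_lon
  faces[[length(faces) + 1L]] <- cbind(o + j, o + jn, north)
  triangle_mesh(verts, do.call(rbind, faces))
}

# L-shaped prism: union of [0,4]x[0,1] and [0,2]x[1,2] extruded over z.
l_prism_mesh <- function(z0 = 0, z1 = 10) {
  poly <- cbind(c(0, 4, 4, 2, 2, 0), c(0, 0, 1, 1, 2, 2))
  extrude_polygon(poly, z0, z1, cap_apex = c(1, 0.5))
}

l_prism_inside <- function(x, y, z) {
  (x >= 0 & x <= 4 & y >= 0 & y <= 1) | (x >= 0 & x <= 2 & y > 1 & y <= 2)
}

# Brute-force voxel-average centroid of an analytic inside() region.
voxel_centroid <- function(inside, xlim, ylim, zlim, h = 0.05) {
  gx <- seq(xlim[1] + h / 2, xlim[2] - h / 2, by = h)
  gy <- seq(ylim[1] + h / 2, ylim[2] - h / 2, by = h)
  gz <- seq(zlim[1] + h / 2, zlim[2] - h / 2, by = h)
  g <- expand.grid(x = gx, y = gy, z = gz)
  keep <- inside(g$x, g$y, g$z)
  c(mean(g$x[keep]), mean(g$y[keep]), mean(g$z[keep]))
}

# Even-odd point-in-polygon test, vectorised over points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Rasterisation area oracle: pixel-count area of a polygon at `h` mm pixels.
raster_area <- function(poly, h = 0.02) {
  xr <- range(poly[, 1]) + c(-h, h)
  yr <- range(poly[, 2]) + c(-h, h)
  gx <- seq(xr[1], xr[2], by = h)
  gy <- seq(yr[1], yr[2], by = h)
  g <- expand.grid(x = gx, y = gy)
  sum(points_in_polygon(g$x, g$y, poly)) * h^2
}

# Random star-convex polygon: r(theta) with low-order Fourier perturbation.
star_polygon <- function(seed, n = 96L, r0 = 1.5) {
  set.seed(seed)
  a <- stats::rnorm(3, 0, 0.08)
  b <- stats::rnorm(3, 0, 0.08)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- r0 * (1 + a[1] * cos(th) + b[1] * sin(th) +
               a[2] * cos(2 * th) + b[2] * sin(2 * th) +
               a[3] * cos(3 * th) + b[3] * sin(3 * th))
  cbind(r * cos(th), r * sin(th))
}

rotation_matrix <- function(axis = c(1, 0, 0), angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(
    x * x * C + c_, x * y * C - z * s_, x * z * C + y * s_,
    y * x * C + z * s_, y * y * C + c_, y * z * C - x * s_,
    z * x * C - y * s_, z * y * C + x * s_, z * z * C + c_
  ), nrow = 3, byrow = TRUE)
}

rotate_mesh <- function(mesh, R) {
  triangle_mesh(mesh$vertices %*% t(R), mesh$faces)
}

# Hand-rolled one-way ANOVA F from sums of squares (independent oracle).
anova_f_bruteforce <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  k <- length(groups)
  N <- length(all_v)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Short protocol for fast unit tests (not the study conditions).
short_protocol <- function() {
  build_protocol(protocol_config(relax_hold = 30, rest_hold = 2))
}

# Merge several closed meshes into one multi-component mesh.
merge_meshes <- function(...) {
  ms <- list(...)
  offs <- cumsum(c(0L, vapply(ms, function(m) nrow(m$vertices), 1L)))
  verts <- do.call(rbind, lapply(ms, `[[`, "vertices"))
  faces <- do.call(rbind, Map(function(m, o) m$faces + o, ms,
                              offs[seq_along(ms)]))
  triangle_mesh(verts, faces)
}
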