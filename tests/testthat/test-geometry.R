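test_that("volume centroid matches symmetry and a voxel oracle", {
  cuboid <- cuboid_mesh(c(0, 2), c(0, 4), c(0, 10))
  expect_equal(volume_centroid(cuboid), c(1, 2, 5), tolerance = 1e-9)

  sph <- sphere_mesh(1, center = c(3, 3, 3))
  expect_equal(volume_centroid(sph), c(3, 3, 3), tolerance = 1e-3)

  lp <- l_prism_mesh(0, 10)
  oracle <- voxel_centroid(l_prism_inside, c(0, 4), c(0, 2), c(0, 10),
                           h = 0.05)
  expect_equal(volume_centroid(lp), oracle, tolerance = 0.05)
})

test_that("non-watertight meshes fall back to the surface centroid", {
  cuboid <- cuboid_mesh(c(0, 2), c(0, 2), c(0, 2))
  open_mesh <- triangle_mesh(cuboid$vertices,
                             cuboid$faces[-1, , drop = FALSE])
  expect_false(is_watertight(open_mesh))
  expect_warning(cen <- volume_centroid(open_mesh), "not watertight")
  expect_length(cen, 3L)
})

test_that("slicing axis selection follows extents, PCA and tie-breaks", {
  long <- cuboid_mesh(c(0, 2), c(0, 4), c(0, 60))
  expect_equal(slicing_axis(long, "largest-extent"), c(0, 0, 1))

  R <- rotation_matrix(c(1, 0, 0), 30 * pi / 180)
  tilted <- rotate_mesh(long, R)
  ax <- slicing_axis(tilted, "principal")
  true_ax <- as.numeric(R %*% c(0, 0, 1))
  angle <- acos(min(1, abs(sum(ax * true_ax)))) * 180 / pi
  expect_lt(angle, 1)

  cube <- cuboid_mesh(c(0, 2), c(0, 2), c(0, 2))
  expect_equal(slicing_axis(cube, "largest-extent"), c(0, 0, 1))
})

test_that("cross-section areas match analytic sections", {
  cyl <- cylinder_mesh(1.5, 60, n = 256L)
  cs <- cross_section(cyl, c(0, 0, 1), 25)
  expect_equal(length(cs$contours), 1L)
  expect_equal(cs$area, pi * 1.5^2, tolerance = 1e-3)

  box <- cuboid_mesh(c(0, 3), c(0, 4), c(0, 50))
  cs2 <- cross_section(box, c(0, 0, 1), 20)
  expect_equal(cs2$area, 12, tolerance = 1e-12)

  # plane misses the mesh: empty section, not an error
  cs3 <- cross_section(box, c(0, 0, 1), 99)
  expect_equal(length(cs3$contours), 0L)
  expect_equal(cs3$area, 0)
})

test_that("disjoint lobes contribute additively", {
  one <- cylinder_mesh(1, 40, n = 128L, center = c(0, 0))
  two <- merge_meshes(cylinder_mesh(1, 40, n = 128L, center = c(-3, 0)),
                      cylinder_mesh(1, 40, n = 128L, center = c(3, 0)))
  a1 <- cross_section(one, c(0, 0, 1), 15)$area
  a2 <- cross_section(two, c(0, 0, 1), 15)$area
  expect_equal(a2, 2 * pi, tolerance = 2e-3 * 2 * pi)
  expect_equal(a2, 2 * a1, tolerance = 1e-9)
})

test_that("csa_profile reproduces the 300-slice averaging procedure", {
  cyl <- cylinder_mesh(1.5, 60, n = 256L)
  prof <- csa_profile(cyl)
  expect_equal(prof$n_requested, 300L)
  expect_equal(prof$n_valid, 300L)
  expect_equal(prof$mean, pi * 1.5^2, tolerance = 1e-3)
  expect_lt(prof$std, 0.005 * prof$mean)
  # positions are centroid +/- k * spacing, k = 1..150
  gaps <- diff(prof$slice_positions)
  expect_equal(sort(unique(round(gaps, 9))), c(0.1, 0.2))
  expect_equal(sum(abs(gaps - 0.1) < 1e-9), 298L)
  cen_ax <- sum(volume_centroid(cyl) * c(0, 0, 1))
  expect_false(any(abs(prof$slice_positions - cen_ax) < 1e-9))
})

test_that("tapered frustum mean matches the closed-form average", {
  fr <- frustum_mesh(1, 2, 0, 60, n = 256L)
  prof <- csa_profile(fr)
  cen_z <- volume_centroid(fr)[3]
  k <- seq_len(150)
  zs <- sort(c(cen_z - k * 0.1, cen_z + k * 0.1))
  r <- 1 + zs / 60
  analytic <- mean(pi * r^2)
  expect_equal(prof$mean, analytic, tolerance = 5e-3 * analytic)
})

test_that("a short specimen raises an error rather than biased statistics", {
  # < half of the 30 mm default window intersects a 12 mm specimen
  short <- cylinder_mesh(1.5, 12, n = 64L)
  expect_error(csa_profile(short), "short specimen")
  # a 20 mm specimen still covers 2/3 of the window: valid, with empty
  # end slices excluded from the statistics
  ok <- csa_profile(cylinder_mesh(1.5, 20, n = 64L))
  expect_lt(ok$n_valid, ok$n_requested)
  expect_gte(ok$n_valid, 150L)
  expect_equal(ok$mean, pi * 1.5^2, tolerance = 2e-3)
})

test_that("slice areas scale as s^2 and survive rigid rotation", {
  base <- frustum_mesh(1, 1.5, 0, 50, n = 96L, n_z = 26L)
  prof <- csa_profile(base, n_slices = 100L)
  for (s in c(2, 0.5)) {
    scaled <- triangle_mesh(base$vertices * s, base$faces)
    prof_s <- csa_profile(scaled, n_slices = 100L, spacing = 0.1 * s)
    expect_equal(prof_s$areas, prof$areas * s^2, tolerance = 1e-6)
  }
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  rot <- rotate_mesh(base, R)
  ax <- as.numeric(R %*% c(0, 0, 1))
  prof_r <- csa_profile(rot, axis = ax, n_slices = 100L)
  expect_equal(prof_r$areas, prof$areas, tolerance = 1e-6)
})

test_that("per-slice areas agree with a rasterization oracle", {
  for (seed in 1:10) {
    poly <- star_polygon(seed)
    mesh <- extrude_polygon(poly, 0, 20)
    for (z in c(5, 10, 15)) {
      a_mesh <- cross_section(mesh, c(0, 0, 1), z)$area
      a_raster <- raster_area(poly, h = 0.02)
      expect_equal(a_mesh, a_raster, tolerance = 5e-3 * a_raster)
    }
  }
})

test_that("csa_profile writes a readable CSV + JSON summary", {
  cyl <- cylinder_mesh(1, 40, n = 64L)
  prof <- csa_profile(cyl, n_slices = 50L)
  prefix <- withr::local_tempfile()
  paths <- write_csa_profile(prof, prefix)
  df <- utils::read.csv(paths["csv"])
  expect_equal(names(df), c("position_mm", "area_mm2"))
  expect_equal(nrow(df), 50L)
  js <- jsonlite::read_json(paths["json"])
  expect_equal(js$n_valid, prof$n_valid)
  expect_equal(js$mean_mm2, prof$mean, tolerance = 1e-12)
})
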