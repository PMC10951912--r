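test_that("digitized ball yields an accurate watertight mesh", {
  sh <- ball5_shape()
  true_v <- 4 / 3 * pi * 5^3
  expect_lt(abs(sh$mesh_volume - true_v) / true_v, 0.05)
  expect_lt(abs(sh$mesh_volume - sh$volume) / sh$volume, 0.05)
  # watertight: every edge shared by exactly two triangles
  e <- rbind(sh$triangles[, 1:2], sh$triangles[, 2:3], sh$triangles[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
  expect_gte(sh$sphericity, 0.95)
  expect_lt(sh$elongation, 1.02)
  # axes orthonormal
  expect_equal(sh$axes %*% t(sh$axes), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("mask_to_mesh rejects empty, multi-component and anisotropic masks", {
  arr <- array(FALSE, c(10, 10, 10))
  expect_error(mask_to_mesh(labeled_volume(arr, 100)), "foreground")
  arr[2, 2, 2] <- TRUE; arr[8, 8, 8] <- TRUE
  expect_error(mask_to_mesh(labeled_volume(arr, 100)), "one connected")
  arr2 <- array(TRUE, c(4, 4, 4))
  expect_error(mask_to_mesh(labeled_volume(arr2, c(100, 100, 200))),
               "isotropic")
})

test_that("principal axes of an axis-aligned ellipsoid are ordered and aligned", {
  sh <- fixture("ell_10_6_4", mask_to_mesh(ellipsoid_volume(c(5, 3, 2), 0.1)))
  expect_gt(abs(sh$axes["major", 1]), 0.99)
  expect_gt(abs(sh$axes["intermediate", 2]), 0.99)
  expect_gt(abs(sh$axes["minor", 3]), 0.99)
})

test_that("axes of a rotated ellipsoid match the generating rotation within 2 degrees", {
  set.seed(5)
  qr_ <- qr(matrix(rnorm(9), 3))
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  sh <- mask_to_mesh(ellipsoid_volume(c(3, 2, 1.2), 0.08, rotation = rot))
  # generating axes are the columns of t(rotation) = rows of rotation
  for (i in 1:3) {
    ali <- abs(sum(sh$axes[i, ] * rot[i, ]))
    expect_gt(ali, cos(2 * pi / 180))
  }
})

test_that("border and center distances obey the sphere identities", {
  sh <- ball5_shape()
  p <- rbind(sh$center, sh$center + c(4.5, 0, 0))
  db <- distance_to_border(sh, p, method = "mesh")
  expect_equal(db[1], 5, tolerance = 0.1)   # one voxel
  expect_equal(db[2], 0.5, tolerance = 0.1)
  expect_equal(distance_to_center(sh, p), c(0, 4.5), tolerance = 1e-12)
  q <- c(1.23, -0.5, 2.2)
  expect_equal(distance_to_center(sh, matrix(sh$center + q, 1)),
               sqrt(sum(q^2)), tolerance = 1e-12)
  pts <- sample_uniform_interior(sh, 300, seed = 3)
  tot <- distance_to_border(sh, pts, method = "edt") +
    distance_to_center(sh, pts)
  expect_lt(max(abs(tot - 5)), 0.1)
})

test_that("mesh and EDT border distances agree within one voxel", {
  sh <- small_ellipsoid_shape()
  pts <- sample_uniform_interior(sh, 20, seed = 11)
  dm <- distance_to_border(sh, pts, method = "mesh")
  de <- distance_to_border(sh, pts, method = "edt")
  expect_lt(max(abs(dm - de)), 0.1)
})

test_that("mesh distances are invariant under rigid transforms", {
  sh <- small_ellipsoid_shape()
  pts <- sample_uniform_interior(sh, 10, seed = 2)
  d0 <- nucleospat:::cpp_mesh_distance(pts, sh$vertices, sh$triangles)
  set.seed(8)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  shift <- c(3, -2, 7)
  vts <- sweep(sh$vertices %*% rot, 2, shift, `+`)
  pts2 <- sweep(pts %*% rot, 2, shift, `+`)
  d1 <- nucleospat:::cpp_mesh_distance(pts2, vts, sh$triangles)
  expect_lt(max(abs(d1 - d0)), 1e-6)
})

test_that("points outside the shape are flagged with a warning", {
  sh <- small_ellipsoid_shape()
  far <- matrix(sh$center + c(10, 0, 0), 1)
  expect_warning(d <- distance_to_border(sh, far, method = "edt"), "outside")
  expect_equal(attr(d, "outside"), 1L)
})

test_that("shape descriptors recover generating geometry", {
  ds <- fixture("desc_ball", shape_descriptors(ball_volume(2.5, 0.05)))
  expect_gte(ds$sphericity, 0.95)
  expect_lt(abs(ds$elongation - 1), 0.03)
  dp <- shape_descriptors(ellipsoid_volume(c(4, 1, 1), 0.08))
  expect_lt(abs(dp$elongation - 4) / 4, 0.1)
  # unsmoothed boundary mesh of a cube is the cube itself: closed form holds
  cube <- array(FALSE, c(30, 30, 30))
  cube[6:25, 6:25, 6:25] <- TRUE  # 1 µm side at 50 nm
  dc <- shape_descriptors(labeled_volume(cube, 50), smoothing_passes = 0)
  expect_equal(dc$volume, 1, tolerance = 1e-9)
  expect_equal(dc$sphericity, pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-9)
  # with default smoothing the corner rounding shifts it only mildly
  dc2 <- shape_descriptors(labeled_volume(cube, 50))
  expect_lt(abs(dc2$sphericity - pi^(1 / 3) * 6^(2 / 3) / 6), 0.1)
})

test_that("uniform interior sampling is reproducible and uniform", {
  sh <- ball5_shape()
  p1 <- sample_uniform_interior(sh, 1, seed = 99)
  p2 <- sample_uniform_interior(sh, 1, seed = 99)
  expect_identical(p1, p2)

  pts <- sample_uniform_interior(sh, 10000, seed = 4)
  expect_true(all(point_in_shape <- nucleospat:::point_in_shape(sh, pts)))
  # shell fraction: P(border distance < 1) = 1 - (4/5)^3
  db <- distance_to_border(sh, pts, method = "edt")
  expect_lt(abs(mean(db < 1) - (1 - (4 / 5)^3)), 0.03)
  # chi-square over octants around the center
  oct <- 1 + (pts[, 1] > sh$center[1]) + 2 * (pts[, 2] > sh$center[2]) +
    4 * (pts[, 3] > sh$center[3])
  expect_gt(stats::chisq.test(tabulate(oct, 8))$p.value, 0.01)

  ell <- small_ellipsoid_shape()
  pe <- sample_uniform_interior(ell, 5000, seed = 6)
  expect_lt(sqrt(sum((colMeans(pe) - ell$center)^2)), 0.1 * 3)
})

test_that("object patterns validate geometry and radii", {
  sh <- small_ellipsoid_shape()
  ctr <- sample_uniform_interior(sh, 5, seed = 1)
  pat <- object_pattern(ctr, sh, volumes = 0.21, stage = "eG1")
  expect_equal(pat$radii, rep((3 * 0.21 / (4 * pi))^(1 / 3), 5))
  expect_true(all(pat$inside))
  out <- rbind(ctr, sh$center + c(9, 9, 9))
  expect_error(object_pattern(out, sh, strict = TRUE), "outside")
  pat2 <- object_pattern(out, sh)
  expect_false(all(pat2$inside))
})

test_that("pattern and mesh round-trip through CSV and PLY", {
  sh <- small_ellipsoid_shape()
  pat <- object_pattern(sample_uniform_interior(sh, 4, seed = 2), sh,
                        volumes = 0.1)
  csv <- tempfile(fileext = ".csv")
  write_pattern_csv(pat, csv)
  df <- read_pattern_csv(csv)
  expect_equal(as.matrix(df[, c("x_um", "y_um", "z_um")]), pat$centers,
               ignore_attr = TRUE, tolerance = 1e-12)
  ply <- tempfile(fileext = ".ply")
  write_mesh_ply(sh, ply)
  head <- readLines(ply, n = 3)
  expect_identical(head[1], "ply")
  expect_match(head[3], sprintf("element vertex %d", nrow(sh$vertices)))
})
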