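test_that("echo suppression keeps true spots, removes ghosts, and is idempotent", {
  # constant image: every voxel equals its neighborhood max
  const <- labeled_volume(array(7, c(20, 20, 30)), 100)
  expect_equal(suppress_echoes(const)$voxels, const$voxels)
  # bright spot with a dimmer axial ghost inside the neighborhood
  img <- array(0, c(21, 21, 31))
  img[11, 11, 12] <- 100
  img[11, 11, 18] <- 40   # ghost 0.6 um above, within the axial half-extent
  vol <- labeled_volume(img, 100)
  out <- suppress_echoes(vol, echo_fraction = 0.5,
                         echo_radius_um = c(0.15, 0.6))
  expect_equal(out$voxels[11, 11, 12], 100)
  expect_equal(out$voxels[11, 11, 18], 0)
  # two equal spots beyond the neighborhood: both kept
  img2 <- array(0, c(21, 21, 41))
  img2[11, 11, 6] <- 80; img2[11, 11, 36] <- 80
  out2 <- suppress_echoes(labeled_volume(img2, 100))
  expect_equal(sum(out2$voxels > 0), 2)
  # idempotence
  noisy <- labeled_volume(array(abs(rnorm(21 * 21 * 31)), c(21, 21, 31)), 100)
  once <- suppress_echoes(noisy)
  expect_equal(suppress_echoes(once)$voxels, once$voxels)
})

test_that("grayscale opening is idempotent", {
  set.seed(2)
  arr <- array(runif(20^3), c(20, 20, 20))
  open_once <- nucleospat:::morph_box(
    nucleospat:::morph_box(arr, c(1, 1, 1), FALSE), c(1, 1, 1), TRUE)
  open_twice <- nucleospat:::morph_box(
    nucleospat:::morph_box(open_once, c(1, 1, 1), FALSE), c(1, 1, 1), TRUE)
  expect_equal(open_twice, open_once)
})

test_that("CV-minimizing threshold separates identical spots and breaks ties low", {
  sh <- fixture("nuc_img", make_nucleus(500, elongation = 1.2,
                                        spacing_nm = 100, seed = 21))
  pat <- sample_pattern(sh, pattern_spec("hardcore", n_objects = 12,
                                         hardcore_distance_um = 2,
                                         seed = 31))
  img <- render_image(sh, pat, image_spec())$spot
  th <- threshold_min_cv(img)
  sizes <- tabulate(th$labels$voxels[th$labels$voxels > 0])
  expect_equal(length(sizes), 12)
  expect_lt(stats::sd(sizes) / mean(sizes), 0.05)
  # two thresholds with identical CV: the lower one is returned
  flat <- array(0, c(30, 30, 30))
  flat[5:8, 5:8, 5:8] <- 1; flat[20:23, 20:23, 20:23] <- 1
  tie <- threshold_min_cv(labeled_volume(flat, 100),
                          threshold_scan = c(0.4, 0.6),
                          min_object_voxels = 2)
  expect_equal(tie$threshold, 0.4)
  # all-background scan fails with the range in the message
  expect_error(threshold_min_cv(labeled_volume(flat, 100),
                                threshold_scan = c(2, 3)), "2.*3")
})

test_that("threshold scan does not merge or split spots of unequal sizes", {
  sh <- fixture("nuc_img", make_nucleus(500, elongation = 1.2,
                                        spacing_nm = 100, seed = 21))
  ctr <- sample_pattern(sh, pattern_spec("hardcore", n_objects = 6,
                                         hardcore_distance_um = 3,
                                         seed = 33))$centers
  d <- dim(sh$mask$voxels)
  img <- array(0, d)
  for (i in 1:6) {
    sigma <- if (i <= 3) 0.1 else 0.22
    blob <- render_image(sh, object_pattern(ctr[i, , drop = FALSE], sh),
                         image_spec(spot_sigma_um = sigma))$spot$voxels
    img <- img + blob
  }
  th <- threshold_min_cv(labeled_volume(img, 100))
  lab <- th$labels$voxels
  expect_equal(max(lab), 6)
  # every true center sits in a distinct label (recall 1, no merging)
  ids <- vapply(1:6, function(i) {
    iv <- round(ctr[i, ] / 0.1 + 0.5)
    lab[iv[1], iv[2], iv[3]]
  }, numeric(1))
  expect_equal(sort(unique(ids)), 1:6)
})

test_that("nucleus segmentation recovers a gapped lamina shell", {
  sh <- fixture("nuc_img", make_nucleus(500, elongation = 1.2,
                                        spacing_nm = 100, seed = 21))
  empty <- object_pattern(matrix(numeric(0), 0, 3), sh)
  clean <- render_image(sh, empty, image_spec())$lamina
  m1 <- segment_nucleus(clean)
  v1 <- sum(m1$voxels) * 0.1^3
  expect_lt(abs(v1 - sh$volume) / sh$volume, 0.1)
  lab <- nucleospat:::cpp_label3d(as.integer(m1$voxels), dim(m1$voxels), 26L)
  expect_equal(max(lab), 1)
  # three 0.4 um gaps are bridged by the 0.5 um directional closing
  gapped <- render_image(sh, empty,
                         image_spec(n_gaps = 3, gap_radius_um = 0.2),
                         seed = 5)$lamina
  m2 <- segment_nucleus(gapped)
  v2 <- sum(m2$voxels) * 0.1^3
  expect_lt(abs(v2 - sh$volume) / sh$volume, 0.1)
  lab2 <- nucleospat:::cpp_label3d(as.integer(m2$voxels), dim(m2$voxels), 26L)
  expect_equal(max(lab2), 1)
  # featureless image: every watershed region touches the border
  expect_error(segment_nucleus(labeled_volume(array(1, c(30, 30, 30)), 100)),
               "border")
})

test_that("geodesic selection keeps straddling objects whole and drops outside ones", {
  d <- c(30, 20, 20)
  mask <- array(FALSE, d); mask[1:15, , ] <- TRUE
  lab <- array(0L, d)
  lab[13:18, 5:8, 5:8] <- 1L    # straddles the mask boundary
  lab[22:25, 5:8, 5:8] <- 2L    # entirely outside
  lab[5:8, 12:15, 12:15] <- 3L  # entirely inside
  sel <- nucleospat:::select_in_mask(lab, mask)
  expect_equal(sum(sel == 1L), 6 * 4 * 4)  # untruncated
  expect_equal(sum(sel == 2L), 0)
  expect_equal(sum(sel == 3L), 4 * 4 * 4)
})

test_that("spot pipeline on a noisy, echoed image recovers the pattern", {
  sh <- fixture("nuc_img", make_nucleus(500, elongation = 1.2,
                                        spacing_nm = 100, seed = 21))
  pat <- sample_pattern(sh, pattern_spec("hardcore", n_objects = 20,
                                         hardcore_distance_um = 1.2,
                                         seed = 41))
  img <- render_image(sh, pat, image_spec(echo_gain = 0.4, noise_sd = 2,
                                          background = 5), seed = 42)$spot
  res <- segment_spots(img, sh)
  got <- res$pattern$centers
  dmat <- outer(rowSums(got^2), rep(1, 20)) +
    outer(rep(1, nrow(got)), rowSums(pat$centers^2)) -
    2 * got %*% t(pat$centers)
  hits <- sqrt(pmax(apply(dmat, 2, min), 0))
  expect_true(all(hits < 0.1))           # every true spot found within 1 voxel
  expect_lte(nrow(got), 20)              # no echo survives as a spurious spot
})

test_that("dual-threshold blob pipeline separates touching blobs", {
  sh <- fixture("nuc_img", make_nucleus(500, elongation = 1.2,
                                        spacing_nm = 100, seed = 21))
  base <- sh$center
  ctr <- rbind(base + c(-0.5, 0, 0), base + c(0.5, 0, 0))
  pat <- object_pattern(ctr, sh)
  img <- render_image(sh, pat, image_spec(spot_sigma_um = 0.25))$spot
  res <- segment_blobs(img, sh)
  expect_equal(max(res$labels$voxels), 2)
  # union of labels equals the low-threshold mask
  sm <- nucleospat:::gauss3d(img, 0.1)
  op <- nucleospat:::morph_box(nucleospat:::morph_box(sm$voxels, c(1, 1, 1),
                                                      FALSE),
                               c(1, 1, 1), TRUE)
  lowmask <- op >= res$low_threshold
  expect_equal(res$labels$voxels > 0, lowmask)
  # a single isolated blob yields one label equal to its low mask
  one <- render_image(sh, object_pattern(matrix(base, 1), sh),
                      image_spec(spot_sigma_um = 0.25))$spot
  r1 <- segment_blobs(one, sh)
  expect_equal(max(r1$labels$voxels), 1)
  # speckle smaller than the opening radius disappears before thresholding
  spk <- one
  idx <- round((base + c(1.5, 1.5, 0)) / 0.1 + 0.5)
  spk$voxels[idx[1], idx[2], idx[3]] <- max(one$voxels) * 2
  r2 <- segment_blobs(spk, sh)
  expect_equal(max(r2$labels$voxels), 1)
})

test_that("object extraction measures centroids, volumes and radii", {
  sh <- small_ellipsoid_shape()
  d <- dim(sh$mask$voxels)
  lab <- array(0L, d)
  lab[21:24, 21:24, 11:14] <- 1L  # 4x4x4 cube
  pat <- extract_objects(labeled_volume(lab, 100), sh)
  expect_equal(pat$centers[1, ], c(22, 22, 12) * 0.1,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(pat$volumes[1], 64 * 0.1^3, tolerance = 1e-12)
  # digitized ball: equivalent radius within 5%
  ctr <- (c(25, 25, 12) - 0.5) * 0.1
  g1 <- ((seq_len(d[1]) - 0.5) * 0.1 - ctr[1])^2
  g2 <- ((seq_len(d[2]) - 0.5) * 0.1 - ctr[2])^2
  g3 <- ((seq_len(d[3]) - 0.5) * 0.1 - ctr[3])^2
  ball <- outer(outer(g1, g2, `+`), g3, `+`) <= 0.5^2
  patb <- extract_objects(labeled_volume(array(as.integer(ball), d), 100), sh)
  expect_lt(abs(patb$radii[1] - 0.5) / 0.5, 0.05)
  # empty label image
  pe <- extract_objects(labeled_volume(array(0L, c(5, 5, 5)), 100), sh)
  expect_equal(n_objects(pe), 0)
})

test_that("median distance to regions matches constructed geometry", {
  d <- c(40, 20, 20)
  region <- array(FALSE, d); region[1:10, , ] <- TRUE
  lab <- array(0L, d)
  lab[5, 10, 10] <- 1L            # inside the region
  lab[13, 10, 10] <- 2L           # 3 voxels from the region edge internally
  labs <- labeled_volume(lab, 100)
  md <- median_distance_to_regions(labs, labeled_volume(region, 100))
  expect_equal(unname(md["1"]), 0)
  expect_lt(abs(md["2"] - 0.3), 0.1 + 1e-9)
  expect_warning(
    md2 <- median_distance_to_regions(labs,
                                      labeled_volume(array(FALSE, d), 100)),
    "empty")
  expect_true(all(is.infinite(md2)))
})

test_that("proximity classification recovers a constructed anaphase-like fraction", {
  # 79% of single-voxel telomeres placed < 0.25 um from regions
  d <- c(60, 40, 40)
  region <- array(FALSE, d); region[1:12, , ] <- TRUE
  lab <- array(0L, d)
  set.seed(10)
  n_near <- 79; n_far <- 21
  yz <- expand.grid(y = 5:35, z = 5:35)
  yz <- yz[sample.int(nrow(yz), n_near + n_far), ]
  # near group: 0.1-0.2 um from the region face; far group: > 1.5 um
  for (i in seq_len(n_near)) lab[11 + (i %% 2), yz$y[i], yz$z[i]] <- i
  for (i in seq_len(n_far)) lab[30 + (i %% 10), yz$y[n_near + i],
                                yz$z[n_near + i]] <- n_near + i
  md <- median_distance_to_regions(labeled_volume(lab, 100),
                                   labeled_volume(region, 100))
  frac <- mean(md < 0.25)
  expect_lte(abs(frac - 0.79), 1 / length(md))
})
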