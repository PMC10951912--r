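test_that("distance functions match brute-force enumeration on hand patterns", {
  sh <- ball5_shape()
  p <- sh$center + rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0))
  pat <- object_pattern(p, sh)
  # H: all pairwise distances, computed by hand
  h <- empirical_distance_function(pat, "H")
  expect_equal(h$distances, sort(c(1, sqrt(5), 2)), tolerance = 1e-12)
  expect_equal(h$n_contributing, 3)
  # G: nearest neighbors
  g <- empirical_distance_function(pat, "G")
  expect_equal(sort(g$distances), sort(c(1, 1, 2)), tolerance = 1e-12)
  # two points are mutual nearest neighbors
  g2 <- empirical_distance_function(object_pattern(p[1:2, ], sh), "G")
  expect_equal(g2$distances, c(1, 1), tolerance = 1e-12)
  # F with the pattern itself as reference: all zero
  f <- empirical_distance_function(pat, "F", f_sample_points = p)
  expect_equal(f$distances, c(0, 0, 0), tolerance = 1e-12)
  # C against hand-computed norms
  ce <- empirical_distance_function(pat, "C")
  expect_equal(sort(ce$distances), sort(c(0, 1, sqrt(5))), tolerance = 1e-12)
  # B against the sphere closed form R - |p - c|, mesh method
  b <- distance_to_border(sh, p, method = "mesh")
  expect_lt(max(abs(sort(b) - sort(5 - c(0, 1, sqrt(5))))), 0.1)
  # CDFs are monotone from 0 to 1
  expect_true(all(diff(h$cdf) >= 0))
  expect_equal(range(h$cdf), c(0, 1))
  # insufficient objects raise typed errors naming the function
  single <- object_pattern(p[1, , drop = FALSE], sh)
  expect_error(empirical_distance_function(single, "G"), "G")
  expect_error(empirical_distance_function(single, "H"), "H")
  expect_error(empirical_distance_function(pat, "F"), "F")
})

test_that("null simulations honor their constraints", {
  sh <- fixture("nuc800", make_nucleus(800, elongation = 1.5,
                                       spacing_nm = 150, seed = 1))
  pat <- sample_pattern(sh, pattern_spec("peripheral", n_objects = 30,
                                         seed = 2))
  # orbital: border distance preserved within tolerance, per object
  orb <- null_model_spec("orbital", band_tolerance_um = 0.05, seed = 3)
  sim <- simulate_null_pattern(pat, orb)
  d0 <- distance_to_border(sh, pat$centers, method = "edt")
  d1 <- distance_to_border(sh, sim$centers, method = "edt")
  expect_lte(max(abs(d1 - d0)), 0.05 + 1e-9)
  # hard-core random: separation and clearance for centromere-sized objects
  r <- (3 * 0.21 / (4 * pi))^(1 / 3)
  patc <- sample_pattern(sh, pattern_spec("hardcore", n_objects = 30,
                                          radius_um = r, seed = 4))
  hcm <- null_model_spec("random", hardcore = TRUE, seed = 5)
  simc <- simulate_null_pattern(patc, hcm)
  dm <- as.matrix(stats::dist(simc$centers)); diag(dm) <- Inf
  expect_gte(min(dm), 2 * r)
  expect_gte(min(distance_to_border(sh, simc$centers, method = "edt")), r)
  # random model in a ball: mean border distance ~ R/4 (uniform law)
  ball <- ball5_shape()
  patb <- object_pattern(sample_uniform_interior(ball, 100, seed = 6), ball)
  rm_ <- null_model_spec("random", seed = 7, n_sims = 200)
  sims <- nucleospat:::with_seed(7, {
    nucleospat:::simulate_null_centers(patb, rm_, 200)
  })
  mb <- mean(vapply(sims, function(ctr)
    mean(distance_to_border(ball, ctr, method = "edt")), numeric(1)))
  expect_lt(abs(mb - 5 / 4), 0.05)
})

test_that("SDI follows the randomized rank convention and is seed-stable", {
  sh <- fixture("nuc800", make_nucleus(800, elongation = 1.5,
                                       spacing_nm = 150, seed = 1))
  m <- null_model_spec("random", n_sims = 99, seed = 8)
  # strongly peripheral: observed B summary below all simulations
  per <- sample_pattern(sh, pattern_spec("peripheral", n_objects = 30,
                                         seed = 9))
  s1 <- compute_sdi(per, "B", m)
  expect_true(all(s1$simulated_summaries > s1$observed_summary))
  expect_gt(s1$sdi, 0); expect_lte(s1$sdi, 1 / 100)
  # strongly internal: observed above all simulations
  int <- sample_pattern(sh, pattern_spec("orbital_band", n_objects = 30,
                                         band_center_um = 2.5,
                                         band_width_um = 1, seed = 10))
  s2 <- compute_sdi(int, "B", m)
  expect_gt(s2$sdi, 99 / 100); expect_lte(s2$sdi, 1)
  # reproducibility under the model seed
  expect_identical(compute_sdi(per, "B", m)$sdi, s1$sdi)
  expect_equal(length(s1$simulated_summaries), 99)
})

test_that("SDIs of model-drawn patterns are uniform (null calibration)", {
  pool <- nucleus_pool(6)
  sdis_r <- numeric(0); sdis_o <- numeric(0)
  for (i in 1:90) {
    sh <- pool[[1 + (i %% length(pool))]]
    pat <- sample_pattern(sh, pattern_spec("csr", n_objects = 30,
                                           seed = 100 + i))
    # csr patterns are draws from the completely random model
    sdis_r[i] <- compute_sdi(pat, "B",
                             null_model_spec("random", seed = 200 + i))$sdi
    # an orbital-model draw, scored against fresh orbital simulations
    obs <- simulate_null_pattern(pat, null_model_spec("orbital",
                                                      seed = 250 + i))
    sdis_o[i] <- compute_sdi(obs, "G",
                             null_model_spec("orbital", seed = 300 + i))$sdi
  }
  expect_true(all(sdis_r >= 0 & sdis_r <= 1))
  expect_gt(population_uniformity_test(sdis_r)$p_value, 0.01)
  expect_gt(population_uniformity_test(sdis_o)$p_value, 0.01)
})

test_that("envelope curves detect clustering and hard-core regularity", {
  sh <- fixture("nuc800", make_nucleus(800, elongation = 1.5,
                                       spacing_nm = 150, seed = 1))
  m <- null_model_spec("random", seed = 12)
  cl <- sample_pattern(sh, pattern_spec("clustered", n_objects = 40,
                                        cluster_count = 5,
                                        cluster_sigma_um = 0.4, seed = 13))
  env_cl <- envelope_curve(cl, "G", m)
  short <- env_cl$r > 0.2 & env_cl$r < 0.8
  expect_gt(max(env_cl$delta[short]), 0)
  hc <- sample_pattern(sh, pattern_spec("hardcore", n_objects = 40,
                                        hardcore_distance_um = 1.5,
                                        seed = 14))
  env_hc <- envelope_curve(hc, "G", m)
  below <- env_hc$r < 1.5 & env_hc$r > 0.3
  expect_true(all(env_hc$delta[below] <= 0))
  # a pattern drawn from the model stays mostly within the envelope
  null_pat <- sample_pattern(sh, pattern_spec("csr", n_objects = 40,
                                              seed = 15))
  env0 <- envelope_curve(null_pat, "G", m)
  inside <- env0$delta >= env0$env_lo & env0$delta <= env0$env_hi
  expect_gte(mean(inside), 0.9)
})

test_that("population uniformity test matches hand-computed KS values", {
  pt <- population_uniformity_test(c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(pt$ks_statistic, 0.1, tolerance = 1e-12)
  expect_false(pt$reject)
  deg <- suppressWarnings(population_uniformity_test(rep(0.01, 54)))
  expect_lt(deg$p_value, 1e-6)
  expect_true(deg$reject)
  expect_error(population_uniformity_test(c(0.1, 0.2)), "at least 5")
  expect_error(population_uniformity_test(c(0.1, 0.5, 0.7, 0.9, 1.2)),
               "\\[0, 1\\]")
})

test_that("uniform SDI cohorts of the study size rarely reject", {
  # 54 nuclei is the largest cohort analyzed per stage
  set.seed(20)
  rej <- vapply(1:60, function(i)
    population_uniformity_test(runif(54))$reject, logical(1))
  expect_lt(mean(rej), 0.15)
})
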