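# Shared fixtures, memoized so expensive digitizations happen once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# digitized ball as a labeled_volume
ball_volume <- function(r_um, s_um = 0.1, pad = 0.5) {
  n <- ceiling(2 * (r_um + pad) / s_um)
  ctr <- n / 2 * s_um
  g <- (seq_len(n) - 0.5) * s_um - ctr
  arr <- outer(outer(g^2, g^2, `+`), g^2, `+`) <= r_um^2
  labeled_volume(arr, s_um * 1000)
}

# digitized axis-aligned ellipsoid (semi-axes in µm)
ellipsoid_volume <- function(semi, s_um = 0.1, rotation = NULL, pad = 0.5) {
  n <- ceiling(2 * (max(semi) + pad) / s_um)
  ctr <- n / 2 * s_um
  g <- (seq_len(n) - 0.5) * s_um - ctr
  if (is.null(rotation)) {
    arr <- outer(outer((g / semi[1])^2, (g / semi[2])^2, `+`),
                 (g / semi[3])^2, `+`) <= 1
  } else {
    pts <- cbind(rep(g, times = n * n), rep(rep(g, each = n), times = n),
                 rep(g, each = n * n))
    q <- pts %*% t(rotation)
    arr <- array((q[, 1] / semi[1])^2 + (q[, 2] / semi[2])^2 +
                 (q[, 3] / semi[3])^2 <= 1, dim = c(n, n, n))
  }
  labeled_volume(arr, s_um * 1000)
}

ball5_shape <- function() fixture("ball5", mask_to_mesh(ball_volume(5, 0.1)))

small_ellipsoid_shape <- function()
  fixture("ell_small", mask_to_mesh(ellipsoid_volume(c(3, 2, 1.4), 0.1)))

# pool of modest synthetic nuclei reused across statistical tests; the SDI
# calibration does not depend on nuclei being distinct across cohorts
nucleus_pool <- function(k = 8, volume = 800, spacing_nm = 150) {
  fixture(sprintf("pool_%d_%d_%d", k, volume, spacing_nm), {
    lapply(seq_len(k), function(i)
      make_nucleus(volume, elongation = 1.2 + 0.1 * (i %% 4),
                   spacing_nm = spacing_nm, seed = 9000 + i))
  })
}

# count isolated strict local maxima above a threshold (26-neighborhood)
count_local_maxima <- function(vol, threshold) {
  v <- vol$voxels
  mx <- nucleospat:::morph_box(v, c(1, 1, 1), TRUE)
  peaks <- v >= mx & v > threshold
  lab <- nucleospat:::cpp_label3d(as.integer(peaks), dim(v), 26L)
  max(lab)
}

# positions of local maxima (voxel centers, µm)
local_maxima_positions <- function(vol, threshold) {
  v <- vol$voxels
  s <- vol$spacing[1] / 1000
  mx <- nucleospat:::morph_box(v, c(1, 1, 1), TRUE)
  idx <- which(v >= mx & v > threshold)
  (arrayInd(idx, dim(v)) - 0.5) * s
}
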