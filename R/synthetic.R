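# Synthetic nuclei, object patterns, image volumes and qPCR tables with known
# ground truth. Defaults emulate HeLa interphase nuclei: volumes 800-1300 um^3,
# 65-142 point-like telomeres or 67-84 sized (~0.21-0.27 um^3) centromeres.

#' Generate a synthetic nucleus
#'
#' Digitizes an (optionally radially perturbed) ellipsoid at isotropic
#' spacing. Semi-axes are set from the requested volume and elongation
#' (major:minor ratio, with the intermediate axis the geometric mean), then
#' rescaled once after digitization so the measured voxel volume is within 3%
#' of the request.
#'
#' @param volume_um3 Target volume in µm³ (HeLa: ~800 in G1/S, ~1300 in G2).
#' @param elongation Major/minor semi-axis ratio (>= 1).
#' @param spacing_nm Isotropic voxel size in nm, in `[50, 200]`.
#' @param perturbation Relative amplitude of a smooth random radial
#'   perturbation (0 = exact ellipsoid; values up to ~0.25 keep the mask
#'   star-shaped).
#' @param rotation Optional 3 x 3 rotation matrix applied to the ellipsoid
#'   axes before digitization.
#' @param pad_um Clear margin between the nuclear surface and the volume
#'   faces (µm); rendered lamina shells must decay before the field of view
#'   ends, as in real acquisitions.
#' @param seed Integer seed (the generator is a pure function of arguments
#'   and seed).
#' @param smoothing_passes Passed to [mask_to_mesh()].
#' @return A [mask_to_mesh()] `nuclear_shape`; attributes `true_semiaxes` and
#'   `true_axes` record the generating geometry.
#' @export
make_nucleus <- function(volume_um3, elongation = 1.5, spacing_nm = 100,
                         perturbation = 0, rotation = NULL, seed = NULL,
                         smoothing_passes = 2, pad_um = 1) {
  stopifnot(volume_um3 > 0, elongation >= 1,
            spacing_nm >= 50, spacing_nm <= 200)
  s <- spacing_nm / 1000
  e <- elongation
  with_seed(seed, {
    m <- (3 * volume_um3 / (4 * pi * e^1.5))^(1 / 3)
    semi <- c(e * m, sqrt(e) * m, m)
    if (is.null(rotation)) rotation <- diag(3)
    # smooth radial perturbation: a few random cosine lobes
    nlobe <- 4L
    w <- matrix(rnorm(3 * nlobe), nlobe, 3)
    w <- w / sqrt(rowSums(w^2))
    ph <- runif(nlobe, 0, 2 * pi)
    amp <- if (perturbation > 0) perturbation / nlobe else 0

    identity_rot <- all(abs(rotation - diag(3)) < 1e-12)
    digitize <- function(semi) {
      ext <- 2 * (max(semi) * (1 + perturbation) + pad_um + 2 * s)
      nv <- ceiling(ext / s)
      ctr <- nv / 2 * s
      g <- (seq_len(nv) - 0.5) * s - ctr
      if (identity_rot && amp == 0) {
        # separable quadratic form: no per-voxel coordinate matrix needed
        rho2 <- outer(outer((g / semi[1])^2, (g / semi[2])^2, `+`),
                      (g / semi[3])^2, `+`)
        return(array(rho2 <= 1, dim = c(nv, nv, nv)))
      }
      pts <- cbind(rep(g, times = nv * nv),
                   rep(rep(g, each = nv), times = nv),
                   rep(g, each = nv * nv))
      q <- pts %*% t(rotation)            # body frame
      rho2 <- (q[, 1] / semi[1])^2 + (q[, 2] / semi[2])^2 +
              (q[, 3] / semi[3])^2
      if (amp > 0) {
        r <- sqrt(rowSums(q^2))
        u <- q / pmax(r, 1e-12)
        f <- 1
        for (l in seq_len(nlobe))
          f <- f + amp * cos(3 * (u %*% w[l, ]) * pi + ph[l])
        if (any(f <= 0.2))
          stop("perturbation produces a non-star-shaped mask")
        rho2 <- rho2 / as.vector(f)^2
      }
      array(rho2 <= 1, dim = c(nv, nv, nv))
    }
    fg <- digitize(semi)
    vmeas <- sum(fg) * s^3
    if (abs(vmeas - volume_um3) / volume_um3 > 0.005) {
      semi <- semi * (volume_um3 / vmeas)^(1 / 3)
      fg <- digitize(semi)
      vmeas <- sum(fg) * s^3
    }
    if (abs(vmeas - volume_um3) / volume_um3 > 0.03)
      stop("digitized volume deviates more than 3% from request")
    sh <- mask_to_mesh(labeled_volume(fg, spacing_nm, "synthetic nucleus"),
                       smoothing_passes = smoothing_passes)
    attr(sh, "true_semiaxes") <- semi
    attr(sh, "true_axes") <- t(rotation)
    sh
  })
}

#' Specification of a synthetic object pattern
#'
#' @param model One of `"csr"` (uniform independent), `"hardcore"` (uniform
#'   with minimum center separation and envelope clearance), `"clustered"`
#'   (Gaussian offspring around uniform parents), `"orbital_band"` /
#'   `"peripheral"` (uniform conditioned on border distance in a band),
#'   `"polarized"` (a set fraction of objects on one half-axis).
#' @param n_objects Number of objects.
#' @param radius_um Per-object or scalar equivalent-sphere radius (0 = points).
#' @param hardcore_distance_um Minimal center separation for `"hardcore"`;
#'   default twice the radius (contact distance).
#' @param cluster_count,cluster_sigma_um Clustered-model parameters.
#' @param band_center_um,band_width_um Border-distance band for
#'   `"orbital_band"`; `"peripheral"` uses the band `[0, band_width_um]`.
#' @param polarity_axis,polarity_fraction Polarized-model parameters; axis is
#'   `"major"`, `"intermediate"` or `"minor"`; fraction in `[0.5, 1]`.
#' @param seed Integer seed.
#' @return A `pattern_spec` list.
#' @export
pattern_spec <- function(model = c("csr", "hardcore", "clustered",
                                   "orbital_band", "peripheral", "polarized"),
                         n_objects = 100, radius_um = 0,
                         hardcore_distance_um = NULL,
                         cluster_count = 8, cluster_sigma_um = 0.5,
                         band_center_um = 0.25, band_width_um = 0.5,
                         polarity_axis = "minor", polarity_fraction = 1,
                         seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_objects >= 0, all(radius_um >= 0),
            cluster_sigma_um >= 0, band_width_um >= 0,
            polarity_fraction >= 0.5, polarity_fraction <= 1)
  structure(list(model = model, n_objects = n_objects, radius_um = radius_um,
                 hardcore_distance_um = hardcore_distance_um,
                 cluster_count = cluster_count,
                 cluster_sigma_um = cluster_sigma_um,
                 band_center_um = band_center_um,
                 band_width_um = band_width_um,
                 polarity_axis = polarity_axis,
                 polarity_fraction = polarity_fraction, seed = seed),
            class = "pattern_spec")
}

#' Sample a synthetic object pattern inside a nucleus
#'
#' @param shape A [mask_to_mesh()] shape.
#' @param spec A [pattern_spec()].
#' @param stage Stage label attached to the pattern.
#' @return An [object_pattern()].
#' @export
sample_pattern <- function(shape, spec, stage = "other") {
  stopifnot(is_nuclear_shape(shape), inherits(spec, "pattern_spec"))
  n <- spec$n_objects
  radii <- rep_len(spec$radius_um, max(n, 1L))
  with_seed(spec$seed, {
    centers <- switch(spec$model,
      csr = sample_uniform_interior(shape, n),
      hardcore = sample_hardcore(shape, n, radii, spec$hardcore_distance_um),
      clustered = sample_clustered(shape, n, spec$cluster_count,
                                   spec$cluster_sigma_um),
      orbital_band = sample_band(shape, n,
                                 spec$band_center_um - spec$band_width_um / 2,
                                 spec$band_center_um + spec$band_width_um / 2),
      peripheral = sample_band(shape, n, 0, spec$band_width_um),
      polarized = sample_polarized(shape, n, spec$polarity_axis,
                                   spec$polarity_fraction)
    )
    object_pattern(centers, shape, volumes = 4 / 3 * pi * radii[seq_len(n)]^3,
                   stage = stage, strict = TRUE)
  })
}

# sequential rejection (dart throwing); border clearance >= r_i and pairwise
# center separation >= max(hc, r_i + r_j)
sample_hardcore <- function(shape, n, radii, hc = NULL) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  pk <- sum(4 / 3 * pi * radii[seq_len(n)]^3) / shape$volume
  if (pk >= 0.3)
    stop("hard-core packing fraction >= 0.3; spec infeasible")
  out <- matrix(NA_real_, n, 3)
  max_attempts <- 10000L * n
  attempts <- 0L
  got <- 0L
  while (got < n) {
    if (attempts >= max_attempts)
      stop("hard-core rejection sampling failed: center-separation/",
           "envelope constraints unsatisfiable at this density")
    cand <- sample_uniform_interior(shape, 1L)
    attempts <- attempts + 1L
    r <- radii[got + 1L]
    if (r > 0 &&
        distance_to_border(shape, cand, method = "edt") < r) next
    if (got > 0) {
      dd <- sqrt(colSums((t(out[seq_len(got), , drop = FALSE]) -
                          as.vector(cand))^2))
      minsep <- pmax(if (is.null(hc)) 0 else hc,
                     radii[seq_len(got)] + r)
      if (any(dd < minsep)) next
    }
    got <- got + 1L
    out[got, ] <- cand
  }
  out
}

sample_clustered <- function(shape, n, k, sigma) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  parents <- sample_uniform_interior(shape, k)
  assign <- sample.int(k, n, replace = TRUE)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    repeat {
      p <- parents[assign[i], ] + rnorm(3, 0, sigma)
      if (point_in_shape(shape, p)) { out[i, ] <- p; break }
    }
  }
  out
}

sample_band <- function(shape, n, lo, hi) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  out <- matrix(NA_real_, n, 3)
  got <- 0L; tried <- 0L
  while (got < n) {
    m <- max(4L * (n - got), 128L)
    cand <- sample_uniform_interior(shape, m)
    d <- distance_to_border(shape, cand, method = "edt")
    keep <- which(d >= lo & d <= hi)
    tried <- tried + m
    if (length(keep)) {
      take <- keep[seq_len(min(length(keep), n - got))]
      out[(got + 1):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
    if (tried > 1e6 && got == 0L)
      stop("band sampling failed: no interior position with border ",
           "distance in [", lo, ", ", hi, "] um")
  }
  out
}

sample_polarized <- function(shape, n, axis, fraction) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  ax <- shape$axes[match.arg(axis, rownames(shape$axes)), ]
  n_pos <- round(fraction * n)
  pos <- matrix(NA_real_, 0, 3); neg <- matrix(NA_real_, 0, 3)
  tried <- 0L
  while (nrow(pos) < n_pos || nrow(neg) < n - n_pos) {
    cand <- sample_uniform_interior(shape, max(2L * n, 64L))
    proj <- sweep(cand, 2, shape$center) %*% ax
    pos <- rbind(pos, cand[proj >= 0, , drop = FALSE])
    neg <- rbind(neg, cand[proj < 0, , drop = FALSE])
    tried <- tried + 1L
    if (tried > 1000L) stop("polarized sampling failed")
  }
  rbind(pos[seq_len(n_pos), , drop = FALSE],
        neg[seq_len(n - n_pos), , drop = FALSE])
}

#' Specification of a synthetic two-channel image
#'
#' Forward model for the spot channel: isotropic 3D Gaussians at the object
#' centers, plus one axially displaced "echo" ghost per spot (amplitude
#' `echo_gain` times the spot amplitude, mimicking reconstruction echoes in
#' structured-illumination volumes), plus Gaussian read noise and a constant
#' background. The lamina channel is a Gaussian shell on the nuclear surface
#' with optional random gaps.
#'
#' @param spot_amplitude Peak spot intensity.
#' @param spot_sigma_um Spot Gaussian sigma (µm).
#' @param lamina_shell_sigma_um Shell thickness sigma (µm).
#' @param echo_offset_um Axial (+z) displacement of the ghost copies.
#' @param echo_gain Ghost amplitude as a fraction of the spot amplitude, in
#'   `[0, 1)`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param background Constant background level.
#' @param n_gaps,gap_radius_um Number and radius of random holes punched in
#'   the lamina shell.
#' @return An `image_spec` list.
#' @export
image_spec <- function(spot_amplitude = 100, spot_sigma_um = 0.12,
                       lamina_shell_sigma_um = 0.15, echo_offset_um = 0.6,
                       echo_gain = 0, noise_sd = 0, background = 0,
                       n_gaps = 0, gap_radius_um = 0.3) {
  stopifnot(echo_gain >= 0, echo_gain < 1, spot_sigma_um > 0,
            lamina_shell_sigma_um > 0)
  structure(as.list(environment()), class = "image_spec")
}

#' Render a synthetic two-channel volume from a shape and pattern
#'
#' @param shape A [mask_to_mesh()] shape.
#' @param pattern An [object_pattern()] bound to `shape`.
#' @param spec An [image_spec()].
#' @param seed Integer seed for noise and gap placement.
#' @return List with `spot` and `lamina` ([labeled_volume()]s) and
#'   `ground_truth` (centers, labels, and a `close_pairs` warning record for
#'   spot pairs closer than one voxel).
#' @export
render_image <- function(shape, pattern, spec = image_spec(), seed = NULL) {
  stopifnot(is_nuclear_shape(shape), is_object_pattern(pattern),
            inherits(spec, "image_spec"))
  s <- shape$spacing_um
  d <- dim(shape$mask$voxels)
  with_seed(seed, {
    spot <- array(0, d)
    add_gauss <- function(img, ctr, amp, sigma) {
      rad <- ceiling(4 * sigma / s)
      iv <- round(ctr / s + 0.5)  # voxel index of center
      lo <- pmax(iv - rad, 1); hi <- pmin(iv + rad, d)
      if (any(lo > hi)) return(img)
      gx <- ((lo[1]:hi[1]) - 0.5) * s - ctr[1]
      gy <- ((lo[2]:hi[2]) - 0.5) * s - ctr[2]
      gz <- ((lo[3]:hi[3]) - 0.5) * s - ctr[3]
      blob <- amp * exp(-(outer(outer(gx^2, gy^2, `+`), gz^2, `+`)) /
                        (2 * sigma^2))
      img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
        img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
      img
    }
    n <- n_objects(pattern)
    for (i in seq_len(n)) {
      ctr <- pattern$centers[i, ]
      spot <- add_gauss(spot, ctr, spec$spot_amplitude, spec$spot_sigma_um)
      if (spec$echo_gain > 0)
        spot <- add_gauss(spot, ctr + c(0, 0, spec$echo_offset_um),
                          spec$echo_gain * spec$spot_amplitude,
                          spec$spot_sigma_um)
    }
    close_pairs <- integer(0)
    if (n > 1) {
      dd <- as.matrix(stats::dist(pattern$centers))
      diag(dd) <- Inf
      close_pairs <- which(apply(dd, 1, min) < s)
      if (length(close_pairs))
        warning(sprintf("%d spot(s) closer than one voxel to a neighbor",
                        length(close_pairs)))
    }
    lam <- spec$spot_amplitude *
      exp(-shape$border_field^2 / (2 * spec$lamina_shell_sigma_um^2))
    if (spec$n_gaps > 0) {
      surf <- which(abs(shape$border_field) < s)
      gaps <- surf[sample.int(length(surf), min(spec$n_gaps, length(surf)))]
      ai <- (arrayInd(gaps, d) - 0.5) * s
      vox <- which(lam > 0.01 * spec$spot_amplitude)
      pv <- (arrayInd(vox, d) - 0.5) * s
      for (gi in seq_len(nrow(ai))) {
        hit <- rowSums(sweep(pv, 2, ai[gi, ])^2) < spec$gap_radius_um^2
        lam[vox[hit]] <- 0
      }
    }
    if (spec$background > 0) {
      spot <- spot + spec$background
      lam <- lam + spec$background
    }
    if (spec$noise_sd > 0) {
      spot <- spot + array(rnorm(length(spot), 0, spec$noise_sd), d)
      lam <- lam + array(rnorm(length(lam), 0, spec$noise_sd), d)
    }
    list(spot = labeled_volume(spot, shape$mask$spacing, "spots"),
         lamina = labeled_volume(lam, shape$mask$spacing, "lamina"),
         ground_truth = list(centers = pattern$centers,
                             labels = pattern$labels,
                             close_pairs = close_pairs))
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Builds a Ct table for which the delta-delta-Ct estimator recovers the
#' requested fold enrichments in expectation under 100% amplification
#' efficiency. For each condition, two samples are generated: one expressing
#' untargeted methyltransferase (the within-condition control construct,
#' `M.EcoGII`) and one expressing the lamin-fused construct (`M-LB1`). The
#' `M-LB1` sample's target Ct is lowered by `log2(fold)` relative to the
#' control construct; the inter-LAD reference region is flat by construction.
#'
#' @param true_folds Named numeric vector of fold enrichments per target
#'   region (e.g. `c(telomere = 10, "LAD-CFHR3" = 30)`), all > 0.
#' @param conditions Named numeric vector of per-condition multipliers on the
#'   folds (e.g. `c(control = 1, siLAP2 = 0.5)`).
#' @param ilad_reference Name of the reference region (default `"iLAD-SMIM2"`).
#' @param ct_reference Baseline Ct value.
#' @param noise_sd Gaussian Ct noise per replicate.
#' @param n_replicates Technical replicates per (sample, region).
#' @param seed Integer seed.
#' @return A data.frame with columns `sample_id, construct, condition,
#'   region, ct, replicate`.
#' @export
make_qpcr_table <- function(true_folds, conditions = c(control = 1),
                            ilad_reference = "iLAD-SMIM2",
                            ct_reference = 25, noise_sd = 0,
                            n_replicates = 3, seed = NULL) {
  stopifnot(all(true_folds > 0), all(conditions > 0),
            !is.null(names(true_folds)))
  if (is.null(names(conditions)))
    names(conditions) <- paste0("cond", seq_along(conditions))
  regions <- c(names(true_folds), ilad_reference)
  with_seed(seed, {
    rows <- list()
    for (cond in names(conditions)) {
      for (construct in c("M.EcoGII", "M-LB1")) {
        sid <- paste(cond, construct, sep = "_")
        for (reg in regions) {
          base <- ct_reference
          if (construct == "M-LB1" && reg != ilad_reference)
            base <- base - log2(true_folds[[reg]] * conditions[[cond]])
          ct <- base + if (noise_sd > 0) rnorm(n_replicates, 0, noise_sd)
                       else rep(0, n_replicates)
          rows[[length(rows) + 1L]] <-
            data.frame(sample_id = sid, construct = construct,
                       condition = cond, region = reg, ct = ct,
                       replicate = seq_len(n_replicates))
        }
      }
    }
    do.call(rbind, rows)
  })
}
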