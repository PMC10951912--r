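# Image-processing pipelines: nucleus (directional closing + marker
# watershed on the lamin channel), point-like spots (echo suppression,
# h-maxima, CV-minimizing threshold) and sized blobs (dual threshold with
# constrained dilation), plus per-object measurement.

#' Segmentation parameters
#'
#' Defaults are stated here once and are overridable per call; `"auto"`
#' values are derived from the image: h-extrema depths are 10% of the channel
#' dynamic range, the threshold scan is 64 evenly spaced quantiles between
#' the 50th and 99.9th intensity percentile, and the centromere low/high
#' thresholds are 20% / 60% of the dynamic range.
#'
#' @param gaussian_sigma_um Smoothing sigma (µm).
#' @param closing_length_um Length of the directional closing line elements.
#' @param h_minima,h_maxima Extrema depths, or `"auto"`.
#' @param echo_fraction Echo-filter proportion in (0, 1).
#' @param echo_radius_um Neighborhood half-extents, `c(lateral, axial)` µm.
#' @param threshold_scan Ordered candidate thresholds, or `NULL` for auto.
#' @param min_object_voxels Minimum component size kept during the scan.
#' @param low_threshold,high_threshold Dual thresholds for [segment_blobs()],
#'   or `NULL` for auto.
#' @param opening_radius_um Size-opening radius for [segment_blobs()].
#' @param exclude_labels Integer label ids dropped from the final object set
#'   (replaces interactive removal of rare false positives).
#' @return A `seg_params` list.
#' @export
seg_params <- function(gaussian_sigma_um = 0.1, closing_length_um = 0.5,
                       h_minima = "auto", h_maxima = "auto",
                       echo_fraction = 0.5, echo_radius_um = c(0.15, 0.6),
                       threshold_scan = NULL, min_object_voxels = 5,
                       low_threshold = NULL, high_threshold = NULL,
                       opening_radius_um = 0.1, exclude_labels = integer(0)) {
  stopifnot(echo_fraction > 0, echo_fraction < 1)
  if (!is.null(low_threshold) && !is.null(high_threshold) &&
      low_threshold >= high_threshold)
    stop("low_threshold must be below high_threshold")
  structure(as.list(environment()), class = "seg_params")
}

gauss3d <- function(vol, sigma_um) {
  s <- spacing_um(vol)
  out <- cpp_gaussian3d(as.numeric(vol$voxels), dim(vol$voxels), sigma_um / s)
  dim(out) <- dim(vol$voxels)
  labeled_volume(out, vol$spacing, vol$channel)
}

# grayscale erosion/dilation with a line element along one axis, or a box
morph_line <- function(arr, axis, half_vox, maximum) {
  out <- cpp_line_extremum(as.numeric(arr), dim(arr), axis - 1L,
                           as.integer(half_vox), maximum)
  dim(out) <- dim(arr)
  out
}

morph_box <- function(arr, half_vox, maximum) {
  for (ax in 1:3)
    if (half_vox[ax] > 0) arr <- morph_line(arr, ax, half_vox[ax], maximum)
  arr
}

auto_h <- function(arr) 0.1 * diff(range(arr))

regional_minima <- function(arr) {
  eps <- 1e-5 * diff(range(arr))
  if (eps == 0) return(array(TRUE, dim(arr)))
  neg <- -arr
  rec <- cpp_reconstruct_dilation(as.numeric(neg - eps), as.numeric(neg),
                                  dim(arr))
  out <- (neg - rec) > eps / 2
  dim(out) <- dim(arr)
  out
}

#' h-maxima / h-minima transforms
#'
#' Suppress intensity peaks (valleys) shallower than `h` by grayscale
#' reconstruction.
#'
#' @param vol A [labeled_volume()].
#' @param h Extrema depth in intensity units.
#' @return A [labeled_volume()].
#' @export
h_maxima <- function(vol, h) {
  out <- cpp_reconstruct_dilation(as.numeric(vol$voxels) - h,
                                  as.numeric(vol$voxels), dim(vol$voxels))
  dim(out) <- dim(vol$voxels)
  labeled_volume(out, vol$spacing, vol$channel)
}

#' @rdname h_maxima
#' @export
h_minima <- function(vol, h) {
  neg <- -as.numeric(vol$voxels)
  out <- -cpp_reconstruct_dilation(neg - h, neg, dim(vol$voxels))
  dim(out) <- dim(vol$voxels)
  labeled_volume(out, vol$spacing, vol$channel)
}

#' Segment the nucleus from a lamina channel
#'
#' Resamples to isotropic 100 nm, Gaussian-smooths, applies a directional
#' closing (grayscale closing with line elements along each axis, combined by
#' voxelwise maximum) to bridge small gaps in the lamina signal, detects
#' extended minima at depth `h_minima`, floods a marker-based watershed from
#' them, discards watershed regions touching the image border and returns the
#' largest remaining region as a binary mask.
#'
#' @param lamina A [labeled_volume()] of the lamina channel.
#' @param params A [seg_params()].
#' @param target_nm Isotropic working resolution.
#' @return Binary [labeled_volume()] (one connected nucleus mask).
#' @export
segment_nucleus <- function(lamina, params = seg_params(), target_nm = 100) {
  stopifnot(is_labeled_volume(lamina), inherits(params, "seg_params"))
  vol <- resample_isotropic(lamina, target_nm)
  s <- spacing_um(vol)[1]
  sm <- gauss3d(vol, params$gaussian_sigma_um)
  half <- max(1L, round(params$closing_length_um / (2 * s)))
  closed <- sm$voxels
  acc <- NULL
  for (ax in 1:3) {
    cl <- morph_line(morph_line(closed, ax, half, TRUE), ax, half, FALSE)
    acc <- if (is.null(acc)) cl else pmax(acc, cl)
  }
  dim(acc) <- dim(closed)
  h <- if (identical(params$h_minima, "auto")) auto_h(acc) else params$h_minima
  hm <- h_minima(labeled_volume(acc, vol$spacing), h)$voxels
  markers <- cpp_label3d(as.integer(regional_minima(hm)), dim(acc), 26L)
  dim(markers) <- dim(acc)
  ws <- cpp_watershed(as.numeric(hm), as.integer(markers), dim(acc))
  dim(ws) <- dim(acc)
  d <- dim(ws)
  border_labels <- unique(c(ws[1, , ], ws[d[1], , ], ws[, 1, ], ws[, d[2], ],
                            ws[, , 1], ws[, , d[3]]))
  keep <- setdiff(seq_len(max(ws)), border_labels)
  if (!length(keep))
    stop("nucleus segmentation failed: every watershed region touches the ",
         "image border")
  sizes <- tabulate(ws[ws %in% keep], nbins = max(ws))
  best <- which.max(sizes)
  labeled_volume(array(ws == best, d), vol$spacing, "nucleus mask")
}

#' Suppress axial echo artifacts
#'
#' Voxels whose value falls below `echo_fraction` times the maximum of an
#' axially elongated box neighborhood around them are set to 0; reconstruction
#' ghosts (dimmer axially displaced copies of bright spots) fall below the
#' true spot's peak in their shared neighborhood and are removed, while
#' isolated spots are their own neighborhood maximum and survive. Idempotent.
#'
#' @param vol A [labeled_volume()].
#' @param echo_fraction Proportion of the neighborhood maximum, in (0, 1).
#' @param echo_radius_um Neighborhood half-extents `c(lateral, axial)` in µm.
#' @return A [labeled_volume()].
#' @export
suppress_echoes <- function(vol, echo_fraction = 0.5,
                            echo_radius_um = c(0.15, 0.6)) {
  stopifnot(is_labeled_volume(vol), echo_fraction > 0, echo_fraction < 1)
  s <- spacing_um(vol)
  half <- round(c(echo_radius_um[1], echo_radius_um[1],
                  echo_radius_um[2]) / s)
  if (all(half < 1))
    stop("echo neighborhood smaller than one voxel at this spacing")
  mx <- morph_box(vol$voxels, half, TRUE)
  out <- vol$voxels
  out[out < echo_fraction * mx] <- 0
  labeled_volume(out, vol$spacing, vol$channel)
}

#' Threshold selection minimizing the coefficient of variation of object size
#'
#' For each candidate threshold, 26-connected components of the
#' super-threshold set are labeled, components below `min_object_voxels` are
#' dropped, and the coefficient of variation (sd/mean) of component voxel
#' counts is computed. The CV is minimized over the thresholds that retain
#' the constellation — those whose object count is within 10% of the maximum
#' count observed along the scan; without this restriction the CV degenerates
#' at high thresholds where only a few equal-sized peak tips survive. Ties go
#' to the lowest threshold.
#'
#' @param vol A [labeled_volume()].
#' @param threshold_scan Ordered candidate thresholds; `NULL` for the default
#'   quantile scan.
#' @param min_object_voxels Minimum component size.
#' @return List with `threshold`, `labels` (integer [labeled_volume()]) and
#'   `cv_curve` (data.frame threshold/cv/n_objects).
#' @export
threshold_min_cv <- function(vol, threshold_scan = NULL,
                             min_object_voxels = 5) {
  stopifnot(is_labeled_volume(vol))
  v <- vol$voxels
  if (is.null(threshold_scan)) {
    # spots are sparse: pure quantile scans stall in the background pedestal,
    # so span from the median up to just below the brightest peak
    lo <- stats::quantile(v, 0.5, names = FALSE)
    hi <- max(v) - 0.05 * (max(v) - lo)
    if (hi <= lo) hi <- max(v)
    threshold_scan <- seq(lo, hi, length.out = 64)
  }
  threshold_scan <- sort(threshold_scan)
  d <- dim(v)
  cvs <- rep(NA_real_, length(threshold_scan))
  nobj <- integer(length(threshold_scan))
  for (ti in seq_along(threshold_scan)) {
    lab <- cpp_label3d(as.integer(v >= threshold_scan[ti]), d, 26L)
    if (max(lab) == 0) next
    sizes <- tabulate(lab[lab > 0L])
    sizes <- sizes[sizes >= min_object_voxels]
    nobj[ti] <- length(sizes)
    if (length(sizes) >= 2) cvs[ti] <- stats::sd(sizes) / mean(sizes)
  }
  if (all(is.na(cvs)))
    stop(sprintf("no threshold in [%g, %g] yields >= 2 objects",
                 min(threshold_scan), max(threshold_scan)))
  eligible <- nobj >= ceiling(0.9 * max(nobj)) & !is.na(cvs)
  if (!any(eligible)) eligible <- !is.na(cvs)
  cvs_sel <- ifelse(eligible, cvs, NA_real_)
  best <- which.min(cvs_sel)  # first minimum = lowest threshold on ties
  thr <- threshold_scan[best]
  lab <- cpp_label3d(as.integer(v >= thr), d, 26L)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_object_voxels)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab <- match(lab, sort(unique(lab[lab > 0L]))) # compact ids
  lab[is.na(lab)] <- 0L
  dim(lab) <- d
  list(threshold = thr,
       labels = labeled_volume(array(as.integer(lab), d), vol$spacing,
                               vol$channel),
       cv_curve = data.frame(threshold = threshold_scan, cv = cvs,
                             n_objects = nobj))
}

# keep whole labels having at least one voxel inside the mask (the geodesic
# selection rule: border-straddling objects are retained untruncated)
select_in_mask <- function(lab_arr, mask_arr) {
  inside <- unique(lab_arr[mask_arr & lab_arr > 0L])
  out <- lab_arr
  out[!(out %in% inside)] <- 0L
  out
}

#' Segment point-like spots (telomere pipeline)
#'
#' Gaussian smoothing, echo suppression, h-maxima simplification,
#' CV-minimizing threshold selection, component labeling, then selection of
#' labels overlapping the nucleus mask with geodesic reconstruction semantics:
#' an object with at least one voxel inside the mask is kept whole, an object
#' entirely outside is removed.
#'
#' @param spot A [labeled_volume()] of the spot channel.
#' @param nucleus Binary nucleus mask ([labeled_volume()]) or a
#'   [mask_to_mesh()] shape (its mask is used and object measurement binds to
#'   it).
#' @param params A [seg_params()].
#' @return List with `labels`, `pattern` (an [object_pattern()]),
#'   `threshold`, `cv_curve`.
#' @export
segment_spots <- function(spot, nucleus, params = seg_params()) {
  stopifnot(is_labeled_volume(spot))
  shape <- if (is_nuclear_shape(nucleus)) nucleus else mask_to_mesh(nucleus)
  sm <- gauss3d(spot, params$gaussian_sigma_um)
  es <- suppress_echoes(sm, params$echo_fraction, params$echo_radius_um)
  h <- if (identical(params$h_maxima, "auto")) auto_h(es$voxels)
       else params$h_maxima
  hm <- h_maxima(es, h)
  th <- threshold_min_cv(hm, params$threshold_scan, params$min_object_voxels)
  lab <- select_in_mask(th$labels$voxels, as_binary_array(shape$mask))
  if (length(params$exclude_labels)) lab[lab %in% params$exclude_labels] <- 0L
  if (!any(lab > 0L)) stop("no spot overlaps the nucleus mask")
  labels <- labeled_volume(lab, spot$spacing, spot$channel)
  list(labels = labels,
       pattern = extract_objects(labels, shape),
       threshold = th$threshold, cv_curve = th$cv_curve)
}

#' Segment sized blobs with a dual threshold (centromere pipeline)
#'
#' Gaussian smoothing, grayscale size opening, binarization at a low
#' threshold, seed labeling at a high threshold, then constrained dilation of
#' the seeds inside the low mask (each low-mask voxel joins its geodesically
#' nearest seed) so touching blobs separable at the high threshold stay
#' distinct; in-nucleus selection as in [segment_spots()].
#'
#' @inheritParams segment_spots
#' @param crest A [labeled_volume()] of the blob channel.
#' @return List with `labels`, `pattern`, `low_threshold`, `high_threshold`.
#' @export
segment_blobs <- function(crest, nucleus, params = seg_params()) {
  stopifnot(is_labeled_volume(crest))
  shape <- if (is_nuclear_shape(nucleus)) nucleus else mask_to_mesh(nucleus)
  sm <- gauss3d(crest, params$gaussian_sigma_um)
  s <- spacing_um(sm)
  half <- pmax(round(params$opening_radius_um / s), 0)
  op <- morph_box(morph_box(sm$voxels, half, FALSE), half, TRUE)
  rng <- range(op)
  lo <- if (is.null(params$low_threshold)) rng[1] + 0.2 * diff(rng)
        else params$low_threshold
  hi <- if (is.null(params$high_threshold)) rng[1] + 0.6 * diff(rng)
        else params$high_threshold
  if (lo >= hi) stop("low threshold must be below high threshold")
  d <- dim(op)
  lowmask <- op >= lo
  seeds <- cpp_label3d(as.integer(op >= hi), d, 26L)
  if (max(seeds) == 0) stop("no high-threshold seed found")
  lab <- cpp_seeded_dilate(as.integer(seeds), as.integer(lowmask), d)
  dim(lab) <- d
  lab <- select_in_mask(lab, as_binary_array(shape$mask))
  if (length(params$exclude_labels)) lab[lab %in% params$exclude_labels] <- 0L
  if (!any(lab > 0L)) stop("no blob overlaps the nucleus mask")
  labels <- labeled_volume(lab, crest$spacing, crest$channel)
  list(labels = labels, pattern = extract_objects(labels, shape),
       low_threshold = lo, high_threshold = hi)
}

#' Measure labeled objects and bind them to a nuclear shape
#'
#' Per label: centroid (average of voxel center positions), volume (voxel
#' count times voxel volume), equivalent-sphere radius and elongation (ratio
#' of extreme principal extents of the voxel coordinate covariance; 1 for a
#' single voxel).
#'
#' @param labels Integer [labeled_volume()].
#' @param shape A [mask_to_mesh()] shape the objects belong to.
#' @return An [object_pattern()]; objects whose centroid falls outside the
#'   mask (border-straddling objects kept by geodesic selection) are flagged
#'   in its `inside` field. Per-object elongation is attached as attribute
#'   `"elongation"`.
#' @export
extract_objects <- function(labels, shape) {
  stopifnot(is_labeled_volume(labels), is_nuclear_shape(shape))
  lab <- labels$voxels
  s <- spacing_um(labels)
  vox <- which(lab > 0L)
  if (!length(vox)) {
    pat <- object_pattern(matrix(numeric(0), 0, 3), shape,
                          volumes = numeric(0), labels = integer(0))
    attr(pat, "elongation") <- numeric(0)
    return(pat)
  }
  l <- as.integer(lab[vox])
  ids <- sort(unique(l))
  ai <- sweep(arrayInd(vox, dim(lab)) - 0.5, 2, s, `*`)
  cnt <- as.vector(rowsum(rep(1, length(l)), l))
  ctr <- rowsum(ai, l) / cnt
  # per-object covariance eigen-extents for elongation
  cxx <- rowsum(ai^2, l) / cnt - ctr^2
  cxy <- rowsum(ai[, 1] * ai[, 2], l) / cnt - ctr[, 1] * ctr[, 2]
  cxz <- rowsum(ai[, 1] * ai[, 3], l) / cnt - ctr[, 1] * ctr[, 3]
  cyz <- rowsum(ai[, 2] * ai[, 3], l) / cnt - ctr[, 2] * ctr[, 3]
  elo <- vapply(seq_along(ids), function(i) {
    cv <- matrix(c(cxx[i, 1], cxy[i], cxz[i],
                   cxy[i], cxx[i, 2], cyz[i],
                   cxz[i], cyz[i], cxx[i, 3]), 3, 3)
    ev <- pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0)
    if (ev[3] <= 1e-12) 1 else sqrt(ev[1] / ev[3])
  }, numeric(1))
  vols <- cnt * prod(rep(s[1], 3))
  pat <- object_pattern(ctr, shape, volumes = vols, labels = ids)
  attr(pat, "elongation") <- elo
  pat
}

#' Median distance from labeled objects to reference regions
#'
#' Computes the Euclidean distance map of the inverted region mask (distance
#' from every voxel to the nearest region voxel, 0 inside regions) and
#' summarizes it per labeled object by the median over the object's voxels.
#'
#' @param labels Integer [labeled_volume()] of objects (e.g. telomeres).
#' @param region_mask Binary [labeled_volume()] of reference regions (e.g.
#'   lamina-associated structures), aligned with `labels`.
#' @return Named numeric vector of median distances (µm) per label; all
#'   `Inf` (with a warning) when the region mask is empty.
#' @export
median_distance_to_regions <- function(labels, region_mask) {
  stopifnot(is_labeled_volume(labels), is_labeled_volume(region_mask))
  lab <- labels$voxels
  ids <- sort(unique(lab[lab > 0L]))
  reg <- as_binary_array(region_mask)
  if (!any(reg)) {
    warning("empty region mask: distances are infinite")
    return(setNames(rep(Inf, length(ids)), ids))
  }
  s <- spacing_um(region_mask)
  emap <- sqrt(cpp_edt3d(as.integer(!reg), dim(reg), s))
  vox <- which(lab > 0L)
  med <- tapply(emap[vox], as.integer(lab[vox]), stats::median)
  setNames(as.numeric(med), names(med))
}
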