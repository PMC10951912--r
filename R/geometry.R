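#' @useDynLib nucleospat, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd setNames
NULL

# ---- internal helpers -------------------------------------------------------

# Restore the caller's RNG state on exit; all stochastic operations in the
# package funnel through this so that generators are pure functions of
# (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

as_binary_array <- function(x) {
  if (is_labeled_volume(x)) x <- x$voxels
  if (is.logical(x)) return(x)
  x != 0
}

# boundary faces of a binary array in one axis direction; returns the
# 0-based corner lattice coordinates of the quad, oriented outward
face_shift <- function(fg, axis, step) {
  d <- dim(fg)
  nb <- array(FALSE, d)
  src <- lapply(d, seq_len)
  dst <- src
  n <- d[axis]
  if (step > 0) { dst[[axis]] <- seq_len(n - 1); src[[axis]] <- 2:n }
  else          { dst[[axis]] <- 2:n;           src[[axis]] <- seq_len(n - 1) }
  nb[dst[[1]], dst[[2]], dst[[3]]] <- fg[src[[1]], src[[2]], src[[3]]]
  fg & !nb
}

# ---- nuclear shape ----------------------------------------------------------

#' Extract a nuclear shape from a binary mask
#'
#' Builds a closed, watertight triangular boundary mesh from an isotropic
#' binary mask by extracting the voxel boundary faces (every face separating a
#' foreground from a background voxel, consistently oriented outward) and
#' applying a small number of Laplacian smoothing passes to remove the voxel
#' terracing that would otherwise inflate surface area. Vertices are in
#' micrometers with the center-of-voxel convention. Also computes the mask
#' centroid, the principal axes (eigenvectors of the foreground voxel
#' coordinate covariance, ordered major to minor, sign fixed so each axis's
#' largest-magnitude component is positive), volume, surface area, sphericity
#' and elongation, and caches a signed border-distance field for fast
#' distance lookups.
#'
#' @param mask Binary [labeled_volume()] (or 3D logical array with `spacing_nm`
#'   attached via `spacing_nm` argument) with exactly one connected foreground
#'   component and isotropic spacing.
#' @param smoothing_passes Number of Laplacian smoothing passes (each vertex
#'   replaced by the mean of its mesh neighbors). Default 2.
#' @param spacing_nm Voxel size if `mask` is a bare array.
#' @return An object of class `nuclear_shape` with fields `mask`, `vertices`
#'   (V x 3 µm), `triangles` (T x 3 vertex indices), `center`, `axes` (3 x 3
#'   matrix, rows major/intermediate/minor), `volume` (µm³, voxel count),
#'   `mesh_volume`, `surface_area` (µm², mesh), `sphericity`, `elongation`.
#' @export
mask_to_mesh <- function(mask, smoothing_passes = 2, spacing_nm = 100) {
  if (!is_labeled_volume(mask)) mask <- labeled_volume(mask, spacing_nm)
  if (!is_isotropic(mask))
    stop("mask_to_mesh requires isotropic spacing; resample first")
  fg <- as_binary_array(mask)
  if (!any(fg)) stop("mask has no foreground voxels")
  lab <- cpp_label3d(as.integer(fg), dim(fg), 26L)
  ncomp <- max(lab)
  if (ncomp != 1L)
    stop(sprintf("mask must have exactly one connected component (found %d)",
                 ncomp))
  s <- spacing_um(mask)[1]
  d <- dim(fg)

  # quad corner offsets per direction: rows are 0-based corner lattice
  # coordinates relative to the (i-1, j-1, k-1) corner of voxel (i,j,k);
  # `plane` gives the fixed-axis corner value offset, `rev` flips orientation
  quads <- list(
    list(axis = 1, step = +1, rev = FALSE,
         corners = list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1))),
    list(axis = 1, step = -1, rev = TRUE,
         corners = list(c(0, 0, 0), c(0, 1, 0), c(0, 1, 1), c(0, 0, 1))),
    list(axis = 2, step = +1, rev = TRUE,
         corners = list(c(0, 1, 0), c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))),
    list(axis = 2, step = -1, rev = FALSE,
         corners = list(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1))),
    list(axis = 3, step = +1, rev = FALSE,
         corners = list(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))),
    list(axis = 3, step = -1, rev = TRUE,
         corners = list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  )
  nxc <- d[1] + 1L; nyc <- d[2] + 1L
  key_of <- function(cx, cy, cz) cx + nxc * (cy + nyc * cz)
  tri_keys <- vector("list", length(quads))
  for (q in seq_along(quads)) {
    spec <- quads[[q]]
    bdr <- face_shift(fg, spec$axis, spec$step)
    if (!any(bdr)) { tri_keys[[q]] <- NULL; next }
    vox <- which(bdr)
    ai <- arrayInd(vox, d) - 1L  # 0-based voxel origin corner
    ks <- lapply(spec$corners, function(off)
      key_of(ai[, 1] + off[1], ai[, 2] + off[2], ai[, 3] + off[3]))
    p1 <- ks[[1]]; p2 <- ks[[2]]; p3 <- ks[[3]]; p4 <- ks[[4]]
    if (spec$rev) {
      tri <- rbind(cbind(p1, p4, p3), cbind(p1, p3, p2))
    } else {
      tri <- rbind(cbind(p1, p2, p3), cbind(p1, p3, p4))
    }
    tri_keys[[q]] <- tri
  }
  tri_all <- do.call(rbind, tri_keys)
  ukeys <- sort(unique(as.vector(tri_all)))
  vid <- match(tri_all, ukeys)
  triangles <- matrix(vid, ncol = 3)
  cz <- ukeys %/% (nxc * nyc)
  rem <- ukeys %% (nxc * nyc)
  cy <- rem %/% nxc
  cx <- rem %% nxc
  vertices <- cbind(cx, cy, cz) * s

  # Laplacian smoothing over mesh edges
  if (smoothing_passes > 0) {
    e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
    e <- rbind(e, e[, c(2, 1)])
    e <- unique(e)
    deg <- tabulate(e[, 1], nbins = nrow(vertices))
    for (pass in seq_len(smoothing_passes)) {
      acc <- rowsum(vertices[e[, 2], , drop = FALSE], e[, 1],
                    reorder = TRUE)
      vertices <- acc / deg
    }
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))

  # geometry from the foreground voxels
  vox <- which(fg)
  ai <- arrayInd(vox, d)
  ctr_vox <- (ai - 0.5) * s
  center <- colMeans(ctr_vox)
  cv <- stats::cov(ctr_vox)
  eg <- eigen(cv, symmetric = TRUE)
  axes <- t(eg$vectors)  # rows = axes, ordered by decreasing eigenvalue
  for (r in 1:3) {
    m <- which.max(abs(axes[r, ]))
    if (axes[r, m] < 0) axes[r, ] <- -axes[r, ]
  }
  rownames(axes) <- c("major", "intermediate", "minor")
  ev <- pmax(eg$values, 0)
  elongation <- if (ev[3] > 0) sqrt(ev[1] / ev[3]) else Inf

  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  cr <- cbind((v2[, 2] - v1[, 2]) * (v3[, 3] - v1[, 3]) -
              (v2[, 3] - v1[, 3]) * (v3[, 2] - v1[, 2]),
              (v2[, 3] - v1[, 3]) * (v3[, 1] - v1[, 1]) -
              (v2[, 1] - v1[, 1]) * (v3[, 3] - v1[, 3]),
              (v2[, 1] - v1[, 1]) * (v3[, 2] - v1[, 2]) -
              (v2[, 2] - v1[, 2]) * (v3[, 1] - v1[, 1]))
  surface_area <- sum(sqrt(rowSums(cr^2))) / 2
  mesh_volume <- sum(v1[, 1] * cr[, 1] + v1[, 2] * cr[, 2] +
                     v1[, 3] * cr[, 3]) / 6
  volume <- length(vox) * s^3
  sphericity <- pi^(1 / 3) * (6 * volume)^(2 / 3) / surface_area

  # signed border-distance field (µm): positive inside, negative outside;
  # half-voxel offset places the zero level on the voxel boundary surface
  din <- sqrt(cpp_edt3d(as.integer(fg), d, rep(s, 3)))
  dout <- sqrt(cpp_edt3d(as.integer(!fg), d, rep(s, 3)))
  bf <- din - dout - 0.5 * s * (2 * as.numeric(fg) - 1)
  dim(bf) <- d

  structure(
    list(mask = labeled_volume(fg, spacing_nm = mask$spacing,
                               channel = "nucleus mask"),
         vertices = vertices, triangles = triangles,
         center = center, axes = axes,
         volume = volume, mesh_volume = mesh_volume,
         surface_area = surface_area, sphericity = sphericity,
         elongation = elongation, border_field = bf,
         spacing_um = s, cache = new.env(parent = emptyenv())),
    class = "nuclear_shape"
  )
}

#' @export
print.nuclear_shape <- function(x, ...) {
  cat(sprintf(paste0("<nuclear_shape> V = %.1f um^3 (mesh %.1f), A = %.1f um^2,",
                     " sphericity %.3f, elongation %.2f, %d vertices\n"),
              x$volume, x$mesh_volume, x$surface_area, x$sphericity,
              x$elongation, nrow(x$vertices)))
  invisible(x)
}

#' @rdname mask_to_mesh
#' @param x Object to test.
#' @export
is_nuclear_shape <- function(x) inherits(x, "nuclear_shape")

# lazily cached per-shape quantities (flat foreground vector, bounding box)
shape_cache <- function(shape, what) {
  cache <- shape$cache
  if (is.null(cache[[what]])) {
    fg <- shape$mask$voxels
    if (what == "fgvec") cache$fgvec <- as.vector(fg)
    if (what == "bbox") {
      s <- shape$spacing_um
      rx <- range(which(apply(fg, 1, any)))
      ry <- range(which(apply(fg, 2, any)))
      rz <- range(which(apply(fg, 3, any)))
      cache$bbox <- list(lo = (c(rx[1], ry[1], rz[1]) - 1) * s,
                         hi = c(rx[2], ry[2], rz[2]) * s)
    }
    if (what == "interior") {
      iv <- which(as.vector(fg))
      bd <- as.vector(shape$border_field)[iv]
      ord <- order(bd)
      cache$interior <- list(voxel = iv[ord], bd = bd[ord])
    }
    if (what == "bfvec") cache$bfvec <- as.numeric(shape$border_field)
  }
  cache[[what]]
}

# fast border-distance lookup (signed; no outside checks)
border_lookup <- function(shape, points) {
  cpp_trilinear(shape_cache(shape, "bfvec"), dim(shape$border_field),
                rep(shape$spacing_um, 3), points)
}

# voxel-containment test under the center-of-voxel convention
point_in_shape <- function(shape, points) {
  points <- as_points(points)
  s <- shape$spacing_um
  d <- dim(shape$mask$voxels)
  ii <- floor(points / s) + 1
  ok <- ii[, 1] >= 1 & ii[, 1] <= d[1] &
        ii[, 2] >= 1 & ii[, 2] <= d[2] &
        ii[, 3] >= 1 & ii[, 3] <= d[3]
  out <- logical(nrow(points))
  if (any(ok)) {
    lin <- ii[ok, 1] + d[1] * ((ii[ok, 2] - 1) + d[2] * (ii[ok, 3] - 1))
    out[ok] <- shape_cache(shape, "fgvec")[lin]
  }
  out
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  points
}

#' Distance from points to the nuclear border
#'
#' @param shape A [mask_to_mesh()] result.
#' @param points n x 3 matrix of positions in µm.
#' @param method `"mesh"` for exact point-to-triangle distance against the
#'   boundary mesh (the reference measurement), or `"edt"` for a trilinear
#'   lookup into the precomputed Euclidean distance transform (fast path,
#'   agrees with the mesh within about one voxel).
#' @return Numeric vector of non-negative distances (µm). Points outside the
#'   nucleus beyond a one-voxel tolerance trigger a warning and carry an
#'   attribute `outside` marking them.
#' @export
distance_to_border <- function(shape, points, method = c("mesh", "edt")) {
  method <- match.arg(method)
  stopifnot(is_nuclear_shape(shape))
  points <- as_points(points)
  signed <- border_lookup(shape, points)
  outside <- signed < -shape$spacing_um
  if (any(outside))
    warning(sprintf("%d point(s) outside the nucleus beyond one voxel",
                    sum(outside)))
  d <- if (method == "mesh") {
    cpp_mesh_distance(points, shape$vertices, shape$triangles)
  } else {
    pmax(signed, 0)
  }
  if (any(outside)) attr(d, "outside") <- which(outside)
  d
}

#' Distance from points to the nucleus center
#'
#' @inheritParams distance_to_border
#' @return Numeric vector of Euclidean distances to the mask centroid (µm).
#' @export
distance_to_center <- function(shape, points) {
  stopifnot(is_nuclear_shape(shape))
  points <- as_points(points)
  sqrt(rowSums(sweep(points, 2, shape$center)^2))
}

#' Morphometric descriptors of a binary region
#'
#' Volume is the voxel count times the voxel volume; surface area is measured
#' on the smoothed boundary mesh; sphericity is
#' \eqn{\pi^{1/3} (6V)^{2/3} / A}; elongation is the ratio of the largest to
#' smallest principal extent (square root of the covariance eigenvalue ratio).
#'
#' @param mask Binary [labeled_volume()] or 3D logical array.
#' @param spacing_nm Voxel size if `mask` is a bare array.
#' @param smoothing_passes Passed to [mask_to_mesh()].
#' @return List with `volume` (µm³), `surface_area` (µm²), `sphericity`,
#'   `elongation`.
#' @export
shape_descriptors <- function(mask, spacing_nm = 100, smoothing_passes = 2) {
  sh <- mask_to_mesh(mask, smoothing_passes = smoothing_passes,
                     spacing_nm = spacing_nm)
  list(volume = sh$volume, surface_area = sh$surface_area,
       sphericity = sh$sphericity, elongation = sh$elongation)
}

#' Sample points uniformly inside a nuclear shape
#'
#' Rejection sampling from the foreground bounding box with a containment
#' test against the voxel mask (whose boundary is the mesh surface).
#'
#' @param shape A [mask_to_mesh()] result.
#' @param n Number of points.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return n x 3 matrix of positions (µm), strictly inside the shape.
#' @export
sample_uniform_interior <- function(shape, n, seed = NULL) {
  stopifnot(is_nuclear_shape(shape), n >= 1)
  with_seed(seed, {
    bb <- shape_cache(shape, "bbox")
    lo <- bb$lo
    hi <- bb$hi
    out <- matrix(NA_real_, n, 3)
    got <- 0L; tried <- 0L
    while (got < n) {
      m <- max(2L * (n - got), 64L)
      cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                    runif(m, lo[3], hi[3]))
      keep <- point_in_shape(shape, cand)
      tried <- tried + m
      k <- which(keep)
      if (length(k)) {
        take <- k[seq_len(min(length(k), n - got))]
        out[(got + 1):(got + length(take)), ] <- cand[take, , drop = FALSE]
        got <- got + length(take)
      }
      if (tried >= max(10000L, 100L * n) && got / tried < 0.01)
        stop("interior sampling acceptance below 1%; degenerate shape")
    }
    colnames(out) <- c("x", "y", "z")
    out
  })
}

# ---- object patterns --------------------------------------------------------

#' Create an object pattern bound to a nuclear shape
#'
#' @param centers n x 3 matrix of object centers (µm).
#' @param shape The [mask_to_mesh()] shape the objects live in.
#' @param volumes Per-object volumes (µm³); scalar recycled; 0 = point objects.
#' @param labels Integer object ids (default `1:n`).
#' @param stage Cell-cycle stage annotation: `"eG1"`, `"G1S"`, `"G2"` or
#'   `"other"`.
#' @param strict Error (rather than record) when a center falls outside the
#'   shape.
#' @return Object of class `object_pattern` with fields `centers`, `volumes`,
#'   `radii` (equivalent-sphere radii), `labels`, `shape`, `stage`, `inside`.
#' @export
object_pattern <- function(centers, shape, volumes = 0, labels = NULL,
                           stage = c("other", "eG1", "G1S", "G2"),
                           strict = FALSE) {
  stage <- match.arg(stage)
  stopifnot(is_nuclear_shape(shape))
  centers <- as_points(centers)
  n <- nrow(centers)
  volumes <- rep_len(as.numeric(volumes), n)
  if (any(volumes < 0)) stop("object volumes must be >= 0")
  if (is.null(labels)) labels <- seq_len(n)
  inside <- point_in_shape(shape, centers)
  if (strict && any(!inside))
    stop(sprintf("%d object center(s) outside the nuclear shape",
                 sum(!inside)))
  structure(
    list(centers = centers, volumes = volumes,
         radii = (3 * volumes / (4 * pi))^(1 / 3),
         labels = as.integer(labels), shape = shape, stage = stage,
         inside = inside),
    class = "object_pattern"
  )
}

#' @export
print.object_pattern <- function(x, ...) {
  cat(sprintf("<object_pattern> %d objects (stage %s), mean radius %.3f um\n",
              nrow(x$centers), x$stage, mean(x$radii)))
  invisible(x)
}

#' @rdname object_pattern
#' @param x Object to test.
#' @export
is_object_pattern <- function(x) inherits(x, "object_pattern")

#' Number of objects in a pattern
#' @param pattern An [object_pattern()].
#' @export
n_objects <- function(pattern) nrow(pattern$centers)

# ---- simple exporters -------------------------------------------------------

#' Write a boundary mesh as ASCII PLY
#' @param shape A [mask_to_mesh()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(shape, path) {
  v <- shape$vertices; f <- shape$triangles - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(v, trim = TRUE), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(3L, f), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read an object pattern as CSV
#'
#' Columns: `label, x_um, y_um, z_um, volume_um3, radius_um`.
#' @param pattern An [object_pattern()].
#' @param path CSV path.
#' @return `path` invisibly (write); a data.frame (read).
#' @export
write_pattern_csv <- function(pattern, path) {
  df <- data.frame(label = pattern$labels,
                   x_um = pattern$centers[, 1],
                   y_um = pattern$centers[, 2],
                   z_um = pattern$centers[, 3],
                   volume_um3 = pattern$volumes,
                   radius_um = pattern$radii)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path) {
  utils::read.csv(path)
}
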