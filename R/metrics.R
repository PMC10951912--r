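# Polarity, peripherality and 2D circularity metrics.

#' Polarity index of an object pattern along a nuclear principal axis
#'
#' Object centers are expressed in the nucleus principal frame (origin at the
#' mask centroid) and counted on each side of the plane orthogonal to the
#' chosen axis. The index is `max(n_plus, n_minus) / (n_plus + n_minus)`:
#' 0.5 when positions split equally between the two half-axes, 1 when all
#' positions lie on one half. A coordinate of exactly 0 counts as positive
#' (deterministic tie rule); the index is invariant to the sign convention of
#' the axes.
#'
#' @param pattern A non-empty [object_pattern()].
#' @param axis `"major"`, `"intermediate"` or `"minor"`.
#' @return A `polarity_result`: `axis`, `n_plus`, `n_minus`, `index`.
#' @export
polarity_index <- function(pattern, axis = c("minor", "major",
                                             "intermediate")) {
  stopifnot(is_object_pattern(pattern))
  axis <- match.arg(axis)
  if (n_objects(pattern) == 0)
    stop("polarity index is undefined for an empty pattern")
  ax <- pattern$shape$axes[axis, ]
  proj <- as.vector(sweep(pattern$centers, 2, pattern$shape$center) %*% ax)
  n_plus <- sum(proj >= 0)
  n_minus <- sum(proj < 0)
  structure(list(axis = axis, n_plus = n_plus, n_minus = n_minus,
                 index = max(n_plus, n_minus) / (n_plus + n_minus)),
            class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf("<polarity_result> %s axis: %d+ / %d- -> index %.3f\n",
              x$axis, x$n_plus, x$n_minus, x$index))
  invisible(x)
}

#' Fraction of objects within a cutoff distance of the nuclear border
#'
#' Conventional cutoffs: 0.5 µm for telomeres, 1 µm for centromeres (the
#' separation between the peripheral and internal pools), 0.25 µm for
#' proximity to lamina-associated structures.
#'
#' @param pattern An [object_pattern()].
#' @param cutoff_um Border-distance cutoff in µm.
#' @param method Border-distance method (see [distance_to_border()]).
#' @return A `periphery_result`: `cutoff_um`, `n_peripheral`, `n_internal`,
#'   `fraction_peripheral`.
#' @export
peripheral_fraction <- function(pattern, cutoff_um = 0.5, method = "mesh") {
  stopifnot(is_object_pattern(pattern), cutoff_um >= 0)
  d <- distance_to_border(pattern$shape, pattern$centers, method = method)
  np <- sum(d < cutoff_um)
  structure(list(cutoff_um = cutoff_um, n_peripheral = np,
                 n_internal = length(d) - np,
                 fraction_peripheral = if (length(d)) np / length(d)
                                       else NA_real_),
            class = "periphery_result")
}

#' @export
print.periphery_result <- function(x, ...) {
  cat(sprintf("<periphery_result> %d/%d objects within %.2f um (%.1f%%)\n",
              x$n_peripheral, x$n_peripheral + x$n_internal, x$cutoff_um,
              100 * x$fraction_peripheral))
  invisible(x)
}

# marching-squares contour length at iso level 0.5, with linearly
# interpolated edge crossings on a lightly box-smoothed copy of the binary
# image (raw midpoint crossings on a staircase overestimate smooth contours)
marching_squares_perimeter <- function(mask, smooth_passes = 2) {
  m <- matrix(0, nrow(mask) + 6, ncol(mask) + 6)
  m[4:(nrow(mask) + 3), 4:(ncol(mask) + 3)] <- as.numeric(mask != 0)
  box <- function(x) {
    y <- x
    y[2:(nrow(x) - 1), ] <- (x[1:(nrow(x) - 2), ] + x[2:(nrow(x) - 1), ] +
                             x[3:nrow(x), ]) / 3
    z <- y
    z[, 2:(ncol(x) - 1)] <- (y[, 1:(ncol(x) - 2)] + y[, 2:(ncol(x) - 1)] +
                             y[, 3:ncol(x)]) / 3
    z
  }
  for (i in seq_len(smooth_passes)) m <- box(m)
  a <- m[-nrow(m), -ncol(m)]; b <- m[-1, -ncol(m)]
  cc <- m[-1, -1];            d <- m[-nrow(m), -1]
  iso <- 0.5
  code <- (a > iso) + 2L * (b > iso) + 4L * (cc > iso) + 8L * (d > iso)
  cells <- which(code > 0L & code < 15L)
  if (!length(cells)) return(0)
  # edge crossing offsets within the unit cell: bottom (a-b) along x,
  # right (b-c) along y, top (d-c) along x, left (a-d) along y
  tcross <- function(v0, v1) (iso - v0) / (v1 - v0)
  per <- 0
  seg <- function(p, q) sqrt(sum((p - q)^2))
  for (cell in cells) {
    va <- a[cell]; vb <- b[cell]; vc <- cc[cell]; vd <- d[cell]
    pb <- c(tcross(va, vb), 0)        # bottom edge point
    pr <- c(1, tcross(vb, vc))        # right
    pt <- c(tcross(vd, vc), 1)        # top
    pl <- c(0, tcross(va, vd))        # left
    per <- per + switch(code[cell],
      seg(pl, pb),                    # 1: a
      seg(pb, pr),                    # 2: b
      seg(pl, pr),                    # 3: a,b
      seg(pr, pt),                    # 4: c
      {cmid <- (va + vb + vc + vd) / 4 # 5: a,c saddle
       if (cmid > iso) seg(pl, pt) + seg(pb, pr)
       else seg(pl, pb) + seg(pr, pt)},
      seg(pb, pt),                    # 6: b,c
      seg(pl, pt),                    # 7: a,b,c
      seg(pl, pt),                    # 8: d
      seg(pb, pt),                    # 9: a,d
      {cmid <- (va + vb + vc + vd) / 4 # 10: b,d saddle
       if (cmid > iso) seg(pl, pb) + seg(pr, pt)
       else seg(pl, pt) + seg(pb, pr)},
      seg(pr, pt),                    # 11: a,b,d
      seg(pl, pr),                    # 12: c,d
      seg(pb, pr),                    # 13: a,c,d
      seg(pl, pb)                     # 14: b,c,d
    )
  }
  per
}

#' 2D circularity (form factor) of a binary region
#'
#' `4 * pi * Area / Perimeter^2` with the area from the pixel count and the
#' perimeter from the marching-squares contour length. 1 for a disk;
#' values below ~0.6 indicate lobulated, abnormal nuclear outlines.
#'
#' @param mask2d Binary 2D matrix containing a single region.
#' @return Circularity score in `(0, ~1]`.
#' @export
circularity_2d <- function(mask2d) {
  stopifnot(length(dim(mask2d)) == 2)
  fg <- mask2d != 0
  area <- sum(fg)
  if (area == 0) stop("empty region")
  per <- marching_squares_perimeter(fg)
  4 * pi * area / per^2
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- as.numeric(tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * 256) + 1,
                                     1), 256), nbins = 256))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(256))
  tot <- w[256]; mtot <- mu[256]
  between <- (mtot * w - mu * tot)^2 / (w * (tot - w))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  rng[1] + k / 256 * diff(rng)
}

#' Circularity of a nucleus from a 3D volume
#'
#' Axial maximum-intensity projection of the nuclear channel, Otsu threshold,
#' largest connected component, then [circularity_2d()].
#'
#' @param vol A [labeled_volume()] of the nuclear channel.
#' @return Circularity score of the projected nucleus.
#' @export
nucleus_circularity <- function(vol) {
  stopifnot(is_labeled_volume(vol))
  mip <- apply(vol$voxels, c(1, 2), max)
  fg <- mip >= otsu_threshold(as.vector(mip))
  lab <- cpp_label3d(as.integer(fg), c(dim(fg), 1L), 26L)
  if (max(lab) == 0) stop("no foreground after thresholding")
  biggest <- which.max(tabulate(lab[lab > 0]))
  circularity_2d(matrix(lab == biggest, nrow(fg), ncol(fg)))
}
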