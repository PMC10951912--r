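#' Create a labeled 3D volume
#'
#' A `labeled_volume` is a 3D voxel grid (raw intensities, a binary mask, or
#' non-negative integer labels with 0 = background) together with its physical
#' voxel size. All physical coordinates in the package follow the
#' center-of-voxel convention: voxel `(i, j, k)` (1-based array index) is
#' centered at `(i - 0.5) * spacing` along each axis, expressed in micrometers
#' after conversion from the nanometer spacing.
#'
#' @param voxels 3D numeric, integer or logical array.
#' @param spacing_nm Per-axis voxel size in nanometers (length 1 or 3).
#' @param channel Free-text channel label.
#' @return An object of class `labeled_volume` with fields `voxels`,
#'   `spacing` (nm, length 3) and `channel`.
#' @export
labeled_volume <- function(voxels, spacing_nm = 100, channel = "") {
  if (length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop("`voxels` must be a non-empty 3D array")
  spacing_nm <- as.numeric(spacing_nm)
  if (length(spacing_nm) == 1L) spacing_nm <- rep(spacing_nm, 3L)
  if (length(spacing_nm) != 3L || any(!is.finite(spacing_nm)) ||
      any(spacing_nm <= 0))
    stop("`spacing_nm` must be 3 positive values")
  if (is.integer(voxels) && any(voxels < 0L))
    stop("label grids must contain non-negative integers (0 = background)")
  structure(
    list(voxels = voxels, spacing = spacing_nm, channel = as.character(channel)),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels @ %g x %g x %g nm [%s]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (nzchar(x$channel)) x$channel else "unnamed"))
  invisible(x)
}

#' @rdname labeled_volume
#' @param x Object to test.
#' @export
is_labeled_volume <- function(x) inherits(x, "labeled_volume")

# spacing in µm, length 3
spacing_um <- function(vol) vol$spacing / 1000

is_isotropic <- function(vol) {
  s <- vol$spacing
  diff(range(s)) < 1e-9 * mean(s)
}

#' Resample a volume to an isotropic grid
#'
#' Linear (trilinear) interpolation onto a grid of cubic voxels covering the
#' same physical extent, using the center-of-voxel convention. Binary and
#' label images are resampled by nearest-value rounding of the interpolated
#' field (labels are interpolated as one-hot indicator stacks only when few
#' labels are present; intensity images are interpolated directly).
#'
#' @param vol A [labeled_volume()].
#' @param target_nm Isotropic voxel size of the output, in nanometers.
#' @return A [labeled_volume()] with equal spacing along all axes.
#' @export
resample_isotropic <- function(vol, target_nm = 100) {
  stopifnot(is_labeled_volume(vol))
  if (is_isotropic(vol) && abs(vol$spacing[1] - target_nm) < 1e-9) return(vol)
  s <- spacing_um(vol)
  t_um <- target_nm / 1000
  d <- dim(vol$voxels)
  extent <- d * s
  nd <- pmax(1L, as.integer(round(extent / t_um)))
  gx <- (seq_len(nd[1]) - 0.5) * t_um
  gy <- (seq_len(nd[2]) - 0.5) * t_um
  gz <- (seq_len(nd[3]) - 0.5) * t_um
  pts <- cbind(rep(gx, times = nd[2] * nd[3]),
               rep(rep(gy, each = nd[1]), times = nd[3]),
               rep(gz, each = nd[1] * nd[2]))
  v <- as.numeric(vol$voxels)
  out <- cpp_trilinear(v, d, s, pts)
  arr <- array(out, dim = nd)
  if (is.logical(vol$voxels)) arr <- arr >= 0.5
  labeled_volume(arr, spacing_nm = target_nm, channel = vol$channel)
}

#' Read a TIFF stack as a labeled volume
#'
#' Reads a single- or multi-page grayscale TIFF into a 3D array. TIFF files
#' rarely carry trustworthy 3D spacing metadata, so the voxel size is a
#' required argument.
#'
#' @param path Path to a TIFF file.
#' @param spacing_nm Per-axis voxel size in nanometers.
#' @param channel Channel label to attach.
#' @return A [labeled_volume()].
#' @export
read_volume_tiff <- function(path, spacing_nm, channel = "") {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF volumes requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  # readTIFF returns row x col = y x x; store as (x, y, z)
  arr <- array(0, dim = c(d2[2], d2[1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  labeled_volume(arr, spacing_nm = spacing_nm, channel = channel)
}

#' Write a labeled volume to a multi-page TIFF
#'
#' @param vol A [labeled_volume()]; intensities are rescaled to `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF volumes requires the 'tiff' package")
  v <- vol$voxels
  rng <- range(v)
  v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]))
  tiff::writeTIFF(pages, path)
  invisible(path)
}
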