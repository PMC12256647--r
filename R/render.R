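#' Render a ground-truth scene to a two-channel voxel grid
#'
#' A surrogate for confocal acquisition: each object is painted as a solid
#' sphere of its radius (a voxel is foreground iff its center lies inside
#' the sphere), channels are rendered independently, an anisotropy-aware
#' Gaussian blur emulates the point-spread function, and additive Gaussian
#' noise (clipped at zero) is applied per voxel.  Voxel spacing is given in
#' `(z, y, x)` order to match the axial-coarse geometry of confocal stacks
#' (e.g. 0.3 x 0.06 x 0.06 um at the highest resolutions used in practice;
#' the default here is a coarser in-plane spacing that keeps grids small).
#'
#' @param scene A `coloc_scene` from [generate_coloc_scene()].
#' @param spacing Voxel spacing in um, `(z, y, x)`.
#' @param psf_sigma Physical sigma of the Gaussian blur (um); 0 disables
#'   blurring.
#' @param amplitude Foreground intensity painted inside each sphere.
#' @param background Constant background intensity added to every voxel.
#' @param noise_sd SD of the additive Gaussian noise; 0 disables noise.
#' @param seed Integer seed for the noise (required when `noise_sd > 0`).
#' @param max_voxels Guard against runaway allocation: an error is raised
#'   if the grid (all channels) would exceed this many voxels.
#'
#' @return An object of class `voxel_grid`: list with `channels` (named
#'   list of 3D arrays indexed `[z, y, x]`), `spacing` (um, `(z, y, x)`),
#'   `dim` and `bbox`.
#' @export
render_scene <- function(scene,
                         spacing = c(0.3, 0.1, 0.1),
                         psf_sigma = 0,
                         amplitude = 100,
                         background = 0,
                         noise_sd = 0,
                         seed = NULL,
                         max_voxels = 6e7) {
  stopifnot(inherits(scene, "coloc_scene"),
            length(spacing) == 3, all(spacing > 0),
            psf_sigma >= 0, noise_sd >= 0)
  sz <- spacing[1]; sy <- spacing[2]; sx <- spacing[3]
  d <- c(max(1L, ceiling(scene$bbox[3] / sz)),
         max(1L, ceiling(scene$bbox[2] / sy)),
         max(1L, ceiling(scene$bbox[1] / sx)))
  n_chan <- 2L
  if (prod(d) * n_chan > max_voxels) {
    stop("scene would require ", prod(d) * n_chan,
         " voxels, exceeding max_voxels = ", max_voxels)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("'seed' is required when noise_sd > 0")
    set.seed(as.integer(seed))
  }

  paint <- function(channel) {
    arr <- array(0, dim = d)
    o <- scene$objects[scene$objects$channel == channel, , drop = FALSE]
    for (i in seq_len(nrow(o))) {
      x <- o$x[i]; y <- o$y[i]; z <- o$z[i]; r <- o$radius[i]
      zi <- max(1L, floor((z - r) / sz)):min(d[1], ceiling((z + r) / sz) + 1L)
      yi <- max(1L, floor((y - r) / sy)):min(d[2], ceiling((y + r) / sy) + 1L)
      xi <- max(1L, floor((x - r) / sx)):min(d[3], ceiling((x + r) / sx) + 1L)
      dz2 <- ((zi - 0.5) * sz - z)^2
      dy2 <- ((yi - 0.5) * sy - y)^2
      dx2 <- ((xi - 0.5) * sx - x)^2
      inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r^2
      sub <- arr[zi, yi, xi, drop = FALSE]
      sub[inside] <- amplitude
      arr[zi, yi, xi] <- sub
    }
    if (psf_sigma > 0) {
      arr <- gauss_blur_3d(arr, psf_sigma / spacing)
    }
    arr <- arr + background
    if (noise_sd > 0) {
      arr <- arr + stats::rnorm(length(arr), sd = noise_sd)
      arr[arr < 0] <- 0
    }
    arr
  }

  structure(
    list(channels = list(candidate = paint("candidate"),
                         reference = paint("reference")),
         spacing = spacing,
         dim = d,
         bbox = scene$bbox),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$dim, collapse = " x "), "(z, y, x) voxels,",
      length(x$channels), "channel(s):",
      paste(names(x$channels), collapse = ", "), "\n")
  cat("  spacing (z, y, x) um:", paste(x$spacing, collapse = ", "), "\n")
  invisible(x)
}

# Separable Gaussian blur of a 3D array; sigma_vox gives per-axis sigmas in
# voxel units.  Truncated at 3 sigma with per-position renormalization at
# the array edges (no implicit zero padding bias).
gauss_blur_3d <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3, length(sigma_vox) == 3)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- dim(arr)[ax]
    rad <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-rad, rad), sd = s)
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      idx <- (j - rad):(j + rad)
      ok <- idx >= 1L & idx <= n
      K[idx[ok], j] <- k[ok] / sum(k[ok])
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dm <- dim(a)
    res <- crossprod(K, matrix(a, dm[1], dm[2] * dm[3]))
    dim(res) <- dm
    arr <- aperm(res, order(perm))
  }
  arr
}
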