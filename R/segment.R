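#' Smooth a channel and threshold it to a binary mask
#'
#' Applies a Gaussian pre-smoothing with a physical sigma (converted to a
#' per-axis voxel sigma by dividing by the voxel spacing) followed by a
#' fixed or automatic intensity threshold.  The default smoothing sigma of
#' 0.10 um plays the role of the "surface detail" scale of commercial
#' surface-rendering tools; a voxel enters the mask iff its (smoothed)
#' intensity is strictly greater than the threshold.
#'
#' @param grid A `voxel_grid`.
#' @param channel Channel name (must exist in `grid$channels`).
#' @param sigma_um Physical smoothing sigma in um; 0 disables smoothing.
#' @param threshold A numeric fixed threshold, or `"otsu"` for automatic
#'   between-class-variance maximization (see [auto_threshold()]).
#' @return A logical 3D array `[z, y, x]` with attribute `"threshold"`
#'   giving the threshold actually used.
#' @export
smooth_and_threshold <- function(grid, channel, sigma_um = 0.10,
                                 threshold = "otsu") {
  stopifnot(inherits(grid, "voxel_grid"), sigma_um >= 0)
  if (!channel %in% names(grid$channels)) {
    stop("channel '", channel, "' not present in grid (channels: ",
         paste(names(grid$channels), collapse = ", "), ")")
  }
  arr <- grid$channels[[channel]]
  if (sigma_um > 0) {
    arr <- gauss_blur_3d(arr, sigma_um / grid$spacing)
  }
  thr <- if (identical(threshold, "otsu")) auto_threshold(arr)
         else {
           stopifnot(is.numeric(threshold), length(threshold) == 1)
           threshold
         }
  mask <- arr > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Automatic threshold by between-class variance maximization
#'
#' Otsu's criterion on a fixed-bin histogram: the threshold is the bin
#' edge that maximizes the between-class variance of the two classes it
#' induces.  Errors on a constant image, where no threshold separates
#' anything.
#'
#' @param x Numeric vector or array of intensities.
#' @param n_bins Number of histogram bins.
#' @return A single numeric threshold (use as `intensity > threshold`).
#' @export
auto_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) {
    stop("automatic threshold is undefined on a constant image")
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  valid <- omega > 0 & omega < 1
  sb2 <- rep(-Inf, n_bins)
  sb2[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  # the criterion is flat across an empty gap between modes: take the
  # midpoint of the maximal plateau rather than its lower edge
  at_max <- which(sb2 >= max(sb2) * (1 - 1e-12))
  edges[round(mean(range(at_max))) + 1L]
}

#' Label connected components of a 3D binary mask
#'
#' Maximal connected voxel sets under 6-, 18- or 26-neighborhood
#' connectivity.  Labels are `1..K`, assigned deterministically in order
#' of each component's first voxel in array (column-major, z-fastest)
#' order, so repeated runs on the same mask produce identical labelings.
#'
#' @param mask Logical 3D array `[z, y, x]`.
#' @param connectivity One of 6 (faces), 18 (faces + edges), 26 (faces +
#'   edges + corners).
#' @return Integer 3D array of the same dimensions; 0 is background.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3,
            connectivity %in% c(6L, 18L, 26L))
  d <- dim(mask)
  labels <- array(0L, dim = d)
  idx <- which(mask)
  if (!length(idx)) return(labels)

  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  ord <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  offs <- switch(as.character(connectivity),
                 "6" = offs[ord == 1, ],
                 "18" = offs[ord <= 2, ],
                 "26" = offs)
  # forward half: each unordered neighbor pair is visited once
  fwd <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  offs <- offs[fwd, , drop = FALSE]

  coords <- arrayInd(idx, d)
  rankmap <- integer(prod(d))
  rankmap[idx] <- seq_along(idx)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    dz <- offs$dz[k]; dy <- offs$dy[k]; dx <- offs$dx[k]
    zc <- coords[, 1] + dz; yc <- coords[, 2] + dy; xc <- coords[, 3] + dx
    sel <- zc >= 1L & zc <= d[1] & yc >= 1L & yc <= d[2] &
      xc >= 1L & xc <= d[3]
    if (!any(sel)) next
    nidx <- idx[sel] + dz + dy * d[1] + dx * d[1] * d[2]
    nb <- rankmap[nidx]
    hit <- nb > 0L
    if (any(hit)) {
      edges[[k]] <- cbind(which(sel)[hit], nb[hit])
    }
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el)) {
    g <- igraph::add_edges(g, t(el))
  }
  membership <- igraph::components(g)$membership
  # renumber by first appearance along ascending linear index
  relabel <- match(membership, unique(membership))
  labels[idx] <- relabel
  labels
}

#' Measure labeled objects: voxel count, volume, centroid, radius
#'
#' For every label, collects the voxel count, the physical volume
#' `count * s_z * s_y * s_x`, the unweighted centroid of voxel centers
#' (the center of voxel index `i` along an axis of spacing `s` sits at
#' `(i - 0.5) * s` with 1-based indices, i.e. `(index + 0.5) * s` in
#' 0-based convention) and the equivalent-sphere radius
#' `(3 V / (4 pi))^(1/3)`.
#'
#' @param labels Integer 3D array from [label_components()].
#' @param spacing Voxel spacing in um, `(z, y, x)`.
#' @param channel Optional channel name recorded per object.
#' @return An object table: data frame with columns `object_id`,
#'   `channel`, `voxel_count`, `volume_um3`, `x_um`, `y_um`, `z_um`,
#'   `radius_um`.
#' @export
measure_objects <- function(labels, spacing, channel = NA_character_) {
  stopifnot(length(dim(labels)) == 3, length(spacing) == 3,
            all(spacing > 0))
  empty <- data.frame(object_id = integer(0), channel = character(0),
                      voxel_count = integer(0), volume_um3 = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), radius_um = numeric(0),
                      stringsAsFactors = FALSE)
  idx <- which(labels > 0L)
  if (!length(idx)) return(empty)
  lab <- labels[idx]
  n_obj <- max(lab)
  counts <- tabulate(lab, nbins = n_obj)
  coords <- arrayInd(idx, dim(labels))
  sz <- spacing[1]; sy <- spacing[2]; sx <- spacing[3]
  sums <- rowsum(cbind((coords[, 1] - 0.5) * sz,
                       (coords[, 2] - 0.5) * sy,
                       (coords[, 3] - 0.5) * sx), lab)
  vol <- counts * sz * sy * sx
  data.frame(
    object_id = seq_len(n_obj),
    channel = channel,
    voxel_count = counts,
    volume_um3 = vol,
    x_um = sums[, 3] / counts,
    y_um = sums[, 2] / counts,
    z_um = sums[, 1] / counts,
    radius_um = (3 * vol / (4 * pi))^(1 / 3),
    stringsAsFactors = FALSE
  )
}

#' Exclude small objects from an object table
#'
#' Removes renderings likely to be false objects from background
#' fluorescence.  By default objects with fewer than 15 voxels are
#' excluded (objects with exactly `min_voxels` voxels are retained); a
#' physical-volume threshold in um^3 can be used instead via
#' `min_volume_um3`, since voxel counts depend on the imaging spacing.
#' Order and object ids are preserved.
#'
#' @param table An object table (see [measure_objects()]).
#' @param min_voxels Minimum voxel count retained (default 15).
#' @param min_volume_um3 If non-`NULL`, threshold on `volume_um3` instead.
#' @return The filtered object table.
#' @export
filter_min_volume <- function(table, min_voxels = 15L,
                              min_volume_um3 = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(min_volume_um3)) {
    stopifnot(min_volume_um3 >= 0)
    keep <- table$volume_um3 >= min_volume_um3
  } else {
    stopifnot(min_voxels >= 0)
    keep <- table$voxel_count >= min_voxels
  }
  table[keep, , drop = FALSE]
}

#' Segment one channel of a voxel grid into an object table
#'
#' Composes [smooth_and_threshold()], [label_components()],
#' [measure_objects()] and [filter_min_volume()].
#'
#' @inheritParams smooth_and_threshold
#' @inheritParams label_components
#' @inheritParams filter_min_volume
#' @return The filtered object table, with attribute `"threshold"`.
#' @export
segment_channel <- function(grid, channel, sigma_um = 0.10,
                            threshold = "otsu", connectivity = 26L,
                            min_voxels = 15L, min_volume_um3 = NULL) {
  mask <- smooth_and_threshold(grid, channel, sigma_um = sigma_um,
                               threshold = threshold)
  labels <- label_components(mask, connectivity = connectivity)
  tab <- measure_objects(labels, grid$spacing, channel = channel)
  tab <- filter_min_volume(tab, min_voxels = min_voxels,
                           min_volume_um3 = min_volume_um3)
  attr(tab, "threshold") <- attr(mask, "threshold")
  tab
}
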