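#' Write / read a voxel grid as multi-page TIFF with a YAML sidecar
#'
#' The TIFF is written channel-major (all Z pages of the first channel,
#' then the next channel) as 16-bit pages; intensities are scaled by a
#' factor recorded in the sidecar so values round-trip to within the
#' 16-bit quantization step.  The sidecar YAML records the channel names,
#' Z-page count, voxel spacing (z, y, x, um) and the intensity scale.
#'
#' @param grid A `voxel_grid`.
#' @param tiff_path Output TIFF path; the sidecar defaults to
#'   `<tiff_path>.yaml`.
#' @param sidecar_path Optional explicit sidecar path.
#' @return The TIFF path, invisibly (`write_voxel_grid`); a `voxel_grid`
#'   (`read_voxel_grid`).
#' @export
write_voxel_grid <- function(grid, tiff_path,
                             sidecar_path = paste0(tiff_path, ".yaml")) {
  stopifnot(inherits(grid, "voxel_grid"))
  top <- max(1e-12, max(vapply(grid$channels, max, numeric(1))))
  pages <- list()
  for (ch in names(grid$channels)) {
    arr <- grid$channels[[ch]] / top
    for (z in seq_len(dim(arr)[1])) {
      pages[[length(pages) + 1L]] <- arr[z, , ]
    }
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  yaml::write_yaml(list(channels = as.list(names(grid$channels)),
                        n_z = dim(grid$channels[[1]])[1],
                        spacing_zyx_um = as.list(grid$spacing),
                        intensity_scale = top,
                        bbox_xyz_um = as.list(grid$bbox)),
                   sidecar_path)
  invisible(tiff_path)
}

#' @rdname write_voxel_grid
#' @export
read_voxel_grid <- function(tiff_path,
                            sidecar_path = paste0(tiff_path, ".yaml")) {
  if (!file.exists(sidecar_path)) {
    stop("spacing sidecar not found: ", sidecar_path)
  }
  meta <- yaml::read_yaml(sidecar_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  n_z <- meta$n_z
  chans <- unlist(meta$channels)
  stopifnot(length(pages) == n_z * length(chans))
  d2 <- dim(pages[[1]])
  channels <- list()
  for (i in seq_along(chans)) {
    arr <- array(0, dim = c(n_z, d2[1], d2[2]))
    for (z in seq_len(n_z)) {
      arr[z, , ] <- pages[[(i - 1L) * n_z + z]]
    }
    channels[[chans[i]]] <- arr * meta$intensity_scale
  }
  structure(
    list(channels = channels,
         spacing = as.numeric(unlist(meta$spacing_zyx_um)),
         dim = dim(channels[[1]]),
         bbox = as.numeric(unlist(meta$bbox_xyz_um))),
    class = "voxel_grid"
  )
}

#' Write / read an object table CSV
#'
#' Fixed column order: `object_id, channel, voxel_count, volume_um3, x_um,
#' y_um, z_um, radius_um`.
#'
#' @param table An object table.
#' @param path CSV path.
#' @return `path` invisibly (`write_object_table`); an object table
#'   (`read_object_table`).
#' @export
write_object_table <- function(table, path) {
  cols <- c("object_id", "channel", "voxel_count", "volume_um3",
            "x_um", "y_um", "z_um", "radius_um")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_object_table
#' @export
read_object_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
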