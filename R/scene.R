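#' Generate a ground-truth two-channel bouton scene
#'
#' Places spherical "bouton" objects in a 3D bounding box for two channels,
#' a reference channel (e.g. an anterograde tracer such as CTB) and a
#' candidate channel (e.g. VGluT2 immunolabel).  Every reference object is
#' paired with one overlapping candidate object; `n_extra_candidate`
#' additional candidate objects are placed without an overlapping partner.
#' The ground-truth candidate colocalization fraction is therefore exactly
#' `n_reference / (n_reference + n_extra_candidate)`.
#'
#' Radii are drawn from a lognormal law (right-skewed, as bouton sizes are)
#' truncated to `radius_range`.  A paired candidate center is offset from
#' its reference center by a uniformly random vector of length at most
#' `min(pair_offset_max, 0.5 * min(r_ref, r_cand))`, which guarantees the
#' pair overlaps under the interbouton criterion.  All other object pairs
#' (same channel, and cross-channel pairs that are not a designated
#' pairing) are kept at a surface-to-surface gap of at least
#' `min_separation` by rejection sampling, so that unpaired objects never
#' overlap and same-channel objects never merge when rendered.
#'
#' @param n_reference Number of reference-channel objects (each gets one
#'   paired, overlapping candidate object).
#' @param n_extra_candidate Number of unpaired candidate-channel objects.
#' @param radius_meanlog,radius_sdlog Lognormal parameters of the bouton
#'   radius law, in log-micrometers (default: median 0.5 um, sdlog 0.3).
#' @param radius_range Truncation bounds for radii (um); draws outside are
#'   resampled.
#' @param pair_offset_max Upper bound (um) on the center offset of a paired
#'   candidate; the effective bound is never more than half the smaller of
#'   the two radii so the pair always overlaps.
#' @param bbox Numeric length-3: extents of the bounding box in um, in
#'   (x, y, z) order.
#' @param min_separation Minimum surface-to-surface gap (um) between any
#'   two objects that are not a designated pair.
#' @param seed Integer seed; all randomness in the call flows from it.
#' @param max_attempts Rejection-sampling cap per object before a placement
#'   failure error is raised.
#'
#' @return An object of class `coloc_scene`: a list with elements `bbox`,
#'   `objects` (data frame with columns `id`, `channel`, `x`, `y`, `z`,
#'   `radius`, `paired_id`), `coloc_fraction`, `n_reference`,
#'   `n_extra_candidate`, `seed`.
#' @export
generate_coloc_scene <- function(n_reference,
                                 n_extra_candidate,
                                 radius_meanlog = log(0.5),
                                 radius_sdlog = 0.3,
                                 radius_range = c(0.3, 2.0),
                                 pair_offset_max = Inf,
                                 bbox = c(24, 24, 10),
                                 min_separation = 1.0,
                                 seed,
                                 max_attempts = 10000) {
  if (missing(seed)) stop("'seed' is required for scene generation")
  stopifnot(length(bbox) == 3, all(bbox > 0),
            n_reference >= 0, n_extra_candidate >= 0,
            min_separation >= 0, pair_offset_max > 0,
            length(radius_range) == 2, radius_range[1] > 0,
            radius_range[2] >= radius_range[1])
  set.seed(as.integer(seed))

  n_total <- 2L * n_reference + n_extra_candidate
  centers <- matrix(NA_real_, n_total, 3)
  radii <- numeric(n_total)
  chan <- character(n_total)
  paired <- rep(NA_integer_, n_total)
  n_placed <- 0L

  draw_radius <- function() {
    for (i in seq_len(1000L)) {
      r <- stats::rlnorm(1, radius_meanlog, radius_sdlog)
      if (r >= radius_range[1] && r <= radius_range[2]) return(r)
    }
    stop("could not draw a radius inside 'radius_range'")
  }
  inside <- function(center, r) {
    all(center >= r) && all(center <= bbox - r)
  }
  # TRUE iff 'center' keeps a min_separation gap from all placed objects,
  # except the one at row 'exempt' (a designated pairing).
  separated <- function(center, r, exempt = 0L) {
    if (n_placed == 0L) return(TRUE)
    rows <- seq_len(n_placed)
    if (exempt > 0L) rows <- rows[rows != exempt]
    if (!length(rows)) return(TRUE)
    d <- sqrt(colSums((t(centers[rows, , drop = FALSE]) - center)^2))
    all(d >= radii[rows] + r + min_separation)
  }
  accept <- function(center, r, channel, paired_id = NA_integer_) {
    n_placed <<- n_placed + 1L
    centers[n_placed, ] <<- center
    radii[n_placed] <<- r
    chan[n_placed] <<- channel
    paired[n_placed] <<- paired_id
    n_placed
  }
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }

  for (i in seq_len(n_reference)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      r_ref <- draw_radius()
      r_cand <- draw_radius()
      if (any(bbox < 2 * max(r_ref, r_cand))) next
      c_ref <- r_ref + stats::runif(3) * (bbox - 2 * r_ref)
      off_len <- stats::runif(1, 0, min(pair_offset_max,
                                        0.5 * min(r_ref, r_cand)))
      c_cand <- c_ref + rand_dir() * off_len
      if (!inside(c_cand, r_cand)) next
      if (!separated(c_ref, r_ref)) next
      ref_row <- n_placed + 1L
      if (!separated(c_cand, r_cand, exempt = 0L)) {
        # candidate checked against everything already placed; its own
        # reference is not placed yet so no exemption is needed here
        next
      }
      i_ref <- accept(c_ref, r_ref, "reference")
      i_cand <- accept(c_cand, r_cand, "candidate", paired_id = i_ref)
      paired[i_ref] <- i_cand
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("placement failure: could not place reference/candidate pair ",
           i, " after ", max_attempts,
           " attempts; enlarge 'bbox' or reduce 'min_separation'")
    }
  }

  for (i in seq_len(n_extra_candidate)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      r <- draw_radius()
      if (any(bbox < 2 * r)) next
      ctr <- r + stats::runif(3) * (bbox - 2 * r)
      if (!separated(ctr, r)) next
      accept(ctr, r, "candidate")
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("placement failure: could not place unpaired candidate ", i,
           " after ", max_attempts, " attempts")
    }
  }

  objects <- data.frame(
    id = seq_len(n_total),
    channel = chan,
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = radii,
    paired_id = paired,
    stringsAsFactors = FALSE
  )
  n_candidate <- n_reference + n_extra_candidate
  structure(
    list(
      bbox = bbox,
      objects = objects,
      coloc_fraction = if (n_candidate > 0) n_reference / n_candidate
                       else NA_real_,
      n_reference = n_reference,
      n_extra_candidate = n_extra_candidate,
      seed = as.integer(seed)
    ),
    class = "coloc_scene"
  )
}

#' @export
print.coloc_scene <- function(x, ...) {
  cat("coloc_scene:", x$n_reference, "reference objects,",
      x$n_reference + x$n_extra_candidate, "candidate objects\n")
  cat("  bbox (um):", paste(signif(x$bbox, 4), collapse = " x "), "\n")
  cat("  ground-truth candidate colocalization fraction:",
      signif(x$coloc_fraction, 4), "\n")
  invisible(x)
}

#' Convert a ground-truth scene to per-channel object tables
#'
#' Produces the same table layout as [measure_objects()] directly from the
#' ground-truth centers and radii, bypassing rendering and segmentation.
#' Volumes are the exact sphere volumes, so the radius/volume consistency
#' invariant holds by construction.  Useful as a noiseless oracle input to
#' [summarize_image()].
#'
#' @param scene A `coloc_scene`.
#' @return A named list with elements `candidate` and `reference`, each an
#'   object table (see [measure_objects()] for columns; `voxel_count` is
#'   `NA` as no voxelization occurred).
#' @export
scene_object_tables <- function(scene) {
  stopifnot(inherits(scene, "coloc_scene"))
  mk <- function(channel) {
    o <- scene$objects[scene$objects$channel == channel, , drop = FALSE]
    data.frame(
      object_id = o$id,
      channel = channel,
      voxel_count = NA_integer_,
      volume_um3 = 4 / 3 * pi * o$radius^3,
      x_um = o$x, y_um = o$y, z_um = o$z,
      radius_um = o$radius,
      stringsAsFactors = FALSE
    )
  }
  list(candidate = mk("candidate"), reference = mk("reference"))
}

#' Sample a soma-size dataset from a normal mixture
#'
#' Draws soma areas from a mixture of normal components, recording the true
#' component of every draw.  The defaults emulate the two soma populations
#' of the thalamic laminae this workflow was designed for: an
#' interneuron-like component near 125.2 um^2 and a relay-like component
#' near 251.7 um^2.  Draws that would be non-positive are resampled (a
#' physical area cannot be <= 0).
#'
#' @param components Data frame (or matrix) with columns `weight`, `mean`,
#'   `sd` (one row per component).  Weights must sum to 1 (+/- 1e-9) and
#'   SDs must be positive.
#' @param n Number of cells to draw.
#' @param seed Integer seed.
#' @param lamina,gaba_status Optional labels stored per cell.
#' @return A `soma_dataset` data frame with columns `area_um2`, `lamina`,
#'   `gaba_status`, `component` (true component index, ascending mean
#'   order of `components` as given).
#' @export
sample_soma_sizes <- function(components = data.frame(
                                weight = c(0.5, 0.5),
                                mean = c(125.2, 251.7),
                                sd = c(30, 60)),
                              n,
                              seed,
                              lamina = NA_character_,
                              gaba_status = NA_character_) {
  if (missing(seed)) stop("'seed' is required")
  components <- as.data.frame(components)
  stopifnot(all(c("weight", "mean", "sd") %in% names(components)),
            n >= 0)
  if (abs(sum(components$weight) - 1) > 1e-9) {
    stop("component weights must sum to 1")
  }
  if (any(components$sd <= 0)) stop("component SDs must be positive")
  set.seed(as.integer(seed))
  k <- nrow(components)
  if (n == 0) {
    return(structure(data.frame(area_um2 = numeric(0),
                                lamina = character(0),
                                gaba_status = character(0),
                                component = integer(0),
                                stringsAsFactors = FALSE),
                     class = c("soma_dataset", "data.frame")))
  }
  comp <- sample.int(k, n, replace = TRUE, prob = components$weight)
  area <- stats::rnorm(n, components$mean[comp], components$sd[comp])
  bad <- which(area <= 0)
  while (length(bad)) {
    area[bad] <- stats::rnorm(length(bad), components$mean[comp[bad]],
                              components$sd[comp[bad]])
    bad <- bad[area[bad] <= 0]
  }
  structure(
    data.frame(area_um2 = area,
               lamina = rep_len(lamina, n),
               gaba_status = rep_len(gaba_status, n),
               component = comp,
               stringsAsFactors = FALSE),
    class = c("soma_dataset", "data.frame")
  )
}

#' Write / read a ground-truth scene as CSV
#'
#' One row per object with columns `channel, x, y, z, radius, paired_id`;
#' the bounding box and requested fraction are stored as commented header
#' lines so a scene round-trips through a single plain-text file.
#'
#' @param scene A `coloc_scene`.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_scene_csv`); a `coloc_scene`
#'   (`read_scene_csv`).
#' @export
write_scene_csv <- function(scene, path) {
  stopifnot(inherits(scene, "coloc_scene"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# bbox_um: ", paste(scene$bbox, collapse = ",")),
    paste0("# n_reference: ", scene$n_reference),
    paste0("# n_extra_candidate: ", scene$n_extra_candidate),
    paste0("# seed: ", scene$seed)
  ), con)
  utils::write.csv(scene$objects, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scene_csv
#' @export
read_scene_csv <- function(path) {
  header <- readLines(path, n = 10L)
  header <- header[startsWith(header, "# ")]
  get <- function(key) {
    line <- header[startsWith(header, paste0("# ", key, ":"))]
    sub(paste0("# ", key, ": *"), "", line)
  }
  bbox <- as.numeric(strsplit(get("bbox_um"), ",")[[1]])
  objects <- utils::read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE)
  n_reference <- as.integer(get("n_reference"))
  n_extra <- as.integer(get("n_extra_candidate"))
  n_candidate <- n_reference + n_extra
  structure(
    list(bbox = bbox, objects = objects,
         coloc_fraction = if (n_candidate > 0) n_reference / n_candidate
                          else NA_real_,
         n_reference = n_reference,
         n_extra_candidate = n_extra,
         seed = as.integer(get("seed"))),
    class = "coloc_scene"
  )
}
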