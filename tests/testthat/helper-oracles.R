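# Independent oracles used across the suite.  These deliberately take the
# slow, obvious route (queues, double loops, full enumeration) so they
# share no code path with the package implementations they check.

# Breadth-first flood fill over a logical 3D mask.
flood_fill_labels <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ord <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[ord == 1, , drop = FALSE],
                 "18" = offs[ord <= 2, , drop = FALSE],
                 "26" = offs)
  labels <- array(0L, dim = d)
  next_label <- 0L
  for (lin in which(mask)) {
    if (labels[lin] != 0L) next
    next_label <- next_label + 1L
    queue <- list(arrayInd(lin, d)[1, ])
    labels[lin] <- next_label
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        w <- v + offs[k, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- next_label
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  labels
}

# Voxel-sets of each component as a canonical (sorted) list, for
# partition comparison independent of label numbering.
component_partition <- function(labels) {
  idx <- which(labels > 0L)
  parts <- split(idx, labels[idx])
  unname(parts[order(vapply(parts, min, numeric(1)))])
}

# Double-loop exact nearest neighbor; ties toward lowest id.
brute_nn <- function(from, to) {
  out <- data.frame(object_id = from$object_id,
                    neighbor_id = NA_integer_,
                    center_distance_um = NA_real_)
  for (i in seq_len(nrow(from))) {
    best_d <- Inf; best_id <- NA_integer_
    for (j in seq_len(nrow(to))) {
      dij <- sqrt((from$x_um[i] - to$x_um[j])^2 +
                    (from$y_um[i] - to$y_um[j])^2 +
                    (from$z_um[i] - to$z_um[j])^2)
      if (dij < best_d ||
          (dij == best_d && to$object_id[j] < best_id)) {
        best_d <- dij; best_id <- to$object_id[j]
      }
    }
    out$neighbor_id[i] <- best_id
    out$center_distance_um[i] <- best_d
  }
  out
}

# Two-sided exact Mann-Whitney p by full enumeration of all
# choose(n1 + n2, n1) assignments of the pooled midranks.
enum_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Welch's t and Welch-Satterthwaite df from the textbook formulas.
welch_formula <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# Random object table of n centroids in a box, with ids offset so the two
# channels never share ids.
random_table <- function(n, channel, id_offset = 0L, box = c(10, 10, 5)) {
  data.frame(object_id = id_offset + seq_len(n),
             channel = channel,
             voxel_count = NA_integer_,
             volume_um3 = rep(4 / 3 * pi * 0.5^3, n),
             x_um = runif(n, 0, box[1]),
             y_um = runif(n, 0, box[2]),
             z_um = runif(n, 0, box[3]),
             radius_um = rep(0.5, n))
}

# Minimal object table from explicit centers/radii.
table_from_points <- function(xyz, radii, channel = "candidate",
                              ids = seq_len(nrow(xyz))) {
  data.frame(object_id = ids, channel = channel,
             voxel_count = NA_integer_,
             volume_um3 = 4 / 3 * pi * radii^3,
             x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
             radius_um = radii)
}
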