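make_grid <- function(arr, spacing = c(0.3, 0.1, 0.1)) {
  structure(list(channels = list(candidate = arr), spacing = spacing,
                 dim = dim(arr), bbox = rev(dim(arr)) * rev(spacing)),
            class = "voxel_grid")
}

test_that("thresholding: fixed thresholds select exactly the bright voxels", {
  arr <- array(0, dim = c(4, 6, 6))
  g <- make_grid(arr)
  m <- smooth_and_threshold(g, "candidate", sigma_um = 0, threshold = 10)
  expect_false(any(m))
  expect_error(smooth_and_threshold(g, "missing", threshold = 10),
               "not present")

  arr[2, 2:3, 2:3] <- 100
  arr[4, 5:6, 5:6] <- 100
  g2 <- make_grid(arr)
  m2 <- smooth_and_threshold(g2, "candidate", sigma_um = 0,
                             threshold = 50)
  expect_equal(as.vector(m2), as.vector(arr > 50))
  expect_equal(sum(m2), 8)
})

test_that("automatic threshold separates a bimodal histogram", {
  set.seed(31)
  x <- c(rnorm(4000, 10, 2), rnorm(1000, 100, 5))
  thr <- auto_threshold(x)
  expect_gt(thr, 10 + 3 * 2)
  expect_lt(thr, 100 - 3 * 5)
  # exhaustive oracle: scan every candidate cut between sorted unique
  # values; the returned threshold must attain the maximal between-class
  # variance (up to histogram resolution).  The criterion is flat across
  # the empty gap between modes, so positions are compared by objective,
  # not by location.
  bcv_at <- function(ct) {
    lo <- x[x <= ct]; hi <- x[x > ct]
    length(lo) / length(x) * length(hi) / length(x) *
      (mean(hi) - mean(lo))^2
  }
  ux <- sort(unique(x))
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  bcv_max <- max(vapply(cuts, bcv_at, numeric(1)))
  expect_gt(bcv_at(thr) / bcv_max, 0.999)

  expect_error(auto_threshold(rep(5, 100)), "constant")
})

test_that("connectivity semantics: corner contact joins only at 26", {
  m <- array(FALSE, dim = c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE  # touches (1,1,1) only at a corner
  expect_equal(max(label_components(m, 26)), 1)
  expect_equal(max(label_components(m, 18)), 2)
  expect_equal(max(label_components(m, 6)), 2)

  m2 <- array(FALSE, dim = c(4, 8, 8))
  m2[2, 2:3, 2:3] <- TRUE
  m2[3, 6:7, 6:7] <- TRUE
  expect_equal(max(label_components(m2, 26)), 2)
})

test_that("component labeling matches a flood-fill oracle on random masks", {
  set.seed(77)
  for (conn in c(6L, 18L, 26L)) {
    for (rep in 1:3) {
      m <- array(runif(14 * 13 * 12) < 0.2, dim = c(14, 13, 12))
      got <- label_components(m, conn)
      want <- flood_fill_labels(m, conn)
      expect_equal(max(got), max(want))
      expect_identical(component_partition(got),
                       component_partition(want))
    }
  }
})

test_that("labeling order is deterministic (first-voxel order)", {
  set.seed(5)
  m <- array(runif(10^3) < 0.15, dim = c(10, 10, 10))
  expect_identical(label_components(m, 26), label_components(m, 26))
  lab <- label_components(m, 26)
  firsts <- vapply(component_partition(lab), min, numeric(1))
  expect_identical(order(firsts), seq_along(firsts))
})

test_that("object measurements follow the voxel-center convention", {
  # single voxel at 0-based (z, y, x) = (2, 3, 4)
  lab <- array(0L, dim = c(5, 6, 7))
  lab[3, 4, 5] <- 1L
  tab <- measure_objects(lab, spacing = c(0.3, 0.06, 0.06))
  expect_equal(tab$volume_um3, 0.3 * 0.06 * 0.06)
  expect_equal(tab$volume_um3, 0.00108)
  expect_equal(c(tab$x_um, tab$y_um, tab$z_um), c(0.27, 0.21, 0.75))

  # 2x2x2 block centered measurement
  lab2 <- array(0L, dim = c(6, 6, 6))
  lab2[2:3, 2:3, 2:3] <- 1L
  tab2 <- measure_objects(lab2, spacing = c(0.2, 0.1, 0.1))
  expect_equal(tab2$voxel_count, 8)
  expect_equal(tab2$volume_um3, 8 * 0.2 * 0.1 * 0.1)
  # voxels 2 and 3 have centers at 1.5 s and 2.5 s -> block center 2 s
  expect_equal(c(tab2$z_um, tab2$y_um, tab2$x_um),
               c(2 * 0.2, 2 * 0.1, 2 * 0.1))

  # equivalent-sphere radius from volume
  expect_equal((3 * 0.0185 / (4 * pi))^(1 / 3), 0.16407, tolerance = 1e-4)
  lab3 <- array(0L, dim = c(2, 2, 2)); lab3[1, 1, 1] <- 1L
  t3 <- measure_objects(lab3, spacing = rep(0.0185^(1 / 3), 3))
  expect_equal(t3$radius_um, (3 * 0.0185 / (4 * pi))^(1 / 3),
               tolerance = 1e-9)

  expect_equal(nrow(measure_objects(array(0L, dim = c(3, 3, 3)),
                                    c(1, 1, 1))), 0)
})

test_that("radius-volume consistency holds for every emitted object", {
  set.seed(19)
  m <- array(runif(12^3) < 0.25, dim = c(12, 12, 12))
  tab <- measure_objects(label_components(m, 26), c(0.3, 0.06, 0.06))
  expect_true(all(abs(tab$radius_um -
                        (3 * tab$volume_um3 / (4 * pi))^(1 / 3)) < 1e-9))
})

test_that("minimum-volume filter keeps exactly the objects at or above 15 voxels", {
  tab <- data.frame(object_id = 1:5, channel = "candidate",
                    voxel_count = c(3L, 14L, 15L, 20L, 100L),
                    volume_um3 = c(3, 14, 15, 20, 100) * 0.00108,
                    x_um = 0, y_um = 0, z_um = 0, radius_um = 0.1)
  kept <- filter_min_volume(tab)
  expect_equal(kept$voxel_count, c(15L, 20L, 100L))
  expect_equal(kept$object_id, c(3L, 4L, 5L))
  expect_equal(nrow(filter_min_volume(tab[0, ])), 0)
  expect_equal(nrow(filter_min_volume(tab[tab$voxel_count < 15, ])), 0)
  # physical-volume mode
  kept2 <- filter_min_volume(tab, min_volume_um3 = 0.0185)
  expect_equal(kept2$object_id, c(4L, 5L))
})

test_that("noiseless scene segmentation recovers count and centroids", {
  sc <- generate_coloc_scene(10, 5, seed = 13, bbox = c(14, 14, 8))
  g <- render_scene(sc)
  for (ch in c("candidate", "reference")) {
    tab <- segment_channel(g, ch, sigma_um = 0, threshold = 50)
    truth <- sc$objects[sc$objects$channel == ch, ]
    expect_equal(nrow(tab), nrow(truth))
    diag_um <- sqrt(sum(g$spacing^2))
    for (i in seq_len(nrow(truth))) {
      d <- sqrt((tab$x_um - truth$x[i])^2 + (tab$y_um - truth$y[i])^2 +
                  (tab$z_um - truth$z[i])^2)
      expect_lt(min(d), diag_um)
    }
  }
})

test_that("voxel grids round-trip through TIFF plus sidecar", {
  sc <- generate_coloc_scene(3, 1, seed = 21, bbox = c(6, 6, 4))
  g <- render_scene(sc, background = 5, noise_sd = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_voxel_grid(g, path)
  back <- read_voxel_grid(path)
  expect_equal(back$spacing, g$spacing)
  expect_equal(names(back$channels), names(g$channels))
  # 16-bit quantization bound
  top <- max(g$channels$candidate, g$channels$reference)
  expect_lt(max(abs(back$channels$candidate - g$channels$candidate)),
            top / 65535 * 1.01)
  expect_error(read_voxel_grid(path, sidecar_path = "no-such.yaml"),
               "sidecar")
})
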