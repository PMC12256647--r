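test_that("nearest cross-channel neighbor: basic geometry and tie rule", {
  cand <- table_from_points(matrix(c(0, 0, 0), 1), 0.5, "candidate", 1L)
  refs <- table_from_points(rbind(c(1, 0, 0), c(3, 0, 0)), c(0.5, 0.5),
                            "reference", c(10L, 11L))
  nn <- nearest_cross_channel(cand, refs)
  expect_equal(nn$candidate$neighbor_id, 10L)
  expect_equal(nn$candidate$center_distance_um, 1.0)
  # reference -> candidate direction also computed
  expect_equal(nn$reference$neighbor_id, c(1L, 1L))

  # single object per channel: mutual nearest neighbors
  one <- nearest_cross_channel(cand, refs[1, ])
  expect_equal(one$candidate$neighbor_id, one$reference$object_id)
  expect_equal(one$reference$neighbor_id, one$candidate$object_id)

  # equidistant neighbors resolve to the lowest id
  refs_tie <- table_from_points(rbind(c(2, 0, 0), c(-2, 0, 0)),
                                c(0.5, 0.5), "reference", c(21L, 20L))
  nn_tie <- nearest_cross_channel(cand, refs_tie)
  expect_equal(nn_tie$candidate$neighbor_id, 20L)

  expect_error(nearest_cross_channel(cand[0, ], refs), "candidate")
  expect_error(nearest_cross_channel(cand, refs[0, ]), "reference")
})

test_that("nearest-neighbor assignment equals the brute-force scan", {
  set.seed(101)
  for (rep in 1:5) {
    cand <- random_table(20, "candidate")
    refs <- random_table(20, "reference", id_offset = 100L)
    nn <- nearest_cross_channel(cand, refs)
    expect_equal(nn$candidate$neighbor_id,
                 brute_nn(cand, refs)$neighbor_id)
    expect_equal(nn$reference$neighbor_id,
                 brute_nn(refs, cand)$neighbor_id)
  }
})

test_that("interbouton distance arithmetic and the strict-zero boundary", {
  expect_equal(interbouton_distance(1.0, 0.6, 0.5), -0.1)
  expect_equal(interbouton_distance(1.0, 0.4, 0.5), 0.1)
  expect_equal(interbouton_distance(1.1, 0.6, 0.5), 0.0)
  # touching spheres (gap exactly 0, binary-exact arithmetic) are NOT
  # colocalized, so neither channel has any colocalization
  cand <- table_from_points(matrix(c(0, 0, 0), 1), 0.5, "candidate", 1L)
  refs <- table_from_points(matrix(c(1, 0, 0), 1), 0.5, "reference", 2L)
  expect_error(
    suppressWarnings(summarize_image(cand, refs)),
    "undefined")  # nothing colocalized in either channel
  expect_error(interbouton_distance(1, -0.1, 0.5), "positive")
  expect_error(interbouton_distance(-1, 0.1, 0.5), ">= 0")
})

test_that("percentages and CI follow their definitions", {
  expect_equal(percent_colocalized(c(rep(TRUE, 4), rep(FALSE, 6))), 40)
  expect_equal(percent_colocalized(rep(TRUE, 7)), 100)
  expect_equal(percent_colocalized(rep(FALSE, 7)), 0)
  expect_error(percent_colocalized(logical(0)), "zero objects")

  expect_equal(compute_ci(50, 50), 1.0)
  expect_equal(compute_ci(40, 80), 0.5)
  expect_error(compute_ci(30, 0), "undefined")
})

test_that("CI of a table against itself is exactly 1", {
  set.seed(55)
  tab <- random_table(40, "candidate")
  other <- tab
  other$object_id <- other$object_id + 1000L
  other$channel <- "reference"
  s <- suppressWarnings(summarize_image(tab, other))
  expect_identical(s$summary$ci, 1)
  expect_equal(s$summary$pct_candidate_coloc, 100)
})

test_that("CI is scale-free in counts: duplicating objects changes nothing", {
  sc <- generate_coloc_scene(20, 10, seed = 31, bbox = c(18, 18, 8))
  tabs <- scene_object_tables(sc)
  s1 <- suppressWarnings(summarize_image(tabs$candidate, tabs$reference))
  dup <- function(t, shift) {
    t2 <- t
    t2$object_id <- t2$object_id + shift
    rbind(t, t2)
  }
  s2 <- suppressWarnings(summarize_image(dup(tabs$candidate, 10000L),
                                         dup(tabs$reference, 10000L)))
  expect_equal(s2$summary$pct_candidate_coloc,
               s1$summary$pct_candidate_coloc)
  expect_equal(s2$summary$pct_reference_coloc,
               s1$summary$pct_reference_coloc)
  expect_equal(s2$summary$ci, s1$summary$ci)
})

test_that("adding unpaired candidates strictly decreases the CI", {
  sc <- generate_coloc_scene(20, 0, seed = 8, bbox = c(20, 20, 8))
  tabs <- scene_object_tables(sc)
  ci_prev <- suppressWarnings(
    summarize_image(tabs$candidate, tabs$reference))$summary$ci
  for (extra in c(5, 15)) {
    sc2 <- generate_coloc_scene(20, extra, seed = 8, bbox = c(20, 20, 8))
    tabs2 <- scene_object_tables(sc2)
    ci <- suppressWarnings(
      summarize_image(tabs2$candidate, tabs2$reference))$summary$ci
    expect_lt(ci, ci_prev)
    ci_prev <- ci
  }
})

test_that("low object counts warn but still produce a summary", {
  sc <- generate_coloc_scene(10, 5, seed = 3, bbox = c(14, 14, 8))
  tabs <- scene_object_tables(sc)
  expect_warning(summarize_image(tabs$candidate, tabs$reference),
                 class = "boutonCI_low_count")
  s <- suppressWarnings(summarize_image(tabs$candidate, tabs$reference,
                                        min_objects_warn = 5))
  expect_equal(s$summary$ci, 10 / 15, tolerance = 1e-12)
})

test_that("group comparison of CI values matches the Welch formula", {
  mk <- function(ci, group, id) {
    data.frame(image_id = id, group = group, n_candidate = 300L,
               n_reference = 300L, pct_candidate_coloc = ci * 80,
               pct_reference_coloc = 80, ci = ci)
  }
  a <- c(1.0, 1.1, 1.0)
  b <- c(0.6, 0.7, 0.65)
  summ <- rbind(do.call(rbind, Map(mk, a, "MP", paste0("m", 1:3))),
                do.call(rbind, Map(mk, b, "K", paste0("k", 1:3))))
  res <- compare_ci_groups(summ)
  oracle <- welch_formula(b, a)  # groups split alphabetically: K first
  expect_equal(unname(res$welch$statistic), oracle$t, tolerance = 1e-12)
  expect_equal(res$welch$df, oracle$df, tolerance = 1e-12)
  expect_equal(res$welch$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(res$descriptives$mean, c(mean(b), mean(a)))
  expect_equal(res$descriptives$sem,
               c(sd(b) / sqrt(3), sd(a) / sqrt(3)))

  # identical groups: t = 0, p = 1
  summ2 <- rbind(do.call(rbind, Map(mk, a, "G1", paste0("a", 1:3))),
                 do.call(rbind, Map(mk, a, "G2", paste0("b", 1:3))))
  res2 <- compare_ci_groups(summ2)
  expect_equal(unname(res2$welch$statistic), 0)
  expect_equal(res2$welch$p_value, 1)

  # fewer than 2 images in a group errors
  expect_error(compare_ci_groups(summ[-(1:2), ]), "at least 2 images")
  expect_error(compare_ci_groups(summ[summ$group == "K", ]),
               "exactly 2 groups")
})
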