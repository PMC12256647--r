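#' Exact cross-channel nearest-neighbor assignment
#'
#' For every object in the candidate table, finds its nearest object (by
#' Euclidean centroid distance) in the reference table, and vice versa.
#' The search is exact (all pairwise distances are evaluated); ties are
#' broken toward the lowest neighbor `object_id`.
#'
#' @param candidates,references Object tables (see [measure_objects()])
#'   with centroids in the same physical frame.
#' @return A list with elements `candidate` and `reference`, each a data
#'   frame with columns `object_id`, `neighbor_id`, `center_distance_um`.
#' @export
nearest_cross_channel <- function(candidates, references) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0) {
    stop("candidate channel object table is empty")
  }
  if (!is.data.frame(references) || nrow(references) == 0) {
    stop("reference channel object table is empty")
  }
  one_way <- function(from, to) {
    # order targets by id so that max.col(ties = "first") breaks distance
    # ties toward the lowest neighbor id
    to <- to[order(to$object_id), , drop = FALSE]
    d2 <- outer(from$x_um, to$x_um, `-`)^2 +
      outer(from$y_um, to$y_um, `-`)^2 +
      outer(from$z_um, to$z_um, `-`)^2
    j <- max.col(-d2, ties.method = "first")
    data.frame(object_id = from$object_id,
               neighbor_id = to$object_id[j],
               center_distance_um = sqrt(d2[cbind(seq_len(nrow(from)), j)]),
               stringsAsFactors = FALSE)
  }
  list(candidate = one_way(candidates, references),
       reference = one_way(references, candidates))
}

#' Interbouton distance
#'
#' The center-to-center Euclidean distance between two objects minus both
#' equivalent-sphere radii.  Negative values mean the equivalent spheres
#' overlap; two objects are deemed colocalized iff their interbouton
#' distance is strictly less than zero (exactly zero — spheres touching —
#' is not colocalized).
#'
#' @param center_distance Center distance(s) in um (>= 0).
#' @param radius_a,radius_b Equivalent radii in um (> 0).
#' @return Numeric vector of interbouton distances (um); may be negative.
#' @export
interbouton_distance <- function(center_distance, radius_a, radius_b) {
  if (any(center_distance < 0)) stop("center_distance must be >= 0")
  if (any(radius_a <= 0) || any(radius_b <= 0)) {
    stop("radii must be positive")
  }
  center_distance - radius_a - radius_b
}

#' Percentage of colocalized objects in one channel
#'
#' @param colocalized Logical vector of per-object colocalization flags
#'   for a single channel of a single image.
#' @return `100 * mean(colocalized)`.
#' @export
percent_colocalized <- function(colocalized) {
  if (!length(colocalized)) {
    stop("cannot compute a percentage over zero objects")
  }
  100 * sum(colocalized) / length(colocalized)
}

#' Colocalization index
#'
#' Per-image CI: the percentage of candidate-channel objects colocalized
#' with a reference object, normalized by the percentage of
#' reference-channel objects colocalized with a candidate object.  A CI of
#' 1.0 indicates that every candidate object also contains the reference
#' marker; values below 1.0 indicate singly labeled candidate objects.
#' The CI can exceed 1 when reference-channel colocalization is incomplete.
#'
#' @param pct_candidate_coloc,pct_reference_coloc Percentages in
#'   `[0, 100]`.
#' @return The CI (non-negative scalar).
#' @export
compute_ci <- function(pct_candidate_coloc, pct_reference_coloc) {
  stopifnot(pct_candidate_coloc >= 0, pct_candidate_coloc <= 100,
            pct_reference_coloc >= 0, pct_reference_coloc <= 100)
  if (pct_reference_coloc == 0) {
    stop("CI is undefined: no reference-channel object is colocalized ",
         "(denominator percentage is 0)")
  }
  pct_candidate_coloc / pct_reference_coloc
}

#' Summarize colocalization for one image
#'
#' Runs the full per-image analysis: cross-channel nearest neighbors,
#' interbouton distances, colocalization flags, both channel percentages,
#' and the CI.  If either channel holds fewer than `min_objects_warn`
#' objects a warning of class `boutonCI_low_count` is signalled (the
#' analysis still runs); the default of 200 reflects the minimum bouton
#' count per image this statistic was designed around.
#'
#' @param candidates,references Object tables from the same image.
#' @param image_id,group Labels carried into the summary row.
#' @param min_objects_warn Minimum per-channel object count below which a
#'   warning is signalled.
#' @return An object of class `image_coloc`: list with `summary` (one-row
#'   data frame: `image_id`, `group`, `n_candidate`, `n_reference`,
#'   `pct_candidate_coloc`, `pct_reference_coloc`, `ci`) and `records`
#'   (per-object data frame: `object_id`, `channel`, `neighbor_id`,
#'   `center_distance_um`, `radius_um`, `neighbor_radius_um`,
#'   `interbouton_um`, `colocalized`).
#' @export
summarize_image <- function(candidates, references,
                            image_id = NA_character_,
                            group = NA_character_,
                            min_objects_warn = 200L) {
  nn <- nearest_cross_channel(candidates, references)
  low <- c(candidate = nrow(candidates),
           reference = nrow(references)) < min_objects_warn
  if (any(low)) {
    warning(structure(
      class = c("boutonCI_low_count", "warning", "condition"),
      list(message = paste0(
        "image ", image_id, ": channel(s) ",
        paste(names(low)[low], collapse = ", "), " have fewer than ",
        min_objects_warn, " objects"),
        call = sys.call())))
  }
  records_for <- function(tab, nn_tab, other, channel) {
    r_self <- tab$radius_um[match(nn_tab$object_id, tab$object_id)]
    r_nb <- other$radius_um[match(nn_tab$neighbor_id, other$object_id)]
    gap <- interbouton_distance(nn_tab$center_distance_um, r_self, r_nb)
    data.frame(object_id = nn_tab$object_id,
               channel = channel,
               neighbor_id = nn_tab$neighbor_id,
               center_distance_um = nn_tab$center_distance_um,
               radius_um = r_self,
               neighbor_radius_um = r_nb,
               interbouton_um = gap,
               colocalized = gap < 0,
               stringsAsFactors = FALSE)
  }
  rec_c <- records_for(candidates, nn$candidate, references, "candidate")
  rec_r <- records_for(references, nn$reference, candidates, "reference")
  pct_c <- percent_colocalized(rec_c$colocalized)
  pct_r <- percent_colocalized(rec_r$colocalized)
  structure(
    list(
      summary = data.frame(image_id = image_id, group = group,
                           n_candidate = nrow(candidates),
                           n_reference = nrow(references),
                           pct_candidate_coloc = pct_c,
                           pct_reference_coloc = pct_r,
                           ci = compute_ci(pct_c, pct_r),
                           stringsAsFactors = FALSE),
      records = rbind(rec_c, rec_r)
    ),
    class = "image_coloc"
  )
}

#' @export
print.image_coloc <- function(x, ...) {
  s <- x$summary
  cat("image_coloc", if (!is.na(s$image_id)) paste0("[", s$image_id, "]"),
      "\n")
  cat(sprintf("  candidate: %d objects, %.1f%% colocalized\n",
              s$n_candidate, s$pct_candidate_coloc))
  cat(sprintf("  reference: %d objects, %.1f%% colocalized\n",
              s$n_reference, s$pct_reference_coloc))
  cat(sprintf("  CI = %.4f\n", s$ci))
  invisible(x)
}

#' Compare per-image CI values between two groups
#'
#' Group statistics operate on per-image CI values (n = images, not
#' objects): per-group mean, SEM and t-based 95% CI, plus a two-sided
#' Welch's t test between exactly two groups.
#'
#' @param summaries A data frame of per-image summary rows (rbind of
#'   `image_coloc$summary`), or a list of `image_coloc` objects.
#' @param grouping Optional named character vector mapping `image_id` to a
#'   group label, overriding the `group` column.
#' @return A list with `descriptives` (per-group data frame from
#'   [describe_group()]) and `welch` (a `bouton_test`, see
#'   [two_sample_test()]).
#' @export
compare_ci_groups <- function(summaries, grouping = NULL) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, function(s) {
      if (inherits(s, "image_coloc")) s$summary else s
    }))
  }
  stopifnot(is.data.frame(summaries), "ci" %in% names(summaries))
  if (!is.null(grouping)) {
    summaries$group <- unname(grouping[as.character(summaries$image_id)])
  }
  groups <- split(summaries$ci, summaries$group)
  if (length(groups) != 2) {
    stop("exactly 2 groups are required for the Welch comparison (got ",
         length(groups), ")")
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) {
    stop("each group needs at least 2 images (group '",
         names(groups)[which.min(sizes)], "' has ", min(sizes), ")")
  }
  desc <- do.call(rbind, lapply(names(groups), function(g) {
    cbind(group = g, describe_group(groups[[g]]))
  }))
  list(descriptives = desc,
       welch = two_sample_test(groups[[1]], groups[[2]],
                               method = "welch",
                               labels = names(groups)))
}
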