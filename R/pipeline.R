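#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML (or an equivalent R list).  A colocalization
#' run must hold exactly one of `inputs` (a manifest of per-image object
#' tables or TIFF stacks) or `simulation` (synthetic scenes); `seed` is
#' mandatory whenever simulation or noise is involved.  All referenced
#' files must exist at validation time.
#'
#' @param config A path to a YAML file, or a list.
#' @return The validated config (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$output_dir)) stop("config needs 'output_dir'")
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulation)
  if (!is.null(config$soma)) {
    # soma pipeline config; colocalization keys are not required
  } else {
    if (has_inputs == has_sim) {
      stop("config must hold exactly one of 'inputs' or 'simulation'")
    }
    if (has_sim && is.null(config$seed)) {
      stop("'seed' is mandatory when simulation is requested")
    }
    if (has_inputs) {
      mf <- config$inputs$manifest
      if (is.null(mf) || !file.exists(mf)) {
        stop("inputs$manifest missing or not found: ", mf)
      }
      man <- utils::read.csv(mf, stringsAsFactors = FALSE)
      base <- dirname(mf)
      resolve <- function(p) ifelse(file.exists(p),
                                    p, file.path(base, p))
      if (all(c("candidate_csv", "reference_csv") %in% names(man))) {
        paths <- resolve(c(man$candidate_csv, man$reference_csv))
      } else if ("tiff" %in% names(man)) {
        paths <- resolve(man$tiff)
        sidecars <- paste0(paths, ".yaml")
        missing_sc <- !file.exists(sidecars)
        if (any(missing_sc)) {
          stop("spacing sidecar not found for: ",
               paste(paths[missing_sc], collapse = ", "))
        }
      } else {
        stop("manifest needs candidate_csv/reference_csv or tiff columns")
      }
      missing_f <- !file.exists(paths)
      if (any(missing_f)) {
        stop("manifest references missing files: ",
             paste(paths[missing_f], collapse = ", "))
      }
    }
  }
  structure(config, class = c("run_config", "list"))
}

# Fill in every tunable with its default so the run manifest is a complete
# audit of the parameters actually used.
coloc_defaults <- function(config) {
  seg <- config$segmentation
  config$segmentation <- list(
    sigma_um = seg$sigma_um %||% 0.10,
    threshold = seg$threshold %||% "otsu",
    connectivity = seg$connectivity %||% 26L,
    min_voxels = seg$min_voxels %||% 15L,
    min_volume_um3 = seg$min_volume_um3
  )
  config$coloc <- list(
    min_objects_warn = config$coloc$min_objects_warn %||% 200L
  )
  if (!is.null(config$simulation)) {
    sc <- config$simulation$scene
    config$simulation$scene <- list(
      radius_meanlog = sc$radius_meanlog %||% log(0.5),
      radius_sdlog = sc$radius_sdlog %||% 0.3,
      radius_range = as.numeric(unlist(sc$radius_range %||% c(0.3, 2.0))),
      pair_offset_max = sc$pair_offset_max %||% Inf,
      bbox = as.numeric(unlist(sc$bbox %||% c(24, 24, 10))),
      min_separation = sc$min_separation %||% 1.0
    )
    rd <- config$simulation$render
    config$simulation$render <- list(
      spacing = as.numeric(unlist(rd$spacing %||% c(0.3, 0.1, 0.1))),
      psf_sigma = rd$psf_sigma %||% 0,
      amplitude = rd$amplitude %||% 100,
      background = rd$background %||% 0,
      noise_sd = rd$noise_sd %||% 0
    )
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the colocalization pipeline end to end
#'
#' simulate (or load) -> segment -> colocalize -> group comparison.  All
#' outputs are deterministic for a fixed config and seed: per-image object
#' tables and colocalization records (CSV), a per-image summary CSV, a
#' group-comparison JSON (when two groups with at least two images each
#' are present), a YAML run manifest echoing every parameter used, and a
#' stage log.
#'
#' @param config A path to a YAML config or a list (see
#'   [read_run_config()]).
#' @return Invisibly, a list with `summaries` (per-image data frame),
#'   `comparison` (or `NULL`) and `output_dir`.
#' @export
run_coloc_pipeline <- function(config) {
  config <- read_run_config(config)
  config <- coloc_defaults(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  images <- list()  # each: list(image_id, group, candidate, reference)
  if (!is.null(config$simulation)) {
    say("stage: simulate (seed ", config$seed, ")")
    specs <- config$simulation$images
    if (is.null(specs)) stop("simulation block needs an 'images' list")
    for (i in seq_along(specs)) {
      im <- specs[[i]]
      scene <- do.call(generate_coloc_scene, c(
        list(n_reference = im$n_reference,
             n_extra_candidate = im$n_extra_candidate %||% 0L,
             seed = as.integer(config$seed) + i),
        config$simulation$scene))
      grid <- do.call(render_scene, c(
        list(scene = scene, seed = as.integer(config$seed) + i),
        config$simulation$render))
      seg <- config$segmentation
      tabs <- lapply(c("candidate", "reference"), function(ch) {
        segment_channel(grid, ch, sigma_um = seg$sigma_um,
                        threshold = seg$threshold,
                        connectivity = seg$connectivity,
                        min_voxels = seg$min_voxels,
                        min_volume_um3 = seg$min_volume_um3)
      })
      images[[i]] <- list(image_id = im$image_id %||% paste0("img", i),
                          group = im$group %||% NA_character_,
                          candidate = tabs[[1]], reference = tabs[[2]])
      say("stage: segment image ", images[[i]]$image_id, ": ",
          nrow(tabs[[1]]), " candidate / ", nrow(tabs[[2]]),
          " reference objects")
    }
  } else {
    say("stage: load object tables")
    mf <- config$inputs$manifest
    man <- utils::read.csv(mf, stringsAsFactors = FALSE)
    base <- dirname(mf)
    resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
    for (i in seq_len(nrow(man))) {
      if ("tiff" %in% names(man)) {
        grid <- read_voxel_grid(resolve(man$tiff[i]))
        seg <- config$segmentation
        cand <- segment_channel(grid, config$channels$candidate %||%
                                  "candidate",
                                sigma_um = seg$sigma_um,
                                threshold = seg$threshold,
                                connectivity = seg$connectivity,
                                min_voxels = seg$min_voxels,
                                min_volume_um3 = seg$min_volume_um3)
        ref <- segment_channel(grid, config$channels$reference %||%
                                 "reference",
                               sigma_um = seg$sigma_um,
                               threshold = seg$threshold,
                               connectivity = seg$connectivity,
                               min_voxels = seg$min_voxels,
                               min_volume_um3 = seg$min_volume_um3)
      } else {
        cand <- read_object_table(resolve(man$candidate_csv[i]))
        ref <- read_object_table(resolve(man$reference_csv[i]))
      }
      images[[i]] <- list(image_id = man$image_id[i],
                          group = man$group[i],
                          candidate = cand, reference = ref)
    }
  }

  say("stage: colocalize (", length(images), " images)")
  summaries <- list()
  for (i in seq_along(images)) {
    im <- images[[i]]
    res <- withCallingHandlers(
      summarize_image(im$candidate, im$reference,
                      image_id = im$image_id, group = im$group,
                      min_objects_warn = config$coloc$min_objects_warn),
      boutonCI_low_count = function(w) {
        say("warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    write_object_table(im$candidate,
                       file.path(out, paste0(im$image_id,
                                             "_candidate_objects.csv")))
    write_object_table(im$reference,
                       file.path(out, paste0(im$image_id,
                                             "_reference_objects.csv")))
    utils::write.csv(res$records,
                     file.path(out, paste0(im$image_id, "_records.csv")),
                     row.names = FALSE)
    summaries[[i]] <- res$summary
  }
  summaries <- do.call(rbind, summaries)
  utils::write.csv(summaries, file.path(out, "image_summaries.csv"),
                   row.names = FALSE)

  comparison <- NULL
  tab <- table(summaries$group[!is.na(summaries$group)])
  if (length(tab) == 2 && all(tab >= 2)) {
    say("stage: compare groups (Welch's t on per-image CI)")
    comparison <- compare_ci_groups(summaries)
    jsonlite::write_json(
      list(descriptives = comparison$descriptives,
           welch = list(t = unname(comparison$welch$statistic),
                        df = comparison$welch$df,
                        p_value = comparison$welch$p_value)),
      file.path(out, "group_comparison.json"),
      auto_unbox = TRUE, digits = NA)
  }

  manifest <- unclass(config)
  yaml::write_yaml(manifest, file.path(out, "run_manifest.yaml"))
  writeLines(log_lines, log_path)
  invisible(list(summaries = summaries, comparison = comparison,
                 output_dir = out))
}

#' Run the soma-size pipeline end to end
#'
#' Glia exclusion by size cutoff, then per-stratum univariate Gaussian
#' mixture fits with BIC model selection and per-cell classification.
#' Outputs: BIC table CSV, component-parameter CSV, per-cell assignment
#' CSV, run manifest and log.
#'
#' @param config A path to a YAML config or a list; the `soma` block
#'   holds either `input_csv` (columns `area_um2`, `lamina`,
#'   `gaba_status`) or a `simulation` block (`components`, `n`), plus
#'   `cutoff_um2` (default 40; 0 disables exclusion), optional
#'   `stratify_by`, `k_range` (default 1..9), `variance_model`.
#' @return Invisibly, a list with `fits` (per-stratum `select_by_bic`
#'   results), `assignments` data frame and `output_dir`.
#' @export
run_soma_pipeline <- function(config) {
  config <- read_run_config(config)
  soma <- config$soma
  if (is.null(soma)) stop("config needs a 'soma' block")
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  soma$cutoff_um2 <- soma$cutoff_um2 %||% 40
  soma$k_range <- as.integer(unlist(soma$k_range %||% c(1L, 9L)))
  soma$k_range <- seq(soma$k_range[1], soma$k_range[length(soma$k_range)])
  soma$variance_model <- soma$variance_model %||% "unequal"

  if (!is.null(soma$input_csv)) {
    if (!file.exists(soma$input_csv)) {
      stop("soma input_csv not found: ", soma$input_csv)
    }
    cells <- utils::read.csv(soma$input_csv, stringsAsFactors = FALSE)
    if (nrow(cells) == 0) stop("soma input CSV holds no cells")
    need <- c("area_um2", "lamina", "gaba_status")
    miss <- setdiff(need, names(cells))
    if (length(miss)) {
      stop("soma input CSV is missing column(s): ",
           paste(miss, collapse = ", "))
    }
  } else if (!is.null(soma$simulation)) {
    if (is.null(config$seed)) {
      stop("'seed' is mandatory when simulation is requested")
    }
    comp <- soma$simulation$components
    if (is.null(comp)) {
      cells <- sample_soma_sizes(n = soma$simulation$n,
                                 seed = config$seed)
    } else {
      comp <- do.call(rbind, lapply(comp, as.data.frame))
      cells <- sample_soma_sizes(comp, n = soma$simulation$n,
                                 seed = config$seed)
    }
    say("stage: simulate soma sizes (n = ", nrow(cells), ")")
  } else {
    stop("soma block needs 'input_csv' or 'simulation'")
  }

  if (soma$cutoff_um2 > 0) {
    n_before <- nrow(cells)
    cells <- suppressMessages(
      exclude_small_cells(cells, cutoff = soma$cutoff_um2))
    say("stage: glia exclusion at ", soma$cutoff_um2, " um^2: ",
        n_before - nrow(cells), " of ", n_before, " cells excluded")
  } else {
    say("stage: glia exclusion disabled (cutoff 0); no cells excluded")
  }

  strata <- if (!is.null(soma$stratify_by)) {
    split(cells, cells[[soma$stratify_by]])
  } else list(all = cells)

  fits <- list()
  bic_rows <- list()
  comp_rows <- list()
  assign_rows <- list()
  for (s in names(strata)) {
    xs <- strata[[s]]$area_um2
    say("stage: mixture fit, stratum '", s, "' (n = ", length(xs), ")")
    sel <- select_by_bic(xs, K_range = soma$k_range,
                         variance_model = soma$variance_model,
                         seed = config$seed %||% 1L)
    fits[[s]] <- sel
    bic_rows[[s]] <- cbind(stratum = s, sel$bic_table)
    comp_rows[[s]] <- data.frame(stratum = s,
                                 component = seq_len(sel$best$K),
                                 weight = sel$best$weights,
                                 mean_um2 = sel$best$means,
                                 sd_um2 = sel$best$sds,
                                 stringsAsFactors = FALSE)
    cls <- classify_cells(sel$best, xs)
    assign_rows[[s]] <- data.frame(stratum = s,
                                   area_um2 = xs,
                                   component = cls$label,
                                   posterior = cls$posterior[
                                     cbind(seq_along(xs), cls$label)],
                                   stringsAsFactors = FALSE)
    say("  selected K = ", sel$best$K, " (BIC = ",
        round(sel$best$bic, 2), ")")
  }
  utils::write.csv(do.call(rbind, bic_rows),
                   file.path(out, "bic_table.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, comp_rows),
                   file.path(out, "components.csv"), row.names = FALSE)
  assignments <- do.call(rbind, assign_rows)
  utils::write.csv(assignments, file.path(out, "assignments.csv"),
                   row.names = FALSE)
  manifest <- unclass(config)
  manifest$soma <- soma
  yaml::write_yaml(manifest, file.path(out, "run_manifest.yaml"))
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(list(fits = fits, assignments = assignments,
                 output_dir = out))
}
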