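#' End-to-end pipeline run
#'
#' Orchestrates `simulate -> normalize -> preprocess -> fit -> metrics`
#' (and, when a cohort section is configured, `-> stats`) from a single
#' configuration, writing maps, feature tables, and a machine-readable
#' `results.json` with provenance (package version, seed, config, content
#' hashes of every output) to `out_dir`. Deterministic given the seed. A
#' stage failure raises an error labelled with the stage name; outputs of
#' completed stages are retained.
#'
#' Configuration is a nested list or the path to a YAML file with (all
#' optional) sections `seed`, `phantom` (arguments of [phantom_config()]),
#' `preprocess` (`register`, `denoise`, `energy`, `b0_method` one of
#' `"two_pool"`/`"spline"`), `fit` (arguments of [fit_options()]),
#' `metrics` (`roi`: which phantom mask to summarize), and `cohort`
#' (arguments of [cohort_config()] plus `contrast_metric`). Unknown section
#' names are rejected.
#'
#' @param config List or YAML path.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the fitted maps, feature table, optional
#'   cohort statistics, and the provenance record.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("cestrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "phantom", "preprocess", "fit", "metrics", "cohort")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## -- simulate ----------------------------------------------------------
  ph_args <- config$phantom %||% list()
  ph_args$seed <- ph_args$seed %||% seed
  if (!is.null(ph_args$grid_shape)) {
    ph_args$grid_shape <- as.integer(unlist(ph_args$grid_shape))
  }
  ph_cfg <- stage("simulate", do.call(phantom_config, ph_args))
  phantom <- stage("simulate", generate_phantom(ph_cfg))

  ## -- normalize ---------------------------------------------------------
  zraw <- stage("normalize", suppressWarnings(
    normalize_to_zspectrum(phantom$saturated_stack, s0_image = NULL,
                           schedule = phantom$schedule,
                           mask = phantom$masks$brain)))

  ## -- preprocess --------------------------------------------------------
  pp <- config$preprocess %||% list()
  do_register <- pp$register %||% !is.null(ph_cfg$motion_shifts_px)
  do_denoise <- pp$denoise %||% TRUE
  b0_method <- pp$b0_method %||% "two_pool"
  stack <- phantom$saturated_stack
  shifts <- NULL
  z <- zraw
  zcorr <- stage("preprocess", {
    if (isTRUE(do_register)) {
      reg <- register_subpixel(stack,
                               reference_frame_index =
                                 phantom$schedule$reference_index)
      stack <- reg$stack
      shifts <- reg$shifts
    }
    # denoise the raw saturated images (before normalization: outside the
    # object S0 ~ 0, and Z ratios there are unbounded noise)
    if (isTRUE(do_denoise)) {
      stack <- denoise_mlsvd(stack)
    }
    if (isTRUE(do_register) || isTRUE(do_denoise)) {
      z <- suppressWarnings(
        normalize_to_zspectrum(stack, s0_image = NULL,
                               schedule = phantom$schedule,
                               mask = phantom$masks$brain))
    }
    b0 <- switch(b0_method,
                 two_pool = estimate_b0_two_pool(z),
                 spline = estimate_b0_spline_minimum(z),
                 stop("b0_method must be 'two_pool' or 'spline'"))
    apply_b0_correction(z, b0)
  })

  ## -- fit ---------------------------------------------------------------
  fit_args <- config$fit %||% list()
  opts <- do.call(fit_options, fit_args)
  maps <- stage("fit", fit_voxelwise_pipeline(zcorr, opts))

  ## -- metrics -----------------------------------------------------------
  roi_name <- (config$metrics %||% list())$roi %||% "tumor"
  features <- stage("metrics", {
    all_maps <- c(maps$maps,
                  list(mtr35 = mtr_asym(zcorr, 3.5),
                       ph_weighted = ph_weighted_map(zcorr)))
    compute_feature_table(all_maps, phantom$masks[[roi_name]],
                          subject_id = "subject1",
                          exclude = !maps$converged)
  })

  ## -- write outputs -----------------------------------------------------
  paths <- character(0)
  for (nm in names(maps$maps)) {
    p <- file.path(out_dir, paste0(nm, ".nii.gz"))
    write_metric_map(maps$maps[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "b0.nii.gz")
  write_metric_map(zcorr$b0_map_ppm, p); paths <- c(paths, p)
  p <- file.path(out_dir, "features.csv")
  write_feature_table(features, p); paths <- c(paths, p)

  ## -- cohort statistics (optional) --------------------------------------
  cohort_stats <- NULL
  if (!is.null(config$cohort)) {
    cohort_stats <- stage("stats", {
      ca <- config$cohort
      metric <- ca$contrast_metric %||% "amide"
      ca$contrast_metric <- NULL
      ca$seed <- ca$seed %||% (seed + 1L)
      if (!is.null(ca$n_per_group)) {
        ca$n_per_group <- as.integer(unlist(ca$n_per_group))
      }
      cc <- do.call(cohort_config, ca)
      coh <- generate_cohort(cc, ph_cfg, mode = "features")
      ft <- coh$features
      wide <- ft[ft$metric == metric, ]
      g1 <- wide$mean[wide$group == cc$group_labels[1]]
      g2 <- wide$mean[wide$group == cc$group_labels[2]]
      cmp <- compare_feature(g1, g2, feature = paste0(metric, "_mean"))
      roc <- roc_analysis(wide$mean, wide$group,
                          positive = cc$group_labels[2])
      list(comparison = cmp, roc = roc, features = ft)
    })
    write_feature_table(cohort_stats$features,
                        file.path(out_dir, "cohort_features.csv"))
    paths <- c(paths, file.path(out_dir, "cohort_features.csv"))
  }

  ## -- provenance + results ---------------------------------------------
  provenance <- list(
    package = "cestfit",
    version = as.character(utils::packageVersion("cestfit")),
    seed = seed,
    config = config,
    outputs = as.list(tools::md5sum(paths))
  )
  results <- list(
    convergence_fraction = maps$convergence_fraction,
    n_failed = maps$n_failed,
    features = features,
    cohort = if (!is.null(cohort_stats)) {
      list(p_value = cohort_stats$comparison$p_value,
           auc = cohort_stats$roc$auc)
    },
    provenance = provenance
  )
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(list(phantom = phantom, zspec = zcorr, maps = maps,
                 features = features, cohort = cohort_stats,
                 registration_shifts = shifts,
                 provenance = provenance, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
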