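#' Configure the end-to-end pipeline
#'
#' One declarative object driving [run_pipeline()]: phantom-generation → DICOM
#' round trip → segmentation → density → report mapping → cohort analytics.
#' Every random consumer draws from a seed derived from `seed`, so a config
#' reruns to identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param n_exams number of phantom exams.
#' @param grid_shape,voxel_spacing,texture_scale,noise_sd phantom geometry,
#'   see [phantom_spec()].
#' @param cohort a [cohort_spec()] or `NULL` to build one from `n_exams` and
#'   `seed`.
#' @param segmenter `"threshold"` (classical intensity baseline, the
#'   desk-scale oracle) or `"vnet"` (requires `model_path`).
#' @param model_path checkpoint from [save_segmenter()]; checked upfront.
#' @param threshold binarization probability for network output.
#' @param keep_dicom keep the per-exam DICOM series on disk.
#' @param force recompute even when a manifest already exists.
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, n_exams = 20, grid_shape = c(48, 48, 48),
                            voxel_spacing = c(1, 1, 1), texture_scale = 4,
                            noise_sd = 5, cohort = NULL,
                            segmenter = c("threshold", "vnet"),
                            model_path = NULL, threshold = 0.5,
                            keep_dicom = FALSE, force = FALSE, seed = 1L) {
  segmenter <- match.arg(segmenter)
  if (segmenter == "vnet") {
    if (is.null(model_path) || !file.exists(model_path)) {
      abort("`segmenter = \"vnet\"` requires an existing `model_path` checkpoint.")
    }
  }
  if (is.null(cohort)) {
    cohort <- cohort_spec(n_exams = n_exams, seed = seed)
  }
  structure(list(out_dir = out_dir, n_exams = as.integer(n_exams),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 texture_scale = texture_scale, noise_sd = noise_sd,
                 cohort = cohort, segmenter = segmenter,
                 model_path = model_path, threshold = threshold,
                 keep_dicom = isTRUE(keep_dicom), force = isTRUE(force),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full density pipeline
#'
#' For each phantom exam: generate the volume and ground truth, write it as a
#' DICOM series (alternating inferior-first / superior-first file order to
#' exercise both z directions), load the series back, segment breast and
#' dense tissue, split laterality and apply the contralateral rule, and
#' compute the volumetric density. Report texts are mapped to categories and
#' the cohort analytics (age summaries, concordance, histogram, ordinal
#' classifier when all four categories are present) are written as a metrics
#' JSON. A manifest records inputs, seeds, per-stage outputs and wall time;
#' rerunning with an existing manifest is a no-op unless `force`.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with `manifest` (also written as
#'   `manifest.json`), `cohort`, `densities` (per-side rows) and `metrics`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  if (file.exists(manifest_path) && !cfg$force) {
    manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    message("Existing manifest found; skipping recomputation (use force = TRUE to rerun).")
    return(invisible(list(manifest = manifest,
                          cohort = read_cohort_csv(file.path(cfg$out_dir, "cohort.csv")),
                          densities = tibble::as_tibble(read.csv(file.path(cfg$out_dir, "densities.csv"))),
                          metrics = jsonlite::read_json(file.path(cfg$out_dir, "metrics.json"),
                                                        simplifyVector = TRUE))))
  }
  t0 <- Sys.time()
  model <- if (cfg$segmenter == "vnet") load_segmenter(cfg$model_path) else NULL

  cohort <- sample_cohort(cfg$cohort)
  write_cohort_csv(cohort, file.path(cfg$out_dir, "cohort.csv"))

  side_rows <- list()
  exam_density <- numeric(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    ex <- cohort[i, ]
    ph <- realize_exam(ex, grid_shape = cfg$grid_shape,
                       voxel_spacing = cfg$voxel_spacing,
                       texture_scale = cfg$texture_scale,
                       noise_sd = cfg$noise_sd)
    series_dir <- file.path(cfg$out_dir, "dicom", ex$exam_id)
    write_dicom_series(ph$volume, series_dir,
                       z_direction = if (i %% 2 == 0) -1L else 1L)
    v <- load_series(series_dir)
    masks <- if (cfg$segmenter == "threshold") {
      segment_threshold(v)
    } else {
      vz <- zscore_normalize(v)
      breast <- segment_threshold(v)$breast
      dense <- segment_volume(model, vz, threshold = cfg$threshold,
                              patch_size = model$cfg$patch_size,
                              steps = c(2, 2, 2))
      mask_pair(breast, dense & breast)
    }
    rows <- density_by_side(masks, exam_id = ex$exam_id)
    sel <- select_reported_density(rows, cancer_laterality = ex$laterality)
    reported <- if (ex$laterality == "none") {
      sel$density[sel$side == "exam"]
    } else sel$density[1]
    exam_density[i] <- reported
    side_rows[[i]] <- dplyr::mutate(sel, laterality = ex$laterality)
    if (!cfg$keep_dicom) unlink(series_dir, recursive = TRUE)
  }
  densities <- dplyr::bind_rows(side_rows)
  write.csv(densities, file.path(cfg$out_dir, "densities.csv"), row.names = FALSE)

  analytic <- cohort %>%
    dplyr::mutate(density = exam_density,
                  category = classify_report_text(.data$report_text))
  metrics <- list(
    n_exams = nrow(analytic),
    mean_density = mean(analytic$density),
    sd_density = sd(analytic$density),
    mean_abs_error_vs_truth = mean(abs(analytic$density - analytic$true_density)),
    age_summary = summarize_by_age(analytic),
    histogram = density_histogram(analytic)
  )
  metrics$concordance <- tryCatch(concordance(analytic),
                                  error = function(e) NULL)
  metrics$classifier <- tryCatch({
    sp <- split_cohort(analytic, seed = cfg$seed)
    fit <- fit_density_classifier(sp$train)
    ev <- evaluate_classifier(fit, sp$test)
    list(thresholds = fit$thresholds, train_accuracy = fit$train_accuracy,
         accuracy_4class = ev$accuracy_4class, auc_binary = ev$auc_binary)
  }, error = function(e) NULL)
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")

  manifest <- list(
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    seed = cfg$seed, n_exams = cfg$n_exams,
    grid_shape = cfg$grid_shape, segmenter = cfg$segmenter,
    noise_sd = cfg$noise_sd,
    outputs = c("cohort.csv", "densities.csv", "metrics.json"),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, cohort = analytic,
                 densities = densities, metrics = metrics))
}

write_cohort_csv <- function(cohort, path) {
  out <- dplyr::mutate(cohort, category = as.integer(.data$category))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

read_cohort_csv <- function(path) {
  t <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if ("category" %in% names(t)) t$category <- density_category(t$category)
  t
}
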