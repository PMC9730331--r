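#' Pipeline configuration
#'
#' Collects every stage parameter in one range-checked object. Defaults
#' reproduce the reference configuration: 100 level-set iterations inside
#' a rectangular prior, disc-2 opening, 32 mutual-information bins,
#' atlas threshold 0.5, equal partial-volume cost weights, the default
#' [score_rule()], and 5-fold stratified cross-validation.
#'
#' @param init_rect optional rectangular prior `c(x0, y0, x1, y1)`.
#' @param max_iterations,opening_radius,mu see [gland_seg_params()].
#' @param mi_bins mutual-information histogram bins.
#' @param atlas_threshold zone probability threshold.
#' @param pv_weights length-3 nonnegative weights
#'   (intensity, probability, distance).
#' @param rule a [score_rule()].
#' @param folds cross-validation folds.
#' @param seed integer seed used by every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(init_rect = NULL, max_iterations = 100L,
                            opening_radius = 2L, mu = 0.1, mi_bins = 32L,
                            atlas_threshold = 0.5,
                            pv_weights = c(1, 1, 1) / 3,
                            rule = score_rule(), folds = 5L, seed = 1L) {
  stopifnot(max_iterations >= 1, opening_radius >= 0, mu >= 0,
            mi_bins >= 2, atlas_threshold >= 0, atlas_threshold <= 1,
            length(pv_weights) == 3, all(pv_weights >= 0),
            sum(pv_weights) > 0, folds >= 2)
  stopifnot(inherits(rule, "score_rule"))
  structure(list(init_rect = init_rect,
                 max_iterations = as.integer(max_iterations),
                 opening_radius = as.integer(opening_radius), mu = mu,
                 mi_bins = as.integer(mi_bins),
                 atlas_threshold = atlas_threshold,
                 pv_weights = pv_weights, rule = rule,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `rule` may
#' be a mapping with `t23`, `t34`, `t45`, `v_sig`, `volume_override`.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  rule <- if (is.null(y$rule)) score_rule() else do.call(score_rule, y$rule)
  args <- y[setdiff(names(y), "rule")]
  do.call(pipeline_config, c(args, list(rule = rule)))
}

split_lesion_rois <- function(lesion_rois) {
  if (inherits(lesion_rois, "mask3d")) {
    labs <- sort(setdiff(unique(as.vector(lesion_rois$labels)), 0L))
    lesion_rois <- lapply(labs, function(l)
      mask3d(lesion_rois$labels == l, lesion_rois$voxel_size,
             lesion_rois$slice_thickness, lesion_rois$slice_gap))
  }
  lesion_rois
}

#' Run the full scoring pipeline
#'
#' Executes gland segmentation on DWI, T2W-to-DWI registration, zonal
#' segmentation (when an atlas is supplied), lesion measurement of the
#' user-provided ROIs, and score assignment, in that order. Lesion ROIs
#' are user input: the pipeline is semi-automated by design.
#'
#' @param volumes named list with at least `dwi` (a [volume3d()]);
#'   optionally `t2w` (registered to DWI when present) and `adc`.
#' @param lesion_rois a label [mask3d()] (labels 1..K, one per lesion) or
#'   a list of binary [mask3d()] masks; may be empty.
#' @param config a [pipeline_config()].
#' @param atlas optional [build_atlas()] result (or list of training
#'   subjects, passed to [build_atlas()]); without it the zonal stage is
#'   skipped and `zones` is `NULL`.
#' @param out optional directory; when given, intermediates (gland, zone
#'   masks, registered T2W, transform JSON, score CSV, run log JSON) are
#'   written there.
#' @return list of class `pipeline_result`: `gland`, `transform`,
#'   `t2w_registered`, `zones`, `measurements`, `scores` (a
#'   [score_cohort()] table, or an empty data.frame when no ROIs), `log`
#'   (per-stage parameters and durations).
#' @export
run_pipeline <- function(volumes, lesion_rois = list(),
                         config = pipeline_config(), atlas = NULL,
                         out = NULL) {
  if (!"dwi" %in% names(volumes)) stop("DWI channel is required")
  set.seed(config$seed)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    res
  }

  gland <- stage("segment", segment_gland(volumes$dwi, gland_seg_params(
    init_rect = config$init_rect, max_iterations = config$max_iterations,
    opening_radius = config$opening_radius, mu = config$mu)))
  log$segment$params <- list(max_iterations = config$max_iterations,
                             opening_radius = config$opening_radius,
                             mu = config$mu)

  transform <- NULL; t2w_reg <- NULL
  if ("t2w" %in% names(volumes)) {
    gm <- gland$labels > 0
    dwi_roi <- volume3d(volumes$dwi$data * gm, volumes$dwi$voxel_size,
                        volumes$dwi$slice_thickness, volumes$dwi$slice_gap)
    t2w_gland <- stage("segment_t2w", segment_gland(volumes$t2w,
      gland_seg_params(init_rect = config$init_rect,
                       max_iterations = config$max_iterations,
                       opening_radius = config$opening_radius,
                       mu = config$mu)))
    t2w_roi <- volume3d(volumes$t2w$data * (t2w_gland$labels > 0),
                        volumes$t2w$voxel_size,
                        volumes$t2w$slice_thickness, volumes$t2w$slice_gap)
    transform <- stage("register", register_t2w_to_dwi(
      t2w_roi, dwi_roi, mi_params(bins = config$mi_bins)))
    t2w_reg <- stage("resample", apply_affine(volumes$t2w, transform))
    log$register$params <- list(bins = config$mi_bins)
  }

  zones <- NULL
  if (!is.null(atlas)) {
    if (!inherits(atlas, "probabilistic_atlas")) atlas <- build_atlas(atlas)
    zones <- stage("zones", segment_zones(
      gland, volumes$dwi, atlas, threshold = config$atlas_threshold,
      params = pv_cost_params(config$pv_weights[1], config$pv_weights[2],
                              config$pv_weights[3])))
    log$zones$params <- list(threshold = config$atlas_threshold,
                             pv_weights = config$pv_weights)
  }

  rois <- split_lesion_rois(lesion_rois)
  measurements <- stage("measure", lapply(rois, measure_lesion))
  scores <- if (length(measurements))
    stage("score", score_cohort(measurements, config$rule))
  else list(scores = data.frame(), summary = NULL)

  res <- structure(list(gland = gland, transform = transform,
                        t2w_registered = t2w_reg, zones = zones,
                        measurements = measurements, scores = scores,
                        log = log, config = config),
                   class = "pipeline_result")
  if (!is.null(out)) write_pipeline_result(res, out)
  res
}

write_pipeline_result <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_volume(res$gland, file.path(out, "gland.nii.gz"))
  if (!is.null(res$zones)) {
    write_volume(res$zones$pz, file.path(out, "pz.nii.gz"))
    write_volume(res$zones$tz, file.path(out, "tz.nii.gz"))
  }
  if (!is.null(res$t2w_registered))
    write_volume(res$t2w_registered, file.path(out, "t2w_registered.nii.gz"))
  if (!is.null(res$transform))
    jsonlite::write_json(list(linear = res$transform$linear,
                              translation = res$transform$translation),
                         file.path(out, "transform.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  if (nrow(res$scores$scores))
    utils::write.csv(res$scores$scores, file.path(out, "scores.csv"),
                     row.names = FALSE)
  jsonlite::write_json(res$log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:\n  stages run:",
      paste(names(x$log), collapse = ", "), "\n")
  if (nrow(x$scores$scores)) print(x$scores)
  else cat("  no lesions scored\n")
  invisible(x)
}
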