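# interface_io: configuration and the top-level pipeline that chains
# segmentation -> splitting (-> manual split) -> periosteal filling ->
# joint-space mask -> JSW map -> summary -> QC. All tunable parameters live
# in one flat-per-module config that round-trips losslessly through YAML.

#' Pipeline configuration
#'
#' @param voxel_size default voxel size in mm.
#' @param stack_slices scan-axis stack length ceiling.
#' @param threshold segmentation threshold: `"otsu"` or a number.
#' @param periosteal_radius_vox periosteal closing radius, voxels.
#' @param closing_radius joint-space bridging radius, mm.
#' @param robust_min robust JSW.MIN toggle (see [summarize_morphometry()]).
#' @param axis joint (scan) axis.
#' @param alpha significance level and Shapiro-Wilk routing gate.
#' @param strata_width matching age-band width, years.
#' @param exact_max largest min-group size for exact nonparametric p-values.
#' @param seed seed for any stochastic stage (phantom noise, cohorts).
#' @param save_maps write JSW maps alongside metrics in [run_pipeline()].
#' @return object of class `pipeline_config` (a named nested list).
#' @export
pipeline_config <- function(voxel_size = 0.082, stack_slices = 330L,
                            threshold = "otsu", periosteal_radius_vox = 5,
                            closing_radius = 2.5, robust_min = FALSE,
                            axis = 3L, alpha = 0.05, strata_width = 5,
                            exact_max = 8L, seed = 1L, save_maps = FALSE) {
  stopifnot(voxel_size > 0, stack_slices >= 4, periosteal_radius_vox >= 0,
            closing_radius > 0, axis %in% 1:3, alpha > 0, alpha < 1,
            strata_width > 0, exact_max >= 0)
  structure(list(
    grid = list(voxel_size = voxel_size, stack_slices = as.integer(stack_slices)),
    segmentation = list(threshold = threshold,
                        periosteal_radius_vox = periosteal_radius_vox,
                        axis = as.integer(axis)),
    morphometry = list(closing_radius = closing_radius, robust_min = robust_min),
    statistics = list(alpha = alpha, strata_width = strata_width,
                      exact_max = as.integer(exact_max)),
    seed = as.integer(seed),
    save_maps = save_maps), class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' The file form round-trips losslessly: `read_config(write_config(cfg, f))`
#' reproduces `cfg` exactly.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, list(
    voxel_size = raw$grid$voxel_size, stack_slices = raw$grid$stack_slices,
    threshold = raw$segmentation$threshold,
    periosteal_radius_vox = raw$segmentation$periosteal_radius_vox,
    axis = raw$segmentation$axis,
    closing_radius = raw$morphometry$closing_radius,
    robust_min = raw$morphometry$robust_min,
    alpha = raw$statistics$alpha, strata_width = raw$statistics$strata_width,
    exact_max = raw$statistics$exact_max,
    seed = raw$seed, save_maps = raw$save_maps))
}

#' Hash of a configuration
#'
#' Stable digest of the canonical YAML form; recorded in every run manifest
#' so outputs can be traced to the exact parameter set that produced them.
#'
#' @param config a [pipeline_config()].
#' @return character hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  rlang::hash(yaml::as.yaml(unclass(config)))
}

#' Run the joint-space pipeline on a set of joint volumes
#'
#' Fixed stage order per joint: bone segmentation, bone splitting (with the
#' programmatic manual-split fallback when a contour is supplied), periosteal
#' filling, joint-space mask, JSW map, morphometric summary, quality control.
#' Identical config and inputs give identical outputs. Any stage error halts
#' the run, naming the stage and the offending item.
#'
#' @param config a [pipeline_config()].
#' @param inputs list of joint items; each a list with `id`, `joint`, one of
#'   `volume` (a [volume_image()]), `phantom` (a [make_phantom()] result) or
#'   `path` (a volume file), optional `motion_grade` (default 1) and optional
#'   `manual_contour` (logical array for [apply_manual_split()]).
#' @param out_dir optional output directory; when given, writes
#'   `metrics.csv`, `qc_records.csv`, `exclusions.csv`, `success_rates.csv`,
#'   a `manifest.json` naming the config hash, and (with `save_maps`) one JSW
#'   map volume per measured joint.
#' @return list with `metrics` (one row per measured, included joint),
#'   `records` (all QC records), `exclusions`, `success_rates` and
#'   `config_hash`.
#' @export
run_pipeline <- function(config, inputs, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seg <- config$segmentation
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed for %s: %s", name, id,
                   conditionMessage(e)), call. = FALSE))
  }

  records <- NULL
  metrics <- NULL
  maps <- list()
  for (item in inputs) {
    id <- item$id %||% "joint"
    joint <- item$joint %||% "MCP"
    grade <- item$motion_grade %||% 1L

    vol <- stage("load", id, {
      if (!is.null(item$volume)) item$volume
      else if (!is.null(item$phantom)) item$phantom$volume
      else if (!is.null(item$path)) read_volume(item$path)
      else stop("no volume, phantom or path")
    })

    bm <- stage("segment", id, segment_bone(vol, threshold = seg$threshold))
    sp <- stage("split", id,
                split_joint_bones(bm, vol$grid, axis = seg$axis))
    outcome <- sp$outcome
    bones <- sp$bones
    if (is.null(bones) && !is.null(item$manual_contour))
      bones <- stage("manual_split", id,
                     apply_manual_split(sp$bridged_mask, item$manual_contour,
                                        vol$grid))

    if (!is.null(bones)) {
      meas <- stage("morphometry", id,
                    measure_joint(bones,
                                  closing_radius = config$morphometry$closing_radius,
                                  periosteal_radius_vox = seg$periosteal_radius_vox,
                                  axis = seg$axis,
                                  robust_min = config$morphometry$robust_min))
      coverage <- stage("qc", id,
                        check_joint_coverage(meas$bones, space = meas$space,
                                             axis = seg$axis))
      ankylotic <- meas$morphometry$ankylotic
      morph <- meas$morphometry
      if (config$save_maps && !is.null(meas$map)) maps[[id]] <- meas$map
    } else {
      coverage <- TRUE
      ankylotic <- FALSE
      morph <- NULL
    }

    records <- rbind(records, quality_records(
      id, joint, grade, coverage_ok = coverage, ankylotic = ankylotic,
      status = outcome$status))
    if (!is.null(morph))
      metrics <- rbind(metrics, cbind(data.frame(id = id, joint = joint,
                                                 stringsAsFactors = FALSE),
                                      as.data.frame(morph)))
  }

  qc <- apply_inclusion_rules(records)
  included_keys <- paste(qc$included$subject, qc$included$joint)
  if (!is.null(metrics))
    metrics <- metrics[paste(metrics$id, metrics$joint) %in% included_keys, ,
                       drop = FALSE]
  rates <- if (nrow(qc$included) > 0) tally_success_rates(qc$included) else NULL
  hash <- config_hash(config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(metrics))
      write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(records, file.path(out_dir, "qc_records.csv"), row.names = FALSE)
    write.csv(qc$exclusions, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
    if (!is.null(rates))
      write.csv(rates, file.path(out_dir, "success_rates.csv"), row.names = FALSE)
    for (id in names(maps))
      write_volume(volume_image(maps[[id]]$values, maps[[id]]$grid),
                   file.path(out_dir, paste0("jswmap_", id, ".nii.gz")))
    jsonlite::write_json(
      list(config_hash = hash,
           config = unclass(config),
           files = list.files(out_dir)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }

  list(metrics = metrics, records = records, exclusions = qc$exclusions,
       success_rates = rates, config_hash = hash, maps = maps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
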