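#' Pipeline configuration
#'
#' Aggregates every stage's parameters with the published operating point
#' as defaults: cortical mask depth 4 voxels, interruption diameter
#' threshold 0.41 mm, ROI radius 48 voxels, void diameter threshold
#' 0.738 mm, erosion 2 voxels.  Configurations round-trip through JSON
#' unchanged ([write_config()] / [read_config()]) and are echoed into
#' every output for a reproducibility audit trail.
#'
#' @param segmentation a [segmentation_params] object.
#' @param min_diameter_mm interruption diameter threshold in mm.
#' @param voids a [void_extension_params] object.
#' @param seed integer seed used wherever randomness is involved.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(segmentation = segmentation_params(),
                            min_diameter_mm = 0.41,
                            voids = void_extension_params(),
                            seed = 1L) {
  stopifnot(inherits(segmentation, "segmentation_params"),
            inherits(voids, "void_extension_params"),
            min_diameter_mm > 0)
  structure(list(segmentation = segmentation,
                 min_diameter_mm = min_diameter_mm,
                 voids = voids,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    segmentation = do.call(segmentation_params, raw$segmentation),
    min_diameter_mm = raw$min_diameter_mm,
    voids = do.call(void_extension_params, raw$voids),
    seed = raw$seed)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Analyze one joint volume
#'
#' Runs segmentation, periosteal contouring (or an operator-corrected
#' contour override), cortical masking, interruption detection, void
#' extension and morphometry on a single grayscale volume.
#'
#' @param vol an [image_volume].
#' @param config a [pipeline_config].
#' @param contour_override optional externally corrected outer-contour
#'   [binary_mask]; replaces [auto_outer_contour()].
#' @param keep_masks also return the intermediate masks.
#' @return A `joint_result` list: `metrics` ([compute_joint_metrics()]),
#'   `morpho` ([morphometry()]), `interruptions`, and optionally `masks`.
#' @export
run_joint <- function(vol, config = pipeline_config(),
                      contour_override = NULL, keep_masks = FALSE) {
  stopifnot(is_volume(vol), inherits(config, "pipeline_config"))
  sp <- config$segmentation
  bone <- laplace_hamming_binarize(vol, sp)
  outer <- if (!is.null(contour_override)) {
    stopifnot(is_mask(contour_override))
    contour_override
  } else {
    auto_outer_contour(bone, sp$closing_radius_mm)
  }
  cortex <- make_cortical_mask(outer, sp$mask_depth_voxels)
  interruptions <- detect_interruptions(bone, cortex, outer,
                                        config$min_diameter_mm,
                                        sp$mask_depth_voxels)
  ext <- extend_voids(bone, outer, interruptions, config$voids,
                      keep_intermediates = keep_masks)
  morpho <- morphometry(vol, bone, outer, sp$mask_depth_voxels)
  out <- list(metrics = ext$metrics, morpho = morpho,
              interruptions = interruptions, config = config)
  if (keep_masks)
    out$masks <- c(list(bone = bone, outer = outer, cortex = cortex,
                        final = ext$final), ext$stages)
  structure(out, class = "joint_result")
}

#' @export
print.joint_result <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}

#' Run the pipeline over a cohort of joints
#'
#' Applies [run_joint()] to each input.  A failing joint is recorded in
#' the cohort table with an error message and does not affect the others.
#' When `output_dir` is given, a JSON report per joint and a cohort CSV
#' (plus a parameter echo) are written; identical configuration, inputs
#' and seed yield byte-identical outputs.
#'
#' @param inputs named list of [image_volume] objects or file paths
#'   readable by [read_volume()].
#' @param config a [pipeline_config].
#' @param output_dir optional output directory.
#' @param contour_overrides optional named list of contour masks or paths,
#'   keyed like `inputs`.
#' @return List `cohort` (data.frame, one row per joint), `results`
#'   (per-joint `joint_result` or `NULL`), `errors` (named character).
#' @export
run_all <- function(inputs, config = pipeline_config(), output_dir = NULL,
                    contour_overrides = NULL) {
  stopifnot(length(inputs) >= 1)
  ids <- names(inputs) %||% paste0("joint", seq_along(inputs))
  if (is.null(names(inputs))) names(inputs) <- ids
  results <- setNames(vector("list", length(inputs)), ids)
  errors <- character(0)
  rows <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    id <- ids[i]
    rows[[i]] <- tryCatch({
      vol <- inputs[[i]]
      if (is.character(vol)) vol <- read_volume(vol)
      ov <- contour_overrides[[id]]
      if (is.character(ov)) ov <- read_mask(ov, role = "outer_contour")
      res <- run_joint(vol, config, contour_override = ov)
      results[[id]] <- res
      m <- res$metrics; mo <- res$morpho
      data.frame(joint_id = id, status = "ok",
                 n_interruptions = m$n_interruptions,
                 total_surface_mm2 = m$total_surface_mm2,
                 total_volume_mm3 = m$total_volume_mm3,
                 bvtv_total = mo$bvtv_total, bvtv_trab = mo$bvtv_trab,
                 tb_th_mm = mo$tb_th_mm, tb_sp_mm = mo$tb_sp_mm,
                 tb_spsd_mm = mo$tb_spsd_mm, tb_n_per_mm = mo$tb_n_per_mm,
                 ct_th_mm = mo$ct_th_mm, ct_po_fraction = mo$ct_po_fraction,
                 ct_po_dm_mm = mo$ct_po_dm_mm,
                 error = NA_character_)
    }, error = function(e) {
      errors[[id]] <<- conditionMessage(e)
      data.frame(joint_id = id, status = "error",
                 n_interruptions = NA_integer_,
                 total_surface_mm2 = NA_real_, total_volume_mm3 = NA_real_,
                 bvtv_total = NA_real_, bvtv_trab = NA_real_,
                 tb_th_mm = NA_real_, tb_sp_mm = NA_real_,
                 tb_spsd_mm = NA_real_, tb_n_per_mm = NA_real_,
                 ct_th_mm = NA_real_, ct_po_fraction = NA_real_,
                 ct_po_dm_mm = NA_real_,
                 error = conditionMessage(e))
    })
  }
  cohort <- do.call(rbind, rows)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(output_dir, "params.json"))
    write.csv(cohort, file.path(output_dir, "cohort.csv"),
              row.names = FALSE)
    for (id in ids) {
      if (is.null(results[[id]])) next
      m <- results[[id]]$metrics
      jsonlite::write_json(
        list(joint_id = id, n_interruptions = m$n_interruptions,
             total_surface_mm2 = m$total_surface_mm2,
             total_volume_mm3 = m$total_volume_mm3,
             per_interruption = m$per_interruption,
             morphometry = unclass(results[[id]]$morpho)),
        file.path(output_dir, paste0(id, ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }
  if (all(cohort$status == "error"))
    warning("all joints failed")
  list(cohort = cohort, results = results, errors = errors)
}
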