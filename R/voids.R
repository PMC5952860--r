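#' Void-extension parameters
#'
#' Constants of the second algorithm stage, which attaches the underlying
#' trabecular void volume to each detected cortical interruption.  The
#' defaults are the published operating point at the native 0.082 mm voxel
#' size: a spherical ROI of 48 voxels (3.936 mm) around each interruption,
#' a void diameter threshold of 0.738 mm (9 voxels; above the trabecular
#' separation seen in healthy MCP joints, so normal marrow spacing is not
#' selected), and a 2-voxel erosion that severs connections of <= 0.328 mm
#' so selected voids cannot leak into the trabecular network.
#'
#' @param roi_radius_voxels ROI dilation radius in voxels.
#' @param void_min_diameter_mm minimum trabecular void diameter in mm.
#' @param erode_voxels erosion radius in voxels.
#' @return A `void_extension_params` list.
#' @export
void_extension_params <- function(roi_radius_voxels = 48L,
                                  void_min_diameter_mm = 0.738,
                                  erode_voxels = 2L) {
  stopifnot(roi_radius_voxels >= 1, void_min_diameter_mm > 0,
            erode_voxels >= 1)
  structure(list(roi_radius_voxels = as.integer(roi_radius_voxels),
                 void_min_diameter_mm = void_min_diameter_mm,
                 erode_voxels = as.integer(erode_voxels)),
            class = "void_extension_params")
}

#' Region of interest around detected interruptions
#'
#' Dilates the interruption voxels by a Euclidean ball of
#' `roi_radius_voxels` (default 48 voxels = 3.936 mm, about half the width
#' of a metacarpal head) and intersects with the outer contour so only the
#' region inside the bone is considered.  The ROI bounds the search for
#' attached voids and prevents connection with the intramedullary canal.
#'
#' @param interruptions an `interruption_set`.
#' @param outer outer-contour [binary_mask].
#' @param roi_radius_voxels dilation radius in voxels.
#' @return A [binary_mask] with role `"roi"` (empty if no interruptions).
#' @export
build_roi <- function(interruptions, outer, roi_radius_voxels = 48L) {
  stopifnot(inherits(interruptions, "interruption_set"), is_mask(outer))
  if (!identical(dim(interruptions$label_map), dim(outer$data)))
    stop("interruption map and outer contour have different shapes")
  imask <- interruption_mask_arr(interruptions)
  if (!any(imask))
    return(binary_mask(outer$data & FALSE, outer$voxel_size_mm, "roi"))
  roi <- ball_dilate(imask, roi_radius_voxels) & outer$data
  binary_mask(array(roi, dim(outer$data)), outer$voxel_size_mm, "roi")
}

#' Select trabecular voids by local thickness
#'
#' Within the ROI, non-bone space is screened by a 3D distance
#' transformation: only voids at least `void_min_diameter_mm` in diameter
#' are selected.  Implemented as a local-thickness threshold, equivalent to
#' the morphological opening with a ball of half that diameter: a voxel is
#' kept iff it lies inside some inscribed sphere of the candidate space
#' with diameter >= the threshold.
#'
#' @param bone bone [binary_mask].
#' @param roi ROI [binary_mask] from [build_roi()].
#' @param void_min_diameter_mm diameter threshold in mm.
#' @return A [binary_mask] with role `"void"`.
#' @export
select_voids <- function(bone, roi, void_min_diameter_mm = 0.738) {
  stopifnot(is_mask(bone), is_mask(roi))
  check_same_grid(bone, roi, "bone/roi")
  candidate <- roi$data & !bone$data
  if (!any(candidate))
    return(binary_mask(candidate, bone$voxel_size_mm, "void"))
  th <- local_thickness_vox(candidate) * bone$voxel_size_mm
  binary_mask(array(candidate & th >= void_min_diameter_mm,
                    dim(candidate)),
              bone$voxel_size_mm, "void")
}

#' Erode selected voids
#'
#' Euclidean-ball erosion by `erode_voxels` (default 2).  Any neck of
#' diameter `<= 2 * erode_voxels` voxels (0.328 mm at default settings)
#' disappears, disconnecting voids from thin trabecular passages before
#' the connectivity test.
#'
#' @param void void [binary_mask] from [select_voids()].
#' @param erode_voxels erosion radius in voxels.
#' @return Eroded [binary_mask] with role `"void"`.
#' @export
erode_voids <- function(void, erode_voxels = 2L) {
  stopifnot(is_mask(void), erode_voxels >= 0)
  binary_mask(array(ball_erode(void$data, erode_voxels), dim(void$data)),
              void$voxel_size_mm, "void")
}

#' Keep voids connected to a cortical interruption
#'
#' Retains eroded void components that overlap or are 26-adjacent to any
#' interruption voxel; isolated intramedullary voids are dropped.
#'
#' @param eroded eroded void [binary_mask].
#' @param interruptions an `interruption_set`.
#' @return Filtered [binary_mask] with role `"void"`.
#' @export
keep_connected_to_interruption <- function(eroded, interruptions) {
  stopifnot(is_mask(eroded), inherits(interruptions, "interruption_set"))
  if (!identical(dim(eroded$data), dim(interruptions$label_map)))
    stop("grids differ")
  imask <- interruption_mask_arr(interruptions)
  if (!any(eroded$data) || !any(imask))
    return(binary_mask(eroded$data & FALSE, eroded$voxel_size_mm, "void"))
  lab <- label3d(eroded$data, 26L)
  touch <- dilate26(imask)
  keep_ids <- unique(lab[touch & lab > 0L])
  binary_mask(array(lab %in% keep_ids & lab > 0L, dim(lab)),
              eroded$voxel_size_mm, "void")
}

#' Restore kept voids to their original size and add the interruptions
#'
#' Restores by geodesic dilation: `erode_voxels` iterations of a
#' unit-neighbourhood dilation, each constrained to the pre-erosion void
#' mask.  Constrained reconstruction rather than free dilation, so the
#' thin connections severed by [erode_voids()] do not regrow (free
#' dilation would undo the leak protection); an isolated cavity is
#' restored to its original extent exactly.  The original interruption
#' voxels are then unioned in.
#'
#' @param kept [binary_mask] from [keep_connected_to_interruption()].
#' @param pre_erosion_void the [select_voids()] output.
#' @param interruptions an `interruption_set`.
#' @param erode_voxels the erosion radius used by [erode_voids()].
#' @return Final [binary_mask] (role `"void"`): interruptions plus their
#'   attached trabecular void volume.
#' @export
restore_and_merge <- function(kept, pre_erosion_void, interruptions,
                              erode_voxels = 2L) {
  stopifnot(is_mask(kept), is_mask(pre_erosion_void),
            inherits(interruptions, "interruption_set"))
  check_same_grid(kept, pre_erosion_void, "kept/pre-erosion masks")
  restored <- kept$data
  if (any(restored)) {
    for (i in seq_len(erode_voxels))
      restored <- dilate26(restored) & pre_erosion_void$data
  }
  final <- restored | interruption_mask_arr(interruptions)
  binary_mask(array(final, dim(final)), kept$voxel_size_mm, "void")
}

#' Run the full void-extension stage
#'
#' Convenience wrapper chaining [build_roi()], [select_voids()],
#' [erode_voids()], [keep_connected_to_interruption()] and
#' [restore_and_merge()], optionally returning every intermediate mask for
#' inspection.
#'
#' @param bone bone [binary_mask].
#' @param outer outer-contour [binary_mask].
#' @param interruptions an `interruption_set`.
#' @param params a [void_extension_params] object.
#' @param keep_intermediates return the per-stage masks as well.
#' @return List with `final` ([binary_mask]), `metrics` (see
#'   [compute_joint_metrics()]) and, if requested, `stages`.
#' @export
extend_voids <- function(bone, outer, interruptions,
                         params = void_extension_params(),
                         keep_intermediates = FALSE) {
  roi <- build_roi(interruptions, outer, params$roi_radius_voxels)
  voids <- select_voids(bone, roi, params$void_min_diameter_mm)
  eroded <- erode_voids(voids, params$erode_voxels)
  kept <- keep_connected_to_interruption(eroded, interruptions)
  final <- restore_and_merge(kept, voids, interruptions,
                             params$erode_voxels)
  metrics <- compute_joint_metrics(final, interruptions)
  out <- list(final = final, metrics = metrics)
  if (keep_intermediates)
    out$stages <- list(roi = roi, voids = voids, eroded = eroded,
                       kept = kept)
  out
}

#' Per-joint interruption metrics
#'
#' Summarizes an analysis into the three clinical endpoints: the number of
#' cortical interruptions, their total surface, and their total volume
#' (cortical interruption plus attached trabecular void).  Volume is
#' measured on the final mask's 26-connected components; a component
#' containing several interruptions is counted once, with all member
#' interruption ids cross-referenced, so no volume is double counted.
#'
#' @param final final void+interruption [binary_mask] from
#'   [restore_and_merge()].
#' @param interruptions the `interruption_set` the mask was built from.
#' @return A `joint_metrics` list: `n_interruptions`, `total_surface_mm2`,
#'   `total_volume_mm3`, `per_interruption` (data.frame: `id`,
#'   `surface_mm2`, `diameter_mm`, `truncated`, `final_component`,
#'   `component_volume_mm3`, `shares_component`), `per_component`
#'   (data.frame: `final_component`, `volume_mm3`, `interruption_ids`).
#' @export
compute_joint_metrics <- function(final, interruptions) {
  stopifnot(is_mask(final), inherits(interruptions, "interruption_set"))
  v <- final$voxel_size_mm
  per <- interruptions$per_component
  if (nrow(per) == 0L) {
    return(structure(list(n_interruptions = 0L, total_surface_mm2 = 0,
                          total_volume_mm3 = 0,
                          per_interruption = data.frame(),
                          per_component = data.frame()),
                     class = "joint_metrics"))
  }
  imask <- interruption_mask_arr(interruptions)
  if (any(imask & !final$data))
    stop("final mask must contain all interruption voxels")
  flab <- label3d(final$data, 26L)
  # final component hosting each interruption
  comp_of <- vapply(seq_len(nrow(per)), function(i) {
    ids <- unique(flab[interruptions$label_map == i])
    ids <- ids[ids > 0]
    ids[1]
  }, numeric(1))
  counts <- tabulate(flab[flab > 0L])
  comp_ids <- sort(unique(comp_of))
  per_component <- data.frame(
    final_component = comp_ids,
    volume_mm3 = counts[comp_ids] * v^3,
    interruption_ids = vapply(comp_ids, function(cid)
      paste(per$id[comp_of == cid], collapse = ";"), character(1)))
  per_interruption <- data.frame(
    id = per$id,
    surface_mm2 = per$surface_mm2,
    diameter_mm = per$max_inscribed_diameter_mm,
    truncated = per$truncated,
    final_component = comp_of,
    component_volume_mm3 = counts[comp_of] * v^3,
    shares_component = duplicated(comp_of) | duplicated(comp_of,
                                                        fromLast = TRUE))
  structure(list(
    n_interruptions = nrow(per),
    total_surface_mm2 = sum(per$surface_mm2),
    total_volume_mm3 = sum(per_component$volume_mm3),
    per_interruption = per_interruption,
    per_component = per_component), class = "joint_metrics")
}

#' @export
print.joint_metrics <- function(x, ...) {
  cat(sprintf(paste0("<joint_metrics> n = %d, surface = %.3f mm^2, ",
                     "volume = %.3f mm^3\n"),
              x$n_interruptions, x$total_surface_mm2, x$total_volume_mm3))
  invisible(x)
}
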