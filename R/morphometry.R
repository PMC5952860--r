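#' Local thickness of a binary structure
#'
#' Direct (model-independent) thickness in the Hildebrand-Rueegsegger
#' sense: for every foreground voxel, the diameter of the largest sphere
#' that contains it and fits entirely inside the structure, computed by
#' sphere painting over the Euclidean distance transform.  Sphere radii use
#' the half-voxel boundary convention (`EDT - 0.5`), so a slab of n voxels
#' has thickness exactly `n * voxel_size`.
#'
#' @param mask a [binary_mask].
#' @return List with `map` (3D array, mm; 0 outside), `mean_mm`, `sd_mm`
#'   over foreground voxels.
#' @export
local_thickness <- function(mask) {
  stopifnot(is_mask(mask))
  if (!any(mask$data)) stop("empty mask")
  th <- local_thickness_vox(mask$data) * mask$voxel_size_mm
  vals <- th[mask$data]
  list(map = th, mean_mm = mean(vals), sd_mm = if (length(vals) > 1)
    sd(vals) else 0)
}

#' Trabecular micro-structure metrics
#'
#' Distance-transform surrogates for the standard-evaluation trabecular
#' parameters, computed in the trabecular region (outer contour eroded by
#' the cortical depth): Tb.Th = mean local thickness of bone, Tb.Sp /
#' Tb.SpSD = mean / SD of local thickness of marrow, and Tb.N from the
#' plate-model relation `1 / (Tb.Th + Tb.Sp)` (definition flagged in the
#' output, since the scanner's ridge-based Tb.N differs).
#'
#' @param bone bone [binary_mask].
#' @param trab_region logical array or [binary_mask]: the trabecular
#'   compartment.
#' @return List `tb_th_mm`, `tb_sp_mm`, `tb_spsd_mm`, `tb_n_per_mm`,
#'   `tb_n_definition`.
#' @export
trabecular_metrics <- function(bone, trab_region) {
  stopifnot(is_mask(bone))
  region <- if (is_mask(trab_region)) trab_region$data else trab_region
  if (!any(region)) stop("empty trabecular region")
  v <- bone$voxel_size_mm
  tb_bone <- bone$data & region
  tb_marrow <- !bone$data & region
  if (!any(tb_bone)) stop("no trabecular bone in region")
  if (!any(tb_marrow))
    stop("trabecular separation undefined: region is solid bone")
  th_b <- local_thickness_vox(tb_bone)[tb_bone] * v
  th_m <- local_thickness_vox(tb_marrow)[tb_marrow] * v
  tb_th <- mean(th_b)
  tb_sp <- mean(th_m)
  list(tb_th_mm = tb_th, tb_sp_mm = tb_sp,
       tb_spsd_mm = if (length(th_m) > 1) sd(th_m) else 0,
       tb_n_per_mm = 1 / (tb_th + tb_sp),
       tb_n_definition = "plate-model 1/(Tb.Th + Tb.Sp)")
}

#' Cortical micro-structure metrics
#'
#' Ct.Th = local thickness of the *full* bone structure averaged over the
#' cortical (peel) voxels -- the inscribed spheres live in the whole
#' cortical shell, so an intact 0.8 mm shell reads 0.8 mm even though the
#' peel itself is only 4 voxels deep.  Ct.Po = enclosed-pore voxel
#' fraction of the cortical peel, where pores are non-bone peel
#' components that do *not* span both faces of the peel (spanning
#' components are cortical interruptions and counted separately, never
#' double counted); Ct.Po.Dm = mean local thickness of those pore voxels.
#'
#' @param bone bone [binary_mask].
#' @param cortex cortical-peel [binary_mask].
#' @param outer the outer contour the peel was derived from.
#' @param depth_voxels peel depth (for the face-spanning test).
#' @return List `ct_th_mm`, `ct_po_fraction`, `ct_po_dm_mm` (NA when there
#'   are no pores).
#' @export
cortical_metrics <- function(bone, cortex, outer, depth_voxels = 4L) {
  stopifnot(is_mask(bone), is_mask(cortex), is_mask(outer))
  if (!any(cortex$data)) stop("empty cortical mask")
  v <- bone$voxel_size_mm
  ct_bone <- bone$data & cortex$data
  if (!any(ct_bone)) stop("no cortical bone inside the cortex mask")
  ct_th <- mean(local_thickness_vox(bone$data)[ct_bone]) * v

  candidate <- cortex$data & !bone$data
  pores <- candidate
  if (any(candidate)) {
    lab <- label3d(candidate, 26L)
    outside_adj <- dilate26(!outer$data)
    interior_adj <- dilate26(cortical_interior(outer, depth_voxels))
    fg <- lab > 0L
    labs_fg <- lab[fg]
    spanning <- intersect(unique(labs_fg[outside_adj[fg]]),
                          unique(labs_fg[interior_adj[fg]]))
    pores <- candidate & !(lab %in% spanning)
  }
  n_pore <- sum(pores)
  list(ct_th_mm = ct_th,
       ct_po_fraction = n_pore / sum(cortex$data),
       ct_po_dm_mm = if (n_pore > 0)
         mean(local_thickness_vox(pores)[pores]) * v else NA_real_)
}

#' Full morphometry panel for a joint
#'
#' Bone volume fractions, mean attenuation, and the trabecular and
#' cortical distance-transform surrogates in one call.  Calibrated
#' volumetric BMD in mg HA/cm^3 is deliberately not computed -- it
#' requires a scanner density calibration -- so BV/TV and mean attenuation
#' stand in for the density endpoints.
#'
#' @param vol grayscale [image_volume] (for mean attenuation); may be
#'   `NULL`.
#' @param bone bone [binary_mask].
#' @param outer outer-contour [binary_mask].
#' @param depth_voxels cortical peel depth in voxels.
#' @return A `morphometry_result` list with fields `bvtv_total`,
#'   `bvtv_trab`, `mean_attenuation`, `tb_th_mm`, `tb_sp_mm`,
#'   `tb_spsd_mm`, `tb_n_per_mm`, `tb_n_definition`, `ct_th_mm`,
#'   `ct_po_fraction`, `ct_po_dm_mm`.
#' @export
morphometry <- function(vol, bone, outer, depth_voxels = 4L) {
  stopifnot(is_mask(bone), is_mask(outer))
  check_same_grid(bone, outer, "bone/outer")
  cortex <- make_cortical_mask(outer, depth_voxels)
  ct <- cortical_metrics(bone, cortex, outer, depth_voxels)
  # trabecular compartment: peel off the full cortical shell (estimated by
  # Ct.Th) rather than only the 4-voxel detection peel, an endosteal
  # surrogate for the inner-contour protocols
  shell_vox <- max(depth_voxels,
                   ceiling(ct$ct_th_mm / bone$voxel_size_mm) + 1L)
  trab <- cortical_interior(outer, shell_vox)
  if (!any(trab))
    stop("no trabecular compartment after removing the cortical shell")
  tb <- trabecular_metrics(bone, trab)
  res <- c(list(
    bvtv_total = sum(bone$data & outer$data) / sum(outer$data),
    bvtv_trab = sum(bone$data & trab) / sum(trab),
    mean_attenuation = if (is_volume(vol))
      mean(vol$data[outer$data]) else NA_real_), tb, ct)
  structure(res, class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result>\n")
  cat(sprintf("  BV/TV total %.3f, trab %.3f\n", x$bvtv_total, x$bvtv_trab))
  cat(sprintf("  Tb.Th %.3f mm, Tb.Sp %.3f mm, Tb.SpSD %.3f mm, Tb.N %.2f /mm\n",
              x$tb_th_mm, x$tb_sp_mm, x$tb_spsd_mm, x$tb_n_per_mm))
  cat(sprintf("  Ct.Th %.3f mm, Ct.Po %.4f, Ct.Po.Dm %s mm\n",
              x$ct_th_mm, x$ct_po_fraction,
              ifelse(is.na(x$ct_po_dm_mm), "n.a.",
                     sprintf("%.3f", x$ct_po_dm_mm))))
  invisible(x)
}
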