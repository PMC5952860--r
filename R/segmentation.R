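#' Segmentation parameters
#'
#' Parameters of the bone binarization and periosteal contouring stage.
#' The scanner's standard evaluation protocol applies Laplace-Hamming
#' filtering and a fixed threshold; the exact manufacturer coefficients are
#' not public, so the defaults here are documented surrogates exposed for
#' adjustment.
#'
#' @param hamming_cutoff low-pass cutoff as a fraction of the Nyquist
#'   frequency, in (0, 1]; `1` disables the window entirely.
#' @param laplace_weight blend weight of the Laplacian edge enhancement,
#'   in \[0, 1\]; `0` disables sharpening.
#' @param threshold_fraction binarization threshold as a fraction of the
#'   filtered dynamic range, in (0, 1).
#' @param closing_radius_mm ball radius of the morphological closing used
#'   by the periosteal auto-contour.  The default 2.5 mm bridges cortical
#'   defects up to about 5 mm; larger defects need an operator-corrected
#'   contour supplied externally, mirroring clinical practice.
#' @param mask_depth_voxels depth of the cortical peel, default 4 voxels
#'   (0.328 mm at the native voxel size).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(hamming_cutoff = 0.8, laplace_weight = 0.5,
                                threshold_fraction = 0.4,
                                closing_radius_mm = 2.5,
                                mask_depth_voxels = 4L) {
  stopifnot(hamming_cutoff > 0, hamming_cutoff <= 1,
            laplace_weight >= 0, laplace_weight <= 1,
            threshold_fraction > 0, threshold_fraction < 1,
            closing_radius_mm > 0, mask_depth_voxels >= 1)
  structure(list(hamming_cutoff = hamming_cutoff,
                 laplace_weight = laplace_weight,
                 threshold_fraction = threshold_fraction,
                 closing_radius_mm = closing_radius_mm,
                 mask_depth_voxels = as.integer(mask_depth_voxels)),
            class = "segmentation_params")
}

# frequency-domain Hamming-window low-pass; cutoff as fraction of Nyquist
hamming_lowpass3 <- function(arr, cutoff) {
  if (cutoff >= 1) return(arr)
  d <- dim(arr)
  nu_axis <- function(n) {
    k <- 0:(n - 1)
    pmin(k, n - k) / (n / 2)
  }
  nx <- nu_axis(d[1]); ny <- nu_axis(d[2]); nz <- nu_axis(d[3])
  nu <- sqrt(outer(outer(nx^2, ny^2, "+"), nz^2, "+"))
  H <- ifelse(nu <= cutoff, 0.54 + 0.46 * cos(pi * nu / cutoff), 0)
  Re(fft(fft(arr) * H, inverse = TRUE)) / prod(d)
}

#' Binarize a grayscale volume by Laplace-Hamming filtering and thresholding
#'
#' The volume is low-pass filtered with a frequency-domain Hamming window
#' (noise suppression), sharpened by subtracting a weighted discrete
#' Laplacian (edge enhancement), and thresholded at a fixed fraction of the
#' filtered dynamic range.  With `hamming_cutoff = 1` and
#' `laplace_weight = 0` this degenerates to plain thresholding.
#'
#' @param vol an [image_volume] (grayscale).
#' @param params a [segmentation_params] object.
#' @return A [binary_mask] with role `"bone"`.
#' @export
laplace_hamming_binarize <- function(vol, params = segmentation_params()) {
  stopifnot(is_volume(vol))
  rng <- range(vol$data)
  if (diff(rng) == 0) stop("no dynamic range: volume is constant-valued")
  filt <- hamming_lowpass3(vol$data, params$hamming_cutoff)
  if (params$laplace_weight > 0)
    filt <- filt - params$laplace_weight * laplacian3(filt)
  frng <- range(filt)
  thr <- frng[1] + params$threshold_fraction * diff(frng)
  binary_mask(filt >= thr, vol$voxel_size_mm, "bone")
}

#' Automatic periosteal (outer) contour
#'
#' Produces the filled solid region bounded by the periosteal surface:
#' morphological closing of the bone mask with a Euclidean ball of
#' `closing_radius_mm`, 3D hole filling, then retention of the largest
#' 26-connected component.  The closing bridges cortical interruptions up
#' to twice the closing radius so the contour follows the outer margin of
#' the original structure across defects.  Operator-corrected contours can
#' be loaded with [read_mask()] and used in place of this function's
#' output.
#'
#' @param bone a [binary_mask] with the segmented bone.
#' @param closing_radius_mm closing ball radius in mm.
#' @return A [binary_mask] with role `"outer_contour"`; contains every bone
#'   voxel of the retained component.
#' @export
auto_outer_contour <- function(bone, closing_radius_mm = 2.5) {
  stopifnot(is_mask(bone))
  if (!any(bone$data)) stop("empty bone mask")
  r <- closing_radius_mm / bone$voxel_size_mm
  closed <- ball_close(bone$data, r)
  filled <- fill_holes3(closed)
  # closing is extensive, so every bone voxel of the retained component is
  # inside it by construction
  main <- largest_component(filled)
  binary_mask(array(main, dim(bone$data)), bone$voxel_size_mm,
              "outer_contour")
}

#' Fixed-depth cortical mask
#'
#' Peels a constant-depth layer (default 4 voxels = 0.328 mm) off the outer
#' contour: the mask is the outer contour minus its Euclidean-ball erosion
#' by `depth_voxels`.  Cortical interruptions are sought inside this peel.
#'
#' @param outer a filled outer-contour [binary_mask].
#' @param depth_voxels peel depth in voxels.
#' @return A [binary_mask] with role `"cortical_mask"`.
#' @export
make_cortical_mask <- function(outer, depth_voxels = 4L) {
  stopifnot(is_mask(outer), depth_voxels >= 0)
  if (depth_voxels == 0)
    return(binary_mask(outer$data & FALSE, outer$voxel_size_mm,
                       "cortical_mask"))
  interior <- ball_erode(outer$data, depth_voxels)
  if (any(outer$data) && !any(interior))
    stop("mask consumes object: depth ", depth_voxels,
         " voxels leaves no interior")
  binary_mask(outer$data & !interior, outer$voxel_size_mm, "cortical_mask")
}

# interior region (outer contour minus cortical peel), the trabecular
# compartment used by morphometry and the endosteal-face test
cortical_interior <- function(outer, depth_voxels = 4L) {
  ball_erode(outer$data, depth_voxels)
}
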