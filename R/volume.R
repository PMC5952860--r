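#' Image volumes and binary masks
#'
#' `image_volume()` wraps a 3D numeric array with an isotropic voxel size in
#' millimetres; `binary_mask()` does the same for a logical array with a
#' `role` tag identifying what the mask delineates.  Both are plain lists
#' with classes `"image_volume"` / `"binary_mask"`.
#'
#' Arrays are stored in R column-major order with the *third* axis as the
#' scan (z) axis, so an acquisition stack is a contiguous block of slices
#' `vol$data[, , i:j]`.  The method is defined on isotropic grids (HR-pQCT
#' reconstructs at 82 um nominal isotropic voxel size); anisotropic input is
#' rejected at load time because every diameter threshold is expressed in
#' voxel units.
#'
#' @param data 3D numeric (volume) or logical/0-1 (mask) array.
#' @param voxel_size_mm positive scalar, isotropic voxel edge length in mm.
#' @param role mask role tag, one of `"bone"`, `"outer_contour"`,
#'   `"cortical_mask"`, `"roi"`, `"void"`, `"interruption"`.
#' @return An `image_volume` or `binary_mask` object.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 8)), 0.082)
#' m <- binary_mask(array(FALSE, c(8, 8, 8)), 0.082, "bone")
#' @export
image_volume <- function(data, voxel_size_mm) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a positive scalar")
  storage.mode(data) <- "double"
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
binary_mask <- function(data, voxel_size_mm, role = "bone") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.logical(data)) {
    u <- unique(as.vector(data))
    if (!all(u %in% c(0, 1)))
      stop("mask data must be logical or 0/1")
    data <- array(data != 0, dim(data))
  }
  role <- match.arg(role, mask_roles())
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a positive scalar")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 role = role),
            class = "binary_mask")
}

mask_roles <- function() {
  c("bone", "outer_contour", "cortical_mask", "roi", "void", "interruption")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels @ %.4g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size_mm,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask:%s> %d x %d x %d voxels @ %.4g mm, %d foreground\n",
              x$role, d[1], d[2], d[3], x$voxel_size_mm, sum(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
dim.binary_mask <- function(x) dim(x$data)

#' @export
as.array.image_volume <- function(x, ...) x$data

#' @export
as.array.binary_mask <- function(x, ...) x$data

is_mask <- function(x) inherits(x, "binary_mask")
is_volume <- function(x) inherits(x, "image_volume")

# shape/voxel-size compatibility guard used across module boundaries
check_same_grid <- function(a, b, what = "masks") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("%s have different shapes (%s vs %s)", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")))
  if (abs(a$voxel_size_mm - b$voxel_size_mm) > 1e-9)
    stop(sprintf("%s have different voxel sizes (%g vs %g mm)", what,
                 a$voxel_size_mm, b$voxel_size_mm))
  invisible(TRUE)
}

#' Convert a physical length to a voxel count
#'
#' Single conversion point between millimetres and voxel units; every
#' diameter/depth/radius threshold in the package goes through it.  At the
#' native 0.082 mm voxel size the method's constants map to integers:
#' 0.328 mm -> 4 voxels (cortical mask depth), 3.936 mm -> 48 voxels (ROI
#' dilation radius), 0.738 mm -> 9 voxels (void diameter threshold).
#'
#' @param length_mm positive length in mm.
#' @param voxel_size_mm positive isotropic voxel size in mm.
#' @return Integer voxel count, `round(length_mm / voxel_size_mm)`.
#' @examples
#' mm_to_voxels(0.328, 0.082)  # 4
#' mm_to_voxels(3.936, 0.082)  # 48
#' @export
mm_to_voxels <- function(length_mm, voxel_size_mm) {
  if (!is.numeric(length_mm) || any(length_mm <= 0))
    stop("`length_mm` must be positive")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be positive")
  as.integer(round(length_mm / voxel_size_mm))
}

#' Scan stack layout
#'
#' Describes how an acquisition is divided into contiguous axial stacks.
#' The joint protocol acquires 3 stacks of 110 slices (9.02 mm each,
#' 27.06 mm total at 0.082 mm voxels).
#'
#' @param n_stacks number of stacks.
#' @param slices_per_stack slices per stack.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @return A `scan_layout` object with derived `stack_length_mm` and
#'   `total_length_mm`.
#' @examples
#' scan_layout(3, 110, 0.082)$total_length_mm  # 27.06
#' @export
scan_layout <- function(n_stacks = 3L, slices_per_stack = 110L,
                        voxel_size_mm = 0.082) {
  stopifnot(n_stacks >= 1, slices_per_stack >= 1, voxel_size_mm > 0)
  structure(list(
    n_stacks = as.integer(n_stacks),
    slices_per_stack = as.integer(slices_per_stack),
    voxel_size_mm = voxel_size_mm,
    stack_length_mm = slices_per_stack * voxel_size_mm,
    total_length_mm = n_stacks * slices_per_stack * voxel_size_mm
  ), class = "scan_layout")
}

#' @export
print.scan_layout <- function(x, ...) {
  cat(sprintf("<scan_layout> %d stacks x %d slices @ %.3g mm (%.4g mm total)\n",
              x$n_stacks, x$slices_per_stack, x$voxel_size_mm,
              x$total_length_mm))
  invisible(x)
}

# z-slice indices of stack i (1-based), for stack-wise QC bookkeeping
stack_slices <- function(layout, i) {
  stopifnot(i >= 1, i <= layout$n_stacks)
  ((i - 1L) * layout$slices_per_stack + 1L):(i * layout$slices_per_stack)
}
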