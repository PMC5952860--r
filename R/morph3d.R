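# Low-level 3D morphology built on the C++ distance-transform kernel.
# Structuring elements are digitized Euclidean balls obtained by
# thresholding the EDT, not iterated 3x3x3 crosses: dilating a point 48
# times must yield a sphere of radius 48 voxels, which iterated crosses do
# not produce.  Foreground connectivity is 26-neighbour, background
# 6-neighbour, throughout.

# squared distance (voxel units) to nearest FALSE voxel.  Space beyond the
# volume border is treated as foreground, which is the right convention for
# anatomy cut by the stack boundary.
edt_sq <- function(mask_arr) {
  d <- dim(mask_arr)
  array(.edt_sq_cpp(as.logical(mask_arr), as.integer(d)), d)
}

# Euclidean distance (voxel units) to nearest background voxel; 0 outside
edt <- function(mask_arr) sqrt(edt_sq(mask_arr))

# distance to nearest foreground voxel; 0 on foreground
dist_to_fg <- function(mask_arr) sqrt(edt_sq(!mask_arr))

# erosion by Euclidean ball of radius r voxels: keep voxels farther than r
# from background
ball_erode <- function(mask_arr, r) {
  if (r <= 0) return(mask_arr)
  edt_sq(mask_arr) > r^2
}

# morphological closing by a Euclidean ball, evaluated as in infinite
# space: the volume is padded by the ball radius so the dilation is never
# clipped at the border and the erosion sees true background all around
ball_close <- function(mask_arr, r) {
  if (r <= 0) return(mask_arr)
  d <- dim(mask_arr)
  p <- as.integer(ceiling(r) + 1)
  dp <- d + 2L * p
  padded <- array(FALSE, dp)
  padded[(p + 1):(p + d[1]), (p + 1):(p + d[2]), (p + 1):(p + d[3])] <-
    mask_arr
  closed <- ball_erode(ball_dilate(padded, r), r)
  closed[(p + 1):(p + d[1]), (p + 1):(p + d[2]), (p + 1):(p + d[3])]
}

# dilation by Euclidean ball of radius r voxels
ball_dilate <- function(mask_arr, r) {
  if (r <= 0) return(mask_arr)
  edt_sq(!mask_arr) <= r^2
}

# 26-neighbourhood dilation = Euclidean ball of radius sqrt(3)
dilate26 <- function(mask_arr) ball_dilate(mask_arr, sqrt(3) + 1e-9)

# connected components; labels consecutive from 1 in scan order
label3d <- function(mask_arr, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  d <- dim(mask_arr)
  array(.label3d_cpp(as.logical(mask_arr), as.integer(d),
                     as.integer(connectivity)), d)
}

# fill background cavities: 6-connected background components that do not
# touch the volume border become foreground
fill_holes3 <- function(mask_arr) {
  bg <- !mask_arr
  lab <- label3d(bg, 6L)
  d <- dim(mask_arr)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0]
  mask_arr | !(lab %in% c(0L, border))
}

# retain the largest 26-connected component
largest_component <- function(mask_arr) {
  lab <- label3d(mask_arr, 26L)
  if (max(lab) == 0L) return(mask_arr & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# local thickness map in voxel units (diameter of largest inscribed sphere
# containing each voxel)
local_thickness_vox <- function(mask_arr) {
  d <- dim(mask_arr)
  array(.local_thickness_cpp(as.logical(mask_arr), as.integer(d)), d)
}

# separable Gaussian blur, sigma in voxels
gauss_blur3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  array(.gauss_blur3_cpp(as.numeric(arr), as.integer(d),
                         as.numeric(sigma_vox)), d)
}

# inscribed-sphere diameter (voxel units) of each labelled component:
# 2 * (max EDT - 0.5), the same half-voxel convention as local thickness
component_diameters_vox <- function(mask_arr, lab) {
  k <- max(lab)
  if (k == 0L) return(numeric(0))
  dmap <- edt(mask_arr)
  fg <- lab > 0L
  dm <- vapply(split(dmap[fg], lab[fg]), max, numeric(1))
  dm <- dm[order(as.integer(names(dm)))]
  unname(pmax(2 * (dm - 0.5), 0))
}

# discrete 6-neighbour Laplacian with replicated edges
laplacian3 <- function(arr) {
  d <- dim(arr)
  sh <- function(ax, by) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  sh(1, 1L) + sh(1, -1L) + sh(2, 1L) + sh(2, -1L) + sh(3, 1L) + sh(3, -1L) -
    6 * arr
}
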