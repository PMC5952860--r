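#' Synthetic joint phantom specification
#'
#' Describes a metacarpal-head-like test object: a spherical cortical
#' shell filled with a cubic rod lattice, with optional drilled
#' interruption channels and sub-cortical void cavities of controlled
#' size, imaged as a two-level grayscale volume (bone ~1000, marrow ~0)
#' with Gaussian blur and additive Gaussian noise.  The geometry gives
#' every downstream stage a known ground truth.
#'
#' Defaults emulate the in vivo acquisition: 0.082 mm voxels, a cortex
#' of 0.8 mm, and a trabecular lattice whose marrow spacing stays below
#' the 0.738 mm void-diameter threshold so normal marrow is never selected
#' as void (rod pitch 0.6 mm gives a maximal marrow inscribed diameter of
#' `sqrt(2) * 0.6 - 0.2 = 0.65` mm).
#'
#' @param shape_voxels volume dimensions (x, y, z).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param cortex_thickness_mm cortical shell thickness in mm.
#' @param trabecular_rod_mm rod diameter in mm.
#' @param trabecular_spacing_mm rod-to-rod gap in mm (pitch = rod + gap).
#' @param interruptions list of interruption descriptors, each a list
#'   `diameter_mm`, `void_volume_mm3`, `direction` (3-vector from the
#'   joint centre to the drill site on the surface).  Use
#'   `void_volume_mm3 = 0` for a channel with no cavity.
#' @param noise_sigma additive Gaussian noise SD in gray units.
#' @param blur_sigma_mm Gaussian point-spread SD in mm.
#' @param seed integer seed; fully determines the output.
#' @param outer_radius_mm outer shell radius; default fits the volume
#'   with a 0.75 mm margin.
#' @param bone_value gray level of bone (marrow is 0).
#' @param decoy_void add an unconnected decoy cavity at the joint centre
#'   (when at least one interruption exists and space allows) so the
#'   connectivity filter is exercised negatively as well.
#' @return A `phantom_spec` list.
#' @seealso [make_joint_phantom()], [rescan_variant()]
#' @export
phantom_spec <- function(shape_voxels = c(112L, 112L, 112L),
                         voxel_size_mm = 0.082,
                         cortex_thickness_mm = 0.8,
                         trabecular_rod_mm = 0.2,
                         trabecular_spacing_mm = 0.4,
                         interruptions = list(),
                         noise_sigma = 50,
                         blur_sigma_mm = 0.05,
                         seed = 1L,
                         outer_radius_mm = NULL,
                         bone_value = 1000,
                         decoy_void = TRUE) {
  stopifnot(length(shape_voxels) == 3, all(shape_voxels >= 16),
            voxel_size_mm > 0, cortex_thickness_mm > 0,
            trabecular_rod_mm > 0, trabecular_spacing_mm > 0,
            noise_sigma >= 0, blur_sigma_mm >= 0)
  structure(list(shape_voxels = as.integer(shape_voxels),
                 voxel_size_mm = voxel_size_mm,
                 cortex_thickness_mm = cortex_thickness_mm,
                 trabecular_rod_mm = trabecular_rod_mm,
                 trabecular_spacing_mm = trabecular_spacing_mm,
                 interruptions = interruptions,
                 noise_sigma = noise_sigma,
                 blur_sigma_mm = blur_sigma_mm,
                 seed = as.integer(seed),
                 outer_radius_mm = outer_radius_mm,
                 bone_value = bone_value,
                 decoy_void = isTRUE(decoy_void)),
            class = "phantom_spec")
}

#' Reference three-interruption configuration
#'
#' Channels of 0.6, 0.8 and 1.2 mm diameter over voids of 2, 4 and 8 mm^3
#' drilled along three orthogonal directions.
#'
#' @return A list usable as the `interruptions` argument of
#'   [phantom_spec()].
#' @export
reference_interruptions <- function() {
  list(list(diameter_mm = 0.6, void_volume_mm3 = 2, direction = c(0, 0, 1)),
       list(diameter_mm = 0.8, void_volume_mm3 = 4, direction = c(1, 0, 0)),
       list(diameter_mm = 1.2, void_volume_mm3 = 8, direction = c(0, -1, 0)))
}

#' Generate a joint phantom with known ground truth
#'
#' Builds the noiseless two-level geometry the specification object describes, carves
#' the interruption channels (radial cylinders through the cortex) and
#' their sub-cortical void cavities (spheres tangent to the periosteal
#' surface, the geometry of a real erosion cavity, so void and channel
#' are connected by construction), then applies Gaussian blur and noise.
#'
#' @param spec a [phantom_spec].
#' @return A `joint_phantom` list: `volume` (noisy [image_volume]),
#'   `clean` (noise-free blurred [image_volume]), and `truth` with
#'   `n_interruptions`, `per_interruption` (id, diameter_mm, requested and
#'   achieved void volume, channel volume, total defect volume, centre,
#'   direction), ground-truth masks (`bone`, `solid`, `void`) as logical
#'   arrays, `decoy` info and the generating `spec`.
#' @export
make_joint_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape_voxels
  v <- spec$voxel_size_mm
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) * v
  cy <- (seq_len(d[2]) - (d[2] + 1) / 2) * v
  cz <- (seq_len(d[3]) - (d[3] + 1) / 2) * v
  R_out <- spec$outer_radius_mm %||% (min(d) * v / 2 - 0.75)
  R_in <- R_out - spec$cortex_thickness_mm
  if (R_out <= 0 || R_in <= 0)
    stop("volume too small for the requested shell")

  CX <- array(cx, d)
  CY <- array(rep(cy, each = d[1]), d)
  CZ <- array(rep(cz, each = d[1] * d[2]), d)
  R2 <- CX^2 + CY^2 + CZ^2

  pitch <- spec$trabecular_rod_mm + spec$trabecular_spacing_mm
  rod_r <- spec$trabecular_rod_mm / 2
  near_line <- function(coord) abs(coord - pitch * round(coord / pitch)) <= rod_r
  LX <- array(near_line(cx), d)
  LY <- array(rep(near_line(cy), each = d[1]), d)
  LZ <- array(rep(near_line(cz), each = d[1] * d[2]), d)
  lattice <- (LX & LY) | (LX & LZ) | (LY & LZ)

  solid <- R2 <= R_out^2
  shell <- solid & R2 > R_in^2
  bone <- shell | (solid & lattice)

  n_int <- length(spec$interruptions)
  void_mask <- array(FALSE, d)
  defect_mask <- array(FALSE, d)
  per <- vector("list", n_int)
  centres <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  ch_radii <- numeric(0)

  for (i in seq_len(n_int)) {
    intr <- spec$interruptions[[i]]
    u <- intr$direction / sqrt(sum(intr$direction^2))
    dm <- intr$diameter_mm
    vol_req <- intr$void_volume_mm3
    if (dm >= 2 * R_in) stop("interruption diameter exceeds object extent")
    r_v <- if (vol_req > 0) (3 * vol_req / (4 * pi))^(1 / 3) else 0
    if (r_v >= R_in) stop("void larger than interior")
    # cavity tangent to the periosteal surface (one voxel below it)
    t_c <- if (r_v > 0) R_out - v - r_v else R_in
    tt <- CX * u[1] + CY * u[2] + CZ * u[3]
    perp2 <- pmax(R2 - tt^2, 0)
    channel <- perp2 <= (dm / 2)^2 & tt >= t_c
    sphere <- if (r_v > 0) (R2 - 2 * t_c * tt + t_c^2) <= r_v^2
      else array(FALSE, d)
    defect_i <- (channel | sphere) & solid
    bone <- bone & !(channel | sphere)
    void_mask <- void_mask | sphere
    defect_mask <- defect_mask | defect_i

    centres <- rbind(centres, u * t_c)
    radii <- c(radii, r_v)
    ch_radii <- c(ch_radii, dm / 2)
    per[[i]] <- data.frame(
      id = i, diameter_mm = dm,
      void_volume_mm3_requested = vol_req,
      void_volume_mm3 = sum(sphere) * v^3,
      channel_volume_mm3 = sum(channel & solid & !sphere) * v^3,
      defect_volume_mm3 = sum(defect_i) * v^3,
      centre_x_mm = u[1] * t_c, centre_y_mm = u[2] * t_c,
      centre_z_mm = u[3] * t_c,
      dir_x = u[1], dir_y = u[2], dir_z = u[3])
  }
  if (n_int > 1) {
    for (i in 1:(n_int - 1)) for (j in (i + 1):n_int) {
      gap <- sqrt(sum((centres[i, ] - centres[j, ])^2)) -
        (radii[i] + radii[j] + ch_radii[i] + ch_radii[j])
      if (gap < 2 * v) stop("overlapping interruptions")
    }
  }

  decoy <- NULL
  if (spec$decoy_void && n_int > 0) {
    r_d <- (3 * 1 / (4 * pi))^(1 / 3)  # 1 mm^3 decoy
    clearance <- if (nrow(centres))
      min(sqrt(rowSums(centres^2)) - radii) - r_d else R_in - r_d
    if (clearance > 4 * v && r_d < R_in) {
      dec_sphere <- R2 <= r_d^2
      bone <- bone & !dec_sphere
      decoy <- list(centre_mm = c(0, 0, 0), radius_mm = r_d,
                    volume_mm3 = sum(dec_sphere) * v^3)
    }
  }

  gray <- array(0, d)
  gray[bone] <- spec$bone_value
  clean <- if (spec$blur_sigma_mm > 0)
    gauss_blur3(gray, spec$blur_sigma_mm / v) else gray
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  noisy <- if (spec$noise_sigma > 0)
    clean + array(rnorm(prod(d), 0, spec$noise_sigma), d) else clean
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())

  truth <- list(
    n_interruptions = n_int,
    per_interruption = if (n_int) do.call(rbind, per) else data.frame(),
    bone = bone, solid = solid, void = void_mask, defect = defect_mask,
    decoy = decoy,
    outer_radius_mm = R_out, inner_radius_mm = R_in,
    spec = spec)
  structure(list(volume = image_volume(noisy, v),
                 clean = image_volume(clean, v),
                 truth = truth),
            class = "joint_phantom")
}

#' @export
print.joint_phantom <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("<joint_phantom> %dx%dx%d @ %.3g mm, %d interruption(s)%s\n",
              d[1], d[2], d[3], x$volume$voxel_size_mm,
              x$truth$n_interruptions,
              if (!is.null(x$truth$decoy)) " + decoy void" else ""))
  invisible(x)
}

#' Repositioned re-scan of a phantom
#'
#' Emulates removing and repositioning the hand between scans: a small
#' rigid integer-voxel shift of the noise-free volume plus a fresh noise
#' realization.  The ground truth is unchanged up to the shift.
#'
#' @param phantom a `joint_phantom` (its `clean` volume is re-used) or an
#'   [image_volume].
#' @param seed seed for the shift draw and the noise.
#' @param max_shift_voxels largest per-axis shift magnitude.
#' @param noise_sigma noise SD; defaults to the generating spec's value
#'   when a phantom is supplied.
#' @param shift integer 3-vector overriding the random draw.
#' @return List `volume` (shifted noisy [image_volume]) and `shift`.
#' @export
rescan_variant <- function(phantom, seed, max_shift_voxels = 3L,
                           noise_sigma = NULL, shift = NULL) {
  if (inherits(phantom, "joint_phantom")) {
    vol <- phantom$clean
    noise_sigma <- noise_sigma %||% phantom$truth$spec$noise_sigma
  } else {
    stopifnot(is_volume(phantom))
    vol <- phantom
    noise_sigma <- noise_sigma %||% 0
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  if (is.null(shift))
    shift <- sample(seq(-max_shift_voxels, max_shift_voxels), 3,
                    replace = TRUE)
  shift <- as.integer(shift)
  if (any(abs(shift) > max_shift_voxels))
    stop("shift exceeds max_shift_voxels")
  arr <- shift_volume(vol$data, shift)
  if (noise_sigma > 0)
    arr <- arr + array(rnorm(length(arr), 0, noise_sigma), dim(arr))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  list(volume = image_volume(arr, vol$voxel_size_mm), shift = shift)
}

# integer-voxel rigid shift with zero fill
shift_volume <- function(arr, shift) {
  d <- dim(arr)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) {
      src[[ax]] <- 1:(d[ax] - s); dst[[ax]] <- (1 + s):d[ax]
    } else {
      src[[ax]] <- (1 - s):d[ax]; dst[[ax]] <- 1:(d[ax] + s)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}
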