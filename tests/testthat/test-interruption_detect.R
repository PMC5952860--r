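test_that("an intact cortex yields zero interruptions", {
  bench <- slab_bench(holes = list())
  det <- detect_interruptions(bench$bone, bench$cortex, bench$outer)
  expect_identical(n_interruptions(det), 0L)
  expect_true(all(det$label_map == 0L))
  ph <- make_joint_phantom(phantom_spec(shape_voxels = c(64, 64, 64),
                                        seed = 3))
  res <- run_joint(ph$volume)
  expect_identical(res$metrics$n_interruptions, 0L)
})

test_that("the 0.41 mm diameter threshold separates 0.30 from 0.60 mm channels", {
  sp <- phantom_spec(
    shape_voxels = c(80, 80, 80), noise_sigma = 0, seed = 4,
    interruptions = list(
      list(diameter_mm = 0.30, void_volume_mm3 = 0, direction = c(0, 0, 1)),
      list(diameter_mm = 0.60, void_volume_mm3 = 0, direction = c(0, 0, -1))),
    decoy_void = FALSE)
  ph <- make_joint_phantom(sp)
  res <- run_joint(ph$volume)
  det <- res$interruptions
  expect_identical(n_interruptions(det), 1L)
  expect_gte(det$per_component$max_inscribed_diameter_mm, 0.41)
  # a single channel above threshold is found alone
  sp1 <- phantom_spec(
    shape_voxels = c(80, 80, 80), noise_sigma = 0, seed = 4,
    interruptions = list(
      list(diameter_mm = 0.6, void_volume_mm3 = 0, direction = c(0, 0, 1))),
    decoy_void = FALSE)
  res1 <- run_joint(make_joint_phantom(sp1)$volume)
  expect_identical(n_interruptions(res1$interruptions), 1L)
})

test_that("raising the diameter threshold never increases the count", {
  sp <- phantom_spec(
    shape_voxels = c(80, 80, 80), noise_sigma = 0, seed = 8,
    interruptions = list(
      list(diameter_mm = 0.6, void_volume_mm3 = 0, direction = c(0, 0, 1)),
      list(diameter_mm = 1.0, void_volume_mm3 = 0, direction = c(0, 0, -1))),
    decoy_void = FALSE)
  ph <- make_joint_phantom(sp)
  bone <- laplace_hamming_binarize(ph$volume, segmentation_params())
  outer <- auto_outer_contour(bone)
  cortex <- make_cortical_mask(outer, 4L)
  counts <- vapply(c(0.41, 0.7, 0.95, 1.3), function(thr)
    n_interruptions(detect_interruptions(bone, cortex, outer, thr)),
    integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], 2L)
})

test_that("reported inscribed diameters agree with a brute-force distance check", {
  bench <- slab_bench(holes = list(list(r = 4.2, cx = 20, cy = 20),
                                   list(r = 6.5, cx = 42, cy = 40)))
  det <- detect_interruptions(bench$bone, bench$cortex, bench$outer)
  expect_identical(n_interruptions(det), 2L)
  bone_idx <- which(bench$bone$data, arr.ind = TRUE)
  for (i in seq_len(nrow(det$per_component))) {
    comp <- which(det$label_map == i, arr.ind = TRUE)
    # brute force: max over component voxels of distance to nearest bone
    dmax <- max(vapply(seq_len(nrow(comp)), function(r)
      sqrt(min(colSums((t(bone_idx) - comp[r, ])^2))), numeric(1)))
    brute <- 2 * (dmax - 0.5) * vx
    expect_equal(det$per_component$max_inscribed_diameter_mm[i], brute,
                 tolerance = 1e-8)
    expect_gte(brute, det$min_diameter_mm)
  }
})

test_that("pores that do not span the peel are not interruptions", {
  bench <- slab_bench(holes = list())
  bone_arr <- bench$bone$data
  # enclosed pore strictly inside the peel (does not touch either face)
  bone_arr[30, 30, bench$top - 2] <- FALSE
  bone <- binary_mask(bone_arr, vx, "bone")
  det <- detect_interruptions(bone, bench$cortex, bench$outer,
                              min_diameter_mm = 0.082)
  expect_identical(n_interruptions(det), 0L)
})

test_that("interruption surface follows the volumetric cross-section rule", {
  # one-voxel column through a 4-voxel peel
  expect_equal(interruption_surface(4, 0.082, 0.328), 0.082^2)
  expect_error(interruption_surface(4, 0.082, 0), "positive")
  expect_error(interruption_surface(0, 0.082, 0.328), "empty")
  # cylindrical channel of radius 0.5 mm: area ~ pi * 0.25 mm^2
  r_vox <- 0.5 / vx
  bench <- slab_bench(holes = list(list(r = r_vox, cx = 30, cy = 30)))
  det <- detect_interruptions(bench$bone, bench$cortex, bench$outer)
  expect_identical(n_interruptions(det), 1L)
  expect_equal(det$per_component$surface_mm2, pi * 0.25, tolerance = 0.15)
  # doubling the radius quadruples the surface (within digitization)
  bench2 <- slab_bench(holes = list(list(r = 2 * r_vox, cx = 30, cy = 30)))
  det2 <- detect_interruptions(bench2$bone, bench2$cortex, bench2$outer)
  expect_equal(det2$per_component$surface_mm2 /
                 det$per_component$surface_mm2, 4, tolerance = 0.10)
})

test_that("detection is invariant under axis permutation of the volume", {
  sp <- phantom_spec(
    shape_voxels = c(72, 72, 72), noise_sigma = 0, seed = 12,
    interruptions = list(
      list(diameter_mm = 0.7, void_volume_mm3 = 2, direction = c(0, 0, 1))),
    decoy_void = FALSE)
  ph <- make_joint_phantom(sp)
  base <- run_joint(ph$volume)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))) {
    vol_p <- image_volume(aperm(ph$volume$data, perm), vx)
    res_p <- run_joint(vol_p)
    expect_identical(res_p$metrics$n_interruptions,
                     base$metrics$n_interruptions)
    expect_equal(res_p$metrics$total_volume_mm3,
                 base$metrics$total_volume_mm3, tolerance = 1e-9)
    expect_equal(res_p$metrics$total_surface_mm2,
                 base$metrics$total_surface_mm2, tolerance = 1e-9)
  }
})

test_that("components crossing the z boundary are flagged truncated", {
  # object cut by the z boundary (as a stack cuts anatomy): peel on the x
  # face, channel drilled along x right at the z = 1 edge
  d <- c(60, 40, 20)
  outer_arr <- array(FALSE, d)
  outer_arr[1:50, , ] <- TRUE         # air beyond x = 50
  bone_arr <- outer_arr
  g <- coord_grids(d)
  y <- g$y + (d[2] + 1) / 2
  z <- g$z + (d[3] + 1) / 2
  hole <- (y - 20)^2 + (z - 1)^2 <= 4^2   # cylinder along x at the z edge
  bone_arr[44:50, , ][hole[44:50, , ]] <- FALSE
  outer <- binary_mask(outer_arr, vx, "outer_contour")
  bone <- binary_mask(bone_arr, vx, "bone")
  cortex <- make_cortical_mask(outer, 4L)
  det <- detect_interruptions(bone, cortex, outer)
  expect_gte(n_interruptions(det), 1L)
  expect_true(all(det$per_component$truncated))
  # the same channel away from the edge is not flagged
  bone_arr2 <- outer_arr
  hole2 <- (y - 20)^2 + (z - 10)^2 <= 4^2
  bone_arr2[44:50, , ][hole2[44:50, , ]] <- FALSE
  det2 <- detect_interruptions(binary_mask(bone_arr2, vx, "bone"),
                               cortex, outer)
  expect_gte(n_interruptions(det2), 1L)
  expect_false(any(det2$per_component$truncated))
})

test_that("shape mismatches and empty inputs raise errors", {
  bench <- slab_bench()
  small <- binary_mask(array(TRUE, c(5, 5, 5)), vx, "bone")
  expect_error(detect_interruptions(small, bench$cortex, bench$outer),
               "shape")
  empty_cortex <- binary_mask(array(FALSE, dim(bench$bone$data)), vx,
                              "cortical_mask")
  expect_error(detect_interruptions(bench$bone, empty_cortex, bench$outer),
               "empty")
})
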