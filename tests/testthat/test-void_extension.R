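# interruption_set with a single seed voxel, for ROI geometry tests
point_interruption_set <- function(d, at, voxel = vx) {
  lm <- array(0L, d)
  lm[at[1], at[2], at[3]] <- 1L
  cortigap:::make_interruption_set(
    lm, data.frame(id = 1L, voxel_count = 1L,
                   surface_mm2 = voxel^3 / (4 * voxel),
                   max_inscribed_diameter_mm = voxel, truncated = FALSE),
    min_diameter_mm = voxel, depth_mm = 4 * voxel, voxel_size_mm = voxel)
}

empty_interruption_set <- function(d, voxel = vx) {
  cortigap:::make_interruption_set(
    array(0L, d),
    data.frame(id = integer(0), voxel_count = integer(0),
               surface_mm2 = numeric(0),
               max_inscribed_diameter_mm = numeric(0),
               truncated = logical(0)),
    0.41, 4 * voxel, voxel)
}

test_that("the ROI around a central interruption is a 48-voxel digital ball", {
  d <- c(101, 101, 101)
  iset <- point_interruption_set(d, c(51, 51, 51))
  outer <- binary_mask(array(TRUE, d), vx, "outer_contour")
  roi <- build_roi(iset, outer, 48L)
  analytic <- 4 / 3 * pi * 48^3
  expect_lt(abs(sum(roi$data) - analytic) / analytic, 0.02)
  expect_identical(roi$role, "roi")
})

test_that("empty interruption sets give an empty ROI, and the ROI is clipped to the contour", {
  d <- c(40, 40, 40)
  outer_arr <- digital_ball(d, 15)
  outer <- binary_mask(outer_arr, vx, "outer_contour")
  expect_false(any(build_roi(empty_interruption_set(d), outer, 48L)$data))
  # interruption near the contour edge: roi stays inside the contour
  iset <- point_interruption_set(d, c(20, 20, 6))
  roi <- build_roi(iset, outer, 48L)
  expect_true(all(outer_arr[roi$data]))
})

test_that("void selection is a local-thickness threshold", {
  # normal marrow spacing (0.4 mm) is never selected at the 0.738 mm cut
  sp <- phantom_spec(shape_voxels = c(64, 64, 64), noise_sigma = 0,
                     blur_sigma_mm = 0, seed = 21)
  ph <- make_joint_phantom(sp)
  bone <- binary_mask(ph$truth$bone, vx, "bone")
  roi <- binary_mask(ph$truth$solid, vx, "roi")
  expect_false(any(select_voids(bone, roi, 0.738)$data))

  # a 2 mm spherical cavity is recovered nearly completely
  d <- c(64, 64, 64)
  cav_r <- 1.0 / vx  # 2 mm diameter
  cavity <- digital_ball(d, cav_r)
  bone2 <- binary_mask(ph$truth$bone & !cavity, vx, "bone")
  voids <- select_voids(bone2, roi, 0.738)
  expect_gte(sum(voids$data & cavity) / sum(cavity), 0.90)
  # raising the threshold above the cavity diameter empties the selection
  expect_false(any(select_voids(bone2, roi, 3.0)$data))
})

test_that("erosion severs sub-0.328 mm connections and shrinks balls by its radius", {
  fx <- two_ball_tube(ball_r = 12, tube_r = 1.2)
  void <- binary_mask(fx$mask, vx, "void")
  eroded <- erode_voids(void, 2L)
  lab <- cortigap:::label3d(eroded$data, 26L)
  expect_identical(max(lab), 2L)
  # a 0.3 mm ball (radius < erosion) vanishes
  tiny <- binary_mask(digital_ball(c(20, 20, 20), 0.15 / vx), vx, "void")
  expect_false(any(erode_voids(tiny, 2L)$data))
  # ball of radius 10 erodes to radius ~8 (within digitization)
  ball <- binary_mask(digital_ball(c(27, 27, 27), 10), vx, "void")
  er <- erode_voids(ball, 2L)$data
  expect_gte(sum(er), 4 / 3 * pi * 7.8^3)
  expect_lte(sum(er), 4 / 3 * pi * 8.6^3)
})

test_that("only voids connected to an interruption survive the filter", {
  fx <- two_ball_tube(ball_r = 10, tube_r = 1.2)
  d <- dim(fx$mask)
  # seed voxel adjacent to the *eroded* ball 1 (erosion pulls the surface
  # from x = 10 to x ~ 12)
  iset <- point_interruption_set(d, c(11, 20, 20))
  void <- binary_mask(fx$mask, vx, "void")
  eroded <- erode_voids(void, 2L)
  kept <- keep_connected_to_interruption(eroded, iset)
  lab <- cortigap:::label3d(eroded$data, 26L)
  comp1 <- lab == lab[12, 20, 20]
  expect_identical(kept$data, comp1 & eroded$data)
  expect_false(any(kept$data & fx$b2))
  # an isolated distant void is dropped entirely
  iso <- binary_mask(digital_ball(d, 6, centre = c(60, 20, 20)), vx, "void")
  eroded_iso <- erode_voids(iso, 2L)
  expect_false(any(keep_connected_to_interruption(eroded_iso, iset)$data))
})

test_that("constrained reconstruction restores isolated cavities exactly and never regrows severed necks", {
  d <- c(31, 31, 31)
  ball <- digital_ball(d, 10)
  pre <- binary_mask(ball, vx, "void")
  kept <- erode_voids(pre, 2L)
  iset <- empty_interruption_set(d)
  restored <- restore_and_merge(kept, pre, iset, 2L)
  expect_identical(restored$data, ball)

  fx <- two_ball_tube(ball_r = 10, tube_r = 1.2)
  dd <- dim(fx$mask)
  pre2 <- binary_mask(fx$mask, vx, "void")
  eroded2 <- erode_voids(pre2, 2L)
  lab <- cortigap:::label3d(eroded2$data, 26L)
  kept2 <- binary_mask(lab == lab[12, 20, 20], vx, "void")
  iset2 <- point_interruption_set(dd, c(9, 20, 20))
  out <- restore_and_merge(kept2, pre2, iset2, 2L)
  expect_gte(sum(out$data & fx$b1) / sum(fx$b1), 0.999)
  expect_false(any(out$data & fx$b2))
  # reconstruction never exceeds its conditioning mask plus interruptions
  expect_true(all(pre2$data[out$data] |
                    (iset2$label_map > 0)[out$data]))

  # empty kept set: output is exactly the interruption voxels
  empty_kept <- binary_mask(array(FALSE, dd), vx, "void")
  out2 <- restore_and_merge(empty_kept, pre2, iset2, 2L)
  expect_identical(out2$data, iset2$label_map > 0L)
})

test_that("joint metrics attribute shared components once and conserve totals", {
  sp <- phantom_spec(interruptions = reference_interruptions(), seed = 11)
  ph <- make_joint_phantom(sp)
  res <- run_joint(ph$volume)
  m <- res$metrics
  expect_identical(m$n_interruptions, 3L)
  expect_equal(m$total_surface_mm2,
               sum(m$per_interruption$surface_mm2))
  expect_equal(m$total_volume_mm3, sum(m$per_component$volume_mm3))
  # volume is at least the interruption voxels alone
  int_only <- sum(res$interruptions$label_map > 0) * vx^3
  expect_gte(m$total_volume_mm3, int_only)
  # no interruptions: all-zero metrics
  d <- c(20, 20, 20)
  m0 <- compute_joint_metrics(
    binary_mask(array(FALSE, d), vx, "void"), empty_interruption_set(d))
  expect_identical(m0$n_interruptions, 0L)
  expect_identical(m0$total_surface_mm2, 0)
  expect_identical(m0$total_volume_mm3, 0)
})

test_that("lowering the void diameter threshold never shrinks the total volume", {
  sp <- phantom_spec(
    shape_voxels = c(96, 96, 96), noise_sigma = 0, seed = 23,
    interruptions = list(
      list(diameter_mm = 0.8, void_volume_mm3 = 3, direction = c(0, 0, 1))),
    decoy_void = FALSE)
  ph <- make_joint_phantom(sp)
  bone <- laplace_hamming_binarize(ph$volume, segmentation_params())
  outer <- auto_outer_contour(bone)
  cortex <- make_cortical_mask(outer, 4L)
  det <- detect_interruptions(bone, cortex, outer)
  vols <- vapply(c(1.2, 0.9, 0.738, 0.55), function(thr) {
    extend_voids(bone, outer, det,
                 void_extension_params(void_min_diameter_mm = thr)
                 )$metrics$total_volume_mm3
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("the final mask stays within the ROI reach of an interruption", {
  sp <- phantom_spec(
    shape_voxels = c(96, 96, 96), noise_sigma = 0, seed = 24,
    interruptions = list(
      list(diameter_mm = 0.8, void_volume_mm3 = 4, direction = c(0, 0, 1))))
  ph <- make_joint_phantom(sp)
  res <- run_joint(ph$volume, keep_masks = TRUE)
  final <- res$masks$final$data
  imask <- res$interruptions$label_map > 0L
  dist_to_int <- cortigap:::dist_to_fg(imask)
  expect_lte(max(dist_to_int[final]), 48)
})

test_that("re-running the void-extension stages on their own output changes nothing", {
  sp <- phantom_spec(
    shape_voxels = c(80, 80, 80), noise_sigma = 0, seed = 25,
    interruptions = list(
      list(diameter_mm = 0.9, void_volume_mm3 = 3, direction = c(1, 0, 0))),
    decoy_void = FALSE)
  ph <- make_joint_phantom(sp)
  bone <- laplace_hamming_binarize(ph$volume, segmentation_params())
  outer <- auto_outer_contour(bone)
  cortex <- make_cortical_mask(outer, 4L)
  det <- detect_interruptions(bone, cortex, outer)
  ext <- extend_voids(bone, outer, det, keep_intermediates = TRUE)
  # second pass: erode/filter/restore with the final mask as conditioning
  eroded2 <- erode_voids(ext$final, 2L)
  kept2 <- keep_connected_to_interruption(eroded2, det)
  final2 <- restore_and_merge(kept2, ext$final, det, 2L)
  expect_identical(final2$data, ext$final$data)
})
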