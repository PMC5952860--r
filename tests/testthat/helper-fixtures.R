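# Geometric fixtures and independent brute-force oracles shared across the
# suite.  Everything is generated in code; nothing is read from disk.

vx <- 0.082  # native voxel size, mm

# coordinate grids centred on the volume (voxel units)
coord_grids <- function(d) {
  cx <- seq_len(d[1]) - (d[1] + 1) / 2
  cy <- seq_len(d[2]) - (d[2] + 1) / 2
  cz <- seq_len(d[3]) - (d[3] + 1) / 2
  list(x = array(cx, d),
       y = array(rep(cy, each = d[1]), d),
       z = array(rep(cz, each = d[1] * d[2]), d))
}

# digital Euclidean ball of radius r voxels centred in a d-volume
digital_ball <- function(d, r, centre = (d + 1) / 2) {
  g <- coord_grids(d)
  ctr <- centre - (d + 1) / 2
  (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= r^2
}

# two balls joined by a thin tube along x; radii in voxels
two_ball_tube <- function(ball_r = 12, tube_r = 1.2, d = c(80, 40, 40),
                          c1 = 20, c2 = 60) {
  g <- coord_grids(d)
  x <- g$x + (d[1] + 1) / 2
  y <- g$y + (d[2] + 1) / 2
  z <- g$z + (d[3] + 1) / 2
  b1 <- (x - c1)^2 + (y - 20)^2 + (z - 20)^2 <= ball_r^2
  b2 <- (x - c2)^2 + (y - 20)^2 + (z - 20)^2 <= ball_r^2
  tube <- (y - 20)^2 + (z - 20)^2 <= tube_r^2 & x > c1 & x < c2
  list(mask = b1 | b2 | tube, b1 = b1, b2 = b2, tube = tube)
}

# slab-cortex test bench: a box-shaped "bone" whose top `depth` slices act
# as the cortical peel, with optional cylindrical holes drilled through it
# (hole: list(r = radius voxels, cx, cy)).  Returns masks shaped like the
# detection API expects.
slab_bench <- function(d = c(60, 60, 30), depth = 4L, holes = list(),
                       voxel = vx) {
  outer_arr <- array(FALSE, d)
  outer_arr[, , 1:(d[3] - 10)] <- TRUE  # object below, air above
  top <- d[3] - 10
  bone_arr <- outer_arr
  for (h in holes) {
    g <- coord_grids(d)
    x <- g$x + (d[1] + 1) / 2
    y <- g$y + (d[2] + 1) / 2
    hole <- (x - h$cx)^2 + (y - h$cy)^2 <= h$r^2
    # drill through the top `depth+2` slices so the hole spans the peel
    for (k in (top - depth - 1):top) bone_arr[, , k] <- bone_arr[, , k] &
      !hole[, , k]
  }
  list(bone = binary_mask(bone_arr, voxel, "bone"),
       outer = binary_mask(outer_arr, voxel, "outer_contour"),
       cortex = make_cortical_mask(binary_mask(outer_arr, voxel,
                                               "outer_contour"), depth),
       top = top, depth = depth)
}

# brute-force squared EDT (distance to nearest FALSE voxel)
brute_edt_sq <- function(mask) {
  d <- dim(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- array(0, d)
  fg <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    p <- fg[r, ]
    out[p[1], p[2], p[3]] <- min(colSums((t(bg) - p)^2))
  }
  out
}

# brute-force local thickness (voxel units): for every foreground voxel,
# the largest 2*(edt-0.5) among spheres that cover it
brute_local_thickness <- function(mask) {
  d <- dim(mask)
  e <- sqrt(brute_edt_sq(mask))
  fg <- which(mask, arr.ind = TRUE)
  rad <- pmax(e[mask] - 0.5, 0)
  out <- array(0, d)
  for (i in seq_len(nrow(fg))) {
    p <- fg[i, ]
    d2 <- colSums((t(fg) - p)^2)
    out[p[1], p[2], p[3]] <- 2 * max(rad[d2 <= rad^2])
  }
  out
}

# independent ICC(2,1) via stats::aov mean squares
aov_icc21 <- function(m1, m2) {
  n <- length(m1)
  df <- data.frame(y = c(m1, m2),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# motion-grade table for a 42-joint, 3-stack cohort: 20 stacks fail on
# scan 1, 13 on scan 2, 2 on both, and two joints fail all three stacks
study_grade_table <- function() {
  g <- data.frame(joint_id = sprintf("J%02d", 1:42),
                  s1_g1 = 1L, s1_g2 = 1L, s1_g3 = 1L,
                  s2_g1 = 1L, s2_g2 = 1L, s2_g3 = 1L)
  g[1:2, c("s1_g1", "s1_g2", "s1_g3")] <- 4L   # two joints all-poor, scan 1
  g[1:2, "s2_g1"] <- 5L                        # ... two stacks poor on both
  g[3:16, "s1_g1"] <- 4L                       # 14 more poor on scan 1
  g[17:27, "s2_g2"] <- 4L                      # 11 more poor on scan 2
  g
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
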