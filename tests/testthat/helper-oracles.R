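# Independent oracles, deliberately naive: these never share code paths with
# the implementation they check.

# Brute-force minimum RMSD over rigid motions: grid search over axis-angle
# rotations (Fibonacci-sphere axes) with optimal translation by centroid
# alignment, followed by one local refinement pass around the best grid
# point.
brute_force_min_rmsd <- function(mobile, reference,
                                 n_axes = 200, coarse_step = 3) {
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  pm <- sweep(mobile, 2, cm)
  pr <- sweep(reference, 2, cr)
  fib_axes <- function(n) {
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  }
  eval_rot <- function(axis, ang) {
    R <- rotation_matrix(axis, ang)
    sqrt(mean(rowSums((pm %*% t(R) - pr)^2)))
  }
  axes <- fib_axes(n_axes)
  best <- list(val = Inf, axis = c(0, 0, 1), ang = 0)
  for (a in seq_len(nrow(axes))) {
    for (ang in seq(0, 359, by = coarse_step)) {
      v <- eval_rot(axes[a, ], ang)
      if (v < best$val) best <- list(val = v, axis = axes[a, ], ang = ang)
    }
  }
  # local refinement: jitter the axis, fine angle sweep
  for (rep in 1:400) {
    axis <- best$axis + rnorm(3, sd = 0.03)
    axis <- axis / sqrt(sum(axis^2))
    for (ang in seq(best$ang - coarse_step, best$ang + coarse_step,
                    by = 0.1)) {
      v <- eval_rot(axis, ang)
      if (v < best$val) best <- list(val = v, axis = axis, ang = ang)
    }
  }
  best$val
}

# Exhaustive per-water cylinder membership test.
brute_force_water_count <- function(waters_xyz, axis_point, axis_dir,
                                    z_lo, z_hi, radial_cutoff) {
  d <- axis_dir / sqrt(sum(axis_dir^2))
  n <- 0
  for (i in seq_len(nrow(waters_xyz))) {
    v <- waters_xyz[i, ] - axis_point
    t_ax <- sum(v * d)
    perp <- sqrt(sum((v - t_ax * d)^2))
    if (t_ax >= z_lo && t_ax <= z_hi && perp <= radial_cutoff) n <- n + 1
  }
  n
}

# Exhaustive distinct-ion coordination count for one frame.
brute_force_ion_count <- function(ion_xyz, oxy_xyz, cutoff) {
  n <- 0
  for (i in seq_len(nrow(ion_xyz))) {
    hit <- FALSE
    for (j in seq_len(nrow(oxy_xyz))) {
      if (sqrt(sum((ion_xyz[i, ] - oxy_xyz[j, ])^2)) <= cutoff) hit <- TRUE
    }
    if (hit) n <- n + 1
  }
  n
}
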