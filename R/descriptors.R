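# conformational_descriptors: quaternary descriptors of pentamer gating --
# ECD spread (radius of gyration about the channel axis) and domain twist
# (average four-COM dihedral), per model and per frame.

#' ECD spread: radius of gyration about the channel axis
#'
#' `sqrt(mean(d_perp^2))` over the selected atoms with unit weights, where
#' `d_perp` is the perpendicular distance to the axis. Default selection:
#' C-alpha of residues 20-190. Contraction of the extracellular domain shows
#' as a decrease in spread.
#'
#' @param model a [pentamer()] (or trajectory frame).
#' @param axis a [pore_axis()].
#' @param sel [selection()] of atoms entering the gyration sum.
#' @return spread in Angstrom.
#' @export
ecd_spread <- function(model, axis, sel = selection(c(20, 190), "CA")) {
  idx <- resolve_selection(model, sel)
  sqrt(mean(axis_coords(model_xyz(model, idx), axis)$perp^2))
}

#' Domain twist: average four-COM dihedral
#'
#' For each subunit `i`, the dihedral angle defined by the centers of mass
#' (unit-weight C-alpha centroids by default) of (1) that subunit's ECD,
#' (2) the full ECD, (3) the full TMD, and (4) the same subunit's TMD; the
#' five dihedrals are combined by a circular mean. A positive twist means the
#' ECD is rotated counterclockwise (viewed from the extracellular side)
#' relative to the TMD; untwisting during activation shows as a decrease.
#'
#' @param model a [pentamer()] (or trajectory frame).
#' @param ecd_sel,tmd_sel [selection()]s resolving per chain (defaults:
#'   C-alpha 20-190 and 197-313).
#' @return twist in degrees, range (-180, 180].
#' @export
domain_twist <- function(model, ecd_sel = selection(c(20, 190), "CA"),
                         tmd_sel = selection(c(197, 313), "CA")) {
  ecd_idx <- resolve_selection(model, ecd_sel, symmetric = TRUE)
  tmd_idx <- resolve_selection(model, tmd_sel, symmetric = TRUE)
  a <- model$atom
  ecd_all <- colMeans(model_xyz(model, ecd_idx))
  tmd_all <- colMeans(model_xyz(model, tmd_idx))
  if (vnorm(ecd_all - tmd_all) < 1e-9) {
    stop("undefined dihedral: ECD and TMD centers of mass coincide")
  }
  dihedrals <- vapply(model$chains, function(ch) {
    e_i <- colMeans(model_xyz(model, ecd_idx[a$chain[ecd_idx] == ch]))
    t_i <- colMeans(model_xyz(model, tmd_idx[a$chain[tmd_idx] == ch]))
    dihedral4(e_i, ecd_all, tmd_all, t_i)
  }, numeric(1))
  circular_mean_deg(dihedrals)
}

#' Spread and twist along a trajectory
#'
#' The channel axis is re-estimated for every frame (the descriptors track
#' the instantaneous assembly rather than a frozen frame-0 axis).
#'
#' @param traj a trajectory.
#' @param spread_sel selection for [ecd_spread()].
#' @param ecd_sel,tmd_sel selections for [domain_twist()].
#' @param lining_sel pore-lining selection for per-frame axis estimation.
#' @return data.frame (class `descriptor_series`) with columns `time` (ns),
#'   `spread` (A), `twist` (degrees).
#' @export
descriptor_series <- function(traj,
                              spread_sel = selection(c(20, 190), "CA"),
                              ecd_sel = selection(c(20, 190), "CA"),
                              tmd_sel = selection(c(197, 313), "CA"),
                              lining_sel = selection(c(222, 247), "CA")) {
  rows <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_model(traj, f)
    ax <- estimate_pore_axis(m, lining_sel, orient_sel = spread_sel)
    c(ecd_spread(m, ax, spread_sel), domain_twist(m, ecd_sel, tmd_sel))
  }, numeric(2))
  out <- data.frame(time = traj$times, spread = rows[1, ], twist = rows[2, ])
  class(out) <- c("descriptor_series", "data.frame")
  out
}

#' Bootstrap summary of a descriptor series
#'
#' @param series a `descriptor_series` (or any data.frame of numeric
#'   columns plus `time`).
#' @param level confidence level for [bootstrap_median_ci()]; the level is a
#'   parameter because different displays use different intervals.
#' @param n_boot,seed bootstrap parameters.
#' @return named list of `summary_stat` objects, one per descriptor column.
#' @export
descriptor_summary <- function(series, level = 0.95, n_boot = 10000, seed) {
  cols <- setdiff(names(series), "time")
  out <- lapply(cols, function(cn) {
    bootstrap_median_ci(series[[cn]], level = level, n_boot = n_boot,
                        seed = seed)
  })
  names(out) <- cols
  out
}
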