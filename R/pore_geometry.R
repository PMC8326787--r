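# pore_geometry: channel (C5) axis estimation, per-residue pore radius
# profiles, gate radii, M2 prime-notation mapping, and pore water occupancy.

#' Construct a pore axis
#'
#' @param point 3-vector, a point on the axis (A).
#' @param direction 3-vector; normalized internally. By convention the
#'   direction points toward the extracellular domain (+z side).
#' @return object of class `pore_axis`.
#' @export
pore_axis <- function(point, direction) {
  structure(list(point = as.numeric(point), direction = unit(direction)),
            class = "pore_axis")
}

#' @export
print.pore_axis <- function(x, ...) {
  cat(sprintf("pore axis: point (%.2f, %.2f, %.2f), direction (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Estimate the channel axis of a pentamer
#'
#' Total-least-squares line through the per-residue ring centroids of the
#' pore-lining C-alpha atoms (default M2 residues 222-247): centroids are
#' computed per residue over the five symmetric copies and the first
#' principal direction of their scatter is the axis. The direction is
#' oriented so the centroid of the extracellular selection (default C-alpha
#' 20-190) has positive projection, fixing "up" toward the ECD.
#'
#' @param model a [pentamer()].
#' @param lining_sel pore-lining selection; must resolve symmetrically.
#' @param orient_sel ECD selection used only to orient the axis.
#' @return a [pore_axis()].
#' @export
estimate_pore_axis <- function(model,
                               lining_sel = selection(c(222, 247), "CA"),
                               orient_sel = selection(c(20, 190), "CA")) {
  idx <- resolve_selection(model, lining_sel, symmetric = TRUE)
  a <- model$atom[idx, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  cents <- rowsum(xyz, group = a$resno) / as.vector(table(a$resno))
  if (nrow(cents) < 2) {
    stop("axis undetermined: need >= 2 residue rings, got ", nrow(cents))
  }
  mid <- colMeans(cents)
  sv <- svd(sweep(cents, 2, mid))
  dir <- sv$v[, 1]
  ecd_idx <- resolve_selection(model, orient_sel)
  ecd_cen <- colMeans(model_xyz(model, ecd_idx))
  if (sum((ecd_cen - mid) * dir) < 0) dir <- -dir
  pore_axis(mid, dir)
}

#' M2 prime-notation index of a pore-lining residue
#'
#' Standard cross-family M2 indexing where the hydrophobic gate I233 is 9'
#' and A237 is 13': `prime = residue_number - 224`.
#'
#' @param residue_number author residue number(s) in the M2 range 222-247.
#' @return integer prime index (vectorized).
#' @export
residue_prime <- function(residue_number) {
  if (any(residue_number < 222 | residue_number > 247)) {
    stop("residue out of M2 range 222-247")
  }
  as.integer(residue_number - 224)
}

#' Per-residue pore radius profile
#'
#' For each residue in `residues`, the pore radius is the mean perpendicular
#' distance of the (up to five) symmetric copies of `atom_name` to the axis,
#' and `z` is their mean axial coordinate. Residues with the atom present in
#' fewer than 4 chains are excluded with a warning.
#'
#' @param model a [pentamer()].
#' @param axis a [pore_axis()].
#' @param residues inclusive residue interval `c(lo, hi)`.
#' @param atom_name atom used for the radius (default "CA"; "CB" gives
#'   side-chain-proximal radii at the gate).
#' @return data.frame (class `pore_profile`) with columns `residue`, `prime`
#'   (NA outside the M2 range), `z`, `radius`, `atom_name`, `n_chains`,
#'   ordered by `z`.
#' @export
pore_profile <- function(model, axis, residues = c(222, 247),
                         atom_name = "CA") {
  resnos <- seq(residues[1], residues[2])
  a <- model$atom
  rows <- lapply(resnos, function(r) {
    sel <- which(is_protein_atom(a) & a$resno == r & a$elety == atom_name)
    n <- length(unique(a$chain[sel]))
    if (n < 4) {
      warning("residue ", r, " has ", atom_name, " in only ", n,
              " chains; excluded from profile")
      return(NULL)
    }
    ac <- axis_coords(model_xyz(model, sel), axis)
    data.frame(residue = r,
               prime = if (r >= 222 && r <= 247) residue_prime(r) else NA_integer_,
               z = mean(ac$axial), radius = mean(ac$perp),
               atom_name = atom_name, n_chains = n)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("empty profile: all residues excluded")
  out <- do.call(rbind, rows)
  out <- out[order(out$z), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' Gate radius at a pore-lining residue
#'
#' Mean perpendicular distance to the axis of the five symmetric copies of
#' one atom; the default (residue 233, C-beta) measures the I9' hydrophobic
#' gate constriction. Radii are center distances; no van-der-Waals radius is
#' subtracted.
#'
#' @param model a [pentamer()].
#' @param axis a [pore_axis()].
#' @param residue author residue number.
#' @param atom_name atom name.
#' @return radius in Angstrom.
#' @export
gate_radius <- function(model, axis, residue = 233, atom_name = "CB") {
  a <- model$atom
  sel <- which(is_protein_atom(a) & a$resno == residue & a$elety == atom_name)
  if (length(unique(a$chain[sel])) != length(model$chains)) {
    stop("incomplete ring: residue ", residue, " has ", atom_name,
         " in ", length(unique(a$chain[sel])), " of ",
         length(model$chains), " chains")
  }
  mean(axis_coords(model_xyz(model, sel), axis)$perp)
}

water_oxygen_idx <- function(atom) {
  which(atom$resid %in% WATER_RESIDS & atom$elety %in% c("O", "OW", "OH2"))
}

#' Pore water occupancy between two lining residues
#'
#' Counts water oxygens inside the axial slab bounded by the C-alpha ring
#' centroids of `lower_residue` and `upper_residue` (closed interval; bounds
#' sorted, so inverted order is handled) and within `radial_cutoff` of the
#' axis. The default slab, I233 (9') to A237 (13'), quantifies hydration of
#' the hydrophobic gate.
#'
#' @param model a [pentamer()] (a single frame).
#' @param axis a [pore_axis()].
#' @param lower_residue,upper_residue bounding residues.
#' @param radial_cutoff cylinder radius in Angstrom.
#' @return integer count of in-pore water oxygens.
#' @export
water_occupancy <- function(model, axis, lower_residue = 233,
                            upper_residue = 237, radial_cutoff = 6) {
  a <- model$atom
  widx <- water_oxygen_idx(a)
  if (length(widx) == 0) {
    warning("no waters in topology; occupancy is 0")
    return(0L)
  }
  ring_z <- vapply(c(lower_residue, upper_residue), function(r) {
    sel <- which(is_protein_atom(a) & a$resno == r & a$elety == "CA")
    if (length(sel) == 0) stop("cannot resolve CA ring of residue ", r)
    mean(axis_coords(model_xyz(model, sel), axis)$axial)
  }, numeric(1))
  zb <- sort(ring_z)
  ac <- axis_coords(model_xyz(model, widx), axis)
  sum(ac$axial >= zb[1] & ac$axial <= zb[2] & ac$perp <= radial_cutoff)
}

#' Per-frame pore water occupancy along a trajectory
#'
#' @param traj a trajectory.
#' @param axis optional fixed [pore_axis()]; by default the axis is
#'   re-estimated for every frame so counts track the instantaneous assembly.
#' @inheritParams water_occupancy
#' @param lining_sel pore-lining selection for per-frame axis estimation.
#' @return data.frame with columns `time` (ns) and `count`.
#' @export
water_occupancy_series <- function(traj, axis = NULL, lower_residue = 233,
                                   upper_residue = 237, radial_cutoff = 6,
                                   lining_sel = selection(c(222, 247), "CA")) {
  counts <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_model(traj, f)
    ax <- if (is.null(axis)) estimate_pore_axis(m, lining_sel) else axis
    as.integer(water_occupancy(m, ax, lower_residue, upper_residue,
                               radial_cutoff))
  }, integer(1))
  data.frame(time = traj$times, count = counts)
}
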