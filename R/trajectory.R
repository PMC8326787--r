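# Trajectory frame sets: a topology-bound sequence of coordinate frames with
# times (ns). Frames are stored as an n_frames x 3N matrix in bio3d xyz
# layout (x1, y1, z1, x2, ...).

#' Construct a trajectory frame set
#'
#' @param topology a [pentamer()] giving atom identities.
#' @param xyz n_frames x 3N coordinate matrix (bio3d xyz layout), N the number
#'   of atoms in the topology.
#' @param times numeric vector of frame times in ns (default: 0, 1, ...).
#' @param ground_truth optional list of generator ground-truth series (see
#'   [generate_trajectory()]).
#' @return object of class `trajectory`.
#' @export
as_trajectory <- function(topology, xyz, times = NULL, ground_truth = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1) stop("trajectory must contain at least one frame")
  if (ncol(xyz) != 3 * nrow(topology$atom)) {
    stop("xyz has ", ncol(xyz), " columns; topology implies ",
         3 * nrow(topology$atom))
  }
  if (is.null(times)) times <- seq_len(nrow(xyz)) - 1
  if (length(times) != nrow(xyz)) stop("times length != frame count")
  structure(list(topology = topology, xyz = xyz, times = as.numeric(times),
                 ground_truth = ground_truth),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", nrow(x$xyz), "frames x", ncol(x$xyz) / 3, "atoms,",
      "t =", min(x$times), "-", max(x$times), "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a trajectory.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

# N x 3 coordinates of one frame.
frame_xyz <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Extract one frame as a model
#'
#' @param traj a trajectory.
#' @param i frame index (1-based).
#' @return a [pentamer()] with the frame's coordinates.
#' @export
frame_model <- function(traj, i) {
  set_model_xyz(traj$topology, frame_xyz(traj, i))
}

#' Restrict a trajectory to the trailing analysis window
#'
#' MD observables here are computed over the tail of each trajectory (300 ns
#' by default) so that initial relaxation is excluded.
#'
#' @param traj a trajectory.
#' @param window_ns width of the trailing window in ns.
#' @return a trajectory containing frames with `time > max(time) - window_ns`.
#' @export
tail_window <- function(traj, window_ns = 300) {
  keep <- traj$times > max(traj$times) - window_ns
  if (!any(keep)) stop("analysis window contains no frames")
  gt <- traj$ground_truth
  if (!is.null(gt)) {
    gt <- lapply(gt, function(g) {
      if (is.matrix(g) && nrow(g) == length(keep)) g[keep, , drop = FALSE]
      else if (length(g) == length(keep) && !is.list(g)) g[keep]
      else g
    })
  }
  as_trajectory(traj$topology, traj$xyz[keep, , drop = FALSE],
                traj$times[keep], gt)
}

#' Read a multi-model PDB trajectory
#'
#' @param path multi-model PDB file (one MODEL per frame).
#' @param topology_path optional separate topology PDB; defaults to the first
#'   model of `path`.
#' @param dt_ns time step between frames, ns.
#' @param times explicit frame times (overrides `dt_ns`).
#' @return a trajectory.
#' @export
read_trajectory <- function(path, topology_path = NULL, dt_ns = 1,
                            times = NULL) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("trajectory PDB format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  top <- if (is.null(topology_path)) {
    a <- pdb$atom
    a$insert[is.na(a$insert)] <- ""
    a$alt[is.na(a$alt)] <- ""
    a$o[is.na(a$o)] <- 1
    a$b[is.na(a$b)] <- 0
    a$elesy[is.na(a$elesy)] <- ""
    pentamer(a[, c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
                   "x", "y", "z", "o", "b", "elesy")],
             title = basename(path))
  } else {
    read_pdb(topology_path)
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1) * dt_ns
  as_trajectory(top, xyz, times)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a trajectory.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$topology$atom
  bio3d::write.pdb(file = path, xyz = traj$xyz,
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = a$eleno, elety = a$elety, chain = a$chain,
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}
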