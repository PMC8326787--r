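# loop_pca: principal component analysis of M2-M3 loop C-alpha coordinates
# across superposed models, treating each subunit as a separate observation;
# projection of further models/frames; 2-D kernel density landscapes.

#' Extract per-subunit loop observations in a common frame
#'
#' Each subunit of each model is rotated into a common subunit frame by
#' superposing its flanking-core C-alpha atoms (default: M2 222-242 plus M3
#' 251-270) onto a designated reference subunit, and the loop C-alpha
#' coordinates (default 243-250) are concatenated into one row per
#' (model, subunit). A naive global superposition would leave the five
#' subunits 72 degrees apart and PCA would measure rotation, not loop
#' conformation; the local core fit removes that.
#'
#' @param models list of [pentamer()] models.
#' @param loop inclusive residue interval of the loop, default `c(243, 250)`.
#' @param core list of intervals defining the flanking core used for the
#'   per-subunit superposition.
#' @param reference optional reference core coordinates (a matrix, as stored
#'   in the `reference` attribute of a previous call) so that trajectory
#'   frames can be placed in the same frame as the training models. Default:
#'   the first chain of the first model.
#' @return matrix with one row per (model, subunit) and `3 * L` columns
#'   (L loop residues); attributes `loop`, `core`, `reference`.
#' @export
extract_loop_observations <- function(models, loop = c(243, 250),
                                      core = list(c(222, 242), c(251, 270)),
                                      reference = NULL) {
  if (inherits(models, "pentamer")) models <- list(models)
  core_sel <- selection(core, atom_names = "CA")
  loop_sel <- selection(loop, atom_names = "CA")
  rows <- list()
  for (m_i in seq_along(models)) {
    model <- models[[m_i]]
    a <- model$atom
    for (ch in model$chains) {
      core_idx <- which(is_protein_atom(a) & a$chain == ch &
                          in_ranges(a$resno, core_sel$ranges) &
                          a$elety == "CA")
      loop_idx <- which(is_protein_atom(a) & a$chain == ch &
                          in_ranges(a$resno, loop_sel$ranges) &
                          a$elety == "CA")
      core_idx <- core_idx[order(a$resno[core_idx])]
      loop_idx <- loop_idx[order(a$resno[loop_idx])]
      n_loop <- loop[2] - loop[1] + 1
      if (length(loop_idx) < n_loop) {
        warning("model ", m_i, " chain ", ch,
                ": incomplete loop CA; observation skipped")
        next
      }
      core_xyz <- model_xyz(model, core_idx)
      if (is.null(reference)) reference <- core_xyz
      if (nrow(core_xyz) != nrow(reference)) {
        warning("model ", m_i, " chain ", ch,
                ": core size mismatch with reference; observation skipped")
        next
      }
      fit <- kabsch_fit(core_xyz, reference)
      loop_fitted <- apply_fit(model_xyz(model, loop_idx), fit)
      rows[[paste0("model", m_i, ":", ch)]] <- as.vector(t(loop_fitted))
    }
  }
  if (length(rows) < 3) {
    stop("insufficient data: ", length(rows),
         " usable (model, subunit) observations; need >= 3")
  }
  obs <- do.call(rbind, rows)
  attr(obs, "loop") <- loop
  attr(obs, "core") <- core
  attr(obs, "reference") <- reference
  obs
}

#' Fit a PCA model to loop observations
#'
#' Rows are centered by their mean (no per-coordinate scaling; all columns
#' share Angstrom units) and the covariance eigenvectors are returned ordered
#' by explained variance. Each component's sign is fixed so its
#' largest-magnitude loading is positive, making results deterministic across
#' eigen-solvers.
#'
#' @param obs observation matrix from [extract_loop_observations()] (rows =
#'   observations, columns = 3L coordinates).
#' @return object of class `pc_model`: `mean` (3L-vector), `components`
#'   (3L x k orthonormal matrix), `explained_fraction` (length k, sums to 1),
#'   `sdev`, plus the `loop`/`core`/`reference` conventions when present.
#' @export
fit_pca <- function(obs) {
  obs <- as.matrix(obs)
  if (nrow(obs) < 3) stop("need >= 3 observations")
  if (ncol(obs) < 2) stop("need >= 2 coordinates")
  if (sum(apply(obs, 2, stats::var)) < 1e-12) {
    stop("degenerate variance: all observations identical")
  }
  pc <- stats::prcomp(obs, center = TRUE, scale. = FALSE)
  comp <- pc$rotation
  for (k in seq_len(ncol(comp))) {
    if (comp[which.max(abs(comp[, k])), k] < 0) comp[, k] <- -comp[, k]
  }
  ev <- pc$sdev^2
  keep <- seq_len(min(nrow(obs) - 1, ncol(obs)))
  structure(list(mean = pc$center,
                 components = comp[, keep, drop = FALSE],
                 explained_fraction = ev[keep] / sum(ev[keep]),
                 sdev = pc$sdev[keep],
                 loop = attr(obs, "loop"), core = attr(obs, "core"),
                 reference = attr(obs, "reference")),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("loop PCA:", length(x$mean) / 3, "residues,",
      ncol(x$components), "components\n")
  ef <- round(100 * x$explained_fraction[seq_len(min(4, ncol(x$components)))], 1)
  cat("  explained variance (%):", paste(ef, collapse = ", "), "...\n")
  invisible(x)
}

#' Project observations onto principal components
#'
#' `projection = (observation - mean) %*% components`; the training mean maps
#' to the origin.
#'
#' @param obs observation matrix (or a single row vector) in the same frame
#'   and column convention as the training data.
#' @param model a `pc_model`.
#' @param n_comp number of components to return (default 2).
#' @return matrix of projections, one row per observation, columns PC1..PCk.
#' @export
pc_project <- function(obs, model, n_comp = 2) {
  if (is.null(dim(obs))) obs <- matrix(obs, nrow = 1)
  obs <- as.matrix(obs)
  if (ncol(obs) != length(model$mean)) {
    stop("dimension mismatch: observations have ", ncol(obs),
         " columns, PC model expects ", length(model$mean))
  }
  n_comp <- min(n_comp, ncol(model$components))
  proj <- sweep(obs, 2, model$mean) %*% model$components[, seq_len(n_comp),
                                                         drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(n_comp))
  proj
}

#' Project trajectory frames onto a fitted loop PCA
#'
#' Every frame is decomposed into five per-subunit loop observations using
#' the PC model's stored loop/core/reference conventions, then projected.
#'
#' @param traj a trajectory.
#' @param model a `pc_model` fitted via [extract_loop_observations()] +
#'   [fit_pca()].
#' @param n_comp number of components.
#' @return data.frame with columns `time`, `subunit`, `PC1`, ..., `PCk`.
#' @export
project_trajectory <- function(traj, model, n_comp = 2) {
  if (is.null(model$loop) || is.null(model$reference)) {
    stop("pc_model lacks loop/reference conventions; fit it from ",
         "extract_loop_observations() output")
  }
  out <- lapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_model(traj, f)
    obs <- extract_loop_observations(list(m), loop = model$loop,
                                     core = model$core,
                                     reference = model$reference)
    proj <- pc_project(obs, model, n_comp)
    data.frame(time = traj$times[f],
               subunit = sub("^model1:", "", rownames(obs)), proj,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' 2-D Gaussian kernel density estimate
#'
#' Gaussian-kernel density on a regular grid (via MASS), with Scott's-rule
#' bandwidth per dimension (`sd * n^(-1/6)`) by default and the grid spanning
#' the data range plus `expand` bandwidths. The returned grid integrates to 1
#' (trapezoidal) up to edge truncation.
#'
#' @param points two-column matrix (or data.frame) of (PC1, PC2) coordinates.
#' @param bandwidth length-2 numeric, Gaussian sd per dimension; NULL for
#'   Scott's rule.
#' @param n grid points per dimension.
#' @param expand grid margin in bandwidths.
#' @return list with `x`, `y` (grid vectors) and `z` (density matrix).
#' @export
kde2d_landscape <- function(points, bandwidth = NULL, n = 128, expand = 3) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(points) < 2) stop("bandwidth error: need >= 2 points")
  if (is.null(bandwidth)) {
    sds <- apply(points, 2, stats::sd)
    if (any(sds < 1e-12)) {
      stop("bandwidth error: zero variance in one dimension")
    }
    bandwidth <- sds * nrow(points)^(-1 / 6)
  }
  bandwidth <- rep(as.numeric(bandwidth), length.out = 2)
  if (any(bandwidth <= 0)) stop("bandwidth error: non-positive bandwidth")
  lims <- c(min(points[, 1]) - expand * bandwidth[1],
            max(points[, 1]) + expand * bandwidth[1],
            min(points[, 2]) - expand * bandwidth[2],
            max(points[, 2]) + expand * bandwidth[2])
  # MASS::kde2d interprets h as 4x the Gaussian kernel sd
  MASS::kde2d(points[, 1], points[, 2], h = 4 * bandwidth, n = n, lims = lims)
}
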