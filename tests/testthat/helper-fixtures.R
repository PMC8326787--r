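# Shared fixtures: small synthetic systems and hand-built minimal models.

quick_spec <- function(seed = 42, ...) {
  args <- list(seed = seed, n_frames = 10, n_ions = 4,
               n_waters_in_pore = 6, n_waters_bulk = 12)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_spec, args)
}

# A hand-built pentamer from per-atom rows. Each row of `at` is
# list(chain, resno, resid, elety, x, y, z). Waters/ions may be included
# with type = "HETATM".
build_model <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(type = if (!is.null(r$type)) r$type else "ATOM",
               eleno = 0L,
               elety = r$elety, alt = "",
               resid = if (!is.null(r$resid)) r$resid else "GLY",
               chain = r$chain, resno = r$resno,
               x = r$x, y = r$y, z = r$z, o = 1, b = 0,
               elesy = substr(r$elety, 1, 1))
  }))
  df$eleno <- seq_len(nrow(df))
  pentamer(df, title = "hand-built")
}

# One CA ring: five chains at azimuths 0, 72, ... at the given radius/z.
ring_rows <- function(resno, radius, z, elety = "CA", radii = NULL) {
  lapply(0:4, function(k) {
    r <- if (is.null(radii)) radius else radii[k + 1]
    th <- 72 * k * pi / 180
    list(chain = LETTERS[k + 1], resno = resno, elety = elety,
         x = r * cos(th), y = r * sin(th), z = z)
  })
}

z_axis <- function() pore_axis(c(0, 0, 0), c(0, 0, 1))

# Apply a rigid motion to every atom of a model.
rigid_move <- function(model, R = diag(3), t = c(0, 0, 0)) {
  set_xyz <- getFromNamespace("set_model_xyz", "pentagate")
  get_xyz <- getFromNamespace("model_xyz", "pentagate")
  set_xyz(model, sweep(get_xyz(model) %*% t(R), 2, -t))
}

rigid_move_traj <- function(traj, R = diag(3), t = c(0, 0, 0)) {
  xyz <- t(apply(traj$xyz, 1, function(row) {
    m <- matrix(row, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(m %*% t(R), 2, -t)))
  }))
  as_trajectory(traj$topology, xyz, traj$times, traj$ground_truth)
}

random_rotation <- function() {
  rotation_matrix(c(rnorm(3)), runif(1, 10, 350))
}
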