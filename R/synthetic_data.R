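# synthetic_data: C5 pentamer models and mock trajectories with prescribed
# spread, twist, pore radii, contact dynamics, ions and waters, plus exact
# ground truth, so every analysis stage is testable without downloads.
#
# The stand-ins are C-alpha-plus-marker-atom skeletons, not chemically valid
# structures: the analyses only ever touch named atoms (CA, CB, carboxylate
# oxygens, NZ, OG1, water O, Na+).

DEFAULT_RING_RADII <- local({
  resno <- 222:250
  # GLIC-like C-alpha funnel narrowing toward the 9' gate; the 233 entry is
  # the gate (C-beta) ring radius, with the C-alpha ring placed 1.5 A out.
  radii <- c(9.5, 9.0, 8.5, 8.0, 7.5, 7.0, 6.5, 6.0, 5.5, 5.0, 4.7,
             2.9,                                    # 233: CB gate radius
             4.6, 4.8, 5.0, 5.2, 5.6, 6.0, 6.5, 7.0, 7.5, 8.0, 8.6,
             9.2, 9.8, 10.4, 11.0, 11.6, 12.2)
  stats::setNames(radii, resno)
})

#' Specification of a synthetic C5 pentamer system
#'
#' The defaults emulate a GLIC-like resting pentamer: residues 15-314 per
#' chain, a pore funnel with a 2.9 A C-beta gate ring at residue 233 (9'),
#' ECD spread 25 A, domain twist 12 degrees, a two-state (formed/broken)
#' E243-K248 contact process with stationary formed fraction 0.75, diffusing
#' Na+ ions, and waters inside and outside the gate region. Trajectories of
#' 100 frames at 10 ns spacing mimic a 1-microsecond replicate.
#'
#' @param n_residues_per_chain residues per chain, starting at residue 15
#'   (>= 300 so all default selections resolve).
#' @param ring_radii named numeric map residue -> ring radius (A) for the
#'   pore region; the entry at `gate_residue` is the C-beta gate radius.
#' @param gate_residue hydrophobic-gate residue (9'), default 233.
#' @param ecd_spread_target ECD radius of gyration about the axis, A.
#' @param twist_deg domain twist, degrees.
#' @param breathing_amplitude ECD spread modulation amplitude per frame, A.
#' @param twist_drift ECD twist drift, degrees per frame.
#' @param contact_k_on,contact_k_off per-frame switching probabilities of the
#'   K248-E243 contact process (broken -> formed, formed -> broken).
#' @param contact_initial initial contact state, "formed" or "broken".
#' @param n_ions number of Na+ ions.
#' @param n_waters_in_pore waters placed inside the gate cylinder each frame.
#' @param n_waters_bulk waters placed well outside it.
#' @param noise_sigma Gaussian positional noise on protein atoms per frame, A.
#' @param n_frames,frame_dt_ns trajectory length and frame spacing.
#' @param seed integer seed; mandatory (all randomness flows from it).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues_per_chain = 300,
                           ring_radii = DEFAULT_RING_RADII,
                           gate_residue = 233,
                           ecd_spread_target = 25,
                           twist_deg = 12,
                           breathing_amplitude = 0.5,
                           twist_drift = 0,
                           contact_k_on = 0.15,
                           contact_k_off = 0.05,
                           contact_initial = c("formed", "broken"),
                           n_ions = 10,
                           n_waters_in_pore = 8,
                           n_waters_bulk = 40,
                           noise_sigma = 0,
                           n_frames = 100,
                           frame_dt_ns = 10,
                           seed) {
  if (missing(seed)) stop("spec error: seed is mandatory")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0 || seed > 2^31 - 10) {
    stop("spec error: seed must be a non-negative 32-bit integer")
  }
  contact_initial <- match.arg(contact_initial)
  spec <- list(n_residues_per_chain = n_residues_per_chain,
               ring_radii = ring_radii, gate_residue = gate_residue,
               ecd_spread_target = ecd_spread_target, twist_deg = twist_deg,
               breathing_amplitude = breathing_amplitude,
               twist_drift = twist_drift,
               contact_k_on = contact_k_on, contact_k_off = contact_k_off,
               contact_initial = contact_initial,
               n_ions = n_ions, n_waters_in_pore = n_waters_in_pore,
               n_waters_bulk = n_waters_bulk, noise_sigma = noise_sigma,
               n_frames = n_frames, frame_dt_ns = frame_dt_ns, seed = seed)
  first_res <- 15
  last_res <- first_res + n_residues_per_chain - 1
  ring_res <- as.integer(names(ring_radii))
  if (any(ring_res < first_res | ring_res > last_res) ||
      !(gate_residue %in% ring_res)) {
    stop("spec error: ring_radii residues (incl. gate ", gate_residue,
         ") must lie within ", first_res, "-", last_res)
  }
  if (last_res < 314) {
    stop("spec error: chains must span residues 15-314 ",
         "(n_residues_per_chain >= 300) so default selections resolve")
  }
  if (any(ring_radii <= 0)) stop("spec error: ring radii must be positive")
  probs <- c(contact_k_on, contact_k_off)
  if (any(probs < 0 | probs > 1)) {
    stop("spec error: switching probabilities must lie in [0, 1]")
  }
  if (n_frames < 1) stop("spec error: n_frames must be >= 1")
  structure(spec, class = "synthetic_spec")
}

MARKER_RESID <- c(`35` = "GLU", `158` = "THR", `233` = "ILE", `237` = "ALA",
                  `243` = "GLU", `248` = "LYS")

cyl_point <- function(radius, az_deg, z) {
  th <- az_deg * pi / 180
  c(radius * cos(th), radius * sin(th), z)
}

# Deterministic single-subunit template in cylindrical terms; returns a
# data.frame of (resno, resid, elety, radius, az_offset, z) where az_offset
# is relative to the chain base azimuth (twist applied to ECD rows already).
subunit_template <- function(spec) {
  first_res <- 15
  resnos <- seq(first_res, first_res + spec$n_residues_per_chain - 1)
  ring <- spec$ring_radii
  rows <- list()
  for (r in resnos) {
    ecd <- r <= 195
    if (ecd) {
      radius <- spec$ecd_spread_target
      az <- spec$twist_deg + (r - 105) * (40 / 180)
      z <- 130 - (r - first_res) * 65 / 180
    } else {
      z <- 60 - (r - 196) * 50 / 118
      az <- 0
      key <- as.character(r)
      if (key %in% names(ring)) {
        radius <- if (r == spec$gate_residue) ring[[key]] + 1.5 else ring[[key]]
      } else {
        radius <- 18
      }
    }
    resid <- if (as.character(r) %in% names(MARKER_RESID))
      MARKER_RESID[[as.character(r)]] else "GLY"
    add <- function(elety, rad, azo, zz) {
      rows[[length(rows) + 1]] <<- data.frame(
        resno = r, resid = resid, elety = elety,
        radius = rad, az_offset = azo, z = zz)
    }
    add("CA", radius, az, z)
    if (r == 35) {                       # proton-sensor glutamate
      add("CD", radius + 1.6, az, z - 0.4)
      add("OE1", radius + 2.4, az + 2, z)
      add("OE2", radius + 2.4, az - 2, z - 0.8)
    } else if (r == 158) {               # loop-F threonine
      add("CB", radius + 1.2, az, z)
      add("OG1", radius + 2.2, az, z - 0.5)
    } else if (r == spec$gate_residue) { # 9' gate: CB defines the gate ring
      add("CB", spec$ring_radii[[as.character(r)]], az, z)
    } else if (r == 237) {               # 13' alanine
      add("CB", radius - 1.0, az, z)
    } else if (r == 243) {               # M2-M3 loop glutamate
      add("CD", radius + 1.0, az, z - 0.5)
      add("OE1", radius + 1.8, az + 3, z - 0.6)
      add("OE2", radius + 1.8, az - 3, z - 1.0)
    }
    # K248 NZ is added per chain in the generator (pose depends on the
    # contact state); the template carries only its CA.
  }
  do.call(rbind, rows)
}

element_of <- function(elety) {
  substr(elety, 1, 1)
}

# z of the CA ring of residue r under the template z-map (TMD branch).
template_tmd_z <- function(r) 60 - (r - 196) * 50 / 118

# K248 NZ poses (contact / released) for a chain at base azimuth az_deg,
# relative to that chain's E243 OE1 position.
nz_poses <- function(spec, az_deg) {
  ring <- spec$ring_radii
  oe1 <- cyl_point(ring[["243"]] + 1.8, az_deg + 3, template_tmd_z(243) - 0.6)
  u_r <- c(cos(az_deg * pi / 180), sin(az_deg * pi / 180), 0)
  list(contact = oe1 + 0.5 * u_r + c(0, 0, -2.9),
       released = oe1 + 7 * u_r + c(0, 0, 2))
}

#' Generate a synthetic C5 pentamer model
#'
#' Builds an exactly C5-symmetric model about the z axis with chains A-E at
#' azimuths 0, 72, ..., 288 degrees, the prescribed pore ring radii, ECD
#' spread, and domain twist, marker residues (E35, T158, I233, A237, E243,
#' K248) carrying side-chain stand-in atoms, plus randomly placed pore/bulk
#' waters and Na+ ions. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [pentamer()] model.
#' @export
generate_pentamer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  tmpl <- subunit_template(spec)
  chains <- LETTERS[1:5]
  prot <- list()
  for (k in 0:4) {
    ch <- chains[k + 1]
    az <- tmpl$az_offset + 72 * k
    th <- az * pi / 180
    df <- data.frame(type = "ATOM", eleno = 0L, elety = tmpl$elety, alt = "",
                     resid = tmpl$resid, chain = ch, resno = tmpl$resno,
                     x = tmpl$radius * cos(th), y = tmpl$radius * sin(th),
                     z = tmpl$z, o = 1, b = 0,
                     elesy = element_of(tmpl$elety))
    nz <- nz_poses(spec, 72 * k)[[
      if (spec$contact_initial == "formed") "contact" else "released"]]
    df <- rbind(df, data.frame(type = "ATOM", eleno = 0L, elety = "NZ",
                               alt = "", resid = "LYS", chain = ch,
                               resno = 248L, x = nz[1], y = nz[2], z = nz[3],
                               o = 1, b = 0, elesy = "N"))
    df <- df[order(df$resno, df$elety != "CA", df$elety), ]
    prot[[ch]] <- df
  }
  prot <- do.call(rbind, prot)
  wat <- place_waters(spec)
  ion <- place_ions(spec)
  atom <- rbind(prot, wat, ion)
  atom$eleno <- seq_len(nrow(atom))
  rownames(atom) <- NULL
  pentamer(atom, title = sprintf("synthetic C5 pentamer (seed %d)", spec$seed))
}

# Water slab bounds of the gate cylinder (between CA rings of 233 and 237),
# shrunk slightly so closed-interval boundary effects cannot flip counts.
pore_slab <- function(spec) {
  zb <- sort(c(template_tmd_z(spec$gate_residue), template_tmd_z(237)))
  c(zb[1] + 0.15, zb[2] - 0.15)
}

random_pore_water_xyz <- function(spec) {
  slab <- pore_slab(spec)
  n <- spec$n_waters_in_pore
  r <- 4 * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th), stats::runif(n, slab[1], slab[2]))
}

random_bulk_water_xyz <- function(spec) {
  n <- spec$n_waters_bulk
  r <- stats::runif(n, 15, 40)
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th), stats::runif(n, 0, 140))
}

place_waters <- function(spec) {
  xyz <- rbind(random_pore_water_xyz(spec), random_bulk_water_xyz(spec))
  n <- nrow(xyz)
  if (n == 0) return(NULL)
  data.frame(type = "HETATM", eleno = 0L, elety = "O", alt = "",
             resid = "HOH", chain = "W", resno = seq_len(n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
             elesy = "O")
}

place_ions <- function(spec) {
  n <- spec$n_ions
  if (n == 0) return(NULL)
  # up to five ions start coordinated (3 A) to the five E35 carboxylates,
  # emulating environmental cations transiently bound to the proton sensor;
  # the rest (and, over time, all of them) diffuse in the extracellular shell
  n_near <- min(5L, n)
  z35 <- 130 - (35 - 15) * 65 / 180
  az35 <- spec$twist_deg + (35 - 105) * (40 / 180) + 2
  near <- t(vapply(seq_len(n_near) - 1L, function(k) {
    cyl_point(spec$ecd_spread_target + 2.4 + 3.0, 72 * k + az35, z35)
  }, numeric(3)))
  n_far <- n - n_near
  far <- if (n_far > 0) {
    r <- stats::runif(n_far, 18, 35)
    th <- stats::runif(n_far, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th), stats::runif(n_far, 60, 130))
  } else NULL
  xyz <- rbind(near, far)
  data.frame(type = "HETATM", eleno = 0L, elety = "NA", alt = "",
             resid = "NA", chain = "I", resno = seq_len(n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
             elesy = "NA")
}

#' Generate a synthetic trajectory with ground truth
#'
#' Starting from [generate_pentamer()], frames apply: sinusoidal ECD
#' breathing (spread modulation of amplitude `breathing_amplitude`, period 20
#' frames), linear ECD twist drift, an independent two-state Markov contact
#' process per subunit moving the K248 NZ stand-in between a contact pose
#' (within the salt-bridge cutoff of the E243 carboxylate) and a released
#' pose, Gaussian random walks of the Na+ ions, per-frame uniform
#' resampling of pore/bulk water positions (pore waters stay inside the gate
#' cylinder, bulk waters outside), and optional Gaussian noise on protein
#' atoms. The exact per-frame ground truth is returned alongside.
#'
#' @param spec a [synthetic_spec()].
#' @return a trajectory whose `ground_truth` holds `spread` (A), `twist`
#'   (degrees), `contact_states` (n_frames x 5 logical), `n_waters_in_pore`,
#'   and the generating `spec`.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  model <- generate_pentamer(spec)
  set.seed(spec$seed + 1L)
  a <- model$atom
  template <- as.matrix(a[, c("x", "y", "z")])
  n_at <- nrow(template)
  nf <- spec$n_frames
  chains <- model$chains
  ecd_rows <- which(is_protein_atom(a) & a$resno <= 195)
  prot_rows <- which(is_protein_atom(a))
  wat_rows <- which(a$resid == "HOH")
  pore_wat_rows <- wat_rows[seq_len(spec$n_waters_in_pore)]
  bulk_wat_rows <- setdiff(wat_rows, pore_wat_rows)
  ion_rows <- which(a$resid == "NA")
  nz_rows <- vapply(chains, function(ch) {
    which(a$chain == ch & a$resno == 248 & a$elety == "NZ")
  }, integer(1))
  poses <- lapply(0:4, function(k) nz_poses(spec, 72 * k))

  S <- spec$ecd_spread_target
  xyz <- matrix(0, nf, 3 * n_at)
  spread_truth <- numeric(nf)
  twist_truth <- numeric(nf)
  states <- matrix(FALSE, nf, 5, dimnames = list(NULL, chains))
  state <- rep(spec$contact_initial == "formed", 5)
  ion_xyz <- template[ion_rows, , drop = FALSE]

  for (t in seq_len(nf)) {
    fr <- template
    # ECD breathing: uniform radial scaling about the z axis
    spread_truth[t] <- S + spec$breathing_amplitude * sin(2 * pi * (t - 1) / 20)
    scale_f <- spread_truth[t] / S
    fr[ecd_rows, 1:2] <- fr[ecd_rows, 1:2] * scale_f
    # ECD twist drift about the z axis
    drift <- spec$twist_drift * (t - 1)
    twist_truth[t] <- spec$twist_deg + drift
    if (drift != 0) {
      R <- rotation_matrix(c(0, 0, 1), drift)
      fr[ecd_rows, ] <- fr[ecd_rows, , drop = FALSE] %*% t(R)
    }
    # two-state contact process, one chain per column
    u <- stats::runif(5)
    if (t > 1) {
      state <- ifelse(state, u >= spec$contact_k_off, u < spec$contact_k_on)
    }
    states[t, ] <- state
    for (k in 1:5) {
      fr[nz_rows[k], ] <- if (state[k]) poses[[k]]$contact
                          else poses[[k]]$released
    }
    # waters: resample inside/outside the gate cylinder
    if (length(pore_wat_rows) > 0) {
      fr[pore_wat_rows, ] <- random_pore_water_xyz(spec)
    }
    if (length(bulk_wat_rows) > 0) {
      fr[bulk_wat_rows, ] <- random_bulk_water_xyz(spec)
    }
    # ions: Gaussian random walk, 1 A rms per axis per frame
    if (length(ion_rows) > 0 && t > 1) {
      ion_xyz <- ion_xyz + matrix(stats::rnorm(3 * length(ion_rows)),
                                  ncol = 3)
    }
    if (length(ion_rows) > 0) fr[ion_rows, ] <- ion_xyz
    if (spec$noise_sigma > 0) {
      fr[prot_rows, ] <- fr[prot_rows, ] +
        matrix(stats::rnorm(3 * length(prot_rows), sd = spec$noise_sigma),
               ncol = 3)
    }
    xyz[t, ] <- as.vector(t(fr))
  }
  times <- (seq_len(nf) - 1) * spec$frame_dt_ns
  as_trajectory(model, xyz, times,
                ground_truth = list(spread = spread_truth,
                                    twist = twist_truth,
                                    contact_states = states,
                                    n_waters_in_pore = spec$n_waters_in_pore,
                                    spec = spec))
}

#' Write a synthetic fixture to disk
#'
#' Produces `topology.pdb` (the model), `trajectory.pdb` (multi-model PDB,
#' one MODEL per frame), and `ground_truth.json` (frame times, ground-truth
#' series, and the generating spec). Two runs with the same seed produce
#' byte-identical files.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
write_fixture <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traj <- generate_trajectory(spec)
  paths <- list(topology = file.path(dir, "topology.pdb"),
                trajectory = file.path(dir, "trajectory.pdb"),
                ground_truth = file.path(dir, "ground_truth.json"))
  write_pdb(traj$topology, paths$topology)
  write_trajectory(traj, paths$trajectory)
  gt <- traj$ground_truth
  payload <- list(times = traj$times,
                  spread = gt$spread, twist = gt$twist,
                  contact_states = gt$contact_states,
                  n_waters_in_pore = gt$n_waters_in_pore,
                  spec = unclass(spec))
  jsonlite::write_json(payload, paths$ground_truth, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read a synthetic fixture from disk
#'
#' @param dir directory written by [write_fixture()].
#' @return a trajectory with ground truth re-attached.
#' @export
read_fixture <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  traj <- read_trajectory(file.path(dir, "trajectory.pdb"),
                          topology_path = file.path(dir, "topology.pdb"),
                          times = gt$times)
  traj$ground_truth <- list(spread = gt$spread, twist = gt$twist,
                            contact_states = gt$contact_states,
                            n_waters_in_pore = gt$n_waters_in_pore,
                            spec = gt$spec)
  traj
}
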