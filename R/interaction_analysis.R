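# interaction_analysis: cutoff-based electrostatic contacts, sodium
# coordination, intersubunit distances, and bootstrap median summaries.
# Distances are plain Euclidean (no periodic imaging): all protein-internal
# measures are image-safe for whole-molecule trajectories.

new_contact_series <- function(frame_times, values, per_subunit = NULL,
                               cutoff, group_a, group_b,
                               pairing = c("intra", "inter", "ion")) {
  pairing <- match.arg(pairing)
  stopifnot(length(values) == length(frame_times), cutoff > 0)
  structure(list(frame_times = frame_times, values = values,
                 per_subunit = per_subunit, cutoff = cutoff,
                 group_a = group_a, group_b = group_b, pairing = pairing),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("contact series: %d frames, cutoff %.2f A (%s) %s vs %s\n",
              length(x$values), x$cutoff, x$pairing, x$group_a, x$group_b))
  invisible(x)
}

carboxylate_atoms <- function(resid) {
  switch(resid, GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"),
         stop("selection error: residue type ", resid,
              " has no side-chain carboxylate"))
}

#' Sodium coordination of an acidic residue over a trajectory
#'
#' Per sampled frame, counts the distinct monovalent cations within `cutoff`
#' (inclusive) of any side-chain carboxylate oxygen of any copy of `residue`
#' (default: the proton sensor E35, Na+ within 5 A, frames sampled every
#' 10 ns). Counts are reported pooled over the five subunits and per subunit.
#'
#' @param traj a trajectory.
#' @param residue author residue number of a GLU/ASP.
#' @param ion_name ion residue name in the topology ("NA" or "SOD").
#' @param cutoff coordination cutoff, Angstrom.
#' @param stride_ns sampling interval in ns (frames are subsampled to
#'   approximately this spacing; use 0 to keep every frame).
#' @return a `contact_series`; `values` are pooled distinct-ion counts,
#'   `per_subunit` an n_frames x 5 count matrix (columns in chain order).
#' @export
ion_coordination_series <- function(traj, residue = 35, ion_name = "NA",
                                    cutoff = 5, stride_ns = 10) {
  top <- traj$topology
  a <- top$atom
  res_rows <- which(is_protein_atom(a) & a$resno == residue)
  if (length(res_rows) == 0) stop("selection error: residue ", residue,
                                  " not in topology")
  resid <- unique(a$resid[res_rows])[1]
  ox_names <- carboxylate_atoms(resid)
  ox_idx <- lapply(top$chains, function(ch) {
    ii <- res_rows[a$chain[res_rows] == ch & a$elety[res_rows] %in% ox_names]
    if (length(ii) == 0) stop("selection error: residue ", residue,
                              " chain ", ch, " lacks carboxylate oxygens")
    ii
  })
  ion_names <- if (ion_name %in% c("NA", "SOD")) CATION_RESIDS else ion_name
  # match on residue or atom name; PDB parsers sometimes mangle resid "NA"
  ion_idx <- which((!is.na(a$resid) & a$resid %in% ion_names) |
                     (!is.na(a$elety) & a$elety %in% ion_names))
  frames <- seq_len(n_frames(traj))
  if (stride_ns > 0 && n_frames(traj) > 1) {
    dt <- diff(traj$times[1:2])
    step <- max(1L, as.integer(round(stride_ns / dt)))
    frames <- seq(1L, n_frames(traj), by = step)
  }
  nch <- length(top$chains)
  per_sub <- matrix(0L, length(frames), nch,
                    dimnames = list(NULL, top$chains))
  pooled <- integer(length(frames))
  for (k in seq_along(frames)) {
    xyz <- frame_xyz(traj, frames[k])
    if (length(ion_idx) > 0) {
      ions <- xyz[ion_idx, , drop = FALSE]
      near_any <- rep(FALSE, length(ion_idx))
      for (c_i in seq_len(nch)) {
        ox <- xyz[ox_idx[[c_i]], , drop = FALSE]
        d2 <- outer(rowSums(ions^2), rowSums(ox^2), "+") -
          2 * ions %*% t(ox)
        near <- apply(d2 <= cutoff^2 + 1e-9, 1, any)
        per_sub[k, c_i] <- sum(near)
        near_any <- near_any | near
      }
      pooled[k] <- sum(near_any)
    }
  }
  new_contact_series(traj$times[frames], pooled, per_sub, cutoff,
                     paste0(resid, residue, ":", paste(ox_names, collapse = "/")),
                     ion_name, pairing = "ion")
}

#' Minimum heavy-atom distance between two selections
#'
#' @param model a [pentamer()] (or a single trajectory frame via
#'   [frame_model()]).
#' @param group_a,group_b [selection()]s; both must resolve to >= 1 atom.
#' @return minimum pairwise distance in Angstrom.
#' @export
min_group_distance <- function(model, group_a, group_b) {
  ia <- resolve_selection(model, group_a)
  ib <- resolve_selection(model, group_b)
  xa <- model_xyz(model, ia)
  xb <- model_xyz(model, ib)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

#' Intrasubunit salt-bridge contact series
#'
#' Per frame and per subunit, tests whether any atom of `atoms_b` on residue
#' `res_b` lies within `cutoff` of any atom of `atoms_a` on residue `res_a`
#' of the same subunit. The default is the M2-M3 loop contact: K248 side-chain
#' nitrogen to E243 carboxylate oxygens at the 4 A salt-bridge convention.
#'
#' @param traj a trajectory.
#' @param res_a,res_b author residue numbers.
#' @param atoms_a,atoms_b atom names defining the charged groups.
#' @param cutoff contact cutoff, Angstrom.
#' @return a `contact_series`; `values` is the per-frame number of subunits
#'   in contact (0-5), `per_subunit` a logical n_frames x 5 matrix.
#' @export
salt_bridge_series <- function(traj, res_a = 243, res_b = 248,
                               atoms_a = c("OE1", "OE2"), atoms_b = "NZ",
                               cutoff = 4) {
  top <- traj$topology
  a <- top$atom
  idx_a <- lapply(top$chains, function(ch) {
    which(is_protein_atom(a) & a$chain == ch & a$resno == res_a &
            a$elety %in% atoms_a)
  })
  idx_b <- lapply(top$chains, function(ch) {
    which(is_protein_atom(a) & a$chain == ch & a$resno == res_b &
            a$elety %in% atoms_b)
  })
  if (any(lengths(idx_a) == 0) || any(lengths(idx_b) == 0)) {
    stop("selection error: contact groups unresolved in >= 1 chain")
  }
  nch <- length(top$chains)
  per_sub <- matrix(FALSE, n_frames(traj), nch,
                    dimnames = list(NULL, top$chains))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_xyz(traj, f)
    for (c_i in seq_len(nch)) {
      xa <- xyz[idx_a[[c_i]], , drop = FALSE]
      xb <- xyz[idx_b[[c_i]], , drop = FALSE]
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
      per_sub[f, c_i] <- any(d2 <= cutoff^2 + 1e-9)
    }
  }
  new_contact_series(traj$times, rowSums(per_sub), per_sub, cutoff,
                     paste0(res_a, ":", paste(atoms_a, collapse = "/")),
                     paste0(res_b, ":", paste(atoms_b, collapse = "/")),
                     pairing = "intra")
}

#' Fraction of frames in contact
#'
#' For a series with per-subunit states, contact fractions are computed per
#' subunit and pooled (every (frame, subunit) cell counted once), matching
#' per-simulation pooling of subunit observations; otherwise the fraction of
#' frames whose pooled value reaches `threshold`.
#'
#' @param series a `contact_series`, or a plain numeric/logical vector of
#'   per-frame values.
#' @param threshold minimum count that qualifies as "in contact".
#' @param pool_subunits use the per-subunit matrix when available.
#' @return fraction in `[0, 1]`.
#' @export
contact_fraction <- function(series, threshold = 1, pool_subunits = TRUE) {
  if (inherits(series, "contact_series")) {
    if (pool_subunits && !is.null(series$per_subunit)) {
      vals <- series$per_subunit
    } else {
      vals <- series$values
    }
  } else {
    vals <- series
  }
  if (length(vals) == 0) stop("empty contact series")
  mean(vals >= threshold)
}

#' Intersubunit C-alpha distances across the five interfaces
#'
#' Distance between the C-alpha of `res_a` on the principal subunit `i` and
#' the C-alpha of `res_b` on its complementary neighbor `i + 1` (azimuthal
#' order), for all five interfaces. The default pair E35-T158 spans the
#' beta1-beta2/loop-F interface.
#'
#' @param x a [pentamer()] or a trajectory.
#' @param res_a,res_b author residue numbers (principal, complementary).
#' @param axis optional [pore_axis()] for the subunit ordering; estimated
#'   from `x` (or the first frame) when NULL.
#' @return for a model, a named numeric vector of 5 distances ("A>B" names);
#'   for a trajectory, a data.frame with `time` plus one column per interface.
#' @export
intersubunit_ca_distance <- function(x, res_a = 35, res_b = 158, axis = NULL) {
  if (inherits(x, "trajectory")) {
    m0 <- frame_model(x, 1)
    if (is.null(axis)) axis <- estimate_pore_axis(m0)
    ord <- subunit_order(m0, axis)
    pair_idx <- interface_ca_indices(x$topology, res_a, res_b, ord)
    out <- t(vapply(seq_len(n_frames(x)), function(f) {
      xyz <- frame_xyz(x, f)
      vapply(pair_idx, function(p) {
        sqrt(sum((xyz[p[1], ] - xyz[p[2], ])^2))
      }, numeric(1))
    }, numeric(5)))
    df <- data.frame(time = x$times, out, check.names = FALSE)
    return(df)
  }
  if (is.null(axis)) axis <- estimate_pore_axis(x)
  ord <- subunit_order(x, axis)
  pair_idx <- interface_ca_indices(x, res_a, res_b, ord)
  xyz <- model_xyz(x)
  vapply(pair_idx, function(p) {
    sqrt(sum((xyz[p[1], ] - xyz[p[2], ])^2))
  }, numeric(1))
}

interface_ca_indices <- function(model, res_a, res_b, ord) {
  a <- model$atom
  find_ca <- function(ch, r) {
    i <- which(is_protein_atom(a) & a$chain == ch & a$resno == r &
                 a$elety == "CA")
    if (length(i) != 1) {
      stop("pairing error: missing CA for residue ", r, " chain ", ch)
    }
    i
  }
  out <- lapply(seq_along(ord), function(i) {
    j <- (i %% length(ord)) + 1
    c(find_ca(ord[i], res_a), find_ca(ord[j], res_b))
  })
  names(out) <- vapply(seq_along(ord), function(i) {
    paste0(ord[i], ">", ord[(i %% length(ord)) + 1])
  }, character(1))
  out
}

#' Percentile-bootstrap confidence interval of the median
#'
#' Resamples the per-simulation (or per-subunit) values with replacement
#' `n_boot` times and reports the percentile interval of the resampled
#' medians. Deterministic given `seed`; the caller's RNG state is preserved.
#'
#' @param samples numeric vector, length >= 1.
#' @param level confidence level (default 0.95).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed (mandatory for reproducibility).
#' @return object of class `summary_stat`: `median`, `ci_low`, `ci_high`,
#'   `n_samples`, `level`, `n_boot`, `seed`.
#' @export
bootstrap_median_ci <- function(samples, level = 0.95, n_boot = 10000, seed) {
  if (length(samples) == 0) stop("empty sample vector")
  if (missing(seed)) stop("seed is required")
  n <- length(samples)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boot_meds <- apply(idx, 1, function(i) stats::median(samples[i]))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot_meds, c(alpha, 1 - alpha), type = 7))
  structure(list(median = stats::median(samples), ci_low = ci[1],
                 ci_high = ci[2], n_samples = n, level = level,
                 n_boot = n_boot, seed = seed),
            class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("median %.4g [%.4g, %.4g] (%d%% bootstrap CI, n = %d, B = %d)\n",
              x$median, x$ci_low, x$ci_high, round(100 * x$level),
              x$n_samples, x$n_boot))
  invisible(x)
}
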