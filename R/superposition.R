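# superposition: rigid-body least-squares (Kabsch) fitting and
# selection-restricted RMSD between models and across trajectory frames.

#' Kabsch rigid-body superposition
#'
#' Least-squares superposition of `mobile` onto `reference` with a proper
#' rotation (reflections excluded), via SVD of the 3x3 covariance of the
#' centered point sets. All atoms are weighted equally.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3, paired by row.
#' @return object of class `fit_result`: `rotation` (3x3, det +1),
#'   `translation` (3-vector; fitted coords are `x %*% t(rotation) +
#'   translation`), `rmsd` (A), `n_atoms`.
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 ||
      ncol(reference) != 3) {
    stop("mobile and reference must be N x 3 matrices of equal N")
  }
  n <- nrow(mobile)
  if (n < 3) stop("insufficient atoms: need >= 3 paired points, got ", n)
  if (!all(is.finite(mobile)) || !all(is.finite(reference))) {
    stop("non-finite coordinates")
  }
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  pm <- sweep(mobile, 2, cm)
  pr <- sweep(reference, 2, cr)
  sv_m <- svd(pm)$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1)) {
    warning("conditioning: mobile points are (near-)collinear; ",
            "rotation is not unique")
  }
  H <- crossprod(pm, pr)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- pm %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - pr)^2)))
  structure(list(rotation = R,
                 translation = drop(cr - R %*% cm),
                 rmsd = rmsd, n_atoms = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("kabsch fit: rmsd %.4f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

#' Apply a fitted rigid motion to coordinates
#'
#' @param xyz N x 3 matrix.
#' @param fit a `fit_result` from [kabsch_fit()].
#' @return transformed N x 3 matrix.
#' @export
apply_fit <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, -fit$translation)
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Resolve a selection on a model and return coords ordered by a chain map
# (named list chain -> position), plus the (resno, elety) identity strings.
sel_coords_by_chain <- function(model, sel, chain_order) {
  idx <- resolve_selection(model, sel, symmetric = TRUE)
  a <- model$atom[idx, , drop = FALSE]
  out <- lapply(chain_order, function(ch) {
    sub <- a[a$chain == ch, , drop = FALSE]
    sub <- sub[order(sub$resno, sub$elety), , drop = FALSE]
    list(xyz = as.matrix(sub[, c("x", "y", "z")]),
         id = paste(sub$resno, sub$elety, sep = "|"))
  })
  list(xyz = do.call(rbind, lapply(out, `[[`, "xyz")),
       id = unlist(lapply(out, `[[`, "id")))
}

#' RMSD between two pentamer models after rigid superposition
#'
#' Superposes `b` onto `a` on `fit_sel` and reports the RMSD over
#' `measure_sel`. Chains are paired by azimuthal order ([subunit_order()]),
#' and the cyclic offset between the two pentamers is chosen to minimize the
#' fitted RMSD, so deposited chain labels need not correspond. Selections
#' must resolve to matching (residue, atom) identities in both models.
#'
#' @param a,b [pentamer()] models.
#' @param fit_sel selection used for the superposition.
#' @param measure_sel selection over which RMSD is reported (default:
#'   `fit_sel`).
#' @param chain_map `"azimuthal"` (default) or `"identity"` to pair chains by
#'   their labels as-is.
#' @return RMSD in Angstrom.
#' @export
rmsd_between_models <- function(a, b, fit_sel, measure_sel = fit_sel,
                                chain_map = c("azimuthal", "identity")) {
  chain_map <- match.arg(chain_map)
  if (chain_map == "azimuthal") {
    ord_a <- subunit_order(a, estimate_pore_axis(a))
    ord_b <- subunit_order(b, estimate_pore_axis(b))
  } else {
    ord_a <- a$chains
    ord_b <- b$chains
  }
  fa <- sel_coords_by_chain(a, fit_sel, ord_a)
  ma <- sel_coords_by_chain(a, measure_sel, ord_a)
  best <- Inf
  offsets <- if (chain_map == "azimuthal") 0:4 else 0
  for (off in offsets) {
    ord_b_off <- ord_b[((seq_along(ord_b) - 1 + off) %% 5) + 1]
    fb <- sel_coords_by_chain(b, fit_sel, ord_b_off)
    if (length(fa$id) != length(fb$id) || any(fa$id != fb$id)) {
      first <- if (length(fa$id) != length(fb$id)) {
        "atom counts differ"
      } else {
        paste("first mismatch:", fa$id[which(fa$id != fb$id)[1]], "vs",
              fb$id[which(fa$id != fb$id)[1]])
      }
      stop("pairing error between models on fit selection (", first, ")")
    }
    mb <- sel_coords_by_chain(b, measure_sel, ord_b_off)
    if (length(ma$id) != length(mb$id) || any(ma$id != mb$id)) {
      stop("pairing error between models on measure selection")
    }
    fit <- kabsch_fit(fb$xyz, fa$xyz)
    r <- rmsd_xyz(apply_fit(mb$xyz, fit), ma$xyz)
    if (r < best) best <- r
  }
  best
}

#' Restrict a C-alpha selection to residues complete in both models
#'
#' Deposited models differ in which residues could be built; this helper
#' intersects a C-alpha selection with the residues whose C-alpha is present
#' in all five chains of both models, so [rmsd_between_models()] sees
#' matching identities.
#'
#' @param a,b [pentamer()] models.
#' @param sel a C-alpha [selection()].
#' @return a [selection()] covering the common complete residues.
#' @export
common_ca_selection <- function(a, b, sel) {
  complete_res <- function(model) {
    at <- model$atom
    keep <- is_protein_atom(at) & at$elety == "CA" &
      in_ranges(at$resno, sel$ranges)
    tab <- table(at$resno[keep], at$chain[keep])
    as.integer(rownames(tab)[rowSums(tab > 0) == length(model$chains)])
  }
  resnos <- sort(intersect(complete_res(a), complete_res(b)))
  if (length(resnos) == 0) stop("no common complete residues in selection")
  brk <- c(0, which(diff(resnos) > 1), length(resnos))
  ranges <- t(vapply(seq_len(length(brk) - 1), function(i) {
    c(resnos[brk[i] + 1], resnos[brk[i + 1]])
  }, numeric(2)))
  selection(ranges, atom_names = "CA", chains = sel$chains)
}

#' Per-frame RMSD of a trajectory against a reference model
#'
#' Each frame is superposed on `fit_sel` onto the reference and the RMSD is
#' reported over `measure_sel`, e.g. ECD C-alpha (residues 15-48, 66-192) or
#' TMD C-alpha (197-313) deviations over time, or loop-F-only deviations.
#'
#' @param traj a trajectory (see [as_trajectory()]).
#' @param reference a [pentamer()]; its topology must resolve the same
#'   selections with identical (residue, atom) identity.
#' @param fit_sel,measure_sel [selection()]s.
#' @return data.frame with columns `time` (ns) and `rmsd` (A).
#' @export
per_frame_rmsd <- function(traj, reference, fit_sel, measure_sel = fit_sel) {
  top <- traj$topology
  fit_idx <- resolve_selection(top, fit_sel, symmetric = TRUE)
  mea_idx <- resolve_selection(top, measure_sel, symmetric = TRUE)
  ref_fit <- sel_coords_by_chain(reference, fit_sel, reference$chains)
  ref_mea <- sel_coords_by_chain(reference, measure_sel, reference$chains)
  ta <- top$atom
  id_fit <- paste(ta$chain[fit_idx], ta$resno[fit_idx], ta$elety[fit_idx])
  ref_a <- reference$atom
  ref_fit_idx <- resolve_selection(reference, fit_sel, symmetric = TRUE)
  id_ref <- paste(ref_a$chain[ref_fit_idx], ref_a$resno[ref_fit_idx],
                  ref_a$elety[ref_fit_idx])
  if (length(id_fit) != length(id_ref) || any(id_fit != id_ref)) {
    stop("pairing error: trajectory topology and reference selections differ")
  }
  ref_fit_xyz <- model_xyz(reference, ref_fit_idx)
  ref_mea_xyz <- model_xyz(reference,
                           resolve_selection(reference, measure_sel,
                                             symmetric = TRUE))
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_xyz(traj, f)
    fit <- kabsch_fit(xyz[fit_idx, , drop = FALSE], ref_fit_xyz)
    rmsd_xyz(apply_fit(xyz[mea_idx, , drop = FALSE], fit), ref_mea_xyz)
  }, numeric(1))
  data.frame(time = traj$times, rmsd = vals)
}
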