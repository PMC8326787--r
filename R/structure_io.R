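# structure_io: coordinate model I/O, atom selections, and the rotational
# (azimuthal) subunit order of the pentamer.

WATER_RESIDS <- c("HOH", "WAT", "SOL", "TIP3")
CATION_RESIDS <- c("NA", "SOD")

#' Construct a pentamer coordinate model
#'
#' A `pentamer` wraps an atom table in author (PDB) numbering. Protein atoms
#' are `ATOM` records; waters and monovalent cations are retained as labeled
#' `HETATM` records. The model must contain exactly five protein chains.
#'
#' @param atom data.frame with columns `type` ("ATOM"/"HETATM"), `eleno`,
#'   `elety` (atom name, e.g. "CA"), `alt`, `resid` (3-letter residue name),
#'   `chain`, `resno` (author residue number), `x`, `y`, `z`, `o` (occupancy),
#'   `b`, `elesy` (element symbol).
#' @param title free-text provenance string.
#' @return object of class `pentamer`.
#' @export
pentamer <- function(atom, title = "") {
  required <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
                "x", "y", "z", "o", "b", "elesy")
  missing_cols <- setdiff(required, names(atom))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  if (any(atom$resno < 1)) stop("residue numbers must be >= 1")
  if (any(!nzchar(atom$elety))) stop("empty atom names in atom table")
  prot <- is_protein_atom(atom)
  chains <- sort(unique(atom$chain[prot]))
  if (length(chains) != 5) {
    stop("assembly error: expected 5 protein chains, found ", length(chains))
  }
  structure(list(atom = atom, chains = chains, title = title),
            class = "pentamer")
}

is_protein_atom <- function(atom) {
  atom$type == "ATOM" & !(atom$resid %in% c(WATER_RESIDS, CATION_RESIDS))
}

#' @export
print.pentamer <- function(x, ...) {
  cat("pentamer model:", x$title, "\n")
  cat("  protein atoms:", sum(is_protein_atom(x$atom)),
      " chains:", paste(x$chains, collapse = ","), "\n")
  cat("  hetero atoms:", sum(!is_protein_atom(x$atom)), "\n")
  invisible(x)
}

# N x 3 coordinate matrix for (a subset of) the atom table.
model_xyz <- function(model, idx = NULL) {
  a <- model$atom
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# Replace coordinates (N x 3, full atom table order).
set_model_xyz <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atom))
  model$atom$x <- xyz[, 1]
  model$atom$y <- xyz[, 2]
  model$atom$z <- xyz[, 3]
  model
}

#' Read a pentameric coordinate model from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations to the
#' highest-occupancy copy (ties broken toward altloc "A"), and keeps waters
#' (HOH/WAT/SOL/TIP3) and monovalent cations (NA/SOD) as labeled heteroatoms.
#' Insertion codes are rejected. The protein content must form exactly five
#' chains.
#'
#' @param path PDB file path.
#' @return a [pentamer()] model.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("PDB format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  atom <- pdb$atom
  atom$insert[is.na(atom$insert)] <- ""
  if (any(nzchar(atom$insert))) {
    stop("insertion codes are not supported (found in ", path, ")")
  }
  atom$alt[is.na(atom$alt)] <- ""
  atom$o[is.na(atom$o)] <- 1
  atom$b[is.na(atom$b)] <- 0
  atom$elesy[is.na(atom$elesy)] <- ""
  atom <- resolve_altloc(atom)
  atom <- atom[, c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
                   "x", "y", "z", "o", "b", "elesy")]
  rownames(atom) <- NULL
  pentamer(atom, title = basename(path))
}

# Keep one atom per (chain, resno, resid, elety): highest occupancy, ties by
# altloc (so "A" wins over "B").
resolve_altloc <- function(atom) {
  key <- paste(atom$chain, atom$resno, atom$resid, atom$elety, sep = "|")
  if (!anyDuplicated(key)) return(atom)
  ord <- order(key, -atom$o, atom$alt)
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(key[ord]), , drop = FALSE]
  atom[order(atom$eleno), , drop = FALSE]
}

#' Write a model to a PDB file
#'
#' Fixed-column PDB output (via bio3d). Coordinates are written with three
#' decimals, so a write/read round trip reproduces coordinates to 1e-3 A.
#'
#' @param model a [pentamer()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atom
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = a$eleno, elety = a$elety, chain = a$chain,
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Define an atom selection
#'
#' Selections name inclusive author-numbered residue intervals, a set of atom
#' names, and the chains they apply to. Intervals are normalized to be sorted
#' and non-overlapping. Preset ranges used by the analyses (all configurable
#' at call sites): model-alignment ECD 17-192 and TMD 196-314; trajectory-RMSD
#' ECD 15-48 plus 66-192 and TMD 197-313; ECD spread 20-190; M2-M3 loop
#' 243-250.
#'
#' @param ranges numeric vector `c(lo, hi)`, a list of such vectors, or a
#'   2-column matrix of inclusive intervals.
#' @param atom_names character vector of atom names, or `NULL` for all atoms.
#' @param chains `"all"` or a character vector of chain ids.
#' @return object of class `selection`.
#' @export
selection <- function(ranges, atom_names = "CA", chains = "all") {
  if (is.numeric(ranges) && !is.matrix(ranges)) {
    if (length(ranges) %% 2 != 0) stop("ranges vector must have even length")
    ranges <- matrix(ranges, ncol = 2, byrow = TRUE)
  } else if (is.list(ranges)) {
    ranges <- do.call(rbind, lapply(ranges, function(r) r[1:2]))
  }
  ranges <- matrix(as.numeric(ranges), ncol = 2)
  if (any(ranges[, 2] < ranges[, 1])) stop("interval with hi < lo")
  ranges <- ranges[order(ranges[, 1]), , drop = FALSE]
  if (nrow(ranges) > 1 &&
      any(ranges[-1, 1] <= ranges[-nrow(ranges), 2])) {
    stop("selection intervals overlap")
  }
  structure(list(ranges = ranges, atom_names = atom_names, chains = chains),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  rng <- paste(apply(x$ranges, 1, function(r) paste0(r[1], "-", r[2])),
               collapse = ",")
  cat("selection: residues", rng, "| atoms:",
      if (is.null(x$atom_names)) "all" else paste(x$atom_names, collapse = ","),
      "| chains:", paste(x$chains, collapse = ","), "\n")
  invisible(x)
}

in_ranges <- function(resno, ranges) {
  hit <- rep(FALSE, length(resno))
  for (i in seq_len(nrow(ranges))) {
    hit <- hit | (resno >= ranges[i, 1] & resno <= ranges[i, 2])
  }
  hit
}

#' Resolve a selection to ordered atom indices
#'
#' Returns row indices into `model$atom`, deterministically ordered by
#' (chain, residue number, atom name). With `symmetric = TRUE` every selected
#' (residue, atom) position must be present in all five chains; positions
#' missing from one or more chains are dropped from all chains with a warning
#' so per-chain counts stay equal.
#'
#' @param model a [pentamer()].
#' @param sel a [selection()].
#' @param symmetric require equal per-chain atom counts (drop incomplete
#'   positions).
#' @return integer vector of atom-table row indices.
#' @export
resolve_selection <- function(model, sel, symmetric = FALSE) {
  a <- model$atom
  keep <- is_protein_atom(a) & in_ranges(a$resno, sel$ranges)
  if (!is.null(sel$atom_names)) keep <- keep & a$elety %in% sel$atom_names
  if (!identical(sel$chains, "all")) keep <- keep & a$chain %in% sel$chains
  idx <- which(keep)
  if (length(idx) == 0) {
    stop("empty selection: no atoms match residues ",
         paste(apply(sel$ranges, 1, paste, collapse = "-"), collapse = ","))
  }
  sub <- a[idx, , drop = FALSE]
  ord <- order(sub$chain, sub$resno, sub$elety)
  idx <- idx[ord]
  if (symmetric) {
    sub <- a[idx, , drop = FALSE]
    pos <- paste(sub$resno, sub$elety, sep = "|")
    nch <- length(model$chains)
    tab <- table(pos)
    incomplete <- names(tab)[tab < nch]
    if (length(incomplete) > 0) {
      warning("dropping positions missing in >=1 chain: ",
              paste(incomplete, collapse = ", "))
      keep2 <- !(pos %in% incomplete)
      idx <- idx[keep2]
      if (length(idx) == 0) {
        stop("asymmetry error: no position present in all chains")
      }
    }
    if (any(table(tab <- a$chain[idx]) != length(idx) / nch)) {
      stop("asymmetry error: unequal per-chain atom counts after cleaning")
    }
  }
  idx
}

#' Azimuthal subunit order of the pentamer
#'
#' Chains sorted by the azimuth of their C-alpha centroid about the pore
#' axis, counterclockwise when viewed from the extracellular (+axis) side,
#' starting at the alphabetically first chain. Under this convention the
#' complementary neighbor of subunit `i` is subunit `i + 1` (mod 5): subunit
#' `i` presents the principal (+) face of interface `i`.
#'
#' @param model a [pentamer()].
#' @param axis a [pore_axis()], typically from [estimate_pore_axis()].
#' @return character vector of 5 chain ids in azimuthal order.
#' @export
subunit_order <- function(model, axis) {
  a <- model$atom
  prot <- is_protein_atom(a) & a$elety == "CA"
  # right-handed basis (e1, e2, direction)
  d <- axis$direction
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * d) * d)
  e2 <- vcross(d, e1)
  az <- vapply(model$chains, function(ch) {
    cen <- colMeans(model_xyz(model, which(prot & a$chain == ch)))
    v <- cen - axis$point
    vp <- v - sum(v * d) * d
    if (vnorm(vp) < 1e-9) stop("ordering error: chain ", ch, " centroid on axis")
    atan2(sum(vp * e2), sum(vp * e1))
  }, numeric(1))
  gaps <- c(diff(sort(az)), 2 * pi - (max(az) - min(az)))
  if (min(gaps) < 1e-9) {
    stop("ordering error: indistinguishable chain azimuths")
  }
  ord <- model$chains[order(az)]
  # rotate cyclically to start at the alphabetically first chain
  start <- which(ord == min(ord))
  ord[((seq_along(ord) - 1 + start - 1) %% length(ord)) + 1]
}

#' Non-loop C-alpha selection
#'
#' The union of the model-alignment ranges (ECD 17-192, TMD 196-314) minus
#' configurable flexible-loop intervals: by default the beta1-beta2 loop
#' (30-36), loop F (151-160) and the M2-M3 loop (243-250).
#'
#' @param loops list of `c(lo, hi)` intervals to exclude.
#' @param domains list of `c(lo, hi)` intervals to include before exclusion.
#' @return a [selection()] of C-alpha atoms.
#' @export
nonloop_ca_selection <- function(loops = list(c(30, 36), c(151, 160), c(243, 250)),
                                 domains = list(c(17, 192), c(196, 314))) {
  resnos <- unlist(lapply(domains, function(r) seq(r[1], r[2])))
  for (lp in loops) resnos <- setdiff(resnos, seq(lp[1], lp[2]))
  resnos <- sort(resnos)
  # collapse to maximal runs
  brk <- c(0, which(diff(resnos) > 1), length(resnos))
  ranges <- t(vapply(seq_len(length(brk) - 1), function(i) {
    c(resnos[brk[i] + 1], resnos[brk[i + 1]])
  }, numeric(2)))
  selection(ranges, atom_names = "CA")
}
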