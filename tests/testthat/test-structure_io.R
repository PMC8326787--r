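# Coordinate model I/O, selections, and azimuthal subunit ordering.

test_that("PDB write/read round trip preserves the model at fixed-width precision", {
  m <- generate_pentamer(quick_spec())
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  m2 <- read_pdb(path)
  expect_s3_class(m2, "pentamer")
  expect_identical(m2$chains, m$chains)
  expect_equal(nrow(m2$atom), nrow(m$atom))
  xyz_in <- as.matrix(m$atom[, c("x", "y", "z")])
  xyz_out <- as.matrix(m2$atom[, c("x", "y", "z")])
  expect_lt(max(abs(xyz_in - xyz_out)), 1e-3 + 1e-9)
  # waters and ions survive as labeled heteroatoms
  expect_equal(sum(m2$atom$resid %in% "HOH"), 18)
  expect_equal(sum(m2$atom$type == "HETATM"), 22)
})

test_that("read_pdb rejects non-pentameric assemblies, naming the chain count", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  n <- 4 * 3
  bio3d::write.pdb(file = tmp, xyz = as.vector(t(matrix(rnorm(3 * n), ncol = 3))),
                   resno = rep(1:3, 4), resid = rep("GLY", n),
                   eleno = seq_len(n), elety = rep("CA", n),
                   chain = rep(LETTERS[1:4], each = 3),
                   o = rep(1, n), b = rep(0, n))
  expect_error(read_pdb(tmp), "4")
  expect_error(read_pdb(withr::local_tempfile(fileext = ".pdb")), "no such file")
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  m <- generate_pentamer(quick_spec())
  a <- m$atom
  # duplicate one atom as altloc A (0.6) / B (0.4) with distinct coords
  i <- which(a$chain == "A" & a$resno == 35 & a$elety == "OE1")
  dup <- a[i, ]
  a$alt[i] <- "B"
  a$o[i] <- 0.4
  a$x[i] <- a$x[i] + 5
  dup$alt <- "A"
  dup$o <- 0.6
  a <- rbind(a, dup)
  a$eleno <- seq_len(nrow(a))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = a$eleno, elety = a$elety, chain = a$chain,
                   alt = a$alt, o = a$o, b = a$b, elesy = a$elesy)
  m2 <- read_pdb(tmp)
  kept <- m2$atom[m2$atom$chain == "A" & m2$atom$resno == 35 &
                    m2$atom$elety == "OE1", ]
  expect_equal(nrow(kept), 1)
  expect_equal(kept$o, 0.6)
  expect_equal(kept$x, dup$x, tolerance = 1e-3)
})

test_that("selections resolve to deterministic, symmetric atom sets", {
  m <- generate_pentamer(quick_spec())
  idx <- resolve_selection(m, selection(c(17, 192), "CA"))
  expect_length(idx, 880)  # 176 residues x 5 chains
  expect_true(all(table(m$atom$chain[idx]) == 176))
  expect_length(resolve_selection(m, selection(c(243, 250), "CA")), 40)
  expect_error(resolve_selection(m, selection(c(9000, 9010), "CA")),
               "empty selection")
  # order-stable under permuted atom records
  perm <- sample(nrow(m$atom))
  a2 <- m$atom[perm, ]
  a2$eleno <- seq_len(nrow(a2))
  m2 <- pentamer(a2)
  id <- function(mm, ii) paste(mm$atom$chain[ii], mm$atom$resno[ii],
                               mm$atom$elety[ii])
  expect_identical(id(m2, resolve_selection(m2, selection(c(17, 192), "CA"))),
                   id(m, idx))
})

test_that("symmetric resolution drops incomplete positions from all chains", {
  m <- generate_pentamer(quick_spec())
  a <- m$atom
  a <- a[!(a$chain == "C" & a$resno == 100 & a$elety == "CA"), ]
  a$eleno <- seq_len(nrow(a))
  m2 <- pentamer(a)
  expect_warning(idx <- resolve_selection(m2, selection(c(90, 110), "CA"),
                                          symmetric = TRUE),
                 "100")
  expect_length(idx, 20 * 5)  # residue 100 dropped everywhere
  expect_false(any(m2$atom$resno[idx] == 100))
})

test_that("subunit order follows the counterclockwise azimuth convention", {
  m <- generate_pentamer(quick_spec())
  ax <- estimate_pore_axis(m)
  expect_identical(subunit_order(m, ax), LETTERS[1:5])

  # relabeling chains arbitrarily: azimuthal order is recovered, matching a
  # brute-force azimuth computation
  relabel <- c(A = "D", B = "A", C = "E", D = "B", E = "C")
  a <- m$atom
  a$chain <- ifelse(a$chain %in% names(relabel), relabel[a$chain], a$chain)
  m2 <- pentamer(a)
  ord <- subunit_order(m2, estimate_pore_axis(m2))
  az_oracle <- sapply(sort(unique(relabel)), function(ch) {
    prot <- a$type == "ATOM" & a$chain == ch & a$elety == "CA"
    cen <- unname(colMeans(as.matrix(a[prot, c("x", "y", "z")])))
    (atan2(cen[2], cen[1]) * 180 / pi) %% 360
  })
  expected <- names(sort(az_oracle))
  shift <- which(expected == "A")
  expected <- expected[((seq_along(expected) - 1 + shift - 1) %% 5) + 1]
  expect_identical(ord, expected)

  # whole-model rotation about the axis: same cyclic order
  m3 <- rigid_move(m, rotation_matrix(c(0, 0, 1), 100))
  expect_identical(subunit_order(m3, estimate_pore_axis(m3)), LETTERS[1:5])
})

test_that("degenerate chain azimuths raise an ordering error", {
  rows <- c(
    unlist(lapply(0:2, function(k) {
      lapply(1:3, function(r) {
        th <- 72 * k * pi / 180
        list(chain = LETTERS[k + 1], resno = r, elety = "CA",
             x = 10 * cos(th), y = 10 * sin(th), z = r * 2)
      })
    }), recursive = FALSE),
    # chains D and E stacked at the same azimuth
    lapply(1:3, function(r) list(chain = "D", resno = r, elety = "CA",
                                 x = 10, y = 10, z = r * 2 + 20)),
    lapply(1:3, function(r) list(chain = "E", resno = r, elety = "CA",
                                 x = 10, y = 10, z = r * 2 + 40))
  )
  m <- build_model(rows)
  expect_error(subunit_order(m, z_axis()), "ordering error")
})

test_that("insertion codes are rejected", {
  m <- generate_pentamer(quick_spec())
  a <- m$atom
  tmp <- withr::local_tempfile(fileext = ".pdb")
  ins <- rep("", nrow(a))
  ins[10] <- "A"
  bio3d::write.pdb(file = tmp, xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = a$eleno, elety = a$elety, chain = a$chain,
                   insert = ins, o = a$o, b = a$b, elesy = a$elesy)
  expect_error(read_pdb(tmp), "insertion")
})
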