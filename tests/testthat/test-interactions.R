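# Electrostatic contacts, ion coordination, intersubunit distances,
# bootstrap summaries.

one_frame_traj <- function(model) {
  xyz <- matrix(as.vector(t(as.matrix(model$atom[, c("x", "y", "z")]))),
                nrow = 1)
  as_trajectory(model, xyz)
}

# model with an ion at a prescribed distance from chain A's E35 OE1
ion_at_distance <- function(dist) {
  spec <- quick_spec(seed = 3, n_ions = 0, n_waters_in_pore = 0,
                     n_waters_bulk = 0)
  m <- generate_pentamer(spec)
  a <- m$atom
  oe1 <- unlist(a[a$chain == "A" & a$resno == 35 & a$elety == "OE1",
                  c("x", "y", "z")])
  u <- c(1, 0, 0) # radial: points away from every other carboxylate
  ion <- data.frame(type = "HETATM", eleno = 0L, elety = "NA", alt = "",
                    resid = "NA", chain = "I", resno = 1L,
                    x = oe1[1] + dist * u[1], y = oe1[2] + dist * u[2],
                    z = oe1[3] + dist * u[3], o = 1, b = 0, elesy = "NA")
  a <- rbind(a, ion)
  a$eleno <- seq_len(nrow(a))
  pentamer(a)
}

test_that("ion coordination honors the inclusive 5 A cutoff", {
  near <- ion_coordination_series(one_frame_traj(ion_at_distance(4.9)),
                                  stride_ns = 0)
  expect_equal(near$values, 1L)
  expect_equal(unname(near$per_subunit[1, ]), c(1L, 0L, 0L, 0L, 0L))
  far <- ion_coordination_series(one_frame_traj(ion_at_distance(5.1)),
                                 stride_ns = 0)
  expect_equal(far$values, 0L)

  # wrong residue type
  tr <- one_frame_traj(ion_at_distance(4.9))
  expect_error(ion_coordination_series(tr, residue = 158, stride_ns = 0),
               "carboxylate")
})

test_that("random-ion coordination equals the exhaustive pairwise oracle", {
  spec <- quick_spec(seed = 17, n_ions = 20, n_frames = 4,
                     n_waters_in_pore = 0, n_waters_bulk = 0)
  tr <- generate_trajectory(spec)
  got <- ion_coordination_series(tr, stride_ns = 0)
  a <- tr$topology$atom
  oxy_rows <- which(a$type == "ATOM" & a$resno == 35 &
                      a$elety %in% c("OE1", "OE2"))
  ion_rows <- which(a$resid == "NA")
  for (f in seq_len(n_frames(tr))) {
    xyz <- matrix(tr$xyz[f, ], ncol = 3, byrow = TRUE)
    expect_equal(got$values[f],
                 brute_force_ion_count(xyz[ion_rows, , drop = FALSE],
                                       xyz[oxy_rows, , drop = FALSE], 5))
  }
})

test_that("minimum group distance is the heavy-atom pairwise minimum", {
  m <- build_model(list(
    list(chain = "A", resno = 1, elety = "CA", x = 0, y = 0, z = 0),
    list(chain = "B", resno = 2, elety = "CA", x = 7.25, y = 0, z = 0),
    list(chain = "C", resno = 3, elety = "CA", x = 50, y = 0, z = 0),
    list(chain = "D", resno = 4, elety = "CA", x = 60, y = 0, z = 0),
    list(chain = "E", resno = 5, elety = "CA", x = 70, y = 0, z = 0)))
  d <- min_group_distance(m, selection(c(1, 1), NULL),
                          selection(c(2, 5), NULL))
  expect_equal(d, 7.25, tolerance = 1e-12)
  expect_error(min_group_distance(m, selection(c(9, 9), NULL),
                                  selection(c(2, 5), NULL)),
               "empty selection")
})

test_that("contact fraction counts threshold crossings and is cutoff-monotone", {
  expect_equal(contact_fraction(c(1, 0, 1, 1, 0)), 0.6)
  expect_equal(contact_fraction(c(0, 0, 0)), 0)
  expect_error(contact_fraction(numeric(0)), "empty")

  spec <- quick_spec(seed = 23, n_frames = 40, contact_k_on = 0.3,
                     contact_k_off = 0.3)
  tr <- generate_trajectory(spec)
  f4 <- contact_fraction(salt_bridge_series(tr, cutoff = 4.0))
  f3 <- contact_fraction(salt_bridge_series(tr, cutoff = 3.0))
  f8 <- contact_fraction(salt_bridge_series(tr, cutoff = 8.0))
  expect_lte(f3, f4)
  expect_lte(f4, f8)
})

test_that("two-state contact dynamics recover the stationary probability", {
  # stationary formed fraction 0.35; 2000 frames x 5 subunits
  k_on <- 0.07; k_off <- 0.13
  spec <- synthetic_spec(seed = 51, n_frames = 2000, contact_k_on = k_on,
                         contact_k_off = k_off, contact_initial = "broken",
                         n_ions = 0, n_waters_in_pore = 0, n_waters_bulk = 0)
  tr <- generate_trajectory(spec)
  sb <- salt_bridge_series(tr)
  # detector reproduces the generator's ground-truth states exactly
  expect_identical(unname(sb$per_subunit),
                   unname(tr$ground_truth$contact_states))
  p <- k_on / (k_on + k_off)
  rho <- 1 - k_on - k_off
  se <- sqrt(p * (1 - p) * (1 + rho) / (1 - rho) / (2000 * 5))
  expect_lt(abs(contact_fraction(sb) - p), 3 * se)

  # switching off: the initial state persists
  frozen <- generate_trajectory(synthetic_spec(seed = 52, n_frames = 50,
                                               contact_k_on = 0, contact_k_off = 0,
                                               n_ions = 0, n_waters_in_pore = 0,
                                               n_waters_bulk = 0))
  expect_equal(contact_fraction(salt_bridge_series(frozen)), 1.0)
})

test_that("intersubunit CA distances follow the principal-to-complementary rule", {
  # stand-ins placed 9.00 A apart across each interface: residue 35 on chain
  # i and residue 158 on chain i+1 at equal radius/z, chord 9
  radius <- 20
  dth <- 2 * asin(9 / (2 * radius)) * 180 / pi
  rows <- unlist(lapply(0:4, function(k) {
    list(list(chain = LETTERS[k + 1], resno = 35, elety = "CA",
              x = radius * cospi((72 * k) / 180),
              y = radius * sinpi((72 * k) / 180), z = 100),
         list(chain = LETTERS[k + 1], resno = 158, elety = "CA",
              x = radius * cospi((72 * (k - 1) + dth) / 180),
              y = radius * sinpi((72 * (k - 1) + dth) / 180), z = 100))
  }), recursive = FALSE)
  m <- build_model(rows)
  d <- intersubunit_ca_distance(m, axis = z_axis())
  expect_equal(unname(d), rep(9, 5), tolerance = 1e-9)

  R <- rotation_matrix(c(1, 1, 1), 40)
  m2 <- rigid_move(m, R, c(3, 3, -8))
  ax2 <- pore_axis(drop(R %*% c(0, 0, 0)) + c(3, 3, -8), drop(R %*% c(0, 0, 1)))
  expect_equal(unname(intersubunit_ca_distance(m2, axis = ax2)), rep(9, 5),
               tolerance = 1e-9)
})

test_that("randomized intersubunit distances match a brute-force pairing oracle", {
  spec <- quick_spec(seed = 61)
  m <- generate_pentamer(spec)
  set.seed(62)
  set_xyz <- getFromNamespace("set_model_xyz", "pentagate")
  get_xyz <- getFromNamespace("model_xyz", "pentagate")
  m <- set_xyz(m, get_xyz(m) + matrix(rnorm(3 * nrow(m$atom), sd = 0.2),
                                      ncol = 3))
  ax <- estimate_pore_axis(m)
  got <- intersubunit_ca_distance(m, 35, 158, axis = ax)
  ord <- subunit_order(m, ax)
  a <- m$atom
  ca <- function(ch, r) {
    unlist(a[a$type == "ATOM" & a$chain == ch & a$resno == r &
               a$elety == "CA", c("x", "y", "z")])
  }
  for (i in 1:5) {
    j <- (i %% 5) + 1
    expect_equal(unname(got[i]),
                 sqrt(sum((ca(ord[i], 35) - ca(ord[j], 158))^2)),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap median CI is deterministic and matches a resampling oracle", {
  const <- bootstrap_median_ci(rep(3.5, 4), seed = 1)
  expect_equal(const$median, 3.5)
  expect_equal(c(const$ci_low, const$ci_high), c(3.5, 3.5))

  single <- bootstrap_median_ci(7.7, seed = 1)
  expect_equal(c(single$median, single$ci_low, single$ci_high),
               rep(7.7, 3))

  x <- c(1, 2, 3, 4, 5)
  got <- bootstrap_median_ci(x, level = 0.95, n_boot = 2000, seed = 99)
  expect_equal(got$median, 3)
  # independently coded resampling with the same seed and generator
  set.seed(99)
  idx <- matrix(sample.int(5, 5 * 2000, replace = TRUE), nrow = 2000)
  meds <- numeric(2000)
  for (b in 1:2000) meds[b] <- median(x[idx[b, ]])
  ci <- unname(quantile(meds, c(0.025, 0.975), type = 7))
  expect_equal(c(got$ci_low, got$ci_high), ci)

  # identical seeds agree; the caller's RNG stream is untouched
  set.seed(1234)
  before <- rnorm(1)
  set.seed(1234)
  invisible(bootstrap_median_ci(x, seed = 5))
  expect_equal(rnorm(1), before)
  expect_identical(bootstrap_median_ci(x, seed = 5)[c("ci_low", "ci_high")],
                   bootstrap_median_ci(x, seed = 5)[c("ci_low", "ci_high")])

  # CI width shrinks to zero as the sample degenerates
  w <- vapply(c(1, 0.1, 0.001), function(s) {
    st <- bootstrap_median_ci(c(10 - s, 10, 10 + s), n_boot = 500, seed = 2)
    st$ci_high - st$ci_low
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("bootstrap CI coverage of a Gaussian median is near nominal", {
  set.seed(321)
  n_rep <- 150
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(25)
    st <- bootstrap_median_ci(x, level = 0.95, n_boot = 1000,
                              seed = 10000 + r)
    covered[r] <- st$ci_low <= 0 && 0 <= st$ci_high
  }
  expect_lt(abs(mean(covered) - 0.95), 0.05)
})
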