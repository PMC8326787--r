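# Loop PCA: observation extraction, component fitting, projection, KDE.

test_that("a C5-exact model yields five identical loop observations", {
  m <- generate_pentamer(quick_spec())
  obs <- extract_loop_observations(m)
  expect_equal(nrow(obs), 5)
  expect_equal(ncol(obs), 24)  # 8 loop residues x 3 coordinates
  d <- as.matrix(dist(obs))
  expect_lt(max(d), 1e-6)
})

test_that("chain relabeling permutes but does not alter observations", {
  m <- generate_pentamer(quick_spec())
  obs <- extract_loop_observations(m)
  relabel <- c(A = "C", B = "E", C = "A", D = "B", E = "D")
  a <- m$atom
  a$chain <- ifelse(a$chain %in% names(relabel), relabel[a$chain], a$chain)
  m2 <- pentamer(a)
  obs2 <- extract_loop_observations(m2, reference = attr(obs, "reference"))
  o1 <- obs[order(apply(obs, 1, function(r) r[1])), ]
  o2 <- obs2[order(apply(obs2, 1, function(r) r[1])), ]
  expect_equal(unname(o1), unname(o2), tolerance = 1e-9)
})

test_that("PCA recovers constructed variance fractions exactly", {
  set.seed(41)
  p <- 24
  v1 <- rnorm(p); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- rnorm(p); v2 <- v2 - sum(v2 * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
  centre <- rnorm(p)
  a_coef <- c(-2, -1, 0, 1, 2)              # sample variance 2.5
  b_coef <- c(1, 1, -4, 1, 1) * sqrt(2.5 / 20)  # variance 2.5/4, cov(a,b) = 0
  obs <- t(vapply(1:5, function(i) centre + a_coef[i] * v1 + b_coef[i] * v2,
                  numeric(p)))
  pcm <- fit_pca(obs)
  expect_equal(pcm$explained_fraction[1:2], c(0.8, 0.2), tolerance = 1e-9)
  expect_equal(sum(pcm$explained_fraction), 1, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(pcm$components) - diag(ncol(pcm$components)))),
            1e-9)
  # components span the construction directions
  expect_equal(abs(sum(pcm$components[, 1] * v1)), 1, tolerance = 1e-9)
  expect_equal(abs(sum(pcm$components[, 2] * v2)), 1, tolerance = 1e-9)

  expect_error(fit_pca(matrix(rep(1:24, 5), nrow = 5, byrow = TRUE)),
               "degenerate variance")
})

test_that("explained fractions are row-permutation invariant; translation only moves the mean", {
  set.seed(43)
  obs <- matrix(rnorm(25 * 12), nrow = 25)
  pcm <- fit_pca(obs)
  pcm_perm <- fit_pca(obs[sample(25), ])
  expect_equal(pcm$explained_fraction, pcm_perm$explained_fraction,
               tolerance = 1e-9)

  shift <- rep(3.3, 12)
  pcm_shift <- fit_pca(sweep(obs, 2, -shift))
  expect_equal(pcm_shift$mean, pcm$mean + shift, tolerance = 1e-9)
  expect_equal(unname(pc_project(obs[1, ], pcm)),
               unname(pc_project(obs[1, ] + shift, pcm_shift)),
               tolerance = 1e-8)
})

test_that("projection follows the dot-product rule", {
  set.seed(44)
  obs <- matrix(rnorm(20 * 9), nrow = 20)
  pcm <- fit_pca(obs)
  expect_equal(unname(pc_project(pcm$mean, pcm)), matrix(0, 1, 2),
               tolerance = 1e-10)
  along1 <- pcm$mean + 2 * pcm$components[, 1]
  expect_equal(unname(pc_project(along1, pcm)), matrix(c(2, 0), 1, 2),
               tolerance = 1e-9)
  x <- rnorm(9)
  oracle <- c(sum((x - pcm$mean) * pcm$components[, 1]),
              sum((x - pcm$mean) * pcm$components[, 2]))
  expect_equal(unname(drop(pc_project(x, pcm))), oracle, tolerance = 1e-10)
  expect_error(pc_project(rnorm(5), pcm), "dimension mismatch")
})

test_that("loop PCA separates models deformed along known directions", {
  # five models whose loop is displaced radially by per-model amounts;
  # per-subunit extraction gives 25 observations dominated by one component
  base_spec <- quick_spec(seed = 45)
  amounts <- c(-1, -0.5, 0, 0.5, 1)
  models <- lapply(amounts, function(am) {
    m <- generate_pentamer(base_spec)
    a <- m$atom
    loop_rows <- which(a$type == "ATOM" & a$resno >= 243 & a$resno <= 250 &
                         a$elety == "CA")
    r <- sqrt(a$x[loop_rows]^2 + a$y[loop_rows]^2)
    a$x[loop_rows] <- a$x[loop_rows] * (r + am) / r
    a$y[loop_rows] <- a$y[loop_rows] * (r + am) / r
    pentamer(a)
  })
  obs <- extract_loop_observations(models)
  expect_equal(nrow(obs), 25)
  pcm <- fit_pca(obs)
  expect_gt(pcm$explained_fraction[1], 0.99)
  proj <- pc_project(obs, pcm)
  # the five models order monotonically along PC1
  pc1_by_model <- vapply(1:5, function(i) {
    mean(proj[grepl(paste0("^model", i, ":"), rownames(proj)), 1])
  }, numeric(1))
  expect_true(all(diff(pc1_by_model) > 0) || all(diff(pc1_by_model) < 0))

  # trajectory projection agrees with direct observation projection
  m3 <- models[[3]]
  xyz <- matrix(as.vector(t(as.matrix(m3$atom[, c("x", "y", "z")]))), nrow = 1)
  pcm$loop <- c(243, 250)
  tp <- project_trajectory(as_trajectory(m3, xyz), pcm)
  direct <- pc_project(extract_loop_observations(m3, reference = pcm$reference),
                       pcm)
  expect_equal(as.matrix(tp[, c("PC1", "PC2")]), unname(direct),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("kernel density landscapes normalize and localize correctly", {
  set.seed(46)
  pts <- cbind(rnorm(200), rnorm(200, sd = 2))
  k <- kde2d_landscape(pts, n = 96)
  trap <- function(k) {
    dx <- diff(k$x[1:2]); dy <- diff(k$y[1:2])
    wx <- rep(1, length(k$x)); wx[c(1, length(wx))] <- 0.5
    wy <- rep(1, length(k$y)); wy[c(1, length(wy))] <- 0.5
    sum(outer(wx, wy) * k$z) * dx * dy
  }
  expect_equal(trap(k), 1, tolerance = 1e-3)

  # repeated single point with fixed bandwidth: N-independent Gaussian peak
  h <- c(0.5, 0.5)
  for (n_copy in c(5, 50)) {
    pts1 <- matrix(rep(c(1, -2), n_copy), ncol = 2, byrow = TRUE)
    k1 <- kde2d_landscape(pts1, bandwidth = h, n = 101)
    peak <- max(k1$z)
    expect_equal(peak, 1 / (2 * pi * h[1] * h[2]), tolerance = 1e-3)
    ix <- which(k1$z == peak, arr.ind = TRUE)
    expect_equal(c(k1$x[ix[1]], k1$y[ix[2]]), c(1, -2), tolerance = 0.05)
  }

  # two well-separated clusters give two local maxima at the centroids
  cl <- rbind(cbind(rnorm(100, -5, 0.3), rnorm(100, 0, 0.3)),
              cbind(rnorm(100, 5, 0.3), rnorm(100, 0, 0.3)))
  k2 <- kde2d_landscape(cl, n = 128)
  left <- k2$x < 0
  peak_l <- which(k2$z[left, ] == max(k2$z[left, ]), arr.ind = TRUE)
  peak_r <- which(k2$z[!left, ] == max(k2$z[!left, ]), arr.ind = TRUE)
  expect_equal(k2$x[left][peak_l[1]], -5, tolerance = 0.3)
  expect_equal(k2$x[!left][peak_r[1]], 5, tolerance = 0.3)

  expect_error(kde2d_landscape(pts[1, , drop = FALSE]), "bandwidth error")
  expect_error(kde2d_landscape(cbind(rnorm(10), rep(2, 10))),
               "zero variance")
})
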