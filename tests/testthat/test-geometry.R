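test_that("plane fitting matches analytic least squares", {
  pts <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  fit <- fit_plane(pts)
  expect_equal(abs(fit$normal[3]), 1, tolerance = 1e-12)
  expect_equal(fit$rms_out_of_plane, 0, tolerance = 1e-12)
  # square + centre point lifted by h: by symmetry the plane is z = h/5,
  # residuals (h/5) x4 and 4h/5, so rms = 2h/5
  h <- 0.5
  fit2 <- fit_plane(rbind(pts, c(0, 0, h)))
  expect_equal(fit2$rms_out_of_plane, 2 * h / 5, tolerance = 1e-12)
  expect_equal(abs(fit2$normal[3]), 1, tolerance = 1e-12)
  # axis hint fixes the sign
  expect_equal(fit_plane(pts, axis_hint = c(0, 0, -1))$normal[3], -1,
               tolerance = 1e-12)
  expect_error(fit_plane(pts[1:2, ]), "3 points")
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "degeneracy|collinear")
})

test_that("guanine angles behave as central angles at the tetrad centroid", {
  m <- build_ideal_g4()
  topo <- detect_topology(m)
  g <- topo$tetrads[[1]]$guanines
  a <- guanine_angles(m$xyz, m, g)
  expect_equal(a$adjacent, rep(90, 4), tolerance = 1e-9)
  expect_equal(a$opposite, rep(180, 2), tolerance = 1e-9)

  # rotating one guanine +10 deg about the channel axis skews its two
  # adjacent angles to 100 and 80 and leaves the far pair at 90
  rot10 <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  mm <- m
  rows <- which(m$atom$resno == g[1])
  mm$xyz[rows, ] <- m$xyz[rows, ] %*% t(rot10(10))
  a2 <- guanine_angles(mm$xyz, mm, g, centroid = c(0, 0, 0))
  expect_equal(sort(a2$adjacent[c(1, 4)]), c(80, 100), tolerance = 1e-6)
  expect_equal(a2$adjacent[2:3], rep(90, 2), tolerance = 1e-6)

  # radial displacement away from a fixed vertex leaves the subtended
  # angles unchanged (central angles depend on direction only)
  mm2 <- m
  com <- g4integrity:::.base_com(m$xyz, m, g[1])
  u <- com / sqrt(sum(com^2))
  mm2$xyz[rows, ] <- sweep(m$xyz[rows, ], 2, 2 * u, `+`)
  a3 <- guanine_angles(mm2$xyz, mm2, g, centroid = c(0, 0, 0))
  a0 <- guanine_angles(m$xyz, m, g, centroid = c(0, 0, 0))
  expect_equal(a3$adjacent, a0$adjacent, tolerance = 1e-9)
  expect_equal(a3$opposite[1], a0$opposite[1], tolerance = 1e-6)
})

test_that("tetrad COM distances recover the stack rise", {
  m <- build_ideal_g4(rise = 3.3)
  topo <- detect_topology(m)
  g <- lapply(topo$tetrads, `[[`, "guanines")
  expect_equal(tetrad_com_distance(m$xyz, m, g[[1]], g[[2]]), 3.3,
               tolerance = 1e-9)
  expect_equal(tetrad_com_distance(m$xyz, m, g[[2]], g[[3]]), 3.3,
               tolerance = 1e-9)
  expect_equal(tetrad_com_distance(m$xyz, m, g[[1]], g[[3]]), 6.6,
               tolerance = 1e-9)
  expect_equal(tetrad_com_distance(m$xyz, m, g[[1]], g[[1]]), 0)
})

test_that("twist angles recover the builder parameter with correct sign", {
  for (tw in c(30, -25, 0)) {
    m <- build_ideal_g4(twist = tw)
    topo <- detect_topology(m)
    expect_equal(twist_angle(m$xyz, m, topo, 1, 2), tw, tolerance = 1e-9)
  }
  m <- build_ideal_g4()
  topo <- detect_topology(m)
  expect_equal(twist_angle(m$xyz, m, topo, 1, 2, anchor = "N9"), 30,
               tolerance = 1e-9)
  bad <- topo
  bad$cols[2, 1] <- NA
  expect_error(twist_angle(m$xyz, m, bad, 1, 2), "order_tetrads")
})

test_that("Kabsch superposition is exact on rigid motions and matches the
           rotation-search oracle", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(X, X)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch_superpose(X, X)$rotation, diag(3), tolerance = 1e-9)
  rt <- random_rigid()
  expect_lt(kabsch_superpose(X, apply_rigid(X, rt))$rmsd, 1e-9)
  for (k in 1:5) {
    n <- sample(4:12, 1)
    A <- matrix(rnorm(3 * n, sd = 3), n, 3)
    B <- matrix(rnorm(3 * n, sd = 3), n, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, rmsd_rotation_oracle(A, B),
                 tolerance = 1e-4)
  }
  # weights: duplicating a point equals doubling its weight
  A <- matrix(rnorm(15), 5, 3); B <- matrix(rnorm(15), 5, 3)
  wa <- kabsch_superpose(A, B, weights = c(2, 1, 1, 1, 1))$rmsd
  dup <- kabsch_superpose(A[c(1, 1:5), ], B[c(1, 1:5), ])$rmsd
  expect_equal(wa, dup, tolerance = 1e-12)
  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "n >= 3")
  expect_true(kabsch_superpose(cbind(1:5, 0, 0), cbind(1:5, 0, 0))$degenerate)
})

test_that("RMSD series and matrices respect superposition invariances", {
  m <- build_ideal_g4()
  sel <- select_atoms(m, "guanine and base and heavy")
  same <- g4_trajectory(m, list(m$xyz, m$xyz, m$xyz))
  expect_equal(rmsd_series(same, 1, sel)$value, rep(0, 3), tolerance = 1e-12)
  shifted <- g4_trajectory(m, list(m$xyz, sweep(m$xyz, 2, c(10, 0, 0), `+`)))
  expect_equal(rmsd_series(shifted, 1, sel)$value[2], 0, tolerance = 1e-12)
  expect_error(rmsd_series(same, 1, integer()), "empty")

  tr <- generate_ensemble(m, n_frames = 8, sigma_core = 0.3, seed = 2)
  mm <- rmsd_matrix(tr, sel, stride = 2)
  expect_equal(dim(mm), c(4, 4))
  expect_equal(max(abs(mm - t(mm))), 0)
  expect_equal(diag(mm), rep(0, 4))
  expect_true(all(mm >= 0))
})

test_that("loop flexibility separates whole-DNA from tetrad-only RMSD maps", {
  m <- build_ideal_g4()
  tr <- generate_ensemble(m, n_frames = 40, sigma_core = 0.4, seed = 8)
  sel_tet <- select_atoms(m, "guanine and resno 2:4 or guanine and resno 8:10 or guanine and resno 14:16 or guanine and resno 20:22")
  sel_all <- select_atoms(m, "nucleic and heavy")
  m_tet <- rmsd_matrix(tr, sel_tet, stride = 2)
  m_all <- rmsd_matrix(tr, sel_all, stride = 2)
  off <- upper.tri(m_tet)
  expect_gt(mean(m_all[off]), mean(m_tet[off]))
})
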