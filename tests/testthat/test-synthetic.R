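test_that("the ideal builder satisfies its own ground truth", {
  m <- build_ideal_g4()
  expect_equal(m$built$tetrads,
               rbind(c(2L, 8L, 14L, 20L), c(3L, 9L, 15L, 21L),
                     c(4L, 10L, 16L, 22L)))
  expect_length(m$ions, 2)
  # calibrated Hoogsteen distances
  pairs <- detect_hoogsteen_pairs(m$xyz, m)
  expect_equal(range(c(pairs$d_N1_O6, pairs$d_N2_N7)), c(2.9, 2.9),
               tolerance = 1e-9)
  # C1' radius matches the requested value
  r <- m$built$radius
  c1 <- m$xyz[which(m$atom$resno == 2 & m$atom$elety == "C1'"), ]
  expect_equal(sqrt(sum(c1[1:2]^2)), r, tolerance = 1e-9)
  # explicit radius is honored
  m9 <- build_ideal_g4(radius = 9.5)
  c19 <- m9$xyz[which(m9$atom$resno == 2 & m9$atom$elety == "C1'"), ]
  expect_equal(sqrt(sum(c19[1:2]^2)), 9.5, tolerance = 1e-9)

  # single-tetrad edge case: topology exists, no stack descriptors
  m1 <- build_ideal_g4(n_tetrads = 1, ions = FALSE)
  t1 <- detect_topology(m1)
  expect_length(t1$tetrads, 1)

  expect_error(build_ideal_g4(sequence = "AGTCAGTC"), "incompatible")
})

test_that("ensembles are reproducible and degenerate to the model at zero noise", {
  m <- build_ideal_g4()
  tr0 <- generate_ensemble(m, n_frames = 4, sigma_core = 0, sigma_loop = 0,
                           seed = 1, rigid_motion = FALSE)
  for (f in tr0$frames) expect_identical(f, m$xyz)

  a <- generate_ensemble(m, n_frames = 6, sigma_core = 0.3, seed = 7)
  b <- generate_ensemble(m, n_frames = 6, sigma_core = 0.3, seed = 7)
  cc <- generate_ensemble(m, n_frames = 6, sigma_core = 0.3, seed = 8)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, cc$frames))
  expect_error(generate_ensemble(m, n_frames = 2, sigma_core = 0.1), "seed")
  expect_error(generate_ensemble(m, n_frames = 2, sigma_core = 0.1, seed = 1,
                                 events = list(list(type = "meteor", frame = 1))),
               "unknown event")
  # the generator restores the caller's RNG state
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_ensemble(m, n_frames = 2,
                                             sigma_core = 0.1, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("the pipeline closes: builder parameters are recovered end to end", {
  m <- build_ideal_g4(rise = 3.3, twist = 30)
  topo <- detect_topology(m)
  expect_length(topo$tetrads, 3)
  expect_length(topo$channel_ions, 2)

  # zero noise, random rigid motion on: exact recovery
  tr0 <- generate_ensemble(m, n_frames = 5, sigma_core = 0, sigma_loop = 0,
                           seed = 2)
  expect_lt(max(abs(twist_series(tr0, topo)$value - 30)), 1e-6)
  expect_lt(max(abs(com_distance_series(tr0, topo)$value - 3.3)), 1e-6)

  # moderate noise: twist within a degree, rise within 0.1 A on average
  tr <- generate_ensemble(m, n_frames = 100, sigma_core = 0.3, seed = 6)
  expect_lt(abs(mean(twist_series(tr, topo)$value) - 30), 1)
  expect_lt(abs(mean(com_distance_series(tr, topo)$value) - 3.3), 0.1)
})

test_that("no destabilization events arise without injection across seeds", {
  m <- build_ideal_g4()
  topo <- detect_topology(m)
  for (seed in 1:8) {
    tr <- generate_ensemble(m, n_frames = 30, sigma_core = 0.3, seed = seed)
    expect_equal(nrow(detect_guanine_expulsion(tr, topo)), 0, info = seed)
    expect_equal(nrow(detect_leakage(channel_occupancy(tr, topo))), 0,
                 info = seed)
  }
})

test_that("injected twist offsets shift the recovered mode accordingly", {
  ref_model <- build_ideal_g4(twist = 30)
  off_model <- build_ideal_g4(twist = 37)
  topo <- detect_topology(ref_model)
  ref <- twist_series(generate_ensemble(ref_model, n_frames = 80,
                                        sigma_core = 0.25, seed = 21), topo)
  off <- twist_series(generate_ensemble(off_model, n_frames = 80,
                                        sigma_core = 0.25, seed = 22),
                      detect_topology(off_model))
  d <- twist_distribution(off, reference = ref)
  expect_equal(d$shift, 7, tolerance = 2)   # within the 2-degree bin width
})
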