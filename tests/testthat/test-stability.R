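test_that("twist distributions report circular mode, width and shift", {
  d <- twist_distribution(rep(30, 100))
  expect_equal(d$mode, 30, tolerance = 1e-9)
  expect_equal(d$width, 0, tolerance = 1e-6)
  expect_equal(twist_distribution(rep(30, 100), reference = rep(30, 100))$shift,
               0, tolerance = 1e-9)

  set.seed(4)
  x <- rnorm(2000, mean = 20, sd = 6)
  shifted <- twist_distribution(x + 7, reference = x)
  expect_equal(shifted$shift, 7, tolerance = 2)   # within one bin width

  # wrapping: data straddling +/-180 has the same width as the unwrapped copy
  y <- rnorm(2000, mean = 0, sd = 8)
  w0 <- twist_distribution(y)$width
  w180 <- twist_distribution(y + 180)$width
  expect_equal(w180, w0, tolerance = 1e-9)
  # and the same as the classic linear sd for well-centred data (oracle)
  expect_equal(w0, sd(y), tolerance = 0.1)

  expect_error(twist_distribution(numeric()), "empty")
  # histogram is normalized
  expect_equal(sum(twist_distribution(x)$density) * 2, 1, tolerance = 1e-9)
})

test_that("guanine expulsion is detected from injected ground truth only", {
  m <- build_ideal_g4()
  topo <- detect_topology(m)
  # intact trajectory: no events
  tr0 <- generate_ensemble(m, n_frames = 40, sigma_core = 0.3, seed = 9)
  expect_equal(nrow(detect_guanine_expulsion(tr0, topo)), 0)

  # injected expulsion at frame 20
  ev <- list(list(type = "guanine_expulsion", frame = 20, magnitude = 12,
                  resno = 8))
  tr <- generate_ensemble(m, n_frames = 50, sigma_core = 0.3, seed = 11,
                          events = ev)
  e <- detect_guanine_expulsion(tr, topo)
  expect_equal(nrow(e), 1)
  expect_equal(e$guanine, 8)
  expect_equal(e$onset, 20, tolerance = 0)
  expect_true(e$persists_to_end)

  # sub-threshold displacement: Hoogsteen bonds break but the excursion
  # stays below the excess-distance threshold, so no event
  ev5 <- list(list(type = "guanine_expulsion", frame = 20, magnitude = 5,
                   resno = 8))
  tr5 <- generate_ensemble(m, n_frames = 50, sigma_core = 0.3, seed = 11,
                           events = ev5)
  expect_equal(nrow(detect_guanine_expulsion(tr5, topo)), 0)
})

test_that("the verdict follows persistent disruption, not leakage alone", {
  m <- build_ideal_g4()
  topo <- detect_topology(m)
  th <- g4_thresholds()

  clean <- analyze_trajectory(
    generate_ensemble(m, n_frames = 40, sigma_core = 0.3, seed = 1),
    label = "Native", topology = topo)
  expect_equal(clean$verdict, "stable")
  expect_equal(nrow(clean$events$guanine_expulsion), 0)
  expect_equal(nrow(clean$events$cation_leakage), 0)

  both <- analyze_trajectory(
    generate_ensemble(m, n_frames = 40, sigma_core = 0.3, seed = 2,
                      events = list(
                        list(type = "cation_leak", frame = 15, magnitude = 15,
                             ion = 1),
                        list(type = "guanine_expulsion", frame = 15,
                             magnitude = 12, resno = 8))),
    label = "damaged", topology = topo)
  expect_equal(both$verdict, "destabilized")

  leak_only <- analyze_trajectory(
    generate_ensemble(m, n_frames = 40, sigma_core = 0.3, seed = 3,
                      events = list(
                        list(type = "cation_leak", frame = 15, magnitude = 15,
                             ion = 1))),
    label = "leak", topology = topo)
  expect_equal(leak_only$verdict, "stable")
  expect_equal(nrow(leak_only$events$cation_leakage), 1)

  # missing mandatory series are reported by name
  expect_error(stability_report("x", list(twist = metric_series(1:3)),
                                data.frame(), data.frame()),
               "rmsd_tetrad.*com_distance")
})

test_that("stability reports round-trip through JSON exactly", {
  m <- build_ideal_g4()
  topo <- detect_topology(m)
  rep1 <- analyze_trajectory(
    generate_ensemble(m, n_frames = 30, sigma_core = 0.3, seed = 7,
                      events = list(
                        list(type = "guanine_expulsion", frame = 10,
                             magnitude = 12, resno = 14))),
    label = "NC 14-15", topology = topo)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_report(rep1, f1)
  back <- read_report(f1)
  expect_equal(back$verdict, rep1$verdict)
  expect_equal(back$label, rep1$label)
  expect_equal(back$events$guanine_expulsion$onset,
               rep1$events$guanine_expulsion$onset)
  write_report(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("threshold configs read back what they write", {
  th <- g4_thresholds(dmax = 3.2, min_out = 5)
  f <- tempfile(fileext = ".cfg")
  write_thresholds(th, f)
  back <- read_thresholds(f)
  expect_equal(back, th)
  writeLines(c("dmax = 3.0", "bogus = 1"), f)
  expect_error(read_thresholds(f), "unknown threshold")
})
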