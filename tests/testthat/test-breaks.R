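test_that("star notation parses positions, chemistry and the no-lesion case", {
  cf <- parse_star_notation("A G★GG TTA GGG TTA GGG TTA GGG", "CA")
  expect_equal(cf$positions, 2L)
  expect_equal(cf$breaks[[1]]$downstream_pos, 3L)
  expect_equal(cf$chemistry, "CA")
  expect_equal(cf$label, "CA 2-3")

  cf2 <- parse_star_notation("A GGG TTA GGG TTA G*G*G TTA GGG", "NC")
  expect_equal(cf2$positions, c(14L, 15L))
  expect_equal(cf2$label, "NC 14-15-16")
  expect_equal(vapply(cf2$breaks, `[[`, "", "chemistry"), c("NC", "NC"))

  cf3 <- parse_star_notation("AGGG", "CA")
  expect_length(cf3$positions, 0)
  expect_equal(cf3$label, "Native")

  expect_error(parse_star_notation("*AGGG", "CA"), "positional")
  expect_error(parse_star_notation("AGGG*", "CA"), "positional")
  expect_error(parse_star_notation("AGXG", "CA"), "parse error")
})

test_that("render is the inverse of parse on every scheme row", {
  for (row in scheme_rows()) {
    cf <- parse_star_notation(row, "CA")
    expect_identical(render_star_notation(cf, star = "*"), row)
    cf2 <- parse_star_notation(render_star_notation(cf), "CA")
    expect_identical(cf2$positions, cf$positions)
    expect_identical(cf2$sequence, cf$sequence)
    expect_identical(cf2$label, cf$label)
  }
  # spot renders
  expect_identical(
    render_star_notation(break_config(positions = c(3, 9)), star = "*"),
    "A GG*G TTA GG*G TTA GGG TTA GGG")
  expect_identical(
    render_star_notation(break_config(positions = 21), star = "*"),
    "A GGG TTA GGG TTA GGG TTA GG*G")
  expect_identical(
    render_star_notation(break_config(), star = "*"),
    "A GGG TTA GGG TTA GGG TTA GGG")
})

test_that("damage scheme enumeration reproduces the published counts", {
  configs <- enumerate_break_scheme()
  expect_length(configs, 27)
  labels <- vapply(configs, `[[`, "", "label")
  expect_false(anyDuplicated(labels) > 0)
  chem <- vapply(configs, `[[`, "", "chemistry")
  nb <- vapply(configs, function(cf) length(cf$breaks), 1L)
  site <- lapply(configs, `[[`, "site_class")
  tetrad_only <- vapply(site, function(s) all(s == "tetrad"), TRUE)
  expect_equal(sum(chem == "CA" & nb == 1L & tetrad_only), 6)
  expect_equal(sum(chem == "NC" & nb == 1L & tetrad_only), 6)
  expect_equal(sum(chem == "CA" & nb == 2L), 6)
  expect_equal(sum(chem == "NC" & nb == 2L), 6)
  loops <- vapply(site, function(s) any(s == "loop"), TRUE)
  expect_equal(sum(loops), 3)
  expect_true(all(chem[loops] == "CA"))

  expect_length(enumerate_break_scheme(loop_positions = integer()), 24)
  expect_length(enumerate_break_scheme(tetrad_singles = integer(),
                                       tetrad_doubles = list(),
                                       loop_positions = integer()), 0)
  expect_error(enumerate_break_scheme(tetrad_singles = c(2, 2)), "duplicate")
  expect_error(enumerate_break_scheme(tetrad_doubles = list(c(3, 3))), "duplicate")
})

test_that("applying breaks cuts one backbone bond per lesion, moves nothing", {
  m <- build_ideal_g4()
  native <- apply_breaks(m, break_config())
  expect_identical(native$bonds, m$bonds)
  expect_identical(native$xyz, m$xyz)

  for (cf in enumerate_break_scheme()) {
    dm <- apply_breaks(m, cf)
    expect_equal(nrow(m$bonds) - nrow(dm$bonds), length(cf$breaks),
                 info = cf$label)
    expect_identical(dm$xyz, m$xyz)
  }

  ca <- apply_breaks(m, break_config(positions = 2, chemistry = "CA"))
  expect_setequal(ca$termini$end[ca$termini$resno == 2], "3'-OH")
  expect_setequal(ca$termini$end[ca$termini$resno == 3], "5'-PO4")
  expect_equal(unname(attr(ca, "phosphate_owner")["2-3"]), 3)

  nc <- apply_breaks(m, break_config(positions = 2, chemistry = "NC"))
  expect_setequal(nc$termini$end[nc$termini$resno == 2], "3'-PO4")
  expect_setequal(nc$termini$end[nc$termini$resno == 3], "5'-OH")
  expect_equal(unname(attr(nc, "phosphate_owner")["2-3"]), 2)

  expect_error(apply_breaks(m, break_config("A", integer())), NA)
  expect_error(apply_breaks(m, break_config(paste(rep("G", 40), collapse = ""),
                                            positions = 30)),
               "positional")
})

test_that("break tables round-trip through CSV byte-identically", {
  configs <- enumerate_break_scheme()
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_break_table(configs, f1)
  back <- read_break_table(f1)
  write_break_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(vapply(back, `[[`, "", "label"),
                   vapply(configs, `[[`, "", "label"))
})
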