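# Heavy-atom nucleotide templates, bond tables and atomic masses.
#
# Base atoms lie in the template xy-plane in the standard base reference
# frame.  Sugar/backbone atoms are an idealized rigid attachment placed
# relative to C1'; their internal geometry is schematic (analysis metrics are
# base/C1' driven, connectivity is name-based), but bond lengths are kept in
# a plausible 1.4-1.7 A range.

.base_xy <- list(
  G = rbind(
    N9  = c(-1.289, 4.551), C8 = c( 0.023, 4.962), N7 = c( 0.870, 3.969),
    C5  = c( 0.071, 2.833), C6 = c( 0.424, 1.460), O6 = c( 1.554, 0.955),
    N1  = c(-0.700, 0.641), C2 = c(-1.999, 1.087), N2 = c(-2.949, 0.139),
    N3  = c(-2.342, 2.364), C4 = c(-1.265, 3.177)),
  A = rbind(
    N9  = c(-1.291, 4.498), C8 = c( 0.024, 4.897), N7 = c( 0.877, 3.902),
    C5  = c( 0.071, 2.771), C6 = c( 0.369, 1.398), N6 = c( 1.611, 0.909),
    N1  = c(-0.668, 0.532), C2 = c(-1.912, 1.023), N3 = c(-2.320, 2.290),
    C4  = c(-1.267, 3.124)),
  T = rbind(
    N1  = c(-1.284, 4.500), C2 = c(-1.462, 3.135), O2 = c(-2.562, 2.608),
    N3  = c(-0.298, 2.407), C4 = c( 0.994, 2.897), O4 = c( 1.944, 2.119),
    C5  = c( 1.106, 4.338), C7 = c( 2.466, 4.961), C6 = c(-0.024, 5.057)),
  C = rbind(
    N1  = c(-1.285, 4.542), C2 = c(-1.472, 3.158), O2 = c(-2.628, 2.709),
    N3  = c(-0.391, 2.344), C4 = c( 0.837, 2.868), N4 = c( 1.875, 2.027),
    C5  = c( 1.056, 4.275), C6 = c(-0.023, 4.965)))

# C1' position in the same frame (purine value; pyrimidines use it too,
# attached to N1 instead of N9 -- schematic but consistent).
.c1p_xy <- c(-2.477, 5.399)

# sugar/backbone offsets relative to C1' (template frame, dx dy dz)
.sugar_offsets <- rbind(
  "O4'" = c(-0.70,  1.20,  0.45),
  "C4'" = c(-2.00,  1.70,  0.75),
  "C5'" = c(-2.30,  3.10,  1.25),
  "O5'" = c(-3.30,  3.90,  1.55),
  "P"   = c(-4.10,  4.90,  2.15),
  "OP1" = c(-5.30,  5.40,  2.95),
  "OP2" = c(-3.60,  5.80,  3.35),
  "C2'" = c( 0.80,  0.90, -1.00),
  "C3'" = c(-0.40,  1.70, -1.60),
  "O3'" = c(-1.00,  2.90, -2.10))

#' @noRd
.residue_template <- function(code) {
  code <- toupper(code)
  base <- .base_xy[[code]]
  if (is.null(base)) stop("unknown nucleotide code: ", code)
  base3 <- cbind(base, 0)
  c1p <- c(.c1p_xy, 0)
  sugar <- sweep(.sugar_offsets, 2, c1p, `+`)
  xyz <- rbind(base3, "C1'" = c1p, sugar)
  elesy <- substr(rownames(xyz), 1, 1)
  list(xyz = xyz, names = rownames(xyz), elesy = elesy)
}

.base_atom_names <- list(
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  T = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"))

.sugar_atom_names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
.backbone_atom_names <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")

# intra-residue heavy-atom bonds, by atom name
.bonds_common <- list(
  c("P", "OP1"), c("P", "OP2"), c("P", "O5'"), c("O5'", "C5'"),
  c("C5'", "C4'"), c("C4'", "O4'"), c("C4'", "C3'"), c("C3'", "O3'"),
  c("C3'", "C2'"), c("C2'", "C1'"), c("C1'", "O4'"))
.bonds_base <- list(
  G = list(c("C1'", "N9"), c("N9", "C8"), c("C8", "N7"), c("N7", "C5"),
           c("C5", "C6"), c("C6", "O6"), c("C6", "N1"), c("N1", "C2"),
           c("C2", "N2"), c("C2", "N3"), c("N3", "C4"), c("C4", "C5"),
           c("C4", "N9")),
  A = list(c("C1'", "N9"), c("N9", "C8"), c("C8", "N7"), c("N7", "C5"),
           c("C5", "C6"), c("C6", "N6"), c("C6", "N1"), c("N1", "C2"),
           c("C2", "N3"), c("N3", "C4"), c("C4", "C5"), c("C4", "N9")),
  T = list(c("C1'", "N1"), c("N1", "C2"), c("C2", "O2"), c("C2", "N3"),
           c("N3", "C4"), c("C4", "O4"), c("C4", "C5"), c("C5", "C7"),
           c("C5", "C6"), c("C6", "N1")),
  C = list(c("C1'", "N1"), c("N1", "C2"), c("C2", "O2"), c("C2", "N3"),
           c("N3", "C4"), c("C4", "N4"), c("C4", "C5"), c("C5", "C6"),
           c("C6", "N1")))

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, K = 39.098, NA_ = 22.990)

#' @noRd
.mass_of <- function(elesy) {
  m <- .atomic_masses[ifelse(toupper(elesy) == "NA", "NA_", toupper(elesy))]
  m[is.na(m)] <- 12.011
  unname(m)
}

# Frozen tetrad placement (see tools/calibrate_tetrad.R): translating the
# standard-frame guanine template by (TX, TY) and replicating it by 90 deg
# rotations about z yields a tetrad whose four Hoogsteen N1->O6 and N2->N7
# heavy-atom distances are exactly 2.9 A, with O6 lining the channel
# (r_O6 = 2.30 A) and C1' outermost.
.tetrad_placement <- list(
  tx = -2.459855344977,
  ty = 1.157351812167,
  c1p_radius = 8.2072096222,   # C1' distance from the channel axis
  hoogsteen_d = 2.9)

.residue_name <- function(code) paste0("D", toupper(code))
.code_of_resid <- function(resid) {
  r <- toupper(sub("^D", "", resid))
  r <- sub("[35]$", "", r)
  ifelse(r %in% c("A", "C", "G", "T"), r,
         ifelse(r %in% c("GUA"), "G",
         ifelse(r %in% c("ADE"), "A",
         ifelse(r %in% c("THY"), "T",
         ifelse(r %in% c("CYT"), "C", NA_character_)))))
}

.ion_resids <- c("K", "NA", "POT", "SOD", "K+", "NA+")
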