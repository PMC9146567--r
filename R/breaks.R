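# Strand-break lesion model: chemistry, star notation, damage-scheme
# enumeration, and application of breaks to a structure's connectivity.

#' Reference human telomeric G4 sequence
#'
#' The 22-nucleotide intramolecular human telomeric repeat
#' `AGGGTTAGGGTTAGGGTTAGGG`, which folds into a three-tetrad parallel
#' G-quadruplex. Used as the default sequence throughout the package.
#'
#' @format A length-one character string.
#' @export
htelo_sequence <- "AGGGTTAGGGTTAGGGTTAGGG"

.check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(toupper(sequence), "")[[1]]
  if (!all(res %in% c("A", "C", "G", "T")))
    stop("sequence contains non-nucleotide codes: ",
         paste(unique(setdiff(res, c("A", "C", "G", "T"))), collapse = ", "))
  res
}

#' Create a strand-break lesion
#'
#' A strand break severs the phosphodiester backbone between two consecutive
#' nucleotides. Canonical (`"CA"`) breaks leave a 3'-OH upstream and a
#' 5'-phosphate downstream (the ligatable chemistry); non-canonical (`"NC"`)
#' breaks leave a 3'-phosphate upstream and a 5'-OH downstream.
#'
#' @param upstream_pos 1-based index of the residue on the 5' side of the cut;
#'   the downstream residue is `upstream_pos + 1`.
#' @param chemistry `"CA"` or `"NC"`.
#' @return A `strand_break` object (list with `upstream_pos`,
#'   `downstream_pos`, `chemistry`, and the implied terminal chemistries).
#' @export
strand_break <- function(upstream_pos, chemistry = c("CA", "NC")) {
  chemistry <- match.arg(chemistry)
  upstream_pos <- as.integer(upstream_pos)
  stopifnot(length(upstream_pos) == 1L, upstream_pos >= 1L)
  term <- if (chemistry == "CA") {
    c(upstream = "3'-OH", downstream = "5'-PO4")
  } else {
    c(upstream = "3'-PO4", downstream = "5'-OH")
  }
  structure(list(upstream_pos = upstream_pos,
                 downstream_pos = upstream_pos + 1L,
                 chemistry = chemistry, termini = term),
            class = "strand_break")
}

#' Create a break configuration
#'
#' Bundles a nucleotide sequence with a (possibly empty) set of strand breaks
#' of one chemistry, a human-readable label, and a per-break site class
#' (`"tetrad"` when both flanking residues are guanines, `"loop"` otherwise).
#'
#' @param sequence one-letter nucleotide string.
#' @param positions integer vector of upstream break positions (may be empty).
#' @param chemistry `"CA"` or `"NC"` (ignored when `positions` is empty).
#' @param label optional label; derived from positions when `NULL`.
#' @return A `break_config` object.
#' @export
break_config <- function(sequence = htelo_sequence, positions = integer(),
                         chemistry = c("CA", "NC"), label = NULL) {
  chemistry <- match.arg(chemistry)
  res <- .check_sequence(sequence)
  positions <- sort(as.integer(positions))
  if (anyDuplicated(positions))
    stop("duplicate break positions: ",
         paste(positions[duplicated(positions)], collapse = ", "))
  if (length(positions) && (min(positions) < 1L || max(positions) >= length(res)))
    stop("break position outside 1..", length(res) - 1L)
  breaks <- lapply(positions, strand_break, chemistry = chemistry)
  site <- vapply(positions, function(p)
    if (res[p] == "G" && res[p + 1L] == "G") "tetrad" else "loop", "")
  if (is.null(label)) label <- .config_label(positions, chemistry)
  structure(list(sequence = paste(res, collapse = ""), breaks = breaks,
                 positions = positions, chemistry = chemistry,
                 site_class = site, label = label),
            class = "break_config")
}

# "Native", "CA 2-3", "NC 2-3-4" (adjacent pair), "CA 3-4/14-15"
.config_label <- function(positions, chemistry) {
  if (!length(positions)) return("Native")
  runs <- split(positions, cumsum(c(1L, diff(positions) != 1L)))
  parts <- vapply(runs, function(r)
    paste(seq(min(r), max(r) + 1L), collapse = "-"), "")
  paste(chemistry, paste(parts, collapse = "/"))
}

#' @export
print.break_config <- function(x, ...) {
  cat("<break_config> ", x$label, "\n  ",
      render_star_notation(x, star = "*"), "\n", sep = "")
  invisible(x)
}

#' @export
format.break_config <- function(x, ...) x$label

#' Parse star-annotated sequence notation
#'
#' Reads a nucleotide string in which a star (Unicode `★` or the ASCII
#' alias `*`) between two letters marks a strand break between those two
#' residues. Whitespace is ignored for numbering; residues are numbered
#' 1-based from the first letter.
#'
#' @param text star-annotated sequence string.
#' @param chemistry break chemistry of every break in `text`.
#' @param star characters accepted as the break marker.
#' @return A [break_config].
#' @examples
#' parse_star_notation("A G*GG TTA GGG TTA GGG TTA GGG", "CA")
#' @export
parse_star_notation <- function(text, chemistry = c("CA", "NC"),
                                star = c("★", "*")) {
  chemistry <- match.arg(chemistry)
  chars <- strsplit(text, "")[[1]]
  chars <- chars[!grepl("^\\s$", chars)]
  is_star <- chars %in% star
  letters_ <- toupper(chars[!is_star])
  if (!all(letters_ %in% c("A", "C", "G", "T")))
    stop("parse error: non-nucleotide character in '", text, "'")
  if (length(chars) && (is_star[1L] || is_star[length(chars)]))
    stop("positional error: star at start or end of sequence")
  if (any(is_star & c(FALSE, is_star[-length(is_star)])))
    stop("positional error: consecutive stars")
  # upstream residue index of each star = number of letters seen before it
  idx <- cumsum(!is_star)
  positions <- idx[is_star]
  break_config(paste(letters_, collapse = ""), positions, chemistry)
}

#' Render a break configuration in star notation
#'
#' Inverse of [parse_star_notation()]. The rendered string follows the
#' `"A GGG TTA ..."` spacing convention: the first residue stands alone and
#' the rest are grouped in triplets. `parse_star_notation(render_star_notation(x))`
#' reproduces `x` for every valid configuration.
#'
#' @param config a [break_config].
#' @param star marker character to emit.
#' @return Character string.
#' @export
render_star_notation <- function(config, star = "★") {
  stopifnot(inherits(config, "break_config"))
  res <- strsplit(config$sequence, "")[[1]]
  n <- length(res)
  out <- character(0)
  for (i in seq_len(n)) {
    out <- c(out, res[i])
    if (i %in% config$positions) out <- c(out, star)
    group_end <- i == 1L || (i > 1L && (i - 1L) %% 3L == 0L)
    if (group_end && i < n) out <- c(out, " ")
  }
  paste(out, collapse = "")
}

#' Enumerate the strand-break damage scheme
#'
#' Generates the full set of damage configurations studied for the h-telo
#' parallel G4: every single and double tetrad-backbone break position in
#' both CA and NC chemistry, plus loop breaks in CA chemistry only. With the
#' default position lists this yields 27 configurations
#' (6 singles + 6 doubles, times two chemistries, plus 3 CA loop breaks).
#'
#' @param sequence nucleotide string.
#' @param tetrad_singles upstream positions of single tetrad-backbone breaks.
#' @param tetrad_doubles list of length-2 integer vectors (upstream positions).
#' @param loop_positions upstream positions of CA-only loop breaks. The
#'   default takes the first inter-nucleotide junction of each TTA loop.
#' @param include_native also prepend the undamaged configuration.
#' @return List of [break_config] objects with unique labels.
#' @export
enumerate_break_scheme <- function(sequence = htelo_sequence,
                                   tetrad_singles = c(2L, 3L, 9L, 14L, 15L, 21L),
                                   tetrad_doubles = list(c(2L, 3L), c(2L, 14L),
                                                         c(3L, 9L), c(3L, 14L),
                                                         c(3L, 15L), c(14L, 15L)),
                                   loop_positions = c(5L, 11L, 17L),
                                   include_native = FALSE) {
  if (anyDuplicated(tetrad_singles) || anyDuplicated(loop_positions))
    stop("duplicate positions in input lists")
  if (anyDuplicated(vapply(tetrad_doubles, paste, "", collapse = ",")))
    stop("duplicate positions in input lists")
  for (d in tetrad_doubles)
    if (length(d) != 2L || anyDuplicated(d))
      stop("duplicate positions in input lists")
  configs <- list()
  if (include_native)
    configs <- c(configs, list(break_config(sequence, integer(), "CA",
                                            label = "Native")))
  for (chem in c("CA", "NC")) {
    for (p in tetrad_singles)
      configs <- c(configs, list(break_config(sequence, p, chem)))
    for (d in tetrad_doubles)
      configs <- c(configs, list(break_config(sequence, d, chem)))
  }
  for (p in loop_positions)
    configs <- c(configs, list(break_config(sequence, p, "CA")))
  labels <- vapply(configs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("scheme produced duplicate labels")
  configs
}

#' Apply strand breaks to a structure's connectivity
#'
#' Removes the backbone O3'-P bond crossing each break and attaches the
#' terminal-chemistry annotations implied by the break type. Coordinates are
#' never modified: terminal chemistry is an annotation layer, not an
#' atom-level rebuild. For CA breaks the bridging phosphate stays with the
#' downstream residue (where the PDB convention places it); for NC breaks it
#' is annotated as belonging to the upstream 3'-phosphate terminus.
#'
#' @param model a [g4_model].
#' @param config a [break_config]; residue numbering must match the model.
#' @return The modified `g4_model`, with a `termini` annotation table.
#' @export
apply_breaks <- function(model, config) {
  stopifnot(inherits(model, "g4_model"), inherits(config, "break_config"))
  resnos <- sort(unique(model$atom$resno[!.is_ion_row(model$atom)]))
  term <- model$termini
  if (is.null(term))
    term <- data.frame(resno = integer(), end = character(),
                       chemistry = character(), stringsAsFactors = FALSE)
  for (br in config$breaks) {
    up <- br$upstream_pos; down <- br$downstream_pos
    if (!(up %in% resnos) || !(down %in% resnos))
      stop("positional error: break ", up, "-", down, " outside model")
    i <- which(model$atom$resno == up & model$atom$elety == "O3'")
    j <- which(model$atom$resno == down & model$atom$elety == "P")
    if (length(i) != 1L || length(j) != 1L)
      stop("backbone atoms missing at break ", up, "-", down)
    b <- model$bonds
    hit <- (b[, 1L] == i & b[, 2L] == j) | (b[, 1L] == j & b[, 2L] == i)
    if (!any(hit))
      stop("no backbone bond present at break ", up, "-", down)
    model$bonds <- b[!hit, , drop = FALSE]
    phosphate_owner <- if (br$chemistry == "CA") down else up
    term <- rbind(term,
      data.frame(resno = c(up, down),
                 end = c(br$termini[["upstream"]], br$termini[["downstream"]]),
                 chemistry = br$chemistry, stringsAsFactors = FALSE))
    attr(model, "phosphate_owner") <-
      c(attr(model, "phosphate_owner"), stats::setNames(phosphate_owner,
                                                        paste0(up, "-", down)))
  }
  model$termini <- term
  model$break_label <- config$label
  model
}

#' Read / write a break-specification table
#'
#' Plain-CSV interchange format with columns `label`, `chemistry`,
#' `star_notation` (ASCII `*` as marker). Writing then reading reproduces the
#' file byte-identically.
#'
#' @param configs list of [break_config] objects.
#' @param path file path.
#' @return `read_break_table` returns a list of `break_config`;
#'   `write_break_table` returns `path` invisibly.
#' @export
write_break_table <- function(configs, path) {
  lines <- c("label,chemistry,star_notation",
             vapply(configs, function(cf)
               paste(cf$label, cf$chemistry,
                     render_star_notation(cf, star = "*"), sep = ","), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_break_table
#' @export
read_break_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "chemistry", "star_notation") %in% names(tab)))
  lapply(seq_len(nrow(tab)), function(i) {
    cf <- parse_star_notation(tab$star_notation[i], tab$chemistry[i])
    cf$label <- tab$label[i]
    cf
  })
}
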