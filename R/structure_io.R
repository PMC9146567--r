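# Structure and trajectory containers plus PDB input/output.
#
# PDB parsing and formatting are delegated to bio3d; this layer adds
# multi-model validation, CONECT handling, template-based connectivity
# inference and ion registration.

.is_ion_row <- function(atom) toupper(atom$resid) %in% .ion_resids

#' Construct a structure model
#'
#' A `g4_model` holds an atom table (`eleno`, `elety`, `resid`, `chain`,
#' `resno`, `elesy`), an n x 3 coordinate matrix in Angstrom, a two-column
#' bond matrix (atom row indices), and the row indices of monovalent cations.
#'
#' @param atom data frame of atom records.
#' @param xyz n x 3 numeric matrix of coordinates.
#' @param bonds two-column integer matrix of bonded atom indices.
#' @return A `g4_model` object.
#' @export
g4_model <- function(atom, xyz, bonds = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(is.data.frame(atom), ncol(xyz) == 3L, nrow(xyz) == nrow(atom),
            all(is.finite(xyz)))
  if (is.null(bonds)) bonds <- matrix(integer(), 0L, 2L)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) && (min(bonds) < 1L || max(bonds) > nrow(atom)))
    stop("connectivity references invalid atoms")
  bonds <- .canonical_bonds(bonds)
  structure(list(atom = atom, xyz = xyz, bonds = bonds,
                 ions = which(.is_ion_row(atom)), termini = NULL),
            class = "g4_model")
}

.canonical_bonds <- function(bonds) {
  if (!nrow(bonds)) return(matrix(integer(), 0L, 2L))
  b <- cbind(pmin(bonds[, 1L], bonds[, 2L]), pmax(bonds[, 1L], bonds[, 2L]))
  b <- unique(b)
  b[order(b[, 1L], b[, 2L]), , drop = FALSE]
}

#' @export
print.g4_model <- function(x, ...) {
  nres <- length(unique(x$atom$resno[!.is_ion_row(x$atom)]))
  cat("<g4_model> ", nrow(x$atom), " atoms, ", nres, " residues, ",
      length(x$ions), " ions, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Construct a trajectory
#'
#' A `g4_trajectory` couples a topology model with an ordered list of
#' per-frame coordinate sets (all with the model's atom count) and optional
#' frame times in ns.
#'
#' @param model a [g4_model].
#' @param frames list of n x 3 coordinate matrices.
#' @param times optional numeric vector of frame times (ns).
#' @return A `g4_trajectory`.
#' @export
g4_trajectory <- function(model, frames, times = NULL) {
  stopifnot(inherits(model, "g4_model"), is.list(frames), length(frames) >= 1L)
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != nrow(model$atom) || ncol(f) != 3L)
      stop("every frame must match the topology atom count")
  if (!is.null(times)) stopifnot(length(times) == length(frames))
  structure(list(model = model, frames = frames, times = times),
            class = "g4_trajectory")
}

#' @export
print.g4_trajectory <- function(x, ...) {
  cat("<g4_trajectory> ", length(x$frames), " frames x ",
      nrow(x$model$atom), " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [g4_trajectory].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Infer covalent connectivity from nucleotide templates
#'
#' Heavy-atom bonds are assigned by atom name within each standard
#' nucleotide residue, plus the inter-residue O3'-P backbone bond between
#' consecutive residue numbers on the same chain. Unknown residues are kept
#' but skipped with a warning. Ions receive no bonds.
#'
#' @param atom atom table of a [g4_model].
#' @return Two-column integer bond matrix.
#' @export
infer_connectivity <- function(atom) {
  bonds <- list()
  ion <- .is_ion_row(atom)
  keys <- paste(atom$chain, atom$resno, sep = "|")
  for (key in unique(keys[!ion])) {
    rows <- which(keys == key & !ion)
    code <- .code_of_resid(atom$resid[rows[1L]])
    if (is.na(code)) {
      warning("unknown residue '", atom$resid[rows[1L]],
              "': template connectivity skipped")
      next
    }
    for (bp in c(.bonds_common, .bonds_base[[code]])) {
      i <- rows[atom$elety[rows] == bp[1L]]
      j <- rows[atom$elety[rows] == bp[2L]]
      if (length(i) == 1L && length(j) == 1L)
        bonds[[length(bonds) + 1L]] <- c(i, j)
    }
  }
  # inter-residue O3'(i) -> P(i+1)
  nuc <- which(!ion)
  for (ch in unique(atom$chain[nuc])) {
    resnos <- sort(unique(atom$resno[nuc][atom$chain[nuc] == ch]))
    for (r in resnos[-length(resnos)]) {
      if (!((r + 1L) %in% resnos)) next
      i <- which(!ion & atom$chain == ch & atom$resno == r & atom$elety == "O3'")
      j <- which(!ion & atom$chain == ch & atom$resno == r + 1L & atom$elety == "P")
      if (length(i) == 1L && length(j) == 1L)
        bonds[[length(bonds) + 1L]] <- c(i, j)
    }
  }
  .canonical_bonds(do.call(rbind, c(bonds, list(matrix(integer(), 0L, 2L)))))
}

#' Read a (multi-model) PDB file
#'
#' Each `MODEL`/`ENDMDL` block becomes one trajectory frame (a single
#' implicit model is allowed). `K`/`NA` ion records are registered as channel
#' cation candidates. `CONECT` records, when present, define the
#' connectivity; otherwise bonds are inferred from standard nucleotide
#' templates plus inter-residue O3'-P links (see [infer_connectivity()]).
#'
#' @param path PDB file path.
#' @return A [g4_trajectory].
#' @export
read_g4_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    blk <- cumsum(model_starts)
    counts <- tapply(is_atom[blk > 0L], blk[blk > 0L], sum)
    if (length(unique(counts)) > 1L)
      stop("format error: atom count differs across MODEL records")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom[, c("eleno", "elety", "resid", "chain", "resno", "elesy")]
  atom$chain[is.na(atom$chain)] <- "A"
  if (all(is.na(atom$elesy)) || any(!nzchar(atom$elesy)) || anyNA(atom$elesy))
    atom$elesy <- substr(gsub("[^A-Za-z]", "", atom$elety), 1L, 1L)
  nat <- nrow(atom)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  # CONECT records (eleno-based)
  conect <- lines[rec == "CONECT"]
  bonds <- NULL
  if (length(conect)) {
    eleno_map <- match(seq_len(max(atom$eleno)), atom$eleno)
    pairs <- list()
    for (ln in conect) {
      ids <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))),
                                                  "\\s+")[[1]]))
      ids <- ids[!is.na(ids)]
      if (length(ids) >= 2L)
        for (k in 2:length(ids))
          pairs[[length(pairs) + 1L]] <- c(eleno_map[ids[1L]], eleno_map[ids[k]])
    }
    pairs <- do.call(rbind, pairs)
    pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
    bonds <- .canonical_bonds(pairs)
  } else {
    bonds <- infer_connectivity(atom)
  }
  model <- g4_model(atom, frames[[1L]], bonds)
  g4_trajectory(model, frames)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Frames are written as `MODEL`/`ENDMDL` blocks (bio3d formatting); the
#' model's connectivity is appended as `CONECT` records so that broken
#' backbones survive a round trip. Coordinates are stored at the PDB
#' fixed-width precision of 3 decimals.
#'
#' @param traj a [g4_trajectory] (or [g4_model], written as one frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_g4_pdb <- function(traj, path) {
  if (inherits(traj, "g4_model")) traj <- g4_trajectory(traj, list(traj$xyz))
  stopifnot(inherits(traj, "g4_trajectory"))
  model <- traj$model
  rng <- range(vapply(traj$frames, range, numeric(2)))
  if (rng[1L] < -999.999 || rng[2L] > 9999.999)
    stop("format error: coordinates out of PDB fixed-width range")
  xyz <- do.call(rbind, lapply(traj$frames, function(f) as.numeric(t(f))))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(file = tmp, xyz = xyz,
                   type = ifelse(.is_ion_row(model$atom), "HETATM", "ATOM"),
                   eleno = model$atom$eleno, elety = model$atom$elety,
                   resid = model$atom$resid, chain = model$atom$chain,
                   resno = model$atom$resno, elesy = model$atom$elesy)
  lines <- readLines(tmp, warn = FALSE)
  lines <- lines[!grepl("^END\\s*$", lines)]
  conect <- character(0)
  if (nrow(model$bonds)) {
    eleno <- model$atom$eleno
    conect <- apply(model$bonds, 1L, function(b)
      sprintf("CONECT%5d%5d", eleno[b[1L]], eleno[b[2L]]))
  }
  writeLines(c(lines, conect, "END"), path)
  invisible(path)
}

#' Select atoms with a mini-grammar
#'
#' Evaluates a selection expression over a model's atom table and returns a
#' sorted, duplicate-free vector of atom row indices. The grammar is a
#' boolean combination (`and`, `or`, `not`, parentheses) of predicates:
#'
#' * `resno A:B` or `resno 2 5 8` - residue number ranges/lists
#' * `resid DG DT` - residue names
#' * `name N1 O6` - atom names
#' * `element N O` - element symbols
#' * `guanine`, `adenine`, `thymine`, `cytosine` - by base identity
#' * `base`, `sugar`, `backbone` - standard atom-name groups
#' * `heavy`, `hydrogen` - by element
#' * `nucleic`, `ion` - nucleotide vs registered cation records
#' * `all`, `none`
#'
#' `not` binds tightest, then `and`, then `or`.
#'
#' @param model a [g4_model].
#' @param spec selection string, e.g. `"guanine and base and resno 2:4"`.
#' @return Integer vector of atom indices (possibly empty).
#' @examples
#' m <- build_ideal_g4()
#' length(select_atoms(m, "guanine and base and heavy"))
#' @export
select_atoms <- function(model, spec) {
  stopifnot(inherits(model, "g4_model"), is.character(spec), length(spec) == 1L)
  atom <- model$atom
  toks <- .sel_tokenize(spec)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  mask <- .sel_or(st, atom, model)
  if (st$pos <= length(st$toks))
    stop("selection parse error near '", st$toks[st$pos], "'")
  which(mask)
}

.sel_tokenize <- function(spec) {
  spec <- gsub("\\(", " ( ", spec)
  spec <- gsub("\\)", " ) ", spec)
  toks <- strsplit(trimws(spec), "\\s+")[[1]]
  if (!length(toks) || !nzchar(toks[1L])) stop("selection parse error: empty spec")
  toks
}

.sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
.sel_next <- function(st) { t <- .sel_peek(st); st$pos <- st$pos + 1L; t }

.sel_or <- function(st, atom, model) {
  m <- .sel_and(st, atom, model)
  while (identical(tolower(.sel_peek(st)), "or")) {
    .sel_next(st)
    m <- m | .sel_and(st, atom, model)
  }
  m
}

.sel_and <- function(st, atom, model) {
  m <- .sel_not(st, atom, model)
  while (identical(tolower(.sel_peek(st)), "and")) {
    .sel_next(st)
    m <- m & .sel_not(st, atom, model)
  }
  m
}

.sel_not <- function(st, atom, model) {
  if (identical(tolower(.sel_peek(st)), "not")) {
    .sel_next(st)
    return(!.sel_not(st, atom, model))
  }
  .sel_primary(st, atom, model)
}

.sel_args <- function(st) {
  stopwords <- c("and", "or", "not", "(", ")")
  out <- character(0)
  while (!is.na(.sel_peek(st)) && !(tolower(.sel_peek(st)) %in% stopwords))
    out <- c(out, .sel_next(st))
  if (!length(out)) stop("selection parse error: predicate needs arguments")
  out
}

.sel_primary <- function(st, atom, model) {
  tok <- .sel_next(st)
  if (is.na(tok)) stop("selection parse error: unexpected end of spec")
  code <- .code_of_resid(atom$resid)
  ion <- .is_ion_row(atom)
  switch(tolower(tok),
    "(" = {
      m <- .sel_or(st, atom, model)
      if (!identical(.sel_next(st), ")"))
        stop("selection parse error: missing ')'")
      m
    },
    "all" = rep(TRUE, nrow(atom)),
    "none" = rep(FALSE, nrow(atom)),
    "ion" = ion,
    "nucleic" = !ion & !is.na(code),
    "guanine" = !ion & code %in% "G",
    "adenine" = !ion & code %in% "A",
    "thymine" = !ion & code %in% "T",
    "cytosine" = !ion & code %in% "C",
    "heavy" = toupper(atom$elesy) != "H",
    "hydrogen" = toupper(atom$elesy) == "H",
    "base" = {
      m <- rep(FALSE, nrow(atom))
      for (cd in names(.base_atom_names))
        m <- m | (!ion & code %in% cd & atom$elety %in% .base_atom_names[[cd]])
      m
    },
    "sugar" = !ion & !is.na(code) & atom$elety %in% .sugar_atom_names,
    "backbone" = !ion & !is.na(code) & atom$elety %in% .backbone_atom_names,
    "resno" = {
      args <- .sel_args(st)
      nums <- integer(0)
      for (a in args) {
        if (grepl("^\\d+:\\d+$", a)) {
          ab <- as.integer(strsplit(a, ":")[[1]])
          nums <- c(nums, seq(ab[1L], ab[2L]))
        } else if (grepl("^\\d+$", a)) {
          nums <- c(nums, as.integer(a))
        } else stop("selection parse error: bad resno '", a, "'")
      }
      atom$resno %in% nums
    },
    "resid" = toupper(atom$resid) %in% toupper(.sel_args(st)),
    "name" = atom$elety %in% .sel_args(st),
    "element" = toupper(atom$elesy) %in% toupper(.sel_args(st)),
    stop("selection parse error: unknown token '", tok, "'")
  )
}
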