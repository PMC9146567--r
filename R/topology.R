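# Tetrad detection from Hoogsteen hydrogen-bond geometry, stacking order,
# loop assignment and channel-ion registration.

.guanine_resnos <- function(model) {
  atom <- model$atom
  sort(unique(atom$resno[!.is_ion_row(atom) & .code_of_resid(atom$resid) %in% "G"]))
}

.atom_row <- function(model, resno, name) {
  i <- which(model$atom$resno == resno & model$atom$elety == name &
               !.is_ion_row(model$atom))
  if (length(i) == 1L) i else NA_integer_
}

#' Detect Hoogsteen guanine pairs
#'
#' A directed pair i -> j is reported when both heavy-atom donor-acceptor
#' distances of the Hoogsteen edge are within `dmax`:
#' `d(N1_i, O6_j) <= dmax` and `d(N2_i, N7_j) <= dmax`. The pure distance
#' criterion (no angle term) is robust for models without hydrogens, which
#' lesioned termini frequently are.
#'
#' @param xyz n x 3 coordinate matrix (one frame).
#' @param model a [g4_model].
#' @param dmax donor-acceptor distance cutoff in Angstrom.
#' @return Data frame with columns `donor`, `acceptor` (residue numbers),
#'   `d_N1_O6`, `d_N2_N7`.
#' @export
detect_hoogsteen_pairs <- function(xyz, model, dmax = 3.5) {
  gres <- .guanine_resnos(model)
  need <- c("N1", "N2", "O6", "N7")
  rows <- lapply(gres, function(r) {
    idx <- vapply(need, function(nm) .atom_row(model, r, nm), 1L)
    if (anyNA(idx)) {
      warning("guanine ", r, " missing Hoogsteen atoms; skipped")
      NULL
    } else idx
  })
  keep <- !vapply(rows, is.null, TRUE)
  gres <- gres[keep]; rows <- rows[keep]
  n <- length(gres)
  out <- list()
  if (n >= 2L) {
    coords <- lapply(rows, function(idx) xyz[idx, , drop = FALSE])
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d1 <- sqrt(sum((coords[[i]][1L, ] - coords[[j]][3L, ])^2))  # N1->O6
      d2 <- sqrt(sum((coords[[i]][2L, ] - coords[[j]][4L, ])^2))  # N2->N7
      if (d1 <= dmax && d2 <= dmax)
        out[[length(out) + 1L]] <- data.frame(donor = gres[i], acceptor = gres[j],
                                              d_N1_O6 = d1, d_N2_N7 = d2)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), acceptor = integer(),
                      d_N1_O6 = numeric(), d_N2_N7 = numeric()))
  do.call(rbind, out)
}

#' Find guanine tetrads as directed 4-cycles
#'
#' Tetrads are simple directed 4-cycles in the Hoogsteen donor -> acceptor
#' graph. Each guanine joins at most one tetrad; when a guanine belongs to
#' several candidate cycles the cycle with the smaller mean donor-acceptor
#' distance wins (ties broken by residue indices). Output is ordered by the
#' smallest residue index of each tetrad, and each cycle is rotated to start
#' at its smallest residue, preserving the donor -> acceptor direction.
#'
#' @param pairs data frame from [detect_hoogsteen_pairs()] (one frame).
#' @return List of integer 4-vectors (cyclically ordered residue numbers),
#'   each with a `mean_distance` attribute. May be empty.
#' @export
find_tetrads <- function(pairs) {
  if (!nrow(pairs)) return(list())
  adj <- split(pairs$acceptor, pairs$donor)
  dist_of <- function(i, j) {
    k <- which(pairs$donor == i & pairs$acceptor == j)[1L]
    mean(c(pairs$d_N1_O6[k], pairs$d_N2_N7[k]))
  }
  nodes <- sort(unique(c(pairs$donor, pairs$acceptor)))
  cycles <- list()
  seen <- character(0)
  for (a in nodes) {
    for (b in adj[[as.character(a)]]) {
      if (is.null(adj[[as.character(b)]])) next
      for (cc in adj[[as.character(b)]]) {
        if (cc == a || is.null(adj[[as.character(cc)]])) next
        for (d in adj[[as.character(cc)]]) {
          if (d == a || d == b || d == cc) next
          if (!(a %in% adj[[as.character(d)]])) next
          cyc <- c(a, b, cc, d)
          rot <- which.min(cyc)
          canon <- cyc[((seq_len(4L) + rot - 2L) %% 4L) + 1L]
          key <- paste(canon, collapse = ",")
          if (key %in% seen) next
          seen <- c(seen, key)
          md <- mean(c(dist_of(a, b), dist_of(b, cc), dist_of(cc, d), dist_of(d, a)))
          cycles[[length(cycles) + 1L]] <- structure(canon, mean_distance = md)
        }
      }
    }
  }
  if (!length(cycles)) return(list())
  md <- vapply(cycles, attr, 1, "mean_distance")
  keys <- vapply(cycles, paste, "", collapse = ",")
  ord <- order(md, keys)
  used <- integer(0)
  out <- list()
  for (k in ord) {
    cyc <- cycles[[k]]
    if (any(cyc %in% used)) next
    used <- c(used, cyc)
    out[[length(out) + 1L]] <- cyc
  }
  out[order(vapply(out, min, numeric(1)))]
}

.base_com <- function(xyz, model, resno) {
  atom <- model$atom
  code <- .code_of_resid(atom$resid)
  rows <- which(atom$resno == resno & !.is_ion_row(atom) &
                  !is.na(code) &
                  atom$elety %in% .base_atom_names[[code[match(resno, atom$resno)]]] &
                  toupper(atom$elesy) != "H")
  if (!length(rows)) stop("missing base atoms for residue ", resno)
  w <- .mass_of(atom$elesy[rows])
  colSums(xyz[rows, , drop = FALSE] * w) / sum(w)
}

.tetrad_centroid <- function(xyz, model, guanines) {
  coms <- t(vapply(guanines, function(r) .base_com(xyz, model, r), numeric(3)))
  colMeans(coms)
}

#' Order tetrads along the channel axis
#'
#' Computes the channel axis as the principal direction through the tetrad
#' centroids (falling back to the mean tetrad plane normal when centroids
#' coincide), fixes its sign to run 5' to 3' along the strands, sorts
#' tetrads by their centroid projection, and rotates each tetrad's cyclic
#' guanine order so that column k follows the same strand wherever strand
#' continuity (sequence-adjacent guanines in consecutive tetrads) allows.
#' Loops and channel ions are then assigned.
#'
#' @param tetrads list of cyclic guanine 4-vectors from [find_tetrads()].
#' @param xyz frame coordinates.
#' @param model a [g4_model].
#' @param radius,margin channel cylinder radius and axial margin (Angstrom)
#'   used to register channel ions.
#' @return A `g4_topology`: list with `tetrads` (each with `guanines`,
#'   `centroid`, `normal`), `axis`, `cols` (tetrad x column residue matrix),
#'   `loops`, `channel_ions`, `degenerate_axis`.
#' @export
order_tetrads <- function(tetrads, xyz, model, radius = 3, margin = 2) {
  stopifnot(length(tetrads) >= 1L)
  cents <- t(vapply(tetrads, function(tt) .tetrad_centroid(xyz, model, tt),
                    numeric(3)))
  normals <- lapply(tetrads, function(tt) {
    coms <- t(vapply(tt, function(r) .base_com(xyz, model, r), numeric(3)))
    fit_plane(coms)$normal
  })
  degenerate <- FALSE
  if (length(tetrads) >= 2L) {
    cc <- sweep(cents, 2L, colMeans(cents))
    sv <- svd(cc)
    if (sv$d[1L] < 1e-6) {
      degenerate <- TRUE
      axis <- .unit(Reduce(`+`, normals))
    } else axis <- sv$v[, 1L]
  } else {
    axis <- normals[[1L]]
  }
  # orient 5' -> 3': sequence-consecutive guanines across tetrads vote
  votes <- 0
  memb <- rep(seq_along(tetrads), each = 4L)
  gs <- unlist(tetrads)
  proj <- cents %*% axis
  for (k in seq_along(gs)) {
    m <- match(gs[k] + 1L, gs)
    if (!is.na(m) && memb[m] != memb[k])
      votes <- votes + sign(proj[memb[m]] - proj[memb[k]])
  }
  if (votes < 0) axis <- -axis
  proj <- drop(cents %*% axis)
  ord <- order(proj)
  tetrads <- tetrads[ord]; cents <- cents[ord, , drop = FALSE]
  normals <- normals[ord]; proj <- proj[ord]
  # align normals with axis
  normals <- lapply(normals, function(nv) if (sum(nv * axis) < 0) -nv else nv)
  # column alignment by strand continuity
  rot <- function(v, r) v[((seq_len(4L) + r - 1L) %% 4L) + 1L]
  cols <- matrix(NA_integer_, length(tetrads), 4L)
  cols[1L, ] <- rot(tetrads[[1L]], which.min(tetrads[[1L]]) - 1L)
  if (length(tetrads) >= 2L) {
    for (t in 2:length(tetrads)) {
      best <- 0L; best_score <- -1L
      for (r in 0:3) {
        cand <- rot(tetrads[[t]], r)
        score <- sum(abs(cand - cols[t - 1L, ]) == 1L)
        if (score > best_score) { best_score <- score; best <- r }
      }
      cols[t, ] <- rot(tetrads[[t]], best)
    }
  }
  tets <- lapply(seq_along(tetrads), function(t)
    list(guanines = cols[t, ], centroid = cents[t, ], normal = normals[[t]]))
  topo <- structure(list(tetrads = tets, axis = .unit(axis), cols = cols,
                         loops = assign_loops(model, unlist(tetrads)),
                         channel_ions = integer(0),
                         degenerate_axis = degenerate),
                    class = "g4_topology")
  if (length(model$ions)) {
    occ <- .ions_in_channel(xyz, model, topo, radius, margin)
    topo$channel_ions <- model$ions[occ]
  }
  topo
}

#' @export
print.g4_topology <- function(x, ...) {
  cat("<g4_topology> ", length(x$tetrads), " tetrads, ",
      length(x$loops), " loops, ", length(x$channel_ions), " channel ions\n",
      sep = "")
  for (t in x$tetrads)
    cat("  tetrad:", paste(t$guanines, collapse = "-"), "\n")
  invisible(x)
}

#' Assign loop runs
#'
#' Returns the maximal runs of residues that belong to no tetrad, in strand
#' order - for native h-telo these are the 5' overhang residue 1 and the
#' three TTA loops 5-7, 11-13 and 17-19.
#'
#' @param model a [g4_model].
#' @param tetrad_resnos residue numbers of all tetrad guanines.
#' @return List of integer vectors (residue runs); may be empty.
#' @export
assign_loops <- function(model, tetrad_resnos) {
  resnos <- sort(unique(model$atom$resno[!.is_ion_row(model$atom)]))
  free <- setdiff(resnos, tetrad_resnos)
  if (!length(free)) return(list())
  unname(split(free, cumsum(c(1L, diff(free) != 1L))))
}

#' Detect the full tetrad topology of one frame
#'
#' Convenience wrapper: Hoogsteen pair detection, 4-cycle search, and
#' ordering along the channel axis. The default analysis pipeline detects
#' topology once on the first frame and tracks that fixed tetrad definition
#' across the trajectory, so that descriptors compare like with like.
#'
#' @param traj a [g4_trajectory] (or [g4_model]).
#' @param frame frame index used for detection.
#' @param dmax Hoogsteen distance cutoff (Angstrom).
#' @param radius,margin channel cylinder parameters (Angstrom).
#' @return A `g4_topology`.
#' @export
detect_topology <- function(traj, frame = 1L, dmax = 3.5, radius = 3, margin = 2) {
  if (inherits(traj, "g4_model")) traj <- g4_trajectory(traj, list(traj$xyz))
  xyz <- traj$frames[[frame]]
  pairs <- detect_hoogsteen_pairs(xyz, traj$model, dmax)
  tets <- find_tetrads(pairs)
  if (!length(tets)) stop("no tetrads detected at frame ", frame)
  order_tetrads(tets, xyz, traj$model, radius, margin)
}

#' Export a topology as JSON
#'
#' @param topology a `g4_topology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  obj <- list(
    tetrads = lapply(topology$tetrads, function(t)
      list(guanines = t$guanines, centroid = round(t$centroid, 4),
           normal = round(t$normal, 6))),
    axis = round(topology$axis, 6),
    loops = topology$loops,
    channel_ions = topology$channel_ions)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
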