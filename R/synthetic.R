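# Synthetic G4 models and stochastic conformational ensembles: an ideal
# parallel three-tetrad quadruplex with controllable rise/twist, axial
# cations, a rigid core with flexible loops, and optional injected
# destabilization events. The noise model is i.i.d. Gaussian per coordinate
# - a statistical stand-in for conformational flexibility, not a physical
# force field.

.rz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

# G tracts: maximal runs of G with length >= n_tetrads; first 4 runs are the
# strands, first n_tetrads guanines of each run are the tetrad guanines
.find_tracts <- function(res, n_tetrads) {
  runs <- rle(res == "G")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  g_runs <- which(runs$values & runs$lengths >= n_tetrads)
  if (length(g_runs) < 4L)
    stop("sequence incompatible with ", n_tetrads,
         " tetrads: needs 4 G tracts of length >= ", n_tetrads)
  lapply(g_runs[1:4], function(k) seq(starts[k], starts[k] + n_tetrads - 1L))
}

#' Build an ideal parallel G-quadruplex model
#'
#' Places a planar guanine template at four-fold rotations about the channel
#' (z) axis for each tetrad; tetrad k is rotated by `k * twist` and
#' translated by `k * rise` along the axis, so the builder's twist and rise
#' are recovered exactly by the descriptor suite on the noise-free model.
#' Loop and overhang residues are placed on smooth arcs outside the core,
#' and one channel cation sits on the axis midway between each pair of
#' consecutive tetrad planes. The default C1' radius is calibrated so that
#' all Hoogsteen heavy-atom donor-acceptor distances are exactly 2.9 A.
#'
#' @param n_tetrads number of stacked tetrads (>= 1).
#' @param rise axial separation of consecutive tetrad planes, Angstrom.
#' @param twist inter-tetrad twist, degrees (positive = right-handed).
#' @param radius C1' distance from the channel axis, Angstrom.
#' @param sequence nucleotide sequence; needs four G tracts of length
#'   >= `n_tetrads`.
#' @param ions place K+ cations between consecutive tetrad planes.
#' @return A [g4_model] with a `built` element recording the ground truth
#'   (parameters, tetrad residue matrix, core and loop residues).
#' @examples
#' m <- build_ideal_g4()
#' detect_topology(m)
#' @export
build_ideal_g4 <- function(n_tetrads = 3L, rise = 3.3, twist = 30,
                           radius = NULL, sequence = htelo_sequence,
                           ions = TRUE) {
  stopifnot(n_tetrads >= 1L, rise > 0)
  if (is.null(radius)) radius <- .tetrad_placement$c1p_radius
  stopifnot(radius > 0)
  res <- .check_sequence(sequence)
  tracts <- .find_tracts(res, n_tetrads)
  n_res <- length(res)
  # strand/level of each tetrad guanine
  strand_of <- rep(NA_integer_, n_res)
  level_of <- rep(NA_integer_, n_res)
  for (s in 1:4) for (k in seq_len(n_tetrads)) {
    strand_of[tracts[[s]][k]] <- s - 1L
    level_of[tracts[[s]][k]] <- k - 1L
  }
  core <- which(!is.na(strand_of))
  # placed-template C1' geometry (pre-rotation)
  t2 <- c(.tetrad_placement$tx, .tetrad_placement$ty, 0)
  c1p0 <- c(.c1p_xy, 0) + t2
  u_rad <- .unit(c(c1p0[1:2], 0))
  rad_off <- (radius - .tetrad_placement$c1p_radius) * u_rad
  place_core <- function(tmpl_xyz, s, k) {
    p <- sweep(tmpl_xyz, 2L, t2 + rad_off, `+`)
    p <- p %*% t(.rz(s * 90 + k * twist))
    p[, 3L] <- p[, 3L] + k * rise
    p
  }
  az0 <- atan2(c1p0[2L], c1p0[1L]) * 180 / pi
  top_z <- (n_tetrads - 1L) * rise
  loop_radius <- radius + 5
  place_arc <- function(tmpl_xyz, az, z) {
    p <- tmpl_xyz %*% t(.rz(az))
    com <- colMeans(p)
    target <- c(loop_radius * cos(az * pi / 180),
                loop_radius * sin(az * pi / 180), z)
    sweep(p, 2L, target - com, `+`)
  }
  # anchor azimuth/z of a core residue's C1'
  anchor <- function(r) {
    s <- strand_of[r]; k <- level_of[r]
    c1 <- as.numeric((c1p0 + rad_off) %*% t(.rz(s * 90 + k * twist)))
    c(az = atan2(c1[2L], c1[1L]) * 180 / pi, z = k * rise)
  }
  atom_rows <- list(); xyz_rows <- list()
  eleno <- 0L
  add_residue <- function(r, placed, tmpl) {
    n <- nrow(placed)
    atom_rows[[length(atom_rows) + 1L]] <<- data.frame(
      eleno = eleno + seq_len(n), elety = tmpl$names,
      resid = .residue_name(res[r]), chain = "A", resno = r,
      elesy = tmpl$elesy, stringsAsFactors = FALSE)
    xyz_rows[[length(xyz_rows) + 1L]] <<- placed
    eleno <<- eleno + n
  }
  # non-core residues in maximal runs, with flanking core anchors
  runs <- split(setdiff(seq_len(n_res), core),
                cumsum(c(1L, diff(setdiff(seq_len(n_res), core)) != 1L)))
  run_of <- rep(NA_integer_, n_res)
  for (i in seq_along(runs)) run_of[runs[[i]]] <- i
  arc_pos <- function(r) {
    run <- runs[[run_of[r]]]
    L <- length(run)
    i <- match(r, run)
    prev <- run[1L] - 1L
    nxt <- run[L] + 1L
    if (prev >= 1L && nxt <= n_res && !is.na(strand_of[prev]) &&
        !is.na(strand_of[nxt])) {
      a1 <- anchor(prev); a2 <- anchor(nxt)
      daz <- (a2[["az"]] - a1[["az"]]) %% 360
      frac <- i / (L + 1)
      c(az = a1[["az"]] + frac * daz, z = a1[["z"]] + frac * (a2[["z"]] - a1[["z"]]))
    } else if (nxt <= n_res && !is.na(strand_of[nxt])) {   # 5' overhang
      a2 <- anchor(nxt)
      c(az = a2[["az"]] - 35 * (L - i + 1L), z = a2[["z"]] - 2.5 * (L - i + 1L))
    } else if (prev >= 1L && !is.na(strand_of[prev])) {    # 3' overhang
      a1 <- anchor(prev)
      c(az = a1[["az"]] + 35 * i, z = a1[["z"]] + 2.5 * i)
    } else {
      c(az = 35 * i, z = top_z + 2.5 * i)
    }
  }
  for (r in seq_len(n_res)) {
    tmpl <- .residue_template(res[r])
    placed <- if (!is.na(strand_of[r])) {
      place_core(tmpl$xyz, strand_of[r], level_of[r])
    } else {
      ap <- arc_pos(r)
      place_arc(tmpl$xyz, ap[["az"]], ap[["z"]])
    }
    add_residue(r, placed, tmpl)
  }
  if (ions && n_tetrads >= 2L) {
    for (k in seq_len(n_tetrads - 1L)) {
      eleno <- eleno + 1L
      atom_rows[[length(atom_rows) + 1L]] <- data.frame(
        eleno = eleno, elety = "K", resid = "K", chain = "A",
        resno = n_res + k, elesy = "K", stringsAsFactors = FALSE)
      xyz_rows[[length(xyz_rows) + 1L]] <- matrix(c(0, 0, (k - 0.5) * rise), 1L)
    }
  }
  atom <- do.call(rbind, atom_rows)
  xyz <- do.call(rbind, xyz_rows)
  model <- g4_model(atom, xyz, infer_connectivity(atom))
  tet_matrix <- t(vapply(seq_len(n_tetrads), function(k)
    vapply(tracts, `[`, 1L, k), integer(4)))
  model$built <- list(n_tetrads = n_tetrads, rise = rise, twist = twist,
                      radius = radius, sequence = paste(res, collapse = ""),
                      tetrads = tet_matrix, core_resnos = core,
                      loop_resnos = setdiff(seq_len(n_res), core))
  model
}

#' Generate a stochastic conformational ensemble
#'
#' Each frame is the model plus independent Gaussian displacement of every
#' coordinate - `sigma_core` on tetrad residues and ions, `sigma_loop` on
#' all other residues (default four times the core noise, emulating the
#' rigid-core / flexible-loop contrast of G4 dynamics) - optionally followed
#' by a random global rigid motion, which is on by default so that any
#' orientation dependence in downstream descriptors surfaces immediately.
#' Injected destabilization events are applied deterministically from their
#' onset frame, before the rigid motion:
#'
#' * `type = "cation_leak"`: channel ion `ion` (index among the model's
#'   ions) is displaced `magnitude` Angstrom radially off the axis.
#' * `type = "guanine_expulsion"`: all atoms of residue `resno` are
#'   displaced `magnitude` Angstrom radially outward from the channel axis;
#'   its Hoogsteen partners stay in place.
#'
#' @param model a [g4_model] from [build_ideal_g4()].
#' @param n_frames number of frames.
#' @param sigma_core core noise, Angstrom per coordinate.
#' @param sigma_loop loop noise, Angstrom per coordinate.
#' @param seed mandatory RNG seed (the generator restores the caller's RNG
#'   state on exit).
#' @param events list of event lists, e.g.
#'   `list(list(type = "guanine_expulsion", frame = 200, magnitude = 12, resno = 8))`.
#' @param rigid_motion apply a random global rotation + translation per frame.
#' @param core_resnos residues treated as rigid core (default: the builder's
#'   tetrad guanines).
#' @return A [g4_trajectory].
#' @export
generate_ensemble <- function(model, n_frames = 100L, sigma_core = 0.3,
                              sigma_loop = 4 * sigma_core, seed,
                              events = list(), rigid_motion = TRUE,
                              core_resnos = NULL) {
  stopifnot(inherits(model, "g4_model"), n_frames >= 1L,
            sigma_core >= 0, sigma_loop >= 0)
  if (missing(seed)) stop("seed is mandatory for ensemble generation")
  if (is.null(core_resnos)) {
    if (is.null(model$built)) stop("supply core_resnos for non-builder models")
    core_resnos <- model$built$core_resnos
  }
  for (ev in events)
    if (!identical(ev$type, "cation_leak") &&
        !identical(ev$type, "guanine_expulsion"))
      stop("unknown event type: '", ev$type, "'")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  atom <- model$atom
  is_core <- (atom$resno %in% core_resnos & !.is_ion_row(atom)) | .is_ion_row(atom)
  sigma <- ifelse(is_core, sigma_core, sigma_loop)
  n <- nrow(atom)
  # precompute event displacement vectors (model frame, z = channel axis)
  ev_disp <- lapply(events, function(ev) {
    if (ev$type == "cation_leak") {
      idx <- model$ions[if (is.null(ev$ion)) 1L else ev$ion]
      if (is.na(idx)) stop("event refers to a missing ion")
      p <- model$xyz[idx, ]
      u <- if (sqrt(sum(p[1:2]^2)) < 1e-6) c(1, 0, 0) else .unit(c(p[1:2], 0))
      list(rows = idx, vec = ev$magnitude * u, frame = ev$frame)
    } else {
      rows <- which(atom$resno == ev$resno & !.is_ion_row(atom))
      if (!length(rows)) stop("event refers to a missing residue")
      com <- .base_com(model$xyz, model, ev$resno)
      u <- .unit(c(com[1:2], 0))
      list(rows = rows, vec = ev$magnitude * u, frame = ev$frame)
    }
  })
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- model$xyz + matrix(stats::rnorm(3L * n, sd = rep(sigma, 3L)), n, 3L)
    for (ed in ev_disp)
      if (f >= ed$frame)
        xyz[ed$rows, ] <- sweep(xyz[ed$rows, , drop = FALSE], 2L, ed$vec, `+`)
    if (rigid_motion) {
      q <- stats::rnorm(4L)
      q <- q / sqrt(sum(q^2))
      R <- .quat_to_rot(q)
      tr <- stats::rnorm(3L, sd = 5)
      xyz <- xyz %*% t(R) + matrix(tr, n, 3L, byrow = TRUE)
    }
    frames[[f]] <- xyz
  }
  g4_trajectory(model, frames)
}

.quat_to_rot <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3L, 3L)
}
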