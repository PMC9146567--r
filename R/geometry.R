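# Descriptor suite: plane fits, guanine angles, tetrad centre-of-mass
# distances, inter-tetrad twist, Kabsch superposition, RMSD series and
# pairwise 2D-RMSD matrices.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# numerically stable angle between two vectors, degrees (atan2 form avoids
# the acos derivative blow-up near 0 and 180 degrees)
.vec_angle <- function(a, b) {
  cr <- c(a[2L] * b[3L] - a[3L] * b[2L],
          a[3L] * b[1L] - a[1L] * b[3L],
          a[1L] * b[2L] - a[2L] * b[1L])
  atan2(sqrt(sum(cr^2)), sum(a * b)) * 180 / pi
}

# signed angle from a to b about unit axis, degrees, in (-180, 180]
.signed_angle <- function(a, b, axis) {
  cr <- c(a[2L] * b[3L] - a[3L] * b[2L],
          a[3L] * b[1L] - a[1L] * b[3L],
          a[1L] * b[2L] - a[2L] * b[1L])
  atan2(sum(cr * axis), sum(a * b)) * 180 / pi
}

.circular_mean_deg <- function(x) {
  r <- x * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

#' Least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared point-to-plane distances
#' (the smallest principal component of the centered points).
#'
#' @param points m x 3 matrix, m >= 3, not collinear.
#' @param axis_hint optional vector; the normal sign is chosen so that
#'   `normal . axis_hint >= 0`.
#' @return List with `centroid`, unit `normal`, and `rms_out_of_plane`
#'   (Angstrom).
#' @export
fit_plane <- function(points, axis_hint = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("plane fit needs at least 3 points")
  centroid <- colMeans(points)
  cc <- sweep(points, 2L, centroid)
  sv <- svd(cc)
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1))
    stop("degeneracy error: points are collinear")
  normal <- sv$v[, 3L]
  if (!is.null(axis_hint) && sum(normal * axis_hint) < 0) normal <- -normal
  rms <- sqrt(mean((cc %*% normal)^2))
  list(centroid = centroid, normal = .unit(normal), rms_out_of_plane = rms)
}

#' Intra-tetrad guanine angles
#'
#' Angles subtended at the tetrad centroid by the base-heavy-atom centres of
#' mass of guanine pairs: the four cyclically adjacent pairs and the two
#' diagonal (opposite) pairs. In an undamaged four-fold symmetric tetrad
#' these are 90 and 180 degrees respectively, the native reference values.
#'
#' @param xyz frame coordinates.
#' @param model a [g4_model].
#' @param guanines cyclic 4-vector of tetrad residue numbers.
#' @param centroid angle vertex; defaults to the mean of the four base
#'   centres of mass. Supplying a fixed vertex makes the angles exactly
#'   invariant to radial displacement of a guanine.
#' @return List with `adjacent` (4 angles, degrees) and `opposite` (2 angles).
#' @export
guanine_angles <- function(xyz, model, guanines, centroid = NULL) {
  stopifnot(length(guanines) == 4L)
  coms <- t(vapply(guanines, function(r) .base_com(xyz, model, r), numeric(3)))
  if (is.null(centroid)) centroid <- colMeans(coms)
  v <- sweep(coms, 2L, centroid)
  adj <- vapply(1:4, function(k)
    .vec_angle(v[k, ], v[(k %% 4L) + 1L, ]), 1)
  opp <- c(.vec_angle(v[1L, ], v[3L, ]), .vec_angle(v[2L, ], v[4L, ]))
  list(adjacent = adj, opposite = opp)
}

#' Distance between tetrad centres of mass
#'
#' Euclidean distance between the mass-weighted centres of mass of the
#' guanine heavy atoms of two tetrads. For an ideal stack this equals the
#' rise times the number of intervening steps.
#'
#' @param xyz frame coordinates.
#' @param model a [g4_model].
#' @param guanines_i,guanines_j residue numbers of the two tetrads.
#' @return Distance in Angstrom.
#' @export
tetrad_com_distance <- function(xyz, model, guanines_i, guanines_j) {
  com <- function(guanines) {
    rows <- which(model$atom$resno %in% guanines & !.is_ion_row(model$atom) &
                    toupper(model$atom$elesy) != "H")
    w <- .mass_of(model$atom$elesy[rows])
    colSums(xyz[rows, , drop = FALSE] * w) / sum(w)
  }
  sqrt(sum((com(guanines_i) - com(guanines_j))^2))
}

#' Inter-tetrad twist angle
#'
#' For each strand column k the edge vector from the anchor atom (default
#' C1') of column k to column k+1 (cyclic) is formed within each tetrad,
#' projected onto the plane perpendicular to the channel axis, and the
#' signed angle between corresponding projected vectors is measured. The
#' twist is the circular mean of the four signed angles, positive for a
#' right-handed rotation looking down the axis.
#'
#' @param xyz frame coordinates.
#' @param model a [g4_model].
#' @param topology a `g4_topology` (supplies strand-matched columns).
#' @param i,j tetrad indices (consecutive in the stack).
#' @param axis channel axis; when `NULL` it is recomputed from this frame's
#'   tetrad centroids so the descriptor is rigid-motion invariant.
#' @param anchor `"C1'"` (default) or `"N9"` edge-vector convention.
#' @return Signed twist in degrees, in (-180, 180].
#' @export
twist_angle <- function(xyz, model, topology, i = 1L, j = i + 1L,
                        axis = NULL, anchor = c("C1'", "N9")) {
  anchor <- match.arg(anchor)
  cols <- topology$cols
  if (is.null(cols) || anyNA(cols[c(i, j), ]))
    stop("unmatched strand columns; re-run order_tetrads")
  if (is.null(axis)) axis <- .frame_axis(xyz, model, topology)
  pt <- function(t, k) {
    row <- .atom_row(model, cols[t, k], anchor)
    if (is.na(row)) stop("missing ", anchor, " for residue ", cols[t, k])
    xyz[row, ]
  }
  proj <- function(v) v - sum(v * axis) * axis
  angles <- vapply(1:4, function(k) {
    k2 <- (k %% 4L) + 1L
    vi <- proj(pt(i, k2) - pt(i, k))
    vj <- proj(pt(j, k2) - pt(j, k))
    .signed_angle(vi, vj, axis)
  }, 1)
  .circular_mean_deg(angles)
}

# per-frame channel axis from the topology's guanine sets (sign follows the
# tetrad stacking order, so it is rotation-covariant)
.frame_axis <- function(xyz, model, topology) {
  cents <- t(vapply(topology$tetrads, function(t)
    .tetrad_centroid(xyz, model, t$guanines), numeric(3)))
  if (nrow(cents) == 1L) {
    coms <- t(vapply(topology$tetrads[[1L]]$guanines,
                     function(r) .base_com(xyz, model, r), numeric(3)))
    return(fit_plane(coms)$normal)
  }
  cc <- sweep(cents, 2L, colMeans(cents))
  sv <- svd(cc)
  axis <- sv$v[, 1L]
  if (sum((cents[nrow(cents), ] - cents[1L, ]) * axis) < 0) axis <- -axis
  .unit(axis)
}

#' Kabsch superposition
#'
#' Optimal proper-rotation least-squares alignment of matched point sets:
#' returns the rotation `R` and translation `t` minimizing the weighted RMSD
#' of `R x_i + t` onto `y_i`. Reflections are excluded.
#'
#' @param X,Y n x 3 matrices of matched points, n >= 3.
#' @param weights optional non-negative weights.
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom), and logical `degenerate` (collinear input flagged).
#' @export
kabsch_superpose <- function(X, Y, weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 3L || nrow(Y) != nrow(X)) stop("need matched point sets, n >= 3")
  if (is.null(weights)) weights <- rep(1, nrow(X))
  stopifnot(all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  H <- t(Xc * w) %*% Yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  degenerate <- sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-300)
  diff <- Xc %*% t(R) - Yc
  rmsd <- sqrt(sum(w * rowSums(diff^2)))
  list(rotation = R, translation = as.numeric(cy - R %*% cx), rmsd = rmsd,
       degenerate = degenerate)
}

#' Per-frame RMSD series against a reference frame
#'
#' Kabsch-superposed RMSD of the selected atoms of every frame onto the
#' reference frame.
#'
#' @param traj a [g4_trajectory].
#' @param ref reference frame index.
#' @param selection atom indices (e.g. from [select_atoms()]).
#' @return A `g4_metric_series` (data frame `frame`, `value` with attributes
#'   `metric` and `units`).
#' @export
rmsd_series <- function(traj, ref = 1L, selection) {
  if (!length(selection)) stop("selection is empty")
  Y <- traj$frames[[ref]][selection, , drop = FALSE]
  vals <- vapply(traj$frames, function(f)
    kabsch_superpose(f[selection, , drop = FALSE], Y)$rmsd, 1)
  metric_series(vals, metric = "rmsd", units = "angstrom")
}

#' Pairwise 2D-RMSD matrix
#'
#' Symmetric matrix of Kabsch-superposed RMSD values between all retained
#' frame pairs, the map used to reveal conformational basins. A rigid
#' tetrad core gives a uniformly low tetrad-only map while flexible loops
#' push the whole-DNA map higher.
#'
#' @param traj a [g4_trajectory].
#' @param selection atom indices.
#' @param stride keep every `stride`-th frame.
#' @return Matrix with attributes `frames` (indices used) and `selection`.
#' @export
rmsd_matrix <- function(traj, selection, stride = 1L) {
  if (!length(selection)) stop("selection is empty")
  stopifnot(stride >= 1L)
  keep <- seq(1L, n_frames(traj), by = stride)
  sub <- lapply(traj$frames[keep], function(f) f[selection, , drop = FALSE])
  n <- length(sub)
  m <- matrix(0, n, n)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    v <- kabsch_superpose(sub[[i]], sub[[j]])$rmsd
    m[i, j] <- v; m[j, i] <- v
  }
  attr(m, "frames") <- keep
  attr(m, "selection") <- selection
  m
}

#' Metric series container
#'
#' @param values numeric per-frame values.
#' @param metric descriptor name.
#' @param units unit string.
#' @param frames frame indices.
#' @return A `g4_metric_series` data frame.
#' @export
metric_series <- function(values, metric = "metric", units = "",
                          frames = seq_along(values)) {
  out <- data.frame(frame = frames, value = as.numeric(values))
  attr(out, "metric") <- metric
  attr(out, "units") <- units
  class(out) <- c("g4_metric_series", "data.frame")
  out
}

#' @export
print.g4_metric_series <- function(x, ...) {
  cat("<g4_metric_series> ", attr(x, "metric"), " [", attr(x, "units"), "], ",
      nrow(x), " frames, mean ", signif(mean(x$value), 4), "\n", sep = "")
  invisible(x)
}

#' Write a metric series as CSV
#' @param series a `g4_metric_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("frame", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-frame descriptor series over a trajectory
#'
#' Convenience builders for the standard descriptor time series with the
#' topology tracked from the detection frame: inter-tetrad twist,
#' consecutive tetrad centre-of-mass distance, and intra-tetrad angles.
#'
#' @param traj a [g4_trajectory].
#' @param topology a `g4_topology`.
#' @param i,j tetrad indices.
#' @param anchor edge-vector anchor atom for twist.
#' @return A `g4_metric_series`.
#' @export
twist_series <- function(traj, topology, i = 1L, j = i + 1L, anchor = "C1'") {
  vals <- vapply(traj$frames, function(f)
    twist_angle(f, traj$model, topology, i, j, axis = NULL, anchor = anchor), 1)
  metric_series(vals, metric = sprintf("twist_%d_%d", i, j), units = "degrees")
}

#' @rdname twist_series
#' @export
com_distance_series <- function(traj, topology, i = 1L, j = i + 1L) {
  gi <- topology$tetrads[[i]]$guanines
  gj <- topology$tetrads[[j]]$guanines
  vals <- vapply(traj$frames, function(f)
    tetrad_com_distance(f, traj$model, gi, gj), 1)
  metric_series(vals, metric = sprintf("com_distance_%d_%d", i, j),
                units = "angstrom")
}

#' @rdname twist_series
#' @param which_angle `"adjacent"` or `"opposite"`; the mean of the
#'   corresponding angles per frame.
#' @export
angle_series <- function(traj, topology, i = 1L,
                         which_angle = c("adjacent", "opposite")) {
  which_angle <- match.arg(which_angle)
  g <- topology$tetrads[[i]]$guanines
  vals <- vapply(traj$frames, function(f) {
    a <- guanine_angles(f, traj$model, g)
    mean(a[[which_angle]])
  }, 1)
  metric_series(vals, metric = sprintf("%s_angle_t%d", which_angle, i),
                units = "degrees")
}
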