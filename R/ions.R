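# Channel cation occupancy and leakage-event detection.

# logical vector over model$ions: inside the channel cylinder at this frame
.ions_in_channel <- function(xyz, model, topology, radius, margin) {
  if (!length(model$ions)) return(logical(0))
  cents <- t(vapply(topology$tetrads, function(t)
    .tetrad_centroid(xyz, model, t$guanines), numeric(3)))
  axis <- .frame_axis(xyz, model, topology)
  origin <- colMeans(cents)
  proj <- drop(sweep(cents, 2L, origin) %*% axis)
  lo <- min(proj) - margin
  hi <- max(proj) + margin
  vapply(model$ions, function(i) {
    v <- xyz[i, ] - origin
    ax <- sum(v * axis)
    rad <- sqrt(max(sum(v^2) - ax^2, 0))
    rad <= radius && ax >= lo && ax <= hi
  }, TRUE)
}

#' Channel cation occupancy
#'
#' Classifies every registered cation, at every frame, as inside or outside
#' the channel: inside means within `radius` of the channel axis and with an
#' axial projection between the first and last tetrad centroid extended by
#' `margin` at both ends. Axis and bounds are recomputed per frame from the
#' tracked tetrad guanines, so occupancy is invariant under rigid motion of
#' a frame.
#'
#' @param traj a [g4_trajectory].
#' @param topology a `g4_topology` with at least 2 tetrads.
#' @param radius cylinder radius in Angstrom.
#' @param margin axial margin in Angstrom.
#' @return A `g4_channel_state`: logical frames x ions matrix with the
#'   channel geometry attached as attributes.
#' @export
channel_occupancy <- function(traj, topology, radius = 3, margin = 2) {
  stopifnot(inherits(traj, "g4_trajectory"), length(topology$tetrads) >= 2L)
  ions <- traj$model$ions
  if (!length(ions)) {
    warning("no ions in model; empty channel state")
    state <- matrix(logical(0), nrow = n_frames(traj), ncol = 0L)
  } else {
    state <- t(vapply(traj$frames, function(f)
      .ions_in_channel(f, traj$model, topology, radius, margin),
      logical(length(ions))))
    state <- matrix(state, nrow = n_frames(traj))
  }
  colnames(state) <- if (length(ions)) paste0("ion", seq_along(ions)) else NULL
  structure(state, ions = ions, radius = radius, margin = margin,
            class = c("g4_channel_state", class(state)))
}

#' Detect cation leakage events
#'
#' A leakage event is an in-to-out transition after which the ion stays
#' outside the channel for at least `min_out` consecutive frames (hysteresis
#' against brief excursions). Re-entry, when it happens, is recorded.
#'
#' @param state a `g4_channel_state` from [channel_occupancy()].
#' @param min_out minimum out-of-channel dwell, in frames.
#' @return Data frame with one row per event: `ion` (column index), `atom`
#'   (atom row in the model), `exit_frame`, `reentry_frame` (`NA` if never),
#'   `dwell_out`, `persists_to_end`.
#' @export
detect_leakage <- function(state, min_out = 10L) {
  stopifnot(inherits(state, "g4_channel_state"))
  events <- list()
  nf <- nrow(state)
  for (k in seq_len(ncol(state))) {
    inside <- state[, k]
    t <- 1L
    while (t < nf) {
      if (inside[t] && !inside[t + 1L]) {
        exit <- t + 1L
        run_end <- exit
        while (run_end < nf && !inside[run_end + 1L]) run_end <- run_end + 1L
        dwell <- run_end - exit + 1L
        if (dwell >= min_out) {
          reentry <- if (run_end < nf) run_end + 1L else NA_integer_
          events[[length(events) + 1L]] <- data.frame(
            ion = k, atom = attr(state, "ions")[k], exit_frame = exit,
            reentry_frame = reentry, dwell_out = dwell,
            persists_to_end = run_end == nf)
        }
        t <- run_end
      } else t <- t + 1L
    }
  }
  if (!length(events))
    return(data.frame(ion = integer(), atom = integer(), exit_frame = integer(),
                      reentry_frame = integer(), dwell_out = integer(),
                      persists_to_end = logical()))
  do.call(rbind, events)
}

#' Write leakage events as CSV
#' @param events data frame from [detect_leakage()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_leakage_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
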