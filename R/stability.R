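# Distribution summaries, destabilization-event detection, and the
# per-structure stability verdict.

.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

.circular_sd_deg <- function(x) {
  r <- x * pi / 180
  R <- sqrt(mean(cos(r))^2 + mean(sin(r))^2)
  R <- min(max(R, 1e-12), 1)
  sqrt(-2 * log(R)) * 180 / pi
}

#' Circular twist-angle distribution
#'
#' Histograms an angle series on 2-degree bins over (-180, 180], reports the
#' circular mode (circular mean of the values in the fullest bin), the
#' circular standard deviation, and - when a reference distribution is
#' supplied - the circular shift of the mode relative to the reference.
#' Strand breaks typically widen this distribution and shift its mode by a
#' few degrees relative to the undamaged structure.
#'
#' @param series a `g4_metric_series` of angles (degrees) or numeric vector.
#' @param reference optional reference series/vector or `g4_twist_distribution`.
#' @param bin bin width in degrees.
#' @return A `g4_twist_distribution`: list with `breaks`, `density`
#'   (normalized), `mode`, `width`, `shift` (`NA` without a reference),
#'   `n`.
#' @export
twist_distribution <- function(series, reference = NULL, bin = 2) {
  x <- if (inherits(series, "g4_metric_series")) series$value else as.numeric(series)
  if (!length(x)) stop("empty series")
  x <- .wrap180(x)
  breaks <- seq(-180, 180, by = bin)
  cuts <- findInterval(x, breaks, rightmost.closed = TRUE, left.open = TRUE)
  cuts[cuts == 0L] <- 1L
  counts <- tabulate(cuts, nbins = length(breaks) - 1L)
  dens <- counts / (sum(counts) * bin)
  top <- which.max(counts)
  mode <- .circular_mean_deg(x[cuts == top])
  width <- .circular_sd_deg(x)
  shift <- NA_real_
  if (!is.null(reference)) {
    ref_mode <- if (inherits(reference, "g4_twist_distribution")) {
      reference$mode
    } else twist_distribution(reference, bin = bin)$mode
    shift <- .wrap180(mode - ref_mode)
  }
  structure(list(breaks = breaks, density = dens, mode = mode, width = width,
                 shift = shift, n = length(x)),
            class = "g4_twist_distribution")
}

#' @export
print.g4_twist_distribution <- function(x, ...) {
  cat("<g4_twist_distribution> mode ", signif(x$mode, 4), " deg, width ",
      signif(x$width, 4), " deg",
      if (!is.na(x$shift)) paste0(", shift ", signif(x$shift, 4), " deg"),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Detect guanine expulsion from a tetrad
#'
#' Re-evaluates the Hoogsteen bonds of every tracked tetrad guanine at every
#' frame. A guanine is flagged when both of its in-tetrad Hoogsteen
#' partnerships (the pair it donates and the pair it accepts) are broken; an
#' expulsion event is a run of at least `hbond_frames` consecutive flagged
#' frames during which the guanine's base centre of mass also moves more
#' than `dist_thresh` beyond its reference-frame distance from the (per
#' frame) tetrad centroid. The excess-distance form keeps the criterion
#' rigid-motion invariant and insensitive to the finite native base-centroid
#' distance.
#'
#' @param traj a [g4_trajectory].
#' @param topology a `g4_topology` (tetrads tracked from the detection frame).
#' @param dmax Hoogsteen distance cutoff (Angstrom).
#' @param dist_thresh excess displacement threshold (Angstrom).
#' @param hbond_frames minimum persistence, in frames.
#' @return Data frame with one row per event: `guanine`, `tetrad`, `onset`,
#'   `end`, `persists_to_end`, `max_excess`.
#' @export
detect_guanine_expulsion <- function(traj, topology, dmax = 3.5,
                                     dist_thresh = 8, hbond_frames = 10L) {
  model <- traj$model
  nf <- n_frames(traj)
  cols <- topology$cols
  nt <- nrow(cols)
  ref <- traj$frames[[1L]]
  ref_dist <- matrix(0, nt, 4L)
  for (t in seq_len(nt)) {
    cen <- .tetrad_centroid(ref, model, cols[t, ])
    for (k in 1:4)
      ref_dist[t, k] <- sqrt(sum((.base_com(ref, model, cols[t, k]) - cen)^2))
  }
  broken <- array(FALSE, c(nf, nt, 4L))
  excess <- array(0, c(nf, nt, 4L))
  hb_atoms <- function(r) vapply(c("N1", "N2", "O6", "N7"),
                                 function(nm) .atom_row(model, r, nm), 1L)
  rows <- lapply(seq_len(nt), function(t) lapply(1:4, function(k)
    hb_atoms(cols[t, k])))
  pair_ok <- function(xyz, don, acc) {
    d1 <- sqrt(sum((xyz[don[1L], ] - xyz[acc[3L], ])^2))
    d2 <- sqrt(sum((xyz[don[2L], ] - xyz[acc[4L], ])^2))
    d1 <= dmax && d2 <= dmax
  }
  for (f in seq_len(nf)) {
    xyz <- traj$frames[[f]]
    for (t in seq_len(nt)) {
      cen <- .tetrad_centroid(xyz, model, cols[t, ])
      for (k in 1:4) {
        nxt <- (k %% 4L) + 1L
        prv <- ((k - 2L) %% 4L) + 1L
        donate <- pair_ok(xyz, rows[[t]][[k]], rows[[t]][[nxt]])
        accept <- pair_ok(xyz, rows[[t]][[prv]], rows[[t]][[k]])
        broken[f, t, k] <- !donate && !accept
        d <- sqrt(sum((.base_com(xyz, model, cols[t, k]) - cen)^2))
        excess[f, t, k] <- d - ref_dist[t, k]
      }
    }
  }
  events <- list()
  for (t in seq_len(nt)) for (k in 1:4) {
    flags <- broken[, t, k]
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in seq_along(r$values)) {
      if (!r$values[s] || r$lengths[s] < hbond_frames) next
      ex <- excess[starts[s]:ends[s], t, k]
      if (max(ex) <= dist_thresh) next
      events[[length(events) + 1L]] <- data.frame(
        guanine = cols[t, k], tetrad = t, onset = starts[s], end = ends[s],
        persists_to_end = ends[s] == nf, max_excess = max(ex))
    }
  }
  if (!length(events))
    return(data.frame(guanine = integer(), tetrad = integer(), onset = integer(),
                      end = integer(), persists_to_end = logical(),
                      max_excess = numeric()))
  do.call(rbind, events)
}

#' Assemble a stability report and verdict
#'
#' Aggregates the descriptor series and detected events of one structure
#' into a report. The verdict is `"destabilized"` when at least one
#' disruption-class event - guanine expulsion or tetrad disruption -
#' persists to the final frame; cation leakage on its own is recorded but
#' does not flip the verdict unless it co-occurs with such a persistent
#' disruption (the combination seen in the single destabilized damaged-G4
#' replica).
#'
#' @param label structure label (e.g. a break-configuration label).
#' @param series named list of `g4_metric_series`; must contain at least
#'   `rmsd_tetrad`, `twist` and `com_distance`.
#' @param expulsion_events data frame from [detect_guanine_expulsion()].
#' @param leakage_events data frame from [detect_leakage()].
#' @param reference_twist optional reference twist series/distribution for
#'   the mode-shift summary.
#' @return A `g4_stability_report`.
#' @export
stability_report <- function(label, series, expulsion_events, leakage_events,
                             reference_twist = NULL) {
  required <- c("rmsd_tetrad", "twist", "com_distance")
  missing <- setdiff(required, names(series))
  if (length(missing))
    stop("missing mandatory series: ", paste(missing, collapse = ", "))
  tw <- twist_distribution(series$twist, reference = reference_twist)
  persistent_disruption <- (nrow(expulsion_events) > 0L &&
                              any(expulsion_events$persists_to_end))
  verdict <- if (persistent_disruption) "destabilized" else "stable"
  summaries <- list(
    rmsd_tetrad_p95 = as.numeric(stats::quantile(series$rmsd_tetrad$value, 0.95)),
    rmsd_tetrad_mean = mean(series$rmsd_tetrad$value),
    com_distance_mean = mean(series$com_distance$value),
    twist_mode = tw$mode, twist_width = tw$width, twist_shift = tw$shift)
  if (!is.null(series$rmsd_whole))
    summaries$rmsd_whole_mean <- mean(series$rmsd_whole$value)
  if (!is.null(series$adjacent_angle))
    summaries$adjacent_angle_mean <- .circular_mean_deg(series$adjacent_angle$value)
  if (!is.null(series$opposite_angle))
    summaries$opposite_angle_mean <- .circular_mean_deg(series$opposite_angle$value)
  structure(list(label = label, verdict = verdict,
                 events = list(
                   guanine_expulsion = expulsion_events,
                   cation_leakage = leakage_events),
                 summaries = summaries),
            class = "g4_stability_report")
}

#' @export
print.g4_stability_report <- function(x, ...) {
  cat("<g4_stability_report> ", x$label, ": ", toupper(x$verdict), "\n",
      "  expulsion events: ", nrow(x$events$guanine_expulsion),
      ", leakage events: ", nrow(x$events$cation_leakage), "\n",
      "  tetrad RMSD p95: ", signif(x$summaries$rmsd_tetrad_p95, 4),
      " A, twist mode: ", signif(x$summaries$twist_mode, 4), " deg\n",
      sep = "")
  invisible(x)
}

#' Serialize / deserialize a stability report (JSON)
#'
#' `read_report(write_report(x))` reproduces the report exactly.
#'
#' @param report a `g4_stability_report`.
#' @param path file path.
#' @return `write_report` returns `path` invisibly; `read_report` returns
#'   the `g4_stability_report`.
#' @export
write_report <- function(report, path) {
  obj <- list(label = report$label, verdict = report$verdict,
              events = report$events, summaries = report$summaries)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_df <- function(d, template) {
    if (is.null(d) || !length(d) || (is.list(d) && !length(d[[1]])))
      return(template)
    as.data.frame(d, stringsAsFactors = FALSE)
  }
  expul <- fix_df(obj$events$guanine_expulsion,
                  data.frame(guanine = integer(), tetrad = integer(),
                             onset = integer(), end = integer(),
                             persists_to_end = logical(), max_excess = numeric()))
  leak <- fix_df(obj$events$cation_leakage,
                 data.frame(ion = integer(), atom = integer(),
                            exit_frame = integer(), reentry_frame = integer(),
                            dwell_out = integer(), persists_to_end = logical()))
  summaries <- obj$summaries
  if (is.null(summaries$twist_shift)) summaries$twist_shift <- NA_real_
  structure(list(label = obj$label, verdict = obj$verdict,
                 events = list(guanine_expulsion = expul, cation_leakage = leak),
                 summaries = summaries),
            class = "g4_stability_report")
}

#' Analyze one trajectory end to end
#'
#' Full pipeline: topology detection on the first frame, descriptor series,
#' channel occupancy and leakage, expulsion detection, and the stability
#' verdict.
#'
#' @param traj a [g4_trajectory].
#' @param label structure label carried into the report.
#' @param thresholds a [g4_thresholds] list.
#' @param reference_twist optional reference twist series.
#' @param topology optional pre-computed `g4_topology`.
#' @return A `g4_stability_report`.
#' @export
analyze_trajectory <- function(traj, label = "structure",
                               thresholds = g4_thresholds(),
                               reference_twist = NULL, topology = NULL) {
  th <- thresholds
  if (is.null(topology)) {
    # instantaneous thermal noise can hide individual Hoogsteen bonds in a
    # single frame, so scan the first few frames and keep the richest topology
    best <- NULL
    for (f in seq_len(min(10L, n_frames(traj)))) {
      cand <- tryCatch(detect_topology(traj, frame = f, dmax = th$dmax,
                                       radius = th$radius, margin = th$margin),
                       error = function(e) NULL)
      if (!is.null(cand) &&
          (is.null(best) || length(cand$tetrads) > length(best$tetrads)))
        best <- cand
    }
    if (is.null(best)) stop("no tetrads detected in the first frames")
    topology <- best
  }
  sel_tet <- which(traj$model$atom$resno %in% unlist(lapply(topology$tetrads,
                                                            `[[`, "guanines")) &
                     toupper(traj$model$atom$elesy) != "H" &
                     !.is_ion_row(traj$model$atom))
  sel_all <- select_atoms(traj$model, "nucleic and heavy")
  series <- list(
    rmsd_tetrad = rmsd_series(traj, 1L, sel_tet),
    rmsd_whole = rmsd_series(traj, 1L, sel_all),
    twist = twist_series(traj, topology, 1L, 2L),
    com_distance = com_distance_series(traj, topology, 1L, 2L),
    adjacent_angle = angle_series(traj, topology, 1L, "adjacent"),
    opposite_angle = angle_series(traj, topology, 1L, "opposite"))
  leak <- if (length(traj$model$ions) && length(topology$tetrads) >= 2L) {
    detect_leakage(channel_occupancy(traj, topology, th$radius, th$margin),
                   min_out = th$min_out)
  } else {
    data.frame(ion = integer(), atom = integer(), exit_frame = integer(),
               reentry_frame = integer(), dwell_out = integer(),
               persists_to_end = logical())
  }
  expul <- detect_guanine_expulsion(traj, topology, dmax = th$dmax,
                                    dist_thresh = th$dist_thresh,
                                    hbond_frames = th$hbond_frames)
  stability_report(label, series, expul, leak, reference_twist = reference_twist)
}

#' Threshold configuration
#'
#' All tunable thresholds of the analysis pipeline, with their defaults:
#' Hoogsteen cutoff `dmax` (3.5 A), channel cylinder `radius` (3 A) and
#' axial `margin` (2 A), leakage hysteresis `min_out` (10 frames),
#' expulsion excess-distance `dist_thresh` (8 A) and persistence
#' `hbond_frames` (10 frames), histogram `bins` width (2 degrees).
#'
#' @param dmax,radius,margin,min_out,dist_thresh,hbond_frames,bins see above.
#' @return Named list of thresholds (class `g4_thresholds`).
#' @export
g4_thresholds <- function(dmax = 3.5, radius = 3, margin = 2, min_out = 10L,
                          dist_thresh = 8, hbond_frames = 10L, bins = 2) {
  structure(list(dmax = dmax, radius = radius, margin = margin,
                 min_out = as.integer(min_out), dist_thresh = dist_thresh,
                 hbond_frames = as.integer(hbond_frames), bins = bins),
            class = "g4_thresholds")
}

#' Read / write a threshold configuration file
#'
#' Plain `key = value` format, one threshold per line; `#` starts a comment.
#'
#' @param path file path.
#' @param thresholds a [g4_thresholds] list.
#' @return `read_thresholds` returns a `g4_thresholds`;
#'   `write_thresholds` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  th <- g4_thresholds()
  for (ln in lines) {
    kv <- strsplit(ln, "=")[[1]]
    if (length(kv) != 2L) stop("bad config line: '", ln, "'")
    key <- trimws(kv[1L]); val <- as.numeric(trimws(kv[2L]))
    if (!key %in% names(th)) stop("unknown threshold: '", key, "'")
    th[[key]] <- if (key %in% c("min_out", "hbond_frames")) as.integer(val) else val
  }
  th
}

#' @rdname read_thresholds
#' @export
write_thresholds <- function(thresholds, path) {
  writeLines(paste(names(thresholds), unlist(thresholds), sep = " = "), path)
  invisible(path)
}
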