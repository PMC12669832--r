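#' Straight-line interpolation of a detection gap
#'
#' @param p_before,p_after Length-2 numeric vectors, the observed positions
#'   flanking the gap (any consistent unit).
#' @param k_missing Number of missing frames to fill.
#' @return A `k_missing` x 2 matrix of evenly spaced points on the open
#'   segment between the flanks (endpoints excluded).
#' @export
#' @examples
#' interpolate_linear(c(0, 0), c(10, 0), 1)  # midpoint (5, 0)
interpolate_linear <- function(p_before, p_after, k_missing) {
  stopifnot(length(p_before) == 2, length(p_after) == 2, k_missing >= 1)
  f <- seq_len(k_missing) / (k_missing + 1)
  cbind(p_before[1] + f * (p_after[1] - p_before[1]),
        p_before[2] + f * (p_after[2] - p_before[2]))
}

#' Circular-arc interpolation of a detection gap near the arena wall
#'
#' A larva lost near the wall keeps following it, so the gap is filled along
#' the minor circular arc about the arena center, with the radius blended
#' linearly between the two flanking radii. If the flanks are antipodal
#' (within `tol` radians) the arc direction is undefined and the gap falls
#' back to straight-line interpolation, with a warning.
#'
#' @inheritParams interpolate_linear
#' @param center Arena center, length-2 numeric.
#' @param tol Angular tolerance for the antipodal degenerate case (radians).
#' @return A `k_missing` x 2 matrix of points at evenly spaced angles along
#'   the minor arc, endpoints excluded.
#' @export
#' @examples
#' interpolate_arc(c(25, 0), c(0, 25), 1, center = c(0, 0))  # 45 deg, r = 25
interpolate_arc <- function(p_before, p_after, k_missing, center,
                            tol = 1e-8) {
  stopifnot(length(p_before) == 2, length(p_after) == 2,
            length(center) == 2, k_missing >= 1)
  v0 <- p_before - center
  v1 <- p_after - center
  r0 <- sqrt(sum(v0^2)); r1 <- sqrt(sum(v1^2))
  stopifnot(r0 > 0, r1 > 0)
  a0 <- atan2(v0[2], v0[1])
  a1 <- atan2(v1[2], v1[1])
  da <- (a1 - a0 + pi) %% (2 * pi) - pi  # signed minor-arc angle in (-pi, pi]
  if (abs(abs(da) - pi) < tol) {
    warning("antipodal arc endpoints; falling back to linear interpolation")
    return(interpolate_linear(p_before, p_after, k_missing))
  }
  f <- seq_len(k_missing) / (k_missing + 1)
  ang <- a0 + f * da
  rad <- r0 + f * (r1 - r0)
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}

# maximal runs of missing frames in a raw track; row indices
find_gaps <- function(track) {
  miss <- is.na(track$x_px)
  if (!any(miss)) return(list())
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  lapply(idx, function(i) c(start = starts[i], end = ends[i]))
}

#' Classify a detection gap
#'
#' Decides how a maximal run of missing frames is to be filled, in priority
#' order: a gap with no detection after it is held at the last coordinate
#' (`end_hold`); a gap whose flanking positions both lie within the
#' container-proximity radius during the pre-search or investigation phase is
#' read as container contact (`container_contact`); a gap whose flanks both
#' lie beyond the edge-gap threshold is wall-following (`arc`); a gap whose
#' flanking frames are edge-flagged gets edge-zone membership without
#' coordinates (`edge_assigned`); anything else is a straight line
#' (`linear`).
#'
#' @param track A [raw_track()].
#' @param gap Length-2 integer vector `(start, end)` of row indices of the
#'   missing run within `track`, as produced internally; the flanking rows
#'   `start - 1` and `end + 1` must be observed (or absent, for a terminal
#'   gap).
#' @param config An [arena_config()].
#' @param events Optional [event_log()]; without it the container-contact
#'   class cannot be assigned.
#' @return A single string naming the gap class.
#' @export
classify_gap <- function(track, gap, config, events = NULL) {
  stopifnot(inherits(track, "raw_track"), inherits(config, "arena_config"))
  i0 <- gap[[1]]; i1 <- gap[[2]]
  if (i0 <= 1) stop("track starts with missing frames; no observation before gap")
  r_of <- function(i) {
    sqrt((track$x_px[i] - config$center_x_px)^2 +
         (track$y_px[i] - config$center_y_px)^2) * config$px_to_mm
  }
  if (i1 >= nrow(track)) return("end_hold")
  r_before <- r_of(i0 - 1)
  r_after <- r_of(i1 + 1)
  if (!is.null(events) && !events$excluded) {
    t0 <- track$frame[i0] / config$frame_rate
    t1 <- track$frame[i1] / config$frame_rate
    in_contact_window <- t0 >= events$t_container_placed &&
      t1 < events$t_container_removed
    if (in_contact_window &&
        r_before <= config$container_proximity_mm &&
        r_after <= config$container_proximity_mm) {
      return("container_contact")
    }
  }
  if (r_before > config$edge_gap_threshold_mm &&
      r_after > config$edge_gap_threshold_mm) {
    return("arc")
  }
  if (isTRUE(track$edge_flag[i0 - 1]) && isTRUE(track$edge_flag[i1 + 1])) {
    return("edge_assigned")
  }
  "linear"
}

#' Repair a raw track: fill every gap and convert to millimeters
#'
#' Applies [classify_gap()] to every missing run and fills it accordingly;
#' converts pixel coordinates to millimeters re-centered on the arena center
#' (so the distance to center is `sqrt(x_mm^2 + y_mm^2)`), and derives the
#' per-frame time axis `t_s = frame / frame_rate`.
#'
#' Fill rules per class: `end_hold` repeats the last tracked coordinate;
#' `container_contact` holds the position at which the larva vanished near
#' the container; `arc` uses [interpolate_arc()]; `linear` uses
#' [interpolate_linear()]; `edge_assigned` frames have no recoverable
#' position (`x_mm`/`y_mm` are `NA`) but are assigned the midpoint radius of
#' the edge zone so that they contribute dwell time to the edge zone while
#' contributing nothing to track length.
#'
#' @inheritParams classify_gap
#' @param pad_to_frame Optional frame index up to which the track is padded
#'   by repeating the last coordinate (`held`), for recordings where the
#'   tracker lost the larva before the experiment ended.
#' @return A tibble of class `repaired_track` with columns `larva_id`,
#'   `frame`, `t_s`, `x_mm`, `y_mm`, `r_mm`, `provenance`; provenance is one
#'   of `observed`, `linear`, `arc`, `held`, `edge_assigned`,
#'   `container_contact`.
#' @export
repair_track <- function(track, config, events = NULL, pad_to_frame = NULL) {
  stopifnot(inherits(track, "raw_track"), inherits(config, "arena_config"))
  n <- nrow(track)
  x <- (track$x_px - config$center_x_px) * config$px_to_mm
  y <- (track$y_px - config$center_y_px) * config$px_to_mm
  prov <- rep("observed", n)
  gaps <- find_gaps(track)
  for (gap in gaps) {
    i0 <- gap[[1]]; i1 <- gap[[2]]
    cls <- classify_gap(track, gap, config, events)
    k <- i1 - i0 + 1
    fill <- switch(cls,
      end_hold = {
        prov[i0:i1] <- "held"
        matrix(c(x[i0 - 1], y[i0 - 1]), nrow = k, ncol = 2, byrow = TRUE)
      },
      container_contact = {
        prov[i0:i1] <- "container_contact"
        matrix(c(x[i0 - 1], y[i0 - 1]), nrow = k, ncol = 2, byrow = TRUE)
      },
      arc = {
        prov[i0:i1] <- "arc"
        interpolate_arc(c(x[i0 - 1], y[i0 - 1]), c(x[i1 + 1], y[i1 + 1]),
                        k, center = c(0, 0))
      },
      edge_assigned = {
        prov[i0:i1] <- "edge_assigned"
        matrix(NA_real_, nrow = k, ncol = 2)
      },
      linear = {
        prov[i0:i1] <- "linear"
        interpolate_linear(c(x[i0 - 1], y[i0 - 1]), c(x[i1 + 1], y[i1 + 1]), k)
      },
      stop("unknown gap class: ", cls)
    )
    x[i0:i1] <- fill[, 1]
    y[i0:i1] <- fill[, 2]
  }
  frame <- track$frame
  if (!is.null(pad_to_frame) && pad_to_frame > frame[n]) {
    extra <- seq.int(frame[n] + 1, pad_to_frame)
    frame <- c(frame, extra)
    x <- c(x, rep(x[n], length(extra)))
    y <- c(y, rep(y[n], length(extra)))
    prov <- c(prov, rep("held", length(extra)))
  }
  r <- sqrt(x^2 + y^2)
  # edge-assigned frames: zone membership is known, position is not
  edge_mid <- (max(config$zone_edges_mm) + config$arena_radius_mm) / 2
  r[prov == "edge_assigned"] <- edge_mid
  out <- tibble::tibble(
    larva_id = track$larva_id[1],
    frame = frame,
    t_s = frame / config$frame_rate,
    x_mm = x, y_mm = y, r_mm = r,
    provenance = prov
  )
  class(out) <- c("repaired_track", class(out))
  out
}
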