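#' Distance categories and zones
#'
#' The arena radius is divided into seven half-open distance categories
#' `[0,4), [4,8), [8,12), [12,16), [16,20), [20,24)` and `>=24` mm from the
#' center; pairwise unions give the four behavioral zones: center (0-8 mm),
#' search (8-16 mm), neutral (16-24 mm) and edge (>24 mm).
#'
#' @param r_mm Numeric vector of distances to the arena center.
#' @param edges Ordered inner category boundaries (mm).
#' @return `category_of`: an ordered factor over the seven category labels.
#'   `zone_of`: a factor with levels `center`, `search`, `neutral`, `edge`.
#' @export
#' @examples
#' category_of(c(5, 8, 27))   # "4-8", "8-12", ">24"
#' zone_of(c(5, 8, 27))       # center, search, edge
category_of <- function(r_mm, edges = c(4, 8, 12, 16, 20, 24)) {
  stopifnot(all(r_mm >= 0 | is.na(r_mm)))
  labs <- category_labels(edges)
  idx <- findInterval(r_mm, edges) + 1L  # half-open [lo, hi)
  factor(labs[idx], levels = labs, ordered = TRUE)
}

category_labels <- function(edges = c(4, 8, 12, 16, 20, 24)) {
  lo <- c(0, edges)
  c(paste0(lo[-length(lo)], "-", edges), paste0(">", edges[length(edges)]))
}

zone_labels <- function() c("center", "search", "neutral", "edge")

#' @rdname category_of
#' @export
zone_of <- function(r_mm, edges = c(4, 8, 12, 16, 20, 24)) {
  idx <- findInterval(r_mm, edges) + 1L
  z <- zone_labels()[pmin((idx + 1L) %/% 2L, 4L)]
  factor(z, levels = zone_labels())
}

# rows of a repaired track falling in the half-open time window [t0, t1)
window_rows <- function(track, window) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  which(track$t_s >= window[1] & track$t_s < window[2])
}

#' Dwell time per distance category
#'
#' Each frame inside the window contributes `1/frame_rate` seconds to the
#' category of its distance to center; at 2 frames per second the
#' attribution error at a category transition is at most half a second.
#'
#' @param track A `repaired_track`.
#' @param window Half-open time window `c(t0, t1)` in seconds.
#' @param config An [arena_config()].
#' @return Named numeric vector of seconds, one entry per category.
#' @export
dwell_times <- function(track, window, config) {
  rows <- window_rows(track, window)
  labs <- category_labels(config$zone_edges_mm)
  out <- stats::setNames(numeric(length(labs)), labs)
  if (length(rows) == 0) return(out)
  tab <- table(category_of(track$r_mm[rows], config$zone_edges_mm))
  out[names(tab)] <- as.numeric(tab) / config$frame_rate
  out
}

#' Collapse per-category dwell times into the four zones
#'
#' @param time_per_category Named vector as returned by [dwell_times()] (or
#'   the per-category track lengths); must have 7 entries.
#' @return Named vector over `center`, `search`, `neutral`, `edge`.
#' @export
zone_times <- function(time_per_category) {
  stopifnot(length(time_per_category) == 7)
  stats::setNames(c(
    sum(time_per_category[1:2]),
    sum(time_per_category[3:4]),
    sum(time_per_category[5:6]),
    time_per_category[7]
  ), zone_labels())
}

#' Track length within a window, with per-category attribution
#'
#' Sums the Euclidean distances between consecutive coordinates. Each step
#' is attributed to the distance category of its starting frame. Steps into
#' or out of frames without a recoverable position (edge-assigned frames)
#' contribute nothing.
#'
#' @inheritParams dwell_times
#' @return List with `total_mm` and the named vector `per_category_mm`.
#' @export
track_length <- function(track, window, config) {
  rows <- window_rows(track, window)
  labs <- category_labels(config$zone_edges_mm)
  per <- stats::setNames(numeric(length(labs)), labs)
  if (length(rows) < 2) return(list(total_mm = 0, per_category_mm = per))
  i <- rows[-length(rows)]
  step <- sqrt(diff(track$x_mm[rows])^2 + diff(track$y_mm[rows])^2)
  step[is.na(step)] <- 0
  cat_i <- category_of(track$r_mm[i], config$zone_edges_mm)
  sums <- tapply(step, cat_i, sum, default = 0)
  per[names(sums)] <- as.numeric(sums)
  list(total_mm = sum(step), per_category_mm = per)
}

#' Per-frame speed and its summary
#'
#' Instantaneous speed is the step length between consecutive frames times
#' the frame rate; the plotted trace is a 10-frame moving average, the
#' scalar summary is the median of the instantaneous speed over the window.
#' Steps with no recoverable position are `NA`.
#'
#' @inheritParams dwell_times
#' @param avg_frames Width of the moving-average window for the smoothed
#'   trace.
#' @return List with `series` (tibble `t_s`, `speed_mm_s`, `speed_smooth`)
#'   and `median_mm_s`.
#' @export
speed_series <- function(track, window, config, avg_frames = 10) {
  rows <- window_rows(track, window)
  if (length(rows) < 2) {
    return(list(series = tibble::tibble(t_s = numeric(), speed_mm_s = numeric(),
                                        speed_smooth = numeric()),
                median_mm_s = NA_real_))
  }
  i <- rows[-length(rows)]
  step <- sqrt(diff(track$x_mm[rows])^2 + diff(track$y_mm[rows])^2)
  v <- step * config$frame_rate
  smooth <- stats::filter(v, rep(1 / avg_frames, avg_frames), sides = 1)
  list(
    series = tibble::tibble(t_s = track$t_s[i], speed_mm_s = v,
                            speed_smooth = as.numeric(smooth)),
    median_mm_s = stats::median(v, na.rm = TRUE)
  )
}

#' Count center-zone revisits
#'
#' A revisit is an inward crossing of the center-zone border: a consecutive
#' frame pair with the first distance strictly outside and the second at or
#' inside the radius. Starting inside the zone does not count.
#'
#' @inheritParams dwell_times
#' @param radius_mm Center-zone radius.
#' @return Integer count.
#' @export
#' @examples
#' tr <- tibble::tibble(t_s = 0:5 / 2, r_mm = c(25, 12, 7, 9, 7, 30),
#'                      x_mm = 0, y_mm = 0)
#' count_revisits(tr, c(0, 3), radius_mm = 8)  # 2
count_revisits <- function(track, window, radius_mm = 8) {
  rows <- window_rows(track, window)
  if (length(rows) < 2) return(0L)
  r <- track$r_mm[rows]
  sum(r[-length(r)] > radius_mm & r[-1] <= radius_mm)
}

#' Count stops
#'
#' A stop begins at the first frame whose displacement to the next position
#' falls below `stop_displacement_mm`. A stop ends only once the larva has
#' moved continuously -- every one of the next `stop_window_frames` steps at
#' or above the threshold; stop phases separated by `stop_window_frames`
#' frames or fewer are counted as a single stop. Both rules reduce to one
#' grouping: sub-threshold runs separated by more than `stop_window_frames`
#' moving steps form distinct stops.
#'
#' @inheritParams dwell_times
#' @return List with `n_stops` and `intervals`, a tibble of the first/last
#'   frame index of each (merged) stop.
#' @export
count_stops <- function(track, window, config) {
  rows <- window_rows(track, window)
  if (length(rows) < 2) {
    return(list(n_stops = 0L,
                intervals = tibble::tibble(start_frame = integer(),
                                           end_frame = integer())))
  }
  step <- sqrt(diff(track$x_mm[rows])^2 + diff(track$y_mm[rows])^2)
  frames <- track$frame[rows][-length(rows)]
  ok <- !is.na(step)
  sub <- step < config$stop_displacement_mm & ok
  if (!any(sub)) {
    return(list(n_stops = 0L,
                intervals = tibble::tibble(start_frame = integer(),
                                           end_frame = integer())))
  }
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sub_idx <- which(r$values)
  # group consecutive sub-threshold runs separated by <= stop_window_frames
  # moving steps into one stop
  grp <- cumsum(c(TRUE, vapply(seq_along(sub_idx)[-1], function(j) {
    gap <- starts[sub_idx[j]] - ends[sub_idx[j - 1]] - 1
    gap > config$stop_window_frames
  }, logical(1))))
  intervals <- tibble::tibble(
    start_frame = frames[starts[sub_idx][!duplicated(grp)]],
    end_frame = frames[ends[sub_idx][rev(!duplicated(rev(grp)))]]
  )
  list(n_stops = max(grp), intervals = intervals)
}

#' Mean distance to center in 1-minute bins
#'
#' @inheritParams dwell_times
#' @param bin_s Bin width in seconds (default 60).
#' @return Tibble with `bin`, `t_start_s`, `duration_s`, `mean_r_mm`; a
#'   trailing partial bin is reported with its actual duration.
#' @export
minute_bins <- function(track, window, bin_s = 60) {
  rows <- window_rows(track, window)
  if (length(rows) == 0) {
    return(tibble::tibble(bin = integer(), t_start_s = numeric(),
                          duration_s = numeric(), mean_r_mm = numeric()))
  }
  t <- track$t_s[rows]
  idx <- floor((t - window[1]) / bin_s)
  u <- sort(unique(idx))
  tibble::tibble(
    bin = u + 1L,
    t_start_s = window[1] + u * bin_s,
    duration_s = vapply(u, function(b) {
      min(window[2], window[1] + (b + 1) * bin_s) - (window[1] + b * bin_s)
    }, numeric(1)),
    mean_r_mm = as.numeric(tapply(track$r_mm[rows], idx, mean))
  )
}

#' Search score: preference for the search zone over the edge zone
#'
#' The time spent in the edge zone is subtracted from the time spent in the
#' search zone and divided by the total time analyzed. Positive values mean
#' a search-zone preference (residency around the former stimulus
#' location), negative values an edge preference (wall-hugging); the score
#' is bounded in `[-1, 1]`.
#'
#' @param time_per_zone_s Named vector over the four zones (see
#'   [zone_times()]), seconds.
#' @param total_time_s Total analyzed time, seconds.
#' @return Score in `[-1, 1]`.
#' @export
#' @examples
#' search_score(c(center = 0, search = 105, neutral = 0, edge = 195), 300)
search_score <- function(time_per_zone_s, total_time_s) {
  stopifnot(total_time_s > 0, all(time_per_zone_s >= 0),
            all(time_per_zone_s <= total_time_s + 1e-9))
  unname((time_per_zone_s[["search"]] - time_per_zone_s[["edge"]]) /
           total_time_s)
}

#' All per-phase metrics for one larva
#'
#' Runs every metric over each phase window of the timeline and returns one
#' row per phase. Scalar metrics are plain columns; the binned quantities
#' (per-category dwell and length, per-zone dwell, per-minute mean
#' distances) are list columns.
#'
#' @param track A `repaired_track`.
#' @param timeline An `experiment_timeline` from [segment_phases()].
#' @param config An [arena_config()].
#' @return A tibble with one row per phase.
#' @export
phase_metrics <- function(track, timeline, config) {
  stopifnot(inherits(timeline, "experiment_timeline"))
  rows <- lapply(names(timeline), function(ph) {
    w <- timeline[[ph]]
    dur <- diff(w)
    tpc <- dwell_times(track, w, config)
    tpz <- zone_times(tpc)
    len <- track_length(track, w, config)
    spd <- speed_series(track, w, config)
    stops <- count_stops(track, w, config)
    wr <- window_rows(track, w)
    tibble::tibble(
      larva_id = track$larva_id[1],
      phase = ph,
      duration_s = dur,
      median_r_mm = if (length(wr)) stats::median(track$r_mm[wr]) else NA_real_,
      total_length_mm = len$total_mm,
      median_speed_mm_s = spd$median_mm_s,
      time_in_center_zone_s = tpz[["center"]],
      n_revisits = count_revisits(track, w, config$center_zone_radius_mm),
      n_stops = stops$n_stops,
      search_score = if (dur > 0) search_score(tpz, dur) else NA_real_,
      time_per_category_s = list(tpc),
      length_per_category_mm = list(len$per_category_mm),
      time_per_zone_s = list(tpz),
      r_per_minute_mm = list(minute_bins(track, w))
    )
  })
  dplyr::bind_rows(rows)
}
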