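#' Configuration of the run-and-turn track simulator
#'
#' The simulator emulates what the analysis pipeline assumes about real
#' recordings: a 2 frames/s centroid track in a 6 cm circular arena, with
#' wall-hugging (thigmotactic) crawling during baseline, center-orbiting
#' movement during local search, stop episodes, and detection dropout.
#' Larvae move as run-and-turn agents: per frame the heading is perturbed
#' by a persistence-limited noise term and steered toward a target radius
#' (near the wall in baseline mode, at the attraction ring in search mode);
#' the steering gain tapers off near the target ring so that the agent
#' orbits it rather than sitting on it.
#'
#' Default speeds are the medians observed in apple-juice experiments
#' (0.64 mm/s baseline, 0.92 mm/s search); the default dropout rate matches
#' the mean detection-failure fraction of real recordings (26%); the default
#' event times give a 5 min baseline, a 7 min 16 s pre-search (the mean time
#' to find a fermented-yeast container), a 1 min investigation and a 5 min
#' analyzed search window.
#'
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @param n_larvae Cohort size.
#' @param frame_rate Frames per second.
#' @param arena_radius_mm Arena radius.
#' @param px_to_mm,center_x_px,center_y_px Geometry used to express the
#'   output in tracker pixel coordinates.
#' @param mode `"baseline_thigmotaxis"`, `"local_search"` or `"neutral"`
#'   (no radial bias).
#' @param search_after_removal If `TRUE` the agent switches from the base
#'   `mode` to `local_search` at the container-removed event, emulating a
#'   larva that starts a local search.
#' @param mean_speed_mm_s,search_speed_mm_s,speed_sd_mm_s Per-frame crawl
#'   speed distribution in the baseline-like and search modes.
#' @param heading_persistence Concentration of the per-frame heading change
#'   (heading noise has standard deviation `1/sqrt(heading_persistence)`
#'   radians).
#' @param wall_attraction_strength,wall_offset_mm Steering gain toward the
#'   wall-following ring at `arena_radius_mm - wall_offset_mm`.
#' @param ring_attraction_radius_mm,ring_attraction_strength Radius and
#'   steering gain of the attraction ring in search mode.
#' @param steering_taper_mm Distance scale over which the steering gain
#'   fades near the target ring.
#' @param stop_rate_per_min Stop-initiation rate; stop durations are
#'   `1 + Poisson(stop_duration_mean_frames - 1)` frames.
#' @param stop_duration_mean_frames Mean stop duration in frames.
#' @param stop_jitter_mm Maximal per-frame displacement while stopped
#'   (below any sensible stop threshold).
#' @param dropout_rate Expected fraction of frames lost to detection
#'   failure.
#' @param mean_gap_frames Mean length of a dropout run (geometric).
#' @param wall_dropout_multiplier Relative dropout propensity beyond the
#'   edge-gap threshold radius, to exercise arc interpolation.
#' @param t_container_placed,t_first_contact,t_container_removed Event
#'   times (s) written to the generated event log.
#' @param search_window_s Recording continues this long past container
#'   removal.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_larvae = 15,
                       frame_rate = 2,
                       arena_radius_mm = 30,
                       px_to_mm = 0.2673,
                       center_x_px = 512,
                       center_y_px = 512,
                       mode = c("baseline_thigmotaxis", "local_search", "neutral"),
                       search_after_removal = FALSE,
                       mean_speed_mm_s = 0.64,
                       search_speed_mm_s = 0.92,
                       speed_sd_mm_s = 0.25,
                       heading_persistence = 4,
                       wall_attraction_strength = 0.35,
                       wall_offset_mm = 2,
                       ring_attraction_radius_mm = 12,
                       ring_attraction_strength = 0.35,
                       steering_taper_mm = 4,
                       stop_rate_per_min = 1.5,
                       stop_duration_mean_frames = 6,
                       stop_jitter_mm = 0.02,
                       dropout_rate = 0.26,
                       mean_gap_frames = 4,
                       wall_dropout_multiplier = 1,
                       t_container_placed = 300,
                       t_first_contact = 736,
                       t_container_removed = 796,
                       search_window_s = 300) {
  mode <- match.arg(mode)
  stopifnot(
    n_larvae >= 1, frame_rate > 0, arena_radius_mm > 0, px_to_mm > 0,
    mean_speed_mm_s >= 0, search_speed_mm_s >= 0, speed_sd_mm_s >= 0,
    heading_persistence > 0, wall_attraction_strength >= 0,
    ring_attraction_strength >= 0, ring_attraction_radius_mm > 0,
    stop_rate_per_min >= 0, stop_duration_mean_frames >= 1,
    dropout_rate >= 0, dropout_rate < 1, mean_gap_frames >= 1,
    t_container_placed < t_first_contact,
    t_first_contact < t_container_removed
  )
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

wrap_angle <- function(a) (a + pi) %% (2 * pi) - pi

#' Simulate one larval track and its event log
#'
#' Runs the run-and-turn agent of [sim_config()] for the full experiment
#' duration and returns the track in pixel units with dropout applied,
#' alongside the event log -- exactly the pair of inputs the pipeline
#' expects for a real larva.
#'
#' @param config A [sim_config()].
#' @param larva_id Label for the generated animal.
#' @return List with `track` (a [raw_track()]) and `events` (an
#'   [event_log()]).
#' @export
simulate_larva <- function(config, larva_id = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fr <- config$frame_rate
  n <- floor((config$t_container_removed + config$search_window_s) * fr) + 1
  x <- numeric(n); y <- numeric(n)
  h <- stats::runif(1, -pi, pi)
  noise <- stats::rnorm(n, 0, 1 / sqrt(config$heading_persistence))
  z_speed <- stats::rnorm(n)
  u_stop <- stats::runif(n)
  u_jit <- stats::runif(n, 0, config$stop_jitter_mm)
  p_stop <- config$stop_rate_per_min / (60 * fr)
  # per-frame behavioral mode (vectorized): search mode sets the attraction
  # ring and speed; baseline sets the wall-following ring
  t_frames <- (seq_len(n) - 1) / fr
  searching <- config$mode == "local_search" |
    (config$search_after_removal & t_frames >= config$t_container_removed)
  target_r <- ifelse(searching, config$ring_attraction_radius_mm,
                     config$arena_radius_mm - config$wall_offset_mm)
  gain <- ifelse(searching, config$ring_attraction_strength,
                 if (config$mode == "neutral") 0
                 else config$wall_attraction_strength)
  mu_v <- ifelse(searching, config$search_speed_mm_s, config$mean_speed_mm_s)
  R <- config$arena_radius_mm
  taper <- config$steering_taper_mm
  sd_v <- config$speed_sd_mm_s
  stop_left <- 0L
  px <- 0; py <- 0  # larvae start at the arena center
  for (i in 2:n) {
    h <- h + noise[i]
    r <- sqrt(px * px + py * py)
    if (gain[i] > 0 && r > 1e-9) {
      bearing <- atan2(py, px)
      if (r > target_r[i]) bearing <- bearing + pi  # head inward
      w <- abs(r - target_r[i]) / taper
      if (w > 1) w <- 1
      h <- h + gain[i] * w * wrap_angle(bearing - h)
    }
    if (stop_left > 0L) {
      step <- u_jit[i]
      stop_left <- stop_left - 1L
    } else if (u_stop[i] < p_stop) {
      stop_left <- 1L + stats::rpois(1, config$stop_duration_mean_frames - 1)
      step <- u_jit[i]
    } else {
      step <- max(0, mu_v[i] + sd_v * z_speed[i]) / fr
    }
    qx <- px + step * cos(h)
    qy <- py + step * sin(h)
    rp <- sqrt(qx * qx + qy * qy)
    if (rp > R) {
      # reflective wall: fold the radius back and mirror the heading about
      # the wall tangent at the contact angle
      phi <- atan2(qy, qx)
      rf <- 2 * R - rp
      if (rf < 0) rf <- 0
      qx <- rf * cos(phi)
      qy <- rf * sin(phi)
      h <- wrap_angle(2 * phi + pi - h)
    }
    px <- qx; py <- qy
    x[i] <- px; y[i] <- py
  }
  keep <- rep(TRUE, n)
  if (config$dropout_rate > 0) {
    # renewal correction: only frames outside a gap can start one, so the
    # start probability is inflated to make the realized missing fraction
    # match dropout_rate in expectation
    p_start <- config$dropout_rate /
      (config$mean_gap_frames * (1 - config$dropout_rate))
    r_all <- sqrt(x^2 + y^2)
    u_drop <- stats::runif(n)
    # 21.3 mm is the edge-gap threshold of the analysis; dropout beyond it
    # can be elevated to exercise arc interpolation
    i <- 2L
    while (i < n) {
      mult <- if (r_all[i] > 21.3) config$wall_dropout_multiplier else 1
      if (u_drop[i] < p_start * mult) {
        len <- 1L + stats::rgeom(1, 1 / config$mean_gap_frames)
        keep[i:min(i + len - 1L, n - 1L)] <- FALSE
        i <- i + len
      }
      i <- i + 1L
    }
  }
  track <- raw_track(
    larva_id,
    frame = (0:(n - 1))[keep],
    x_px = x[keep] / config$px_to_mm + config$center_x_px,
    y_px = y[keep] / config$px_to_mm + config$center_y_px
  )
  events <- event_log(larva_id, 0, config$t_container_placed,
                      config$t_first_contact, config$t_container_removed)
  list(track = track, events = events)
}

#' Simulate a cohort of larvae
#'
#' Generates `n` independent larvae; each larva's seed is derived from the
#' master seed as `(seed + i * 99991) mod (2^31 - 1)` so that cohorts are
#' reproducible and individual larvae re-simulable in isolation.
#'
#' @param config A [sim_config()]; its `seed` is the master seed.
#' @param n Number of larvae (defaults to `config$n_larvae`).
#' @return List with `tracks` and `events` (named lists, one entry per
#'   larva) and `config`, the echoed configuration.
#' @export
simulate_cohort <- function(config, n = config$n_larvae) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  sims <- lapply(seq_len(n), function(i) {
    child <- config
    child$seed <- (config$seed + i * 99991) %% (2^31 - 1)
    simulate_larva(child, larva_id = sprintf("sim%03d", i))
  })
  list(
    tracks = stats::setNames(lapply(sims, `[[`, "track"),
                             vapply(sims, function(s) s$track$larva_id[1],
                                    character(1))),
    events = stats::setNames(lapply(sims, `[[`, "events"),
                             vapply(sims, function(s) s$events$larva_id,
                                    character(1))),
    config = config
  )
}

#' Arena configuration matching a simulator configuration
#'
#' @param config A [sim_config()].
#' @return An [arena_config()] with the simulator's geometry.
#' @export
arena_config_for <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arena_config(
    center_x_px = config$center_x_px, center_y_px = config$center_y_px,
    px_to_mm = config$px_to_mm, frame_rate = config$frame_rate,
    arena_radius_mm = config$arena_radius_mm
  )
}
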