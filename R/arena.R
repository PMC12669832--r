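#' Arena geometry and analysis constants
#'
#' Bundles everything the pipeline needs to know about the recording setup:
#' where the arena center sits in pixel coordinates, the pixel-to-millimeter
#' scale, the frame rate, and the thresholds used by gap repair and the
#' behavioral metrics. Defaults correspond to the standard 6 cm circular
#' arena recorded at 2 frames per second on a FIM table.
#'
#' @param center_x_px,center_y_px Arena center in pixel coordinates of the
#'   tracking table.
#' @param px_to_mm Scale factor, millimeters per pixel.
#' @param frame_rate Frames per second of the recording.
#' @param arena_radius_mm Arena radius (the lid defining the walkable area has
#'   a diameter of 6 cm).
#' @param zone_edges_mm Ordered inner boundaries of the seven concentric
#'   distance categories; the last category is unbounded above. The four
#'   zones are pairwise unions of the categories: center (0-8 mm),
#'   search (8-16 mm), neutral (16-24 mm), edge (>24 mm).
#' @param center_zone_radius_mm Radius of the center zone used for the
#'   revisit count and for container-proximity during gap repair. See
#'   [center_zone_radius_cm()] for how the default is derived.
#' @param edge_gap_threshold_mm Radial distance above which a detection gap
#'   whose flanking positions both lie beyond it is interpolated along a
#'   circular arc (wall-following) rather than a straight line.
#' @param stop_displacement_mm Per-frame displacement below which the larva
#'   is considered stopped.
#' @param stop_window_frames Number of consecutive moving frames that
#'   terminates a stop; stops separated by at most this many frames merge.
#' @param container_proximity_mm Radius around the center within which a
#'   disappearance during the pre-search or investigation phase is read as
#'   container contact. Defaults to `center_zone_radius_mm`.
#'
#' @return An object of class `arena_config` (a validated list).
#' @export
#' @examples
#' cfg <- arena_config()
#' cfg$px_to_mm
arena_config <- function(center_x_px = 512,
                         center_y_px = 512,
                         px_to_mm = 0.2673,
                         frame_rate = 2,
                         arena_radius_mm = 30,
                         zone_edges_mm = c(4, 8, 12, 16, 20, 24),
                         center_zone_radius_mm = 8,
                         edge_gap_threshold_mm = 21.3,
                         stop_displacement_mm = 0.05,
                         stop_window_frames = 5,
                         container_proximity_mm = center_zone_radius_mm) {
  stopifnot(
    px_to_mm > 0, frame_rate > 0, arena_radius_mm > 0,
    length(zone_edges_mm) >= 1, all(diff(zone_edges_mm) > 0),
    center_zone_radius_mm > 0, edge_gap_threshold_mm > 0,
    stop_displacement_mm > 0, stop_window_frames >= 1
  )
  structure(
    list(
      center_x_px = center_x_px, center_y_px = center_y_px,
      px_to_mm = px_to_mm, frame_rate = frame_rate,
      arena_radius_mm = arena_radius_mm,
      zone_edges_mm = zone_edges_mm,
      center_zone_radius_mm = center_zone_radius_mm,
      edge_gap_threshold_mm = edge_gap_threshold_mm,
      stop_displacement_mm = stop_displacement_mm,
      stop_window_frames = as.integer(stop_window_frames),
      container_proximity_mm = container_proximity_mm
    ),
    class = "arena_config"
  )
}

#' @export
print.arena_config <- function(x, ...) {
  cat("<arena_config>\n")
  cat(sprintf("  center: (%g, %g) px, scale %g mm/px, %g fps\n",
              x$center_x_px, x$center_y_px, x$px_to_mm, x$frame_rate))
  cat(sprintf("  arena radius %g mm; category edges %s mm\n",
              x$arena_radius_mm, paste(x$zone_edges_mm, collapse = ", ")))
  cat(sprintf("  center zone %g mm; arc threshold %g mm; stop < %g mm / %d frames\n",
              x$center_zone_radius_mm, x$edge_gap_threshold_mm,
              x$stop_displacement_mm, x$stop_window_frames))
  invisible(x)
}

#' Read an arena configuration from YAML or JSON
#'
#' Any field of [arena_config()] may be given; unspecified fields keep their
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `arena_config`.
#' @export
read_arena_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(arena_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown arena_config fields: ", paste(bad, collapse = ", "))
  }
  do.call(arena_config, vals)
}

#' Derivation of the center-zone radius
#'
#' The revisit boundary is not a free parameter: it is the container radius
#' plus the median larval body length plus a slack term absorbing larval size
#' variation and imprecise container placement. With the standard values
#' 0.35 + 0.35 + 0.10 cm this gives 0.80 cm, i.e. the 8 mm default of
#' [arena_config()].
#'
#' @param container_radius_cm Radius of the stimulus container.
#' @param median_larva_cm Median larval body length.
#' @param slack_cm Allowance for size variance and placement error.
#' @return Radius in cm.
#' @export
#' @examples
#' center_zone_radius_cm()  # 0.8
center_zone_radius_cm <- function(container_radius_cm = 0.35,
                                  median_larva_cm = 0.35,
                                  slack_cm = 0.10) {
  stopifnot(container_radius_cm >= 0, median_larva_cm >= 0, slack_cm >= 0)
  container_radius_cm + median_larva_cm + slack_cm
}
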