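#' Raw centroid track for one larva
#'
#' A raw track is the per-frame centroid sequence a tracker emits, in pixel
#' units, with detection failures kept as explicit missing frames. The frame
#' axis is completed: every integer frame between the first and last observed
#' detection is present, undetected frames carrying `NA` coordinates. Frames
#' before the first and after the last detection are outside the track.
#'
#' @param larva_id Label identifying the animal.
#' @param frame Integer frame indices of observed detections.
#' @param x_px,y_px Centroid coordinates in pixels.
#' @param edge_flag Optional logical per observed frame, marking frames
#'   verified to lie at the arena wall (used by gap repair to assign
#'   edge-zone membership when the exact position is unrecoverable).
#' @return A tibble of class `raw_track` with columns `larva_id`, `frame`,
#'   `x_px`, `y_px`, `edge_flag`, one row per frame in `[min(frame), max(frame)]`.
#' @export
raw_track <- function(larva_id, frame, x_px, y_px, edge_flag = FALSE) {
  stopifnot(length(frame) >= 1, length(x_px) == length(frame),
            length(y_px) == length(frame))
  frame <- as.integer(frame)
  if (anyDuplicated(frame)) {
    stop("duplicate frame index for larva '", larva_id, "': ",
         paste(unique(frame[duplicated(frame)]), collapse = ", "))
  }
  ord <- order(frame)
  frame <- frame[ord]; x_px <- x_px[ord]; y_px <- y_px[ord]
  edge_flag <- rep_len(edge_flag, length(frame))[ord]
  keep <- !is.na(x_px) & !is.na(y_px)
  if (!any(keep)) stop("track for larva '", larva_id, "' has no observed frame")
  # trim leading/trailing missing rows: the track spans observed detections
  rng <- range(frame[keep])
  full <- seq.int(rng[1], rng[2])
  idx <- match(full, frame)
  out <- tibble::tibble(
    larva_id = as.character(larva_id),
    frame = full,
    x_px = ifelse(is.na(idx), NA_real_, x_px[idx]),
    y_px = ifelse(is.na(idx), NA_real_, y_px[idx]),
    edge_flag = ifelse(is.na(idx), FALSE, edge_flag[idx])
  )
  class(out) <- c("raw_track", class(out))
  out
}

#' Read a tracker export table into raw tracks
#'
#' Reads a comma-separated tracking table (header row, one row per larva and
#' frame) and returns one [raw_track()] per larva. Column names vary between
#' tracker versions, so the mapping is configurable.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping the roles `frame`, `x`,
#'   `y` and optionally `larva` and `edge_flag` to column names in the file.
#'   Without a `larva` column the whole file is one track named by `larva_id`.
#' @param larva_id Track label used when the file holds a single larva.
#' @return Named list of `raw_track` objects.
#' @export
read_track_table <- function(path,
                             column_map = c(frame = "frame", x = "x", y = "y"),
                             larva_id = "larva1") {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  for (role in c("frame", "x", "y")) {
    if (!column_map[[role]] %in% names(tab)) {
      stop("column '", column_map[[role]], "' (role ", role, ") not in ", path)
    }
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  fr <- num(tab[[column_map[["frame"]]]])
  bad <- which(is.na(fr) | fr != floor(fr))
  if (length(bad) > 0) {
    stop("unparseable frame index in rows: ", paste(utils::head(bad, 20), collapse = ", "))
  }
  x <- tab[[column_map[["x"]]]]
  y <- tab[[column_map[["y"]]]]
  # empty fields encode missing detections; anything else must parse
  parse_coord <- function(v, what) {
    out <- num(v)
    bad <- which(is.na(out) & !(is.na(v) | trimws(v) == ""))
    if (length(bad) > 0) {
      stop("unparseable ", what, " in rows: ", paste(utils::head(bad, 20), collapse = ", "))
    }
    out
  }
  x <- parse_coord(x, "x coordinate")
  y <- parse_coord(y, "y coordinate")
  ids <- if ("larva" %in% names(column_map) && column_map[["larva"]] %in% names(tab)) {
    as.character(tab[[column_map[["larva"]]]])
  } else {
    rep(as.character(larva_id), nrow(tab))
  }
  edge <- if ("edge_flag" %in% names(column_map) && column_map[["edge_flag"]] %in% names(tab)) {
    tolower(trimws(tab[[column_map[["edge_flag"]]]])) %in% c("1", "true", "t", "yes")
  } else {
    rep(FALSE, nrow(tab))
  }
  out <- lapply(split(seq_len(nrow(tab)), ids), function(i) {
    raw_track(ids[i[1]], fr[i], x[i], y[i], edge[i])
  })
  out[unique(ids)]
}

#' Stitch track fragments of one larva into a single track
#'
#' Trackers split a larva's trajectory into several fragments when detection
#' drops for a while; downstream analysis wants one track per animal with the
#' inter-fragment frames marked missing.
#'
#' @param fragments List of [raw_track()] objects sharing a `larva_id`, with
#'   non-overlapping frame ranges (overlap is tolerated only where the
#'   coordinates agree).
#' @return A single `raw_track` spanning the union of frames.
#' @export
stitch_fragments <- function(fragments) {
  stopifnot(length(fragments) >= 1)
  if (length(fragments) == 1) return(fragments[[1]])
  ids <- vapply(fragments, function(f) f$larva_id[1], character(1))
  if (length(unique(ids)) != 1) {
    stop("fragments belong to different larvae: ", paste(unique(ids), collapse = ", "))
  }
  all <- dplyr::bind_rows(lapply(fragments, function(f) {
    f[!is.na(f$x_px), c("frame", "x_px", "y_px", "edge_flag")]
  }))
  dup <- all$frame[duplicated(all$frame)]
  if (length(dup) > 0) {
    for (fi in unique(dup)) {
      rows <- all[all$frame == fi, ]
      if (nrow(unique(rows[, c("x_px", "y_px")])) > 1) {
        stop("fragments overlap with conflicting coordinates at frame ", fi)
      }
    }
    all <- all[!duplicated(all$frame), ]
  }
  raw_track(ids[1], all$frame, all$x_px, all$y_px, all$edge_flag)
}

#' Fraction of missing frames in a raw track
#'
#' Quality-control quantity: the share of frames between the first and last
#' detection in which the tracker lost the larva. Detection failure rates of
#' a quarter or more of all frames are common with reflective arena walls.
#'
#' @param track A [raw_track()].
#' @return Fraction in `[0, 1]`.
#' @export
missing_fraction <- function(track) {
  stopifnot(inherits(track, "raw_track"), nrow(track) >= 1)
  mean(is.na(track$x_px))
}

#' Write / read a repaired track as a normalized CSV
#'
#' The normalized per-larva format has columns `larva_id`, `frame`, `t_s`,
#' `x_mm`, `y_mm`, `r_mm`, `provenance`. Coordinates are printed with 17
#' significant digits so that a write/read round trip is bit-exact.
#'
#' @param track A `repaired_track` tibble (see [repair_track()]).
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_track_csv`); a `repaired_track`
#'   (`read_track_csv`).
#' @export
write_track_csv <- function(track, path) {
  cols <- c("larva_id", "frame", "t_s", "x_mm", "y_mm", "r_mm", "provenance")
  stopifnot(all(cols %in% names(track)))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  lines <- paste(
    track$larva_id, track$frame, fmt(track$t_s), fmt(track$x_mm),
    fmt(track$y_mm), fmt(track$r_mm), track$provenance, sep = ","
  )
  writeLines(c(paste(cols, collapse = ","), lines), path)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = c(
    larva_id = "character", frame = "integer", t_s = "numeric",
    x_mm = "numeric", y_mm = "numeric", r_mm = "numeric",
    provenance = "character"
  ))
  out <- tibble::as_tibble(tab)
  class(out) <- c("repaired_track", class(out))
  out
}
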