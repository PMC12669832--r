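#' Experiment event log for one larva
#'
#' Records the manually logged timestamps that structure an experiment:
#' recording start, container placement, the larva's first physical contact
#' with the container, and container removal. All times are seconds from
#' recording start. A larva can be excluded (no contact within the
#' pre-search window, a contact that failed video review, or an approach via
#' the arena lid), in which case the contact/removal times may be absent.
#'
#' @param larva_id Label identifying the animal.
#' @param t_start Recording start (usually 0).
#' @param t_container_placed Container placement, end of the baseline phase.
#' @param t_first_contact First verified head contact with the container.
#' @param t_container_removed Container removal, start of the search phase.
#' @param excluded Whether the larva is excluded from analysis.
#' @param reason One of `"no-contact"`, `"false-contact"`, `"lid-approach"`
#'   when excluded, `NA` otherwise.
#' @return An object of class `event_log`.
#' @export
event_log <- function(larva_id,
                      t_start = 0,
                      t_container_placed = NA_real_,
                      t_first_contact = NA_real_,
                      t_container_removed = NA_real_,
                      excluded = FALSE,
                      reason = NA_character_) {
  if (!excluded) {
    ts <- c(t_container_placed, t_first_contact, t_container_removed)
    if (anyNA(ts)) {
      missing <- c("t_container_placed", "t_first_contact",
                   "t_container_removed")[is.na(ts)]
      stop("missing event time(s) for non-excluded larva '", larva_id, "': ",
           paste(missing, collapse = ", "))
    }
    stopifnot(
      t_start <= t_container_placed,
      t_container_placed < t_first_contact,
      t_first_contact < t_container_removed
    )
  } else {
    stopifnot(reason %in% c("no-contact", "false-contact", "lid-approach"))
  }
  structure(
    list(larva_id = as.character(larva_id), t_start = t_start,
         t_container_placed = t_container_placed,
         t_first_contact = t_first_contact,
         t_container_removed = t_container_removed,
         excluded = isTRUE(excluded), reason = reason),
    class = "event_log"
  )
}

#' Read experiment event logs from CSV or JSON
#'
#' The CSV dialect has one row per larva with columns `larva_id`, `t_start`,
#' `t_container_placed`, `t_first_contact`, `t_container_removed` and
#' optionally `excluded`, `reason`. The JSON dialect is an array of objects
#' with the same fields.
#'
#' @param path File path (`.csv` or `.json`).
#' @return Named list of [event_log()] objects.
#' @export
read_events <- function(path) {
  stopifnot(file.exists(path))
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
  tab <- tibble::as_tibble(tab)
  if (!"excluded" %in% names(tab)) tab$excluded <- FALSE
  if (!"reason" %in% names(tab)) tab$reason <- NA_character_
  if (!"t_start" %in% names(tab)) tab$t_start <- 0
  out <- lapply(seq_len(nrow(tab)), function(i) {
    event_log(tab$larva_id[i], tab$t_start[i], tab$t_container_placed[i],
              tab$t_first_contact[i], tab$t_container_removed[i],
              isTRUE(tab$excluded[i] %in% c(TRUE, "TRUE", "true", 1)),
              as.character(tab$reason[i]))
  })
  names(out) <- vapply(out, function(e) e$larva_id, character(1))
  out
}

#' Segment an experiment into its four phases
#'
#' The paradigm has four consecutive windows: a 5 min baseline (acclimation,
#' free exploration), a pre-search phase of up to 15 min ending with the
#' larva's first container contact, a 1 min investigation phase, and a
#' search phase after container removal of which the first 5 min are
#' analyzed. Control recordings without a container are segmented the same
#' way using artificial event times.
#'
#' @param events An [event_log()] for a non-excluded larva.
#' @param recording_end_s Optional recording end; if the recording stops
#'   before the 5 min search window completes, the analyzed search window is
#'   truncated (with a warning).
#' @param search_analyzed_s Length of the analyzed search window (default
#'   300 s).
#' @return An object of class `experiment_timeline`: a named list of
#'   half-open `[t0, t1)` windows `baseline`, `pre_search`, `investigation`,
#'   `search_analyzed`.
#' @export
#' @examples
#' tl <- segment_phases(event_log("a", 0, 300, 736, 796))
#' tl$search_analyzed  # 796 to 1096
segment_phases <- function(events, recording_end_s = NULL,
                           search_analyzed_s = 300) {
  stopifnot(inherits(events, "event_log"))
  if (events$excluded) stop("larva '", events$larva_id, "' is excluded (",
                            events$reason, ")")
  end <- events$t_container_removed + search_analyzed_s
  if (!is.null(recording_end_s) && recording_end_s < end) {
    warning(sprintf(
      "recording ends at %g s; search window truncated to %g s",
      recording_end_s, recording_end_s - events$t_container_removed))
    end <- recording_end_s
  }
  structure(
    list(
      baseline = c(events$t_start, events$t_container_placed),
      pre_search = c(events$t_container_placed, events$t_first_contact),
      investigation = c(events$t_first_contact, events$t_container_removed),
      search_analyzed = c(events$t_container_removed, end)
    ),
    larva_id = events$larva_id,
    class = "experiment_timeline"
  )
}

#' @export
print.experiment_timeline <- function(x, ...) {
  cat("<experiment_timeline>", attr(x, "larva_id"), "\n")
  for (ph in names(x)) {
    cat(sprintf("  %-15s [%7.1f, %7.1f) s  (%.1f s)\n",
                ph, x[[ph]][1], x[[ph]][2], diff(x[[ph]])))
  }
  invisible(x)
}
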