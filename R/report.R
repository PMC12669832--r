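#' Run the full analysis over a cohort
#'
#' Repairs every track, segments its experiment into phases, computes all
#' per-phase metrics, and runs the cohort-level statistics: each scalar
#' metric is compared between baseline and the analyzed search window with
#' the paired Wilcoxon signed-rank test, and the search score of each of
#' those two phases is tested against zero with the one-sample Wilcoxon
#' signed-rank test.
#'
#' @param cohort Either a list with `tracks` and `events` (named lists of
#'   [raw_track()] / [event_log()] objects, as produced by
#'   [simulate_cohort()]), or a manifest data frame with columns
#'   `track_file` and `events_file` (plus optional `column_map` handling via
#'   `...` arguments to [read_track_table()]).
#' @param config An [arena_config()].
#' @param qc_max_missing Larvae whose [missing_fraction()] exceeds this are
#'   excluded with a logged reason.
#' @param ... Passed to [read_track_table()] when reading from a manifest.
#' @return List with `metrics` (per-larva, per-phase tibble), `scores`
#'   (wide tibble of search scores), `stats` (tibble of test results),
#'   `minute_bins`, `excluded` (tibble of excluded larvae and reasons) and
#'   `qc` (per-larva missing fractions).
#' @export
run_pipeline <- function(cohort, config, qc_max_missing = 0.6, ...) {
  stopifnot(inherits(config, "arena_config"))
  if (is.data.frame(cohort)) {
    stopifnot(nrow(cohort) >= 1,
              all(c("track_file", "events_file") %in% names(cohort)))
    tracks <- list(); events <- list()
    for (i in seq_len(nrow(cohort))) {
      tr <- read_track_table(cohort$track_file[i], ...)
      ev <- read_events(cohort$events_file[i])
      tracks <- c(tracks, tr)
      events <- c(events, ev)
    }
    cohort <- list(tracks = tracks, events = events)
  }
  stopifnot(length(cohort$tracks) >= 1,
            length(cohort$tracks) == length(cohort$events))

  ids <- names(cohort$tracks)
  excluded <- tibble::tibble(larva_id = character(), reason = character())
  metrics <- list(); bins <- list(); qc <- list()
  for (id in ids) {
    ev <- cohort$events[[id]]
    if (ev$excluded) {
      excluded <- dplyr::bind_rows(
        excluded, tibble::tibble(larva_id = id, reason = ev$reason))
      next
    }
    track <- cohort$tracks[[id]]
    mf <- missing_fraction(track)
    qc[[id]] <- tibble::tibble(larva_id = id, missing_fraction = mf)
    if (mf > qc_max_missing) {
      excluded <- dplyr::bind_rows(
        excluded,
        tibble::tibble(larva_id = id,
                       reason = sprintf("missing_fraction %.2f > %.2f",
                                        mf, qc_max_missing)))
      next
    }
    tl <- segment_phases(ev)
    end_frame <- floor(tl$search_analyzed[2] * config$frame_rate)
    rep_tr <- repair_track(track, config, ev, pad_to_frame = end_frame)
    pm <- phase_metrics(rep_tr, tl, config)
    metrics[[id]] <- pm
    mb <- dplyr::bind_rows(lapply(seq_len(nrow(pm)), function(j) {
      b <- pm$r_per_minute_mm[[j]]
      if (nrow(b) == 0) return(NULL)
      b$larva_id <- id; b$phase <- pm$phase[j]; b
    }))
    bins[[id]] <- mb
  }
  if (length(metrics) == 0) stop("no analyzable larvae in cohort")
  metrics <- dplyr::bind_rows(metrics)
  bins <- dplyr::bind_rows(bins)

  scores <- tidyr::pivot_wider(
    metrics[, c("larva_id", "phase", "search_score")],
    names_from = "phase", values_from = "search_score"
  )

  paired_metrics <- c("median_r_mm", "total_length_mm", "median_speed_mm_s",
                      "time_in_center_zone_s", "n_revisits", "n_stops",
                      "search_score")
  base <- metrics[metrics$phase == "baseline", ]
  srch <- metrics[metrics$phase == "search_analyzed", ]
  srch <- srch[match(base$larva_id, srch$larva_id), ]
  stats_rows <- lapply(paired_metrics, function(m) {
    # a degenerate all-zero-difference contrast (e.g. no revisits in either
    # phase) yields p = 1 with a note; no need to warn per metric here
    res <- suppressWarnings(wilcoxon_paired(base[[m]], srch[[m]]))
    res$comparison <- paste0(m, ": baseline vs search")
    res
  })
  for (ph in c("baseline", "search_analyzed")) {
    res <- wilcoxon_one_sample(metrics$search_score[metrics$phase == ph])
    res$comparison <- paste0("search_score vs 0: ", ph)
    stats_rows <- c(stats_rows, list(res))
  }
  stats_tbl <- dplyr::bind_rows(stats_rows)
  stats_tbl <- stats_tbl[, c("comparison", "method", "statistic", "p_value",
                             "n", "stars", "note")]

  list(metrics = metrics, scores = scores, stats = stats_tbl,
       minute_bins = bins, excluded = excluded,
       qc = dplyr::bind_rows(qc))
}

#' Compare a metric across experimental conditions
#'
#' Two conditions are compared with the Mann-Whitney U test; three or more
#' with the Kruskal-Wallis test followed by post hoc pairwise comparisons
#' when the global test is significant.
#'
#' @param groups Named list of numeric vectors, one per condition.
#' @return A tibble of test results (global test first, post hoc rows
#'   appended when run).
#' @export
compare_conditions <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (length(groups) == 2) {
    res <- mann_whitney_u(groups[[1]], groups[[2]])
    res$comparison <- paste(names(groups), collapse = " vs ")
    return(res[, c("comparison", "method", "statistic", "p_value", "n",
                   "stars")])
  }
  kw <- kruskal_wallis(groups)
  out <- kw$global
  out$comparison <- paste(names(groups), collapse = " vs ")
  out <- out[, c("comparison", "method", "statistic", "p_value", "n", "stars")]
  if (!is.null(kw$posthoc)) out <- dplyr::bind_rows(out, kw$posthoc)
  out
}

#' Parse and format min:s time strings
#'
#' @param x Character vector like `"07:16"` (`parse_min_s`) or numeric
#'   seconds (`format_min_s`).
#' @return Seconds as numeric, or `"m:ss"` strings rounded to the nearest
#'   second.
#' @export
parse_min_s <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    stopifnot(length(p) == 2)
    as.numeric(p[1]) * 60 + as.numeric(p[2])
  }, numeric(1))
}

#' @rdname parse_min_s
#' @export
format_min_s <- function(x) {
  s <- round(x)
  sprintf("%d:%02d", s %/% 60, s %% 60)
}

#' Summarize the time larvae needed to find the container
#'
#' The pre-search duration (container placement to first contact) is the
#' time-to-contact. Given per-larva times for one or more conditions, this
#' returns per-condition sample sizes and arithmetic mean times, formatted
#' min:s to the nearest second.
#'
#' @param times Either a data frame with columns `condition` and `time`
#'   (min:s strings or numeric seconds), or a named list of [event_log()]
#'   lists, in which case times are computed from the event logs and the
#'   list names are the conditions.
#' @return Tibble with `condition`, `n`, `mean_s`, `mean_min_s`.
#' @export
summarize_time_to_contact <- function(times) {
  if (!is.data.frame(times)) {
    stopifnot(is.list(times), length(times) >= 1)
    times <- dplyr::bind_rows(lapply(names(times), function(cond) {
      evs <- Filter(function(e) !e$excluded, times[[cond]])
      stopifnot(length(evs) >= 1)
      tibble::tibble(
        condition = cond,
        time = vapply(evs, function(e) e$t_first_contact - e$t_container_placed,
                      numeric(1))
      )
    }))
  }
  stopifnot(all(c("condition", "time") %in% names(times)))
  secs <- if (is.character(times$time)) parse_min_s(times$time) else
    as.numeric(times$time)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(condition = times$condition, s = secs),
                    .data$condition),
    n = dplyr::n(), mean_s = mean(.data$s), .groups = "drop"
  )
  out$mean_min_s <- format_min_s(out$mean_s)
  out$condition <- as.character(out$condition)
  out
}
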