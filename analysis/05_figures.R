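#!/usr/bin/env Rscript
# Figures mirroring the standard presentation of a local-search experiment:
# grayscale position rasters sorted by time-to-contact, per-category pie
# charts of dwell proportions, the search-score box plot, and the
# distance-to-center time course. Written as PDFs under results/figures/.

library(larvasearch)
suppressPackageStartupMessages({library(dplyr); library(ggplot2)})

cfg <- arena_config()
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
events <- c(read_events("scratch/sim/search_events.csv"),
            read_events("scratch/sim/control_events.csv"))

tracks <- lapply(list.files("scratch/repaired", full.names = TRUE),
                 read_track_csv)
names(tracks) <- vapply(tracks, function(t) t$larva_id[1], character(1))
search_ids <- grep("^search_", names(tracks), value = TRUE)
tls <- lapply(events[search_ids], segment_phases)

p <- grayscale_position_plot(tracks[search_ids], tls, cfg)
ggsave("results/figures/position_raster_search.pdf", p, width = 8, height = 5)

metrics <- utils::read.csv("results/phase_metrics.csv")
per_cat <- utils::read.csv("results/category_dwell.csv")
for (ph in c("baseline", "search_analyzed")) {
  sub <- per_cat |> filter(cohort == "search", phase == ph)
  dwell <- tapply(sub$time_s, sub$category, sum)
  dwell <- dwell[unique(sub$category)]  # keep category order
  pie <- zone_pie_figure(dwell, title = sprintf("time per category (%s)", ph))
  ggsave(sprintf("results/figures/pie_time_%s.pdf", ph), pie,
         width = 4, height = 4)
}

stats_tbl <- utils::read.csv("results/stats.csv")
p_score <- stats_tbl$p_value[
  stats_tbl$comparison == "search | search_score: baseline vs search"]
box <- metric_box_figure(metrics |> filter(cohort == "search"),
                         "search_score", p_value = p_score)
ggsave("results/figures/search_score_box.pdf", box, width = 4, height = 4)

bins <- utils::read.csv("results/minute_bins.csv") |>
  filter(cohort == "search", phase %in% c("baseline", "search_analyzed"))
for (ph in unique(bins$phase)) {
  fig <- distance_time_figure(bins |> filter(phase == ph))
  ggsave(sprintf("results/figures/distance_%s.pdf", ph), fig,
         width = 5, height = 4)
}
cat("figures written to results/figures/\n")
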