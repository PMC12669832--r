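#!/usr/bin/env Rscript
# Nonparametric statistics over the per-larva metrics:
#   - within each cohort, baseline vs analyzed-search contrasts with the
#     paired Wilcoxon signed-rank test;
#   - each phase's search score against zero with the one-sample test;
#   - the search-phase score across cohorts with the Mann-Whitney U test.
# Writes a tidy results/stats.csv.

library(larvasearch)
suppressPackageStartupMessages(library(dplyr))

m <- utils::read.csv("results/phase_metrics.csv")
paired_metrics <- c("median_r_mm", "total_length_mm", "median_speed_mm_s",
                    "time_in_center_zone_s", "n_revisits", "n_stops",
                    "search_score")

rows <- list()
for (co in unique(m$cohort)) {
  base <- m |> filter(cohort == co, phase == "baseline") |> arrange(larva_id)
  srch <- m |> filter(cohort == co, phase == "search_analyzed") |>
    arrange(larva_id)
  stopifnot(identical(base$larva_id, srch$larva_id))
  for (metric in paired_metrics) {
    res <- suppressWarnings(wilcoxon_paired(base[[metric]], srch[[metric]]))
    res$comparison <- sprintf("%s | %s: baseline vs search", co, metric)
    rows <- c(rows, list(res))
  }
  for (ph in c("baseline", "search_analyzed")) {
    res <- wilcoxon_one_sample(m$search_score[m$cohort == co & m$phase == ph])
    res$comparison <- sprintf("%s | search_score vs 0: %s", co, ph)
    rows <- c(rows, list(res))
  }
}

cross <- compare_conditions(list(
  search = m$search_score[m$cohort == "search" & m$phase == "search_analyzed"],
  control = m$search_score[m$cohort == "control" & m$phase == "search_analyzed"]
))
cross$note <- NA_character_
rows <- c(rows, list(cross))

stats_tbl <- bind_rows(rows) |>
  select(comparison, method, statistic, p_value, n, stars, note)
utils::write.csv(stats_tbl, "results/stats.csv", row.names = FALSE)
print(as.data.frame(stats_tbl |> select(-note)), digits = 3, right = FALSE)
cat("statistics written to results/stats.csv\n")
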