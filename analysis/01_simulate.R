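#!/usr/bin/env Rscript
# Generate the two synthetic cohorts used throughout the analysis:
#   - "search": larvae that switch from wall-hugging to center-orbiting at
#     container removal (the local-search phenotype)
#   - "control": larvae that stay in wall-hugging mode throughout (the
#     without-container control)
# Tracks and event logs are written in the pipeline's input formats under
# scratch/sim/ so the downstream steps can be run from files, exactly as
# they would be on real tracker exports.

library(larvasearch)

seed <- 20260928
n_larvae <- 15
out_dir <- "scratch/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

write_cohort <- function(coh, label) {
  rows <- lapply(names(coh$tracks), function(id) {
    tr <- coh$tracks[[id]]
    data.frame(larva_id = paste(label, id, sep = "_"), frame = tr$frame,
               x = ifelse(is.na(tr$x_px), "", sprintf("%.17g", tr$x_px)),
               y = ifelse(is.na(tr$y_px), "", sprintf("%.17g", tr$y_px)))
  })
  tracks_file <- file.path(out_dir, paste0(label, "_tracks.csv"))
  utils::write.csv(do.call(rbind, rows), tracks_file, row.names = FALSE,
                   quote = FALSE)
  evs <- do.call(rbind, lapply(coh$events, function(e) {
    data.frame(larva_id = paste(label, e$larva_id, sep = "_"),
               t_start = e$t_start,
               t_container_placed = e$t_container_placed,
               t_first_contact = e$t_first_contact,
               t_container_removed = e$t_container_removed)
  }))
  events_file <- file.path(out_dir, paste0(label, "_events.csv"))
  utils::write.csv(evs, events_file, row.names = FALSE, quote = FALSE)
  cat(sprintf("%s cohort: %d larvae, mean missing fraction %.1f%%\n",
              label, length(coh$tracks),
              100 * mean(vapply(coh$tracks, missing_fraction, numeric(1)))))
  invisible(list(tracks = tracks_file, events = events_file))
}

search_cfg <- sim_config(seed = seed, n_larvae = n_larvae,
                         search_after_removal = TRUE)
control_cfg <- sim_config(seed = seed + 1, n_larvae = n_larvae)

write_cohort(simulate_cohort(search_cfg), "search")
write_cohort(simulate_cohort(control_cfg), "control")

# echo the generating configuration for provenance
jsonlite::write_json(
  list(seed = seed, n_larvae = n_larvae,
       search = unclass(search_cfg), control = unclass(control_cfg)),
  file.path(out_dir, "sim_config.json"), auto_unbox = TRUE, digits = NA)
cat("inputs written to", out_dir, "\n")
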