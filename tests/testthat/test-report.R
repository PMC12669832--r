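sc <- sim_config(seed = 33, n_larvae = 6, search_after_removal = TRUE)
coh <- simulate_cohort(sc)
acfg <- arena_config_for(sc)
res <- run_pipeline(coh, acfg)

test_that("the pipeline emits one paired comparison per scalar metric", {
  paired <- res$stats[res$stats$method == "wilcoxon_paired", ]
  expect_equal(nrow(paired), 7)
  one_sample <- res$stats[res$stats$method == "wilcoxon_one_sample", ]
  expect_equal(nrow(one_sample), 2)
  expect_true(all(res$stats$p_value >= 0 & res$stats$p_value <= 1))
  expect_equal(nrow(res$scores), 6)
})

test_that("the pipeline reads cohorts from a file manifest identically", {
  dir <- withr::local_tempdir()
  manifest <- do.call(rbind, lapply(names(coh$tracks), function(id) {
    tf <- file.path(dir, paste0(id, "_track.csv"))
    tr <- coh$tracks[[id]]
    writeLines(c(
      "larva_id,frame,x,y",
      sprintf("%s,%d,%s,%s", id, tr$frame,
              ifelse(is.na(tr$x_px), "", sprintf("%.17g", tr$x_px)),
              ifelse(is.na(tr$y_px), "", sprintf("%.17g", tr$y_px)))
    ), tf)
    ef <- file.path(dir, paste0(id, "_events.csv"))
    ev <- coh$events[[id]]
    writeLines(c(
      "larva_id,t_start,t_container_placed,t_first_contact,t_container_removed",
      sprintf("%s,%g,%g,%g,%g", id, ev$t_start, ev$t_container_placed,
              ev$t_first_contact, ev$t_container_removed)
    ), ef)
    data.frame(track_file = tf, events_file = ef)
  }))
  res2 <- run_pipeline(manifest, acfg,
                       column_map = c(frame = "frame", x = "x", y = "y",
                                      larva = "larva_id"))
  expect_equal(res2$scores, res$scores)
  expect_equal(res2$stats$p_value, res$stats$p_value)

  expect_error(run_pipeline(data.frame(track_file = character(),
                                       events_file = character()), acfg))
})

test_that("excluded larvae are dropped with logged reasons", {
  coh2 <- coh
  coh2$events[[2]] <- event_log(names(coh$tracks)[2], excluded = TRUE,
                                reason = "no-contact")
  res2 <- run_pipeline(coh2, acfg)
  expect_equal(res2$excluded$reason, "no-contact")
  expect_equal(nrow(res2$scores), 5)
  # QC exclusion by missing fraction: threshold set between the 3rd and 4th
  # order statistic so exactly half the cohort fails QC
  mfs <- sort(vapply(coh$tracks, missing_fraction, numeric(1)))
  res3 <- run_pipeline(coh, acfg, qc_max_missing = mean(mfs[3:4]))
  expect_equal(nrow(res3$excluded), 3)
  expect_match(res3$excluded$reason[1], "missing_fraction")
  expect_equal(nrow(res3$scores), 3)
})

test_that("condition comparisons pick the two- vs k-sample test", {
  set.seed(41)
  two <- compare_conditions(list(a = rnorm(8), b = rnorm(8, 2)))
  expect_equal(two$method, "mann_whitney_u")
  three <- compare_conditions(list(a = rnorm(8), b = rnorm(8, 2),
                                   c = rnorm(8, 4)))
  expect_equal(three$method[1], "kruskal_wallis")
  expect_true(all(three$method[-1] == "posthoc"))
})

test_that("time-to-contact summaries format min:s and average per condition", {
  expect_equal(parse_min_s(c("07:16", "0:30")), c(436, 30))
  expect_equal(format_min_s(c(205, 253.5)), c("3:25", "4:14"))
  one <- summarize_time_to_contact(
    data.frame(condition = "x", time = 60))
  expect_equal(one$mean_min_s, "1:00")
  # from event logs: pre-search duration is contact minus placement
  evs <- list(cond1 = list(event_log("a", 0, 300, 360, 420),
                           event_log("b", 0, 300, 480, 540)))
  tab <- summarize_time_to_contact(evs)
  expect_equal(tab$mean_s, 120)
  expect_equal(tab$n, 2L)
})

test_that("figures encode the documented structure", {
  tls <- lapply(coh$events, segment_phases)
  reps <- lapply(names(coh$tracks), function(id) {
    repair_track(coh$tracks[[id]], acfg, coh$events[[id]],
                 pad_to_frame = floor(tls[[id]]$search_analyzed[2] *
                                        acfg$frame_rate))
  })
  names(reps) <- names(coh$tracks)
  p <- grayscale_position_plot(reps, tls, acfg)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_equal(length(unique(built$data[[1]]$fill)), 4)

  props <- category_proportions(res$metrics$time_per_category_s[
    res$metrics$phase == "search_analyzed"])
  expect_equal(sum(props$proportion), 1, tolerance = 1e-9)
  pie <- zone_pie_figure(res$metrics$time_per_category_s[[1]])
  expect_s3_class(pie, "ggplot")

  box <- metric_box_figure(res$metrics, "search_score", p_value = 0.01)
  expect_s3_class(box, "ggplot")
  dt <- distance_time_figure(res$minute_bins[
    res$minute_bins$phase == "baseline", ])
  expect_s3_class(dt, "ggplot")
})

test_that("position raster rows are sorted by time-to-contact", {
  # two larvae with pre-search 100 s and 50 s: the faster one on top
  t1 <- r_track(rep(10, 1200)); t1$larva_id <- "slow"
  t2 <- r_track(rep(25, 1200)); t2$larva_id <- "fast"
  tls <- list(slow = segment_phases(event_log("slow", 0, 100, 200, 260)),
              fast = segment_phases(event_log("fast", 0, 100, 150, 210)))
  p <- grayscale_position_plot(list(slow = t1, fast = t2), tls, arena_config())
  lv <- levels(p$data$larva_id)
  expect_equal(lv, c("slow", "fast"))  # last level plots on top
})
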