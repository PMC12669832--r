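cfg <- arena_config()

test_that("distance categories are half-open and map onto the four zones", {
  expect_equal(as.character(category_of(c(5, 8, 27))),
               c("4-8", "8-12", ">24"))
  expect_equal(as.character(zone_of(c(5, 8, 27))),
               c("center", "search", "edge"))
  # every boundary belongs to the upper category
  expect_equal(as.character(category_of(c(0, 4, 12, 16, 24))),
               c("0-4", "4-8", "12-16", "16-20", ">24"))
  # zone = pairwise union of categories, checked across the whole range
  r <- seq(0, 35, by = 0.25)
  idx <- as.integer(category_of(r))
  expect_equal(as.integer(zone_of(r)), pmin((idx + 1L) %/% 2L, 4L))
})

test_that("dwell time attributes 1/frame_rate per frame and is conserved", {
  # constant r = 10 mm for 300 s at 2 fps
  tr <- r_track(rep(10, 600))
  d <- dwell_times(tr, c(0, 300), cfg)
  expect_equal(unname(d["8-12"]), 300)
  expect_equal(sum(d), 300)

  # 50/50 split between r = 5 and r = 25
  tr <- r_track(rep(c(5, 25), each = 300))
  d <- dwell_times(tr, c(0, 300), cfg)
  expect_equal(unname(d[c("4-8", ">24")]), c(150, 150))
  expect_equal(sum(d), 300)

  expect_equal(sum(dwell_times(tr, c(100, 100), cfg)), 0)  # empty window
})

test_that("zone times are the pairwise sums of category times", {
  set.seed(52)
  for (i in 1:20) {
    tr <- r_track(runif(200, 0, 30))
    d <- dwell_times(tr, c(0, 100), cfg)
    z <- zone_times(d)
    expect_identical(unname(z["center"]), unname(d[["0-4"]] + d[["4-8"]]))
    expect_identical(unname(z["search"]), unname(d[["8-12"]] + d[["12-16"]]))
    expect_identical(unname(z["neutral"]), unname(d[["16-20"]] + d[["20-24"]]))
    expect_identical(unname(z["edge"]), unname(d[[">24"]]))
    expect_equal(sum(z), 100)
  }
})

test_that("track length cumulates Euclidean steps with category attribution", {
  # stationary
  tr <- mm_track(rep(3, 50), rep(0, 50))
  expect_equal(track_length(tr, c(0, 25), cfg)$total_mm, 0)

  # straight crawl, 0.5 mm per frame, 100 frames -> 49.5 mm over 99 steps
  tr <- mm_track(seq(0, by = 0.5, length.out = 100), rep(0, 100))
  len <- track_length(tr, c(0, 50), cfg)
  expect_equal(len$total_mm, 49.5)
  expect_equal(sum(len$per_category_mm), len$total_mm)

  # full revolution at radius 10: length approaches 2*pi*10 as N grows
  for (N in c(60, 360)) {
    a <- seq(0, 2 * pi, length.out = N + 1)
    tr <- mm_track(10 * cos(a), 10 * sin(a), frame_rate = 2)
    len <- track_length(tr, c(0, (N + 1) / 2), cfg)
    expect_equal(len$total_mm, 2 * N * 10 * sin(pi / N), tolerance = 1e-9)
  }
  expect_lt(abs(track_length(
    mm_track(10 * cos(seq(0, 2 * pi, length.out = 721)),
             10 * sin(seq(0, 2 * pi, length.out = 721))),
    c(0, 400), cfg)$total_mm - 2 * pi * 10), 0.01)

  # steps into/out of position-less frames contribute nothing
  tr <- mm_track(c(0, 1, NA, 3, 4), c(0, 0, NA, 0, 0))
  tr$r_mm[3] <- 27
  expect_equal(track_length(tr, c(0, 3), cfg)$total_mm, 2)
})

test_that("speed is step length times frame rate; summary is the median", {
  tr <- mm_track(seq(0, by = 0.5, length.out = 21), rep(0, 21))
  sp <- speed_series(tr, c(0, 11), cfg)
  expect_equal(sp$series$speed_mm_s, rep(1, 20))
  expect_equal(sp$median_mm_s, 1)
  # constant speed: moving average equals instantaneous once filled
  expect_equal(sp$series$speed_smooth[10:20], rep(1, 11))

  # alternating 0 / 1 mm steps: 10-frame average 1 mm/s in steady state
  # (each step of 1 mm at 2 fps is 2 mm/s; alternating 0 gives mean 1)
  x <- cumsum(rep(c(0, 1), 30))
  tr <- mm_track(c(0, x), rep(0, 61))
  sp <- speed_series(tr, c(0, 30), cfg)
  expect_equal(unique(round(sp$series$speed_smooth[10:59], 9)), 1)
  # oracle: direct convolution
  conv <- as.numeric(stats::filter(sp$series$speed_mm_s,
                                   rep(0.1, 10), sides = 1))
  expect_equal(sp$series$speed_smooth, conv)
})

test_that("revisits are inward center-zone crossings only", {
  tr <- r_track(c(25, 12, 7, 9, 7, 30))
  expect_equal(count_revisits(tr, c(0, 3), radius_mm = 8), 2)
  expect_equal(count_revisits(r_track(rep(c(12, 9), 10)), c(0, 10), 8), 0)
  expect_equal(count_revisits(r_track(rep(5, 10)), c(0, 5), 8), 0)
  # landing exactly on the border is an entry
  expect_equal(count_revisits(r_track(c(10, 8)), c(0, 1), 8), 1)
})

test_that("closed loops have equal entries and exits", {
  set.seed(61)
  for (i in 1:50) {
    r <- c(20, runif(198, 0, 30), 20)  # starts and ends outside
    tr <- r_track(r)
    entries <- count_revisits(tr, c(0, 100), 8)
    exits <- sum(r[-length(r)] <= 8 & r[-1] > 8)
    expect_equal(entries, exits)
    # time reversal swaps entries and exits
    rev_entries <- count_revisits(r_track(rev(r)), c(0, 100), 8)
    expect_equal(rev_entries, exits)
  }
})

test_that("stop counting follows the start/end/merge rules", {
  steps_track <- function(steps) mm_track(c(0, cumsum(steps)),
                                          rep(0, length(steps) + 1))
  w <- function(steps) c(0, (length(steps) + 1) / 2)
  # one stop of two sub-threshold frames, ended by six moving frames
  s <- c(.2, .2, .01, .01, .2, .2, .2, .2, .2, .2)
  expect_equal(count_stops(steps_track(s), w(s), cfg)$n_stops, 1)
  # two sub-threshold runs separated by 4 moving frames merge
  s <- c(.01, .2, .2, .2, .2, .01, rep(.2, 6))
  expect_equal(count_stops(steps_track(s), w(s), cfg)$n_stops, 1)
  # separated by 6 moving frames: two stops
  s <- c(.01, rep(.2, 6), .01, rep(.2, 6))
  expect_equal(count_stops(steps_track(s), w(s), cfg)$n_stops, 2)
  # all moving
  s <- rep(.2, 20)
  expect_equal(count_stops(steps_track(s), w(s), cfg)$n_stops, 0)
})

test_that("stop counting matches the brute-force state machine", {
  set.seed(71)
  for (i in 1:300) {
    n <- 120
    steps <- ifelse(runif(n) < 0.25, runif(n, 0, 0.049), runif(n, 0.05, 0.6))
    tr <- mm_track(c(0, cumsum(steps)), rep(0, n + 1))
    got <- count_stops(tr, c(0, (n + 1) / 2), cfg)$n_stops
    want <- brute_count_stops(steps, cfg$stop_displacement_mm,
                              cfg$stop_window_frames)
    expect_equal(got, want)
  }
})

test_that("minute bins average r over consecutive 60 s windows", {
  tr <- r_track(rep(10, 600))
  b <- minute_bins(tr, c(0, 300))
  expect_equal(nrow(b), 5)
  expect_equal(b$mean_r_mm, rep(10, 5))
  expect_equal(b$duration_s, rep(60, 5))

  # r rising linearly 0 -> 30 over the first minute: bin mean 15
  tr <- r_track(seq(0, 30, length.out = 120))
  b <- minute_bins(tr, c(0, 60))
  expect_equal(b$mean_r_mm, 15)

  # trailing partial bin keeps its actual duration
  tr <- r_track(rep(5, 300))
  b <- minute_bins(tr, c(0, 150))
  expect_equal(b$duration_s, c(60, 60, 30))
})

test_that("search score is the normalized search-minus-edge dwell", {
  z <- function(s, e) c(center = 0, search = s, neutral = 300 - s - e, edge = e)
  expect_equal(search_score(z(300, 0), 300), 1)
  expect_equal(search_score(z(0, 300), 300), -1)
  expect_equal(search_score(z(105, 195), 300), -0.3)
  expect_equal(search_score(z(120, 120), 300), 0)
  # antisymmetry under swapping search and edge dwell
  set.seed(81)
  for (i in 1:50) {
    s <- runif(1, 0, 150); e <- runif(1, 0, 150)
    expect_equal(search_score(z(s, e), 300), -search_score(z(e, s), 300))
  }
})

test_that("per-phase metrics satisfy the conservation invariants", {
  set.seed(91)
  sc <- sim_config(seed = 91, search_after_removal = TRUE, dropout_rate = 0.1)
  sim <- simulate_larva(sc, "inv")
  acfg <- arena_config_for(sc)
  tl <- segment_phases(sim$events)
  rep_tr <- repair_track(sim$track, acfg, sim$events,
                         pad_to_frame = floor(tl$search_analyzed[2] * acfg$frame_rate))
  pm <- phase_metrics(rep_tr, tl, acfg)
  expect_equal(pm$phase, c("baseline", "pre_search", "investigation",
                           "search_analyzed"))
  for (j in seq_len(nrow(pm))) {
    expect_equal(sum(pm$time_per_zone_s[[j]]), pm$duration_s[j],
                 tolerance = 1 / acfg$frame_rate)
    expect_identical(sum(pm$time_per_zone_s[[j]]),
                     sum(pm$time_per_category_s[[j]]))
    expect_equal(sum(pm$length_per_category_mm[[j]]), pm$total_length_mm[j])
    expect_gte(pm$search_score[j], -1)
    expect_lte(pm$search_score[j], 1)
  }
})
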