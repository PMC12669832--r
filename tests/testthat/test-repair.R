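# px-scale track builder centered on the configured arena center
px_track <- function(x_mm, y_mm, cfg = arena_config(), id = "p",
                     frames = seq_along(x_mm) - 1L, edge_flag = FALSE) {
  raw_track(id, frames,
            x_mm / cfg$px_to_mm + cfg$center_x_px,
            y_mm / cfg$px_to_mm + cfg$center_y_px,
            edge_flag = edge_flag)
}

test_that("linear interpolation spaces points evenly on the open segment", {
  expect_equal(interpolate_linear(c(0, 0), c(10, 0), 1),
               cbind(5, 0))
  expect_equal(interpolate_linear(c(0, 0), c(9, 0), 2),
               cbind(c(3, 6), c(0, 0)))
  expect_equal(interpolate_linear(c(2, 3), c(2, 3), 3),
               cbind(rep(2, 3), rep(3, 3)))
})

test_that("linear interpolation preserves collinearity", {
  set.seed(21)
  for (i in 1:50) {
    p0 <- runif(2, -30, 30); p1 <- runif(2, -30, 30)
    k <- sample(1:8, 1)
    pts <- interpolate_linear(p0, p1, k)
    v <- p1 - p0
    cross <- (pts[, 1] - p0[1]) * v[2] - (pts[, 2] - p0[2]) * v[1]
    expect_lt(max(abs(cross)), 1e-9)
  }
})

test_that("arc interpolation follows the minor arc with blended radius", {
  # symmetric quarter arc at constant radius: midpoint at 45 degrees
  p <- interpolate_arc(c(25, 0), c(0, 25), 1, center = c(0, 0))
  expect_equal(p[1, ], 25 * c(cos(pi / 4), sin(pi / 4)), tolerance = 1e-12)

  # unequal radii: midpoint angle 45 degrees, radius the mean of 24 and 26
  p <- interpolate_arc(c(24, 0), c(0, 26), 1, center = c(0, 0))
  expect_equal(atan2(p[1, 2], p[1, 1]), pi / 4, tolerance = 1e-12)
  expect_equal(sqrt(sum(p[1, ]^2)), 25, tolerance = 1e-12)

  # equal endpoints: k copies of the point
  p <- interpolate_arc(c(25, 0), c(25, 0), 4, center = c(0, 0))
  expect_equal(p, cbind(rep(25, 4), rep(0, 4)))

  # antipodal endpoints fall back to linear, with a warning
  expect_warning(p <- interpolate_arc(c(25, 0), c(-25, 0), 1, center = c(0, 0)),
                 "antipodal")
  expect_equal(p, cbind(0, 0))
})

test_that("arc points match a parametric oracle and stay between flank radii", {
  set.seed(31)
  for (i in 1:200) {
    a0 <- runif(1, -pi, pi)
    da <- runif(1, -pi + 0.05, pi - 0.05)
    r0 <- runif(1, 22, 30); r1 <- runif(1, 22, 30)
    k <- sample(1:6, 1)
    p0 <- r0 * c(cos(a0), sin(a0))
    p1 <- r1 * c(cos(a0 + da), sin(a0 + da))
    pts <- interpolate_arc(p0, p1, k, center = c(0, 0))
    # oracle: parametric minor arc with linear radius blend
    f <- seq_len(k) / (k + 1)
    oracle <- cbind((r0 + f * (r1 - r0)) * cos(a0 + f * da),
                    (r0 + f * (r1 - r0)) * sin(a0 + f * da))
    expect_equal(pts, oracle, tolerance = 1e-9)
    radii <- sqrt(rowSums(pts^2))
    expect_true(all(radii >= min(r0, r1) - 1e-9))
    expect_true(all(radii <= max(r0, r1) + 1e-9))
  }
})

test_that("gaps are classified in the documented priority order", {
  cfg <- arena_config()
  ev <- event_log("p", 0, 10, 30, 60)

  # both flanks beyond the edge-gap threshold -> arc
  tr <- px_track(c(25, NA, 27), c(0, NA, 1))
  expect_equal(classify_gap(tr, c(2, 2), cfg, ev), "arc")

  # mixed flanks -> linear
  tr <- px_track(c(25, NA, 10), c(0, NA, 0))
  expect_equal(classify_gap(tr, c(2, 2), cfg, ev), "linear")

  # terminal gap -> end_hold (raw_track trims trailing NA, so build a
  # padded classification case via repair below instead); here use an
  # interior run ending at the table edge through find_gaps on a stitched
  # fragment pair is not possible -- assert via repair_track padding
  tr <- px_track(c(0, 1, 2), c(0, 0, 0))
  rep_tr <- repair_track(tr, cfg, pad_to_frame = 6)
  expect_equal(rep_tr$provenance[4:7], rep("held", 4))
  expect_equal(rep_tr$x_mm[4:7], rep(rep_tr$x_mm[3], 4))

  # disappearance near the container during pre-search -> container_contact
  tr <- px_track(c(3, NA, NA, 4), c(0, NA, NA, 0), frames = c(40, 41, 42, 43))
  expect_equal(classify_gap(tr, c(2, 3), cfg, ev), "container_contact")
  # same geometry outside the contact window -> linear
  expect_equal(classify_gap(tr, c(2, 3), cfg, NULL), "linear")

  # edge-flagged flanks below the radial threshold -> edge_assigned
  tr <- px_track(c(20, NA, 20), c(0, NA, 1), edge_flag = c(TRUE, FALSE, TRUE))
  expect_equal(classify_gap(tr, c(2, 2), cfg, ev), "edge_assigned")
})

test_that("repair converts px to mm and fills every gap with provenance", {
  cfg <- arena_config()
  # gap-free: all observed, coordinates scaled by the px-to-mm coefficient
  tr <- raw_track("p", 0:4, cfg$center_x_px + (0:4), cfg$center_y_px + rep(10, 5))
  rep_tr <- repair_track(tr, cfg)
  expect_true(all(rep_tr$provenance == "observed"))
  expect_equal(rep_tr$x_mm, (0:4) * 0.2673)
  expect_equal(rep_tr$r_mm, sqrt((0:4)^2 + 100) * 0.2673, tolerance = 1e-9)
  expect_equal(rep_tr$t_s, (0:4) / 2)

  # interior linear gap: 10 missing frames of 100
  x <- seq(0, 49.5, by = 0.5); y <- rep(0, 100)
  x_in <- x; x_in[40:49] <- NA
  tr <- px_track(x_in, ifelse(is.na(x_in), NA, y))
  expect_equal(missing_fraction(tr), 0.10)
  rep_tr <- repair_track(tr, cfg)
  expect_equal(sum(rep_tr$provenance == "linear"), 10)
  expect_equal(rep_tr$x_mm, x, tolerance = 1e-9)  # linear fill restores the line
  expect_equal(nrow(rep_tr), diff(range(tr$frame)) + 1)

  # edge-assigned frames get the edge-zone midpoint radius and no position
  tr <- px_track(c(20, NA, NA, 20), c(0, NA, NA, 1),
                 edge_flag = c(TRUE, FALSE, FALSE, TRUE))
  rep_tr <- repair_track(tr, cfg)
  expect_true(all(is.na(rep_tr$x_mm[2:3])))
  expect_equal(rep_tr$r_mm[2:3], rep((24 + 30) / 2, 2))
})

test_that("repair is idempotent when its output is fed back as input", {
  set.seed(41)
  cfg <- arena_config()
  x <- cumsum(rnorm(80)); y <- cumsum(rnorm(80))
  x[c(10:13, 50:52)] <- NA; y[c(10:13, 50:52)] <- NA
  tr <- px_track(x, y)
  r1 <- repair_track(tr, cfg)
  tr2 <- raw_track("p", r1$frame,
                   r1$x_mm / cfg$px_to_mm + cfg$center_x_px,
                   r1$y_mm / cfg$px_to_mm + cfg$center_y_px)
  r2 <- repair_track(tr2, cfg)
  expect_equal(r2$x_mm, r1$x_mm, tolerance = 1e-12)
  expect_equal(r2$y_mm, r1$y_mm, tolerance = 1e-12)
  expect_equal(r2$r_mm, r1$r_mm, tolerance = 1e-12)
})
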