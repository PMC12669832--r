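# Independent reference implementations used as oracles. These are written
# deliberately as brute-force enumerations / explicit state machines, kept
# separate from the package's own code paths.

# Exact two-sided signed-rank p by enumerating all 2^n sign patterns of the
# ranks of |d| (tie-free d assumed).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16, !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact two-sided Mann-Whitney p by enumerating all choose(n+m, n)
# assignments of the pooled ranks to group A (tie-free pooled data assumed).
enum_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n <- length(a); m <- length(b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  u_all <- apply(sets, 2, function(ix) sum(rk[ix])) - n * (n + 1) / 2
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Kruskal-Wallis H from the direct rank-sum formula with tie correction.
brute_kw_h <- function(groups) {
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  rk <- rank(v)
  rbar <- tapply(rk, g, mean)
  ni <- lengths(groups)
  h <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Stop counting by an explicit per-step state machine over a step-length
# sequence, followed by an interval-merge pass. Independent of the rle
# grouping used by the package.
brute_count_stops <- function(steps, threshold = 0.05, window = 5) {
  intervals <- list()
  in_stop <- FALSE
  move_run <- 0L
  start <- NA_integer_
  last_sub <- NA_integer_
  for (i in seq_along(steps)) {
    if (steps[i] < threshold) {
      if (!in_stop) {
        in_stop <- TRUE
        start <- i
      }
      last_sub <- i
      move_run <- 0L
    } else if (in_stop) {
      move_run <- move_run + 1L
      if (move_run >= window) {
        intervals[[length(intervals) + 1L]] <- c(start, last_sub)
        in_stop <- FALSE
        move_run <- 0L
      }
    }
  }
  if (in_stop) intervals[[length(intervals) + 1L]] <- c(start, last_sub)
  if (length(intervals) == 0) return(0L)
  merged <- intervals[[1]]
  n_stops <- 1L
  if (length(intervals) > 1) {
    for (j in 2:length(intervals)) {
      gap <- intervals[[j]][1] - merged[2] - 1L
      if (gap > window) {
        n_stops <- n_stops + 1L
        merged <- intervals[[j]]
      } else {
        merged[2] <- intervals[[j]][2]
      }
    }
  }
  n_stops
}

# Build a repaired_track tibble directly from mm coordinates (frame_rate fps),
# bypassing repair: convenient for metric tests.
mm_track <- function(x_mm, y_mm, frame_rate = 2, larva_id = "t") {
  n <- length(x_mm)
  out <- tibble::tibble(
    larva_id = larva_id,
    frame = seq_len(n) - 1L,
    t_s = (seq_len(n) - 1) / frame_rate,
    x_mm = x_mm, y_mm = y_mm,
    r_mm = sqrt(x_mm^2 + y_mm^2),
    provenance = "observed"
  )
  class(out) <- c("repaired_track", class(out))
  out
}

# Track with a prescribed distance-to-center profile (positions on the x axis).
r_track <- function(r_mm, frame_rate = 2) mm_track(r_mm, rep(0, length(r_mm)),
                                                   frame_rate = frame_rate)
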