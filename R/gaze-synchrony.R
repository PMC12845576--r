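#' Clean and temporally align a pair of gaze series
#'
#' Drops samples with any missing coordinate, then linearly interpolates
#' both 3-D pupil-position series onto a shared regular grid (default
#' 0.02 s) spanning their temporal overlap, so the two streams are sample-
#' by-sample comparable despite variable native rates (~80 Hz).
#'
#' @param a,b Gaze series: data.frames with numeric columns `t`, `x`, `y`,
#'   `z` (timestamps in seconds, strictly increasing after cleaning).
#' @param grid_interval Grid spacing in seconds, default 0.02.
#' @return A list of two equal-length data.frames on the common grid.
#' @export
clean_and_align <- function(a, b, grid_interval = 0.02) {
  clean <- function(s) {
    stopifnot(all(c("t", "x", "y", "z") %in% names(s)))
    s <- s[stats::complete.cases(s[, c("t", "x", "y", "z")]), , drop = FALSE]
    s <- s[order(s$t), , drop = FALSE]
    s[!duplicated(s$t), , drop = FALSE]
  }
  a <- clean(a); b <- clean(b)
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("each gaze series needs at least 2 complete samples", call. = FALSE)
  t0 <- max(min(a$t), min(b$t))
  t1 <- min(max(a$t), max(b$t))
  if (t1 <= t0)
    stop("gaze series have no temporal overlap", call. = FALSE)
  grid <- seq(t0, t1, by = grid_interval)
  resample <- function(s) {
    data.frame(t = grid,
               x = stats::approx(s$t, s$x, xout = grid)$y,
               y = stats::approx(s$t, s$y, xout = grid)$y,
               z = stats::approx(s$t, s$z, xout = grid)$y)
  }
  list(a = resample(a), b = resample(b))
}

#' Instantaneous gaze velocity
#'
#' Per-axis first differences of position divided by timestamp
#' differences. The n-sample position series yields n-1 velocity samples,
#' stamped at the end of each difference interval.
#'
#' @param s A gaze series data.frame with columns `t`, `x`, `y`, `z`.
#' @return A data.frame with columns `t`, `vx`, `vy`, `vz`.
#' @export
compute_velocity <- function(s) {
  stopifnot(all(c("t", "x", "y", "z") %in% names(s)))
  if (nrow(s) < 2)
    stop("velocity needs at least 2 samples", call. = FALSE)
  dt <- diff(s$t)
  if (any(dt <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  data.frame(t = s$t[-1],
             vx = diff(s$x) / dt, vy = diff(s$y) / dt, vz = diff(s$z) / dt)
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW between two univariate series:
#' absolute-difference local cost, steps (i-1,j), (i,j-1), (i-1,j-1), no
#' warping-window constraint, boundary-anchored path. Identical series
#' have distance 0; the distance is symmetric and non-negative.
#'
#' @param x,y Non-empty numeric vectors.
#' @return The accumulated cost of the optimal warping path.
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2))  # 1
#' @export
dtw_distance <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0)
    stop("dtw_distance requires non-empty series", call. = FALSE)
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(x)), all(is.finite(y)))
  prev <- c(0, rep(Inf, m))          # row i-1 of the DP table, 1-indexed j+1
  for (i in seq_len(n)) {
    cur <- rep(Inf, m + 1)
    cost <- abs(x[i] - y)
    for (j in seq_len(m)) {
      cur[j + 1] <- cost[j] + min(prev[j + 1], cur[j], prev[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

#' Per-trial DTW distance between two velocity series
#'
#' DTW is computed independently on the x, y and z velocity components and
#' the three distances are averaged into one per-trial value.
#'
#' @param va,vb Velocity series data.frames (columns `vx`, `vy`, `vz`).
#' @return A single non-negative distance.
#' @export
velocity_dtw <- function(va, vb) {
  mean(c(dtw_distance(va$vx, vb$vx),
         dtw_distance(va$vy, vb$vy),
         dtw_distance(va$vz, vb$vz)))
}

#' Min-max normalized synchrony index from DTW distances
#'
#' Distances are negated (larger distance = less synchrony) and min-max
#' scaled over the set of trials, so the most synchronous trial of the
#' normalization set maps to 1 and the least to 0. With a degenerate range
#' (all distances equal, including a single trial) every trial is assigned
#' 0.5 rather than asserting either extreme.
#'
#' @param distances Per-trial DTW distances, length >= 1.
#' @return Values in \[0, 1\], same length.
#' @examples
#' normalize_sync(c(2, 4, 6))  # 1.0 0.5 0.0
#' @export
normalize_sync <- function(distances) {
  stopifnot(length(distances) >= 1, all(is.finite(distances)))
  raw <- -distances
  rng <- range(raw)
  if (rng[1] == rng[2]) return(rep(0.5, length(distances)))
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Per-trial synchrony weight
#'
#' `gamma_t = gamma0 * dtw_norm`, the weight the agreement term receives
#' in the free energy; bounded by the base weight `gamma0`.
#'
#' @param dtw_norm Normalized synchrony in \[0, 1\].
#' @param gamma0 Base synchrony weight in \[0, 1\].
#' @return `gamma_t` in \[0, `gamma0`\] (vectorized over `dtw_norm`).
#' @export
gamma_weight <- function(dtw_norm, gamma0) {
  stopifnot(all(dtw_norm >= 0 & dtw_norm <= 1),
            gamma0 >= 0, gamma0 <= 1)
  gamma0 * dtw_norm
}

#' Zero-lag cross-correlation of paired velocity series
#'
#' Pearson correlation of the grid-aligned velocity components at zero
#' lag, averaged over the x, y and z axes; the instantaneous-coordination
#' counterpart of the shape-based DTW index. Constant components are
#' undefined and excluded; if all three are constant the result is `NA`.
#'
#' @param va,vb Equal-length velocity series data.frames.
#' @return Mean correlation in \[-1, 1\], or `NA` if undefined.
#' @export
cross_correlation <- function(va, vb) {
  stopifnot(nrow(va) == nrow(vb), nrow(va) >= 2)
  per_axis <- vapply(c("vx", "vy", "vz"), function(ax) {
    x <- va[[ax]]; y <- vb[[ax]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }, numeric(1))
  if (all(is.na(per_axis))) NA_real_ else mean(per_axis, na.rm = TRUE)
}

#' Per-trial synchrony table for one session
#'
#' Full pipeline from paired raw gaze streams to the model's synchrony
#' inputs: per trial, clean and align the two streams, differentiate into
#' velocities, compute the axis-averaged DTW distance and the zero-lag
#' cross-correlation; then min-max normalize the DTW distances over the
#' session's trials and scale by the base weight `gamma0`.
#'
#' @param gaze_a,gaze_b Gaze stream data.frames for the two participants,
#'   with columns `trial_id`, `t`, `x`, `y`, `z` (extra columns ignored;
#'   if a `phase` column is present only `phase == "object_presentation"`
#'   rows are used).
#' @param gamma0 Base synchrony weight.
#' @param grid_interval Alignment grid spacing in seconds.
#' @return A data.frame with one row per trial present in both streams:
#'   `trial_id`, `dtw_raw` (negated distance), `dtw_norm`, `xcorr`,
#'   `gamma_t`.
#' @export
session_synchrony <- function(gaze_a, gaze_b, gamma0 = 0.5,
                              grid_interval = 0.02) {
  keep_phase <- function(g) {
    if ("phase" %in% names(g)) g[g$phase == "object_presentation", , drop = FALSE]
    else g
  }
  gaze_a <- keep_phase(gaze_a); gaze_b <- keep_phase(gaze_b)
  trials <- sort(intersect(unique(gaze_a$trial_id), unique(gaze_b$trial_id)))
  if (length(trials) == 0)
    stop("no trial present in both gaze streams", call. = FALSE)
  res <- lapply(trials, function(tr) {
    al <- clean_and_align(gaze_a[gaze_a$trial_id == tr, , drop = FALSE],
                          gaze_b[gaze_b$trial_id == tr, , drop = FALSE],
                          grid_interval)
    va <- compute_velocity(al$a); vb <- compute_velocity(al$b)
    c(dist = velocity_dtw(va, vb), xcorr = cross_correlation(va, vb))
  })
  dist <- vapply(res, `[[`, numeric(1), "dist")
  dtw_norm <- normalize_sync(dist)
  data.frame(trial_id = trials,
             dtw_raw = -dist,
             dtw_norm = dtw_norm,
             xcorr = vapply(res, `[[`, numeric(1), "xcorr"),
             gamma_t = gamma_weight(dtw_norm, gamma0))
}
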