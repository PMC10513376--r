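# Shared fixtures and independent oracles (brute-force reimplementations
# kept deliberately naive and separate from the package's vectorized code).

# a straight-line track: constant velocity vel (um/frame) from start
line_track <- function(track_id, n, start = c(0, 0, 0), vel = c(1, 0, 0),
                       experiment_id = "exp1", label = "poking") {
  data.table::data.table(
    experiment_id = experiment_id, track_id = track_id,
    frame_index = seq_len(n),
    x = start[1] + vel[1] * (seq_len(n) - 1),
    y = start[2] + vel[2] * (seq_len(n) - 1),
    z = start[3] + vel[3] * (seq_len(n) - 1),
    label = label)
}

toy_dataset <- function() {
  pts <- rbind(line_track("t1", 10), line_track("t2", 10, start = c(5, 5, 0),
                                                label = "scanning"))
  synkin::track_dataset(pts, name = "toy")
}

random_track_dataset <- function(n_tracks = 5, n_points = 12, seed = 1,
                                 labels = "poking") {
  set.seed(seed)
  pts <- data.table::rbindlist(lapply(seq_len(n_tracks), function(i) {
    data.table::data.table(
      experiment_id = "exp1", track_id = paste0("t", i),
      frame_index = seq_len(n_points),
      x = cumsum(rnorm(n_points, sd = 2)),
      y = cumsum(rnorm(n_points, sd = 2)),
      z = rnorm(n_points, sd = 0.2),
      label = sample(labels, n_points, replace = TRUE))
  }))
  synkin::track_dataset(pts, name = "random")
}

# ---- oracle: explicit-window aggregation --------------------------------
# recomputes window means/variances/scalars by materializing every window
oracle_window <- function(base_dt, width = 5, coast_threshold = 1 / 30) {
  n <- nrow(base_dt)
  h <- (width - 1) / 2
  feats <- intersect(synkin::feature_names_canonical()[1:29],
                     names(base_dt))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    c_i <- min(max(i, h + 1), n - h)       # edge copy: clamp the center
    win <- base_dt[(c_i - h):(c_i + h), ]
    out <- list()
    for (f in feats) {
      out[[paste0("mean_", f)]] <- mean(win[[f]])
      out[[paste0("var_", f)]] <- stats::var(win[[f]])
    }
    p1 <- unlist(win[1, c("position_x", "position_y", "position_z")])
    p2 <- unlist(win[width, c("position_x", "position_y", "position_z")])
    out$total_window_displacement <- sqrt(sum((p2 - p1)^2))
    out$cumulative_track_length <- sum(win$delta_displacement_length)
    out$coast_coefficient <- mean(win$speed < coast_threshold)
    rows[[i]] <- out
  }
  data.table::rbindlist(rows)
}

# ---- oracle: one-way ANOVA F --------------------------------------------
oracle_anova_f <- function(x, y) {
  y <- factor(y)
  groups <- split(x, y)
  k <- length(groups)
  n <- length(x)
  grand <- mean(x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ssb <= 0) return(0)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# ---- oracle: brute-force greedy mRMR trace ------------------------------
# re-evaluates the criterion over all candidates at every step
oracle_mrmr <- function(X, y, n, scheme = "quotient") {
  f <- vapply(seq_len(ncol(X)), function(j) oracle_anova_f(X[, j], y), 0)
  names(f) <- colnames(X)
  selected <- character(0)
  for (step in seq_len(n)) {
    cand <- setdiff(colnames(X), selected)
    crit <- vapply(cand, function(cf) {
      if (length(selected) == 0) return(f[[cf]])
      r <- vapply(selected, function(sf) {
        v <- suppressWarnings(cor(X[, cf], X[, sf]))
        if (is.na(v)) 0 else abs(v)
      }, 0)
      red <- mean(r)
      if (scheme == "quotient") f[[cf]] / max(red, 1e-12)
      else f[[cf]] - red
    }, 0)
    best <- cand[order(-crit, cand)][1]
    selected <- c(selected, best)
  }
  selected
}

# small labeled feature matrix built from the simulator
small_sim_fm <- function(scheme = "binary", n_exp = 3, cells = 15,
                         frames = 20, seed = 99) {
  ds <- synkin::simulate_field(synkin::sim_config(
    n_experiments = n_exp, cells_per_experiment = cells, n_frames = frames,
    short_track_fraction = 0, seed = seed))
  ds <- synkin::map_labels(ds, scheme)
  synkin::assemble_feature_matrix(synkin::filter_short_tracks(ds))
}
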