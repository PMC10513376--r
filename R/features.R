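# Feature engineering: 29 per-timepoint base features plus 61 window
# features over a centered 5-point moving window, 90 columns total.

BASE_FEATURES <- c(
  "acceleration_x", "acceleration_y", "acceleration_z",
  "acceleration_global",
  "delta_displacement_x", "delta_displacement_y", "delta_displacement_z",
  "delta_displacement_length",
  "displacement_x", "displacement_y", "displacement_z",
  "displacement_length",
  "distance_from_origin",
  "position_x", "position_y", "position_z",
  "elapsed_time_track", "elapsed_time_prev",
  "velocity_x", "velocity_y", "velocity_z",
  "speed",
  "velocity_angle_x", "velocity_angle_y", "velocity_angle_z",
  "dist_nearest_1", "avg_dist_nearest_3", "avg_dist_nearest_5",
  "avg_dist_nearest_9")

WINDOW_SCALARS <- c("total_window_displacement", "cumulative_track_length",
                    "coast_coefficient")

#' Canonical feature dictionary
#'
#' The 90 feature names in their canonical order: the 29 base features
#' (kinematics, positions, timing, neighbor distances), their 29 window
#' means, their 29 window variances, and 3 window scalars (total window
#' displacement, cumulative track length, coast coefficient). This order is
#' stable across runs and defines the columns of every feature matrix.
#'
#' @return character vector of length 90.
#' @export
feature_names_canonical <- function() {
  c(BASE_FEATURES, paste0("mean_", BASE_FEATURES),
    paste0("var_", BASE_FEATURES), WINDOW_SCALARS)
}

#' Sliding-window specification
#'
#' Windows are `width_points` frames wide (5 frames = 5 min at the nominal
#' 1 frame/min interval), centered on each timepoint, and advance by
#' `step_points` frames. For timepoints too close to a track's start or end
#' for a full window, the first/last computed window values are copied over.
#'
#' @param width_points odd window width in frames (default 5).
#' @param center logical; windows are centered (only `TRUE` is supported).
#' @param step_points window step in frames (default 1).
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(width_points = 5L, center = TRUE, step_points = 1L) {
  width_points <- as.integer(width_points)
  step_points <- as.integer(step_points)
  if (is.na(width_points) || width_points < 3L || width_points %% 2L == 0L)
    stop("`width_points` must be an odd integer >= 3")
  if (!isTRUE(center)) stop("only centered windows are supported")
  if (is.na(step_points) || step_points < 1L)
    stop("`step_points` must be >= 1")
  structure(list(width_points = width_points, center = TRUE,
                 step_points = step_points), class = "window_spec")
}

#' Per-timepoint kinematic features for every track
#'
#' Computes the kinematic subset of the base features from positions and
#' times: velocity by central difference at interior points and one-sided
#' difference at track endpoints, acceleration by the same scheme applied
#' to the velocity series, step ("delta") displacements, displacement from
#' the track origin, elapsed times, speed, and the angle of the velocity
#' vector with each axis (degrees in \[0, 180\]; 90 where speed is zero).
#'
#' @param ds a [track_dataset()]; every track must have >= 2 points.
#' @return a data.table keyed by (experiment_id, track_id, frame_index)
#'   with the kinematic base feature columns (neighbor features unset).
#' @export
compute_kinematics <- function(ds) {
  stopifnot(inherits(ds, "track_dataset"))
  short <- ds$points[, .N, by = .(experiment_id, track_id)][N < 2L]
  if (nrow(short) > 0L)
    stop("track(s) with fewer than 2 points (filter first): ",
         paste(short[, paste0("(", experiment_id, ", ", track_id, ")")],
               collapse = ", "))
  dt <- ds$points[, c(.(frame_index = frame_index, time_s = time_s,
                        label = label),
                      kinematics_one(x, y, z, time_s)),
                  by = .(experiment_id, track_id)]
  setkeyv(dt, c("experiment_id", "track_id", "frame_index"))
  dt[]
}

# central/one-sided difference of series f over times t
.cdiff <- function(f, t) {
  n <- length(f)
  if (n == 2L) return((f[2L] - f[1L]) / (t[2L] - t[1L]) * c(1, 1))
  fwd <- shift(f, -1L); bwd <- shift(f, 1L)
  tf <- shift(t, -1L); tb <- shift(t, 1L)
  d <- (fwd - bwd) / (tf - tb)
  d[1L] <- (f[2L] - f[1L]) / (t[2L] - t[1L])
  d[n] <- (f[n] - f[n - 1L]) / (t[n] - t[n - 1L])
  d
}

kinematics_one <- function(x, y, z, t) {
  n <- length(x)
  vx <- .cdiff(x, t); vy <- .cdiff(y, t); vz <- .cdiff(z, t)
  ax <- .cdiff(vx, t); ay <- .cdiff(vy, t); az <- .cdiff(vz, t)
  speed <- sqrt(vx^2 + vy^2 + vz^2)
  dx <- x - x[1L]; dy <- y - y[1L]; dz <- z - z[1L]
  disp_len <- sqrt(dx^2 + dy^2 + dz^2)
  ddx <- c(0, diff(x)); ddy <- c(0, diff(y)); ddz <- c(0, diff(z))
  angle <- function(v) {
    a <- rep(90, n)
    ok <- speed > 0
    a[ok] <- acos(pmin(1, pmax(-1, v[ok] / speed[ok]))) * 180 / pi
    a
  }
  list(
    acceleration_x = ax, acceleration_y = ay, acceleration_z = az,
    acceleration_global = sqrt(ax^2 + ay^2 + az^2),
    delta_displacement_x = ddx, delta_displacement_y = ddy,
    delta_displacement_z = ddz,
    delta_displacement_length = sqrt(ddx^2 + ddy^2 + ddz^2),
    displacement_x = dx, displacement_y = dy, displacement_z = dz,
    displacement_length = disp_len,
    distance_from_origin = disp_len,
    position_x = x, position_y = y, position_z = z,
    elapsed_time_track = t - t[1L],
    elapsed_time_prev = c(FRAME_INTERVAL_S, diff(t)),
    velocity_x = vx, velocity_y = vy, velocity_z = vz,
    speed = speed,
    velocity_angle_x = angle(vx), velocity_angle_y = angle(vy),
    velocity_angle_z = angle(vz))
}

#' Nearest-neighbor distance features
#'
#' For each (track, frame), Euclidean distances from the cell to every
#' other cell of the same experiment present at that frame:
#' `dist_nearest_1` is the minimum and `avg_dist_nearest_k` the mean of the
#' k smallest for k in {3, 5, 9}. When fewer than k neighbors are present
#' the mean is taken over those available; a cell alone at a frame receives
#' `fallback` (default: the diagonal of its experiment's bounding box) so
#' the feature matrix stays dense.
#'
#' @param ds a [track_dataset()].
#' @param fallback numeric distance used when a cell has no neighbors, or
#'   `NULL` for the per-experiment bounding-box diagonal.
#' @return a data.table keyed by (experiment_id, track_id, frame_index)
#'   with columns `dist_nearest_1`, `avg_dist_nearest_3/5/9`.
#' @export
compute_neighbor_features <- function(ds, fallback = NULL) {
  stopifnot(inherits(ds, "track_dataset"))
  pts <- ds$points
  diag_by_exp <- pts[, .(fb = sqrt(diff(range(x))^2 + diff(range(y))^2 +
                                     diff(range(z))^2)),
                     by = experiment_id]
  fb_map <- setNames(diag_by_exp$fb, diag_by_exp$experiment_id)
  out <- pts[, {
    m <- cbind(x, y, z)
    nc <- .N
    fb <- if (is.null(fallback)) fb_map[[experiment_id[1L]]] else fallback
    if (nc == 1L) {
      list(track_id = track_id,
           dist_nearest_1 = fb, avg_dist_nearest_3 = fb,
           avg_dist_nearest_5 = fb, avg_dist_nearest_9 = fb)
    } else {
      dm <- as.matrix(stats::dist(m))
      diag(dm) <- Inf
      srt <- apply(dm, 1L, sort)          # columns: sorted dists per cell
      avg_k <- function(k) {
        kk <- min(k, nc - 1L)
        if (kk == 1L) srt[1L, ] else colMeans(srt[seq_len(kk), , drop = FALSE])
      }
      list(track_id = track_id,
           dist_nearest_1 = srt[1L, ],
           avg_dist_nearest_3 = avg_k(3L),
           avg_dist_nearest_5 = avg_k(5L),
           avg_dist_nearest_9 = avg_k(9L))
    }
  }, by = .(experiment_id, frame_index)]
  setkeyv(out, c("experiment_id", "track_id", "frame_index"))
  out[]
}

#' Window aggregation of base features for one track
#'
#' For every timepoint with a full centered window: the mean and sample
#' variance (divisor n-1) of each base feature over the window, the total
#' displacement across the window (straight-line distance between the
#' window's first and last positions), the cumulative track length (sum of
#' step displacements of the window's points), and the coast coefficient
#' (fraction of window points whose speed is below `coast_threshold`; with
#' the default threshold 1/30 um/s a point "coasts" when it moves less than
#' 2 um/min). Timepoints within half a window of the track's start or end
#' copy the first/last computed window values.
#'
#' @param track_features data.table of base features for a single track, in
#'   frame order (as produced by [compute_kinematics()] joined with
#'   [compute_neighbor_features()], restricted to one track).
#' @param spec a [window_spec()].
#' @param coast_threshold speed threshold in um/s (default 1/30).
#' @return data.table with 61 window-feature columns, one row per input
#'   row retained by the window step.
#' @export
window_aggregate <- function(track_features, spec = window_spec(),
                             coast_threshold = 1 / 30) {
  stopifnot(inherits(spec, "window_spec"))
  dt <- as.data.table(track_features)
  missing_cols <- setdiff(BASE_FEATURES, names(dt))
  # neighbor features may be absent in unit-level use; window stats are
  # computed for whichever base columns are present
  base <- setdiff(BASE_FEATURES, missing_cols)
  w <- spec$width_points
  h <- (w - 1L) %/% 2L
  n <- nrow(dt)
  if (n < w)
    stop("track has ", n, " points but the window needs ", w)
  lags <- seq.int(-h, h)
  out <- data.table(.row = seq_len(n))
  for (col in base) {
    s <- shift(dt[[col]], lags)            # list of w shifted vectors
    sm <- Reduce(`+`, s)
    mu <- sm / w
    sqdev <- Reduce(`+`, lapply(s, function(v) (v - mu)^2))
    set(out, j = paste0("mean_", col), value = mu)
    set(out, j = paste0("var_", col), value = sqdev / (w - 1))
  }
  px <- shift(dt$position_x, lags[c(1L, w)])
  py <- shift(dt$position_y, lags[c(1L, w)])
  pz <- shift(dt$position_z, lags[c(1L, w)])
  set(out, j = "total_window_displacement",
      value = sqrt((px[[2L]] - px[[1L]])^2 + (py[[2L]] - py[[1L]])^2 +
                     (pz[[2L]] - pz[[1L]])^2))
  dl <- shift(dt$delta_displacement_length, lags)
  set(out, j = "cumulative_track_length", value = Reduce(`+`, dl))
  sp <- shift(dt$speed, lags)
  set(out, j = "coast_coefficient",
      value = Reduce(`+`, lapply(sp, function(v)
        as.numeric(v < coast_threshold))) / w)
  # edge rule: copy first/last computed window values outward
  first_full <- h + 1L
  last_full <- n - h
  wcols <- setdiff(names(out), ".row")
  for (col in wcols) {
    v <- out[[col]]
    v[seq_len(h)] <- v[first_full]
    v[seq.int(last_full + 1L, length.out = h)] <- v[last_full]
    set(out, j = col, value = v)
  }
  if (spec$step_points > 1L) {
    centers <- seq.int(first_full, last_full, by = spec$step_points)
    keep <- sort(unique(c(seq_len(h), centers,
                          seq.int(last_full + 1L, length.out = h))))
    out <- out[keep]
  }
  out[, .row := NULL]
  out[]
}

#' Assemble the 90-column feature matrix
#'
#' Runs kinematics, neighbor distances and window aggregation over a
#' filtered dataset and returns one sample per (track, timepoint) with
#' exactly the 90 features of [feature_names_canonical()], plus the keys
#' (experiment_id, track_id, frame_index) and the behavior label.
#'
#' @param ds a filtered [track_dataset()] (all tracks >= window width).
#' @param spec a [window_spec()].
#' @param coast_threshold speed threshold in um/s for the coast
#'   coefficient (default 1/30).
#' @param neighbor_fallback see [compute_neighbor_features()].
#' @param require_labels if `TRUE` (training mode) an unlabeled timepoint
#'   is an error; if `FALSE` (prediction mode) labels may be missing.
#' @return a `feature_matrix`: a data.table with key columns, the 90
#'   features, and `label`; feature names in `attr(, "feature_names")`.
#' @export
assemble_feature_matrix <- function(ds, spec = window_spec(),
                                    coast_threshold = 1 / 30,
                                    neighbor_fallback = NULL,
                                    require_labels = FALSE) {
  stopifnot(inherits(ds, "track_dataset"))
  if (spec$step_points != 1L)
    stop("assemble_feature_matrix() requires step_points = 1 (one sample ",
         "per timepoint)")
  lens <- ds$points[, .N, by = .(experiment_id, track_id)]
  if (any(lens$N < spec$width_points))
    stop("dataset contains tracks shorter than the window (",
         spec$width_points, " points); apply filter_short_tracks() first")
  kin <- compute_kinematics(ds)
  nb <- compute_neighbor_features(ds, fallback = neighbor_fallback)
  base <- nb[kin]                          # keyed join
  setkeyv(base, c("experiment_id", "track_id", "frame_index"))
  if (require_labels && anyNA(base$label))
    stop("unlabeled timepoints present but labels are required")
  wins <- base[, window_aggregate(.SD, spec, coast_threshold),
               by = .(experiment_id, track_id),
               .SDcols = c(BASE_FEATURES, "frame_index")]
  fm <- cbind(base[, c("experiment_id", "track_id", "frame_index", "label",
                       BASE_FEATURES), with = FALSE],
              wins[, setdiff(names(wins), c("experiment_id", "track_id")),
                   with = FALSE])
  setcolorder(fm, c("experiment_id", "track_id", "frame_index", "label",
                    feature_names_canonical()))
  setattr(fm, "feature_names", feature_names_canonical())
  setattr(fm, "class", c("feature_matrix", class(fm)))
  fm[]
}

#' Extract the numeric feature block of a feature matrix
#' @param fm a `feature_matrix`.
#' @param features optional character vector of feature names to keep.
#' @return numeric matrix with one row per sample.
#' @export
feature_block <- function(fm, features = NULL) {
  features <- features %||% attr(fm, "feature_names") %||%
    feature_names_canonical()
  missing_cols <- setdiff(features, names(fm))
  if (length(missing_cols) > 0L)
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  as.matrix(as.data.table(fm)[, features, with = FALSE])
}

#' Write / read a feature matrix as CSV with a sidecar name list
#'
#' The CSV holds keys, label and features; the sidecar `<path>.features.txt`
#' lists the feature names in canonical order, one per line.
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  fwrite(as.data.table(fm), path)
  writeLines(attr(fm, "feature_names") %||% feature_names_canonical(),
             paste0(path, ".features.txt"))
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  fm <- fread(path)
  side <- paste0(path, ".features.txt")
  fn <- if (file.exists(side)) readLines(side) else feature_names_canonical()
  fm[, `:=`(experiment_id = as.character(experiment_id),
            track_id = as.character(track_id),
            label = as.character(label))]
  setkeyv(fm, c("experiment_id", "track_id", "frame_index"))
  setattr(fm, "feature_names", fn)
  setattr(fm, "class", c("feature_matrix", class(fm)))
  fm[]
}
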