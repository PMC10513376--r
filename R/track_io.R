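#' CSV dialect for Imaris-like track exports
#'
#' Track tables exported from microscopy analysis software vary in their
#' column names, header layout and bookkeeping columns. A `dialect_config`
#' describes how to read one such table: the number of header rows (only the
#' first is used for column names; extra header rows, e.g. unit rows, are
#' skipped), a map from the internal column roles to the column names found
#' in the file, and a regular expression identifying fluorescence-channel
#' columns, which are dropped on input because they carry no positional
#' information.
#'
#' @param header_rows integer, total header rows in the file (>= 1).
#' @param columns named character vector mapping roles to file column names.
#'   Recognized roles: `track_id`, `frame`, `x`, `y`, `z` (positions in um),
#'   `label`, `experiment_id`, `donor_id`, `disease`, `treatment`. Roles
#'   `track_id`, `frame`, `x`, `y` are required at read time.
#' @param channel_pattern regular expression; matching columns are dropped.
#' @return an object of class `dialect_config`.
#' @export
#' @examples
#' dialect_config(columns = c(track_id = "TrackID", frame = "Frame",
#'                            x = "PositionX", y = "PositionY"))
dialect_config <- function(header_rows = 1L,
                           columns = c(
                             track_id = "TrackID", frame = "Frame",
                             x = "PositionX", y = "PositionY",
                             z = "PositionZ", label = "Behavior",
                             experiment_id = "ExperimentID",
                             donor_id = "DonorID", disease = "Disease",
                             treatment = "Treatment"),
                           channel_pattern = "Channel|Intensity") {
  header_rows <- as.integer(header_rows)
  if (is.na(header_rows) || header_rows < 1L)
    stop("`header_rows` must be a positive integer")
  known <- c("track_id", "frame", "x", "y", "z", "label", "experiment_id",
             "donor_id", "disease", "treatment")
  if (is.null(names(columns)) || !all(names(columns) %in% known))
    stop("`columns` must be named with roles among: ",
         paste(known, collapse = ", "))
  req <- c("track_id", "frame", "x", "y")
  if (!all(req %in% names(columns)))
    stop("`columns` must define at least: ", paste(req, collapse = ", "))
  structure(list(header_rows = header_rows, columns = columns,
                 channel_pattern = channel_pattern),
            class = "dialect_config")
}

RAW_LABELS <- c("poking", "round", "dancing", "scanning")
THREE_CLASS_LABELS <- c("poking", "dancing", "scanning")
BINARY_LABELS <- c("synapse", "kinapse")
FRAME_INTERVAL_S <- 60

POINT_COLS <- c("experiment_id", "track_id", "frame_index", "time_s",
                "x", "y", "z", "label", "donor_id", "disease", "treatment")

#' Construct a track dataset
#'
#' The central container: one row per (track, timepoint), ordered by
#' experiment, track and frame. Frames within a track must be consecutive
#' (no duplicates, no gaps); `time_s` is track-relative seconds assuming
#' the nominal 60 s frame interval unless supplied.
#'
#' @param points a data.frame/data.table with at least `track_id`,
#'   `frame_index`, `x`, `y`; optional `experiment_id` (default "exp1"),
#'   `z` (default 0 with a warning: 2-D acquisition), `time_s`, `label`,
#'   `donor_id`, `disease`, `treatment`.
#' @param name dataset name.
#' @return an object of class `track_dataset`.
#' @export
track_dataset <- function(points, name = "dataset") {
  dt <- as.data.table(points)
  if (!all(c("track_id", "frame_index", "x", "y") %in% names(dt)))
    stop("`points` must contain track_id, frame_index, x, y")
  if (!"experiment_id" %in% names(dt)) dt[, experiment_id := "exp1"]
  if (!"z" %in% names(dt)) {
    warning("no z coordinate: filling z = 0 (2-D acquisition assumed)")
    dt[, z := 0]
  }
  for (col in c("label", "donor_id", "disease", "treatment")) {
    if (!col %in% names(dt)) dt[, (col) := NA_character_]
    else set(dt, j = col, value = as.character(dt[[col]]))
  }
  dt[, `:=`(experiment_id = as.character(experiment_id),
            track_id = as.character(track_id),
            frame_index = as.integer(frame_index),
            x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
            label = as.character(label))]
  setkeyv(dt, c("experiment_id", "track_id", "frame_index"))
  if (!"time_s" %in% names(dt))
    dt[, time_s := FRAME_INTERVAL_S * (frame_index - frame_index[1L]),
       by = .(experiment_id, track_id)]
  setcolorder(dt, POINT_COLS)
  ds <- structure(list(points = dt[], name = as.character(name)),
                  class = "track_dataset")
  validate_track_dataset(ds)
  ds
}

validate_track_dataset <- function(ds) {
  dt <- ds$points
  bad <- dt[, {
    d <- diff(frame_index)
    list(dup = any(d == 0L), gap = any(d > 1L), nonmono = any(d < 0L))
  }, by = .(experiment_id, track_id)]
  offenders <- bad[dup | gap | nonmono]
  if (nrow(offenders) > 0L)
    stop("track(s) with duplicated, gapped or non-monotone frames: ",
         paste(offenders[, paste0("(", experiment_id, ", ", track_id, ")")],
               collapse = ", "))
  lab <- dt$label[!is.na(dt$label)]
  unknown <- setdiff(unique(lab), c(RAW_LABELS, BINARY_LABELS))
  if (length(unknown) > 0L)
    stop("unknown behavior label(s): ", paste(unknown, collapse = ", "))
  invisible(ds)
}

#' @export
print.track_dataset <- function(x, ...) {
  nt <- nrow(unique(x$points[, .(experiment_id, track_id)]))
  cat(sprintf(
    "<track_dataset '%s': %d tracks, %d points, %d experiment(s)>\n",
    x$name, nt, nrow(x$points), length(unique(x$points$experiment_id))))
  invisible(x)
}

#' Number of tracks in a dataset
#' @param ds a `track_dataset`.
#' @return integer count of (experiment_id, track_id) pairs.
#' @export
n_tracks <- function(ds) {
  stopifnot(inherits(ds, "track_dataset"))
  nrow(unique(ds$points[, .(experiment_id, track_id)]))
}

#' Read cell tracks from a CSV file
#'
#' Reads a per-timepoint track table in the dialect described by a
#' [dialect_config()]: columns are renamed to internal roles,
#' fluorescence-channel columns are dropped, rows are grouped by track and
#' sorted by frame, and the result is validated (consecutive frames, known
#' labels). Positions are taken as continuous micrometers in a fixed lab
#' frame. A missing z column is accepted and filled with 0 (2-D data).
#'
#' @param path path to a CSV file.
#' @param dialect a [dialect_config()].
#' @param name dataset name (default: file name).
#' @return a [track_dataset()].
#' @export
read_tracks <- function(path, dialect = dialect_config(), name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(inherits(dialect, "dialect_config"))
  raw <- fread(path, header = TRUE, skip = 0L)
  if (dialect$header_rows > 1L)
    raw <- raw[-seq_len(dialect$header_rows - 1L)]
  cols <- dialect$columns
  req <- c("track_id", "frame", "x", "y")
  missing_req <- req[!cols[req] %in% names(raw)]
  if (length(missing_req) > 0L)
    stop("missing required column(s): ",
         paste(cols[missing_req], collapse = ", "))
  if (nzchar(dialect$channel_pattern)) {
    chan <- grep(dialect$channel_pattern, names(raw), value = TRUE)
    chan <- setdiff(chan, unname(cols))
    if (length(chan) > 0L) raw[, (chan) := NULL]
  }
  present <- cols[cols %in% names(raw)]
  out <- raw[, unname(present), with = FALSE]
  setnames(out, unname(present), names(present))
  out[, c("frame_index", "x", "y") :=
        .(as.integer(frame), as.numeric(x), as.numeric(y))]
  out[, frame := NULL]
  if ("label" %in% names(out)) out[is.na(label) | label == "", label := NA]
  track_dataset(out, name = name %||% basename(path))
}

#' Write cell tracks to a CSV file
#'
#' Inverse of [read_tracks()]: serializes a dataset in the dialect's column
#' names so that a write/read round trip reproduces the dataset.
#'
#' @param ds a [track_dataset()].
#' @param path output CSV path.
#' @param dialect a [dialect_config()].
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ds, path, dialect = dialect_config()) {
  stopifnot(inherits(ds, "track_dataset"))
  cols <- dialect$columns
  out <- copy(ds$points)
  out[, frame := frame_index]
  roles <- intersect(names(cols), c(names(out)))
  out <- out[, roles, with = FALSE]
  setnames(out, roles, unname(cols[roles]))
  fwrite(out, path)
  invisible(path)
}

#' Remove tracks shorter than a minimum duration
#'
#' Cells that leave the imaged field quickly yield tracks too short for the
#' 5-point (300 s) sliding window; they are excluded. The operation is
#' idempotent and leaves its input unmodified.
#'
#' @param ds a [track_dataset()].
#' @param min_points minimum number of timepoints to retain a track
#'   (default 5, i.e. 300 s at 1 frame/min).
#' @return a filtered [track_dataset()].
#' @export
filter_short_tracks <- function(ds, min_points = 5L) {
  stopifnot(inherits(ds, "track_dataset"))
  min_points <- as.integer(min_points)
  if (is.na(min_points) || min_points < 1L)
    stop("`min_points` must be >= 1")
  pts <- ds$points[, if (.N >= min_points) .SD,
                   by = .(experiment_id, track_id)]
  out <- ds
  out$points <- pts
  out
}

#' Merge several track datasets
#'
#' Union of tracks across datasets. Experiments are the grouping unit for
#' all cross-validation, so a collision on (experiment_id, track_id) is an
#' error rather than silently deduplicated.
#'
#' @param ds_list list of [track_dataset()] objects.
#' @param name name for the merged dataset.
#' @return a [track_dataset()].
#' @export
merge_datasets <- function(ds_list, name = "merged") {
  stopifnot(length(ds_list) >= 1L,
            all(vapply(ds_list, inherits, TRUE, "track_dataset")))
  pts <- rbindlist(lapply(ds_list, `[[`, "points"))
  keys <- unique(pts[, .(experiment_id, track_id)])
  per_ds <- lapply(ds_list, function(d)
    unique(d$points[, .(experiment_id, track_id)]))
  n_total <- sum(vapply(per_ds, nrow, 0L))
  if (nrow(keys) != n_total) {
    all_keys <- rbindlist(per_ds)
    coll <- all_keys[duplicated(all_keys)]
    stop("(experiment_id, track_id) collision(s) while merging: ",
         paste(unique(
           coll[, paste0("(", experiment_id, ", ", track_id, ")")]),
           collapse = ", "))
  }
  track_dataset(pts, name = name)
}

#' Map behavior labels to a classification scheme
#'
#' Under `three_class`, the raw label `round` is merged into `poking` (the
#' two differ only morphologically, which positional features cannot see)
#' and the labels are {poking, dancing, scanning}. Under `binary`, poking
#' and round map to `synapse` (long-lasting arrested contact) while dancing
#' and scanning map to `kinapse` (motile transient contact). Unlabeled
#' points pass through unchanged; track and point counts are preserved.
#'
#' @param ds a [track_dataset()].
#' @param scheme `"three_class"` or `"binary"`.
#' @return a relabeled [track_dataset()].
#' @export
map_labels <- function(ds, scheme = c("three_class", "binary")) {
  stopifnot(inherits(ds, "track_dataset"))
  scheme <- match.arg(scheme)
  map <- if (scheme == "three_class") {
    c(poking = "poking", round = "poking", dancing = "dancing",
      scanning = "scanning")
  } else {
    c(poking = "synapse", round = "synapse", dancing = "kinapse",
      scanning = "kinapse")
  }
  pts <- copy(ds$points)
  lab <- pts$label
  known <- is.na(lab) | lab %in% names(map)
  if (!all(known))
    stop("unrecognized raw label(s): ",
         paste(unique(lab[!known]), collapse = ", "))
  pts[!is.na(label), label := unname(map[label])]
  out <- ds
  out$points <- pts
  out
}

#' Class labels of a scheme
#' @param scheme `"three_class"` or `"binary"`.
#' @return character vector of class labels in canonical order.
#' @export
scheme_classes <- function(scheme = c("three_class", "binary")) {
  scheme <- match.arg(scheme)
  if (scheme == "three_class") THREE_CLASS_LABELS else BINARY_LABELS
}

`%||%` <- function(a, b) if (is.null(a)) b else a
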