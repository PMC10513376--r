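# Parametric simulator of labeled T-cell tracks. Three motion models
# emulate the phenomenology of the behaviors: poking cells revert toward an
# anchor with small noise (synapse-like arrest), scanning cells follow a
# persistent random walk with large steps (fast crawling), dancing cells
# oscillate inside a bounded envelope around an anchor that occasionally
# relocates. The generative forms and their defaults are this package's
# own; they are tuned once so the classes are learnable but overlap.

#' Behavior motion-model parameters
#'
#' Units are micrometers and frames (1 frame = 60 s nominal).
#'
#' @param poking_rho anchor-reversion rate in (0, 1): each frame the offset
#'   from the anchor shrinks by this fraction before noise is added.
#' @param poking_sigma per-axis step noise of poking cells (um); the
#'   default keeps most per-frame displacements under the 2 um/min coast
#'   threshold.
#' @param scanning_step mean step length of scanning cells (um/frame);
#'   6 um/min is a typical crawling speed for activated T cells.
#' @param scanning_kappa heading noise of scanning cells (radians/frame
#'   s.d.); 0 gives perfectly straight, collinear motion.
#' @param dancing_sigma radius of the dancing oscillation envelope (um):
#'   horizontal offsets from the anchor never exceed it.
#' @param dancing_p_jump per-frame probability that a dancing cell
#'   relocates its anchor.
#' @param dancing_jump_length anchor relocation distance (um).
#' @param sigma_z half-width of the uniform z jitter (um); z is
#'   near-constant because the co-culture is a monolayer.
#' @return an object of class `behavior_params`.
#' @export
behavior_params <- function(poking_rho = 0.6, poking_sigma = 0.45,
                            scanning_step = 6, scanning_kappa = 0.35,
                            dancing_sigma = 2.5, dancing_p_jump = 0.05,
                            dancing_jump_length = 8, sigma_z = 0.15) {
  stopifnot(poking_rho > 0, poking_rho < 1, poking_sigma >= 0,
            scanning_step > 0, scanning_kappa >= 0, dancing_sigma > 0,
            dancing_p_jump >= 0, dancing_p_jump <= 1,
            dancing_jump_length >= 0, sigma_z >= 0)
  structure(as.list(environment()), class = "behavior_params")
}

#' Simulation configuration
#'
#' Defaults emulate the acquisition geometry of the motivating assays:
#' fields of ~100 cells imaged for 2 h at 1 frame/min (120 frames), with a
#' poking-heavy behavior mixture and a fraction of short tracks (cells that
#' leave the field early) injected to exercise the track filter.
#'
#' @param n_experiments number of simulated experiments.
#' @param cells_per_experiment cells per experiment.
#' @param n_frames frames per full track (default 120 = 2 h).
#' @param field_um field side lengths in um, length-2 vector.
#' @param mixture named behavior proportions (must sum to 1).
#' @param short_track_fraction expected fraction of cells yielding tracks
#'   of fewer than 5 frames.
#' @param switch_mean_dwell mean behavior dwell time in frames for the
#'   optional semi-Markov behavior switching, or `NULL` (default) for
#'   single-behavior tracks.
#' @param heterogeneity_sdlog s.d. (log scale) of the per-track lognormal
#'   multiplier applied to the motion scales, emulating cell-to-cell
#'   variability; this is what makes the classes overlap.
#' @param params a [behavior_params()].
#' @param experiment_prefix prefix for generated experiment ids.
#' @param seed integer seed; the whole field is reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_experiments = 6L, cells_per_experiment = 100L,
                       n_frames = 120L, field_um = c(300, 300),
                       mixture = c(poking = 0.5, scanning = 0.3,
                                   dancing = 0.2),
                       short_track_fraction = 0.1,
                       switch_mean_dwell = NULL,
                       heterogeneity_sdlog = 0.3,
                       params = behavior_params(),
                       experiment_prefix = "sim", seed = 1L) {
  if (abs(sum(mixture) - 1) > 1e-8) stop("`mixture` must sum to 1")
  if (is.null(names(mixture)) ||
      !setequal(names(mixture), THREE_CLASS_LABELS))
    stop("`mixture` must be named with: ",
         paste(THREE_CLASS_LABELS, collapse = ", "))
  stopifnot(n_frames >= 5L, n_experiments >= 1L,
            cells_per_experiment >= 1L, length(field_um) == 2L,
            short_track_fraction >= 0, short_track_fraction < 1,
            inherits(params, "behavior_params"))
  structure(list(n_experiments = as.integer(n_experiments),
                 cells_per_experiment = as.integer(cells_per_experiment),
                 n_frames = as.integer(n_frames),
                 field_um = as.numeric(field_um),
                 frame_interval_s = FRAME_INTERVAL_S,
                 mixture = mixture[THREE_CLASS_LABELS],
                 short_track_fraction = short_track_fraction,
                 switch_mean_dwell = switch_mean_dwell,
                 heterogeneity_sdlog = heterogeneity_sdlog,
                 params = params,
                 experiment_prefix = experiment_prefix,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# reflect coordinates into [0, L]
.reflect <- function(v, L) {
  v <- abs(v)
  period <- 2 * L
  v <- v %% period
  ifelse(v > L, period - v, v)
}

#' Simulate one cell track
#'
#' Generates an (x, y, z) trajectory frame by frame according to the
#' behavior label of each frame (see [behavior_params()] for the motion
#' models), recording the label per timepoint. Deterministic given `seed`.
#'
#' @param behavior_sequence a single behavior name or a vector of length
#'   `n_frames` with one of poking/scanning/dancing per frame.
#' @param params a [behavior_params()].
#' @param n_frames number of frames (default: length of the sequence).
#' @param seed optional integer seed (set locally).
#' @param start length-3 start position (um); default origin.
#' @param field optional length-2 field size; when given, x and y are
#'   reflected back into \[0, field\].
#' @return data.table with columns frame_index, x, y, z, label.
#' @export
simulate_track <- function(behavior_sequence, params = behavior_params(),
                           n_frames = length(behavior_sequence),
                           seed = NULL, start = c(0, 0, 0), field = NULL) {
  stopifnot(inherits(params, "behavior_params"), n_frames >= 1L)
  if (length(behavior_sequence) == 1L)
    behavior_sequence <- rep(behavior_sequence, n_frames)
  if (length(behavior_sequence) != n_frames)
    stop("`behavior_sequence` must have length 1 or n_frames")
  unknown <- setdiff(unique(behavior_sequence), THREE_CLASS_LABELS)
  if (length(unknown) > 0L)
    stop("unknown behavior(s): ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  p <- params
  pos <- matrix(NA_real_, n_frames, 2L)
  pos[1L, ] <- start[1:2]
  anchor <- start[1:2]
  heading <- runif(1L, 0, 2 * pi)
  for (i in seq_len(n_frames)[-1L]) {
    b <- behavior_sequence[i]
    if (b == "poking") {
      if (behavior_sequence[i - 1L] != "poking") anchor <- pos[i - 1L, ]
      pos[i, ] <- anchor + (1 - p$poking_rho) * (pos[i - 1L, ] - anchor) +
        p$poking_sigma * rnorm(2L)
    } else if (b == "scanning") {
      heading <- heading + p$scanning_kappa * rnorm(1L)
      pos[i, ] <- pos[i - 1L, ] +
        p$scanning_step * c(cos(heading), sin(heading))
    } else {                               # dancing
      if (behavior_sequence[i - 1L] != "dancing") anchor <- pos[i - 1L, ]
      if (runif(1L) < p$dancing_p_jump) {
        phi <- runif(1L, 0, 2 * pi)
        anchor <- anchor + p$dancing_jump_length * c(cos(phi), sin(phi))
      }
      psi <- runif(1L, 0, 2 * pi)
      r <- p$dancing_sigma * sqrt(runif(1L))   # uniform in the disc
      pos[i, ] <- anchor + r * c(cos(psi), sin(psi))
    }
  }
  if (!is.null(field)) {
    pos[, 1L] <- .reflect(pos[, 1L], field[1L])
    pos[, 2L] <- .reflect(pos[, 2L], field[2L])
  }
  z <- start[3L] + p$sigma_z * runif(n_frames, -1, 1)
  data.table(frame_index = seq_len(n_frames), x = pos[, 1L], y = pos[, 2L],
             z = z, label = behavior_sequence)
}

# semi-Markov behavior sequence: geometric dwell, uniform next behavior
.behavior_sequence <- function(n_frames, mixture, mean_dwell) {
  if (is.null(mean_dwell)) {
    rep(sample(names(mixture), 1L, prob = mixture), n_frames)
  } else {
    seq_out <- character(0)
    b <- sample(names(mixture), 1L, prob = mixture)
    while (length(seq_out) < n_frames) {
      dwell <- 1L + stats::rgeom(1L, 1 / mean_dwell)
      seq_out <- c(seq_out, rep(b, dwell))
      b <- sample(setdiff(names(mixture), b), 1L)
    }
    seq_out[seq_len(n_frames)]
  }
}

#' Simulate a labeled field of cell tracks
#'
#' Generates `cells_per_experiment` tracks per experiment: behaviors drawn
#' i.i.d. from the mixture (or switched semi-Markov when
#' `switch_mean_dwell` is set), start positions uniform in the field, and a
#' configured fraction of short (< 5 frame) tracks injected at random start
#' frames to exercise [filter_short_tracks()]. Per-track lognormal
#' multipliers on the motion scales add cell-to-cell variability. The
#' result round-trips through [write_tracks()] / [read_tracks()].
#'
#' @param cfg a [sim_config()].
#' @return a labeled [track_dataset()].
#' @export
simulate_field <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  all_pts <- vector("list", cfg$n_experiments * cfg$cells_per_experiment)
  idx <- 0L
  for (e in seq_len(cfg$n_experiments)) {
    exp_id <- paste0(cfg$experiment_prefix, "_exp", e)
    for (cell in seq_len(cfg$cells_per_experiment)) {
      short <- runif(1L) < cfg$short_track_fraction
      len <- if (short) sample(2:4, 1L) else cfg$n_frames
      first_frame <- if (short)
        sample.int(cfg$n_frames - len + 1L, 1L) else 1L
      beh <- .behavior_sequence(len, cfg$mixture, cfg$switch_mean_dwell)
      scale_mult <- stats::rlnorm(1L, 0, cfg$heterogeneity_sdlog)
      p <- cfg$params
      p$poking_sigma <- p$poking_sigma * scale_mult
      p$scanning_step <- p$scanning_step * scale_mult
      p$dancing_sigma <- p$dancing_sigma * scale_mult
      start <- c(runif(1L, 0, cfg$field_um[1L]),
                 runif(1L, 0, cfg$field_um[2L]), 10)
      tr <- simulate_track(beh, params = p, n_frames = len,
                           start = start, field = cfg$field_um)
      tr[, `:=`(experiment_id = exp_id,
                track_id = sprintf("cell%03d", cell),
                frame_index = frame_index + first_frame - 1L)]
      idx <- idx + 1L
      all_pts[[idx]] <- tr
    }
  }
  pts <- rbindlist(all_pts)
  pts[, `:=`(donor_id = "synthetic", disease = "none",
             treatment = "none")]
  track_dataset(pts, name = paste0(cfg$experiment_prefix, "_field"))
}
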