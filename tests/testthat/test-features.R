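test_that("kinematics match closed-form arithmetic", {
  # two points 6 um apart in x, 60 s apart
  two <- track_dataset(data.table::data.table(
    track_id = "t", frame_index = 1:2, x = c(0, 6), y = 0, z = 0))
  kin <- suppressWarnings(compute_kinematics(two))
  expect_equal(kin$speed, c(0.1, 0.1))
  expect_equal(kin$velocity_angle_x, c(0, 0))
  expect_equal(kin$delta_displacement_length, c(0, 6))
  expect_equal(kin$elapsed_time_prev, c(60, 60))

  # stationary track: everything kinematic is zero, angles hit sentinel
  still <- track_dataset(data.table::data.table(
    track_id = "t", frame_index = 1:5, x = 1, y = 2, z = 3))
  ks <- compute_kinematics(still)
  for (col in c("speed", "acceleration_global", "displacement_length",
                "distance_from_origin", "delta_displacement_length"))
    expect_equal(ks[[col]], rep(0, 5))
  expect_equal(ks$velocity_angle_x, rep(90, 5))

  # straight uniform motion: zero acceleration at interior points
  lin <- track_dataset(line_track("t", 5, vel = c(2, 1, 0)))
  kl <- compute_kinematics(lin)
  expect_equal(kl$acceleration_global[2:4], rep(0, 3))
  expect_equal(kl$speed, rep(sqrt(5) / 60, 5))
})

test_that("kinematic invariants hold on random tracks", {
  ds <- random_track_dataset(n_tracks = 6, n_points = 15, seed = 3)
  kin <- compute_kinematics(ds)
  expect_equal(kin$speed,
               sqrt(kin$velocity_x^2 + kin$velocity_y^2 + kin$velocity_z^2))
  first <- kin[, .SD[1], by = .(experiment_id, track_id)]
  expect_equal(first$displacement_length, rep(0, 6))
  expect_equal(first$distance_from_origin, rep(0, 6))
  moving <- kin[speed > 0]
  for (col in c("velocity_angle_x", "velocity_angle_y", "velocity_angle_z"))
    expect_true(all(moving[[col]] >= 0 & moving[[col]] <= 180))
})

test_that("neighbor features follow the k-smallest rule", {
  pts <- data.table::data.table(
    experiment_id = "e", track_id = c("a", "b", "c"), frame_index = 1L,
    x = c(0, 3, 0), y = c(0, 0, 4), z = 0)
  # single-frame tracks are not valid track_datasets for kinematics, but
  # neighbor features only need positions per frame
  ds <- structure(list(points = data.table::as.data.table(
    cbind(pts, time_s = 0, label = NA_character_, donor_id = NA_character_,
          disease = NA_character_, treatment = NA_character_)),
    name = "nb"), class = "track_dataset")
  data.table::setkeyv(ds$points, c("experiment_id", "track_id",
                                   "frame_index"))
  nb <- compute_neighbor_features(ds)
  a <- nb[track_id == "a"]
  expect_equal(a$dist_nearest_1, 3)
  expect_equal(a$avg_dist_nearest_3, 3.5)  # only 2 neighbors available
  expect_equal(a$avg_dist_nearest_9, 3.5)

  line <- data.table::data.table(
    experiment_id = "e", track_id = paste0("c", 0:9), frame_index = 1L,
    x = 0:9, y = 0, z = 0, time_s = 0, label = NA_character_,
    donor_id = NA_character_, disease = NA_character_,
    treatment = NA_character_)
  ds2 <- structure(list(points = line, name = "line"),
                   class = "track_dataset")
  data.table::setkeyv(ds2$points, c("experiment_id", "track_id",
                                    "frame_index"))
  nb2 <- compute_neighbor_features(ds2)
  expect_equal(nb2[track_id == "c0", avg_dist_nearest_3], 2)  # (1+2+3)/3
  expect_equal(nb2[track_id == "c0", avg_dist_nearest_5], 3)
  expect_equal(nb2[track_id == "c0", avg_dist_nearest_9], 5)

  # a cell alone at a frame gets the fallback constant
  alone <- data.table::copy(line)[1]
  ds3 <- structure(list(points = alone, name = "alone"),
                   class = "track_dataset")
  nb3 <- compute_neighbor_features(ds3, fallback = 123)
  expect_equal(nb3$dist_nearest_1, 123)
  expect_equal(nb3$avg_dist_nearest_9, 123)
})

test_that("window aggregation: zero case, coast arithmetic, edge copy", {
  still <- track_dataset(data.table::data.table(
    track_id = "t", frame_index = 1:5, x = 1, y = 2, z = 3))
  base <- compute_kinematics(still)
  w <- window_aggregate(base)
  expect_equal(w$coast_coefficient, rep(1, 5))
  expect_equal(w$cumulative_track_length, rep(0, 5))
  # every motion/position variance is exactly 0 (elapsed_time_track is the
  # one base feature that legitimately varies on a stationary track)
  vcols <- setdiff(grep("^var_", names(w), value = TRUE),
                   "var_elapsed_time_track")
  expect_true(all(as.matrix(w[, vcols, with = FALSE]) == 0))
  expect_equal(as.data.frame(w), as.data.frame(w[rep(1, 5)]))  # edge copy

  # coast counting with speeds straddling the 1/30 threshold
  spd <- c(0.01, 0.02, 0.04, 0.05, 0.01)
  dt <- data.table::data.table(position_x = cumsum(spd) * 60, position_y = 0,
                               position_z = 0, speed = spd,
                               delta_displacement_length = spd * 60)
  w2 <- window_aggregate(dt)
  expect_equal(w2$coast_coefficient[3], 3 / 5)

  # 7-point track: rows 1-2 copy row 3, rows 6-7 copy row 5
  ds7 <- random_track_dataset(n_tracks = 1, n_points = 7, seed = 8)
  b7 <- compute_kinematics(ds7)
  w7 <- window_aggregate(b7)
  expect_equal(as.data.frame(w7[1]), as.data.frame(w7[3]))
  expect_equal(as.data.frame(w7[2]), as.data.frame(w7[3]))
  expect_equal(as.data.frame(w7[6]), as.data.frame(w7[5]))
  expect_equal(as.data.frame(w7[7]), as.data.frame(w7[5]))
  expect_false(isTRUE(all.equal(w7[3], w7[4])))

  expect_error(window_aggregate(b7[1:3]), "window")
})

test_that("window values match the brute-force oracle", {
  for (seed in 1:5) {
    ds <- random_track_dataset(n_tracks = 2, n_points = 5 + seed * 3,
                               seed = seed)
    base <- compute_kinematics(ds)
    for (tid in unique(base$track_id)) {
      one <- base[track_id == tid]
      got <- window_aggregate(one)
      want <- oracle_window(one)
      expect_equal(as.data.frame(got[, names(want), with = FALSE]),
                   as.data.frame(want), tolerance = 1e-9)
    }
  }
})

test_that("coast coefficient is quantized to fifths for width 5", {
  ds <- random_track_dataset(n_tracks = 5, n_points = 20, seed = 21)
  fm <- assemble_feature_matrix(ds)
  fifths <- (0:5) / 5
  expect_true(all(fm$coast_coefficient %in% fifths))
})

test_that("assemble_feature_matrix emits the canonical 90 columns", {
  ds <- random_track_dataset(n_tracks = 2, n_points = 10, seed = 2)
  fm <- assemble_feature_matrix(ds)
  fn <- attr(fm, "feature_names")
  expect_length(fn, 90)
  expect_length(grep("^(mean_|var_)", fn, invert = TRUE), 32)  # 29 + 3
  expect_equal(fn, feature_names_canonical())
  expect_equal(nrow(fm), 20)
  expect_true(all(fn %in% names(fm)))
  expect_false(anyNA(feature_block(fm)))

  # shuffled input gives the identical matrix (keyed determinism)
  shuffled <- track_dataset(ds$points[sample(.N)], name = "shuffled")
  fm2 <- assemble_feature_matrix(shuffled)
  expect_equal(as.data.frame(fm2), as.data.frame(fm))

  # unfiltered short tracks are rejected
  short <- track_dataset(line_track("s", 3))
  expect_error(assemble_feature_matrix(short), "filter_short_tracks")
})

test_that("features are translation-invariant except positions", {
  ds <- random_track_dataset(n_tracks = 3, n_points = 10, seed = 13)
  fm <- assemble_feature_matrix(ds)
  shifted <- data.table::copy(ds$points)
  shifted[, `:=`(x = x + 50, y = y - 20, z = z + 5)]
  fm2 <- assemble_feature_matrix(track_dataset(shifted, name = "shifted"))
  pos_cols <- c("position_x", "position_y", "position_z",
                "mean_position_x", "mean_position_y", "mean_position_z")
  same <- setdiff(feature_names_canonical(), pos_cols)
  expect_equal(as.data.frame(fm2[, same, with = FALSE]),
               as.data.frame(fm[, same, with = FALSE]), tolerance = 1e-8)
  expect_equal(fm2$position_x, fm$position_x + 50)
})

test_that("feature matrix round-trips through CSV with its sidecar", {
  fm <- assemble_feature_matrix(random_track_dataset(seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  expect_true(file.exists(paste0(path, ".features.txt")))
  fm2 <- read_feature_matrix(path)
  expect_equal(attr(fm2, "feature_names"), feature_names_canonical())
  expect_equal(as.data.frame(fm2), as.data.frame(fm), tolerance = 1e-12)
})
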