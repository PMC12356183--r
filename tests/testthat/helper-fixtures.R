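# Shared fixtures: small hand-built tables and a default test camera.

test_camera <- function() camera_spec(8.8, 13.2, 5472, 3648)

# minimal image table (one drone, barometer + lidar columns)
test_images <- function(n = 3, drone = "d1") {
  correct_altitudes(data.frame(
    image = sprintf("img%02d", seq_len(n)),
    drone = drone,
    timestamp = NA_character_,
    focal_length_mm = 8.8, sensor_width_mm = 13.2,
    image_width_px = 5472, image_height_px = 3648,
    barometer_alt_m = 30 + seq_len(n),
    lidar_alt_m = NA_real_,
    launch_height_m = 1.5, lens_offset_m = NA_real_,
    stringsAsFactors = FALSE
  ))
}

# quality-score table builder: list of per-image overrides on an all-1 base
quality_fixture <- function(...) {
  rows <- list(...)
  base <- c(focus = 1, straightness = 1, roll = 1, arch = 1, pitch = 1,
            length_measurability = 1, width_measurability = 1)
  out <- lapply(seq_along(rows), function(i) {
    sc <- base
    sc[names(rows[[i]])] <- rows[[i]]
    c(list(image = sprintf("img%02d", i)), as.list(sc))
  })
  do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
}

# small joint dataset: calibration flight plus a few whales, one drone
small_joint_data <- function(seed = 1, n_cal = 15, n_subjects = 2,
                             images_per_subject = 2, stations = c(0.3, 0.5, 0.7)) {
  cal <- simulate_calibration(n_images = n_cal, seed = seed)
  wh <- simulate_whales(
    n_subjects = n_subjects, images_per_subject = images_per_subject,
    morphology = whale_morphology(stations = stations), seed = seed + 1)
  list(data = bind_measurement_data(cal$data, wh$data),
       cal_truth = cal$truth, whale_truth = wh$truth)
}
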