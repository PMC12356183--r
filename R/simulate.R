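#' Drone scenario for simulation
#'
#' Describes one simulated drone system: its camera, the altimeters on
#' board (each with a true additive bias, multiplicative scaling and noise
#' sd), the pixel-measurement noise, and the altitude range flown. These
#' are the ground-truth values a recovery study tries to estimate back.
#'
#' @param drone Drone identifier token.
#' @param camera A [camera_spec()].
#' @param altimeters Data frame with columns `kind` (`"barometer"` or
#'   `"lidar"`), `bias` (m), `scaling`, `sd` (m, `>= 0`).
#' @param pixel_sd Pixel-measurement noise sd (px, `>= 0`).
#' @param altitude_range Range `c(lo, hi)` of true flight altitudes (m).
#'   The default spans low passes through high transects; a wide range —
#'   in particular including low altitudes — is what identifies the
#'   altimeter intercept (bias) separately from its scaling.
#' @return A `drone_scenario` object.
#' @export
drone_scenario <- function(drone = "drone1",
                           camera = camera_spec(8.8, 13.2, 5472, 3648),
                           altimeters = data.frame(kind = "barometer",
                                                   bias = 2, scaling = 1,
                                                   sd = 1),
                           pixel_sd = 5,
                           altitude_range = c(10, 60)) {
  stopifnot(inherits(camera, "camera_spec"),
            is.data.frame(altimeters),
            all(c("kind", "bias", "scaling", "sd") %in% names(altimeters)),
            all(altimeters$kind %in% c("barometer", "lidar")),
            all(altimeters$sd >= 0),
            pixel_sd >= 0,
            length(altitude_range) == 2L,
            altitude_range[1] > 0, altitude_range[2] > altitude_range[1])
  structure(list(drone = drone, camera = camera, altimeters = altimeters,
                 pixel_sd = pixel_sd, altitude_range = altitude_range),
            class = "drone_scenario")
}

#' Default two-drone scenarios
#'
#' A pair of simulator defaults contrasting instrumentation: `drone1`
#' carries both a LiDAR (small noise) and a barometer (biased, noisy);
#' `drone2` is barometer-only. Useful for studying how altimeter quality
#' propagates into posterior width: the LiDAR-equipped drone should yield
#' narrower length and body-condition posteriors on matched data.
#'
#' @return Named list of two [drone_scenario()] objects.
#' @export
default_scenarios <- function() {
  list(
    drone1 = drone_scenario(
      drone = "drone1",
      altimeters = data.frame(kind = c("lidar", "barometer"),
                              bias = c(0, 2), scaling = c(1, 1),
                              sd = c(0.3, 1.5)),
      pixel_sd = 5
    ),
    drone2 = drone_scenario(
      drone = "drone2",
      altimeters = data.frame(kind = "barometer", bias = 2, scaling = 1,
                              sd = 1.5),
      pixel_sd = 5
    )
  )
}

# simulate altimeter readings and the image-table rows for a vector of
# true altitudes under one scenario
.sim_images <- function(scenario, image_ids, a_true,
                        timestamps = NA_character_) {
  alts <- scenario$altimeters
  n <- length(a_true)
  baro <- rep(NA_real_, n)
  lid <- rep(NA_real_, n)
  for (r in seq_len(nrow(alts))) {
    reading <- stats::rnorm(n, alts$bias[r] + alts$scaling[r] * a_true,
                            alts$sd[r])
    if (alts$kind[r] == "barometer") baro <- reading else lid <- reading
  }
  data.frame(
    image = image_ids, drone = scenario$drone, timestamp = timestamps,
    focal_length_mm = scenario$camera$focal_length_mm,
    sensor_width_mm = scenario$camera$sensor_width_mm,
    image_width_px = scenario$camera$image_width_px,
    image_height_px = scenario$camera$image_height_px,
    barometer_alt_m = baro, lidar_alt_m = lid,
    launch_height_m = 0, lens_offset_m = 0,
    stringsAsFactors = FALSE
  )
}

# noisy pixel length for true metric length L at true altitude a; negative
# draws (pathological noise) are resampled, counted in a warning
.sim_pixels <- function(L, a, camera, pixel_sd) {
  mu <- L * camera$focal_length_mm * camera$image_width_px /
    (camera$sensor_width_mm * a)
  px <- stats::rnorm(length(mu), mu, pixel_sd)
  n_bad <- 0L
  while (any(px <= 0)) {
    bad <- px <= 0
    n_bad <- n_bad + sum(bad)
    px[bad] <- stats::rnorm(sum(bad), mu[bad], pixel_sd)
  }
  if (n_bad > 0) {
    warning(sprintf("resampled %d non-positive pixel length(s)", n_bad),
            call. = FALSE)
  }
  px
}

#' Simulate a calibration flight
#'
#' Generates a calibration dataset under the scenario's generative model:
#' true altitudes uniform over the scenario's altitude range, altimeter
#' readings Normal(bias + scaling x altitude, sd^2), and pixel lengths of
#' the known-size object Normal(true pixels, pixel_sd^2). The output is
#' schema-compatible with [read_measurements()] tables and carries a truth
#' record for recovery checks.
#'
#' @param scenario A [drone_scenario()].
#' @param n_images Number of calibration images.
#' @param object_length_m Known length of the calibration object (m).
#' @param seed Integer seed.
#' @param prefix Image-id prefix (to keep ids unique when binding several
#'   simulated flights).
#' @return List with `data` (a `measurement_data`) and `truth` (data frame
#'   `image`, `altitude_m`).
#' @export
simulate_calibration <- function(scenario = drone_scenario(), n_images = 20,
                                 object_length_m = 1, seed = 1,
                                 prefix = NULL) {
  stopifnot(inherits(scenario, "drone_scenario"), n_images >= 1,
            object_length_m > 0)
  set.seed(as.integer(seed))
  if (is.null(prefix)) prefix <- paste0(scenario$drone, "_cal")
  ids <- sprintf("%s_%03d", prefix, seq_len(n_images))
  a <- stats::runif(n_images, scenario$altitude_range[1],
                    scenario$altitude_range[2])
  images <- .sim_images(scenario, ids, a)
  px <- .sim_pixels(rep(object_length_m, n_images), a, scenario$camera,
                    scenario$pixel_sd)
  measurements <- data.frame(
    subject = "cal_obj", image = ids, label = "CAL", length_px = px,
    timepoint = "t0", known_length_m = object_length_m,
    stringsAsFactors = FALSE
  )
  list(data = measurement_data(correct_altitudes(images), measurements),
       truth = data.frame(image = ids, altitude_m = a,
                          stringsAsFactors = FALSE))
}

#' Whale morphology configuration for simulation
#'
#' True total lengths are drawn Normal(`mean_length_m`, `sd_length_m`^2)
#' (truncated positive); the width profile is a smooth unimodal
#' parabolic-taper template of standardized widths, perturbed per subject
#' by a biological coefficient of variation.
#'
#' @param mean_length_m,sd_length_m Population total-length distribution
#'   (m).
#' @param stations Station positions (fractions of TL) at which widths are
#'   measured.
#' @param width_template Function mapping station fraction to standardized
#'   width; default parabola peaking at 0.21 mid-body.
#' @param biological_cv Per-subject relative perturbation of the template.
#' @return A `whale_morphology` object.
#' @export
whale_morphology <- function(mean_length_m = 11, sd_length_m = 1,
                             stations = seq(0.05, 0.95, by = 0.05),
                             width_template = function(s) 0.84 * s * (1 - s),
                             biological_cv = 0.05) {
  stopifnot(mean_length_m > 0, sd_length_m >= 0,
            all(stations > 0), all(stations < 1),
            !is.unsorted(stations, strictly = TRUE),
            is.function(width_template), biological_cv >= 0)
  structure(list(mean_length_m = mean_length_m, sd_length_m = sd_length_m,
                 stations = stations, width_template = width_template,
                 biological_cv = biological_cv),
            class = "whale_morphology")
}

#' Simulate whale measurements
#'
#' Generates multi-image animal measurements under a scenario: each
#' subject gets a true total length and width profile from the morphology
#' configuration, each image a true altitude and noisy altimeter readings,
#' and each measurement a noisy pixel length. Labels follow the package
#' convention: `"TL"` plus `"W<percent>"` per width station.
#'
#' @param scenario A [drone_scenario()].
#' @param n_subjects Number of simulated whales.
#' @param images_per_subject Images per whale.
#' @param morphology A [whale_morphology()].
#' @param measure_widths Measure the width profile in addition to TL
#'   (default `TRUE`).
#' @param timepoint Timepoint token assigned to all measurements.
#' @param seed Integer seed.
#' @return List with `data` (a `measurement_data`) and `truth` (list with
#'   per-image `altitudes` and per-subject `subjects` incl. true TL and
#'   widths).
#' @export
simulate_whales <- function(scenario = drone_scenario(), n_subjects = 6,
                            images_per_subject = 3,
                            morphology = whale_morphology(),
                            measure_widths = TRUE,
                            timepoint = "t0", seed = 1) {
  stopifnot(inherits(scenario, "drone_scenario"), n_subjects >= 1,
            images_per_subject >= 1,
            inherits(morphology, "whale_morphology"))
  set.seed(as.integer(seed))
  subjects <- sprintf("whale%02d", seq_len(n_subjects))
  tl <- abs(stats::rnorm(n_subjects, morphology$mean_length_m,
                         morphology$sd_length_m))
  st <- morphology$stations
  base_sw <- morphology$width_template(st)
  widths <- t(vapply(seq_len(n_subjects), function(i) {
    tl[i] * base_sw * (1 + stats::rnorm(length(st), 0,
                                        morphology$biological_cv))
  }, numeric(length(st))))
  widths <- pmax(widths, 1e-3)
  wlabels <- sprintf("W%g", round(st * 100, 4))

  n_img <- n_subjects * images_per_subject
  ids <- sprintf("%s_%s_img%02d", scenario$drone,
                 rep(subjects, each = images_per_subject),
                 rep(seq_len(images_per_subject), n_subjects))
  a <- stats::runif(n_img, scenario$altitude_range[1],
                    scenario$altitude_range[2])
  images <- .sim_images(scenario, ids, a)

  rows <- list()
  for (i in seq_len(n_subjects)) {
    for (j in seq_len(images_per_subject)) {
      img_i <- (i - 1) * images_per_subject + j
      Ls <- c(tl[i], if (measure_widths) widths[i, ])
      labs <- c("TL", if (measure_widths) wlabels)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects[i], image = ids[img_i], label = labs,
        length_px = .sim_pixels(Ls, a[img_i], scenario$camera,
                                scenario$pixel_sd),
        timepoint = timepoint, known_length_m = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  truth_sub <- data.frame(subject = subjects, tl_m = tl,
                          stringsAsFactors = FALSE)
  truth_sub <- cbind(truth_sub,
                     stats::setNames(as.data.frame(widths), wlabels))
  list(data = measurement_data(correct_altitudes(images), measurements),
       truth = list(altitudes = data.frame(image = ids, altitude_m = a,
                                           stringsAsFactors = FALSE),
                    subjects = truth_sub,
                    stations = stats::setNames(st, wlabels)))
}

#' Simulate a growth cohort
#'
#' Generates repeated total-length measurements of a cohort across years
#' under sex-specific von Bertalanffy-Putter growth: individual asymptotic
#' lengths Normal(sex mean, sd^2), true lengths at each observed age equal
#' to the growth mean plus process noise, and per-year measurements by a
#' drone scenario sampled per subject-year. Calibration flights for every
#' scenario are included so the output is directly fittable by
#' [growth_curve_sampler()].
#'
#' @param scenarios List of [drone_scenario()]s (default
#'   [default_scenarios()]); drones must have distinct `drone` tokens.
#' @param n_subjects Number of individuals (`>= 2`).
#' @param years Number of consecutive observation years (`>= 2`).
#' @param growth_truth Named list of generating values: `mu_female`,
#'   `mu_male` (asymptotic-length means, m), `sigma_Linf` (m), `k` (1/yr),
#'   `t0` (yr), `sigma_growth` (m).
#' @param age_range Range of ages at first observation (yr).
#' @param images_per_obs Images per subject-year.
#' @param p_female Probability a subject is female.
#' @param age_uncertainty Half-width (yr) of the reported age interval; 0
#'   (default) reports exact ages.
#' @param calibration_images Calibration images simulated per scenario.
#' @param object_length_m Calibration object length (m).
#' @param seed Integer seed.
#' @return List with `observations` (subject, timepoint, sex, age bounds),
#'   `data` (a `measurement_data` incl. calibration), and `truth`
#'   (subjects with sex, individual asymptotic length, and true lengths
#'   per year).
#' @export
simulate_growth_cohort <- function(scenarios = default_scenarios(),
                                   n_subjects = 30, years = 7,
                                   growth_truth = list(
                                     mu_female = 12.5, mu_male = 11.9,
                                     sigma_Linf = 0.6, k = 0.25, t0 = -1.8,
                                     sigma_growth = 0.3),
                                   age_range = c(1, 30),
                                   images_per_obs = 2,
                                   p_female = 0.5,
                                   age_uncertainty = 0,
                                   calibration_images = 15,
                                   object_length_m = 1,
                                   seed = 1) {
  stopifnot(n_subjects >= 2, years >= 2, age_uncertainty >= 0)
  if (inherits(scenarios, "drone_scenario")) scenarios <- list(scenarios)
  set.seed(as.integer(seed))
  gt <- growth_truth

  subjects <- sprintf("whale%03d", seq_len(n_subjects))
  sex <- ifelse(stats::runif(n_subjects) < p_female, "female", "male")
  mu <- ifelse(sex == "female", gt$mu_female, gt$mu_male)
  linf <- stats::rnorm(n_subjects, mu, gt$sigma_Linf)
  age0 <- stats::runif(n_subjects, age_range[1], age_range[2])

  obs_rows <- list(); img_rows <- list(); meas_rows <- list()
  truth_len <- list()
  for (i in seq_len(n_subjects)) {
    for (t in seq_len(years)) {
      age <- age0[i] + (t - 1)
      true_len <- max(0.5, growth_mean_length(age, linf[i], gt$k, gt$t0) +
                        stats::rnorm(1, 0, gt$sigma_growth))
      tp <- sprintf("year%d", t)
      sc <- scenarios[[sample.int(length(scenarios), 1)]]
      ids <- sprintf("%s_%s_%s_img%02d", sc$drone, subjects[i], tp,
                     seq_len(images_per_obs))
      a <- stats::runif(images_per_obs, sc$altitude_range[1],
                        sc$altitude_range[2])
      img_rows[[length(img_rows) + 1L]] <- .sim_images(sc, ids, a)
      meas_rows[[length(meas_rows) + 1L]] <- data.frame(
        subject = subjects[i], image = ids, label = "TL",
        length_px = .sim_pixels(rep(true_len, images_per_obs), a,
                                sc$camera, sc$pixel_sd),
        timepoint = tp, known_length_m = NA_real_, stringsAsFactors = FALSE
      )
      obs_rows[[length(obs_rows) + 1L]] <- data.frame(
        subject = subjects[i], timepoint = tp, sex = sex[i],
        age_min = max(0, age - age_uncertainty),
        age_max = age + age_uncertainty,
        stringsAsFactors = FALSE
      )
      truth_len[[length(truth_len) + 1L]] <- data.frame(
        subject = subjects[i], timepoint = tp, age = age,
        length_m = true_len, drone = sc$drone, stringsAsFactors = FALSE
      )
    }
  }
  for (s in seq_along(scenarios)) {
    cal <- simulate_calibration(scenarios[[s]], n_images = calibration_images,
                                object_length_m = object_length_m,
                                seed = seed + 1000 + s)
    img_rows[[length(img_rows) + 1L]] <- cal$data$images[
      , names(img_rows[[1]]), drop = FALSE]
    meas_rows[[length(meas_rows) + 1L]] <- cal$data$measurements
  }
  images <- do.call(rbind, img_rows)
  measurements <- do.call(rbind, meas_rows)
  rownames(images) <- rownames(measurements) <- NULL
  list(
    observations = do.call(rbind, obs_rows),
    data = measurement_data(correct_altitudes(images), measurements),
    truth = list(
      subjects = data.frame(subject = subjects, sex = sex,
                            asymptotic_length_m = linf,
                            age_first_obs = age0, stringsAsFactors = FALSE),
      lengths = do.call(rbind, truth_len),
      growth = gt
    )
  )
}
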