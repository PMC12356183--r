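test_that("growth mean length has the right asymptote, root, and half-point", {
  expect_equal(growth_mean_length(1e6, 12, 0.3, 0), 12)
  expect_equal(growth_mean_length(0, 12, 0.3, 0), 0)
  expect_equal(growth_mean_length(log(2) / 0.3, 12, 0.3, 0), 6.0,
               tolerance = 1e-12)
  # clamped at zero before t0, monotone nondecreasing after
  expect_equal(growth_mean_length(1, 12, 0.3, 2), 0)
  ages <- seq(0, 40, 0.5)
  expect_true(all(diff(growth_mean_length(ages, 12, 0.3, -1.5)) >= 0))
  # Putter exponent generalization still hits the asymptote
  expect_equal(growth_mean_length(1e6, 12, 0.3, 0, putter_exponent = 2.89),
               12)
})

test_that("growth sampler validates its inputs", {
  g <- simulate_growth_cohort(n_subjects = 3, years = 2,
                              calibration_images = 5, seed = 1)
  obs <- g$observations
  expect_error(growth_curve_sampler(obs[, c("subject", "timepoint")],
                                    g$data, iterations = 10),
               "age")
  one <- obs[obs$subject == obs$subject[1], ]
  m <- g$data$measurements
  keep <- m$subject == obs$subject[1] | is.finite(m$known_length_m)
  d1 <- measurement_data(g$data$images, m[keep, , drop = FALSE])
  expect_error(growth_curve_sampler(one, d1, iterations = 10),
               "at least 2 subjects")
})

test_that("all-unknown sexes disable the sex effect with a warning", {
  g <- simulate_growth_cohort(n_subjects = 3, years = 2,
                              calibration_images = 6, seed = 2)
  obs <- g$observations
  obs$sex <- "unknown"
  expect_warning(
    d <- growth_curve_sampler(obs, g$data, iterations = 300, burn_in = 100,
                              seed = 3),
    "sex effect disabled")
  expect_true("mu_Linf[all]" %in% colnames(d$draws))
})

test_that("tiny-noise single measurements reduce to the raw converted lengths", {
  sc <- drone_scenario(altimeters = data.frame(kind = "lidar", bias = 0,
                                               scaling = 1, sd = 0.01),
                       pixel_sd = 0.5)
  g <- simulate_growth_cohort(list(sc), n_subjects = 3, years = 2,
                              images_per_obs = 1, calibration_images = 8,
                              growth_truth = list(
                                mu_female = 12.5, mu_male = 11.9,
                                sigma_Linf = 0.6, k = 0.25, t0 = -1.8,
                                sigma_growth = 0.2),
                              seed = 4)
  d <- growth_curve_sampler(g$observations, g$data, iterations = 2000,
                            burn_in = 1000, seed = 5)
  sm <- summarize_draws(d)
  lat <- sm[grepl("^L\\[", sm$parameter), ]
  m <- g$data$measurements
  m <- m[!is.finite(m$known_length_m), ]
  img <- g$data$images[match(m$image, g$data$images$image), ]
  conv <- pixels_to_meters(m$length_px, img$lidar_corrected_m,
                           sc$camera)
  key <- sprintf("L[%s,%s,TL]", m$subject, m$timepoint)
  expect_equal(lat$mean[match(key, lat$parameter)], conv, tolerance = 0.02)
})

test_that("growth draws keep expected lengths monotone in age", {
  g <- simulate_growth_cohort(n_subjects = 5, years = 3,
                              calibration_images = 8,
                              age_uncertainty = 1.5, seed = 6)
  d <- growth_curve_sampler(g$observations, g$data, iterations = 1500,
                            burn_in = 700, seed = 7)
  expect_equal(check_growth_monotonicity(d), 1)
  # interval-aged observations got latent age parameters within bounds
  age_cols <- grep("^age\\[", colnames(d$draws), value = TRUE)
  expect_gt(length(age_cols), 0)
  pm <- d$param_map
  for (col in age_cols[1:3]) {
    sub <- pm$subject[pm$parameter == col]
    tp <- pm$timepoint[pm$parameter == col]
    o <- g$observations[g$observations$subject == sub &
                          g$observations$timepoint == tp, ]
    expect_true(all(d$draws[, col] >= o$age_min - 1e-9 &
                      d$draws[, col] <= o$age_max + 1e-9))
  }
})

test_that("lidar years shrink the posterior of barometer-only years", {
  # one individual measured by a noisy barometer drone in year 1 and a
  # lidar drone in later years: the growth constraint should leave the
  # year-1 posterior sd below the raw converted-measurement scatter
  noisy <- drone_scenario(
    drone = "noisy",
    altimeters = data.frame(kind = "barometer", bias = 2, scaling = 1,
                            sd = 3),
    pixel_sd = 5)
  sharp <- drone_scenario(
    drone = "sharp",
    altimeters = data.frame(kind = "lidar", bias = 0, scaling = 1,
                            sd = 0.1),
    pixel_sd = 2)
  set.seed(8)
  g <- simulate_growth_cohort(list(noisy), n_subjects = 6, years = 3,
                              images_per_obs = 2, calibration_images = 12,
                              seed = 8)
  # re-measure years 2-3 with the sharp drone: rebuild those images
  obs <- g$observations
  d_noisy <- growth_curve_sampler(obs, g$data, iterations = 2500,
                                  burn_in = 1200, seed = 9)
  g2 <- simulate_growth_cohort(list(noisy, sharp), n_subjects = 6,
                               years = 3, images_per_obs = 2,
                               calibration_images = 12, seed = 8)
  d_mixed <- growth_curve_sampler(g2$observations, g2$data,
                                  iterations = 2500, burn_in = 1200,
                                  seed = 9)
  sd_of <- function(d, g) {
    tl <- g$truth$lengths
    noisy_keys <- sprintf("L[%s,%s,TL]",
                          tl$subject[tl$drone == "noisy"],
                          tl$timepoint[tl$drone == "noisy"])
    noisy_keys <- intersect(noisy_keys, colnames(d$draws))
    mean(apply(d$draws[, noisy_keys, drop = FALSE], 2, sd))
  }
  expect_lt(sd_of(d_mixed, g2), sd_of(d_noisy, g))
})

test_that("growth curve summary returns one curve per sex on the age grid", {
  g <- simulate_growth_cohort(n_subjects = 6, years = 2,
                              calibration_images = 8, seed = 10)
  d <- growth_curve_sampler(g$observations, g$data, iterations = 800,
                            burn_in = 400, seed = 11)
  gc <- growth_curve_summary(d, ages = c(0, 5, 10, 20))
  expect_setequal(unique(gc$sex), c("female", "male"))
  expect_equal(nrow(gc), 8)
  expect_true(all(gc$lower <= gc$mean & gc$mean <= gc$upper))
  # curves rise with age
  for (sx in unique(gc$sex)) {
    expect_true(all(diff(gc$mean[gc$sex == sx]) > 0))
  }
})
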