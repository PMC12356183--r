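test_that("sampler runs are bit-identical under the same seed", {
  fix <- small_joint_data(seed = 1, n_subjects = 1)
  s <- build_sampler(fix$data)
  d1 <- run_sampler(s, iterations = 400, burn_in = 200, seed = 5)
  d2 <- run_sampler(s, iterations = 400, burn_in = 200, seed = 5)
  expect_identical(d1$draws, d2$draws)
  d3 <- run_sampler(s, iterations = 400, burn_in = 200, seed = 6)
  expect_false(identical(d1$draws, d3$draws))
})

test_that("thinning and burn-in control the number of retained draws", {
  fix <- small_joint_data(seed = 2, n_subjects = 1)
  s <- build_sampler(fix$data)
  d <- run_sampler(s, iterations = 1000, burn_in = 400, thinning = 3,
                   seed = 1)
  expect_equal(nrow(d$draws), 200)
  expect_false(any(!is.finite(d$draws)))
})

test_that("each altimeter gets its own bias/scaling/noise parameters", {
  cal1 <- simulate_calibration(default_scenarios()$drone1, n_images = 8,
                               seed = 3)
  cal2 <- simulate_calibration(default_scenarios()$drone2, n_images = 8,
                               seed = 4)
  s <- build_sampler(bind_measurement_data(cal1$data, cal2$data))
  alts <- s$prep$altimeters
  expect_setequal(alts, c("drone1:barometer", "drone1:lidar",
                          "drone2:barometer"))
  expect_true(all(sprintf("beta0[%s]", alts) %in% s$prep$par_names))
  expect_true(all(sprintf("sigma_alt[%s]", alts) %in% s$prep$par_names))
  # pixel noise is shared per drone
  expect_setequal(grep("^sigma_px", s$prep$par_names, value = TRUE),
                  c("sigma_px[drone1]", "sigma_px[drone2]"))
})

test_that("grouping controls how measurements pool into latent lengths", {
  cal <- simulate_calibration(n_images = 6, seed = 5)
  wh <- simulate_whales(n_subjects = 1, images_per_subject = 3,
                        measure_widths = FALSE, seed = 6)
  data <- bind_measurement_data(cal$data, wh$data)
  # per-subject: one latent length shared by the 3 image likelihoods
  s_sub <- build_sampler(data, grouping = "subject")
  expect_equal(nrow(s_sub$prep$groups), 1)
  expect_equal(sum(s_sub$prep$px$grp > 0), 3)
  # per-image: one latent per (subject, image)
  s_img <- build_sampler(data, grouping = "image")
  expect_equal(nrow(s_img$prep$groups), 3)
})

test_that("build-time validation rejects malformed model inputs", {
  cal <- simulate_calibration(n_images = 5, seed = 7)
  # no calibration data at all
  wh <- simulate_whales(n_subjects = 1, images_per_subject = 1, seed = 8)
  expect_error(build_sampler(wh$data), "calibration")
  # image with no altimeter reading
  broken <- cal$data
  broken$images$barometer_alt_m[2] <- NA
  broken$images <- correct_altitudes(broken$images)
  expect_error(build_sampler(broken), "no usable altimeter")
  # invalid MCMC controls
  s <- build_sampler(cal$data)
  expect_error(run_sampler(s, iterations = 100, burn_in = 100),
               "iterations > burn_in")
})

test_that("posterior for a known-altitude length matches the conjugate normal", {
  # point-mass altitudes and fixed pixel sd: the latent length posterior is
  # Normal(sum(x * Lp) / sum(x^2), sd = sigma_px / sqrt(sum(x^2))) with
  # x = c / a (flat prior, truncation far away)
  sc <- drone_scenario(altimeters = data.frame(kind = "lidar", bias = 0,
                                               scaling = 1, sd = 0),
                       pixel_sd = 4)
  cal <- simulate_calibration(sc, n_images = 3, seed = 9)
  wh <- simulate_whales(sc, n_subjects = 1, images_per_subject = 4,
                        measure_widths = FALSE, seed = 10)
  data <- bind_measurement_data(cal$data, wh$data)
  spec <- uncertainty_model_spec(
    image_altitude = prior_fixed(),
    altimeter_bias = prior_fixed(0),
    altimeter_scaling = prior_fixed(1),
    altimeter_sd = prior_fixed(1),
    pixel_sd = prior_fixed(4),
    object_length = prior_uniform(0.01, 30))
  d <- run_sampler(build_sampler(data, spec, grouping = "subject"),
                   iterations = 6000, burn_in = 1000, seed = 11)
  tl_col <- grep("TL", colnames(d$draws), value = TRUE)
  draws <- d$draws[, tl_col]

  m <- wh$data$measurements
  img <- wh$data$images[match(m$image, wh$data$images$image), ]
  x <- img$focal_length_mm * img$image_width_px /
    (img$sensor_width_mm * img$lidar_corrected_m)
  post_mean <- sum(x * m$length_px) / sum(x^2)
  post_sd <- 4 / sqrt(sum(x^2))
  ess <- diagnose_draws(d)$ess[match(tl_col, colnames(d$draws))]
  mcse_mean <- post_sd / sqrt(ess)
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse_mean)
  expect_lt(abs(sd(draws) - post_sd), 3 * post_sd / sqrt(2 * ess))
})

test_that("pooling images narrows the length posterior", {
  # same whale measured once vs four times: per-subject pooling should
  # shrink the posterior sd on average over replicates
  sd1 <- sd4 <- numeric(3)
  for (r in 1:3) {
    cal <- simulate_calibration(n_images = 12, seed = 20 + r)
    wh <- simulate_whales(n_subjects = 1, images_per_subject = 4,
                          measure_widths = FALSE, seed = 30 + r)
    data4 <- bind_measurement_data(cal$data, wh$data)
    m1 <- wh$data
    keep <- m1$measurements$image == m1$measurements$image[1]
    m1 <- measurement_data(m1$images, m1$measurements[keep, , drop = FALSE])
    data1 <- bind_measurement_data(cal$data, m1)
    d4 <- run_sampler(build_sampler(data4, grouping = "subject"),
                      iterations = 3000, burn_in = 1500, seed = r)
    d1 <- run_sampler(build_sampler(data1, grouping = "subject"),
                      iterations = 3000, burn_in = 1500, seed = r)
    tl4 <- grep("TL", colnames(d4$draws), value = TRUE)
    tl1 <- grep("TL", colnames(d1$draws), value = TRUE)
    sd4[r] <- sd(d4$draws[, tl4])
    sd1[r] <- sd(d1$draws[, tl1])
  }
  expect_lt(mean(sd4), mean(sd1))
})

test_that("noisier altimeters widen length posteriors (joint dependency)", {
  sds <- c(0.3, 3)
  width <- sapply(seq_along(sds), function(i) {
    sc <- drone_scenario(altimeters = data.frame(kind = "barometer",
                                                 bias = 0, scaling = 1,
                                                 sd = sds[i]),
                         pixel_sd = 3)
    cal <- simulate_calibration(sc, n_images = 15, seed = 40)
    wh <- simulate_whales(sc, n_subjects = 1, images_per_subject = 2,
                          measure_widths = FALSE, seed = 41)
    d <- run_sampler(build_sampler(bind_measurement_data(cal$data, wh$data),
                                   grouping = "subject"),
                     iterations = 4000, burn_in = 2000, seed = 42)
    tl <- grep("TL", colnames(d$draws), value = TRUE)
    h <- hpdi(d$draws[, tl])
    h["upper"] - h["lower"]
  })
  expect_lt(width[1], width[2])
})

test_that("posterior length concentrates on truth as noise vanishes", {
  sc_lo <- drone_scenario(altimeters = data.frame(kind = "lidar", bias = 0,
                                                  scaling = 1, sd = 0.05),
                          pixel_sd = 0.5)
  sc_hi <- drone_scenario(altimeters = data.frame(kind = "lidar", bias = 0,
                                                  scaling = 1, sd = 1),
                          pixel_sd = 8)
  res <- lapply(list(sc_lo, sc_hi), function(sc) {
    cal <- simulate_calibration(sc, n_images = 10, seed = 50)
    wh <- simulate_whales(sc, n_subjects = 1, images_per_subject = 2,
                          measure_widths = FALSE, seed = 51)
    d <- run_sampler(build_sampler(bind_measurement_data(cal$data, wh$data),
                                   grouping = "subject"),
                     iterations = 4000, burn_in = 2000, seed = 52)
    tl <- grep("TL", colnames(d$draws), value = TRUE)
    c(sd = sd(d$draws[, tl]),
      err = abs(mean(d$draws[, tl]) - wh$truth$subjects$tl_m))
  })
  expect_lt(res[[1]]["sd"], res[[2]]["sd"] / 3)
  expect_lt(res[[1]]["err"], 0.05)
})
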