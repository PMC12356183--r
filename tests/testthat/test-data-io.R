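test_that("altimeter log syncing matches nearest entries within the gap", {
  log_t <- c(0, 5, 10, 15)
  log_a <- c(28, 29, 30, 31)
  # image stamped t=2 with +3 s clock offset lands exactly on the t=5 entry
  expect_equal(unname(sync_altitude_log(log_t, log_a, 2, clock_offset_s = 3,
                                        max_gap_s = 1)), 29)
  # shifted time 10 s from the nearest entry, gap 2 s: absent
  expect_true(is.na(sync_altitude_log(log_t, log_a, 22, clock_offset_s = 3,
                                      max_gap_s = 2)))
  # matched entry is a null return: absent (caller falls back to barometer)
  expect_true(is.na(sync_altitude_log(log_t, c(28, -1, 30, 31), 2,
                                      clock_offset_s = 3, max_gap_s = 1)))
  # several images at once, names preserved
  res <- sync_altitude_log(log_t, log_a, c(i1 = 4.6, i2 = 9.9, i3 = 100),
                           clock_offset_s = 0, max_gap_s = 1)
  expect_equal(res, c(i1 = 29, i2 = 30, i3 = NA))
})

test_that("altimeter log syncing rejects invalid inputs", {
  expect_error(sync_altitude_log(c(5, 1), c(30, 30), 2, 0, 1), "sorted")
  expect_error(sync_altitude_log(c(1, 5), c(30, 30), 2, 0, -1),
               "non-negative")
  expect_error(sync_altitude_log(c(1, 5), 30, 2, 0, 1), "equal length")
})

test_that("altitude corrections add launch height and lens offset", {
  img <- data.frame(
    image = c("a", "b", "c"), drone = "d1",
    barometer_alt_m = c(24.3, NA, 18), lidar_alt_m = c(NA, 30.0, 25),
    launch_height_m = c(1.7, NA, 0), lens_offset_m = c(NA, -0.12, -0.12),
    stringsAsFactors = FALSE
  )
  out <- correct_altitudes(img)
  expect_equal(out$barometer_corrected_m, c(26.0, NA, 18))  # launch 0: identity
  expect_equal(out$lidar_corrected_m, c(NA, 29.88, 24.88))
  # raw values preserved, and the correction is idempotent
  expect_equal(out$barometer_alt_m, img$barometer_alt_m)
  expect_identical(correct_altitudes(out), out)
})

test_that("barometer-only images without a launch height warn and stay absent", {
  img <- data.frame(image = "a", drone = "d1", barometer_alt_m = 20,
                    lidar_alt_m = NA_real_, launch_height_m = NA_real_,
                    lens_offset_m = NA_real_, stringsAsFactors = FALSE)
  expect_warning(out <- correct_altitudes(img), "launch height")
  expect_true(is.na(out$barometer_corrected_m))
})

test_that("quality filtering applies the exclusion rules", {
  scores <- quality_fixture(
    c(),                      # all good
    c(focus = 3),             # any 3 excludes
    c(roll = 2, arch = 2),    # two 2s among arch/pitch/roll excludes
    c(roll = 2, pitch = 2),
    c(roll = 2),              # a single pose 2 is fine
    c(straightness = 2, length_measurability = 2),  # non-pose 2s are fine
    c(arch = 2, pitch = 2, roll = 2, width_measurability = 3)
  )
  res <- filter_by_quality(scores)
  expect_setequal(res$kept, c("img01", "img05", "img06"))
  expect_setequal(res$excluded, c("img02", "img03", "img04", "img07"))
  expect_match(res$reasons$reason[res$reasons$image == "img02"], "score 3")
  expect_match(res$reasons$reason[res$reasons$image == "img03"],
               "arch/pitch/roll")
  # any-3 rule takes precedence in the recorded reason
  expect_match(res$reasons$reason[res$reasons$image == "img07"], "score 3")
})

test_that("quality filtering partitions the input and validates scores", {
  set.seed(7)
  n <- 40
  scores <- data.frame(
    image = sprintf("r%02d", 1:n), focus = sample(1:3, n, TRUE),
    straightness = sample(1:3, n, TRUE), roll = sample(1:3, n, TRUE),
    arch = sample(1:3, n, TRUE), pitch = sample(1:3, n, TRUE),
    length_measurability = sample(1:3, n, TRUE),
    width_measurability = sample(1:3, n, TRUE), stringsAsFactors = FALSE
  )
  res <- filter_by_quality(scores)
  expect_setequal(c(res$kept, res$excluded), scores$image)
  expect_length(intersect(res$kept, res$excluded), 0)
  scores$roll[1] <- 4
  expect_error(filter_by_quality(scores), "must be 1, 2 or 3")
  expect_error(filter_by_quality(scores[, -3]), "missing score column")
})

test_that("measurement tables round-trip through write and read", {
  fix <- small_joint_data(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(fix$data, path)
  back <- read_measurements(path)
  m0 <- fix$data$measurements[order(fix$data$measurements$image,
                                    fix$data$measurements$label), ]
  m1 <- back$measurements[order(back$measurements$image,
                                back$measurements$label), ]
  rownames(m0) <- rownames(m1) <- NULL
  expect_equal(m1, m0)
  i0 <- fix$data$images[order(fix$data$images$image), ]
  i1 <- back$images[order(back$images$image), names(i0)]
  rownames(i0) <- rownames(i1) <- NULL
  expect_equal(i1, i0)
})

test_that("reading a table with both altimeters yields two usable readings", {
  img <- test_images(2)
  img$lidar_alt_m <- c(31.2, 32.1)
  img$lens_offset_m <- 0.1
  img <- correct_altitudes(img)
  data <- measurement_data(img, data.frame(
    subject = "w1", image = img$image, label = "TL", length_px = c(900, 940),
    timepoint = "t0", known_length_m = NA_real_, stringsAsFactors = FALSE))
  rd <- aeromorph:::altimeter_readings(data$images)
  expect_setequal(unique(rd$altimeter), c("d1:barometer", "d1:lidar"))
  expect_equal(nrow(rd), 4)
  # lidar readings carry the lens offset, barometer the launch height
  expect_equal(sort(rd$altitude_m[rd$kind == "lidar"]), c(31.3, 32.2))
  expect_equal(sort(rd$altitude_m[rd$kind == "barometer"]), c(32.5, 33.5))
})

test_that("reader errors name the offending column or row", {
  fix <- small_joint_data(seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(fix$data, path)
  tab <- read.csv(path, check.names = FALSE)
  bad1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[, setdiff(names(tab), "length_px")], bad1, row.names = FALSE)
  expect_error(read_measurements(bad1), "length_px")
  tab2 <- tab
  tab2$barometer_alt_m <- as.character(tab2$barometer_alt_m)
  tab2$barometer_alt_m[4] <- "oops"
  bad2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab2, bad2, row.names = FALSE)
  expect_error(read_measurements(bad2), "row 4")
  expect_error(read_measurements("/nonexistent/file.csv"), "not found")
})

test_that("duplicate measurements and orphan references are rejected", {
  img <- test_images(1)
  meas <- data.frame(subject = "w1", image = "img01", label = "TL",
                     length_px = 900, timepoint = "t0",
                     known_length_m = NA_real_, stringsAsFactors = FALSE)
  expect_error(measurement_data(img, rbind(meas, transform(meas, image = "ghost"))),
               "ghost")
  expect_silent(measurement_data(img, meas))
})

test_that("the shipped synthetic example table loads and builds a sampler", {
  path <- system.file("extdata", "synthetic_example_measurements.csv",
                      package = "aeromorph")
  data <- read_measurements(path)
  expect_gt(nrow(data$images), 10)
  expect_true(any(is.finite(data$measurements$known_length_m)))
  expect_s3_class(build_sampler(data), "aeromorph_sampler")
})
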