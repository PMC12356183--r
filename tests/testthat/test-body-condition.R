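test_that("geometry matches closed forms: rectangle, triangle, cylinder, cone", {
  # constant width 2 m spanning TL = 10 m (stations 0.001..0.999 ~ full body)
  full <- width_profile(10 / 0.998, c(0.001, 0.999), c(2, 2))
  expect_equal(projected_area(full), 20, tolerance = 1e-12)
  expect_equal(body_volume(full, "circular"), pi * 1^2 * 10,
               tolerance = 1e-12)
  # linear taper 2 -> 0 m over 10 m: triangle area, cone volume
  cone <- width_profile(10 / 0.998, c(0.001, 0.999), c(2, 0))
  expect_equal(projected_area(cone), 10, tolerance = 1e-12)
  expect_equal(body_volume(cone, "circular"), pi * 1^2 * 10 / 3,
               tolerance = 1e-12)
})

test_that("elliptical volume scales exactly with the height-width ratio", {
  prof <- width_profile(12, seq(0.1, 0.9, 0.1),
                        c(1, 1.8, 2.3, 2.5, 2.4, 2.1, 1.6, 0.9, 0.4))
  vc <- body_volume(prof, "circular")
  expect_equal(body_volume(prof, "elliptical", hw_ratio = 0.5), vc / 2)
  expect_equal(body_volume(prof, "elliptical", hw_ratio = 1), vc)
})

test_that("projected area is invariant to redundant collinear stations", {
  prof <- width_profile(10, c(0.1, 0.5, 0.9), c(2, 1.5, 0.5))
  # insert midpoints on the same line segments
  prof2 <- width_profile(10, c(0.1, 0.3, 0.5, 0.7, 0.9),
                         c(2, 1.75, 1.5, 1.0, 0.5))
  expect_equal(projected_area(prof2), projected_area(prof), tolerance = 1e-12)
})

test_that("standardized widths divide by total length and are scale invariant", {
  prof <- width_profile(10, c(0.3, 0.5), c(2, 3))
  expect_equal(unname(standardized_widths(prof)), c(0.2, 0.3))
  prof_scaled <- width_profile(30, c(0.3, 0.5), c(6, 9))
  expect_equal(standardized_widths(prof_scaled), standardized_widths(prof))
  expect_equal(unname(standardized_widths(
    width_profile(10, c(0.3, 0.5), c(0, 3))))[1], 0)
})

test_that("body area index matches rectangle arithmetic and is dimensionless", {
  # constant width 2 m, TL 10 m, region (0.2, 0.7): 10 m^2 / (5 m)^2 = 0.4
  prof <- width_profile(10, c(0.1, 0.5, 0.9), c(2, 2, 2))
  expect_equal(body_area_index(prof, c(0.2, 0.7)), 0.4, tolerance = 1e-12)
  expect_equal(body_area_index(prof, c(0.2, 0.7), scale = 100), 40)
  # scale invariance: all dimensions scaled by c
  p2 <- width_profile(25, c(0.1, 0.5, 0.9), c(5, 5, 5))
  expect_equal(body_area_index(p2, c(0.2, 0.7)),
               body_area_index(prof, c(0.2, 0.7)))
  expect_error(body_area_index(prof, c(0.05, 0.7)), "outside measured")
  expect_error(body_area_index(prof, c(0.4, 0.4004)), "narrower")
})

test_that("increasing any width never decreases area or volume", {
  st <- seq(0.1, 0.9, 0.2)
  w <- c(1, 2, 2.5, 2, 1)
  base <- width_profile(10, st, w)
  for (k in seq_along(st)) {
    w2 <- w
    w2[k] <- w[k] + 0.5
    bumped <- width_profile(10, st, w2)
    expect_gt(projected_area(bumped), projected_area(base))
    expect_gt(body_volume(bumped), body_volume(base))
  }
})

test_that("width profile validation rejects malformed inputs", {
  expect_error(width_profile(0, c(0.2, 0.5), c(1, 1)), "positive")
  expect_error(width_profile(10, c(0.5, 0.2), c(1, 1)), "increasing")
  expect_error(width_profile(10, c(0.2, 0.5), c(1, -1)), "non-negative")
  expect_error(width_profile(10, c(0, 0.5), c(1, 1)), "inside")
  expect_error(projected_area(width_profile(10, 0.5, 1)), "at least 2")
})

# fabricate a posterior_draws object with TL and width parameters
fake_bc_draws <- function(n = 100, subj = "w1", tp = "t0", seed = 1,
                          tl_mean = 10, tl_sd = 0.3, w_cv = 0.1) {
  set.seed(seed)
  st <- c(0.2, 0.4, 0.6, 0.8)
  labels <- c("TL", "W20", "W40", "W60", "W80")
  w_mean <- tl_mean * c(NA, 0.13, 0.20, 0.18, 0.10)[-1]
  mat <- cbind(
    rnorm(n, tl_mean, tl_sd),
    sapply(w_mean, function(m) rnorm(n, m, w_cv * m))
  )
  params <- sprintf("L[%s,%s,%s]", subj, tp, labels)
  colnames(mat) <- params
  structure(list(
    draws = mat,
    param_map = data.frame(parameter = params, type = "length",
                           subject = subj, timepoint = tp, label = labels,
                           stringsAsFactors = FALSE),
    seed = seed, model = "measurement"
  ), class = "posterior_draws")
}

test_that("body condition metrics agree with a per-draw brute-force recomputation", {
  bc <- body_condition(fake_bc_draws(n = 100))
  mat <- fake_bc_draws(n = 100)$draws
  st <- c(0.2, 0.4, 0.6, 0.8)
  # independent recomputation with bare trapezoid/frustum sums
  for (r in c(1, 37, 100)) {
    tl <- unname(mat[r, 1]); w <- unname(mat[r, -1])
    dx <- diff(st) * tl
    area <- sum(dx * (w[-4] + w[-1]) / 2)
    vol <- sum(pi * dx / 12 * (w[-4]^2 + w[-4] * w[-1] + w[-1]^2))
    got <- bc$draws[["w1 t0"]][r, ]
    expect_equal(unname(got["projected_area"]), area, tolerance = 1e-12)
    expect_equal(unname(got["volume_circular"]), vol, tolerance = 1e-12)
    expect_equal(unname(got["total_length"]), tl)
  }
})

test_that("degenerate draws collapse to the deterministic metrics", {
  d <- fake_bc_draws(n = 50, tl_sd = 0, w_cv = 0)
  d$draws <- d$draws[rep(1, 50), ]
  bc <- body_condition(d)
  s <- bc$summary
  expect_true(all(s$sd < 1e-12))
  expect_true(all(abs(s$upper - s$lower) < 1e-12))
})

test_that("volume uncertainty exceeds single-width uncertainty (dimensional scale)", {
  bc <- body_condition(fake_bc_draws(n = 4000, w_cv = 0.10, tl_sd = 0))
  s <- bc$summary
  cv <- function(metric) {
    row <- s[s$metric == metric, ]
    row$sd / row$mean
  }
  expect_gt(cv("volume_circular"), cv("standardized_width_W40"))
  expect_gt(cv("volume_circular"), cv("projected_area"))
})

test_that("subjects without usable TL or widths are skipped with a warning", {
  d <- fake_bc_draws()
  # drop all width columns for the subject
  d$draws <- d$draws[, 1:2]
  d$param_map <- d$param_map[1:2, ]
  expect_error(expect_warning(body_condition(d), "skipping"), "usable")
})
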