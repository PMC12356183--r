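#' Build the measurement-error MCMC sampler
#'
#' Assembles the Bayesian hierarchical measurement-error model from
#' calibration and animal measurements. Calibration rows (finite
#' `known_length_m`) train the altimeter and pixel-noise parameters; animal
#' rows receive latent true lengths. Each altimeter present on a drone
#' (barometer and/or LiDAR) gets its own bias, scaling and noise
#' parameters, so drones with different instrumentation are calibrated
#' jointly but separately. Every image contributes one latent altitude
#' shared by all measurements and readings from that image — this is what
#' propagates the joint dependency of pixel lengths and altitude into the
#' length posteriors.
#'
#' `grouping` controls how animal measurements pool into latent lengths:
#' `"image"` gives every (subject, image, label) its own latent value;
#' `"timepoint"` (default) pools images of a subject within a timepoint —
#' appropriate for widths and daily body condition; `"subject"` pools all
#' images of a subject — appropriate for lengths on annual/seasonal scales.
#'
#' @param data A `measurement_data` object containing both calibration and
#'   animal measurements (see [read_measurements()],
#'   [bind_measurement_data()]).
#' @param spec An [uncertainty_model_spec()].
#' @param grouping One of `"timepoint"`, `"subject"`, `"image"`.
#' @return An `aeromorph_sampler` object; run it with [run_sampler()].
#' @export
build_sampler <- function(data, spec = uncertainty_model_spec(),
                          grouping = c("timepoint", "subject", "image")) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(data, "measurement_data"))
  stopifnot(inherits(spec, "uncertainty_model_spec"))
  prep <- .prep_measurement(data, spec, grouping)
  structure(list(model = "measurement", prep = prep, spec = spec,
                 grouping = grouping),
            class = "aeromorph_sampler")
}

# shared data preparation for both samplers; `label_filter` optionally
# restricts animal rows (growth uses TL only)
.prep_measurement <- function(data, spec, grouping, label_filter = NULL) {
  images <- data$images
  meas <- data$measurements
  if (!"barometer_corrected_m" %in% names(images)) {
    images <- correct_altitudes(images)
  }

  orphan <- setdiff(meas$image, images$image)
  if (length(orphan)) {
    stop(sprintf("measurement references unknown image(s): %s",
                 paste(utils::head(orphan, 3), collapse = ", ")),
         call. = FALSE)
  }
  is_cal <- is.finite(meas$known_length_m)
  if (!any(is_cal)) {
    stop("no calibration (training) data: at least one measurement needs a known length",
         call. = FALSE)
  }
  if (!is.null(label_filter)) {
    drop <- !is_cal & !(meas$label %in% label_filter)
    if (any(drop)) {
      message(sprintf("dropping %d measurement(s) with labels outside %s",
                      sum(drop), paste(label_filter, collapse = "/")))
      meas <- meas[!drop, , drop = FALSE]
      is_cal <- is.finite(meas$known_length_m)
    }
  }

  images <- images[images$image %in% meas$image, , drop = FALSE]
  rownames(images) <- NULL
  rd_long <- altimeter_readings(images)
  no_read <- setdiff(images$image, rd_long$image)
  if (length(no_read)) {
    stop(sprintf("image(s) with no usable altimeter reading: %s",
                 paste(utils::head(no_read, 3), collapse = ", ")),
         call. = FALSE)
  }

  img_idx <- function(x) match(x, images$image)
  altimeters <- sort(unique(rd_long$altimeter))
  drones <- sort(unique(images$drone))

  # observed altitude per image (lidar preferred) for initialisation and
  # for the fixed-altitude mode
  a_obs <- vapply(seq_len(nrow(images)), function(i) {
    r <- rd_long[rd_long$image == images$image[i], , drop = FALSE]
    if (any(r$kind == "lidar")) mean(r$altitude_m[r$kind == "lidar"])
    else mean(r$altitude_m)
  }, numeric(1))

  # latent length groups for animal measurements
  ani <- meas[!is_cal, , drop = FALSE]
  if (nrow(ani)) {
    key <- switch(grouping,
      image = paste(ani$subject, ani$image, ani$label, sep = "\r"),
      timepoint = paste(ani$subject, ani$timepoint, ani$label, sep = "\r"),
      subject = paste(ani$subject, ani$label, sep = "\r"))
    uk <- unique(key)
    grp_of_ani <- match(key, uk)
    first <- match(uk, key)
    groups <- data.frame(
      subject = ani$subject[first],
      timepoint = if (grouping == "subject") NA_character_
                  else ani$timepoint[first],
      image = if (grouping == "image") ani$image[first] else NA_character_,
      label = ani$label[first],
      stringsAsFactors = FALSE
    )
    groups$parameter <- sprintf("L[%s]", vapply(seq_len(nrow(groups)),
      function(i) {
        parts <- c(groups$subject[i],
                   if (grouping == "image") groups$image[i]
                   else if (grouping == "timepoint") groups$timepoint[i],
                   groups$label[i])
        paste(parts[!is.na(parts)], collapse = ",")
      }, character(1)))
  } else {
    groups <- data.frame(subject = character(), timepoint = character(),
                         image = character(), label = character(),
                         parameter = character(), stringsAsFactors = FALSE)
    grp_of_ani <- integer(0)
  }

  grp <- integer(nrow(meas))
  grp[!is_cal] <- grp_of_ani
  px <- list(
    Lp = meas$length_px,
    img = img_idx(meas$image),
    grp = grp,
    drone = match(images$drone[img_idx(meas$image)], drones),
    L_known = ifelse(is_cal, meas$known_length_m, NA_real_)
  )
  rd <- list(
    y = rd_long$altitude_m,
    img = img_idx(rd_long$image),
    alt = match(rd_long$altimeter, altimeters)
  )

  par_names <- c(
    sprintf("a[%s]", images$image),
    sprintf("beta0[%s]", altimeters),
    sprintf("beta1[%s]", altimeters),
    sprintf("sigma_alt[%s]", altimeters),
    sprintf("sigma_px[%s]", drones),
    groups$parameter
  )
  param_map <- data.frame(
    parameter = par_names,
    type = c(rep("altitude", nrow(images)),
             rep("altimeter_bias", length(altimeters)),
             rep("altimeter_scaling", length(altimeters)),
             rep("altimeter_sd", length(altimeters)),
             rep("pixel_sd", length(drones)),
             rep("length", nrow(groups))),
    subject = c(rep(NA, nrow(images) + 3 * length(altimeters) +
                      length(drones)), groups$subject),
    timepoint = c(rep(NA, nrow(images) + 3 * length(altimeters) +
                        length(drones)), groups$timepoint),
    label = c(rep(NA, nrow(images) + 3 * length(altimeters) +
                    length(drones)), groups$label),
    stringsAsFactors = FALSE
  )

  # connected components of the (image, latent group) measurement graph:
  # used for joint scaling moves that travel along the length-altitude
  # ridge (pixel likelihoods constrain only L / a)
  n_img <- nrow(images)
  n_grp <- nrow(groups)
  components <- list()
  lat_rows <- which(px$grp > 0L)
  if (length(lat_rows)) {
    parent <- seq_len(n_img + n_grp)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (m in lat_rows) {
      ra <- find(px$img[m])
      rb <- find(n_img + px$grp[m])
      if (ra != rb) parent[ra] <- rb
    }
    involved <- unique(px$img[lat_rows])
    roots_img <- vapply(involved, find, integer(1))
    roots_grp <- vapply(seq_len(n_grp) + n_img, find, integer(1))
    components <- lapply(unique(roots_grp), function(rt) {
      I <- involved[roots_img == rt]
      S <- which(roots_grp == rt)
      list(img = I,
           grp = S,
           cal_rows = which(px$grp == 0L & px$img %in% I),
           read_rows = which(rd$img %in% I),
           n_free = length(I) + length(S))
    })
  }

  list(
    images = images[, c("image", "drone")],
    c_img = images$focal_length_mm * images$image_width_px /
      images$sensor_width_mm,
    a_obs = a_obs,
    altimeters = altimeters,
    drones = drones,
    read = rd,
    read_by_alt = lapply(seq_along(altimeters), function(j) which(rd$alt == j)),
    px = px,
    px_by_drone = lapply(seq_along(drones), function(d) which(px$drone == d)),
    components = components,
    groups = groups,
    par_names = par_names,
    param_map = param_map
  )
}

#' Run an MCMC sampler
#'
#' Runs the Metropolis-within-Gibbs chain of a sampler built by
#' [build_sampler()] or [growth_curve_sampler()] (which runs it
#' internally). Draws are reproducible: the same sampler, settings and seed
#' give bit-identical output.
#'
#' @param sampler An `aeromorph_sampler`.
#' @param iterations Total MCMC iterations.
#' @param burn_in Iterations discarded from the start (default half);
#'   proposal scales adapt only during burn-in.
#' @param thinning Keep every `thinning`-th post-burn-in draw.
#' @param seed Integer random seed.
#' @return A `posterior_draws` object: retained draws (matrix), `param_map`
#'   describing each column, acceptance rates, and convergence diagnostics
#'   (effective sample size and split-chain scale reduction via
#'   [diagnose_draws()]).
#' @export
run_sampler <- function(sampler, iterations = 10000,
                        burn_in = floor(iterations / 2), thinning = 1,
                        seed = 1) {
  stopifnot(inherits(sampler, "aeromorph_sampler"))
  res <- .run_chain(sampler$prep, sampler$spec, sampler$growth,
                    iterations, burn_in, thinning, seed)
  param_map <- sampler$prep$param_map
  if (!is.null(sampler$growth)) {
    param_map <- rbind(param_map, sampler$growth$param_map)
  }
  draws <- structure(
    list(draws = res$draws,
         param_map = param_map,
         seed = seed, iterations = iterations, burn_in = burn_in,
         thinning = thinning, model = sampler$model,
         acceptance = res$acceptance),
    class = "posterior_draws"
  )
  draws$diagnostics <- diagnose_draws(draws)
  draws
}

#' @export
print.aeromorph_sampler <- function(x, ...) {
  cat(sprintf(paste0("<aeromorph_sampler> %s model: %d images, %d altimeters,",
                     " %d drones, %d latent lengths\n"),
              x$model, nrow(x$prep$images), length(x$prep$altimeters),
              length(x$prep$drones), nrow(x$prep$groups)))
  invisible(x)
}
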