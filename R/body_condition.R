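#' Width profile of a measured body
#'
#' A total length plus perpendicular widths measured at stations along the
#' body, each station a fraction of total length in (0, 1). This is the
#' geometric input to all body-condition metrics.
#'
#' @param total_length_m Total length (m), `> 0`.
#' @param stations Strictly increasing station positions in (0, 1).
#' @param widths_m Widths (m) at the stations, `>= 0`, same length as
#'   `stations`.
#' @return A `width_profile` object.
#' @export
width_profile <- function(total_length_m, stations, widths_m) {
  if (!is.numeric(total_length_m) || length(total_length_m) != 1L ||
      !is.finite(total_length_m) || total_length_m <= 0) {
    stop("`total_length_m` must be a single positive number", call. = FALSE)
  }
  if (length(stations) != length(widths_m)) {
    stop("`stations` and `widths_m` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(stations)) || any(stations <= 0) || any(stations >= 1)) {
    stop("stations must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.unsorted(stations, strictly = TRUE)) {
    stop("stations must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(widths_m)) || any(widths_m < 0)) {
    stop("widths must be finite and non-negative", call. = FALSE)
  }
  structure(list(total_length_m = total_length_m,
                 stations = as.numeric(stations),
                 widths_m = as.numeric(widths_m)),
            class = "width_profile")
}

#' Standardized widths
#'
#' Widths divided by total length: dimensionless, scale-invariant
#' body-condition indices comparable across individuals.
#'
#' @param profile A [width_profile()].
#' @return Numeric vector, one value per station, named by station.
#' @export
standardized_widths <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  out <- profile$widths_m / profile$total_length_m
  names(out) <- format(profile$stations)
  out
}

#' Dorsal projected area
#'
#' Projected area orthogonal to the dorsoventral axis, computed as a series
#' of trapezoids between consecutive width stations:
#' \deqn{A = \sum_k \Delta x_k \frac{w_k + w_{k+1}}{2}, \quad
#'   \Delta x_k = (s_{k+1} - s_k) \, TL.}
#' The body is treated as spanning the measured stations only (no
#' extrapolated end caps at rostrum or fluke).
#'
#' @param profile A [width_profile()] with at least 2 stations.
#' @return Area in m^2.
#' @export
projected_area <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  w <- profile$widths_m
  s <- profile$stations
  if (length(w) < 2L) stop("need at least 2 width stations", call. = FALSE)
  dx <- diff(s) * profile$total_length_m
  sum(dx * (w[-length(w)] + w[-1]) / 2)
}

#' Body volume from frustum segments
#'
#' Volume assuming a circular or elliptical cross-section, integrating
#' conical/elliptical frustums between consecutive stations with linearly
#' interpolated width:
#' \deqn{V = \sum_k \frac{\pi \Delta x_k}{12} \, r \,
#'   (w_k^2 + w_k w_{k+1} + w_{k+1}^2),}
#' where \eqn{r} is the height-to-width ratio of the cross-section
#' (`hw_ratio`; 1 for circular). The elliptical volume is exactly
#' `hw_ratio` times the circular one; heights are not measured
#' independently.
#'
#' @param profile A [width_profile()] with at least 2 stations.
#' @param cross_section `"circular"` or `"elliptical"`.
#' @param hw_ratio Dorsoventral height as a fraction of width, `> 0`;
#'   forced to 1 for a circular cross-section.
#' @return Volume in m^3.
#' @export
body_volume <- function(profile, cross_section = c("circular", "elliptical"),
                        hw_ratio = 1) {
  stopifnot(inherits(profile, "width_profile"))
  cross_section <- match.arg(cross_section)
  if (!is.numeric(hw_ratio) || length(hw_ratio) != 1L || hw_ratio <= 0) {
    stop("`hw_ratio` must be a single positive number", call. = FALSE)
  }
  if (cross_section == "circular") hw_ratio <- 1
  w <- profile$widths_m
  s <- profile$stations
  if (length(w) < 2L) stop("need at least 2 width stations", call. = FALSE)
  dx <- diff(s) * profile$total_length_m
  w1 <- w[-length(w)]
  w2 <- w[-1]
  sum(pi * dx / 12 * hw_ratio * (w1^2 + w1 * w2 + w2^2))
}

#' Body area index
#'
#' The projected area of a body region divided by the squared length of
#' that region:
#' \deqn{BAI = \frac{A_{[lo, hi]}}{((hi - lo) \, TL)^2},}
#' a dimensionless, scale-invariant condition metric. Widths at the region
#' bounds are linearly interpolated between stations. Reported as a raw
#' ratio by default; set `scale = 100` for a percentage convention.
#'
#' @param profile A [width_profile()] with at least 2 stations.
#' @param region Fractions of total length `c(lo, hi)` bounding the
#'   region; must lie within the measured stations, with
#'   `hi - lo >= min_region`.
#' @param scale Multiplier applied to the ratio (default 1).
#' @param min_region Minimum admissible region width as a fraction of TL.
#' @return Dimensionless BAI.
#' @export
body_area_index <- function(profile, region = c(0.2, 0.7), scale = 1,
                            min_region = 1e-3) {
  stopifnot(inherits(profile, "width_profile"))
  if (length(region) != 2L || !all(is.finite(region))) {
    stop("`region` must be c(lo, hi)", call. = FALSE)
  }
  lo <- region[1]; hi <- region[2]
  s <- profile$stations
  if (length(s) < 2L) stop("need at least 2 width stations", call. = FALSE)
  if (hi - lo < min_region) {
    stop("region is narrower than the minimum admissible width",
         call. = FALSE)
  }
  if (lo < s[1] || hi > s[length(s)]) {
    stop(sprintf("region (%g, %g) outside measured stations [%g, %g]",
                 lo, hi, s[1], s[length(s)]), call. = FALSE)
  }
  w <- profile$widths_m
  inner <- s > lo & s < hi
  ss <- c(lo, s[inner], hi)
  ww <- c(stats::approx(s, w, xout = lo)$y, w[inner],
          stats::approx(s, w, xout = hi)$y)
  dx <- diff(ss) * profile$total_length_m
  area <- sum(dx * (ww[-length(ww)] + ww[-1]) / 2)
  scale * area / ((hi - lo) * profile$total_length_m)^2
}

# default mapping from measurement labels to stations: "TL" is the total
# length; "W<percent>" is a width at percent/100 of TL
station_from_label <- function(labels) {
  out <- rep(NA_real_, length(labels))
  m <- regmatches(labels, regexec("^W(\\d+(?:\\.\\d+)?)$", labels))
  has <- lengths(m) == 2
  out[has] <- as.numeric(vapply(m[has], `[`, character(1), 2)) / 100
  out
}

#' Body-condition metrics over posterior draws
#'
#' Computes standardized widths, projected area, circular and elliptical
#' body volume, and body area index for each posterior draw of each
#' subject-timepoint, then summarizes each metric with mean, sd and HPDI.
#' Working per draw (rather than on posterior means) propagates the full
#' measurement uncertainty into every metric, and uncertainty grows with
#' dimensional scale: widths to areas to volumes.
#'
#' @param draws A `posterior_draws` object whose latent lengths include a
#'   `"TL"` label and at least 2 width labels (`"W<percent>"` by default)
#'   per subject-timepoint. Subjects missing these are skipped with a
#'   warning.
#' @param bai_region BAI region as fractions of TL; default `c(0.2, 0.7)`.
#' @param hw_ratio Height-to-width ratio for the elliptical volume.
#' @param bai_scale Multiplier for BAI (1 = raw ratio).
#' @param stations Optional named numeric vector mapping width labels to
#'   station fractions, overriding the `"W<percent>"` convention.
#' @param mass HPDI mass.
#' @return A `body_condition_draws` object: list with `draws` (named list
#'   per subject-timepoint of per-draw metric matrices) and `summary` (tidy
#'   data frame: `subject`, `timepoint`, `metric`, `mean`, `sd`, `lower`,
#'   `upper`).
#' @export
body_condition <- function(draws, bai_region = c(0.2, 0.7), hw_ratio = 1,
                           bai_scale = 1, stations = NULL, mass = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  pm <- draws$param_map
  len <- pm[pm$type == "length", , drop = FALSE]
  if (!nrow(len)) stop("no latent length parameters in `draws`", call. = FALSE)
  len$st <- if (is.null(stations)) {
    station_from_label(len$label)
  } else {
    unname(stations[len$label])
  }
  key <- paste(len$subject, len$timepoint, sep = "\r")
  mat <- draws$draws
  out_draws <- list()
  rows <- list()
  for (kk in unique(key)) {
    sel <- len[key == kk, , drop = FALSE]
    tl_par <- sel$parameter[sel$label == "TL"]
    wsel <- sel[!is.na(sel$st), , drop = FALSE]
    wsel <- wsel[order(wsel$st), , drop = FALSE]
    subj <- sel$subject[1]; tp <- sel$timepoint[1]
    if (length(tl_par) != 1L || nrow(wsel) < 2L) {
      warning(sprintf("skipping %s %s: needs a TL and >= 2 width stations",
                      subj, tp), call. = FALSE)
      next
    }
    tl <- mat[, tl_par]
    wmat <- mat[, wsel$parameter, drop = FALSE]
    n <- length(tl)
    sw <- sweep(wmat, 1, tl, "/")
    colnames(sw) <- sprintf("standardized_width_%s", wsel$label)
    pa <- numeric(n); vc <- numeric(n); ve <- numeric(n); bai <- numeric(n)
    for (r in seq_len(n)) {
      prof <- width_profile(tl[r], wsel$st, wmat[r, ])
      pa[r] <- projected_area(prof)
      vc[r] <- body_volume(prof, "circular")
      ve[r] <- body_volume(prof, "elliptical", hw_ratio = hw_ratio)
      bai[r] <- body_area_index(prof, region = bai_region, scale = bai_scale)
    }
    metrics <- cbind(total_length = tl, sw, projected_area = pa,
                     volume_circular = vc, volume_elliptical = ve, bai = bai)
    out_draws[[paste(subj, tp)]] <- metrics
    ints <- apply(metrics, 2, hpdi, mass = mass)
    rows[[paste(subj, tp)]] <- data.frame(
      subject = subj, timepoint = tp, metric = colnames(metrics),
      mean = colMeans(metrics), sd = apply(metrics, 2, stats::sd),
      lower = ints[1, ], upper = ints[2, ],
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no subject had usable TL + width draws", call. = FALSE)
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(draws = out_draws, summary = summary),
            class = "body_condition_draws")
}

#' @export
print.body_condition_draws <- function(x, ...) {
  cat(sprintf("<body_condition_draws> %d subject-timepoint(s), %d metric(s)\n",
              length(x$draws), length(unique(x$summary$metric))))
  invisible(x)
}
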