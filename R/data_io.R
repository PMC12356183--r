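#' Table dialect for collated measurement files
#'
#' Collated photogrammetry tables (one row per pixel measurement, joined with
#' per-image camera and altimeter metadata) vary in column naming across
#' labs and collation tools. A dialect names the columns the readers expect
#' and the conventions used to interpret them. The default dialect matches
#' the wide, one-measurement-per-row layout produced by common
#' measurement-collation GUIs.
#'
#' A LiDAR altimeter often records null or erroneous returns over water
#' (refracted or scattered laser pulses). `lidar_null` decides which raw
#' values are treated as missing; the default treats any non-positive or
#' non-finite reading as null, so that analysis can fall back to the
#' barometer for those images.
#'
#' @param sep Field separator (default `","`).
#' @param image_col,drone_col,timestamp_col Identifier columns.
#' @param focal_length_col,sensor_width_col,image_width_col,image_height_col
#'   Camera constant columns (mm, mm, px, px).
#' @param barometer_col,lidar_col Raw altitude columns (m); either may be
#'   absent from a file, but at least one must be present.
#' @param launch_height_col Height of the camera above the water surface at
#'   launch (m); added to barometer readings, which are zeroed at launch.
#' @param lens_offset_col Signed distance between the LiDAR unit and the
#'   camera lens (m); added to LiDAR readings as given (positive when the
#'   lens sits below the LiDAR unit).
#' @param subject_col,label_col,length_px_col,timepoint_col Measurement
#'   columns: subject identifier, measurement label (e.g. `"TL"` for total
#'   length, `"W20"` for the width at 20% of TL), pixel length, and a
#'   temporal grouping token (e.g. a date or year).
#' @param known_length_col True object length (m) for calibration rows;
#'   `NA` or absent for animal rows.
#' @param lidar_null Function mapping raw LiDAR values to a logical
#'   "is null" vector.
#'
#' @return A `measurement_dialect` object.
#' @export
measurement_dialect <- function(sep = ",",
                                image_col = "image",
                                drone_col = "drone",
                                timestamp_col = "timestamp",
                                focal_length_col = "focal_length_mm",
                                sensor_width_col = "sensor_width_mm",
                                image_width_col = "image_width_px",
                                image_height_col = "image_height_px",
                                barometer_col = "barometer_alt_m",
                                lidar_col = "lidar_alt_m",
                                launch_height_col = "launch_height_m",
                                lens_offset_col = "lens_offset_m",
                                subject_col = "subject",
                                label_col = "label",
                                length_px_col = "length_px",
                                timepoint_col = "timepoint",
                                known_length_col = "known_length_m",
                                lidar_null = function(x) !is.finite(x) | x <= 0) {
  structure(as.list(environment()), class = "measurement_dialect")
}

.required_image_cols <- function(dialect) {
  c(dialect$image_col, dialect$drone_col, dialect$focal_length_col,
    dialect$sensor_width_col, dialect$image_width_col)
}

.required_measurement_cols <- function(dialect) {
  c(dialect$subject_col, dialect$label_col, dialect$length_px_col)
}

#' Read a collated measurement table
#'
#' Reads a delimiter-separated table holding one pixel measurement per row,
#' joined with per-image metadata, and splits it into a per-image table and a
#' per-measurement table. Altitude corrections ([correct_altitudes()]) are
#' applied on read. Rows carrying a finite known object length are
#' calibration measurements; the rest are animal measurements. Unknown
#' columns are preserved in the image table.
#'
#' @param path Path to a delimited text file.
#' @param dialect A [measurement_dialect()].
#' @return A `measurement_data` object: a list with elements `images` (one
#'   row per image: identifiers, camera constants, raw and corrected
#'   altitudes) and `measurements` (one row per measurement: `subject`,
#'   `image`, `label`, `length_px`, `timepoint`, `known_length_m`).
#' @seealso [write_measurements()], [measurement_data()]
#' @export
read_measurements <- function(path, dialect = measurement_dialect()) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(.required_image_cols(dialect), .required_measurement_cols(dialect))
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  has_baro  <- dialect$barometer_col %in% names(raw)
  has_lidar <- dialect$lidar_col %in% names(raw)
  if (!has_baro && !has_lidar) {
    stop(sprintf("need at least one altitude column (%s or %s)",
                 dialect$barometer_col, dialect$lidar_col), call. = FALSE)
  }
  for (col in intersect(c(dialect$barometer_col, dialect$lidar_col,
                          dialect$launch_height_col, dialect$lens_offset_col,
                          dialect$length_px_col, dialect$known_length_col),
                        names(raw))) {
    vals <- raw[[col]]
    if (!is.numeric(vals) && !is.logical(vals)) {
      suppressWarnings(num <- as.numeric(vals))
      bad <- which(!is.na(vals) & vals != "" & is.na(num))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                     col, bad[1], vals[bad[1]]), call. = FALSE)
      }
      raw[[col]] <- num
    }
  }

  pick <- function(col, default = NA) {
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  images <- data.frame(
    image            = as.character(raw[[dialect$image_col]]),
    drone            = as.character(raw[[dialect$drone_col]]),
    timestamp        = as.character(pick(dialect$timestamp_col)),
    focal_length_mm  = as.numeric(raw[[dialect$focal_length_col]]),
    sensor_width_mm  = as.numeric(raw[[dialect$sensor_width_col]]),
    image_width_px   = as.numeric(raw[[dialect$image_width_col]]),
    image_height_px  = as.numeric(pick(dialect$image_height_col)),
    barometer_alt_m  = as.numeric(pick(dialect$barometer_col)),
    lidar_alt_m      = as.numeric(pick(dialect$lidar_col)),
    launch_height_m  = as.numeric(pick(dialect$launch_height_col)),
    lens_offset_m    = as.numeric(pick(dialect$lens_offset_col)),
    stringsAsFactors = FALSE
  )
  # null lidar returns become missing so downstream falls back to barometer
  images$lidar_alt_m[dialect$lidar_null(images$lidar_alt_m)] <- NA_real_
  images <- images[!duplicated(images$image), , drop = FALSE]
  rownames(images) <- NULL
  images <- correct_altitudes(images)

  measurements <- data.frame(
    subject        = as.character(raw[[dialect$subject_col]]),
    image          = as.character(raw[[dialect$image_col]]),
    label          = as.character(raw[[dialect$label_col]]),
    length_px      = as.numeric(raw[[dialect$length_px_col]]),
    timepoint      = as.character(pick(dialect$timepoint_col, "t0")),
    known_length_m = as.numeric(pick(dialect$known_length_col)),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(measurements$length_px) | measurements$length_px <= 0)) {
    bad <- which(!is.finite(measurements$length_px) |
                   measurements$length_px <= 0)[1]
    stop(sprintf("non-positive or missing pixel length at data row %d", bad),
         call. = FALSE)
  }
  key <- paste(measurements$subject, measurements$image, measurements$label)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (subject, image, label) measurement: %s",
                 key[duplicated(key)][1]), call. = FALSE)
  }
  measurement_data(images, measurements)
}

#' Construct a measurement dataset from in-memory tables
#'
#' @param images Per-image data frame (see [read_measurements()] for the
#'   column contract).
#' @param measurements Per-measurement data frame.
#' @return A `measurement_data` object.
#' @export
measurement_data <- function(images, measurements) {
  stopifnot(is.data.frame(images), is.data.frame(measurements))
  if (anyDuplicated(images$image)) {
    stop("image ids must be unique", call. = FALSE)
  }
  orphan <- setdiff(measurements$image, images$image)
  if (length(orphan)) {
    stop(sprintf("measurement references unknown image(s): %s",
                 paste(utils::head(orphan, 3), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(images = images, measurements = measurements),
            class = "measurement_data")
}

#' @export
print.measurement_data <- function(x, ...) {
  n_cal <- sum(is.finite(x$measurements$known_length_m))
  cat(sprintf(paste0("<measurement_data> %d images (%d drones), ",
                     "%d measurements (%d calibration, %d animal)\n"),
              nrow(x$images), length(unique(x$images$drone)),
              nrow(x$measurements), n_cal,
              nrow(x$measurements) - n_cal))
  invisible(x)
}

#' Combine measurement datasets
#'
#' Row-binds the image and measurement tables of several datasets, e.g. to
#' pool calibration flights with animal observations.
#'
#' @param ... `measurement_data` objects.
#' @return A single `measurement_data`.
#' @export
bind_measurement_data <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "measurement_data")))
  images <- do.call(rbind, lapply(parts, `[[`, "images"))
  images <- images[!duplicated(images$image), , drop = FALSE]
  rownames(images) <- NULL
  measurements <- do.call(rbind, lapply(parts, `[[`, "measurements"))
  rownames(measurements) <- NULL
  measurement_data(images, measurements)
}

#' Write a collated measurement table
#'
#' Inverse of [read_measurements()]: joins the image metadata back onto the
#' measurement rows and writes a single delimited table. Reading the file
#' back yields identical records.
#'
#' @param data A `measurement_data` object.
#' @param path Output path.
#' @param dialect A [measurement_dialect()].
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path, dialect = measurement_dialect()) {
  stopifnot(inherits(data, "measurement_data"))
  m <- data$measurements
  i <- data$images[match(m$image, data$images$image), , drop = FALSE]
  out <- data.frame(x = m$subject, stringsAsFactors = FALSE)
  names(out) <- dialect$subject_col
  out[[dialect$image_col]] <- m$image
  out[[dialect$label_col]] <- m$label
  out[[dialect$length_px_col]] <- m$length_px
  out[[dialect$timepoint_col]] <- m$timepoint
  out[[dialect$known_length_col]] <- m$known_length_m
  out[[dialect$drone_col]] <- i$drone
  out[[dialect$timestamp_col]] <- i$timestamp
  out[[dialect$focal_length_col]] <- i$focal_length_mm
  out[[dialect$sensor_width_col]] <- i$sensor_width_mm
  out[[dialect$image_width_col]] <- i$image_width_px
  out[[dialect$image_height_col]] <- i$image_height_px
  out[[dialect$barometer_col]] <- i$barometer_alt_m
  out[[dialect$lidar_col]] <- i$lidar_alt_m
  out[[dialect$launch_height_col]] <- i$launch_height_m
  out[[dialect$lens_offset_col]] <- i$lens_offset_m
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Apply altitude corrections to an image table
#'
#' Barometer altimeters are zeroed at launch, so the recorded launch height
#' (water surface to camera lens) is added to every barometer reading.
#' LiDAR altimeters measure from the LiDAR unit rather than the lens, so the
#' signed lens offset is added to every LiDAR reading. Raw readings are
#' preserved; corrected values are written to `barometer_corrected_m` and
#' `lidar_corrected_m`. The operation is idempotent: corrected columns are
#' recomputed from the raw columns each call.
#'
#' @param images Per-image data frame with columns `barometer_alt_m`,
#'   `lidar_alt_m`, `launch_height_m`, `lens_offset_m` (any may be all-`NA`).
#' @return `images` with corrected-altitude columns.
#' @export
correct_altitudes <- function(images) {
  stopifnot(is.data.frame(images))
  for (col in c("barometer_alt_m", "lidar_alt_m",
                "launch_height_m", "lens_offset_m")) {
    if (is.null(images[[col]])) images[[col]] <- NA_real_
  }
  baro_ok <- is.finite(images$barometer_alt_m)
  lh <- images$launch_height_m
  images$barometer_corrected_m <- ifelse(
    baro_ok & is.finite(lh), images$barometer_alt_m + lh, NA_real_)
  missing_lh <- baro_ok & !is.finite(lh)
  if (any(missing_lh)) {
    has_lidar <- is.finite(images$lidar_alt_m)
    if (any(missing_lh & !has_lidar)) {
      warning(sprintf(paste0("%d barometer-only image(s) lack a launch height;",
                             " corrected altitude left absent"),
                      sum(missing_lh & !has_lidar)), call. = FALSE)
    }
  }
  off <- images$lens_offset_m
  off[!is.finite(off)] <- 0
  images$lidar_corrected_m <- ifelse(
    is.finite(images$lidar_alt_m), images$lidar_alt_m + off, NA_real_)
  images
}

#' Synchronize an altimeter log with image timestamps
#'
#' LiDAR altimeters typically log on a separate clock from the camera. The
#' offset between a displayed GPS time and the camera timestamp, recorded
#' once per flight, shifts each image time onto the log's clock; the image
#' is then matched to the nearest log entry within a maximum gap.
#' Nearest-neighbour matching (rather than interpolation) is used because
#' altimeter logs are dense relative to image cadence and interpolating
#' across dropouts would mask null returns.
#'
#' @param log_times Log timestamps, sorted ascending (`POSIXct` or numeric
#'   seconds).
#' @param log_altitudes Altitudes (m) recorded at `log_times`; null returns
#'   may be encoded as `NA` or flagged by `null_values`.
#' @param image_times Camera timestamps for the images to match.
#' @param clock_offset_s Scalar seconds to add to each image time to place
#'   it on the log clock.
#' @param max_gap_s Maximum |time difference| (s) for a match; `>= 0`.
#' @param null_values Function flagging null/erroneous log altitudes
#'   (default: non-finite or non-positive).
#' @return Numeric altitude per image; `NA` where no log entry lies within
#'   `max_gap_s` or where the matched entry is null.
#' @export
sync_altitude_log <- function(log_times, log_altitudes, image_times,
                              clock_offset_s, max_gap_s = 1,
                              null_values = function(x) !is.finite(x) | x <= 0) {
  lt <- as.numeric(log_times)
  it <- as.numeric(image_times)
  if (length(lt) != length(log_altitudes)) {
    stop("`log_times` and `log_altitudes` must have equal length",
         call. = FALSE)
  }
  if (is.unsorted(lt, strictly = FALSE)) {
    stop("altimeter log must be sorted by time", call. = FALSE)
  }
  if (!is.numeric(max_gap_s) || length(max_gap_s) != 1L || max_gap_s < 0) {
    stop("`max_gap_s` must be a single non-negative number", call. = FALSE)
  }
  shifted <- it + clock_offset_s
  # nearest log entry: candidate below via findInterval, compare with next
  lo <- findInterval(shifted, lt)
  hi <- pmin(lo + 1L, length(lt))
  lo <- pmax(lo, 1L)
  pick_hi <- abs(lt[hi] - shifted) < abs(lt[lo] - shifted)
  idx <- ifelse(pick_hi, hi, lo)
  alt <- as.numeric(log_altitudes)[idx]
  gap <- abs(lt[idx] - shifted)
  alt[gap > max_gap_s | null_values(alt)] <- NA_real_
  names(alt) <- names(image_times)
  alt
}

#' Filter images by photogrammetric quality scores
#'
#' Each image is scored 1 (good), 2 (medium) or 3 (poor) on seven
#' attributes: camera focus, body straightness, roll, arch, pitch, length
#' measurability and width measurability. An image is excluded when any
#' attribute scores 3, or when at least two of the body-position attributes
#' arch, pitch and roll score 2.
#'
#' @param scores Data frame with an `image` column and score columns
#'   `focus`, `straightness`, `roll`, `arch`, `pitch`,
#'   `length_measurability`, `width_measurability`, each in `{1, 2, 3}`.
#' @return A list with character vectors `kept` and `excluded`, and a data
#'   frame `reasons` (`image`, `kept`, `reason`) recording the triggered
#'   rule per image. `kept` and `excluded` partition the input.
#' @export
filter_by_quality <- function(scores) {
  stopifnot(is.data.frame(scores))
  attrs <- c("focus", "straightness", "roll", "arch", "pitch",
             "length_measurability", "width_measurability")
  missing <- setdiff(c("image", attrs), names(scores))
  if (length(missing)) {
    stop(sprintf("missing score column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sc <- as.matrix(scores[attrs])
  if (!all(sc %in% c(1, 2, 3))) {
    stop("all quality scores must be 1, 2 or 3", call. = FALSE)
  }
  any3 <- rowSums(sc == 3) > 0
  pose2 <- rowSums(sc[, c("arch", "pitch", "roll"), drop = FALSE] == 2) >= 2
  excluded <- any3 | pose2
  reason <- character(nrow(sc))
  reason[!excluded] <- "passed"
  reason[pose2] <- "two or more scores of 2 in arch/pitch/roll"
  reason[any3] <- vapply(which(any3), function(i) {
    sprintf("score 3 in %s", paste(attrs[sc[i, ] == 3], collapse = ", "))
  }, character(1))
  list(
    kept = as.character(scores$image[!excluded]),
    excluded = as.character(scores$image[excluded]),
    reasons = data.frame(image = as.character(scores$image),
                         kept = !excluded, reason = reason,
                         stringsAsFactors = FALSE)
  )
}

# Long-format altimeter readings for modelling: one row per (image,
# altimeter) with the corrected altitude where available, else the raw
# reading. Images whose LiDAR return was null contribute no lidar row.
altimeter_readings <- function(images) {
  baro <- images[is.finite(images$barometer_alt_m) |
                   is.finite(images$barometer_corrected_m), , drop = FALSE]
  lid <- images[is.finite(images$lidar_alt_m), , drop = FALSE]
  rows <- list()
  if (nrow(baro)) {
    rows$baro <- data.frame(
      image = baro$image,
      altimeter = paste0(baro$drone, ":barometer"),
      kind = "barometer",
      altitude_m = ifelse(is.finite(baro$barometer_corrected_m),
                          baro$barometer_corrected_m, baro$barometer_alt_m),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(lid)) {
    rows$lidar <- data.frame(
      image = lid$image,
      altimeter = paste0(lid$drone, ":lidar"),
      kind = "lidar",
      altitude_m = ifelse(is.finite(lid$lidar_corrected_m),
                          lid$lidar_corrected_m, lid$lidar_alt_m),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(image = character(), altimeter = character(),
                      kind = character(), altitude_m = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
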