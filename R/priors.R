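#' Prior distribution constructors
#'
#' Small declarative prior objects used to configure the measurement-error
#' and growth models. `prior_fixed()` pins a parameter at a known value
#' instead of sampling it; for the image-altitude prior, `prior_fixed()`
#' with no value fixes each image's altitude at its observed (corrected)
#' altimeter reading, which is useful for validation against closed-form
#' posteriors.
#'
#' @param min,max Support bounds, `min < max`.
#' @param mean,sd Location and scale; `sd > 0`.
#' @param value Fixed value, or `NULL` for "fix at the observed value"
#'   (altitude only).
#' @return A `prior` object.
#' @name priors
NULL

#' @rdname priors
#' @export
prior_uniform <- function(min, max) {
  stopifnot(is.finite(min), is.finite(max), min < max)
  structure(list(family = "uniform", min = min, max = max), class = "prior")
}

#' @rdname priors
#' @export
prior_loguniform <- function(min, max) {
  stopifnot(is.finite(min), is.finite(max), min > 0, min < max)
  structure(list(family = "loguniform", min = min, max = max),
            class = "prior")
}

#' @rdname priors
#' @export
prior_normal <- function(mean, sd) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  structure(list(family = "normal", mean = mean, sd = sd), class = "prior")
}

#' @rdname priors
#' @export
prior_halfnormal <- function(sd) {
  stopifnot(is.finite(sd), sd > 0)
  structure(list(family = "halfnormal", sd = sd), class = "prior")
}

#' @rdname priors
#' @export
prior_fixed <- function(value = NULL) {
  if (!is.null(value)) stopifnot(is.numeric(value), all(is.finite(value)))
  structure(list(family = "fixed", value = value), class = "prior")
}

#' @export
print.prior <- function(x, ...) {
  cat(switch(x$family,
    uniform = sprintf("<prior> Uniform(%g, %g)\n", x$min, x$max),
    loguniform = sprintf("<prior> log-Uniform(%g, %g)\n", x$min, x$max),
    normal = sprintf("<prior> Normal(%g, %g^2)\n", x$mean, x$sd),
    halfnormal = sprintf("<prior> half-Normal(0, %g^2)\n", x$sd),
    fixed = if (is.null(x$value)) "<prior> fixed at observed value\n"
            else sprintf("<prior> fixed at %s\n",
                         paste(format(x$value), collapse = ", "))
  ))
  invisible(x)
}

.is_fixed <- function(p) identical(p$family, "fixed")

# log-density of a prior at x (vectorised); -Inf outside support
.prior_logpdf <- function(p, x) {
  switch(p$family,
    uniform = ifelse(x >= p$min & x <= p$max, -log(p$max - p$min), -Inf),
    loguniform = ifelse(x >= p$min & x <= p$max,
                        -log(x) - log(log(p$max / p$min)), -Inf),
    normal = stats::dnorm(x, p$mean, p$sd, log = TRUE),
    halfnormal = ifelse(x > 0,
                        log(2) + stats::dnorm(x, 0, p$sd, log = TRUE), -Inf),
    fixed = ifelse(x == p$value, 0, -Inf)
  )
}

.prior_check <- function(p, families, what) {
  if (!inherits(p, "prior") || !(p$family %in% families)) {
    stop(sprintf("`%s` must be a prior of family: %s", what,
                 paste(families, collapse = ", ")), call. = FALSE)
  }
  p
}

#' Measurement-error model specification
#'
#' Prior families and hyperparameters for the Bayesian hierarchical
#' measurement-error model. The defaults are deliberately non-informative —
#' wider than any realistic flight or animal — so that posteriors are driven
#' by the calibration data; start from these and tighten only with
#' subject-matter justification.
#'
#' Parameters and their roles:
#' \describe{
#'   \item{image_altitude}{True altitude of each image (m). Default
#'     log-Uniform(0.1, 130): flat in log altitude, the reference prior
#'     for a positive scale-like quantity. A flat-in-altitude
#'     `prior_uniform()` is available but subtly favours inflating all
#'     latent altitudes and lengths together (the posterior volume of the
#'     length-altitude ridge grows with scale); the log-uniform prior
#'     cancels that volume term exactly. `prior_fixed()` pins each
#'     altitude at its observed altimeter value.}
#'   \item{altimeter_bias}{Additive bias of each altimeter (m); default
#'     Normal(0, 10^2).}
#'   \item{altimeter_scaling}{Multiplicative scaling of each altimeter;
#'     default Normal(1, 0.05^2). Unlike the other defaults this one is
#'     deliberately informative: altimeter scale error is a few percent at
#'     most for both barometers and LiDAR, and a diffuse scaling prior
#'     leaves the joint model with an unidentified scale direction —
#'     latent altitudes, latent lengths and 1/scaling can drift together
#'     with almost no likelihood penalty once many images carry latent
#'     lengths (see the methods vignette).}
#'   \item{altimeter_sd}{Altimeter noise standard deviation (m); default
#'     half-Normal(0, 10^2).}
#'   \item{pixel_sd}{Pixel-measurement noise standard deviation (px), shared
#'     per drone; default half-Normal(0, 20^2).}
#'   \item{object_length}{True length of each measured animal dimension (m);
#'     default log-Uniform(0.01, 30), for the same scale-invariance reason
#'     as the altitude prior.}
#' }
#'
#' @param image_altitude,altimeter_bias,altimeter_scaling,altimeter_sd,pixel_sd,object_length
#'   [priors] objects; see Details for allowed families.
#' @return An `uncertainty_model_spec` object.
#' @export
uncertainty_model_spec <- function(image_altitude = prior_loguniform(0.1, 130),
                                   altimeter_bias = prior_normal(0, 10),
                                   altimeter_scaling = prior_normal(1, 0.05),
                                   altimeter_sd = prior_halfnormal(10),
                                   pixel_sd = prior_halfnormal(20),
                                   object_length = prior_loguniform(0.01, 30)) {
  spec <- list(
    image_altitude = .prior_check(image_altitude,
                                  c("uniform", "loguniform", "fixed"),
                                  "image_altitude"),
    altimeter_bias = .prior_check(altimeter_bias, c("normal", "fixed"),
                                  "altimeter_bias"),
    altimeter_scaling = .prior_check(altimeter_scaling, c("normal", "fixed"),
                                     "altimeter_scaling"),
    altimeter_sd = .prior_check(altimeter_sd, c("halfnormal", "fixed"),
                                "altimeter_sd"),
    pixel_sd = .prior_check(pixel_sd, c("halfnormal", "fixed"), "pixel_sd"),
    object_length = .prior_check(object_length, c("uniform", "loguniform"),
                                 "object_length")
  )
  structure(spec, class = "uncertainty_model_spec")
}
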