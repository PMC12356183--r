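#' Growth-model specification
#'
#' Priors and structural settings for the hierarchical von
#' Bertalanffy-Putter growth model. Expected length at age follows
#' \deqn{E[L] = L_\infty \left(1 - e^{-k (age - t_0)}\right)^{b},}
#' clamped at zero below \eqn{t_0}; the Putter exponent \eqn{b} defaults to
#' 1, the classic von Bertalanffy case. Individual asymptotic lengths
#' \eqn{L_{\infty,i}} are drawn around a sex-level mean; the growth rate
#' \eqn{k} and age-at-length-zero \eqn{t_0} are shared across individuals.
#' Latent per-observation lengths scatter around the growth mean with
#' process standard deviation `growth_sd`, which lets individuals deviate
#' from the curve without swamping it.
#'
#' @param mean_asymptotic_length Prior for the sex-level mean of
#'   \eqn{L_\infty} (m); default Normal(10, 20^2), effectively flat over
#'   whale scales.
#' @param asymptotic_length_sd Prior for the between-individual sd of
#'   \eqn{L_\infty} (m); default half-Normal(0, 2^2).
#' @param growth_rate Prior for \eqn{k} (1/yr); default Uniform(0.01, 1).
#' @param age_zero Prior for \eqn{t_0} (yr); Normal(0, 2^2), truncated
#'   above at the earliest observed age so the curve cannot start after the
#'   data.
#' @param growth_sd Prior for the process sd around the growth mean (m);
#'   default half-Normal(0, 1).
#' @param putter_exponent Putter exponent \eqn{b > 0}; default 1.
#' @param sex_effect Give each sex its own mean asymptotic length
#'   (default `TRUE`). Subjects of unknown sex form their own group; if no
#'   subject has a known sex, the effect is disabled with a warning.
#' @return A `growth_model_spec` object.
#' @export
growth_model_spec <- function(mean_asymptotic_length = prior_normal(10, 20),
                              asymptotic_length_sd = prior_halfnormal(2),
                              growth_rate = prior_uniform(0.01, 1),
                              age_zero = prior_normal(0, 2),
                              growth_sd = prior_halfnormal(1),
                              putter_exponent = 1,
                              sex_effect = TRUE) {
  stopifnot(is.numeric(putter_exponent), putter_exponent > 0)
  structure(list(
    mu_prior = .prior_check(mean_asymptotic_length, "normal",
                            "mean_asymptotic_length"),
    sInf_prior = .prior_check(asymptotic_length_sd, "halfnormal",
                              "asymptotic_length_sd"),
    k_prior = .prior_check(growth_rate, "uniform", "growth_rate"),
    t0_prior = .prior_check(age_zero, "normal", "age_zero"),
    sL_prior = .prior_check(growth_sd, "halfnormal", "growth_sd"),
    exponent = putter_exponent,
    sex_effect = isTRUE(sex_effect)
  ), class = "growth_model_spec")
}

#' Expected length at age under the growth model
#'
#' Evaluates the von Bertalanffy-Putter mean length
#' \eqn{L_\infty (1 - e^{-k(age - t_0)})^b}, floored at zero. Monotone
#' nondecreasing in age for `k > 0` and approaching `asymptotic_length` as
#' age grows.
#'
#' @param age Age in years (vectorised), `>= 0` for biological use but the
#'   function is total.
#' @param asymptotic_length \eqn{L_\infty} (m), `> 0`.
#' @param growth_rate \eqn{k} (1/yr), `> 0`.
#' @param age_zero \eqn{t_0} (yr).
#' @param putter_exponent Putter exponent \eqn{b}; default 1.
#' @return Expected length (m).
#' @examples
#' growth_mean_length(10, asymptotic_length = 12, growth_rate = 0.3,
#'                    age_zero = 0)
#' @export
growth_mean_length <- function(age, asymptotic_length, growth_rate, age_zero,
                               putter_exponent = 1) {
  stopifnot(all(asymptotic_length > 0), all(growth_rate > 0),
            putter_exponent > 0)
  asymptotic_length * .vbp_g(age, growth_rate, age_zero, putter_exponent)
}

#' Hierarchical growth-curve sampler
#'
#' Jointly fits the photogrammetric measurement-error model and a
#' hierarchical von Bertalanffy-Putter growth model. Repeated total-length
#' measurements of individuals across timepoints are constrained by the
#' growth curve, which keeps each individual's estimated size trajectory
#' biologically realistic (nondecreasing expected length with age) and
#' shrinks noisy measurement years — e.g. barometer-only drones — toward
#' the growth-consistent trajectory informed by more precise years.
#'
#' @param observations Data frame with one row per (subject, timepoint):
#'   columns `subject`, `timepoint`, `sex` (`"female"`, `"male"` or
#'   `"unknown"`), and either `age` (known age in years) or `age_min` /
#'   `age_max` (interval age, given a uniform prior).
#' @param data A `measurement_data` holding the calibration measurements
#'   and the subjects' total-length (`label == "TL"`) pixel measurements;
#'   non-TL animal rows are dropped with a message.
#' @param spec An [uncertainty_model_spec()] for the measurement-error
#'   part.
#' @param growth A [growth_model_spec()].
#' @param iterations,burn_in,thinning,seed MCMC controls as in
#'   [run_sampler()].
#' @return A `posterior_draws` object covering measurement-error
#'   parameters, latent per-observation lengths (`L[subject,timepoint,TL]`),
#'   individual asymptotic lengths (`Linf[subject]`), sex-level means
#'   (`mu_Linf[sex]`), `k`, `t0`, `sigma_growth`, `sigma_Linf`, and latent
#'   ages for interval-aged observations.
#' @export
growth_curve_sampler <- function(observations, data,
                                 spec = uncertainty_model_spec(),
                                 growth = growth_model_spec(),
                                 iterations = 10000,
                                 burn_in = floor(iterations / 2),
                                 thinning = 1, seed = 1) {
  stopifnot(inherits(data, "measurement_data"),
            inherits(growth, "growth_model_spec"))
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  needed <- c("subject", "timepoint")
  missing <- setdiff(needed, names(obs))
  if (length(missing)) {
    stop(sprintf("`observations` missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(obs$sex)) obs$sex <- "unknown"
  obs$sex[!obs$sex %in% c("female", "male")] <- "unknown"
  if (!is.null(obs$age) && is.null(obs$age_min)) {
    obs$age_min <- obs$age
    obs$age_max <- obs$age
  }
  if (is.null(obs$age_min) || is.null(obs$age_max)) {
    stop("`observations` needs `age` or `age_min`/`age_max` columns",
         call. = FALSE)
  }
  if (any(obs$age_min < 0 | obs$age_max < obs$age_min)) {
    stop("ages must satisfy 0 <= age_min <= age_max", call. = FALSE)
  }

  # drop observations with no usable TL measurements, and vice versa
  m <- data$measurements
  tl <- m[!is.finite(m$known_length_m) & m$label == "TL", , drop = FALSE]
  obs_key <- paste(obs$subject, obs$timepoint, sep = "\r")
  tl_key <- paste(tl$subject, tl$timepoint, sep = "\r")
  unused <- !(obs_key %in% tl_key)
  if (any(unused)) {
    warning(sprintf("dropping %d observation(s) with no usable TL measurements",
                    sum(unused)), call. = FALSE)
    obs <- obs[!unused, , drop = FALSE]
    obs_key <- obs_key[!unused]
  }
  stray <- !(tl_key %in% obs_key)
  if (any(stray)) {
    warning(sprintf("dropping %d TL measurement(s) without a matching observation row",
                    sum(stray)), call. = FALSE)
    keep <- !(paste(m$subject, m$timepoint, sep = "\r") %in%
                unique(tl_key[stray])) | is.finite(m$known_length_m)
    data <- measurement_data(data$images, m[keep, , drop = FALSE])
  }
  if (length(unique(obs$subject)) < 2L) {
    stop("growth model needs at least 2 subjects", call. = FALSE)
  }

  prep <- .prep_measurement(data, spec, grouping = "timepoint",
                            label_filter = "TL")
  groups <- prep$groups
  gkey <- paste(groups$subject, groups$timepoint, sep = "\r")
  oidx <- match(gkey, obs_key)
  if (anyNA(oidx)) {
    stop("internal error: latent group without observation row", call. = FALSE)
  }

  subjects <- sort(unique(obs$subject))
  sex_of_subject <- obs$sex[match(subjects, obs$subject)]
  if (growth$sex_effect && all(sex_of_subject == "unknown")) {
    warning("all sexes unknown; sex effect disabled", call. = FALSE)
    growth$sex_effect <- FALSE
  }
  sex_levels <- if (growth$sex_effect) {
    intersect(c("female", "male", "unknown"), unique(sex_of_subject))
  } else "all"
  sex_idx <- if (growth$sex_effect) {
    match(sex_of_subject, sex_levels)
  } else rep(1L, length(subjects))

  grp_age_min <- obs$age_min[oidx]
  grp_age_max <- obs$age_max[oidx]
  age_free <- grp_age_max > grp_age_min

  gprep <- list(
    subjects = subjects,
    sex_levels = sex_levels,
    sex_idx = sex_idx,
    sub_by_sex = lapply(seq_along(sex_levels),
                        function(s) which(sex_idx == s)),
    grp_subj = match(groups$subject, subjects),
    grp_age_min = grp_age_min,
    grp_age_max = grp_age_max,
    t0_max = min(grp_age_min),
    mu_prior = growth$mu_prior,
    sInf_prior = growth$sInf_prior,
    k_prior = growth$k_prior,
    t0_prior = growth$t0_prior,
    sL_prior = growth$sL_prior,
    exponent = growth$exponent
  )
  gprep$par_names <- c(
    sprintf("Linf[%s]", subjects),
    sprintf("mu_Linf[%s]", sex_levels),
    "k", "t0", "sigma_growth", "sigma_Linf",
    sprintf("age[%s,%s]", groups$subject, groups$timepoint)
  )
  gprep$param_map <- data.frame(
    parameter = gprep$par_names,
    type = c(rep("asymptotic_length", length(subjects)),
             rep("mean_asymptotic_length", length(sex_levels)),
             "growth_rate", "age_zero", "growth_sd", "asymptotic_length_sd",
             rep("age", nrow(groups))),
    subject = c(subjects, rep(NA, length(sex_levels) + 4), groups$subject),
    timepoint = c(rep(NA, length(subjects) + length(sex_levels) + 4),
                  groups$timepoint),
    label = NA_character_,
    stringsAsFactors = FALSE
  )

  sampler <- structure(
    list(model = "growth", prep = prep, spec = spec, growth = gprep,
         grouping = "timepoint", observations = obs),
    class = "aeromorph_sampler"
  )
  run_sampler(sampler, iterations = iterations, burn_in = burn_in,
              thinning = thinning, seed = seed)
}

#' Population growth-curve summary
#'
#' Posterior mean and HPDI of the expected length at each age on a grid,
#' per sex, evaluated from the sex-level mean asymptotic length and the
#' shared growth parameters of each retained draw.
#'
#' @param draws `posterior_draws` from [growth_curve_sampler()].
#' @param ages Age grid in years.
#' @param mass HPDI mass.
#' @return Data frame `sex`, `age`, `mean`, `lower`, `upper`.
#' @export
growth_curve_summary <- function(draws, ages = seq(0, 40, by = 0.5),
                                 mass = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  mat <- draws$draws
  mu_cols <- grep("^mu_Linf\\[", colnames(mat), value = TRUE)
  if (!length(mu_cols) || !all(c("k", "t0") %in% colnames(mat))) {
    stop("`draws` does not look like growth-curve output", call. = FALSE)
  }
  exponent <- 1
  out <- lapply(mu_cols, function(col) {
    sex <- sub("^mu_Linf\\[(.*)\\]$", "\\1", col)
    curves <- vapply(ages, function(ag) {
      mat[, col] * .vbp_g(ag, mat[, "k"], mat[, "t0"], exponent)
    }, numeric(nrow(mat)))
    ints <- apply(curves, 2, hpdi, mass = mass)
    data.frame(sex = sex, age = ages, mean = colMeans(curves),
               lower = ints[1, ], upper = ints[2, ],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Check biological monotonicity of growth draws
#'
#' For every retained draw and every subject, verifies that the expected
#' lengths at the subject's (drawn) observation ages are nondecreasing in
#' age — the biological-realism constraint the growth curve imposes on
#' repeated measurements. Holds by construction for `k > 0`; this function
#' is the runtime verification.
#'
#' @param draws `posterior_draws` from [growth_curve_sampler()].
#' @return Fraction of draws for which all subjects' expected lengths are
#'   monotone nondecreasing across their observation ages.
#' @export
check_growth_monotonicity <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  mat <- draws$draws
  pm <- draws$param_map
  age_cols <- pm$parameter[pm$type == "age"]
  if (!length(age_cols)) return(1)
  subj <- pm$subject[pm$type == "age"]
  ok <- rep(TRUE, nrow(mat))
  for (s in unique(subj)) {
    cols <- age_cols[subj == s]
    if (length(cols) < 2) next
    linf <- mat[, sprintf("Linf[%s]", s)]
    for (r in seq_len(nrow(mat))) {
      ages <- mat[r, cols]
      el <- linf[r] * .vbp_g(sort(ages), mat[r, "k"], mat[r, "t0"], 1)
      if (any(diff(el) < -1e-12)) ok[r] <- FALSE
    }
  }
  mean(ok)
}
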