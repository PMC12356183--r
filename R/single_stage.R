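#' Single-stage Bayesian regression with measurement uncertainty
#'
#' Fits a simple linear regression `y ~ x` where each predictor value is
#' known only through its measurement posterior (summarized by a mean and
#' standard deviation, e.g. from [summarize_draws()]). The model is
#' \deqn{x_i \sim N(m_i, s_i^2), \quad y_i \sim N(\alpha + \beta x_i,
#'   \sigma^2),}
#' sampled by Gibbs: latent `x_i`, then `(alpha, beta)`, are conjugate
#' normal updates and `sigma^2` is conjugate inverse-gamma. This is the
#' single-stage counterpart of a two-stage multiple-imputation analysis
#' ([run_two_stage()]); at desk scale the two approaches should agree.
#'
#' @param x_mean,x_sd Per-observation posterior mean and sd of the
#'   predictor.
#' @param y Response vector.
#' @param coef_prior_sd Prior sd of the Normal(0, sd^2) priors on intercept
#'   and slope.
#' @param sigma_prior Shape/rate of the inverse-gamma prior on
#'   `sigma^2` as `c(shape, rate)`; default weakly informative
#'   `c(0.01, 0.01)`.
#' @param iterations,burn_in,thinning,seed MCMC controls.
#' @return A `posterior_draws` object with parameters `intercept`, `slope`,
#'   `sigma`.
#' @export
single_stage_regression <- function(x_mean, x_sd, y,
                                    coef_prior_sd = 100,
                                    sigma_prior = c(0.01, 0.01),
                                    iterations = 10000,
                                    burn_in = floor(iterations / 2),
                                    thinning = 1, seed = 1) {
  n <- length(y)
  stopifnot(length(x_mean) == n, length(x_sd) == n, all(x_sd >= 0),
            iterations > burn_in, burn_in >= 0)
  set.seed(as.integer(seed))
  x <- x_mean
  ab <- c(mean(y), 0)
  s2 <- stats::var(y) + 1e-6
  prior_prec <- 1 / coef_prior_sd^2
  n_keep <- floor((iterations - burn_in) / thinning)
  out <- matrix(NA_real_, n_keep, 3,
                dimnames = list(NULL, c("intercept", "slope", "sigma")))
  keep_i <- 0L
  meas_prec <- ifelse(x_sd > 0, 1 / x_sd^2, Inf)
  for (it in seq_len(iterations)) {
    # latent predictors
    prec <- meas_prec + ab[2]^2 / s2
    mu <- (x_mean * meas_prec + ab[2] * (y - ab[1]) / s2) / prec
    fixed <- !is.finite(meas_prec)
    x <- stats::rnorm(n, mu, 1 / sqrt(prec))
    x[fixed] <- x_mean[fixed]
    # coefficients
    X2 <- sum(x^2)
    P <- matrix(c(n / s2 + prior_prec, sum(x) / s2,
                  sum(x) / s2, X2 / s2 + prior_prec), 2, 2)
    b <- c(sum(y) / s2, sum(x * y) / s2)
    U <- chol(P)
    mu_ab <- backsolve(U, forwardsolve(t(U), b))
    ab <- as.numeric(mu_ab + backsolve(U, stats::rnorm(2)))
    # residual variance
    r <- y - ab[1] - ab[2] * x
    s2 <- 1 / stats::rgamma(1, sigma_prior[1] + n / 2,
                            sigma_prior[2] + sum(r^2) / 2)
    if (it > burn_in && (it - burn_in) %% thinning == 0L) {
      keep_i <- keep_i + 1L
      out[keep_i, ] <- c(ab, sqrt(s2))
    }
  }
  structure(list(
    draws = out,
    param_map = data.frame(parameter = colnames(out), type = "regression",
                           subject = NA, timepoint = NA, label = NA,
                           stringsAsFactors = FALSE),
    seed = seed, iterations = iterations, burn_in = burn_in,
    thinning = thinning, model = "single_stage_regression"
  ), class = "posterior_draws")
}
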