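#' Highest posterior density interval
#'
#' The shortest contiguous interval containing a given mass of the sample.
#' Computed on the sorted draws by sliding a window of `ceiling(mass * n)`
#' draws and taking the narrowest; ties are broken by the leftmost window.
#'
#' @param x Numeric draws (length >= 2).
#' @param mass Interval mass in (0, 1); default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
hpdi <- function(x, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("`mass` must be a single number in (0, 1)", call. = FALSE)
  }
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) stop("need at least 2 finite draws", call. = FALSE)
  m <- max(2L, ceiling(mass * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  width <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(width)  # which.min returns the first (leftmost) minimum
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Summarize posterior draws
#'
#' Per-parameter posterior mean, standard deviation and highest posterior
#' density interval.
#'
#' @param draws A `posterior_draws` object (see [run_sampler()]) or a
#'   numeric matrix with one column per parameter.
#' @param mass HPDI mass; default 0.95.
#' @param params Optional character vector restricting the summary to a
#'   subset of parameters.
#' @return A data frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper` (plus any parameter metadata available in `draws$param_map`).
#' @export
summarize_draws <- function(draws, mass = 0.95, params = NULL) {
  mat <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  if (nrow(mat) < 2L) stop("need at least 2 retained draws", call. = FALSE)
  if (!is.null(params)) {
    missing <- setdiff(params, colnames(mat))
    if (length(missing)) {
      stop(sprintf("unknown parameter(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    mat <- mat[, params, drop = FALSE]
  }
  ints <- apply(mat, 2, hpdi, mass = mass)
  out <- data.frame(
    parameter = colnames(mat),
    mean = colMeans(mat),
    sd = apply(mat, 2, stats::sd),
    lower = ints[1, ],
    upper = ints[2, ],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (inherits(draws, "posterior_draws") && !is.null(draws$param_map)) {
    meta <- draws$param_map[match(out$parameter, draws$param_map$parameter),
                            setdiff(names(draws$param_map), "parameter"),
                            drop = FALSE]
    out <- cbind(out, meta)
    rownames(out) <- NULL
  }
  out
}

# Effective sample size via the initial positive sequence of autocovariances
.ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE,
                   demean = TRUE)$acf[-1]
  # sum pairs rho_{2k} + rho_{2k+1} while positive (Geyer initial positive)
  s <- 0
  k <- 1L
  while (k + 1L <= length(ac)) {
    pair <- ac[k] + ac[k + 1L]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

# split-chain potential scale reduction factor on a single chain
.split_rhat <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(1)
  h <- floor(n / 2)
  chains <- cbind(x[1:h], x[(n - h + 1):n])
  m <- ncol(chains); nn <- nrow(chains)
  means <- colMeans(chains)
  b <- nn * stats::var(means)
  w <- mean(apply(chains, 2, stats::var))
  if (w == 0) return(1)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Convergence diagnostics for posterior draws
#'
#' Effective sample size (initial-positive-sequence autocovariance
#' estimator) and split-chain potential scale reduction factor per
#' parameter, computed on the retained draws.
#'
#' @param draws A `posterior_draws` object or draw matrix.
#' @return Data frame with columns `parameter`, `ess`, `rhat`.
#' @export
diagnose_draws <- function(draws) {
  mat <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  data.frame(
    parameter = colnames(mat),
    ess = apply(mat, 2, .ess),
    rhat = apply(mat, 2, .split_rhat),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Persist posterior draws as text
#'
#' Writes the draw-by-parameter matrix as a delimited table plus a JSON
#' metadata sidecar (`<path>.meta.json`) holding the seed, chain settings
#' and parameter map, so a run can be reloaded losslessly with
#' [read_draws()].
#'
#' @param draws A `posterior_draws` object.
#' @param path Output path for the draw table.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  utils::write.csv(as.data.frame(draws$draws, check.names = FALSE), path,
                   row.names = FALSE)
  meta <- list(
    seed = draws$seed, iterations = draws$iterations,
    burn_in = draws$burn_in, thinning = draws$thinning,
    model = draws$model, param_map = draws$param_map
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  mat <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  pm <- meta$param_map
  if (!is.null(pm)) pm <- as.data.frame(pm, stringsAsFactors = FALSE)
  structure(
    list(draws = mat, param_map = pm, seed = meta$seed,
         iterations = meta$iterations, burn_in = meta$burn_in,
         thinning = meta$thinning, model = meta$model),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d draws x %d parameters (%s model, seed %s)\n",
              nrow(x$draws), ncol(x$draws),
              if (is.null(x$model)) "?" else x$model,
              if (is.null(x$seed)) "?" else x$seed))
  invisible(x)
}
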