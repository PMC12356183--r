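#' Draw multiply-imputed datasets from posterior draws
#'
#' Forms `n_imputations` completed datasets by sampling retained posterior
#' draw indices and reading off the requested quantities. All quantities in
#' one imputation come from the same draw index, preserving the joint
#' posterior correlation between, say, a subject's length and widths.
#' Indices are sampled without replacement while `n_imputations` does not
#' exceed the number of retained draws, so at `n_imputations == n_draws`
#' the imputation set is the posterior itself, permuted.
#'
#' @param draws A `posterior_draws` object.
#' @param quantities Parameter names to impute (default: all latent
#'   lengths).
#' @param n_imputations Number of imputed datasets, `>= 2`.
#' @param seed Integer seed.
#' @return An `imputation_set`: list with `datasets` (matrix, one row per
#'   imputation, one column per quantity), `indices` (source draw index per
#'   imputation) and `seed`.
#' @export
draw_imputations <- function(draws, quantities = NULL, n_imputations = 100,
                             seed = 1) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (n_imputations < 2) stop("`n_imputations` must be >= 2", call. = FALSE)
  mat <- draws$draws
  if (is.null(quantities)) {
    pm <- draws$param_map
    quantities <- pm$parameter[pm$type == "length"]
    if (!length(quantities)) quantities <- colnames(mat)
  }
  unknown <- setdiff(quantities, colnames(mat))
  if (length(unknown)) {
    stop(sprintf("unknown quantity(ies): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- nrow(mat)
  idx <- if (n_imputations <= n) {
    sample.int(n, n_imputations, replace = FALSE)
  } else {
    sample.int(n, n_imputations, replace = TRUE)
  }
  structure(list(
    datasets = mat[idx, quantities, drop = FALSE],
    indices = idx,
    quantities = quantities,
    seed = seed
  ), class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> %d imputations x %d quantities (seed %s)\n",
              nrow(x$datasets), ncol(x$datasets), x$seed))
  invisible(x)
}

#' Perturb a frequentist fit by sampling around its MLE
#'
#' Draws parameter vectors from a multivariate normal centred at the
#' maximum-likelihood estimates with the fit's variance-covariance matrix —
#' the frequentist analogue of sampling a posterior in the second stage of
#' a two-stage analysis. The covariance must be symmetric positive
#' semi-definite; tiny negative eigenvalues (numerical noise) are clamped
#' to zero, larger ones are an error.
#'
#' @param estimates Named numeric vector of MLEs.
#' @param vcov Variance-covariance matrix of the estimates.
#' @param n_perturbations Number of draws.
#' @param seed Integer seed.
#' @return Matrix `n_perturbations` x `length(estimates)`.
#' @export
perturb_frequentist <- function(estimates, vcov, n_perturbations = 10,
                                seed = 1) {
  estimates <- unlist(estimates)
  vcov <- as.matrix(vcov)
  p <- length(estimates)
  if (!all(dim(vcov) == p)) {
    stop("`vcov` must be a square matrix matching `estimates`", call. = FALSE)
  }
  if (max(abs(vcov - t(vcov))) > 1e-8 * max(1, max(abs(vcov)))) {
    stop("`vcov` must be symmetric", call. = FALSE)
  }
  vcov <- (vcov + t(vcov)) / 2
  ev <- eigen(vcov, symmetric = TRUE)
  tol <- 1e-8 * max(1, abs(ev$values[1]))
  if (any(ev$values < -tol)) {
    stop("`vcov` is not positive semi-definite", call. = FALSE)
  }
  ev$values <- pmax(ev$values, 0)
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n_perturbations * p), n_perturbations, p)
  draws <- sweep(z %*% diag(sqrt(ev$values), p) %*% t(ev$vectors), 2,
                 estimates, "+")
  colnames(draws) <- names(estimates)
  draws
}

#' Pool perturbed estimates
#'
#' Concatenates the perturbed estimates across imputations and summarizes
#' each parameter with mean, sd and HPDI. The pooled collection
#' approximates a sample from the posterior of the equivalent single-stage
#' Bayesian analysis, so these summaries are read as multiply-imputed
#' point estimates and uncertainties. A Rubin's-rules summary
#' (within/between-imputation variance decomposition) is attached as
#' attribute `"rubin"` for comparison; the pooled concatenation is the
#' primary output.
#'
#' @param perturbed A `perturbed_estimates` object from [run_two_stage()],
#'   or a matrix of stacked parameter draws with an `imputation` attribute
#'   (optional).
#' @param mass HPDI mass.
#' @return Data frame `parameter`, `mean`, `sd`, `lower`, `upper`.
#' @export
pool_estimates <- function(perturbed, mass = 0.95) {
  mat <- if (inherits(perturbed, "perturbed_estimates")) {
    perturbed$estimates
  } else as.matrix(perturbed)
  if (nrow(mat) < 2L) stop("need at least 2 perturbed draws", call. = FALSE)
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
  imp <- if (inherits(perturbed, "perturbed_estimates")) {
    perturbed$imputation
  } else attr(perturbed, "imputation")
  if (!is.null(imp) && length(unique(imp)) > 1L) {
    per_imp_mean <- rowsum(mat, imp) / as.vector(table(imp))
    within <- sapply(seq_len(ncol(mat)), function(j) {
      mean(tapply(mat[, j], imp, stats::var))
    })
    between <- apply(per_imp_mean, 2, stats::var)
    m <- nrow(per_imp_mean)
    attr(out, "rubin") <- data.frame(
      parameter = colnames(mat),
      mean = colMeans(per_imp_mean),
      sd = sqrt(within + (1 + 1 / m) * between),
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Two-stage uncertainty propagation
#'
#' The full multiple-imputation pipeline: sample imputed datasets from the
#' measurement posteriors, run the primary analysis on each, perturb or
#' sample its estimates, and pool. The analysis callback receives one
#' imputation (a named numeric vector of the imputed quantities) and
#' returns either a frequentist fit — `list(estimates = <named vector>,
#' vcov = <matrix>)`, perturbed via [perturb_frequentist()] — or a matrix
#' (or named vector) of posterior draws from a Bayesian analysis, used
#' as-is. Failing imputations are skipped and counted; more than 20%
#' failures aborts.
#'
#' @param draws A `posterior_draws` object.
#' @param analysis Callback, `function(imputed_values) -> fit`.
#' @param quantities Parameters to impute (default: latent lengths).
#' @param n_imputations Number of imputed datasets.
#' @param perturbations Perturbation draws per frequentist fit.
#' @param seed Integer seed driving imputation and perturbation.
#' @param mass HPDI mass for the pooled summary.
#' @return A `perturbed_estimates` object: list with `estimates` (stacked
#'   draws), `imputation` (imputation id per row), `failures`, `pooled`
#'   (the [pool_estimates()] summary).
#' @export
run_two_stage <- function(draws, analysis, quantities = NULL,
                          n_imputations = 100, perturbations = 10,
                          seed = 1, mass = 0.95) {
  stopifnot(is.function(analysis))
  imps <- draw_imputations(draws, quantities = quantities,
                           n_imputations = n_imputations, seed = seed)
  pieces <- list()
  imp_id <- list()
  failures <- 0L
  for (i in seq_len(nrow(imps$datasets))) {
    fit <- tryCatch(analysis(imps$datasets[i, ]), error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- failures + 1L
      next
    }
    if (is.list(fit) && !is.null(fit$estimates) && !is.null(fit$vcov)) {
      pert <- perturb_frequentist(fit$estimates, fit$vcov,
                                  n_perturbations = perturbations,
                                  seed = seed + i)
    } else {
      pert <- fit
      if (is.null(dim(pert))) pert <- matrix(pert, 1,
                                             dimnames = list(NULL, names(fit)))
      pert <- as.matrix(pert)
    }
    pieces[[length(pieces) + 1L]] <- pert
    imp_id[[length(imp_id) + 1L]] <- rep(i, nrow(pert))
  }
  if (failures > 0.2 * n_imputations) {
    stop(sprintf("analysis callback failed on %d of %d imputations (> 20%%)",
                 failures, n_imputations), call. = FALSE)
  }
  if (!length(pieces)) stop("all imputations failed", call. = FALSE)
  est <- do.call(rbind, pieces)
  obj <- structure(list(
    estimates = est,
    imputation = unlist(imp_id),
    failures = failures,
    n_imputations = n_imputations,
    seed = seed
  ), class = "perturbed_estimates")
  obj$pooled <- pool_estimates(obj, mass = mass)
  obj
}

#' @export
print.perturbed_estimates <- function(x, ...) {
  cat(sprintf("<perturbed_estimates> %d draws over %d imputations (%d failed)\n",
              nrow(x$estimates), x$n_imputations, x$failures))
  print(x$pooled)
  invisible(x)
}
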