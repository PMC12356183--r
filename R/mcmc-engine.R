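# Internal MCMC engine.
#
# The joint model (measurement mode):
#   altimeter reading   y_ij ~ Normal(beta0_j + beta1_j * a_i, sigma_j^2)
#   pixel measurement   Lp_m ~ Normal(L_s * c_i / a_i, sigma_px_d^2)
# with c_i = f * I_w / S_w (expected pixels per metre at 1 m altitude is
# c_i / a_i, i.e. the reciprocal of the ground sampling distance).
# Calibration objects have L_s fixed at the known length; animal lengths
# are latent with a bounded-uniform prior. In growth mode the latent
# lengths instead get a Normal prior centred on a von Bertalanffy-Putter
# mean, and the growth hyperparameters are sampled too.
#
# Update scheme per sweep:
#   a_i        random-walk Metropolis, vectorised over images, adaptive
#   beta0/beta1 exact bivariate-normal Gibbs per altimeter (conjugate)
#   sigma_j, sigma_px  log-scale random-walk Metropolis, adaptive
#   L_s        exact truncated-normal Gibbs (conjugate given everything)
#   growth: Linf_i and mu_sex conjugate; k, t0, sds, latent ages Metropolis
# Proposal scales adapt in batches of 50 during burn-in toward 0.44
# acceptance (standard scalar-target adaptation), then freeze.

.rowsum_n <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

# vectorised truncated-normal draw via inverse CDF; degenerate windows
# (mass numerically zero inside the bounds) collapse to the clamped mean
.rtnorm <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  bad <- !is.finite(plo) | !is.finite(phi) | (phi - plo) < 1e-14
  u <- stats::runif(n, pmin(plo, phi), pmax(plo, phi))
  x <- stats::qnorm(u, mean, sd)
  x[bad] <- pmin(pmax(mean[bad], lo[bad]), hi[bad])
  pmin(pmax(x, lo), hi)
}

.halfnorm_lp <- function(x, sd) {
  ifelse(x > 0, -0.5 * (x / sd)^2, -Inf)
}

# conjugate draw for (b0, b1) in y = b0 + b1 x + Normal(0, s2) noise with
# independent Normal priors; either coefficient may be fixed
.draw_linear_coefs <- function(y, x, s2, b0, b1, fix0, fix1, pb0, pb1) {
  if (fix0 && fix1) return(c(b0, b1))
  if (!fix0 && !fix1) {
    P <- matrix(c(length(y) / s2 + 1 / pb0$sd^2, sum(x) / s2,
                  sum(x) / s2, sum(x^2) / s2 + 1 / pb1$sd^2), 2, 2)
    b <- c(sum(y) / s2 + pb0$mean / pb0$sd^2,
           sum(x * y) / s2 + pb1$mean / pb1$sd^2)
    U <- chol(P)
    mu <- backsolve(U, forwardsolve(t(U), b))
    return(as.numeric(mu + backsolve(U, stats::rnorm(2))))
  }
  if (fix0) {
    r <- y - b0
    prec <- sum(x^2) / s2 + 1 / pb1$sd^2
    m <- (sum(x * r) / s2 + pb1$mean / pb1$sd^2) / prec
    return(c(b0, stats::rnorm(1, m, 1 / sqrt(prec))))
  }
  r <- y - b1 * x
  prec <- length(y) / s2 + 1 / pb0$sd^2
  m <- (sum(r) / s2 + pb0$mean / pb0$sd^2) / prec
  c(stats::rnorm(1, m, 1 / sqrt(prec)), b1)
}

# von Bertalanffy-Putter expected-length multiplier g(age) so that
# E[L] = Linf * g(age); clamped at zero below t0
.vbp_g <- function(age, k, t0, exponent) {
  pmax(0, 1 - exp(-k * (age - t0)))^exponent
}

.run_chain <- function(prep, spec, growth, iterations, burn_in, thinning,
                       seed) {
  if (!is.numeric(iterations) || iterations < 1) {
    stop("`iterations` must be a positive integer", call. = FALSE)
  }
  if (!(iterations > burn_in && burn_in >= 0)) {
    stop("need iterations > burn_in >= 0", call. = FALSE)
  }
  if (thinning < 1) stop("`thinning` must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))

  n_img <- nrow(prep$images)
  n_alt <- length(prep$altimeters)
  n_drone <- length(prep$drones)
  n_grp <- nrow(prep$groups)
  rd <- prep$read
  px <- prep$px
  has_latent <- n_grp > 0L

  fix_a <- .is_fixed(spec$image_altitude)
  fix_b0 <- .is_fixed(spec$altimeter_bias)
  fix_b1 <- .is_fixed(spec$altimeter_scaling)
  fix_salt <- .is_fixed(spec$altimeter_sd)
  fix_spx <- .is_fixed(spec$pixel_sd)

  alo <- if (fix_a) -Inf else spec$image_altitude$min
  ahi <- if (fix_a) Inf else spec$image_altitude$max
  Llo <- spec$object_length$min
  Lhi <- spec$object_length$max
  a_log_prior <- identical(spec$image_altitude$family, "loguniform")
  L_log_prior <- identical(spec$object_length$family, "loguniform")

  # --- initial state ------------------------------------------------------
  a <- pmin(pmax(prep$a_obs, if (fix_a) -Inf else alo + 1e-6),
            if (fix_a) Inf else ahi - 1e-6)
  b0 <- rep(if (fix_b0) spec$altimeter_bias$value else spec$altimeter_bias$mean,
            n_alt)
  b1 <- rep(if (fix_b1) spec$altimeter_scaling$value
            else spec$altimeter_scaling$mean, n_alt)
  s_alt <- rep(if (fix_salt) spec$altimeter_sd$value else 1, n_alt)
  s_px <- rep(if (fix_spx) spec$pixel_sd$value else 5, n_drone)

  cpx <- prep$c_img[px$img]                      # px per metre x altitude
  conv0 <- px$Lp * a[px$img] / cpx               # naive converted lengths
  if (has_latent) {
    lat <- px$grp > 0L
    L <- .rowsum_n(conv0[lat], px$grp[lat], n_grp) /
      .rowsum_n(rep(1, sum(lat)), px$grp[lat], n_grp)
  } else {
    L <- numeric(0)
  }

  is_growth <- !is.null(growth)
  if (is_growth) {
    gp <- growth
    n_sub <- length(gp$subjects)
    n_sex <- length(gp$sex_levels)
    age <- (gp$grp_age_min + gp$grp_age_max) / 2
    k <- (gp$k_prior$min + gp$k_prior$max) / 2
    t0 <- min(0, gp$t0_max) - 0.01
    sL <- 1
    sInf <- 1
    Linf <- .rowsum_n(pmax(L, 0.1), gp$grp_subj, n_sub) /
      .rowsum_n(rep(1, n_grp), gp$grp_subj, n_sub)
    Linf <- pmax(Linf, 0.5) * 1.05
    mu_sex <- as.numeric(tapply(Linf, gp$sex_idx, mean))
    L <- pmax(L, 0.01)
    Llo <- 0
    Lhi <- Inf
  }

  # latent L clamped into support
  if (has_latent) L <- pmin(pmax(L, Llo + 1e-4), if (is.finite(Lhi)) Lhi - 1e-4 else L)

  Lval <- px$L_known
  if (has_latent) Lval[lat] <- L[px$grp[lat]]
  spx_row <- s_px[px$drone]

  init_lp <- sum(stats::dnorm(rd$y, b0[rd$alt] + b1[rd$alt] * a[rd$img],
                              s_alt[rd$alt], log = TRUE)) +
    sum(stats::dnorm(px$Lp, Lval * cpx / a[px$img], spx_row, log = TRUE))
  if (!is.finite(init_lp)) {
    stop(sprintf(paste0("non-finite log-density at initialization ",
                        "(altitude range %.2f-%.2f, lengths %.2f-%.2f); ",
                        "check priors and units"),
                 min(a), max(a),
                 if (has_latent) min(L) else NA,
                 if (has_latent) max(L) else NA), call. = FALSE)
  }

  # --- adaptation bookkeeping --------------------------------------------
  ls_a <- rep(log(0.5), n_img)       # proposal scales (log)
  acc_a <- numeric(n_img)
  ls_salt <- rep(log(0.3), n_alt); acc_salt <- numeric(n_alt)
  ls_spx <- rep(log(0.3), n_drone); acc_spx <- numeric(n_drone)
  comps <- if (fix_a) list() else prep$components
  n_comp <- length(comps)
  ls_comp <- rep(log(0.05), n_comp); acc_comp <- numeric(n_comp)
  if (is_growth) {
    ls_k <- log(0.05); acc_k <- 0
    ls_t0 <- log(0.3); acc_t0 <- 0
    ls_sL <- log(0.3); acc_sL <- 0
    ls_sInf <- log(0.3); acc_sInf <- 0
    ls_age <- rep(log(1), n_grp); acc_age <- numeric(n_grp)
    age_free <- gp$grp_age_max > gp$grp_age_min
  }
  batch_len <- 50L
  batch_no <- 0L

  n_keep <- floor((iterations - burn_in) / thinning)
  par_names <- prep$par_names
  if (is_growth) par_names <- c(par_names, growth$par_names)
  out <- matrix(NA_real_, n_keep, length(par_names),
                dimnames = list(NULL, par_names))
  keep_i <- 0L

  total_acc_a <- 0; total_a_updates <- 0

  for (it in seq_len(iterations)) {
    # -- 1. image altitudes ------------------------------------------------
    if (!fix_a) {
      prop <- a + stats::rnorm(n_img) * exp(ls_a)
      ok <- prop >= alo & prop <= ahi
      prop_s <- ifelse(ok, prop, a)
      dr <- stats::dnorm(rd$y, b0[rd$alt] + b1[rd$alt] * prop_s[rd$img],
                         s_alt[rd$alt], log = TRUE) -
        stats::dnorm(rd$y, b0[rd$alt] + b1[rd$alt] * a[rd$img],
                     s_alt[rd$alt], log = TRUE)
      dlp <- .rowsum_n(dr, rd$img, n_img)
      dp <- stats::dnorm(px$Lp, Lval * cpx / prop_s[px$img], spx_row,
                         log = TRUE) -
        stats::dnorm(px$Lp, Lval * cpx / a[px$img], spx_row, log = TRUE)
      dlp <- dlp + .rowsum_n(dp, px$img, n_img)
      if (a_log_prior) dlp <- dlp + log(a) - log(prop_s)
      accept <- ok & (log(stats::runif(n_img)) < dlp)
      a[accept] <- prop[accept]
      acc_a <- acc_a + accept
      total_acc_a <- total_acc_a + sum(accept)
      total_a_updates <- total_a_updates + n_img
    }

    # -- 2./3. altimeter parameters ---------------------------------------
    for (j in seq_len(n_alt)) {
      rows <- prep$read_by_alt[[j]]
      yy <- rd$y[rows]
      xx <- a[rd$img[rows]]
      cf <- .draw_linear_coefs(yy, xx, s_alt[j]^2, b0[j], b1[j],
                               fix_b0, fix_b1,
                               spec$altimeter_bias, spec$altimeter_scaling)
      b0[j] <- cf[1]; b1[j] <- cf[2]
      if (!fix_salt) {
        mu <- b0[j] + b1[j] * xx
        ls_new <- log(s_alt[j]) + stats::rnorm(1) * exp(ls_salt[j])
        s_new <- exp(ls_new)
        d <- sum(stats::dnorm(yy, mu, s_new, log = TRUE)) -
          sum(stats::dnorm(yy, mu, s_alt[j], log = TRUE)) +
          .halfnorm_lp(s_new, spec$altimeter_sd$sd) -
          .halfnorm_lp(s_alt[j], spec$altimeter_sd$sd) +
          ls_new - log(s_alt[j])
        if (is.finite(d) && log(stats::runif(1)) < d) {
          s_alt[j] <- s_new
          acc_salt[j] <- acc_salt[j] + 1
        }
      }
    }

    # -- 4. pixel noise per drone -----------------------------------------
    if (!fix_spx) {
      mu_px <- Lval * cpx / a[px$img]
      for (d in seq_len(n_drone)) {
        rows <- prep$px_by_drone[[d]]
        if (!length(rows)) next
        ls_new <- log(s_px[d]) + stats::rnorm(1) * exp(ls_spx[d])
        s_new <- exp(ls_new)
        dd <- sum(stats::dnorm(px$Lp[rows], mu_px[rows], s_new, log = TRUE)) -
          sum(stats::dnorm(px$Lp[rows], mu_px[rows], s_px[d], log = TRUE)) +
          .halfnorm_lp(s_new, spec$pixel_sd$sd) -
          .halfnorm_lp(s_px[d], spec$pixel_sd$sd) +
          ls_new - log(s_px[d])
        if (is.finite(dd) && log(stats::runif(1)) < dd) {
          s_px[d] <- s_new
          acc_spx[d] <- acc_spx[d] + 1
        }
      }
      spx_row <- s_px[px$drone]
    }

    # -- growth hyperparameters -------------------------------------------
    if (is_growth) {
      g <- .vbp_g(age, k, t0, gp$exponent)
      mu_g <- Linf[gp$grp_subj] * g

      # latent lengths: pixel likelihood x growth prior, conjugate
      x <- cpx[lat] / a[px$img[lat]]
      w <- 1 / spx_row[lat]^2
      prec <- .rowsum_n(x * x * w, px$grp[lat], n_grp) + 1 / sL^2
      mp <- .rowsum_n(x * px$Lp[lat] * w, px$grp[lat], n_grp) + mu_g / sL^2
      L <- .rtnorm(n_grp, mp / prec, 1 / sqrt(prec), 0, Inf)
      Lval[lat] <- L[px$grp[lat]]

      # individual asymptotic lengths, conjugate
      precI <- .rowsum_n(g^2, gp$grp_subj, n_sub) / sL^2 + 1 / sInf^2
      mpI <- .rowsum_n(g * L, gp$grp_subj, n_sub) / sL^2 +
        mu_sex[gp$sex_idx] / sInf^2
      Linf <- .rtnorm(n_sub, mpI / precI, 1 / sqrt(precI), 0, Inf)

      # sex-level means, conjugate
      pm <- gp$mu_prior
      for (sx in seq_len(n_sex)) {
        idx <- gp$sub_by_sex[[sx]]
        prec_s <- length(idx) / sInf^2 + 1 / pm$sd^2
        m_s <- (sum(Linf[idx]) / sInf^2 + pm$mean / pm$sd^2) / prec_s
        mu_sex[sx] <- stats::rnorm(1, m_s, 1 / sqrt(prec_s))
      }

      # growth rate k (bounded uniform prior)
      kp <- k + stats::rnorm(1) * exp(ls_k)
      if (kp >= gp$k_prior$min && kp <= gp$k_prior$max) {
        g_new <- .vbp_g(age, kp, t0, gp$exponent)
        d <- sum(stats::dnorm(L, Linf[gp$grp_subj] * g_new, sL, log = TRUE)) -
          sum(stats::dnorm(L, Linf[gp$grp_subj] * g, sL, log = TRUE))
        if (is.finite(d) && log(stats::runif(1)) < d) {
          k <- kp; g <- g_new; acc_k <- acc_k + 1
        }
      }

      # age at length zero t0 (normal prior truncated above)
      t0p <- t0 + stats::rnorm(1) * exp(ls_t0)
      if (t0p <= gp$t0_max) {
        g_new <- .vbp_g(age, k, t0p, gp$exponent)
        d <- sum(stats::dnorm(L, Linf[gp$grp_subj] * g_new, sL, log = TRUE)) -
          sum(stats::dnorm(L, Linf[gp$grp_subj] * g, sL, log = TRUE)) +
          stats::dnorm(t0p, gp$t0_prior$mean, gp$t0_prior$sd, log = TRUE) -
          stats::dnorm(t0, gp$t0_prior$mean, gp$t0_prior$sd, log = TRUE)
        if (is.finite(d) && log(stats::runif(1)) < d) {
          t0 <- t0p; g <- g_new; acc_t0 <- acc_t0 + 1
        }
      }

      # process noise around the growth mean
      mu_g <- Linf[gp$grp_subj] * g
      lsn <- log(sL) + stats::rnorm(1) * exp(ls_sL)
      sn <- exp(lsn)
      d <- sum(stats::dnorm(L, mu_g, sn, log = TRUE)) -
        sum(stats::dnorm(L, mu_g, sL, log = TRUE)) +
        .halfnorm_lp(sn, gp$sL_prior$sd) - .halfnorm_lp(sL, gp$sL_prior$sd) +
        lsn - log(sL)
      if (is.finite(d) && log(stats::runif(1)) < d) {
        sL <- sn; acc_sL <- acc_sL + 1
      }

      # between-individual spread of asymptotic length
      lsn <- log(sInf) + stats::rnorm(1) * exp(ls_sInf)
      sn <- exp(lsn)
      d <- sum(stats::dnorm(Linf, mu_sex[gp$sex_idx], sn, log = TRUE)) -
        sum(stats::dnorm(Linf, mu_sex[gp$sex_idx], sInf, log = TRUE)) +
        .halfnorm_lp(sn, gp$sInf_prior$sd) -
        .halfnorm_lp(sInf, gp$sInf_prior$sd) +
        lsn - log(sInf)
      if (is.finite(d) && log(stats::runif(1)) < d) {
        sInf <- sn; acc_sInf <- acc_sInf + 1
      }

      # latent ages for interval-aged observations (uniform prior)
      if (any(age_free)) {
        ap <- age + stats::rnorm(n_grp) * exp(ls_age)
        okA <- age_free & ap >= gp$grp_age_min & ap <= gp$grp_age_max
        ap_s <- ifelse(okA, ap, age)
        g_new <- .vbp_g(ap_s, k, t0, gp$exponent)
        dA <- stats::dnorm(L, Linf[gp$grp_subj] * g_new, sL, log = TRUE) -
          stats::dnorm(L, Linf[gp$grp_subj] * g, sL, log = TRUE)
        accA <- okA & (log(stats::runif(n_grp)) < dA)
        age[accA] <- ap[accA]
        acc_age <- acc_age + accA
      }
    } else if (has_latent) {
      # -- 5. latent lengths: conjugate truncated normal (exact Gibbs under
      # a flat length prior; under the log-uniform prior the conjugate draw
      # serves as an independence proposal corrected by the 1/L tilt)
      x <- cpx[lat] / a[px$img[lat]]
      w <- 1 / spx_row[lat]^2
      prec <- .rowsum_n(x * x * w, px$grp[lat], n_grp)
      mp <- .rowsum_n(x * px$Lp[lat] * w, px$grp[lat], n_grp)
      L_new <- .rtnorm(n_grp, mp / prec, 1 / sqrt(prec), Llo, Lhi)
      if (L_log_prior) {
        accL <- log(stats::runif(n_grp)) < (log(L) - log(L_new))
        L[accL] <- L_new[accL]
      } else {
        L <- L_new
      }
      Lval[lat] <- L[px$grp[lat]]
    }

    # -- joint length-altitude scaling moves -------------------------------
    # The pixel likelihood constrains only L / a, leaving a ridge in the
    # (lengths, altitudes) block; scaling a connected component of latent
    # lengths and their images' altitudes by a common factor moves along
    # that ridge, with acceptance governed by the altimeter readings (and
    # any calibration measurements or growth priors touching the block).
    if (n_comp) {
      for (ci in rep(seq_len(n_comp), 3L)) {
        cm <- comps[[ci]]
        eps <- stats::rnorm(1) * exp(ls_comp[ci])
        lam <- exp(eps)
        a_new <- a[cm$img] * lam
        L_new <- L[cm$grp] * lam
        if (any(a_new < alo | a_new > ahi)) next
        if (!is_growth && any(L_new < Llo | L_new > Lhi)) next
        a_prop <- a
        a_prop[cm$img] <- a_new
        rr <- cm$read_rows
        dlt <- sum(stats::dnorm(
          rd$y[rr],
          b0[rd$alt[rr]] + b1[rd$alt[rr]] * a_prop[rd$img[rr]],
          s_alt[rd$alt[rr]], log = TRUE)) -
          sum(stats::dnorm(
            rd$y[rr],
            b0[rd$alt[rr]] + b1[rd$alt[rr]] * a[rd$img[rr]],
            s_alt[rd$alt[rr]], log = TRUE)) +
          cm$n_free * eps
        cr <- cm$cal_rows
        if (length(cr)) {
          dlt <- dlt +
            sum(stats::dnorm(px$Lp[cr],
                             px$L_known[cr] * cpx[cr] / a_prop[px$img[cr]],
                             spx_row[cr], log = TRUE)) -
            sum(stats::dnorm(px$Lp[cr],
                             px$L_known[cr] * cpx[cr] / a[px$img[cr]],
                             spx_row[cr], log = TRUE))
        }
        # log-uniform priors contribute -log(lambda) per scaled coordinate,
        # cancelling the corresponding part of the Jacobian term
        if (a_log_prior) dlt <- dlt - length(cm$img) * eps
        if (!is_growth && L_log_prior) dlt <- dlt - length(cm$grp) * eps
        if (is_growth) {
          mu_c <- Linf[gp$grp_subj[cm$grp]] *
            .vbp_g(age[cm$grp], k, t0, gp$exponent)
          dlt <- dlt +
            sum(stats::dnorm(L_new, mu_c, sL, log = TRUE)) -
            sum(stats::dnorm(L[cm$grp], mu_c, sL, log = TRUE))
        }
        if (is.finite(dlt) && log(stats::runif(1)) < dlt) {
          a[cm$img] <- a_new
          L[cm$grp] <- L_new
          acc_comp[ci] <- acc_comp[ci] + 1
        }
      }
      Lval[lat] <- L[px$grp[lat]]
    }

    # -- adaptation --------------------------------------------------------
    if (it <= burn_in && it %% batch_len == 0L) {
      batch_no <- batch_no + 1L
      delta <- min(0.05, 1 / sqrt(batch_no))
      step <- function(ls, acc) ls + ifelse(acc / batch_len > 0.44,
                                            delta, -delta)
      ls_a <- step(ls_a, acc_a); acc_a[] <- 0
      ls_salt <- step(ls_salt, acc_salt); acc_salt[] <- 0
      ls_spx <- step(ls_spx, acc_spx); acc_spx[] <- 0
      if (n_comp) {
        # three proposals per sweep
        ls_comp <- step(ls_comp, acc_comp / 3)
        acc_comp[] <- 0
      }
      if (is_growth) {
        ls_k <- step(ls_k, acc_k); acc_k <- 0
        ls_t0 <- step(ls_t0, acc_t0); acc_t0 <- 0
        ls_sL <- step(ls_sL, acc_sL); acc_sL <- 0
        ls_sInf <- step(ls_sInf, acc_sInf); acc_sInf <- 0
        ls_age <- step(ls_age, acc_age); acc_age[] <- 0
      }
    }

    # -- record ------------------------------------------------------------
    if (it > burn_in && (it - burn_in) %% thinning == 0L) {
      keep_i <- keep_i + 1L
      if (keep_i <= n_keep) {
        row <- c(a, b0, b1, s_alt, s_px, L)
        if (is_growth) row <- c(row, Linf, mu_sex, k, t0, sL, sInf, age)
        out[keep_i, ] <- row
      }
    }
  }

  list(draws = out,
       acceptance = list(
         altitude = if (total_a_updates > 0) total_acc_a / total_a_updates
                    else NA_real_))
}
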