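#' Survival probability on the logit scale
#'
#' Inverse-logit of the survival linear predictor: sex-specific intercept
#' plus landscape and drought effects, the size-spline value, and the
#' site-year random effect.
#'
#' @param mu_phi logit-scale intercept.
#' @param theta_rice,R_w landscape effect and distance-weighted covariate.
#' @param theta_drought,spei drought effect and drought index.
#' @param f_size size-spline value at the individual's size.
#' @param eta site-year random-effect value.
#' @return survival probability in (0, 1).
#' @export
survival_prob <- function(mu_phi, theta_rice = 0, R_w = 0,
                          theta_drought = 0, spei = 0, f_size = 0, eta = 0) {
  stats::plogis(mu_phi + theta_rice * R_w + theta_drought * spei +
                f_size + eta)
}

#' Cumulative annual recapture probability
#'
#' Probability of at least one detection over `n_days` secondary occasions
#' with constant daily probability `p`: `p* = 1 - (1 - p)^n_days`.
#'
#' @param p_daily daily detection probability in `[0, 1]`.
#' @param n_days number of sampled days (>= 0).
#' @return cumulative probability, vectorized over both arguments.
#' @seealso [annual_recapture_draws()] for the posterior version.
#' @export
annual_recapture <- function(p_daily, n_days) {
  if (any(p_daily < 0 | p_daily > 1)) stop("'p_daily' must be in [0, 1]")
  if (any(n_days < 0)) stop("'n_days' must be nonnegative")
  1 - (1 - p_daily)^n_days
}

#' Posterior cumulative annual recapture probability
#'
#' Computes `p*` per posterior draw from a fitted robust-design model and
#' summarizes the draws.  Two variants are exposed because the averaging
#' set matters: the plain variant uses the sex-specific daily intercept
#' only; the random-effects variant draws day-level deviations (site, year
#' and day-within-year components) for each of the `n_days` occasions
#' before accumulating, which lowers the mean through the nonlinearity.
#'
#' @param fit a `cmr_fit` from [fit_cmr()].
#' @param n_days number of sampled days.
#' @param sex `"F"` or `"M"`.
#' @param include_random_effects draw day-level random effects per occasion?
#' @param seed seed for the random-effect simulation.
#' @return list with `draws` and a `summary` row (mean, 2.5%, 97.5%).
#' @export
annual_recapture_draws <- function(fit, n_days = 21, sex = c("F", "M"),
                                   include_random_effects = FALSE, seed = 1) {
  sex <- match.arg(sex)
  col <- if (sex == "F") "psex[1]" else "psex[2]"
  p0 <- fit$draws[, col]
  if (!include_random_effects) {
    ps <- annual_recapture(p0, n_days)
  } else {
    set.seed(seed)
    sd_tot <- sqrt(fit$draws[, "sd_ps"]^2 + fit$draws[, "sd_pt"]^2 +
                   fit$draws[, "sd_day"]^2)
    mu <- stats::qlogis(p0)
    ps <- vapply(seq_along(p0), function(d) {
      xi <- stats::rnorm(n_days, 0, sd_tot[d])
      1 - prod(1 - stats::plogis(mu[d] + xi))
    }, numeric(1))
  }
  list(draws = ps,
       summary = data.frame(mean = mean(ps),
                            q2.5 = stats::quantile(ps, 0.025),
                            q97.5 = stats::quantile(ps, 0.975),
                            row.names = NULL))
}

#' Prior settings for the integrated growth-survival model
#'
#' Survival, daily detection, and availability intercepts carry flat
#' Beta(1, 1) priors on the probability scale (sex-specific).  Covariate
#' effects are N(0, 10); the landscape kernel scale is Unif(0.01, 10) km;
#' all random-effect SDs are Exp(1); spline coefficients share a normal
#' shrinkage prior whose SD is itself Exp(1).  Growth-submodel priors are
#' taken from [growth_priors()].
#'
#' @param theta_sd SD of normal priors on survival covariate effects.
#' @param sigma_rice_range uniform prior range (km) for the survival kernel
#'   scale.
#' @param sd_rate exponential rate for random-effect SD priors.
#' @param spline_sd_rate exponential rate for the spline shrinkage SD.
#' @param growth priors for the growth submodel.
#' @return list of prior settings.
#' @export
cmr_priors <- function(theta_sd = 10, sigma_rice_range = c(0.01, 10),
                       sd_rate = 1, spline_sd_rate = 1,
                       growth = growth_priors()) {
  list(theta_sd = theta_sd, sigma_rice_range = sigma_rice_range,
       sd_rate = sd_rate, spline_sd_rate = spline_sd_rate, growth = growth)
}

cmr_model_string <- function(gof, has_onlyfirst = TRUE) {
  ## yearly no-detection products are only needed for the goodness-of-fit
  ## monitors; leaving them out of a plain fit trims the sampled graph
  gof_block <- if (gof) "
  for (s in 1:nsite) { for (t in 1:nyear) { for (x in 1:2) {
    for (j in 1:maxday) { onemp[x,s,t,j] <- 1 - p[x,s,t,j]*dmask[s,t,j] }
    pnodet[x,s,t] <- prod(onemp[x,s,t,])
  } } }
  for (q in 1:nq) { pd[q] <- 1 - pnodet[sex[qi[q]], site[qi[q]], qt[q]] }"
  else ""
  paste0("
model {
  ## distance-weighted covariates: precomputed on a fine kernel-scale grid
  ## and interpolated, so scale updates touch one node per site-year
  for (s in 1:nsite) { for (t in 1:nyear) {
    Rwk[s,t] <- interp.lin(sig_rice_k, sgrid, RwG[s,t,])
    Rwp[s,t] <- interp.lin(sig_rice_phi, sgrid, RwG[s,t,])
  } }
  ## size-survival spline on a reference grid
  for (g in 1:G) { fg[g] <- inprod(Bg[g,], bspl[]) }
  for (kk in 1:K) { bspl[kk] ~ dnorm(0, pow(sdb, -2)) }
  sdb ~ dexp(spline_sd_rate)
  ## detection: site / year-in-site / day-in-year random-effect chain
  for (s in 1:nsite) {
    ups[s] ~ dnorm(0, tau_ps)
    rho[s] ~ dnorm(0, tau_phis)
    for (t in 1:nyear) {
      delta[s,t] ~ dnorm(ups[s], tau_pt)
      eta[s,t] ~ dnorm(rho[s], tau_phit)
      for (j in 1:maxday) {
        xi[s,t,j] ~ dnorm(delta[s,t], tau_day)
        for (x in 1:2) {
          p[x,s,t,j] <- ilogit(mu_p[x] + xi[s,t,j])
          l1p[x,s,t,j] <- log(1 - p[x,s,t,j])
          lgt[x,s,t,j] <- mu_p[x] + xi[s,t,j]
        }
      }
      ## all-days no-detection log-likelihood, shared across individuals
      for (x in 1:2) { S0[x,s,t] <- inprod(dmask[s,t,], l1p[x,s,t,]) }
    }
  }
  for (t in 1:nyear) {
    sgt[t] ~ dnorm(0, tau_gt)
    zek[t] ~ dnorm(0, tau_tk)
  }
  ## sex-specific intercepts (flat on the probability scale) and effects
  for (x in 1:2) {
    psex[x] ~ dbeta(1, 1);    mu_p[x] <- logit(psex[x])
    phisex[x] ~ dbeta(1, 1);  mu_phi[x] <- logit(phisex[x])
    gamsex[x] ~ dbeta(1, 1);  mu_gam[x] <- logit(gamsex[x])
    mu_k[x] ~ dnorm(0, pow(mu_k_sd, -2))
    eps_a[x] ~ dnorm(eps_a_mean[x], pow(eps_a_sd, -2))
    for (s in 1:nsite) {
      lam[x,s] ~ dnorm(0, tau_sa)
      alk[x,s] ~ dnorm(0, tau_sk)
    }
  }
  th_rice ~ dnorm(0, pow(theta_sd, -2))
  th_dr ~ dnorm(0, pow(theta_sd, -2))
  b_rice ~ dnorm(0, pow(beta_sd, -2))
  b_dr ~ dnorm(0, pow(beta_sd, -2))
  sig_rice_phi ~ dunif(sigp_lo, sigp_hi)
  sig_rice_k ~ dunif(sigk_lo, sigk_hi)
  tau_ps <- pow(sd_ps,-2);     sd_ps ~ dexp(sd_rate)
  tau_pt <- pow(sd_pt,-2);     sd_pt ~ dexp(sd_rate)
  tau_day <- pow(sd_day,-2);   sd_day ~ dexp(sd_rate)
  tau_phis <- pow(sd_phis,-2); sd_phis ~ dexp(sd_rate)
  tau_phit <- pow(sd_phit,-2); sd_phit ~ dexp(sd_rate)
  tau_gt <- pow(sd_gt,-2);     sd_gt ~ dexp(sd_rate)
  tau_sa <- pow(sd_sa,-2);     sd_sa ~ dexp(sd_a_rate)
  tau_sk <- pow(sd_sk,-2);     sd_sk ~ dexp(growth_sd_rate)
  tau_tk <- pow(sd_tk,-2);     sd_tk ~ dexp(growth_sd_rate)
  tau_ik <- pow(sd_ik,-2);     sd_ik ~ dexp(growth_sd_rate)
  tau_err <- pow(sd_err,-2);   sd_err ~ dexp(sd_err_rate)
  ## individuals: first-capture year conditioning
  for (i in 1:nind) {
    iok[i] ~ dnorm(0, tau_ik)
    a[i] <- eps_a[sex[i]] + lam[sex[i], site[i]]
    cl1[i] <- inprod(YD[i, first[i], ], lgt[sex[i], site[i], first[i], ]) +
              inprod(M1[i, ], l1p[sex[i], site[i], first[i], ])
  }
  ## years after first capture, flattened to index q (ordered by individual
  ## then year): latent alive/available states are marginalized by a
  ## forward pass over (alive & present, alive & absent, dead)
  for (q in 1:nq) {
    gam[q] <- ilogit(mu_gam[sex[qi[q]]] + sgt[qt[q]])
    fphi[q] <- interp.lin(L[qi[q], qt[q]-1], xg, fg)
    phi[q] <- ilogit(mu_phi[sex[qi[q]]] + th_rice*Rwp[site[qi[q]], qt[q]-1] +
                     th_dr*spei[site[qi[q]], qt[q]-1] + fphi[q] +
                     eta[site[qi[q]], qt[q]-1])
    cl[q] <- S0[sex[qi[q]], site[qi[q]], qt[q]] +
             inprod(YD[qi[q], qt[q], ], lgt[sex[qi[q]], site[qi[q]], qt[q], ])
    aprev[q] <- fwA[qprev[q]] + fwB[qprev[q]] + isf[q] * exp(cl1[qi[q]])
    dprev[q] <- fwD[qprev[q]]
    fwA[q+1] <- aprev[q] * phi[q] * gam[q] * exp(cl[q])
    fwB[q+1] <- aprev[q] * phi[q] * (1-gam[q]) * nodet0q[q]
    fwD[q+1] <- (dprev[q] + aprev[q] * (1-phi[q])) * nodet0q[q]
    ## latent size chain (von Bertalanffy step from year t-1 to t)
    logk[q] <- mu_k[sex[qi[q]]] + b_rice*Rwk[site[qi[q]], qt[q]-1] +
               b_dr*spei[site[qi[q]], qt[q]-1] +
               alk[sex[qi[q]], site[qi[q]]] + zek[qt[q]-1] + iok[qi[q]]
    EL[q] <- a[qi[q]] - (a[qi[q]] - L[qi[q], qt[q]-1]) *
             exp(-exp(logk[q]) / a[qi[q]])
    L[qi[q], qt[q]] ~ dnorm(EL[q], tau_err)
  }
  ## dummy forward slot: rows with isf = 1 point here and receive zero mass
  fwA[1] <- 0;  fwB[1] <- 0;  fwD[1] <- 0
  ## one Bernoulli likelihood term per individual
  for (u in 1:na) {
    ones_a[u] ~ dbern(fwA[lastq[u]] + fwB[lastq[u]] + fwD[lastq[u]])
  }
", if (has_onlyfirst) "
  for (v in 1:nb) {
    ones_b[v] ~ dbern(exp(cl1[onlyfirst[v]]))
  }" else "", "
", gof_block, "
}
")
}

#' Fit the integrated robust-design growth-survival model
#'
#' Combines the robust-design capture-mark-recapture model (annual primary
#' periods, daily secondary occasions, random temporary emigration, latent
#' alive states conditioned on first capture) with the von Bertalanffy
#' growth chain, so individual sizes are imputed in years without capture
#' and size feeds survival through a penalized B-spline.  Both landscape
#' kernels (growth and survival) have their spatial scales estimated
#' jointly, recomputing the distance-weighted covariate at every draw.
#' Detection uses sex-specific intercepts with nested site / year-in-site /
#' day-in-year random effects; availability has sex intercepts and a year
#' random effect.
#'
#' @param histories a `cmr_data` object from [build_capture_histories()].
#' @param rings a [ring_covariates()] object covering every site-year.
#' @param spei SPEI table (see [read_spei()]).
#' @param priors list from [cmr_priors()].
#' @param mcmc list from [mcmc_profile()].
#' @param seed integer master seed.
#' @param gof monitor the expected-recapture quantities needed by
#'   [freeman_tukey_gof()]?
#' @param size_grid reference grid (mm) on which the size-survival spline
#'   is evaluated; latent sizes are interpolated on this grid.
#' @param n_knots number of interior spline knots.
#' @return object of class `c("cmr_fit", "growsurv_fit")` with posterior
#'   draws, summary table, derived spatial scales for both kernels
#'   (`scales_phi`, `scales_k`), sex contrasts (`sex_contrasts`), the
#'   spline curve draws (`fg` columns of `draws`), convergence diagnostics,
#'   and the data/config needed to reproduce the fit.
#' @export
fit_cmr <- function(histories, rings, spei, priors = cmr_priors(),
                    mcmc = mcmc_profile("test"), seed, gof = TRUE,
                    size_grid = seq(100, 1200, by = 10), n_knots = 5) {
  stopifnot(inherits(histories, "cmr_data"), inherits(rings, "ring_covariates"))
  h <- histories
  nind <- dim(h$y)[1]; nyear <- dim(h$y)[2]; maxday <- dim(h$y)[3]
  site_map <- match(h$sites, rings$sites)
  if (anyNA(site_map)) stop("capture-history sites missing from ring set")
  if (!identical(as.character(h$years), as.character(rings$years)))
    stop("capture-history years do not match the ring covariate years")
  nsite <- length(rings$sites)
  spei_m <- spei_matrix(spei, rings)
  ## re-index detection mask arrays onto the ring set's site order
  dmask <- array(0, c(nsite, nyear, maxday))
  dmask[site_map, , ] <- h$day_mask
  site <- site_map[h$site]
  first <- h$first_year; fday <- h$first_day
  ## which days count: after first capture in the first year, all effort
  ## days in later years
  mask <- array(0, c(nind, nyear, maxday))
  for (i in seq_len(nind)) {
    if (first[i] < nyear)
      for (t in (first[i] + 1L):nyear) mask[i, t, ] <- dmask[site[i], t, ]
    if (fday[i] < maxday) {
      m1 <- dmask[site[i], first[i], ]
      m1[seq_len(fday[i])] <- 0
      mask[i, first[i], ] <- m1
    }
  }
  YD <- h$y * mask
  ## first-year day mask per individual (days after first capture)
  M1 <- t(vapply(seq_len(nind), function(i) mask[i, first[i], ],
                 numeric(maxday)))
  nodet0 <- 1 - pmin(apply(YD, 1:2, max), 1)
  det_year <- apply(h$y, 1:2, max)
  ## flattened individual-year index for years after first capture,
  ## ordered by individual then year so the forward recursion can walk it
  qi <- integer(0); qt <- integer(0)
  for (i in seq_len(nind)) if (first[i] < nyear) {
    ts <- (first[i] + 1L):nyear
    qi <- c(qi, rep.int(i, length(ts))); qt <- c(qt, ts)
  }
  nq <- length(qi)
  if (nq == 0L) stop("no individual-years after first capture; ",
                     "the survival model is not estimable")
  isf <- as.integer(qt == first[qi] + 1L)      # first transition of its chain
  ## forward arrays are shifted by one: slot 1 is an all-zero dummy row so
  ## first transitions have a well-defined (empty) predecessor
  qprev <- ifelse(isf == 1L, 1L, seq_len(nq))
  nodet0q <- nodet0[cbind(qi, qt)]
  lastq <- vapply(seq_len(nind), function(i) {
    w <- which(qi == i)
    if (length(w)) max(w) + 1L else 0L
  }, integer(1))
  with_q <- which(lastq > 0L); only_first <- which(lastq == 0L)
  ## latent sizes: observed first measurements are data on L
  Lobs <- h$svl_obs
  Lobs[cbind(seq_len(nind), first)] <- h$svl_obs[cbind(seq_len(nind), first)]
  ## spline basis on the reference grid, knots from observed sizes
  svl_all <- h$svl_obs[!is.na(h$svl_obs)]
  Bg <- spline_basis(size_grid, knots_from = svl_all, n_knots = n_knots,
                     boundary = range(size_grid))
  ## the centered partition-of-unity basis has one exact redundancy (its
  ## row sums are zero); dropping a column restores full rank without
  ## changing the space of centered curves
  Bg <- Bg[, -ncol(Bg), drop = FALSE]
  nring <- length(rings$grid$midpoints)

  ## covariate surface over the kernel-scale grid (log-spaced, denser at
  ## short scales where the weighting changes fastest)
  sgrid <- exp(seq(log(max(priors$sigma_rice_range[1], 0.01)),
                   log(priors$sigma_rice_range[2]), length.out = 120))
  RwG <- array(0, c(nsite, nyear, length(sgrid)))
  for (g in seq_along(sgrid)) {
    w <- kernel_weights(sgrid[g], rings$grid)
    RwG[, , g] <- apply(rings$standardized, 1:2,
                        function(x) sum(w * x))
  }
  dat <- list(nind = nind, nyear = nyear, nsite = nsite, maxday = maxday,
              G = length(size_grid), K = ncol(Bg),
              sgrid = sgrid, RwG = RwG, spei = spei_m,
              Bg = Bg, xg = size_grid,
              sex = ifelse(h$sex == "F", 1L, 2L),
              site = site, first = first,
              YD = YD, M1 = M1, dmask = dmask,
              nodet0q = nodet0q, L = Lobs,
              qi = qi, qt = qt, nq = nq, isf = isf, qprev = qprev,
              na = length(with_q), nb = length(only_first),
              lastq = lastq[with_q], onlyfirst = only_first,
              ones_a = rep(1L, length(with_q)),
              ones_b = rep(1L, length(only_first)),
              theta_sd = priors$theta_sd,
              sigp_lo = priors$sigma_rice_range[1],
              sigp_hi = priors$sigma_rice_range[2],
              sigk_lo = priors$growth$sigma_rice_range[1],
              sigk_hi = priors$growth$sigma_rice_range[2],
              sd_rate = priors$sd_rate,
              spline_sd_rate = priors$spline_sd_rate,
              eps_a_mean = as.numeric(priors$growth$eps_a_mean),
              eps_a_sd = priors$growth$eps_a_sd,
              mu_k_sd = priors$growth$mu_k_sd,
              beta_sd = priors$growth$beta_sd,
              growth_sd_rate = priors$growth$sd_rate,
              sd_a_rate = priors$growth$sd_a_rate,
              sd_err_rate = priors$growth$sd_err_rate)
  ## inits: fill the latent size chain forward
  Linit <- Lobs
  for (i in seq_len(nind)) for (t in seq_len(nyear)[-1])
    if (t > first[i] && is.na(Linit[i, t]) && !is.na(Linit[i, t - 1]))
      Linit[i, t] <- Linit[i, t - 1] + 30
  Linit[!is.na(Lobs)] <- NA
  ## field-typical starting values: JAGS would otherwise initialize the
  ## probability intercepts at 0.5 and log k at 0, far from the region the
  ## data support, wasting the warm-up of short chains
  crude_p <- min(max(sum(YD) / max(sum(mask), 1), 0.005), 0.3)
  inits <- list(L = Linit, sig_rice_k = 1, sig_rice_phi = 2,
                psex = rep(crude_p, 2), phisex = c(0.5, 0.5),
                gamsex = c(0.6, 0.6), mu_k = c(5.5, 5.5),
                sd_err = 25)

  monitors <- c("psex", "phisex", "gamsex", "th_rice", "th_dr",
                "sig_rice_phi", "sd_ps", "sd_pt", "sd_day", "sd_phis",
                "sd_phit", "sd_gt", "fg", "bspl", "sdb",
                "eps_a", "mu_k", "b_rice", "b_dr", "sig_rice_k",
                "sd_sa", "sd_sk", "sd_tk", "sd_ik", "sd_err")
  if (gof) monitors <- c(monitors, "phi", "gam", "pd")
  if (length(only_first) == 0L) {
    dat$nb <- NULL; dat$onlyfirst <- NULL; dat$ones_b <- NULL
  }
  fit <- run_jags(cmr_model_string(gof, length(only_first) > 0L), dat,
                  monitors, mcmc, seed, inits = inits)
  core <- c("psex", "phisex", "gamsex", "th_rice", "th_dr", "sig_rice_phi",
            "sd_ps", "sd_pt", "sd_phis", "sd_phit", "sd_gt",
            "eps_a", "mu_k", "b_rice", "b_dr", "sig_rice_k", "sd_err")
  summ <- posterior_summary(fit$draws, fit$convergence, core)
  d <- fit$draws
  contrasts <- c(
    p_F_gt_M = mean(d[, "psex[1]"] > d[, "psex[2]"]),
    phi_F_gt_M = mean(d[, "phisex[1]"] > d[, "phisex[2]"]),
    gamma_F_gt_M = mean(d[, "gamsex[1]"] > d[, "gamsex[2]"]),
    eps_a_F_gt_M = mean(d[, "eps_a[1]"] > d[, "eps_a[2]"]))
  obs_recap <- vapply(seq_len(nind), function(i)
    if (first[i] < nyear) sum(det_year[i, (first[i] + 1L):nyear]) else 0L,
    numeric(1))
  structure(list(draws = d, samples = fit$samples, summary = summ,
                 scales_phi = scale_summaries(d[, "sig_rice_phi"], rings$grid),
                 scales_k = scale_summaries(d[, "sig_rice_k"], rings$grid),
                 sex_contrasts = contrasts,
                 convergence = fit$convergence,
                 histories = h, rings = rings, spei = spei,
                 size_grid = size_grid, spline_basis = Bg,
                 q_index = data.frame(i = qi, t = qt),
                 obs_recaptures = obs_recap,
                 priors = priors, mcmc = mcmc, seed = seed,
                 model = "cmr"),
            class = c("cmr_fit", "growsurv_fit"))
}

#' Freeman-Tukey goodness of fit for the robust-design model
#'
#' For each posterior draw, the expected number of between-year recaptures
#' of each individual is compared with the observed count and with a
#' replicate count simulated from the same draw using the Freeman-Tukey
#' discrepancy `sum_i (sqrt(obs_i) - sqrt(exp_i))^2`.  The Bayesian p-value
#' is the probability that the replicate discrepancy exceeds the observed
#' one.
#'
#' @param fit a `cmr_fit` from [fit_cmr()] run with `gof = TRUE`.
#' @param seed seed for the replicate simulation.
#' @return object of class `gs_gof` with `p_value`, `d_obs`, `d_rep`.
#' @export
freeman_tukey_gof <- function(fit, seed = 1) {
  getm <- function(nm) {
    cols <- grep(paste0("^", nm, "\\["), colnames(fit$draws))
    if (!length(cols))
      stop("fit does not carry the goodness-of-fit monitors; ",
           "re-run fit_cmr(gof = TRUE)")
    idx <- as.integer(sub(paste0("^", nm, "\\[(\\d+)\\]$"), "\\1",
                          colnames(fit$draws)[cols]))
    fit$draws[, cols[order(idx)], drop = FALSE]
  }
  phi <- getm("phi"); gam <- getm("gam"); pd <- getm("pd")
  qi <- fit$q_index$i; qt <- fit$q_index$t
  nq <- length(qi); nd <- nrow(phi)
  isf <- c(TRUE, qi[-1L] != qi[-nq])  # row starts a new individual's chain
  set.seed(seed)
  ## forward expectation and forward replicate of the alive/available chain
  pal <- matrix(0, nd, nq)       # P(alive at year t | alive at first capture)
  zrep <- matrix(0L, nd, nq)     # replicate alive indicator
  for (q in seq_len(nq)) {
    prev_alive <- if (isf[q]) 1 else pal[, q - 1L]
    pal[, q] <- prev_alive * phi[, q]
    zprev <- if (isf[q]) 1L else zrep[, q - 1L]
    zrep[, q] <- zprev * stats::rbinom(nd, 1L, phi[, q])
  }
  e_q <- pal * gam * pd
  det_rep <- zrep * stats::rbinom(nd * nq, 1L, gam) *
    stats::rbinom(nd * nq, 1L, pd)
  agg <- function(m) t(rowsum(t(m), group = qi, reorder = TRUE))
  exp_i <- agg(e_q)
  rep_i <- agg(det_rep)
  obs_full <- fit$obs_recaptures[sort(unique(qi))]
  obs <- matrix(obs_full, nd, length(obs_full), byrow = TRUE)
  d_obs <- rowSums((sqrt(obs) - sqrt(exp_i))^2)
  d_rep <- rowSums((sqrt(rep_i) - sqrt(exp_i))^2)
  structure(list(p_value = mean(d_rep >= d_obs), d_obs = d_obs,
                 d_rep = d_rep, statistic = "Freeman-Tukey"),
            class = "gs_gof")
}
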