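#' Assemble consecutive-year growth intervals from capture records
#'
#' Uses the first measurement of each individual in each year and forms one
#' growth interval per consecutive-year pair, isolating the effect of a
#' single year's conditions on growth.  Pairs of measurements separated by
#' more than one year are excluded, as are individuals of unknown sex
#' (unless `include_unknown_sex = TRUE`, for use with the latent-sex fitting
#' mode).  An individual recorded at two different sites violates the
#' site-fidelity assumption and raises an error.
#'
#' @param captures a `capture_records` data frame from [read_captures()].
#' @param include_unknown_sex keep individuals with sex `U`?
#' @return data frame of class `growth_intervals` with columns
#'   `individual_id`, `sex`, `site`, `year` (start year of the interval),
#'   `L0` (SVL mm at the start year), `L1` (SVL mm one year later), and
#'   `dt` (interval length in years, always 1).
#' @export
assemble_growth_intervals <- function(captures, include_unknown_sex = FALSE) {
  df <- as.data.frame(captures)
  multi <- tapply(df$site, df$individual_id, function(s) length(unique(s)))
  if (any(multi > 1L))
    stop("individual(s) observed at more than one site: ",
         paste(utils::head(names(multi)[multi > 1L], 3), collapse = ", "))
  if (!include_unknown_sex) df <- df[df$sex != "U", , drop = FALSE]
  df <- df[order(df$individual_id, df$date), , drop = FALSE]
  ## first measurement per individual-year
  firsts <- df[!duplicated(df[c("individual_id", "year")]), , drop = FALSE]
  out <- do.call(rbind, lapply(split(firsts, firsts$individual_id), function(d) {
    d <- d[order(d$year), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    i <- which(diff(d$year) == 1L)
    if (!length(i)) return(NULL)
    data.frame(individual_id = d$individual_id[i], sex = d$sex[i],
               site = d$site[i], year = d$year[i],
               L0 = d$svl_mm[i], L1 = d$svl_mm[i + 1L], dt = 1,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(individual_id = character(), sex = character(),
                      site = character(), year = integer(), L0 = numeric(),
                      L1 = numeric(), dt = numeric())
  rownames(out) <- NULL
  class(out) <- c("growth_intervals", class(out))
  out
}

#' Expected length under the von Bertalanffy growth curve
#'
#' `EL = a - (a - L_prev) * exp(-(k / a) * dt)`: length approaches the
#' asymptote `a` at a rate controlled by the growth coefficient `k`
#' (mm/year).  Vectorized over all arguments.
#'
#' @param a asymptotic SVL (mm), positive.
#' @param k growth coefficient (mm/yr), nonnegative.
#' @param L_prev SVL at the start of the interval (mm), positive.
#' @param dt interval length in years.
#' @return expected SVL (mm) at the end of the interval.
#' @export
expected_length <- function(a, k, L_prev, dt = 1) {
  if (any(a <= 0)) stop("asymptotic length 'a' must be positive")
  if (any(k < 0)) stop("growth coefficient 'k' must be nonnegative")
  if (any(L_prev <= 0)) stop("'L_prev' must be positive")
  a - (a - L_prev) * exp(-(k / a) * dt)
}

#' Growth coefficient on the log-linear scale
#'
#' `k = exp(mu_k + beta_rice * R_w + beta_drought * spei + alpha + zeta +
#' iota)`, combining the sex-specific intercept, the distance-weighted
#' landscape covariate, the drought index, and site/year/individual random
#' effects.
#'
#' @param mu_k sex-specific log growth-rate intercept.
#' @param beta_rice,R_w landscape effect and distance-weighted covariate.
#' @param beta_drought,spei drought effect and drought-index value.
#' @param alpha,zeta,iota site, year and individual random-effect values.
#' @return growth coefficient `k` (mm/yr), always positive.
#' @export
growth_rate <- function(mu_k, beta_rice = 0, R_w = 0, beta_drought = 0,
                        spei = 0, alpha = 0, zeta = 0, iota = 0) {
  exp(mu_k + beta_rice * R_w + beta_drought * spei + alpha + zeta + iota)
}

#' Log joint density of observed lengths given growth parameters
#'
#' The observation model puts each end-of-interval length around its
#' von Bertalanffy expectation with normal error:
#' `L1 ~ N(EL(a, k, L0, dt), sigma_err)`.  This evaluates the summed log
#' density at fixed parameter values, the quantity against which an
#' independently coded likelihood can be checked.
#'
#' @param intervals a `growth_intervals` data frame.
#' @param a,k asymptote and growth coefficient, scalar or per interval.
#' @param sigma_err residual SD (mm).
#' @return scalar log density.
#' @export
growth_loglik <- function(intervals, a, k, sigma_err) {
  el <- expected_length(a, k, intervals$L0, intervals$dt)
  sum(stats::dnorm(intervals$L1, el, sigma_err, log = TRUE))
}

#' Prior settings for the growth model
#'
#' Normal priors are parameterized as (mean, SD); exponential priors by
#' rate.  Defaults: asymptote N(900, 200) for females and N(700, 200) for
#' males, N(0, 10) on the log growth-rate intercepts and covariate effects,
#' Unif(0.01, 10) km on the kernel scale, Exp(1) on growth random-effect
#' SDs, and Exp(0.1) on the site-asymptote SD and the residual SD.
#'
#' @param eps_a_mean,eps_a_sd asymptote prior means (female, male) and SD.
#' @param mu_k_sd,beta_sd SDs of the normal priors on intercepts/effects.
#' @param sigma_rice_range uniform prior range (km) for the kernel scale.
#' @param sd_rate,sd_a_rate,sd_err_rate exponential rates for SD priors.
#' @return list of prior settings.
#' @export
growth_priors <- function(eps_a_mean = c(F = 900, M = 700), eps_a_sd = 200,
                          mu_k_sd = 10, beta_sd = 10,
                          sigma_rice_range = c(0.01, 10),
                          sd_rate = 1, sd_a_rate = 0.1, sd_err_rate = 0.1) {
  list(eps_a_mean = eps_a_mean, eps_a_sd = eps_a_sd, mu_k_sd = mu_k_sd,
       beta_sd = beta_sd, sigma_rice_range = sigma_rice_range,
       sd_rate = sd_rate, sd_a_rate = sd_a_rate, sd_err_rate = sd_err_rate)
}

growth_model_string <- function(has_data, latent_sex = FALSE) {
  sex_block <- if (latent_sex) "
  for (n in 1:nint) { sex[n] ~ dcat(sex_pr[]) }" else ""
  likelihood <- if (has_data) paste0(sex_block, "
  for (i in 1:nind) { iok[i] ~ dnorm(0, tau_ik) }
  for (n in 1:nint) {
    a[n] <- eps_a[sex[n]] + lam[sex[n], site[n]]
    logk[n] <- mu_k[sex[n]] + b_rice*Rw[sy[n]] + b_dr*spei[sy[n]] +
               alk[sex[n], site[n]] + zek[yr[n]] + iok[ind[n]]
    EL[n] <- a[n] - (a[n] - L0[n]) * exp(-exp(logk[n]) * dt[n] / a[n])
    L1[n] ~ dnorm(EL[n], tau_err)
  }") else ""
  paste0("
model {
  for (r in 1:nring) {
    wr[r] <- A[r] * exp(-pow(mids[r], 2) / (2 * pow(sig_rice, 2)))
    w[r] <- wr[r] / sum(wr[])
  }
  for (n in 1:nsy) { Rw[n] <- inprod(w[], X[n, ]) }
  for (x in 1:2) {
    eps_a[x] ~ dnorm(eps_a_mean[x], pow(eps_a_sd, -2))
    mu_k[x] ~ dnorm(0, pow(mu_k_sd, -2))
    for (s in 1:nsite) {
      lam[x, s] ~ dnorm(0, tau_sa)
      alk[x, s] ~ dnorm(0, tau_sk)
    }
  }
  for (t in 1:nyear) { zek[t] ~ dnorm(0, tau_tk) }
  b_rice ~ dnorm(0, pow(beta_sd, -2))
  b_dr ~ dnorm(0, pow(beta_sd, -2))
  sig_rice ~ dunif(sig_lo, sig_hi)
  tau_sa <- pow(sd_sa, -2);  sd_sa ~ dexp(sd_a_rate)
  tau_sk <- pow(sd_sk, -2);  sd_sk ~ dexp(sd_rate)
  tau_tk <- pow(sd_tk, -2);  sd_tk ~ dexp(sd_rate)
  tau_ik <- pow(sd_ik, -2);  sd_ik ~ dexp(sd_rate)
  tau_err <- pow(sd_err, -2); sd_err ~ dexp(sd_err_rate)
", likelihood, "
}
")
}

#' Fit the hierarchical von Bertalanffy growth model
#'
#' Fits the growth model to consecutive-year intervals by MCMC: sex-specific
#' asymptotes with site random effects, a log-linear model for the growth
#' coefficient with landscape and drought effects plus site, year and
#' individual random effects, and a distance-weighted landscape covariate
#' whose kernel scale is estimated jointly (so the covariate is recomputed
#' at every draw).  An empty interval table is allowed and yields a
#' prior-only run.
#'
#' @param intervals a `growth_intervals` data frame
#'   (see [assemble_growth_intervals()]); may have zero rows.
#' @param rings a [ring_covariates()] object covering every site-year.
#' @param spei data frame `site`, `year`, `spei06` (see [read_spei()]).
#' @param priors list from [growth_priors()].
#' @param mcmc list from [mcmc_profile()].
#' @param seed integer master seed; the fit is reproducible given `seed`
#'   and `mcmc`.
#' @param gof also monitor per-interval expected lengths so
#'   [growth_gof()] can be computed? Default `TRUE` when intervals exist.
#' @param latent_sex treat unknown-sex individuals (sex `"U"`) as having
#'   a latent sex with a Bernoulli prior at the observed sex ratio,
#'   instead of excluding them.  Requires intervals assembled with
#'   `include_unknown_sex = TRUE`.
#' @return object of class `c("growth_fit", "growsurv_fit")` with posterior
#'   draws, a summary table, derived spatial scales (`scales`), convergence
#'   diagnostics, and the data/config needed to reproduce the fit.
#' @export
fit_growth <- function(intervals, rings, spei, priors = growth_priors(),
                       mcmc = mcmc_profile("test"), seed,
                       gof = nrow(intervals) > 0, latent_sex = FALSE) {
  stopifnot(inherits(rings, "ring_covariates"))
  nint <- nrow(intervals)
  nsite <- length(rings$sites); nyear <- length(rings$years)
  spei_m <- spei_matrix(spei, rings)
  nring <- length(rings$grid$midpoints)
  X <- matrix(aperm(rings$standardized, c(3, 1, 2)), nrow = nring)
  X <- t(X)  # (site x year flattened, site fastest) x ring

  dat <- list(nring = nring, nsy = nsite * nyear,
              A = rings$grid$cell_counts, mids = rings$grid$midpoints,
              X = X, nsite = nsite, nyear = nyear,
              eps_a_mean = as.numeric(priors$eps_a_mean),
              eps_a_sd = priors$eps_a_sd, mu_k_sd = priors$mu_k_sd,
              beta_sd = priors$beta_sd,
              sig_lo = priors$sigma_rice_range[1],
              sig_hi = priors$sigma_rice_range[2],
              sd_rate = priors$sd_rate, sd_a_rate = priors$sd_a_rate,
              sd_err_rate = priors$sd_err_rate)
  if (nint > 0) {
    si <- match(intervals$site, rings$sites)
    yi <- match(as.character(intervals$year), rings$years)
    if (anyNA(si) || anyNA(yi))
      stop("interval site/year not found in the ring covariate set")
    ids <- unique(intervals$individual_id)
    sexv <- ifelse(intervals$sex == "F", 1L,
                   ifelse(intervals$sex == "M", 2L, NA_integer_))
    if (anyNA(sexv) && !latent_sex)
      stop("unknown-sex intervals present; use latent_sex = TRUE or ",
           "exclude them in assemble_growth_intervals()")
    dat <- c(dat, list(
      nint = nint, nind = length(ids),
      sex = sexv,
      site = si, yr = yi, sy = (yi - 1L) * nsite + si,
      ind = match(intervals$individual_id, ids),
      L0 = intervals$L0, L1 = intervals$L1, dt = intervals$dt,
      spei = as.vector(spei_m)))
    if (latent_sex) {
      known <- sexv[!is.na(sexv)]
      pF <- if (length(known)) mean(known == 1L) else 0.5
      dat$sex_pr <- c(pF, 1 - pF)
    }
  }
  monitors <- c("eps_a", "mu_k", "b_rice", "b_dr", "sig_rice",
                "sd_sa", "sd_sk", "sd_tk", "sd_ik", "sd_err")
  if (gof && nint > 0) monitors <- c(monitors, "EL")
  ## start the chain at a crude closed-form growth estimate: the prior
  ## means (JAGS defaults) sit far from field-typical log k and short
  ## chains would spend their burn-in travelling there
  inits <- list(sig_rice = 1, sd_err = 25)
  if (nint > 0) {
    sx <- ifelse(intervals$sex == "F", 1L, 2L)
    a0 <- as.numeric(priors$eps_a_mean)[sx]
    ratio <- pmin(pmax((a0 - intervals$L1) / (a0 - intervals$L0),
                       0.05), 0.999)
    k0 <- -a0 * log(ratio) / intervals$dt
    mu0 <- vapply(1:2, function(x) {
      v <- k0[sx == x & k0 > 0]
      if (length(v)) log(stats::median(v)) else 5.5
    }, numeric(1))
    inits$mu_k <- pmin(pmax(mu0, 2), 7)
  }
  fit <- run_jags(growth_model_string(nint > 0, latent_sex), dat,
                  monitors, mcmc, seed, inits = inits)
  core <- setdiff(monitors, "EL")
  summ <- posterior_summary(fit$draws, fit$convergence, core)
  scales <- scale_summaries(fit$draws[, "sig_rice"], rings$grid)
  structure(list(draws = fit$draws, samples = fit$samples, summary = summ,
                 scales = scales, convergence = fit$convergence,
                 intervals = intervals, rings = rings, spei = spei,
                 priors = priors, mcmc = mcmc, seed = seed,
                 model = "growth"),
            class = c("growth_fit", "growsurv_fit"))
}

#' Posterior-predictive goodness of fit for the growth model
#'
#' For each posterior draw, compares the residual sum of squares of the
#' observed end-of-interval lengths around their expected values with the
#' RSS of a replicate dataset simulated from the same draw.  The Bayesian
#' p-value is the probability that the replicate discrepancy exceeds the
#' observed one; values near 0 or 1 indicate misfit.
#'
#' @param fit a `growth_fit` from [fit_growth()] run with `gof = TRUE`.
#' @param seed integer seed for the replicate simulation.
#' @return object of class `gs_gof` with elements `p_value`, `d_obs`,
#'   `d_rep` (per-draw discrepancies), and `statistic = "RSS"`.
#' @export
growth_gof <- function(fit, seed = 1) {
  el_cols <- grep("^EL\\[", colnames(fit$draws))
  if (!length(el_cols))
    stop("fit does not carry expected lengths; re-run fit_growth(gof = TRUE)")
  el <- fit$draws[, el_cols, drop = FALSE]
  sde <- fit$draws[, "sd_err"]
  obs <- fit$intervals$L1
  set.seed(seed)
  d_obs <- rowSums((matrix(obs, nrow(el), ncol(el), byrow = TRUE) - el)^2)
  rep_l <- el + matrix(stats::rnorm(length(el), 0, rep(sde, ncol(el))),
                       nrow(el), ncol(el))
  d_rep <- rowSums((rep_l - el)^2)
  structure(list(p_value = mean(d_rep >= d_obs), d_obs = d_obs,
                 d_rep = d_rep, statistic = "RSS"),
            class = "gs_gof")
}

#' @export
print.gs_gof <- function(x, ...) {
  cat(sprintf("Posterior-predictive check (%s): Bayesian p-value = %.3f\n",
              x$statistic, x$p_value))
  if (x$p_value < 0.05 || x$p_value > 0.95)
    cat("  extreme p-value: evidence of lack of fit\n")
  invisible(x)
}
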