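#' Truth samplers for simulate-and-refit studies
#'
#' Draw generating parameter values for one validation replicate.  The CMR
#' sampler varies the quantities whose recovery the study scores --
#' survival, detection, availability, the landscape effect on survival and
#' its spatial scale -- over ranges centered on plausible field values,
#' holding the remaining components at [default_truth()]; size-survival is
#' size-independent here (shape experiments are run separately through
#' [shape_recovery()]).  The growth sampler keeps the landscape effect at
#' its central value so bias and coverage are assessed at the
#' scientifically relevant point.
#'
#' @param seed integer seed for the draw.
#' @return a `gs_truth` list.
#' @export
cmr_truth_sampler <- function(seed) {
  set.seed(seed)
  default_truth(
    phi_sex = stats::runif(2, 0.35, 0.60),
    p_sex = sort(stats::runif(2, 0.04, 0.09), decreasing = TRUE),
    gamma_sex = stats::runif(2, 0.45, 0.75),
    theta_rice = stats::runif(1, -0.2, 0.8),
    theta_drought = stats::runif(1, -0.2, 0.2),
    sigma_rice_phi = stats::runif(1, 0.5, 5))
}

#' @rdname cmr_truth_sampler
#' @export
growth_truth_sampler <- function(seed) {
  set.seed(seed)
  default_truth(
    mu_k = c(stats::runif(1, 5.3, 6.0), stats::runif(1, 5.4, 6.1)),
    beta_drought = stats::runif(1, -0.2, 0.4),
    sigma_rice_k = stats::runif(1, 0.4, 2.5))
}

## parameters scored by default in each study, mapped to draw columns
cmr_score_map <- c("phi_F" = "phisex[1]", "phi_M" = "phisex[2]",
                   "p_F" = "psex[1]", "gamma_F" = "gamsex[1]",
                   "theta_rice" = "th_rice",
                   "sigma_rice_phi" = "sig_rice_phi")
growth_score_map <- c("beta_rice" = "b_rice", "mu_k_F" = "mu_k[1]",
                      "mu_k_M" = "mu_k[2]", "eps_a_F" = "eps_a[1]",
                      "sigma_rice_k" = "sig_rice")

truth_value <- function(truth, param) {
  switch(param,
         phi_F = truth$phi_sex[1], phi_M = truth$phi_sex[2],
         p_F = truth$p_sex[1], gamma_F = truth$gamma_sex[1],
         theta_rice = truth$theta_rice,
         sigma_rice_phi = truth$sigma_rice_phi,
         beta_rice = truth$beta_rice,
         mu_k_F = truth$mu_k[1], mu_k_M = truth$mu_k[2],
         eps_a_F = truth$eps_a[1],
         sigma_rice_k = truth$sigma_rice_k,
         stop("no truth mapping for parameter '", param, "'"))
}

#' Simulate-and-refit recovery study
#'
#' Repeats simulate, fit, and score: each replicate draws generating values
#' from `truth_sampler`, simulates a study under `design`, fits the model,
#' and records the posterior mean, 95% credible interval, interval
#' coverage of the generating value, bias, and a posterior-predictive
#' p-value.  Per-replicate seeds are derived from the master seed by a
#' fixed splitting rule, so results are independent of execution order and
#' reproducible end to end.  Replicates whose fit raises a convergence
#' warning are flagged, never dropped.
#'
#' @param n_reps number of replicates.
#' @param model `"cmr"` (integrated robust-design model) or `"growth"`.
#' @param design a [study_design()].
#' @param truth_sampler function(seed) returning a `gs_truth`; defaults to
#'   the matching sampler above.
#' @param mcmc list from [mcmc_profile()]; recovery replicates default to
#'   a single short chain.
#' @param seed master seed.
#' @param params names of scored parameters (see `cmr_score_map`).
#' @param gof also record a goodness-of-fit p-value per replicate?
#' @param fitter optional replacement fitting function
#'   `function(sim, mcmc, seed)` returning a list with a `summary` data
#'   frame (columns `parameter`, `mean`, `q2.5`, `q97.5` using draw-column
#'   names) and optionally `gof_p` and `converged`; used for harness
#'   self-tests with a stub estimator.
#' @param n_intervals growth-study size (growth model only).
#' @return object of class `recovery_report`.
#' @export
run_recovery_study <- function(n_reps, model = c("cmr", "growth"),
                               design = study_design(),
                               truth_sampler = NULL,
                               mcmc = mcmc_profile("test", chains = 1,
                                                   n_iter = 1000,
                                                   n_adapt = 250,
                                                   n_burn = 250),
                               seed = 1, params = NULL, gof = TRUE,
                               fitter = NULL, n_intervals = 260) {
  model <- match.arg(model)
  stopifnot(n_reps >= 1)
  if (is.null(truth_sampler))
    truth_sampler <- if (model == "cmr") cmr_truth_sampler else
      growth_truth_sampler
  if (is.null(params))
    params <- names(if (model == "cmr") cmr_score_map else growth_score_map)
  map <- if (model == "cmr") cmr_score_map else growth_score_map
  rep_seeds <- (as.integer(seed) + seq_len(n_reps) * 7919L) %% 2147483587L
  rows <- list(); gofs <- rep(NA_real_, n_reps)
  conv <- rep(NA, n_reps)
  for (r in seq_len(n_reps)) {
    rs <- rep_seeds[r]
    truth <- truth_sampler(rs)
    sim <- if (model == "cmr") {
      simulate_study(design, truth, shape = "independent", seed = rs)
    } else {
      simulate_growth_study(n_intervals, design, truth, seed = rs)
    }
    if (!is.null(fitter)) {
      res <- fitter(sim, mcmc, rs)
      summ <- res$summary
      gofs[r] <- res$gof_p %||% NA_real_
      conv[r] <- isTRUE(res$converged)
    } else if (model == "cmr") {
      fit <- suppressWarnings(
        fit_cmr(sim$histories, sim$rings, sim$spei, mcmc = mcmc,
                seed = rs, gof = gof))
      summ <- posterior_summary(fit$draws,
                                pars = unique(sub("\\[.*", "", map)))
      if (gof) gofs[r] <- freeman_tukey_gof(fit, seed = rs)$p_value
      conv[r] <- !isTRUE(fit$convergence$flag)
    } else {
      fit <- suppressWarnings(
        fit_growth(sim$intervals, sim$rings, sim$spei, mcmc = mcmc,
                   seed = rs, gof = gof))
      summ <- posterior_summary(fit$draws,
                                pars = unique(sub("\\[.*", "", map)))
      if (gof) gofs[r] <- growth_gof(fit, seed = rs)$p_value
      conv[r] <- !isTRUE(fit$convergence$flag)
    }
    for (pm in params) {
      row <- summ[summ$parameter == map[[pm]], , drop = FALSE]
      tv <- truth_value(truth$params %||% truth, pm)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, seed = rs, parameter = pm, truth = tv,
        mean = row$mean, q2.5 = row$q2.5, q97.5 = row$q97.5,
        covered = row$q2.5 <= tv & tv <= row$q97.5,
        bias = row$mean - tv, stringsAsFactors = FALSE)
    }
  }
  structure(list(results = do.call(rbind, rows),
                 gof_p = gofs, converged = conv,
                 model = model, n_reps = n_reps, seed = seed,
                 rep_seeds = rep_seeds, design = design, mcmc = mcmc),
            class = "recovery_report")
}

#' @export
summary.recovery_report <- function(object, ...) {
  res <- object$results
  out <- do.call(rbind, lapply(split(res, res$parameter), function(d) {
    n <- nrow(d); x <- sum(d$covered)
    bt <- stats::binom.test(x, n, p = 0.95)
    data.frame(parameter = d$parameter[1], n = n,
               mean_bias = mean(d$bias),
               bias_se = stats::sd(d$bias) / sqrt(n),
               coverage = x / n,
               cov_lo = bt$conf.int[1], cov_hi = bt$conf.int[2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery study (%s model): %d replicates\n", x$model,
              x$n_reps))
  print(summary(x), digits = 3)
  if (any(!x$converged, na.rm = TRUE))
    cat(sum(!x$converged, na.rm = TRUE), "replicate(s) flagged for",
        "possible non-convergence (included above)\n")
  invisible(x)
}

#' Exact binomial bounds for credible-interval coverage
#'
#' The acceptance region for observed coverage out of `n` replicates when
#' the nominal rate is `p`: the equal-tailed exact binomial interval on
#' counts.
#'
#' @param n replicates; @param p nominal coverage; @param level interval level.
#' @return counts `c(lo, hi)` delimiting the acceptance region.
#' @export
coverage_bounds <- function(n, p = 0.95, level = 0.95) {
  a <- (1 - level) / 2
  c(lo = stats::qbinom(a, n, p), hi = stats::qbinom(1 - a, n, p))
}

#' Spline shape-recovery experiment
#'
#' Simulates a study whose size-survival relationship follows a known
#' shape, fits the integrated model, and compares the posterior spline
#' curve with the generating curve over an SVL grid.  Both curves are
#' centered over the reference grid (the fitted spline is sum-to-zero
#' constrained, so only the centered shape is identified).
#'
#' @param shape one of the four shapes in [size_survival_shape()].
#' @param design a [study_design()].
#' @param truth a [default_truth()] list.
#' @param mcmc list from [mcmc_profile()].
#' @param seed integer seed.
#' @param svl_window SVL range (mm) over which recovery is summarized.
#' @return object of class `shape_recovery`: per-grid-point data frame
#'   (`svl`, `truth`, `mean`, `q2.5`, `q97.5`, `covered`), the coverage
#'   proportion within the window, and the sign-agreement proportion of
#'   finite differences within the window.
#' @export
shape_recovery <- function(shape, design = study_design(),
                           truth = default_truth(),
                           mcmc = mcmc_profile("test", chains = 1),
                           seed = 1, svl_window = c(300, 950)) {
  sim <- simulate_study(design, truth, shape = shape, seed = seed)
  fit <- suppressWarnings(
    fit_cmr(sim$histories, sim$rings, sim$spei, mcmc = mcmc, seed = seed,
            gof = FALSE))
  xg <- fit$size_grid
  fcols <- grep("^fg\\[", colnames(fit$draws))
  fgn <- as.integer(sub("^fg\\[(\\d+)\\]$", "\\1", colnames(fit$draws)[fcols]))
  fdraws <- fit$draws[, fcols[order(fgn)], drop = FALSE]
  ftrue <- size_survival_shape(shape, truth$shape_amplitude)(xg)
  ftrue <- ftrue - mean(ftrue)
  fmean <- colMeans(fdraws)
  ## the fitted curve is centered over the grid by construction; recenter
  ## draws exactly to guard against numeric drift
  fdraws <- fdraws - rowMeans(fdraws)
  fmean <- fmean - mean(fmean)
  lo <- apply(fdraws, 2, stats::quantile, 0.025)
  hi <- apply(fdraws, 2, stats::quantile, 0.975)
  curve <- data.frame(svl = xg, truth = ftrue, mean = fmean,
                      q2.5 = lo, q97.5 = hi,
                      covered = lo <= ftrue & ftrue <= hi)
  win <- curve$svl >= svl_window[1] & curve$svl <= svl_window[2]
  ## slope-sign agreement over ~50 mm steps (single grid steps compare
  ## Monte-Carlo noise, not shape), and only where the true curve moves
  coarse <- which(win)[seq(1, sum(win), by = 5)]
  dmean <- diff(curve$mean[coarse]); dtrue <- diff(curve$truth[coarse])
  nz <- abs(dtrue) > 0.1 * max(abs(dtrue))
  sign_agree <- if (any(nz)) mean(sign(dmean[nz]) == sign(dtrue[nz])) else NA
  structure(list(shape = shape, curve = curve,
                 window = svl_window,
                 coverage_in_window = mean(curve$covered[win]),
                 sign_agreement = sign_agree,
                 max_abs_fit = max(abs(curve$mean[win])),
                 mean_cri_width = mean((hi - lo)[win]),
                 seed = seed),
            class = "shape_recovery")
}

#' @export
print.shape_recovery <- function(x, ...) {
  cat(sprintf(paste0("Shape recovery ('%s'): CRI coverage %.2f over ",
                     "%d-%d mm; sign agreement %.2f\n"),
              x$shape, x$coverage_in_window, x$window[1], x$window[2],
              ifelse(is.na(x$sign_agreement), NaN, x$sign_agreement)))
  invisible(x)
}
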