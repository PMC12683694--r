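#' MCMC run configuration
#'
#' Two named profiles are provided.  `"paper"` mirrors a full-inference run
#' (4 chains, 10,000 burn-in, 250,000 iterations thinned by 10).  `"test"`
#' is a short profile for desk-scale work and simulation studies (2 chains,
#' 300 adaptation + 300 burn-in, 1500 kept iterations); it is sized so a
#' single integrated-model fit completes in well under a minute on one CPU.
#' Any component can be overridden.
#'
#' @param profile `"test"` or `"paper"`.
#' @param chains,n_adapt,n_burn,n_iter,thin overrides for the chosen profile.
#' @return list of MCMC settings.
#' @export
mcmc_profile <- function(profile = c("test", "paper"), chains = NULL,
                         n_adapt = NULL, n_burn = NULL, n_iter = NULL,
                         thin = NULL) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    test  = list(chains = 2L, n_adapt = 300L, n_burn = 300L,
                 n_iter = 1500L, thin = 1L),
    paper = list(chains = 4L, n_adapt = 1000L, n_burn = 10000L,
                 n_iter = 250000L, thin = 10L))
  if (!is.null(chains)) cfg$chains <- as.integer(chains)
  if (!is.null(n_adapt)) cfg$n_adapt <- as.integer(n_adapt)
  if (!is.null(n_burn)) cfg$n_burn <- as.integer(n_burn)
  if (!is.null(n_iter)) cfg$n_iter <- as.integer(n_iter)
  if (!is.null(thin)) cfg$thin <- as.integer(thin)
  cfg$profile <- profile
  cfg
}

## Run a JAGS model and return draws plus convergence diagnostics.
## `seed` drives both JAGS RNG state (one stream per chain) and nothing else.
run_jags <- function(model_string, data, monitors, mcmc, seed,
                     inits = NULL, quiet = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  seed <- as.integer(seed)
  init_fun <- function(chain) {
    ini <- if (is.null(inits)) list() else inits
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- (seed * 97L + chain * 1003L) %% 2147483587L + 1L
    ini
  }
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = lapply(seq_len(mcmc$chains), init_fun),
                             n.chains = mcmc$chains, n.adapt = mcmc$n_adapt,
                             quiet = quiet)
  if (mcmc$n_burn > 0) update(model, mcmc$n_burn, progress.bar = "none")
  samples <- rjags::coda.samples(model, variable.names = monitors,
                                 n.iter = mcmc$n_iter, thin = mcmc$thin,
                                 progress.bar = "none")
  draws <- do.call(rbind, lapply(samples, as.matrix))
  conv <- convergence_check(samples)
  list(samples = samples, draws = draws, convergence = conv)
}

## Potential scale reduction (R-hat) per parameter when >1 chain; flags > 1.01.
convergence_check <- function(samples, threshold = 1.01) {
  if (length(samples) < 2L)
    return(list(rhat = NULL, flag = FALSE,
                note = "single chain; R-hat not computed"))
  keep <- apply(as.matrix(samples[[1]]), 2, function(x) stats::var(x) > 0)
  rhat <- tryCatch({
    gd <- coda::gelman.diag(samples[, keep, drop = FALSE],
                            autoburnin = FALSE, multivariate = FALSE)
    stats::setNames(gd$psrf[, 1], rownames(gd$psrf))
  }, error = function(e) NULL)
  flag <- !is.null(rhat) && any(rhat > threshold, na.rm = TRUE)
  if (flag)
    warning("possible non-convergence: max R-hat = ",
            round(max(rhat, na.rm = TRUE), 3))
  list(rhat = rhat, flag = flag)
}

## Posterior summary table for a draws matrix restricted to named parameters.
posterior_summary <- function(draws, convergence = NULL, pars = NULL) {
  if (!is.null(pars)) {
    keep <- unlist(lapply(pars, function(p)
      grep(paste0("^", p, "(\\[|$)"), colnames(draws), value = TRUE)))
    draws <- draws[, unique(keep), drop = FALSE]
  }
  qs <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975)))
  ess <- tryCatch(coda::effectiveSize(coda::mcmc(draws)),
                  error = function(e) rep(NA_real_, ncol(draws)))
  out <- data.frame(parameter = colnames(draws),
                    mean = colMeans(draws),
                    sd = apply(draws, 2, stats::sd),
                    q2.5 = qs[, 1], q97.5 = qs[, 2],
                    ess = as.numeric(ess[colnames(draws)]),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(convergence$rhat))
    out$rhat <- as.numeric(convergence$rhat[out$parameter])
  out
}

## Derived spatial-scale summaries from posterior draws of the kernel scale.
scale_summaries <- function(sigma_draws, grid) {
  sm <- vapply(sigma_draws, function(s) {
    es <- effect_scales(s, grid)
    c(es$scale_max, es$scale_90)
  }, numeric(2))
  list(draws = data.frame(sigma = sigma_draws,
                          scale_max = sm[1, ], scale_90 = sm[2, ]),
       summary = data.frame(
         parameter = c("sigma", "scale_max", "scale_90"),
         mean = c(mean(sigma_draws), mean(sm[1, ]), mean(sm[2, ])),
         q2.5 = c(stats::quantile(sigma_draws, 0.025),
                  stats::quantile(sm[1, ], 0.025),
                  stats::quantile(sm[2, ], 0.025)),
         q97.5 = c(stats::quantile(sigma_draws, 0.975),
                   stats::quantile(sm[1, ], 0.975),
                   stats::quantile(sm[2, ], 0.975)),
         row.names = NULL))
}
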