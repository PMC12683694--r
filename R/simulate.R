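#' Study design for synthetic data
#'
#' Dimensions of a simulated capture-mark-recapture study.  Defaults
#' emulate the motivating field design: 19 sites trapped over 6 years with
#' around four weeks of daily trapping per site-year, and a population
#' large enough that roughly 1800 individuals are captured at least once.
#'
#' @param n_sites,n_years study dimensions.
#' @param n_days days trapped per site-year: a scalar, or a
#'   `n_sites x n_years` matrix.
#' @param n_pop simulated population size (individuals at risk of capture);
#'   only those captured at least once appear in the exported data.
#' @param sex_ratio proportion female.
#' @return list of class `study_design`.
#' @export
study_design <- function(n_sites = 19, n_years = 6, n_days = 28,
                         n_pop = 4200, sex_ratio = 0.55) {
  if (length(n_days) == 1L) n_days <- matrix(n_days, n_sites, n_years)
  stopifnot(all(dim(n_days) == c(n_sites, n_years)), all(n_days >= 1))
  structure(list(n_sites = n_sites, n_years = n_years, n_days = n_days,
                 n_pop = n_pop, sex_ratio = sex_ratio),
            class = "study_design")
}

#' Generating parameter values for a synthetic study
#'
#' Defaults are centered on demographic values typical of a semi-aquatic
#' snake population in a rice agroecosystem: annual apparent survival near
#' 0.47, availability 0.55-0.62, daily detection 0.02-0.03, a positive
#' landscape effect on both growth (0.34) and survival (0.33), sex-specific
#' asymptotic sizes (females larger), and modest site/year heterogeneity.
#' Every value can be overridden; the full list is stored in the truth
#' record of each simulated study.
#'
#' @param ... named overrides of any default component.
#' @return list of class `gs_truth` (female value first in all sex pairs).
#' @export
default_truth <- function(...) {
  tr <- list(
    phi_sex = c(0.48, 0.46), gamma_sex = c(0.55, 0.62),
    p_sex = c(0.03, 0.02),
    theta_rice = 0.33, theta_drought = 0.01, sigma_rice_phi = 6.1,
    sd_phis = 0.44, sd_phit = 0.21,
    sd_ps = 0.26, sd_pt = 0.60, sd_day = 0.40, sd_gt = 0.73,
    eps_a = c(881, 645), mu_k = c(5.66, 5.83),
    beta_rice = 0.34, beta_drought = 0.13, sigma_rice_k = 0.8,
    sd_sa = 37.6, sd_sk = 0.32, sd_tk = 0.38, sd_ik = 0.35, sd_err = 26.2,
    init_size_mean = c(620, 540), init_size_sd = c(150, 110),
    init_size_range = c(180, 1050),
    shape_amplitude = 0.75)
  over <- list(...)
  bad <- setdiff(names(over), names(tr))
  if (length(bad)) stop("unknown truth component(s): ",
                        paste(bad, collapse = ", "))
  tr[names(over)] <- over
  class(tr) <- "gs_truth"
  tr
}

#' Size-survival shape functions
#'
#' The four functional forms used to probe whether the survival spline can
#' recover a known size effect, each on the logit scale and roughly
#' centered over the typical size range: `independent` (no effect),
#' `linear`, `quadratic` (peak near 600 mm), and `asymptotic` (rising to a
#' plateau).
#'
#' @param shape one of `"independent"`, `"linear"`, `"quadratic"`,
#'   `"asymptotic"`.
#' @param amplitude logit-scale amplitude of the effect.
#' @return function mapping SVL (mm) to a logit-scale contribution.
#' @export
size_survival_shape <- function(shape = c("independent", "linear",
                                          "quadratic", "asymptotic"),
                                amplitude = 0.75) {
  shape <- match.arg(shape)
  switch(shape,
    independent = function(x) rep(0, length(x)),
    linear = function(x) amplitude * (x - 600) / 300,
    quadratic = function(x) amplitude * (1 - ((x - 600) / 300)^2) -
      amplitude * 0.25,
    asymptotic = function(x) amplitude * (1 - exp(-(x - 200) / 250)) -
      amplitude * 0.75)
}

#' Simulate ring-structured landscape covariates and a drought index
#'
#' Generates per-site-year ring proportions whose mean distance profile is
#' hump-shaped -- cover rising from the site to a peak around 0.5-0.7 km,
#' then declining gradually -- with site- and year-level noise on the logit
#' scale, plus a site-year drought index that is standard normal with a
#' shared year component (so wet and dry years hit all sites together).
#' In raster mode, a binary cover raster per site is drawn from the same
#' profile and ring proportions are extracted from it with
#' [extract_ring_proportions()], exercising the raster path end to end.
#'
#' @param n_sites,n_years dimensions.
#' @param seed integer seed; output is bit-identical given the seed.
#' @param grid a [ring_grid()].
#' @param peak_km,peak_prop location (km) and height of the mean profile
#'   peak.
#' @param site_sd,year_sd,ring_sd logit-scale noise SDs.
#' @param tilt_sd SD of the per-site-year logit-scale tilt across distance
#'   (a random slope from inner to outer rings).  The tilt decorrelates
#'   near-field and far-field cover, the feature of real landscapes that
#'   makes the kernel scale estimable.
#' @param year_share share of drought-index variance from the common year
#'   component.
#' @param mode `"rings"` draws proportions directly at the ring level;
#'   `"raster"` draws per-site rasters first.
#' @param cellsize raster cell size in m (raster mode).
#' @return list with `rings` (a [ring_covariates()]), `spei` (data frame
#'   `site`, `year`, `spei06`), and the configuration used.
#' @export
simulate_landscape <- function(n_sites, n_years, seed, grid = ring_grid(),
                               peak_km = 0.6, peak_prop = 0.5,
                               site_sd = 0.6, year_sd = 0.3, ring_sd = 0.15,
                               tilt_sd = 0.6, year_share = 0.5,
                               mode = c("rings", "raster"), cellsize = 50) {
  mode <- match.arg(mode)
  set.seed(seed)
  d <- grid$midpoints
  shp <- 1.6
  prof <- peak_prop * (d / peak_km)^shp * exp(shp * (1 - d / peak_km)) +
    0.12 * exp(-((d - 5) / 4)^2)
  prof <- pmin(pmax(prof, 0.02), 0.95)
  sites <- sprintf("S%02d", seq_len(n_sites))
  years <- as.character(2000 + seq_len(n_years))
  raw <- array(NA_real_, c(n_sites, n_years, length(d)),
               dimnames = list(sites, years, NULL))
  site_eff <- stats::rnorm(n_sites, 0, site_sd)
  site_tilt <- stats::rnorm(n_sites, 0, tilt_sd)
  dctr <- (d - mean(d)) / (max(d) - min(d))   # -0.5 .. 0.5 across rings
  for (s in seq_len(n_sites)) for (t in seq_len(n_years)) {
    shift <- site_eff[s] + stats::rnorm(1, 0, year_sd)
    tilt <- site_tilt[s] + stats::rnorm(1, 0, tilt_sd)
    lp <- stats::qlogis(prof) + shift + tilt * dctr
    if (mode == "rings") {
      raw[s, t, ] <- stats::plogis(lp + stats::rnorm(length(d), 0, ring_sd))
    } else {
      raw[s, t, ] <- simulate_site_raster_rings(stats::plogis(lp), 0, grid,
                                                cellsize)
    }
  }
  spei_year <- stats::rnorm(n_years, 0, sqrt(year_share))
  spei <- expand.grid(site = sites, year = as.integer(years),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  spei$spei06 <- spei_year[match(as.character(spei$year), years)] +
    stats::rnorm(nrow(spei), 0, sqrt(1 - year_share))
  list(rings = ring_covariates(raw, grid), spei = spei,
       config = list(peak_km = peak_km, peak_prop = peak_prop,
                     site_sd = site_sd, year_sd = year_sd,
                     ring_sd = ring_sd, tilt_sd = tilt_sd,
                     year_share = year_share, mode = mode, seed = seed))
}

## one site-year in raster mode: draw a binary raster from the radial
## probability profile, then run the standard extraction
simulate_site_raster_rings <- function(prob_prof, shift, grid, cellsize) {
  max_m <- max(grid$edges) * 1000
  n <- ceiling(2 * max_m / cellsize) + 2
  ctr <- n * cellsize / 2
  cx <- (seq_len(n) - 0.5) * cellsize
  dist_km <- sqrt(outer((cx - ctr)^2, (cx - ctr)^2, "+")) / 1000
  pr <- stats::approx(grid$midpoints,
                      stats::plogis(stats::qlogis(prob_prof) + shift),
                      xout = pmin(dist_km, max(grid$midpoints)),
                      rule = 2)$y
  ras <- matrix(stats::rbinom(n * n, 1, pr), n, n)
  out <- extract_ring_proportions(ras, cbind(ctr, ctr), cellsize,
                                  grid = grid, partial = "flag")
  as.numeric(out)
}

#' Simulate a complete capture-mark-recapture study with known truth
#'
#' Generates landscapes, individuals, growth, survival, availability and
#' daily detections from the generating model, then conditions on first
#' capture when exporting: sizes start from sex-specific distributions at a
#' uniformly drawn entry year, evolve by the von Bertalanffy chain, annual
#' survival follows the logit-linear model with the chosen size-survival
#' shape, availability is an independent Bernoulli per individual-year, and
#' detections are daily Bernoulli draws with nested site/year/day effects.
#' Only individuals detected at least once appear in the exported capture
#' table; every latent quantity is kept in the truth record.
#'
#' @param design a [study_design()].
#' @param truth a [default_truth()] list.
#' @param shape size-survival shape name (see [size_survival_shape()]).
#' @param seed integer master seed.
#' @param landscape optional result of [simulate_landscape()]; generated
#'   from the seed when omitted.
#' @return list of class `gs_simulation` with `captures`, `effort`,
#'   `rings`, `spei`, `histories` (a ready `cmr_data`), `intervals`
#'   (consecutive-year growth pairs), and `truth` (a `truth_record`).
#' @export
simulate_study <- function(design = study_design(), truth = default_truth(),
                           shape = c("quadratic", "independent", "linear",
                                     "asymptotic"),
                           seed, landscape = NULL) {
  shape <- match.arg(shape)
  if (is.null(landscape))
    landscape <- simulate_landscape(design$n_sites, design$n_years,
                                    seed = seed + 101L)
  rings <- landscape$rings; spei <- landscape$spei
  ns <- design$n_sites; nyr <- design$n_years; npop <- design$n_pop
  grid <- rings$grid
  spei_m <- spei_matrix(spei, rings)
  set.seed(seed)
  fshape <- size_survival_shape(shape, truth$shape_amplitude)
  wk <- kernel_weights(truth$sigma_rice_k, grid)
  wp <- kernel_weights(truth$sigma_rice_phi, grid)
  Rwk <- apply(rings$standardized, 1:2, function(x) sum(wk * x))
  Rwp <- apply(rings$standardized, 1:2, function(x) sum(wp * x))

  sex <- ifelse(stats::runif(npop) < design$sex_ratio, 1L, 2L)
  site <- sample.int(ns, npop, replace = TRUE)
  entry <- sample.int(nyr, npop, replace = TRUE)
  ## random effects
  rho <- stats::rnorm(ns, 0, truth$sd_phis)
  eta <- matrix(stats::rnorm(ns * nyr, rho, truth$sd_phit), ns, nyr)
  ups <- stats::rnorm(ns, 0, truth$sd_ps)
  delta <- matrix(stats::rnorm(ns * nyr, ups, truth$sd_pt), ns, nyr)
  maxday <- max(design$n_days)
  xi <- array(stats::rnorm(ns * nyr * maxday, rep(delta, maxday),
                           truth$sd_day), c(ns, nyr, maxday))
  sgt <- stats::rnorm(nyr, 0, truth$sd_gt)
  lam <- matrix(stats::rnorm(2 * ns, 0, truth$sd_sa), 2, ns)
  alk <- matrix(stats::rnorm(2 * ns, 0, truth$sd_sk), 2, ns)
  zek <- stats::rnorm(nyr, 0, truth$sd_tk)
  iok <- stats::rnorm(npop, 0, truth$sd_ik)

  L <- matrix(NA_real_, npop, nyr)
  z <- matrix(0L, npop, nyr)
  avail <- matrix(0L, npop, nyr)
  Y <- array(0L, c(npop, nyr, maxday))
  L0 <- stats::rnorm(npop, truth$init_size_mean[sex],
                     truth$init_size_sd[sex])
  L0 <- pmin(pmax(L0, truth$init_size_range[1]), truth$init_size_range[2])
  for (i in seq_len(npop)) L[i, entry[i]] <- L0[i]
  z[cbind(seq_len(npop), entry)] <- 1L
  phi_true <- matrix(NA_real_, npop, nyr)

  for (t in seq_len(nyr)) {
    act <- which(z[, t] == 1L & entry <= t)
    if (length(act)) {
      gam <- stats::plogis(stats::qlogis(truth$gamma_sex[sex[act]]) + sgt[t])
      avail[act, t] <- stats::rbinom(length(act), 1L, gam)
      pres <- act[avail[act, t] == 1L]
      for (i in pres) {
        nd <- design$n_days[site[i], t]
        pd <- stats::plogis(stats::qlogis(truth$p_sex[sex[i]]) +
                            xi[site[i], t, seq_len(nd)])
        Y[i, t, seq_len(nd)] <- stats::rbinom(nd, 1L, pd)
      }
    }
    if (t < nyr && length(act)) {
      lp <- stats::qlogis(truth$phi_sex[sex[act]]) +
        truth$theta_rice * Rwp[cbind(site[act], t)] +
        truth$theta_drought * spei_m[cbind(site[act], t)] +
        fshape(L[cbind(act, rep(t, length(act)))]) +
        eta[cbind(site[act], rep(t, length(act)))]
      phi_true[act, t] <- stats::plogis(lp)
      z[act, t + 1L] <- stats::rbinom(length(act), 1L, phi_true[act, t])
      k <- exp(truth$mu_k[sex[act]] +
               truth$beta_rice * Rwk[cbind(site[act], t)] +
               truth$beta_drought * spei_m[cbind(site[act], t)] +
               alk[cbind(sex[act], site[act])] + zek[t] + iok[act])
      a <- truth$eps_a[sex[act]] + lam[cbind(sex[act], site[act])]
      el <- expected_length(pmax(a, 200), k, L[cbind(act, rep(t, length(act)))])
      L[act, t + 1L] <- pmax(stats::rnorm(length(act), el, truth$sd_err), 120)
    }
  }
  ## export: condition on first capture
  det_year <- apply(Y, 1:2, max)
  seen <- which(rowSums(det_year) > 0L)
  sites <- rings$sites; years <- as.integer(rings$years)
  ## synthetic calendar: effort days are consecutive dates from 1 June
  effort <- do.call(rbind, lapply(seq_len(ns), function(s)
    do.call(rbind, lapply(seq_len(nyr), function(t) {
      nd <- design$n_days[s, t]
      data.frame(site = sites[s], year = years[t],
                 date = as.Date(sprintf("%d-06-01", years[t])) +
                   seq_len(nd) - 1L,
                 stringsAsFactors = FALSE)
    }))))
  effort <- read_effort(effort)
  caps <- do.call(rbind, lapply(seen, function(i) {
    hits <- which(Y[i, , ] == 1L, arr.ind = TRUE)
    data.frame(individual_id = sprintf("ind%05d", i),
               site = sites[site[i]],
               date = as.Date(sprintf("%d-06-01", years[hits[, 1]])) +
                 hits[, 2] - 1L,
               sex = c("F", "M")[sex[i]],
               svl_mm = round(L[i, hits[, 1]], 1),
               stringsAsFactors = FALSE)
  }))
  caps <- caps[order(caps$individual_id, caps$date), , drop = FALSE]
  captures <- read_captures(caps)
  histories <- build_capture_histories(captures, effort)
  intervals <- assemble_growth_intervals(captures)
  truth_rec <- structure(
    list(params = truth, shape = shape, design = design, seed = seed,
         landscape_config = landscape$config,
         Rw_k = Rwk, Rw_phi = Rwp,
         latent = list(z = z, avail = avail, L = L, entry = entry,
                       sex = sex, site = site, phi = phi_true,
                       seen = seen),
         effects = list(rho = rho, eta = eta, ups = ups, delta = delta,
                        xi = xi, sgt = sgt, lam = lam, alk = alk,
                        zek = zek, iok = iok)),
    class = "truth_record")
  structure(list(captures = captures, effort = effort, rings = rings,
                 spei = spei, histories = histories, intervals = intervals,
                 truth = truth_rec),
            class = "gs_simulation")
}

#' @export
print.gs_simulation <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study: %d observed individuals ",
                     "(%d simulated), %d sites, %d years, %d growth ",
                     "intervals\n"),
              x$histories$counts$individuals, x$truth$design$n_pop,
              length(x$histories$sites), length(x$histories$years),
              nrow(x$intervals)))
  invisible(x)
}

#' Simulate a consecutive-year growth dataset with known truth
#'
#' A lighter generator for growth-only studies: draws intervals directly
#' (site, year, sex, start length) and generates end-of-year lengths from
#' the growth model, bypassing the capture process.
#'
#' @param n_intervals number of growth intervals.
#' @param design a [study_design()] (only sites/years used).
#' @param truth a [default_truth()] list.
#' @param seed integer seed.
#' @param landscape optional [simulate_landscape()] result.
#' @return list with `intervals`, `rings`, `spei`, `truth`.
#' @export
simulate_growth_study <- function(n_intervals = 260,
                                  design = study_design(),
                                  truth = default_truth(), seed,
                                  landscape = NULL) {
  if (is.null(landscape))
    landscape <- simulate_landscape(design$n_sites, design$n_years,
                                    seed = seed + 101L)
  rings <- landscape$rings; spei <- landscape$spei
  set.seed(seed)
  ns <- design$n_sites; nyr <- design$n_years
  spei_m <- spei_matrix(spei, rings)
  wk <- kernel_weights(truth$sigma_rice_k, rings$grid)
  Rwk <- apply(rings$standardized, 1:2, function(x) sum(wk * x))
  ## ~15% of individuals contribute two intervals, as repeat recaptures do
  n_ind <- ceiling(n_intervals / 1.15)
  ind <- c(seq_len(n_ind), sample.int(n_ind, n_intervals - n_ind, TRUE))
  sex <- ifelse(stats::runif(n_ind) < design$sex_ratio, 1L, 2L)[ind]
  site <- sample.int(ns, n_ind, TRUE)[ind]
  year <- sample.int(nyr - 1L, n_intervals, TRUE)
  iok <- stats::rnorm(n_ind, 0, truth$sd_ik)[ind]
  lam <- matrix(stats::rnorm(2 * ns, 0, truth$sd_sa), 2, ns)
  alk <- matrix(stats::rnorm(2 * ns, 0, truth$sd_sk), 2, ns)
  zek <- stats::rnorm(nyr, 0, truth$sd_tk)
  L0 <- stats::rnorm(n_intervals, truth$init_size_mean[sex],
                     truth$init_size_sd[sex])
  L0 <- pmin(pmax(L0, truth$init_size_range[1]), truth$init_size_range[2])
  a <- pmax(truth$eps_a[sex] + lam[cbind(sex, site)], 200)
  k <- exp(truth$mu_k[sex] + truth$beta_rice * Rwk[cbind(site, year)] +
           truth$beta_drought * spei_m[cbind(site, year)] +
           alk[cbind(sex, site)] + zek[year] + iok)
  L1 <- stats::rnorm(n_intervals, expected_length(a, k, L0), truth$sd_err)
  intervals <- data.frame(
    individual_id = sprintf("ind%05d", ind),
    sex = c("F", "M")[sex], site = rings$sites[site],
    year = as.integer(rings$years)[year],
    L0 = L0, L1 = L1, dt = 1, stringsAsFactors = FALSE)
  class(intervals) <- c("growth_intervals", class(intervals))
  list(intervals = intervals, rings = rings, spei = spei,
       truth = structure(list(params = truth, design = design, seed = seed,
                              Rw_k = Rwk),
                         class = "truth_record"))
}

#' Export a synthetic study to CSV files plus a truth JSON
#'
#' Writes the exact schemas consumed by the readers: `captures.csv`,
#' `effort.csv`, `rings.csv`, `spei.csv`, and `truth.json` (generating
#' parameter values, design and seed; latent trajectories are omitted from
#' the JSON for size).
#'
#' @param sim a `gs_simulation` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(sim$captures)[
    c("individual_id", "site", "date", "sex", "svl_mm")],
    file.path(dir, "captures.csv"), row.names = FALSE)
  utils::write.csv(sim$effort[c("site", "year", "date")],
                   file.path(dir, "effort.csv"), row.names = FALSE)
  write_rings(sim$rings, file.path(dir, "rings.csv"))
  utils::write.csv(sim$spei, file.path(dir, "spei.csv"), row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(
    list(params = unclass(tr$params), shape = tr$shape, seed = tr$seed,
         design = list(n_sites = tr$design$n_sites,
                       n_years = tr$design$n_years,
                       n_pop = tr$design$n_pop)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
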