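test_that("capture histories respect the effort mask", {
  rec <- read_captures(tiny_captures())
  eff <- read_effort(tiny_effort())
  h <- build_capture_histories(rec, eff)
  expect_s3_class(h, "cmr_data")
  expect_equal(h$counts$individuals, 3)
  ## detections never outside effort
  for (s in seq_along(h$sites)) {
    ids <- which(h$site == s)
    for (t in seq_along(h$years))
      expect_true(all(h$y[ids, t, ] <= h$day_mask[s, t, ]))
  }
  ## a1 captured 2018 and 2019: one between-year recapture at lag 1;
  ## a3 captured 2018, 2019, 2021: lags 1 and 3
  expect_equal(h$counts$recaptures_between_years, 3)
  expect_equal(as.numeric(h$counts$by_lag[c("1", "3")]), c(2, 1))
  ## every capture appears in the daily indicator (within-year included)
  expect_equal(sum(h$y), 6)
  ## capture on an unsampled day errors
  bad <- tiny_captures(); bad$date[1] <- "2018-08-20"
  expect_error(build_capture_histories(read_captures(bad), eff),
               "not a sampled effort day")
})

test_that("size observations land on the first yearly measurement", {
  df <- tiny_captures()
  df <- rbind(df, data.frame(individual_id = "a1", site = "S1",
                             date = "2018-06-05", sex = "F", svl_mm = 520))
  h <- build_capture_histories(read_captures(df), read_effort(tiny_effort()))
  expect_equal(h$svl_obs[1, 1], 500)      # first 2018 measurement, not 520
})

test_that("marginal likelihood matches exhaustive latent-state enumeration", {
  set.seed(99)
  for (rep in 1:12) {
    nind <- sample(1:4, 1); nyear <- sample(2:3, 1); nday <- sample(1:3, 1)
    y <- array(0L, c(nind, nyear, nday))
    first <- integer(nind); fday <- integer(nind)
    for (i in seq_len(nind)) {
      first[i] <- sample(seq_len(nyear), 1)
      fday[i] <- sample(seq_len(nday), 1)
      y[i, first[i], fday[i]] <- 1L
      ## random later detections
      if (first[i] < nyear) for (t in (first[i] + 1):nyear)
        y[i, t, ] <- rbinom(nday, 1, 0.3)
    }
    phi <- matrix(runif(nind * (nyear - 1), 0.2, 0.9), nind)
    gam <- matrix(runif(nind * nyear, 0.3, 0.9), nind)
    p <- matrix(runif(nyear * nday, 0.1, 0.6), nyear)
    got <- joint_marginal_loglik(y, first, fday, phi, gam, p)
    oracle <- enum_marginal_loglik(y, first, fday, phi, gam, p)
    expect_equal(got, oracle, tolerance = 1e-8)
  }
})

test_that("marginal likelihood honors hand-computed and degenerate cases", {
  ## one individual, detected year 1 day 1, never again; 1 day per year
  y <- array(0L, c(1, 2, 1)); y[1, 1, 1] <- 1L
  got <- joint_marginal_loglik(y, first = 1L, first_day = 1L,
                               phi = 0.5, gamma = 0.5, p = 0.5)
  ## survivor present-and-missed, survivor absent, or dead:
  ## 0.5*0.5*0.5 + 0.5*0.5 + 0.5 = 0.875
  expect_equal(got, log(0.875), tolerance = 1e-12)

  ## p = 1: an alive and available individual must be detected
  y2 <- array(0L, c(1, 2, 1)); y2[1, 1, 1] <- 1L
  ll <- joint_marginal_loglik(y2, 1L, 1L, phi = 1, gamma = 1, p = 1)
  expect_equal(ll, -Inf)  # no detection in year 2 is impossible

  ## phi = 0: detection after the first year has probability zero
  y3 <- array(0L, c(1, 2, 1)); y3[1, 1, 1] <- 1L; y3[1, 2, 1] <- 1L
  expect_equal(joint_marginal_loglik(y3, 1L, 1L, 0, 0.5, 0.5), -Inf)

  ## instance-size guard
  expect_error(joint_marginal_loglik(array(0L, c(5, 2, 2)), rep(1L, 5),
                                     rep(1L, 5), 0.5, 0.5, 0.5),
               "too large")
})

test_that("survival probability is a monotone inverse-logit", {
  expect_equal(survival_prob(0), 0.5)
  ## linearity on the logit scale: one covariate SD moves the logit by theta
  base <- survival_prob(0.2, theta_rice = 0.33, R_w = 0)
  up <- survival_prob(0.2, theta_rice = 0.33, R_w = 1)
  expect_equal(qlogis(up) - qlogis(base), 0.33, tolerance = 1e-12)
  rw <- seq(-3, 3, 0.5)
  expect_true(all(diff(survival_prob(0, 0.33, rw)) > 0))
})

test_that("cumulative annual recapture follows the closed form", {
  expect_equal(annual_recapture(0, 10), 0)
  expect_equal(annual_recapture(0.3, 1), 0.3)
  expect_equal(annual_recapture(0.03, 21), 0.4725195, tolerance = 1e-6)
  ## never decreasing in effort
  ps <- annual_recapture(0.05, 0:40)
  expect_true(all(diff(ps) >= 0))
  expect_error(annual_recapture(1.2, 5), "must be in")
})

test_that("spline basis is a partition of unity and matches Cox-de Boor", {
  x <- seq(150, 1100, by = 25)
  B <- spline_basis(x, n_knots = 5, center = FALSE)
  expect_true(all(abs(rowSums(B) - 1) < 1e-9))
  Bc <- spline_basis(x, n_knots = 5, center = TRUE)
  expect_true(all(abs(colMeans(Bc)) < 1e-12))
  ## independent Cox-de Boor recursion at interior points
  kn <- attr(B, "knots"); bd <- attr(B, "boundary")
  full <- c(rep(bd[1], 4), kn, rep(bd[2], 4))
  for (xx in c(300, 612.5, 987.5)) {
    oracle <- vapply(seq_len(ncol(B)), function(i)
      coxdeboor(xx, full, i, 3), numeric(1))
    got <- spline_basis(xx, knots_from = x, n_knots = 5, center = FALSE)
    expect_equal(as.numeric(got), oracle, tolerance = 1e-9)
  }
  expect_error(spline_basis(rep(500, 10), n_knots = 5), "distinct")
})

test_that("integrated fit runs, converges on its monitors, and is reproducible", {
  des <- study_design(n_sites = 5, n_years = 4, n_days = 10, n_pop = 220)
  sim <- simulate_study(des, default_truth(p_sex = c(0.07, 0.06)),
                        shape = "independent", seed = 77)
  fit <- suppressWarnings(
    fit_cmr(sim$histories, sim$rings, sim$spei, mcmc = test_mcmc(500),
            seed = 5, gof = TRUE))
  s <- fit$summary
  expect_true(all(c("phisex[1]", "psex[2]", "th_rice", "sig_rice_phi",
                    "gamsex[1]", "b_rice", "eps_a[1]") %in% s$parameter))
  expect_true(all(is.finite(s$mean)))
  probs <- s[grepl("^(phisex|psex|gamsex)", s$parameter), ]
  expect_true(all(probs$q2.5 >= 0 & probs$q97.5 <= 1))
  ## derived scales and sex contrasts present
  sc <- fit$scales_phi$draws
  expect_true(all(sc$scale_max[sc$sigma <= 9] <= sc$scale_90[sc$sigma <= 9]))
  expect_true(all(fit$sex_contrasts >= 0 & fit$sex_contrasts <= 1))
  ft <- freeman_tukey_gof(fit, seed = 2)
  expect_true(ft$p_value >= 0 && ft$p_value <= 1)
  ## determinism contract
  fit2 <- suppressWarnings(
    fit_cmr(sim$histories, sim$rings, sim$spei, mcmc = test_mcmc(500),
            seed = 5, gof = TRUE))
  expect_identical(fit$draws, fit2$draws)
  ## posterior annual recapture: both averaging variants exposed
  p1 <- annual_recapture_draws(fit, 21)
  p2 <- annual_recapture_draws(fit, 21, include_random_effects = TRUE,
                               seed = 3)
  expect_true(p1$summary$mean >= 0 && p1$summary$mean <= 1)
  expect_true(p2$summary$mean >= 0 && p2$summary$mean <= 1)
})
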