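test_that("growth intervals use first yearly measurements of consecutive years", {
  rec <- read_captures(tiny_captures())
  iv <- assemble_growth_intervals(rec)
  ## a1: 2018 -> 2019 qualifies; a3: 2018 -> 2019 qualifies, 2019 -> 2021 does
  ## not (two-year gap); a2 has a single capture
  expect_equal(nrow(iv), 2)
  expect_setequal(iv$individual_id, c("a1", "a3"))
  expect_equal(iv$L0[iv$individual_id == "a1"], 500)
  expect_equal(iv$L1[iv$individual_id == "a1"], 560)
  expect_true(all(iv$dt == 1))

  ## within-year recaptures: only the first measurement of a year is used
  df <- tiny_captures()
  df <- rbind(df, data.frame(individual_id = "a1", site = "S1",
                             date = "2018-07-15", sex = "F", svl_mm = 540))
  iv2 <- assemble_growth_intervals(read_captures(df))
  expect_equal(iv2$L0[iv2$individual_id == "a1"], 500)

  ## unknown sex excluded by default, kept on request
  df$sex[df$individual_id == "a1"] <- "U"
  iv3 <- assemble_growth_intervals(read_captures(df))
  expect_false("a1" %in% iv3$individual_id)
  iv4 <- assemble_growth_intervals(read_captures(df),
                                   include_unknown_sex = TRUE)
  expect_true("a1" %in% iv4$individual_id)

  ## site fidelity violation
  df2 <- tiny_captures(); df2$site[2] <- "S9"
  expect_error(assemble_growth_intervals(read_captures(df2)),
               "more than one site")
})

test_that("von Bertalanffy expectation behaves at its limits", {
  expect_equal(expected_length(800, 100, 800), 800)      # fixed point
  expect_equal(expected_length(800, 0, 500), 500)        # no growth
  expect_equal(expected_length(800, 120, 500, dt = 0), 500)
  ## frozen scalar evaluation at field-realistic parameter values
  expect_equal(expected_length(881.43, exp(5.66), 500), 606.050139,
               tolerance = 1e-6)
  ## EL strictly between L_prev and the asymptote, monotone in dt
  el1 <- expected_length(800, 150, 400, dt = 1)
  el2 <- expected_length(800, 150, 400, dt = 2)
  expect_true(el1 > 400 && el1 < 800)
  expect_true(el2 > el1)
  expect_equal(expected_length(800, 150, 400, dt = 1e6), 800,
               tolerance = 1e-6)
  expect_error(expected_length(-5, 100, 400), "positive")
  expect_error(expected_length(800, -1, 400), "nonnegative")
})

test_that("growth coefficient is log-linear and monotone in the covariate", {
  expect_equal(growth_rate(5.66), exp(5.66))
  expect_equal(growth_rate(5.66, beta_rice = 0.34, R_w = 1), exp(6.00))
  rw <- seq(-2, 2, by = 0.5)
  k <- growth_rate(5.66, beta_rice = 0.34, R_w = rw)
  expect_true(all(diff(k) > 0))
  expect_true(all(k > 0))
})

test_that("log joint density matches an independently coded normal sum", {
  ## three-interval toy dataset, fixed parameter values
  iv <- data.frame(individual_id = c("x", "y", "z"), sex = "F", site = "S1",
                   year = 2018L, L0 = c(400, 550, 700),
                   L1 = c(470, 600, 720), dt = 1)
  a <- c(880, 880, 910); k <- c(250, 180, 120); s_err <- 25
  got <- growth_loglik(iv, a, k, s_err)
  ## oracle: hand-coded density formula, no shared helpers
  oracle <- 0
  for (i in 1:3) {
    el <- a[i] - (a[i] - iv$L0[i]) * exp(-k[i] / a[i] * iv$dt[i])
    oracle <- oracle + (-0.5 * log(2 * pi) - log(s_err) -
                        (iv$L1[i] - el)^2 / (2 * s_err^2))
  }
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("prior-only growth fit recovers the prior on the rice effect", {
  land <- simulate_landscape(3, 2, seed = 9)
  empty <- assemble_growth_intervals(read_captures(tiny_captures())[0, ])
  fit <- fit_growth(empty, land$rings, land$spei,
                    mcmc = test_mcmc(1500), seed = 4, gof = FALSE)
  b <- fit$draws[, "b_rice"]
  expect_lt(abs(mean(b)), 1.5)          # prior mean 0, SD 10
  expect_gt(sd(b), 7); expect_lt(sd(b), 13)
  sig <- fit$draws[, "sig_rice"]
  expect_gt(min(sig), 0.01); expect_lt(max(sig), 10)
})

test_that("growth fit recovers parameters and is seed-reproducible", {
  des <- study_design(n_sites = 8, n_years = 4)
  gs <- simulate_growth_study(180, des, default_truth(), seed = 21)
  fit <- suppressWarnings(fit_growth(gs$intervals, gs$rings, gs$spei,
                                     mcmc = test_mcmc(800), seed = 7))
  s <- fit$summary
  get <- function(p) s[s$parameter == p, ]
  ## asymptotes are well identified even in a small study
  expect_lt(abs(get("eps_a[1]")$mean - 881), 80)
  expect_lt(abs(get("eps_a[2]")$mean - 645), 60)
  expect_true(get("sd_err")$q2.5 < 26.2 && get("sd_err")$q97.5 > 26.2)
  ## derived spatial scales respect their definitions (interior mode)
  sc <- fit$scales$draws
  expect_true(all(sc$scale_max[sc$sigma <= 9] <= sc$scale_90[sc$sigma <= 9]))
  ## bit reproducibility given seed and config
  fit2 <- suppressWarnings(fit_growth(gs$intervals, gs$rings, gs$spei,
                                      mcmc = test_mcmc(800), seed = 7))
  expect_identical(fit$draws, fit2$draws)
})

test_that("RSS posterior-predictive check flags corrupted lengths", {
  des <- study_design(n_sites = 6, n_years = 4)
  gs <- simulate_growth_study(150, des, default_truth(), seed = 31)
  fit <- suppressWarnings(fit_growth(gs$intervals, gs$rings, gs$spei,
                                     mcmc = test_mcmc(800), seed = 8))
  g <- growth_gof(fit, seed = 1)
  expect_true(g$p_value >= 0 && g$p_value <= 1)
  ## well-specified data should not look extreme
  expect_gt(g$p_value, 0.02); expect_lt(g$p_value, 0.98)
  ## gross misspecification probe: shift every observed length by +200 mm
  fit_bad <- fit
  fit_bad$intervals$L1 <- fit_bad$intervals$L1 + 200
  expect_lt(growth_gof(fit_bad, seed = 1)$p_value, 0.01)
})

test_that("latent-sex mode accepts unknown-sex intervals", {
  land <- simulate_landscape(4, 3, seed = 19)
  gs <- simulate_growth_study(60, study_design(4, 3), seed = 23,
                              landscape = land)
  iv <- gs$intervals
  iv$sex[1:8] <- "U"
  expect_error(fit_growth(iv, gs$rings, gs$spei, mcmc = test_mcmc(200),
                          seed = 2), "latent_sex")
  fit <- suppressWarnings(fit_growth(iv, gs$rings, gs$spei,
                                     mcmc = test_mcmc(300), seed = 2,
                                     gof = FALSE, latent_sex = TRUE))
  expect_true(all(is.finite(fit$summary$mean)))
})
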