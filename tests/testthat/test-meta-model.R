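test_that("posterior medians recover simulated coefficients within their own intervals", {
  obs <- simulate_experiments(n_studies = 60, beta0 = 6.0, beta1 = -0.30,
                              resid_scale = 0.4, sigma_d = 0.2,
                              sigma_c = 0.2, seed = 101)
  fit <- fit_meta_model(obs, mcmc = quick_mcmc(seed = 5))
  s <- posterior_summary(fit)
  b0 <- s[s$parameter == "beta0", ]
  b1 <- s[s$parameter == "beta1", ]
  expect_true(b0$lo < 6.0 && 6.0 < b0$hi)
  expect_true(b1$lo < -0.30 && -0.30 < b1$hi)
  expect_true(all(fit$diagnostics$ess > 100))
})

test_that("with vanishing measurement error the posterior concentrates on OLS", {
  set.seed(21)
  n <- 50
  diet <- runif(n, 0, 20)
  disc <- 5.5 - 0.25 * diet + rnorm(n, 0, 0.5)
  obs <- experiment_observations(data.frame(
    study_id = paste0("s", 1:n), diet_d15n = diet, diet_sigma = 0,
    consumer_d15n = diet + disc, consumer_sigma = 0))
  fit <- fit_meta_model(obs, mcmc = quick_mcmc(seed = 2))
  ols <- ols_delta_fit(obs)
  s <- posterior_summary(fit)
  expect_equal(s$median[s$parameter == "beta0"], ols[1], tolerance = 0.02)
  expect_equal(s$median[s$parameter == "beta1"], ols[2], tolerance = 0.02)
})

test_that("latent-state model corrects measurement-error attenuation of the slope", {
  # heavy diet-side error attenuates the naive slope towards zero; the
  # latent-state fit should undo (at least not worsen) that shrinkage
  obs <- simulate_experiments(n_studies = 80, beta0 = 6, beta1 = -0.3,
                              resid_scale = 0.2, sigma_d = 2.5,
                              sigma_c = 0.2, seed = 31)
  # with sigma_d >> resid_scale the residual scale is weakly identified and
  # its chain mixes slowly; the slope behaviour under test is unaffected, so
  # the convergence warning for that nuisance parameter is expected here
  suppressWarnings(
    fit <- fit_meta_model(obs, mcmc = quick_mcmc(seed = 3, n_iter = 20000,
                                                 burn = 6000, thin = 4)))
  naive_slope <- ols_delta_fit(obs)[2]
  post_slope <- posterior_summary(fit)$median[2]
  expect_gte(abs(post_slope), abs(naive_slope) - 0.01)
})

test_that("fits are bit-reproducible and insensitive to study order", {
  obs <- simulate_experiments(n_studies = 30, seed = 41)
  f1 <- fit_meta_model(obs, mcmc = quick_mcmc(seed = 9))
  f2 <- fit_meta_model(obs, mcmc = quick_mcmc(seed = 9))
  expect_identical(posterior_summary(f1), posterior_summary(f2))

  set.seed(1)
  perm <- sample(nrow(obs))
  f3 <- fit_meta_model(obs[perm, ], mcmc = quick_mcmc(seed = 9))
  s1 <- posterior_summary(f1)
  s3 <- posterior_summary(f3)
  expect_equal(s1$median, s3$median, tolerance = 0.05)
})

test_that("degenerate inputs are rejected", {
  obs <- simulate_experiments(n_studies = 5, seed = 1)
  expect_error(fit_meta_model(obs[1:2, ]), "at least 3")
  expect_error(experiment_observations(data.frame(
    study_id = "a", diet_d15n = 1, diet_sigma = -0.1,
    consumer_d15n = 5, consumer_sigma = 0.2)), "negative")
})

test_that("posterior summaries match order-statistics expectations", {
  const <- data.frame(x = rep(3.2, 40))
  s <- posterior_summary(const)
  expect_equal(s$median, 3.2)
  expect_equal(s$lo, 3.2)
  expect_equal(s$hi, 3.2)

  # type-7 interpolation at p = 0.025/0.975 on 1..100: 1 + 0.025*99 = 3.475
  s <- posterior_summary(data.frame(x = 1:100), level = 0.95)
  expect_equal(s$median, 50.5)
  expect_equal(s$lo, 3.475)
  expect_equal(s$hi, 97.525)

  # HPD interval is never wider than the central one, here on skewed draws
  set.seed(8)
  skewed <- data.frame(x = exp(rnorm(5000)))
  cen <- posterior_summary(skewed, type = "central")
  hpd <- posterior_summary(skewed, type = "hpd")
  expect_lte(hpd$hi - hpd$lo, cen$hi - cen$lo)

  expect_error(posterior_summary(data.frame(x = numeric(0))), "empty")
})

test_that("credible intervals achieve close-to-nominal coverage", {
  reps <- 12
  hits <- c(beta0 = 0, beta1 = 0)
  for (r in seq_len(reps)) {
    obs <- simulate_experiments(n_studies = 40, seed = 500 + r)
    fit <- fit_meta_model(obs, mcmc = mcmc_control(2500, 800, thin = 1,
                                                   chains = 2,
                                                   seed = 600 + r))
    s <- posterior_summary(fit)
    hits["beta0"] <- hits["beta0"] + (s$lo[1] < 5.92 && 5.92 < s$hi[1])
    hits["beta1"] <- hits["beta1"] + (s$lo[2] < -0.27 && -0.27 < s$hi[2])
  }
  # 95% nominal; allow two misses in twelve
  expect_gte(hits[["beta0"]], reps - 2)
  expect_gte(hits[["beta1"]], reps - 2)
})

test_that("an independent JAGS fit of the same model agrees", {
  obs <- simulate_experiments(n_studies = 40, seed = 77)
  fit <- fit_meta_model(obs, mcmc = quick_mcmc(seed = 7, n_iter = 5000,
                                               burn = 2000))

  model_str <- "
  model {
    for (i in 1:n) {
      d_obs[i] ~ dnorm(theta_d[i], 1 / (sd_d[i]^2))
      c_obs[i] ~ dnorm(theta_c[i], 1 / (sd_c[i]^2))
      theta_c[i] ~ dnorm(theta_d[i] + beta0 + beta1 * theta_d[i], tau_prec)
      theta_d[i] ~ dnorm(d_anchor[i], 0.01)
    }
    beta0 ~ dnorm(0, 0.01)
    beta1 ~ dnorm(0, 0.01)
    tau ~ dt(0, 1 / 25, 1) T(0, )
    tau_prec <- 1 / (tau^2)
  }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(n = nrow(obs), d_obs = obs$diet_d15n,
                                      d_anchor = obs$diet_d15n,
                                      c_obs = obs$consumer_d15n,
                                      sd_d = obs$diet_sigma,
                                      sd_c = obs$consumer_sigma),
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 7),
                          n.chains = 1, quiet = TRUE)
  update(jm, 2000, progress.bar = "none")
  jdraws <- rjags::coda.samples(jm, c("beta0", "beta1", "tau"), 6000,
                                progress.bar = "none")[[1]]
  s <- posterior_summary(fit)
  expect_equal(s$median[s$parameter == "beta0"],
               unname(median(jdraws[, "beta0"])), tolerance = 0.1)
  expect_equal(s$median[s$parameter == "beta1"],
               unname(median(jdraws[, "beta1"])), tolerance = 0.02)
  expect_equal(s$median[s$parameter == "resid_scale"],
               unname(median(jdraws[, "tau"])), tolerance = 0.1)
})

test_that("covariate comparison prefers the true model structure", {
  cfg_mcmc <- quick_mcmc(seed = 13, n_iter = 2500, burn = 800)

  # no true covariate effect: basic model preferred or within a few units
  obs0 <- simulate_experiments(n_studies = 59, seed = 201)
  cmp0 <- compare_covariate_models(obs0, list("diet_source"),
                                   mcmc = cfg_mcmc)
  expect_identical(cmp0$model, c("basic", "+diet_source"))
  expect_equal(cmp0$delta_aic[1], 0)
  expect_equal(cmp0$delta_waic[1], 0)
  expect_gte(cmp0$delta_aic[2], -2)

  # strong (+2 permil) diet-source offset: covariate model wins clearly
  obs1 <- simulate_experiments(n_studies = 59, seed = 202,
                               covariate_effects = list(
                                 diet_source = c(natural = 2)))
  cmp1 <- compare_covariate_models(obs1, list("diet_source"),
                                   mcmc = cfg_mcmc)
  expect_lt(cmp1$delta_aic[2], -4)
  expect_lt(cmp1$delta_waic[2], -4)

  # a fitted covariate offset lands near its simulated value
  fitc <- fit_meta_model(obs1, covariates = "diet_source", mcmc = cfg_mcmc)
  sc <- posterior_summary(fitc)
  off <- sc[sc$parameter == "diet_source_natural", ]
  expect_true(off$lo < 2 && 2 < off$hi)

  expect_error(
    compare_covariate_models(
      obs0[obs0$diet_source == "natural", ], list("diet_source")),
    "single level")
})

test_that("equilibrium filtering and WAIC degeneracy are flagged, not silent", {
  obs <- simulate_experiments(n_studies = 20, seed = 301)
  obs$equilibrium[1:6] <- FALSE
  expect_message(filtered <- filter_equilibrium(obs), "kept 14 of 20")
  expect_equal(nrow(filtered), 14)

  zero_sig <- experiment_observations(data.frame(
    study_id = c("a", "b", "c"), diet_d15n = c(1, 5, 9),
    diet_sigma = 0, consumer_d15n = c(6, 9, 12), consumer_sigma = 0))
  # convergence is beside the point for this 3-study degenerate fixture
  suppressWarnings(
    fit <- fit_meta_model(zero_sig, mcmc = quick_mcmc(seed = 1, n_iter = 600,
                                                      burn = 200)))
  expect_warning(w <- waic(fit), "undefined")
  expect_true(is.na(w$waic))
})
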