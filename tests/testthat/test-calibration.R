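test_that("the RMSE objective matches hand arithmetic", {
  expect_equal(rmse(c(100, 110), c(103, 106)), sqrt((9 + 16) / 2))
  cfg <- tiny_campaign(n_days = 30L, seed = 6L, noise_sigma = 0)
  ds <- generate_plant_dataset(cfg)
  infl <- influent_loads(ds$schedule, ds$specs, cfg$digester)
  # observations generated at the same params -> zero objective
  expect_equal(objective_rmse(cfg$true_params, infl, ds$biogas,
                              cfg$digester), 0, tolerance = 1e-9)
  # a constant offset shows up as exactly |delta|
  expect_equal(objective_rmse(cfg$true_params, infl, ds$biogas + 25,
                              cfg$digester), 25, tolerance = 1e-9)
  expect_error(objective_rmse(cfg$true_params, infl, ds$biogas[-1],
                              cfg$digester), "align")
})

test_that("noiseless calibration recovers the generating rates", {
  cfg <- campaign_config(n_days = 365L, noise_sigma = 0, seed = 8L)
  ds <- generate_plant_dataset(cfg)
  infl <- influent_loads(ds$schedule, ds$specs, cfg$digester)
  res <- estimate_hydrolysis_rates(infl, ds$biogas, cfg$digester,
                                   init = kinetic_params(0.375, 0.115, 0.18),
                                   seed = 2L)
  k_hat <- c(res$params$k_ch, res$params$k_pr, res$params$k_li)
  expect_lt(max(abs(k_hat / c(0.25, 0.23, 0.12) - 1)), 0.05)
  expect_lt(res$objective_value, 1)
  expect_true(res$converged)
})

test_that("calibration honours bounds, the initial guess, and determinism", {
  cfg <- tiny_campaign(n_days = 90L, seed = 9L, noise_sigma = 0.05)
  ds <- generate_plant_dataset(cfg)
  infl <- influent_loads(ds$schedule, ds$specs, cfg$digester)
  res <- estimate_hydrolysis_rates(infl, ds$biogas, cfg$digester, seed = 3L)
  k_hat <- c(res$params$k_ch, res$params$k_pr, res$params$k_li)
  expect_true(all(k_hat >= 0.001 & k_hat <= 10))
  # objective at the optimum never exceeds the initial guess's
  f_init <- objective_rmse(kinetic_params(), infl, ds$biogas, cfg$digester)
  expect_lte(res$objective_value, f_init + 1e-9)
  # observed series equal to the initial simulation -> returns the guess
  sim0 <- adm_simulate(infl, kinetic_params(), cfg$digester)
  res0 <- estimate_hydrolysis_rates(infl, sim0$biogas_m3_d, cfg$digester,
                                    seed = 3L)
  expect_equal(c(res0$params$k_ch, res0$params$k_pr, res0$params$k_li),
               c(0.25, 0.23, 0.12), tolerance = 1e-4)
  expect_lt(res0$objective_value, 1e-6)
  # deterministic given the same seed and data
  res2 <- estimate_hydrolysis_rates(infl, ds$biogas, cfg$digester, seed = 3L)
  expect_identical(k_hat,
                   c(res2$params$k_ch, res2$params$k_pr, res2$params$k_li))
  expect_error(estimate_hydrolysis_rates(infl, ds$biogas, cfg$digester,
                                         bounds = c(1, 0.5)), "bounds")
})

test_that("recovery holds across random true rates on informative campaigns", {
  # non-collinear macronutrient loads: the generator's episodic feeding
  # provides the mix variation; noiseless data, rates drawn inside bounds
  set.seed(7)
  draws <- 0
  attempt <- 0
  while (draws < 10 && attempt < 40) {
    attempt <- attempt + 1
    k_true <- 10^runif(3, log10(0.05), log10(1))
    cfg <- campaign_config(
      n_days = 365L, noise_sigma = 0, seed = 100L + attempt,
      true_params = kinetic_params(k_true[1], k_true[2], k_true[3]))
    ds <- generate_plant_dataset(cfg)
    infl <- influent_loads(ds$schedule, ds$specs, cfg$digester)
    loads <- as.matrix(infl[, c("x_ch_kg_d", "x_pr_kg_d", "x_li_kg_d")])
    cm <- stats::cor(loads)
    if (max(abs(cm[upper.tri(cm)])) > 0.995) next  # near-collinear: skip
    draws <- draws + 1
    # initial guess perturbed up to +/- 50 % around the truth
    init <- pmin(pmax(k_true * runif(3, 0.5, 1.5), 0.001), 10)
    res <- estimate_hydrolysis_rates(
      infl, ds$biogas, cfg$digester,
      init = kinetic_params(init[1], init[2], init[3]), seed = 2L)
    k_hat <- c(res$params$k_ch, res$params$k_pr, res$params$k_li)
    expect_lt(max(abs(k_hat / k_true - 1)), 0.05)
  }
  expect_equal(draws, 10)
})

test_that("adm_model fits, predicts and summarises like an R model object", {
  cfg <- campaign_config(n_days = 500L, noise_sigma = 0.05, seed = 10L)
  ds <- generate_plant_dataset(cfg)
  fit <- adm_model(ds, config = cfg$digester, seed = 2L)
  expect_s3_class(fit, "adm_model")
  expect_named(coef(fit), c("k_ch", "k_pr", "k_li"))
  expect_length(fitted(fit), 500)
  expect_equal(residuals(fit), ds$biogas - fitted(fit))
  expect_length(predict(fit, type = "methane"), 500)
  s <- summary(fit)
  expect_s3_class(s, "summary.adm_model")
  expect_gt(s$scores$train$nse_daily, 0.9)
  expect_output(print(fit), "Hydrolysis")
  # uncalibrated fit keeps the supplied parameters
  fit0 <- adm_model(ds, config = cfg$digester, calibrate = FALSE)
  expect_identical(unname(coef(fit0)), c(0.25, 0.23, 0.12))
})
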