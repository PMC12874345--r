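test_that("Buswell stoichiometry gives textbook yields", {
  # glucose-equivalent carbohydrate: equimolar CH4/CO2
  b <- buswell_yields(c(C = 6, H = 10, O = 5, N = 0))
  expect_equal(b$ch4_fraction, 0.5)
  expect_equal(b$v_ch4, 0.4147, tolerance = 1e-4)
  # degenerate substrates
  expect_equal(buswell_yields(c(C = 1, H = 4, O = 0, N = 0))$ch4_fraction, 1)
  expect_equal(buswell_yields(c(C = 1, H = 0, O = 2, N = 0))$v_ch4, 0)
  # lipids are methane-rich, proteins balanced
  expect_gt(buswell_yields(c(C = 57, H = 104, O = 6, N = 0))$ch4_fraction,
            0.65)
  expect_error(buswell_yields(c(C = 1, H = 0, O = 3, N = 0)), "negative")
  # gas reference conditions scale the molar volume
  warm <- buswell_yields(c(C = 6, H = 10, O = 5, N = 0),
                         gas_temp_k = 2 * 273.15)
  expect_equal(warm$v_ch4, 2 * b$v_ch4, tolerance = 1e-12)
})

test_that("state derivative implements CSTR + first-order hydrolysis", {
  cfg <- digester_config(hrt_d = 10)
  kp <- kinetic_params()
  zero <- c(x_ch = 0, x_pr = 0, x_li = 0)
  d0 <- adm_derivative(zero, c(0, 0, 0), kp, cfg)
  expect_equal(unname(d0$deriv), c(0, 0, 0))
  expect_equal(d0$gas_m3_d, 0)
  # pure decay: dx = -(D + k) x; hydrolysis part alone is -k x
  d1 <- adm_derivative(c(x_ch = 1, x_pr = 0, x_li = 0), c(0, 0, 0), kp, cfg)
  expect_equal(unname(d1$deriv[1]), -(0.1 + 0.25))
  # dilution-only: k = 0.001 floor, x = 2, x_in = 0, D = 0.1
  kp0 <- kinetic_params(0.001, 0.001, 0.001)
  d2 <- adm_derivative(c(x_ch = 2, x_pr = 0, x_li = 0), c(0, 0, 0), kp0, cfg)
  expect_equal(unname(d2$deriv[1]), -0.1 * 2 - 0.001 * 2)
  expect_error(adm_derivative(c(x_ch = NaN, x_pr = 0, x_li = 0),
                              c(0, 0, 0), kp, cfg), "non-finite")
})

test_that("constant-feed simulation converges to the closed-form steady state", {
  cfg <- digester_config(v_liq = 1200, hrt_d = 15)
  kp <- kinetic_params()
  # hand algebra: X* = 30 (1/15) / ((1/15) + 0.25)
  ss <- analytic_steady_state(c(30 * 80, 0, 0), kp, cfg)
  expect_equal(unname(ss$x_star[1]), 30 * (1 / 15) / ((1 / 15) + 0.25),
               tolerance = 1e-12)
  expect_equal(analytic_steady_state(c(0, 0, 0), kp, cfg)$biogas_m3_d, 0)
  # randomized draws: simulate from empty state, compare at t >> HRT
  set.seed(42)
  for (i in 1:10) {
    k <- 10^runif(3, log10(0.02), log10(2))
    loads <- runif(3, 200, 6000)
    kpi <- kinetic_params(k[1], k[2], k[3])
    const <- data.frame(x_ch_kg_d = loads[1], x_pr_kg_d = loads[2],
                        x_li_kg_d = loads[3])[rep(1, 250), ]
    sim <- adm_simulate(const, kpi, cfg,
                        init = c(x_ch = 0, x_pr = 0, x_li = 0))
    want <- steady_state_oracle(loads, k, 1200, 15)
    expect_equal(sim$biogas_m3_d[250], want["biogas"], tolerance = 5e-3,
                 ignore_attr = TRUE)
    expect_equal(sim$methane_m3_d[250], want["methane"], tolerance = 5e-3,
                 ignore_attr = TRUE)
  }
})

test_that("exact stepper agrees with the adaptive solver", {
  cfg <- tiny_campaign(n_days = 40L, seed = 3L)
  ds <- generate_plant_dataset(cfg)
  infl <- influent_loads(ds$schedule, ds$specs, cfg$digester)
  kp <- cfg$true_params
  s1 <- adm_simulate(infl, kp, cfg$digester, method = "exact")
  s2 <- adm_simulate(infl, kp, cfg$digester, method = "lsoda")
  expect_equal(s1$biogas_m3_d, s2$biogas_m3_d, tolerance = 1e-5)
  expect_equal(s1$methane_m3_d, s2$methane_m3_d, tolerance = 1e-5)
})

test_that("simulation respects mass limits, non-negativity and linearity", {
  cfg <- tiny_campaign(n_days = 80L, seed = 4L)
  ds <- generate_plant_dataset(cfg)
  dig <- cfg$digester
  infl <- influent_loads(ds$schedule, ds$specs, dig)
  sim <- adm_simulate(infl, cfg$true_params, dig,
                      init = c(x_ch = 0, x_pr = 0, x_li = 0))
  # cumulative gas never exceeds complete conversion of the fed mass
  y <- lapply(dig$formulas, buswell_yields)
  cap <- cumsum(infl$x_ch_kg_d) * y$ch$v_gas +
    cumsum(infl$x_pr_kg_d) * y$pr$v_gas +
    cumsum(infl$x_li_kg_d) * y$li$v_gas
  expect_true(all(cumsum(sim$biogas_m3_d) <= cap + 1e-8))
  expect_true(all(attr(sim, "trajectory") >= -1e-12))
  expect_true(all(sim$ch4_fraction >= 0 & sim$ch4_fraction <= 1))
  expect_equal(sim$methane_m3_d, sim$biogas_m3_d * sim$ch4_fraction,
               tolerance = 1e-12)
  # zero feed, zero state -> all-zero series
  zero <- infl
  zero[, c("x_ch_kg_d", "x_pr_kg_d", "x_li_kg_d")] <- 0
  sim0 <- adm_simulate(zero, cfg$true_params, dig,
                       init = c(x_ch = 0, x_pr = 0, x_li = 0))
  expect_equal(sim0$biogas_m3_d, rep(0, nrow(zero)))
  # doubled feed doubles the gas (linear system)
  dbl <- infl
  dbl[, c("x_ch_kg_d", "x_pr_kg_d", "x_li_kg_d")] <-
    2 * infl[, c("x_ch_kg_d", "x_pr_kg_d", "x_li_kg_d")]
  sim2 <- adm_simulate(dbl, cfg$true_params, dig,
                       init = c(x_ch = 0, x_pr = 0, x_li = 0))
  expect_equal(sim2$biogas_m3_d, 2 * sim$biogas_m3_d, tolerance = 1e-10)
})

test_that("monod extension approaches first-order output in the fast-uptake limit", {
  dig_m <- digester_config(mode = "monod_extension")
  mo <- list(mu_max = 200, k_s = 0.001, yield_fraction = 0.02, k_dec = 0)
  kp <- kinetic_params(monod = mo)
  loads <- c(4000, 900, 350)
  const <- data.frame(x_ch_kg_d = loads[1], x_pr_kg_d = loads[2],
                      x_li_kg_d = loads[3])[rep(1, 300), ]
  sim <- adm_simulate(const, kp, dig_m,
                      init = c(x_ch = 0, x_pr = 0, x_li = 0, s_ch = 0,
                               s_pr = 0, s_li = 0, x_bio = 1))
  fo <- analytic_steady_state(loads, kp, digester_config())
  # gas deficit equals the biomass yield fraction in the limit
  expect_equal(sim$biogas_m3_d[300], (1 - mo$yield_fraction) * fo$biogas_m3_d,
               tolerance = 2e-3)
  expect_error(analytic_steady_state(loads, kp, dig_m), "first_order")
})

test_that("simulation output table writes the expected CSV schema", {
  cfg <- tiny_campaign(n_days = 20L, seed = 5L)
  ds <- generate_plant_dataset(cfg)
  infl <- influent_loads(ds$schedule, ds$specs, cfg$digester)
  sim <- adm_simulate(infl, cfg$true_params, cfg$digester)
  f <- tempfile(fileext = ".csv")
  write_simulation_csv(sim, f)
  back <- utils::read.csv(f)
  expect_named(back, c("date", "biogas_m3_d", "methane_m3_d", "ch4_fraction"))
  expect_equal(nrow(back), 20)
})
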