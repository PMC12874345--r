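test_that("crude carbohydrates close the Weender balance", {
  # printed table rows recomputed from the closure formula
  expect_equal(crude_carbohydrates(150.0, 123.7, 27.0), 699.3)
  expect_equal(crude_carbohydrates(33.4, 76.0, 44.5), 846.1)
  expect_equal(crude_carbohydrates(123.1, 116.9, 29.0), 731.0)
  expect_equal(crude_carbohydrates(57.5, 42.5, 15.9), 884.1)
  expect_equal(crude_carbohydrates(100.0, 117.8, 51.0), 731.2)
  expect_equal(crude_carbohydrates(0, 0, 0), 1000)
  expect_error(crude_carbohydrates(-1, 0, 0), "xa")
  expect_error(crude_carbohydrates(600, 300, 200), "exceeds 1000")
})

test_that("crude protein follows the 6.25 nitrogen factor", {
  expect_equal(crude_protein_from_nitrogen(20, 4), 100)
  expect_equal(crude_protein_from_nitrogen(5, 5), 0)
  expect_equal(crude_protein_from_nitrogen(10, 2), 50)
  expect_error(crude_protein_from_nitrogen(3, 5), "exceeds")
})

test_that("spec validation flags closure violations without erroring", {
  # the packaged cattle-manure row is a documented closure violation
  expect_warning(plant_feedstocks(quiet = FALSE), "cattle_manure")
  specs <- plant_feedstocks()
  expect_s3_class(specs, "feedstock_set")
  expect_length(specs, 8)
  expect_equal(specs$maize_silage$xc, 846.1)
  # exact-closure rows load silently
  expect_silent(feedstock_spec("ok", 30, 90, xa = 100, xc = 700, xp = 150,
                               xl = 50))
  expect_error(feedstock_spec("bad", 120, 90, xa = 0, xc = 1000, xp = 0,
                              xl = 0), "ts_pct_fm")
  expect_error(feedstock_spec("fib", 30, 90, xa = 100, xc = 700, xp = 150,
                              xl = 50, adl = 300, adf = 200, ndf = 400),
               "adl <= adf <= ndf")
})

test_that("carbohydrate degradability resolves DQ > ADL > XF", {
  specs <- plant_feedstocks()
  # DQ_XC takes precedence when present
  expect_equal(degradable_fractions(specs$cattle_manure)$fd_ch, 0.69)
  # ADL rule: lignin fully recalcitrant
  dl <- degradable_fractions(specs$deep_litter)
  expect_equal(dl$fd_ch, 1 - 123.2 / 699.3, tolerance = 1e-12)
  expect_equal(dl$rule, "adl")
  ad <- degradable_fractions(
    suppressWarnings(feedstock_spec("x", 30, 90, 0, 800, 100, 100,
                                    adl = 100)))
  expect_equal(ad$fd_ch, 0.875)
  # XF fallback with configurable alpha
  fg <- degradable_fractions(specs$fresh_grass, xf_alpha = 0.5)
  expect_equal(fg$rule, "xf")
  expect_equal(fg$fd_ch, 1 - 0.5 * 267.4 / 713.5, tolerance = 1e-12)
  # protein and lipid fully degradable always
  for (sp in specs) {
    d <- degradable_fractions(sp)
    expect_identical(c(d$fd_pr, d$fd_li), c(1, 1))
    expect_true(d$fd_ch >= 0 && d$fd_ch <= 1)
  }
  bare <- simple_spec(dq = NA_real_)
  expect_error(degradable_fractions(bare), "no degradability")
  expect_equal(degradable_fractions(bare, default_fd_ch = 0.8)$fd_ch, 0.8)
})

test_that("ADL-rule degradability is non-increasing in ADL", {
  adls <- seq(0, 600, by = 50)
  fd <- vapply(adls, function(a) {
    degradable_fractions(
      suppressWarnings(feedstock_spec("x", 30, 90, 0, 700, 200, 100,
                                      adl = a)))$fd_ch
  }, 0)
  expect_true(all(diff(fd) <= 0))
})

test_that("influent loads follow the TS/VS/fraction arithmetic", {
  cfg <- digester_config(v_liq = 1200, hrt_d = 15)
  # one feedstock, 10 t/d, TS 30 % FM, VS 90 % TS -> VS 2.7 t/d, OLR 2.25
  sched <- simple_schedule(rep(10, 5))
  infl <- influent_loads(sched, list(sub = simple_spec()), cfg)
  expect_equal(infl$vs_t_d, rep(2.7, 5))
  expect_equal(infl$olr, rep(2.25, 5))
  expect_equal(infl$q_m3_d, rep(80, 5))
  # maize-like: x_ch = 10000 * 0.301 * 0.8461 with full degradability
  mz <- simple_spec("maize_silage", ts = 30.1, vs = 96.7, xa = 33.4,
                    xc = 846.1, xp = 76.0, xl = 44.5, dq = 1)
  sched2 <- simple_schedule(rep(10, 3), name = "maize_silage")
  infl2 <- influent_loads(sched2, list(maize_silage = mz), cfg)
  expect_equal(infl2$x_ch_kg_d[1], 10000 * 0.301 * 0.8461, tolerance = 1e-12)
  expect_equal(infl2$vs_maize_t_d[1], 10 * 0.301 * 0.967, tolerance = 1e-12)
  # zero-feed day zeroes everything
  infl0 <- influent_loads(simple_schedule(c(0, 10)),
                          list(sub = simple_spec()), cfg)
  expect_equal(infl0$adm1_inputs_kg_d[1], 0)
  expect_equal(infl0$olr[1], 0)
  # identity: adm1 inputs = sum of the three loads, exactly
  expect_identical(infl2$adm1_inputs_kg_d,
                   infl2$x_ch_kg_d + infl2$x_pr_kg_d + infl2$x_li_kg_d)
})

test_that("influent transformation is linear and conserves VS", {
  cfg <- campaign_config(n_days = 60L, seed = 11L)
  sched <- generate_feed_schedule(cfg)
  dig <- cfg$digester
  infl1 <- influent_loads(sched, cfg$feedstocks, dig)
  fs <- setdiff(names(sched), c("day", "date"))
  doubled <- feed_schedule(sched$date, 2 * as.matrix(sched[, fs]))
  infl2 <- influent_loads(doubled, cfg$feedstocks, dig)
  for (col in c("x_ch_kg_d", "x_pr_kg_d", "x_li_kg_d", "vs_t_d", "olr")) {
    expect_equal(infl2[[col]], 2 * infl1[[col]], tolerance = 1e-12)
  }
  # conservation: total VS equals the per-feedstock sum to machine precision
  expect_equal(infl1$vs_t_d, rowSums(attr(infl1, "vs_by_feedstock")),
               tolerance = 1e-14)
})

test_that("feedstock and schedule tables round-trip through CSV", {
  specs <- plant_feedstocks()
  sched <- generate_feed_schedule(tiny_campaign(n_days = 20L, seed = 2L))
  f <- tempfile(fileext = ".csv")
  fs <- setdiff(names(sched), c("day", "date"))
  utils::write.csv(data.frame(date = sched$date, sched[, fs],
                              check.names = FALSE),
                   f, row.names = FALSE, quote = FALSE)
  back <- read_schedule_table(f)
  expect_equal(as.matrix(back[, fs]), as.matrix(sched[, fs]),
               tolerance = 1e-9)
  expect_error(influent_loads(
    feed_schedule(sched$date,
                  stats::setNames(sched[, fs], c("mystery", fs[-1]))),
    specs, digester_config()), "mystery")
})
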