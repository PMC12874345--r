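test_that("feature combinations have the defined columns", {
  cfg <- tiny_campaign(n_days = 40L, seed = 12L)
  ds <- generate_plant_dataset(cfg)
  infl <- influent_loads(ds$schedule, ds$specs, cfg$digester)
  n_feed <- length(setdiff(names(ds$schedule), c("day", "date")))
  expect_equal(n_feed, 8)
  fm1 <- build_feature_set(ds, infl, "feedstocks")
  expect_length(fm_features(fm1), 8)
  fm2 <- build_feature_set(ds, infl, "feedstocks_olr")
  expect_length(fm_features(fm2), 9)
  expect_true("olr" %in% fm_features(fm2))
  fm3 <- build_feature_set(ds, infl, "feedstocks_olr_vsmaize")
  expect_length(fm_features(fm3), 10)
  fm4 <- build_feature_set(ds, infl, "feedstocks_adm1")
  expect_length(fm_features(fm4), 9)
  expect_equal(fm4$adm1_inputs,
               infl$x_ch_kg_d + infl$x_pr_kg_d + infl$x_li_kg_d)
  expect_error(build_feature_set(ds, infl, "everything"), "arg")
  expect_false(anyNA(fm3))
})

test_that("methane target uses step-interpolated weekly CH4 content", {
  biogas <- c(100, 100, 100, 200, 200, 200, 200, 300)
  wk <- data.frame(day = c(1, 8), ch4_fraction = c(0.5, 0.6))
  ch4 <- methane_from_weekly_ch4(biogas, wk)
  expect_equal(ch4, c(rep(0.5, 7), 0.6) * biogas)
})

test_that("chronological split cuts at the year boundary without overlap", {
  sp <- make_split(n_days = 730L, seed = 13L)
  expect_equal(nrow(sp$train), 365)
  expect_equal(nrow(sp$test), 365)
  expect_length(intersect(sp$train$day, sp$test$day), 0)
  expect_lt(max(sp$train$day), min(sp$test$day))
  expect_equal(unique(format(sp$train$date, "%Y")), "2023")
  one_year <- build_feature_set(generate_plant_dataset(
    tiny_campaign(n_days = 100L, seed = 14L)), combo_id = "feedstocks")
  expect_error(chronological_split(one_year), "two calendar years")
})

test_that("random forest fits, stays in range, and is seed-deterministic", {
  sp <- make_split(seed = 15L)
  rf <- fit_random_forest(sp$train, hyper = list(num_trees = 150), seed = 4L)
  pred <- predict(rf, sp$test)
  expect_length(pred, nrow(sp$test))
  # ensemble means cannot leave the training target range
  expect_true(all(pred >= min(sp$train$.target) - 1e-9))
  expect_true(all(pred <= max(sp$train$.target) + 1e-9))
  # same seed -> bit-identical predictions
  rf2 <- fit_random_forest(sp$train, hyper = list(num_trees = 150), seed = 4L)
  expect_identical(pred, predict(rf2, sp$test))
  # constant target -> constant prediction
  const <- sp$train
  const$.target <- rep(500, nrow(const))
  attr(const, "features") <- attr(sp$train, "features")
  rfc <- fit_random_forest(const, hyper = list(num_trees = 50), seed = 1L)
  expect_equal(predict(rfc, sp$test), rep(500, nrow(sp$test)))
})

test_that("random forest finds a planted single-feature signal", {
  set.seed(77)
  n <- 300
  X <- data.frame(signal = runif(n), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n))
  fm <- data.frame(day = 1:n, date = as.Date("2023-01-01") + 1:n - 1, X,
                   .target = X$signal)
  attr(fm, "features") <- names(X)
  class(fm) <- c("feature_matrix", "data.frame")
  rf <- fit_random_forest(fm, hyper = list(num_trees = 200), seed = 5L)
  r2 <- 1 - mean((predict(rf, fm) - fm$.target)^2) / stats::var(fm$.target)
  expect_gt(r2, 0.95)
  imp <- rf_importance(rf)
  expect_equal(names(which.max(imp)), "signal")
})

test_that("grid search enumerates exhaustively with forward-chaining folds", {
  sp <- make_split(seed = 16L, n_days = 500L)
  one <- grid_search("random_forest", list(num_trees = 40L), sp$train,
                     n_folds = 3)
  expect_equal(one$best$num_trees, 40L)
  grid <- list(num_trees = c(30L, 60L), max_depth = c(3L, 6L))
  gs <- grid_search("random_forest", grid, sp$train, n_folds = 3, seed = 2L)
  # the winner is a member of the grid
  expect_true(gs$best$num_trees %in% grid$num_trees)
  expect_true(gs$best$max_depth %in% grid$max_depth)
  # independent recomputation of the CV table: refit every configuration
  # on the same expanding-window folds and compare scores
  n <- nrow(sp$train)
  cuts <- floor(seq(0, n, length.out = 5))
  redo <- apply(expand.grid(grid), 1, function(row) {
    hp <- as.list(row)
    mean(sapply(1:3, function(i) {
      tr <- sp$train[seq_len(cuts[i + 1]), ]
      va <- sp$train[seq(cuts[i + 1] + 1, cuts[i + 2]), ]
      attr(tr, "features") <- attr(va, "features") <- fm_features(sp$train)
      class(tr) <- class(va) <- class(sp$train)
      m <- fit_random_forest(tr, hyper = hp, seed = 2L)
      mean((va$.target - predict(m, va))^2)
    }))
  })
  expect_equal(unname(gs$scores$cv_mse), unname(redo), tolerance = 1e-9)
  expect_equal(which.min(gs$scores$cv_mse),
               which(gs$scores$num_trees == gs$best$num_trees &
                       gs$scores$max_depth == gs$best$max_depth))
  expect_error(grid_search("random_forest", list(), sp$train), "empty")
})

test_that("no test-period leakage: training artifacts derive from year 1 only", {
  sp <- make_split(seed = 17L)
  m <- fit_lstm(sp$train, hyper = list(units = 4L, epochs = 1L), seed = 1L)
  feats <- fm_features(sp$train)
  tr <- as.matrix(sp$train[, feats])
  expect_equal(m$scaler_x$lo, apply(tr, 2, min))
  expect_equal(m$scaler_x$lo + m$scaler_x$rng,
               apply(tr, 2, max),
               tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m$scaler_y$lo, min(sp$train$.target), ignore_attr = TRUE)
})
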