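# Pipeline orchestration: generate -> fractionate -> calibrate -> simulate
# -> train -> evaluate -> profile, with seeded, hash-stamped artifacts.

.log_stage <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

# CSV writer stamping every artifact with the campaign seed and config hash.
.write_stamped_csv <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config_hash=%s", seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hash-stamped pipeline CSV
#'
#' @param path CSV written by \code{\link{run_pipeline}}.
#' @return Data.frame (the stamp comment line is skipped).
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default: the synthetic-campaign
#' settings, the model hyperparameters (calibrated plant values), the LSTM
#' window, the feature combinations and targets evaluated, Shapley and
#' profiling settings. Any entry can be overridden through the YAML config
#' file or the \code{config} argument of \code{\link{run_pipeline}}.
#'
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    n_days = 730L,
    noise_sigma = 0.05,
    target_olr = 6.1,
    summer_factor = 0.6,
    gap_prob = 0.3,
    feed_jitter_sd = 0.1,
    true_k = c(0.25, 0.23, 0.12),
    v_liq = 1200, hrt_d = 14,
    calibration_multi_start = 3,
    rf = list(num_trees = 500, max_depth = 10, min_split = 15,
              min_leaf = 2, mtry = "sqrt"),
    lstm = list(units = 128L, dropout = 0.1, optimizer = "adam",
                batch_size = 16L, epochs = 50L, lr = 0.01),
    lstm_window = 7L,
    combos = c("feedstocks", "feedstocks_olr", "feedstocks_olr_vsmaize",
               "feedstocks_adm1"),
    targets = c("biogas", "methane"),
    shap_combo = "feedstocks_olr_vsmaize",
    shap_background = 100L,
    shap_instances = 60L,
    shap_n_perm = 32L,
    profile_repetitions = 1L
  )
}

#' Run the full benchmark pipeline
#'
#' Generates a seeded synthetic plant campaign, calibrates the mechanistic
#' digester model on year 1, trains the random-forest and LSTM baselines on
#' every configured feature combination, evaluates everything on year 2
#' (daily and weekly NSE, RMSE), computes Shapley feature shares and the
#' feature/biogas Pearson correlation matrix, profiles training and testing
#' of each model family, and writes all tables as hash-stamped CSVs.
#'
#' @param config NULL (defaults), a named list overriding
#'   \code{\link{pipeline_defaults}} entries, or the path of a YAML file of
#'   overrides.
#' @param out_dir Output directory (created; default a tempdir subdir).
#' @param seed Overrides the config seed when non-NULL.
#' @return Invisibly, a list: \code{comparison} (model x combo NSE table),
#'   \code{profiling}, \code{shap}, \code{correlation}, \code{calibration},
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL) {
  defaults <- pipeline_defaults()
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(defaults, config %||% list())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(out_dir)) out_dir <- tempfile("biogasbench_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  dig <- digester_config(v_liq = cfg$v_liq, hrt_d = cfg$hrt_d)
  camp <- campaign_config(
    n_days = cfg$n_days, noise_sigma = cfg$noise_sigma,
    target_olr = cfg$target_olr, summer_factor = cfg$summer_factor,
    gap_prob = cfg$gap_prob, feed_jitter_sd = cfg$feed_jitter_sd,
    true_params = kinetic_params(cfg$true_k[1], cfg$true_k[2],
                                 cfg$true_k[3]),
    digester = dig, seed = cfg$seed)
  hash <- config_hash(cfg)
  stamp <- function(df, name) {
    .write_stamped_csv(df, file.path(out_dir, name), cfg$seed, hash)
  }

  .log_stage("generate: synthetic campaign (", cfg$n_days, " days, seed ",
             cfg$seed, ")")
  ds <- generate_plant_dataset(camp)
  fs <- schedule_feedstocks(ds$schedule)
  stamp(data.frame(date = ds$schedule$date,
                   ds$schedule[, fs, drop = FALSE], check.names = FALSE),
        "schedule.csv")
  stamp(data.frame(date = ds$schedule$date, biogas_m3_d = ds$biogas,
                   methane_m3_d = ds$methane), "observations.csv")

  .log_stage("fractionate: influent loads")
  infl <- influent_loads(ds$schedule, ds$specs, dig)
  idx <- chronological_indices(ds)

  .log_stage("calibrate: hydrolysis rates (year 1)")
  prof_adm_train <- profile_execution(function() {
    adm_model(ds, config = dig, multi_start = cfg$calibration_multi_start,
              seed = cfg$seed)
  }, phase = "train", repetitions = cfg$profile_repetitions)
  adm <- prof_adm_train$value
  prof_adm_test <- profile_execution(function() {
    adm_simulate(infl, adm$params, dig)
  }, phase = "test", repetitions = cfg$profile_repetitions)
  sim <- prof_adm_test$value

  scores <- list()
  add_score <- function(family, combo, target, obs_te, pred_te) {
    ev <- evaluate_series(obs_te, pred_te)
    scores[[length(scores) + 1]] <<- data.frame(
      model = family, combo = combo, target = target,
      nse_daily = ev$nse_daily, nse_weekly = ev$nse_weekly, rmse = ev$rmse)
  }
  obs <- list(biogas = ds$biogas, methane = ds$methane)
  for (tg in cfg$targets) {
    pred <- if (tg == "biogas") sim$biogas_m3_d else sim$methane_m3_d
    add_score("adm1_like", "adm1", tg, obs[[tg]][idx$test], pred[idx$test])
  }

  profs <- list(adm1_like_train = prof_adm_train,
                adm1_like_test = prof_adm_test)
  models <- list()
  for (family in c("random_forest", "lstm")) {
    for (combo in cfg$combos) {
      for (tg in cfg$targets) {
        fm <- build_feature_set(ds, infl, combo, target = tg, config = dig)
        sp <- chronological_split(fm)
        do_fit <- function() {
          if (family == "random_forest") {
            fit_random_forest(sp$train, hyper = cfg$rf, seed = cfg$seed)
          } else {
            fit_lstm(sp$train, hyper = cfg$lstm, window = cfg$lstm_window,
                     seed = cfg$seed)
          }
        }
        do_pred <- function(m) {
          if (family == "random_forest") {
            stats::predict(m, sp$test)
          } else {
            stats::predict(m, sp$test, context = sp$train)
          }
        }
        profile_this <- combo == cfg$shap_combo && tg == "biogas"
        if (profile_this) {
          ptr <- profile_execution(do_fit, phase = "train",
                                   repetitions = cfg$profile_repetitions)
          m <- ptr$value
          pte <- profile_execution(function() do_pred(m), phase = "test",
                                   repetitions = cfg$profile_repetitions)
          pred_te <- pte$value
          profs[[paste0(family, "_train")]] <- ptr
          profs[[paste0(family, "_test")]] <- pte
        } else {
          m <- do_fit()
          pred_te <- do_pred(m)
        }
        .log_stage("train/evaluate: ", family, " / ", combo, " / ", tg)
        add_score(family, combo, tg, sp$test$.target, pred_te)
        if (profile_this) models[[family]] <- list(model = m, split = sp)
      }
    }
  }

  comparison <- do.call(rbind, scores)
  wide <- stats::reshape(
    comparison, direction = "wide", idvar = c("model", "combo"),
    timevar = "target")
  stamp(wide, "comparison.csv")

  .log_stage("evaluate: Shapley attribution (", cfg$shap_combo, ")")
  shap_tabs <- list()
  for (family in names(models)) {
    m <- models[[family]]$model
    sp <- models[[family]]$split
    set.seed(cfg$seed)
    bg_rows <- sample(nrow(sp$train),
                      min(cfg$shap_background, nrow(sp$train)))
    in_rows <- sample(nrow(sp$test),
                      min(cfg$shap_instances, nrow(sp$test)))
    feats <- fm_features(sp$train)
    if (family == "random_forest") {
      phi <- shapley_values(
        m, sp$test[in_rows, feats, drop = FALSE],
        sp$train[bg_rows, feats, drop = FALSE],
        mode = if (length(feats) <= 12) "exact" else "sampling",
        n_perm = cfg$shap_n_perm, seed = cfg$seed)
      tab <- normalized_importance(phi)
    } else {
      tab <- lstm_shap(m, sp$test, sp$train, instances = in_rows,
                       background = bg_rows, n_perm = cfg$shap_n_perm,
                       seed = cfg$seed)
    }
    tab$model <- family
    shap_tabs[[family]] <- tab
  }
  shap_all <- do.call(rbind, shap_tabs)
  stamp(shap_all, "shap_shares.csv")

  .log_stage("evaluate: correlation matrix")
  fm_corr <- build_feature_set(ds, infl, "feedstocks_olr_vsmaize",
                               target = "biogas", config = dig)
  cm <- pearson_matrix(cbind(fm_corr[, fm_features(fm_corr)],
                             biogas = ds$biogas))
  stamp(as.data.frame(pearson_report(cm)), "correlation.csv")

  prof_tab <- do.call(rbind, lapply(names(profs), function(nm) {
    p <- profs[[nm]]
    data.frame(model = sub("_(train|test)$", "", nm), phase = p$phase,
               wall_s = p$wall_s, wall_sd_s = p$wall_sd_s,
               mem_peak_mb = p$mem_peak_mb, mem_mean_mb = p$mem_mean_mb,
               mem_sd_mb = p$mem_sd_mb, n_samples = p$n_samples)
  }))
  stamp(prof_tab, "profiling.csv")

  yaml::write_yaml(c(cfg, list(config_hash = hash)),
                   file.path(out_dir, "config_echo.yaml"))
  .log_stage("done: artifacts in ", out_dir)
  invisible(list(comparison = wide, comparison_long = comparison,
                 profiling = prof_tab, shap = shap_all,
                 correlation = cm, calibration = adm$calibration,
                 adm = adm, out_dir = out_dir))
}

#' Shapley shares of an LSTM over original features
#'
#' Attribution is computed on the flattened window features (every feature
#' at every lag) in sampling mode, then summed across lags per original
#' feature before taking the mean absolute value, so shares are comparable
#' with the per-feature shares of memoryless models.
#'
#' @param model An \code{lstm_model}.
#' @param test,train Feature matrices (test rows are explained; train
#'   supplies the background and the window context).
#' @param instances,background Row indices into test/train to use.
#' @param n_perm Permutations for sampling-mode Shapley.
#' @param seed RNG seed.
#' @return A \code{\link{normalized_importance}} table over the original
#'   features.
#' @export
lstm_shap <- function(model, test, train, instances, background,
                      n_perm = 32L, seed = 1L) {
  feats <- model$features
  w <- model$window
  p <- length(feats)
  full <- rbind(as.matrix(train[, feats, drop = FALSE]),
                as.matrix(test[, feats, drop = FALSE]))
  n_tr <- nrow(train)
  flat_names <- as.vector(outer(feats, seq_len(w) - 1L,
                                function(f, l) paste0(f, ".lag", l)))
  # flattened windows: lag 0 = the predicted day itself
  flatten <- function(rows_abs) {
    out <- matrix(NA_real_, length(rows_abs), p * w,
                  dimnames = list(NULL, flat_names))
    for (i in seq_along(rows_abs)) {
      win <- full[(rows_abs[i] - w + 1):rows_abs[i], , drop = FALSE]
      out[i, ] <- as.vector(t(win[w:1, , drop = FALSE]))  # lag-major blocks
    }
    as.data.frame(out)
  }
  predict_flat <- function(Xf) {
    Xf <- as.matrix(Xf)
    n <- nrow(Xf)
    Xw <- lapply(seq_len(w), function(t) {
      lag <- w - t                        # timestep t is lag w-t
      block <- Xf[, (lag * p + 1):((lag + 1) * p), drop = FALSE]
      colnames(block) <- feats
      .scale_apply(block, model$scaler_x)
    })
    fw <- .lstm_forward(model$weights, Xw, as.integer(model$hyper$units))
    fw$yhat * model$scaler_y$rng + model$scaler_y$lo
  }
  inst <- flatten(n_tr + instances)
  bg_rows_abs <- background[background > w - 1]   # need a full window
  if (!length(bg_rows_abs)) bg_rows_abs <- seq.int(w, n_tr)
  bg <- flatten(bg_rows_abs)
  phi <- shapley_values(predict_flat, inst, bg, mode = "sampling",
                        n_perm = n_perm, seed = seed)
  per_feature <- vapply(seq_len(p), function(j) {
    rowSums(phi[, seq.int(j, p * w, by = p), drop = FALSE])
  }, numeric(nrow(phi)))
  per_feature <- matrix(per_feature, nrow = nrow(phi),
                        dimnames = list(NULL, feats))
  normalized_importance(per_feature)
}
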