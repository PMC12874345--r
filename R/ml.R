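#' Assemble a feature matrix for the data-driven models
#'
#' Builds one of the four studied input combinations from a plant dataset
#' and its influent transformation:
#' \describe{
#'   \item{feedstocks}{one column per feedstock, fresh mass fed (t/d)}
#'   \item{feedstocks_olr}{plus the organic loading rate (kg VS m^-3 d^-1)}
#'   \item{feedstocks_olr_vsmaize}{plus OLR and maize-silage VS flow (t VS/d)}
#'   \item{feedstocks_adm1}{feedstock columns plus the summed degradable
#'     macronutrient load x_ch + x_pr + x_li (kg/d)}
#' }
#'
#' @param dataset A \code{\link{plant_dataset}}.
#' @param influent Matching \code{\link{influent_loads}} (computed if NULL).
#' @param combo_id One of the four combination ids above.
#' @param target \code{"biogas"} or \code{"methane"} daily series.
#' @param config \code{\link{digester_config}} used when \code{influent} must
#'   be computed.
#' @return Class \code{feature_matrix}: data.frame with \code{day},
#'   \code{date}, the feature columns and a \code{.target} column; feature
#'   names in attribute \code{"features"}, combo in \code{"combo_id"}.
#' @export
build_feature_set <- function(dataset, influent = NULL,
                              combo_id = c("feedstocks", "feedstocks_olr",
                                           "feedstocks_olr_vsmaize",
                                           "feedstocks_adm1"),
                              target = c("biogas", "methane"),
                              config = digester_config()) {
  combo_id <- match.arg(combo_id)
  target <- match.arg(target)
  if (is.null(influent)) {
    influent <- influent_loads(dataset$schedule, dataset$specs, config)
  }
  if (nrow(influent) != nrow(dataset$schedule)) {
    stop("influent not aligned with dataset days", call. = FALSE)
  }
  fs <- schedule_feedstocks(dataset$schedule)
  X <- dataset$schedule[, fs, drop = FALSE]
  if (combo_id %in% c("feedstocks_olr", "feedstocks_olr_vsmaize")) {
    X$olr <- influent$olr
  }
  if (combo_id == "feedstocks_olr_vsmaize") {
    X$vs_maize <- influent$vs_maize_t_d
  }
  if (combo_id == "feedstocks_adm1") {
    X$adm1_inputs <- influent$adm1_inputs_kg_d
  }
  y <- switch(target,
              biogas = dataset$biogas,
              methane = {
                if (is.null(dataset$methane)) {
                  if (is.null(dataset$ch4_weekly)) {
                    stop("dataset has neither methane nor weekly CH4 content",
                         call. = FALSE)
                  }
                  methane_from_weekly_ch4(dataset$biogas, dataset$ch4_weekly)
                } else dataset$methane
              })
  if (anyNA(X) || anyNA(y)) stop("missing values in features or target",
                                 call. = FALSE)
  out <- data.frame(day = dataset$schedule$day, date = dataset$schedule$date,
                    X, .target = y, check.names = FALSE)
  attr(out, "features") <- setdiff(names(out), c("day", "date", ".target"))
  attr(out, "combo_id") <- combo_id
  attr(out, "target_name") <- target
  class(out) <- c("feature_matrix", "data.frame")
  out
}

# Feature-column names of a feature matrix.
fm_features <- function(fm) attr(fm, "features")

#' Split a feature matrix at the first calendar-year boundary
#'
#' Training rows are the first calendar year, test rows all later days; no
#' shuffling, no overlap, order preserved.
#'
#' @param fm A \code{\link{build_feature_set}} result.
#' @return List \code{train}, \code{test} of feature matrices.
#' @export
chronological_split <- function(fm) {
  idx <- .year_split_idx(fm$date)
  keep <- function(i) {
    out <- fm[i, , drop = FALSE]
    attributes(out)[c("features", "combo_id", "target_name")] <-
      attributes(fm)[c("features", "combo_id", "target_name")]
    class(out) <- class(fm)
    out
  }
  list(train = keep(idx$train), test = keep(idx$test))
}

#' Fit the random-forest baseline
#'
#' Ensemble regression on the daily feature matrix. Defaults follow the
#' tuned plant configuration: 500 trees, depth 10, at least 15 samples to
#' split a node, at least 2 per leaf, square-root feature subsampling.
#' Fitting is seeded and single-threaded, so identical seeds give
#' bit-identical predictions.
#'
#' @param train A training \code{feature_matrix}.
#' @param hyper Named list overriding \code{num_trees} (500),
#'   \code{max_depth} (10), \code{min_split} (15), \code{min_leaf} (2),
#'   \code{mtry} ("sqrt" or an integer).
#' @param seed RNG seed (default 1).
#' @return Object of class \code{rf_model}.
#' @export
fit_random_forest <- function(train, hyper = list(), seed = 1L) {
  if (nrow(train) == 0) stop("empty training set", call. = FALSE)
  hp <- utils::modifyList(list(num_trees = 500, max_depth = 10,
                               min_split = 15, min_leaf = 2, mtry = "sqrt"),
                          hyper)
  feats <- fm_features(train)
  X <- train[, feats, drop = FALSE]
  if (!all(vapply(X, is.numeric, TRUE))) {
    stop("non-numeric feature column", call. = FALSE)
  }
  mtry <- if (identical(hp$mtry, "sqrt")) {
    max(1L, floor(sqrt(length(feats))))
  } else as.integer(hp$mtry)
  fit <- ranger::ranger(
    x = X, y = train$.target,
    num.trees = hp$num_trees, max.depth = hp$max_depth,
    min.node.size = hp$min_split, min.bucket = hp$min_leaf,
    mtry = mtry, importance = "impurity",
    seed = seed, num.threads = 1)
  structure(list(fit = fit, features = feats, hyper = hp, seed = seed,
                 combo_id = attr(train, "combo_id"),
                 target_name = attr(train, "target_name"),
                 train_range = range(train$.target)),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  X <- as.data.frame(newdata)[, object$features, drop = FALSE]
  stats::predict(object$fit, data = X, num.threads = 1)$predictions
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("Random forest (%d trees, depth %s) on %d features [%s -> %s]\n",
              x$hyper$num_trees, x$hyper$max_depth, length(x$features),
              x$combo_id %||% "?", x$target_name %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impurity-based feature importance of a random forest
#'
#' @param object An \code{rf_model}.
#' @return Named numeric vector of impurity importances.
#' @export
rf_importance <- function(object) {
  ranger::importance(object$fit)
}

#' Exhaustive grid search with forward-chaining cross-validation
#'
#' Evaluates every configuration in the grid by expanding-window
#' cross-validation on the (chronologically ordered) training matrix: the
#' rows are cut into \code{n_folds + 1} consecutive segments, fold i trains
#' on segments 1..i and validates on segment i+1, and the mean validation
#' MSE is minimised. Ties are broken by grid enumeration order.
#'
#' @param family \code{"random_forest"} or \code{"lstm"}.
#' @param grid Named list of hyperparameter value vectors (expanded with
#'   \code{expand.grid}).
#' @param train Training \code{feature_matrix}.
#' @param n_folds Number of forward-chaining folds (default 5).
#' @param seed Seed forwarded to every fit.
#' @param window LSTM window length (days), forwarded to \code{fit_lstm}.
#' @return List \code{best} (named list of the winning configuration),
#'   \code{scores} (data.frame of every configuration and its mean CV MSE).
#' @export
grid_search <- function(family = c("random_forest", "lstm"), grid, train,
                        n_folds = 5, seed = 1L, window = 7L) {
  family <- match.arg(family)
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  cfgs <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(train)
  cuts <- floor(seq(0, n, length.out = n_folds + 2))
  folds <- lapply(seq_len(n_folds), function(i) {
    list(fit = seq_len(cuts[i + 1]),
         val = seq(cuts[i + 1] + 1, cuts[i + 2]))
  })
  subset_fm <- function(fm, i) {
    out <- fm[i, , drop = FALSE]
    attributes(out)[c("features", "combo_id", "target_name")] <-
      attributes(fm)[c("features", "combo_id", "target_name")]
    class(out) <- class(fm)
    out
  }
  score_one <- function(hp) {
    errs <- vapply(folds, function(fo) {
      tr <- subset_fm(train, fo$fit)
      va <- subset_fm(train, fo$val)
      pred <- if (family == "random_forest") {
        stats::predict(fit_random_forest(tr, hyper = hp, seed = seed), va)
      } else {
        if (nrow(tr) <= window + 1) return(NA_real_)
        m <- fit_lstm(tr, hyper = hp, window = window, seed = seed)
        stats::predict(m, va, context = tr)
      }
      mean((va$.target - pred)^2)
    }, 0)
    mean(errs, na.rm = TRUE)
  }
  scores <- vapply(seq_len(nrow(cfgs)), function(i) {
    score_one(as.list(cfgs[i, , drop = FALSE]))
  }, 0)
  best_i <- which.min(scores)     # first minimum = enumeration order
  list(best = as.list(cfgs[best_i, , drop = FALSE]),
       scores = cbind(cfgs, cv_mse = scores))
}
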