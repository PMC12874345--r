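#' Nash--Sutcliffe efficiency
#'
#' NSE = 1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2). A value of 1 is a
#' perfect match, 0 performs no better than the observed mean, negative
#' values worse than the mean.
#'
#' @param obs Observed series.
#' @param sim Simulated/predicted series, same length.
#' @return Scalar NSE, always <= 1.
#' @examples
#' nse(c(1, 2, 3), c(1, 1, 3))  # 0.5
#' @export
nse <- function(obs, sim) {
  if (length(obs) != length(sim)) {
    stop("obs and sim differ in length (", length(obs), " vs ", length(sim),
         ")", call. = FALSE)
  }
  if (length(obs) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(obs)) || any(!is.finite(sim))) {
    stop("non-finite values in obs or sim", call. = FALSE)
  }
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) {
    stop("observed series has zero variance; NSE undefined", call. = FALSE)
  }
  1 - sum((obs - sim)^2) / sst
}

#' Root-mean-square error
#'
#' @param obs,sim Equal-length numeric series.
#' @return Scalar RMSE in the units of the series.
#' @export
rmse <- function(obs, sim) {
  if (length(obs) != length(sim)) {
    stop("obs and sim differ in length", call. = FALSE)
  }
  sqrt(mean((obs - sim)^2))
}

#' Aggregate a daily series into weekly totals
#'
#' Sums consecutive non-overlapping 7-day blocks starting at the first day;
#' a trailing partial block is dropped.
#'
#' @param x Daily numeric series.
#' @return Numeric vector of weekly sums (possibly empty, with a warning,
#'   when fewer than 7 days are supplied).
#' @export
weekly_totals <- function(x) {
  n_weeks <- length(x) %/% 7L
  if (n_weeks == 0L) {
    warning("series shorter than 7 days; no complete week", call. = FALSE)
    return(numeric(0))
  }
  colSums(matrix(x[seq_len(7L * n_weeks)], nrow = 7L))
}

#' Daily and weekly scores of a prediction
#'
#' @param obs,sim Equal-length daily series.
#' @return List: \code{nse_daily}, \code{nse_weekly} (on 7-day block sums),
#'   \code{rmse}.
#' @export
evaluate_series <- function(obs, sim) {
  list(nse_daily = nse(obs, sim),
       nse_weekly = nse(weekly_totals(obs), weekly_totals(sim)),
       rmse = rmse(obs, sim))
}

#' Pearson correlation matrix of a set of series
#'
#' @param x Numeric matrix or data.frame, one column per series.
#' @return Symmetric correlation matrix; entries involving a zero-variance
#'   series are NA with a warning.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 observations", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance series: ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  }
  suppressWarnings(stats::cor(x))
}

#' Reporting view of a correlation matrix
#'
#' Rounds to \code{digits} decimals and displays coefficients below
#' \code{threshold} in absolute value as 0, the convention used for plant
#' correlation heat maps.
#'
#' @param m Correlation matrix.
#' @param digits Decimal places (default 2).
#' @param threshold Absolute value under which entries display as 0
#'   (default 0.05).
#' @return Matrix of rounded/thresholded coefficients.
#' @export
pearson_report <- function(m, digits = 2, threshold = 0.05) {
  r <- round(m, digits)
  r[abs(m) < threshold] <- 0
  r
}

# Resolve a prediction function from a fitted model or a bare function.
.predict_fun <- function(model) {
  if (is.function(model)) return(model)
  function(X) stats::predict(model, X)
}

#' Shapley feature attributions of a regression model
#'
#' Computes per-instance, per-feature Shapley values with the interventional
#' value function v(S) = mean over background rows of the model output with
#' out-of-coalition features replaced by the background values. Exact mode
#' enumerates all 2^p coalitions (p <= 12); sampling mode averages marginal
#' contributions over seeded random feature permutations.
#'
#' @param model A fitted model with a \code{predict} method accepting a
#'   data.frame of features, or a bare function \code{f(X) -> numeric}.
#' @param instances Data.frame/matrix of rows to explain.
#' @param background Data.frame/matrix of reference rows (non-empty).
#' @param mode \code{"auto"} (exact when p <= 12), \code{"exact"} or
#'   \code{"sampling"}.
#' @param n_perm Number of permutations in sampling mode (default 128).
#' @param seed RNG seed for sampling mode.
#' @return Matrix (instances x features) of Shapley values, with attributes
#'   \code{"mode"} and \code{"base_value"} (mean background prediction).
#' @export
shapley_values <- function(model, instances, background,
                           mode = c("auto", "exact", "sampling"),
                           n_perm = 128, seed = 1L) {
  mode <- match.arg(mode)
  f <- .predict_fun(model)
  instances <- as.data.frame(instances)
  background <- as.data.frame(background)
  if (nrow(background) == 0) stop("background must be non-empty", call. = FALSE)
  if (!identical(names(instances), names(background))) {
    stop("instances and background must share columns", call. = FALSE)
  }
  p <- ncol(instances)
  if (mode == "auto") mode <- if (p <= 12) "exact" else "sampling"
  if (mode == "exact" && p > 12) {
    stop("exact Shapley enumeration limited to p <= 12 features (got ", p,
         "); use mode = 'sampling'", call. = FALSE)
  }
  ni <- nrow(instances)
  nb <- nrow(background)
  # value of one coalition (logical length-p) for all instances
  coalition_value <- function(in_S) {
    X <- background[rep(seq_len(nb), times = ni), , drop = FALSE]
    for (j in which(in_S)) X[[j]] <- rep(instances[[j]], each = nb)
    colMeans(matrix(f(X), nrow = nb))
  }
  base <- mean(f(background))
  phi <- matrix(0, ni, p, dimnames = list(NULL, names(instances)))
  if (mode == "exact") {
    nS <- bitwShiftL(1L, p)
    v <- matrix(NA_real_, ni, nS)
    member <- vapply(0:(nS - 1L), function(mask) {
      as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))))
    }, logical(p))           # p x nS
    for (m in seq_len(nS)) v[, m] <- coalition_value(member[, m])
    sizes <- colSums(member)
    w <- factorial(sizes) * factorial(p - 1L - pmin(sizes, p - 1L)) /
      factorial(p)           # weight of S (as the set without j)
    for (j in seq_len(p)) {
      without <- which(!member[j, ])
      with_j <- without + bitwShiftL(1L, j - 1L)
      contrib <- v[, with_j, drop = FALSE] - v[, without, drop = FALSE]
      phi[, j] <- as.vector(contrib %*% w[without])
    }
  } else {
    set.seed(seed)
    v_empty <- coalition_value(rep(FALSE, p))
    for (r in seq_len(n_perm)) {
      perm <- sample.int(p)
      in_S <- rep(FALSE, p)
      v_prev <- v_empty
      for (j in perm) {
        in_S[j] <- TRUE
        v_cur <- coalition_value(in_S)
        phi[, j] <- phi[, j] + (v_cur - v_prev)
        v_prev <- v_cur
      }
    }
    phi <- phi / n_perm
  }
  attr(phi, "mode") <- mode
  attr(phi, "base_value") <- base
  phi
}

#' Mean-absolute-Shapley table with normalised shares
#'
#' @param phi Shapley matrix from \code{\link{shapley_values}} (or any
#'   instances x features attribution matrix).
#' @return Data.frame \code{feature}, \code{mean_abs_shap}, \code{share},
#'   sorted by decreasing share; shares sum to 1.
#' @export
normalized_importance <- function(phi) {
  m <- colMeans(abs(as.matrix(phi)))
  tot <- sum(m)
  if (tot == 0) stop("all attributions are zero", call. = FALSE)
  out <- data.frame(feature = names(m), mean_abs_shap = unname(m),
                    share = unname(m / tot))
  out[order(-out$share), , drop = FALSE]
}
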