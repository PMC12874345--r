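# Long short-term memory regressor in base R.
#
# Single LSTM layer over sliding windows of daily features, last hidden
# state -> (inverted) dropout -> linear output; mean-squared-error loss,
# Adam updates, mini-batches over shuffled windows. All randomness (weight
# init, dropout masks, batch order) flows from one seed, so fits are
# reproducible bit-for-bit.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform init of all weights; forget-gate bias starts at 1.
.lstm_init <- function(p, H) {
  r1 <- sqrt(6 / (p + H + 4 * H))
  W <- matrix(stats::runif((p + H) * 4 * H, -r1, r1), p + H, 4 * H)
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1
  r2 <- sqrt(6 / (H + 1))
  Wy <- matrix(stats::runif(H, -r2, r2), H, 1)
  list(W = W, b = b, Wy = Wy, by = 0)
}

# Forward pass over a batch of windows.
# Xw: list of length `window`, each a B x p matrix (timestep-major).
# Returns yhat (B) and, if keep = TRUE, the cached tensors for BPTT.
.lstm_forward <- function(weights, Xw, H, drop_mask = NULL, keep = FALSE) {
  B <- nrow(Xw[[1]])
  Tn <- length(Xw)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  cache <- if (keep) vector("list", Tn)
  idx <- list(i = 1:H, f = (H + 1):(2 * H), g = (2 * H + 1):(3 * H),
              o = (3 * H + 1):(4 * H))
  for (t in seq_len(Tn)) {
    z <- cbind(Xw[[t]], h)
    A <- z %*% weights$W
    A <- sweep(A, 2, weights$b, `+`)
    i_g <- sigmoid(A[, idx$i, drop = FALSE])
    f_g <- sigmoid(A[, idx$f, drop = FALSE])
    g_g <- tanh(A[, idx$g, drop = FALSE])
    o_g <- sigmoid(A[, idx$o, drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h <- o_g * tc
    if (keep) {
      cache[[t]] <- list(z = z, i = i_g, f = f_g, g = g_g, o = o_g,
                         c_prev = c_prev, tc = tc)
    }
  }
  h_out <- if (is.null(drop_mask)) h else h * drop_mask
  yhat <- as.vector(h_out %*% weights$Wy + weights$by)
  list(yhat = yhat, h = h, h_out = h_out, cache = cache)
}

# Backward pass (gradients of mean((yhat - y)^2) over the batch).
.lstm_backward <- function(weights, fw, y, H, drop_mask = NULL) {
  B <- length(y)
  Tn <- length(fw$cache)
  dy <- matrix(2 * (fw$yhat - y) / B, B, 1)
  gWy <- t(fw$h_out) %*% dy
  gby <- sum(dy)
  dh <- dy %*% t(weights$Wy)
  if (!is.null(drop_mask)) dh <- dh * drop_mask
  dc <- matrix(0, B, H)
  gW <- matrix(0, nrow(weights$W), ncol(weights$W))
  gb <- rep(0, length(weights$b))
  p <- nrow(weights$W) - H
  for (t in rev(seq_len(Tn))) {
    ca <- fw$cache[[t]]
    dc <- dc + dh * ca$o * (1 - ca$tc^2)
    da_o <- (dh * ca$tc) * ca$o * (1 - ca$o)
    da_i <- (dc * ca$g) * ca$i * (1 - ca$i)
    da_g <- (dc * ca$i) * (1 - ca$g^2)
    da_f <- (dc * ca$c_prev) * ca$f * (1 - ca$f)
    dA <- cbind(da_i, da_f, da_g, da_o)
    gW <- gW + t(ca$z) %*% dA
    gb <- gb + colSums(dA)
    dz <- dA %*% t(weights$W)
    dh <- dz[, (p + 1):(p + H), drop = FALSE]
    dc <- dc * ca$f
  }
  list(W = gW, b = gb, Wy = gWy, by = gby)
}

.adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$w[[nm]] <- state$w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# Min-max scaler fitted on training rows only.
.fit_scaler <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}
.scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$lo), 2, sc$rng, `/`)

# Window index matrix: row r = feature-series rows feeding target row
# targets[r]; each window spans `window` consecutive days ending at the
# target day.
.window_index <- function(n_rows, window, target_rows) {
  t(vapply(target_rows, function(t) (t - window + 1):t, integer(window)))
}

#' Fit the LSTM baseline
#'
#' Gated recurrent network over sliding windows of \code{window} consecutive
#' days of features, predicting the target of the window's last day.
#' Defaults follow the tuned plant configuration: 128 units, dropout 0.1 on
#' the final hidden state, Adam, batch size 16, 50 epochs. Features and
#' target are min--max scaled on the training rows only; predictions are
#' returned on the original scale. Fully seeded (weight initialisation,
#' batch shuffling, dropout masks), so identical seeds reproduce identical
#' predictions.
#'
#' @param train Training \code{feature_matrix} (chronologically ordered).
#' @param hyper Named list overriding \code{units} (128), \code{dropout}
#'   (0.1), \code{optimizer} ("adam"), \code{batch_size} (16), \code{epochs}
#'   (50), \code{lr} (0.01).
#' @param window Window length in days (default 7, the plant's weekly
#'   feeding rhythm).
#' @param seed RNG seed.
#' @return Object of class \code{lstm_model} with the training loss per
#'   epoch in \code{$log}.
#' @export
fit_lstm <- function(train, hyper = list(), window = 7L, seed = 1L) {
  hp <- utils::modifyList(list(units = 128L, dropout = 0.1,
                               optimizer = "adam", batch_size = 16L,
                               epochs = 50L, lr = 0.01),
                          hyper)
  if (!identical(hp$optimizer, "adam")) {
    stop("only the Adam optimizer is implemented", call. = FALSE)
  }
  feats <- fm_features(train)
  n <- nrow(train)
  if (n <= window) {
    stop("window (", window, ") must be shorter than the training series (",
         n, ")", call. = FALSE)
  }
  X <- as.matrix(train[, feats, drop = FALSE])
  y <- train$.target
  scx <- .fit_scaler(X)
  scy <- .fit_scaler(matrix(y, ncol = 1))
  Xs <- .scale_apply(X, scx)
  ys <- as.vector(.scale_apply(matrix(y, ncol = 1), scy))

  H <- as.integer(hp$units)
  p <- length(feats)
  set.seed(seed)
  w <- .lstm_init(p, H)
  zeros <- lapply(w, function(x) x * 0)
  opt <- list(w = w, m = zeros, v = zeros)

  targets <- seq.int(window, n)
  idx <- .window_index(n, window, targets)
  n_win <- length(targets)
  losses <- numeric(hp$epochs)
  step <- 0L
  if (hp$epochs >= 1) for (ep in seq_len(hp$epochs)) {
    ord <- sample.int(n_win)
    ep_loss <- 0
    for (start in seq(1, n_win, by = hp$batch_size)) {
      rows <- ord[start:min(start + hp$batch_size - 1, n_win)]
      B <- length(rows)
      Xw <- lapply(seq_len(window), function(t) {
        Xs[idx[rows, t], , drop = FALSE]
      })
      mask <- if (hp$dropout > 0) {
        matrix(stats::rbinom(B * H, 1, 1 - hp$dropout), B, H) /
          (1 - hp$dropout)
      }
      fw <- .lstm_forward(opt$w, Xw, H, drop_mask = mask, keep = TRUE)
      gr <- .lstm_backward(opt$w, fw, ys[targets[rows]], H, drop_mask = mask)
      step <- step + 1L
      opt <- .adam_step(opt, gr, hp$lr, step)
      ep_loss <- ep_loss + sum((fw$yhat - ys[targets[rows]])^2)
    }
    losses[ep] <- ep_loss / n_win
  }
  structure(list(weights = opt$w, hyper = hp, window = as.integer(window),
                 features = feats, scaler_x = scx, scaler_y = scy,
                 seed = seed, log = losses,
                 combo_id = attr(train, "combo_id"),
                 target_name = attr(train, "target_name"),
                 tail_context = X[max(1, n - window + 2):n, , drop = FALSE]),
            class = "lstm_model")
}

#' Predict from a fitted LSTM
#'
#' Each prediction for day t consumes the feature window ending at day t.
#' For the first \code{window - 1} rows of \code{newdata} the window reaches
#' back into \code{context} (by default the tail of the training features,
#' the natural choice when the test period chronologically follows
#' training); with \code{context = NA} the first row is repeated instead.
#'
#' @param object An \code{lstm_model}.
#' @param newdata Feature matrix/data.frame of the days to predict.
#' @param context Data.frame/matrix of rows immediately preceding
#'   \code{newdata}, or NA for first-row padding.
#' @param ... Unused.
#' @return Numeric predictions on the original target scale; dropout is
#'   inactive at inference.
#' @export
predict.lstm_model <- function(object, newdata, context = NULL, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  w <- object$window
  ctx <- if (is.null(context)) {
    object$tail_context
  } else if (length(context) == 1 && is.na(context)) {
    X[rep(1, w - 1), , drop = FALSE]
  } else {
    as.matrix(as.data.frame(context)[, object$features, drop = FALSE])
  }
  if (nrow(ctx) > w - 1) ctx <- ctx[(nrow(ctx) - w + 2):nrow(ctx), , drop = FALSE]
  if (nrow(ctx) < w - 1) {
    ctx <- rbind(ctx[rep(1, w - 1 - nrow(ctx)), , drop = FALSE], ctx)
  }
  series <- .scale_apply(rbind(ctx, X), object$scaler_x)
  n <- nrow(X)
  targets <- seq.int(w, w - 1 + n)
  idx <- .window_index(nrow(series), w, targets)
  H <- as.integer(object$hyper$units)
  Xw <- lapply(seq_len(w), function(t) series[idx[, t], , drop = FALSE])
  fw <- .lstm_forward(object$weights, Xw, H)
  fw$yhat * object$scaler_y$rng + object$scaler_y$lo
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf(
    "LSTM (%d units, dropout %.2f, window %d d) on %d features [%s -> %s]\n",
    x$hyper$units, x$hyper$dropout, x$window, length(x$features),
    x$combo_id %||% "?", x$target_name %||% "?"))
  if (x$hyper$epochs >= 1) {
    cat(sprintf("  trained %d epochs, final loss %.5f (scaled)\n",
                x$hyper$epochs, x$log[length(x$log)]))
  }
  invisible(x)
}
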