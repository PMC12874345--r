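# Shared fixtures and independent oracles, built in code at test time.

# A small synthetic campaign; defaults keep module tests fast.
tiny_campaign <- function(n_days = 120L, seed = 1L, noise_sigma = 0.05, ...) {
  campaign_config(n_days = n_days, seed = seed, noise_sigma = noise_sigma,
                  ...)
}

# A single-feedstock spec with full degradability, for hand arithmetic.
simple_spec <- function(name = "sub", ts = 30, vs = 90,
                        xa = 0, xc = 1000, xp = 0, xl = 0, dq = 1) {
  suppressWarnings(
    feedstock_spec(name, ts_pct_fm = ts, vs_pct_ts = vs,
                   xa = xa, xc = xc, xp = xp, xl = xl, dq_xc = dq))
}

simple_schedule <- function(fm_t_d, name = "sub", n = length(fm_t_d),
                            start = "2023-01-01") {
  m <- matrix(fm_t_d, ncol = 1, dimnames = list(NULL, name))
  feed_schedule(as.Date(start) + seq_len(n) - 1, m)
}

# Campaign -> feature matrix -> chronological split, in one call.
make_split <- function(seed = 1L, combo = "feedstocks_olr_vsmaize",
                       target = "biogas", n_days = 500L) {
  cfg <- campaign_config(n_days = n_days, seed = seed)
  ds <- generate_plant_dataset(cfg)
  fm <- build_feature_set(ds, combo_id = combo, target = target,
                          config = cfg$digester)
  c(chronological_split(fm), list(fm = fm, ds = ds))
}

# All permutations of 1..n (recursive; only used for n <= 6).
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Independent brute-force Shapley oracle: average marginal contribution over
# every permutation, with the interventional value function computed row by
# row. Deliberately naive and structured differently from the package code.
shapley_brute_force <- function(f, x, background) {
  x <- as.numeric(x)
  p <- length(x)
  bg <- as.matrix(background)
  value_of <- function(S) {
    tot <- 0
    for (r in seq_len(nrow(bg))) {
      z <- bg[r, ]
      z[S] <- x[S]
      tot <- tot + f(matrix(z, 1, dimnames = list(NULL, colnames(bg))))
    }
    tot / nrow(bg)
  }
  pm <- perms(p)
  phi <- numeric(p)
  for (i in seq_len(nrow(pm))) {
    S <- integer(0)
    v_prev <- value_of(S)
    for (j in pm[i, ]) {
      S <- c(S, j)
      v <- value_of(S)
      phi[j] <- phi[j] + (v - v_prev)
      v_prev <- v
    }
  }
  phi / nrow(pm)
}

# First-order CSTR steady state recomputed from scratch (independent of
# analytic_steady_state): solves 0 = load/V - (D + k) x per class and
# converts hydrolysed mass with Buswell yields evaluated here.
steady_state_oracle <- function(loads, k, v_liq, hrt) {
  D <- 1 / hrt
  x <- (loads / v_liq) / (D + k)
  yields <- list(c(C = 6, H = 10, O = 5, N = 0),
                 c(C = 5, H = 7, O = 2, N = 1),
                 c(C = 57, H = 104, O = 6, N = 0))
  mass <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)
  gas <- ch4 <- 0
  for (j in 1:3) {
    f <- yields[[j]]
    M <- sum(mass * f)
    n_ch4 <- (4 * f["C"] + f["H"] - 2 * f["O"] - 3 * f["N"]) / 8
    n_gas <- f["C"]
    gas <- gas + k[j] * x[j] * v_liq * n_gas * 0.022414 * 1000 / M
    ch4 <- ch4 + k[j] * x[j] * v_liq * n_ch4 * 0.022414 * 1000 / M
  }
  c(biogas = unname(gas), methane = unname(ch4))
}
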