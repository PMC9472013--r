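# Shared fixtures: every test input is generated in code at test time.

# full preprocessing + two-layer fit on one synthetic curve
fit_curve_pipeline <- function(cfg, seed) {
  cv <- baseline_correct(gen_force_curve(cfg, seed = seed))
  ind <- to_indentation(cv, detect_contact(cv))
  fit_two_layer(ind)
}

# single-layer generation + single Hertz fit at truth modulus E_true
fit_single_pipeline <- function(E_true, seed, noise_sd = 0.01) {
  cfg <- synth_config(seed = seed, E1_true = E_true,
                      noise_sd_force = noise_sd)
  cv <- baseline_correct(gen_force_curve(cfg, seed = seed,
                                         single_layer = TRUE))
  ind <- to_indentation(cv, detect_contact(cv))
  fit_single_hertz(ind)
}

# independent polygon-area oracle: shoelace formula on the closed path
# (approach forward, retract backward), positive-force region
shoelace_area <- function(delta_app, f_app, delta_ret, f_ret) {
  f_app <- pmax(f_app, 0); f_ret <- pmax(f_ret, 0)
  x <- c(delta_app, rev(delta_ret))
  y <- c(f_app, rev(f_ret))
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# exact two-sided Mann-Whitney U p-value by full enumeration of group
# assignments (feasible for n1 + n2 <= 10)
mw_enumerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}
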