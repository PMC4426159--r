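# Shared fixtures, built in code.

# two equal-sized groups, rates (2, 1) per person-year in a single age band
# (hand-workable: y_mean = 1.5, C = -1/6)
two_group_21 <- function() {
  d <- matrix(c(20000, 10000), nrow = 1,
              dimnames = list(NULL, c("low", "high")))
  p <- matrix(c(10000, 10000), nrow = 1, dimnames = dimnames(d))
  register_table(d, p)
}

# G groups, I age bands, identical age-specific rates everywhere
equal_rate_table <- function(G = 5, I = 3) {
  rates <- seq(0.001, 0.003, length.out = I)
  p <- matrix(10000 * seq_len(G), nrow = I, ncol = G, byrow = TRUE)
  d <- round(p * rates)   # d/p identical across g within each age band
  register_table(d, p, seg_groups = paste0("g", seq_len(G)))
}

# labels follow register_table()'s defaults (age1, age2, ...)
uniform_stdpop <- function(I = 3) {
  standard_population(rep(1, I), age_groups = paste0("age", seq_len(I)))
}

# register-scale synthetic table, generated once per test run
preset_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_table(synthetic_preset("finland-1996-men",
                                                seed = 20260911L))
    cache
  }
})

# independent trapezoid oracle: C = 1 - 2 * area under the piecewise-linear
# concentration curve
trapezoid_C <- function(curve) {
  s <- curve$s
  L <- curve$L
  1 - sum(diff(s) * (utils::head(L, -1) + utils::tail(L, -1)))
}

# independent brute-force evaluation of the serial-correlation-corrected
# variance (loop form, no shared code with kwv_interval)
kwv_var_oracle <- function(f, R, y, n_obs) {
  G <- length(f)
  ybar <- sum(f * y)
  C <- 2 / ybar * sum(y * f * R) - 1
  q <- numeric(G)
  acc <- 0
  for (g in seq_len(G)) {
    acc <- acc + f[g] * y[g] / ybar
    q[g] <- acc
  }
  a <- numeric(G)
  for (g in seq_len(G)) {
    q_prev <- if (g == 1) 0 else q[g - 1]
    a[g] <- y[g] / ybar * (2 * R[g] - 1 - C) + 2 - q_prev - q[g]
  }
  (sum(f * a^2) - (1 + C)^2) / n_obs
}
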