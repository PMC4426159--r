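# interval_montecarlo: the five simulation procedures, the percentile
# interval, the orchestrator and the empirical cross-year variance

test_that("percentile interval uses type-7 order-statistic interpolation", {
  rs <- structure(list(values = as.numeric(1:10000), n_failed = 0L,
                       method = "MC", config = sim_config(seed = 1)),
                  class = "replicate_set")
  est <- percentile_interval(rs, alpha = 0.05)
  expect_equal(est$lower, 250.975)    # 1 + 0.025 * 9999
  expect_equal(est$upper, 9750.025)
  expect_equal(est$replicate_median, 5000.5)
  expect_equal(est$length, est$upper - est$lower)

  rs$values <- rep(0.3, 50)
  est0 <- percentile_interval(rs)
  expect_equal(est0$length, 0)
  expect_equal(est0$lower, 0.3)
})

test_that("sim_config validates its fields", {
  expect_error(sim_config("MC", estimator = "formula"),
               "estimator must be 'wls'")
  expect_error(sim_config("nonsense"), "unknown method")
  expect_error(sim_config("BIN", n_replicates = 0), "n_replicates")
  expect_error(sim_config("MC", variance_divisor = c(1, 0)), "positive")
  expect_identical(sim_config("mc-rate")$method, "MC_RATE")
})

test_that("fixed seed gives bit-identical replicate sets for every method", {
  sim <- preset_fixture()
  prof <- build_seg_profile(sim$table, sim$stdpop)
  for (m in c("MC", "MC_RATE", "BIN", "POIS", "MN")) {
    cfg <- sim_config(m, n_replicates = 200, seed = 77)
    run <- function() switch(m,
      MC = draw_mc(prof, cfg), MC_RATE = draw_mc_rate(prof, cfg),
      BIN = draw_bin(sim$table, sim$stdpop, cfg),
      POIS = draw_pois(sim$table, sim$stdpop, cfg),
      MN = draw_mn(sim$table, sim$stdpop, cfg))
    expect_identical(run()$values, run()$values, label = m)
  }
})

test_that("MC: degenerate variance pins every replicate at the observed C", {
  sim <- preset_fixture()
  prof <- build_seg_profile(sim$table, sim$stdpop)
  C_obs <- concentration_index_formula(prof)$C
  cfg <- sim_config("MC", n_replicates = 100, seed = 3,
                    variance_divisor = rep(1e12, 20))
  vals <- draw_mc(prof, cfg)$values
  expect_lt(max(abs(vals - C_obs)), 1e-5)
})

test_that("MC: shrinking the divisor widens the interval, not the median", {
  sim <- preset_fixture()
  prof <- build_seg_profile(sim$table, sim$stdpop)
  C_obs <- concentration_index_formula(prof)$C
  base <- percentile_interval(
    draw_mc(prof, sim_config("MC", n_replicates = 4000, seed = 11)),
    C_obs = C_obs)
  inflated <- percentile_interval(
    draw_mc(prof, sim_config("MC", n_replicates = 4000, seed = 11,
                             variance_divisor = prof$n / 4)),
    C_obs = C_obs)
  expect_gt(inflated$length, 1.5 * base$length)
  # medians agree within Monte Carlo error of the wider run
  # median standard error ~ 1.2533 sd/sqrt(N), sd proxied by length/3.92
  mc_se <- 1.2533 * (inflated$length / 3.92) / sqrt(4000)
  expect_lt(abs(inflated$replicate_median - base$replicate_median),
            4 * mc_se)
})

test_that("MC_RATE: zero-rate groups are degenerate at zero; estimators agree", {
  d <- matrix(c(0, 30, 40, 0, 25, 35), nrow = 1)   # group 1 has no events
  p <- matrix(2e4, 1, 6)
  tab <- register_table(d, p)
  prof <- build_seg_profile(tab, uniform_stdpop(1))
  cfg_f <- sim_config("MC_RATE", estimator = "formula",
                      n_replicates = 500, seed = 5)
  rep_f <- draw_mc_rate(prof, cfg_f)
  expect_true(all(rep_f$rates[1, ] == 0))
  cfg_w <- sim_config("MC_RATE", estimator = "wls",
                      n_replicates = 500, seed = 5)
  rep_w <- draw_mc_rate(prof, cfg_w)
  expect_equal(rep_f$values, rep_w$values, tolerance = 1e-10)
})

test_that("BIN: degenerate probabilities reproduce the observed table", {
  # each age band's deaths sit entirely in one group: rho is 0/1
  d <- matrix(c(50, 0, 0, 0, 0, 80), nrow = 3)
  p <- matrix(1e4, 3, 2)
  tab <- register_table(d, p)
  sp <- uniform_stdpop(3)
  est <- run_interval(tab, sp, sim_config("BIN", n_replicates = 300,
                                          seed = 9))
  expect_equal(est$length, 0)
  expect_equal(est$replicate_median, est$C, tolerance = 1e-12)
  # middle age band has D_i = 0 and contributes nothing, without error
})

test_that("POIS: zero cells stay zero; replicate rate means track the table", {
  d <- matrix(c(0, 40, 200, 0, 60, 100), nrow = 3)
  p <- matrix(1e4, 3, 2)
  tab <- register_table(d, p)
  sp <- uniform_stdpop(3)
  reps <- draw_pois(tab, sp, sim_config("POIS", n_replicates = 4000,
                                        seed = 21))
  y_obs <- age_standardize(tab, sp)
  y_bar <- rowMeans(reps$rates)
  # Poisson mean identity: mean simulated rate ~ observed rate
  expect_equal(unname(y_bar), unname(y_obs), tolerance = 0.03)
})

test_that("MN: age-group totals are conserved in every replicate", {
  d <- matrix(c(12, 30, 8, 0, 25, 45), nrow = 2)
  p <- matrix(c(1e4, 2e4, 1e4, 2e4, 1e4, 2e4), nrow = 2)
  tab <- register_table(d, p)
  sp <- uniform_stdpop(2)
  reps <- draw_mn(tab, sp, sim_config("MN", n_replicates = 500, seed = 31))
  # person-years are constant within each age band, so the fixed band
  # totals sum_g X_ig = D_i make the total simulated rate mass
  # sum_g y*_g = sum_i (w_i / p_i) D_i identical in every replicate
  tot <- colSums(reps$rates)
  expect_equal(max(tot) - min(tot), 0, tolerance = 1e-9)
  # groups with rho = 0 never receive events: group 1 band mass bounded
  d2 <- matrix(c(0, 100, 50, 30), nrow = 1)
  tab2 <- register_table(d2, matrix(1e4, 1, 4))
  reps2 <- draw_mn(tab2, uniform_stdpop(1),
                   sim_config("MN", n_replicates = 300, seed = 8))
  expect_true(all(reps2$rates[1, ] == 0))
})

test_that("run_interval: orchestration contracts", {
  sim <- preset_fixture()
  cfg1 <- sim_config("BIN", n_replicates = 1, seed = 4)
  est1 <- run_interval(sim$table, sim$stdpop, cfg1)
  expect_equal(est1$lower, est1$upper)        # single replicate
  expect_equal(est1$n_replicates, 1L)
  # point estimate is the observed-data C, not a replicate statistic
  prof <- build_seg_profile(sim$table, sim$stdpop)
  expect_equal(est1$C, concentration_index_formula(prof)$C)

  cfg <- sim_config("MN", n_replicates = 500, seed = 12)
  a <- run_interval(sim$table, sim$stdpop, cfg)
  b <- run_interval(sim$table, sim$stdpop, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("median consistency holds for the near-symmetric methods", {
  sim <- preset_fixture()
  prof <- build_seg_profile(sim$table, sim$stdpop)
  C_obs <- concentration_index_formula(prof)$C
  for (m in c("MC", "MC_RATE", "BIN", "MN")) {
    est <- run_interval(sim$table, sim$stdpop,
                        sim_config(m, n_replicates = 3000, seed = 6))
    mc_se <- 1.2533 * (est$length / 3.92) / sqrt(3000)
    expect_lt(abs(est$replicate_median - C_obs), 3 * mc_se)
  }
})

test_that("interval length shrinks like 1/sqrt(k) when counts scale by k", {
  sim <- preset_fixture()
  k <- 4L
  scaled <- register_table(sim$table$deaths * k, sim$table$person_years * k)
  l1 <- run_interval(sim$table, sim$stdpop,
                     sim_config("MC_RATE", n_replicates = 4000,
                                seed = 14))$length
  lk <- run_interval(scaled, sim$stdpop,
                     sim_config("MC_RATE", n_replicates = 4000,
                                seed = 14))$length
  expect_equal(l1 / lk, sqrt(k), tolerance = 0.1)
})

test_that("empirical cross-year variances follow the sample-variance rule", {
  rates <- rbind(g1 = c(50, 50, 50), g2 = c(10, 16, 13))
  panel <- multi_year_rates(rates, years = c("1996", "1997", "1998"))
  v <- empirical_rate_variance(panel, c("1996", "1997", "1998"))
  expect_equal(unname(v), c(0, var(c(10, 16, 13))))
  # two-point window: (a - b)^2 / 2
  v2 <- empirical_rate_variance(panel, c("1996", "1997"))
  expect_equal(unname(v2[2]), (10 - 16)^2 / 2)
  expect_error(empirical_rate_variance(panel, c("1996", "2001")), "2001")
  expect_error(empirical_rate_variance(panel, "1996"), "two years")
})

test_that("empirical variances can replace the model variance in MC-rate", {
  cfg <- synthetic_config(G = 10, total_person_years = 3e6, years = 7,
                          seed = 303)
  panel <- generate_panel(cfg)
  regs <- attr(panel, "registers")
  target <- regs[[4]]
  v_emp <- empirical_rate_variance(panel, panel$years)
  est_emp <- run_interval(target$table, target$stdpop,
                          sim_config("MC_RATE", n_replicates = 3000,
                                     seed = 2, rate_variances = v_emp))
  est_mod <- run_interval(target$table, target$stdpop,
                          sim_config("MC_RATE", n_replicates = 3000,
                                     seed = 2))
  # on a well-calibrated synthetic panel the empirical and model variances
  # agree in aggregate, so the interval lengths are close
  expect_equal(est_emp$length / est_mod$length, 1, tolerance = 0.35)
})
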