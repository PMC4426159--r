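# Monte Carlo percentile intervals for the concentration index from
# aggregated register data.  Five procedures, differing in what is
# perturbed and under which distribution:
#   MC      — the WLS dependent variable 2*sigma2_R*y_g/ybar, normal
#   MC_RATE — the age-standardized rates y_g, normal
#   BIN     — cell death counts, independent Binomial(D_i, rho_ig)
#   POIS    — cell death counts, Poisson(d_ig)
#   MN      — cell counts within each age group, Multinomial(D_i, rho_i)
# Population shares, ranks, person-years and standard weights are held
# fixed throughout ("fixed proportions"), so only the outcome varies.

SIM_METHODS <- c("MC", "MC_RATE", "BIN", "POIS", "MN")
ALL_METHODS <- c("REG", "KWV", SIM_METHODS)

#' Simulation configuration
#'
#' Bundles the knobs of the Monte Carlo interval procedures.
#'
#' @param method one of `"MC"`, `"MC_RATE"`, `"BIN"`, `"POIS"`, `"MN"`
#'   (case-insensitive; `"mc-rate"` is accepted for `"MC_RATE"`).
#' @param estimator `"formula"` or `"wls"`.  MC perturbs the regression's
#'   dependent variable and therefore only supports `"wls"` (the default
#'   there); for the other methods both estimators give identical replicate
#'   values because the mean rate is recomputed per replicate.
#' @param n_replicates number of simulated datasets N (default 10,000).
#' @param seed integer RNG seed; every draw function seeds from it, so a
#'   fixed configuration is bit-reproducible.
#' @param alpha two-sided nominal error rate (default 0.05).
#' @param variance_divisor optional positive per-group values replacing the
#'   observed event counts n_g in the MC / MC_RATE variances.  Values below
#'   n_g inflate the assumed error ("fewer events, more variation") and so
#'   widen the interval without moving its centre.
#' @param rate_variances optional per-group variances for the standardized
#'   rates, replacing the model variance `y_g^2 / n_g` in MC / MC_RATE —
#'   e.g. empirical cross-year variances from [empirical_rate_variance()].
#' @param max_fail_frac a run aborts if more than this fraction of
#'   replicates yields an undefined index (simulated mean rate <= 0);
#'   default 0.01.
#' @return A `sim_config` list.
#' @export
sim_config <- function(method = c("MC", "MC_RATE", "BIN", "POIS", "MN"),
                       estimator = NULL, n_replicates = 10000L,
                       seed = 1L, alpha = 0.05,
                       variance_divisor = NULL, rate_variances = NULL,
                       max_fail_frac = 0.01) {
  if (length(method) == 1L) method <- normalize_method(method)
  method <- match.arg(method)
  if (is.null(estimator)) estimator <- if (method == "MC") "wls" else "formula"
  estimator <- match.arg(estimator, c("formula", "wls"))
  if (method == "MC" && estimator != "wls")
    stop("MC perturbs the regression outcome variable: estimator must be 'wls'")
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 1L, alpha > 0, alpha < 1,
            max_fail_frac >= 0, max_fail_frac <= 1)
  if (!is.null(variance_divisor) && any(variance_divisor <= 0))
    stop("variance_divisor entries must be positive")
  if (!is.null(rate_variances) && any(rate_variances < 0))
    stop("rate_variances entries must be non-negative")
  structure(list(method = method, estimator = estimator,
                 n_replicates = n_replicates, seed = as.integer(seed),
                 alpha = alpha, variance_divisor = variance_divisor,
                 rate_variances = rate_variances,
                 max_fail_frac = max_fail_frac),
            class = "sim_config")
}

normalize_method <- function(m) {
  m <- toupper(gsub("-", "_", as.character(m)))
  if (m == "MCRATE") m <- "MC_RATE"
  if (!m %in% ALL_METHODS)
    stop(sprintf("unknown method '%s' (known: %s)", m,
                 paste(ALL_METHODS, collapse = ", ")))
  m
}

new_replicate_set <- function(values, n_failed, method, config,
                              extras = list()) {
  if (any(!is.finite(values)))
    stop("internal error: non-finite replicate values")
  structure(c(list(values = values, n_failed = as.integer(n_failed),
                   method = method, config = config), extras),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("%s replicate set: %d values (%d failed), median %.4f\n",
              x$method, length(x$values), x$n_failed,
              stats::median(x$values)))
  invisible(x)
}

# per-group sd of the simulated standardized rates (shared by MC / MC_RATE)
rate_sd <- function(profile, config) {
  if (!is.null(config$rate_variances)) {
    stopifnot(length(config$rate_variances) == length(profile$y))
    return(sqrt(config$rate_variances))
  }
  div <- config$variance_divisor
  if (is.null(div)) div <- profile$n
  stopifnot(length(div) %in% c(1L, length(profile$y)))
  div <- rep_len(div, length(profile$y))
  # a group with zero rate has zero model variance (degenerate draw at 0);
  # a positive rate with no event count to divide by is unresolvable
  if (any(div == 0 & profile$y > 0)) {
    g <- profile$seg_groups[which(div == 0 & profile$y > 0)]
    stop(sprintf(paste0("group(s) %s have zero events: supply ",
                        "`variance_divisor` to define the simulation variance"),
                 paste(g, collapse = ", ")))
  }
  ifelse(profile$y == 0, 0, profile$y / sqrt(div))
}

#' MC: perturb the regression outcome variable
#'
#' Each replicate draws the G values of the WLS dependent variable
#' \eqn{2\sigma_R^2 y_g/\bar y} from independent normals centred at the
#' observed values with standard deviation
#' \eqn{2\sigma_R^2 y_g/(\bar y\sqrt{n_g})}, then refits the regression with
#' ranks, weights and \eqn{\sigma_R^2} fixed; the replicate value is the
#' slope.  Draws are not truncated at zero (truncation would break the
#' symmetry and the median-equals-observed-C property); the number of
#' negative draws is recorded in `n_negative_draws`.
#'
#' @param profile a [build_seg_profile()] result.
#' @param config a [sim_config()] (its `method` field is not consulted).
#' @return A `replicate_set`.
#' @export
draw_mc <- function(profile, config) {
  stopifnot(inherits(profile, "seg_profile"))
  G <- length(profile$y)
  N <- config$n_replicates
  scale <- 2 * profile$sigma2_R / profile$y_mean
  mu <- scale * profile$y
  sdv <- scale * rate_sd(profile, config)
  set.seed(config$seed)
  Z <- matrix(stats::rnorm(G * N, mean = mu, sd = sdv), nrow = G)
  k <- slope_weights(profile)
  values <- drop(crossprod(Z, k))
  new_replicate_set(values, 0L, "MC", config,
                    extras = list(n_negative_draws = sum(Z < 0)))
}

#' MC-rate: perturb the age-standardized rates
#'
#' Each replicate draws the group rates from independent normals
#' \eqn{y_g^* \sim N(y_g, y_g^2/n_g)}, recomputes the weighted mean rate
#' from the draws, and evaluates the concentration index with shares and
#' ranks fixed.  Because the mean is recomputed per replicate, the formula
#' and WLS estimators coincide exactly on the same draws.  Replicates with
#' a non-positive simulated mean rate are excluded and counted in
#' `n_failed`.
#'
#' @inheritParams draw_mc
#' @return A `replicate_set`.
#' @export
draw_mc_rate <- function(profile, config) {
  stopifnot(inherits(profile, "seg_profile"))
  G <- length(profile$y)
  N <- config$n_replicates
  sdv <- rate_sd(profile, config)
  set.seed(config$seed)
  Y <- matrix(stats::rnorm(G * N, mean = profile$y, sd = sdv), nrow = G)
  finish_rate_replicates(Y, profile, config, "MC_RATE")
}

# shared tail: standardized-rate matrix (G x N) -> index values
finish_rate_replicates <- function(Y, profile, config, method) {
  f <- profile$f
  ym <- drop(crossprod(Y, f))
  ok <- ym > 0
  if (config$estimator == "wls") {
    k <- slope_weights(profile)
    # z*_g = 2 sigma2_R y*_g / ybar*; slope = sum_g k_g z*_g
    values <- 2 * profile$sigma2_R * drop(crossprod(Y, k)) / ym
  } else {
    values <- 2 * drop(crossprod(Y, f * profile$R)) / ym - 1
  }
  new_replicate_set(values[ok], sum(!ok), method, config,
                    extras = list(rates = Y[, ok, drop = FALSE]))
}

# rho_ig = d_ig / D_i with empty age groups giving rho = 0 (their draws are
# identically zero); zero probabilities are explicitly permitted.
cell_probs <- function(deaths) {
  D <- rowSums(deaths)
  rho <- deaths / ifelse(D > 0, D, 1)
  rho[D == 0, ] <- 0
  list(D = D, rho = rho)
}

# count matrix draws (I*G x N, age fastest) -> standardized rates (G x N)
standardize_count_draws <- function(Dstar, table, w) {
  I <- nrow(table$deaths)
  G <- ncol(table$deaths)
  coefs <- as.vector(w / table$person_years)   # w_i / p_ig, cell order (i, g)
  rowsum(Dstar * coefs, group = rep(seq_len(G), each = I), reorder = FALSE)
}

#' BIN: resample cell counts as independent binomials
#'
#' Holds person-years fixed, treats the events as random: each cell count is
#' drawn as \eqn{d_{ig}^* \sim B(D_i, \rho_{ig})} with
#' \eqn{D_i = \sum_g d_{ig}} the observed age-group total and
#' \eqn{\rho_{ig} = d_{ig}/D_i}.  The G binomials within an age group share
#' the index \eqn{D_i} but are drawn independently, so the simulated total
#' event count varies between replicates.  Each replicate is
#' age-standardized with the observed person-years and weights, and the
#' index recomputed.
#'
#' @param table a [register_table()].
#' @param stdpop a matching [standard_population()].
#' @param config a [sim_config()].
#' @return A `replicate_set`.
#' @export
draw_bin <- function(table, stdpop, config) {
  profile <- build_seg_profile(table, stdpop)
  cp <- cell_probs(table$deaths)
  if (all(cp$D == 0))
    stop("no events in any age group: counts cannot be resampled")
  I <- nrow(table$deaths); G <- ncol(table$deaths)
  N <- config$n_replicates
  set.seed(config$seed)
  Dstar <- matrix(stats::rbinom(I * G * N, size = rep(cp$D, G),
                                prob = as.vector(cp$rho)),
                  nrow = I * G)
  Y <- standardize_count_draws(Dstar, table, align_stdpop(table, stdpop))
  finish_rate_replicates(Y, profile, config, "BIN")
}

#' POIS: resample cell counts as Poissons
#'
#' As [draw_bin()], but each cell count is drawn
#' \eqn{d_{ig}^* \sim Pois(\lambda_{ig})} with \eqn{\lambda_{ig}} the
#' observed count (zero cells always draw zero).  With many small-mean
#' cells the replicate distribution is right-skewed, which is what makes
#' the POIS interval the one method that can be visibly asymmetric.
#'
#' @inheritParams draw_bin
#' @return A `replicate_set`.
#' @export
draw_pois <- function(table, stdpop, config) {
  profile <- build_seg_profile(table, stdpop)
  I <- nrow(table$deaths); G <- ncol(table$deaths)
  N <- config$n_replicates
  set.seed(config$seed)
  Dstar <- matrix(stats::rpois(I * G * N, lambda = as.vector(table$deaths)),
                  nrow = I * G)
  Y <- standardize_count_draws(Dstar, table, align_stdpop(table, stdpop))
  finish_rate_replicates(Y, profile, config, "POIS")
}

#' MN: resample counts as multinomials within age groups
#'
#' Holds each age-group total \eqn{D_i} exactly fixed and redistributes it
#' across income groups:
#' \eqn{(X_{i1},\dots,X_{iG}) \sim Multinomial(D_i, \rho_i)} with
#' \eqn{\rho_{ig} = d_{ig}/D_i}, so \eqn{\sum_g X_{ig} = D_i} in every
#' replicate.  Appropriate when the event total is considered reliable and
#' only the socioeconomic attribution is uncertain.
#'
#' @inheritParams draw_bin
#' @return A `replicate_set`.
#' @export
draw_mn <- function(table, stdpop, config) {
  profile <- build_seg_profile(table, stdpop)
  cp <- cell_probs(table$deaths)
  if (all(cp$D == 0))
    stop("no events in any age group: counts cannot be resampled")
  I <- nrow(table$deaths); G <- ncol(table$deaths)
  N <- config$n_replicates
  w <- align_stdpop(table, stdpop)
  set.seed(config$seed)
  Y <- matrix(0, nrow = G, ncol = N)
  for (i in seq_len(I)) {
    if (cp$D[i] == 0) next
    X <- stats::rmultinom(N, size = cp$D[i], prob = cp$rho[i, ])
    Y <- Y + (w[i] / table$person_years[i, ]) * X
  }
  finish_rate_replicates(Y, profile, config, "MN")
}

#' Percentile interval from a replicate set
#'
#' The empirical `alpha/2` and `1 - alpha/2` quantiles of the simulated
#' index values (order statistics with linear interpolation, quantile
#' type 7).  The point estimate attached to the interval is always the
#' index computed from the observed data, never a replicate summary; the
#' replicate median is reported alongside.
#'
#' @param replicates a `replicate_set` from one of the `draw_*()` functions.
#' @param alpha two-sided nominal error rate.
#' @param C_obs observed-data concentration index to attach as the point
#'   estimate (defaults to the replicate median if omitted).
#' @return An `interval_estimate`.
#' @export
percentile_interval <- function(replicates, alpha = 0.05, C_obs = NULL) {
  stopifnot(inherits(replicates, "replicate_set"))
  v <- replicates$values
  if (length(v) == 0L) stop("all replicates failed: no index values")
  stopifnot(alpha > 0, alpha < 1)
  qs <- stats::quantile(v, c(alpha / 2, 1 - alpha / 2),
                        names = FALSE, type = 7)
  med <- stats::median(v)
  if (is.null(C_obs)) C_obs <- med
  new_interval_estimate(replicates$method, C_obs, qs[1L], qs[2L], alpha,
                        estimator = replicates$config$estimator,
                        n_replicates = length(v),
                        replicate_median = med,
                        n_failed = replicates$n_failed)
}

#' Run one simulation interval end to end
#'
#' Builds the profile, computes the observed-data concentration index with
#' the configured estimator, generates the replicates for the configured
#' method and returns the percentile interval.  A run errors out if the
#' fraction of failed replicates exceeds `config$max_fail_frac`.
#'
#' @inheritParams draw_bin
#' @return An `interval_estimate`.
#' @export
run_interval <- function(table, stdpop, config) {
  stopifnot(inherits(config, "sim_config"))
  profile <- build_seg_profile(table, stdpop)
  C_obs <- concentration_index(profile, config$estimator)$C
  reps <- switch(config$method,
                 MC = draw_mc(profile, config),
                 MC_RATE = draw_mc_rate(profile, config),
                 BIN = draw_bin(table, stdpop, config),
                 POIS = draw_pois(table, stdpop, config),
                 MN = draw_mn(table, stdpop, config))
  if (reps$n_failed > config$max_fail_frac * config$n_replicates)
    stop(sprintf("%d of %d replicates had an undefined index (> %.1f%%)",
                 reps$n_failed, config$n_replicates,
                 100 * config$max_fail_frac))
  percentile_interval(reps, config$alpha, C_obs = C_obs)
}

#' Multi-year panel of group rates
#'
#' Age-standardized rates per socioeconomic group over consecutive years,
#' used for the empirical cross-year variance check.
#'
#' @param rates numeric matrix, groups in rows (least to most advantaged),
#'   years in columns.
#' @param years column labels; default from `colnames(rates)`.
#' @param seg_groups row labels.
#' @return An object of class `multi_year_rates`.
#' @export
multi_year_rates <- function(rates, years = colnames(rates),
                             seg_groups = rownames(rates)) {
  rates <- as.matrix(rates)
  if (is.null(years)) years <- paste0("year", seq_len(ncol(rates)))
  if (is.null(seg_groups)) seg_groups <- paste0("seg", seq_len(nrow(rates)))
  if (anyNA(rates) || any(rates < 0))
    stop("rates must be present and non-negative for every group-year")
  dimnames(rates) <- list(seg_groups, years)
  structure(list(rates = rates, years = as.character(years),
                 seg_groups = as.character(seg_groups)),
            class = "multi_year_rates")
}

#' Empirical cross-year rate variances
#'
#' Sample variance (denominator n - 1) of each group's age-standardized
#' rate over a window of years — e.g. the study year with its two
#' preceding years.  The result can be passed as `rate_variances` in
#' [sim_config()] to replace the model variance `y_g^2/n_g` of the MC-rate
#' method with an empirically observed one.
#'
#' @param panel a [multi_year_rates()] object.
#' @param window character vector of year labels (at least two), all of
#'   which must be present in the panel.
#' @return Named numeric vector of per-group variances.
#' @export
empirical_rate_variance <- function(panel, window) {
  stopifnot(inherits(panel, "multi_year_rates"))
  window <- as.character(window)
  missing <- setdiff(window, panel$years)
  if (length(missing))
    stop("years missing from the panel: ", paste(missing, collapse = ", "))
  if (length(window) < 2L) stop("window must contain at least two years")
  apply(panel$rates[, window, drop = FALSE], 1L, stats::var)
}
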