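# Synthetic aggregated register generator.  Emulates the structure of a
# Nordic-style mortality register aggregated by income: G income groups of
# equal person-year share (income vigintiles by default), ages 1-74 in a
# 1-4 band followed by 5-year bands, a log-linear mortality gradient across
# the income ranks, and Poisson event counts.  Because the generator is the
# stated world for every stochastic test, its defaults are frozen here and
# documented in the methods vignette.

# default age bands: 1-4, then 5-year bands up to 70-74
default_age_bands <- function() {
  c("1-4", paste(seq(5, 70, by = 5), seq(9, 74, by = 5), sep = "-"))
}

# Illustrative European-standard-style weights for those bands (the classic
# 0-74 standard truncated at age 1); normalized to 100,000 at use.
default_std_weights <- function() {
  w <- c(8000, rep(7000, 10), 6000, 5000, 4000, 3000)
  names(w) <- default_age_bands()
  w
}

# Stable male-style age pyramid (person-year shares per band, sums to 1):
# slightly young-leaning at the oldest bands, as male cohorts are.
default_age_pyramid <- function() {
  a <- c(5.2, 6.6, 6.8, 6.6, 6.4, 6.3, 6.9, 7.6, 8.1, 8.4,
         7.6, 6.0, 4.6, 3.3, 2.4)
  a <- a / sum(a)
  names(a) <- default_age_bands()
  a
}

# Baseline amenable-style mortality hazard per band (deaths per person-year),
# exponential in the band midpoint (slope 0.11 / year), scaled so that the
# overall directly standardized rate of the default world is 102 per
# 100,000 person-years at the default gradient.
default_baseline_rates <- function(overall_rate = 102,
                                   gradient = -1.701015, G = 20) {
  mid <- c(2.5, seq(7, 72, by = 5))
  shape <- exp(0.11 * mid)
  w <- default_std_weights()
  w <- w / sum(w) * 1e5
  f <- rep(1 / G, G)
  R <- cumsum(f) - 0.5 * f
  meanexp <- mean(exp(gradient * (R - 0.5)))
  b <- shape * overall_rate / (sum(w * shape) * meanexp)
  names(b) <- default_age_bands()
  b
}

#' Configuration for the synthetic register generator
#'
#' Defaults describe a Finnish-scale register: 20 equal income groups, ages
#' 1-74 in a 1-4 band plus 5-year bands, about 4.8 million person-years,
#' and a log-linear mortality gradient over the income ranks strong enough
#' to give a concentration index near -0.27.
#'
#' @param G number of socioeconomic groups (default 20).
#' @param total_person_years total person-years at risk (default 4,789,000).
#' @param gradient log-rate slope over the centred relative rank: the cell
#'   expectation is `p_ig * baseline_i * exp(gradient * (R_g - 0.5))`.
#'   Negative values concentrate mortality among the disadvantaged (negative
#'   true C).  Default -1.701015, giving true C = -0.27 for G = 20.
#' @param baseline_rates per-age-band hazards (deaths per person-year);
#'   default an exponential-in-age curve scaled to an overall standardized
#'   rate of 102 per 100,000.
#' @param age_pyramid person-year shares per age band (default a stable
#'   male-style pyramid).
#' @param group_shares person-year share per SEG (default equal, 1/G).
#' @param years panel length for [generate_panel()] (default 7).
#' @param seed integer RNG seed.
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(G = 20L, total_person_years = 4789000,
                             gradient = -1.701015,
                             baseline_rates = NULL,
                             age_pyramid = default_age_pyramid(),
                             group_shares = NULL,
                             years = 7L, seed = 1L) {
  G <- as.integer(G)
  stopifnot(G >= 2L, total_person_years > 0, is.finite(gradient))
  if (is.null(baseline_rates))
    baseline_rates <- default_baseline_rates(gradient = gradient, G = G)
  stopifnot(length(baseline_rates) == length(age_pyramid),
            all(baseline_rates >= 0), all(age_pyramid > 0))
  if (is.null(group_shares)) group_shares <- rep(1 / G, G)
  stopifnot(length(group_shares) == G, all(group_shares > 0))
  group_shares <- group_shares / sum(group_shares)
  age_pyramid <- age_pyramid / sum(age_pyramid)
  structure(list(G = G, total_person_years = total_person_years,
                 gradient = gradient, baseline_rates = baseline_rates,
                 age_pyramid = age_pyramid, group_shares = group_shares,
                 years = as.integer(years), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Calibrated synthetic presets
#'
#' `"finland-1996-men"` reproduces the scale of a mid-1990s male amenable
#' mortality register: 2.3 million person-years in 20 income vigintiles,
#' overall standardized rate 102 per 100,000 (about 2,200 expected deaths a
#' year) and true concentration index -0.27.
#'
#' @param name preset name.
#' @param seed RNG seed stored in the returned configuration.
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(name = "finland-1996-men", seed = 1L) {
  switch(name,
         "finland-1996-men" = synthetic_config(
           G = 20L, total_person_years = 2300000,
           gradient = -1.701015,
           baseline_rates = default_baseline_rates(overall_rate = 102,
                                                   gradient = -1.701015),
           seed = seed),
         stop(sprintf("unknown preset '%s'", name)))
}

# expected standardized rates and the implied true index of a configuration
synthetic_truth <- function(config) {
  w <- default_std_weights()[names(config$baseline_rates)]
  if (anyNA(w)) { # custom band labels: weight proportional to pyramid
    w <- config$age_pyramid
  }
  w <- w / sum(w) * 1e5
  f <- config$group_shares
  R <- cumsum(f) - 0.5 * f
  mult <- exp(config$gradient * (R - 0.5))
  y_true <- sum(w * config$baseline_rates) * mult
  ym <- sum(f * y_true)
  list(y_true = y_true,
       true_C = 2 / ym * sum(y_true * f * R) - 1,
       overall_rate = ym)
}

#' Generate a synthetic aggregated register table
#'
#' Person-years are allocated deterministically (fixed proportions: equal
#' group shares split over age bands by the stable pyramid); death counts
#' are drawn independently per cell as
#' \eqn{d_{ig} \sim Pois(p_{ig}\, b_i\, e^{gradient \cdot (R_g - 0.5)})}.
#' The expected-rate ("true") concentration index of the generating
#' process is returned alongside the table.
#'
#' @param config a [synthetic_config()] or [synthetic_preset()].
#' @return A list of class `synthetic_register` with elements `table`
#'   (a [register_table()]), `stdpop` (the default standard population for
#'   the bands), `true_C`, `true_rates` and `config`.
#' @examples
#' sim <- generate_table(synthetic_preset("finland-1996-men", seed = 7))
#' sim$true_C
#' @export
generate_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  I <- length(config$age_pyramid)
  G <- config$G
  p <- config$total_person_years *
    outer(config$age_pyramid, config$group_shares)
  f <- config$group_shares
  R <- cumsum(f) - 0.5 * f
  lambda <- p * outer(config$baseline_rates,
                      exp(config$gradient * (R - 0.5)))
  set.seed(config$seed)
  d <- matrix(stats::rpois(I * G, as.vector(lambda)), nrow = I,
              dimnames = list(names(config$age_pyramid),
                              paste0("g", seq_len(G))))
  if (sum(d) == 0) d[which.max(lambda)] <- 1  # guard: keep the index defined
  dimnames(p) <- dimnames(d)
  truth <- synthetic_truth(config)
  sp <- standard_population(default_std_weights()[names(config$age_pyramid)])
  if (anyNA(sp$weights)) sp <- standard_population(config$age_pyramid)
  structure(list(table = register_table(d, p), stdpop = sp,
                 true_C = truth$true_C, true_rates = truth$y_true,
                 config = config),
            class = "synthetic_register")
}

#' @export
print.synthetic_register <- function(x, ...) {
  cat(sprintf("Synthetic register (G = %d, %.0f person-years): %d deaths, true C = %.4f\n",
              x$config$G, x$config$total_person_years, sum(x$table$deaths),
              x$true_C))
  invisible(x)
}

#' Generate a multi-year panel of standardized group rates
#'
#' Draws `config$years` independent yearly tables from the same generating
#' process and returns the observed age-standardized rate of each group in
#' each year — the input of [empirical_rate_variance()].
#'
#' @inheritParams generate_table
#' @return A [multi_year_rates()] panel; the per-year `synthetic_register`
#'   objects are attached as attribute `"registers"`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$years < 3L) stop("a panel needs at least 3 years")
  regs <- vector("list", config$years)
  rates <- matrix(NA_real_, nrow = config$G, ncol = config$years)
  for (j in seq_len(config$years)) {
    cfg_j <- config
    cfg_j$seed <- (config$seed + 9973L * j) %% 2147483647L
    regs[[j]] <- generate_table(cfg_j)
    rates[, j] <- age_standardize(regs[[j]]$table, regs[[j]]$stdpop)
  }
  panel <- multi_year_rates(rates, years = paste0("y", seq_len(config$years)),
                            seg_groups = regs[[1L]]$table$seg_groups)
  attr(panel, "registers") <- regs
  panel
}

#' Random valid register table for property sweeps
#'
#' Draws an unstructured but valid aggregated table: G uniform on 2..20,
#' I uniform on 1..15, cell person-years log-uniform, a random log-linear
#' group gradient, and Poisson death counts.  Used by the bound and
#' estimator-equivalence property checks; a degenerate all-zero draw gets a
#' single death added so the index stays defined.
#'
#' @param seed integer seed.
#' @param G,I optionally fix the dimensions instead of drawing them.
#' @return A [register_table()].
#' @export
random_register_table <- function(seed, G = NULL, I = NULL) {
  set.seed(as.integer(seed))
  if (is.null(G)) G <- sample(2:20, 1L)
  if (is.null(I)) I <- sample(1:15, 1L)
  p <- matrix(exp(stats::runif(I * G, log(5e2), log(5e5))), nrow = I)
  base <- exp(stats::runif(I, log(1e-5), log(5e-3)))
  grad <- stats::runif(1L, -3, 3)
  f <- colSums(p) / sum(p)
  R <- cumsum(f) - 0.5 * f
  lambda <- p * outer(base, exp(grad * (R - 0.5)))
  d <- matrix(stats::rpois(I * G, as.vector(lambda)), nrow = I)
  if (sum(d) == 0) d[which.max(lambda)] <- 1
  register_table(d, p)
}
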