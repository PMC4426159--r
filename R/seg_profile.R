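#' Directly age-standardized rates per socioeconomic group
#'
#' Standardizes the age-specific rates of each SEG to a common standard
#' population:
#' \deqn{y_g = \sum_i (d_{ig} / p_{ig}) \, w_i,}
#' where \eqn{w_i} are the standard-population weights.  Because the weights
#' sum to 100,000, the result is a rate per 100,000 person-years.
#'
#' @param table a [register_table()].
#' @param stdpop a [standard_population()] whose age groups match the table.
#' @return Named numeric vector of standardized rates, one per SEG.
#' @examples
#' d <- matrix(c(6, 8, 10, 4), 2, 2,
#'             dimnames = list(c("young", "old"), c("low", "high")))
#' p <- matrix(c(6000, 4000, 5000, 2000), 2, 2, dimnames = dimnames(d))
#' sp <- standard_population(c(young = 60000, old = 40000))
#' age_standardize(register_table(d, p), sp)
#' @export
age_standardize <- function(table, stdpop) {
  w <- align_stdpop(table, stdpop)
  rates <- table$deaths / table$person_years
  drop(crossprod(rates, w))[table$seg_groups]
}

#' Build the per-group profile used by all estimators
#'
#' Derives, per socioeconomic group g (ordered least to most advantaged):
#' the population share \eqn{f_g = p_g / \sum p_g} (person-year shares),
#' the relative rank \eqn{R_g = \sum_{\gamma<g} f_\gamma + 0.5 f_g}
#' (cumulative population proportion up to the group midpoint), the
#' age-standardized rate \eqn{y_g}, the event total \eqn{n_g}, the
#' person-year total \eqn{p_g}, the weighted mean rate
#' \eqn{\bar y = \sum_g f_g y_g} and the weighted rank variance
#' \eqn{\sigma_R^2 = \sum_g f_g (R_g - 0.5)^2}.
#'
#' @inheritParams age_standardize
#' @return An object of class `seg_profile` with elements `f`, `R`, `y`,
#'   `n`, `p`, `y_mean`, `sigma2_R`, `seg_groups`, and the originating
#'   `table`/`stdpop` (kept so the count-resampling interval methods can
#'   reuse them).
#' @export
build_seg_profile <- function(table, stdpop) {
  y <- age_standardize(table, stdpop)
  p <- colSums(table$person_years)
  n <- colSums(table$deaths)
  f <- p / sum(p)
  R <- cumsum(f) - 0.5 * f
  sigma2_R <- sum(f * (R - 0.5)^2)
  y_mean <- sum(f * y)
  structure(list(f = f, R = R, y = y, n = n, p = p,
                 y_mean = y_mean, sigma2_R = sigma2_R,
                 seg_groups = table$seg_groups,
                 table = table, stdpop = stdpop),
            class = "seg_profile")
}

#' @export
print.seg_profile <- function(x, ...) {
  cat(sprintf("SEG profile: G = %d groups\n", length(x$f)))
  df <- data.frame(seg = x$seg_groups, f = x$f, R = x$R, y = x$y,
                   n = x$n, p = x$p, row.names = NULL)
  print(df, digits = 4)
  cat(sprintf("weighted mean rate %.3f per 100,000; sigma2_R = %.5f\n",
              x$y_mean, x$sigma2_R))
  invisible(x)
}

#' Construct a profile directly from group summaries
#'
#' Escape hatch for data already reduced to group-level standardized rates
#' (no age detail).  Only the estimators and the MC / MC-rate interval
#' methods can be used on such a profile; the count-resampling methods need
#' the full table.
#'
#' @param y standardized rates per group (per 100,000 person-years).
#' @param p person-years per group (determines shares and WLS weights).
#' @param n event counts per group (drives the simulation variances).
#' @param seg_groups optional labels, least to most advantaged.
#' @return A `seg_profile` (with `table` and `stdpop` set to `NULL`).
#' @export
seg_profile_from_rates <- function(y, p, n, seg_groups = names(y)) {
  stopifnot(length(y) == length(p), length(y) == length(n))
  if (length(y) < 2L) stop("G >= 2 groups required")
  if (any(p <= 0)) stop("person-years must be positive")
  if (any(y < 0)) stop("rates must be non-negative")
  if (is.null(seg_groups)) seg_groups <- paste0("seg", seq_along(y))
  f <- p / sum(p)
  R <- cumsum(f) - 0.5 * f
  names(y) <- names(p) <- names(n) <- names(f) <- names(R) <- seg_groups
  structure(list(f = f, R = R, y = y, n = n, p = p,
                 y_mean = sum(f * y), sigma2_R = sum(f * (R - 0.5)^2),
                 seg_groups = as.character(seg_groups),
                 table = NULL, stdpop = NULL),
            class = "seg_profile")
}
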