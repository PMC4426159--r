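#' Concentration index from the arithmetic formula
#'
#' The concentration index for grouped data,
#' \deqn{C = \frac{2}{\bar y} \sum_{g=1}^G y_g f_g R_g \; - \; 1,}
#' with groups ranked from the least to the most advantaged.  C is twice
#' the area between the diagonal and the concentration curve; it is 0 under
#' complete equality, negative when the outcome is concentrated among the
#' disadvantaged, and bounded by \eqn{[-1, 1]} for non-binary rate outcomes.
#'
#' @param profile a [build_seg_profile()] result.
#' @return An object of class `concentration_estimate`: list with `C`, the
#'   concentration `curve` (data frame of points `(s, L)` starting at (0,0)
#'   and ending at (1,1)) and `estimator = "formula"`.
#' @seealso [concentration_index_wls()] for the regression route, which is
#'   numerically equivalent.
#' @export
concentration_index_formula <- function(profile) {
  stopifnot(inherits(profile, "seg_profile"))
  if (profile$y_mean <= 0)
    stop("concentration index undefined: mean standardized rate is zero ",
         "(no events in any group)")
  C <- 2 / profile$y_mean * sum(profile$y * profile$f * profile$R) - 1
  structure(list(C = C, curve = concentration_curve(profile),
                 estimator = "formula"),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("Concentration index (%s estimator): C = %.4f\n",
              x$estimator, x$C))
  invisible(x)
}

#' Concentration curve for grouped data
#'
#' Cumulative proportion of the outcome, `L(s)`, against the cumulative
#' proportion of the population, `s`, with groups ordered least to most
#' advantaged and a leading (0, 0) point.  The curve is piecewise linear
#' between the group points; twice the signed area between the diagonal and
#' the curve equals the concentration index.
#'
#' @inheritParams concentration_index_formula
#' @return Data frame with columns `s` and `L`.
#' @export
concentration_curve <- function(profile) {
  stopifnot(inherits(profile, "seg_profile"))
  if (profile$y_mean <= 0)
    stop("concentration curve undefined: mean standardized rate is zero")
  s <- c(0, cumsum(profile$f))
  L <- c(0, cumsum(profile$f * profile$y) / profile$y_mean)
  data.frame(s = s, L = L)
}

#' Concentration index via weighted least squares
#'
#' The "convenient regression" route: the WLS model
#' \deqn{2\sigma_R^2 \frac{y_g}{\bar y}\sqrt{p_g}
#'       = \beta_0\sqrt{p_g} + \beta_1 R_g\sqrt{p_g} + e_g}
#' has slope \eqn{\beta_1} computationally identical to the concentration
#' index.  The fit is solved by ordinary least squares on the
#' \eqn{\sqrt{p_g}}-premultiplied design, exactly as written; the slope
#' standard error is the conventional WLS output that the REG interval uses.
#'
#' @inheritParams concentration_index_formula
#' @return An object of class `wls_fit`: list with `beta0`, `beta1` (= C),
#'   `residuals` (on the premultiplied scale), `se_beta1` (`NA` when
#'   `G < 3`), `weights` (the person-years \eqn{p_g}) and `df_residual`.
#' @export
concentration_index_wls <- function(profile) {
  stopifnot(inherits(profile, "seg_profile"))
  if (profile$y_mean <= 0)
    stop("concentration index undefined: mean standardized rate is zero")
  G <- length(profile$f)
  if (G < 2L) stop("G >= 2 groups required for the WLS slope")
  if (diff(range(profile$R)) < .Machine$double.eps)
    stop("singular fit: all relative ranks are equal")
  sw <- sqrt(profile$p)
  z <- 2 * profile$sigma2_R * profile$y / profile$y_mean
  X <- cbind(intercept = sw, rank = profile$R * sw)
  fit <- stats::lm.fit(X, z * sw)
  beta <- unname(fit$coefficients)
  se <- NA_real_
  if (G >= 3L) {
    rss <- sum(fit$residuals^2)
    xtx_inv <- chol2inv(fit$qr$qr[seq_len(2L), seq_len(2L), drop = FALSE])
    se <- sqrt(rss / (G - 2L) * xtx_inv[2L, 2L])
  }
  structure(list(beta0 = beta[1L], beta1 = beta[2L],
                 residuals = unname(fit$residuals), se_beta1 = se,
                 weights = profile$p, df_residual = G - 2L,
                 profile = profile),
            class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf("WLS concentration index fit: C = beta1 = %.4f (se %.4g)\n",
              x$beta1, x$se_beta1))
  invisible(x)
}

#' Concentration index, choosing the estimator
#'
#' Convenience wrapper returning the index by either the arithmetic formula
#' or the WLS regression; the two are equivalent to numerical precision.
#'
#' @inheritParams concentration_index_formula
#' @param estimator `"formula"` or `"wls"`.
#' @return A `concentration_estimate`.
#' @export
concentration_index <- function(profile, estimator = c("formula", "wls")) {
  estimator <- match.arg(estimator)
  if (estimator == "formula") return(concentration_index_formula(profile))
  fit <- concentration_index_wls(profile)
  structure(list(C = fit$beta1, curve = concentration_curve(profile),
                 estimator = "wls"),
            class = "concentration_estimate")
}

# Linear slope functional: C* = sum_g k_g z*_g for any replacement z* of the
# WLS dependent variable with ranks/weights held fixed.  Used by the MC
# simulation so each replicate refit is a dot product.
slope_weights <- function(profile) {
  p <- profile$p
  R <- profile$R
  Rbar <- sum(p * R) / sum(p)
  k <- p * (R - Rbar)
  k / sum(k * (R - Rbar))
}
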