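#' Dimensionless time
#'
#' Maps calendar time to the dimensionless time of the growth model,
#' `x = (t - mu)/sigma_sqrt2 + c*sigma_sqrt2/2`. The additive aging term
#' shifts the effective origin: x = 0 at `t = mu - c*sigma_sqrt2^2/2`
#' (19.6 wk for the Florence set, down from mu = 26.0 wk).
#'
#' @param t calendar time (wk since Jan. 1); vectorized.
#' @param p a [growth_params()] object.
#' @return Dimensionless time x, same length as `t`.
#' @export
dimensionless_time <- function(t, p) {
  p <- as_growth_params(p)
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  (t - p$mu) / p$sigma_sqrt2 + p$c * p$sigma_sqrt2 / 2
}

#' Error function
#'
#' erf(x) = (2/sqrt(pi)) * integral of exp(-u^2) from 0 to x, computed from
#' the normal CDF as 2*pnorm(x*sqrt(2)) - 1. Odd in x, tends to +/-1.
#'
#' @param x numeric vector.
#' @return erf(x).
#' @export
erf_value <- function(x) {
  if (!is.numeric(x) || any(is.na(x)))
    stop("'x' must be numeric and non-missing", call. = FALSE)
  2 * stats::pnorm(x * sqrt(2)) - 1
}

#' Growth quantifier
#'
#' The dimensionless cumulative driver of biomass:
#' `Q(x) = (1 - k*x_i) * (erf(x) - erf(x_i)) +
#'         (k/sqrt(pi)) * (exp(-x_i^2) - exp(-x^2))`.
#' It combines the cumulative Gaussian solar-energy supply (erf term) with
#' the partition coefficient k between light-gathering and structural tissue.
#' Q(x_i) = 0 and Q increases monotonically to the asymptote
#' [quantifier_asymptote()]. With x_i = 0 it reduces to
#' `Q = erf(x) + (k/sqrt(pi)) * (1 - exp(-x^2))`.
#'
#' @param x dimensionless time; must satisfy `x >= x_i` (pre-initiation times
#'   are handled by [quantifier_table()], which clamps Q to 0).
#' @param p a [growth_params()] object.
#' @return Q, same length as `x`.
#' @export
growth_quantifier <- function(x, p) {
  p <- as_growth_params(p)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  if (any(x < p$x_i))
    stop("growth_quantifier() requires x >= x_i; ",
         "use quantifier_table() for pre-initiation times", call. = FALSE)
  (1 - p$k * p$x_i) * (erf_value(x) - erf_value(p$x_i)) +
    (p$k / sqrt(pi)) * (exp(-p$x_i^2) - exp(-x^2))
}

#' Asymptote of the growth quantifier
#'
#' The season total `Q(Inf) = (1 - k*x_i)*(1 - erf(x_i)) +
#' (k/sqrt(pi))*exp(-x_i^2)`; equals `1 + k/sqrt(pi)` when x_i = 0
#' (3.821 for the Florence set).
#'
#' @inheritParams growth_quantifier
#' @return Q(Inf).
#' @export
quantifier_asymptote <- function(p) {
  p <- as_growth_params(p)
  (1 - p$k * p$x_i) * (1 - erf_value(p$x_i)) +
    (p$k / sqrt(pi)) * exp(-p$x_i^2)
}

#' Growth-quantifier table
#'
#' Evaluates x, erf x, exp(-x^2) and Q at each calendar time. Q is clamped to
#' 0 before the initiation time [initiation_time()] (growth has not begun).
#'
#' @param times calendar times (wk); finite numeric.
#' @param p a [growth_params()] object.
#' @return A data frame with columns `t`, `x`, `erf_x`, `gauss_x`, `Q`, one
#'   row per input time.
#' @examples
#' quantifier_table(c(19.6, 29.5), growth_params())
#' @export
quantifier_table <- function(times, p) {
  p <- as_growth_params(p)
  if (length(times) == 0L)
    return(data.frame(t = numeric(), x = numeric(), erf_x = numeric(),
                      gauss_x = numeric(), Q = numeric()))
  x <- dimensionless_time(times, p)
  Q <- ifelse(x >= p$x_i, growth_quantifier(pmax(x, p$x_i), p), 0)
  data.frame(t = times, x = x, erf_x = erf_value(x),
             gauss_x = exp(-x^2), Q = Q)
}
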