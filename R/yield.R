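#' Fit the yield factor
#'
#' Ordinary least squares of biomass yield on the growth quantifier,
#' `Y = b + A*Q`. The model's structural form is proportional (Y = A*Q), but
#' the default keeps an intercept because observed series typically carry a
#' small pre-initiation biomass; set `with_intercept = FALSE` to force the
#' line through the origin.
#'
#' @param Q growth-quantifier values.
#' @param Y biomass yields (Mg/ha).
#' @param with_intercept include an intercept term (default TRUE).
#' @return An object of class `"yield_fit"` with fields `A` (slope, Mg/ha per
#'   unit Q), `b` (intercept, 0 when forced through origin), `r2`,
#'   `n_points`, `with_intercept`, and the underlying `lm` fit.
#' @examples
#' fl <- fixture_florence()
#' fit_yield_factor(fl$quantifier$Q, fl$quantifier$Y)
#' @export
fit_yield_factor <- function(Q, Y, with_intercept = TRUE) {
  if (length(Q) != length(Y))
    stop("'Q' and 'Y' must have equal length", call. = FALSE)
  if (any(!is.finite(Q)) || any(!is.finite(Y)))
    stop("non-finite values in yield-factor data", call. = FALSE)
  if (length(Q) < 3L)
    stop("yield-factor fit needs at least 3 points", call. = FALSE)
  if (stats::var(Q) == 0)
    stop("yield-factor fit needs variation in Q", call. = FALSE)
  dat <- data.frame(Q = Q, Y = Y)
  lmfit <- if (with_intercept) stats::lm(Y ~ Q, data = dat)
           else stats::lm(Y ~ 0 + Q, data = dat)
  A <- unname(stats::coef(lmfit)["Q"])
  b <- if (with_intercept) unname(stats::coef(lmfit)["(Intercept)"]) else 0
  if (A <= 0)
    stop("yield-factor fit produced a non-positive slope", call. = FALSE)
  # r^2 about the mean (with intercept) or about zero (through origin),
  # computed directly: summary.lm warns on zero-residual fits
  tss <- if (with_intercept) sum((Y - mean(Y))^2) else sum(Y^2)
  r2 <- 1 - sum(stats::residuals(lmfit)^2) / tss
  structure(list(A = A, b = b, r2 = r2,
                 n_points = length(Q), with_intercept = with_intercept,
                 lm = lmfit),
            class = "yield_fit")
}

#' @export
print.yield_fit <- function(x, ...) {
  cat(sprintf("Yield-factor fit%s, n = %d\n",
              if (x$with_intercept) "" else " (through origin)", x$n_points))
  cat(sprintf("  Y_hat = %.4f + %.4f * Q   (Mg/ha), r^2 = %.4f\n",
              x$b, x$A, x$r2))
  invisible(x)
}

#' @export
coef.yield_fit <- function(object, ...) c(A = object$A, b = object$b)

#' @export
predict.yield_fit <- function(object, Q, ...) object$b + object$A * Q

#' Scan candidate initiation times
#'
#' Evaluates the season-total growth quantifier [quantifier_asymptote()] over
#' a grid of non-negative dimensionless initiation times and reports the grid
#' argmax. For the Florence partition coefficient the total is maximal at
#' x_i = 0: starting growth at the shifted origin captures the most solar
#' energy. The domain is restricted to x_i >= 0 because the asymptote formula
#' grows without bound as x_i decreases below zero, so the maximization is
#' only well-posed on the non-negative domain.
#'
#' @param p a [growth_params()] object (its own `x_i` is ignored).
#' @param x_i_grid non-empty vector of candidate x_i values, all >= 0.
#' @return An object of class `"initiation_scan"`: a data frame with columns
#'   `x_i`, `t_i`, `Q_total`, with attribute `argmax` (the x_i maximizing
#'   Q_total over the grid).
#' @export
initiation_scan <- function(p, x_i_grid) {
  p <- as_growth_params(p)
  if (length(x_i_grid) == 0L)
    stop("'x_i_grid' must be non-empty", call. = FALSE)
  if (any(!is.finite(x_i_grid)) || any(x_i_grid < 0))
    stop("'x_i_grid' entries must be finite and >= 0", call. = FALSE)
  rows <- lapply(x_i_grid, function(xi) {
    pi_ <- p; pi_$x_i <- xi
    data.frame(x_i = xi, t_i = initiation_time(pi_),
               Q_total = quantifier_asymptote(pi_))
  })
  out <- do.call(rbind, rows)
  attr(out, "argmax") <- out$x_i[which.max(out$Q_total)]
  class(out) <- c("initiation_scan", "data.frame")
  out
}

#' @export
print.initiation_scan <- function(x, ...) {
  cat("Initiation-time scan (", nrow(x), " candidates)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  cat("argmax Q_total at x_i =", attr(x, "argmax"), "\n")
  invisible(x)
}

#' Calibrate the yield factor against a field series
#'
#' Computes the growth-quantifier table at the sampling times of a field
#' series and regresses observed yield on Q ([fit_yield_factor()]).
#' Pre-initiation samplings enter with Q clamped to 0, matching the
#' convention that growth (and hence Q) starts at t_i.
#'
#' @param series a field series data frame with columns `t` and `Y`.
#' @param p a [growth_params()] object.
#' @param with_intercept passed to [fit_yield_factor()].
#' @return A list with components `fit` (the `"yield_fit"`) and `table` (the
#'   quantifier table with the observed `Y` appended), so the printed-table
#'   reconstruction is inspectable.
#' @export
calibrate <- function(series, p, with_intercept = TRUE) {
  p <- as_growth_params(p)
  if (!all(c("t", "Y") %in% names(series)))
    stop("series must have columns 't' and 'Y'", call. = FALSE)
  t_i <- initiation_time(p)
  if (sum(series$t >= t_i) < 3L)
    stop("calibration needs at least 3 samplings at or after the ",
         "initiation time (t_i = ", format(t_i), " wk)", call. = FALSE)
  tab <- quantifier_table(series$t, p)
  tab$Y <- series$Y
  list(fit = fit_yield_factor(tab$Q, tab$Y, with_intercept = with_intercept),
       table = tab)
}
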