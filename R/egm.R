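#' Fit the expanded growth model to a field series
#'
#' The main entry point: given sampled calendar times, biomass yields and
#' per-element nutrient uptakes, it (i) evaluates the growth quantifier Q at
#' each sampling under the chosen parameter set, (ii) calibrates the yield
#' factor by OLS of Y on Q, and (iii) fits the hyperbolic uptake-vs-biomass
#' phase relation for every element present. Elements are detected from
#' columns named `<element>_u`.
#'
#' @param data a field series data frame with columns `t` (wk), `Y` (Mg/ha)
#'   and optionally `<element>_u` uptake columns (kg/ha); see
#'   [read_field_series()] and [fixture_florence()].
#' @param params a [growth_params()] object, the name `"florence-1982"`, or a
#'   config-file path.
#' @param elements character vector of elements to fit; default all detected.
#' @param with_intercept include an intercept in the yield-factor fit.
#' @return An object of class `"egm"`: a list with components `params`,
#'   `yield` (a `"yield_fit"`), `phases` (named list of `"phase_fit"`),
#'   `quantifier` (the per-sampling Q table with observed Y), `data`, `call`.
#'   Methods: `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`,
#'   `plot`, `simulate`.
#' @examples
#' fl <- fixture_florence()
#' fit <- egm(fl$series)
#' coef(fit)
#' predict(fit, times = c(24, 29.5))
#' @export
egm <- function(data, params = growth_params(), elements = NULL,
                with_intercept = TRUE) {
  params <- as_growth_params(params)
  if (!all(c("t", "Y") %in% names(data)))
    stop("'data' must have columns 't' and 'Y'", call. = FALSE)
  cal <- calibrate(data, params, with_intercept = with_intercept)
  if (is.null(elements))
    elements <- sub("_u$", "", grep("_u$", names(data), value = TRUE))
  phases <- list()
  for (el in elements)
    phases[[el]] <- fit_phase(data, el)
  structure(list(params = params, yield = cal$fit, phases = phases,
                 quantifier = cal$table, data = data,
                 call = match.call()),
            class = "egm")
}

#' @export
print.egm <- function(x, ...) {
  cat("Expanded growth model fit (parameter set: ", x$params$label, ")\n",
      sep = "")
  cat(sprintf("  %d samplings, t_i = %.1f wk, Q_total = %.3f\n",
              nrow(x$data), initiation_time(x$params),
              quantifier_asymptote(x$params)))
  cat(sprintf("  yield: Y_hat = %.3f + %.3f * Q (Mg/ha), r^2 = %.4f\n",
              x$yield$b, x$yield$A, x$yield$r2))
  for (el in names(x$phases)) {
    ph <- x$phases[[el]]
    cat(sprintf("  %s: N_um = %.1f kg/ha, K_y = %.2f Mg/ha, r^2 = %.4f\n",
                el, ph$N_um, ph$K_y, ph$r2_linear))
  }
  invisible(x)
}

#' @export
summary.egm <- function(object, ...) {
  ph <- object$phases
  phase_table <- if (length(ph)) data.frame(
    element = names(ph),
    N_um = vapply(ph, function(p) p$N_um, 0),
    K_y = vapply(ph, function(p) p$K_y, 0),
    slope = vapply(ph, function(p) p$slope, 0),
    intercept = vapply(ph, function(p) p$intercept, 0),
    r2_linear = vapply(ph, function(p) p$r2_linear, 0),
    n = vapply(ph, function(p) p$n_points, 0L),
    row.names = NULL
  ) else data.frame()
  res <- stats::residuals(object)
  structure(list(params = object$params, yield = object$yield,
                 phase_table = phase_table, quantifier = object$quantifier,
                 residuals = res, rmse = sqrt(mean(res^2))),
            class = "summary.egm")
}

#' @export
print.summary.egm <- function(x, ...) {
  cat("Expanded growth model — summary\n\nParameters:\n")
  print(x$params)
  cat("\nYield factor:\n")
  print(x$yield)
  cat(sprintf("  residual RMSE = %.3f Mg/ha\n", x$rmse))
  if (nrow(x$phase_table)) {
    cat("\nPhase relations:\n")
    print(x$phase_table, row.names = FALSE, digits = 4)
  }
  cat("\nQuantifier table:\n")
  print(x$quantifier, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.egm <- function(object, ...) {
  out <- c(A = object$yield$A, b = object$yield$b)
  for (el in names(object$phases)) {
    ph <- object$phases[[el]]
    v <- c(ph$N_um, ph$K_y)
    names(v) <- paste0(el, c("_um", "_Ky"))
    out <- c(out, v)
  }
  out
}

#' @export
fitted.egm <- function(object, ...) {
  object$yield$b + object$yield$A * object$quantifier$Q
}

#' @export
residuals.egm <- function(object, ...) {
  object$data$Y - stats::fitted(object)
}

#' Predict season trajectories from a fitted model
#'
#' @param object an `"egm"` fit.
#' @param times calendar times (wk) at which to evaluate; defaults to a dense
#'   0.1-wk grid over 15–32 wk.
#' @param ... unused.
#' @return An `"egm_trajectory"` data frame (see [simulate_trajectory()]).
#' @export
predict.egm <- function(object, times = NULL, ...) {
  if (is.null(times))
    return(simulate_trajectory(object$params, object$yield, object$phases))
  if (any(!is.finite(times))) stop("'times' must be finite", call. = FALSE)
  tab <- quantifier_table(times, object$params)
  out <- tab
  out$Y_hat <- object$yield$b + object$yield$A * out$Q
  Ypos <- pmax(out$Y_hat, 0)
  for (el in names(object$phases)) {
    ph <- object$phases[[el]]
    out[[paste0(el, "_u_hat")]] <- predict_uptake(Ypos, ph)
    out[[paste0(el, "_c_hat")]] <-
      ifelse(out$Y_hat > 0, out[[paste0(el, "_u_hat")]] / out$Y_hat,
             ph$N_um / ph$K_y)
  }
  class(out) <- c("egm_trajectory", "data.frame")
  out
}

#' Simulate replicate field series from a fitted model
#'
#' Draws noisy Table-1-style datasets from the fitted parameters via
#' [generate_field_series()], i.e. parametric-bootstrap replicates of the
#' observed sampling design.
#'
#' @param object an `"egm"` fit.
#' @param nsim number of replicate series.
#' @param seed integer seed (required for reproducibility; if NULL the current
#'   RNG state is used).
#' @param times sampling times; default the fitted series' times.
#' @param noise_cv observation coefficient of variation.
#' @param noise_model `"multiplicative-lognormal"`, `"additive-gaussian"` or
#'   `"none"`.
#' @param ... unused.
#' @return A list of `nsim` field-series data frames (a single data frame if
#'   `nsim = 1`).
#' @export
simulate.egm <- function(object, nsim = 1, seed = NULL, times = NULL,
                         noise_cv = 0.05,
                         noise_model = "multiplicative-lognormal", ...) {
  if (is.null(times)) times <- object$data$t
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    cfg <- synth_config(growth = object$params, A = object$yield$A,
                        b = object$yield$b, phases = object$phases,
                        sampling_times = times, noise_cv = noise_cv,
                        noise_model = noise_model, seed = seed + i - 1L)
    out[[i]] <- generate_field_series(cfg)
  }
  if (nsim == 1L) out[[1L]] else out
}

#' Plot a fitted expanded growth model
#'
#' Three base-graphics panels: yield against the growth quantifier with the
#' fitted line, per-element uptake against biomass with the fitted
#' hyperbolas, and the simulated biomass trajectory over calendar time with
#' the observations.
#'
#' @param x an `"egm"` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.egm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (length(x$phases)) 3L else 2L),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  qt <- x$quantifier
  graphics::plot(qt$Q, qt$Y, xlab = "growth quantifier Q",
                 ylab = "biomass Y (Mg/ha)", main = "yield factor", ...)
  graphics::abline(x$yield$b, x$yield$A)
  if (length(x$phases)) {
    yy <- seq(0, max(x$data$Y) * 1.05, length.out = 200)
    ymax <- max(vapply(x$phases, function(p) p$N_um, 0))
    graphics::plot(NA, xlim = range(yy), ylim = c(0, ymax),
                   xlab = "biomass Y (Mg/ha)", ylab = "uptake (kg/ha)",
                   main = "phase relations")
    for (i in seq_along(x$phases)) {
      el <- names(x$phases)[i]
      graphics::lines(yy, predict_uptake(yy, x$phases[[el]]), lty = i)
      ucol <- paste0(el, "_u")
      if (ucol %in% names(x$data))
        graphics::points(x$data$Y, x$data[[ucol]], pch = i)
    }
    graphics::legend("bottomright", legend = names(x$phases),
                     lty = seq_along(x$phases), pch = seq_along(x$phases))
  }
  traj <- predict(x)
  graphics::plot(traj$t, traj$Y_hat, type = "l", xlab = "calendar time (wk)",
                 ylab = "biomass Y (Mg/ha)", main = "season trajectory")
  graphics::points(x$data$t, x$data$Y)
  invisible(x)
}
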