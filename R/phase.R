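#' Linearize the hyperbolic phase relation
#'
#' The phase relation `N_u = N_um * Y / (K_y + Y)` rearranges to the line
#' `Y/N_u = K_y/N_um + Y/N_um`, so plotting Y/N_u against Y turns the
#' hyperbola into ordinary least squares. Rows with non-positive uptake are
#' dropped with a warning (a zero uptake at positive biomass is not
#' physical).
#'
#' @param Y biomass yield (Mg/ha); all > 0.
#' @param uptake cumulative nutrient uptake (kg/ha).
#' @return A data frame with columns `Y` and `ratio` (= Y/uptake), input
#'   order preserved.
#' @export
linearize <- function(Y, uptake) {
  if (length(Y) != length(uptake))
    stop("'Y' and 'uptake' must have equal length", call. = FALSE)
  if (any(!is.finite(Y)) || any(!is.finite(uptake)))
    stop("non-finite values in phase data", call. = FALSE)
  if (any(Y <= 0))
    stop("all Y must be > 0 for the linearized phase relation", call. = FALSE)
  bad <- uptake <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive uptake dropped from the ",
            "phase fit", call. = FALSE)
    Y <- Y[!bad]; uptake <- uptake[!bad]
  }
  data.frame(Y = Y, ratio = Y / uptake)
}

#' Fit the hyperbolic nutrient-uptake phase relation
#'
#' Estimates the potential maximum uptake `N_um` (kg/ha) and the
#' half-saturation biomass `K_y` (Mg/ha) of `N_u = N_um*Y/(K_y + Y)`.
#' The canonical route regresses Y/N_u on Y ([linearize()]); slope s and
#' intercept a map to `N_um = 1/s`, `K_y = a/s`. A nonlinear least-squares
#' route (`method = "nls"`, initialized from the linearized fit) is provided
#' for comparison; its `r2_linear` diagnostic is still that of the linearized
#' regression.
#'
#' @param series a field series data frame with column `Y` and an uptake
#'   column named `<element>_u` (or `uptake`).
#' @param element element label ("N", "P", "K", ...).
#' @param method `"linearized"` (default) or `"nls"`.
#' @return An object of class `"phase_fit"` with fields `element`, `N_um`,
#'   `K_y`, `slope`, `intercept`, `r2_linear`, `n_points`, `method`.
#' @examples
#' fl <- fixture_florence()
#' fit_phase(fl$series, "N")  # N_um ~ 273 kg/ha
#' @export
fit_phase <- function(series, element = "N",
                      method = c("linearized", "nls")) {
  method <- match.arg(method)
  ucol <- paste0(element, "_u")
  if (!ucol %in% names(series)) {
    if ("uptake" %in% names(series)) ucol <- "uptake"
    else stop("series has no column '", ucol, "'", call. = FALSE)
  }
  lin <- linearize(series$Y, series[[ucol]])
  if (nrow(lin) < 3L)
    stop("phase fit needs at least 3 valid observations", call. = FALSE)
  if (stats::var(lin$Y) == 0)
    stop("phase fit needs variation in Y", call. = FALSE)
  lf <- stats::lm(ratio ~ Y, data = lin)
  # direct r^2 (summary.lm warns on zero-residual fits, which are routine
  # for noiseless synthetic data)
  r2 <- 1 - sum(stats::residuals(lf)^2) /
    sum((lin$ratio - mean(lin$ratio))^2)
  s <- unname(stats::coef(lf)["Y"])
  a <- unname(stats::coef(lf)["(Intercept)"])
  if (s <= 0 || a <= 0)
    stop("phase relation not supported by data (non-positive slope or ",
         "intercept in the linearized fit)", call. = FALSE)
  N_um <- 1 / s
  K_y <- a / s
  if (method == "nls") {
    # scaleOffset keeps the convergence test meaningful when residuals are
    # (near) zero, as on noiseless data
    nf <- stats::nls(uptake ~ N_um * Y / (K_y + Y),
                     data = data.frame(Y = lin$Y, uptake = lin$Y / lin$ratio),
                     start = list(N_um = N_um, K_y = K_y),
                     control = stats::nls.control(maxiter = 100,
                                                  scaleOffset = 1))
    N_um <- unname(stats::coef(nf)["N_um"])
    K_y <- unname(stats::coef(nf)["K_y"])
  }
  structure(list(element = element, N_um = N_um, K_y = K_y,
                 slope = s, intercept = a,
                 r2_linear = r2,
                 n_points = nrow(lin), method = method),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf("Hyperbolic phase fit (%s), element %s, n = %d\n",
              x$method, x$element, x$n_points))
  cat(sprintf("  N_um = %.1f kg/ha   K_y = %.2f Mg/ha\n", x$N_um, x$K_y))
  cat(sprintf("  linearized: slope = %.6g, intercept = %.6g, r^2 = %.4f\n",
              x$slope, x$intercept, x$r2_linear))
  invisible(x)
}

#' @export
coef.phase_fit <- function(object, ...) {
  c(N_um = object$N_um, K_y = object$K_y)
}

#' Predicted nutrient uptake at given biomass
#'
#' `N_um * Y / (K_y + Y)`: zero at Y = 0, strictly increasing and concave,
#' bounded above by N_um.
#'
#' @param Y biomass (Mg/ha), >= 0; vectorized.
#' @param p a `"phase_fit"` (or any list with `N_um`, `K_y`).
#' @return Predicted uptake (kg/ha).
#' @export
predict_uptake <- function(Y, p) {
  if (any(!is.finite(Y)) || any(Y < 0))
    stop("'Y' must be finite and >= 0", call. = FALSE)
  p$N_um * Y / (p$K_y + Y)
}

#' Predicted nutrient concentration at given biomass
#'
#' `N_c = N_u/Y = N_um/(K_y + Y)` in g/kg; strictly decreasing in Y — the
#' dilution of nutrient-rich leaf tissue by structural stalk as the plant
#' grows. The Y -> 0+ limit is `N_um/K_y`.
#'
#' @param Y biomass (Mg/ha), > 0; vectorized.
#' @inheritParams predict_uptake
#' @return Predicted concentration (g/kg).
#' @export
predict_concentration <- function(Y, p) {
  if (any(!is.finite(Y)) || any(Y <= 0))
    stop("'Y' must be finite and > 0", call. = FALSE)
  p$N_um / (p$K_y + Y)
}

#' @export
predict.phase_fit <- function(object, Y,
                              type = c("uptake", "concentration"), ...) {
  type <- match.arg(type)
  if (type == "uptake") predict_uptake(Y, object)
  else predict_concentration(Y, object)
}

#' Nutrient-use efficiency ratio
#'
#' Fitted potential uptake divided by the applied fertilizer amount, rounded
#' to 2 decimals for reporting. A value near 1 means the crop's potential
#' uptake nearly matches the application (273/268 = 1.02 for nitrogen in the
#' Florence study).
#'
#' @param p a `"phase_fit"` (or list with `N_um`).
#' @param applied applied nutrient (kg/ha), > 0.
#' @return N_um / applied, rounded to 2 d.p.
#' @export
efficiency_ratio <- function(p, applied) {
  if (!is.numeric(applied) || length(applied) != 1L || !is.finite(applied) ||
      applied <= 0)
    stop("'applied' must be a single positive number", call. = FALSE)
  round(p$N_um / applied, 2)
}
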