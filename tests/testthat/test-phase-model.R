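fl <- fixture_florence()

test_that("linearization produces Y/uptake pairs in order", {
  expect_equal(linearize(1.83, 60)$ratio, 1.83 / 60)
  expect_equal(linearize(1, 1), data.frame(Y = 1, ratio = 1))
  lin <- linearize(fl$series$Y, fl$series$N_u)
  expect_equal(lin$Y, fl$series$Y)
  expect_equal(lin$ratio,
               c(0.0312, 0.0305, 0.0383, 0.0596, 0.0949, 0.1087),
               tolerance = 1e-2)
  expect_warning(bad <- linearize(c(1, 2, 3), c(5, 0, 6)), "non-positive")
  expect_identical(nrow(bad), 2L)
  expect_error(linearize(c(-1, 2), c(5, 5)), "Y must be > 0")
})

test_that("nitrogen phase fit recovers the published potential uptake", {
  fit <- fit_phase(fl$series, "N")
  expect_lte(abs(fit$N_um - 273), 1)
  # against the normal-equation oracle on the printed ratios
  o <- ols_oracle(fl$series$Y, fl$series$Y / fl$series$N_u)
  expect_equal(fit$slope, o$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(fit$N_um, 1 / o$slope, tolerance = 1e-10)
  expect_equal(fit$K_y, o$intercept / o$slope, tolerance = 1e-10)
  expect_equal(fit$K_y, 6.850, tolerance = 1e-3)
  expect_equal(fit$r2_linear, 0.9933, tolerance = 1e-3)
  expect_identical(fit$n_points, 6L)
})

test_that("phosphorus and potassium fits match the oracle values", {
  for (case in list(list(el = "P", N_um = 72.12, K_y = 22.96),
                    list(el = "K", N_um = 350.46, K_y = 4.286))) {
    fit <- fit_phase(fl$series, case$el)
    o <- ols_oracle(fl$series$Y, fl$series$Y / fl$series[[paste0(case$el, "_u")]])
    expect_equal(fit$N_um, 1 / o$slope, tolerance = 1e-10)
    expect_equal(fit$K_y, o$intercept / o$slope, tolerance = 1e-10)
    expect_equal(fit$N_um, case$N_um, tolerance = 1e-2)
    expect_equal(fit$K_y, case$K_y, tolerance = 1e-2)
  }
})

test_that("linearized fits are strong for all three elements", {
  # pinned to what the data support: the nitrogen relation is very tight,
  # phosphorus the loosest (its linearized r^2 is 0.866 on these samplings)
  r2 <- vapply(c("N", "P", "K"),
               function(el) fit_phase(fl$series, el)$r2_linear, 0)
  expect_gt(r2[["N"]], 0.95)
  expect_true(all(r2 > 0.85))
})

test_that("noiseless hyperbolic data are recovered exactly", {
  truth <- phase_params("N", N_um = 200, K_y = 5)
  Y <- c(0.5, 1, 3, 6, 12, 20)
  dat <- data.frame(Y = Y, N_u = predict_uptake(Y, truth))
  fit <- fit_phase(dat, "N")
  expect_equal(fit$N_um, 200, tolerance = 1e-10)
  expect_equal(fit$K_y, 5, tolerance = 1e-10)
  expect_equal(fit$r2_linear, 1, tolerance = 1e-10)
  # nonlinear route agrees on exact data
  nfit <- fit_phase(dat, "N", method = "nls")
  expect_equal(nfit$N_um, 200, tolerance = 1e-6)
  expect_equal(nfit$K_y, 5, tolerance = 1e-6)
})

test_that("degenerate phase inputs are rejected", {
  expect_error(fit_phase(data.frame(Y = c(1, 2), N_u = c(10, 15)), "N"),
               "at least 3")
  expect_error(fit_phase(data.frame(Y = c(2, 2, 2), N_u = c(10, 11, 12)), "N"),
               "variation")
  # superlinear uptake makes Y/uptake decrease: negative slope
  Y <- c(1, 2, 4, 8)
  expect_error(fit_phase(data.frame(Y = Y, N_u = Y^2), "N"),
               "not supported")
  expect_error(fit_phase(fl$series, "Zn"), "no column")
})

test_that("uptake prediction is saturating, concave and bounded", {
  p <- phase_params("N", N_um = 273, K_y = 6.9)
  expect_equal(predict_uptake(0, p), 0)
  expect_equal(predict_uptake(p$K_y, p), p$N_um / 2)
  Y <- seq(0, 60, by = 0.5)
  u <- predict_uptake(Y, p)
  expect_true(all(diff(u) > 0))
  expect_true(all(diff(diff(u)) < 0))
  expect_true(all(u < p$N_um))
  expect_error(predict_uptake(-1, p), ">= 0")
  # fitted N relation vs a held comparison point
  fit <- fit_phase(fl$series, "N")
  expect_equal(predict_uptake(22.5, fit), 209, tolerance = 0.01)
})

test_that("concentration prediction dilutes with biomass", {
  p <- phase_params("N", N_um = 273, K_y = 6.9)
  expect_equal(predict_concentration(1e-9, p), p$N_um / p$K_y,
               tolerance = 1e-6)
  expect_equal(predict_concentration(p$K_y, p) /
                 predict_concentration(2 * p$K_y, p), 1.5)
  Y <- seq(0.1, 40, by = 0.1)
  expect_true(all(diff(predict_concentration(Y, p)) < 0))
  expect_error(predict_concentration(0, p), "> 0")
  fit <- fit_phase(fl$series, "N")
  expect_equal(predict_concentration(18.8, fit), 10.63, tolerance = 0.01)
  # predict() method mirrors the functions
  expect_equal(predict(fit, 10, type = "uptake"), predict_uptake(10, fit))
  expect_equal(predict(fit, 10, type = "concentration"),
               predict_concentration(10, fit))
})

test_that("round-trip residuals stay within the linearized-fit scatter", {
  fit <- fit_phase(fl$series, "N")
  rel <- abs(predict_uptake(fl$series$Y, fit) - fl$series$N_u) / fl$series$N_u
  expect_lt(max(rel), 0.25)
})

test_that("efficiency ratio reports potential over applied nutrient", {
  fit <- fit_phase(fl$series, "N")
  expect_equal(efficiency_ratio(fit, 268), 1.02)
  expect_equal(efficiency_ratio(phase_params("N", 200, 5), 200), 1)
  pfit <- fit_phase(fl$series, "P")
  expect_equal(efficiency_ratio(pfit, 36), 2, tolerance = 0.05)
  expect_error(efficiency_ratio(fit, 0), "positive")
})
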