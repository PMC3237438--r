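florence <- growth_params()

test_that("dimensionless time is the affine aging-shifted standardization", {
  expect_equal(dimensionless_time(21.0, florence), 0.175)
  expect_equal(dimensionless_time(26.8, florence), 0.900)
  # x = 0 at the shifted origin mu - c*sigma_sqrt2^2/2
  t0 <- florence$mu - florence$c * florence$sigma_sqrt2^2 / 2
  expect_equal(dimensionless_time(t0, florence), 0)
  # affine in t with slope 1/sigma_sqrt2
  x2 <- dimensionless_time(c(20, 28), florence)
  expect_equal((x2[2] - x2[1]) / (28 - 20), 1 / florence$sigma_sqrt2)
  expect_error(dimensionless_time(NA_real_, florence), "finite")
  expect_error(dimensionless_time(Inf, florence), "finite")
})

test_that("the printed reconstruction table pins the dimensionless-time form", {
  # regressing the published x column on t must give slope 1/8 and a zero
  # crossing at 19.6 wk (the 26.0 -> 19.6 aging shift)
  tab <- fixture_florence()$quantifier
  o <- ols_oracle(tab$t, tab$x)
  expect_equal(o$slope, 1 / 8, tolerance = 1e-6)
  expect_equal(-o$intercept / o$slope, 19.6, tolerance = 1e-3)
})

test_that("initiation time inverts the dimensionless-time map", {
  expect_equal(initiation_time(florence), 19.6)
  expect_equal(dimensionless_time(initiation_time(florence), florence),
               florence$x_i)
  p0 <- growth_params(c = 0)
  expect_equal(initiation_time(p0), p0$mu)
  p5 <- growth_params(x_i = 0.5)
  expect_equal(initiation_time(p5), 23.6)
  # root-finding cross-check
  root <- uniroot(function(t) dimensionless_time(t, p5) - p5$x_i,
                  c(0, 60), tol = 1e-12)$root
  expect_equal(initiation_time(p5), root, tolerance = 1e-9)
})

test_that("erf matches a quadrature oracle and the printed values", {
  expect_identical(erf_value(0), 0)
  xs <- seq(0, 3, by = 0.05)
  expect_lt(max(abs(erf_value(xs) - erf_quadrature(xs))), 1e-6)
  expect_equal(erf_value(-xs), -erf_value(xs))  # odd
  expect_equal(erf_value(0.550), 0.5633, tolerance = 5e-4)
  expect_equal(erf_value(1.2375), 0.9198, tolerance = 5e-4)
  expect_gt(erf_value(10), 1 - 1e-12)
})

test_that("growth quantifier reproduces printed values and limits", {
  expect_equal(growth_quantifier(0.300, florence), 0.571, tolerance = 1e-3)
  expect_equal(growth_quantifier(1.150, florence), 2.965, tolerance = 1e-3)
  expect_equal(growth_quantifier(florence$x_i, florence), 0)
  expect_error(growth_quantifier(-0.1, florence), "x_i")
  # k = 0, x_i = 0: Q collapses to erf exactly
  p0 <- growth_params(k = 0)
  xs <- seq(0, 4, by = 0.25)
  expect_equal(growth_quantifier(xs, p0), erf_value(xs))
  # Q at x_i vanishes for nonzero x_i too
  p5 <- growth_params(x_i = 0.5)
  expect_equal(growth_quantifier(0.5, p5), 0)
})

test_that("the Q - erf gap in the printed table identifies k = 5", {
  # solve each published row for k: k = sqrt(pi)*(Q - erf x)/(1 - exp(-x^2));
  # the t = 22.0 row gives 5.0 to rounding
  tab <- fixture_florence()$quantifier
  r <- tab[tab$t == 22.0, ]
  expect_equal(sqrt(pi) * (r$Q - r$erf_x) / (1 - r$gauss_x), 5,
               tolerance = 0.01)
})

test_that("quantifier asymptote is the season total", {
  expect_equal(quantifier_asymptote(florence), 3.821, tolerance = 1e-3)
  expect_equal(quantifier_asymptote(growth_params(k = 0)), 1)
  # brute-force limit for a shifted initiation
  p5 <- growth_params(x_i = 0.5)
  expect_equal(quantifier_asymptote(p5), growth_quantifier(10, p5),
               tolerance = 1e-9)
  expect_lt(abs(growth_quantifier(6, florence) -
                quantifier_asymptote(florence)), 1e-6)
})

test_that("quantifier table clamps pre-initiation times and handles edges", {
  expect_identical(nrow(quantifier_table(numeric(), florence)), 0L)
  one <- quantifier_table(initiation_time(florence), florence)
  expect_equal(one$x, florence$x_i)
  expect_equal(one$Q, 0)
  two <- quantifier_table(c(19.6, 29.5), florence)
  expect_equal(two$Q, c(0, 3.131), tolerance = 1e-3)
  pre <- quantifier_table(c(15, 17, 19), florence)
  expect_true(all(pre$Q == 0))
  expect_true(all(pre$x < 0))
})

test_that("Q is strictly increasing past initiation", {
  xs <- seq(0, 5, by = 0.01)
  expect_true(all(diff(growth_quantifier(xs, florence)) > 0))
  p <- growth_params(mu = 24, sigma_sqrt2 = 6, c = 0.1, k = 2, x_i = 0.2)
  xs <- seq(0.2, 5, by = 0.01)
  expect_true(all(diff(growth_quantifier(xs, p)) > 0))
})

test_that("parameter-set validation and config round trip", {
  expect_error(growth_params(sigma_sqrt2 = 0), "sigma_sqrt2")
  expect_error(growth_params(c = -0.1), "'c'")
  expect_error(growth_params(k = -1), "'k'")
  shipped <- read_growth_params(system.file("extdata", "florence-1982.params",
                                            package = "egm"))
  expect_equal(shipped[c("mu", "sigma_sqrt2", "c", "k", "x_i")],
               florence[c("mu", "sigma_sqrt2", "c", "k", "x_i")])
  tmp <- tempfile(fileext = ".params")
  p <- growth_params(mu = 24.5, sigma_sqrt2 = 7.25, c = 0.15, k = 3.5,
                     x_i = 0.125, label = "roundtrip")
  write_growth_params(p, tmp)
  expect_equal(read_growth_params(tmp), p)
  writeLines(c("mu = 1", "bogus = 2"), tmp)
  expect_error(read_growth_params(tmp), "unknown key")
})
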