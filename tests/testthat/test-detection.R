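test_that("hazard-rate curve has the shoulder and closed-form values", {
  expect_equal(hazard_rate_g(0, 150, 3), 1)
  expect_equal(hazard_rate_g(150, 150, 3), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(hazard_rate_g(300, 150, 3), 1 - exp(-0.125), tolerance = 1e-12)
  expect_error(hazard_rate_g(-1, 150, 3), ">= 0")
})

test_that("truncation is the smallest grid distance reaching the coverage", {
  set.seed(1)
  d <- runif(5000, 0, 400)
  w <- choose_truncation(d, coverage = 0.905)
  # brute-force oracle over the grid
  grid <- seq(50, 400, by = 50)
  oracle <- grid[which(sapply(grid, function(g) mean(d <= g)) >= 0.905)[1]]
  expect_equal(w, oracle)
  expect_equal(choose_truncation(runif(100, 0, 99), 0.905), 100)
  expect_equal(choose_truncation(c(10, 320), 1.0), 350)
  expect_error(choose_truncation(numeric(0)), "empty")
  expect_error(choose_truncation(1:10, coverage = 0.5), "coverage")
})

test_that("the MLE recovers hazard-rate parameters from simulated data", {
  set.seed(7)
  x <- rhazard(2000, sigma = 120, b = 2.5, w = 300)
  fit <- fit_detection(x, 300)
  expect_lt(abs(fit$sigma - 120) / 120, 0.10)
  expect_lt(abs(fit$b - 2.5) / 2.5, 0.20)
  expect_true(fit$esw > 0 && fit$esw <= 300)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  # optimum is at least as good as a crude start
  nll_at <- function(sigma, b) {
    mu <- integrate(hazard_rate_g, 0, 300, sigma = sigma, b = b)$value
    sum(log(hazard_rate_g(x, sigma, b))) - length(x) * log(mu)
  }
  expect_gte(fit$loglik, nll_at(150, 2.5))
  expect_error(fit_detection(rep(100, 50), 300), "identical")
  expect_error(fit_detection(x[1:5], 300), "fewer than")
})

test_that("effective strip width grows with sigma and respects the bound", {
  esw <- sapply(c(60, 120, 240), function(s) volewatch:::esw_hr(s, 2.5, 300))
  expect_true(all(diff(esw) > 0))
  expect_true(all(esw <= 300))
  # step-function limit: huge b makes g an indicator of x < sigma
  expect_equal(volewatch:::esw_hr(150, 60, 300), 150, tolerance = 0.03)
})

test_that("a no-information covariate costs exactly two AIC points", {
  set.seed(8)
  x <- rhazard(400, 130, 2.5, 300)
  # both levels carry identical distances, so the covariate model nests the
  # plain one at beta_season = 0 with the same likelihood
  xx <- c(x, x)
  lab <- rep(c("spring", "autumn"), each = length(x))
  f0 <- fit_detection(xx, 300)
  f1 <- fit_detection(xx, 300, season = lab)
  expect_lt(abs(f1$loglik - f0$loglik), 0.01)
  expect_equal(f1$n_params, f0$n_params + 1)
  expect_equal(f1$aic, f0$aic + 2, tolerance = 0.01 / f0$aic)
  expect_lt(abs(f1$sigma[["spring"]] - f1$sigma[["autumn"]]) / f0$sigma, 0.01)
  expect_identical(class(compare_by_aic(f0, f1)), "hr_fit")
  expect_equal(compare_by_aic(f0, f1)$n_params, f0$n_params)
})

test_that("AIC comparison picks the true covariate model and breaks ties", {
  set.seed(9)
  lab <- rep(c("spring", "autumn"), each = 1000)
  x <- c(rhazard(1000, 80, 2.5, 300), rhazard(1000, 190, 2.5, 300))
  f0 <- fit_detection(x, 300)
  f1 <- fit_detection(x, 300, season = lab)
  expect_lt(f1$aic, f0$aic)
  best <- compare_by_aic(f0, f1)
  expect_length(best$sigma, 2)
  # tie rule: equal AIC resolves toward fewer parameters
  fake <- function(aic, k, d) structure(
    list(aic = aic, n_params = k, w = 300, n = length(d), distances = d),
    class = "hr_fit")
  d <- 1:20
  expect_equal(compare_by_aic(fake(410.2, 3, d), fake(413.0, 4, d))$aic, 410.2)
  expect_equal(compare_by_aic(fake(410.2, 4, d), fake(410.2, 3, d))$n_params, 3)
  expect_error(compare_by_aic(fake(1, 2, 1:20), fake(1, 2, 2:21)),
               "different data")
})

test_that("density follows D = n / (2 mu L) and the conversion table", {
  stub <- function(esw) structure(list(esw = esw, sigma = 1, vcov = NULL,
                                       theta = c(0, 0), w = 300),
                                  class = "hr_fit")
  est <- estimate_density(50, 20, stub(200))
  expect_equal(est$density, 6.25)
  expect_equal(estimate_density(10, 20, stub(200))$conversion_coef, 2.5)
  expect_equal(estimate_density(10, 20, stub(250))$conversion_coef, 2.0)
  # KAI-to-density conversion, including the tabulated maximum
  expect_equal(kai_to_density(1.0, 2.5), 2.5)
  expect_equal(kai_to_density(0, 2.5), 0)
  expect_equal(kai_to_density(1.92, 2.5), 4.8)
  expect_error(kai_to_density(1, -2), "conversion_coef")
  # single session: point estimate without a CI
  one <- estimate_density(50, 20, stub(200), per_session_counts = 50)
  expect_true(all(is.na(one$ci95)))
  expect_equal(one$density, 6.25)
})

test_that("density estimation is invariant to the distance unit", {
  set.seed(10)
  xm <- rhazard(600, 120, 2.5, 300)
  fm <- fit_detection(xm, 300)
  fk <- fit_detection(xm / 1000, 0.3)
  # ESW scales with the unit; density from consistent inputs matches
  expect_equal(fk$esw * 1000, fm$esw, tolerance = 1e-3)
  dm <- estimate_density(600, 60, fm)$density
  dk <- 600 / (2 * fk$esw * 60)  # everything in km
  expect_equal(dm, dk, tolerance = 1e-3)
})

test_that("hazard-rate fits stay near truth on half-normal data", {
  set.seed(11)
  # robustness: data from a different key with similar effective width
  x <- abs(rnorm(4000, 0, 130))
  x <- x[x <= 300][1:1500]
  fit <- fit_detection(x, 300)
  esw_true <- integrate(function(z) exp(-z^2 / (2 * 130^2)), 0, 300)$value
  expect_lt(abs(fit$esw - esw_true) / esw_true, 0.12)
})

test_that("phase partition thresholds the nonzero KAI range", {
  expect_equal(partition_phases(c(0, 0.1, 1.8, 2.0)),
               c("low", "low", "high", "high"))
  expect_equal(partition_phases(c(0, 1, 2, 3), labels = c("high", "low", "low", "high")),
               c("high", "low", "low", "high"))
  expect_warning(ph <- partition_phases(rep(2, 5)), "constant")
  expect_equal(ph, rep("low", 5))
  expect_error(partition_phases(c(1, 2)), "at least 4")
  expect_error(partition_phases(1:4, labels = c("a", "b", "c", "d")), "low/high")
})
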