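test_that("the intercept-only fit is the log mean count", {
  set.seed(1)
  des <- data.frame(n = rpois(40, 7), log_length = 0, time_index = 0,
                    season = factor(rep("spring", 40),
                                    levels = c("spring", "summer", "autumn", "winter")),
                    prey_index = 0)
  f <- fit_poisson(des, include_time = FALSE)
  expect_equal(unname(coef(f)[1]), log(mean(des$n)), tolerance = 1e-9)
  expect_length(coef(f), 1)
})

test_that("known coefficients are recovered within 3 standard errors", {
  des <- toy_design(n = 200, a0 = -1, a2 = 0.03, a4 = 1.5, seed = 31)
  f <- fit_poisson(des)
  truth <- c(`(Intercept)` = -1, log_length = 1, time_index = 0.03,
             prey_index = 1.5)
  for (nm in names(truth)) {
    expect_lt(abs(f$coefficients[[nm]] - truth[[nm]]) / f$se[[nm]], 3)
  }
  expect_true(f$r_squared >= 0 && f$r_squared <= 1)
  # agrees with the reference IRLS implementation
  g <- stats::glm(n ~ log_length + time_index + season + prey_index,
                  stats::poisson(), des)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-8)
})

test_that("duplicated covariates raise a named rank-deficiency error", {
  des <- toy_design(n = 40, seed = 2)
  des$time_index <- des$prey_index  # perfectly collinear
  expect_error(fit_poisson(des), "prey_index|time_index")
})

test_that("IRLS matches a brute-force likelihood grid on a toy design", {
  set.seed(12)
  des <- data.frame(n = 0L, log_length = 0, time_index = 0,
                    season = factor(rep("spring", 60),
                                    levels = c("spring", "summer", "autumn", "winter")),
                    prey_index = runif(60))
  des$n <- rpois(60, exp(0.5 + 1.2 * des$prey_index))
  f <- fit_poisson(des, include_time = FALSE)
  ll <- function(a0, a4) sum(dpois(des$n, exp(a0 + a4 * des$prey_index), log = TRUE))
  grid <- expand.grid(a0 = seq(0, 1, 0.005), a4 = seq(0.5, 2, 0.005))
  best <- grid[which.max(mapply(ll, grid$a0, grid$a4)), ]
  expect_equal(unname(coef(f)), c(best$a0, best$a4), tolerance = 0.01)
  expect_gte(f$loglik, ll(best$a0, best$a4))
})

test_that("r-squared reaches 1 when the model reproduces the counts", {
  k <- c(2, 4, 8, 16, 32)
  des <- data.frame(n = rep(k, 4), log_length = 0, time_index = 0,
                    season = factor(rep("spring", 20),
                                    levels = c("spring", "summer", "autumn", "winter")),
                    prey_index = rep(log(k) / log(32), 4))
  f <- fit_poisson(des, include_time = FALSE)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(fitted(f)), des$n, tolerance = 1e-6)
})

test_that("permutation p-values follow the add-one formula", {
  # overwhelming effect: no permutation can beat the observed coefficient
  des <- toy_design(n = 40, a4 = 4, seed = 5)
  expect_equal(permute_coefficient(des, "prey_index", n_perm = 99, seed = 1),
               0.01)
  expect_error(permute_coefficient(des, "prey_index", n_perm = 50), ">= 99")
  expect_error(permute_coefficient(des, "elevation", 99), "unknown covariate")
  expect_error(permute_coefficient(des, "prey_index", 99, block_size = 99),
               "block_size")
})

test_that("block size one reproduces the plain permutation distribution", {
  des <- toy_design(n = 40, a4 = 0.5, seed = 6)
  p1 <- permute_coefficient(des, "prey_index", 199, seed = 9)
  p2 <- permute_coefficient(des, "prey_index", 199, seed = 9, block_size = 1)
  expect_equal(p1, p2)
  # block permutation runs and returns a valid p for larger blocks
  p4 <- permute_coefficient(des, "prey_index", 199, seed = 9, block_size = 4)
  expect_true(p4 > 0 && p4 <= 1)
})

test_that("season p-values are invariant to relabeling the levels", {
  des <- toy_design(n = 48, seed = 7)
  p_a <- permute_coefficient(des, "season", 199, seed = 3)
  rl <- des
  rl$season <- factor(as.character(rl$season),
                      levels = c("winter", "autumn", "summer", "spring"))
  p_b <- permute_coefficient(rl, "season", 199, seed = 3)
  expect_equal(p_a, p_b)
})

test_that("half-series tests detect level shifts and respect direction", {
  expect_equal(half_series_test(1:20, "greater", n_perm = 999, seed = 1), 0.001)
  expect_gt(half_series_test(1:20, "less", n_perm = 999, seed = 1), 0.99)
  expect_equal(half_series_test(rep(3, 10), "greater", 99, seed = 1), 1)
  expect_error(half_series_test(1:3, "greater"), "at least 4")
})

test_that("half-series p-values are uniform under an i.i.d. null", {
  set.seed(33)
  p <- replicate(300, half_series_test(rnorm(16), "greater", n_perm = 99))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("paired correlation permutation test matches the sign cases", {
  a <- c(3, 1, 4, 1, 5, 9, 2, 6)
  neg <- paired_correlation_test(a, -a, n_perm = 199, seed = 2)
  expect_equal(neg$r, -1)
  expect_equal(neg$p, 1 / 200)
  expect_equal(paired_correlation_test(a, a, 99, seed = 2)$r, 1)
  expect_error(paired_correlation_test(a, rep(1, 8), 99), "zero variance")
  expect_error(paired_correlation_test(a[1:4], a[1:4] * 2, 99), "at least 5")
})

test_that("response designs assemble counts, seasons and prey values", {
  b <- simulate_scenario(scenario_config(seed = 3, n_years = 6))
  ses <- b$sessions[b$sessions$period == "day", ]
  cnt <- b$counts[b$counts$session_id %in% ses$session_id, ]
  prey <- data.frame(time = c(-1, 25), value = c(0.5, 0.5))
  des <- response_design(ses, cnt, "carrion_crow", prey)
  expect_equal(nrow(des), nrow(ses))
  expect_true(all(des$prey_index == 0.5))
  kai <- compute_kai(ses, cnt, "carrion_crow")
  expect_equal(des$n, kai$max_count[match(des$session_id, kai$session_id)])
})
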