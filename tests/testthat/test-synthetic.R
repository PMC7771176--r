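test_that("noise-free vole dynamics are an exact sawtooth with zero troughs", {
  cfg <- scenario_config(seed = 1, noise_sdlog = 0)
  v <- simulate_vole_dynamics(cfg)
  expect_equal(min(v$aa_density), 0)
  expect_equal(max(v$aa_density), cfg$vole_max_density,
               tolerance = 0.05)
  # between 3 and 4 peaks over 20 years with a 5.5-year period
  mid <- 2:(nrow(v) - 1)
  peaks <- sum(diff(sign(diff(v$aa_density))) == -2 &
                 v$aa_density[mid] > cfg$vole_max_density / 2)
  expect_true(peaks >= 3 && peaks <= 4)
})

test_that("the dominant spectral period matches the configured cycle", {
  cfg <- scenario_config(seed = 2, noise_sdlog = 0.1)
  v <- simulate_vole_dynamics(cfg)
  sp <- stats::spec.pgram(stats::ts(v$aa_density, frequency = cfg$seasons_per_year),
                          plot = FALSE, taper = 0, detrend = TRUE)
  fpeak <- sp$freq[which.max(sp$spec)]
  expect_equal(1 / fpeak, cfg$cycle_period, tolerance = 0.25)
})

test_that("vole densities map onto the communal score bands", {
  expect_true(density_to_fredon(50) %in% 0:1)
  expect_true(density_to_fredon(99) %in% 0:1)
  expect_equal(density_to_fredon(150), 2L)
  expect_true(density_to_fredon(800) %in% 3:5)
  expect_equal(density_to_fredon(0), 0L)
  expect_equal(density_to_fredon(c(10, 150, 300, 500, 900)),
               c(0L, 2L, 3L, 4L, 5L))
})

test_that("transect simulation saturates and hits its calibration point", {
  expect_equal(simulate_transect(0, 100, seed = 1)$n_positive, 0)
  expect_gt(simulate_transect(1e6, 1000, seed = 1)$n_positive / 1000, 0.999)
  # k = ln2/200: density 200 gives a positive-interval probability of 1/2
  tr <- simulate_transect(200, 10000, seed = 2)
  expect_equal(tr$p_true, 0.5)
  expect_lt(abs(tr$n_positive / 10000 - 0.5), 0.02)
})

test_that("sessions are calibrated: expected counts equal the GLM mean", {
  cfg <- scenario_config(seed = 3)
  ls <- simulate_landscape()
  session <- list(time_index = 5, season = "autumn", period = "day",
                  itinerary_length = 19.6, n_replicates = 1)
  lam <- exp(0 + log(19.6) + 0.4 + 0.5 * 0.8)  # crow truth at prey 0.8
  set.seed(99)
  sims <- replicate(300, sum(simulate_session(cfg, ls, session,
                                              "carrion_crow", 0.8)$counts))
  se <- sd(sims) / sqrt(300)
  expect_lt(abs(mean(sims) - lam), 4 * se)
})

test_that("perfect detection recovers every placed individual", {
  cfg <- scenario_config(seed = 4, road_avoidance_scale = 0)
  cfg$species$carrion_crow$detection <- c(sigma = 1e7, b = 2.5)
  ls <- simulate_landscape()
  session <- list(time_index = 5, season = "autumn", period = "day",
                  itinerary_length = 19.6, n_replicates = 1)
  set.seed(5)
  sim <- simulate_session(cfg, ls, session, "carrion_crow", 1)
  expect_equal(sum(sim$counts), sim$truth$n_placed)
})

test_that("generated observation distances stay inside the strip", {
  b <- simulate_scenario(scenario_config(seed = 6, n_years = 6))
  obs <- b$observations
  per <- b$sessions$period[match(obs$session_id, b$sessions$session_id)]
  expect_true(all(obs$distance[per == "night"] <= 300))
  expect_true(all(obs$distance[per == "day"] <= 350))
  d <- perpendicular_distance(cbind(obs$x, obs$y), b$landscape)
  expect_equal(d, obs$distance, tolerance = 1e-6)
})

test_that("ground-truth phases agree with the partition rule on true means", {
  b <- simulate_scenario(scenario_config(seed = 7, noise_sdlog = 0))
  gt <- b$ground_truth[b$ground_truth$species_id == "common_buzzard", ]
  expect_equal(partition_phases(gt$lambda), gt$phase)
})

test_that("fixtures are bit-identical under a fixed seed and validated on read", {
  cfg <- scenario_config(seed = 8, n_years = 6)
  d1 <- file.path(tempdir(), "fxa"); d2 <- file.path(tempdir(), "fxb")
  m1 <- make_fixture(cfg, d1, force = TRUE)
  m2 <- make_fixture(cfg, d2, force = TRUE)
  expect_identical(unname(unlist(m1$files)), unname(unlist(m2$files)))
  expect_error(make_fixture(cfg, d1), "force")
  # the bundle passes the readers' validation end to end
  got <- read_sessions(file.path(d1, "counts.csv"))
  expect_equal(nrow(got$rejected), 0)
  expect_true(all(got$counts$session_id %in% got$sessions$session_id))
  tr <- read_transects(file.path(d1, "transects.csv"))
  expect_true(all(tr$n_positive <= tr$n_intervals))
  fred <- read_fredon(file.path(d1, "fredon.csv"))
  expect_true(all(fred$score %in% 0:5))
  ls <- read_landscape(file.path(d1, "landscape.geojson"))
  expect_equal(ls$itinerary_length, 19.7, tolerance = 1e-6)
  expect_s3_class(read_traits(file.path(d1, "traits.csv")), "species_traits")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("scenario scale matches the monitored study design", {
  cfg <- scenario_config(seed = 9)
  b <- simulate_scenario(cfg)
  night <- b$sessions[b$sessions$period == "night", ]
  expect_equal(nrow(night), 80)  # 4 sessions a year over 20 years
  expect_true(all(night$n_replicates == 3))
  expect_setequal(unique(b$sessions$itinerary_length), c(18.6, 19.6))
})
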