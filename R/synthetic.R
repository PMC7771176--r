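# Synthetic study generator: landscape, cyclic vole dynamics, transect
# and communal-score surveys, and roadside-count sessions simulated from
# known numerical-response, detection and habitat-affinity parameters.
# The vole cycle is a phenomenological sawtooth, not a mechanistic model:
# the generator exists to test the analysis, not vole biology. All
# randomness flows from one seed through a documented splitting scheme.

# Deterministic per-stage child seeds, kept below 2^31.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1103 * k) %% 2147483647
}

#' Scenario configuration for the synthetic generator
#'
#' Defaults emulate the monitored system: 5-6-year montane water vole
#' cycles with peaks near 1,000 ind/ha and troughs near zero, occasional
#' noncyclic common-vole outbreaks, four count sessions a year on a
#' ~19.7 km itinerary, species with known Poisson numerical-response
#' coefficients (a0 intercept, a1 on log length, a2 per-year trend, a3
#' season contrasts, a4 on the prey index), hazard-rate detection
#' parameters, and signed habitat affinities (positive = drawn closer).
#'
#' @param n_years study span (years).
#' @param seasons_per_year count sessions per year.
#' @param cycle_period water-vole cycle period, years (4-8).
#' @param vole_max_density cycle peak, individuals per hectare.
#' @param ma_baseline,ma_outbreak_prob,ma_outbreak_density common-vole
#'   baseline density, per-year outbreak probability, outbreak density.
#' @param noise_sdlog lognormal noise on vole densities (0 = exact sawtooth).
#' @param rise_fraction fraction of the cycle spent increasing.
#' @param species list per species: activity, body_mass, group, glm_truth
#'   (a0, a1, a2, a4 and a3 season vector), detection (sigma, b),
#'   habitat_affinity (forest, building).
#' @param road_avoidance_scale placement deficit scale near the road,
#'   meters (0 disables).
#' @param n_replicates_night,n_replicates_day replicate runs per session.
#' @param truncation_night,truncation_day strip half-widths, meters.
#' @param transect_intervals intervals per transect survey (11.6 km of
#'   10-m intervals).
#' @param transect_k saturation constant of the sign-detection curve
#'   (default ln 2 / 200: density 200 ind/ha gives proportion 0.5).
#' @param n_communes communes scored each autumn.
#' @param seed mandatory RNG seed.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_years = 20, seasons_per_year = 4,
                            cycle_period = 5.5, vole_max_density = 1000,
                            ma_baseline = 10, ma_outbreak_prob = 0.2,
                            ma_outbreak_density = 800,
                            noise_sdlog = 0.25, rise_fraction = 0.75,
                            species = default_species(),
                            road_avoidance_scale = 30,
                            n_replicates_night = 3, n_replicates_day = 1,
                            truncation_night = 300, truncation_day = 350,
                            transect_intervals = 1160,
                            transect_k = log(2) / 200,
                            n_communes = 7, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (cycle_period < 4 || cycle_period > 8)
    stop("cycle_period must lie in [4, 8]")
  if (vole_max_density < 0 || ma_baseline < 0) stop("densities must be >= 0")
  structure(as.list(environment()), class = "scenario_config")
}

#' Default synthetic species set
#'
#' Four focal species spanning the design space: an abundant corvid with a
#' weak prey effect, a raptor with a strong prey effect, a nocturnal
#' carnivore with a time trend and no prey effect, and a lagomorph with a
#' moderate prey effect and declining trend.
#'
#' @return Named list of per-species truth, see [scenario_config()].
#' @export
default_species <- function() {
  list(
    carrion_crow = list(
      activity = "day", body_mass = 550, group = "corvid",
      glm_truth = list(a0 = 0.0, a1 = 1, a2 = 0,
                       a3 = c(spring = 0, summer = 0.1, autumn = 0.4, winter = 0.1),
                       a4 = 0.5),
      detection = c(sigma = 180, b = 2.5),
      habitat_affinity = c(forest = -0.8, building = 0.5)),
    common_buzzard = list(
      activity = "day", body_mass = 800, group = "raptor",
      glm_truth = list(a0 = -1.4, a1 = 1, a2 = 0,
                       a3 = c(spring = 0, summer = 0.2, autumn = 0.8, winter = 0.1),
                       a4 = 2.0),
      detection = c(sigma = 160, b = 2.5),
      habitat_affinity = c(forest = 0, building = 0)),
    red_fox = list(
      activity = "night", body_mass = 6000, group = "mammalian carnivore",
      glm_truth = list(a0 = -2.3, a1 = 1, a2 = 0.08,
                       a3 = c(spring = 0, summer = 0, autumn = 0.1, winter = 0),
                       a4 = 0),
      detection = c(sigma = 120, b = 2.5),
      habitat_affinity = c(forest = 0.8, building = 0)),
    hare = list(
      activity = "night", body_mass = 4000, group = "lagomorph",
      glm_truth = list(a0 = -0.9, a1 = 1, a2 = -0.04,
                       a3 = c(spring = 0, summer = 0, autumn = 0, winter = 0),
                       a4 = 0.8),
      detection = c(sigma = 100, b = 2.5),
      habitat_affinity = c(forest = -0.8, building = 0)))
}

#' Traits table of the synthetic species set
#' @param config a [scenario_config()].
#' @return A [species_traits()] data frame.
#' @export
scenario_traits <- function(config) {
  sp <- config$species
  species_traits(data.frame(
    species_id = names(sp),
    body_mass = vapply(sp, `[[`, numeric(1), "body_mass"),
    activity = vapply(sp, `[[`, character(1), "activity"),
    group = vapply(sp, `[[`, character(1), "group"),
    tfi_override = NA_real_,
    stringsAsFactors = FALSE))
}

#' Simulate cyclic grassland vole dynamics
#'
#' Water vole: asymmetric sawtooth (slow rise over `rise_fraction` of the
#' cycle, fast crash), trough at zero, peak at `vole_max_density`, with
#' multiplicative lognormal noise. Common vole: low baseline with
#' Bernoulli outbreak years peaking in autumn.
#'
#' @param config a [scenario_config()].
#' @return Data frame with time (decimal years from study start), year,
#'   season, aa_density and ma_density (ind/ha).
#' @export
simulate_vole_dynamics <- function(config) {
  stopifnot(config$n_years >= config$cycle_period)
  set.seed(child_seed(config$seed, 1L))
  spy <- config$seasons_per_year
  t <- seq(0, config$n_years - 1 / spy, by = 1 / spy)
  phase <- (t %% config$cycle_period) / config$cycle_period
  rf <- config$rise_fraction
  shape <- ifelse(phase < rf, phase / rf, (1 - phase) / (1 - rf))
  aa <- config$vole_max_density * shape
  if (config$noise_sdlog > 0)
    aa <- aa * stats::rlnorm(length(aa), 0, config$noise_sdlog)

  years <- floor(t)
  outbreak <- stats::rbinom(config$n_years, 1, config$ma_outbreak_prob)
  season_shape <- c(0.4, 0.7, 1, 0.5)  # spring summer autumn winter
  season_idx <- (seq_along(t) - 1L) %% spy + 1L
  ma <- ifelse(outbreak[years + 1L] == 1,
               config$ma_outbreak_density * season_shape[pmin(season_idx, 4L)],
               config$ma_baseline)
  if (config$noise_sdlog > 0)
    ma <- ma * stats::rlnorm(length(ma), 0, config$noise_sdlog)

  data.frame(time = t, year = years,
             season = factor(c("spring", "summer", "autumn", "winter")[pmin(season_idx, 4L)],
                             levels = c("spring", "summer", "autumn", "winter")),
             aa_density = aa, ma_density = ma)
}

#' Map a vole density to a communal ordinal score
#'
#' Banded mapping consistent with the calibration of communal scores:
#' densities below 100 ind/ha score 0-1, 100-200 scores 2, above 200
#' scores 3-5, with configurable sub-band thresholds.
#'
#' @param density ind/ha (>= 0).
#' @param thresholds five increasing cut points for scores 1..5.
#' @return Integer scores 0-5.
#' @export
density_to_fredon <- function(density, thresholds = c(50, 100, 200, 450, 700)) {
  stopifnot(all(density >= 0), length(thresholds) == 5L,
            !is.unsorted(thresholds))
  findInterval(density, thresholds)
}

#' Simulate one transect survey
#'
#' Each 10-m interval is positive for fresh signs with probability
#' 1 - exp(-k * density * detectability), a saturating relation to density.
#'
#' @param true_density ind/ha.
#' @param n_intervals number of intervals.
#' @param detectability in (0, 1].
#' @param k saturation constant (default ln 2 / 200).
#' @param seed optional RNG seed.
#' @return List with n_intervals, n_positive, p_true.
#' @export
simulate_transect <- function(true_density, n_intervals,
                              detectability = 1, k = log(2) / 200,
                              seed = NULL) {
  stopifnot(n_intervals > 0, detectability > 0, detectability <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- 1 - exp(-k * true_density * detectability)
  list(n_intervals = n_intervals,
       n_positive = stats::rbinom(1, n_intervals, p),
       p_true = p)
}

#' Deterministic synthetic landscape
#'
#' A 6 x 6 km grassland square (the farmland mask) crossed by a ~19.7 km
#' serpentine itinerary, with forest blocks along two edges and three
#' building clusters.
#'
#' @return A [landscape] object in meters.
#' @export
simulate_landscape <- function() {
  xs <- c(750, 2250, 3750, 5250)
  lo <- 1100; hi <- 4900
  pts <- list()
  for (i in seq_along(xs)) {
    ys <- if (i %% 2L == 1L) c(lo, hi) else c(hi, lo)
    pts[[length(pts) + 1L]] <- c(xs[i], ys[1L])
    pts[[length(pts) + 1L]] <- c(xs[i], ys[2L])
  }
  itinerary <- do.call(rbind, pts)
  sq <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  landscape(
    itinerary = itinerary,
    forest = list(sq(0, 5300, 6000, 6000), sq(0, 0, 1500, 700)),
    buildings = list(sq(2900, 2900, 3100, 3100),
                     sq(1150, 1950, 1300, 2100),
                     sq(4700, 3950, 4900, 4150)),
    farmland = list(sq(0, 0, 6000, 6000)))
}

# Placement of individuals in the strip: uniform along-track and across
# [0, w] on both sides, tilted by road avoidance (deficit near the track)
# and by signed habitat affinity (log-linear in habitat distance, 500 m
# scale, distances capped at 1 km), via self-normalised rejection.
place_individuals <- function(n, landscape, w, affinity, road_scale) {
  if (n == 0L)
    return(list(xy = matrix(numeric(0), 0L, 2L), dist = numeric(0)))
  total <- polyline_length(landscape$itinerary)
  out_xy <- matrix(NA_real_, 0L, 2L); out_d <- numeric(0)
  while (nrow(out_xy) < n) {
    m <- max(200L, 4L * (n - nrow(out_xy)))
    u <- stats::runif(m, 0, total)
    x <- stats::runif(m, 0, w)
    side <- sample(c(-1, 1), m, replace = TRUE)
    at <- polyline_point_at(landscape$itinerary, u)
    xy <- at$point + at$normal * (side * x)
    keep <- rep(FALSE, m)
    for (ring in landscape$farmland) keep <- keep | points_in_polygon(xy, ring)
    lw <- rep(0, m)
    if (road_scale > 0) lw <- lw + log1p(-exp(-(x / road_scale)^2))
    if (affinity[["forest"]] != 0 && length(landscape$forest)) {
      df <- pmin(nearest_habitat_distance(xy, landscape$forest), 1000)
      lw <- lw - affinity[["forest"]] * df / 500
    }
    if (affinity[["building"]] != 0 && length(landscape$buildings)) {
      db <- pmin(nearest_habitat_distance(xy, landscape$buildings), 1000)
      lw <- lw - affinity[["building"]] * db / 500
    }
    acc <- keep & (log(stats::runif(m)) < lw - max(lw[keep], 0))
    out_xy <- rbind(out_xy, xy[acc, , drop = FALSE])
    out_d <- c(out_d, x[acc])
  }
  list(xy = out_xy[seq_len(n), , drop = FALSE], dist = out_d[seq_len(n)])
}

# Mean detection probability under the placement distance density (road
# avoidance included), so that expected per-replicate counts equal the
# numerical-response mean exactly.
mean_detection <- function(sigma, b, w, road_scale) {
  f <- function(x) {
    wgt <- if (road_scale > 0) 1 - exp(-(x / road_scale)^2) else rep(1, length(x))
    hazard_rate_g(x, sigma, b) * wgt
  }
  wnorm <- function(x) if (road_scale > 0) 1 - exp(-(x / road_scale)^2) else rep(1, length(x))
  num <- stats::integrate(f, 0, w, rel.tol = 1e-8)$value
  den <- stats::integrate(wnorm, 0, w, rel.tol = 1e-8)$value
  num / den
}

#' Simulate one roadside-count session for one species
#'
#' The expected per-replicate number of observations is
#' lambda = exp(a0 + a1 log L + a2 t + a3[season] + a4 prey). Individuals
#' are placed in the strip (with road-avoidance and habitat tilt) in a
#' number calibrated so each replicate's detections have mean lambda;
#' every individual is then detected independently on each replicate with
#' probability g(x; sigma, b).
#'
#' @param config a [scenario_config()].
#' @param landscape a [landscape].
#' @param session list/row with time_index, season, period,
#'   itinerary_length, n_replicates.
#' @param species_id one of `names(config$species)`.
#' @param prey_index prey index value at the session date, in [0, 1].
#' @return List with `counts` (per replicate), `observations`
#'   (one row per detection: replicate, x, y, distance) and `truth`
#'   (lambda, n_placed).
#' @export
simulate_session <- function(config, landscape, session, species_id,
                             prey_index) {
  sp <- config$species[[species_id]]
  if (is.null(sp)) stop("unknown species: ", species_id)
  g <- sp$glm_truth
  lambda <- exp(g$a0 + g$a1 * log(session$itinerary_length) +
                g$a2 * session$time_index +
                g$a3[[as.character(session$season)]] + g$a4 * prey_index)
  if (lambda > 1e6) stop("lambda overflow (> 1e6)")
  w <- if (session$period == "day") config$truncation_day else config$truncation_night
  pbar <- mean_detection(sp$detection[["sigma"]], sp$detection[["b"]], w,
                         config$road_avoidance_scale)
  n_true <- stats::rpois(1, lambda / pbar)
  placed <- place_individuals(n_true, landscape, w, sp$habitat_affinity,
                              config$road_avoidance_scale)
  # near serpentine corners the true map distance can be smaller than the
  # generative offset; detection follows the actual distance to the track
  if (n_true > 0)
    placed$dist <- perpendicular_distance(placed$xy, landscape)
  pdet <- if (n_true > 0)
    hazard_rate_g(placed$dist, sp$detection[["sigma"]], sp$detection[["b"]])
    else numeric(0)
  counts <- integer(session$n_replicates)
  obs <- vector("list", session$n_replicates)
  for (r in seq_len(session$n_replicates)) {
    det <- if (n_true > 0) stats::runif(n_true) < pdet else logical(0)
    counts[r] <- sum(det)
    if (any(det))
      obs[[r]] <- data.frame(replicate = r,
                             x = placed$xy[det, 1L], y = placed$xy[det, 2L],
                             distance = placed$dist[det])
  }
  list(counts = counts, observations = do.call(rbind, obs),
       truth = list(lambda = lambda, n_placed = n_true))
}

#' Simulate a complete monitoring scenario
#'
#' Runs the generator end to end: vole dynamics, transect and communal
#' score surveys, and every roadside-count session for every species, with
#' full ground truth retained.
#'
#' @param config a [scenario_config()].
#' @param landscape a [landscape]; defaults to [simulate_landscape()].
#' @return List with sessions, counts, observations, transects, fredon,
#'   traits, landscape, voles and ground_truth (per-session per-species
#'   lambda, placed number, phase label; per-session prey index and vole
#'   phase).
#' @export
simulate_scenario <- function(config, landscape = simulate_landscape()) {
  voles <- simulate_vole_dynamics(config)

  # true prey index on the generator's own scale
  s <- voles$aa_density + voles$ma_density / 4
  prey_true <- s / max(s)

  set.seed(child_seed(config$seed, 2L))
  # transect surveys: twice a year (spring/autumn) over the last 60% of the study
  tr_era <- voles$time >= 0.4 * config$n_years &
    voles$season %in% c("spring", "autumn")
  transects <- do.call(rbind, lapply(which(tr_era), function(i) {
    rbind(
      data.frame(time = voles$time[i], species_id = "arvicola",
                 simulate_transect(voles$aa_density[i],
                                   config$transect_intervals,
                                   k = config$transect_k)[1:2]),
      data.frame(time = voles$time[i], species_id = "microtus",
                 simulate_transect(voles$ma_density[i],
                                   config$transect_intervals,
                                   k = config$transect_k)[1:2]))
  }))

  # communal scores: each autumn, median over communes with local spread
  set.seed(child_seed(config$seed, 3L))
  autumns <- which(voles$season == "autumn")
  fredon <- do.call(rbind, lapply(autumns, function(i) {
    local <- voles$aa_density[i] * stats::rlnorm(config$n_communes, 0, 0.4)
    data.frame(commune_id = seq_len(config$n_communes),
               year = voles$year[i], time = voles$time[i],
               score = density_to_fredon(local))
  }))

  # sessions: one night and one day block per simulated season
  set.seed(child_seed(config$seed, 4L))
  rows <- list(); counts <- list(); obs <- list(); truth <- list()
  sid <- 0L
  for (i in seq_len(nrow(voles))) {
    for (period in c("night", "day")) {
      sid <- sid + 1L
      # recorded effort length changes mid-series (a small itinerary
      # re-route), which keeps the effort coefficient identifiable
      len <- if (voles$time[i] < config$n_years / 2) 18.6 else 19.6
      session <- list(
        session_id = sprintf("S%03d_%s", sid, period),
        time_index = voles$time[i], season = voles$season[i],
        period = period, itinerary_length = len,
        n_replicates = if (period == "night") config$n_replicates_night
                       else config$n_replicates_day)
      rows[[sid]] <- data.frame(
        session_id = session$session_id,
        date = as.Date("2000-01-01") + round(voles$time[i] * 365.25),
        season = voles$season[i], period = period,
        itinerary_length = len, n_replicates = session$n_replicates,
        time_index = voles$time[i], stringsAsFactors = FALSE)
      for (spn in names(config$species)) {
        if (config$species[[spn]]$activity != period) next
        sim <- simulate_session(config, landscape, session, spn, prey_true[i])
        counts[[length(counts) + 1L]] <- data.frame(
          session_id = session$session_id,
          replicate = seq_along(sim$counts), species_id = spn,
          count = sim$counts, stringsAsFactors = FALSE)
        if (!is.null(sim$observations))
          obs[[length(obs) + 1L]] <- data.frame(
            session_id = session$session_id, species_id = spn,
            sim$observations, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          session_id = session$session_id, species_id = spn,
          time_index = voles$time[i], lambda = sim$truth$lambda,
          n_placed = sim$truth$n_placed, prey_index = prey_true[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  sessions <- do.call(rbind, rows)
  ground <- do.call(rbind, truth)

  # per-species phase labels from the true expected counts: high when the
  # session's lambda exceeds the midpoint of that species' lambda range
  ground$phase <- NA_character_
  for (spn in unique(ground$species_id)) {
    idx <- ground$species_id == spn
    lam <- ground$lambda[idx]
    thr <- min(lam) + 0.5 * (max(lam) - min(lam))
    ground$phase[idx] <- ifelse(lam > thr, "high", "low")
  }
  aa_thr <- min(voles$aa_density) + 0.5 * diff(range(voles$aa_density))
  voles$phase <- ifelse(voles$aa_density > aa_thr, "high", "low")

  list(sessions = sessions, counts = do.call(rbind, counts),
       observations = do.call(rbind, obs), transects = transects,
       fredon = fredon, traits = scenario_traits(config),
       landscape = landscape, voles = voles, ground_truth = ground,
       prey_true = data.frame(time = voles$time, value = prey_true),
       config = config)
}

write_landscape_geojson <- function(landscape, path) {
  feat <- function(layer, type, coords) {
    list(type = "Feature", properties = list(layer = layer),
         geometry = list(type = type, coordinates = coords))
  }
  ring_coords <- function(ring) {
    closed <- rbind(ring, ring[1L, , drop = FALSE])
    list(lapply(seq_len(nrow(closed)), function(i) as.numeric(closed[i, ])))
  }
  line_coords <- function(line)
    lapply(seq_len(nrow(line)), function(i) as.numeric(line[i, ]))
  features <- c(
    list(feat("itinerary", "LineString", line_coords(landscape$itinerary))),
    lapply(landscape$forest, function(r) feat("forest", "Polygon", ring_coords(r))),
    lapply(landscape$buildings, function(r) feat("building", "Polygon", ring_coords(r))),
    lapply(landscape$farmland, function(r) feat("farmland", "Polygon", ring_coords(r))))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_observations_geojson <- function(df, path) {
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         properties = list(session_id = df$session_id[i],
                           species_id = df$species_id[i]),
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic dataset bundle to disk
#'
#' Generates a scenario and writes it in the same dialects the readers
#' accept (CSV, GeoJSON), with the full ground truth and a JSON manifest
#' (seed and per-file MD5 hashes). Bit-identical across runs with the
#' same seed.
#'
#' @param config a [scenario_config()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return The manifest, invisibly.
#' @export
make_fixture <- function(config, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0L && !force)
    stop("output directory not empty (use force = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulate_scenario(config)

  write_sessions(bundle$sessions, bundle$counts, file.path(dir, "counts.csv"))
  tr <- data.frame(
    survey_date = as.Date("2000-01-01") + round(bundle$transects$time * 365.25),
    species_id = bundle$transects$species_id,
    n_intervals = bundle$transects$n_intervals,
    n_positive = bundle$transects$n_positive)
  utils::write.csv(tr, file.path(dir, "transects.csv"), row.names = FALSE)
  utils::write.csv(bundle$fredon[c("commune_id", "year", "score")],
                   file.path(dir, "fredon.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$traits),
                   file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(bundle$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$voles, file.path(dir, "voles.csv"), row.names = FALSE)
  write_landscape_geojson(bundle$landscape, file.path(dir, "landscape.geojson"))
  if (!is.null(bundle$observations))
    write_observations_geojson(bundle$observations,
                               file.path(dir, "observations.geojson"))

  files <- sort(dir(dir))
  manifest <- list(seed = config$seed,
                   n_years = config$n_years,
                   files = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
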