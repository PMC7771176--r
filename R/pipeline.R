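# End-to-end orchestration: reads a dataset bundle, runs every analysis
# stage in order, and writes report tables shaped like the study's
# published tables (coefficient/p/r2 per species; conversion coefficients
# and densities by phase; community density/TFI snapshots; habitat
# randomization summaries) plus a JSON provenance manifest.

#' Pipeline run configuration
#'
#' @param input_dir directory holding `counts.csv`, `transects.csv`,
#'   `fredon.csv`, `traits.csv`, `landscape.geojson` and
#'   `observations.geojson` (the [make_fixture()] layout).
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param prey_species names of the two transect species combined into the
#'   prey index (heavier species first; the second carries the 1/4 weight).
#' @param exclude_species species excluded from the secondary community
#'   totals.
#' @param n_boot,n_perm,n_sim bootstrap/permutation/simulation counts.
#' @param coverage minimum fraction retained by [choose_truncation()] when
#'   no fixed truncation applies.
#' @param truncation_night,truncation_day fixed strip half-widths, meters.
#' @param phase_quantile threshold position for [partition_phases()].
#' @param seed RNG seed for all stochastic stages.
#' @return A classed config list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            prey_species = c("arvicola", "microtus"),
                            exclude_species = NULL,
                            n_boot = 1000, n_perm = 999, n_sim = 1000,
                            coverage = 0.92,
                            truncation_night = 300, truncation_day = 350,
                            phase_quantile = 0.5, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

run_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  stage_log(stage, sprintf("done in %.1fs", proc.time()[["elapsed"]] - t0))
  out
}

# Prey index interpolated to arbitrary session times, clamped to the
# index span (sessions slightly outside the surveyed span take the
# nearest knot's value).
prey_at <- function(prey, times) {
  t <- pmin(pmax(times, min(prey$time)), max(prey$time))
  interpolate_index(prey, t)
}

#' Run the full analysis pipeline
#'
#' Executes abundance -> prey index -> numerical response -> density ->
#' TFI -> habitat stages on a dataset bundle and writes one CSV per stage
#' plus a JSON manifest. Idempotent for fixed inputs and seed.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @return List of stage outputs, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ip <- function(f) file.path(config$input_dir, f)
  op <- function(f) file.path(config$out_dir, f)

  inputs <- run_stage("read", {
    sc <- read_sessions(ip("counts.csv"))
    list(sessions = sc$sessions, counts = sc$counts,
         transects = read_transects(ip("transects.csv")),
         fredon = read_fredon(ip("fredon.csv")),
         traits = read_traits(ip("traits.csv")),
         landscape = read_landscape(ip("landscape.geojson")),
         observations = read_observations(ip("observations.geojson")))
  })
  sessions <- inputs$sessions
  origin <- min(sessions$date)
  predators <- inputs$traits$species_id

  abundance <- run_stage("abundance", {
    kai <- compute_kai(sessions, inputs$counts, species = predators)
    utils::write.csv(kai, op("kai.csv"), row.names = FALSE)
    tr <- inputs$transects
    ti <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
      b <- transect_index(tr$n_intervals[i], tr$n_positive[i],
                          n_boot = config$n_boot,
                          seed = child_seed(config$seed, 100 + i))
      data.frame(survey_date = tr$survey_date[i], species_id = tr$species_id[i],
                 proportion = b$proportion, se = b$se,
                 ci_lower = b$ci95[1L], ci_upper = b$ci95[2L])
    }))
    utils::write.csv(ti, op("transect_index.csv"), row.names = FALSE)
    list(kai = kai, transect_index = ti)
  })

  prey <- run_stage("prey_index", {
    ti <- abundance$transect_index
    aa <- ti[ti$species_id == config$prey_species[1L], ]
    ma <- ti[ti$species_id == config$prey_species[2L], ]
    fredon_std <- standardize_fredon(inputs$fredon)
    fr <- data.frame(
      time = decimal_year(as.Date(paste0(names(fredon_std), "-10-15")), origin),
      value = unname(fredon_std))
    idx <- prey_resource_index(
      data.frame(time = decimal_year(aa$survey_date, origin),
                 proportion = aa$proportion),
      data.frame(time = decimal_year(ma$survey_date, origin),
                 proportion = ma$proportion),
      fredon = fr)
    utils::write.csv(as.data.frame(idx), op("prey_index.csv"), row.names = FALSE)
    idx
  })

  glm_table <- run_stage("numerical_response", {
    rows <- lapply(predators, function(sp) {
      act <- inputs$traits$activity[inputs$traits$species_id == sp]
      ses <- sessions[sessions$period == act | act == "both", ]
      if (nrow(ses) < 10L) return(NULL)
      cnt <- inputs$counts[inputs$counts$session_id %in% ses$session_id, ]
      kai_sp <- compute_kai(ses, cnt, sp)
      des <- data.frame(
        session_id = ses$session_id,
        n = kai_sp$max_count[match(ses$session_id, kai_sp$session_id)],
        log_length = log(ses$itinerary_length),
        time_index = ses$time_index,
        season = factor(as.character(ses$season),
                        levels = c("spring", "summer", "autumn", "winter")),
        prey_index = prey_at(prey, ses$time_index))
      fit <- fit_poisson(des, include_time = TRUE)
      p_time <- permute_coefficient(des, "time_index", config$n_perm,
                                    seed = child_seed(config$seed, 200))
      include_time <- p_time <= 0.05
      if (!include_time) fit <- fit_poisson(des, include_time = FALSE)
      data.frame(
        species_id = sp,
        time_p = if (include_time) p_time else NA_real_,
        season_p = permute_coefficient(des, "season", config$n_perm,
                                       seed = child_seed(config$seed, 201),
                                       include_time = include_time),
        prey_p = permute_coefficient(des, "prey_index", config$n_perm,
                                     seed = child_seed(config$seed, 202),
                                     include_time = include_time),
        r_squared = fit$r_squared,
        prey_coef = fit$coefficients[["prey_index"]])
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, op("numerical_response.csv"), row.names = FALSE)
    tab
  })

  density_table <- run_stage("density", {
    obs <- inputs$observations
    obs$distance <- perpendicular_distance(cbind(obs$x, obs$y),
                                           inputs$landscape)
    rows <- lapply(predators, function(sp) {
      act <- inputs$traits$activity[inputs$traits$species_id == sp]
      w <- if (act == "day") config$truncation_day else config$truncation_night
      d <- obs$distance[obs$species_id == sp]
      if (length(d) < 10L) return(NULL)
      fit <- tryCatch(fit_detection(d, w), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      act_sessions <- sessions$session_id[sessions$period == act | act == "both"]
      kai <- abundance$kai[abundance$kai$species_id == sp &
                             abundance$kai$session_id %in% act_sessions, ]
      phase <- partition_phases(kai$kai, quantile = config$phase_quantile)
      ses <- sessions[match(kai$session_id, sessions$session_id), ]
      per_sp <- lapply(c("low", "high"), function(ph) {
        sel <- kai$session_id[phase == ph]
        if (length(sel) == 0L) return(NULL)
        in_phase <- obs$species_id == sp & obs$session_id %in% sel
        eff <- sum(ses$itinerary_length[ses$session_id %in% sel] *
                     ses$n_replicates[ses$session_id %in% sel])
        n_det <- sum(obs$distance[in_phase] <= w)
        per_session <- vapply(sel, function(s)
          sum(obs$session_id == s & obs$species_id == sp &
                obs$distance <= w), numeric(1))
        est <- estimate_density(n_det, eff, fit, per_session)
        data.frame(species_id = sp, phase = ph, n_sessions = length(sel),
                   density = est$density, ci_lower = est$ci95[1L],
                   ci_upper = est$ci95[2L],
                   conversion_coef = est$conversion_coef,
                   sigma = unname(fit$sigma[1L]), b = fit$b, w = w,
                   max_density = max(kai$kai[phase == ph]) * est$conversion_coef)
      })
      do.call(rbind, per_sp)
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, op("density.csv"), row.names = FALSE)
    tab
  })

  tfi_out <- run_stage("tfi", {
    coefs <- stats::setNames(
      vapply(predators, function(sp) {
        r <- density_table[density_table$species_id == sp, ]
        if (nrow(r) == 0L) return(NA_real_)
        r$conversion_coef[1L]
      }, numeric(1)), predators)
    snaps <- lapply(split(abundance$kai, abundance$kai$session_id), function(k) {
      sp <- k$species_id[!is.na(coefs[k$species_id])]
      if (length(sp) == 0L) return(NULL)
      dens <- stats::setNames(kai_to_density(k$kai[match(sp, k$species_id)],
                                             coefs[sp]), sp)
      community_snapshot(dens, traits = inputs$traits,
                         exclude = config$exclude_species)
    })
    snaps <- snaps[!vapply(snaps, is.null, logical(1))]
    totals <- vapply(snaps, function(s) s$totals[["tfi"]], numeric(1))
    tab <- do.call(rbind, lapply(names(snaps), function(id) {
      t <- snaps[[id]]$table
      t$session_id <- id
      t
    }))
    utils::write.csv(tab, op("community.csv"), row.names = FALSE)
    list(snapshots = snaps, totals = totals)
  })

  habitat_table <- run_stage("habitat", {
    obs <- inputs$observations
    rows <- list()
    for (sp in unique(obs$species_id)) {
      act <- inputs$traits$activity[inputs$traits$species_id == sp]
      if (length(act) == 0L) next
      w <- if (act == "day") config$truncation_day else config$truncation_night
      pts <- as.matrix(obs[obs$species_id == sp, c("x", "y")])
      pts <- pts[perpendicular_distance(pts, inputs$landscape) <= w, ,
                 drop = FALSE]
      if (nrow(pts) < 5L) next
      for (hb in c("forest", "building")) {
        ht <- habitat_randomization_test(pts, inputs$landscape, hb, w,
                                         n_sim = config$n_sim,
                                         seed = child_seed(config$seed, 300))
        rows[[length(rows) + 1L]] <- data.frame(
          species_id = sp, habitat = hb, n_obs = ht$n_obs,
          mean_observed = ht$mean_observed,
          mean_null = mean(ht$null_means),
          direction = ht$direction, p_value = ht$p_value)
      }
    }
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, op("habitat.csv"), row.names = FALSE)
    tab
  })

  outputs <- c("kai.csv", "transect_index.csv", "prey_index.csv",
               "numerical_response.csv", "density.csv", "community.csv",
               "habitat.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("volewatch")),
    seed = config$seed,
    inputs = as.list(tools::md5sum(ip(c("counts.csv", "transects.csv",
                                        "fredon.csv", "traits.csv",
                                        "landscape.geojson",
                                        "observations.geojson")))),
    outputs = as.list(tools::md5sum(op(outputs))))
  jsonlite::write_json(manifest, op("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(abundance = abundance, prey_index = prey,
                 numerical_response = glm_table, density = density_table,
                 tfi = tfi_out, habitat = habitat_table,
                 manifest = manifest))
}
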