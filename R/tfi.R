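# Theoretical daily food intake (TFI) and community aggregation.
#
# Per-species TFI (grams of wet prey per day) is normally supplied
# directly in the traits table; when absent it falls back to an
# allometric chain TFI = FMR(M) / (energy density x assimilation), with
# field metabolic rate FMR = a * M^c (kJ/day, M in grams) per energetics
# group. The fallback coefficients are documented defaults, not ground
# truth for any particular study.

#' Energetics configuration
#'
#' @param fmr named list of `c(a, c)` pairs per energetics group, giving
#'   FMR = a * M^c in kJ/day with body mass M in grams. Defaults are
#'   Nagy-style all-mammal / all-bird regressions, with lagomorphs on the
#'   herbivore-mammal line.
#' @param prey_energy_density kJ per gram of wet prey mass.
#' @param assimilation_efficiency fraction of ingested energy assimilated.
#' @return Object of class `energetics_config`.
#' @export
energetics_config <- function(
    fmr = list(`mammalian carnivore` = c(a = 4.82, c = 0.734),
               raptor = c(a = 10.5, c = 0.681),
               corvid = c(a = 10.5, c = 0.681),
               lagomorph = c(a = 5.95, c = 0.727)),
    prey_energy_density = 6.5,
    assimilation_efficiency = 0.8) {
  if (any(vapply(fmr, `[[`, numeric(1), 1L) <= 0)) stop("FMR 'a' must be > 0")
  if (prey_energy_density <= 0) stop("prey_energy_density must be > 0")
  if (assimilation_efficiency <= 0 || assimilation_efficiency > 1)
    stop("assimilation_efficiency must be in (0, 1]")
  structure(list(fmr = fmr, prey_energy_density = prey_energy_density,
                 assimilation_efficiency = assimilation_efficiency),
            class = "energetics_config")
}

#' Per-species theoretical daily food intake
#'
#' Returns the traits table's `tfi_override` when present, otherwise the
#' allometric fallback FMR(M) / (prey_energy_density x assimilation).
#'
#' @param traits a [species_traits()] table (or a one-row slice).
#' @param config an [energetics_config()].
#' @return Named numeric vector, grams wet prey per day per species.
#' @export
species_tfi <- function(traits, config = energetics_config()) {
  out <- numeric(nrow(traits))
  for (i in seq_len(nrow(traits))) {
    if (!is.na(traits$tfi_override[i])) {
      out[i] <- traits$tfi_override[i]
    } else {
      co <- config$fmr[[traits$group[i]]]
      if (is.null(co)) stop("no FMR coefficients for group: ", traits$group[i])
      fmr <- co[["a"]] * traits$body_mass[i]^co[["c"]]
      out[i] <- fmr / (config$prey_energy_density * config$assimilation_efficiency)
    }
  }
  names(out) <- traits$species_id
  out
}

#' Community snapshot: density, biomass and TFI with totals and shares
#'
#' For one session (or phase), combines per-species densities with body
#' masses and per-capita intakes into a community table: biomass
#' (kg.km-2) = density x body mass, TFI (kg.km-2.day-1) = density x
#' per-capita intake, plus totals, percentage shares of each total, and
#' totals excluding a designated species (the "without crow" variant).
#' Aggregated per-species TFI values (already kg.km-2.day-1) may be
#' supplied directly instead, e.g. when re-deriving published tables.
#'
#' @param density named numeric vector, individuals per km2.
#' @param traits optional [species_traits()] matching the density names.
#' @param tfi_per_capita optional named vector, grams per day (defaults to
#'   [species_tfi()] on `traits`).
#' @param tfi_total optional named vector, kg.km-2.day-1, bypassing the
#'   per-capita computation.
#' @param exclude optional species_id excluded from the secondary totals.
#' @param config an [energetics_config()] for the fallback chain.
#' @return Object of class `community_snapshot`: `table` (species,
#'   density, biomass, tfi and share columns), `totals`, `totals_excluding`.
#' @export
community_snapshot <- function(density, traits = NULL, tfi_per_capita = NULL,
                               tfi_total = NULL, exclude = NULL,
                               config = energetics_config()) {
  if (is.null(names(density))) stop("density must be a named vector")
  if (any(density < 0)) stop("negative density")
  sp <- names(density)
  biomass <- rep(NA_real_, length(sp))
  if (!is.null(traits)) {
    m <- match(sp, traits$species_id)
    if (anyNA(m)) stop("missing traits for: ", paste(sp[is.na(m)], collapse = ", "))
    biomass <- density * traits$body_mass[m] / 1000
    if (is.null(tfi_per_capita) && is.null(tfi_total))
      tfi_per_capita <- species_tfi(traits[m, , drop = FALSE], config)
  }
  if (is.null(tfi_total)) {
    if (is.null(tfi_per_capita))
      stop("supply traits, tfi_per_capita or tfi_total")
    tfi <- density * tfi_per_capita[sp] / 1000
  } else {
    tfi <- tfi_total[sp]
    if (anyNA(tfi)) stop("tfi_total missing species")
  }

  tab <- data.frame(species_id = sp, density = unname(density),
                    biomass = unname(biomass), tfi = unname(tfi),
                    stringsAsFactors = FALSE)
  totals <- c(density = sum(tab$density), biomass = sum(tab$biomass),
              tfi = sum(tab$tfi))
  share <- function(v, tot) if (is.na(tot) || tot == 0) rep(NA_real_, length(v)) else 100 * v / tot
  tab$density_share <- share(tab$density, totals["density"])
  tab$biomass_share <- share(tab$biomass, totals["biomass"])
  tab$tfi_share <- share(tab$tfi, totals["tfi"])

  totals_excluding <- NULL
  if (!is.null(exclude)) {
    if (!exclude %in% sp) stop("exclude species not present")
    keep <- tab$species_id != exclude
    totals_excluding <- c(density = sum(tab$density[keep]),
                          biomass = sum(tab$biomass[keep]),
                          tfi = sum(tab$tfi[keep]))
  }
  structure(list(table = tab, totals = totals,
                 totals_excluding = totals_excluding, exclude = exclude),
            class = "community_snapshot")
}

#' @export
print.community_snapshot <- function(x, digits = 1, ...) {
  tab <- x$table
  fmt <- function(v, s) ifelse(is.na(v), "-",
                               sprintf("%.*f (%.*f)", digits, v, digits, s))
  out <- data.frame(species = tab$species_id,
                    density = fmt(tab$density, tab$density_share),
                    tfi = fmt(tab$tfi, tab$tfi_share))
  print(out, row.names = FALSE)
  cat(sprintf("Total: density %.*f, TFI %.*f\n", digits,
              x$totals["density"], digits, x$totals["tfi"]))
  if (!is.null(x$totals_excluding))
    cat(sprintf("Total without %s: density %.*f, TFI %.*f\n", x$exclude,
                digits, x$totals_excluding["density"],
                digits, x$totals_excluding["tfi"]))
  invisible(x)
}

#' Summaries of total TFI by abundance phase
#'
#' Reports the range of total TFI per phase, the maximizing session, and
#' the amplification ratio max(all totals) / min(low-phase totals),
#' rounded to one decimal.
#'
#' @param totals numeric vector of per-session total TFI (kg.km-2.day-1),
#'   optionally named by session.
#' @param phase character vector of `low`/`high` labels, same length.
#' @return List with `by_phase` (min/max/n per phase), `max_session`,
#'   `amplification`.
#' @export
phase_summary <- function(totals, phase) {
  stopifnot(length(totals) == length(phase))
  phases <- c("low", "high")
  by_phase <- lapply(phases, function(ph) {
    v <- totals[phase == ph]
    if (length(v) == 0L) return(list(min = NA_real_, max = NA_real_, n = 0L))
    list(min = min(v), max = max(v), n = length(v))
  })
  names(by_phase) <- phases
  max_session <- if (!is.null(names(totals))) names(totals)[which.max(totals)]
    else which.max(totals)
  low_min <- by_phase$low$min
  amplification <- if (is.na(low_min) || low_min == 0) NA_real_ else
    round(max(totals) / low_min, 1)
  list(by_phase = by_phase, max_session = max_session,
       amplification = amplification)
}
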