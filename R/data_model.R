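# Core domain tables, readers/writers and the season calendar.
#
# Tabular inputs are UTF-8 CSV with ISO-8601 dates; geometry is GeoJSON
# (RFC 7946) reprojected on load to a local metric frame when supplied in
# geographic coordinates.

#' Season calendar
#'
#' Month-based season definition used to stamp each count session. The
#' default is the meteorological calendar: March-May spring, June-August
#' summer, September-November autumn, December-February winter.
#'
#' @param spring,summer,autumn,winter integer month vectors; together they
#'   must partition 1:12.
#' @return An object of class `season_calendar`.
#' @export
season_calendar <- function(spring = 3:5, summer = 6:8, autumn = 9:11,
                            winter = c(12L, 1L, 2L)) {
  months <- sort(c(spring, summer, autumn, winter))
  if (!identical(as.integer(months), 1:12))
    stop("season months must partition 1:12")
  structure(list(spring = as.integer(spring), summer = as.integer(summer),
                 autumn = as.integer(autumn), winter = as.integer(winter)),
            class = "season_calendar")
}

#' Assign a season to calendar dates
#'
#' @param date `Date` vector (or coercible).
#' @param calendar a [season_calendar()].
#' @return Factor with levels spring, summer, autumn, winter.
#' @export
assign_season <- function(date, calendar = season_calendar()) {
  stopifnot(inherits(calendar, "season_calendar"))
  m <- as.integer(format(as.Date(date), "%m"))
  out <- character(length(m))
  for (s in names(calendar)) out[m %in% calendar[[s]]] <- s
  factor(out, levels = c("spring", "summer", "autumn", "winter"))
}

#' Decimal years since an origin date
#'
#' @param date `Date` vector.
#' @param origin `Date`; defaults to the earliest date supplied.
#' @return Numeric vector of years elapsed (365.25-day years).
#' @export
decimal_year <- function(date, origin = NULL) {
  date <- as.Date(date)
  if (is.null(origin)) origin <- min(date)
  as.numeric(date - as.Date(origin)) / 365.25
}

#' Species traits table
#'
#' Validates a traits table: one row per species with its adult average
#' body mass (grams), activity period, energetics group, and optionally a
#' directly supplied theoretical daily food intake (grams wet prey per
#' day) that bypasses the allometric chain.
#'
#' @param df data frame with columns `species_id`, `body_mass`, `activity`
#'   (`day`, `night` or `both`), `group` (`mammalian carnivore`, `raptor`,
#'   `corvid` or `lagomorph`) and optionally `tfi_override`.
#' @return The validated data frame, classed `species_traits`.
#' @export
species_traits <- function(df) {
  req <- c("species_id", "body_mass", "activity", "group")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("traits table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$species_id)) stop("duplicate species_id in traits table")
  if (any(df$body_mass <= 0)) stop("body_mass must be > 0")
  if (!all(df$activity %in% c("day", "night", "both")))
    stop("activity must be one of day/night/both")
  if (!all(df$group %in% c("mammalian carnivore", "raptor", "corvid", "lagomorph")))
    stop("unknown energetics group")
  if (!is.null(df$tfi_override) && any(!is.na(df$tfi_override) & df$tfi_override <= 0))
    stop("tfi_override must be > 0 when present")
  if (is.null(df$tfi_override)) df$tfi_override <- NA_real_
  class(df) <- c("species_traits", "data.frame")
  df
}

#' Read a species traits CSV
#' @param path CSV with the [species_traits()] columns.
#' @return A `species_traits` data frame.
#' @export
read_traits <- function(path) {
  species_traits(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read roadside-count sessions and counts
#'
#' Parses a long-format count table (one row per session x replicate x
#' species) into a session table and a count-event table. Rows violating
#' invariants (malformed date, negative count, missing itinerary length)
#' are rejected with their line numbers; rows for species absent from
#' `known_species` are kept but flagged.
#'
#' @param path CSV with columns `session_id`, `date`, `period` (`day` or
#'   `night`), `replicate`, `species_id`, `count`, `itinerary_length` (km).
#' @param calendar a [season_calendar()].
#' @param known_species optional character vector; species outside it are
#'   flagged (`unknown_species = TRUE`), never dropped.
#' @return List with elements `sessions` (session_id, date, season, period,
#'   itinerary_length, n_replicates, time_index), `counts` (session_id,
#'   replicate, species_id, count, unknown_species) and `rejected`
#'   (line, reason).
#' @export
read_sessions <- function(path, calendar = season_calendar(),
                          known_species = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("session_id", "date", "period", "replicate", "species_id",
           "count", "itinerary_length")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("count table missing columns: ", paste(miss, collapse = ", "))

  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  count <- suppressWarnings(as.numeric(raw$count))
  len <- suppressWarnings(as.numeric(raw$itinerary_length))
  repl <- suppressWarnings(as.integer(raw$replicate))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(date)] <- "malformed date"
  reason[is.na(count) | count < 0 | count != floor(count)] <- "invalid count"
  reason[is.na(len) | len <= 0] <- "missing or nonpositive itinerary length"
  reason[is.na(repl) | repl < 1] <- "invalid replicate index"
  bad <- !is.na(reason)
  rejected <- data.frame(line = line[bad], reason = reason[bad],
                         stringsAsFactors = FALSE)
  if (any(bad)) warning(sum(bad), " row(s) rejected; see $rejected")

  ok <- raw[!bad, , drop = FALSE]
  date <- date[!bad]; count <- count[!bad]; len <- len[!bad]; repl <- repl[!bad]
  if (nrow(ok) == 0L) stop("no valid rows in ", path)

  counts <- data.frame(session_id = ok$session_id, replicate = repl,
                       species_id = ok$species_id, count = as.integer(count),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(counts[, c("session_id", "replicate", "species_id")]))
    stop("duplicate (session, replicate, species) rows")
  counts$unknown_species <- if (is.null(known_species)) FALSE else
    !(counts$species_id %in% known_species)
  if (any(counts$unknown_species))
    warning("unknown species flagged: ",
            paste(unique(counts$species_id[counts$unknown_species]), collapse = ", "))

  ord <- order(date, ok$session_id)
  first <- !duplicated(ok$session_id[ord])
  sid <- ok$session_id[ord][first]
  sdate <- date[ord][first]
  speriod <- ok$period[ord][first]
  slen <- len[ord][first]
  nrep <- tapply(repl, ok$session_id, function(r) length(unique(r)))
  nrep <- as.integer(nrep[sid])
  if (any(nrep > 4L)) stop("more than 4 replicates in a session")
  if (!all(speriod %in% c("day", "night"))) stop("period must be day or night")

  sessions <- data.frame(session_id = sid, date = sdate,
                         season = assign_season(sdate, calendar),
                         period = speriod, itinerary_length = slen,
                         n_replicates = nrep,
                         time_index = decimal_year(sdate),
                         stringsAsFactors = FALSE)
  rownames(sessions) <- NULL
  list(sessions = sessions, counts = counts, rejected = rejected)
}

#' Write sessions and counts back to the long CSV dialect
#'
#' Inverse of [read_sessions()]: the written file re-reads to the same
#' sessions and counts (up to column order).
#'
#' @param sessions,counts as returned by [read_sessions()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, counts, path) {
  m <- match(counts$session_id, sessions$session_id)
  if (anyNA(m)) stop("count rows reference unknown sessions")
  out <- data.frame(session_id = counts$session_id,
                    date = format(sessions$date[m], "%Y-%m-%d"),
                    period = sessions$period[m],
                    replicate = counts$replicate,
                    species_id = counts$species_id,
                    count = counts$count,
                    itinerary_length = sessions$itinerary_length[m],
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read interval-transect survey records
#'
#' @param path CSV with columns `survey_date`, `species_id`, `n_intervals`,
#'   `n_positive`.
#' @return Validated data frame with `survey_date` as `Date`.
#' @export
read_transects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$survey_date <- as.Date(df$survey_date)
  if (anyNA(df$survey_date)) stop("malformed survey_date")
  if (any(df$n_intervals <= 0)) stop("n_intervals must be > 0")
  if (any(df$n_positive < 0 | df$n_positive > df$n_intervals))
    stop("n_positive must lie in [0, n_intervals]")
  df
}

#' Read communal ordinal abundance scores
#'
#' @param path CSV with columns `commune_id`, `year`, `score` (integer 0-5).
#' @return Validated data frame.
#' @export
read_fredon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(df$score %in% 0:5)) stop("scores must be integers in 0..5")
  df
}

geojson_feature_coords <- function(feature) {
  geom <- feature$geometry
  coords <- geom$coordinates
  switch(geom$type,
         Point = matrix(unlist(coords), ncol = 2, byrow = TRUE),
         LineString = do.call(rbind, lapply(coords, function(p) unlist(p)[1:2])),
         Polygon = do.call(rbind, lapply(coords[[1L]], function(p) unlist(p)[1:2])),
         stop("unsupported geometry type: ", geom$type))
}

#' Read a landscape from GeoJSON
#'
#' Expects features carrying a `layer` property among `itinerary`,
#' `forest`, `building` and `farmland`. Geographic coordinates are
#' projected to a local metric frame on load; metric coordinates are kept
#' as-is. Invalid (self-intersecting) polygons are dropped with a warning.
#'
#' @param path GeoJSON file.
#' @return A [landscape] object.
#' @export
read_landscape <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  layers <- list(itinerary = NULL, forest = list(), building = list(),
                 farmland = list())
  feats <- list()
  for (f in gj$features) {
    layer <- f$properties$layer
    if (is.null(layer)) next
    feats[[length(feats) + 1L]] <- list(layer = layer,
                                        coords = geojson_feature_coords(f))
  }
  if (length(feats) == 0L) stop("no layered features found")
  allc <- do.call(rbind, lapply(feats, `[[`, "coords"))
  reproject <- looks_lonlat(allc)
  origin <- colMeans(allc)
  for (f in feats) {
    coords <- if (reproject) project_lonlat(f$coords, origin) else f$coords
    if (f$layer == "itinerary") {
      layers$itinerary <- coords
    } else if (f$layer %in% c("forest", "building", "farmland")) {
      # drop duplicated closing vertex of GeoJSON rings
      n <- nrow(coords)
      if (n > 1L && all(coords[1L, ] == coords[n, ]))
        coords <- coords[-n, , drop = FALSE]
      if (!ring_is_simple(coords)) {
        warning("dropping invalid (self-intersecting) ", f$layer, " polygon")
        next
      }
      layers[[f$layer]] <- c(layers[[f$layer]], list(coords))
    }
  }
  landscape(itinerary = layers$itinerary, forest = layers$forest,
            buildings = layers$building, farmland = layers$farmland)
}

#' Landscape container
#'
#' Holds the itinerary polyline, forest and building polygon sets, and the
#' farmland mask (the area where animals and random null positions may
#' occur), all in one planar metric frame.
#'
#' @param itinerary polyline vertex matrix (meters).
#' @param forest,buildings,farmland lists of polygon ring matrices.
#' @return Object of class `landscape` with the geometry plus
#'   `itinerary_length` in km.
#' @export
landscape <- function(itinerary, forest = list(), buildings = list(),
                      farmland = list()) {
  if (is.null(itinerary)) stop("itinerary feature required")
  itinerary <- as_coords(itinerary)
  if (length(farmland) == 0L) stop("farmland_mask required")
  for (ring in c(forest, buildings, farmland))
    if (!ring_is_simple(as_coords(ring))) stop("invalid polygon in landscape")
  structure(list(itinerary = itinerary,
                 forest = lapply(forest, as_coords),
                 buildings = lapply(buildings, as_coords),
                 farmland = lapply(farmland, as_coords),
                 itinerary_length = polyline_length(itinerary, "km")),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("landscape: itinerary", sprintf("%.2f km,", x$itinerary_length),
      length(x$forest), "forest,", length(x$buildings), "building,",
      length(x$farmland), "farmland polygon(s)\n")
  invisible(x)
}

#' Read georeferenced observation points from GeoJSON
#'
#' Point features with `session_id` and `species_id` properties. The
#' perpendicular distance to the itinerary is computed and cached when a
#' landscape is supplied.
#'
#' @param path GeoJSON file of Point features.
#' @param landscape optional [landscape] used to derive distances and to
#'   share the projection origin for lon/lat input.
#' @return Data frame with session_id, species_id, x, y and (if landscape
#'   given) `distance` in meters.
#' @export
read_observations <- function(path, landscape = NULL) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    if (f$geometry$type != "Point") return(NULL)
    xy <- unlist(f$geometry$coordinates)[1:2]
    data.frame(session_id = as.character(f$properties$session_id),
               species_id = as.character(f$properties$species_id),
               x = xy[1L], y = xy[2L], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("no Point features found")
  if (looks_lonlat(cbind(df$x, df$y))) {
    xy <- project_lonlat(cbind(df$x, df$y))
    df$x <- xy[, 1L]; df$y <- xy[, 2L]
  }
  if (!is.null(landscape))
    df$distance <- perpendicular_distance(cbind(df$x, df$y), landscape)
  df
}

#' Bounding box of a study area from a KML file
#'
#' Reads the first set of coordinates found in a KML document (read-only
#' support for deposited study-area files).
#'
#' @param path KML file.
#' @return Named numeric vector (xmin, xmax, ymin, ymax) in the KML's
#'   lon/lat degrees.
#' @export
read_kml_bbox <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//*[local-name()='coordinates']")
  if (length(nodes) == 0L) stop("no coordinates in KML")
  txt <- paste(xml2::xml_text(nodes), collapse = " ")
  toks <- strsplit(trimws(txt), "[[:space:]]+")[[1L]]
  xy <- do.call(rbind, lapply(strsplit(toks, ","),
                              function(p) as.numeric(p[1:2])))
  c(xmin = min(xy[, 1L]), xmax = max(xy[, 1L]),
    ymin = min(xy[, 2L]), ymax = max(xy[, 2L]))
}
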