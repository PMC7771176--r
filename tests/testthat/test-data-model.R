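test_that("count tables parse into sessions and events", {
  f <- counts_csv(tempfile(fileext = ".csv"), c(
    "S1,2008-10-15,night,1,red_fox,2,18.6",
    "S1,2008-10-15,night,2,red_fox,5,18.6",
    "S1,2008-10-15,night,3,red_fox,3,18.6",
    "S2,2014-04-01,night,1,red_fox,1,19.6"))
  got <- read_sessions(f)
  expect_equal(nrow(got$sessions), 2)
  expect_equal(got$sessions$n_replicates, c(3L, 1L))
  expect_equal(nrow(got$counts), 4)
  # per-session itinerary lengths preserved (the mid-study re-route)
  expect_equal(got$sessions$itinerary_length, c(18.6, 19.6))
  expect_equal(as.character(got$sessions$season), c("autumn", "spring"))
})

test_that("invalid rows are rejected with their line numbers", {
  f <- counts_csv(tempfile(fileext = ".csv"), c(
    "S1,2008-10-15,night,1,red_fox,2,18.6",
    "S1,2008-10-15,night,2,red_fox,-1,18.6",
    "S1,not-a-date,night,3,red_fox,3,18.6",
    "S1,2008-10-15,night,4,red_fox,3,"))
  expect_warning(got <- read_sessions(f), "rejected")
  expect_equal(got$rejected$line, c(3L, 4L, 5L))
  expect_match(got$rejected$reason[1], "count")
  expect_equal(nrow(got$counts), 1)
})

test_that("unknown species are flagged, not dropped", {
  f <- counts_csv(tempfile(fileext = ".csv"), c(
    "S1,2008-10-15,night,1,red_fox,2,18.6",
    "S1,2008-10-15,night,1,grey_heron,1,18.6"))
  expect_warning(got <- read_sessions(f, known_species = "red_fox"),
                 "grey_heron")
  expect_equal(sum(got$counts$unknown_species), 1)
  expect_equal(nrow(got$counts), 2)
})

test_that("write_sessions round-trips through read_sessions", {
  f <- counts_csv(tempfile(fileext = ".csv"), c(
    "S1,2008-10-15,night,1,red_fox,2,18.6",
    "S1,2008-10-15,night,2,red_fox,5,18.6",
    "S2,2014-04-01,day,1,carrion_crow,40,19.6"))
  a <- read_sessions(f)
  f2 <- tempfile(fileext = ".csv")
  write_sessions(a$sessions, a$counts, f2)
  b <- read_sessions(f2)
  expect_equal(a$sessions, b$sessions)
  expect_equal(a$counts, b$counts)
  bad <- a$counts
  bad$session_id[1] <- "nope"
  expect_error(write_sessions(a$sessions, bad, tempfile()), "unknown sessions")
})

test_that("season assignment is total and follows the calendar", {
  expect_equal(as.character(assign_season(as.Date("2008-10-15"))), "autumn")
  expect_equal(as.character(assign_season(as.Date("2014-04-01"))), "spring")
  expect_equal(as.character(assign_season(as.Date("1999-12-31"))), "winter")
  # every day of a year maps to exactly one season
  days <- seq(as.Date("2011-01-01"), as.Date("2011-12-31"), by = "day")
  s <- assign_season(days)
  expect_false(anyNA(s))
  expect_equal(sort(unique(as.character(s))),
               sort(c("spring", "summer", "autumn", "winter")))
  # custom calendar shifts the boundary
  cal <- season_calendar(spring = 4:6, summer = 7:9, autumn = 10:12,
                         winter = 1:3)
  expect_equal(as.character(assign_season(as.Date("2011-03-15"), cal)), "winter")
  expect_error(season_calendar(spring = 3:6, summer = 6:8), "partition")
})

test_that("landscape GeoJSON reads with layers, lengths and validation", {
  ls0 <- landscape(
    itinerary = cbind(c(0, 19600), c(0, 0)),
    forest = list(square_ring(0, 500, 800, 1200),
                  square_ring(5000, 500, 6000, 1500)),
    buildings = list(square_ring(10000, -300, 10200, -100)),
    farmland = list(square_ring(-500, -2000, 20000, 2000)))
  f <- tempfile(fileext = ".geojson")
  volewatch:::write_landscape_geojson(ls0, f)
  got <- read_landscape(f)
  expect_equal(got$itinerary_length, 19.6)
  expect_length(got$forest, 2)
  expect_length(got$buildings, 1)
  expect_error(landscape(cbind(c(0, 1), c(0, 1)), farmland = list()),
               "farmland_mask required")
  bowtie <- cbind(c(0, 100, 100, 0), c(0, 100, 0, 100))
  expect_error(landscape(cbind(c(0, 1), c(0, 1)), farmland = list(bowtie)),
               "invalid polygon")
})

test_that("geographic coordinates are projected to meters on load", {
  # a ~1.1 km west-east line at 47N spans ~0.0145 degrees of longitude
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(layer = "itinerary"),
         geometry = list(type = "LineString",
                         coordinates = list(c(6.29, 46.95), c(6.3045, 46.95)))),
    list(type = "Feature", properties = list(layer = "farmland"),
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(6.28, 46.94), c(6.32, 46.94),
                                                 c(6.32, 46.96), c(6.28, 46.96),
                                                 c(6.28, 46.94)))))))
  f <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  got <- read_landscape(f)
  expect_gt(got$itinerary_length, 1.0)
  expect_lt(got$itinerary_length, 1.2)
})

test_that("KML bounding boxes are extracted read-only", {
  kml <- paste0('<?xml version="1.0" encoding="UTF-8"?>',
                '<kml xmlns="http://www.opengis.net/kml/2.2"><Document><Placemark>',
                '<Polygon><outerBoundaryIs><LinearRing><coordinates>',
                '6.25,46.93,0 6.33,46.93,0 6.33,46.97,0 6.25,46.97,0',
                '</coordinates></LinearRing></outerBoundaryIs></Polygon>',
                '</Placemark></Document></kml>')
  f <- tempfile(fileext = ".kml")
  writeLines(kml, f)
  bb <- read_kml_bbox(f)
  expect_equal(unname(bb), c(6.25, 6.33, 46.93, 46.97))
})

test_that("traits tables are validated", {
  df <- data.frame(species_id = c("red_fox", "carrion_crow"),
                   body_mass = c(6000, 550),
                   activity = c("night", "day"),
                   group = c("mammalian carnivore", "corvid"))
  tr <- species_traits(df)
  expect_s3_class(tr, "species_traits")
  expect_true(all(is.na(tr$tfi_override)))
  expect_error(species_traits(transform(df, body_mass = c(-1, 550))),
               "body_mass")
  expect_error(species_traits(df[c(1, 1), ]), "duplicate")
})
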