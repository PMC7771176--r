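# Abundance indices: KAI from roadside counts, transect relative
# abundance with bootstrap uncertainty, standardized communal scores, and
# the composite grassland prey-resource index.

#' Kilometric abundance index (KAI)
#'
#' For each session and species, the maximum count over the session's
#' replicate runs divided by the itinerary length: a lower bound on the
#' number of animals present per km of track. Species-replicate pairs with
#' no row count as zero (observers record all target species every run).
#'
#' @param sessions,counts as returned by [read_sessions()].
#' @param species optional character vector restricting the species set;
#'   defaults to all species present in `counts`.
#' @return Data frame with session_id, species_id, max_count, kai
#'   (animals per km), ordered by session date.
#' @export
compute_kai <- function(sessions, counts, species = NULL) {
  if (any(sessions$itinerary_length <= 0)) stop("itinerary_length must be > 0")
  if (is.null(species)) species <- sort(unique(counts$species_id))
  m <- match(counts$session_id, sessions$session_id)
  if (anyNA(m)) stop("count rows reference unknown sessions")
  out <- expand.grid(session_id = sessions$session_id, species_id = species,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_counts <- paste(counts$session_id, counts$species_id, sep = "\r")
  key_out <- paste(out$session_id, out$species_id, sep = "\r")
  mx <- tapply(counts$count, key_counts, max)
  out$max_count <- as.integer(ifelse(key_out %in% names(mx), mx[key_out], 0L))
  sm <- match(out$session_id, sessions$session_id)
  out$kai <- out$max_count / sessions$itinerary_length[sm]
  out$date <- sessions$date[sm]
  out[order(out$species_id, out$date), c("session_id", "species_id",
                                         "max_count", "kai", "date")]
}

#' Transect relative abundance with bootstrap uncertainty
#'
#' Proportion of 10-m transect intervals positive for fresh activity
#' signs, with a nonparametric bootstrap (resampling interval outcomes
#' with replacement) for the standard error and a percentile 95% CI.
#'
#' @param n_intervals,n_positive interval totals for one survey/species.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for reproducibility.
#' @return List with proportion, se, ci95 (length-2), n_boot.
#' @export
transect_index <- function(n_intervals, n_positive, n_boot = 1000,
                           seed = NULL) {
  if (n_intervals <= 0) stop("n_intervals must be > 0")
  if (n_positive < 0 || n_positive > n_intervals)
    stop("n_positive must lie in [0, n_intervals]")
  if (n_boot < 1) stop("n_boot must be >= 1")
  p <- n_positive / n_intervals
  if (!is.null(seed)) set.seed(seed)
  # resampling Bernoulli interval outcomes: counts are binomial draws
  boot_p <- stats::rbinom(n_boot, n_intervals, p) / n_intervals
  list(proportion = p,
       se = stats::sd(boot_p),
       ci95 = unname(stats::quantile(boot_p, c(0.025, 0.975))),
       n_boot = n_boot)
}

#' Standardize communal ordinal scores
#'
#' For each year, the median score across communes divided by the highest
#' score recorded over the whole series, giving a [0, 1] index.
#'
#' @param records data frame with `commune_id`, `year`, `score` columns.
#' @param years optional years to evaluate; defaults to all years present.
#' @return Named numeric vector of standardized values, one per year
#'   (NA for years with no record).
#' @export
standardize_fredon <- function(records, years = NULL) {
  if (nrow(records) == 0L) stop("no records")
  series_max <- max(records$score)
  if (series_max == 0) stop("all scores zero: standardization undefined")
  if (is.null(years)) years <- sort(unique(records$year))
  vapply(years, function(y) {
    sc <- records$score[records$year == y]
    if (length(sc) == 0L) return(NA_real_)
    stats::median(sc) / series_max
  }, numeric(1)) -> v
  names(v) <- years
  v
}

#' Grassland prey-resource index
#'
#' Combines the two grassland vole indices on a common [0, 1] scale. Over
#' the transect era the index at each survey date is
#' S(t) = p_Aa(t) + p_Ma(t)/4, normalized by the series maximum of S; the
#' quarter weight reflects the roughly four-fold body-mass difference
#' between the two species. Before the transect era the standardized
#' communal score is passed through unchanged. The two segments are
#' concatenated in time order without rescaling: the peak amplitude is
#' only index-scale, but the phase timing is preserved.
#'
#' @param transects_aa,transects_ma data frames with `time` (decimal years
#'   or `Date`) and `proportion`, on the same survey dates.
#' @param fredon optional data frame with `time` and `value` (already in
#'   [0, 1]) covering the pre-transect era.
#' @param ma_weight weight of the second species (default 1/4, the
#'   body-mass ratio).
#' @return Object of class `prey_index`: data frame with time, value,
#'   source (`transect` or `fredon`), times strictly increasing.
#' @export
prey_resource_index <- function(transects_aa, transects_ma, fredon = NULL,
                                ma_weight = 0.25) {
  to_time <- function(t) if (inherits(t, "Date")) decimal_year(t, as.Date("1970-01-01")) else as.numeric(t)
  t_aa <- to_time(transects_aa$time)
  t_ma <- to_time(transects_ma$time)
  if (length(t_aa) != length(t_ma) || any(abs(sort(t_aa) - sort(t_ma)) > 1e-9))
    stop("the two transect series must share survey dates")
  o <- order(t_aa)
  s <- transects_aa$proportion[o] + ma_weight * transects_ma$proportion[order(t_ma)]
  if (max(s) <= 0) stop("all-zero transect series: max normalization undefined")
  tr <- data.frame(time = t_aa[o], value = s / max(s), source = "transect",
                   stringsAsFactors = FALSE)
  if (!is.null(fredon) && nrow(fredon) > 0L) {
    ft <- to_time(fredon$time)
    keep <- ft < min(tr$time) & !is.na(fredon$value)
    fr <- data.frame(time = ft[keep], value = fredon$value[keep],
                     source = "fredon", stringsAsFactors = FALSE)
    tr <- rbind(fr[order(fr$time), ], tr)
  }
  if (any(tr$value < 0 | tr$value > 1)) stop("index values outside [0, 1]")
  if (any(diff(tr$time) <= 0)) stop("times must be strictly increasing")
  rownames(tr) <- NULL
  class(tr) <- c("prey_index", "data.frame")
  tr
}

#' Interpolate a prey index at arbitrary dates
#'
#' Linear interpolation between the two bracketing index estimates; exact
#' at the knots; no extrapolation outside the observed span.
#'
#' @param series a `prey_index` (or any data frame with `time`, `value`).
#' @param time numeric (decimal years) query times.
#' @return Numeric vector of interpolated values in [0, 1].
#' @export
interpolate_index <- function(series, time) {
  time <- as.numeric(time)
  if (any(time < min(series$time) | time > max(series$time)))
    stop("query time outside the index span: no extrapolation")
  stats::approx(series$time, series$value, xout = time, method = "linear",
                ties = "ordered")$y
}

#' @export
print.prey_index <- function(x, ...) {
  cat("grassland prey-resource index:", nrow(x), "points,",
      sum(x$source == "fredon"), "from communal scores;",
      sprintf("span %.2f-%.2f\n", min(x$time), max(x$time)))
  invisible(x)
}

#' @export
plot.prey_index <- function(x, ...) {
  graphics::plot(x$time, x$value, type = "n", xlab = "time (years)",
                 ylab = "prey index", ylim = c(0, 1), ...)
  graphics::lines(x$time, x$value, col = "grey50")
  graphics::points(x$time, x$value,
                   pch = ifelse(x$source == "fredon", 1, 19))
  invisible(x)
}
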