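# Monte-Carlo habitat randomization: does a species sit closer to (or
# farther from) forests or buildings than uniformly placed points in the
# observed strip along the itinerary?

#' Uniform random positions in the observed strip
#'
#' Rejection-sampled uniform positions within the intersection of (a) the
#' buffer of half-width `w` around the itinerary and (b) the farmland
#' mask. A guard aborts when the acceptance rate collapses (degenerate
#' mask).
#'
#' @param n number of positions.
#' @param landscape a [landscape] object.
#' @param w strip half-width, meters (the species' truncation distance).
#' @param seed RNG seed.
#' @param min_acceptance abort threshold on the rejection acceptance rate.
#' @return n x 2 coordinate matrix.
#' @export
sample_strip <- function(n, landscape, w, seed = NULL,
                         min_acceptance = 1e-3) {
  stopifnot(inherits(landscape, "landscape"), w > 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  box <- bbox_of(landscape$itinerary, pad = w)
  out <- matrix(NA_real_, 0L, 2L)
  tried <- 0L
  batch <- max(1000L, 4L * n)
  while (nrow(out) < n) {
    pts <- cbind(stats::runif(batch, box["xmin"], box["xmax"]),
                 stats::runif(batch, box["ymin"], box["ymax"]))
    ok <- perpendicular_distance(pts, landscape) <= w
    if (any(ok)) {
      inside <- rep(FALSE, sum(ok))
      cand <- pts[ok, , drop = FALSE]
      for (ring in landscape$farmland)
        inside <- inside | points_in_polygon(cand, ring)
      out <- rbind(out, cand[inside, , drop = FALSE])
    }
    tried <- tried + batch
    if (tried >= 10000L && nrow(out) / tried < min_acceptance)
      stop("strip/farmland intersection acceptance rate below ",
           min_acceptance, ": degenerate mask")
  }
  out[seq_len(n), , drop = FALSE]
}

#' Habitat randomization test
#'
#' Compares the mean distance from the observed positions of a species to
#' the nearest habitat polygon with the distribution of that mean over
#' `n_sim` simulations of the same number of uniform random positions in
#' the observed strip. Two-tailed p with the add-one correction:
#' p = min(1, 2 min(P(null <= obs), P(null >= obs))).
#'
#' @param observations n x 2 coordinate matrix of observed positions.
#' @param landscape a [landscape] object.
#' @param habitat `"forest"` or `"building"`.
#' @param w strip half-width, meters.
#' @param n_sim number of null simulations (>= 99).
#' @param seed RNG seed (recorded in the output).
#' @return Object of class `habitat_test`: n_obs, mean_observed,
#'   null_means, p_value, direction (`closer`/`farther`), habitat, w, seed.
#' @export
habitat_randomization_test <- function(observations, landscape,
                                       habitat = c("forest", "building"),
                                       w, n_sim = 1000, seed = NULL) {
  habitat <- match.arg(habitat)
  observations <- as_coords(observations)
  n_obs <- nrow(observations)
  if (n_obs < 1L) stop("need at least one observation")
  if (n_sim < 99) stop("n_sim must be >= 99")
  polys <- if (habitat == "forest") landscape$forest else landscape$buildings
  if (length(polys) == 0L) stop("no ", habitat, " polygons in landscape")
  if (!is.null(seed)) set.seed(seed)

  mean_observed <- mean(nearest_habitat_distance(observations, polys))
  # one pooled draw, reshaped: cheaper than n_sim rejection runs
  pool <- sample_strip(n_sim * n_obs, landscape, w)
  d <- nearest_habitat_distance(pool, polys)
  null_means <- colMeans(matrix(d, nrow = n_obs))

  p_low <- (1 + sum(null_means <= mean_observed)) / (n_sim + 1)
  p_high <- (1 + sum(null_means >= mean_observed)) / (n_sim + 1)
  structure(list(n_obs = n_obs, mean_observed = mean_observed,
                 null_means = null_means,
                 p_value = min(1, 2 * min(p_low, p_high)),
                 direction = if (mean_observed < mean(null_means)) "closer"
                             else "farther",
                 habitat = habitat, w = w, n_sim = n_sim, seed = seed),
            class = "habitat_test")
}

#' @export
print.habitat_test <- function(x, ...) {
  cat(sprintf("habitat randomization: %d obs vs %s, mean %.0f m (null %.0f m), %s, p = %.4g\n",
              x$n_obs, x$habitat, x$mean_observed, mean(x$null_means),
              x$direction, x$p_value))
  invisible(x)
}
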