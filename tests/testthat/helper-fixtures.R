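# Shared fixture builders; everything is generated in code.

square_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# A minimal landscape: straight 10 km west-east track through a grassland
# block, one forest square north of the track, one building south of it.
# The farmland mask is clipped to the track's x-extent so the observed
# strip is an exact rectangle (no endcap lobes).
toy_landscape <- function() {
  landscape(
    itinerary = cbind(c(1000, 11000), c(4000, 4000)),
    forest = list(square_ring(3000, 5000, 5000, 7000)),
    buildings = list(square_ring(8000, 2500, 8200, 2700)),
    farmland = list(square_ring(1000, 0, 11000, 8000)))
}

# Perpendicular distances drawn from a hazard-rate detection process on
# [0, w] by rejection (uniform availability, detection g).
rhazard <- function(n, sigma, b, w) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::runif(4 * n, 0, w)
    out <- c(out, x[stats::runif(4 * n) < hazard_rate_g(x, sigma, b)])
  }
  out[seq_len(n)]
}

# Session/count CSV text for the reader tests.
counts_csv <- function(path, rows) {
  writeLines(c("session_id,date,period,replicate,species_id,count,itinerary_length",
               rows), path)
  path
}

# A small numerical-response design with known coefficients.
toy_design <- function(n = 80, a0 = -1, a2 = 0, a3 = c(0, 0.2, 0.6, 0.1),
                       a4 = 1.5, two_lengths = TRUE, seed = 1) {
  set.seed(seed)
  len <- if (two_lengths) rep(c(18.6, 19.6), each = n / 2) else rep(19.6, n)
  des <- data.frame(
    n = 0L, log_length = log(len),
    time_index = seq(0, 19, length.out = n),
    season = factor(rep(c("spring", "summer", "autumn", "winter"), n / 4),
                    levels = c("spring", "summer", "autumn", "winter")),
    prey_index = stats::runif(n))
  eta <- a0 + 1 * des$log_length + a2 * des$time_index +
    a3[as.integer(des$season)] + a4 * des$prey_index
  des$n <- stats::rpois(n, exp(eta))
  attr(des, "truth") <- c(a0 = a0, a1 = 1, a2 = a2, a4 = a4)
  des
}
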