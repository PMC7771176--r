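# Numerical response of predators to prey abundance: Poisson count
# regression of per-session observation numbers on effort, time, season
# and the grassland prey index, with inference by permutation (irregular,
# autocorrelated series make the nominal GLM degrees of freedom
# untrustworthy), plus half-series mean comparisons and paired-series
# correlation tests.

#' Assemble a numerical-response design
#'
#' One row per session: the response count (the session maximum over
#' replicates, i.e. the count behind the KAI), log itinerary length, time
#' index, season, and the prey index interpolated to the session date.
#'
#' @param sessions session table from [read_sessions()].
#' @param counts count events from [read_sessions()].
#' @param species_id species to model.
#' @param prey prey-index series ([prey_resource_index()]); its `time`
#'   axis must be on the same scale as `sessions$time_index`.
#' @return Data frame with n, log_length, time_index, season, prey_index.
#' @export
response_design <- function(sessions, counts, species_id, prey) {
  kai <- compute_kai(sessions, counts, species = species_id)
  m <- match(sessions$session_id, kai$session_id)
  data.frame(session_id = sessions$session_id,
             n = kai$max_count[m],
             log_length = log(sessions$itinerary_length),
             time_index = sessions$time_index,
             season = factor(as.character(sessions$season),
                             levels = c("spring", "summer", "autumn", "winter")),
             prey_index = interpolate_index(prey, sessions$time_index),
             stringsAsFactors = FALSE)
}

design_matrix <- function(design, include_time = TRUE, drop_season = FALSE) {
  design$season <- droplevels(factor(design$season,
                                     levels = c("spring", "summer", "autumn", "winter")))
  # constant covariate columns are absorbed into the intercept
  varies <- function(v) stats::sd(v) > 0
  terms <- c(if (varies(design$log_length)) "log_length",
             if (include_time && varies(design$time_index)) "time_index",
             if (!drop_season && nlevels(design$season) > 1L) "season",
             if (varies(design$prey_index)) "prey_index")
  if (length(terms) == 0L) return(stats::model.matrix(~1, data = design))
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(f, data = design)
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit the Poisson numerical-response model
#'
#' Log-link Poisson GLM of per-session counts on log itinerary length,
#' optionally a linear time trend, season and the prey index. Fitting is
#' maximum likelihood via iteratively reweighted least squares. The
#' reported r-squared is the squared Pearson correlation between observed
#' and fitted counts.
#'
#' @param design a [response_design()] data frame (or equivalent).
#' @param include_time keep the linear time trend (drop it when it is not
#'   statistically significant).
#' @return Object of class `nr_fit` with coefficients, standard errors,
#'   log-likelihood, fitted means, deviance residuals and r_squared.
#' @export
fit_poisson <- function(design, include_time = TRUE) {
  req <- c("n", "log_length", "season", "prey_index")
  miss <- setdiff(req, names(design))
  if (length(miss)) stop("design missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(design[intersect(names(design),
                             c(req, if (include_time) "time_index"))]))
    stop("missing covariate values")
  if (any(design$prey_index < 0 | design$prey_index > 1))
    stop("prey_index must lie in [0, 1]")
  X <- design_matrix(design, include_time)
  check_full_rank(X)
  y <- design$n
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  mu <- fit$fitted.values
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(vc))
  names(se) <- colnames(X)
  r2 <- if (stats::sd(y) > 0 && stats::sd(mu) > 0)
    stats::cor(y, mu)^2 else NA_real_
  structure(list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
                 se = se, vcov = vc,
                 loglik = sum(stats::dpois(y, mu, log = TRUE)),
                 deviance = fit$deviance,
                 fitted = mu,
                 residuals = sign(y - mu) *
                   sqrt(pmax(0, stats::poisson()$dev.resids(y, mu, 1))),
                 r_squared = r2, y = y, X = X,
                 include_time = include_time, design = design),
            class = "nr_fit")
}

#' @export
coef.nr_fit <- function(object, ...) object$coefficients

#' @export
logLik.nr_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = length(object$y), class = "logLik")
}

#' @export
residuals.nr_fit <- function(object, ...) object$residuals

#' @export
fitted.nr_fit <- function(object, ...) object$fitted

#' @export
predict.nr_fit <- function(object, newdata = NULL, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- drop(object$X %*% object$coefficients)
  } else {
    X <- design_matrix(newdata, object$include_time)
    eta <- drop(X %*% object$coefficients[colnames(X)])
  }
  if (type == "response") exp(eta) else eta
}

#' @export
simulate.nr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, stats::rpois(length(object$fitted), object$fitted),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
print.nr_fit <- function(x, ...) {
  cat("Poisson numerical-response model (log link),",
      length(x$y), "sessions\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  cat(sprintf("logLik %.2f, r-squared %.3f\n", x$loglik, x$r_squared))
  invisible(x)
}

#' @export
summary.nr_fit <- function(object, ...) print(object)

permute_rows <- function(n, block_size = NULL) {
  if (is.null(block_size) || block_size <= 1L) return(sample.int(n))
  if (block_size > n) stop("block_size larger than the series")
  blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
  unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
}

#' Permutation p-value for a model coefficient
#'
#' Permutes the target covariate's values across sessions (optionally in
#' contiguous blocks, a sensitivity handle for autocorrelation), refits,
#' and returns p = (1 + #(|a*| >= |a_obs|)) / (n_perm + 1). For the
#' multi-level season term the statistic is the likelihood-ratio deviance
#' reduction rather than a single coefficient.
#'
#' @param design a [response_design()] data frame.
#' @param covariate one of `log_length`, `time_index`, `season`,
#'   `prey_index`.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @param block_size optional contiguous block length (1 = plain
#'   permutation).
#' @param include_time as in [fit_poisson()].
#' @return The permutation p-value, in (0, 1].
#' @export
permute_coefficient <- function(design, covariate, n_perm = 999, seed = NULL,
                                block_size = NULL, include_time = TRUE) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!covariate %in% c("log_length", "time_index", "season", "prey_index"))
    stop("unknown covariate: ", covariate)
  if (covariate == "time_index" && !include_time)
    stop("time_index not in the model")
  if (!is.null(seed)) set.seed(seed)

  X <- design_matrix(design, include_time)
  check_full_rank(X)
  y <- design$n
  is_factor <- covariate == "season"
  cols <- if (is_factor) grep("^season", colnames(X)) else
    which(colnames(X) == covariate)
  if (length(cols) == 0L) stop("covariate absent from the design matrix")

  dev_of <- function(Xp) {
    f <- suppressWarnings(stats::glm.fit(Xp, y, family = stats::poisson()))
    f$deviance
  }
  coef_of <- function(Xp) {
    f <- suppressWarnings(stats::glm.fit(Xp, y, family = stats::poisson()))
    f$coefficients[cols]
  }

  if (is_factor) {
    dev_reduced <- dev_of(X[, -cols, drop = FALSE])
    obs <- dev_reduced - dev_of(X)
  } else {
    obs <- abs(coef_of(X))
  }

  n <- nrow(X)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- permute_rows(n, block_size)
    Xp <- X
    Xp[, cols] <- X[idx, cols]
    stat <- if (is_factor) dev_reduced - dev_of(Xp) else abs(coef_of(Xp))
    if (!is.na(stat) && stat >= obs - 1e-12) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_perm + 1)
}

#' One-tailed permutation test comparing series halves
#'
#' Splits a session-ordered series at its temporal midpoint and tests
#' whether the mean of the second half exceeds (or falls below) the mean
#' of the first, by permuting session labels.
#'
#' @param values numeric series in time order (>= 4 values).
#' @param direction `greater` tests mean(second) > mean(first).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return One-tailed permutation p-value.
#' @export
half_series_test <- function(values, direction = c("greater", "less"),
                             n_perm = 999, seed = NULL) {
  direction <- match.arg(direction)
  n <- length(values)
  if (n < 4L) stop("need at least 4 sessions")
  if (!is.null(seed)) set.seed(seed)
  cut <- floor(n / 2)
  stat <- function(v) mean(v[(cut + 1L):n]) - mean(v[1:cut])
  obs <- stat(values)
  perm <- replicate(n_perm, stat(sample(values)))
  if (direction == "greater") (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  else (1 + sum(perm <= obs + 1e-12)) / (n_perm + 1)
}

#' Permutation test of a Pearson correlation between paired series
#'
#' @param series_a,series_b aligned numeric series (>= 5 points).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List with `r` (Pearson correlation) and `p` (two-tailed
#'   permutation p-value on |r|).
#' @export
paired_correlation_test <- function(series_a, series_b, n_perm = 999,
                                    seed = NULL) {
  if (length(series_a) != length(series_b)) stop("series lengths differ")
  if (length(series_a) < 5L) stop("need at least 5 points")
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0)
    stop("zero variance in a series")
  if (!is.null(seed)) set.seed(seed)
  r <- stats::cor(series_a, series_b)
  perm <- replicate(n_perm, abs(stats::cor(series_a, sample(series_b))))
  list(r = r, p = (1 + sum(perm >= abs(r) - 1e-12)) / (n_perm + 1))
}
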