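# Validation statistics for the field model: empirical semivariograms with a
# spherical-model fit, and candidate-distribution scoring by histogram SSE
# and AIC.

#' Empirical semivariogram
#'
#' Computes the classical (Matheron) semivariance over horizontal lag bins:
#' `gamma(h) = mean over pairs in the bin of (z_i - z_j)^2 / 2`.  Lags are
#' horizontal-only distances — vertical structure is governed by separate,
#' much shorter de-correlation lengths, and missions are short enough that
#' time is ignored.  For large data sets a random subsample keeps the pair
#' count manageable.
#'
#' @param values Field values on the log scale (the scale the model works
#'   on), one per position.
#' @param x,y Horizontal positions, meters.
#' @param breaks Lag bin edges, meters; default 100 m bins to 2000 m.
#' @param subsample Fraction of points to use (default 1 = all).
#' @param seed Seed for the subsample draw.
#' @return An object of class `semivariogram`: data.frame with `lag` (bin
#'   center), `gamma` (`NA` for empty bins, reported rather than fabricated),
#'   and `n_pairs`.
#' @export
empirical_variogram <- function(values, x, y, breaks = seq(0, 2000, by = 100),
                                subsample = 1, seed = 1) {
  stopifnot(length(values) == length(x), length(x) == length(y))
  if (length(values) < 2) stop("need at least two points")
  if (subsample < 1) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    keep <- sample(length(values), max(2, round(subsample * length(values))))
    values <- values[keep]; x <- x[keep]; y <- y[keep]
  }
  d <- as.numeric(stats::dist(cbind(x, y)))
  dv <- as.numeric(stats::dist(values))^2 / 2
  bin <- cut(d, breaks, right = FALSE)
  gamma <- tapply(dv, bin, mean)
  n_pairs <- tapply(dv, bin, length)
  n_pairs[is.na(n_pairs)] <- 0
  out <- data.frame(lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    gamma = as.numeric(gamma),
                    n_pairs = as.integer(n_pairs))
  class(out) <- c("semivariogram", "data.frame")
  out
}

#' Spherical variogram model
#'
#' `gamma(h) = nugget + sill * (1.5 h/a - 0.5 (h/a)^3)` for `h < a`, and
#' `nugget + sill` beyond the range `a`.  `sill` is the partial sill.
#'
#' @param h Lag distances, meters.
#' @param nugget,sill,range Model parameters (all `>= 0`).
#' @return Model semivariance at `h`.
#' @export
spherical_model <- function(h, nugget, sill, range) {
  hr <- pmin(h / range, 1)
  nugget + sill * (1.5 * hr - 0.5 * hr^3)
}

#' Fit a spherical model to an empirical semivariogram
#'
#' Weighted least squares with per-bin pair counts as weights, over the
#' non-empty bins.  Parameters are optimized on a log scale to enforce
#' positivity.  A fit whose partial sill is negligible against the nugget is
#' flagged: the range is unidentifiable for a pure-nugget field.
#'
#' @param vg A `semivariogram` (needs >= 3 non-empty bins).
#' @return A list of class `spherical_fit`: `nugget`, `sill` (partial),
#'   `range` (meters), `converged`, `range_identifiable`, `sse` (weighted).
#' @export
fit_spherical <- function(vg) {
  ok <- !is.na(vg$gamma) & vg$n_pairs > 0
  if (sum(ok) < 3) stop("need at least 3 non-empty bins")
  h <- vg$lag[ok]; g <- vg$gamma[ok]; w <- vg$n_pairs[ok]
  obj <- function(p) {
    m <- spherical_model(h, exp(p[1]), exp(p[2]), exp(p[3]))
    sum(w * (g - m)^2)
  }
  gmax <- max(g); hmax <- max(h)
  starts <- list(c(g[1] + 1e-6 * gmax, max(gmax - g[1], 1e-6 * gmax), hmax / 2),
                 c(0.1 * gmax, gmax, hmax / 4),
                 c(0.5 * gmax, 0.5 * gmax, hmax))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(stats::optim(log(pmax(s, 1e-12)), obj, method = "Nelder-Mead",
                                 control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("spherical fit failed to converge; inspect the variogram bins")
  polish <- tryCatch(stats::optim(best$par, obj, method = "BFGS",
                                  control = list(maxit = 500, reltol = 1e-14)),
                     error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  p <- exp(best$par)
  structure(list(nugget = p[1], sill = p[2], range = p[3],
                 converged = best$convergence == 0,
                 range_identifiable = p[2] > 0.05 * (p[1] + p[2]),
                 sse = best$value),
            class = "spherical_fit")
}

#' @export
print.spherical_fit <- function(x, ...) {
  cat(sprintf("spherical variogram fit: nugget %.4g, partial sill %.4g, range %.1f m%s\n",
              x$nugget, x$sill, x$range,
              if (!x$range_identifiable) " (range unidentifiable: pure nugget)" else ""))
  invisible(x)
}

# ---- candidate distribution fitting ----------------------------------------

# Burr type XII density / log-likelihood: f(x) = (c k / s) (x/s)^(c-1) /
# (1 + (x/s)^c)^(k+1), x > 0.  No installed package provides it.
dburr <- function(x, shape1, shape2, scale, log = FALSE) {
  c1 <- shape1; k1 <- shape2
  lx <- log(x / scale)
  ld <- log(c1) + log(k1) - log(scale) + (c1 - 1) * lx -
        (k1 + 1) * log1p(exp(c1 * lx))
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

pburr <- function(q, shape1, shape2, scale) {
  p <- 1 - (1 + (pmax(q, 0) / scale)^shape1)^(-shape2)
  p[q <= 0] <- 0
  p
}

fit_one_dist <- function(values, dist) {
  n <- length(values)
  switch(dist,
    "log-normal" = {
      lv <- log(values)
      mu <- mean(lv); sd <- stats::sd(lv) * sqrt((n - 1) / n)
      ll <- sum(stats::dnorm(lv, mu, sd, log = TRUE) - lv)
      list(params = c(meanlog = mu, sdlog = sd), loglik = ll, n_params = 2,
           density = function(x) stats::dlnorm(x, mu, sd),
           cdf = function(x) stats::plnorm(x, mu, sd))
    },
    "normal" = {
      mu <- mean(values); sd <- stats::sd(values) * sqrt((n - 1) / n)
      list(params = c(mean = mu, sd = sd),
           loglik = sum(stats::dnorm(values, mu, sd, log = TRUE)), n_params = 2,
           density = function(x) stats::dnorm(x, mu, sd),
           cdf = function(x) stats::pnorm(x, mu, sd))
    },
    "gamma" = {
      fit <- suppressWarnings(MASS::fitdistr(values, "gamma"))
      sh <- fit$estimate[["shape"]]; ra <- fit$estimate[["rate"]]
      list(params = c(shape = sh, rate = ra), loglik = as.numeric(fit$loglik),
           n_params = 2, density = function(x) stats::dgamma(x, sh, ra),
           cdf = function(x) stats::pgamma(x, sh, ra))
    },
    "beta" = {
      # the beta support is (0, 1): fit on values rescaled by the data
      # maximum (with a small pad) and carry the Jacobian into the
      # likelihood so AIC stays comparable across candidates
      sc <- max(values) * 1.001
      u <- values / sc
      m <- mean(u); v <- stats::var(u)
      a0 <- max(m * (m * (1 - m) / v - 1), 0.1)
      b0 <- max((1 - m) * (m * (1 - m) / v - 1), 0.1)
      nll <- function(p) -sum(stats::dbeta(u, exp(p[1]), exp(p[2]), log = TRUE))
      fit <- suppressWarnings(stats::optim(log(c(a0, b0)), nll))
      a <- exp(fit$par[1]); b <- exp(fit$par[2])
      list(params = c(shape1 = a, shape2 = b, scale = sc),
           loglik = -fit$value - n * log(sc), n_params = 2,
           density = function(x) stats::dbeta(x / sc, a, b) / sc,
           cdf = function(x) stats::pbeta(x / sc, a, b))
    },
    "Burr" = {
      m <- stats::median(values)
      nll <- function(p) -sum(dburr(values, exp(p[1]), exp(p[2]), exp(p[3]), log = TRUE))
      fit <- suppressWarnings(stats::optim(log(c(1.5, 1.5, m)), nll,
                                           control = list(maxit = 2000)))
      p <- exp(fit$par)
      list(params = c(shape1 = p[1], shape2 = p[2], scale = p[3]),
           loglik = -fit$value, n_params = 3,
           density = function(x) dburr(x, p[1], p[2], p[3]),
           cdf = function(x) pburr(x, p[1], p[2], p[3]))
    },
    stop("unknown candidate distribution: ", dist))
}

#' Score candidate distributions against a sample
#'
#' Fits each candidate by maximum likelihood, then scores it by (a) the sum
#' of squared errors between its density and a density-normalized histogram
#' of the data (50 equal-width bins over the data range; the fitted density
#' is bin-averaged through its CDF, so sharply peaked densities are compared
#' without midpoint discretization error) and (b) the Akaike information
#' criterion
#' `AIC = 2 k - 2 log L`.  The report is sorted by SSE.  The beta candidate
#' is fitted on values rescaled into (0, 1) by the sample maximum, with the
#' rescaling Jacobian folded into its likelihood.  A candidate whose fit
#' fails is flagged and the others are still reported.
#'
#' @param values Positive sample values (`n >= 30`).
#' @param candidates Character vector of candidate names, a subset of
#'   `c("log-normal", "gamma", "beta", "Burr", "normal")`.
#' @param n_bins Histogram bin count for the SSE score.
#' @return A data.frame of class `distfit_report`: `distribution`, `sse`,
#'   `aic`, `loglik`, `n_params`, `ok`, sorted by SSE, with the fitted
#'   parameter sets in `attr(, "fits")`.
#' @export
best_fit <- function(values,
                     candidates = c("log-normal", "gamma", "beta", "Burr", "normal"),
                     n_bins = 50) {
  values <- as.numeric(values)
  if (length(values) < 30) stop("need at least 30 values")
  if (any(values <= 0)) stop("values must be positive")
  brk <- seq(min(values), max(values), length.out = n_bins + 1)
  hist <- graphics::hist(values, breaks = brk, plot = FALSE)
  dens <- hist$density
  fits <- list()
  rows <- lapply(candidates, function(d) {
    f <- tryCatch(fit_one_dist(values, d), error = function(e) NULL)
    if (is.null(f))
      return(data.frame(distribution = d, sse = NA_real_, aic = NA_real_,
                        loglik = NA_real_, n_params = NA_integer_, ok = FALSE))
    fits[[d]] <<- f$params
    model_dens <- diff(f$cdf(brk)) / diff(brk)
    sse <- sum((model_dens - dens)^2)
    data.frame(distribution = d, sse = sse,
               aic = 2 * f$n_params - 2 * f$loglik,
               loglik = f$loglik, n_params = f$n_params, ok = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(!out$ok, out$sse), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("distfit_report", "data.frame")
  out
}
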