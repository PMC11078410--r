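# Spatiotemporal log-Gaussian-process field model.
#
# Fluorescence is modelled as log-normal: a GP is fitted to centred
# log-measurements over (x, y, z, tau) with an anisotropic squared-exponential
# kernel, and predictions are back-transformed with the log-normal moment
# formulas, which makes predictive variance depend on the predictive mean.

#' Hyperparameters of the log-Gaussian-process model
#'
#' @param M De-correlation lengths, numeric length 4:
#'   `(M_x, M_y, M_z)` in meters and `M_tau` in seconds.  At a lag of one
#'   de-correlation length along an axis the kernel has fallen to
#'   `sigma_c^2 * exp(-1/2)`.
#' @param sigma_c Process scale of the centred log-values (unitless, log
#'   space).  Interpreted as a standard deviation by default.
#' @param sigma_n Nugget scale (unitless, log space): short-range process
#'   plus sensor noise.  Interpreted as a standard deviation by default.
#' @param as_variance If `TRUE`, `sigma_c` and `sigma_n` are taken to be
#'   variances rather than standard deviations.  The default follows the
#'   "nugget standard deviation" reading; the switch covers configurations
#'   written with variances.
#' @param log_floor Strictly positive floor applied to measurements before
#'   the log transform (real fluorometers emit zeros); micrograms/L.
#' @return An object of class `lgp_hyperparams` with elements `M`,
#'   `sigma_c2`, `sigma_n2` (variances) and `log_floor`.
#' @examples
#' hp <- lgp_hyperparams(M = c(600, 600, 3, 10000), sigma_c = 1.6, sigma_n = 0.7)
#' @export
lgp_hyperparams <- function(M, sigma_c, sigma_n, as_variance = FALSE,
                            log_floor = 0.01) {
  M <- as.numeric(M)
  stopifnot(length(M) == 4)
  if (any(M <= 0) || sigma_c <= 0 || sigma_n < 0)
    stop("de-correlation lengths and sigma_c must be positive; sigma_n >= 0")
  structure(
    list(M = M,
         sigma_c2 = if (as_variance) sigma_c else sigma_c^2,
         sigma_n2 = if (as_variance) sigma_n else sigma_n^2,
         log_floor = log_floor),
    class = "lgp_hyperparams")
}

#' Center log-transformed measurements
#'
#' Measurements become unitless under the logarithm; the GP is fitted to
#' `z = ln(y) - m_GP` where `m_GP = mean(ln y)`.
#'
#' @param y Positive measurement values.  Values below `floor` are clipped
#'   up to it before the log (zeros are routine sensor output).
#' @param floor Clipping floor, same units as `y`.
#' @return A list with `z` (centred log values, mean exactly 0) and `m_GP`.
#' @export
log_transform <- function(y, floor = 0.01) {
  if (any(!is.finite(y) | y < 0))
    stop("measurements must be non-negative and finite")
  y <- pmax(y, floor)
  if (any(y <= 0))
    stop("measurements must be positive after clipping")
  ly <- log(y)
  m <- mean(ly)
  list(z = ly - m, m_GP = m)
}

#' Anisotropic squared-exponential kernel
#'
#' `k(s, s') = sigma_c^2 * exp(-1/2 * sum_d ((s_d - s'_d) / M_d)^2)` over the
#' four dimensions (x, y, z, tau).  Each lag is divided by its de-correlation
#' length, so the covariance falls to `sigma_c^2 * exp(-1/2)` at one length.
#'
#' @param s,s_prime Numeric 4-vectors `(x, y, z, tau)`, or matrices with 4
#'   columns (rows are locations; recycled pairwise row-by-row).
#' @param hp An `lgp_hyperparams`.
#' @return Covariance value(s) in log space.
#' @export
lgp_kernel <- function(s, s_prime, hp) {
  s <- matrix(as.numeric(s), ncol = 4)
  sp <- matrix(as.numeric(s_prime), ncol = 4)
  d2 <- sweep(s, 2, hp$M, "/") - sweep(sp, 2, hp$M, "/")
  hp$sigma_c2 * exp(-0.5 * rowSums(d2^2))
}

# Full cross-covariance matrix between two location sets (n x 4 matrices).
kernel_matrix <- function(A, B, hp) {
  As <- sweep(A, 2, hp$M, "/")
  Bs <- sweep(B, 2, hp$M, "/")
  d2 <- outer(rowSums(As^2), rep(1, nrow(Bs))) +
        outer(rep(1, nrow(As)), rowSums(Bs^2)) -
        2 * tcrossprod(As, Bs)
  d2[d2 < 0] <- 0
  hp$sigma_c2 * exp(-0.5 * d2)
}

#' Build a GP training set from positive measurements
#'
#' Duplicate (location, time) rows are merged by averaging their values
#' before any solve, which protects the conditioning of the covariance
#' matrix.
#'
#' @param S Numeric matrix with 4 columns `(x, y, z, tau)` or a data.frame
#'   with columns `x`, `y`, `z`, `time`.
#' @param y Positive measurement values, one per row of `S`.
#' @param hp An `lgp_hyperparams` (supplies the log floor).
#' @return An object of class `lgp_training` with elements `S`, `y`, `z`
#'   (centred log values) and `m_GP`.
#' @export
lgp_training <- function(S, y, hp = lgp_hyperparams(c(600, 600, 3, 10000), 1.6, 0.7)) {
  if (is.data.frame(S)) S <- as.matrix(S[, c("x", "y", "z", "time")])
  S <- matrix(as.numeric(S), ncol = 4)
  stopifnot(nrow(S) == length(y))
  key <- apply(S, 1, paste, collapse = "\r")
  if (anyDuplicated(key)) {
    y <- as.numeric(tapply(y, key, mean)[unique(key)])
    S <- S[!duplicated(key), , drop = FALSE]
  }
  lt <- log_transform(y, floor = hp$log_floor)
  structure(list(S = S, y = y, z = lt$z, m_GP = lt$m_GP), class = "lgp_training")
}

#' GP prediction with log-normal back-transformation
#'
#' Computes the predictive mean and variance of the latent log field at the
#' query locations, evaluated at the common prediction time `tau_now`, and
#' back-transforms them to the fluorescence scale.  Because time enters every
#' kernel evaluation, the full covariance system is rebuilt on every call
#' (full re-evaluation per iteration rather than incremental ingestion).
#'
#' The nugget variance is added to the training-covariance diagonal only;
#' the reported predictive variance is that of the latent field, excluding
#' the nugget.
#'
#' With an empty training set the prior is returned (`m_GP = 0`, variance
#' `sigma_c^2`) with a warning; in a mission this path is only reachable
#' before the pilot survey has produced data.
#'
#' @param train An `lgp_training` (or `NULL`/zero rows for the prior).
#' @param S_star Query locations: matrix with 3 columns `(x, y, z)` or a
#'   data.frame with columns `x`, `y`, `z`.
#' @param tau_now Prediction time, seconds since mission epoch.
#' @param hp An `lgp_hyperparams`.
#' @return A data.frame with one row per query:
#'   `f_mean`, `f_var` (log space, `f_mean` includes `m_GP`),
#'   `y_hat`, `sigma_y2` (fluorescence scale).
#' @export
gp_predict <- function(train, S_star, tau_now, hp) {
  if (is.data.frame(S_star)) S_star <- as.matrix(S_star[, c("x", "y", "z")])
  S_star <- matrix(as.numeric(S_star), ncol = 3)
  Q <- cbind(S_star, tau_now)
  if (is.null(train) || nrow(train$S) == 0) {
    warning("empty training set: returning the prior")
    f_mean <- rep(0, nrow(Q))
    f_var <- rep(hp$sigma_c2, nrow(Q))
  } else {
    K <- kernel_matrix(train$S, train$S, hp)
    diag(K) <- diag(K) + hp$sigma_n2
    L <- tryCatch(chol(K), error = function(e)
      stop("training covariance is not positive definite after the nugget; ",
           "check hyperparameters and duplicated points: ", conditionMessage(e)))
    Ks <- kernel_matrix(Q, train$S, hp)          # n_* x n
    alpha <- backsolve(L, backsolve(L, train$z, transpose = TRUE))
    f_mean <- as.numeric(Ks %*% alpha) + train$m_GP
    V <- backsolve(L, t(Ks), transpose = TRUE)   # n x n_*
    f_var <- hp$sigma_c2 - colSums(V^2)
    f_var <- pmin(pmax(f_var, 0), hp$sigma_c2)
  }
  mo <- lognormal_moments(f_mean, f_var)
  data.frame(f_mean = f_mean, f_var = f_var,
             y_hat = mo$y_hat, sigma_y2 = mo$sigma_y2)
}

#' Log-normal moments from log-space predictive moments
#'
#' `y_hat = exp(f + v/2)` and `sigma_y2 = y_hat^2 * (exp(v) - 1)`: the mean
#' and variance of a log-normal variable whose log has mean `f` and variance
#' `v`.  The fluorescence-scale variance therefore grows with the predicted
#' mean, unlike for a linear GP.
#'
#' @param f_mean Log-space mean(s), including the data mean `m_GP`.
#' @param f_var Log-space variance(s), `>= 0`.
#' @return A list with `y_hat` and `sigma_y2`.
#' @export
lognormal_moments <- function(f_mean, f_var) {
  if (any(f_var < 0)) stop("log-space variance must be non-negative")
  y_hat <- exp(f_mean + f_var / 2)
  list(y_hat = y_hat, sigma_y2 = y_hat^2 * (exp(f_var) - 1))
}

#' Export model predictions over the grid as a data.frame
#'
#' Evaluates the model at every grid-cell center, for plotting horizontal or
#' vertical slices of the predicted field and its uncertainty.
#'
#' @param train An `lgp_training`.
#' @param cfg A `volume_config`.
#' @param tau_now Prediction time, seconds.
#' @param hp An `lgp_hyperparams`.
#' @return A data.frame `cell`, `x`, `y`, `z`, `y_hat`, `sigma_y2`,
#'   `f_mean`, `f_var`.
#' @export
predict_grid <- function(train, cfg, tau_now, hp) {
  ctr <- cell_center(cfg)
  pr <- gp_predict(train, ctr[, c("x", "y", "z")], tau_now, hp)
  cbind(ctr, pr[, c("y_hat", "sigma_y2", "f_mean", "f_var")])
}
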