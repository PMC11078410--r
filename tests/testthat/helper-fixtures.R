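# Shared fixtures and independent oracles for the test suite.

# field-trial style volume: 1500 x 1500 x 50 m, 15 x 15 x 10 grid
trial_volume <- function() {
  volume_config(78 + 57.29 / 60, 11 + 56.85 / 60, -45,
                c(1500, 1500, 50), c(15, 15, 10))
}

# smallest legal grid (cell count floor is 256)
small_volume <- function() {
  volume_config(60, 5, 0, c(800, 800, 40), c(8, 8, 4))
}

trial_hyperparams <- function() {
  lgp_hyperparams(M = c(600, 600, 3, 10000), sigma_c = 1.6, sigma_n = 0.7)
}

# Independent direct-solve GP oracle: explicit loops, explicit matrix
# inverse, its own kernel formula.  Kept deliberately naive so it shares no
# code path with the package implementation.
gp_oracle <- function(S, y, Q, tau_now, hp) {
  k <- function(a, b) {
    d <- (a - b) / hp$M
    hp$sigma_c2 * exp(-0.5 * sum(d^2))
  }
  n <- nrow(S)
  m_GP <- mean(log(y))
  z <- log(y) - m_GP
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) K[i, j] <- k(S[i, ], S[j, ])
  K <- K + diag(hp$sigma_n2, n)
  Kinv <- solve(K)
  nq <- nrow(Q)
  f_mean <- numeric(nq); f_var <- numeric(nq)
  for (q in seq_len(nq)) {
    s_star <- c(Q[q, ], tau_now)
    ks <- numeric(n)
    for (i in seq_len(n)) ks[i] <- k(s_star, S[i, ])
    f_mean[q] <- sum(ks * (Kinv %*% z)) + m_GP
    f_var[q] <- hp$sigma_c2 - as.numeric(t(ks) %*% Kinv %*% ks)
  }
  list(f_mean = f_mean, f_var = f_var)
}

# random GP instance: n training points, m query points inside a small box
random_gp_instance <- function(n, m, hp) {
  S <- cbind(runif(n, 0, 1000), runif(n, 0, 1000), runif(n, 0, 40),
             runif(n, 0, 5000))
  y <- exp(rnorm(n, 0.5, 1))
  Q <- cbind(runif(m, 0, 1000), runif(m, 0, 1000), runif(m, 0, 40))
  list(S = S, y = y, Q = Q, tau_now = 6000)
}

# simulate a Gaussian field with known spherical covariance + nugget at
# random 2D points (dense Cholesky; used by the geostats recovery tests)
simulate_spherical_field <- function(n, nugget, sill, range, extent = 2000) {
  x <- runif(n, 0, extent); y <- runif(n, 0, extent)
  h <- as.matrix(stats::dist(cbind(x, y)))
  C <- ifelse(h < range,
              sill * (1 - 1.5 * h / range + 0.5 * (h / range)^3), 0)
  diag(C) <- sill + nugget
  L <- chol(C + diag(1e-8, n))
  list(x = x, y = y, values = as.numeric(t(L) %*% rnorm(n)))
}
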