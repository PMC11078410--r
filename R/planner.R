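# Pilot-survey path generation and the myopic adaptive waypoint planner.

#' Planner configuration
#'
#' @param n_theta Number of horizontal candidate directions, uniformly spaced
#'   around the vehicle (>= 3).
#' @param r Candidate radius in meters.  Default: one horizontal grid cell
#'   extent, so a planning step matches the segmentation resolution; pass a
#'   value to override.
#' @param z_d Vertical candidate step in meters; default one vertical grid
#'   cell extent.
#' @param k_mu Utility weight on the predicted fluorescence mean (unitless).
#' @param k_sigma Utility weight on the fluorescence-scale predictive
#'   variance (unitless).
#' @param k_l Vehicle-separation weight in meters: the characteristic
#'   standoff radius at which the per-vehicle penalty equals 1.
#' @param undulation Pilot-survey undulation: list/vector
#'   `(min_depth, max_depth, n_cycles)` where `n_cycles` is the number of
#'   full surface-to-depth-to-surface cycles per volume crossing.
#' @return An object of class `planner_config`.
#' @export
planner_config <- function(n_theta = 8, r = NULL, z_d = NULL,
                           k_mu = 1, k_sigma = 1, k_l = 300,
                           undulation = c(0, NA, 2)) {
  if (n_theta < 3) stop("n_theta must be >= 3")
  if (!is.null(r) && r <= 0) stop("candidate radius r must be positive")
  if (k_l < 0) stop("k_l must be non-negative")
  structure(
    list(n_theta = as.integer(n_theta), r = r, z_d = z_d,
         k_mu = k_mu, k_sigma = k_sigma, k_l = k_l,
         undulation = as.numeric(undulation)),
    class = "planner_config")
}

planner_radius <- function(plan, cfg) {
  if (!is.null(plan$r)) plan$r else cell_size(cfg)[1]
}

planner_zstep <- function(plan, cfg) {
  if (!is.null(plan$z_d)) plan$z_d else cell_size(cfg)[3]
}

#' Pilot-survey x-position for one vehicle
#'
#' The fleet crosses the volume in parallel transects that split the x-extent
#' evenly: `x_v = V_x * (2 * n_v + 1) / (2 * N_v)` with `n_v` 0-indexed.
#' Positions are symmetric about `V_x / 2`.
#'
#' @param n_v Vehicle number, 0-indexed.
#' @param N_v Fleet size.
#' @param V_x Volume x-extent, meters.
#' @return The transect x-coordinate in meters, strictly inside `(0, V_x)`.
#' @export
pilot_x <- function(n_v, N_v, V_x) {
  if (any(n_v < 0) || any(n_v >= N_v)) stop("require 0 <= n_v < N_v")
  V_x * (2 * n_v + 1) / (2 * N_v)
}

#' Pilot-survey waypoint list for one vehicle
#'
#' A pre-planned crossing from `y = 0` to `y = V_y` at the vehicle's transect
#' x-position, undulating between the configured minimum and maximum depths
#' (defaults: surface and volume bottom) as a sawtooth with the configured
#' number of cycles.
#'
#' @param cfg A `volume_config`.
#' @param plan A `planner_config`.
#' @param n_v,N_v Vehicle index (0-based) and fleet size.
#' @return A data.frame of waypoints `x`, `y`, `z`, ordered along the path;
#'   `y` is strictly increasing from 0 to `V_y`.
#' @export
pilot_path <- function(cfg, plan, n_v, N_v) {
  xv <- pilot_x(n_v, N_v, cfg$extent[1])
  und <- plan$undulation
  zmin <- und[1]
  zmax <- if (is.na(und[2])) cfg$extent[3] else und[2]
  ncyc <- max(1, round(und[3]))
  # one vertex per half cycle: surface, bottom, surface, ...
  nseg <- 2 * ncyc
  yy <- seq(0, cfg$extent[2], length.out = nseg + 1)
  zz <- rep(c(zmin, zmax), length.out = nseg + 1)
  data.frame(x = xv, y = yy, z = zz)
}

#' Candidate waypoints around the current position
#'
#' Generates up to `3 * n_theta` candidates on a horizontal circle of radius
#' `r` at three depth layers `z + (-z_d, 0, +z_d)`, then screens out any that
#' fall outside the operational volume.  Candidates are ordered by depth
#' layer (up, level, down), then by angle index; the order defines the
#' deterministic tie-break used by [choose_waypoint()].
#'
#' @param x_v Current vehicle position: numeric `(x, y, z)`.
#' @param plan A `planner_config`.
#' @param cfg A `volume_config`.
#' @return A data.frame `x`, `y`, `z` of surviving candidates.
#' @export
candidate_waypoints <- function(x_v, plan, cfg) {
  r <- planner_radius(plan, cfg)
  zd <- planner_zstep(plan, cfg)
  th <- 2 * pi * (seq_len(plan$n_theta) - 1) / plan$n_theta
  cand <- expand.grid(i = seq_len(plan$n_theta), dz = c(-zd, 0, zd))
  cand <- cand[order(cand$dz, cand$i), ]
  out <- data.frame(x = x_v[1] + r * cos(th[cand$i]),
                    y = x_v[2] + r * sin(th[cand$i]),
                    z = x_v[3] + cand$dz)
  keep <- in_volume(out$x, out$y, out$z, cfg)
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no candidate waypoint falls inside the volume (degenerate geometry)")
  rownames(out) <- NULL
  out
}

#' Waypoint utility
#'
#' `U = k_mu * y_hat + k_sigma * sigma_y2 - sum_k (k_l / d_k)^2` where the
#' sum runs over the other vehicles and `d_k` is the *horizontal* distance
#' from the candidate to vehicle k's last known position (the vertical extent
#' of the volume is far smaller than the horizontal, so only horizontal
#' separation matters for collision pressure).  A candidate exactly at
#' another vehicle's position scores `-Inf` and can never be chosen.
#'
#' @param y_hat,sigma_y2 Model outputs at the candidate(s): fluorescence-scale
#'   predictive mean and variance.
#' @param cand Candidate positions: data.frame or matrix with columns
#'   `x`, `y` (and optionally `z`, ignored for the separation term).
#' @param fleet Last known positions of the *other* vehicles: data.frame with
#'   columns `x`, `y` (zero rows for a lone vehicle), or `NULL`.
#' @param plan A `planner_config`.
#' @return Numeric utility score(s), unitless.
#' @export
utility <- function(y_hat, sigma_y2, cand, fleet, plan) {
  cand <- as.data.frame(cand)
  score <- plan$k_mu * y_hat + plan$k_sigma * sigma_y2
  if (!is.null(fleet) && nrow(fleet) > 0 && plan$k_l > 0) {
    for (k in seq_len(nrow(fleet))) {
      d <- sqrt((cand$x - fleet$x[k])^2 + (cand$y - fleet$y[k])^2)
      pen <- ifelse(d == 0, Inf, (plan$k_l / d)^2)
      score <- score - pen
    }
  }
  score
}

#' Choose the next waypoint
#'
#' Evaluates the on-board model for every surviving candidate at the current
#' time and returns the candidate maximising the utility.  Exact ties break
#' to the lowest candidate index, so the choice is deterministic.
#'
#' The model is evaluated at the *grid-cell center* of each candidate, not
#' at the candidate's exact point.  The planner's currency is grid cells —
#' they are what gets sampled, segmented and exchanged — and because the
#' vertical de-correlation length is much shorter than a cell, exact-point
#' evaluation at the cell-boundary planes the candidate geometry tends to
#' land on would report near-prior uncertainty forever, trapping
#' variance-seeking vehicles on the boundaries (most visibly the surface).
#'
#' @param x_v Current vehicle position `(x, y, z)`.
#' @param train An `lgp_training` (the on-board model state).
#' @param tau_now Current time, seconds.
#' @param hp An `lgp_hyperparams`.
#' @param fleet Other vehicles' last known positions (see [utility()]).
#' @param plan A `planner_config`.
#' @param cfg A `volume_config`.
#' @return A list with `waypoint` (numeric `x`, `y`, `z`), `score`, and the
#'   evaluated `candidates` data.frame (`x, y, z, y_hat, sigma_y2, score`).
#' @export
choose_waypoint <- function(x_v, train, tau_now, hp, fleet, plan, cfg) {
  cand <- candidate_waypoints(x_v, plan, cfg)
  at <- cell_center(cfg, cell_index(cand$x, cand$y, cand$z, cfg))
  pr <- gp_predict(train, at[, c("x", "y", "z")], tau_now, hp)
  sc <- utility(pr$y_hat, pr$sigma_y2, cand, fleet, plan)
  best <- which.max(sc)   # first maximum = lowest index on ties
  cand$y_hat <- pr$y_hat
  cand$sigma_y2 <- pr$sigma_y2
  cand$score <- sc
  list(waypoint = c(x = cand$x[best], y = cand$y[best], z = cand$z[best]),
       score = sc[best], candidates = cand)
}
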