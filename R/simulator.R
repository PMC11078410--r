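# Synthetic patchy-bloom field, vehicle kinematics, and the multi-vehicle
# mission loop: pilot survey -> data exchange -> adaptive sampling cycles,
# with RMSE-versus-truth evaluation at every exchange event.

#' Generate a static synthetic patchy bloom field
#'
#' The log-field is the sum of (i) a smooth vertical profile with a
#' subsurface maximum (a Gaussian bump in depth, the dominant vertical
#' structure of a stratified spring bloom) and (ii) a horizontal stationary
#' Gaussian random field with squared-exponential covariance, drawn via
#' random Fourier features so it can be evaluated anywhere in the volume.
#' Both terms are standardized over the grid-cell centers and combined with
#' weights `sqrt(frac_vertical)` and `sqrt(1 - frac_vertical)`, then scaled
#' so that the log-values at the cell centers have exactly mean `log_mean`
#' and standard deviation `sd_log`.  The field is `exp` of this Gaussian
#' surface: strictly positive, log-normally distributed, patchy at the
#' horizontal correlation length.
#'
#' @param cfg A `volume_config`.
#' @param sd_log Standard deviation of the log field over the grid.
#' @param log_mean Mean of the log field (log micrograms/L; 0 = median 1).
#' @param corr_len Horizontal correlation length of the patches, meters.
#' @param z_max_depth Depth of the subsurface chlorophyll maximum, meters.
#' @param z_width Vertical half-width (Gaussian sigma) of the maximum, meters.
#' @param frac_vertical Fraction of log-field variance carried by the
#'   vertical profile (the rest is horizontal patchiness).
#' @param n_features Number of random Fourier features for the horizontal
#'   term.
#' @param seed RNG seed; identical seeds give identical fields.
#' @return An object of class `truth_field` with elements `eval(x, y, z)`
#'   (vectorized field evaluation, micrograms/L), `cells` (truth at the grid
#'   cell centers), `cfg` and `params`.
#' @export
make_truth_field <- function(cfg, sd_log = 1.6, log_mean = 0,
                             corr_len = 300, z_max_depth = 30, z_width = 12,
                             frac_vertical = 0.5, n_features = 256, seed = 1) {
  stopifnot(sd_log > 0, corr_len > 0, frac_vertical >= 0, frac_vertical <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- matrix(stats::rnorm(2 * n_features, sd = 1 / corr_len), ncol = 2)
  b <- stats::runif(n_features, 0, 2 * pi)
  g_raw <- function(x, y) {
    ph <- cbind(x, y) %*% t(W) + matrix(b, nrow = length(x), ncol = n_features,
                                        byrow = TRUE)
    sqrt(2 / n_features) * rowSums(cos(ph))
  }
  bump_raw <- function(z) exp(-(z - z_max_depth)^2 / (2 * z_width^2))
  # standardize each term over its marginal set of cell centers; on the
  # product grid the variances then add exactly, giving total sd 1
  cs <- cell_size(cfg)
  zc <- (seq_len(cfg$grid_dims[3]) - 0.5) * cs[3]
  bz <- bump_raw(zc)
  b_mu <- mean(bz); b_sd <- stats::sd(bz) * sqrt((length(bz) - 1) / length(bz))
  xy <- expand.grid(x = (seq_len(cfg$grid_dims[1]) - 0.5) * cs[1],
                    y = (seq_len(cfg$grid_dims[2]) - 0.5) * cs[2])
  gz <- g_raw(xy$x, xy$y)
  g_mu <- mean(gz); g_sd <- stats::sd(gz) * sqrt((length(gz) - 1) / length(gz))
  w_v <- sqrt(frac_vertical); w_h <- sqrt(1 - frac_vertical)
  eval_fun <- function(x, y, z) {
    n <- max(length(x), length(y), length(z))
    x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
    anom <- w_v * (bump_raw(z) - b_mu) / b_sd + w_h * (g_raw(x, y) - g_mu) / g_sd
    exp(log_mean + sd_log * anom)
  }
  ctr <- cell_center(cfg)
  ctr$truth <- eval_fun(ctr$x, ctr$y, ctr$z)
  structure(list(eval = eval_fun, cells = ctr, cfg = cfg,
                 params = list(sd_log = sd_log, log_mean = log_mean,
                               corr_len = corr_len, z_max_depth = z_max_depth,
                               z_width = z_width, frac_vertical = frac_vertical,
                               n_features = n_features, seed = seed)),
            class = "truth_field")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate one sensor reading
#'
#' The fluorometer reading is the true field value at the vehicle position
#' under multiplicative log-space noise: `truth * exp(eps)` with
#' `eps ~ N(0, sigma_n^2)`, matching the nugget term of the on-board model.
#'
#' @param x,y,z Sampling position (local frame, meters).
#' @param field A `truth_field`.
#' @param sigma_n Nugget standard deviation (log space).
#' @return Positive reading(s), micrograms/L.  Uses the current RNG stream.
#' @export
sense <- function(x, y, z, field, sigma_n) {
  n <- max(length(x), length(y), length(z))
  field$eval(x, y, z) * exp(stats::rnorm(n, 0, sigma_n))
}

# move a point toward a waypoint by at most `step` meters; returns the new
# position and whether the waypoint was reached this step
step_toward <- function(pos, wp, step) {
  d <- wp - pos
  len <- sqrt(sum(d^2))
  if (len <= step) list(pos = wp, arrived = TRUE)
  else list(pos = pos + d * (step / len), arrived = FALSE)
}

#' Run a multi-vehicle adaptive sampling mission
#'
#' Simulates `n_vehicles` vehicles through the full mission cycle: each runs
#' the pre-planned pilot survey, surfaces for a hub data exchange, then
#' alternates adaptive waypoint-chasing phases of `exchange_period` seconds
#' with further exchanges, until `duration` is reached.  Sampling happens
#' once per clock tick while submerged; measurements are segmented into the
#' shared grid at every waypoint arrival and exchange; the on-board model is
#' trained on the vehicle's own grid merged with whatever the hub has
#' relayed from the rest of the fleet (quantized through the wire format).
#' Surfacing is instantaneous and every inter-vehicle byte string respects
#' the SBD limit.
#'
#' @param n_vehicles Fleet size `N_v >= 1`.
#' @param field A `truth_field`.
#' @param config A `mission_config` (see [mission_config()]).
#' @param duration Mission length, seconds; defaults to the config value.
#' @param seed Seed driving all mission randomness (sensor noise).
#' @return An object of class `mission_log`: a list with `positions`,
#'   `measurements`, `waypoints`, `messages` (per-exchange byte lengths),
#'   `snapshots` (per vehicle and exchange: model predictions at all cell
#'   centers), `rmse` (per vehicle and exchange, log and fluorescence
#'   scales), and the inputs needed to reproduce the run.
#' @export
run_mission <- function(n_vehicles, field, config, duration = NULL, seed = 1) {
  stopifnot(n_vehicles >= 1)
  cfg <- config$volume
  hp <- config$hyperparams
  plan <- config$planner
  scheme <- config$scheme
  sim <- config$simulator
  if (is.null(duration)) duration <- sim$duration
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  hub <- hub_state(scheme)
  mk_vehicle <- function(i) {
    pp <- pilot_path(cfg, plan, i - 1L, n_vehicles)
    list(id = i,
         pos = c(pp$x[1], pp$y[1], pp$z[1]),
         phase = "pilot",
         wp_queue = pp[-(1:2), , drop = FALSE],
         wp = c(pp$x[2], pp$y[2], pp$z[2]),
         grid = grid_state(cfg, 1L),
         buffer = list(),
         queue = NULL,            # unsent cell records
         fleet = NULL,            # others' last known local positions
         next_exchange = Inf,
         train = NULL)
  }
  vehicles <- lapply(seq_len(n_vehicles), mk_vehicle)

  pos_log <- list(); meas_log <- list(); wp_log <- list()
  msg_log <- list(); snap_log <- list(); rmse_log <- list()

  segment_now <- function(v, t) {
    if (length(v$buffer) > 0) {
      batch <- do.call(rbind, v$buffer)
      before_t <- v$grid$time
      v$grid <- segment_measurements(batch, v$grid)
      v$buffer <- list()
      changed <- which(!is.na(v$grid$time) &
                       (is.na(before_t) | v$grid$time != before_t))
      if (length(changed) > 0) {
        rec <- data.frame(cell = changed - 1L,
                          time = v$grid$time[changed],
                          chan1 = v$grid$value[changed, 1])
        v$queue <- rbind(v$queue[!(v$queue$cell %in% rec$cell), , drop = FALSE], rec)
      }
    }
    v
  }

  retrain <- function(v) {
    cells <- grid_cells(v$grid)
    if (nrow(cells) > 0)
      v$train <- lgp_training(
        cbind(cells$x, cells$y, cells$z, cells$time), cells$chan1, hp)
    v
  }

  do_exchange <- function(v, t) {
    v <- segment_now(v, t)
    ll <- local_to_latlon(v$pos[1], v$pos[2], cfg)
    q <- v$queue
    if (!is.null(q) && nrow(q) > 0) q <- q[order(-q$time), , drop = FALSE]
    report <- encode_message(1, v$id, ll$lat, ll$lon, q, scheme)
    n_sent <- min(if (is.null(q)) 0 else nrow(q), max_records(scheme$n_c))
    v$queue <- if (n_sent > 0 && nrow(q) > n_sent) q[-seq_len(n_sent), , drop = FALSE] else NULL
    ex <- hub_exchange(hub, report, t)
    hub <<- ex$hub
    msg_log[[length(msg_log) + 1]] <<- data.frame(
      time = t, vehicle = v$id, report_bytes = length(report),
      reply_bytes = length(ex$reply))
    rep <- decode_message(ex$reply, scheme)
    if (nrow(rep$records) > 0) {
      for (k in seq_len(nrow(rep$records))) {
        ci <- rep$records$cell[k] + 1L
        if (is.na(v$grid$time[ci]) || rep$records$time[k] > v$grid$time[ci]) {
          v$grid$time[ci] <- rep$records$time[k]
          v$grid$value[ci, 1] <- rep$records$chan1[k]
        }
      }
    }
    if (nrow(ex$positions) > 0) {
      loc <- latlon_to_local(ex$positions$lat, ex$positions$lon, cfg)
      v$fleet <- data.frame(vehicle = ex$positions$vehicle,
                            x = loc$x, y = loc$y, time = ex$positions$time)
    }
    v <- retrain(v)
    pr <- predict_grid(v$train, cfg, t, hp)
    snap_log[[length(snap_log) + 1]] <<- cbind(
      data.frame(vehicle = v$id, time = t), pr)
    truth <- field$cells$truth
    rmse_log[[length(rmse_log) + 1]] <<- data.frame(
      vehicle = v$id, time = t,
      rmse_log = sqrt(mean((pr$f_mean - log(truth))^2)),
      rmse_flu = sqrt(mean((pr$y_hat - truth)^2)),
      n_train = if (is.null(v$train)) 0L else nrow(v$train$S))
    v$next_exchange <- t + sim$exchange_period
    v
  }

  replan <- function(v, t) {
    v <- segment_now(v, t)
    v <- retrain(v)
    fl <- if (!is.null(v$fleet)) v$fleet[, c("x", "y")] else NULL
    ch <- choose_waypoint(v$pos, v$train, t, hp, fl, plan, cfg)
    v$wp <- ch$waypoint
    wp_log[[length(wp_log) + 1]] <<- data.frame(
      vehicle = v$id, time = t, x = ch$waypoint[1], y = ch$waypoint[2],
      z = ch$waypoint[3], score = ch$score)
    v
  }

  ticks <- seq(0, duration, by = sim$tick)
  for (t in ticks[-1]) {
    for (i in seq_len(n_vehicles)) {
      v <- vehicles[[i]]
      # move
      mv <- step_toward(v$pos, v$wp, sim$speed * sim$tick)
      v$pos <- mv$pos
      pos_log[[length(pos_log) + 1]] <- data.frame(
        vehicle = v$id, time = t, x = v$pos[1], y = v$pos[2], z = v$pos[3],
        phase = v$phase)
      # sample every movement tick; surfacing is instantaneous, so the
      # vehicle is operationally submerged whenever it is under way, and
      # the fluorometer reads at the surface (z = 0) like anywhere else
      rd <- sense(v$pos[1], v$pos[2], v$pos[3], field, sqrt(hp$sigma_n2))
      m <- data.frame(x = v$pos[1], y = v$pos[2], z = v$pos[3],
                      time = t, chl = rd)
      v$buffer[[length(v$buffer) + 1]] <- m
      meas_log[[length(meas_log) + 1]] <- cbind(data.frame(vehicle = v$id), m)
      if (mv$arrived) {
        if (v$phase == "pilot") {
          if (nrow(v$wp_queue) > 0) {
            v$wp <- c(v$wp_queue$x[1], v$wp_queue$y[1], v$wp_queue$z[1])
            v$wp_queue <- v$wp_queue[-1, , drop = FALSE]
          } else {
            v$phase <- "adaptive"
            v$pos[3] <- 0           # surface for the exchange
            v <- do_exchange(v, t)
            v <- replan(v, t)
          }
        } else {
          v <- replan(v, t)
        }
      }
      if (v$phase == "adaptive" && t >= v$next_exchange) {
        v$pos[3] <- 0
        v <- do_exchange(v, t)
        v <- replan(v, t)
      }
      vehicles[[i]] <- v
    }
  }

  structure(
    list(positions = do.call(rbind, pos_log),
         measurements = do.call(rbind, meas_log),
         waypoints = do.call(rbind, wp_log),
         messages = do.call(rbind, msg_log),
         snapshots = do.call(rbind, snap_log),
         rmse = do.call(rbind, rmse_log),
         n_vehicles = n_vehicles, duration = duration, seed = seed,
         config = config),
    class = "mission_log")
}

#' @export
print.mission_log <- function(x, ...) {
  cat(sprintf("mission_log: %d vehicle(s), %.0f s, %d measurements, %d exchanges\n",
              x$n_vehicles, x$duration,
              if (is.null(x$measurements)) 0L else nrow(x$measurements),
              if (is.null(x$messages)) 0L else nrow(x$messages)))
  if (!is.null(x$rmse)) {
    term <- terminal_rmse(x)
    cat(sprintf("  terminal fleet RMSE: %.3f (log scale), %.3f (fluorescence)\n",
                term["rmse_log"], term["rmse_flu"]))
  }
  invisible(x)
}

#' RMSE learning curve of the on-board models
#'
#' Compares each stored model snapshot (predictions at every grid-cell
#' center) against the ground-truth field, per vehicle and exchange event,
#' on both the log scale (`f_mean` vs `ln` truth — the scale on which the
#' noise floor is the nugget standard deviation) and the fluorescence scale
#' (`y_hat` vs truth, micrograms/L).
#'
#' @param mission A `mission_log`.
#' @param field A `truth_field` (defaults to comparing against the cell
#'   truths captured in the mission's snapshots via the field used there).
#' @return A data.frame `vehicle`, `time`, `rmse_log`, `rmse_flu`, plus the
#'   fleet mean per time under `vehicle = 0`.
#' @export
rmse_curve <- function(mission, field = NULL) {
  snaps <- mission$snapshots
  if (is.null(snaps)) stop("mission log holds no model snapshots")
  truth <- if (!is.null(field)) field$cells$truth else NULL
  if (is.null(truth)) {
    out <- mission$rmse[, c("vehicle", "time", "rmse_log", "rmse_flu")]
  } else {
    sp <- split(snaps, list(snaps$vehicle, snaps$time), drop = TRUE)
    out <- do.call(rbind, lapply(sp, function(d) {
      d <- d[order(d$cell), ]
      data.frame(vehicle = d$vehicle[1], time = d$time[1],
                 rmse_log = sqrt(mean((d$f_mean - log(truth))^2)),
                 rmse_flu = sqrt(mean((d$y_hat - truth)^2)))
    }))
  }
  fleet <- do.call(rbind, lapply(split(out, out$time), function(d)
    data.frame(vehicle = 0L, time = d$time[1],
               rmse_log = mean(d$rmse_log), rmse_flu = mean(d$rmse_flu))))
  res <- rbind(out, fleet)
  res <- res[order(res$time, res$vehicle), ]
  rownames(res) <- NULL
  res
}

#' Terminal fleet RMSE of a mission
#'
#' The fleet-averaged RMSE at the final exchange event.
#'
#' @param mission A `mission_log`.
#' @return Named numeric: `rmse_log` and `rmse_flu`.
#' @export
terminal_rmse <- function(mission) {
  r <- mission$rmse
  last <- r[r$time == max(r$time), , drop = FALSE]
  c(rmse_log = mean(last$rmse_log), rmse_flu = mean(last$rmse_flu))
}
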