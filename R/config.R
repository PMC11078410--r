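# Mission configuration: one flat JSON document covering the operational
# volume, model hyperparameters, planner weights, wire-format quantization
# and simulator settings, under the operator-facing symbol names.

#' Assemble a mission configuration
#'
#' @param volume A `volume_config`.
#' @param hyperparams An `lgp_hyperparams`.
#' @param planner A `planner_config`.
#' @param scheme A `quant_scheme`.
#' @param simulator Named list of simulator settings: `tick` (s), `speed`
#'   (m/s, nominal vehicle speed in 1.0-1.5), `exchange_period` (s),
#'   `duration` (s), and truth-field generator settings `sd_log`,
#'   `log_mean`, `corr_len`, `z_max_depth`, `z_width`, `frac_vertical`,
#'   `n_features`.
#' @param seed Top-level mission seed.
#' @return An object of class `mission_config`.
#' @export
mission_config <- function(volume, hyperparams, planner, scheme, simulator,
                           seed = 1L) {
  stopifnot(inherits(volume, "volume_config"),
            inherits(hyperparams, "lgp_hyperparams"),
            inherits(planner, "planner_config"),
            inherits(scheme, "quant_scheme"))
  need <- c("tick", "speed", "exchange_period", "duration")
  missing <- setdiff(need, names(simulator))
  if (length(missing))
    stop("simulator config lacks key(s): ", paste(missing, collapse = ", "))
  if (simulator$speed < 0.5 || simulator$speed > 3)
    stop("vehicle speed outside a plausible AUV envelope (m/s): ", simulator$speed)
  structure(list(volume = volume, hyperparams = hyperparams, planner = planner,
                 scheme = scheme, simulator = simulator, seed = as.integer(seed)),
            class = "mission_config")
}

#' Default mission configuration
#'
#' `profile = "simulation"` is the reduced desk-scale setup (1000 x 1000 x
#' 50 m volume, 10 x 10 x 5 grid, 10 s tick, 600 s exchange period) sized so
#' a four-vehicle run completes in minutes on one CPU.  `profile = "field"`
#' carries the field-trial operator inputs: 1500 x 1500 x 50 m volume at
#' 78N 57.29 / 11E 56.85 oriented -45 degrees, a 15 x 15 x 10 grid,
#' de-correlation lengths (600, 600, 3) m and 10000 s, sigma_c 1.6,
#' sigma_n 0.7, utility weights (1, 1, 300 m).
#'
#' @param profile `"simulation"` or `"field"`.
#' @param seed Mission seed.
#' @return A `mission_config`.
#' @export
default_mission_config <- function(profile = c("simulation", "field"), seed = 1L) {
  profile <- match.arg(profile)
  hp <- lgp_hyperparams(M = c(600, 600, 3, 10000), sigma_c = 1.6, sigma_n = 0.7)
  plan <- planner_config(n_theta = 8, k_mu = 1, k_sigma = 1, k_l = 300)
  scheme <- quant_scheme(n_c = 1L)
  if (profile == "field") {
    vol <- volume_config(78 + 57.29 / 60, 11 + 56.85 / 60, -45,
                         c(1500, 1500, 50), c(15, 15, 10))
    sim <- list(tick = 10, speed = 1.2, exchange_period = 600, duration = 7200,
                sd_log = 1.6, log_mean = 0, corr_len = 450, z_max_depth = 30,
                z_width = 12, frac_vertical = 0.5, n_features = 256)
  } else {
    vol <- volume_config(78 + 57.29 / 60, 11 + 56.85 / 60, -45,
                         c(1000, 1000, 50), c(10, 10, 5))
    sim <- list(tick = 10, speed = 1.2, exchange_period = 600, duration = 3600,
                sd_log = 1.6, log_mean = 0, corr_len = 300, z_max_depth = 30,
                z_width = 12, frac_vertical = 0.5, n_features = 256)
  }
  mission_config(vol, hp, plan, scheme, sim, seed)
}

#' Build the truth field described by a mission configuration
#' @param config A `mission_config`.
#' @param seed Field seed; defaults to the config seed.
#' @return A `truth_field`.
#' @export
config_truth_field <- function(config, seed = config$seed) {
  s <- config$simulator
  make_truth_field(config$volume, sd_log = s$sd_log, log_mean = s$log_mean,
                   corr_len = s$corr_len, z_max_depth = s$z_max_depth,
                   z_width = s$z_width, frac_vertical = s$frac_vertical,
                   n_features = s$n_features, seed = seed)
}

config_key <- function(section, lst, key, section_name) {
  if (is.null(lst[[key]]))
    stop("mission config is missing required key '", section_name, ".", key, "'")
  lst[[key]]
}

#' Load a mission configuration from JSON
#'
#' The document has flat sections `volume`, `model`, `planner`, `comms`,
#' `simulator` and a top-level `seed`, with every operator symbol under its
#' standard name (`V_x`, `n_x`, `M_x`, `M_tau`, `sigma_c`, `sigma_n`,
#' `k_mu`, `k_sigma`, `k_l`, `n_theta`, ...).  Missing required keys are
#' reported by name.
#'
#' @param path JSON file path.
#' @return A `mission_config`.
#' @export
load_mission_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  v <- doc$volume
  if (is.null(v)) stop("mission config is missing section 'volume'")
  k <- function(lst, key, sec) config_key(doc, lst, key, sec)
  vol <- volume_config(
    k(v, "V_lat", "volume"), k(v, "V_lon", "volume"), k(v, "V_theta", "volume"),
    c(k(v, "V_x", "volume"), k(v, "V_y", "volume"), k(v, "V_z", "volume")),
    c(k(v, "n_x", "volume"), k(v, "n_y", "volume"), k(v, "n_z", "volume")))
  m <- doc$model
  if (is.null(m)) stop("mission config is missing section 'model'")
  hp <- lgp_hyperparams(
    M = c(k(m, "M_x", "model"), k(m, "M_y", "model"),
          k(m, "M_z", "model"), k(m, "M_tau", "model")),
    sigma_c = k(m, "sigma_c", "model"), sigma_n = k(m, "sigma_n", "model"),
    as_variance = isTRUE(m$sigma_as_variance),
    log_floor = if (is.null(m$log_floor)) 0.01 else m$log_floor)
  p <- doc$planner
  if (is.null(p)) stop("mission config is missing section 'planner'")
  plan <- planner_config(
    n_theta = k(p, "n_theta", "planner"), r = p$r, z_d = p$z_d,
    k_mu = k(p, "k_mu", "planner"), k_sigma = k(p, "k_sigma", "planner"),
    k_l = k(p, "k_l", "planner"),
    undulation = if (is.null(p$undulation)) c(0, NA, 2) else p$undulation)
  cm <- doc$comms
  if (is.null(cm)) cm <- list()
  scheme <- quant_scheme(
    log_min = if (is.null(cm$log_min)) log(0.01) else cm$log_min,
    log_max = if (is.null(cm$log_max)) log(100) else cm$log_max,
    time_ref = if (is.null(cm$time_ref)) 0 else cm$time_ref,
    time_step = if (is.null(cm$time_step)) 60 else cm$time_step,
    n_c = if (is.null(cm$n_c)) 1L else cm$n_c)
  s <- doc$simulator
  if (is.null(s)) stop("mission config is missing section 'simulator'")
  defaults <- default_mission_config()$simulator
  for (nm in names(defaults)) if (is.null(s[[nm]])) s[[nm]] <- defaults[[nm]]
  mission_config(vol, hp, plan, scheme, s,
                 seed = if (is.null(doc$seed)) 1L else doc$seed)
}

#' Write a mission configuration to JSON
#' @param config A `mission_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mission_config <- function(config, path) {
  v <- config$volume; hp <- config$hyperparams; p <- config$planner
  sc <- config$scheme
  doc <- list(
    volume = list(V_lat = v$origin_lat, V_lon = v$origin_lon, V_theta = v$theta,
                  V_x = v$extent[1], V_y = v$extent[2], V_z = v$extent[3],
                  n_x = v$grid_dims[1], n_y = v$grid_dims[2], n_z = v$grid_dims[3]),
    model = list(M_x = hp$M[1], M_y = hp$M[2], M_z = hp$M[3], M_tau = hp$M[4],
                 sigma_c = sqrt(hp$sigma_c2), sigma_n = sqrt(hp$sigma_n2),
                 sigma_as_variance = FALSE, log_floor = hp$log_floor),
    planner = list(n_theta = p$n_theta, r = p$r, z_d = p$z_d, k_mu = p$k_mu,
                   k_sigma = p$k_sigma, k_l = p$k_l, undulation = p$undulation),
    comms = list(log_min = sc$log_min, log_max = sc$log_max,
                 time_ref = sc$time_ref, time_step = sc$time_step, n_c = sc$n_c),
    simulator = config$simulator,
    seed = config$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
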