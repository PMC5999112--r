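#' Default configuration
#'
#' All simulation inputs are configuration; this returns the fully
#' materialized default set. Wind defaults follow the reference study
#' conditions (mean wind 1 m/s, flier ground speed 0.3 m/s, turbulence
#' intensities 5--30%, fliers started 6--20 m downwind); the free plume
#' parameters (dispersion coefficient scale and sensor threshold) default
#' to the output of [calibrate_plume()] with its documented anchors.
#'
#' @return A nested list of class `mothnav_config` with sections `wind`,
#'   `plume`, `navigator`, `experiment` and `seed`.
#' @export
default_config <- function() {
  cal <- calibrate_plume()
  cfg <- list(
    wind = list(
      U_mean = 1.0,
      turbulence_intensity = 0.15,
      gust = list(enabled = FALSE, amplitude_frac = 0.5,
                  hold_s = 10, rate_per_run = 3),
      meander = list(enabled = FALSE, amplitude = 0.2, period_s = 100)
    ),
    plume = list(
      pulse_interval_T = 1.0,
      mass_per_pulse = 1.0,
      a_scale = cal$a_scale,      # A_h = a_scale * TI * U unless A_h set
      A_h = NA_real_,             # explicit override (m/s); NA = derived
      A_z = NA_real_,
      B_h = 1.0, B_z = 1.0,
      z0 = 0.0,
      threshold_Cstar = cal$threshold_Cstar,
      sigma_floor = 0.01,
      form = "standard"
    ),
    navigator = list(
      ground_speed = 0.3,
      alpha_min_deg = 30, alpha_max_deg = 120,
      strategy = "crossing_time",
      internal_counter_tau_s = 1.0,
      surge_timer_origin = "exit"
    ),
    experiment = list(
      n_fields = 10,
      n_flights_per_field = 100,
      ti_grid = seq(0.05, 0.30, by = 0.05),
      radii_R = c(0.15, 0.20, 0.25),
      start_x_range = c(6, 20),
      start_y_halfwidth = NA_real_,  # NA = 0.4 m, widened to 1 m w/ meander
      dt = 0.05,
      max_sim_time = 600,
      spin_up = NA_real_,            # NA = 1.5 * max start distance / U
      prune_margin = 5,
      metrics_radius = 0.25
    ),
    seed = list(master = 1)
  )
  class(cfg) <- c("mothnav_config", "list")
  cfg
}

# recursive merge of user values onto defaults, rejecting unknown keys
.merge_config <- function(default, user, path = "") {
  if (is.null(user)) return(default)
  if (!is.list(default) || !is.list(user)) return(user)
  unknown <- setdiff(names(user), names(default))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "),
         call. = FALSE)
  for (nm in names(user)) {
    if (is.list(default[[nm]])) {
      default[[nm]] <- .merge_config(default[[nm]], user[[nm]],
                                     paste0(path, ".", nm))
    } else {
      val <- user[[nm]]
      # serialized configs lose numeric storage of NA and integers
      if (is.numeric(default[[nm]]) && !is.double(val))
        val <- suppressWarnings(as.numeric(val))
      default[[nm]] <- val
    }
  }
  default
}

.validate_config <- function(cfg) {
  w <- cfg$wind; p <- cfg$plume; n <- cfg$navigator; e <- cfg$experiment
  # constructors carry the range checks for wind/navigator
  wind_model(U_mean = w$U_mean, turbulence_intensity = w$turbulence_intensity,
             gust_enabled = w$gust$enabled,
             gust_amplitude_frac = w$gust$amplitude_frac,
             gust_hold_s = w$gust$hold_s,
             gust_rate_per_run = w$gust$rate_per_run,
             meander_enabled = w$meander$enabled,
             meander_amplitude = w$meander$amplitude,
             meander_period_s = w$meander$period_s)
  navigator_params(ground_speed = n$ground_speed,
                   alpha_min_deg = n$alpha_min_deg,
                   alpha_max_deg = n$alpha_max_deg,
                   strategy = n$strategy,
                   internal_counter_tau = n$internal_counter_tau_s,
                   success_radius_R = max(e$radii_R),
                   surge_timer_origin = n$surge_timer_origin)
  if (p$pulse_interval_T <= 0) stop("plume.pulse_interval_T must be > 0", call. = FALSE)
  if (p$mass_per_pulse <= 0) stop("plume.mass_per_pulse must be > 0", call. = FALSE)
  if (p$threshold_Cstar <= 0) stop("plume.threshold_Cstar must be > 0", call. = FALSE)
  if (!is.na(p$A_h) && p$A_h <= 0) stop("plume.A_h must be > 0", call. = FALSE)
  if (e$dt <= 0 || e$dt >= p$pulse_interval_T)
    stop("experiment.dt must satisfy 0 < dt < plume.pulse_interval_T", call. = FALSE)
  if (any(e$ti_grid < 0)) stop("experiment.ti_grid must be >= 0", call. = FALSE)
  if (any(e$radii_R <= 0)) stop("experiment.radii_R must be > 0", call. = FALSE)
  if (length(e$start_x_range) != 2 || any(e$start_x_range <= 0) ||
      diff(e$start_x_range) < 0)
    stop("experiment.start_x_range must be a positive increasing pair", call. = FALSE)
  if (e$n_fields < 1 || e$n_flights_per_field < 1)
    stop("experiment.n_fields and n_flights_per_field must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Load and validate a configuration file
#'
#' Reads a YAML or JSON configuration (selected by file extension), fills
#' every unset key from [default_config()], rejects unknown keys by name,
#' and validates ranges. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @return A validated `mothnav_config`.
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  cfg <- .merge_config(unclass(default_config()), user)
  class(cfg) <- c("mothnav_config", "list")
  .validate_config(cfg)
  cfg
}

#' Write a configuration to file
#'
#' @param cfg A `mothnav_config`.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly. `load_config(write_config(cfg, p))` round-trips.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mothnav_config"))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

# resolved per-condition models -----------------------------------------

# effective start half-width: widened when meander is on, per the stated
# coupling of the start band to the wind condition
.start_halfwidth <- function(cfg) {
  hw <- cfg$experiment$start_y_halfwidth
  if (!is.na(hw)) return(hw)
  if (cfg$wind$meander$enabled) 1.0 else 0.4
}

.spin_up <- function(cfg) {
  su <- cfg$experiment$spin_up
  if (!is.na(su)) return(su)
  1.5 * max(cfg$experiment$start_x_range) / cfg$wind$U_mean
}

#' Materialize the wind and plume models of a configuration
#'
#' @param cfg A `mothnav_config`.
#' @param ti Turbulence intensity for this condition (defaults to
#'   `cfg$wind$turbulence_intensity`). Unless overridden explicitly, the
#'   plume growth coefficients are derived as `A = a_scale * ti * U`.
#' @return A list with elements `wind` ([wind_model()]), `plume`
#'   ([plume_model()]) and `navigator` ([navigator_params()]).
#' @export
resolve_models <- function(cfg, ti = NULL) {
  stopifnot(inherits(cfg, "mothnav_config"))
  if (is.null(ti)) ti <- cfg$wind$turbulence_intensity
  w <- cfg$wind; p <- cfg$plume; n <- cfg$navigator
  A_h <- if (!is.na(p$A_h)) p$A_h else p$a_scale * ti * w$U_mean
  A_z <- if (!is.na(p$A_z)) p$A_z else A_h
  list(
    wind = wind_model(U_mean = w$U_mean, turbulence_intensity = ti,
                      gust_enabled = w$gust$enabled,
                      gust_amplitude_frac = w$gust$amplitude_frac,
                      gust_hold_s = w$gust$hold_s,
                      gust_rate_per_run = w$gust$rate_per_run,
                      meander_enabled = w$meander$enabled,
                      meander_amplitude = w$meander$amplitude,
                      meander_period_s = w$meander$period_s),
    plume = plume_model(pulse_interval_T = p$pulse_interval_T,
                        mass_per_pulse_m = p$mass_per_pulse,
                        A_h = A_h, A_z = A_z, B_h = p$B_h, B_z = p$B_z,
                        release_height_z0 = p$z0,
                        threshold_Cstar = p$threshold_Cstar,
                        sigma_floor = p$sigma_floor,
                        form = p$form),
    navigator = navigator_params(ground_speed = n$ground_speed,
                                 alpha_min_deg = n$alpha_min_deg,
                                 alpha_max_deg = n$alpha_max_deg,
                                 strategy = n$strategy,
                                 internal_counter_tau = n$internal_counter_tau_s,
                                 success_radius_R = cfg$experiment$metrics_radius,
                                 surge_timer_origin = n$surge_timer_origin)
  )
}

#' Named test scenarios
#'
#' Small, fast, deterministic-by-construction configurations used by the
#' test suite and useful for exploring the model:
#' \describe{
#' \item{`zero_turbulence_straight_shot`}{no turbulence, no gusts or
#'   meander; overlapping puffs form a continuous corridor along the
#'   centerline, so a flier started inside it flies straight upwind and
#'   deterministically reaches the source.}
#' \item{`single_puff_chord`}{a single frozen-size puff (growth ~ 0, size
#'   pinned at `sigma_floor = 0.3` m) advected over a flier in laminar
#'   wind: the chord-crossing scenario whose crossing time has the
#'   closed-form value `2 rho / U` for a stationary sensor.}
#' \item{`tuned_internal_counter`}{default wind at TI 0.15 with the
#'   internal-counter baseline, tau set near the typical measured crossing
#'   time of the calibrated plume at the anchor distance.}
#' \item{`paper_defaults`}{the full default configuration (reference study
#'   conditions).}
#' }
#'
#' @param name One of the scenario names above.
#' @return A validated `mothnav_config`.
#' @export
make_fixture <- function(name = c("zero_turbulence_straight_shot",
                                  "single_puff_chord",
                                  "tuned_internal_counter",
                                  "paper_defaults")) {
  name <- match.arg(name)
  cfg <- default_config()
  if (name == "zero_turbulence_straight_shot") {
    cfg$wind$turbulence_intensity <- 0
    cfg$experiment$ti_grid <- 0
    cfg$plume$A_h <- 0.2
    cfg$plume$A_z <- 0.2
    cfg$plume$threshold_Cstar <- 0.01
    cfg$experiment$n_fields <- 1
    cfg$experiment$n_flights_per_field <- 5
    cfg$experiment$start_x_range <- c(7, 8)
    cfg$experiment$start_y_halfwidth <- 0.05
  } else if (name == "single_puff_chord") {
    cfg$wind$turbulence_intensity <- 0
    cfg$plume$pulse_interval_T <- 1e6   # effectively a single puff at t = 0
    cfg$plume$A_h <- 1e-9               # growth frozen: size pinned at floor
    cfg$plume$A_z <- 1e-9
    cfg$plume$sigma_floor <- 0.3
    # threshold set for a detectable radius of exactly 0.2 m:
    # C* = peak * exp(-rho^2 / (2 sigma^2))
    peak <- 1 / ((2 * pi)^1.5 * 0.3^2 * 0.3)
    cfg$plume$threshold_Cstar <- peak * exp(-0.2^2 / (2 * 0.3^2))
    cfg$experiment$dt <- 0.05
    cfg$experiment$spin_up <- 0
  } else if (name == "tuned_internal_counter") {
    cfg$navigator$strategy <- "internal_counter"
    # typical crossing time: anchor-radius chord over the relative speed of
    # an upwind-surging flier
    cfg$navigator$internal_counter_tau_s <-
      2 * 0.2 / (cfg$wind$U_mean + cfg$navigator$ground_speed)
  }
  .validate_config(cfg)
  cfg
}

#' Run manifest
#'
#' Captures everything needed to reproduce a run bit-identically: the fully
#' resolved configuration, the seed tree root, package version and
#' timestamp, plus an FNV-1a fingerprint of the resolved configuration and
#' master seed (the timestamp is excluded from the hash so that replays of
#' the same configuration match).
#'
#' @param cfg A `mothnav_config`.
#' @return A list with `config`, `seed_master`, `version`, `timestamp`,
#'   `hash`.
#' @export
run_manifest <- function(cfg) {
  stopifnot(inherits(cfg, "mothnav_config"))
  payload <- jsonlite::toJSON(list(config = unclass(cfg)),
                              auto_unbox = TRUE, digits = NA)
  list(config = cfg,
       seed_master = cfg$seed$master,
       version = as.character(utils::packageVersion("mothnav")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       hash = fnv1a_hash(as.character(payload)))
}
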