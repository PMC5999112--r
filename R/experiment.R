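#' Run the full Monte-Carlo navigation experiment
#'
#' For every turbulence intensity in the configured grid, realizes
#' `n_fields` independent turbulence/plume fields and runs
#' `n_flights_per_field` navigation flights per field (start positions
#' drawn uniformly from the configured downwind range and transverse band).
#' Flights that never detect a puff are excluded; censored flights count as
#' failures. Success probabilities are aggregated per radius with the
#' standard deviation taken across field replicates, and flight metrics are
#' averaged over successful flights (at the `metrics_radius`). The whole
#' experiment is deterministic given the master seed: every field and
#' flight has its own derived random stream (see [child_seed()]), so adding
#' replicates never perturbs existing ones.
#'
#' @param cfg A `mothnav_config` from [load_config()] / [default_config()].
#' @param progress Print one line per condition as the sweep advances?
#' @return An object of class `experiment_summary`: `$flights` (one row per
#'   flight), `$success` (per TI and radius: mean and SD across fields),
#'   `$metrics` (per TI: mean and SD of each metric over successful
#'   flights), `$manifest`.
#' @export
run_experiment <- function(cfg = default_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "mothnav_config"))
  .validate_config(cfg)
  e <- cfg$experiment
  flights <- vector("list", length(e$ti_grid))
  for (i in seq_along(e$ti_grid)) {
    ti <- e$ti_grid[i]
    if (progress)
      message(sprintf("TI = %.2f (%d fields x %d flights)...",
                      ti, e$n_fields, e$n_flights_per_field))
    nav <- resolve_models(cfg, ti)$navigator
    flights[[i]] <- .run_condition(cfg, ti, i, list(default = nav))
  }
  flights <- do.call(rbind, flights)
  flights$strategy <- NULL
  out <- list(flights = flights,
              success = .summarize_success(flights, e$radii_R),
              metrics = .summarize_metrics(flights, e$metrics_radius),
              manifest = run_manifest(cfg))
  class(out) <- "experiment_summary"
  out
}

# run every flight of one (TI, condition) cell for one or more navigator
# parameter sets against the *same* realized fields and flight seeds
# (paired design used by compare_strategies)
.run_condition <- function(cfg, ti, ti_index, navs) {
  e <- cfg$experiment
  models <- resolve_models(cfg, ti)
  spin <- .spin_up(cfg)
  horizon <- spin + e$max_sim_time
  prune_x <- max(e$start_x_range) + e$prune_margin
  hw <- .start_halfwidth(cfg)
  master <- cfg$seed$master
  rows <- list()
  for (f in seq_len(e$n_fields)) {
    fseed <- child_seed(master, "field", ti_index, f)
    field <- simulate_field(models$wind, models$plume, horizon,
                            dt = e$dt, prune_x = prune_x, seed = fseed)
    for (s in seq_along(navs)) {
      nav <- navs[[s]]
      for (j in seq_len(e$n_flights_per_field)) {
        flseed <- child_seed(master, "flight", ti_index, f, j)
        set.seed(flseed)
        x0 <- stats::runif(1, e$start_x_range[1], e$start_x_range[2])
        y0 <- stats::runif(1, -hw, hw)
        rec <- run_flight(field, nav, c(x0, y0), place_time = spin,
                          max_sim_time = e$max_sim_time, seed = NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          ti = ti, strategy = names(navs)[s],
          field_id = f, flight_id = j, seed = flseed,
          start_x_m = x0, start_y_m = y0,
          started = rec$started, crossed = rec$crossed,
          censored = if (is.na(rec$censored)) "" else rec$censored,
          y_at_cross_m = rec$y_at_cross,
          t_start_s = rec$t_start,
          flight_time_s = rec$flight_time,
          search_time_s = rec$search_time,
          trajectory_length_m = rec$trajectory_length,
          lateral_deviation = rec$lateral_deviation,
          n_search_cycles = rec$n_search_cycles,
          n_counter_turns = rec$n_counter_turns,
          n_detections = rec$n_detections,
          t_c_mean_s = rec$t_c_mean
        )
      }
    }
  }
  do.call(rbind, rows)
}

.summarize_success <- function(flights, radii) {
  started <- flights[flights$started, , drop = FALSE]
  out <- list()
  for (ti in unique(flights$ti)) {
    d <- started[started$ti == ti, , drop = FALSE]
    for (R in radii) {
      ok <- d$crossed & !is.na(d$y_at_cross_m) & abs(d$y_at_cross_m) <= R
      per_field <- tapply(ok, d$field_id, mean)
      out[[length(out) + 1L]] <- data.frame(
        ti = ti, R = R,
        p_success = mean(per_field, na.rm = TRUE),
        sd_success = stats::sd(per_field, na.rm = TRUE),
        n_started = nrow(d)
      )
    }
  }
  do.call(rbind, out)
}

.summarize_metrics <- function(flights, metrics_radius) {
  started <- flights[flights$started, , drop = FALSE]
  cols <- c("flight_time_s", "search_time_s", "trajectory_length_m",
            "lateral_deviation", "n_search_cycles", "n_counter_turns",
            "t_c_mean_s")
  out <- list()
  for (ti in unique(flights$ti)) {
    d <- started[started$ti == ti, , drop = FALSE]
    ok <- d$crossed & !is.na(d$y_at_cross_m) &
      abs(d$y_at_cross_m) <= metrics_radius
    s <- d[ok, , drop = FALSE]
    row <- data.frame(ti = ti, n_started = nrow(d), n_success = nrow(s))
    for (cn in cols) {
      row[[paste0("mean_", cn)]] <- mean(s[[cn]], na.rm = TRUE)
      row[[paste0("sd_", cn)]] <- stats::sd(s[[cn]], na.rm = TRUE)
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat("<experiment_summary>\n")
  cat(sprintf("  %d flights (%d started), manifest %s\n",
              nrow(x$flights), sum(x$flights$started), x$manifest$hash))
  cat("  success probability (mean +/- SD across fields):\n")
  s <- x$success
  for (i in seq_len(nrow(s)))
    cat(sprintf("    TI %.2f  R %.2f m : %.3f +/- %.3f\n",
                s$ti[i], s$R[i], s$p_success[i], s$sd_success[i]))
  invisible(x)
}

#' Compare the crossing-time strategy with internal-counter baselines
#'
#' Runs the crossing-time navigator and the fixed internal-counter variant
#' at each `tau` against the *same* realized fields, start positions and
#' random streams (a paired design), at the single turbulence intensity of
#' `cfg$wind$turbulence_intensity`. The `tau = 0` row reports the
#' crossing-time strategy itself as the reference point.
#'
#' @param cfg A `mothnav_config`.
#' @param tau_grid Positive internal-counter durations (s) to test.
#' @return A data frame with columns `tau_s`, `p_success` (at the
#'   configured `metrics_radius`), `sd_success` (across fields) and
#'   `n_started`; the first row (`tau_s = 0`) is the crossing-time
#'   reference.
#' @export
compare_strategies <- function(cfg = default_config(),
                               tau_grid = c(0.25, 0.5, 1, 2, 5)) {
  stopifnot(inherits(cfg, "mothnav_config"), all(tau_grid > 0))
  .validate_config(cfg)
  ti <- cfg$wind$turbulence_intensity
  base <- resolve_models(cfg)$navigator
  navs <- list(crossing_time = base)
  for (tau in tau_grid) {
    nv <- base
    nv$strategy <- "internal_counter"
    nv$internal_counter_tau <- tau
    navs[[sprintf("tau_%g", tau)]] <- nv
  }
  flights <- .run_condition(cfg, ti, 1L, navs)
  R <- cfg$experiment$metrics_radius
  out <- list()
  for (s in seq_along(navs)) {
    d <- flights[flights$strategy == names(navs)[s] & flights$started, ,
                 drop = FALSE]
    ok <- d$crossed & !is.na(d$y_at_cross_m) & abs(d$y_at_cross_m) <= R
    per_field <- tapply(ok, d$field_id, mean)
    out[[s]] <- data.frame(
      tau_s = if (s == 1) 0 else tau_grid[s - 1],
      strategy = names(navs)[s],
      p_success = mean(per_field, na.rm = TRUE),
      sd_success = stats::sd(per_field, na.rm = TRUE),
      n_started = nrow(d)
    )
  }
  do.call(rbind, out)
}

#' Write experiment outputs to a directory
#'
#' Writes the per-flight metrics CSV (RFC-4180, `.` decimal, units in
#' column names) and a summary JSON. Both carry the resolved configuration
#' and seed tree in a provenance header (`#`-prefixed lines in the CSV, a
#' `manifest` block in the JSON) including the manifest hash, so replays
#' can be matched to the configuration that produced them.
#'
#' @param summary An [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_experiment <- function(summary, dir) {
  stopifnot(inherits(summary, "experiment_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- summary$manifest
  csv <- file.path(dir, "flights.csv")
  hdr <- c(
    sprintf("# mothnav %s flight records", man$version),
    sprintf("# manifest_hash: %s", man$hash),
    sprintf("# seed_master: %d", man$seed_master),
    sprintf("# timestamp: %s", man$timestamp),
    sprintf("# config: %s", jsonlite::toJSON(unclass(man$config),
                                             auto_unbox = TRUE, digits = NA))
  )
  con <- file(csv, "w")
  writeLines(hdr, con)
  utils::write.csv(summary$flights, con, row.names = FALSE, quote = FALSE)
  close(con)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(manifest = list(hash = man$hash, version = man$version,
                         seed_master = man$seed_master,
                         timestamp = man$timestamp,
                         config = unclass(man$config)),
         success = summary$success,
         metrics = summary$metrics),
    js, auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  invisible(c(csv = csv, json = js))
}
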