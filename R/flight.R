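#' Run one navigation flight in a realized field
#'
#' The flier is placed at `start` at time `place_time` and waits,
#' stationary, until the first above-threshold puff crosses its position
#' (fliers that never detect anything within the flight window never start
#' and are excluded from experiment statistics). From first detection the
#' plume and flier advance jointly in `dt` steps under the surge-and-cast
#' state machine of [flier_step()], with the flier steering relative to the
#' instantaneous wind (shared gust/meander state plus its own local
#' fluctuation draws). The flight terminates when the flier crosses the
#' source line `x = 0` (success is classified later against a radius), or is
#' censored at `max_sim_time` after placement or on escaping downstream past
#' the field's pruning boundary.
#'
#' @param field A [simulate_field()] result.
#' @param params A [navigator_params()].
#' @param start Length-2 numeric start position `(x, y)` (m).
#' @param place_time Time (s) on the field clock at which the flier is
#'   placed (typically after the plume spin-up).
#' @param max_sim_time Maximum waiting + flying time (s) after placement.
#' @param seed Optional integer seed for the flight's random stream (local
#'   wind fluctuations seen by the flier, cast angles and sides).
#' @param keep_trajectory Keep the per-step trajectory samples
#'   (`t, x, y, mode, detected`) in the record? Default `FALSE` to save
#'   memory in large sweeps.
#' @return An object of class `flight_record`: outcome flags (`started`,
#'   `crossed`, `censored`), `t_start` (first detection, field clock),
#'   `t_cross` and `y_at_cross` (linearly interpolated at the crossing),
#'   event counters, and the metrics of [compute_metrics()].
#' @export
run_flight <- function(field, params, start, place_time = 0,
                       max_sim_time = 600, seed = NULL,
                       keep_trajectory = FALSE) {
  stopifnot(inherits(field, "plume_field"),
            inherits(params, "navigator_params"),
            length(start) == 2, max_sim_time > 0)
  if (!is.null(seed)) set.seed(seed)
  dt <- field$dt
  from <- as.integer(round(place_time / dt)) + 1L
  k_end <- min(field$n_steps,
               as.integer(round((place_time + max_sim_time) / dt)) + 1L)
  rec <- list(started = FALSE, crossed = FALSE, censored = NA_character_,
              start_x = start[1], start_y = start[2],
              t_start = NA_real_, t_cross = NA_real_,
              y_at_cross = NA_real_,
              flight_time = NA_real_, search_time = NA_real_,
              trajectory_length = NA_real_, lateral_deviation = NA_real_,
              n_detections = 0L, n_search_cycles = 0L,
              n_counter_turns = 0L, t_c_mean = NA_real_,
              ground_speed = params$ground_speed, dt = dt,
              trajectory = NULL)
  class(rec) <- "flight_record"

  k0 <- .first_detection_step(field, start[1], start[2], from = from)
  if (is.na(k0) || k0 > k_end) return(rec)   # never started

  rec$started <- TRUE
  rec$t_start <- (k0 - 1L) * dt
  state <- flier_state(start[1], start[2])
  U <- field$wind$U_mean
  sd_fl <- field$wind$turbulence_intensity * U
  Cs <- field$plume$threshold_Cstar
  px <- field$px; py <- field$py
  birth <- field$birth; death <- field$death
  lob <- field$lob; hib <- field$hib
  peak <- field$peak; sig <- field$sigma_h
  Ug <- field$Ug; Vm <- field$Vm

  n_max <- k_end - k0 + 2L
  xs <- numeric(n_max); ys <- numeric(n_max)
  md <- character(n_max); dets <- logical(n_max)
  xs[1] <- start[1]; ys[1] <- start[2]
  md[1] <- "WAITING"; dets[1] <- TRUE
  ii <- 1L
  tc_sum <- 0; tc_n <- 0L
  frac <- 1

  for (k in k0:k_end) {
    # sensor: exact superposition over live puffs
    i1 <- lob[k]; i2 <- hib[k]
    conc <- 0
    if (i2 >= i1) {
      cand <- i1:i2
      cand <- cand[death[cand] >= k]
      if (length(cand)) {
        j <- k - birth[cand] + 1L
        dx <- px[cbind(cand, j)] - state$x
        dy <- py[cbind(cand, j)] - state$y
        conc <- sum(peak[j] * exp(-(dx * dx + dy * dy) / (2 * sig[j]^2)))
      }
    }
    detected <- conc >= Cs

    in_puff_before <- state$mode == "IN_PUFF"
    wind <- c(U + Ug[k] + (if (sd_fl > 0) stats::rnorm(1, 0, sd_fl) else 0),
              Vm[k] + (if (sd_fl > 0) stats::rnorm(1, 0, sd_fl) else 0))
    x_prev <- state$x
    y_prev <- state$y
    state <- flier_step(state, detected, wind, dt, params)
    if (in_puff_before && !detected) {       # a crossing was just recorded
      tc_sum <- tc_sum + state$t_c_last
      tc_n <- tc_n + 1L
    }

    ii <- ii + 1L
    xs[ii] <- state$x; ys[ii] <- state$y
    md[ii] <- state$last_move_mode; dets[ii] <- detected

    if (state$x <= 0) {                      # crossed the source line
      frac <- if (x_prev > state$x) x_prev / (x_prev - state$x) else 1
      rec$crossed <- TRUE
      rec$t_cross <- (k - 1L) * dt + frac * dt
      rec$y_at_cross <- y_prev + frac * (state$y - y_prev)
      xs[ii] <- x_prev + frac * (state$x - x_prev)
      ys[ii] <- rec$y_at_cross
      break
    }
    if (state$x > field$prune_x) { rec$censored <- "escaped_downstream"; break }
  }
  if (!rec$crossed && is.na(rec$censored)) rec$censored <- "max_sim_time"

  # undo the overshoot of the partial final step in the time accumulators
  if (rec$crossed && frac < 1) {
    over <- (1 - frac) * dt
    if (identical(state$last_move_mode, "CAST"))
      state$t_cast <- state$t_cast - over
    else state$t_upwind <- state$t_upwind - over
  }

  rec$n_detections <- state$n_detections
  rec$n_search_cycles <- state$n_search_cycles
  rec$n_counter_turns <- state$n_counter_turns
  rec$t_c_mean <- if (tc_n > 0) tc_sum / tc_n else NA_real_
  rec$search_time <- state$t_cast
  traj <- data.frame(
    t = rec$t_start + (seq_len(ii) - 1L) * dt,
    x = xs[seq_len(ii)], y = ys[seq_len(ii)],
    mode = md[seq_len(ii)], detected = dets[seq_len(ii)]
  )
  if (rec$crossed) traj$t[ii] <- rec$t_cross
  rec <- .fill_metrics(rec, traj)
  if (keep_trajectory) rec$trajectory <- traj
  rec
}

# shared by run_flight and compute_metrics
.fill_metrics <- function(rec, traj) {
  n <- nrow(traj)
  if (n < 2) return(rec)
  dx <- diff(traj$x); dy <- diff(traj$y)
  steps <- sqrt(dx * dx + dy * dy)
  rec$trajectory_length <- sum(steps)
  if (rec$crossed) rec$flight_time <- rec$t_cross - rec$t_start
  rec$search_time <- sum(steps[traj$mode[-1] == "CAST"]) / rec$ground_speed
  # lateral deviation: path integral of the unsigned perpendicular distance
  # from the chord joining the first and last trajectory points, normalized
  # by the squared chord length (dimensionless)
  cx <- traj$x[n] - traj$x[1]; cy <- traj$y[n] - traj$y[1]
  L <- sqrt(cx * cx + cy * cy)
  rec$lateral_deviation <- NA_real_          # degenerate chord stays flagged
  if (L > 0) {
    d <- abs((traj$x - traj$x[1]) * cy - (traj$y - traj$y[1]) * cx) / L
    dmid <- (d[-1] + d[-n]) / 2          # trapezoid along the path
    rec$lateral_deviation <- sum(dmid * steps) / L^2
  }
  rec
}

#' Recompute the metrics of a flight record
#'
#' Computes trajectory length (sum of step displacements), total flight
#' time (first detection to source-line crossing), search time (path time
#' spent casting), and the lateral deviation -- the path integral of the
#' unsigned perpendicular distance from the straight line joining the first
#' and last trajectory points, normalized by the squared length of that
#' line -- from the stored trajectory samples. Event counters
#' (`n_search_cycles`, `n_counter_turns`, `n_detections`) are carried from
#' the record.
#'
#' @param record A [run_flight()] record with `keep_trajectory = TRUE`, or
#'   any list with a `$trajectory` data frame (`t, x, y, mode`), `$crossed`,
#'   `$t_start`, `$t_cross` and `$ground_speed`.
#' @return The record with `trajectory_length`, `flight_time`,
#'   `search_time` and `lateral_deviation` (re)filled. A degenerate
#'   zero-length chord leaves `lateral_deviation` as `NA`.
#' @export
compute_metrics <- function(record) {
  if (is.null(record$trajectory))
    stop("record has no trajectory samples; run with keep_trajectory = TRUE",
         call. = FALSE)
  .fill_metrics(record, record$trajectory)
}

#' Classify a crossed flight as successful
#'
#' A flight is successful iff it crossed the source line `x = 0` with
#' `|y| <= R` (the boundary counts as success). Censored flights are not
#' successful at any radius; fliers that never started are excluded from
#' statistics upstream and may not be classified.
#'
#' @param record A [run_flight()] record.
#' @param R Success radius (m), `> 0`.
#' @return Logical.
#' @export
classify_success <- function(record, R) {
  stopifnot(R > 0)
  if (!record$started)
    stop("flight never started; it is excluded from statistics, not classified",
         call. = FALSE)
  isTRUE(record$crossed) && abs(record$y_at_cross) <= R
}

#' @export
print.flight_record <- function(x, ...) {
  cat("<flight_record>\n")
  if (!x$started) {
    cat(sprintf("  never started (start at x = %.3g, y = %.3g m)\n",
                x$start_x, x$start_y))
    return(invisible(x))
  }
  if (x$crossed)
    cat(sprintf("  crossed x = 0 at y = %+.3f m after %.2f s\n",
                x$y_at_cross, x$flight_time))
  else
    cat(sprintf("  censored (%s)\n", x$censored))
  cat(sprintf("  path %.2f m, search %.2f s, %d cycles, %d counter-turns, %d detections\n",
              x$trajectory_length, x$search_time, x$n_search_cycles,
              x$n_counter_turns, x$n_detections))
  invisible(x)
}
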