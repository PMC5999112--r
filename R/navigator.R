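#' Navigator parameters
#'
#' The navigator is a point agent with a single binary odor sensor and
#' knowledge of the instantaneous wind vector at its own position (optomotor
#' anemotaxis). It flies at a constant ground speed; only the heading is
#' controlled. Two strategies are available:
#' \describe{
#' \item{`crossing_time`}{surge and casting-leg durations equal the most
#'   recently measured puff crossing time `t_c` (the contiguous time the
#'   sensor was above threshold while traversing the last patch);}
#' \item{`internal_counter`}{the identical state machine, but every surge
#'   and casting leg lasts a fixed duration `internal_counter_tau`,
#'   producing a constant-width zigzag regardless of the local puff size.}
#' }
#'
#' @param ground_speed Constant ground speed (m/s), default 0.3.
#' @param alpha_min_deg,alpha_max_deg Counter-turn angle range relative to
#'   the upwind direction (degrees); one angle is drawn uniformly per
#'   casting cycle and kept constant within that cycle. Must satisfy
#'   `0 < alpha_min <= alpha_max < 180`.
#' @param strategy `"crossing_time"` or `"internal_counter"`.
#' @param internal_counter_tau Fixed leg duration (s) for the
#'   internal-counter baseline, `> 0`.
#' @param success_radius_R Radius (m) around the source defining a
#'   successful crossing (used by the experiment layer).
#' @param surge_timer_origin `"exit"` (default): the surge countdown of
#'   duration `t_c` starts when detection is lost, so time spent inside the
#'   patch is not counted against the surge budget. `"entry"`: the countdown
#'   starts at patch entry (the budget is consumed while still inside, so
#'   the post-exit surge lasts only `max(0, t_c - time inside)`).
#' @return An object of class `navigator_params`.
#' @export
navigator_params <- function(ground_speed = 0.3,
                             alpha_min_deg = 30,
                             alpha_max_deg = 120,
                             strategy = c("crossing_time", "internal_counter"),
                             internal_counter_tau = 1,
                             success_radius_R = 0.25,
                             surge_timer_origin = c("exit", "entry")) {
  strategy <- match.arg(strategy)
  surge_timer_origin <- match.arg(surge_timer_origin)
  if (ground_speed <= 0) stop("`ground_speed` must be > 0", call. = FALSE)
  if (!(alpha_min_deg > 0 && alpha_min_deg <= alpha_max_deg &&
        alpha_max_deg < 180))
    stop("need 0 < alpha_min_deg <= alpha_max_deg < 180", call. = FALSE)
  if (strategy == "internal_counter" && internal_counter_tau <= 0)
    stop("`internal_counter_tau` must be > 0", call. = FALSE)
  if (success_radius_R <= 0) stop("`success_radius_R` must be > 0", call. = FALSE)
  structure(
    list(ground_speed = ground_speed,
         alpha_min_deg = alpha_min_deg,
         alpha_max_deg = alpha_max_deg,
         strategy = strategy,
         internal_counter_tau = internal_counter_tau,
         success_radius_R = success_radius_R,
         surge_timer_origin = surge_timer_origin),
    class = "navigator_params"
  )
}

#' @export
print.navigator_params <- function(x, ...) {
  cat("<navigator_params>\n")
  cat(sprintf("  ground speed %.3g m/s, cast angles [%g, %g] deg\n",
              x$ground_speed, x$alpha_min_deg, x$alpha_max_deg))
  cat(sprintf("  strategy: %s%s, surge timer from patch %s\n", x$strategy,
              if (x$strategy == "internal_counter")
                sprintf(" (tau = %.3g s)", x$internal_counter_tau) else "",
              x$surge_timer_origin))
  invisible(x)
}

#' Initial flier state
#'
#' @param x,y Start position (m).
#' @return A `flier_state` list: position, behavioral `mode` (`WAITING`,
#'   `IN_PUFF`, `SURGE` or `CAST`), the last measured crossing time
#'   `t_c_last`, the running stopwatch `time_in_mode`, the current cast
#'   angle and side, and event counters (`n_detections` puff entries,
#'   `n_search_cycles` surge-to-cast transitions, `n_counter_turns` side
#'   flips).
#' @export
flier_state <- function(x, y) {
  structure(
    list(x = x, y = y,
         mode = "WAITING",
         t_c_last = NA_real_,
         time_in_mode = 0,
         cast_angle = NA_real_,
         cast_side = 0L,
         n_detections = 0L,
         n_search_cycles = 0L,
         n_counter_turns = 0L,
         t_cast = 0,         # accumulated casting (search) time
         t_upwind = 0,       # accumulated IN_PUFF + SURGE time
         last_move_mode = NA_character_,
         clock = 0),
    class = "flier_state"
  )
}

#' Advance the navigator state machine by one time step
#'
#' Implements the surge-and-cast flow: a waiting flier starts on first
#' detection; while detecting it flies upwind (180 degrees to the
#' instantaneous wind vector) and accumulates the crossing stopwatch; on
#' losing detection the accumulated contiguous detection time is recorded as
#' `t_c` and an upwind surge of duration `t_c` begins; if no new odor
#' arrives within the surge budget, casting starts -- alternating legs of
#' duration `t_c` at a fixed angle drawn once per cycle uniformly from
#' `[alpha_min, alpha_max]`, first side chosen at random, side flipped at
#' every leg end -- until a new detection restarts the upwind phase. Any
#' moving step displaces the flier by `ground_speed * dt` along the chosen
#' heading; the heading is always defined relative to the *instantaneous*
#' wind passed in, so in gusty or strongly fluctuating wind the flier may
#' momentarily move downwind.
#'
#' Under the `internal_counter` strategy the surge and casting budgets use
#' the fixed `internal_counter_tau` instead of the measured `t_c`.
#'
#' @param state A [flier_state()].
#' @param detected Logical: is the local concentration at or above the
#'   sensor threshold at the current position and time?
#' @param wind Length-2 instantaneous wind vector at the flier position
#'   (m/s). Must be finite; `NaN` wind is a fatal error.
#' @param dt Time step (s), `> 0`.
#' @param params A [navigator_params()].
#' @return The updated state, with `clock` advanced by `dt`.
#' @export
flier_step <- function(state, detected, wind, dt, params) {
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (any(!is.finite(wind))) stop("non-finite wind vector", call. = FALSE)

  mode <- state$mode
  leg_budget <- if (params$strategy == "internal_counter")
    params$internal_counter_tau else state$t_c_last

  # --- transitions driven by the sensor --------------------------------
  if (detected) {
    if (mode != "IN_PUFF") {              # (re-)entering a patch
      state$n_detections <- state$n_detections + 1L
      state$mode <- "IN_PUFF"
      state$time_in_mode <- 0             # crossing stopwatch restarts
      mode <- "IN_PUFF"
    }
  } else if (mode == "IN_PUFF") {         # patch exit: record crossing time
    state$t_c_last <- state$time_in_mode
    leg_budget <- if (params$strategy == "internal_counter")
      params$internal_counter_tau else state$t_c_last
    surge_left <- if (params$surge_timer_origin == "entry")
      max(leg_budget - state$time_in_mode, 0) else leg_budget
    if (surge_left > dt / 2) {
      state$mode <- "SURGE"
      state$time_in_mode <- 0
    } else {
      state <- .start_cast(state, params)
    }
    mode <- state$mode
  }

  # --- movement & timers ------------------------------------------------
  if (mode == "WAITING") {
    state$clock <- state$clock + dt
    return(state)                         # stationary; not an error
  }

  up <- -wind
  nrm <- sqrt(sum(up^2))
  heading <- if (nrm > 0) up / nrm else c(-1, 0)  # degenerate calm wind
  if (mode == "CAST") {
    a <- state$cast_side * state$cast_angle * pi / 180
    heading <- c(cos(a) * heading[1] - sin(a) * heading[2],
                 sin(a) * heading[1] + cos(a) * heading[2])
  }
  state$x <- state$x + params$ground_speed * dt * heading[1]
  state$y <- state$y + params$ground_speed * dt * heading[2]
  state$time_in_mode <- state$time_in_mode + dt
  state$clock <- state$clock + dt
  state$last_move_mode <- mode
  if (mode == "CAST") state$t_cast <- state$t_cast + dt
  else state$t_upwind <- state$t_upwind + dt

  # --- timer expiries ---------------------------------------------------
  if (mode == "SURGE" && state$time_in_mode >= leg_budget - dt / 2) {
    state <- .start_cast(state, params)
  } else if (mode == "CAST" && state$time_in_mode >= leg_budget - dt / 2) {
    state$cast_side <- -state$cast_side   # counter-turn: flip side
    state$n_counter_turns <- state$n_counter_turns + 1L
    state$time_in_mode <- 0               # angle kept within the cycle
  }
  state
}

# Begin a new casting cycle: draw one angle for the whole cycle and a random
# initial side.
.start_cast <- function(state, params) {
  state$mode <- "CAST"
  state$time_in_mode <- 0
  state$cast_angle <- stats::runif(1, params$alpha_min_deg, params$alpha_max_deg)
  state$cast_side <- if (stats::runif(1) < 0.5) -1L else 1L
  state$n_search_cycles <- state$n_search_cycles + 1L
  state
}

#' Measure the puff crossing time from a detection series
#'
#' The crossing time `t_c` is the duration of the last *completed* maximal
#' contiguous run of `TRUE` in a binary detection series sampled at `dt`
#' resolution (a run still open at the end of the series has not been
#' completed and cannot yet be measured).
#'
#' @param detections Logical vector, detection at each step.
#' @param dt Sampling interval (s).
#' @return `t_c = (run length) * dt` (s), or `NA` if no completed run
#'   exists.
#' @examples
#' measure_crossing_time(c(FALSE, TRUE, TRUE, TRUE, FALSE), dt = 0.1)
#' @export
measure_crossing_time <- function(detections, dt) {
  stopifnot(is.logical(detections), dt > 0)
  r <- rle(detections)
  true_runs <- which(r$values)
  # drop a run that is still open at the end of the series
  if (length(true_runs) && true_runs[length(true_runs)] == length(r$values))
    true_runs <- true_runs[-length(true_runs)]
  if (!length(true_runs)) return(NA_real_)
  r$lengths[true_runs[length(true_runs)]] * dt
}
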