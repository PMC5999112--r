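#' Construct a stochastic wind model
#'
#' The instantaneous planar wind is decomposed by time scale into a constant
#' streamwise mean `U`, intermittent gusts `U_g(t)` (step changes held for
#' ~10 s that occur a few times per run), a slow sinusoidal cross-stream
#' meander `V_m(t)` (~100 s period), and white turbulent fluctuations
#' `u', v'` redrawn independently at every call:
#' \deqn{u = U + U_g(t) + u', \qquad v = V_m(t) + v'.}
#' The fluctuation level is set by the turbulence intensity
#' `TI = u'_rms / U`, identical in both components, and does not depend on
#' the gust or meander state.
#'
#' @param U_mean Streamwise mean wind speed (m/s), `> 0`.
#' @param turbulence_intensity Ratio of rms fluctuation to mean wind
#'   (dimensionless, `>= 0`).
#' @param gust_enabled,gust_amplitude_frac,gust_hold_s,gust_rate_per_run
#'   Gust process settings: on/off flag, maximum `|U_g|/U` (must lie in
#'   `[0, 0.5]`), hold duration of each gust (s), and the expected number of
#'   gust events per run.
#' @param meander_enabled,meander_amplitude,meander_period_s Meander
#'   settings: on/off flag, peak `|V_m|/U` (dimensionless), and modulation
#'   period (s, `> 0`).
#' @return An object of class `wind_model`. Gusts must be realized with
#'   [realize_wind()] before [gust_process()] or [sample_wind()] are used
#'   with gusts enabled.
#' @seealso [sample_wind()], [gust_process()], [meander_process()]
#' @examples
#' w <- wind_model(U_mean = 1, turbulence_intensity = 0.15)
#' sample_wind(c(5, 0), t = 3, w)
#' @export
wind_model <- function(U_mean = 1,
                       turbulence_intensity = 0.15,
                       gust_enabled = FALSE,
                       gust_amplitude_frac = 0.5,
                       gust_hold_s = 10,
                       gust_rate_per_run = 3,
                       meander_enabled = FALSE,
                       meander_amplitude = 0.2,
                       meander_period_s = 100) {
  if (!is.numeric(U_mean) || U_mean <= 0)
    stop("`U_mean` must be > 0", call. = FALSE)
  if (!is.numeric(turbulence_intensity) || turbulence_intensity < 0)
    stop("`turbulence_intensity` must be >= 0", call. = FALSE)
  if (gust_amplitude_frac < 0 || gust_amplitude_frac > 0.5)
    stop("`gust_amplitude_frac` must lie in [0, 0.5]", call. = FALSE)
  if (meander_period_s <= 0)
    stop("`meander_period_s` must be > 0", call. = FALSE)
  if (gust_hold_s <= 0)
    stop("`gust_hold_s` must be > 0", call. = FALSE)
  structure(
    list(
      U_mean = U_mean,
      turbulence_intensity = turbulence_intensity,
      gust_enabled = isTRUE(gust_enabled),
      gust_amplitude_frac = gust_amplitude_frac,
      gust_hold_s = gust_hold_s,
      gust_rate_per_run = gust_rate_per_run,
      meander_enabled = isTRUE(meander_enabled),
      meander_amplitude = meander_amplitude,
      meander_period_s = meander_period_s,
      gusts = NULL   # realized schedule: data.frame(t_on, t_off, amplitude)
    ),
    class = "wind_model"
  )
}

#' @export
print.wind_model <- function(x, ...) {
  cat("<wind_model>\n")
  cat(sprintf("  U = %.3g m/s, TI = %.3g\n", x$U_mean, x$turbulence_intensity))
  cat(sprintf("  gusts: %s", if (x$gust_enabled) "on" else "off"))
  if (x$gust_enabled)
    cat(sprintf(" (|Ug| <= %.2g U, hold %.3g s, ~%.3g per run%s)",
                x$gust_amplitude_frac, x$gust_hold_s, x$gust_rate_per_run,
                if (is.null(x$gusts)) ", not realized" else ", realized"))
  cat("\n")
  cat(sprintf("  meander: %s", if (x$meander_enabled) "on" else "off"))
  if (x$meander_enabled)
    cat(sprintf(" (|Vm| <= %.2g U, period %.3g s)",
                x$meander_amplitude, x$meander_period_s))
  cat("\n")
  invisible(x)
}

#' Realize the gust schedule of a wind model
#'
#' Gust events arrive as a Poisson process with expectation
#' `gust_rate_per_run` over `[0, duration]`; each holds a constant amplitude
#' drawn from `Uniform(-a, a) * U_mean` (with `a = gust_amplitude_frac`) for
#' `gust_hold_s` seconds. The schedule is drawn once per run so that
#' [gust_process()] is a deterministic step function afterwards. Draws use
#' the current RNG state; seed with [set.seed()] (or [child_seed()]) first.
#'
#' @param model A [wind_model()].
#' @param duration Run length (s) over which gust onsets may occur.
#' @return The model with a realized `$gusts` schedule.
#' @export
realize_wind <- function(model, duration) {
  stopifnot(inherits(model, "wind_model"), duration >= 0)
  if (!model$gust_enabled) {
    model$gusts <- data.frame(t_on = numeric(0), t_off = numeric(0),
                              amplitude = numeric(0))
    return(model)
  }
  n <- stats::rpois(1, model$gust_rate_per_run)
  t_on <- sort(stats::runif(n, 0, duration))
  amp <- stats::runif(n, -1, 1) * model$gust_amplitude_frac * model$U_mean
  # overlapping gusts would stack beyond the +/-50% bound: later onset wins
  t_off <- t_on + model$gust_hold_s
  if (n > 1) for (i in seq_len(n - 1)) t_off[i] <- min(t_off[i], t_on[i + 1])
  model$gusts <- data.frame(t_on = t_on, t_off = t_off, amplitude = amp)
  model
}

#' Gust speed offset at time t
#'
#' Piecewise-constant streamwise offset `U_g(t)` from the realized schedule;
#' zero outside gust intervals and zero everywhere when gusts are disabled.
#'
#' @param t Time(s) (s); vectorized.
#' @param model A [wind_model()], realized via [realize_wind()] if gusts are
#'   enabled.
#' @return `U_g(t)` (m/s), same length as `t`.
#' @export
gust_process <- function(t, model) {
  stopifnot(inherits(model, "wind_model"))
  if (!model$gust_enabled) return(numeric(length(t)))
  if (is.null(model$gusts))
    stop("gusts enabled but schedule not realized; call realize_wind()",
         call. = FALSE)
  out <- numeric(length(t))
  g <- model$gusts
  for (i in seq_len(nrow(g))) {
    inside <- t >= g$t_on[i] & t < g$t_off[i]
    out[inside] <- g$amplitude[i]
  }
  out
}

#' Meander cross-stream speed at time t
#'
#' Slow sinusoidal modulation of the wind direction, identical everywhere in
#' the field: `V_m(t) = amplitude * U_mean * sin(2 pi t / period)`.
#'
#' @inheritParams gust_process
#' @return `V_m(t)` (m/s), same length as `t`.
#' @export
meander_process <- function(t, model) {
  stopifnot(inherits(model, "wind_model"))
  if (!model$meander_enabled) return(numeric(length(t)))
  model$meander_amplitude * model$U_mean *
    sin(2 * pi * t / model$meander_period_s)
}

#' Sample the instantaneous wind vector
#'
#' Returns `(U + U_g(t) + u', V_m(t) + v')` where `u', v'` are independent
#' zero-mean Gaussian draws with standard deviation
#' `turbulence_intensity * U_mean`, redrawn at every call: the fluctuations
#' are white in time and uncorrelated in space on the scales of the flier,
#' and their statistics do not depend on the gust or meander state.
#'
#' @param position Length-2 numeric `(x, y)` (m). The fluctuation field is
#'   spatially uncorrelated, so the value only matters for the caller's
#'   bookkeeping.
#' @param t Time (s), `>= 0`.
#' @param model A [wind_model()] (realized if gusts are enabled).
#' @return Length-2 numeric velocity `(u, v)` (m/s).
#' @export
sample_wind <- function(position, t, model) {
  stopifnot(inherits(model, "wind_model"), t >= 0, length(position) == 2)
  sd <- model$turbulence_intensity * model$U_mean
  fl <- if (sd > 0) stats::rnorm(2, 0, sd) else c(0, 0)
  c(model$U_mean + gust_process(t, model) + fl[1],
    meander_process(t, model) + fl[2])
}
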