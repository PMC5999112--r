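#' Construct a Gaussian-puff plume model
#'
#' A pulsating point source at the origin releases one instantaneous odor
#' parcel ("puff") of mass `m` every `T` seconds. Each puff is advected by
#' the wind and grows with age `a = t - t_i` as
#' `sigma_{h,z}(a) = A_{h,z} a^{B_{h,z}}` (with `B ~ 1` for practical
#' atmospheric conditions, and a small floor `sigma_floor` so a newborn puff
#' has finite size). The concentration of a single puff is a normalized
#' trivariate Gaussian
#' \deqn{C(r) = \frac{m}{(2\pi)^{3/2}\sigma_h^2\sigma_z}
#'       \exp\left(-\frac{|r - r_p|^2}{2\sigma_h^2}\right) F_z,}
#' evaluated on the flight plane of the source, so the vertical factor
#' `F_z = exp(-z0^2 / (2 sigma_z^2))` is 1 for a ground-level release
#' (`z0 = 0`) while `sigma_z` is kept in the prefactor (peak concentration
#' decays as age^-3). The total field is the superposition of all released
#' puffs, and a binary sensor reports detection wherever the field is at or
#' above the threshold `C*`.
#'
#' The growth coefficients default to `A_h = A_z = a_scale * TI * U`:
#' proportional to the turbulence intensity (which sets the dispersion), with
#' a calibrated fraction `a_scale < 1` because only eddies smaller than a
#' puff contribute to its internal (relative) dispersion; see
#' [calibrate_plume()].
#'
#' @param pulse_interval_T Time between releases (s), `> 0`.
#' @param mass_per_pulse_m Odor mass per pulse (arbitrary mass units), `> 0`.
#' @param A_h,A_z Growth-rate coefficients (m/s), `> 0`.
#' @param B_h,B_z Growth exponents (dimensionless), default 1.
#' @param release_height_z0 Source height (m); 0 places source and flier in
#'   the same plane.
#' @param threshold_Cstar Lowest detectable concentration (mass/m^3), `> 0`.
#' @param sigma_floor Minimal puff size (m) at age 0.
#' @param form `"standard"` (default) uses the vertical factor
#'   `exp(-z0^2/(2 sigma_z^2))` of a normalized Gaussian; `"printed"` keeps
#'   the variant `exp(-z0^2/sigma_z^2)` for fidelity experiments. Identical
#'   when `z0 = 0`.
#' @return An object of class `plume_model`.
#' @examples
#' p <- plume_model(A_h = 0.05, A_z = 0.05, threshold_Cstar = 0.01)
#' puff_sigma(10, p)
#' @export
plume_model <- function(pulse_interval_T = 1,
                        mass_per_pulse_m = 1,
                        A_h = 0.019,
                        A_z = A_h,
                        B_h = 1,
                        B_z = 1,
                        release_height_z0 = 0,
                        threshold_Cstar = 0.588,
                        sigma_floor = 0.01,
                        form = c("standard", "printed")) {
  form <- match.arg(form)
  if (pulse_interval_T <= 0) stop("`pulse_interval_T` must be > 0", call. = FALSE)
  if (mass_per_pulse_m <= 0) stop("`mass_per_pulse_m` must be > 0", call. = FALSE)
  if (A_h <= 0 || A_z <= 0) stop("`A_h` and `A_z` must be > 0", call. = FALSE)
  if (threshold_Cstar <= 0) stop("`threshold_Cstar` must be > 0", call. = FALSE)
  if (sigma_floor <= 0) stop("`sigma_floor` must be > 0", call. = FALSE)
  structure(
    list(pulse_interval_T = pulse_interval_T,
         mass_per_pulse_m = mass_per_pulse_m,
         A_h = A_h, A_z = A_z, B_h = B_h, B_z = B_z,
         release_height_z0 = release_height_z0,
         threshold_Cstar = threshold_Cstar,
         sigma_floor = sigma_floor,
         form = form),
    class = "plume_model"
  )
}

#' @export
print.plume_model <- function(x, ...) {
  cat("<plume_model>\n")
  cat(sprintf("  T = %.3g s, m = %.3g, C* = %.4g\n",
              x$pulse_interval_T, x$mass_per_pulse_m, x$threshold_Cstar))
  cat(sprintf("  sigma_h = %.4g age^%.3g, sigma_z = %.4g age^%.3g (floor %.3g m)\n",
              x$A_h, x$B_h, x$A_z, x$B_z, x$sigma_floor))
  cat(sprintf("  z0 = %.3g m, form = %s\n", x$release_height_z0, x$form))
  invisible(x)
}

#' Release times of the pulsating source
#'
#' @param t_end End of the release window (s), `>= 0`.
#' @param model A [plume_model()].
#' @return Numeric vector `{0, T, 2T, ...} <= t_end`; each time stamps one
#'   puff released at the origin.
#' @export
release_schedule <- function(t_end, model) {
  stopifnot(inherits(model, "plume_model"), t_end >= 0)
  seq(0, t_end, by = model$pulse_interval_T)
}

#' Puff sizes as a function of age
#'
#' @param age Puff age(s) (s), `>= 0`; vectorized.
#' @param model A [plume_model()].
#' @return A list with components `sigma_h` and `sigma_z` (m); both are
#'   `A age^B` floored at `sigma_floor` (a newborn puff has a small finite
#'   size, never zero).
#' @export
puff_sigma <- function(age, model) {
  stopifnot(inherits(model, "plume_model"))
  if (any(age < 0))
    stop("negative puff age: puff queried before its release", call. = FALSE)
  list(sigma_h = pmax(model$A_h * age^model$B_h, model$sigma_floor),
       sigma_z = pmax(model$A_z * age^model$B_z, model$sigma_floor))
}

# Single-puff peak (center) concentration at a given age, on the flight
# plane. Internal helper shared by concentration_at / detectable_radius.
.puff_peak <- function(age, model) {
  s <- puff_sigma(age, model)
  fz <- if (model$release_height_z0 == 0) 1 else {
    if (model$form == "printed")
      exp(-model$release_height_z0^2 / s$sigma_z^2)
    else
      exp(-model$release_height_z0^2 / (2 * s$sigma_z^2))
  }
  model$mass_per_pulse_m / ((2 * pi)^1.5 * s$sigma_h^2 * s$sigma_z) * fz
}

#' Odor concentration at a point
#'
#' Superposition of all released puffs: each contributes its normalized
#' Gaussian evaluated at the horizontal distance between `point` and the
#' puff center, using the sizes implied by its age at time `t`.
#'
#' @param point Length-2 numeric `(x, y)` (m).
#' @param t Time (s).
#' @param puffs A data frame with columns `release_time`, `x`, `y` (one row
#'   per puff, centers advected to time `t`); see [advect_puffs()].
#' @param model A [plume_model()].
#' @return Concentration (mass/m^3), `>= 0`. Puffs not yet released
#'   (`release_time > t`) contribute nothing.
#' @export
concentration_at <- function(point, t, puffs, model) {
  stopifnot(inherits(model, "plume_model"), length(point) == 2)
  if (nrow(puffs) == 0) return(0)
  live <- puffs$release_time <= t
  if (!any(live)) return(0)
  age <- t - puffs$release_time[live]
  s <- puff_sigma(age, model)
  peak <- .puff_peak(age, model)
  d2 <- (puffs$x[live] - point[1])^2 + (puffs$y[live] - point[2])^2
  sum(peak * exp(-d2 / (2 * s$sigma_h^2)))
}

#' Binary odor detection at a point
#'
#' @inheritParams concentration_at
#' @return `TRUE` iff [concentration_at()] is at or above the detection
#'   threshold `C*` (the boundary case counts as detected).
#' @export
detect <- function(point, t, puffs, model) {
  concentration_at(point, t, puffs, model) >= model$threshold_Cstar
}

#' Detectable radius of a single puff
#'
#' Radius of the `C = C*` isoline of one puff of the given age:
#' `rho = sigma_h sqrt(2 ln(C_peak / C*))` when the peak is still above
#' threshold, `NA` once the puff has become undetectable (it never becomes
#' detectable again for monotone growth, which justifies pruning).
#'
#' @param age Puff age(s) (s), `>= 0`; vectorized.
#' @param model A [plume_model()].
#' @return Radius (m), or `NA` where the puff is undetectable.
#' @export
detectable_radius <- function(age, model) {
  stopifnot(inherits(model, "plume_model"))
  s <- puff_sigma(age, model)
  peak <- .puff_peak(age, model)
  ratio <- peak / model$threshold_Cstar
  out <- ifelse(ratio >= 1, s$sigma_h * sqrt(2 * pmax(log(ratio), 0)), NA_real_)
  out
}

#' Advect puff centers by one time step
#'
#' Moves every puff center by `sample_wind(center, t) * dt`; each puff sees
#' an independent fluctuation draw (the turbulence is uncorrelated between
#' locations), while gust and meander offsets are shared.
#'
#' @param puffs Data frame with columns `release_time`, `x`, `y`. Only puffs
#'   already released (`release_time <= t`) are moved.
#' @param wind A [wind_model()] (realized if gusts are enabled).
#' @param t Current time (s).
#' @param dt Time step (s), `> 0`.
#' @return The updated `puffs` data frame.
#' @export
advect_puffs <- function(puffs, wind, t, dt) {
  stopifnot(inherits(wind, "wind_model"), dt > 0)
  live <- which(puffs$release_time <= t)
  n <- length(live)
  if (n == 0) return(puffs)
  sd <- wind$turbulence_intensity * wind$U_mean
  ux <- wind$U_mean + gust_process(t, wind) +
    (if (sd > 0) stats::rnorm(n, 0, sd) else 0)
  vy <- meander_process(t, wind) +
    (if (sd > 0) stats::rnorm(n, 0, sd) else 0)
  puffs$x[live] <- puffs$x[live] + ux * dt
  puffs$y[live] <- puffs$y[live] + vy * dt
  puffs
}

#' Calibrate the free plume parameters
#'
#' The pulse interval, mass, dispersion coefficients and sensor threshold
#' are free parameters of the model. This utility fixes the two that shape
#' the navigation problem -- the growth coefficient scale and the detection
#' threshold -- from two geometric anchors of the patchy-plume picture, at a
#' reference turbulence intensity:
#' \itemize{
#' \item \strong{reach anchor}: the detection reach (largest downwind
#'   distance at which an arriving puff is still detectable,
#'   `U x age_max`) equals `reach_x` at the reference TI. With
#'   `A = a_scale TI U` the reach scales as `1/TI`, so at the reference
#'   value of 25 m the whole 6--20 m start band is inside the plume at low
#'   and intermediate turbulence while at the highest intensities the
#'   plume dies out within the band and only closer fliers can start --
#'   which is what couples flight statistics to turbulence intensity;
#' \item \strong{patchiness anchor}: the maximum detectable diameter a puff
#'   ever attains equals `patch_frac` times the pulse spacing `U T`, so
#'   consecutive puffs separate into discrete patches with clean-air gaps
#'   near the source and near the detection edge -- the regime in which a
#'   puff crossing time is measurable at all.
#' }
#' Solving both gives the coefficient `A_ref` at the reference TI (hence
#' `a_scale = A_ref / (TI_ref U)`, applied as `A = a_scale TI U` at any
#' other turbulence intensity) and the threshold `C*`. Because
#' `A x age_max` is fixed by the anchors, the detectable-radius profile is
#' self-similar across TI: patch geometry as a function of the fractional
#' distance to the reach is identical, only stretched in space.
#'
#' @param U_mean Mean wind speed (m/s).
#' @param ti_ref Reference turbulence intensity for the anchors.
#' @param pulse_interval_T Pulse interval (s).
#' @param mass_per_pulse_m Mass per pulse.
#' @param reach_x Detection reach (m) at the reference TI.
#' @param patch_frac Maximum detectable puff diameter a puff ever attains,
#'   as a fraction of the pulse spacing (default 1: patches at their
#'   largest just touch, so the plume has clean-air gaps near the source
#'   and the far edge and near-connected stretches in between).
#' @return A list with `a_scale`, `A_ref`, `threshold_Cstar`, `age_max_ref`
#'   (age at which a reference-TI puff becomes undetectable) and the
#'   anchors.
#' @examples
#' calibrate_plume()
#' @export
calibrate_plume <- function(U_mean = 1,
                            ti_ref = 0.15,
                            pulse_interval_T = 1,
                            mass_per_pulse_m = 1,
                            reach_x = 25,
                            patch_frac = 1.0) {
  stopifnot(U_mean > 0, ti_ref > 0, pulse_interval_T > 0,
            mass_per_pulse_m > 0, reach_x > 0, patch_frac > 0)
  # With sigma = A age (B = 1) and peak = m / ((2 pi)^{3/2} A^3 age^3), a
  # puff becomes undetectable at age_max where peak = C*; the detectable
  # radius rho(age) = A age sqrt(6 ln(age_max / age)) attains its maximum
  # A age_max sqrt(3) e^{-1/2} at age = age_max e^{-1/2}.
  age_max <- reach_x / U_mean
  rho_max <- patch_frac * U_mean * pulse_interval_T / 2
  A_ref <- rho_max / (sqrt(3) * exp(-0.5) * age_max)
  Cstar <- mass_per_pulse_m / ((2 * pi)^1.5 * (A_ref * age_max)^3)
  list(a_scale = A_ref / (ti_ref * U_mean),
       A_ref = A_ref,
       threshold_Cstar = Cstar,
       age_max_ref = age_max,
       ti_ref = ti_ref, U_mean = U_mean,
       reach_x = reach_x,
       patch_frac = patch_frac,
       pulse_interval_T = pulse_interval_T,
       mass_per_pulse_m = mass_per_pulse_m)
}
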