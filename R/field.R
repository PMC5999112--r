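#' Simulate a turbulence/plume field realization
#'
#' Realizes one stochastic wind history (gust schedule, meander phase) and
#' the trajectories of every puff released over the simulation horizon, on a
#' fixed time grid. Because the turbulent fluctuations are white in time and
#' uncorrelated in space, each puff trajectory is an independent random walk
#' superposed on the shared mean/gust/meander advection and can be
#' precomputed once; many navigator flights can then be run cheaply against
#' the same frozen field (the Monte-Carlo design of the experiment layer).
#'
#' Puffs are pruned once their single-puff peak concentration falls below
#' the detection threshold (they can never become detectable again for
#' monotone growth) or once their center passes `prune_x` downwind of the
#' source, which keeps the live-puff count bounded.
#'
#' @param wind A [wind_model()].
#' @param plume A [plume_model()].
#' @param horizon_s Total simulated time (s): spin-up plus the maximum
#'   flight window.
#' @param dt Time step (s).
#' @param prune_x Downwind pruning distance (m); should exceed the largest
#'   flier start distance by a margin.
#' @param seed Optional integer seed for this field's random stream (gust
#'   schedule and puff advection). `NULL` uses the current RNG state.
#' @return An object of class `plume_field`.
#' @export
simulate_field <- function(wind, plume, horizon_s, dt = 0.02,
                           prune_x = 25, seed = NULL) {
  stopifnot(inherits(wind, "wind_model"), inherits(plume, "plume_model"),
            horizon_s > 0, dt > 0, dt < plume$pulse_interval_T)
  if (!is.null(seed)) set.seed(seed)

  n_steps <- floor(horizon_s / dt) + 1L
  times <- (seq_len(n_steps) - 1) * dt

  wind <- realize_wind(wind, horizon_s)
  Ug <- gust_process(times, wind)
  Vm <- meander_process(times, wind)

  releases <- release_schedule(horizon_s, plume)
  birth <- as.integer(round(releases / dt)) + 1L
  birth <- birth[birth <= n_steps]
  n_puffs <- length(birth)

  # age (s) at which a lone puff's peak drops below C*; Inf if never
  age_undet <- .age_undetectable(plume)
  life_cap <- if (is.finite(age_undet)) as.integer(ceiling(age_undet / dt)) + 1L
              else n_steps
  # generous advection-time cap: even against a -50% gust the center covers
  # prune_x well within 2 * prune_x / U
  adv_cap <- as.integer(ceiling(2 * prune_x / wind$U_mean / dt)) + 1L

  sd_fl <- wind$turbulence_intensity * wind$U_mean
  traj <- vector("list", n_puffs)
  life <- integer(n_puffs)
  for (i in seq_len(n_puffs)) {
    n_i <- min(life_cap, adv_cap, n_steps - birth[i] + 1L)
    ks <- birth[i] + seq_len(n_i) - 1L   # global steps occupied
    if (n_i == 1L) {
      traj[[i]] <- list(x = 0, y = 0); life[i] <- 1L; next
    }
    ux <- wind$U_mean + Ug[ks[-n_i]] +
      (if (sd_fl > 0) stats::rnorm(n_i - 1L, 0, sd_fl) else 0)
    vy <- Vm[ks[-n_i]] +
      (if (sd_fl > 0) stats::rnorm(n_i - 1L, 0, sd_fl) else 0)
    x <- c(0, cumsum(ux * dt))
    y <- c(0, cumsum(vy * dt))
    gone <- which(x > prune_x)
    if (length(gone)) {
      n_i <- gone[1]
      x <- x[seq_len(n_i)]; y <- y[seq_len(n_i)]
    }
    traj[[i]] <- list(x = x, y = y)
    life[i] <- n_i
  }
  max_life <- max(life)
  px <- matrix(NA_real_, n_puffs, max_life)
  py <- matrix(NA_real_, n_puffs, max_life)
  for (i in seq_len(n_puffs)) {
    px[i, seq_len(life[i])] <- traj[[i]]$x
    py[i, seq_len(life[i])] <- traj[[i]]$y
  }
  death <- birth + life - 1L

  # per-column (age) lookups shared by all puffs
  ages <- (seq_len(max_life) - 1) * dt
  s <- puff_sigma(ages, plume)
  peak <- .puff_peak(ages, plume)
  # distance beyond which a puff's contribution is < 1e-10 C*: used by the
  # waiting-phase scan; the moving-phase loop sums all live puffs exactly
  eps <- 1e-10 * plume$threshold_Cstar
  dcut <- s$sigma_h * sqrt(2 * pmax(log(peak / eps), 0))

  # fast alive-range bounds: puffs born by step k, not all dead before k
  hib <- findInterval(seq_len(n_steps), birth)
  cmd <- cummax(death)
  lob <- findInterval(seq_len(n_steps) - 0.5, cmd) + 1L

  # per-puff sorted x-track for the waiting-phase scan
  ord <- vector("list", n_puffs)
  pxs <- vector("list", n_puffs)
  for (i in seq_len(n_puffs)) {
    o <- order(traj[[i]]$x)
    ord[[i]] <- o
    pxs[[i]] <- traj[[i]]$x[o]
  }

  structure(
    list(wind = wind, plume = plume,
         dt = dt, n_steps = n_steps, horizon_s = horizon_s,
         prune_x = prune_x, seed = seed,
         Ug = Ug, Vm = Vm,
         birth = birth, life = life, death = death,
         px = px, py = py,
         sigma_h = s$sigma_h, peak = peak, dcut = dcut,
         dcut_cummax = cummax(dcut),
         lob = lob, hib = hib,
         ord = ord, px_sorted = pxs,
         n_puffs = n_puffs),
    class = "plume_field"
  )
}

# age at which the single-puff peak falls to C* (Inf if it never does)
.age_undetectable <- function(plume) {
  if (.puff_peak(0, plume) < plume$threshold_Cstar) return(0)
  upper <- 10
  while (.puff_peak(upper, plume) >= plume$threshold_Cstar && upper < 1e7)
    upper <- upper * 2
  if (upper >= 1e7) return(Inf)
  stats::uniroot(function(a) .puff_peak(a, plume) - plume$threshold_Cstar,
                 lower = upper / 2, upper = upper, tol = 1e-10)$root
}

#' @export
print.plume_field <- function(x, ...) {
  cat("<plume_field>\n")
  cat(sprintf("  %d puffs over %.4g s (dt = %.3g s), pruned at x > %.3g m\n",
              x$n_puffs, x$horizon_s, x$dt, x$prune_x))
  cat(sprintf("  TI = %.3g, U = %.3g m/s, gusts %s, meander %s\n",
              x$wind$turbulence_intensity, x$wind$U_mean,
              if (x$wind$gust_enabled) "on" else "off",
              if (x$wind$meander_enabled) "on" else "off"))
  invisible(x)
}

#' Snapshot of live puffs at a time
#'
#' @param field A [simulate_field()] result.
#' @param t Time (s) in `[0, horizon_s]`; snapped to the field's grid.
#' @return A data frame with columns `release_time`, `x`, `y` of all puffs
#'   released by `t` and not yet pruned, compatible with
#'   [concentration_at()] and [detect()].
#' @export
field_puffs <- function(field, t) {
  stopifnot(inherits(field, "plume_field"))
  k <- as.integer(round(t / field$dt)) + 1L
  stopifnot(k >= 1, k <= field$n_steps)
  idx <- which(field$birth <= k & field$death >= k)
  j <- k - field$birth[idx] + 1L
  data.frame(release_time = (field$birth[idx] - 1L) * field$dt,
             x = field$px[cbind(idx, j)],
             y = field$py[cbind(idx, j)])
}

#' Concentration in a realized field
#'
#' Same superposition as [concentration_at()], evaluated against the
#' precomputed puff tracks of a field at a grid step.
#'
#' @param field A [simulate_field()] result.
#' @param point Length-2 numeric `(x, y)` (m).
#' @param step Grid step index (1-based; time `(step - 1) * dt`).
#' @return Concentration (mass/m^3).
#' @export
field_concentration <- function(field, point, step) {
  stopifnot(inherits(field, "plume_field"),
            step >= 1, step <= field$n_steps)
  k <- as.integer(step)
  i1 <- field$lob[k]; i2 <- field$hib[k]
  if (i2 < i1) return(0)
  cand <- i1:i2
  cand <- cand[field$death[cand] >= k]
  if (!length(cand)) return(0)
  j <- k - field$birth[cand] + 1L
  dx <- field$px[cbind(cand, j)] - point[1]
  dy <- field$py[cbind(cand, j)] - point[2]
  sum(field$peak[j] * exp(-(dx * dx + dy * dy) / (2 * field$sigma_h[j]^2)))
}

# First grid step >= `from` at which the summed concentration at the fixed
# point (x0, y0) reaches the threshold, or NA. Deterministic (no RNG): used
# to skip the waiting phase of a flight in O(total track length) instead of
# stepping. Contributions below 1e-10 C* per puff are truncated, which can
# only delay the reported onset across an astronomically thin boundary band.
.first_detection_step <- function(field, x0, y0, from = 1L) {
  buf <- numeric(field$n_steps)
  Cs <- field$plume$threshold_Cstar
  for (i in seq_len(field$n_puffs)) {
    D <- field$dcut_cummax[field$life[i]]
    rng <- findInterval(c(x0 - D, x0 + D), field$px_sorted[[i]])
    if (rng[2] <= rng[1]) next
    cols <- field$ord[[i]][(rng[1] + 1L):rng[2]]
    dyv <- field$py[i, cols] - y0
    dc <- field$dcut[cols]
    keep <- abs(dyv) <= dc
    if (!any(keep)) next
    cols <- cols[keep]; dyv <- dyv[keep]
    dxv <- field$px[i, cols] - x0
    contrib <- field$peak[cols] *
      exp(-(dxv * dxv + dyv * dyv) / (2 * field$sigma_h[cols]^2))
    gk <- field$birth[i] + cols - 1L
    buf[gk] <- buf[gk] + contrib
  }
  hits <- which(buf >= Cs)
  hits <- hits[hits >= from]
  if (length(hits)) hits[1] else NA_integer_
}
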