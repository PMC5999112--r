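test_that("release schedule is {0, T, ..} <= t_end", {
  p <- plume_model(pulse_interval_T = 1)
  expect_equal(release_schedule(3.5, p), c(0, 1, 2, 3))
  expect_equal(release_schedule(0, p), 0)
  # brute-force enumeration oracle over random (T, t_end)
  set.seed(1)
  for (i in 1:100) {
    T <- runif(1, 0.1, 5); t_end <- runif(1, 0, 50)
    sched <- release_schedule(t_end, plume_model(pulse_interval_T = T))
    expect_equal(length(sched), floor(t_end / T) + 1)
    expect_equal(diff(sched), rep(T, length(sched) - 1), tolerance = 1e-12)
  }
  expect_error(plume_model(pulse_interval_T = 0), "pulse_interval_T")
})

test_that("puff sizes grow linearly from the floor", {
  p <- plume_model(A_h = 0.05, A_z = 0.05, B_h = 1, sigma_floor = 0.01)
  expect_equal(puff_sigma(10, p)$sigma_h, 0.5)
  expect_equal(puff_sigma(0, p)$sigma_h, 0.01)   # floored, never zero
  # B = 1 linearity above the floor
  for (a in c(0.5, 2, 7)) {
    expect_equal(puff_sigma(2 * a, p)$sigma_h, 2 * puff_sigma(a, p)$sigma_h)
  }
  expect_error(puff_sigma(-1, p), "negative")
})

test_that("single-puff concentration has the Gaussian closed form", {
  # sigma_h = sigma_z = 0.5, m = 1: center value 1 / ((2 pi)^{3/2} 0.25 0.5)
  p <- plume_model(A_h = 0.05, A_z = 0.05, threshold_Cstar = 1e-6)
  puffs <- data.frame(release_time = 0, x = 3, y = 0)
  c0 <- concentration_at(c(3, 0), 10, puffs, p)
  expect_equal(c0, 1 / ((2 * pi)^1.5 * 0.25 * 0.5), tolerance = 1e-12)
  # Gaussian shape: value at one sigma_h is e^{-1/2} of the center
  c1 <- concentration_at(c(3.5, 0), 10, puffs, p)
  expect_equal(c1 / c0, exp(-0.5), tolerance = 1e-12)
  # superposition: two co-located puffs double the field
  both <- rbind(puffs, puffs)
  expect_equal(concentration_at(c(3.2, 0.1), 10, both, p),
               2 * concentration_at(c(3.2, 0.1), 10, puffs, p))
  # unreleased puffs contribute nothing
  expect_equal(concentration_at(c(3, 0), 10,
                                data.frame(release_time = 11, x = 3, y = 0), p),
               0)
})

test_that("a puff integrates to its released mass", {
  p <- plume_model(A_h = 0.04, A_z = 0.07, mass_per_pulse_m = 1.7,
                   threshold_Cstar = 1e-9)
  age <- 8
  s <- puff_sigma(age, p)
  puffs <- data.frame(release_time = 0, x = 0, y = 0)
  # planar quadrature of the implemented field (trapezoid on a fine grid)
  h <- s$sigma_h / 25
  g <- seq(-8 * s$sigma_h, 8 * s$sigma_h, by = h)
  plane <- 0
  for (yy in g)
    plane <- plane + sum(vapply(g, function(xx)
      concentration_at(c(xx, yy), age, puffs, p), 0)) * h * h
  # the vertical profile is Gaussian with sd sigma_z: total 3-D mass
  mass <- plane * sqrt(2 * pi) * s$sigma_z
  expect_equal(mass, 1.7, tolerance = 1e-3)
})

test_that("detection threshold uses the >= convention", {
  puffs <- data.frame(release_time = 0, x = 0, y = 0)
  age <- 10
  p <- plume_model(A_h = 0.05, A_z = 0.05, threshold_Cstar = 0.1)
  conc <- concentration_at(c(0.3, 0.1), age, puffs, p)
  # threshold set to the exact local value: the boundary case is detected
  p_eq <- plume_model(A_h = 0.05, A_z = 0.05, threshold_Cstar = conc)
  expect_true(detect(c(0.3, 0.1), age, puffs, p_eq))
  p_above <- plume_model(A_h = 0.05, A_z = 0.05,
                         threshold_Cstar = conc * 2)
  expect_false(detect(c(0.3, 0.1), age, puffs, p_above))
  # half the threshold is undetectable by a wide margin
  expect_false(detect(c(0.3, 0.1), age, puffs,
                      plume_model(A_h = 0.05, A_z = 0.05,
                                  threshold_Cstar = conc * 2)))
})

test_that("detectable radius inverts the Gaussian and agrees with detect", {
  set.seed(33)
  for (i in 1:100) {
    A <- runif(1, 0.005, 0.2)
    Cs <- 10^runif(1, -4, -0.5)
    p <- plume_model(A_h = A, A_z = A, threshold_Cstar = Cs)
    age <- runif(1, 1, 30)
    rho <- detectable_radius(age, p)
    if (is.na(rho)) {
      # undetectable: even the center is below threshold
      expect_false(detect(c(0, 0), age,
                          data.frame(release_time = 0, x = 0, y = 0), p))
      next
    }
    puffs <- data.frame(release_time = 0, x = 0, y = 0)
    eps <- 1e-6
    if (rho > eps)
      expect_true(detect(c(rho - eps, 0), age, puffs, p))
    expect_false(detect(c(rho + eps, 0), age, puffs, p))
  }
  # closed forms: peak at C* has rho 0, peak at C* e^{1/2} has rho sigma_h
  p <- plume_model(A_h = 0.05, A_z = 0.05, threshold_Cstar = 1)
  s <- puff_sigma(5, p)
  peak <- 1 / ((2 * pi)^1.5 * s$sigma_h^2 * s$sigma_z)
  p0 <- plume_model(A_h = 0.05, A_z = 0.05, threshold_Cstar = peak)
  expect_equal(detectable_radius(5, p0), 0, tolerance = 1e-9)
  p1 <- plume_model(A_h = 0.05, A_z = 0.05,
                    threshold_Cstar = peak * exp(-0.5))
  expect_equal(detectable_radius(5, p1), s$sigma_h, tolerance = 1e-9)
})

test_that("peak decays monotonically: undetectable puffs never return", {
  p <- plume_model(A_h = 0.03, A_z = 0.03, threshold_Cstar = 0.05)
  ages <- seq(0.5, 60, by = 0.5)
  rho <- detectable_radius(ages, p)
  dead <- which(is.na(rho))
  if (length(dead)) expect_true(all(is.na(rho[dead[1]:length(rho)])))
  # and a larger growth coefficient gives a larger radius while the puff
  # is still well above threshold (young ages)
  p2 <- plume_model(A_h = 0.06, A_z = 0.06, threshold_Cstar = 0.05)
  expect_gt(detectable_radius(2, p2), detectable_radius(2, p))
})

test_that("uniform advection moves centers exactly with the mean wind", {
  w <- wind_model(U_mean = 1, turbulence_intensity = 0)
  puffs <- data.frame(release_time = c(0, 0.5), x = c(0, 1), y = c(0, 0.2))
  out <- advect_puffs(puffs, w, t = 1, dt = 0.1)
  expect_equal(out$x, c(0.1, 1.1))
  expect_equal(out$y, c(0, 0.2))
  # a puff released at 0 and stepped to t = 5 sits at (5, 0)
  pf <- data.frame(release_time = 0, x = 0, y = 0)
  for (t in seq(0, 4.9, by = 0.1)) pf <- advect_puffs(pf, w, t, 0.1)
  expect_equal(pf$x, 5, tolerance = 1e-9)
  expect_equal(pf$y, 0)
  # unreleased puffs do not move
  pf2 <- advect_puffs(data.frame(release_time = 9, x = 0, y = 0), w, 1, 0.1)
  expect_equal(pf2$x, 0)
})

test_that("turbulent advection diffuses centers like a random walk", {
  w <- wind_model(U_mean = 1, turbulence_intensity = 0.2)
  dt <- 0.05
  n_puffs <- 400
  pf <- data.frame(release_time = numeric(n_puffs), x = 0, y = 0)
  set.seed(5)
  vars <- c()
  for (k in 1:60) {
    pf <- advect_puffs(pf, w, (k - 1) * dt, dt)
    if (k %% 20 == 0) vars <- c(vars, var(pf$y))
  }
  expect_true(all(diff(vars) > 0))   # variance grows with step count
  # random-walk oracle: Var(y) = n (TI U dt)^2 after n steps
  expect_equal(vars[3], 60 * (0.2 * 1 * dt)^2, tolerance = 0.35)
})

test_that("calibration meets its two anchors", {
  cal <- calibrate_plume(U_mean = 1, ti_ref = 0.15, pulse_interval_T = 1,
                         reach_x = 25, patch_frac = 1.0)
  p <- plume_model(A_h = cal$A_ref, A_z = cal$A_ref,
                   threshold_Cstar = cal$threshold_Cstar,
                   sigma_floor = 1e-9)
  # reach anchor: puffs become undetectable at age reach_x / U
  expect_lt(abs(cal$age_max_ref - 25), 1e-9)
  expect_false(is.na(detectable_radius(24.99, p)))
  expect_true(is.na(detectable_radius(25.01, p)))
  # patchiness anchor: the largest detectable diameter equals the spacing
  rho <- detectable_radius(seq(0.1, 25, by = 0.01), p)
  expect_equal(2 * max(rho, na.rm = TRUE), 1.0, tolerance = 1e-3)
})
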