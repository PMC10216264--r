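test_that("generators are pure functions of their parameters and seed", {
  p <- brownian_params(n_steps = 50, seed = 9)
  expect_identical(simulate_monomer_trajectory(p),
                   simulate_monomer_trajectory(p))

  g <- growth_params(duration = 20, seed = 9)
  expect_identical(simulate_filament_timelapse(g),
                   simulate_filament_timelapse(g))

  y <- pyrene_params(seed = 9)
  expect_identical(simulate_pyrene_timecourse(y),
                   simulate_pyrene_timecourse(y))

  expect_identical(generate_point_charge_complex(6, 3, 10, seed = 9),
                   generate_point_charge_complex(6, 3, 10, seed = 9))

  # different seeds give different realizations
  expect_false(identical(
    simulate_monomer_trajectory(p),
    simulate_monomer_trajectory(brownian_params(n_steps = 50, seed = 10))
  ))
})

test_that("zero-diffusion zero-drift trajectories are frozen", {
  tr <- simulate_monomer_trajectory(brownian_params(
    diffusion_coefficient = 0, n_steps = 20, seed = 4
  ))
  for (k in 2:length(tr$times)) {
    expect_equal(tr$coords[, , k], tr$coords[, , 1])
  }
  expect_equal(compute_msd(tr, "G")$msd, rep(0, 21))
})

test_that("Brownian increments have per-axis variance 2 D dt", {
  D <- 5.36  # um^2/s -> 0.536 A^2/ns
  dt <- 0.01
  tr <- simulate_monomer_trajectory(brownian_params(
    diffusion_coefficient = D, time_step = dt, n_steps = 10000,
    n_monomer_atoms = 1, n_subunit_atoms = 1, seed = 31
  ))
  mono <- which(tr$atoms$group == "G")[1]
  expected <- 2 * (D / 10) * dt
  for (axis in 1:3) {
    incr <- diff(tr$coords[mono, axis, ])
    expect_lt(abs(stats::var(incr) - expected) / expected, 0.05)
  }
})

test_that("drift displaces the monomer by drift * t on average", {
  v <- c(0.5, -0.2, 1)  # A/ns
  tr <- simulate_monomer_trajectory(brownian_params(
    diffusion_coefficient = 0, drift_velocity = v, n_steps = 100,
    time_step = 0.05, seed = 1
  ))
  mono <- which(tr$atoms$group == "G")[1]
  disp <- tr$coords[mono, , 101] - tr$coords[mono, , 1]
  expect_equal(disp, v * 5, tolerance = 1e-12)
})

test_that("monomer moves as a rigid body and filament stays static", {
  tr <- simulate_monomer_trajectory(brownian_params(n_steps = 30, seed = 6))
  mono <- which(tr$atoms$group == "G")
  fil <- which(tr$atoms$group != "G")
  for (k in c(10, 31)) {
    d <- tr$coords[mono, , k] - tr$coords[mono, , 1]
    # all monomer atoms share one displacement
    expect_equal(max(apply(d, 2, function(v) diff(range(v)))), 0)
    expect_equal(tr$coords[fil, , k], tr$coords[fil, , 1])
  }
  # monomer starts at the configured offset beyond the F5 centroid
  ids <- compute_inter_distance(tr, "F5", "G")
  expect_equal(ids$l0, 15, tolerance = 1e-6)
})

test_that("Brownian parameter validation rejects bad inputs", {
  expect_error(brownian_params(diffusion_coefficient = -1), ">= 0")
  expect_error(brownian_params(time_step = 0), "> 0")
  expect_error(brownian_params(n_steps = 0), ">= 1")
  expect_error(brownian_params(initial_offset = -2), ">= 0")
  expect_error(brownian_params(diffusion_coefficient = NaN), "finite")
  expect_error(brownian_params(drift_velocity = c(1, 2)), "length 3")
})

test_that("timelapse truth track is exactly linear growth", {
  g <- growth_params(elongation_rate = 12, initial_length = 0.3,
                     duration = 30, noise_sd = 0, seed = 2)
  sim <- simulate_filament_timelapse(g)
  expect_equal(sim$track$lengths_um, 0.3 + 12e-3 * sim$track$times)

  # zero rate, zero noise: every frame identical, track constant
  g0 <- growth_params(elongation_rate = 0, duration = 10, noise_sd = 0,
                      seed = 2)
  sim0 <- simulate_filament_timelapse(g0)
  expect_equal(length(unique(sim0$track$lengths_um)), 1L)
  for (k in 2:dim(sim0$stack$frames)[3]) {
    expect_equal(sim0$stack$frames[, , k], sim0$stack$frames[, , 1])
  }
  expect_error(growth_params(duration = 0.5, frame_interval = 1), "duration")
})

test_that("rendered pixel run grows at the true rate in pixel units", {
  # 35.9 nm/s at 0.07 um/px -> 0.5129 px/frame
  g <- growth_params(elongation_rate = 35.9, pixel_size = 0.07,
                     duration = 120, noise_sd = 0, seed = 1)
  sim <- simulate_filament_timelapse(g)
  track <- extract_filament_lengths(sim$stack)
  run_px <- track$lengths_um / 0.07
  slope_px_frame <- stats::coef(stats::lm(run_px ~ seq_along(run_px)))[[2]]
  expect_lt(abs(slope_px_frame - 35.9 / 1000 / 0.07), 1)
  expect_lt(abs(slope_px_frame - 0.513), 0.1)
})

test_that("pyrene curves have the documented sampling and shape", {
  p <- pyrene_params(noise_sd = 0, seed = 3)
  s <- simulate_pyrene_timecourse(p)
  # floor(7200/10) + 1 samples including t = 0
  expect_length(s$times, 721)
  expect_equal(s$polymerization_start, 300)
  # noiseless series is non-decreasing after the baseline
  post <- s$intensities[s$times >= 300]
  expect_true(all(diff(post) >= 0))
  # analytic maximum slope of the logistic: A k / 4 at t = half_time
  A <- p$amplitude
  k <- p$rate_constant
  f <- function(t) A / (1 + exp(-k * (t - p$half_time)))
  h <- 1e-3
  expect_equal((f(p$half_time + h) - f(p$half_time - h)) / (2 * h), A * k / 4,
               tolerance = 1e-6)
  expect_error(pyrene_params(half_time = 200, baseline_duration = 300),
               "half_time")
})

test_that("point-charge complexes are exact unions of their parts", {
  sys <- generate_point_charge_complex(12, 5, box = 20, seed = 8)
  expect_equal(nrow(sys$complex$positions),
               nrow(sys$filament$positions) + nrow(sys$monomer$positions))
  expect_equal(sys$complex$positions,
               rbind(sys$filament$positions, sys$monomer$positions))
  expect_equal(sys$complex$charges,
               c(sys$filament$charges, sys$monomer$charges))
  expect_error(generate_point_charge_complex(3, 3, box = -1), "box")
  expect_error(generate_point_charge_complex(0, 3, box = 5), ">= 1")
})

test_that("widely separated parts have vanishing interaction energy", {
  sys <- generate_point_charge_complex(6, 6, box = 10, seed = 2,
                                       separation = 100 * 10)
  comps <- components_from_structures(sys$complex, sys$filament, sys$monomer,
                                      dielectric = 1, kappa = 0.1)
  dg <- solvation_delta_g(comps)
  expect_equal(dg$delta_G_mean, 0, tolerance = 1e-10)
})
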