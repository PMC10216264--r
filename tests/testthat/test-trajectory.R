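test_that("MSD matches hand-evaluated displacements from frame 0", {
  # one atom walking 0,1,2 along x
  tr <- make_traj(
    list(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1), matrix(c(2, 0, 0), 1)),
    groups = "G"
  )
  expect_equal(compute_msd(tr, "G")$msd, c(0, 1, 4))

  # adding a static atom halves the average
  tr2 <- make_traj(
    list(rbind(c(0, 0, 0), c(5, 5, 5)),
         rbind(c(1, 0, 0), c(5, 5, 5)),
         rbind(c(2, 0, 0), c(5, 5, 5))),
    groups = c("G", "G")
  )
  expect_equal(compute_msd(tr2, "G")$msd, c(0, 0.5, 2))

  # static trajectory
  tr3 <- make_traj(rep(list(rbind(c(1, 2, 3), c(4, 5, 6))), 4),
                   groups = c("F1", "G"))
  expect_equal(compute_msd(tr3, c("F1", "G"))$msd, rep(0, 4))
})

test_that("MSD equals a brute-force double-loop oracle on random input", {
  set.seed(71)
  for (rep in 1:5) {
    frames <- lapply(1:5, function(k) matrix(rnorm(30), 10, 3))
    tr <- make_traj(frames, groups = sample(c("G", "F1"), 10, replace = TRUE))
    sel <- "G"
    idx <- which(tr$atoms$group == sel)
    oracle <- sapply(1:5, function(k) {
      tot <- 0
      for (i in idx) tot <- tot + sum((frames[[k]][i, ] - frames[[1]][i, ])^2)
      tot / length(idx)
    })
    expect_equal(compute_msd(tr, sel)$msd, oracle, tolerance = 1e-12)
  }
})

test_that("MSD selection errors name the unknown groups", {
  tr <- make_traj(rep(list(matrix(0, 1, 3)), 2), groups = "G")
  expect_error(compute_msd(tr, character(0)), "empty")
  expect_error(compute_msd(tr, c("G", "H2", "Z9")), "H2, Z9")
  expect_error(compute_msd(tr, "G", atoms = "CB"), "no atoms")
})

test_that("MSD scales quadratically under coordinate scaling", {
  set.seed(5)
  frames <- lapply(1:4, function(k) matrix(rnorm(9), 3, 3))
  tr <- make_traj(frames, groups = rep("G", 3))
  tr_scaled <- make_traj(lapply(frames, function(f) 2.5 * f),
                         groups = rep("G", 3))
  expect_equal(compute_msd(tr_scaled, "G")$msd,
               2.5^2 * compute_msd(tr, "G")$msd)
})

test_that("diffusion estimators are exact on ideal MSD curves", {
  # msd = 6 t (A^2 per ns) corresponds to 1 A^2/ns = 10 um^2/s
  t <- seq(0, 5, by = 0.1)
  m <- msd_series(t, 6 * t)
  lin <- estimate_diffusion(m, "linear-fit")
  expect_equal(lin$D, 10)
  expect_equal(lin$fit_r2, 1)
  pw <- estimate_diffusion(m, "pointwise")
  expect_equal(pw$D, 10)
  expect_equal(unique(round(pw$per_time_D$D, 9)), 10)

  # zero MSD gives zero D for both methods
  z <- msd_series(t, rep(0, length(t)))
  expect_equal(estimate_diffusion(z, "linear-fit")$D, 0)
  expect_equal(estimate_diffusion(z, "pointwise")$D, 0)

  # msd = 6 D t recovers any D exactly
  for (D in c(0.1, 2.36, 20)) {
    mD <- msd_series(t, 6 * (D / 10) * t)  # D um^2/s -> A^2/ns slope
    expect_equal(estimate_diffusion(mD, "linear-fit")$D, D)
    expect_equal(estimate_diffusion(mD, "pointwise")$D, D)
  }
})

test_that("negative fitted slopes clamp to zero with a warning flag", {
  t <- 0:10
  m <- msd_series(t, c(0, pmax(0, 5 - 0.5 * t[-1])))
  expect_warning(est <- estimate_diffusion(m, "linear-fit",
                                           fit_window = c(1, 10)), "clamped")
  expect_equal(est$D, 0)
  expect_true(est$clamped)
})

test_that("ensemble-averaged MSD recovers the generating D within 10%", {
  # drift-free Brownian trajectories; seed-averaged curve fit once
  n_seeds <- 100
  D_true <- 8
  msds <- lapply(seq_len(n_seeds), function(s) {
    compute_msd(simulate_monomer_trajectory(brownian_params(
      diffusion_coefficient = D_true, n_steps = 250,
      n_monomer_atoms = 1, n_subunit_atoms = 1, seed = 5000 + s
    )), "G")
  })
  est <- estimate_diffusion(average_msd(msds), "linear-fit",
                            fit_window = c(0, 2.5))
  expect_lt(abs(est$D - D_true) / D_true, 0.1)
})

test_that("inter-distance is zero when static and tracks rigid translations", {
  base <- rbind(c(0, 0, 0), c(0, 0, 2), c(0, 0, 12))
  groups <- c("F1", "F1", "G")
  # static
  tr <- make_traj(rep(list(base), 3), groups)
  expect_equal(compute_inter_distance(tr, "F1", "G")$delta_L, rep(0, 3))

  # monomer translated +5 A along the separation axis (z) at frame 2
  shifted <- base
  shifted[3, 3] <- shifted[3, 3] + 5
  tr2 <- make_traj(list(base, shifted, base), groups)
  ids <- compute_inter_distance(tr2, "F1", "G")
  expect_equal(ids$delta_L, c(0, 5, 0))
  expect_equal(ids$l0, 11)  # monomer z=12 vs F1 centroid z=1

  # translating the filament by the same vector gives the same |delta_L|
  shifted_f <- base
  shifted_f[1:2, 3] <- shifted_f[1:2, 3] - 5
  tr3 <- make_traj(list(base, shifted_f, base), groups)
  expect_equal(abs(compute_inter_distance(tr3, "F1", "G")$delta_L),
               abs(ids$delta_L))
})

test_that("inter-distance scales linearly under coordinate scaling", {
  set.seed(11)
  frames <- lapply(1:4, function(k) matrix(rnorm(12, sd = 4), 4, 3))
  groups <- c("F1", "F1", "G", "G")
  tr <- make_traj(frames, groups)
  trs <- make_traj(lapply(frames, function(f) 3 * f), groups)
  expect_equal(compute_inter_distance(trs, "F1", "G")$delta_L,
               3 * compute_inter_distance(tr, "F1", "G")$delta_L)
})

test_that("inter-distance rejects overlapping selections and picks the terminal subunit", {
  tr <- simulate_monomer_trajectory(brownian_params(n_steps = 3, seed = 2))
  expect_error(compute_inter_distance(tr, c("F5", "G"), "G"), "overlap")
  # default barbed end = subunit group nearest the monomer = F5
  ids <- compute_inter_distance(tr)
  expect_identical(ids$filament_selection, "F5")
  expect_equal(ids$delta_L[1], 0)
})
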