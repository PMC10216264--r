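test_that("length extraction recovers noiseless truth within one pixel", {
  g <- growth_params(elongation_rate = 35.9, duration = 120, noise_sd = 0,
                     seed = 1)
  sim <- simulate_filament_timelapse(g)
  track <- extract_filament_lengths(sim$stack)
  expect_lt(max(abs(track$lengths_um - sim$track$lengths_um)),
            sim$stack$pixel_size_um)
  expect_false(any(track$flags))
})

test_that("blank and single-pixel frames are handled explicitly", {
  blank <- structure(
    list(frames = array(0, dim = c(5, 20, 3)), pixel_size_um = 0.07,
         frame_interval_s = 1, times_s = 0:2),
    class = "timelapse_stack"
  )
  track <- extract_filament_lengths(blank, smooth_sigma = 0)
  expect_equal(track$lengths_um, rep(0, 3))
  expect_true(all(track$flags))

  one_px <- blank
  one_px$frames[3, 7, ] <- 1
  track1 <- extract_filament_lengths(one_px, smooth_sigma = 0)
  expect_equal(track1$lengths_um, rep(0.07, 3))

  empty <- blank
  empty$frames <- array(0, dim = c(5, 20, 1))
  expect_error(extract_filament_lengths(empty), "2 frames")
})

test_that("kymographs are frame-row aligned line profiles", {
  g <- growth_params(elongation_rate = 30, duration = 40, noise_sd = 0,
                     seed = 1)
  stack <- simulate_filament_timelapse(g)$stack
  kymo <- build_kymograph(stack)
  expect_equal(nrow(kymo$intensity), dim(stack$frames)[3])
  expect_equal(kymo$intensity[5, ], stack$frames[stack$filament_row, , 5])

  # permuting frames permutes rows identically
  perm <- sample(dim(stack$frames)[3])
  stack_p <- stack
  stack_p$frames <- stack$frames[, , perm]
  expect_equal(build_kymograph(stack_p)$intensity, kymo$intensity[perm, ])

  # edge advances at rate * dt / (1000 * px) pixels per row
  edge <- apply(kymo$intensity, 1, function(v) max(which(v >= 0.5 * max(v))))
  slope <- stats::coef(stats::lm(edge ~ seq_along(edge)))[[2]]
  expect_lt(abs(slope - 30 * 1 / (1000 * 0.07)), 0.1)

  expect_error(build_kymograph(stack, data.frame(row = 1, col = 10^6)),
               "bounds")
})

test_that("elongation rate fits are exact on exact lines", {
  t <- 0:180
  track <- filament_track(t, 0.100 + 2e-3 * t, source = "truth")
  fit <- fit_elongation_rate(track, window = c(60, 120))
  expect_equal(fit$rate, 2)
  expect_equal(fit$r2, 1)
  expect_equal(fit$n_frames, 61)

  const <- filament_track(t, rep(0.5, length(t)))
  expect_equal(fit_elongation_rate(const, c(0, 180))$rate, 0)

  expect_error(fit_elongation_rate(track, c(60, 61.5)), "at least 3")
})

test_that("rate fits are offset-invariant and time-shift equivariant", {
  set.seed(21)
  t <- 0:150
  len <- 0.2 + 25e-3 / 1000 * t * 1000 + rnorm(151, sd = 0.01)
  len <- pmax(len, 0)
  tr1 <- filament_track(t, len)
  tr2 <- filament_track(t, len + 3)          # constant offset
  tr3 <- filament_track(t + 40, len)         # shifted clock
  f1 <- fit_elongation_rate(tr1, c(60, 120))
  expect_equal(fit_elongation_rate(tr2, c(60, 120))$rate, f1$rate)
  expect_equal(fit_elongation_rate(tr3, c(100, 160))$rate, f1$rate)
})

test_that("noisy synthetic stacks round-trip to the generating rate", {
  # 10% noise; recovery within estimator uncertainty across seeds
  rate <- 35.9
  fits <- lapply(1:25, function(s) {
    sim <- simulate_filament_timelapse(growth_params(
      elongation_rate = rate, duration = 130, noise_sd = 0.1, seed = 400 + s
    ))
    fit_elongation_rate(extract_filament_lengths(sim$stack))
  })
  errs <- vapply(fits, function(f) f$rate - rate, numeric(1))
  ses <- vapply(fits, function(f) f$stderr, numeric(1))
  expect_lt(median(abs(errs)), 3 * median(ses))
})

test_that("one-way ANOVA F matches the brute-force sums-of-squares oracle", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  cmp <- compare_conditions(groups)
  expect_equal(cmp$anova_F, brute_force_anova_F(groups), tolerance = 1e-12)
  expect_equal(cmp$anova_p,
               stats::pf(cmp$anova_F, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  set.seed(17)
  rnd <- list(x = rnorm(8), y = rnorm(12, 1), z = rnorm(5, -1))
  cmp2 <- compare_conditions(rnd)
  expect_equal(cmp2$anova_F, brute_force_anova_F(rnd), tolerance = 1e-9)
})

test_that("Tukey table covers all pairs with sane adjusted p-values", {
  set.seed(8)
  groups <- list(ctrl = rnorm(10), peg = rnorm(10, 3), suc = rnorm(10, -2),
                 bsa = rnorm(10, 0.1))
  cmp <- compare_conditions(groups)
  expect_equal(nrow(cmp$tukey), 4 * 3 / 2)
  expect_true(all(cmp$tukey$p_adj >= 0 & cmp$tukey$p_adj <= 1))
  # clearly separated pairs are starred at p <= 0.001
  row <- cmp$tukey[cmp$tukey$pair == "suc-peg", ]
  expect_identical(row$stars, "***")
  # identical groups have zero mean difference
  same <- compare_conditions(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$tukey$diff, 0)
})

test_that("degenerate and invalid comparisons are rejected", {
  expect_error(compare_conditions(list(a = c(1, 2))), "2 condition")
  expect_error(compare_conditions(list(a = 1:3, b = 2)), "2 observations")
  deg <- compare_conditions(list(a = c(2, 2), b = c(3, 3)))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$anova_p))
})

test_that("null ANOVA rejects at the nominal 5% level", {
  set.seed(314)
  n_sim <- 1000
  rejections <- 0
  for (i in seq_len(n_sim)) {
    g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    if (compare_conditions(g)$anova_p <= 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_sim
  half_width <- 1.96 * sqrt(0.05 * 0.95 / n_sim)
  expect_gt(rate, 0.05 - half_width)
  expect_lt(rate, 0.05 + half_width)
})
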