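# Seeded synthetic-data generators: Brownian monomer trajectories near a
# static filament, growing-filament timelapse stacks, sigmoidal pyrene
# fluorescence curves, and random point-charge complexes. Every generator is
# a pure function of its parameters (seed included).

#' Parameters for the Brownian monomer-near-filament generator
#'
#' Defaults emulate a 5 ns equilibrium run of a monomer placed 15 A beyond
#' the barbed end of a 5-subunit filament, the configuration used to probe
#' monomer diffusion during filament assembly.
#'
#' @param diffusion_coefficient Monomer diffusion coefficient, um^2/s (>= 0).
#' @param time_step Frame spacing, ns (> 0).
#' @param n_steps Number of Brownian steps (>= 1); the trajectory has
#'   `n_steps + 1` frames.
#' @param drift_velocity Length-3 drift vector, A/ns (deterministic bias per
#'   unit time; zero for free diffusion).
#' @param initial_offset Initial monomer offset beyond the terminal subunit
#'   along the filament axis, A (>= 0).
#' @param n_monomer_atoms Atoms in the monomer group (rigid body).
#' @param n_subunit_atoms Atoms per filament subunit group.
#' @param filament_jitter_sd Per-frame Gaussian jitter (A) applied rigidly to
#'   each filament subunit; 0 (default) keeps the filament static.
#' @param seed Integer seed.
#' @return A validated list of class `"brownian_params"`.
#' @export
brownian_params <- function(diffusion_coefficient = 5.36,
                            time_step = 0.01,
                            n_steps = 500,
                            drift_velocity = c(0, 0, 0),
                            initial_offset = 15,
                            n_monomer_atoms = 5,
                            n_subunit_atoms = 4,
                            filament_jitter_sd = 0,
                            seed = 1L) {
  p <- list(
    diffusion_coefficient = diffusion_coefficient, time_step = time_step,
    n_steps = as.integer(n_steps), drift_velocity = as.numeric(drift_velocity),
    initial_offset = initial_offset,
    n_monomer_atoms = as.integer(n_monomer_atoms),
    n_subunit_atoms = as.integer(n_subunit_atoms),
    filament_jitter_sd = filament_jitter_sd, seed = as.integer(seed)
  )
  with(p, {
    if (!all(vapply(p[names(p) != "drift_velocity"], is.finite, logical(1))) ||
        !all(is.finite(drift_velocity))) {
      stop("all Brownian parameters must be finite", call. = FALSE)
    }
    if (time_step <= 0) stop("time_step must be > 0", call. = FALSE)
    if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
    if (diffusion_coefficient < 0) stop("diffusion_coefficient must be >= 0", call. = FALSE)
    if (initial_offset < 0) stop("initial_offset must be >= 0", call. = FALSE)
    if (length(drift_velocity) != 3) stop("drift_velocity must have length 3", call. = FALSE)
    if (n_monomer_atoms < 1 || n_subunit_atoms < 1) {
      stop("atom counts must be >= 1", call. = FALSE)
    }
    if (filament_jitter_sd < 0) stop("filament_jitter_sd must be >= 0", call. = FALSE)
  })
  structure(p, class = "brownian_params")
}

# Small rigid atom cluster (deterministic layout) centred at the origin.
.atom_cluster <- function(n, radius = 3) {
  k <- seq_len(n) - 1
  # points on a coarse helix: fixed, well-spread, no randomness
  m <- cbind(
    radius * cos(2.399963 * k),
    radius * sin(2.399963 * k),
    radius * (k - (n - 1) / 2) / max(1, n - 1)
  )
  # centre exactly so the group centroid sits at the placement point
  sweep(m, 2, colMeans(m))
}

#' Simulate a Brownian monomer trajectory near a static filament
#'
#' Generates a trajectory containing a static 5-subunit filament reference
#' (groups `F1`..`F5` stacked along the z axis with the 27.5 A actin axial
#' rise) and a monomer group `G` placed `initial_offset` A beyond the
#' terminal subunit `F5` along the axis. The monomer moves as a rigid body:
#' one Gaussian displacement per step, per-axis variance `2 D dt` plus
#' `drift dt`, applied to all of its atoms. All atoms are named `"CA"`.
#'
#' @param params A [brownian_params] object.
#' @return A [trajectory].
#' @export
simulate_monomer_trajectory <- function(params) {
  stopifnot(inherits(params, "brownian_params"))
  withr::with_seed(params$seed, {
    rise <- 27.5
    n_sub <- 5L
    centers <- cbind(0, 0, (seq_len(n_sub) - 1) * rise)
    cluster <- .atom_cluster(params$n_subunit_atoms)
    fil_xyz <- do.call(rbind, lapply(seq_len(n_sub), function(i) {
      sweep(cluster, 2, centers[i, ], "+")
    }))
    fil_groups <- rep(paste0("F", seq_len(n_sub)), each = params$n_subunit_atoms)
    mono0 <- sweep(.atom_cluster(params$n_monomer_atoms), 2,
                   c(0, 0, (n_sub - 1) * rise + params$initial_offset), "+")
    n_frames <- params$n_steps + 1L
    # 1 um^2/s = 0.1 A^2/ns
    D_A2ns <- convert_diffusion_units(params$diffusion_coefficient,
                                      "um2/s", "A2/ns")
    sd_step <- sqrt(2 * D_A2ns * params$time_step)
    steps <- matrix(stats::rnorm(3 * params$n_steps, sd = sd_step), ncol = 3)
    steps <- sweep(steps, 2, params$drift_velocity * params$time_step, "+")
    disp <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    n_fil <- nrow(fil_xyz)
    n_mono <- nrow(mono0)
    coords <- array(0, dim = c(n_fil + n_mono, 3, n_frames))
    for (k in seq_len(n_frames)) {
      fk <- fil_xyz
      if (params$filament_jitter_sd > 0 && k > 1) {
        jit <- matrix(stats::rnorm(3 * n_sub, sd = params$filament_jitter_sd),
                      ncol = 3)
        fk <- fk + jit[rep(seq_len(n_sub), each = params$n_subunit_atoms), ]
      }
      coords[seq_len(n_fil), , k] <- fk
      coords[n_fil + seq_len(n_mono), , k] <- sweep(mono0, 2, disp[k, ], "+")
    }
    trajectory(
      times = (seq_len(n_frames) - 1) * params$time_step,
      coords = coords,
      atoms = data.frame(
        name = "CA",
        group = c(fil_groups, rep("G", n_mono))
      )
    )
  })
}

#' Parameters for the growing-filament timelapse generator
#'
#' Defaults emulate single-filament TIRF imaging: 0.07 um/pixel, one frame
#' per second for 15 min, and a control-like elongation rate.
#'
#' @param elongation_rate True elongation rate, nm/s (>= 0 allowed; 0 gives
#'   a static filament).
#' @param initial_length Filament length at t = 0, um.
#' @param frame_interval Frame spacing, s (> 0).
#' @param duration Total imaged time, s (>= frame_interval).
#' @param pixel_size Pixel size, um/pixel (> 0).
#' @param psf_sigma Gaussian point-spread sigma, pixels (0 disables blur).
#' @param noise_sd Additive Gaussian noise sd, intensity units (signal is
#'   rendered at unit amplitude).
#' @param seed Integer seed.
#' @return A validated list of class `"growth_params"`.
#' @export
growth_params <- function(elongation_rate = 35.9,
                          initial_length = 0.5,
                          frame_interval = 1,
                          duration = 900,
                          pixel_size = 0.07,
                          psf_sigma = 1,
                          noise_sd = 0.05,
                          seed = 1L) {
  p <- list(
    elongation_rate = elongation_rate, initial_length = initial_length,
    frame_interval = frame_interval, duration = duration,
    pixel_size = pixel_size, psf_sigma = psf_sigma, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (!all(vapply(p, function(v) all(is.finite(v)), logical(1)))) {
    stop("all growth parameters must be finite", call. = FALSE)
  }
  if (p$frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (p$duration < p$frame_interval) {
    stop("duration must cover at least one frame interval", call. = FALSE)
  }
  if (p$pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (p$elongation_rate < 0 || p$initial_length < 0 ||
      p$psf_sigma < 0 || p$noise_sd < 0) {
    stop("rates, lengths, psf_sigma and noise_sd must be >= 0", call. = FALSE)
  }
  structure(p, class = "growth_params")
}

# Peak response of the separable Gaussian PSF to an infinite 1-px-wide line
# (the vertical kernel's centre weight).
.line_peak <- function(sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  max(k / sum(k))
}

# Separable Gaussian blur with a +/-4 sigma kernel, edges renormalised.
.gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  blur_cols <- function(m) {
    n <- nrow(m)
    nc <- ncol(m)
    pad <- rbind(matrix(0, half, nc), m, matrix(0, half, nc))
    out <- matrix(0, n, nc)
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[(j - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(blur_cols(t(blur_cols(img))))
}

#' Simulate a growing-filament timelapse stack
#'
#' True lengths follow `L(t) = initial_length + rate * t`. Each frame renders
#' the filament as a one-pixel-wide horizontal segment growing rightward from
#' a fixed anchor (mimicking a surface-anchored end), with sub-pixel partial
#' coverage at the tip, convolved with a Gaussian PSF, plus additive Gaussian
#' noise. Returns both the noiseless truth track and the rendered stack.
#'
#' @param params A [growth_params] object.
#' @return List with elements `track` (a `"filament_track"`, `source =
#'   "truth"`) and `stack` (a `"timelapse_stack"`: array `rows x cols x
#'   frames` plus `pixel_size_um`, `frame_interval_s`, `times_s`,
#'   `anchor_col`).
#' @export
simulate_filament_timelapse <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  withr::with_seed(params$seed, {
    times <- seq(0, params$duration, by = params$frame_interval)
    lengths_um <- params$initial_length + params$elongation_rate / 1000 * times
    px <- params$pixel_size
    margin <- max(4L, ceiling(4 * params$psf_sigma) + 2L)
    anchor <- margin + 1L
    n_cols <- anchor + ceiling(max(lengths_um) / px) + margin
    n_rows <- 2L * margin + 1L
    mid <- margin + 1L
    frames <- array(0, dim = c(n_rows, n_cols, length(times)))
    for (k in seq_along(times)) {
      img <- matrix(0, n_rows, n_cols)
      lpx <- lengths_um[k] / px
      if (lpx > 0) {
        full <- floor(lpx)
        cols <- anchor + seq_len(full) - 1L
        img[mid, cols] <- 1
        frac <- lpx - full
        if (frac > 0 && anchor + full <= n_cols) img[mid, anchor + full] <- frac
      }
      if (params$psf_sigma > 0) {
        # normalise so a long 1-px line keeps unit peak intensity after the
        # PSF: noise_sd is then a fraction of the filament signal
        img <- .gaussian_blur(img, params$psf_sigma) / .line_peak(params$psf_sigma)
      }
      if (params$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), sd = params$noise_sd),
                            n_rows, n_cols)
      }
      frames[, , k] <- img
    }
    track <- filament_track(times, lengths_um, source = "truth",
                            filament_id = "synthetic")
    stack <- structure(
      list(frames = frames, pixel_size_um = px,
           frame_interval_s = params$frame_interval, times_s = times,
           anchor_col = anchor, filament_row = mid),
      class = "timelapse_stack"
    )
    list(track = track, stack = stack)
  })
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Timelapse stack: %d frames of %d x %d px (%.3g um/px, %.3g s/frame)\n",
    d[3], d[1], d[2], x$pixel_size_um, x$frame_interval_s
  ))
  invisible(x)
}

#' Parameters for the sigmoidal pyrene fluorescence generator
#'
#' Defaults emulate a 2 h plate-reader polymerization run sampled every 10 s
#' with a 5 min pre-polymerization baseline. The post-baseline signal is a
#' logistic `baseline + A / (1 + exp(-k (t - t_half)))`, whose maximum slope
#' is `A k / 4` at `t = t_half`.
#'
#' @param baseline_level Baseline fluorescence, AU.
#' @param amplitude Logistic amplitude A, AU (> 0).
#' @param rate_constant Logistic rate k, 1/s (> 0).
#' @param half_time Logistic midpoint, s (must exceed `baseline_duration`).
#' @param noise_sd Additive Gaussian noise sd, AU.
#' @param baseline_duration Pre-polymerization baseline length, s (>= 0).
#' @param sampling_interval Sample spacing, s (> 0).
#' @param total_duration Total run length, s (> `baseline_duration`).
#' @param seed Integer seed.
#' @return A validated list of class `"pyrene_params"`.
#' @export
pyrene_params <- function(baseline_level = 100,
                          amplitude = 1000,
                          rate_constant = 0.005,
                          half_time = 1800,
                          noise_sd = 5,
                          baseline_duration = 300,
                          sampling_interval = 10,
                          total_duration = 7200,
                          seed = 1L) {
  p <- list(
    baseline_level = baseline_level, amplitude = amplitude,
    rate_constant = rate_constant, half_time = half_time, noise_sd = noise_sd,
    baseline_duration = baseline_duration,
    sampling_interval = sampling_interval, total_duration = total_duration,
    seed = as.integer(seed)
  )
  if (!all(vapply(p, is.finite, logical(1)))) {
    stop("all pyrene parameters must be finite", call. = FALSE)
  }
  if (p$sampling_interval <= 0) stop("sampling_interval must be > 0", call. = FALSE)
  if (p$baseline_duration < 0) stop("baseline_duration must be >= 0", call. = FALSE)
  if (p$amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (p$rate_constant <= 0) stop("rate_constant must be > 0", call. = FALSE)
  if (p$total_duration <= p$baseline_duration) {
    stop("total_duration must exceed baseline_duration", call. = FALSE)
  }
  if (p$half_time <= p$baseline_duration) {
    stop("half_time must exceed baseline_duration (rise cannot precede polymerization start)",
         call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(p, class = "pyrene_params")
}

#' Simulate a pyrene polymerization fluorescence time course
#'
#' Emits `baseline_level` (plus noise) before `baseline_duration`, then the
#' logistic rise (plus noise). The polymerization start time
#' (`baseline_duration`) is recorded on the returned series.
#'
#' @param params A [pyrene_params] object.
#' @param label Series label (condition name).
#' @return A [fluorescence_series].
#' @export
simulate_pyrene_timecourse <- function(params, label = "synthetic") {
  stopifnot(inherits(params, "pyrene_params"))
  withr::with_seed(params$seed, {
    t <- seq(0, params$total_duration, by = params$sampling_interval)
    y <- rep(params$baseline_level, length(t))
    post <- t >= params$baseline_duration
    y[post] <- params$baseline_level + params$amplitude /
      (1 + exp(-params$rate_constant * (t[post] - params$half_time)))
    if (params$noise_sd > 0) {
      y <- y + stats::rnorm(length(t), sd = params$noise_sd)
    }
    fluorescence_series(t, y, polymerization_start = params$baseline_duration,
                        label = label)
  })
}

#' Generate a random point-charge complex and its isolated parts
#'
#' Builds a filament-like and a monomer-like cloud of point charges in two
#' adjacent cubic boxes of side `box` separated by `separation` along x, and
#' returns the complex together with the two isolated parts. The complex is
#' the exact union of the parts (positions and charges preserved), so its
#' interaction energy reduces to the inter-part cross-term.
#'
#' @param n_filament_charges,n_monomer_charges Particle counts (>= 1).
#' @param box Cube side, A (> 0).
#' @param seed Integer seed.
#' @param separation Gap between the two boxes along x, A (default `box/2`).
#' @param min_dist Minimum allowed inter-particle distance, A.
#' @return List with elements `complex`, `filament`, `monomer`, each a
#'   [point_charges] system.
#' @export
generate_point_charge_complex <- function(n_filament_charges,
                                          n_monomer_charges,
                                          box,
                                          seed = 1L,
                                          separation = box / 2,
                                          min_dist = 0.5) {
  if (n_filament_charges < 1 || n_monomer_charges < 1) {
    stop("charge counts must be >= 1", call. = FALSE)
  }
  if (!is.finite(box) || box <= 0) stop("box must be > 0", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    sample_cloud <- function(n, origin) {
      pos <- matrix(NA_real_, n, 3)
      placed <- 0
      while (placed < n) {
        cand <- origin + stats::runif(3, 0, box)
        ok <- placed == 0 ||
          min(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE], 2,
                                 cand)^2))) >= min_dist
        if (ok) {
          placed <- placed + 1
          pos[placed, ] <- cand
        }
      }
      pos
    }
    fil_pos <- sample_cloud(n_filament_charges, c(0, 0, 0))
    mono_pos <- sample_cloud(n_monomer_charges, c(box + separation, 0, 0))
    fil_q <- stats::runif(n_filament_charges, -1, 1)
    mono_q <- stats::runif(n_monomer_charges, -1, 1)
    list(
      complex = point_charges(rbind(fil_pos, mono_pos), c(fil_q, mono_q),
                              label = "complex", min_dist = min_dist),
      filament = point_charges(fil_pos, fil_q, label = "filament",
                               min_dist = min_dist),
      monomer = point_charges(mono_pos, mono_q, label = "monomer",
                              min_dist = min_dist)
    )
  })
}
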