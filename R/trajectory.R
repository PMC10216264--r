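# Molecular trajectory container and the MSD / diffusion / inter-distance
# analyses applied to monomers diffusing near a filament barbed end.

#' Construct a molecular trajectory
#'
#' A lightweight container for a labelled-atom-group trajectory: coordinates
#' in Angstrom on a uniform time grid in nanoseconds. Groups typically
#' comprise filament subunits (`F1`..`Fk`) and a free monomer (`G`).
#'
#' @param times Frame times in ns; at least two frames, uniformly spaced with
#'   a positive step.
#' @param coords Numeric array `n_atoms x 3 x n_frames`, Angstrom.
#' @param atoms `data.frame` with columns `name` (atom name, e.g. `"CA"`) and
#'   `group` (group label), one row per atom.
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(times, coords, atoms) {
  times <- as.numeric(times)
  if (length(times) < 2) stop("a trajectory needs at least 2 frames", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9 * max(dt)) {
    stop("frame times must be uniformly spaced", call. = FALSE)
  }
  if (!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array", call. = FALSE)
  }
  if (dim(coords)[3] != length(times)) {
    stop("coords frame count does not match times", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  atoms <- as.data.frame(atoms)
  if (!all(c("name", "group") %in% names(atoms))) {
    stop("atoms must have columns 'name' and 'group'", call. = FALSE)
  }
  if (nrow(atoms) != dim(coords)[1]) {
    stop("atoms table does not match coords atom count", call. = FALSE)
  }
  structure(
    list(times = times, coords = coords,
         atoms = data.frame(name = as.character(atoms$name),
                            group = as.character(atoms$group))),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  g <- table(x$atoms$group)
  cat(sprintf(
    "Molecular trajectory: %d frames (%.4g-%.4g ns), %d atoms in %d groups\n",
    length(x$times), x$times[1], x$times[length(x$times)],
    nrow(x$atoms), length(g)
  ))
  cat("  groups:", paste(sprintf("%s(%d)", names(g), g), collapse = ", "), "\n")
  invisible(x)
}

# Resolve an atom selection to row indices; errors name the unknown groups.
.select_atoms <- function(traj, groups, atoms = NULL) {
  if (length(groups) == 0) stop("empty atom selection", call. = FALSE)
  unknown <- setdiff(groups, unique(traj$atoms$group))
  if (length(unknown) > 0) {
    stop("unknown group(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- which(traj$atoms$group %in% groups)
  if (!is.null(atoms)) idx <- idx[traj$atoms$name[idx] %in% atoms]
  if (length(idx) == 0) stop("atom selection matched no atoms", call. = FALSE)
  idx
}

#' Mean square displacement from the initial frame
#'
#' For each frame t, computes the mean over the selected atoms of the squared
#' displacement from their position in the first frame,
#' `MSD(t) = < |r_i(t) - r_i(0)|^2 >_i`. The reference is the first frame
#' (no time-lag averaging), the natural statistic for a short
#' single-trajectory equilibrium run; set `lag_averaged = TRUE` for the
#' conventional sliding-origin estimator.
#'
#' @param traj A [trajectory].
#' @param groups Character vector of group labels to average over
#'   (default the monomer group `"G"`).
#' @param atoms Optional atom-name filter (e.g. `"CA"`); `NULL` keeps all.
#' @param lag_averaged If `TRUE`, average displacements over all time
#'   origins at each lag instead of using frame 0 only.
#' @return An object of class `"msd_series"`: list with `times` (ns),
#'   `msd` (A^2), `selection`, `n_atoms`.
#' @export
compute_msd <- function(traj, groups = "G", atoms = NULL, lag_averaged = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- .select_atoms(traj, groups, atoms)
  xyz <- traj$coords[idx, , , drop = FALSE]
  n_frames <- dim(xyz)[3]
  if (lag_averaged) {
    msd <- vapply(seq_len(n_frames) - 1L, function(lag) {
      if (lag == 0) return(0)
      orig <- seq_len(n_frames - lag)
      tot <- 0
      for (o in orig) {
        d <- matrix(xyz[, , o + lag], ncol = 3) - matrix(xyz[, , o], ncol = 3)
        tot <- tot + mean(rowSums(d^2))
      }
      tot / length(orig)
    }, numeric(1))
    times <- traj$times - traj$times[1]
  } else {
    ref <- matrix(xyz[, , 1], ncol = 3)
    msd <- vapply(seq_len(n_frames), function(k) {
      d <- matrix(xyz[, , k], ncol = 3) - ref
      mean(rowSums(d^2))
    }, numeric(1))
    times <- traj$times
  }
  structure(
    list(times = times, msd = msd,
         selection = list(groups = groups, atoms = atoms),
         n_atoms = length(idx), lag_averaged = lag_averaged),
    class = "msd_series"
  )
}

#' Construct an MSD series from raw values
#'
#' Builds an `"msd_series"` from vectors, e.g. when reading external data or
#' averaging curves; [compute_msd] is the usual producer.
#'
#' @param times Times in ns.
#' @param msd MSD values in A^2; `msd[1]` must be 0 and none negative.
#' @param selection Optional selection descriptor.
#' @param n_atoms Number of atoms averaged (may be `NA`).
#' @return An object of class `"msd_series"`.
#' @export
msd_series <- function(times, msd, selection = list(groups = NA, atoms = NULL),
                       n_atoms = NA_integer_) {
  times <- as.numeric(times)
  msd <- as.numeric(msd)
  if (length(times) != length(msd)) {
    stop("times and msd differ in length", call. = FALSE)
  }
  if (abs(msd[1]) > 1e-12 * max(msd, 1)) {
    stop("msd must start at 0", call. = FALSE)
  }
  if (any(msd < 0)) stop("msd values must be >= 0", call. = FALSE)
  structure(
    list(times = times, msd = msd, selection = selection,
         n_atoms = n_atoms, lag_averaged = FALSE),
    class = "msd_series"
  )
}

#' Average MSD curves over an ensemble
#'
#' Point-wise mean of MSD series sharing one time grid, e.g. over
#' independent trajectory seeds. The seed-averaged curve estimates the
#' ensemble MSD `6 D t` far more stably than any single trajectory.
#'
#' @param series_list List of `"msd_series"` objects on identical time grids.
#' @return An `"msd_series"` containing the point-wise mean.
#' @export
average_msd <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  t0 <- series_list[[1]]$times
  for (s in series_list) {
    if (!inherits(s, "msd_series")) stop("not an msd_series", call. = FALSE)
    if (!isTRUE(all.equal(s$times, t0))) {
      stop("MSD series are on different time grids", call. = FALSE)
    }
  }
  m <- rowMeans(vapply(series_list, `[[`, numeric(length(t0)), "msd"))
  msd_series(t0, m, selection = series_list[[1]]$selection,
             n_atoms = series_list[[1]]$n_atoms)
}

#' @export
print.msd_series <- function(x, ...) {
  cat(sprintf(
    "MSD series: %d frames, %d atoms averaged (groups: %s)%s\n",
    length(x$times), x$n_atoms, paste(x$selection$groups, collapse = ","),
    if (isTRUE(x$lag_averaged)) ", lag-averaged" else ""
  ))
  cat(sprintf("  final MSD %.4g A^2 at %.4g ns\n",
              x$msd[length(x$msd)], x$times[length(x$times)]))
  invisible(x)
}

#' @export
plot.msd_series <- function(x, ...) {
  graphics::plot(x$times, x$msd, type = "l",
    xlab = "time (ns)", ylab = expression(MSD ~ (ring(A)^2)), ...)
  invisible(x)
}

#' Diffusion coefficient from an MSD series
#'
#' Two estimators of the translational diffusion coefficient from an MSD
#' curve, both based on `MSD(t) = 6 D t` for free 3-D diffusion:
#' \describe{
#'   \item{`"linear-fit"`}{ordinary least-squares slope of MSD vs t inside
#'     `fit_window`, divided by 6. Default window is the final half of the
#'     series, skipping the initial regime where local interactions dominate.}
#'   \item{`"pointwise"`}{`D(t) = MSD(t) / (6 t)` at each `t > 0`; the
#'     headline value is the final-time point, and the whole `D(t)` series is
#'     returned.}
#' }
#'
#' @param msd An `"msd_series"` (from [compute_msd]) with times in ns and
#'   MSD in A^2.
#' @param method `"linear-fit"` (default) or `"pointwise"`.
#' @param fit_window Length-2 numeric `(t_min, t_max)` in ns for the linear
#'   fit; `NULL` uses the final 50% of the series.
#' @return An object of class `"diffusion_estimate"`: `D` in um^2/s, plus
#'   `method`, `fit_window`, `fit_r2` (linear-fit), `per_time_D` (pointwise,
#'   um^2/s), and `clamped` (TRUE when a negative fitted slope was clamped
#'   to zero).
#' @export
estimate_diffusion <- function(msd, method = c("linear-fit", "pointwise"),
                               fit_window = NULL) {
  stopifnot(inherits(msd, "msd_series"))
  method <- match.arg(method)
  t <- msd$times
  y <- msd$msd
  if (all(t == 0)) stop("all frame times are zero", call. = FALSE)
  res <- list(method = method, clamped = FALSE, per_time_D = NULL,
              fit_window = NULL, fit_r2 = NA_real_)
  if (method == "pointwise") {
    pos <- t > 0
    Dt <- convert_diffusion_units(y[pos] / (6 * t[pos]), "A2/ns", "um2/s")
    res$per_time_D <- list(times = t[pos], D = Dt)
    res$D <- Dt[length(Dt)]
  } else {
    if (is.null(fit_window)) {
      t_final <- t[length(t)]
      fit_window <- c(t[1] + (t_final - t[1]) / 2, t_final)
    }
    inside <- t >= fit_window[1] & t <= fit_window[2]
    if (sum(inside) < 3) {
      stop("need at least 3 MSD points inside fit_window", call. = FALSE)
    }
    fit <- stats::lm(y[inside] ~ t[inside])
    slope <- unname(stats::coef(fit)[2])
    res$fit_window <- fit_window
    res$fit_r2 <- suppressWarnings(summary(fit)$r.squared)
    D <- convert_diffusion_units(slope / 6, "A2/ns", "um2/s")
    if (D < 0) {
      warning("negative fitted MSD slope; D clamped to 0")
      D <- 0
      res$clamped <- TRUE
    }
    res$D <- D
  }
  if (res$D < 0) {
    res$D <- 0
    res$clamped <- TRUE
  }
  class(res) <- "diffusion_estimate"
  res
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("Diffusion coefficient estimate (%s): D = %.4g um^2/s\n",
              x$method, x$D))
  if (x$method == "linear-fit") {
    cat(sprintf("  fit window %.4g-%.4g ns, r^2 = %.4f%s\n",
                x$fit_window[1], x$fit_window[2], x$fit_r2,
                if (x$clamped) " (negative slope clamped to 0)" else ""))
  }
  invisible(x)
}

#' @export
coef.diffusion_estimate <- function(object, ...) c(D_um2_s = object$D)

#' Filament-monomer inter-distance series
#'
#' Tracks the centre-of-geometry distance between the filament barbed end and
#' a monomer: `l(t)` is the Euclidean distance between the unweighted
#' centroid of the barbed-end selection and that of the monomer selection at
#' frame t, and `delta_L(t) = l(t) - l(0)`. Negative values mean the monomer
#' approached the barbed end relative to its initial separation.
#'
#' By default the barbed end is the terminal subunit group whose frame-0
#' centroid lies nearest the monomer; pass an explicit `filament_groups`
#' vector (e.g. the last two subunits) to override.
#'
#' @param traj A [trajectory].
#' @param filament_groups Group label(s) defining the barbed end; `NULL`
#'   picks the filament group nearest the monomer at frame 0.
#' @param monomer_groups Group label(s) for the monomer (default `"G"`).
#' @param atoms Optional atom-name filter applied to both selections.
#' @param mass_weighted If `TRUE` and the atoms table has a `mass` column,
#'   centroids are mass-weighted.
#' @return An object of class `"inter_distance_series"`: `times` (ns),
#'   `delta_L` (A), `l0` (A), and the resolved selections.
#' @export
compute_inter_distance <- function(traj, filament_groups = NULL,
                                   monomer_groups = "G", atoms = NULL,
                                   mass_weighted = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  mono_idx <- .select_atoms(traj, monomer_groups, atoms)
  if (is.null(filament_groups)) {
    cand <- setdiff(unique(traj$atoms$group), monomer_groups)
    if (length(cand) == 0) stop("no filament groups in trajectory", call. = FALSE)
    m0 <- colMeans(matrix(traj$coords[mono_idx, , 1], ncol = 3))
    d0 <- vapply(cand, function(g) {
      gi <- which(traj$atoms$group == g)
      sqrt(sum((colMeans(matrix(traj$coords[gi, , 1], ncol = 3)) - m0)^2))
    }, numeric(1))
    filament_groups <- cand[which.min(d0)]
  }
  fil_idx <- .select_atoms(traj, filament_groups, atoms)
  if (length(intersect(fil_idx, mono_idx)) > 0) {
    stop("filament and monomer selections overlap", call. = FALSE)
  }
  w_of <- function(idx) {
    if (mass_weighted && "mass" %in% names(traj$atoms)) {
      traj$atoms$mass[idx]
    } else {
      rep(1, length(idx))
    }
  }
  centroid <- function(idx, frame, w) {
    m <- matrix(traj$coords[idx, , frame], ncol = 3)
    colSums(m * w) / sum(w)
  }
  wf <- w_of(fil_idx)
  wm <- w_of(mono_idx)
  l <- vapply(seq_along(traj$times), function(k) {
    sqrt(sum((centroid(fil_idx, k, wf) - centroid(mono_idx, k, wm))^2))
  }, numeric(1))
  structure(
    list(times = traj$times, delta_L = l - l[1], l0 = l[1],
         filament_selection = filament_groups,
         monomer_selection = monomer_groups),
    class = "inter_distance_series"
  )
}

#' @export
print.inter_distance_series <- function(x, ...) {
  cat(sprintf(
    "Inter-distance series: l(0) = %.4g A; delta_L final = %+.4g A (%s vs %s)\n",
    x$l0, x$delta_L[length(x$delta_L)],
    paste(x$filament_selection, collapse = ","),
    paste(x$monomer_selection, collapse = ",")
  ))
  invisible(x)
}

#' @export
plot.inter_distance_series <- function(x, ...) {
  graphics::plot(x$times, x$delta_L, type = "l",
    xlab = "time (ns)", ylab = expression(Delta * L ~ (ring(A))), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
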