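# Bulk pyrene polymerization-curve analysis: baseline correction, half-max
# detection, the +/-10-point slope rate statistic, and control normalization.

#' Construct a fluorescence time series
#'
#' @param times Times in s, uniformly spaced.
#' @param intensities Fluorescence, AU, finite.
#' @param polymerization_start Time at which polymerization was initiated, s.
#' @param label Condition label.
#' @return An object of class `"fluorescence_series"`.
#' @export
fluorescence_series <- function(times, intensities, polymerization_start = 0,
                                label = "") {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities)) {
    stop("times and intensities differ in length", call. = FALSE)
  }
  if (length(times) < 2) stop("need at least 2 samples", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9 * max(dt)) {
    stop("times must be uniformly spaced", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(
    list(times = times, intensities = intensities,
         polymerization_start = polymerization_start, label = label),
    class = "fluorescence_series"
  )
}

#' @export
print.fluorescence_series <- function(x, ...) {
  cat(sprintf(
    "Fluorescence series%s: %d samples, dt = %.3g s, polymerization at %.3g s\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    length(x$times), x$times[2] - x$times[1], x$polymerization_start
  ))
  invisible(x)
}

#' @export
plot.fluorescence_series <- function(x, ...) {
  graphics::plot(x$times, x$intensities, type = "l",
    xlab = "time (s)", ylab = "fluorescence (AU)", ...)
  graphics::abline(v = x$polymerization_start, lty = 3)
  invisible(x)
}

#' Baseline-correct a fluorescence series
#'
#' Subtracts from every sample the mean intensity over the pre-polymerization
#' window `[polymerization_start - pre_window, polymerization_start)`.
#'
#' @param series A [fluorescence_series].
#' @param pre_window Baseline averaging window length, s (default 300 s,
#'   i.e. the 5 min preceding polymerization).
#' @return The corrected [fluorescence_series].
#' @export
baseline_correct <- function(series, pre_window = 300) {
  stopifnot(inherits(series, "fluorescence_series"))
  sel <- series$times >= series$polymerization_start - pre_window &
    series$times < series$polymerization_start
  if (sum(sel) < 2) {
    stop("need at least 2 samples in the pre-polymerization window",
         call. = FALSE)
  }
  series$intensities <- series$intensities - mean(series$intensities[sel])
  series
}

#' Locate the half-maximum point of a polymerization curve
#'
#' The plateau is estimated as the mean of the top 5% of intensities
#' (robust to single-sample noise; set `plateau = "max"` for the literal
#' global maximum). The half-max level is half the plateau, and `t_half` is
#' the time of the first sample at or above that level after the
#' polymerization start.
#'
#' @param series A baseline-corrected [fluorescence_series] with a positive
#'   maximum.
#' @param plateau `"top5"` (default) or `"max"`.
#' @return List with `t_half` (s), `half_max_level` (AU), `index` (sample
#'   index of the crossing).
#' @export
find_half_max <- function(series, plateau = c("top5", "max")) {
  stopifnot(inherits(series, "fluorescence_series"))
  plateau <- match.arg(plateau)
  y <- series$intensities
  plateau_level <- if (plateau == "max") {
    max(y)
  } else {
    k <- max(1L, ceiling(0.05 * length(y)))
    mean(sort(y, decreasing = TRUE)[seq_len(k)])
  }
  if (plateau_level <= 0) {
    stop("non-positive plateau; baseline-correct the series first",
         call. = FALSE)
  }
  half <- plateau_level / 2
  cand <- which(y >= half & series$times >= series$polymerization_start)
  if (length(cand) == 0) {
    stop("series never reaches the half-maximum level", call. = FALSE)
  }
  idx <- cand[1]
  list(t_half = series$times[idx], half_max_level = half, index = idx)
}

#' Polymerization rate as the slope at half-maximum
#'
#' Ordinary least-squares slope of intensity vs time over the `2 n_side + 1`
#' samples centred on the half-max sample (`include_center = FALSE` drops
#' the centre, giving a 2 n_side window). The window must fit entirely
#' inside the series; it is never silently clipped.
#'
#' @param series A baseline-corrected [fluorescence_series].
#' @param half Optional result of [find_half_max]; computed if `NULL`.
#' @param n_side Samples on each side of the half-max point (>= 1,
#'   default 10).
#' @param include_center Include the half-max sample itself (default TRUE).
#' @param plateau Passed to [find_half_max] when `half` is `NULL`.
#' @return An object of class `"halfmax_slope"`: `slope` (AU/s), `t_half`,
#'   `half_max_level`, `window_indices`, `n_points`.
#' @export
half_max_slope <- function(series, half = NULL, n_side = 10,
                           include_center = TRUE,
                           plateau = c("top5", "max")) {
  stopifnot(inherits(series, "fluorescence_series"))
  if (n_side < 1) stop("n_side must be >= 1", call. = FALSE)
  if (is.null(half)) half <- find_half_max(series, match.arg(plateau))
  i <- half$index
  n <- length(series$times)
  if (i - n_side < 1 || i + n_side > n) {
    stop("half-max window extends past the series ends", call. = FALSE)
  }
  idx <- (i - n_side):(i + n_side)
  if (!include_center) idx <- setdiff(idx, i)
  t <- series$times[idx]
  y <- series$intensities[idx]
  fit <- stats::lm(y ~ t)
  structure(
    list(slope = unname(stats::coef(fit)[2]), t_half = half$t_half,
         half_max_level = half$half_max_level,
         window_indices = range(idx), n_points = length(idx),
         label = series$label),
    class = "halfmax_slope"
  )
}

#' @export
print.halfmax_slope <- function(x, ...) {
  cat(sprintf(
    "Half-max slope%s: %.4g AU/s at t_half = %.4g s (%d points)\n",
    if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
    x$slope, x$t_half, x$n_points
  ))
  invisible(x)
}

#' @export
coef.halfmax_slope <- function(object, ...) c(slope_AU_s = object$slope)

#' Full pyrene rate pipeline for one series
#'
#' Convenience wrapper: baseline correction, half-max detection, and the
#' half-max slope, with the module defaults.
#'
#' @inheritParams baseline_correct
#' @inheritParams half_max_slope
#' @return A `"halfmax_slope"` object.
#' @export
pyrene_rate <- function(series, pre_window = 300, n_side = 10,
                        include_center = TRUE, plateau = c("top5", "max")) {
  corrected <- baseline_correct(series, pre_window = pre_window)
  half_max_slope(corrected, n_side = n_side, include_center = include_center,
                 plateau = match.arg(plateau))
}

#' Normalize polymerization rates to a control condition
#'
#' Divides each condition's half-max slope by the control's, so the control
#' maps to exactly 1.0.
#'
#' @param slopes Named numeric vector of slopes (AU/s), or a named list of
#'   `"halfmax_slope"` objects.
#' @param control_label Name of the control entry.
#' @return Named numeric vector of relative assembly rates (control = 1).
#' @export
relative_assembly_rate <- function(slopes, control_label = "control") {
  if (is.list(slopes)) {
    slopes <- vapply(slopes, function(s) {
      if (inherits(s, "halfmax_slope")) s$slope else as.numeric(s)
    }, numeric(1))
  }
  if (is.null(names(slopes))) stop("slopes must be named", call. = FALSE)
  if (!control_label %in% names(slopes)) {
    stop("control label '", control_label, "' not found", call. = FALSE)
  }
  ctrl <- slopes[[control_label]]
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop("control slope must be strictly positive", call. = FALSE)
  }
  slopes / ctrl
}
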