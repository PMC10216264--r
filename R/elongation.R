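# Filament-length extraction from timelapse stacks, kymograph construction,
# elongation-rate fitting, and condition comparison by one-way ANOVA with
# Tukey HSD post-hoc tests.

#' Construct a filament length-vs-time track
#'
#' @param times Times, s, strictly increasing.
#' @param lengths_um Filament lengths, um, non-negative.
#' @param source `"truth"` (generator output) or `"extracted"` (image
#'   analysis output).
#' @param filament_id Identifier.
#' @param flags Optional logical vector marking frames where extraction
#'   failed (blank frame).
#' @return An object of class `"filament_track"`.
#' @export
filament_track <- function(times, lengths_um, source = c("truth", "extracted"),
                           filament_id = "", flags = NULL) {
  source <- match.arg(source)
  times <- as.numeric(times)
  lengths_um <- as.numeric(lengths_um)
  if (length(times) != length(lengths_um)) {
    stop("times and lengths differ in length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(lengths_um < 0)) stop("lengths must be >= 0", call. = FALSE)
  if (is.null(flags)) flags <- rep(FALSE, length(times))
  structure(
    list(times = times, lengths_um = lengths_um, source = source,
         filament_id = filament_id, flags = flags),
    class = "filament_track"
  )
}

#' @export
print.filament_track <- function(x, ...) {
  cat(sprintf(
    "Filament track (%s%s): %d frames, %.3g-%.3g s, length %.3g -> %.3g um\n",
    x$source, if (nzchar(x$filament_id)) paste0(", ", x$filament_id) else "",
    length(x$times), x$times[1], x$times[length(x$times)],
    x$lengths_um[1], x$lengths_um[length(x$lengths_um)]
  ))
  invisible(x)
}

#' @export
plot.filament_track <- function(x, ...) {
  graphics::plot(x$times, x$lengths_um, type = "l",
    xlab = "time (s)", ylab = "length (um)", ...)
  invisible(x)
}

#' Extract filament lengths from a timelapse stack
#'
#' Per frame: collapse the image to a one-dimensional intensity profile along
#' the filament line (maximum over rows per column), threshold it, and take
#' the longest contiguous run of supra-threshold pixels; the length is the
#' run length times the pixel size. Designed for straight, surface-anchored
#' filaments such as those produced by [simulate_filament_timelapse].
#'
#' @param stack A `"timelapse_stack"`.
#' @param policy `"fraction"` (threshold at `fraction` of the frame's peak
#'   profile intensity, default) or `"absolute"` (fixed `threshold`).
#' @param fraction Fraction of the peak used as threshold (default 0.5,
#'   i.e. full width at half maximum).
#' @param threshold Absolute threshold for `policy = "absolute"`.
#' @param smooth_sigma Gaussian pre-smoothing of each frame, pixels (0
#'   disables); suppresses pixel noise that would otherwise break the
#'   supra-threshold run. Default 1 px.
#' @return A `"filament_track"` with `source = "extracted"`; frames with no
#'   supra-threshold pixels get length 0 and a `flags` entry of `TRUE`.
#' @export
extract_filament_lengths <- function(stack, policy = c("fraction", "absolute"),
                                     fraction = 0.5, threshold = NULL,
                                     smooth_sigma = 1) {
  stopifnot(inherits(stack, "timelapse_stack"))
  policy <- match.arg(policy)
  d <- dim(stack$frames)
  if (is.null(d) || d[3] < 2) stop("stack needs at least 2 frames", call. = FALSE)
  lengths <- numeric(d[3])
  flags <- logical(d[3])
  for (k in seq_len(d[3])) {
    frame <- stack$frames[, , k]
    if (smooth_sigma > 0) frame <- .gaussian_blur(frame, smooth_sigma)
    profile <- apply(frame, 2, max)
    thr <- if (policy == "fraction") {
      fraction * max(profile)
    } else {
      if (is.null(threshold)) stop("absolute policy needs a threshold", call. = FALSE)
      threshold
    }
    above <- profile >= thr & profile > 0
    if (!any(above)) {
      lengths[k] <- 0
      flags[k] <- TRUE
      next
    }
    runs <- rle(above)
    run_len <- max(runs$lengths[runs$values])
    lengths[k] <- run_len * stack$pixel_size_um
  }
  filament_track(stack$times_s, lengths, source = "extracted",
                 filament_id = "extracted", flags = flags)
}

#' Build a kymograph from a timelapse stack
#'
#' Samples the stack along a pixel path at every frame and stacks the
#' profiles into a time-by-position image (row t = profile at frame t), the
#' standard representation in which a constant elongation rate appears as a
#' straight edge.
#'
#' @param stack A `"timelapse_stack"`.
#' @param line Data frame with integer columns `row`, `col` (1-based pixel
#'   path); `NULL` uses the full central row.
#' @return An object of class `"kymograph"`: `intensity` matrix (frames x
#'   positions), `pixel_size_um`, `frame_interval_s`.
#' @export
build_kymograph <- function(stack, line = NULL) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$frames)
  if (is.null(line)) {
    row <- if (!is.null(stack$filament_row)) stack$filament_row else (d[1] + 1) %/% 2
    line <- data.frame(row = row, col = seq_len(d[2]))
  }
  if (!all(c("row", "col") %in% names(line))) {
    stop("line must have columns 'row' and 'col'", call. = FALSE)
  }
  if (any(line$row < 1 | line$row > d[1] | line$col < 1 | line$col > d[2])) {
    stop("line path is out of image bounds", call. = FALSE)
  }
  kymo <- t(vapply(seq_len(d[3]), function(k) {
    stack$frames[, , k][cbind(line$row, line$col)]
  }, numeric(nrow(line))))
  structure(
    list(intensity = kymo, pixel_size_um = stack$pixel_size_um,
         frame_interval_s = stack$frame_interval_s),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d frames x %d positions (%.3g um/px, %.3g s/row)\n",
              nrow(x$intensity), ncol(x$intensity),
              x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(
    x = seq_len(ncol(x$intensity)) * x$pixel_size_um,
    y = (seq_len(nrow(x$intensity)) - 1) * x$frame_interval_s,
    z = t(x$intensity), xlab = "position (um)", ylab = "time (s)",
    col = grDevices::gray.colors(256, start = 0, end = 1), ...
  )
  invisible(x)
}

#' Fit a filament elongation rate by linear regression
#'
#' Ordinary least-squares fit of filament length (nm) against time (s)
#' inside an analysis window, the standard early-growth interval over which
#' single filaments grow linearly without overlapping neighbours (default
#' 60-120 s).
#'
#' @param track A `"filament_track"`.
#' @param window Length-2 numeric `(t_start, t_end)` in s; `NULL` uses the
#'   full track.
#' @return An object of class `"elongation_fit"`: `rate` and `stderr` in
#'   nm/s, `r2`, `n_frames`, `window`.
#' @export
fit_elongation_rate <- function(track, window = c(60, 120)) {
  stopifnot(inherits(track, "filament_track"))
  if (is.null(window)) window <- range(track$times)
  inside <- track$times >= window[1] & track$times <= window[2]
  if (sum(inside) < 3) {
    stop("need at least 3 track points inside the window", call. = FALSE)
  }
  t <- track$times[inside]
  if (stats::var(t) == 0) stop("zero time variance in window", call. = FALSE)
  len_nm <- track$lengths_um[inside] * 1000
  fit <- stats::lm(len_nm ~ t)
  sm <- suppressWarnings(summary(fit))  # exact lines trip the perfect-fit warning
  structure(
    list(rate = unname(stats::coef(fit)[2]),
         stderr = sm$coefficients[2, "Std. Error"],
         r2 = sm$r.squared, n_frames = sum(inside), window = window),
    class = "elongation_fit"
  )
}

#' @export
print.elongation_fit <- function(x, ...) {
  cat(sprintf(
    "Elongation rate: %.4g +/- %.2g nm/s (r^2 = %.4f, %d frames, window %g-%g s)\n",
    x$rate, x$stderr, x$r2, x$n_frames, x$window[1], x$window[2]
  ))
  invisible(x)
}

#' @export
coef.elongation_fit <- function(object, ...) {
  c(rate_nm_s = object$rate, stderr_nm_s = object$stderr)
}

#' Compare elongation rates across conditions (one-way ANOVA + Tukey HSD)
#'
#' Standard one-way analysis of variance across condition groups followed by
#' Tukey honestly-significant-difference pairwise comparisons (studentized
#' range distribution, equal-variance assumption). Pairs are starred `***`
#' at adjusted p <= 0.001.
#'
#' @param rates Named list of numeric vectors, one per condition (>= 2
#'   groups, each with >= 2 observations).
#' @return An object of class `"group_comparison"`: `groups` (per-group n,
#'   mean, sd), `anova_F`, `anova_p`, `tukey` (data frame with columns
#'   `pair`, `diff`, `lwr`, `upr`, `p_adj`, `stars`), and `degenerate`
#'   (TRUE when all within-group variances are zero; no p is reported).
#' @export
compare_conditions <- function(rates) {
  if (!is.list(rates) || length(rates) < 2) {
    stop("need at least 2 condition groups", call. = FALSE)
  }
  if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
    stop("rates must be a named list", call. = FALSE)
  }
  if (any(vapply(rates, length, integer(1)) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  df <- data.frame(
    rate = unlist(rates, use.names = FALSE),
    group = factor(rep(names(rates), vapply(rates, length, integer(1))),
                   levels = names(rates))
  )
  groups <- data.frame(
    group = names(rates),
    n = vapply(rates, length, integer(1)),
    mean = vapply(rates, mean, numeric(1)),
    sd = vapply(rates, stats::sd, numeric(1)),
    row.names = NULL
  )
  degenerate <- all(vapply(rates, stats::var, numeric(1)) == 0)
  if (degenerate) {
    out <- list(groups = groups, anova_F = NA_real_, anova_p = NA_real_,
                tukey = NULL, degenerate = TRUE, data = df)
    class(out) <- "group_comparison"
    return(out)
  }
  fit <- stats::aov(rate ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(
    pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
    upr = tk[, "upr"], p_adj = tk[, "p adj"],
    stars = ifelse(tk[, "p adj"] <= 0.001, "***", ""),
    row.names = NULL
  )
  structure(
    list(groups = groups, anova_F = an[["F value"]][1],
         anova_p = an[["Pr(>F)"]][1], tukey = tukey, degenerate = FALSE,
         data = df),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("One-way ANOVA across", nrow(x$groups), "conditions\n")
  print(x$groups, row.names = FALSE)
  if (x$degenerate) {
    cat("  all within-group variances are zero; no test performed\n")
  } else {
    cat(sprintf("  F = %.4g, p = %.4g\n", x$anova_F, x$anova_p))
  }
  invisible(x)
}

#' @export
summary.group_comparison <- function(object, ...) {
  print(object)
  if (!object$degenerate) {
    cat("Tukey HSD pairwise comparisons (*** p <= 0.001):\n")
    tk <- object$tukey
    tk$diff <- signif(tk$diff, 4)
    tk$p_adj <- signif(tk$p_adj, 3)
    print(tk[, c("pair", "diff", "p_adj", "stars")], row.names = FALSE)
  }
  invisible(object)
}
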