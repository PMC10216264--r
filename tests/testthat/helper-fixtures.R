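# Shared fixture builders; everything is generated in code at test time.

# trajectory from a list of per-frame coordinate matrices (n_atoms x 3)
make_traj <- function(frames, groups, names = rep("CA", nrow(frames[[1]])),
                      dt = 1) {
  coords <- array(0, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  trajectory(
    times = (seq_along(frames) - 1) * dt,
    coords = coords,
    atoms = data.frame(name = names, group = groups)
  )
}

# noiseless logistic fluorescence series with a flat pre-polymerization
# baseline (already on the generator's shape, built independently of it)
make_logistic_series <- function(amplitude = 1000, k = 0.005,
                                 half_time = 1800, dt = 10, total = 7200,
                                 baseline = 300, level = 0) {
  t <- seq(0, total, by = dt)
  y <- rep(level, length(t))
  post <- t >= baseline
  y[post] <- level + amplitude / (1 + exp(-k * (t[post] - half_time)))
  fluorescence_series(t, y, polymerization_start = baseline)
}

# brute-force one-way ANOVA F from sums of squares
brute_force_anova_F <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  k <- length(groups)
  n <- length(all)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# direct cross-pair screened-Coulomb sum between two point_charges systems
cross_term_energy <- function(a, b, dielectric = 1, kappa = 0) {
  tot <- 0
  for (i in seq_len(nrow(a$positions))) {
    r <- sqrt(colSums((t(b$positions) - a$positions[i, ])^2))
    tot <- tot + sum(332.0636 * a$charges[i] * b$charges *
                       exp(-kappa * r) / (dielectric * r))
  }
  tot
}
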