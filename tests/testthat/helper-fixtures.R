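# Small seeded fixtures shared across test files.

# a compact three-behaviour configuration with very separable signatures
tiny_config <- function(seed = 1, n_cats = 1, n_days = 1,
                        day_length_s = 600, annotated_window = c(0, 300),
                        oos_fraction = 0, ...) {
  sigs <- rbind(
    behaviour_signature("lying", "inactive", c(0.1, 0.5, 0.86),
                        mean_dwell = 40, noise_sd = 0.02, occupancy = 0.6),
    behaviour_signature("walking", "active", c(0, 1, 0.2), dyn_amp = 0.4,
                        gait_freq = 2, noise_sd = 0.08, mean_dwell = 10,
                        occupancy = 0.25),
    behaviour_signature("eating", "maintenance", c(0.6, 0.78, 0.18),
                        dyn_amp = 0.12, gait_freq = 2, noise_sd = 0.04,
                        mean_dwell = 20, occupancy = 0.15)
  )
  sim_config(signatures = sigs, n_cats = n_cats, n_days = n_days,
             day_length_s = day_length_s,
             annotated_window = annotated_window,
             oos_fraction = oos_fraction, seed = seed, ...)
}

# a one-behaviour configuration (degenerate chain)
single_config <- function(label = "lying", noise_sd = 0, seed = 1) {
  sigs <- behaviour_signature(label, "inactive", c(0.1, 0.5, 0.86),
                              noise_sd = noise_sd, mean_dwell = 30)
  sim_config(signatures = sigs, n_cats = 1, n_days = 1, day_length_s = 600,
             annotated_window = c(0, 300), oos_fraction = 0, seed = seed)
}

# labelled dataset with the 32 feature columns filled from Gaussian class
# clusters: the first `informative` features carry the class means
gaussian_dataset <- function(n_per_class, means, sd = 1, informative = 4,
                             seed = 1) {
  set.seed(seed)
  classes <- names(means)
  rows <- sum(n_per_class)
  y <- rep(classes, times = n_per_class)
  x <- matrix(rnorm(rows * 32, sd = 0.1), rows, 32,
              dimnames = list(NULL, feature_names()))
  for (j in seq_len(informative))
    x[, j] <- unlist(lapply(seq_along(classes), function(i)
      rnorm(n_per_class[i], mean = means[[i]], sd = sd)))
  out <- data.frame(behaviour = y, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(x))
}

# annotation track with given per-behaviour second counts
track_from_counts <- function(counts) {
  beh <- rep(names(counts), times = counts)
  data.frame(second = seq_along(beh) - 1L, behaviour = beh,
             stringsAsFactors = FALSE)
}

# per-behaviour annotated-second counts mirroring the printed study numbers:
# the explicitly printed counts plus plausible values for behaviours whose
# exact counts are only in the appendix; totals match the printed arithmetic
# (166,754 scored - 38,395 out of sight - 4,116 other - 10 - 1 = 124,232)
printed_study_counts <- function() {
  c("climbing" = 32, "jumping horizontal" = 53, "jumping vertical" = 186,
    "fighting" = 10, "playing" = 1, "rolling" = 0, "rubbing" = 900,
    "running" = 0, "trotting" = 308, "walking" = 4500,
    "lying" = 62000, "sitting" = 28000, "standing" = 10500,
    "digging" = 520, "drinking" = 0, "eating" = 7200, "grooming" = 8000,
    "littering" = 950, "scratching" = 713, "shaking" = 120,
    "other" = 4116, "out of sight" = 38395, "allogrooming" = 250,
    "human contact" = 0)
}
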