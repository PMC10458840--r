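#' Simulate a ground-truth behaviour label sequence
#'
#' Draws a semi-Markov behaviour sequence: bout durations come from a gamma
#' law (mean `mean_dwell`, shape `dwell_shape`, rounded up to a whole second)
#' and each bout's successor is drawn from the configured transition weights.
#'
#' @param config a [sim_config()].
#' @param duration_s sequence length in whole seconds.
#' @param seed integer seed.
#' @return A factor of length `duration_s`, one behaviour label per second,
#'   with levels equal to the signature labels.
#' @export
#' @examples
#' cfg <- sim_config(n_cats = 1, n_days = 1, seed = 1)
#' labs <- simulate_labels(cfg, 600, seed = 1)
#' table(labs)
simulate_labels <- function(config, duration_s, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (duration_s < 1) stop("duration_s must be >= 1")
  sig <- config$signatures
  if (nrow(sig) == 0) stop("empty signature set")
  k <- nrow(sig)
  set.seed(seed)
  if (k == 1) {
    return(factor(rep(sig$label, duration_s), levels = sig$label))
  }
  w <- config$transition_weights
  # start from the occupancy-weighted law, then chain bout to bout
  start_p <- sig$occupancy / sig$mean_dwell
  states <- integer(0)
  total <- 0
  cur <- sample.int(k, 1, prob = start_p)
  # grow in chunks: states first (cheap scalar loop), dwells vectorised
  while (total < duration_s) {
    need <- duration_s - total
    n_b <- max(16L, ceiling(1.5 * need / mean(sig$mean_dwell)))
    chunk <- integer(n_b)
    for (i in seq_len(n_b)) {
      chunk[i] <- cur
      cur <- sample.int(k, 1, prob = w[cur, ])
    }
    dw <- pmax(1L, as.integer(ceiling(
      rgamma(n_b, shape = sig$dwell_shape[chunk],
             scale = sig$mean_dwell[chunk] / sig$dwell_shape[chunk]))))
    states <- c(states, rep.int(chunk, dw))
    total <- length(states)
  }
  factor(sig$label[states[seq_len(duration_s)]], levels = sig$label)
}

#' Construct a raw triaxial acceleration trace object
#'
#' @param data numeric n x 3 matrix of acceleration (g), columns X, Y, Z.
#' @param cat_id cat identifier.
#' @param mount `"collar"` or `"harness"`.
#' @param sampling_rate samples per second.
#' @param start_time trace start in seconds from the study origin.
#' @return A list of class `raw_trace`.
#' @export
raw_trace <- function(data, cat_id = "cat01", mount = c("collar", "harness"),
                      sampling_rate = 30, start_time = 0) {
  mount <- match.arg(mount)
  data <- as.matrix(data)
  stopifnot(ncol(data) == 3, is.numeric(data))
  colnames(data) <- c("X", "Y", "Z")
  structure(list(cat_id = cat_id, mount = mount,
                 sampling_rate = sampling_rate,
                 start_time = start_time, data = data),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("Raw trace: %s / %s, %g Hz, %d samples (%.1f s) from t=%g s\n",
              x$cat_id, x$mount, x$sampling_rate, nrow(x$data),
              nrow(x$data) / x$sampling_rate, x$start_time))
  invisible(x)
}

# device axis order (X, Y, Z) expressed in body-frame components (cc, dv, lat)
.mount_axes <- function(mount) {
  switch(mount,
    collar  = c("lat", "dv", "cc"),
    harness = c("cc", "dv", "lat"),
    stop("unknown mount: ", mount)
  )
}

#' Synthesize a raw acceleration trace for a labelled second sequence
#'
#' Each sample is the behaviour's 1 g static gravity orientation plus a
#' sinusoidal dynamic component on the cranio-caudal body axis plus isotropic
#' Gaussian noise. The collar mount additionally applies a slowly drifting
#' random rotation about the neck (cranio-caudal) axis and a damped ringing
#' on the lateral axis after every active-to-inactive transition; the harness
#' applies neither. Device axes follow the mounting convention: collar
#' X/Y/Z = lateral / dorso-ventral / cranio-caudal, harness X/Y/Z =
#' cranio-caudal / dorso-ventral / lateral. Output is clipped to the +-8 g
#' device range.
#'
#' @param labels factor/character vector, one behaviour label per second.
#' @param config a [sim_config()].
#' @param mount `"collar"` or `"harness"`.
#' @param seed integer seed.
#' @param cat_id,start_time metadata stored on the returned trace.
#' @return A [raw_trace()] with `length(labels) * sampling_rate` samples.
#' @export
synthesize_trace <- function(labels, config, mount = c("collar", "harness"),
                             seed, cat_id = "cat01", start_time = 0) {
  stopifnot(inherits(config, "sim_config"))
  mount <- match.arg(mount)
  labels <- normalise_label(as.character(labels))
  if (length(labels) == 0) stop("labels must be nonempty")
  sig <- config$signatures
  idx <- match(labels, sig$label)
  if (anyNA(idx)) stop("labels not covered by signatures: ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "))
  rate <- config$sampling_rate
  n_sec <- length(labels)
  n <- n_sec * rate
  set.seed(seed)

  sidx <- rep(idx, each = rate)          # per-sample signature row
  tt <- (seq_len(n) - 1) / rate          # per-sample time (s)

  # static gravity in body frame
  cc <- sig$g_cc[sidx]; dv <- sig$g_dv[sidx]; lat <- sig$g_lat[sidx]

  # dynamic gait component on the cranio-caudal axis; fresh phase per bout
  bouts <- rle(idx)
  phase <- runif(length(bouts$lengths), 0, 2 * pi)
  phase_s <- rep.int(phase, bouts$lengths * rate)
  cc <- cc + sig$dyn_amp[sidx] * sin(2 * pi * sig$gait_freq[sidx] * tt + phase_s)

  if (mount == "collar") {
    # Ornstein-Uhlenbeck style angular drift about the cc axis
    phi <- exp(-1 / (rate * config$collar_jitter_tau))
    innov_sd <- config$collar_jitter_sd * sqrt(1 - phi^2)
    theta <- as.numeric(stats::filter(rnorm(n, sd = innov_sd), phi,
                                      method = "recursive",
                                      init = rnorm(1, sd = config$collar_jitter_sd)))
    ct <- cos(theta); st <- sin(theta)
    dv2 <- ct * dv - st * lat
    lat <- st * dv + ct * lat
    dv <- dv2
    # damped ringing after each active -> inactive transition
    cat_by_sec <- sig$category[idx]
    trans <- which(cat_by_sec[-1] == "inactive" &
                   cat_by_sec[-n_sec] == "active")  # transition at second t+1
    if (length(trans)) {
      tau <- config$residual_decay
      ring_len <- min(n, ceiling(5 * tau * rate))
      u <- (seq_len(ring_len) - 1) / rate
      ring <- config$residual_amp * exp(-u / tau) *
        sin(2 * pi * config$residual_freq * u)
      for (t0 in trans) {
        s0 <- t0 * rate + 1           # first sample of the inactive second
        span <- s0:min(n, s0 + ring_len - 1)
        lat[span] <- lat[span] + ring[seq_along(span)]
      }
    }
  }

  noise_sd <- sig$noise_sd[sidx]
  body <- cbind(cc = cc + rnorm(n) * noise_sd,
                dv = dv + rnorm(n) * noise_sd,
                lat = lat + rnorm(n) * noise_sd)
  dev <- body[, .mount_axes(mount), drop = FALSE]
  dev[dev > 8] <- 8; dev[dev < -8] <- -8
  raw_trace(dev, cat_id = cat_id, mount = mount, sampling_rate = rate,
            start_time = start_time)
}

# inject "out of sight"/"other" runs into an annotated label vector
.inject_oos <- function(labels, config, seed) {
  n <- length(labels)
  target <- round(config$oos_fraction * n)
  if (target == 0) return(as.character(labels))
  set.seed(seed)
  out <- as.character(labels)
  covered <- 0L
  taken <- rep(FALSE, n)
  # geometric-length runs at random starts until the quota is met
  while (covered < target) {
    len <- min(1L + stats::rgeom(1, 1 / config$oos_run_mean),
               target - covered + 30L)
    s0 <- sample.int(n, 1)
    span <- s0:min(n, s0 + len - 1L)
    span <- span[!taken[span]]
    if (!length(span)) next
    code <- if (runif(1) < config$oos_other_share) "other" else "out of sight"
    out[span] <- code
    taken[span] <- TRUE
    covered <- covered + length(span)
  }
  out
}

#' Generate a full synthetic accelerometer study
#'
#' Simulates ground-truth behaviour sequences for every cat over the whole
#' recording period and an annotation track for the day-1 annotated window
#' (the "scored video" stand-in) in which a configurable fraction of seconds
#' is relabelled with the non-behaviour codes "out of sight"/"other". Raw
#' traces are synthesized lazily, one (cat, mount, day) at a time, from
#' per-day seeds derived from the master seed (a full study at default scale
#' holds ~435 million triaxial samples, far more than is useful to keep in
#' memory); [study_trace()] realises any requested trace deterministically.
#'
#' @param config a [sim_config()].
#' @return A list of class `acc_study` with elements `config` and `cats`;
#'   each cat holds `labels` (ground-truth factor over all seconds),
#'   `annotation` (data.frame `second`, `behaviour` for the annotated
#'   window), and a `trace_seeds` matrix (mount x day).
#' @export
#' @examples
#' study <- generate_study(sim_config(n_cats = 2, n_days = 1,
#'                                    day_length_s = 1200,
#'                                    annotated_window = c(0, 600), seed = 1))
#' study
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_cats <- config$n_cats
  cats <- list()
  if (n_cats > 0) {
    seeds <- matrix(derive_seeds(config$seed, n_cats * (2 + 2 * config$n_days)),
                    nrow = n_cats)
    total_s <- config$n_days * config$day_length_s
    win <- config$annotated_window
    for (i in seq_len(n_cats)) {
      id <- sprintf("cat%02d", i)
      labels <- simulate_labels(config, total_s, seed = seeds[i, 1])
      ann_sec <- win[1]:(win[2] - 1L)
      ann_beh <- .inject_oos(labels[ann_sec + 1L], config, seed = seeds[i, 2])
      trace_seeds <- matrix(seeds[i, -(1:2)], nrow = 2,
                            dimnames = list(c("collar", "harness"), NULL))
      cats[[id]] <- list(cat_id = id, labels = labels,
                         annotation = data.frame(second = ann_sec,
                                                 behaviour = ann_beh,
                                                 stringsAsFactors = FALSE),
                         trace_seeds = trace_seeds)
    }
  }
  structure(list(config = config, cats = cats), class = "acc_study")
}

#' @export
print.acc_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic accelerometer study: %d cats x %d days, 2 mounts, %g Hz\n",
              length(x$cats), cfg$n_days, cfg$sampling_rate))
  cat(sprintf("  annotated seconds per cat: %d\n", diff(cfg$annotated_window)))
  invisible(x)
}

#' Realise the raw trace for one cat, mount and day of a study
#'
#' Traces are synthesized deterministically from the study's stored per-day
#' seeds, so repeated calls return identical data.
#'
#' @param study an `acc_study` from [generate_study()].
#' @param cat_id cat identifier (e.g. `"cat01"`).
#' @param mount `"collar"` or `"harness"`.
#' @param day 1-based day index.
#' @param window optional length-2 vector of seconds *within the day*
#'   (half-open) to restrict the returned trace.
#' @return A [raw_trace()].
#' @export
study_trace <- function(study, cat_id, mount = c("collar", "harness"),
                        day = 1, window = NULL) {
  stopifnot(inherits(study, "acc_study"))
  mount <- match.arg(mount)
  cat <- study$cats[[cat_id]]
  if (is.null(cat)) stop("unknown cat_id: ", cat_id)
  cfg <- study$config
  if (day < 1 || day > cfg$n_days) stop("day out of range")
  day_s <- cfg$day_length_s
  sec0 <- (day - 1L) * day_s
  labels <- cat$labels[(sec0 + 1L):(sec0 + day_s)]
  full <- synthesize_trace(labels, cfg, mount,
                           seed = cat$trace_seeds[mount, day],
                           cat_id = cat_id, start_time = sec0)
  if (is.null(window)) return(full)
  stopifnot(length(window) == 2, window[1] >= 0, window[2] <= day_s,
            window[2] > window[1])
  rate <- cfg$sampling_rate
  keep <- (window[1] * rate + 1L):(window[2] * rate)
  raw_trace(full$data[keep, , drop = FALSE], cat_id = cat_id, mount = mount,
            sampling_rate = rate, start_time = sec0 + window[1])
}
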