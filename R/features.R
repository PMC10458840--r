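#' Names of the 32 per-epoch identifier variables
#'
#' Fixed, documented column order: per-axis mean, sum, min, max, sd,
#' skewness, kurtosis for X, Y, Z (21), pairwise Pearson correlations (3),
#' the same seven statistics of the per-sample vector magnitude (7), and
#' ODBA (1).
#'
#' @return character vector of length 32.
#' @export
feature_names <- function() {
  ax <- c("x", "y", "z")
  st <- c("mean", "sum", "min", "max", "sd", "skew", "kurt")
  c(paste(rep(st, each = 3), rep(ax, times = 7), sep = "_"),
    "corr_xy", "corr_xz", "corr_yz",
    paste("vm", st, sep = "_"),
    "odba")
}

# population skewness / kurtosis (non-excess) from central moments;
# degenerate (zero-variance) windows are encoded as 0
.moments_by_epoch <- function(m) {
  # m: rate x n_epochs matrix, one column per epoch
  n <- nrow(m)
  mu <- colMeans(m)
  d <- m - rep(mu, each = n)
  m2 <- colMeans(d^2)
  m3 <- colMeans(d^3)
  m4 <- colMeans(d^4)
  degen <- m2 <= 0
  skew <- ifelse(degen, 0, m3 / m2^1.5)
  kurt <- ifelse(degen, 0, m4 / m2^2)
  list(mean = mu,
       sum = mu * n,
       min = .col_min(m),
       max = -.col_min(-m),
       sd = sqrt(colSums(d^2) / (n - 1)),   # sample sd (n - 1)
       skew = skew, kurt = kurt, degenerate = degen)
}

.col_min <- function(m) {
  out <- m[1, ]
  for (i in 2:nrow(m)) out <- pmin(out, m[i, ])
  out
}

#' Moment statistics of one 30-sample axis window
#'
#' @param window numeric vector of one epoch's samples for a single axis.
#' @param sampling_rate expected window length (samples per epoch).
#' @return named numeric vector: mean, sum, min, max, sd, skew, kurt, plus a
#'   `degenerate` attribute flagging a zero-variance window (skew/kurt then
#'   encoded as 0 rather than NaN).
#' @export
#' @examples
#' axis_stats(rep(0.5, 30))
axis_stats <- function(window, sampling_rate = 30) {
  if (length(window) != sampling_rate)
    stop("window must have exactly ", sampling_rate, " samples")
  mo <- .moments_by_epoch(matrix(window, ncol = 1))
  out <- c(mean = mo$mean, sum = mo$sum, min = mo$min, max = mo$max,
           sd = mo$sd, skew = mo$skew, kurt = mo$kurt)
  attr(out, "degenerate") <- unname(mo$degenerate)
  out
}

#' Pairwise Pearson correlations between the three axis windows
#'
#' Pairs involving a zero-variance axis are encoded as 0 (with a
#' `degenerate` attribute) so downstream classifiers never see missing
#' values.
#'
#' @param window_x,window_y,window_z equal-length numeric vectors.
#' @return named numeric vector `corr_xy`, `corr_xz`, `corr_yz`.
#' @export
axis_correlations <- function(window_x, window_y, window_z) {
  stopifnot(length(window_x) == length(window_y),
            length(window_y) == length(window_z))
  one <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }
  r <- c(corr_xy = one(window_x, window_y),
         corr_xz = one(window_x, window_z),
         corr_yz = one(window_y, window_z))
  degen <- is.na(r)
  r[degen] <- 0
  attr(r, "degenerate") <- unname(degen)
  r
}

#' Per-sample vector magnitude and its epoch statistics
#'
#' VM_i = sqrt(x_i^2 + y_i^2 + z_i^2).
#'
#' @param samples n x 3 numeric matrix (or a [raw_trace()]).
#' @param sampling_rate samples per epoch for the statistics.
#' @return list with `vm` (per-sample magnitudes) and `stats` (a matrix of
#'   the seven VM statistics, one row per complete epoch).
#' @export
#' @examples
#' vector_magnitude(matrix(c(3, 4, 0), 1))$vm  # 5
vector_magnitude <- function(samples, sampling_rate = 30) {
  if (inherits(samples, "raw_trace")) {
    sampling_rate <- samples$sampling_rate
    samples <- samples$data
  }
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == 3)
  vm <- sqrt(rowSums(samples^2))
  n_ep <- length(vm) %/% sampling_rate
  stats <- NULL
  if (n_ep >= 1) {
    mo <- .moments_by_epoch(matrix(vm[seq_len(n_ep * sampling_rate)],
                                   nrow = sampling_rate))
    stats <- cbind(vm_mean = mo$mean, vm_sum = mo$sum, vm_min = mo$min,
                   vm_max = mo$max, vm_sd = mo$sd, vm_skew = mo$skew,
                   vm_kurt = mo$kurt)
  }
  list(vm = vm, stats = stats)
}

# centred moving average, window w, truncated at the edges (partial windows
# shrink near the trace ends); w even uses floor(w/2) before, w/2 - 1 after
.moving_average <- function(x, w) {
  n <- length(x)
  before <- w %/% 2
  after <- w - before - 1L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - before, 1L)
  hi <- pmin(seq_len(n) + after, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Overall dynamic body acceleration per epoch
#'
#' Each axis is smoothed with a centred moving average spanning one second of
#' samples (edge-truncated); the per-sample dynamic residual is the sample
#' minus its smoothed value. In the default `"absolute"` mode, an epoch's
#' ODBA is the sum over its samples of the absolute residuals of the three
#' axes (the standard dynamic-body-acceleration construction). The
#' `"as_printed"` mode instead takes the epoch's axis sums minus the epoch's
#' summed moving average, without absolute values, summed over axes -- a
#' literal reading of the printed formula, retained for comparison.
#'
#' @param trace a [raw_trace()] or n x 3 matrix.
#' @param sampling_rate samples per second (taken from the trace if given).
#' @param mode `"absolute"` (default) or `"as_printed"`.
#' @return numeric vector, one ODBA value per complete epoch.
#' @export
odba <- function(trace, sampling_rate = 30, mode = c("absolute", "as_printed")) {
  mode <- match.arg(mode)
  if (inherits(trace, "raw_trace")) {
    sampling_rate <- trace$sampling_rate
    trace <- trace$data
  }
  trace <- as.matrix(trace)
  n_ep <- nrow(trace) %/% sampling_rate
  if (n_ep < 1) stop("trace shorter than one epoch")
  used <- seq_len(n_ep * sampling_rate)
  ep <- rep(seq_len(n_ep), each = sampling_rate)
  total <- numeric(n_ep)
  for (j in 1:3) {
    x <- trace[used, j]
    res <- x - .moving_average(x, sampling_rate)
    if (mode == "absolute") res <- abs(res)
    total <- total + rowsum(res, ep)[, 1]
  }
  if (mode == "as_printed") total else unname(total)
}

#' Extract the 32 identifier variables for every complete epoch
#'
#' Raw samples are cut into consecutive non-overlapping epochs of
#' `sampling_rate` samples (epoch k covers samples `[k*rate, (k+1)*rate)`,
#' 0-based half-open); a trailing partial epoch is dropped. Zero-variance
#' axes within an epoch yield skewness/kurtosis/correlations of 0 and set
#' the `degenerate` flag column.
#'
#' @param trace a [raw_trace()] or n x 3 numeric matrix.
#' @param sampling_rate samples per second (taken from the trace if given).
#' @param dba_mode ODBA residual mode, see [odba()].
#' @return data.frame with one row per complete epoch: `epoch` (0-based
#'   index), the 32 feature columns of [feature_names()], and a logical
#'   `degenerate` quality flag.
#' @export
#' @examples
#' tr <- matrix(rnorm(90), ncol = 3)
#' extract_features(tr)[, 1:5]
extract_features <- function(trace, sampling_rate = 30,
                             dba_mode = c("absolute", "as_printed")) {
  dba_mode <- match.arg(dba_mode)
  epoch0 <- 0
  if (inherits(trace, "raw_trace")) {
    sampling_rate <- trace$sampling_rate
    epoch0 <- as.integer(round(trace$start_time))
    trace <- trace$data
  }
  trace <- as.matrix(trace)
  rate <- sampling_rate
  n_ep <- nrow(trace) %/% rate
  if (n_ep < 1) {
    out <- data.frame(matrix(numeric(0), 0, 34))
    names(out) <- c("epoch", feature_names(), "degenerate")
    return(out)
  }
  used <- seq_len(n_ep * rate)
  per_axis <- lapply(1:3, function(j)
    .moments_by_epoch(matrix(trace[used, j], nrow = rate)))
  # correlations, vectorised over epochs
  corr_pair <- function(a, b) {
    ma <- matrix(trace[used, a], nrow = rate)
    mb <- matrix(trace[used, b], nrow = rate)
    da <- ma - rep(colMeans(ma), each = rate)
    db <- mb - rep(colMeans(mb), each = rate)
    va <- colSums(da^2); vb <- colSums(db^2)
    degen <- va <= 0 | vb <= 0
    r <- numeric(n_ep)
    ok <- !degen
    r[ok] <- colSums(da * db)[ok] / sqrt(va[ok] * vb[ok])
    list(r = r, degenerate = degen)
  }
  cxy <- corr_pair(1, 2); cxz <- corr_pair(1, 3); cyz <- corr_pair(2, 3)
  vm <- vector_magnitude(trace[used, , drop = FALSE], rate)
  vm_mo <- .moments_by_epoch(matrix(vm$vm, nrow = rate))
  od <- odba(trace[used, , drop = FALSE], rate, mode = dba_mode)

  st <- c("mean", "sum", "min", "max", "sd", "skew", "kurt")
  out <- data.frame(epoch = epoch0 + seq_len(n_ep) - 1L)
  for (s in st) for (j in 1:3)
    out[[paste(s, c("x", "y", "z")[j], sep = "_")]] <- per_axis[[j]][[s]]
  out$corr_xy <- cxy$r; out$corr_xz <- cxz$r; out$corr_yz <- cyz$r
  for (s in st) out[[paste("vm", s, sep = "_")]] <- vm_mo[[s]]
  out$odba <- od
  out$degenerate <- per_axis[[1]]$degenerate | per_axis[[2]]$degenerate |
    per_axis[[3]]$degenerate | cxy$degenerate | cxz$degenerate |
    cyz$degenerate | vm_mo$degenerate
  out[c("epoch", feature_names(), "degenerate")]
}
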