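#' Write a raw trace as an ActiLife-style CSV
#'
#' Ten preamble lines (the first carries the sampling rate), then a
#' `Timestamp,Accelerometer X,Accelerometer Y,Accelerometer Z` table at full
#' sample resolution. Timestamps are seconds from the study origin; values
#' are written with enough digits to round-trip exactly.
#'
#' @param trace a [raw_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_actigraph_csv <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  n <- nrow(trace$data)
  hdr <- c(
    sprintf("------------ Data File Created By felacc (ActiLife-style raw export) at %g Hz ------------",
            trace$sampling_rate),
    sprintf("Serial Number: SYN-%s-%s", trace$cat_id, trace$mount),
    sprintf("Start Time %.3f", trace$start_time),
    "Start Date 30/06/2021",
    "Epoch Period (hh:mm:ss) 00:00:00",
    "Download Time 00:00:00",
    "Download Date 07/07/2021",
    "Current Memory Address: 0",
    "Current Battery Voltage: 4.07     Mode = 12",
    "--------------------------------------------------"
  )
  ts <- trace$start_time + (seq_len(n) - 1) / trace$sampling_rate
  body <- paste(sprintf("%.6f", ts),
                format(trace$data[, 1], digits = 17, scientific = FALSE, trim = TRUE),
                format(trace$data[, 2], digits = 17, scientific = FALSE, trim = TRUE),
                format(trace$data[, 3], digits = 17, scientific = FALSE, trim = TRUE),
                sep = ",")
  writeLines(c(hdr, "Timestamp,Accelerometer X,Accelerometer Y,Accelerometer Z",
               body), path)
  invisible(path)
}

#' Read an ActiLife-style raw CSV
#'
#' Tolerates an arbitrary number of preamble lines by scanning for the
#' `Timestamp,...` sentinel; the declared sampling rate is parsed from the
#' preamble (`<rate> Hz`). Rejects empty data sections, non-numeric cells,
#' non-monotone timestamps, and timestamp spacing inconsistent with the
#' declared rate, naming the offending line.
#'
#' @param path input file path.
#' @param cat_id,mount metadata stored on the trace (the serial-number
#'   preamble line is used as a fallback).
#' @return A [raw_trace()].
#' @export
read_raw_csv <- function(path, cat_id = NULL, mount = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sent <- grep("^Timestamp,", lines)
  if (!length(sent)) stop("malformed header: no 'Timestamp,...' column line found in ", path)
  sent <- sent[1]
  preamble <- lines[seq_len(sent - 1)]
  rate_m <- regmatches(preamble, regexpr("[0-9.]+ Hz", preamble))
  rate_m <- unlist(rate_m)
  if (!length(rate_m)) stop("malformed header: sampling rate (' Hz') not declared")
  rate <- as.numeric(sub(" Hz", "", rate_m[1]))
  if (is.null(cat_id) || is.null(mount)) {
    ser <- grep("^Serial Number:", preamble, value = TRUE)
    if (length(ser)) {
      parts <- strsplit(sub("^Serial Number:\\s*", "", ser[1]), "-")[[1]]
      if (is.null(cat_id) && length(parts) >= 2) cat_id <- parts[2]
      if (is.null(mount) && length(parts) >= 3) mount <- parts[3]
    }
  }
  if (sent == length(lines)) stop("empty data section in ", path)
  body <- lines[(sent + 1):length(lines)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("empty data section in ", path)
  cells <- strsplit(body, ",", fixed = TRUE)
  bad_n <- which(lengths(cells) != 4)
  if (length(bad_n))
    stop("parse error at line ", sent + bad_n[1], ": expected 4 columns")
  # non-numeric cells surface as a targeted error below, not a coercion warning
  m <- matrix(suppressWarnings(as.numeric(unlist(cells))), ncol = 4,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("parse error at line ", sent + bad, ": non-numeric cell")
  }
  ts <- m[, 1]
  if (length(ts) > 1) {
    d <- diff(ts)
    bad <- which(d <= 0)
    if (length(bad))
      stop("non-monotone timestamp at line ", sent + bad[1] + 1)
    if (abs(stats::median(d) - 1 / rate) > 1e-6)
      stop("timestamp spacing inconsistent with declared rate (", rate, " Hz)")
  }
  raw_trace(m[, 2:4], cat_id = if (is.null(cat_id)) "unknown" else cat_id,
            mount = if (is.null(mount)) "collar" else mount,
            sampling_rate = rate, start_time = ts[1])
}

#' Write an annotation track as a BORIS-style export CSV
#'
#' @param track data.frame with columns `second` and `behaviour`.
#' @param path output file path.
#' @param subject subject (cat) identifier written in the `Subject` column.
#' @return `path`, invisibly.
#' @export
write_boris_csv <- function(track, path, subject = "cat01") {
  stopifnot(all(c("second", "behaviour") %in% names(track)))
  out <- data.frame(Time = track$second, Subject = subject,
                    Behavior = track$behaviour)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a BORIS-style annotation export CSV
#'
#' Expects columns `Time`, `Subject`, `Behavior` with exactly one row per
#' second. Labels are case-normalised against the ethogram; unknown labels
#' and gaps in the second sequence are rejected.
#'
#' @param path input file path.
#' @param ethogram ethogram data.frame, see [cat_ethogram()].
#' @return data.frame with columns `second` (integer) and `behaviour`
#'   (normalised character), and a `cat_id` attribute.
#' @export
read_annotation_csv <- function(path, ethogram = cat_ethogram()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("Time", "Behavior")
  if (!all(need %in% names(d)))
    stop("annotation file must have columns Time and Behavior")
  beh <- normalise_label(d$Behavior)
  unknown <- setdiff(unique(beh), ethogram$behaviour)
  if (length(unknown))
    stop("unknown behaviour label(s): ", paste(unknown, collapse = ", "))
  sec <- as.integer(round(d$Time))
  o <- order(sec)
  sec <- sec[o]; beh <- beh[o]
  if (anyDuplicated(sec)) stop("duplicate annotation seconds")
  if (length(sec) > 1 && any(diff(sec) != 1L))
    stop("annotation must be continuous: gap after second ",
         sec[which(diff(sec) != 1L)[1]])
  out <- data.frame(second = sec, behaviour = beh, stringsAsFactors = FALSE)
  attr(out, "cat_id") <- if ("Subject" %in% names(d)) d$Subject[1] else NA
  out
}

#' Align a raw trace with per-second annotations on 1 s epochs
#'
#' Epoch indices are absolute seconds from the study origin; epoch `k`
#' covers samples `[k * rate, (k + 1) * rate)` of the study clock (0-based,
#' half-open). Epochs outside the annotation window are emitted with an `NA`
#' label; a trailing partial epoch is dropped with a message. An optional
#' whole-second device/video clock offset shifts the trace clock.
#'
#' @param trace a [raw_trace()].
#' @param annotations data.frame `second`, `behaviour` (may be `NULL`).
#' @param clock_offset_s whole-second offset added to the trace clock
#'   (default 0).
#' @return list with `epoch` (0-based absolute indices), `label` (character,
#'   `NA` where unannotated), `data` (trimmed sample matrix), and
#'   `sampling_rate`.
#' @export
align_epochs <- function(trace, annotations = NULL, clock_offset_s = 0) {
  stopifnot(inherits(trace, "raw_trace"))
  rate <- trace$sampling_rate
  n_ep <- nrow(trace$data) %/% rate
  dropped <- nrow(trace$data) - n_ep * rate
  if (dropped > 0)
    message("dropping trailing partial epoch (", dropped, " samples)")
  start_sec <- as.integer(round(trace$start_time + clock_offset_s))
  epoch <- start_sec + seq_len(n_ep) - 1L
  label <- rep(NA_character_, n_ep)
  if (!is.null(annotations) && nrow(annotations)) {
    if (any(!annotations$second %in% epoch))
      stop("trace does not cover every annotated second")
    label[match(annotations$second, epoch)] <- normalise_label(annotations$behaviour)
  }
  list(epoch = epoch, label = label,
       data = trace$data[seq_len(n_ep * rate), , drop = FALSE],
       sampling_rate = rate)
}

#' Filter and merge behaviour labels before modelling
#'
#' Applies the preprocessing rules used before the first modelling round:
#' non-behaviour codes ("out of sight", "other") are removed; the two
#' jumping variants are merged into a single "jumping" class; behaviours
#' observed fewer than `min_count_s` seconds (default 11, so counts of 10 or
#' fewer drop) are removed; unobserved ethogram behaviours are reported as
#' such. Works on an annotation track or any data.frame with a `behaviour`
#' column (e.g. a labelled feature dataset).
#'
#' @param track data.frame with a `behaviour` column.
#' @param ethogram ethogram data.frame.
#' @param min_count_s minimum retained class size in seconds.
#' @param exclude_labels non-behaviour codes removed outright.
#' @param merge named character vector mapping source labels to merged
#'   class labels.
#' @return The filtered data.frame (rows with removed behaviours dropped,
#'   merged labels rewritten), with a `filter_report` attribute: a
#'   data.frame of behaviour, count, action, reason accounting for every
#'   input second and every ethogram behaviour.
#' @export
#' @examples
#' tr <- data.frame(second = 0:9,
#'                  behaviour = c(rep("lying", 6), rep("out of sight", 4)))
#' preprocess_labels(tr, min_count_s = 1)
preprocess_labels <- function(track, ethogram = cat_ethogram(),
                              min_count_s = 11,
                              exclude_labels = c("other", "out of sight"),
                              merge = c("jumping horizontal" = "jumping",
                                        "jumping vertical" = "jumping")) {
  stopifnot("behaviour" %in% names(track))
  beh <- normalise_label(track$behaviour)
  counts0 <- table(beh)
  report <- list()
  add <- function(behaviour, count, action, reason)
    report[[length(report) + 1]] <<- data.frame(
      behaviour = behaviour, count = count, action = action, reason = reason,
      stringsAsFactors = FALSE)

  # unobserved ethogram behaviours (count 0)
  unobserved <- setdiff(ethogram$behaviour, names(counts0))
  for (b in unobserved) add(b, 0L, "removed", "not observed")

  keep <- rep(TRUE, length(beh))
  for (b in intersect(exclude_labels, names(counts0))) {
    keep[beh == b] <- FALSE
    add(b, as.integer(counts0[[b]]), "removed", "non-behaviour code")
  }
  # merge variants
  for (b in intersect(names(merge), names(counts0))) {
    add(b, as.integer(counts0[[b]]), "merged",
        paste0("merged into '", merge[[b]], "'"))
    beh[beh == b] <- merge[[b]]
  }
  # low-occurrence removal on the post-merge classes
  counts1 <- table(beh[keep])
  for (b in names(counts1)) {
    if (b %in% exclude_labels) next
    if (counts1[[b]] < min_count_s) {
      keep[beh == b] <- FALSE
      add(b, as.integer(counts1[[b]]), "removed",
          sprintf("low occurrence (< %d s)", min_count_s))
    } else {
      add(b, as.integer(counts1[[b]]), "kept", "")
    }
  }
  out <- track[keep, , drop = FALSE]
  out$behaviour <- beh[keep]
  rownames(out) <- NULL
  attr(out, "filter_report") <- do.call(rbind, report)
  out
}

#' Cap per-class sample counts by seeded downsampling
#'
#' Classes larger than `cap` are reduced to exactly `cap` rows by uniform
#' sampling without replacement; smaller classes are untouched. Used to keep
#' abundant behaviours (lying and similar) from dominating model training.
#'
#' @param data data.frame with a `behaviour` column.
#' @param cap maximum rows per class (default 7000).
#' @param seed integer seed.
#' @return The capped data.frame (original row order preserved).
#' @export
cap_class_counts <- function(data, cap = 7000, seed = 1) {
  stopifnot("behaviour" %in% names(data), cap >= 1)
  set.seed(seed)
  keep <- logical(nrow(data))
  for (b in unique(data$behaviour)) {
    rows <- which(data$behaviour == b)
    if (length(rows) > cap) rows <- sort(sample(rows, cap))
    keep[rows] <- TRUE
  }
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Splits rows into disjoint, exhaustive train and test partitions,
#' stratified by behaviour class, with seeded sampling. A single-row class
#' goes entirely to the training partition with a warning.
#'
#' @param data data.frame with a `behaviour` column.
#' @param train_frac training fraction in (0, 1), default 0.7.
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
train_test_split <- function(data, train_frac = 0.7, seed = 1) {
  stopifnot("behaviour" %in% names(data))
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  set.seed(seed)
  in_train <- logical(nrow(data))
  for (b in unique(data$behaviour)) {
    rows <- which(data$behaviour == b)
    n <- length(rows)
    if (n == 1) {
      warning("class '", b, "' has a single row; assigned to train")
      in_train[rows] <- TRUE
      next
    }
    n_train <- min(n - 1, max(1, round(train_frac * n)))
    in_train[sample(rows, n_train)] <- TRUE
  }
  list(train = data[in_train, , drop = FALSE],
       test = data[!in_train, , drop = FALSE])
}

#' Write a filtering report as TSV
#'
#' @param report the `filter_report` attribute from [preprocess_labels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
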