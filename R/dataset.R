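#' Build the labelled epoch-feature dataset for one mounting location
#'
#' For each cat in a synthetic study: realise the day-1 annotated-window
#' trace for the given mount, extract the 32 identifier variables per epoch,
#' and attach the annotation labels (including any "out of sight"/"other"
#' codes, which [preprocess_labels()] removes downstream).
#'
#' @param study an `acc_study` from [generate_study()].
#' @param mount `"collar"` or `"harness"`.
#' @param cats optional character vector of cat ids (default: all).
#' @param dba_mode ODBA mode passed to [extract_features()].
#' @return data.frame with columns `cat_id`, `mount`, `epoch`, `behaviour`
#'   and the 32 feature columns (plus the `degenerate` flag).
#' @export
study_features <- function(study, mount = c("collar", "harness"),
                           cats = names(study$cats),
                           dba_mode = "absolute") {
  stopifnot(inherits(study, "acc_study"))
  mount <- match.arg(mount)
  win <- study$config$annotated_window
  out <- vector("list", length(cats))
  for (i in seq_along(cats)) {
    id <- cats[i]
    tr <- study_trace(study, id, mount, day = 1, window = win)
    al <- align_epochs(tr, study$cats[[id]]$annotation)
    fe <- extract_features(tr, dba_mode = dba_mode)
    fe$epoch <- al$epoch
    out[[i]] <- cbind(data.frame(cat_id = id, mount = mount,
                                 behaviour = al$label,
                                 stringsAsFactors = FALSE), fe)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("cat_id", "mount", "epoch", "behaviour", feature_names(), "degenerate")]
}

#' Write / read a labelled feature matrix as CSV
#'
#' Fixed schema: `cat_id`, `mount`, `epoch`, `behaviour`, the 32 feature
#' columns of [feature_names()], and the `degenerate` flag. The reader
#' validates the schema and refuses files missing any feature column.
#'
#' @param data labelled feature data.frame (as from [study_features()]).
#' @param path file path.
#' @return `path` (write) or the validated data.frame (read).
#' @export
write_features_csv <- function(data, path) {
  miss <- setdiff(feature_names(), names(data))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(miss, collapse = ", "))
  cols <- intersect(c("cat_id", "mount", "epoch", "behaviour",
                      feature_names(), "degenerate"), names(data))
  write.csv(data[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(feature_names(), names(d))
  if (length(miss)) stop("not a feature matrix: missing column(s) ",
                         paste(miss, collapse = ", "))
  d
}

#' Ground-truth long-run behaviour occupancy of a study
#'
#' Empirical time share of each behaviour in the simulated ground-truth
#' label sequences (all cats, all days).
#'
#' @param study an `acc_study`.
#' @return named numeric vector of proportions summing to 1.
#' @export
study_occupancy <- function(study) {
  tab <- Reduce(`+`, lapply(study$cats, function(ct) table(ct$labels)))
  prop <- as.numeric(tab) / sum(tab)
  names(prop) <- names(tab)
  prop
}
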