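#' The 24-behaviour domestic cat ethogram
#'
#' Returns the ethogram used throughout the package: 24 scored behaviours,
#' each assigned to exactly one of four categories (active, inactive,
#' maintenance, other). The "other" category mixes genuine social behaviours
#' (allogrooming, human contact) with non-behaviour bookkeeping codes
#' ("other", "out of sight"); only the bookkeeping codes are excluded by
#' default during preprocessing (see [preprocess_labels()]).
#'
#' @return A data.frame with columns `behaviour` and `category`, 24 rows.
#' @seealso [preprocess_labels()], [fixed_round_plans()]
#' @export
#' @examples
#' eth <- cat_ethogram()
#' table(eth$category)
cat_ethogram <- function() {
  data.frame(
    behaviour = c(
      "climbing", "jumping horizontal", "jumping vertical", "fighting",
      "playing", "rolling", "rubbing", "running", "trotting", "walking",
      "lying", "sitting", "standing",
      "digging", "drinking", "eating", "grooming", "littering",
      "scratching", "shaking",
      "other", "out of sight", "allogrooming", "human contact"
    ),
    category = c(
      rep("active", 10),
      rep("inactive", 3),
      rep("maintenance", 7),
      rep("other", 4)
    ),
    stringsAsFactors = FALSE
  )
}

# Non-behaviour bookkeeping codes: excluded from modelling regardless of count.
.exclude_codes <- c("other", "out of sight")

#' Look up ethogram categories for behaviour labels
#'
#' @param behaviour character vector of behaviour labels (normalised).
#' @param ethogram ethogram data.frame as from [cat_ethogram()].
#' @return character vector of categories; `NA` for unknown labels.
#' @export
behaviour_category <- function(behaviour, ethogram = cat_ethogram()) {
  ethogram$category[match(normalise_label(behaviour), ethogram$behaviour)]
}

#' Normalise behaviour labels
#'
#' Case-insensitive, whitespace-trimmed normalisation to the ethogram's
#' lower-case keys; internal runs of whitespace collapse to a single space
#' and underscores are treated as spaces.
#'
#' @param x character vector of labels.
#' @return normalised character vector.
#' @export
normalise_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]_]+", " ", x)
}
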