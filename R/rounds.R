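#' Construct a modelling-round plan
#'
#' A plan maps every behaviour class of the previous round to its class for
#' this round: itself, a merged class label, or the sentinel `"REMOVED"`.
#'
#' @param round_index 1-based round number.
#' @param mapping named character vector: previous-round class ->
#'   new class label or `"REMOVED"`.
#' @param cap per-class sample cap applied this round.
#' @return list of class `round_plan`.
#' @export
round_plan <- function(round_index, mapping, cap = 7000) {
  stopifnot(!is.null(names(mapping)), all(nzchar(names(mapping))))
  structure(list(round_index = as.integer(round_index),
                 mapping = mapping, cap = as.integer(cap)),
            class = "round_plan")
}

#' @export
print.round_plan <- function(x, ...) {
  changed <- x$mapping[x$mapping != names(x$mapping)]
  cat(sprintf("Round %d plan (cap %d): %d classes -> %d\n", x$round_index,
              x$cap, length(x$mapping),
              length(setdiff(unique(x$mapping), "REMOVED"))))
  if (length(changed))
    cat(paste0("  ", names(changed), " -> ", changed, collapse = "\n"), "\n")
  invisible(x)
}

# category of a (possibly merged) class label: ethogram behaviours resolve
# through the ethogram; merged class labels named after a category resolve to
# that category; "jumping" is the merged active jumping class
.label_category <- function(labels, ethogram = cat_ethogram()) {
  cats <- c("active", "inactive", "maintenance", "other")
  out <- behaviour_category(labels, ethogram)
  lab <- normalise_label(labels)
  out[lab %in% cats] <- lab[lab %in% cats]
  out[lab == "jumping"] <- "active"
  out
}

#' The four fixed modelling-round plans
#'
#' The round sequence used with synthetic studies in "fixed-plan mode":
#' round 1 keeps the fifteen behaviours that survive preprocessing (any
#' other label maps to `REMOVED`, making the plan total over any input class
#' set); round 2 removes the six smallest behaviours and merges
#' trotting/walking into "active"; round 3 merges scratching into grooming
#' and drops littering; round 4 collapses everything to the three ethogram
#' categories (active, inactive, maintenance) with a tighter cap of 5000.
#'
#' @param ethogram ethogram data.frame.
#' @return list of four [round_plan()] objects.
#' @export
fixed_round_plans <- function(ethogram = cat_ethogram()) {
  retained <- c("climbing", "jumping", "rubbing", "trotting", "walking",
                "lying", "sitting", "standing", "grooming", "littering",
                "digging", "eating", "scratching", "shaking", "allogrooming")
  all_labels <- union(ethogram$behaviour, "jumping")
  m1 <- setNames(ifelse(all_labels %in% retained, all_labels, "REMOVED"),
                 all_labels)
  m2 <- setNames(retained, retained)
  m2[c("climbing", "jumping", "rubbing", "digging", "shaking",
       "allogrooming")] <- "REMOVED"
  m2[c("trotting", "walking")] <- "active"
  r2_classes <- setdiff(unique(m2), "REMOVED")
  m3 <- setNames(r2_classes, r2_classes)
  m3["scratching"] <- "grooming"
  m3["littering"] <- "REMOVED"
  r3_classes <- setdiff(unique(m3), "REMOVED")
  m4 <- setNames(.label_category(r3_classes, ethogram), r3_classes)
  list(round_plan(1, m1, cap = 7000),
       round_plan(2, m2, cap = 7000),
       round_plan(3, m3, cap = 7000),
       round_plan(4, m4, cap = 5000))
}

#' Apply a round plan to a labelled dataset
#'
#' Rewrites the `behaviour` column through the plan's mapping and drops rows
#' mapped to `REMOVED`. Any behaviour missing from the mapping is an error.
#'
#' @param data data.frame with a `behaviour` column.
#' @param plan a [round_plan()].
#' @return the remapped data.frame.
#' @export
apply_round_plan <- function(data, plan) {
  stopifnot(inherits(plan, "round_plan"), "behaviour" %in% names(data))
  beh <- normalise_label(data$behaviour)
  unknown <- setdiff(unique(beh), names(plan$mapping))
  if (length(unknown))
    stop("plan does not cover class(es): ", paste(unknown, collapse = ", "))
  mapped <- unname(plan$mapping[beh])
  keep <- mapped != "REMOVED"
  out <- data[keep, , drop = FALSE]
  out$behaviour <- mapped[keep]
  rownames(out) <- NULL
  out
}

#' Selection-protocol configuration
#'
#' @param low_sensitivity_threshold sensitivity below which a class counts as
#'   poorly identified (default 0.20).
#' @param require_nonzero_TP also flag classes with zero true positives.
#' @param improvement_epsilon minimum round-over-round improvement in either
#'   overall accuracy or kappa required to continue (auto mode).
#' @param min_categories stop when this few classes remain (default 3).
#' @param seed integer seed driving capping, splitting and model fits.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(low_sensitivity_threshold = 0.20,
                             require_nonzero_TP = TRUE,
                             improvement_epsilon = 0,
                             min_categories = 3, seed = 1) {
  stopifnot(low_sensitivity_threshold >= 0, low_sensitivity_threshold <= 1)
  structure(list(low_sensitivity_threshold = low_sensitivity_threshold,
                 require_nonzero_TP = require_nonzero_TP,
                 improvement_epsilon = improvement_epsilon,
                 min_categories = as.integer(min_categories),
                 seed = as.integer(seed)), class = "selection_config")
}

#' Propose the next round plan from a confusion matrix
#'
#' Implements the greedy merge/remove rule: every class with zero true
#' positives or sensitivity below the threshold is reassigned by its largest
#' off-diagonal row cell -- merged into that class if the two share an
#' ethogram category, removed otherwise. Ties between off-diagonal cells
#' break toward the more frequent target class; classes with no
#' misclassifications map to themselves.
#'
#' @param cm a [confusion_matrix()] from the current round.
#' @param metrics [class_metrics()] for `cm`.
#' @param ethogram ethogram data.frame.
#' @param cfg a [selection_config()].
#' @param round_index index for the returned plan.
#' @param cap cap recorded on the returned plan.
#' @return a [round_plan()].
#' @export
propose_round_plan <- function(cm, metrics, ethogram = cat_ethogram(),
                               cfg = selection_config(), round_index = 2,
                               cap = 7000) {
  classes <- rownames(cm)
  mapping <- setNames(classes, classes)
  freq <- rowSums(cm)
  cats <- .label_category(classes, ethogram)
  for (i in seq_along(classes)) {
    mi <- metrics[metrics$class == classes[i], ]
    sens <- mi$sensitivity
    low <- (cfg$require_nonzero_TP && mi$TP == 0) ||
      (!is.na(sens) && sens < cfg$low_sensitivity_threshold)
    if (!low) next
    row <- as.numeric(cm[i, ])
    row[i] <- -1
    if (max(row) <= 0) next  # never misclassified anywhere; leave as-is
    cand <- which(row == max(row))
    target <- cand[which.max(freq[cand])]
    if (identical(cats[target], cats[i])) {
      mapping[i] <- classes[target]
    } else {
      mapping[i] <- "REMOVED"
    }
  }
  round_plan(round_index, mapping, cap = cap)
}

#' Run the modelling-round protocol for one technique and mount
#'
#' Each round applies its plan (mapping/removal), caps class sizes, makes a
#' seeded 70/30 stratified train/test split, fits the classifier, and
#' evaluates the held-out confusion matrix (overall accuracy, kappa,
#' per-class metrics). With `plans` supplied ("fixed-plan mode") the given rounds
#' are executed in order. Without plans ("auto mode"), follow-up plans are
#' generated by [propose_round_plan()] and the protocol stops when a
#' proposed plan changes nothing, when neither overall accuracy nor kappa
#' improves by more than `improvement_epsilon`, or when `min_categories`
#' classes remain.
#'
#' @param data labelled dataset (preprocessed; see [preprocess_labels()]).
#' @param technique `"rf"` or `"som"`.
#' @param mount mounting-location tag stored on results.
#' @param cfg a [selection_config()].
#' @param plans optional list of [round_plan()]s.
#' @param rf,som technique hyperparameters ([rf_params()], [som_params()];
#'   their seeds are overridden by seeds derived from `cfg$seed`).
#' @param train_frac training fraction of the split.
#' @param max_rounds auto-mode safety limit.
#' @return list of class `modelling_rounds`; each element is a
#'   `round_result` with the trained model, confusion matrix, metrics,
#'   overall accuracy and kappa.
#' @export
run_modelling_rounds <- function(data, technique = c("rf", "som"),
                                 mount = NULL, cfg = selection_config(),
                                 plans = NULL, rf = rf_params(),
                                 som = som_params(), train_frac = 0.7,
                                 max_rounds = 10) {
  technique <- match.arg(technique)
  stopifnot("behaviour" %in% names(data))
  fixed_plans_mode <- !is.null(plans)
  n_rounds <- if (fixed_plans_mode) length(plans) else max_rounds
  seeds <- matrix(derive_seeds(cfg$seed, n_rounds * 3), ncol = 3)
  results <- list()
  current <- data
  for (r in seq_len(n_rounds)) {
    plan <- if (fixed_plans_mode) plans[[r]] else {
      if (r == 1) {
        cls <- sort(unique(normalise_label(current$behaviour)))
        round_plan(1, setNames(cls, cls), cap = 7000)
      } else {
        prev <- results[[r - 1]]
        cap <- if (length(prev$classes) <= cfg$min_categories) 5000 else 7000
        pl <- propose_round_plan(prev$cm, prev$metrics, cfg = cfg,
                                 round_index = r, cap = cap)
        if (all(pl$mapping == names(pl$mapping))) break  # fixed point
        pl
      }
    }
    current <- apply_round_plan(current, plan)
    if (!nrow(current)) stop("round ", r, " removed every epoch")
    capped <- cap_class_counts(current, cap = plan$cap, seed = seeds[r, 1])
    split <- train_test_split(capped, train_frac = train_frac,
                              seed = seeds[r, 2])
    params <- if (technique == "rf") rf else som
    params$seed <- seeds[r, 3]
    model <- behaviour_model(split$train, technique, params, mount = mount)
    pred <- predict(model, split$test)
    cls <- sort(unique(c(split$train$behaviour, split$test$behaviour)))
    cm <- confusion_matrix(split$test$behaviour, as.character(pred), cls)
    metrics <- class_metrics(cm)
    res <- structure(list(
      round = r, technique = technique, mount = mount, plan = plan,
      model = model, cm = cm, metrics = metrics,
      overall_accuracy = overall_accuracy(cm), kappa = cohen_kappa(cm),
      classes = cls, n_train = nrow(split$train), n_test = nrow(split$test)
    ), class = "round_result")
    results[[r]] <- res
    if (!fixed_plans_mode) {
      if (length(cls) <= cfg$min_categories) break
      if (r >= 2) {
        gain_oa <- res$overall_accuracy - results[[r - 1]]$overall_accuracy
        gain_k <- res$kappa$kappa - results[[r - 1]]$kappa$kappa
        if (gain_oa <= cfg$improvement_epsilon &&
            gain_k <= cfg$improvement_epsilon) break
      }
    }
  }
  structure(results, class = "modelling_rounds")
}

#' @export
print.round_result <- function(x, ...) {
  cat(sprintf("Round %d [%s%s]: %d classes, OA = %.3f, kappa = %.3f (%s)\n",
              x$round, toupper(x$technique),
              if (!is.null(x$mount)) paste0("/", x$mount) else "",
              length(x$classes), x$overall_accuracy, x$kappa$kappa,
              x$kappa$interpretation))
  invisible(x)
}

#' @export
print.modelling_rounds <- function(x, ...) {
  cat("Modelling rounds:\n")
  for (r in x) print(r)
  invisible(x)
}

#' Summarise modelling rounds as a kappa/accuracy table
#'
#' One row per round with technique, mount, class count, kappa and overall
#' accuracy -- the layout of a per-round performance table.
#'
#' @param x a `modelling_rounds` list (or a plain list of `round_result`s).
#' @param ... unused.
#' @return data.frame.
#' @export
as.data.frame.modelling_rounds <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) data.frame(
    round = r$round, technique = r$technique,
    mount = if (is.null(r$mount)) NA_character_ else r$mount,
    n_classes = length(r$classes), n_train = r$n_train, n_test = r$n_test,
    kappa = r$kappa$kappa, overall_accuracy = r$overall_accuracy,
    stringsAsFactors = FALSE)))
}

#' Run the full fixed-plan protocol over both mounts and both techniques
#'
#' Builds the labelled dataset per mount, preprocesses labels, and runs the
#' four fixed rounds for RF and SOM on each mount: 2 mounts x 2 techniques
#' x 4 rounds = 16 models.
#'
#' @param study an `acc_study`.
#' @param cfg a [selection_config()] (its seed drives all per-round seeds).
#' @param rf,som technique hyperparameters.
#' @param mounts,techniques subsets to run.
#' @return list of class `protocol_results` with one `modelling_rounds`
#'   element per (mount, technique), named `"<mount>_<technique>"`, and a
#'   `summary` attribute data.frame.
#' @export
run_study_protocol <- function(study, cfg = selection_config(),
                               rf = rf_params(), som = som_params(),
                               mounts = c("collar", "harness"),
                               techniques = c("rf", "som")) {
  stopifnot(inherits(study, "acc_study"))
  plans <- fixed_round_plans()
  seeds <- derive_seeds(cfg$seed, length(mounts) * length(techniques))
  out <- list()
  i <- 0
  for (mount in mounts) {
    dat <- preprocess_labels(study_features(study, mount))
    for (tech in techniques) {
      i <- i + 1
      cfg_i <- cfg
      cfg_i$seed <- seeds[i]
      out[[paste(mount, tech, sep = "_")]] <-
        run_modelling_rounds(dat, tech, mount = mount, cfg = cfg_i,
                             plans = plans, rf = rf, som = som)
    }
  }
  attr(out, "summary") <- do.call(rbind, lapply(out, as.data.frame))
  class(out) <- "protocol_results"
  out
}

#' @export
print.protocol_results <- function(x, ...) {
  df <- attr(x, "summary")
  rownames(df) <- NULL
  cat("Fixed-plan protocol:", length(x), "model series,",
      nrow(df), "models\n")
  print(df, digits = 3)
  invisible(x)
}

#' Serialise round plans to / from YAML
#'
#' @param plans list of [round_plan()]s.
#' @param path file path.
#' @return `path` (write) or the restored plan list (read).
#' @export
write_round_plans_yaml <- function(plans, path) {
  yaml::write_yaml(lapply(plans, function(p)
    list(round = p$round_index, cap = p$cap, mapping = as.list(p$mapping))),
    path)
  invisible(path)
}

#' @rdname write_round_plans_yaml
#' @export
read_round_plans_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p)
    round_plan(p$round, unlist(p$mapping), cap = p$cap))
}
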