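# small polynomial rolling hash so artefacts can record the config that
# produced them (not cryptographic; collision risk is irrelevant here)
.config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in s) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.pipeline_schema <- function() list(
  simulate = names(formals(sim_config)),
  preprocess = c("min_count_s"),
  rf = names(formals(rf_params)),
  som = names(formals(som_params)),
  selection = names(formals(selection_config)),
  budget = c("days", "window", "round"),
  io = c("write_raw"),
  seed = NULL, out_dir = NULL
)

#' Assemble and validate a pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Unknown keys anywhere in the
#' structure are rejected, and stage arguments are validated (via their
#' constructors) before any computation runs.
#'
#' @param config named list (or path to a YAML file) with any of the blocks
#'   `simulate`, `preprocess`, `rf`, `som`, `selection`, `budget`, `io`,
#'   and scalars `seed`, `out_dir`.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  schema <- .pipeline_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (blk in intersect(names(config), names(schema))) {
    allowed <- schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[blk]]), allowed)
    if (length(bad))
      stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) config$out_dir <- "felacc-output"
  sim_args <- config$simulate
  sim_args$seed <- config$seed
  config$sim <- do.call(sim_config, if (is.null(sim_args)) list(seed = config$seed) else sim_args)
  # the hash covers the analytical configuration, not the output location
  config$hash <- .config_hash(config[setdiff(names(config),
                                             c("hash", "out_dir"))])
  class(config) <- "pipeline_config"
  config
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages end to end on a synthetic study: `simulate`
#' (generate the study; write BORIS-style annotation exports and, if
#' requested, ActiLife-style raw CSVs of the annotated windows), `extract`
#' (labelled feature datasets per mount, written as CSV), `rounds` (the
#' fixed-plan protocol for both mounts and techniques; per-round kappa and
#' overall-accuracy table as TSV), `budget` (daily activity budgets under
#' the final-round models plus a Dirichlet regression coefficient table),
#' and `report` (a combined summary). Every artefact records the config
#' hash; a structured log line per stage goes to `pipeline.log`.
#'
#' @param config a [pipeline_config()] (or a list / YAML path coerced
#'   through it).
#' @param stages subset of stages to run, in order.
#' @return invisible list with the in-memory artefacts (`study`,
#'   `datasets`, `protocol`, `budgets`, `fit`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "extract", "rounds",
                                    "budget", "report")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_stage <- function(stage, t0) {
    line <- sprintf("%s\tstage=%s\tseed=%d\tconfig=%s\telapsed=%.2fs",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                    config$seed, config$hash,
                    as.numeric(Sys.time()) - t0)
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  state <- list()
  need <- function(what, producer) {
    if (is.null(state[[what]]))
      stop("missing upstream artefact '", what, "': run the '", producer,
           "' stage first")
    state[[what]]
  }

  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    state$study <- generate_study(config$sim)
    for (id in names(state$study$cats))
      write_boris_csv(state$study$cats[[id]]$annotation,
                      file.path(out_dir, paste0("annotation_", id, ".csv")),
                      subject = id)
    if (isTRUE(config$io$write_raw)) {
      win <- config$sim$annotated_window
      for (id in names(state$study$cats))
        for (m in c("collar", "harness"))
          write_actigraph_csv(
            study_trace(state$study, id, m, day = 1, window = win),
            file.path(out_dir, paste0("raw_", id, "_", m, ".csv")))
    }
    log_stage("simulate", t0)
  }
  if ("extract" %in% stages) {
    t0 <- as.numeric(Sys.time())
    study <- need("study", "simulate")
    state$datasets <- lapply(c(collar = "collar", harness = "harness"),
                             function(m) {
      dat <- study_features(study, m)
      pp_args <- config$preprocess
      dat <- do.call(preprocess_labels,
                     c(list(dat), if (is.null(pp_args)) list() else pp_args))
      write.csv(dat, file.path(out_dir, paste0("features_", m, ".csv")),
                row.names = FALSE)
      write_filter_report(attr(dat, "filter_report"),
                          file.path(out_dir, paste0("filtering_", m, ".tsv")))
      dat
    })
    log_stage("extract", t0)
  }
  if ("rounds" %in% stages) {
    t0 <- as.numeric(Sys.time())
    datasets <- need("datasets", "extract")
    plans <- fixed_round_plans()
    sel <- do.call(selection_config,
                   c(list(seed = config$seed),
                     config$selection[setdiff(names(config$selection), "seed")]))
    rfp <- do.call(rf_params, config$rf[setdiff(names(config$rf), "seed")] %||% list())
    smp <- do.call(som_params, config$som[setdiff(names(config$som), "seed")] %||% list())
    seeds <- derive_seeds(config$seed, 4)
    res <- list(); i <- 0
    for (m in c("collar", "harness"))
      for (tech in c("rf", "som")) {
        i <- i + 1
        sel_i <- sel; sel_i$seed <- seeds[i]
        res[[paste(m, tech, sep = "_")]] <-
          run_modelling_rounds(datasets[[m]], tech, mount = m, cfg = sel_i,
                               plans = plans, rf = rfp, som = smp)
      }
    attr(res, "summary") <- do.call(rbind, lapply(res, as.data.frame))
    class(res) <- "protocol_results"
    state$protocol <- res
    tab <- attr(res, "summary")
    tab$config <- config$hash
    utils::write.table(tab, file.path(out_dir, "rounds_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log_stage("rounds", t0)
  }
  if ("budget" %in% stages) {
    t0 <- as.numeric(Sys.time())
    protocol <- need("protocol", "rounds")
    study <- need("study", "simulate")
    round_i <- config$budget$round %||% length(protocol[[1]])
    budgets <- do.call(rbind, lapply(protocol, function(series) {
      r <- series[[round_i]]
      predict_budgets(r$model, study, days = config$budget$days,
                      window = config$budget$window, round_tag = round_i)
    }))
    attr(budgets, "classes") <-
      protocol[[1]][[round_i]]$model$classes
    class(budgets) <- c("activity_budget", "data.frame")
    state$budgets <- budgets
    write_budgets_csv(budgets, file.path(out_dir, "budgets.csv"))
    yb <- budget_matrix(budgets)
    yb <- zero_adjust(yb, budgets$n_epochs)
    df <- as.data.frame(budgets)
    # drop covariates that do not vary (e.g. a single predicted day)
    terms <- c("mount", "technique", "factor(day)")[
      c(length(unique(df$mount)) > 1, length(unique(df$technique)) > 1,
        length(unique(df$day)) > 1)]
    if (!length(terms)) terms <- "1"
    fit <- dirichlet_reg(stats::as.formula(
      paste("yb ~", paste(terms, collapse = " + "))), data = df)
    state$fit <- fit
    utils::write.table(summary(fit), file.path(out_dir, "dirichlet_fit.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log_stage("budget", t0)
  }
  if ("report" %in% stages) {
    t0 <- as.numeric(Sys.time())
    protocol <- need("protocol", "rounds")
    lines <- c(sprintf("felacc pipeline report (config %s, seed %d)",
                       config$hash, config$seed), "",
               "Per-round kappa / overall accuracy:",
               utils::capture.output(print(
                 attr(protocol, "summary"), digits = 3)))
    if (!is.null(state$budgets)) {
      mean_budget <- aggregate(
        budget_matrix(state$budgets),
        by = list(mount = state$budgets$mount,
                  technique = state$budgets$technique), FUN = mean)
      lines <- c(lines, "", "Mean daily activity budgets (proportions):",
                 utils::capture.output(print(mean_budget, digits = 3)))
    }
    writeLines(lines, file.path(out_dir, "report.txt"))
    log_stage("report", t0)
  }
  invisible(state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
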