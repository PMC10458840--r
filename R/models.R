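#' Random-forest hyperparameters
#'
#' Defaults follow the classification conventions: 500 trees and
#' `mtry = floor(sqrt(p))` variables sampled at each split (5 for the 32
#' identifier variables). Set `mtry = 32` for the literal all-variables
#' reading.
#'
#' @param n_trees number of trees.
#' @param mtry candidate variables per split; `NULL` means
#'   `floor(sqrt(p))` at fit time.
#' @param seed integer seed.
#' @return list of class `rf_params`.
#' @export
rf_params <- function(n_trees = 500, mtry = NULL, seed = 1) {
  stopifnot(n_trees >= 1, is.null(mtry) || mtry >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)), class = "rf_params")
}

#' Supervised-SOM hyperparameters
#'
#' Defaults: an 8 x 6 hexagonal grid, 100 presentations of the dataset
#' (`rlen`), learning rate decaying linearly 0.05 to 0.01, an initial
#' Gaussian neighbourhood radius covering two-thirds of the map diagonal
#' decaying linearly to 1, and equal weighting of the feature and class
#' codebook layers.
#'
#' @param grid_rows,grid_cols map dimensions.
#' @param topology `"hexagonal"` or `"rectangular"` unit layout.
#' @param rlen number of passes through the training data.
#' @param alpha_start,alpha_end learning-rate schedule endpoints.
#' @param radius_start initial neighbourhood radius in grid units; `NULL`
#'   means 2/3 of the map diagonal.
#' @param class_layer_weight weight of the class layer in the winner
#'   distance, in (0, 1).
#' @param seed integer seed.
#' @return list of class `som_params`.
#' @export
som_params <- function(grid_rows = 8, grid_cols = 6,
                       topology = c("hexagonal", "rectangular"),
                       rlen = 100, alpha_start = 0.05, alpha_end = 0.01,
                       radius_start = NULL, class_layer_weight = 0.5,
                       seed = 1) {
  topology <- match.arg(topology)
  stopifnot(grid_rows >= 1, grid_cols >= 1, rlen >= 1,
            alpha_start >= alpha_end, alpha_end > 0,
            class_layer_weight > 0, class_layer_weight < 1)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols), topology = topology,
                 rlen = as.integer(rlen), alpha_start = alpha_start,
                 alpha_end = alpha_end, radius_start = radius_start,
                 class_layer_weight = class_layer_weight,
                 seed = as.integer(seed)), class = "som_params")
}

# grid unit coordinates; hexagonal layout offsets odd rows by half a unit
.som_grid <- function(rows, cols, topology) {
  r <- rep(seq_len(rows), each = cols)
  c <- rep(seq_len(cols), times = rows)
  if (topology == "hexagonal") {
    cbind(x = c + 0.5 * ((r - 1) %% 2), y = (r - 1) * sqrt(3) / 2)
  } else {
    cbind(x = c, y = r - 1)
  }
}

.schema_hash <- function(feature_names) {
  paste0("v1:", paste(feature_names, collapse = "|"))
}

# split a labelled dataset into the feature matrix and the label factor
.dataset_xy <- function(data, features = feature_names()) {
  if (is.matrix(data)) {
    x <- data
  } else {
    miss <- setdiff(features, names(data))
    if (length(miss)) stop("missing feature column(s): ",
                           paste(miss, collapse = ", "))
    x <- as.matrix(data[features])
  }
  if (anyNA(x)) stop("missing values in features")
  y <- if (is.data.frame(data) && "behaviour" %in% names(data))
    factor(data$behaviour) else NULL
  list(x = x, y = y)
}

#' Fit a behaviour classifier for one mounting location
#'
#' Trains either a random forest (majority-vote ensemble of classification
#' trees on the raw identifier variables) or a supervised self-organizing
#' map (features are z-scored on training statistics; codebooks carry a
#' fused feature layer and one-hot class layer; prediction reads the class
#' codebook of the unit nearest in feature space). Both techniques are
#' deterministic under their parameter seed.
#'
#' @param data labelled dataset: a data.frame with the 32 feature columns
#'   and a `behaviour` column.
#' @param technique `"rf"` or `"som"`.
#' @param params an [rf_params()] or [som_params()] matching the technique.
#' @param mount optional mounting-location tag stored on the model.
#' @return An object of class `behaviour_model` with elements `technique`,
#'   `mount`, `classes`, `fit`, `params`, `schema`, and training metadata.
#' @seealso [predict.behaviour_model()]
#' @export
behaviour_model <- function(data, technique = c("rf", "som"), params = NULL,
                            mount = NULL) {
  technique <- match.arg(technique)
  xy <- .dataset_xy(data)
  if (is.null(xy$y)) stop("data must carry a 'behaviour' column")
  y <- droplevels(xy$y)
  if (nlevels(y) < 2) stop("at least 2 behaviour classes are required")
  x <- xy$x
  feats <- colnames(x)

  if (technique == "rf") {
    if (is.null(params)) params <- rf_params()
    stopifnot(inherits(params, "rf_params"))
    mtry <- if (is.null(params$mtry)) floor(sqrt(ncol(x))) else
      min(params$mtry, ncol(x))
    fit <- ranger::ranger(x = x, y = y, num.trees = params$n_trees,
                          mtry = mtry, seed = params$seed, num.threads = 1,
                          verbose = FALSE)
  } else {
    if (is.null(params)) params <- som_params()
    stopifnot(inherits(params, "som_params"))
    fit <- .ssom_fit(x, y, params)
  }

  structure(list(
    technique = technique, mount = mount, classes = levels(y),
    fit = fit, params = params, schema = .schema_hash(feats),
    features = feats,
    class_counts = as.integer(table(y)), n_train = length(y)
  ), class = "behaviour_model")
}

.ssom_fit <- function(x, y, params) {
  n_units <- params$grid_rows * params$grid_cols
  if (n_units > nrow(x) / 10)
    warning("under-populated map: ", n_units, " units for ", nrow(x),
            " training rows")
  centre <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1
  xs <- scale(x, center = centre, scale = scale)
  k <- nlevels(y)
  onehot <- matrix(0, nrow(x), k)
  onehot[cbind(seq_len(nrow(x)), as.integer(y))] <- 1
  grid <- .som_grid(params$grid_rows, params$grid_cols, params$topology)
  radius <- if (is.null(params$radius_start))
    (2 / 3) * sqrt(diff(range(grid[, 1]))^2 + diff(range(grid[, 2]))^2)
  else params$radius_start
  set.seed(params$seed)
  init_rows <- sample.int(nrow(x), n_units, replace = nrow(x) < n_units)
  codes_x <- xs[init_rows, , drop = FALSE]
  codes_y <- matrix(1 / k, n_units, k)
  orders <- t(replicate(params$rlen, sample.int(nrow(x))))
  if (params$rlen == 1) orders <- matrix(orders, nrow = 1)
  trained <- .ssom_train(xs, onehot, codes_x, codes_y, grid, orders,
                         params$alpha_start, params$alpha_end,
                         max(radius, 1), params$class_layer_weight)
  list(codes_x = trained$codes_x, codes_y = trained$codes_y,
       energy = as.numeric(trained$energy), grid = grid,
       centre = centre, scale = scale, class_levels = levels(y))
}

#' Predict behaviour labels for new epochs
#'
#' Random forests predict by tree majority vote; supervised SOMs map each
#' epoch to its nearest unit in (standardized) feature space and return the
#' argmax of that unit's class codebook. The feature schema of `newdata`
#' must match the training schema exactly.
#'
#' @param object a [behaviour_model()].
#' @param newdata data.frame with the model's feature columns, or a feature
#'   matrix.
#' @param ... unused.
#' @return factor of predicted behaviour labels, one per row.
#' @export
predict.behaviour_model <- function(object, newdata, ...) {
  xy <- .dataset_xy(newdata, features = object$features)
  x <- xy$x
  if (!identical(.schema_hash(colnames(x)), object$schema))
    stop("feature schema mismatch: model was trained on a different feature set")
  if (object$technique == "rf") {
    p <- predict(object$fit, data = as.data.frame(x), num.threads = 1)
    factor(as.character(p$predictions), levels = object$classes)
  } else {
    fit <- object$fit
    xs <- scale(x, center = fit$centre, scale = fit$scale)
    winners <- .ssom_map(xs, fit$codes_x)
    lab <- fit$class_levels[max.col(fit$codes_y[winners, , drop = FALSE],
                                    ties.method = "first")]
    factor(lab, levels = object$classes)
  }
}

#' @export
print.behaviour_model <- function(x, ...) {
  cat(sprintf("Behaviour classifier: %s%s, %d classes, %d training epochs\n",
              toupper(x$technique),
              if (!is.null(x$mount)) paste0(" (", x$mount, ")") else "",
              length(x$classes), x$n_train))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Save / load a trained behaviour model as a versioned archive
#'
#' Models are serialised with a format version; loading refuses archives
#' written by a different format version.
#'
#' @param model a `behaviour_model`.
#' @param path file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_behaviour_model <- function(model, path) {
  stopifnot(inherits(model, "behaviour_model"))
  saveRDS(list(format = "felacc-model-1", model = model), path)
  invisible(path)
}

#' @rdname save_behaviour_model
#' @export
load_behaviour_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "felacc-model-1"))
    stop("unsupported model archive version: ", obj$format)
  obj$model
}
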