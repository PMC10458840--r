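#' Predict daily activity budgets with a trained model
#'
#' For each requested cat-day, realises the raw trace, extracts epoch
#' features, predicts every epoch with the model, and tallies predicted
#' class frequencies into a composition (proportions summing to 1).
#'
#' @param model a [behaviour_model()] (its `mount` tag selects the trace).
#' @param study an `acc_study`.
#' @param days integer vector of day indices (default: all days after the
#'   annotated day 1).
#' @param cats cat ids (default: all).
#' @param window optional within-day second window to restrict prediction
#'   (useful to keep small studies fast).
#' @param round_tag optional round label stored on the result.
#' @return data.frame of class `activity_budget`: columns `cat_id`, `day`,
#'   `mount`, `technique`, `round`, `n_epochs`, then one proportion column
#'   per model class; a `classes` attribute names the composition columns.
#' @export
predict_budgets <- function(model, study, days = NULL,
                            cats = names(study$cats), window = NULL,
                            round_tag = NA) {
  stopifnot(inherits(model, "behaviour_model"), inherits(study, "acc_study"))
  mount <- if (is.null(model$mount)) "collar" else model$mount
  if (is.null(days)) days <- setdiff(seq_len(study$config$n_days), 1L)
  if (!length(days)) stop("no days requested")
  rows <- list()
  for (id in cats) {
    for (d in days) {
      tr <- study_trace(study, id, mount, day = d, window = window)
      fe <- extract_features(tr)
      if (!nrow(fe)) stop("empty day: no complete epochs for ", id, " day ", d)
      pred <- predict(model, fe)
      tab <- table(factor(pred, levels = model$classes))
      prop <- as.numeric(tab) / sum(tab)
      row <- data.frame(cat_id = id, day = d, mount = mount,
                        technique = model$technique, round = round_tag,
                        n_epochs = sum(tab), stringsAsFactors = FALSE)
      row[model$classes] <- as.list(prop)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "classes") <- model$classes
  class(out) <- c("activity_budget", "data.frame")
  out
}

#' Extract the composition matrix from an activity-budget table
#'
#' @param budgets an `activity_budget` data.frame (or any data.frame with
#'   the class proportion columns).
#' @param classes composition column names; defaults to the `classes`
#'   attribute.
#' @return numeric matrix, rows summing to 1.
#' @export
budget_matrix <- function(budgets, classes = attr(budgets, "classes")) {
  if (is.null(classes)) stop("classes must be given (no 'classes' attribute)")
  as.matrix(as.data.frame(budgets)[classes])
}

#' Pull compositions away from the boundary
#'
#' The standard compositional zero adjustment
#' `y* = (y * (n_obs - 1) + 1/K) / n_obs`: strictly interior, still sums
#' to 1, and converges to `y` as the number of observations grows. Required
#' before Dirichlet likelihood evaluation whenever a class was never
#' predicted on some cat-day.
#'
#' @param proportions numeric vector summing to 1, or a matrix of row
#'   compositions.
#' @param n_obs number of observations behind each composition (scalar or
#'   per-row vector).
#' @return adjusted vector or matrix.
#' @export
#' @examples
#' zero_adjust(c(1, 0), 100)  # 0.995 0.005
zero_adjust <- function(proportions, n_obs) {
  stopifnot(all(n_obs >= 1))
  if (is.matrix(proportions)) {
    k <- ncol(proportions)
    (proportions * (n_obs - 1) + 1 / k) / n_obs
  } else {
    k <- length(proportions)
    (proportions * (n_obs - 1) + 1 / k) / n_obs
  }
}

#' Dirichlet log-likelihood
#'
#' Sum over observations of
#' `log Gamma(sum_k alpha_k) - sum_k log Gamma(alpha_k) +
#'  sum_k (alpha_k - 1) log y_k`.
#'
#' @param y n x K matrix (or length-K vector) of strictly interior
#'   compositions.
#' @param alpha concentrations: length-K vector or n x K matrix, all > 0.
#' @return total log-likelihood (scalar).
#' @export
dirichlet_loglik <- function(y, alpha) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  if (!is.matrix(alpha))
    alpha <- matrix(alpha, nrow(y), length(alpha), byrow = TRUE)
  stopifnot(all(dim(y) == dim(alpha)))
  if (any(y <= 0) || any(y >= 1))
    stop("compositions must be strictly interior; zero-adjust first")
  if (any(alpha <= 0)) stop("alpha must be positive")
  sum(lgamma(rowSums(alpha)) - rowSums(lgamma(alpha)) +
        rowSums((alpha - 1) * log(y)))
}

#' Draw Dirichlet compositions
#'
#' @param n number of draws.
#' @param alpha length-K concentration vector, or an n x K matrix of per-draw
#'   concentrations.
#' @return n x K matrix of compositions.
#' @export
rdirichlet <- function(n, alpha) {
  if (!is.matrix(alpha)) alpha <- matrix(alpha, n, length(alpha), byrow = TRUE)
  stopifnot(nrow(alpha) == n)
  g <- matrix(rgamma(length(alpha), shape = alpha), n, ncol(alpha))
  g / rowSums(g)
}

# negative log-likelihood and its analytic gradient for the log-link
# common parametrization; b is vec(beta) with beta a p x K matrix
.dirichlet_negll <- function(b, x, y, logy = log(y)) {
  beta <- matrix(b, ncol(x), ncol(y))
  alpha <- exp(x %*% beta)
  -(sum(lgamma(rowSums(alpha)) - rowSums(lgamma(alpha)) +
          rowSums((alpha - 1) * logy)))
}

.dirichlet_neggr <- function(b, x, y, logy = log(y)) {
  beta <- matrix(b, ncol(x), ncol(y))
  alpha <- exp(x %*% beta)
  a0 <- rowSums(alpha)
  core <- alpha * (digamma(a0) - digamma(alpha) + logy)  # n x k
  -as.numeric(crossprod(x, core))                        # p x k, vectorised
}

#' Dirichlet regression with log link (common parametrization)
#'
#' Models each concentration parameter as a log-linear function of the
#' covariates, `alpha_k(x) = exp(x' beta_k)`, and maximises the Dirichlet
#' likelihood by BFGS with the analytic gradient, starting from a
#' method-of-moments fit. Standard errors come from the inverse observed
#' information (numerical Hessian at the optimum); Wald z and two-sided p
#' values are reported per coefficient.
#'
#' @param formula model formula whose left-hand side evaluates (in `data`)
#'   to an n x K composition matrix, e.g.
#'   `budget_matrix(b) ~ mount + technique + factor(day)`.
#' @param data data.frame of covariates.
#' @param zero_adjust_n if not `NULL`, boundary compositions are first
#'   passed through [zero_adjust()] with this `n_obs`.
#' @param maxit BFGS iteration cap.
#' @return object of class `dirichlet_reg` with elements `coefficients`
#'   (p x K matrix), `vcov`, `se`, `z`, `p_value`, `logLik`, `converged`,
#'   `fitted_alpha`, and the model frame pieces.
#' @seealso [compare_budgets()], [dirichlet_loglik()]
#' @export
dirichlet_reg <- function(formula, data = NULL, zero_adjust_n = NULL,
                          maxit = 500) {
  y <- eval(formula[[2]], data, environment(formula))
  y <- as.matrix(y)
  k <- ncol(y)
  if (k < 2) stop("compositions need at least 2 classes")
  if (is.null(colnames(y))) colnames(y) <- paste0("class", seq_len(k))
  if (!is.null(zero_adjust_n)) y <- zero_adjust(y, zero_adjust_n)
  if (any(y <= 0) || any(y >= 1))
    stop("boundary compositions; supply zero_adjust_n")
  rhs <- formula
  rhs[[2]] <- NULL
  x <- stats::model.matrix(rhs, if (is.null(data)) parent.frame() else data)
  n <- nrow(y)
  if (nrow(x) != n) stop("design and response dimensions differ")
  if (n < 2) stop("at least 2 observations are required")
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  p <- ncol(x)
  logy <- log(y)
  negll <- function(b) .dirichlet_negll(b, x, y, logy)
  neggr <- function(b) .dirichlet_neggr(b, x, y, logy)

  # method-of-moments start: alpha0 from the component variances,
  # intercept = log(mean * alpha0), other coefficients 0
  m <- colMeans(y)
  v <- apply(y, 2, var)
  s <- (m * (1 - m)) / pmax(v, 1e-12) - 1
  a0 <- stats::median(s[s > 0])
  if (!is.finite(a0) || a0 <= 0) a0 <- k
  b0 <- matrix(0, p, k)
  ic <- match("(Intercept)", colnames(x))
  if (!is.na(ic)) b0[ic, ] <- log(pmax(m * a0, 1e-8))
  start_ll <- -negll(as.numeric(b0))

  opt <- optim(as.numeric(b0), negll, neggr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12), hessian = TRUE)
  beta <- matrix(opt$par, p, k,
                 dimnames = list(colnames(x), colnames(y)))
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  converged <- opt$convergence == 0 && !is.null(vc) &&
    all(is.finite(vc)) && all(diag(vc) > 0)
  if (is.null(vc)) vc <- matrix(NA_real_, p * k, p * k)
  par_names <- as.character(outer(colnames(x), colnames(y),
                                  function(a, b) paste(b, a, sep = ":")))
  dimnames(vc) <- list(par_names, par_names)
  se <- matrix(sqrt(pmax(diag(vc), 0)), p, k,
               dimnames = dimnames(beta))
  z <- beta / se
  structure(list(
    coefficients = beta, vcov = vc, se = se, z = z,
    p_value = 2 * pnorm(-abs(z)),
    logLik = -opt$value, start_logLik = start_ll,
    converged = converged, n = n, k = k,
    fitted_alpha = exp(x %*% beta), x = x, y = y,
    formula = formula, classes = colnames(y)
  ), class = "dirichlet_reg")
}

#' @export
coef.dirichlet_reg <- function(object, ...) object$coefficients

#' @export
vcov.dirichlet_reg <- function(object, ...) object$vcov

#' @export
logLik.dirichlet_reg <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.dirichlet_reg <- function(x, ...) {
  cat(sprintf("Dirichlet regression (log link): %d obs, %d classes, logLik %.2f%s\n",
              x$n, x$k, x$logLik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.dirichlet_reg <- function(object, ...) {
  tabs <- lapply(object$classes, function(cl) data.frame(
    class = cl, term = rownames(object$coefficients),
    estimate = object$coefficients[, cl], se = object$se[, cl],
    z = object$z[, cl], p_value = object$p_value[, cl],
    row.names = NULL, stringsAsFactors = FALSE))
  out <- do.call(rbind, tabs)
  attr(out, "logLik") <- object$logLik
  attr(out, "converged") <- object$converged
  class(out) <- c("summary.dirichlet_reg", "data.frame")
  out
}

#' @export
print.summary.dirichlet_reg <- function(x, ...) {
  cat(sprintf("Dirichlet regression coefficients (logLik %.2f):\n",
              attr(x, "logLik")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Fitted expected compositions (or concentrations) for new covariates
#'
#' @param object a [dirichlet_reg()] fit.
#' @param newdata data.frame of covariates (default: training frame).
#' @param type `"mean"` for expected proportions `alpha/alpha0`, `"alpha"`
#'   for the concentrations.
#' @param ... unused.
#' @return n x K matrix.
#' @export
predict.dirichlet_reg <- function(object, newdata = NULL,
                                  type = c("mean", "alpha"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x else {
    rhs <- object$formula
    rhs[[2]] <- NULL
    stats::model.matrix(rhs, newdata)
  }
  alpha <- exp(x %*% object$coefficients)
  if (type == "alpha") alpha else alpha / rowSums(alpha)
}

#' @export
simulate.dirichlet_reg <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) rdirichlet(object$n, object$fitted_alpha))
}

#' Wald tests of a covariate contrast per behaviour class
#'
#' Tests `c' beta_k = 0` for every class k, where the contrast vector `c`
#' over the design columns is given directly, named (a single coefficient),
#' or derived as the difference of the design rows of a 2-row covariate
#' data.frame (group 1 minus group 2). A contrast of a group with itself
#' gives effect 0 and p = 1.
#'
#' @param fit a [dirichlet_reg()] fit.
#' @param contrast numeric vector over design columns, a design-column name,
#'   or a 2-row data.frame of covariate settings.
#' @return data.frame: class, estimate, se, z, p_value.
#' @export
compare_budgets <- function(fit, contrast) {
  stopifnot(inherits(fit, "dirichlet_reg"))
  p <- nrow(fit$coefficients)
  if (is.character(contrast) && length(contrast) == 1) {
    if (!contrast %in% rownames(fit$coefficients))
      stop("unknown contrast coefficient: ", contrast)
    cvec <- as.numeric(rownames(fit$coefficients) == contrast)
  } else if (is.data.frame(contrast)) {
    if (nrow(contrast) != 2) stop("data.frame contrast needs exactly 2 rows")
    rhs <- fit$formula
    rhs[[2]] <- NULL
    mm <- stats::model.matrix(rhs, contrast)
    cvec <- as.numeric(mm[1, ] - mm[2, ])
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != p) stop("contrast length must equal ", p)
  }
  out <- lapply(seq_len(fit$k), function(kk) {
    idx <- (kk - 1) * p + seq_len(p)
    est <- sum(cvec * fit$coefficients[, kk])
    v <- as.numeric(t(cvec) %*% fit$vcov[idx, idx] %*% cvec)
    se <- sqrt(max(v, 0))
    z <- if (est == 0) 0 else est / se
    data.frame(class = fit$classes[kk], estimate = est, se = se, z = z,
               p_value = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write activity budgets as a long-format CSV
#'
#' One row per (cat, day, model, class) with the predicted proportion.
#'
#' @param budgets an `activity_budget` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_budgets_csv <- function(budgets, path) {
  classes <- attr(budgets, "classes")
  base <- as.data.frame(budgets)[c("cat_id", "day", "mount", "technique",
                                   "round")]
  long <- do.call(rbind, lapply(classes, function(cl)
    cbind(base, data.frame(class = cl,
                           proportion = as.data.frame(budgets)[[cl]]))))
  write.csv(long[order(long$cat_id, long$day, long$class), ], path,
            row.names = FALSE)
  invisible(path)
}
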