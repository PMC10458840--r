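test_that("zero adjustment moves compositions strictly inside the simplex", {
  expect_equal(zero_adjust(c(1, 0), 100), c(0.995, 0.005))
  y <- c(0.2, 0.3, 0.5)
  expect_equal(zero_adjust(y, 1e9), y, tolerance = 1e-7)
  adj <- zero_adjust(c(1, 0, 0), 10)
  expect_true(all(adj > 0 & adj < 1))
  expect_equal(sum(adj), 1)
  m <- zero_adjust(rbind(c(1, 0), c(0.5, 0.5)), c(10, 20))
  expect_equal(rowSums(m), c(1, 1))
})

test_that("the Dirichlet log-likelihood matches closed forms", {
  # flat Dirichlet on K = 3: density is (K-1)! = 2 everywhere
  expect_equal(dirichlet_loglik(c(0.2, 0.3, 0.5), c(1, 1, 1)), log(2))
  # alpha = (2,1,1), y = (1/2,1/4,1/4): log Gamma(4) - log Gamma(2) + log y1
  expect_equal(dirichlet_loglik(c(1 / 2, 1 / 4, 1 / 4), c(2, 1, 1)),
               lgamma(4) - lgamma(2) - 2 * lgamma(1) + log(1 / 2))
  # additivity over observations
  y <- rbind(c(0.2, 0.8), c(0.6, 0.4))
  a <- c(3, 2)
  expect_equal(dirichlet_loglik(y, a),
               dirichlet_loglik(y[1, ], a) + dirichlet_loglik(y[2, ], a))
  expect_error(dirichlet_loglik(c(1, 0), c(1, 1)), "interior")
})

test_that("the analytic score matches finite differences", {
  set.seed(31)
  n <- 40; k <- 3; p <- 2
  x <- cbind(1, rnorm(n))
  y <- rdirichlet(n, c(2, 3, 1))
  for (rep in 1:3) {
    b <- rnorm(p * k, sd = 0.5)
    beta <- matrix(b, p, k)
    analytic <- -felacc:::.dirichlet_neggr(b, x, y, log(y))
    ll <- function(bv) dirichlet_loglik(y, exp(x %*% matrix(bv, p, k)))
    h <- 1e-6
    numeric_g <- vapply(seq_along(b), function(j) {
      e <- numeric(length(b)); e[j] <- h
      (ll(b + e) - ll(b - e)) / (2 * h)
    }, numeric(1))
    expect_equal(analytic, numeric_g, tolerance = 1e-5)
  }
})

test_that("an intercept-only fit recovers a symmetric Dirichlet", {
  set.seed(32)
  y <- rdirichlet(500, c(2, 2, 2))
  colnames(y) <- c("a", "b", "c")
  fit <- dirichlet_reg(y ~ 1, data = data.frame(row = seq_len(500)))
  expect_true(fit$converged)
  alpha <- exp(coef(fit)[1, ])
  expect_lt(max(alpha) / min(alpha), 1.1)       # components within 10%
  expect_gte(fit$logLik, fit$start_logLik)      # optimizer beat the start
})

test_that("group effects are recovered with shrinking error", {
  delta <- 0.8
  rmse <- sapply(c(50, 500), function(n) {
    errs <- sapply(1:8, function(r) {
      set.seed(1000 + 7 * n + r)
      g <- rep(0:1, each = n / 2)
      alpha <- exp(cbind(log(2) + delta * g, log(3) - 0 * g, log(1.5) + 0 * g))
      y <- rdirichlet(n, alpha)
      colnames(y) <- c("a", "b", "c")
      fit <- dirichlet_reg(y ~ g, data = data.frame(g = g))
      coef(fit)["g", "a"] - delta
    })
    sqrt(mean(errs^2))
  })
  expect_lt(rmse[2], rmse[1])
  expect_lt(rmse[2], 0.2)
})

test_that("duplicating the data preserves estimates and doubles the log-likelihood", {
  set.seed(33)
  g <- rep(0:1, each = 30)
  y <- rdirichlet(60, exp(cbind(0.5 + 0.5 * g, 1 + 0 * g)))
  colnames(y) <- c("a", "b")
  d1 <- data.frame(g = g)
  fit1 <- dirichlet_reg(y ~ g, data = d1)
  fit2 <- dirichlet_reg(rbind(y, y) ~ g, data = rbind(d1, d1))
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-4)
  expect_equal(fit2$logLik, 2 * fit1$logLik, tolerance = 1e-4)
})

test_that("degenerate designs and boundary compositions are refused", {
  y <- rdirichlet(20, c(1, 1))
  d <- data.frame(g = rep(1, 20))
  expect_error(dirichlet_reg(y ~ g, data = d), "rank deficient")
  yb <- y; yb[1, ] <- c(1, 0)
  expect_error(dirichlet_reg(yb ~ 1, data = d), "boundary")
  # ... unless zero adjustment is requested
  fit <- dirichlet_reg(yb ~ 1, data = d, zero_adjust_n = 100)
  expect_true(is.finite(fit$logLik))
})

test_that("self-contrasts give zero effect and p = 1", {
  set.seed(34)
  g <- factor(rep(c("collar", "harness"), each = 25))
  y <- rdirichlet(50, c(2, 2))
  colnames(y) <- c("a", "b")
  fit <- dirichlet_reg(y ~ g, data = data.frame(g = g))
  same <- data.frame(g = factor(c("collar", "collar"),
                                levels = levels(g)))
  res <- compare_budgets(fit, same)
  expect_equal(res$estimate, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
  # named-coefficient and data.frame contrasts agree
  diffd <- data.frame(g = factor(c("harness", "collar"), levels = levels(g)))
  r1 <- compare_budgets(fit, "gharness")
  r2 <- compare_budgets(fit, diffd)
  expect_equal(r1$estimate, r2$estimate)
  expect_error(compare_budgets(fit, "nonexistent"), "unknown contrast")
})

test_that("strong simulated effects are detected with high power", {
  hits <- 0
  for (r in 1:25) {
    set.seed(400 + r)
    n <- 200
    g <- rep(0:1, each = n / 2)
    alpha <- exp(cbind(1 + 1 * g, 1.2 + 0 * g, 0.8 + 0 * g))
    y <- rdirichlet(n, alpha)
    colnames(y) <- c("a", "b", "c")
    fit <- dirichlet_reg(y ~ g, data = data.frame(g = g))
    res <- compare_budgets(fit, "g")
    hits <- hits + (res$p_value[res$class == "a"] < 0.05)
  }
  expect_gte(hits / 25, 0.9)
})

test_that("predicted budgets are proper compositions that conserve epochs", {
  cfg <- tiny_config(n_cats = 2, n_days = 2, day_length_s = 400,
                     annotated_window = c(0, 350), seed = 41)
  study <- generate_study(cfg)
  dat <- study_features(study, "harness")
  m <- behaviour_model(dat, "rf", rf_params(seed = 3), mount = "harness")
  b <- predict_budgets(m, study, days = 2, window = c(0, 200))
  expect_s3_class(b, "activity_budget")
  expect_equal(nrow(b), 2)
  y <- budget_matrix(b)
  expect_equal(unname(rowSums(y)), rep(1, 2), tolerance = 1e-9)
  expect_true(all(b$n_epochs == 200))
  expect_error(predict_budgets(m, study, days = integer(0)), "no days")
})

test_that("budgets from an accurate model recover the ground-truth occupancy", {
  cfg <- tiny_config(n_cats = 1, n_days = 2, day_length_s = 1500,
                     annotated_window = c(0, 1400), seed = 42)
  study <- generate_study(cfg)
  dat <- study_features(study, "harness")
  m <- behaviour_model(dat, "rf", rf_params(seed = 4), mount = "harness")
  b <- predict_budgets(m, study, days = 2)
  y <- budget_matrix(b)[1, ]
  truth <- prop.table(table(study$cats$cat01$labels[1501:3000]))
  for (cl in names(truth))
    expect_lt(abs(y[[cl]] - truth[[cl]]), 0.08)
})

test_that("mean expected compositions follow the fitted concentrations", {
  set.seed(35)
  g <- rep(0:1, each = 40)
  y <- rdirichlet(80, exp(cbind(0.3 + 0.7 * g, 1 + 0 * g)))
  colnames(y) <- c("a", "b")
  fit <- dirichlet_reg(y ~ g, data = data.frame(g = g))
  mu <- predict(fit, data.frame(g = c(0, 1)))
  expect_equal(unname(rowSums(mu)), c(1, 1), tolerance = 1e-12)
  expect_gt(mu[2, "a"], mu[1, "a"])
  al <- predict(fit, data.frame(g = 0), type = "alpha")
  expect_true(all(al > 0))
})
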