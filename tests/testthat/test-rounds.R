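test_that("the fixed round plans reproduce the published class sets", {
  plans <- fixed_round_plans()
  expect_length(plans, 4)

  retained15 <- c("climbing", "jumping", "rubbing", "trotting", "walking",
                  "lying", "sitting", "standing", "grooming", "littering",
                  "digging", "eating", "scratching", "shaking",
                  "allogrooming")
  r1 <- setdiff(unique(plans[[1]]$mapping[retained15]), "REMOVED")
  expect_setequal(r1, retained15)

  r2 <- setdiff(unique(plans[[2]]$mapping), "REMOVED")
  expect_setequal(r2, c("active", "lying", "sitting", "standing",
                        "grooming", "littering", "eating", "scratching"))

  r3 <- setdiff(unique(plans[[3]]$mapping), "REMOVED")
  expect_setequal(r3, c("active", "lying", "sitting", "standing",
                        "grooming", "eating"))

  expect_setequal(setdiff(unique(plans[[4]]$mapping), "REMOVED"),
                  c("active", "inactive", "maintenance"))
  expect_equal(plans[[4]]$cap, 5000)
  expect_equal(plans[[1]]$cap, 7000)
})

test_that("composing the four plans is total over the fifteen behaviours", {
  plans <- fixed_round_plans()
  lab <- c("climbing", "jumping", "rubbing", "trotting", "walking", "lying",
           "sitting", "standing", "grooming", "littering", "digging",
           "eating", "scratching", "shaking", "allogrooming")
  final <- vapply(lab, function(b) {
    for (p in plans) {
      b <- unname(p$mapping[b])
      if (b == "REMOVED") return(b)
    }
    b
  }, character(1))
  expect_true(all(final %in% c("active", "inactive", "maintenance",
                               "REMOVED")))
  # merged targets always share the source's behavioural category
  for (p in plans) {
    chg <- p$mapping[p$mapping != names(p$mapping) & p$mapping != "REMOVED"]
    for (src in names(chg))
      expect_equal(felacc:::.label_category(chg[[src]]),
                   felacc:::.label_category(src))
  }
})

test_that("plans apply as label rewrites with removals dropped", {
  dat <- data.frame(behaviour = c("trotting", "walking", "lying", "shaking"),
                    id = 1:4)
  plans <- fixed_round_plans()
  r2 <- apply_round_plan(dat, plans[[2]])
  expect_equal(r2$behaviour, c("active", "active", "lying"))
  expect_equal(r2$id, 1:3)
  expect_error(apply_round_plan(data.frame(behaviour = "hovering"),
                                plans[[2]]), "hovering")
})

test_that("proposed plans merge within category and remove across", {
  classes <- c("trotting", "walking", "lying", "grooming")
  x <- rbind(c(2, 15, 1, 0),    # trotting mostly identified as walking
             c(1, 80, 2, 0),
             c(0, 1, 120, 2),
             c(0, 9, 1, 2))     # grooming mostly identified as walking
  obs <- rep(classes, rowSums(x))
  idn <- unlist(lapply(1:4, function(i) rep(classes, x[i, ])))
  cm <- confusion_matrix(obs, idn, classes)
  met <- class_metrics(cm)
  plan <- propose_round_plan(cm, met)
  expect_equal(unname(plan$mapping["trotting"]), "walking")   # same category
  expect_equal(unname(plan$mapping["grooming"]), "REMOVED")   # cross category
  expect_equal(unname(plan$mapping["lying"]), "lying")
})

test_that("well-identified classes produce an identity plan", {
  obs <- rep(c("lying", "walking"), each = 50)
  cm <- confusion_matrix(obs, obs)
  plan <- propose_round_plan(cm, class_metrics(cm))
  expect_true(all(plan$mapping == names(plan$mapping)))
})

test_that("off-diagonal ties break toward the more frequent target", {
  classes <- c("trotting", "walking", "rubbing")
  x <- rbind(c(0, 5, 5),        # tied between walking and rubbing
             c(0, 90, 0),
             c(0, 0, 30))
  obs <- rep(classes, rowSums(x))
  idn <- unlist(lapply(1:3, function(i) rep(classes, x[i, ])))
  cm <- confusion_matrix(obs, idn, classes)
  plan <- propose_round_plan(cm, class_metrics(cm))
  expect_equal(unname(plan$mapping["trotting"]), "walking")
})

test_that("fixed-plan mode runs exactly the given rounds, deterministically", {
  cfg <- tiny_config(n_cats = 1, day_length_s = 2000,
                     annotated_window = c(0, 1500), seed = 21)
  study <- generate_study(cfg)
  dat <- study_features(study, "harness")
  # three-behaviour plans: identity, then collapse to categories
  cls <- sort(unique(dat$behaviour))
  plans <- list(round_plan(1, setNames(cls, cls), cap = 400),
                round_plan(2, setNames(felacc:::.label_category(cls), cls),
                           cap = 300))
  res <- run_modelling_rounds(dat, "rf", mount = "harness",
                              cfg = selection_config(seed = 5),
                              plans = plans)
  expect_length(res, 2)
  expect_s3_class(res, "modelling_rounds")
  expect_setequal(res[[2]]$classes, c("active", "inactive", "maintenance"))
  expect_lte(length(res[[2]]$classes), length(res[[1]]$classes))
  res2 <- run_modelling_rounds(dat, "rf", mount = "harness",
                               cfg = selection_config(seed = 5),
                               plans = plans)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  df <- as.data.frame(res)
  expect_equal(df$round, 1:2)
  expect_true(all(c("kappa", "overall_accuracy") %in% names(df)))
})

test_that("auto mode stops once only the category-level classes remain", {
  cfg <- tiny_config(n_cats = 1, day_length_s = 1500,
                     annotated_window = c(0, 1200), seed = 22)
  study <- generate_study(cfg)
  dat <- study_features(study, "harness")
  dat$behaviour <- felacc:::.label_category(dat$behaviour)  # 3 categories
  res <- run_modelling_rounds(dat, "rf", cfg = selection_config(seed = 2))
  expect_length(res, 1)
})

test_that("round plans serialise to YAML and back", {
  plans <- fixed_round_plans()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_round_plans_yaml(plans, path)
  back <- read_round_plans_yaml(path)
  expect_length(back, 4)
  for (i in 1:4) {
    expect_equal(back[[i]]$mapping, plans[[i]]$mapping)
    expect_equal(back[[i]]$cap, plans[[i]]$cap)
  }
})
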