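test_that("ActiLife-style raw CSV round-trips exactly", {
  cfg <- tiny_config()
  labs <- simulate_labels(cfg, 60, seed = 1)
  tr <- synthesize_trace(labs, cfg, "collar", seed = 2, cat_id = "cat07")
  path <- withr::local_tempfile(fileext = ".csv")
  write_actigraph_csv(tr, path)
  back <- read_raw_csv(path)
  expect_equal(nrow(back$data), 1800)  # 60 s at 30 Hz
  expect_identical(back$data, tr$data)
  expect_equal(back$sampling_rate, 30)
  expect_equal(back$cat_id, "cat07")
  expect_equal(back$mount, "collar")
})

test_that("malformed raw files are rejected with a useful error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("header at 30 Hz", "Timestamp,Accelerometer X,Accelerometer Y,Accelerometer Z"),
             path)
  expect_error(read_raw_csv(path), "empty data section")

  writeLines(c("header at 30 Hz",
               "Timestamp,Accelerometer X,Accelerometer Y,Accelerometer Z",
               "0.000000,0.1,0.2,0.3", "0.033333,oops,0.2,0.3"), path)
  expect_error(read_raw_csv(path), "line 4")

  writeLines(c("header at 30 Hz",
               "Timestamp,Accelerometer X,Accelerometer Y,Accelerometer Z",
               "0.066667,0.1,0.2,0.3", "0.033333,0.1,0.2,0.3"), path)
  expect_error(read_raw_csv(path), "non-monotone")

  writeLines(c("no rate here",
               "Timestamp,Accelerometer X,Accelerometer Y,Accelerometer Z",
               "0,0.1,0.2,0.3"), path)
  expect_error(read_raw_csv(path), "sampling rate")
})

test_that("annotation CSV round-trips and rejects bad tracks", {
  track <- data.frame(second = 0:9,
                      behaviour = rep(c("lying", "walking"), 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_boris_csv(track, path, subject = "cat03")
  back <- read_annotation_csv(path)
  expect_equal(back$second, track$second)
  expect_equal(back$behaviour, track$behaviour)
  expect_equal(attr(back, "cat_id"), "cat03")

  bad <- track; bad$behaviour[3] <- "levitating"
  write_boris_csv(bad, path)
  expect_error(read_annotation_csv(path), "levitating")

  gap <- track[-4, ]
  write_boris_csv(gap, path)
  expect_error(read_annotation_csv(path), "gap")
})

test_that("labels are case-normalised against the ethogram", {
  track <- data.frame(second = 0:2,
                      behaviour = c("Lying", "LYING", " lying "))
  path <- withr::local_tempfile(fileext = ".csv")
  write_boris_csv(track, path)
  expect_equal(read_annotation_csv(path)$behaviour, rep("lying", 3))
})

test_that("epoch alignment is half-open, 0-based and offset-aware", {
  cfg <- tiny_config()
  labs <- simulate_labels(cfg, 10, seed = 3)
  tr <- synthesize_trace(labs, cfg, "harness", seed = 4)
  ann <- data.frame(second = 0:9, behaviour = as.character(labs))
  al <- align_epochs(tr, ann)
  expect_equal(al$epoch, 0:9)
  expect_equal(al$label, as.character(labs))
  expect_equal(nrow(al$data), 300)

  # whole-second start offset shifts the epoch indices
  tr2 <- tr; tr2$start_time <- 5
  al2 <- align_epochs(tr2, data.frame(second = 5:14,
                                      behaviour = as.character(labs)))
  expect_equal(al2$epoch, 5:14)
  expect_equal(al2$label, as.character(labs))

  # the same shift expressed as a device/video clock offset
  al3 <- align_epochs(tr, data.frame(second = 2:11,
                                     behaviour = as.character(labs)),
                      clock_offset_s = 2)
  expect_equal(al3$epoch, 2:11)

  expect_error(align_epochs(tr, data.frame(second = 0:10,
                                           behaviour = "lying")),
               "cover")
})

test_that("trailing partial epochs are dropped with a message", {
  tr <- raw_trace(matrix(rnorm(3 * 75), ncol = 3), sampling_rate = 30)
  expect_message(al <- align_epochs(tr), "partial epoch")
  expect_equal(length(al$epoch), 2)
  expect_equal(nrow(al$data), 60)
})

test_that("preprocessing reproduces the printed filtering outcome", {
  track <- track_from_counts(printed_study_counts())
  pp <- preprocess_labels(track)
  classes <- sort(unique(pp$behaviour))
  expect_length(classes, 15)
  expect_true("allogrooming" %in% classes)
  expect_false(any(c("fighting", "playing", "other", "out of sight")
                   %in% classes))
  expect_equal(sum(pp$behaviour == "jumping"), 53 + 186)
  report <- attr(pp, "filter_report")
  expect_equal(report$count[report$behaviour == "fighting"], 10)
  expect_equal(report$action[report$behaviour == "fighting"], "removed")
  # unobserved behaviours are reported as such
  expect_equal(report$action[report$behaviour == "running"], "removed")
  expect_equal(report$reason[report$behaviour == "running"], "not observed")
})

test_that("every annotated second is kept or attributed to one removal reason", {
  track <- track_from_counts(printed_study_counts())
  pp <- preprocess_labels(track)
  report <- attr(pp, "filter_report")
  removed <- sum(report$count[report$action == "removed"])
  expect_equal(nrow(pp) + removed, nrow(track))
  expect_false(anyDuplicated(report$behaviour) > 0)
})

test_that("preprocessing is idempotent on retained behaviours", {
  track <- track_from_counts(c("lying" = 100, "walking" = 50, "eating" = 30))
  pp <- preprocess_labels(track)
  expect_equal(pp$behaviour, track$behaviour)
  expect_equal(nrow(preprocess_labels(pp)), nrow(pp))
})

test_that("class capping downsamples exactly and deterministically", {
  dat <- data.frame(behaviour = rep(c("lying", "shaking"), c(200, 30)),
                    id = 1:230)
  capped <- cap_class_counts(dat, cap = 70, seed = 5)
  expect_equal(sum(capped$behaviour == "lying"), 70)
  expect_equal(sum(capped$behaviour == "shaking"), 30)  # below cap: untouched
  capped2 <- cap_class_counts(dat, cap = 70, seed = 5)
  expect_identical(capped$id, capped2$id)
  capped3 <- cap_class_counts(dat, cap = 70, seed = 6)
  expect_false(identical(capped$id, capped3$id))
})

test_that("the stratified split is disjoint, exhaustive and near 70/30", {
  dat <- data.frame(behaviour = rep(c("a", "b", "c", "d"), each = 250),
                    id = 1:1000)
  sp <- train_test_split(dat, 0.7, seed = 3)
  expect_equal(nrow(sp$train), 700)
  expect_equal(nrow(sp$test), 300)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), dat$id)
  per_class <- table(sp$train$behaviour)
  expect_true(all(abs(per_class - 175) <= 1))
})

test_that("extreme train fractions still leave test rows where possible", {
  dat <- data.frame(behaviour = rep(c("a", "b"), each = 10), id = 1:20)
  sp <- train_test_split(dat, 0.999, seed = 1)
  expect_true(all(table(sp$test$behaviour) >= 1))
  one <- data.frame(behaviour = c("a", "a", "b"), id = 1:3)
  expect_warning(sp1 <- train_test_split(one, 0.7, seed = 1), "single row")
  expect_true("b" %in% sp1$train$behaviour)
})
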