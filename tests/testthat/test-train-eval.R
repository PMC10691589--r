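test_that("training configuration is validated", {
  expect_error(train_control(batch_size = 0), "batch_size")
  expect_error(train_control(monitor = "test_loss"), "arg")
  expect_warning(train_control(max_epochs = 5, early_stop_patience = 14),
                 "patience")
})

test_that("early stopping follows the patience counter", {
  es <- ns$early_stop_epoch
  # strictly decreasing loss never triggers a stop
  expect_true(is.na(es(seq(1, 0.1, length.out = 20), patience = 3)))
  # improvement at epoch 2, flat afterwards, patience 3 -> stop at 5
  expect_equal(es(c(1.0, 0.8, 0.8, 0.8, 0.8, 0.8), patience = 3), 5L)
  # monotone increase stops as soon as the counter fills
  expect_equal(es(c(1, 2, 3, 4, 5), patience = 2), 3L)
})

test_that("a one-epoch budget yields exactly one history row", {
  sp <- random_splits()
  spec <- build_s_lstm(12, 3, units = 4L)
  m <- suppressWarnings(
    fit_fatigue_model(spec, sp, train_control(max_epochs = 1, seed = 1,
                                              batch_size = 8)))
  expect_equal(nrow(m$history), 1L)
  expect_s3_class(m, "fatigue_model")
})

test_that("fits are reproducible for a fixed seed", {
  sp <- random_splits()
  spec <- build_s_lstm(12, 3, units = 4L)
  ctrl <- train_control(max_epochs = 3, seed = 7, batch_size = 8,
                        early_stop_patience = 2)
  m1 <- suppressWarnings(fit_fatigue_model(spec, sp, ctrl))
  m2 <- suppressWarnings(fit_fatigue_model(spec, sp, ctrl))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("training reduces the training loss with a small rate", {
  sp <- random_splits(n = 60)
  spec <- build_s_lstm(12, 3, units = 6L)
  m <- suppressWarnings(fit_fatigue_model(
    spec, sp, train_control(max_epochs = 3, learning_rate = 1e-4,
                            seed = 2, batch_size = 16,
                            monitor = "train_loss")))
  expect_lt(m$history$train_loss[3], m$history$train_loss[1])
})

test_that("dimension mismatches and empty splits are rejected", {
  sp <- random_splits(d = 3)
  expect_error(fit_fatigue_model(build_cnn(200, 6), sp, train_control()),
               "mismatch")
  empty <- sp
  empty$train <- ns$take_windows(sp$train, integer(0))
  expect_error(suppressWarnings(
    fit_fatigue_model(build_s_lstm(12, 3, units = 4L), empty,
                      train_control())), "empty training")
})

test_that("evaluation reports counts, accuracy and recalls coherently", {
  # scripted predictor: an object whose predict() flips 9 labels of a
  # balanced 90-window test set
  truth <- factor(rep(c("Pre", "Mid", "Post"), each = 30),
                  levels = c("Pre", "Mid", "Post"))
  test <- structure(list(
    windows = array(0, c(90, 4, 1)), labels = truth,
    combo = channel_combo("ACC"), cfg = NULL,
    provenance = data.frame(subject_id = "s", site = "LL",
                            start_index = 1:90)),
    class = "window_set")
  pred <- truth
  pred[1:9] <- "Mid"                       # 9 Pre windows mispredicted
  rep_ <- evaluate(scripted_predictor(pred), test)
  expect_equal(rep_$accuracy, 81 / 90)
  expect_equal(sum(rep_$confusion) , 90)
  expect_equal(sum(rep_$confusion) - sum(diag(rep_$confusion)), 9)
  expect_equal(unname(rep_$per_class_recall),
               c(21 / 30, 1, 1))
  # perfect predictor
  perfect <- scripted_predictor(truth)
  expect_equal(evaluate(perfect, test)$accuracy, 1)
  # constant predictor on a balanced set scores 1/3
  constant <- scripted_predictor(factor(rep("Pre", 90),
                                        levels = levels(truth)))
  expect_equal(evaluate(constant, test)$accuracy, 1 / 3)
  expect_error(evaluate(perfect, ns$take_windows(test, integer(0))),
               "empty test")
})

test_that("predict returns classes or calibrated probabilities", {
  sp <- random_splits(n = 40)
  spec <- build_s_lstm(12, 3, units = 4L)
  m <- suppressWarnings(fit_fatigue_model(
    spec, sp, train_control(max_epochs = 2, seed = 3, batch_size = 16)))
  pr <- predict(m, sp$test, type = "prob")
  expect_equal(dim(pr), c(dim(sp$test$windows)[1], 3L))
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-9)
  cl <- predict(m, sp$test)
  expect_s3_class(cl, "factor")
  expect_equal(levels(cl), c("Pre", "Mid", "Post"))
  expect_equal(as.integer(cl), unname(apply(pr, 1, which.max)))
})

test_that("every architecture fits and predicts on tiny windows", {
  sp <- random_splits(n = 40, len = 16, d = 6)
  specs <- list(build_s_lstm(16, 6, units = 6L),
                build_d_lstm(16, 6, units = c(6L, 4L)),
                build_cnn(16, 6),
                build_lstm_attention(16, 6, units = 6L),
                build_hybrid(16, 6, units = 6L))
  for (spec in specs) {
    m <- suppressWarnings(fit_fatigue_model(
      spec, sp, train_control(max_epochs = 1, seed = 4,
                              batch_size = 16)))
    pr <- predict(m, sp$test, type = "prob")
    expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-9,
                 info = spec$name)
    rp <- evaluate(m, sp$test)
    expect_equal(sum(rp$confusion), rp$n_test, info = spec$name)
  }
})

test_that("evaluation reports serialize to JSON", {
  sp <- random_splits(n = 40)
  m <- suppressWarnings(fit_fatigue_model(
    build_s_lstm(12, 3, units = 4L), sp,
    train_control(max_epochs = 1, seed = 3, batch_size = 16)))
  rp <- evaluate(m, sp$test)
  path <- withr::local_tempfile(fileext = ".json")
  eval_report_to_json(rp, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$accuracy, rp$accuracy)
  expect_equal(back$n_test, rp$n_test)
  expect_equal(matrix(unlist(back$confusion), 3, byrow = FALSE),
               unclass(as.matrix(rp$confusion)), ignore_attr = TRUE)
})
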