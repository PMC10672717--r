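test_that("stratified splits preserve class proportions and determinism", {
  df <- tibble::tibble(id = 1:100, label = rep(c("a", "b", "c"), c(60, 30, 10)))
  sp <- split_dataset(df, 0.8, seed = 1)
  expect_equal(unname(table(sp$test$label)["a"]), 12L)
  expect_equal(unname(table(sp$test$label)["b"]), 6L)
  expect_equal(unname(table(sp$test$label)["c"]), 2L)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100L)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)

  sp2 <- split_dataset(df, 0.8, seed = 1)
  expect_identical(sp, sp2)

  big <- tibble::tibble(id = 1:521, label = rep(c("a", "b", "c"), c(269, 192, 60)))
  spb <- split_dataset(big, 0.8, seed = 2)
  expect_equal(nrow(spb$train), 417L)
  expect_equal(nrow(spb$test), 104L)

  expect_error(split_dataset(tibble::tibble(label = c("a", "a", "b")), 0.8),
               "fewer than 2")
  expect_error(split_dataset(df, 1.2), "0, 1")
})

test_that("perfect and degenerate predictions give the expected metrics", {
  truth <- rep(c("a", "b", "c"), each = 4)
  rep_perfect <- eval_report(truth, truth, classes = c("a", "b", "c"))
  expect_equal(rep_perfect$metrics$accuracy, c(1, 1))
  expect_equal(rep_perfect$metrics$f1, c(1, 1))
  expect_equal(diag(rep_perfect$confusion), c(a = 4L, b = 4L, c = 4L))
  expect_equal(sum(rep_perfect$confusion) - sum(diag(rep_perfect$confusion)), 0L)

  rep_const <- eval_report(truth, rep("a", 12), classes = c("a", "b", "c"))
  expect_equal(rep_const$metrics$accuracy[1], 1 / 3)
})

test_that("metrics match an independent per-class tally on a fixed matrix", {
  cm <- matrix(c(39, 8, 4,
                 2, 39, 0,
                 1, 2, 9), nrow = 3, byrow = TRUE,
               dimnames = list(truth = severity_levels3,
                               predicted = severity_levels3))
  rep <- eval_report_from_confusion(cm)
  # hand tally
  n <- sum(cm)
  acc <- (39 + 39 + 9) / n
  rec <- c(39 / 51, 39 / 41, 9 / 12)
  prec <- c(39 / 42, 39 / 49, 9 / 13)
  f1 <- 2 * prec * rec / (prec + rec)
  support <- c(51, 41, 12)
  expect_equal(rep$metrics$accuracy[1], acc, tolerance = 1e-12)
  expect_equal(rep$per_class$recall, unname(rec), tolerance = 1e-12)
  expect_equal(rep$per_class$precision, unname(prec), tolerance = 1e-12)
  expect_equal(rep$metrics$recall[1], sum(support / n * rec), tolerance = 1e-12)
  expect_equal(rep$metrics$recall[2], mean(rec), tolerance = 1e-12)
  expect_equal(rep$metrics$f1[1], sum(support / n * f1), tolerance = 1e-12)
  expect_equal(rep$per_class$support, support)
})

test_that("weighted recall equals accuracy and order does not matter", {
  set.seed(8)
  for (trial in 1:25) {
    truth <- sample(severity_levels3, 60, replace = TRUE)
    pred <- sample(severity_levels3, 60, replace = TRUE)
    rep <- eval_report(truth, pred)
    expect_equal(rep$metrics$recall[1], rep$metrics$accuracy[1],
                 tolerance = 1e-12)
    expect_equal(sum(rep$confusion), 60)
    perm <- sample(60)
    rep2 <- eval_report(truth[perm], pred[perm])
    expect_equal(rep2$confusion, rep$confusion)
    expect_equal(rep2$metrics, rep$metrics)
  }
})

test_that("labels outside the class set are a data error", {
  expect_error(eval_report(c("a", "d"), c("a", "a"), classes = c("a", "b")),
               "outside the class set")
  expect_error(eval_report(character(0), character(0)), "Empty")
})

test_that("training rejects single-class input and learns on an easy task", {
  frames <- generate_images(image_gen_config(width = 48, height = 48),
                            labels = rep(c("remission_mild", "severe"), each = 15),
                            seed = 31)
  samples <- tibble::tibble(image = frames$clean, label = droplevels(frames$label))

  single <- samples[samples$label == "severe", ]
  expect_error(train_small_cnn(single, train_config(epochs = 1)),
               "at least 2 classes")

  cfg <- train_config(epochs = 4, target_size = c(48, 48), seed = 3)
  model <- train_small_cnn(samples, cfg)
  expect_length(model$history, 4L)
  expect_lt(tail(model$history, 1), model$history[1])

  # fixed seed reproduces the weights exactly
  model2 <- train_small_cnn(samples, cfg)
  expect_identical(model$w_conv, model2$w_conv)
  expect_identical(model$w_dense, model2$w_dense)

  pred <- predict(model, samples)
  expect_s3_class(pred, "factor")
  probs <- predict(model, samples, type = "prob")
  expect_equal(rowSums(probs), rep(1, nrow(samples)), tolerance = 1e-9)

  rep <- evaluate(model, samples)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$n_test, 30L)
  expect_error(evaluate(model, samples[0, ]), "Empty")
})

test_that("evaluation reports serialise to JSON and CSV", {
  rep <- eval_report(rep(severity_levels3, each = 5),
                     rep(severity_levels3, times = 5))
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep, jp, cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$n_test, 15L)
  cm <- readr::read_csv(cp, show_col_types = FALSE)
  expect_equal(nrow(cm), 3L)
})
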