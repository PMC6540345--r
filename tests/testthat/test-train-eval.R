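test_that("k-fold splits partition the data into near-equal folds", {
  f <- kfold_split(11, 10, seed = 1)
  expect_length(f, 10)
  expect_setequal(unlist(f), 1:11)
  expect_identical(sort(lengths(f)), c(rep(1L, 9), 2L))
  f2 <- kfold_split(10, 10, seed = 2)
  expect_true(all(lengths(f2) == 1L))
  big <- kfold_split(2560, 10, seed = 3)
  expect_true(all(lengths(big) == 256L))
  expect_identical(kfold_split(100, 5, seed = 9), kfold_split(100, 5, seed = 9))
  expect_false(identical(kfold_split(100, 5, 1), kfold_split(100, 5, 2)))
  expect_error(kfold_split(5, 10), "at least k")
})

test_that("hold-out split is stratified 8:1:1 within each label", {
  labels <- rep(c(0, 1), each = 1000)
  sp <- holdout_split(labels, seed = 4)
  expect_length(sp$train, 1600)
  expect_length(sp$val, 200)
  expect_length(sp$test, 200)
  expect_setequal(c(sp$train, sp$val, sp$test), seq_along(labels))
  for (part in sp)
    expect_identical(unname(table(labels[part]))[1],
                     unname(table(labels[part]))[2])
  all_train <- holdout_split(labels, proportions = c(1, 0, 0), seed = 1)
  expect_length(all_train$train, 2000)
  expect_length(all_train$test, 0)
  expect_error(holdout_split(c(rep(0, 100), rep(1, 5))), "too rare")
})

test_that("evaluation reports accuracy from the confusion counts", {
  d <- toy_mfms(10, seed = 3)
  model <- capsnet_init(small_capsnet(seed = 1))
  model <- capsnet_train(model, d$x, d$y, epochs = 15, batch_size = 10)
  ev <- evaluate_model(model, d$x, d$y)
  expect_equal(ev$accuracy,
               unname((ev$confusion["tp"] + ev$confusion["tn"]) / 10))
  expect_identical(sum(ev$confusion), 10L)
  ev_perfect <- evaluate_model(model, d$x, ev$predicted)
  expect_equal(ev_perfect$accuracy, 1)
  ev_inverted <- evaluate_model(model, d$x, 1L - ev$predicted)
  expect_equal(ev_inverted$accuracy, 0)
  # printed-confusion arithmetic: {tp 3, tn 4, fp 2, fn 1} -> 0.7
  expect_equal((3 + 4) / (3 + 4 + 2 + 1), 0.7)
})

test_that("a 2-fold run on 4 samples returns two fold accuracies", {
  d <- toy_mfms(4, seed = 4)
  ds <- list(mfm = d$x, meta = data.frame(subject_id = "s", trial_id = 1:4,
                                          arousal_label = d$y))
  res <- run_cv(ds, small_capsnet(),
                eval_protocol("kfold", "arousal", k = 2, epochs = 1, seed = 1))
  expect_length(res$fold_accuracy, 2)
  expect_true(all(res$fold_accuracy >= 0 & res$fold_accuracy <= 1))
  expect_equal(res$mean_accuracy, mean(res$fold_accuracy))
  expect_identical(sum(res$confusion), 4L)
})

test_that("fold coverage and determinism hold for cross-validation", {
  d <- toy_mfms(24, seed = 5)
  ds <- list(mfm = d$x, meta = data.frame(subject_id = "s", trial_id = 1:24,
                                          valence_label = d$y))
  pr <- eval_protocol("kfold", "valence", k = 3, epochs = 2, seed = 6)
  res1 <- run_cv(ds, small_capsnet(), pr)
  res2 <- run_cv(ds, small_capsnet(), pr)
  expect_setequal(unlist(res1$folds), 1:24)
  expect_identical(res1$folds, res2$folds)
  expect_identical(res1$fold_accuracy, res2$fold_accuracy)
})

test_that("a single-class training fold is skipped with a warning", {
  d <- toy_mfms(6, seed = 7)
  y <- c(0L, 0L, 0L, 0L, 1L, 1L)
  ds <- list(mfm = d$x, meta = data.frame(subject_id = "s", trial_id = 1:6,
                                          arousal_label = y))
  # force a split where one training set sees only class 0
  pr <- eval_protocol("kfold", "arousal", k = 3, epochs = 1, seed = 11)
  found <- FALSE
  for (s in 1:20) {
    f <- kfold_split(6, 3, seed = s)
    if (any(vapply(f, function(te) all(y[-te] == 0L), logical(1)))) {
      pr$seed <- s; found <- TRUE; break
    }
  }
  skip_if_not(found, "no seed produced a single-class fold")
  expect_warning(res <- run_cv(ds, small_capsnet(), pr), "single-class")
  expect_true(any(is.na(res$fold_accuracy)))
})

test_that("trial-grouped folds keep a trial's segments together", {
  d <- toy_mfms(24, seed = 8)
  meta <- data.frame(subject_id = "s", trial_id = rep(1:6, each = 4),
                     valence_label = rep(rep_len(c(0L, 1L), 6), each = 4))
  ds <- list(mfm = d$x, meta = meta)
  pr <- eval_protocol("kfold", "valence", k = 3, epochs = 1, seed = 2,
                      group_by_trial = TRUE)
  res <- run_cv(ds, small_capsnet(), pr, labels = meta$valence_label)
  for (f in res$folds)
    for (tr in unique(meta$trial_id[f]))
      expect_true(all(which(meta$trial_id == tr) %in% f))
})

test_that("the hold-out protocol trains once and scores the test third", {
  d <- toy_mfms(120, seed = 9)
  ds <- list(mfm = d$x, meta = data.frame(subject_id = "s", trial_id = 1:120,
                                          dominance_label = d$y))
  res <- run_cv(ds, small_capsnet(),
                eval_protocol("holdout", "dominance", epochs = 10, seed = 3))
  expect_length(res$fold_accuracy, 1)
  expect_identical(sum(res$confusion), 12L) # 10% of 120
  expect_gte(res$mean_accuracy, 0.5)
})
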