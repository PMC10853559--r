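test_that("patient-level splitting is leakage-free and deterministic", {
  data <- lapply(1:40, function(i) {
    sid <- sprintf("P%02d", ceiling(i / 2))  # two clips per subject
    labeled_clip(fixed_clip(n = 6), item_score = i %% 4, subject_id = sid)
  })
  sp <- split_by_subject(data, ratio = 0.85, seed = 4)
  sid_of <- function(lst) unique(vapply(lst, `[[`, character(1), "subject_id"))
  expect_length(sid_of(sp$non_testing), 17L)
  expect_length(sid_of(sp$testing), 3L)
  expect_length(intersect(sid_of(sp$non_testing), sid_of(sp$testing)), 0L)
  # a subject's clips always land on one side together
  expect_equal(length(sp$non_testing) %% 2, 0L)

  sp2 <- split_by_subject(data, ratio = 0.85, seed = 4)
  expect_identical(sp, sp2)

  one <- data[1:2]
  expect_error(split_by_subject(one, seed = 1), "2 subjects")
})

test_that("binary decomposition thresholds the ordinal labels", {
  data <- Map(function(s, i) labeled_clip(fixed_clip(n = 6), s, sprintf("S%d", i)),
              c(0, 1, 2, 3), 1:4)
  get_labels <- function(b) vapply(make_binary_task(data, b), `[[`,
                                   integer(1), "binary_label")
  expect_equal(get_labels(1), c(0L, 1L, 1L, 1L))
  expect_equal(get_labels(2), c(0L, 0L, 1L, 1L))
  expect_equal(get_labels(3), c(0L, 0L, 0L, 1L))
  expect_error(make_binary_task(data, 4), "boundary")
})

test_that("a separable task trains to near-perfect validation MCC", {
  task <- make_binary_task(small_task(), 2)
  fit <- train_binary(task, tiny_net(), tiny_train(), folds = 3L)
  expect_s3_class(fit, "binary_tap_classifier")
  expect_length(fit$fold_mcc, 3L)
  expect_gte(fit$fold_mcc[fit$best_fold], 0.95)
})

test_that("training is deterministic under a fixed seed", {
  task <- make_binary_task(small_task(n_per_class = 6), 2)
  f1 <- train_binary(task, tiny_net(), tiny_train(epochs = 4), folds = 3L)
  f2 <- train_binary(task, tiny_net(), tiny_train(epochs = 4), folds = 3L)
  expect_identical(f1$fold_mcc, f2$fold_mcc)
  expect_identical(f1$best_fold, f2$best_fold)
  expect_identical(f1$params, f2$params)
})

test_that("single-class folds raise a stratification error", {
  task <- make_binary_task(small_task(n_per_class = 2), 2)
  expect_error(train_binary(task, tiny_net(), tiny_train(), folds = 3L),
               "stratification|fewer subjects")
})

test_that("grid search evaluates every combination and applies tie-breaks", {
  task <- make_binary_task(small_task(n_per_class = 6), 2)
  single <- grid_search(task, tiny_net(),
                        grid = list(batch_size = 8L, learning_rate = 1e-2, l2 = 5e-5),
                        tcfg = tiny_train(epochs = 3), folds = 3L)
  expect_equal(nrow(single$table), 1L)
  expect_equal(single$best$batch_size, 8L)

  full <- grid_search(task, tiny_net(),
                      grid = list(batch_size = c(8L, 16L),
                                  learning_rate = c(1e-2, 1e-3),
                                  l2 = c(5e-4, 5e-5, 5e-6)),
                      tcfg = tiny_train(epochs = 2), folds = 3L)
  expect_equal(nrow(full$table), 12L)
  # ties prefer smaller batch, then larger learning rate
  top <- full$table[full$table$mean_mcc == max(full$table$mean_mcc), ]
  ord <- order(top$batch_size, -top$learning_rate)
  expect_equal(full$best$batch_size, top$batch_size[ord[1]])
  expect_equal(full$best$learning_rate, top$learning_rate[ord[1]])
})

test_that("the ordinal combine rule counts positive boundary decisions", {
  clip <- simulate_clip(tap_sim_config(duration_s = 4, fps = 30, seed = 2))$clip
  expect_equal(estimate_item_score(clip, stub_scorer(0.9, 0.8, 0.2))$item_score, 2L)
  expect_equal(estimate_item_score(clip, stub_scorer(0.2, 0.1, 0.1))$item_score, 0L)
  expect_equal(estimate_item_score(clip, stub_scorer(0.9, 0.9, 0.9))$label, "3+")
  # non-monotone boundary outputs are absorbed by the count rule
  expect_equal(estimate_item_score(clip, stub_scorer(0.2, 0.9, 0.2))$item_score, 1L)
})

test_that("flipping a boundary decision never decreases the score", {
  clip <- simulate_clip(tap_sim_config(duration_s = 4, fps = 30, seed = 2))$clip
  base <- c(0.2, 0.2, 0.2)
  s0 <- estimate_item_score(clip, do.call(stub_scorer, as.list(base)))$item_score
  for (j in 1:3) {
    up <- base
    up[j] <- 0.9
    sj <- estimate_item_score(clip, do.call(stub_scorer, as.list(up)))$item_score
    expect_gte(sj, s0)
  }
})

test_that("score estimates carry the clip's quality tier", {
  clip <- simulate_clip(tap_sim_config(duration_s = 4, fps = 30,
                                       missing_rate = 0.6, seed = 9))$clip
  est <- estimate_item_score(clip, stub_scorer(0.9, 0.2, 0.1))
  expect_equal(est$confidence, "low")
  expect_equal(est$item_score, 1L)
})
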