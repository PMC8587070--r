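# Splitting, the backpropagation network, the SVM comparator, metrics.

test_that("splits are seeded, proportional and pulse-grouped", {
  tab <- separable_feature_table()
  s1 <- split_dataset(tab, seed = 1)
  s2 <- split_dataset(tab, seed = 1)
  expect_identical(s1$train, s2$train)
  expect_equal(nrow(s1$train) / nrow(tab), 0.7, tolerance = 0.02)
  s3 <- split_dataset(tab, seed = 2)
  expect_false(identical(s1$train, s3$train))
  # pulse grouping: no pulse id on both sides
  lib <- preset_class_library(c("CD", "PS-10"))
  traces <- lapply(1:2, function(i)
    simulate_pure(lib[[i]], 6, 0.5, seed = 50 + i))
  k10 <- build_dataset(traces, 10)
  parts <- split_dataset(k10, seed = 3)
  expect_length(intersect(unique(parts$train$pulse_id),
                          unique(parts$test$pulse_id)), 0L)
  # degenerate split
  expect_warning(split_dataset(tab, train_frac = 1, seed = 1), "empty")
  expect_error(split_dataset(tab, train_frac = 1, seed = 1, strict = TRUE),
               "empty")
})

test_that("the network learns separable classes within 100 epochs", {
  tab <- separable_feature_table()
  parts <- split_dataset(tab, seed = 1)
  fit <- train_bpnn(parts$train, bpnn_config(2, seed = 1))
  rep_ <- evaluate(fit, parts$test)
  expect_gte(rep_$row$accuracy$overall, 0.99)
  # the default topology is 5 inputs, hidden 5-6-4, K outputs
  expect_equal(fit$sizes, c(5L, 5L, 6L, 4L, 2L))
})

test_that("training is deterministic and zero epochs sit at chance", {
  tab <- separable_feature_table()
  f1 <- train_bpnn(tab, bpnn_config(2, epochs = 5, seed = 9))
  f2 <- train_bpnn(tab, bpnn_config(2, epochs = 5, seed = 9))
  expect_identical(f1$net, f2$net)
  f0 <- train_bpnn(tab, bpnn_config(2, epochs = 0, seed = 9))
  acc0 <- mean(predict(f0, tab) == tab$label)
  expect_lt(abs(acc0 - 0.5), 0.25)
  expect_error(train_bpnn(tab[tab$label == "A", ]), "at least 2")
})

test_that("training MSE decreases to convergence on separable data", {
  tab <- separable_feature_table()
  fit <- train_bpnn(tab, bpnn_config(2, seed = 4))
  mse <- fit$curves$train_mse
  expect_lt(mse[length(mse)], mse[1] / 2)
  # mostly monotone: allow plateaus and small fluctuations
  expect_gt(mean(diff(mse) <= 1e-4), 0.9)
})

test_that("bpnn models round-trip through the JSON artifact", {
  tab <- separable_feature_table()
  fit <- train_bpnn(tab, bpnn_config(2, epochs = 10, seed = 2))
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  fit2 <- read_model(path)
  expect_equal(fit2$net$W, fit$net$W, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(predict(fit2, tab), predict(fit, tab))
})

test_that("the SVM comparator shares the evaluation interface", {
  tab <- separable_feature_table()
  parts <- split_dataset(tab, seed = 1)
  sv <- train_svm(parts$train)
  rep_sv <- evaluate(sv, parts$test)
  expect_gte(rep_sv$row$accuracy$overall, 0.99)
  expect_error(train_svm(tab[tab$label == "A", ]), "at least 2")
  fit <- train_bpnn(parts$train, bpnn_config(2, seed = 1))
  rep_nn <- evaluate(fit, parts$test)
  expect_setequal(names(rep_sv$row), names(rep_nn$row))
  expect_equal(rep_sv$levels, rep_nn$levels)
})

test_that("confusion-matrix accuracy matches the 2x2 identity by hand", {
  # TP=40, FP=10, FN=10, TN=40 -> (40+40)/100
  actual <- c(rep("pos", 50), rep("neg", 50))
  pred <- c(rep("pos", 40), rep("neg", 10), rep("pos", 10), rep("neg", 40))
  cm <- confusion_matrix(actual, pred, levels = c("pos", "neg"))
  acc <- accuracy_from_confusion(cm)
  expect_equal(acc$overall, 0.8)
  expect_equal(unname(acc$per_class["pos"]), 0.8)
  # perfect predictions: diagonal matrix, accuracy 1
  cm_p <- confusion_matrix(actual, actual)
  expect_true(all(cm_p[upper.tri(cm_p)] == 0, cm_p[lower.tri(cm_p)] == 0))
  expect_equal(accuracy_from_confusion(cm_p)$overall, 1)
  # all-one-class predictor on balanced 4 classes: 0.25 overall
  act4 <- rep(letters[1:4], each = 25)
  cm4 <- confusion_matrix(act4, rep("a", 100), levels = letters[1:4])
  expect_equal(accuracy_from_confusion(cm4)$overall, 0.25)
})

test_that("accuracy and MSE agree with independent brute-force oracles", {
  set.seed(101)
  for (i in 1:50) {
    K <- sample(2:5, 1)
    n <- sample(20:60, 1)
    actual <- sample(letters[1:K], n, replace = TRUE)
    predicted <- sample(letters[1:K], n, replace = TRUE)
    cm <- confusion_matrix(actual, predicted, levels = letters[1:K])
    # oracle: count loop, no matrix algebra
    correct <- 0
    for (j in seq_len(n)) if (actual[j] == predicted[j]) correct <- correct + 1
    expect_equal(accuracy_from_confusion(cm)$overall, correct / n)
    # per-class one-vs-rest oracle
    for (k in letters[1:K]) {
      tp <- sum(actual == k & predicted == k)
      tn <- sum(actual != k & predicted != k)
      expect_equal(unname(accuracy_from_confusion(cm)$per_class[k]),
                   (tp + tn) / n)
    }
    # MSE oracle: elementwise loop over one-hot targets
    act_mat <- matrix(runif(n * K), n, K, dimnames = list(NULL, letters[1:K]))
    tot <- 0
    for (j in seq_len(n)) for (k in seq_len(K)) {
      tgt <- as.numeric(actual[j] == letters[k])
      tot <- tot + (act_mat[j, k] - tgt)^2
    }
    expect_equal(mse_one_hot(act_mat, actual), unname(tot) / (n * K))
  }
})

test_that("majority vote aggregates rows and breaks ties by activation", {
  act <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4))
  colnames(act) <- c("A", "B")
  votes <- pulsepol:::majority_vote(c(1, 1, 1), act, c("A", "B"))
  expect_equal(unname(votes), "A")
  # 2-2 tie broken by the larger summed activation across the pulse
  act2 <- rbind(c(0.55, 0.45), c(0.52, 0.48), c(0.05, 0.95), c(0.08, 0.92))
  colnames(act2) <- c("A", "B")
  votes2 <- pulsepol:::majority_vote(rep(1, 4), act2, c("A", "B"))
  expect_equal(unname(votes2), "B")
})

test_that("evaluation rejects labels the model never saw", {
  tab <- separable_feature_table()
  fit <- train_bpnn(tab, bpnn_config(2, epochs = 3, seed = 1))
  bad <- tab
  bad$label[1] <- "C"
  expect_error(evaluate(fit, bad), "not known")
})

test_that("a perfect classifier recovers exact mixture counts", {
  # PG and PS-10 are far apart in every feature, so a trained model acts as
  # the oracle classifier here
  lib <- preset_class_library(c("PG", "PS-10"))
  tr <- simulate_mixture(lib, counts = c(8, 6), duration = 1, seed = 71)
  tr_lab <- tr
  tr_lab$label <- "PG"
  tab <- build_dataset(list(tr_lab), "ave")  # detection bookkeeping only
  expect_equal(nrow(tab), 14L)
  traces <- lapply(1:2, function(i)
    simulate_pure(lib[[i]], 12, 1, seed = 80 + i))
  fit <- train_bpnn(build_dataset(traces, "all"),
                    bpnn_config(2, seed = 1))
  pred <- predict_mixture(fit, tr, "all")
  expect_equal(pred$predicted[pred$class == "PG"], 8L)
  expect_equal(pred$predicted[pred$class == "PS-10"], 6L)
  expect_equal(pred$rel_error_preset, c(0, 0))
  # both relative-error conventions are reported
  expect_true(all(c("rel_error_preset", "rel_error_predicted") %in%
                    names(pred)))
  # empty mixture -> no pulses -> error
  empty <- simulate_mixture(lib, counts = c(0, 0), duration = 0.1, seed = 3)
  expect_error(predict_mixture(fit, empty, "all"), "no pulses")
})

test_that("relative-error conventions match the worked 40-vs-100 case", {
  # preset 40, predicted 100: |100-40|/40 = 1.5 and |100-40|/100 = 0.6
  pred <- structure(
    data.frame(class = "DS", predicted = 100L, preset = 40L,
               rel_error_preset = abs(100 - 40) / 40,
               rel_error_predicted = abs(100 - 40) / 100),
    class = c("plp_mixture_prediction", "data.frame"))
  expect_equal(pred$rel_error_preset, 1.5)
  expect_equal(pred$rel_error_predicted, 0.6)
})
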