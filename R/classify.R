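#' Train/test split of a feature table
#'
#' Seeded shuffle-and-split. By default the split is *pulse-grouped*: every
#' feature row derived from the same pulse lands on the same side, so that
#' multi-row schemes (segment or per-sample features) cannot leak near-identical
#' rows of one particle into both sides. Row-level splitting (the simple
#' shuffled split) is available for comparison via `group_by_pulse = FALSE`.
#'
#' @param table a feature table with `label` (and `pulse_id` for grouped
#'   splits).
#' @param train_frac fraction of rows assigned to training (default 0.7).
#' @param seed split seed.
#' @param group_by_pulse keep all rows of one pulse together (default TRUE).
#' @param strict error (instead of warn) when a class is absent from either
#'   side.
#' @return A list with elements `train` and `test`.
#' @export
split_dataset <- function(table, train_frac = 0.7, seed,
                          group_by_pulse = TRUE, strict = FALSE) {
  stopifnot(nrow(table) > 0L, !is.null(table$label))
  if (missing(seed)) stop("seed is required for a reproducible split")
  set.seed(seed)
  if (group_by_pulse && !is.null(table$pulse_id)) {
    ids <- unique(table$pulse_id)
    ids <- sample(ids)
    rows_per_id <- table(table$pulse_id)[as.character(ids)]
    cum <- cumsum(as.numeric(rows_per_id))
    n_train_ids <- sum(cum <= train_frac * nrow(table))
    if (n_train_ids == 0L && train_frac > 0) n_train_ids <- 1L
    train_ids <- ids[seq_len(n_train_ids)]
    in_train <- table$pulse_id %in% train_ids
  } else {
    perm <- sample(nrow(table))
    n_train <- round(train_frac * nrow(table))
    in_train <- seq_len(nrow(table)) %in% perm[seq_len(n_train)]
  }
  train <- table[in_train, , drop = FALSE]
  test <- table[!in_train, , drop = FALSE]
  missing_cls <- union(setdiff(unique(table$label), unique(train$label)),
                       setdiff(unique(table$label), unique(test$label)))
  if (nrow(test) == 0L || length(missing_cls)) {
    msg <- if (nrow(test) == 0L) {
      "test side of the split is empty"
    } else {
      paste("classes missing from one side of the split:",
            paste(missing_cls, collapse = ", "))
    }
    if (strict) stop(msg) else warning(msg)
  }
  list(train = train, test = test)
}

#' Confusion matrix and the accuracy it implies
#'
#' `confusion_matrix()` tabulates actual class (rows) against predicted
#' class (columns). `accuracy_from_confusion()` returns the overall fraction
#' correct (`trace / total`) and, per class, the one-vs-rest accuracy
#' `(TP + TN) / (TP + FP + FN + TN)` computed from the collapsed 2x2 table
#' of that class (the standard confusion-matrix convention).
#'
#' @param actual,predicted class label vectors of equal length.
#' @param levels label set fixing row/column order (default: union, sorted).
#' @return `confusion_matrix()`: a K x K integer matrix.
#'   `accuracy_from_confusion()`: list with `overall` and named `per_class`.
#' @export
confusion_matrix <- function(actual, predicted, levels = NULL) {
  if (is.null(levels)) levels <- sort(union(unique(actual), unique(predicted)))
  tab <- table(factor(actual, levels = levels),
               factor(predicted, levels = levels))
  m <- matrix(as.integer(tab), nrow = length(levels),
              dimnames = list(actual = levels, predicted = levels))
  m
}

#' @rdname confusion_matrix
#' @param cm a K x K confusion matrix (rows actual, columns predicted).
#' @export
accuracy_from_confusion <- function(cm) {
  total <- sum(cm)
  overall <- sum(diag(cm)) / total
  per_class <- vapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    tn <- total - tp - fp - fn
    (tp + tn) / total
  }, numeric(1L))
  names(per_class) <- rownames(cm)
  list(overall = overall, per_class = per_class)
}

#' Mean squared error against one-hot targets
#'
#' `MSE = mean((activation - target)^2)` over all rows and output nodes,
#' with targets the one-hot encoding of the actual labels.
#'
#' @param activations rows x classes activation matrix (columns named by
#'   class).
#' @param actual actual label vector.
#' @return A single non-negative number.
#' @export
mse_one_hot <- function(activations, actual) {
  Y <- outer(as.character(actual), colnames(activations), `==`) * 1
  mean((activations - Y)^2)
}

# Majority vote over the rows of each pulse; ties broken by the largest
# summed activation across the tied classes.
majority_vote <- function(pulse_id, activations, levels) {
  pred <- levels[max.col(activations, ties.method = "first")]
  ids <- unique(pulse_id)
  votes <- vapply(ids, function(id) {
    ix <- which(pulse_id == id)
    cnt <- table(factor(pred[ix], levels = levels))
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) == 1L) return(top)
    sums <- colSums(activations[ix, top, drop = FALSE])
    top[which.max(sums)]
  }, character(1L))
  names(votes) <- as.character(ids)
  votes
}

#' Evaluate a trained classifier on a labeled test table
#'
#' Computes the per-row confusion matrix, and — when the rows carry pulse
#' identifiers — the pulse-level confusion matrix obtained by majority vote
#' over each pulse's row predictions (ties broken by the largest summed
#' activation). Both overall and per-class one-vs-rest accuracies are
#' reported, together with the one-hot MSE of the row activations.
#'
#' @param model a `plp_bpnn` or `plp_svm` model.
#' @param test a labeled feature table.
#' @return A `plp_eval_report`: list with `row` and `pulse` sub-lists
#'   (`confusion`, `accuracy`), `mse`, `levels`, `scheme`, and the model's
#'   training `curves` when available.
#' @export
evaluate <- function(model, test) {
  stopifnot(nrow(test) > 0L, !is.null(test$label))
  levels_ <- model_levels(model)
  extra <- setdiff(unique(test$label), levels_)
  if (length(extra)) {
    stop("test labels not known to the model: ", paste(extra, collapse = ", "))
  }
  act <- predict_activations(model, test)
  pred_row <- levels_[max.col(act, ties.method = "first")]
  cm_row <- confusion_matrix(test$label, pred_row, levels = levels_)
  report <- list(
    row = list(confusion = cm_row,
               accuracy = accuracy_from_confusion(cm_row)),
    mse = mse_one_hot(act, test$label),
    levels = levels_,
    scheme = attr(test, "scheme"),
    curves = if (inherits(model, "plp_bpnn")) model$curves else NULL
  )
  if (!is.null(test$pulse_id)) {
    votes <- majority_vote(test$pulse_id, act, levels_)
    actual_pulse <- vapply(names(votes), function(id) {
      as.character(test$label[test$pulse_id == as.integer(id)][1L])
    }, character(1L))
    cm_pulse <- confusion_matrix(actual_pulse, votes, levels = levels_)
    report$pulse <- list(confusion = cm_pulse,
                         accuracy = accuracy_from_confusion(cm_pulse))
  }
  structure(report, class = "plp_eval_report")
}

#' @export
print.plp_eval_report <- function(x, ...) {
  cat(sprintf("plp_eval_report%s\n",
              if (!is.null(x$scheme)) paste0(" (", x$scheme, ")") else ""))
  cat(sprintf("  row-level accuracy:   %.4f (MSE %.4f)\n",
              x$row$accuracy$overall, x$mse))
  if (!is.null(x$pulse)) {
    cat(sprintf("  pulse-level accuracy: %.4f (majority vote, %d pulses)\n",
                x$pulse$accuracy$overall, sum(x$pulse$confusion)))
  }
  invisible(x)
}

#' SVM comparator on the same five features
#'
#' A support vector machine (radial kernel, one-vs-one, cost 1 by default —
#' comparator settings, not tuned) trained on the identical
#' `[I, q, u, v, DOP]` rows, to check that conclusions about the sampling
#' schemes do not hinge on the classifier.
#'
#' @param train labeled feature table.
#' @param cost,gamma `e1071::svm` hyperparameters (`NULL` gamma uses the
#'   e1071 default `1/ncol`).
#' @param seed seed for the probability-model fit.
#' @return A `plp_svm` model usable with [evaluate()] and [predict_mixture()].
#' @export
train_svm <- function(train, cost = 1, gamma = NULL, seed = 1L) {
  labels <- factor(as.character(train$label))
  if (nlevels(labels) < 2L) {
    stop("training data must contain at least 2 classes, got ",
         nlevels(labels))
  }
  X <- feature_matrix(train)
  set.seed(seed)
  args <- list(x = X, y = labels, kernel = "radial", cost = cost,
               probability = TRUE)
  if (!is.null(gamma)) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  structure(list(fit = fit, levels = levels(labels),
                 scale_I = attr(X, "scale_I")),
            class = "plp_svm")
}

#' @export
model_levels.plp_svm <- function(model) model$levels

#' @export
predict_activations.plp_svm <- function(model, data) {
  X <- feature_matrix(data, scale_I = model$scale_I)
  p <- predict(model$fit, X, probability = TRUE)
  probs <- attr(p, "probabilities")
  probs[, model$levels, drop = FALSE]
}

#' @export
print.plp_svm <- function(x, ...) {
  cat(sprintf("plp_svm: radial kernel, classes: %s\n",
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict the per-class particle counts of a mixed suspension
#'
#' Runs the processing chain on a mixture trace (filter, detect, featurize
#' under the *same* scheme and instrument matrix the model was trained
#' with), classifies every feature row, assigns each pulse the majority
#' class over its rows, and counts pulses per class. When the trace carries
#' ground truth, the preset counts and relative errors are reported under
#' both conventions: `|predicted - preset| / preset` (the package's
#' headline) and `|predicted - preset| / predicted`.
#'
#' @param model a trained classifier.
#' @param trace a mixture `channel_trace`.
#' @param scheme the [sampling_scheme()] the model was trained with.
#' @param A instrument matrix.
#' @param cutoff_hz,threshold processing configuration.
#' @return A `plp_mixture_prediction`: data frame with per-class `predicted`
#'   and (when available) `preset`, `rel_error_preset`, `rel_error_predicted`.
#' @export
predict_mixture <- function(model, trace, scheme, A = ideal_psa_matrix(),
                            cutoff_hz = 6e4, threshold = threshold_spec(),
                            subtract_bg = TRUE) {
  ftr <- if (!isTRUE(trace$filtered)) lowpass_filter(trace, cutoff_hz) else trace
  if (subtract_bg && is.null(ftr$background_channels)) {
    ftr <- subtract_background(ftr, threshold$bg_frac)
  }
  pulses <- detect_pulses(ftr, threshold)
  if (!length(pulses)) stop("no pulses detected in the mixture trace")
  bg <- attr(pulses, "background")
  min_I <- 2 * (bg[["upper"]] - bg[["mean"]])
  rows <- list()
  for (i in seq_along(pulses)) {
    r <- densify(pulses[[i]], scheme, A, label = "unknown", pulse_id = i,
                 min_I = min_I)
    if (!is.null(r) && nrow(r)) rows[[length(rows) + 1L]] <- r
  }
  tab <- do.call(rbind, rows)
  act <- predict_activations(model, tab)
  levels_ <- model_levels(model)
  votes <- majority_vote(tab$pulse_id, act, levels_)
  predicted <- as.integer(table(factor(votes, levels = levels_)))
  out <- data.frame(class = levels_, predicted = predicted,
                    stringsAsFactors = FALSE)
  if (nrow(trace$ground_truth) && any(trace$ground_truth$label %in% levels_)) {
    preset <- as.integer(table(factor(trace$ground_truth$label,
                                      levels = levels_)))
    out$preset <- preset
    out$rel_error_preset <- ifelse(preset > 0,
                                   abs(predicted - preset) / preset, NA_real_)
    out$rel_error_predicted <- ifelse(predicted > 0,
                                      abs(predicted - preset) / predicted,
                                      NA_real_)
  }
  structure(out, n_detected = length(pulses),
            class = c("plp_mixture_prediction", "data.frame"))
}

#' Compare dense-sampling schemes end to end
#'
#' The central experiment: for each seed, simulate one labeled
#' pure-suspension trace per class, detect the pulses once, then for every
#' scheme featurize, split (pulse-grouped, 70/30), train the
#' backpropagation network and evaluate. Reports per-scheme mean and s.d. of
#' the pulse-level and row-level test accuracies and the dense-sampling gain
#' (PLP-All minus PLP-Ave, pulse level).
#'
#' @param classes list of [particle_class] objects.
#' @param schemes list of scheme specifiers (default
#'   `list("ave", 4, 10, 100, "all")`).
#' @param seeds integer vector of replicate seeds (>= 3 recommended).
#' @param n_pulses_per_class transits per class and seed (default 60).
#' @param duration per-trace duration in seconds (default 3).
#' @param snr simulator signal-to-noise ratio; `Inf` disables noise.
#' @param sigma_phi orientation-drift override passed to the simulator
#'   (`NULL` keeps class defaults, `0` disables drift).
#' @param cap_per_class per-class row cap applied to each scheme's dataset
#'   (default `Inf`: each scheme keeps its natural row count, so the
#'   per-sample scheme trains on more rows and casts more votes per pulse,
#'   exactly as the featurization defines).
#' @param epochs,lr,batch_size network settings (defaults 100, 0.5, 32).
#' @param train_frac split fraction (default 0.7).
#' @param A instrument matrix.
#' @param progress print one line per scheme x seed.
#' @return A `plp_scheme_comparison`: list with `results` (one row per
#'   scheme x seed), `summary` (per scheme), and `gap` (mean PLP-All -
#'   PLP-Ave pulse accuracy).
#' @export
run_scheme_comparison <- function(classes,
                                  schemes = list("ave", 4, 10, 100, "all"),
                                  seeds = 1:5,
                                  n_pulses_per_class = 60L,
                                  duration = 3,
                                  snr = 60,
                                  sigma_phi = NULL,
                                  cap_per_class = Inf,
                                  epochs = 100L, lr = 0.5, batch_size = 32L,
                                  train_frac = 0.7,
                                  A = ideal_psa_matrix(),
                                  progress = FALSE) {
  stopifnot(length(schemes) >= 2L, length(seeds) >= 1L)
  results <- data.frame()
  for (seed in seeds) {
    traces <- lapply(seq_along(classes), function(i) {
      simulate_pure(classes[[i]], n_pulses_per_class, duration,
                    A = A, noise = noise_spec(snr = snr),
                    sigma_phi = sigma_phi,
                    seed = seed * 1000L + i)
    })
    for (scheme in schemes) {
      tab <- build_dataset(traces, scheme, A,
                           cap_per_class = cap_per_class, seed = seed)
      parts <- split_dataset(tab, train_frac = train_frac, seed = seed)
      cfg <- bpnn_config(length(classes), epochs = epochs, lr = lr,
                         batch_size = batch_size, seed = seed)
      fit <- train_bpnn(parts$train, cfg)
      rep_ <- evaluate(fit, parts$test)
      results <- rbind(results, data.frame(
        scheme = scheme_label(scheme), seed = seed,
        accuracy_pulse = rep_$pulse$accuracy$overall,
        accuracy_row = rep_$row$accuracy$overall,
        mse = rep_$mse,
        n_rows = nrow(tab),
        stringsAsFactors = FALSE))
      if (progress) {
        message(sprintf("%s seed %d: pulse acc %.3f, row acc %.3f",
                        scheme_label(scheme), seed,
                        rep_$pulse$accuracy$overall,
                        rep_$row$accuracy$overall))
      }
    }
  }
  ord <- vapply(schemes, scheme_label, character(1L))
  summary_ <- do.call(rbind, lapply(ord, function(sc) {
    r <- results[results$scheme == sc, ]
    data.frame(scheme = sc,
               mean_accuracy_pulse = mean(r$accuracy_pulse),
               sd_accuracy_pulse = stats::sd(r$accuracy_pulse),
               mean_accuracy_row = mean(r$accuracy_row),
               mean_mse = mean(r$mse),
               stringsAsFactors = FALSE)
  }))
  gap <- NA_real_
  if (all(c("PLP-All", "PLP-Ave") %in% summary_$scheme)) {
    gap <- summary_$mean_accuracy_pulse[summary_$scheme == "PLP-All"] -
      summary_$mean_accuracy_pulse[summary_$scheme == "PLP-Ave"]
  }
  structure(list(results = results, summary = summary_, gap = gap,
                 seeds = seeds),
            class = "plp_scheme_comparison")
}

#' @export
print.plp_scheme_comparison <- function(x, ...) {
  cat(sprintf("plp_scheme_comparison over %d seeds\n", length(x$seeds)))
  print(x$summary, row.names = FALSE, digits = 4)
  if (is.finite(x$gap)) {
    cat(sprintf("dense-sampling gain (PLP-All - PLP-Ave): %+.1f points\n",
                100 * x$gap))
  }
  invisible(x)
}
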