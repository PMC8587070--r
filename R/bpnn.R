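#' Backpropagation network configuration
#'
#' The reference classifier is a small fully connected sigmoid network with
#' five inputs (`I, q, u, v, DOP`), three hidden layers of 5, 6 and 4 nodes,
#' and one sigmoid output node per class, trained by plain mini-batch
#' gradient descent on the squared error against one-hot targets. The
#' intensity feature is z-scored from training statistics before entering
#' the network; `q`, `u`, `v`, `DOP` are already bounded and enter raw.
#'
#' @param n_classes number of output nodes.
#' @param hidden hidden-layer sizes (default `c(5, 6, 4)`).
#' @param epochs training epochs (default 100, after which the model has
#'   typically converged on these features).
#' @param lr learning rate (default 0.5; sigmoid layers trained on squared
#'   error sit on a long flat plateau at small rates, and this topology
#'   needs rates of this order to leave it within 100 epochs).
#' @param momentum classical momentum coefficient (default 0.9).
#' @param batch_size mini-batch size (default 32).
#' @param val_frac fraction of the training rows held out for the per-epoch
#'   accuracy/MSE curves (default 0.1; 0 disables the curves' held-out part).
#' @param seed seed controlling weight initialization and batch shuffling.
#' @return A `bpnn_config` list.
#' @export
bpnn_config <- function(n_classes, hidden = c(5L, 6L, 4L), epochs = 100L,
                        lr = 0.5, momentum = 0.9, batch_size = 32L,
                        val_frac = 0.1, seed = 1L) {
  stopifnot(n_classes >= 2L, all(hidden >= 1L), epochs >= 0L, lr > 0,
            momentum >= 0, momentum < 1,
            batch_size >= 1L, val_frac >= 0, val_frac < 1)
  structure(list(n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden),
                 epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "bpnn_config")
}

feature_cols <- function() c("I", "q", "u", "v", "DOP")

feature_matrix <- function(data, scale_I = NULL) {
  X <- as.matrix(data[, feature_cols(), drop = FALSE])
  if (is.null(scale_I)) {
    mu <- mean(X[, "I"])
    sd_ <- stats::sd(X[, "I"])
    if (!is.finite(sd_) || sd_ == 0) sd_ <- 1
    scale_I <- c(mean = mu, sd = sd_)
  }
  X[, "I"] <- (X[, "I"] - scale_I[["mean"]]) / scale_I[["sd"]]
  attr(X, "scale_I") <- scale_I
  X
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bpnn_init <- function(sizes) {
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    r <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -r, r),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

bpnn_forward <- function(net, X) {
  acts <- list(X)
  A <- X
  for (l in seq_along(net$W)) {
    A <- sigmoid(sweep(A %*% net$W[[l]], 2L, net$b[[l]], `+`))
    acts[[l + 1L]] <- A
  }
  acts
}

#' Train the backpropagation network
#'
#' Mini-batch gradient descent on the mean squared error between the sigmoid
#' outputs and one-hot class targets ("the signal propagates forward and the
#' error propagates backward"). Deterministic under a fixed config seed.
#' A held-out slice of the training rows is tracked per epoch to produce the
#' accuracy and MSE learning curves.
#'
#' @param train a feature table with columns `I, q, u, v, DOP` and `label`.
#' @param config a [bpnn_config()]; if missing, defaults are derived from
#'   the label set of `train`.
#' @return A `plp_bpnn` model: weights, feature scaling, class levels,
#'   config, and `curves` (per-epoch data frame `epoch`, `train_mse`,
#'   `val_mse`, `val_accuracy`).
#' @examples
#' \donttest{
#' lib <- preset_class_library(c("CD", "PS-10"))
#' traces <- lapply(seq_along(lib), function(i)
#'   simulate_pure(lib[[i]], 15, 1, seed = i))
#' tab <- build_dataset(traces, "ave")
#' fit <- train_bpnn(tab, bpnn_config(2, epochs = 50, seed = 1))
#' utils::tail(fit$curves, 1)
#' }
#' @export
train_bpnn <- function(train, config = NULL) {
  labels <- as.character(train$label)
  levels_ <- sort(unique(labels))
  if (length(levels_) < 2L) {
    stop("training data must contain at least 2 classes, got ",
         length(levels_))
  }
  if (is.null(config)) config <- bpnn_config(length(levels_))
  if (config$n_classes != length(levels_)) {
    stop(sprintf("config expects %d classes but data has %d",
                 config$n_classes, length(levels_)))
  }
  X <- feature_matrix(train)
  scale_I <- attr(X, "scale_I")
  Y <- outer(labels, levels_, `==`) * 1
  n <- nrow(X)
  set.seed(config$seed)
  sizes <- c(ncol(X), config$hidden, config$n_classes)
  net <- bpnn_init(sizes)
  # held-out slice for learning curves
  perm <- sample(n)
  n_val <- floor(config$val_frac * n)
  val_ix <- perm[seq_len(n_val)]
  fit_ix <- if (n_val > 0L) perm[-seq_len(n_val)] else perm
  Xf <- X[fit_ix, , drop = FALSE]; Yf <- Y[fit_ix, , drop = FALSE]
  Xv <- X[val_ix, , drop = FALSE]; Yv <- Y[val_ix, , drop = FALSE]
  nf <- nrow(Xf)
  L <- length(net$W)
  vW <- lapply(net$W, function(w) w * 0)
  vb <- lapply(net$b, function(b) b * 0)
  curves <- data.frame(epoch = integer(), train_mse = numeric(),
                       val_mse = numeric(), val_accuracy = numeric())
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(nf)
    starts <- seq(1L, nf, by = config$batch_size)
    for (s0 in starts) {
      ix <- ord[s0:min(s0 + config$batch_size - 1L, nf)]
      A <- bpnn_forward(net, Xf[ix, , drop = FALSE])
      m <- length(ix)
      out <- A[[L + 1L]]
      delta <- (out - Yf[ix, , drop = FALSE]) * out * (1 - out)
      for (l in seq(L, 1L)) {
        gW <- crossprod(A[[l]], delta) / m
        gb <- colMeans(delta)
        if (l > 1L) {
          Al <- A[[l]]
          delta <- (delta %*% t(net$W[[l]])) * Al * (1 - Al)
        }
        vW[[l]] <- config$momentum * vW[[l]] - config$lr * unname(gW)
        vb[[l]] <- config$momentum * vb[[l]] - config$lr * unname(gb)
        net$W[[l]] <- unname(net$W[[l]] + vW[[l]])
        net$b[[l]] <- net$b[[l]] + vb[[l]]
      }
    }
    out_f <- bpnn_forward(net, Xf)[[L + 1L]]
    train_mse <- mean((out_f - Yf)^2)
    if (!is.finite(train_mse)) {
      stop(sprintf(paste0("training loss became non-finite at epoch %d; ",
                          "the learning rate (%.3g) is likely too large"),
                   epoch, config$lr))
    }
    if (n_val > 0L) {
      out_v <- bpnn_forward(net, Xv)[[L + 1L]]
      val_mse <- mean((out_v - Yv)^2)
      val_acc <- mean(levels_[max.col(out_v, ties.method = "first")] ==
                        labels[val_ix])
    } else {
      val_mse <- NA_real_; val_acc <- NA_real_
    }
    curves <- rbind(curves, data.frame(epoch = epoch, train_mse = train_mse,
                                       val_mse = val_mse,
                                       val_accuracy = val_acc))
  }
  structure(list(net = net, levels = levels_, scale_I = scale_I,
                 config = config, curves = curves, sizes = sizes),
            class = "plp_bpnn")
}

#' @export
print.plp_bpnn <- function(x, ...) {
  cat(sprintf("plp_bpnn: topology %s, %d epochs, classes: %s\n",
              paste(x$sizes, collapse = "-"), x$config$epochs,
              paste(x$levels, collapse = ", ")))
  if (nrow(x$curves)) {
    last <- utils::tail(x$curves, 1L)
    cat(sprintf("  final train MSE %.4f, held-out accuracy %.3f\n",
                last$train_mse, last$val_accuracy))
  }
  invisible(x)
}

# Per-row class activations (rows x classes), shared predict interface.
predict_activations <- function(model, data) {
  UseMethod("predict_activations")
}

#' @export
predict_activations.plp_bpnn <- function(model, data) {
  X <- feature_matrix(data, scale_I = model$scale_I)
  out <- bpnn_forward(model$net, X)[[length(model$net$W) + 1L]]
  colnames(out) <- model$levels
  out
}

#' Predict class labels for feature rows
#'
#' @param object a trained `plp_bpnn`.
#' @param newdata a feature table.
#' @param type `"class"` for labels, `"prob"` for the per-class sigmoid
#'   activations.
#' @param ... unused.
#' @return A character vector of labels or an activation matrix.
#' @export
predict.plp_bpnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  out <- predict_activations(object, newdata)
  if (type == "prob") return(out)
  object$levels[max.col(out, ties.method = "first")]
}

model_levels <- function(model) UseMethod("model_levels")
#' @export
model_levels.plp_bpnn <- function(model) model$levels
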