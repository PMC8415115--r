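#' Dense feed-forward architecture specification
#'
#' @param hidden_layers number of hidden layers, 0..4.
#' @param width neurons per hidden layer (100..1200 in the reference sweep;
#'   any positive value is accepted).
#' @return An `arch_spec` list. Inner activation is the rectifier (ReLU),
#'   the single output unit uses the logistic sigmoid.
#' @export
arch_spec <- function(hidden_layers = 2L, width = 100L) {
  stopifnot(hidden_layers >= 0L, hidden_layers <= 4L, width >= 1L)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 width = as.integer(width)), class = "arch_spec")
}

#' Training configuration for the classifier
#'
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param patience early-stopping patience on validation loss (epochs); the
#'   best-validation weights are restored.
#' @param seed RNG seed; fixed seed makes training reproducible.
#' @return A `train_config` list. The optimiser is Adam (beta1 = 0.9,
#'   beta2 = 0.999) with binary cross-entropy loss.
#' @export
train_config <- function(epochs = 50L, batch_size = 128L, learning_rate = 1e-3,
                         patience = 5L, seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 seed = as.integer(seed)), class = "train_config")
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(d_in, arch) {
  sizes <- c(d_in, rep(arch$width, arch$hidden_layers), 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    # He initialisation for rectifier layers
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b, sizes = sizes)
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- list(X)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) relu(Z) else Z   # output layer kept as logit
  }
  list(A = A, logit = A[[L + 1L]], p = sigmoid(A[[L + 1L]]))
}

# gradients of mean binary cross-entropy wrt weights (and optionally inputs)
mlp_backward <- function(net, fw, y, input_grad = FALSE) {
  L <- length(net$W)
  n <- length(y)
  delta <- (fw$p - y) / n                 # d(loss)/d(logit), BCE + sigmoid
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(fw$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(net$W[[l]])) * (fw$A[[l]] > 0)
    else if (input_grad) delta <- delta %*% t(net$W[[1L]])
  }
  list(gW = gW, gb = gb, gX = if (input_grad) delta else NULL)
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Train the micropattern classifier
#'
#' Trains a dense feed-forward binary classifier (ReLU hidden layers,
#' sigmoid output) on the flattened 0/1 masks of a balanced dataset, using
#' the Adam optimiser with binary cross-entropy loss, minibatches, and early
#' stopping on validation loss (best-validation weights restored). Test-set
#' metrics are attached.
#'
#' @param dataset a [build_balanced_dataset()] result.
#' @param arch an [arch_spec()].
#' @param config a [train_config()].
#' @return A `fibro_mlp` model with weights, per-epoch `history` tibble and
#'   `metrics` ([evaluate_classifier()] on the test split).
#' @export
train_classifier <- function(dataset, arch = arch_spec(), config = train_config()) {
  stopifnot(inherits(dataset, "micro_dataset"))
  sp <- dataset$data$split
  if (!all(c("train", "test") %in% sp)) abort("dataset needs nonempty train and test splits")
  Xtr <- dataset$X[sp == "train", , drop = FALSE]
  ytr <- dataset$y[sp == "train"]
  has_val <- any(sp == "validation")
  Xva <- dataset$X[sp == "validation", , drop = FALSE]
  yva <- dataset$y[sp == "validation"]

  net <- NULL; hist <- NULL
  with_local_seed(config$seed, {
    net <- mlp_init(ncol(Xtr), arch)
    L <- length(net$W)
    mW <- vW <- lapply(net$W, function(w) w * 0)
    mb <- vb <- lapply(net$b, function(b) b * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
    t_adam <- 0L
    best <- list(loss = Inf, W = net$W, b = net$b, epoch = 0L)
    wait <- 0L
    rows <- list()
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(nrow(Xtr))
      for (start in seq(1L, length(idx), by = config$batch_size)) {
        bi <- idx[start:min(start + config$batch_size - 1L, length(idx))]
        fw <- mlp_forward(net, Xtr[bi, , drop = FALSE])
        if (!all(is.finite(fw$p))) abort("non-finite loss: training diverged")
        gr <- mlp_backward(net, fw, ytr[bi])
        t_adam <- t_adam + 1L
        corr <- sqrt(1 - b2^t_adam) / (1 - b1^t_adam)
        for (l in seq_len(L)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gr$gW[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gr$gW[[l]]^2
          net$W[[l]] <- net$W[[l]] - lr * corr * mW[[l]] / (sqrt(vW[[l]]) + eps)
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gr$gb[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gr$gb[[l]]^2
          net$b[[l]] <- net$b[[l]] - lr * corr * mb[[l]] / (sqrt(vb[[l]]) + eps)
        }
      }
      tr_loss <- bce_loss(mlp_forward(net, Xtr)$p, ytr)
      va_loss <- if (has_val) bce_loss(mlp_forward(net, Xva)$p, yva) else tr_loss
      rows[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = tr_loss,
                                      val_loss = va_loss)
      if (va_loss < best$loss - 1e-6) {
        best <- list(loss = va_loss, W = net$W, b = net$b, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    net$W <- best$W; net$b <- best$b
    hist <- dplyr::bind_rows(rows)
  })

  model <- structure(list(net = net, arch = arch, config = config,
                          side = dataset$side, history = hist),
                     class = "fibro_mlp")
  model$metrics <- evaluate_classifier(model,
                                       dataset$X[sp == "test", , drop = FALSE],
                                       dataset$y[sp == "test"])
  model
}

#' @export
print.fibro_mlp <- function(x, ...) {
  cat(sprintf("<fibro_mlp> %d-d input, %d hidden layer(s) x %d, %d epochs trained\n",
              x$net$sizes[1], x$arch$hidden_layers, x$arch$width,
              max(x$history$epoch)))
  if (!is.null(x$metrics))
    cat(sprintf("  test accuracy %.3f, AUC %.3f\n",
                x$metrics$accuracy, x$metrics$auc))
  invisible(x)
}

#' Predicted class-1 probabilities
#'
#' @param object a `fibro_mlp`.
#' @param newdata matrix of flattened masks (rows) or a `micro_dataset`.
#' @param ... unused.
#' @return Numeric vector of probabilities that each window is
#'   discriminative.
#' @export
predict.fibro_mlp <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "micro_dataset")) newdata$X else as.matrix(newdata)
  as.vector(mlp_forward(object$net, X)$p)
}

#' Evaluate a classifier on a labelled set
#'
#' Threshold-0.5 predictions give accuracy, sensitivity, specificity and the
#' 2 x 2 confusion matrix; the area under the ROC curve is threshold-free
#' (rank statistic, ties counted half).
#'
#' @param model a `fibro_mlp` (or any object with a `predict` method giving
#'   probabilities).
#' @param X feature matrix of the evaluation split.
#' @param y 0/1 labels (1 = discriminative).
#' @return An `eval_metrics` list: `accuracy`, `sensitivity`, `specificity`,
#'   `auc`, `confusion` (2 x 2 counts, rows = prediction).
#' @export
evaluate_classifier <- function(model, X, y) {
  if (length(unique(y)) < 2L) abort("single-class test split: AUC undefined")
  p <- predict(model, X)
  pred <- as.integer(p >= 0.5)
  confusion <- matrix(c(sum(pred == 1 & y == 1), sum(pred == 1 & y == 0),
                        sum(pred == 0 & y == 1), sum(pred == 0 & y == 0)),
                      2L, 2L, byrow = TRUE,
                      dimnames = list(prediction = c("discriminative", "indiscriminate"),
                                      truth = c("discriminative", "indiscriminate")))
  structure(list(accuracy = mean(pred == y),
                 sensitivity = mean(pred[y == 1] == 1),
                 specificity = mean(pred[y == 0] == 0),
                 auc = auc_rank(p, y),
                 confusion = confusion, n = length(y)),
            class = "eval_metrics")
}

# Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(tie)
auc_rank <- function(p, y) {
  r <- rank(p)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> n = %d | accuracy %.3f | sensitivity %.3f | specificity %.3f | AUC %.3f\n",
              x$n, x$accuracy, x$sensitivity, x$specificity, x$auc))
  print(x$confusion)
  invisible(x)
}

#' Gradient saliency map of a micropattern
#'
#' The absolute gradient of the classifier's output score (pre-sigmoid
#' logit) with respect to each input element, reshaped to the mask: which
#' elements of the structure the network's decision is most sensitive to.
#' For a model with no hidden layer this is exactly the absolute input
#' weight map.
#'
#' @param model a trained `fibro_mlp`.
#' @param micropattern a side x side mask matrix, a flattened numeric
#'   vector, or one row of a micropattern tibble.
#' @return A `saliency_map` matrix (side x side, non-negative).
#' @export
saliency <- function(model, micropattern) {
  if (is.data.frame(micropattern)) micropattern <- micropattern$mask[[1]]
  x <- as.numeric(micropattern)
  side <- if (is.matrix(micropattern)) nrow(micropattern) else as.integer(sqrt(length(x)))
  X <- matrix(x, 1L)
  fw <- mlp_forward(model$net, X)
  gr <- mlp_backward(model$net, list(A = fw$A, p = fw$logit), y = fw$logit - 1,
                     input_grad = TRUE)
  # with p := logit and y := logit - 1, delta = (p - y)/n = 1, so gX is the
  # exact gradient of the logit wrt the input
  structure(matrix(abs(as.vector(gr$gX)), side, side), class = "saliency_map")
}

#' @rdname glance.fibro_mlp
#' @param x a `fibro_mlp`.
#' @param ... unused.
#' @export
tidy.fibro_mlp <- function(x, ...) x$history

#' Broom-style accessors for a trained classifier
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' tibble of architecture and test metrics.
#'
#' @param x a `fibro_mlp`.
#' @param ... unused.
#' @export
glance.fibro_mlp <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(hidden_layers = x$arch$hidden_layers, width = x$arch$width,
                 side = x$side, epochs = max(x$history$epoch),
                 accuracy = m$accuracy, sensitivity = m$sensitivity,
                 specificity = m$specificity, auc = m$auc, n_test = m$n)
}

#' @export
tidy.eval_metrics <- function(x, ...) {
  tibble::tibble(metric = c("accuracy", "sensitivity", "specificity", "auc"),
                 value = c(x$accuracy, x$sensitivity, x$specificity, x$auc))
}
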