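#' Rectified linear activation
#'
#' `relu(x) = max(0, x)`, applied elementwise.
#'
#' @param x Numeric vector or matrix.
#' @return `x` with negative entries replaced by 0.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Feed-forward network configuration
#'
#' The comparator network is rectangular: six hidden layers of 100 rectifier
#' units each, trained with minibatches of 40 for at most 100 epochs, with
#' early stopping after two consecutive epochs without validation-loss
#' improvement. Loss is categorical cross-entropy, optimized by Adam
#' (these two are implementation choices; the published description fixes
#' only the architecture, epochs, batch size and patience).
#'
#' @param hidden_layers Number of hidden layers.
#' @param units Units per hidden layer.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param patience Consecutive non-improving epochs tolerated before stopping.
#' @param validation_fraction Fraction of the training rows held out (seeded)
#'   for the early-stopping loss.
#' @param learning_rate Adam step size.
#' @return An `mlp_config` list.
#' @export
mlp_config <- function(hidden_layers = 6L, units = 100L, max_epochs = 100L,
                       batch_size = 40L, patience = 2L,
                       validation_fraction = 0.1, learning_rate = 1e-3) {
  stopifnot(hidden_layers >= 1, units >= 1, max_epochs >= 1, batch_size >= 1,
            patience >= 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 units = as.integer(units),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 learning_rate = learning_rate),
            class = "mlp_config")
}

# Forward pass; returns list of pre-activations/activations when keep = TRUE,
# otherwise just the softmax output.
mlp_forward <- function(W, b, X, keep = FALSE) {
  L <- length(W)
  A <- X
  As <- if (keep) vector("list", L + 1) else NULL
  if (keep) As[[1]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% W[[l]] + matrix(b[[l]], nrow(A), length(b[[l]]), byrow = TRUE)
    A <- if (l < L) relu(Z) else {
      # row-wise softmax, shifted for stability
      E <- exp(Z - apply(Z, 1, max))
      E / rowSums(E)
    }
    if (keep) As[[l + 1]] <- A
  }
  if (keep) As else A
}

mlp_loss_acc <- function(P, labels_idx) {
  eps <- 1e-12
  loss <- -mean(log(pmax(P[cbind(seq_len(nrow(P)), labels_idx)], eps)))
  acc <- mean(max.col(P) == labels_idx)
  c(loss = loss, acc = acc)
}

#' Train the multiclass feed-forward baseline
#'
#' Trains the comparator network on a feature dataset whose labels include
#' an explicit outlier class (unlike the nested classifier, this baseline
#' must see labeled outlier examples at training time). Features are
#' standardized with training mean/sd. Training halts at `max_epochs` or as
#' soon as the validation loss has failed to improve for `patience`
#' consecutive epochs; per-epoch accuracy/loss curves are recorded.
#'
#' @param train Feature dataset tibble with a `label` column holding at
#'   least 2 classes.
#' @param config An [mlp_config()].
#' @param seed Integer seed (weight init, shuffling, validation split).
#' @return A `har_mlp` model: weights, feature schema, class labels,
#'   `curves` (tibble: epoch, train_loss, train_acc, val_loss, val_acc) and
#'   `stopped_epoch`.
#' @export
train_mlp <- function(train, config = mlp_config(), seed = 1L) {
  cols <- setdiff(feature_cols(train), "label")
  X <- as.matrix(train[, cols, drop = FALSE])
  classes <- sort(unique(train$label))
  if (length(classes) < 2L) abort("training data must contain >= 2 classes")
  y_idx <- match(train$label, classes)

  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sg, "/")

  seed_rng(seed)
  n <- nrow(X)
  n_val <- max(1L, floor(config$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y_idx[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y_idx[val_idx]

  k <- length(classes)
  sizes <- c(ncol(X), rep(config$units, config$hidden_layers), k)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l)
    matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1]))
  b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate

  Ytr <- matrix(0, length(ytr), k); Ytr[cbind(seq_along(ytr), ytr)] <- 1
  curves <- vector("list", config$max_epochs)
  best_val <- Inf; bad <- 0L; t_adam <- 0L
  stopped <- config$max_epochs

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(nrow(Xtr))
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    for (bidx in batches) {
      As <- mlp_forward(W, b, Xtr[bidx, , drop = FALSE], keep = TRUE)
      delta <- (As[[L + 1]] - Ytr[bidx, , drop = FALSE]) / length(bidx)
      t_adam <- t_adam + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(As[[l]], delta)
        gb <- colSums(delta)
        if (l > 1)
          delta <- (delta %*% t(W[[l]])) * (As[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        cor1 <- 1 - beta1^t_adam; cor2 <- 1 - beta2^t_adam
        W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
      }
    }
    tr_stat <- mlp_loss_acc(mlp_forward(W, b, Xtr), ytr)
    val_stat <- mlp_loss_acc(mlp_forward(W, b, Xval), yval)
    curves[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = tr_stat[["loss"]],
      train_acc = tr_stat[["acc"]], val_loss = val_stat[["loss"]],
      val_acc = val_stat[["acc"]])

    if (val_stat[["loss"]] < best_val - 1e-9) {
      best_val <- val_stat[["loss"]]; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) { stopped <- epoch; break }
    }
  }

  structure(list(W = W, b = b, mu = mu, sigma = sg, features = cols,
                 classes = classes, config = config, seed = seed,
                 curves = dplyr::bind_rows(curves), stopped_epoch = stopped),
            class = "har_mlp")
}

#' Predict activity labels with the feed-forward baseline
#'
#' @param object A `har_mlp` model.
#' @param newdata Feature dataset tibble with the training feature columns.
#' @param ... Unused.
#' @return Character vector of predicted labels, drawn from the training
#'   label set (closed-world prediction: the outlier class must have been
#'   present at training time to be predicted).
#' @export
predict.har_mlp <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0)
    abort(paste0("newdata lacks feature column(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  if (nrow(newdata) == 0L) return(character(0))
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  X <- sweep(sweep(X, 2, object$mu), 2, object$sigma, "/")
  P <- mlp_forward(object$W, object$b, X)
  object$classes[max.col(P)]
}

#' @describeIn train_mlp Per-epoch training curves.
#' @param x A `har_mlp` model.
#' @param ... Unused.
#' @method tidy har_mlp
#' @export
tidy.har_mlp <- function(x, ...) x$curves

#' @describeIn train_mlp One-row summary: epochs run, final losses and
#'   accuracies.
#' @method glance har_mlp
#' @export
glance.har_mlp <- function(x, ...) {
  last <- x$curves[nrow(x$curves), ]
  tibble::tibble(epochs_run = nrow(x$curves),
                 stopped_early = x$stopped_epoch < x$config$max_epochs,
                 train_loss = last$train_loss, train_acc = last$train_acc,
                 val_loss = last$val_loss, val_acc = last$val_acc)
}

#' @describeIn train_mlp Learning-curve plot (loss and accuracy per epoch).
#' @param object A `har_mlp` model.
#' @method autoplot har_mlp
#' @export
autoplot.har_mlp <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves, -"epoch",
                              names_to = c("split", "metric"),
                              names_sep = "_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Feed-forward baseline learning curves") +
    ggplot2::theme_minimal()
}
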