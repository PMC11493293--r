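# Stream training: mini-batch cross-entropy with the adaptive-moment (Adam)
# optimizer. Fully seeded -- a fixed seed reproduces the history bit for bit
# on a fixed-threading BLAS.

#' Training configuration
#'
#' @param epochs Number of passes over the training set (>= 1; default 20).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling shuffling (weight initialization is
#'   seeded by the model builders).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 20L, batch_size = 32L, learning_rate = 1e-3,
                         seed = 1L) {
  if (epochs < 1) abort("`epochs` must be >= 1.", class = "feedstream_bad_config")
  if (batch_size < 1) abort("`batch_size` must be >= 1.",
                            class = "feedstream_bad_config")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

# Coerce inputs to the (H, W, C, N) batch layout the layers expect.
# 2D streams: a list of H x W x 3 arrays (or one 4D array).
# 1D stream: an N x L matrix of feature vectors -> (1, L, 1, N).
as_input_batch <- function(x, kind) {
  if (kind == "conv1d") {
    if (is.matrix(x)) {
      arr <- array(0, dim = c(1L, ncol(x), 1L, nrow(x)))
      arr[1, , 1, ] <- t(x)
      return(arr)
    }
    if (is.numeric(x) && is.null(dim(x))) {
      return(array(x, dim = c(1L, length(x), 1L, 1L)))
    }
    if (is.array(x) && length(dim(x)) == 4L) return(x)
    abort("GLCM stream input must be an N x L matrix or a vector.",
          class = "feedstream_shape_mismatch")
  }
  if (is.list(x)) {
    d <- dim(x[[1]])
    arr <- array(0, dim = c(d[1], d[2], d[3], length(x)))
    for (i in seq_along(x)) arr[, , , i] <- x[[i]]
    return(arr)
  }
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(array(x, dim = c(dim(x), 1L)))
  abort("Image stream input must be a list of H x W x 3 arrays or a 4D array.",
        class = "feedstream_shape_mismatch")
}

check_input_shape <- function(model, xb) {
  d <- dim(xb)
  expected <- switch(model$kind,
    residual = model$config$input_size,
    conv1d = c(1L, model$config$input_length, 1L)
  )
  if (!identical(as.integer(d[1:3]), as.integer(expected))) {
    abort(sprintf("Input shape (%s) does not match the model's expected (%s).",
                  paste(d[1:3], collapse = "x"),
                  paste(expected, collapse = "x")),
          class = "feedstream_shape_mismatch")
  }
  invisible(xb)
}

# scale pixel inputs to zero-centered units; GLCM vectors pass through
scale_input <- function(xb, kind) {
  if (kind == "residual") xb / 127.5 - 1 else xb
}

encode_labels <- function(labels, classes) {
  y <- match(labels, classes)
  if (anyNA(y)) {
    abort("Labels outside the model's class set.", class = "feedstream_bad_label")
  }
  y
}

batch_loss_grad <- function(logits, y_idx) {
  n <- ncol(logits)
  p <- softmax_cols(logits)
  picked <- p[cbind(y_idx, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(y_idx, seq_len(n))] <- dlogits[cbind(y_idx, seq_len(n))] - 1
  list(loss = loss, dlogits = dlogits / n,
       acc = mean(max.col(t(p), ties.method = "first") == y_idx))
}

adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  params <- tree_map(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

#' Train a stream classifier
#'
#' Optimizes the 3-class cross-entropy of a `stream_model` with mini-batch
#' Adam. Training-set loss/accuracy in the history are averages over the
#' mini-batch forward passes of the epoch; validation metrics are full passes
#' in inference mode.
#'
#' @param model A `stream_model` from [build_residual_backbone()] or
#'   [build_conv1d_net()].
#' @param x Training inputs: list of `H x W x 3` arrays (or 4D array) for the
#'   image streams, `N x L` matrix for the GLCM stream.
#' @param labels Character vector of per-sample class labels.
#' @param config A [train_config()].
#' @param x_val,labels_val Optional validation data.
#' @return A `trained_stream`: the fitted `stream_model` plus `$history`, a
#'   tibble with one row per epoch (`epoch`, `train_loss`, `train_acc`,
#'   `val_loss`, `val_acc`).
#' @export
train_stream <- function(model, x, labels, config = train_config(),
                         x_val = NULL, labels_val = NULL) {
  if (!inherits(model, "stream_model")) {
    abort("`model` must be a `stream_model`.", class = "feedstream_bad_config")
  }
  if (!inherits(config, "train_config")) {
    abort("`config` must be a `train_config`.", class = "feedstream_bad_config")
  }
  xb <- scale_input(as_input_batch(x, model$kind), model$kind)
  check_input_shape(model, xb)
  y <- encode_labels(labels, model$classes)
  if (length(unique(y)) < length(model$classes)) {
    abort("Every class must be present in the training data.",
          class = "feedstream_missing_class")
  }
  has_val <- !is.null(x_val)
  if (has_val) {
    xv <- scale_input(as_input_batch(x_val, model$kind), model$kind)
    yv <- encode_labels(labels_val, model$classes)
  }
  n <- dim(xb)[4]
  params <- model_params(model)
  state <- list(m = tree_map(function(p) p * 0, params),
                v = tree_map(function(p) p * 0, params))
  history <- vector("list", config$epochs)
  t_step <- 0L
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      accs <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1L, n)]
        xi <- xb[, , , take, drop = FALSE]
        fw <- net_forward(model, xi, training = TRUE)
        model <- fw$model
        lg <- batch_loss_grad(fw$logits, y[take])
        losses <- c(losses, lg$loss)
        accs <- c(accs, lg$acc)
        bw <- net_backward(model, fw$caches, lg$dlogits)
        t_step <- t_step + 1L
        upd <- adam_update(model_params(model), bw$grads, state,
                           config$learning_rate, t_step)
        state <- upd$state
        model <- model_set_params(model, upd$params)
      }
      val_loss <- NA_real_
      val_acc <- NA_real_
      if (has_val) {
        ev <- net_forward(model, xv, training = FALSE)
        vl <- batch_loss_grad(ev$logits, yv)
        val_loss <- vl$loss
        val_acc <- vl$acc
      }
      history[[epoch]] <- tibble(
        epoch = epoch, train_loss = mean(losses), train_acc = mean(accs),
        val_loss = val_loss, val_acc = val_acc
      )
    }
  })
  model$history <- dplyr::bind_rows(history)
  model$train_config <- config
  class(model) <- c("trained_stream", class(model))
  model
}

#' Predict class scores with a stream classifier
#'
#' @param model A (trained) `stream_model`.
#' @param x Inputs in the stream's format (single item or batch).
#' @return A tibble with one row per input, columns `p_none`, `p_weak`,
#'   `p_strong` (non-negative, summing to 1) and `.pred_class` (the argmax
#'   label; exact ties resolve to the earlier class in none/weak/strong
#'   order). Batch order is preserved.
#' @export
predict_stream <- function(model, x) {
  xb <- scale_input(as_input_batch(x, model$kind), model$kind)
  check_input_shape(model, xb)
  p <- softmax_cols(net_forward(model, xb, training = FALSE)$logits)
  scores <- t(p)
  colnames(scores) <- paste0("p_", model$classes)
  out <- as_tibble(scores)
  out$.pred_class <- model$classes[max.col(scores, ties.method = "first")]
  out
}

#' @export
tidy.trained_stream <- function(x, ...) x$history

#' @export
glance.trained_stream <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(kind = x$kind, epochs = nrow(x$history),
         final_train_loss = last$train_loss, final_train_acc = last$train_acc,
         final_val_loss = last$val_loss, final_val_acc = last$val_acc,
         n_parameters = x$summary$n_parameters)
}

#' Plot a training history
#'
#' @param object A `trained_stream`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracy per epoch for train and validation.
#' @export
autoplot.trained_stream <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = c("split", "metric"), names_sep = "_")
  h <- h[!is.na(h$value), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}
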