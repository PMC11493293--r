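# Stream classifier architectures: a bottleneck residual 2D backbone for the
# flow-image and binary-image streams, and a small 1D convolutional network
# for the 16-value GLCM descriptor. Both end in a softmax over the three
# feeding classes.

#' Residual backbone configuration
#'
#' The full profile reproduces the canonical 50-layer residual network: a
#' 7x7 stride-2 stem convolution plus max-pool, four stages of bottleneck
#' units with block counts (3, 4, 6, 3), global average pooling and a fully
#' connected classifier -- 1 + 3 x (3+4+6+3) = 49 convolution layers, and a
#' 7x7x2048 pre-pool feature map for 224x224x3 input. The reduced profile
#' (block counts (1,1,1,1), 64x64 input, base width 8, last stage stride 1)
#' is a first-class desk-scale variant: the same architecture family small
#' enough to train on a single CPU, with a 4x4 final feature map so class
#' activation maps retain usable spatial resolution.
#'
#' @param profile `"full"` or `"reduced"`; sets all defaults below.
#' @param stage_blocks Four integers: residual units per stage.
#' @param input_size `(height, width, channels)` of the expected input.
#' @param n_classes Number of output classes (>= 2).
#' @param bottleneck Use 3-convolution bottleneck units (default) or
#'   2-convolution basic units.
#' @param base_width Channel width of the stem; stage widths double from it.
#' @param stage_strides Four integers: the stride carried by each stage's
#'   first unit.
#' @param seed Integer seed for weight initialization.
#' @return A `residual_config` object.
#' @export
residual_config <- function(profile = c("full", "reduced"),
                            stage_blocks = NULL, input_size = NULL,
                            n_classes = 3L, bottleneck = TRUE,
                            base_width = NULL, stage_strides = NULL,
                            seed = 1L) {
  profile <- match.arg(profile)
  defaults <- if (profile == "full") {
    list(stage_blocks = c(3L, 4L, 6L, 3L), input_size = c(224L, 224L, 3L),
         base_width = 64L, stage_strides = c(1L, 2L, 2L, 2L))
  } else {
    list(stage_blocks = c(1L, 1L, 1L, 1L), input_size = c(64L, 64L, 3L),
         base_width = 8L, stage_strides = c(1L, 2L, 2L, 1L))
  }
  cfg <- list(
    profile = profile,
    stage_blocks = as.integer(stage_blocks %||% defaults$stage_blocks),
    input_size = as.integer(input_size %||% defaults$input_size),
    n_classes = as.integer(n_classes),
    bottleneck = isTRUE(bottleneck),
    base_width = as.integer(base_width %||% defaults$base_width),
    stage_strides = as.integer(stage_strides %||% defaults$stage_strides),
    seed = as.integer(seed)
  )
  if (length(cfg$stage_blocks) != 4L || any(cfg$stage_blocks < 1L)) {
    abort("`stage_blocks` must be four integers >= 1.",
          class = "feedstream_bad_config")
  }
  if (cfg$n_classes < 2L) {
    abort("`n_classes` must be >= 2.", class = "feedstream_bad_config")
  }
  structure(cfg, class = "residual_config")
}

#' Build the residual stream classifier
#'
#' Constructs the network of [residual_config()]: stem (7x7 stride-2
#' convolution, batch norm, rectification, 3x3 stride-2 max-pool), four stages
#' of residual units with identity/projection shortcuts, global average
#' pooling and a fully connected softmax classifier. The structural summary
#' reports the convolution-layer count (stem + unit main paths; projection
#' shortcuts excluded, matching the conventional 50-layer count), the total
#' weighted-layer count including the classifier, and the pre-pool feature-map
#' shape for the configured input size.
#'
#' @param config A [residual_config()].
#' @return A `stream_model` with elements `layers`, `classes`, `config` and
#'   `summary` (`conv_layers`, `weighted_layers`, `prepool_shape`,
#'   `n_parameters`).
#' @export
build_residual_backbone <- function(config = residual_config()) {
  if (!inherits(config, "residual_config")) {
    abort("`config` must be a `residual_config`.", class = "feedstream_bad_config")
  }
  per_block <- if (config$bottleneck) 3L else 2L
  expansion <- if (config$bottleneck) 4L else 1L
  withr::with_seed(config$seed, {
    layers <- list(
      new_conv(7, 7, config$input_size[3], config$base_width,
               stride = 2L, pad = 3L),
      new_bn(config$base_width),
      new_relu(),
      new_maxpool(3L, 3L, 2L, 1L)
    )
    cin <- config$base_width
    for (s in 1:4) {
      mid <- config$base_width * 2L^(s - 1L)
      for (b in seq_len(config$stage_blocks[s])) {
        stride <- if (b == 1L) config$stage_strides[s] else 1L
        blk <- new_residual_block(cin, mid, stride,
                                  bottleneck = config$bottleneck)
        layers[[length(layers) + 1L]] <- blk
        cin <- blk$cout
      }
    }
    layers[[length(layers) + 1L]] <- new_gap()
    layers[[length(layers) + 1L]] <- new_dense(cin, config$n_classes)
  })
  # shape arithmetic for the summary
  hw <- config$input_size[1:2]
  hw <- vapply(hw, conv_out_len, numeric(1), k = 7, stride = 2, pad = 3)
  hw <- vapply(hw, conv_out_len, numeric(1), k = 3, stride = 2, pad = 1)
  for (s in 1:4) {
    hw <- vapply(hw, conv_out_len, numeric(1), k = 1,
                 stride = config$stage_strides[s], pad = 0)
  }
  summary <- list(
    conv_layers = 1L + per_block * sum(config$stage_blocks),
    weighted_layers = 1L + per_block * sum(config$stage_blocks) + 1L,
    prepool_shape = c(hw, cin),
    n_parameters = sum(unlist(tree_map(length, lapply(layers, layer_params))))
  )
  structure(list(kind = "residual", layers = layers,
                 classes = feeding_classes[seq_len(min(3L, config$n_classes))],
                 config = config, summary = summary),
            class = "stream_model")
}

#' 1D convolutional network configuration
#'
#' Classifier for the GLCM descriptor: stacked 1D convolution + max-pool
#' blocks over the 16-long feature vector, a flatten, one hidden dense layer
#' and a 3-way softmax. Convolution runs along the vector only (width); there
#' is no height dimension.
#'
#' @param input_length Length of the input vector (16 at the default GLCM
#'   configuration).
#' @param conv_blocks List of `(filters, kernel_width, pool_width)` triples.
#' @param dense_units Width of the hidden dense layer.
#' @param n_classes Number of output classes.
#' @param seed Integer seed for weight initialization.
#' @return A `conv1d_config` object.
#' @export
conv1d_config <- function(input_length = 16L,
                          conv_blocks = list(c(32L, 3L, 2L), c(64L, 3L, 2L)),
                          dense_units = 64L, n_classes = 3L, seed = 1L) {
  cfg <- list(input_length = as.integer(input_length),
              conv_blocks = lapply(conv_blocks, as.integer),
              dense_units = as.integer(dense_units),
              n_classes = as.integer(n_classes), seed = as.integer(seed))
  if (!length(cfg$conv_blocks)) {
    abort("At least one conv block is required.", class = "feedstream_bad_config")
  }
  structure(cfg, class = "conv1d_config")
}

#' Build the 1D convolutional stream classifier
#'
#' @param config A [conv1d_config()].
#' @return A `stream_model` (kind `"conv1d"`). Errors if any kernel or pool
#'   window is wider than the remaining vector length.
#' @export
build_conv1d_net <- function(config = conv1d_config()) {
  if (!inherits(config, "conv1d_config")) {
    abort("`config` must be a `conv1d_config`.", class = "feedstream_bad_config")
  }
  withr::with_seed(config$seed, {
    layers <- list()
    len <- config$input_length
    cin <- 1L
    for (blk in config$conv_blocks) {
      filters <- blk[1]; k <- blk[2]; p <- blk[3]
      if (k > len) {
        abort(sprintf("Kernel width %d exceeds remaining length %d.", k, len),
              class = "feedstream_bad_config")
      }
      layers[[length(layers) + 1L]] <- new_conv(1L, k, cin, filters)
      layers[[length(layers) + 1L]] <- new_relu()
      len <- conv_out_len(len, k, 1L, 0L)
      if (p > len) {
        abort(sprintf("Pool width %d exceeds remaining length %d.", p, len),
              class = "feedstream_bad_config")
      }
      layers[[length(layers) + 1L]] <- new_maxpool(1L, p, p, 0L)
      len <- conv_out_len(len, p, p, 0L)
      cin <- filters
    }
    layers[[length(layers) + 1L]] <- new_flatten()
    layers[[length(layers) + 1L]] <- new_dense(len * cin, config$dense_units)
    layers[[length(layers) + 1L]] <- new_relu()
    layers[[length(layers) + 1L]] <- new_dense(config$dense_units,
                                               config$n_classes)
  })
  summary <- list(conv_layers = length(config$conv_blocks),
                  weighted_layers = length(config$conv_blocks) + 2L,
                  flatten_length = len * cin,
                  n_parameters = sum(unlist(tree_map(length,
                                                     lapply(layers, layer_params)))))
  structure(list(kind = "conv1d", layers = layers,
                 classes = feeding_classes[seq_len(min(3L, config$n_classes))],
                 config = config, summary = summary),
            class = "stream_model")
}

#' @export
print.stream_model <- function(x, ...) {
  cat(sprintf("<stream_model:%s> %d weighted layers (%d conv), %s parameters\n",
              x$kind, x$summary$weighted_layers, x$summary$conv_layers,
              format(x$summary$n_parameters, big.mark = ",")))
  if (!is.null(x$summary$prepool_shape)) {
    cat(sprintf("  pre-pool feature map: %s\n",
                paste(x$summary$prepool_shape, collapse = "x")))
  }
  invisible(x)
}

# Forward pass over all layers. Returns logits, per-layer caches and the
# updated model (batch-norm running statistics move during training).
net_forward <- function(model, x, training = TRUE) {
  caches <- vector("list", length(model$layers))
  h <- x
  for (i in seq_along(model$layers)) {
    step <- layer_fw(model$layers[[i]], h, training)
    model$layers[[i]] <- step$layer
    caches[[i]] <- step$cache
    h <- step$y
  }
  list(logits = h, caches = caches, model = model)
}

net_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  d <- dlogits
  for (i in rev(seq_along(model$layers))) {
    step <- layer_bw(model$layers[[i]], caches[[i]], d)
    grads[[i]] <- step$grads
    d <- step$dx
  }
  list(grads = grads, dx = d)
}

softmax_cols <- function(z) {
  z <- z - matrix(apply(z, 2, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}
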