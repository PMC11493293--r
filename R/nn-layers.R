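# Minimal deterministic CNN layer framework over the compiled conv/pool
# kernels. Activations are R arrays in (H, W, C, N) layout; dense inputs are
# (features x N) matrices. Each layer is a plain list with a `type`;
# `layer_fw()` returns the (possibly updated) layer, the output and a cache,
# `layer_bw()` returns the input gradient and parameter gradients mirroring
# `layer_params()`.

new_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  sd <- sqrt(2 / (kh * kw * cin))           # He initialization
  list(type = "conv",
       w = array(rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout)),
       b = numeric(cout), stride = as.integer(stride), pad = as.integer(pad))
}

new_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, channels), beta = numeric(channels),
       rmean = numeric(channels), rvar = rep(1, channels),
       momentum = momentum, eps = eps)
}

new_relu <- function() list(type = "relu")
new_maxpool <- function(kh, kw, stride, pad = 0L) {
  list(type = "maxpool", kh = as.integer(kh), kw = as.integer(kw),
       stride = as.integer(stride), pad = as.integer(pad))
}
new_gap <- function() list(type = "gap")
new_flatten <- function() list(type = "flatten")

new_dense <- function(din, dout) {
  list(type = "dense",
       w = matrix(rnorm(dout * din, 0, sqrt(2 / din)), dout, din),
       b = numeric(dout))
}

# Broadcast a per-channel vector over an (H, W, C, N) activation: a bare
# vector of length H*W*C recycles over the sample dimension in array
# arithmetic (dimensionless operands recycle; dimmed ones must conform).
bc_chan <- function(v, d) rep(v, each = d[1] * d[2])

chan_sum <- function(x) {
  d <- dim(x)
  x3 <- x
  dim(x3) <- c(d[1] * d[2], d[3], d[4])
  rowSums(colSums(x3))
}

chan_mean <- function(x) {
  d <- dim(x)
  chan_sum(x) / (d[1] * d[2] * d[4])
}

layer_fw <- function(layer, x, training = TRUE) {
  switch(layer$type,
    conv = {
      y <- conv2d_fw(x, layer$w, layer$b, layer$stride, layer$pad)
      list(layer = layer, y = y, cache = list(x = x))
    },
    bn = {
      d <- dim(x)
      if (training) {
        m <- chan_mean(x)
        v <- chan_mean(x^2) - m^2
        layer$rmean <- (1 - layer$momentum) * layer$rmean + layer$momentum * m
        layer$rvar <- (1 - layer$momentum) * layer$rvar + layer$momentum * v
      } else {
        m <- layer$rmean
        v <- layer$rvar
      }
      inv_sd <- 1 / sqrt(v + layer$eps)
      xn <- (x - bc_chan(m, d)) * bc_chan(inv_sd, d)
      y <- bc_chan(layer$gamma, d) * xn + bc_chan(layer$beta, d)
      list(layer = layer, y = y, cache = list(xn = xn, inv_sd = inv_sd))
    },
    relu = {
      mask <- x > 0
      y <- x
      y[!mask] <- 0
      list(layer = layer, y = y, cache = list(mask = mask))
    },
    maxpool = {
      p <- maxpool_fw(x, layer$kh, layer$kw, layer$stride, layer$pad)
      list(layer = layer, y = p$y,
           cache = list(idx = p$idx, xdim = dim(x)))
    },
    gap = {
      d <- dim(x)
      x2 <- x
      dim(x2) <- c(d[1] * d[2], d[3] * d[4])
      y <- matrix(colMeans(x2), d[3], d[4])
      list(layer = layer, y = y, cache = list(xdim = d))
    },
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(d[1] * d[2] * d[3], d[4])
      list(layer = layer, y = y, cache = list(xdim = d))
    },
    dense = {
      y <- layer$w %*% x + layer$b
      list(layer = layer, y = y, cache = list(x = x))
    },
    bottleneck = ,
    basic = block_fw(layer, x, training),
    abort(paste0("Unknown layer type: ", layer$type))
  )
}

layer_bw <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- conv2d_bw(cache$x, layer$w, dy, layer$stride, layer$pad)
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    bn = {
      d <- dim(dy)
      xn <- cache$xn
      dgamma <- chan_sum(dy * xn)
      dbeta <- chan_sum(dy)
      dxn <- dy * bc_chan(layer$gamma, d)
      dx <- bc_chan(cache$inv_sd, d) *
        (dxn - bc_chan(chan_mean(dxn), d) - xn * bc_chan(chan_mean(dxn * xn), d))
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = {
      dx <- dy
      dx[!cache$mask] <- 0
      list(dx = dx, grads = list())
    },
    maxpool = {
      list(dx = maxpool_bw(cache$idx, dy, as.integer(cache$xdim)), grads = list())
    },
    gap = {
      d <- cache$xdim
      dx <- array(rep(as.vector(dy), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
      list(dx = dx, grads = list())
    },
    flatten = {
      dx <- dy
      dim(dx) <- cache$xdim
      list(dx = dx, grads = list())
    },
    dense = {
      list(dx = t(layer$w) %*% dy,
           grads = list(w = dy %*% t(cache$x), b = rowSums(dy)))
    },
    bottleneck = ,
    basic = block_bw(layer, cache, dy),
    abort(paste0("Unknown layer type: ", layer$type))
  )
}

# Residual units (post-activation). `bottleneck`: 1x1 reduce -> 3x3 (carries
# the stride) -> 1x1 expand (4x), each with batch norm; `basic`: two 3x3
# convolutions. A 1x1 projection shortcut (with batch norm) is used whenever
# shape or stride changes; otherwise the identity is added before the final
# rectification.
new_residual_block <- function(cin, mid, stride, bottleneck = TRUE) {
  cout <- if (bottleneck) 4L * mid else mid
  blk <- if (bottleneck) {
    list(type = "bottleneck",
         conv1 = new_conv(1, 1, cin, mid), bn1 = new_bn(mid),
         conv2 = new_conv(3, 3, mid, mid, stride = stride, pad = 1), bn2 = new_bn(mid),
         conv3 = new_conv(1, 1, mid, cout), bn3 = new_bn(cout))
  } else {
    list(type = "basic",
         conv1 = new_conv(3, 3, cin, mid, stride = stride, pad = 1), bn1 = new_bn(mid),
         conv2 = new_conv(3, 3, mid, cout, pad = 1), bn2 = new_bn(cout))
  }
  if (stride != 1L || cin != cout) {
    blk$proj_conv <- new_conv(1, 1, cin, cout, stride = stride)
    blk$proj_bn <- new_bn(cout)
  }
  blk$cout <- cout
  blk
}

block_sublayers <- function(block) {
  base <- if (block$type == "bottleneck") {
    c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3")
  } else {
    c("conv1", "bn1", "conv2", "bn2")
  }
  if (!is.null(block$proj_conv)) base <- c(base, "proj_conv", "proj_bn")
  base
}

block_fw <- function(block, x, training) {
  caches <- list()
  h <- x
  main <- setdiff(block_sublayers(block), c("proj_conv", "proj_bn"))
  for (k in seq_along(main)) {
    nm <- main[k]
    step <- layer_fw(block[[nm]], h, training)
    block[[nm]] <- step$layer
    caches[[nm]] <- step$cache
    h <- step$y
    is_last_bn <- k == length(main)
    if (!is_last_bn && block[[nm]]$type == "bn") {
      r <- layer_fw(new_relu(), h, training)
      caches[[paste0(nm, "_relu")]] <- r$cache
      h <- r$y
    }
  }
  if (!is.null(block$proj_conv)) {
    pc <- layer_fw(block$proj_conv, x, training)
    block$proj_conv <- pc$layer
    pb <- layer_fw(block$proj_bn, pc$y, training)
    block$proj_bn <- pb$layer
    caches$proj_conv <- pc$cache
    caches$proj_bn <- pb$cache
    shortcut <- pb$y
  } else {
    shortcut <- x
  }
  s <- h + shortcut
  mask <- s > 0
  y <- s
  y[!mask] <- 0
  caches$out_mask <- mask
  list(layer = block, y = y, cache = caches)
}

block_bw <- function(block, caches, dy) {
  ds <- dy
  ds[!caches$out_mask] <- 0
  grads <- list()
  # shortcut branch
  if (!is.null(block$proj_conv)) {
    pb <- layer_bw(block$proj_bn, caches$proj_bn, ds)
    pc <- layer_bw(block$proj_conv, caches$proj_conv, pb$dx)
    grads$proj_bn <- pb$grads
    grads$proj_conv <- pc$grads
    dx_short <- pc$dx
  } else {
    dx_short <- ds
  }
  # main branch, reverse order with the interleaved rectifications
  main <- setdiff(block_sublayers(block), c("proj_conv", "proj_bn"))
  d <- ds
  for (k in rev(seq_along(main))) {
    nm <- main[k]
    if (k != length(main) && block[[nm]]$type == "bn") {
      d <- layer_bw(new_relu(), caches[[paste0(nm, "_relu")]], d)$dx
    }
    step <- layer_bw(block[[nm]], caches[[nm]], d)
    grads[[nm]] <- step$grads
    d <- step$dx
  }
  list(dx = d + dx_short, grads = grads)
}

# ---- parameter trees -------------------------------------------------------

layer_params <- function(layer) {
  switch(layer$type,
    conv = list(w = layer$w, b = layer$b),
    bn = list(gamma = layer$gamma, beta = layer$beta),
    dense = list(w = layer$w, b = layer$b),
    bottleneck = ,
    basic = {
      nms <- block_sublayers(layer)
      setNames(lapply(nms, function(nm) layer_params(layer[[nm]])), nms)
    },
    list()
  )
}

layer_set_params <- function(layer, p) {
  switch(layer$type,
    conv = { layer$w <- p$w; layer$b <- p$b },
    bn = { layer$gamma <- p$gamma; layer$beta <- p$beta },
    dense = { layer$w <- p$w; layer$b <- p$b },
    bottleneck = ,
    basic = {
      for (nm in block_sublayers(layer)) {
        layer[[nm]] <- layer_set_params(layer[[nm]], p[[nm]])
      }
    }
  )
  layer
}

model_params <- function(model) lapply(model$layers, layer_params)

model_set_params <- function(model, params) {
  for (i in seq_along(model$layers)) {
    model$layers[[i]] <- layer_set_params(model$layers[[i]], params[[i]])
  }
  model
}

# Apply `f` leafwise over parallel trees of numeric leaves. Subtrees are
# matched by name where names exist (gradient trees may order block sublayers
# differently from parameter trees), by position otherwise.
tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    nms <- names(trees[[1]])
    out <- vector("list", length(trees[[1]]))
    names(out) <- nms
    for (i in seq_along(out)) {
      key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, key)))
    }
    out
  } else {
    do.call(f, trees)
  }
}
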