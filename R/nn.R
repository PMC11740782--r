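# Internal CPU conv-net engine.
#
# Tensors are column-major R arrays with dim (H, W, C, N); dense activations
# are matrices (features, N). Layers are mutable environments carrying
# parameters, gradients and the forward cache; networks are plain lists of
# layers. Convolution and pooling kernels live in src/conv_ops.cpp.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

# He-uniform initialisation, drawn from the current RNG stream.
he_init <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

layer_conv <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L) {
  l <- new_layer("conv", k = k, cin = cin, cout = cout,
                 stride = as.integer(stride), pad = as.integer(pad))
  l$params$w <- he_init(c(k, k, cin, cout), fan_in = k * k * cin)
  l$params$b <- numeric(cout)
  l
}

layer_dense <- function(nin, nout) {
  l <- new_layer("dense", nin = nin, nout = nout)
  l$params$w <- matrix(runif(nin * nout, -sqrt(6 / nin), sqrt(6 / nin)),
                       nin, nout)
  l$params$b <- numeric(nout)
  l
}

layer_relu <- function() new_layer("relu")
layer_lrelu <- function(alpha = 0.2) new_layer("lrelu", alpha = alpha)
layer_tanh <- function() new_layer("tanh")
layer_flatten <- function() new_layer("flatten")
layer_maxpool2 <- function() new_layer("maxpool2")
layer_upsample2 <- function() new_layer("upsample2")
layer_dropout <- function(p) new_layer("dropout", p = p)

layer_instnorm <- function(c, eps = 1e-5) {
  l <- new_layer("instnorm", c = c, eps = eps)
  l$params$gamma <- rep(1, c)
  l$params$beta <- rep(0, c)
  l
}

# Residual block: x + conv-IN-relu-conv-IN at constant width.
layer_resblock <- function(k, c) {
  new_layer("resblock", inner = list(
    layer_conv(k, c, c), layer_instnorm(c), layer_relu(),
    layer_conv(k, c, c), layer_instnorm(c)
  ))
}

layer_forward <- function(l, x, training = FALSE) {
  switch(l$type,
    conv = {
      l$cache_x <- x
      .conv2d_fwd(x, l$params$w, l$params$b, l$stride, l$pad)
    },
    dense = {
      l$cache_x <- x
      sweep(crossprod(l$params$w, x), 1, l$params$b, "+")
    },
    relu = {
      l$cache_mask <- x > 0
      x * l$cache_mask
    },
    lrelu = {
      l$cache_mask <- x > 0
      ifelse_keepdim(x, l$cache_mask, l$alpha)
    },
    tanh = {
      l$cache_y <- tanh(x)
      l$cache_y
    },
    flatten = {
      l$cache_dim <- dim(x)
      dim(x) <- c(prod(dim(x)[1:3]), dim(x)[4])
      x
    },
    maxpool2 = {
      r <- .maxpool2_fwd(x)
      l$cache_idx <- r$idx
      l$cache_hw <- dim(x)[1:2]
      r$y
    },
    upsample2 = {
      d <- dim(x)
      l$cache_dim <- d
      x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
        drop = FALSE]
    },
    dropout = {
      if (training && l$p > 0) {
        l$cache_mask <- array(
          (runif(length(x)) >= l$p) / (1 - l$p), dim = dim(x) %||% length(x)
        )
        x * l$cache_mask
      } else {
        l$cache_mask <- NULL
        x
      }
    },
    instnorm = {
      d <- dim(x)
      hw <- d[1] * d[2]
      xm <- x
      dim(xm) <- c(hw, d[3] * d[4])
      mu <- colMeans(xm)
      v <- colMeans(xm^2) - mu^2
      xhat <- (xm - rep(mu, each = hw)) / rep(sqrt(v + l$eps), each = hw)
      l$cache_xhat <- xhat
      l$cache_v <- v
      l$cache_dim <- d
      g <- rep(rep(l$params$gamma, d[4]), each = hw)
      b <- rep(rep(l$params$beta, d[4]), each = hw)
      y <- g * xhat + b
      dim(y) <- d
      y
    },
    resblock = {
      h <- x
      for (il in l$inner) h <- layer_forward(il, h, training)
      x + h
    },
    stop_pocusda("unknown layer type '%s'", l$type)
  )
}

ifelse_keepdim <- function(x, mask, alpha) {
  y <- x * alpha
  y[mask] <- x[mask]
  y
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      r <- .conv2d_bwd(l$cache_x, l$params$w, dy, l$stride, l$pad)
      l$grads$w <- r$dw
      l$grads$b <- r$db
      r$dx
    },
    dense = {
      l$grads$w <- tcrossprod(l$cache_x, dy)
      l$grads$b <- rowSums(dy)
      l$params$w %*% dy
    },
    relu = dy * l$cache_mask,
    lrelu = {
      dx <- dy * l$alpha
      dx[l$cache_mask] <- dy[l$cache_mask]
      dx
    },
    tanh = dy * (1 - l$cache_y^2),
    flatten = {
      dim(dy) <- l$cache_dim
      dy
    },
    maxpool2 = .maxpool2_bwd(l$cache_idx, dy, l$cache_hw[1], l$cache_hw[2]),
    upsample2 = {
      d2 <- dim(dy)
      m <- dy
      dim(m) <- c(2, d2[1] / 2 * d2[2] * d2[3] * d2[4])
      m <- colSums(m)                       # pool row pairs
      dim(m) <- c(d2[1] / 2, d2[2], d2[3], d2[4])
      m <- aperm(m, c(2, 1, 3, 4))
      dim(m) <- c(2, prod(dim(m)) / 2)
      m <- colSums(m)                       # pool column pairs
      dim(m) <- c(d2[2] / 2, d2[1] / 2, d2[3], d2[4])
      aperm(m, c(2, 1, 3, 4))
    },
    dropout = if (is.null(l$cache_mask)) dy else dy * l$cache_mask,
    instnorm = {
      d <- l$cache_dim
      hw <- d[1] * d[2]
      dim(dy) <- c(hw, d[3] * d[4])
      xhat <- l$cache_xhat
      g <- rep(rep(l$params$gamma, d[4]), each = hw)
      dgb <- colSums(dy * xhat)
      dbb <- colSums(dy)
      l$grads$gamma <- rowSums(matrix(dgb, d[3], d[4]))
      l$grads$beta <- rowSums(matrix(dbb, d[3], d[4]))
      dxhat <- dy * g
      istd <- rep(1 / sqrt(l$cache_v + l$eps), each = hw)
      dx <- istd * (dxhat -
        rep(colMeans(dxhat), each = hw) -
        xhat * rep(colMeans(dxhat * xhat), each = hw))
      dim(dx) <- d
      dx
    },
    resblock = {
      dh <- dy
      for (il in rev(l$inner)) dh <- layer_backward(il, dh)
      dy + dh
    },
    stop_pocusda("unknown layer type '%s'", l$type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

net_forward <- function(net, x, training = FALSE) {
  for (l in net) x <- layer_forward(l, x, training)
  x
}

net_backward <- function(net, dy) {
  for (l in rev(net)) dy <- layer_backward(l, dy)
  dy
}

# Flatten (layer, param-name) pairs, descending into residual blocks.
net_param_layers <- function(net) {
  out <- list()
  for (l in net) {
    if (l$type == "resblock") {
      out <- c(out, net_param_layers(l$inner))
    } else if (length(l$params)) {
      out <- c(out, list(l))
    }
  }
  out
}

net_param_count <- function(net) {
  sum(vapply(net_param_layers(net),
             function(l) sum(vapply(l$params, length, 0L)), 0))
}

adam_state <- function(net, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  layers <- net_param_layers(net)
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(layers, function(l) lapply(l$params, function(p) p * 0))
  st$v <- st$m
  st$layers <- layers
  st
}

adam_step <- function(state, lr = state$lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (i in seq_along(state$layers)) {
    l <- state$layers[[i]]
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      state$m[[i]][[nm]] <- b1 * state$m[[i]][[nm]] + (1 - b1) * g
      state$v[[i]][[nm]] <- b2 * state$v[[i]][[nm]] + (1 - b2) * g^2
      l$params[[nm]] <- l$params[[nm]] -
        lr * (state$m[[i]][[nm]] / bc1) /
          (sqrt(state$v[[i]][[nm]] / bc2) + state$eps)
    }
  }
  invisible(state)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Serialize / restore parameters (list-of-lists of plain arrays).
net_get_params <- function(net) {
  lapply(net_param_layers(net), function(l) l$params)
}

net_set_params <- function(net, params) {
  layers <- net_param_layers(net)
  stopifnot(length(layers) == length(params))
  for (i in seq_along(layers)) layers[[i]]$params <- params[[i]]
  invisible(net)
}

# Stack a list of HxW matrices into an (H, W, 1, N) tensor on the given scale.
stack_images <- function(images, scale = 1) {
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  x <- array(0, dim = c(h, w, 1, length(images)))
  for (i in seq_along(images)) x[, , 1, i] <- images[[i]] * scale
  x
}
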