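# Minimal convolutional-network engine used by the regression model.
# Feature maps are arrays [H, W, C, N]; convolutions are 3x3, stride 1,
# zero-padded ("same"), evaluated as im2col gathers followed by BLAS matmul.

.nn_cache <- new.env(parent = emptyenv())

# Linear indices that gather 3x3 patches from a padded [Hp,Wp,C,N] array
# into a (9C) x (H*W*N) matrix. Cached per shape.
conv_idx <- function(h, w, c, n) {
  key <- paste(h, w, c, n, sep = "x")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L; wp <- w + 2L
  # column positions: centre pixel (i, j) of image n
  i <- rep.int(seq_len(h), w * n)
  j <- rep.int(rep(seq_len(w), each = h), n)
  nn <- rep(seq_len(n), each = h * w)
  base <- matrix(0L, nrow = 9L * c, ncol = h * w * n)
  row <- 1L
  for (cc in seq_len(c)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        # padded patch for centre (i, j) spans rows i..i+2, cols j..j+2
        base[row, ] <- (i + di) + hp * (j + dj - 1L) +
          hp * wp * ((cc - 1L) + c * (nn - 1L))
        row <- row + 1L
      }
    }
  }
  .nn_cache[[key]] <- base
  base
}

pad_hw <- function(x) {
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  xp
}

# Forward 3x3 same-convolution. W is (9*Cin) x Cout, b length Cout.
conv_forward <- function(x, w, b) {
  d <- dim(x)
  idx <- conv_idx(d[1], d[2], d[3], d[4])
  # index with a plain vector: a matrix subscript whose column count equals
  # the array rank would be read as per-row coordinates
  k <- matrix(pad_hw(x)[as.vector(idx)], nrow = nrow(idx))
  y <- crossprod(w, k) + b            # Cout x (H*W*N)
  cout <- ncol(w)
  y <- array(y, dim = c(cout, d[1], d[2], d[4]))
  list(out = aperm(y, c(2, 3, 1, 4)), cols = k)
}

conv_backward <- function(dout, x, w, cols) {
  d <- dim(x)
  cout <- ncol(w)
  dy <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = cout)   # Cout x HWN
  db <- rowSums(dy)
  dw <- tcrossprod(dy, cols)                               # Cout x 9Cin
  dk <- w %*% dy                                           # 9Cin x HWN
  idx <- conv_idx(d[1], d[2], d[3], d[4])
  dxp <- numeric((d[1] + 2L) * (d[2] + 2L) * d[3] * d[4])
  for (r in seq_len(nrow(idx))) {
    ii <- idx[r, ]
    dxp[ii] <- dxp[ii] + dk[r, ]
  }
  dxp <- array(dxp, dim = c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  dx <- dxp[2:(d[1] + 1L), 2:(d[2] + 1L), , , drop = FALSE]
  list(dx = dx, dw = t(dw), db = db)
}

relu_forward <- function(x) pmax(x, 0)

relu_backward <- function(dout, out) dout * (out > 0)

# 2x2 max pooling, stride 2.
pool_forward <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  a <- x[io, jo, , , drop = FALSE]
  b <- x[io, jo + 1L, , , drop = FALSE]
  cc <- x[io + 1L, jo, , , drop = FALSE]
  dd <- x[io + 1L, jo + 1L, , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  dim(out) <- dim(a)
  list(out = out, parts = list(a, b, cc, dd))
}

pool_backward <- function(dout, out, parts, in_dim) {
  io <- seq(1L, in_dim[1], by = 2L); jo <- seq(1L, in_dim[2], by = 2L)
  dx <- array(0, dim = in_dim)
  taken <- array(FALSE, dim = dim(out))
  sel <- list(
    list(io, jo), list(io, jo + 1L), list(io + 1L, jo), list(io + 1L, jo + 1L)
  )
  for (k in 1:4) {
    m <- (parts[[k]] == out) & !taken
    taken <- taken | m
    g <- dout * m
    dx[sel[[k]][[1]], sel[[k]][[2]], , ] <- g
  }
  dx
}

fc_forward <- function(x, w, b) {
  # x: [F, N]; w: F x K; b length K
  crossprod(w, x) + b
}

he_init <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))

new_conv_layer <- function(cin, cout) {
  list(type = "conv",
       w = matrix(he_init(9 * cin, 9 * cin * cout), 9 * cin, cout),
       b = numeric(cout))
}

new_res_block <- function(c) {
  list(type = "resblock",
       conv1 = new_conv_layer(c, c),
       conv2 = new_conv_layer(c, c))
}

new_fc_layer <- function(fin, fout) {
  list(type = "fc",
       w = matrix(stats::rnorm(fin * fout, sd = sqrt(1 / fin)), fin, fout),
       b = numeric(fout))
}

# Forward pass through the layer list. Returns the K x N output matrix and,
# when keep_cache, the per-layer caches needed for backprop.
net_forward <- function(layers, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(layers))
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    cache <- list(x = x)
    if (l$type == "conv") {
      cf <- conv_forward(x, l$w, l$b)
      pre <- cf$out
      x <- relu_forward(pre)
      cache$cols <- cf$cols
      cache$out <- x
    } else if (l$type == "pool") {
      cache$in_dim <- dim(x)
      pf <- pool_forward(x)
      x <- pf$out
      cache$parts <- pf$parts
      cache$out <- x
    } else if (l$type == "resblock") {
      cf1 <- conv_forward(x, l$conv1$w, l$conv1$b)
      a1 <- relu_forward(cf1$out)
      cf2 <- conv_forward(a1, l$conv2$w, l$conv2$b)
      pre <- cf2$out + x
      out <- relu_forward(pre)
      cache$cols1 <- cf1$cols; cache$a1 <- a1
      cache$cols2 <- cf2$cols; cache$out <- out
      x <- out
    } else if (l$type == "flatten") {
      cache$in_dim <- dim(x)
      x <- matrix(x, ncol = dim(x)[4])
    } else if (l$type == "fc") {
      x <- fc_forward(x, l$w, l$b)
      cache$out <- x
    }
    if (keep_cache) caches[[li]] <- cache
  }
  list(out = x, caches = caches)
}

# Backward pass; dout is the gradient at the network output (K x N).
# Returns per-layer parameter gradients, matching the layers structure.
net_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    cache <- caches[[li]]
    if (l$type == "fc") {
      x <- cache$x
      grads[[li]] <- list(dw = x %*% t(dout), db = rowSums(dout))
      dout <- l$w %*% dout
    } else if (l$type == "flatten") {
      dout <- array(dout, dim = cache$in_dim)
    } else if (l$type == "conv") {
      dout <- relu_backward(dout, cache$out)
      cb <- conv_backward(dout, cache$x, l$w, cache$cols)
      grads[[li]] <- list(dw = cb$dw, db = cb$db)
      dout <- cb$dx
    } else if (l$type == "pool") {
      dout <- pool_backward(dout, cache$out, cache$parts, cache$in_dim)
    } else if (l$type == "resblock") {
      dpre <- relu_backward(dout, cache$out)
      cb2 <- conv_backward(dpre, cache$a1, l$conv2$w, cache$cols2)
      da1 <- relu_backward(cb2$dx, cache$a1)
      cb1 <- conv_backward(da1, cache$x, l$conv1$w, cache$cols1)
      grads[[li]] <- list(conv1 = list(dw = cb1$dw, db = cb1$db),
                          conv2 = list(dw = cb2$dw, db = cb2$db))
      dout <- cb1$dx + dpre
    }
  }
  grads
}

# Flatten trainable parameters to a named list of arrays (for the optimizer).
net_params <- function(layers) {
  out <- list()
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$type %in% c("conv", "fc")) {
      out[[paste0("l", li, ".w")]] <- l$w
      out[[paste0("l", li, ".b")]] <- l$b
    } else if (l$type == "resblock") {
      out[[paste0("l", li, ".c1.w")]] <- l$conv1$w
      out[[paste0("l", li, ".c1.b")]] <- l$conv1$b
      out[[paste0("l", li, ".c2.w")]] <- l$conv2$w
      out[[paste0("l", li, ".c2.b")]] <- l$conv2$b
    }
  }
  out
}

net_grads_flat <- function(layers, grads) {
  out <- list()
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    g <- grads[[li]]
    if (l$type %in% c("conv", "fc")) {
      out[[paste0("l", li, ".w")]] <- g$dw
      out[[paste0("l", li, ".b")]] <- g$db
    } else if (l$type == "resblock") {
      out[[paste0("l", li, ".c1.w")]] <- g$conv1$dw
      out[[paste0("l", li, ".c1.b")]] <- g$conv1$db
      out[[paste0("l", li, ".c2.w")]] <- g$conv2$dw
      out[[paste0("l", li, ".c2.b")]] <- g$conv2$db
    }
  }
  out
}

net_set_params <- function(layers, params) {
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$type %in% c("conv", "fc")) {
      layers[[li]]$w <- params[[paste0("l", li, ".w")]]
      layers[[li]]$b <- params[[paste0("l", li, ".b")]]
    } else if (l$type == "resblock") {
      layers[[li]]$conv1$w <- params[[paste0("l", li, ".c1.w")]]
      layers[[li]]$conv1$b <- params[[paste0("l", li, ".c1.b")]]
      layers[[li]]$conv2$w <- params[[paste0("l", li, ".c2.w")]]
      layers[[li]]$conv2$b <- params[[paste0("l", li, ".c2.b")]]
    }
  }
  layers
}
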