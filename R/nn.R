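# Minimal CNN engine used by the U-net zoo.
#
# Feature maps are stored as matrices [H*W, C] with pixels in column-major
# grid order, so every layer reduces to BLAS matrix products plus
# precomputed index gathers/scatters:
#   - 3x3 same-padding convolution via im2col (9 indexed copies), weights
#     [9*Cin, Cout]
#   - 1x1 convolution as a plain matrix product
#   - 2x2/stride-2 max pooling with 4 precomputed index vectors
#   - 2x2/stride-2 transposed convolution (each output pixel receives
#     exactly one contribution), weights [Cin, 4*Cout]
# All gather/scatter index tables are built once per architecture at build
# time, so forward/backward passes contain no per-pixel R loops.

# linear indices (column-major, H x W grid) -------------------------------

# im2col index table for k=3, pad=1: IDX[p, j] = row in the padded
# (H+2)x(W+2) feature matrix feeding offset j of output pixel p
conv3_indices <- function(H, W) {
  Hp <- H + 2L
  r <- rep(seq_len(H), times = W)       # 1-based grid coords of pixel p
  c <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  j <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    j <- j + 1L
    idx[, j] <- (c + dc) * Hp + (r + dr) + 1L   # padded coords (r+dr+1, c+dc+1)
  }
  inner <- c * Hp + r + 1L       # padded position of (r+1, c+1)
  list(idx = idx, inner = inner, n_pad = Hp * (W + 2L))
}

pool_indices <- function(H, W) {
  h <- H %/% 2L; w <- W %/% 2L
  r <- rep(seq_len(h), times = w)
  c <- rep(seq_len(w), each = h)
  at <- function(rr, cc) (cc - 1L) * H + rr
  list(i1 = at(2L * r - 1L, 2L * c - 1L),
       i2 = at(2L * r,      2L * c - 1L),
       i3 = at(2L * r - 1L, 2L * c),
       i4 = at(2L * r,      2L * c),
       h = h, w = w)
}

tconv_indices <- function(h, w) {
  H <- 2L * h; W <- 2L * w
  r <- rep(seq_len(h), times = w)
  c <- rep(seq_len(w), each = h)
  at <- function(rr, cc) (cc - 1L) * H + rr
  list(o1 = at(2L * r - 1L, 2L * c - 1L),
       o2 = at(2L * r,      2L * c - 1L),
       o3 = at(2L * r - 1L, 2L * c),
       o4 = at(2L * r,      2L * c),
       H = H, W = W)
}

# layer constructors ------------------------------------------------------

nn_conv3 <- function(H, W, c_in, c_out, relu = TRUE) {
  g <- conv3_indices(H, W)
  list(type = "conv3", H = H, W = W, c_in = c_in, c_out = c_out, relu = relu,
       idx = g$idx, inner = g$inner, n_pad = g$n_pad,
       W_ = matrix(stats::rnorm(9 * c_in * c_out, 0, sqrt(2 / (9 * c_in))),
                   9 * c_in, c_out),
       b_ = rep(0, c_out))
}

nn_conv1 <- function(H, W, c_in, c_out, relu = FALSE) {
  list(type = "conv1", H = H, W = W, c_in = c_in, c_out = c_out, relu = relu,
       W_ = matrix(stats::rnorm(c_in * c_out, 0, sqrt(2 / c_in)), c_in, c_out),
       b_ = rep(0, c_out))
}

nn_pool <- function(H, W, c) {
  g <- pool_indices(H, W)
  c(list(type = "pool", H = H, W = W, c_in = c, c_out = c), g)
}

nn_tconv <- function(h, w, c_in, c_out) {
  g <- tconv_indices(h, w)
  c(list(type = "tconv", h = h, w = w, c_in = c_in, c_out = c_out,
         W_ = matrix(stats::rnorm(c_in * 4 * c_out, 0, sqrt(2 / c_in)),
                     c_in, 4 * c_out),
         b_ = rep(0, c_out)),
    g)
}

# concat pulls the stored encoder skip output in front of the current map
nn_concat <- function(skip_id, c_skip, c_in) {
  list(type = "concat", skip_id = skip_id, c_skip = c_skip, c_in = c_in,
       c_out = c_skip + c_in)
}

# forward / backward ------------------------------------------------------

layer_forward <- function(layer, x, skips, training) {
  cache <- NULL
  if (layer$type == "conv3") {
    Xp <- matrix(0, layer$n_pad, layer$c_in)
    Xp[layer$inner, ] <- x
    P <- matrix(0, nrow(x), 9L * layer$c_in)
    for (j in 1:9) {
      P[, ((j - 1L) * layer$c_in + 1L):(j * layer$c_in)] <- Xp[layer$idx[, j], , drop = FALSE]
    }
    out <- P %*% layer$W_
    out <- sweep(out, 2, layer$b_, `+`)
    if (layer$relu) out[out < 0] <- 0
    if (training) cache <- list(P = P, out = out)
  } else if (layer$type == "conv1") {
    out <- x %*% layer$W_
    out <- sweep(out, 2, layer$b_, `+`)
    if (layer$relu) out[out < 0] <- 0
    if (training) cache <- list(P = x, out = out)
  } else if (layer$type == "pool") {
    A <- x[layer$i1, , drop = FALSE]; B <- x[layer$i2, , drop = FALSE]
    C <- x[layer$i3, , drop = FALSE]; D <- x[layer$i4, , drop = FALSE]
    out <- pmax(A, B, C, D)
    if (training) {
      m1 <- A == out
      m2 <- (B == out) & !m1
      m3 <- (C == out) & !(m1 | m2)
      m4 <- (D == out) & !(m1 | m2 | m3)
      cache <- list(m = list(m1, m2, m3, m4), n_in = nrow(x))
    }
  } else if (layer$type == "tconv") {
    Y4 <- x %*% layer$W_
    out <- matrix(0, layer$H * layer$W, layer$c_out)
    os <- list(layer$o1, layer$o2, layer$o3, layer$o4)
    for (j in 1:4) {
      out[os[[j]], ] <- Y4[, ((j - 1L) * layer$c_out + 1L):(j * layer$c_out), drop = FALSE]
    }
    out <- sweep(out, 2, layer$b_, `+`)
    if (training) cache <- list(X = x)
  } else if (layer$type == "concat") {
    out <- cbind(skips[[layer$skip_id]], x)
  } else stop("unknown layer type: ", layer$type)
  list(out = out, cache = cache)
}

layer_backward <- function(layer, dout, cache) {
  # returns list(dx, dskip = NULL or gradient for the skip source, dW, db)
  if (layer$type == "conv3") {
    if (layer$relu) dout <- dout * (cache$out > 0)
    dW <- crossprod(cache$P, dout)
    db <- colSums(dout)
    dP <- tcrossprod(dout, layer$W_)
    dXp <- matrix(0, layer$n_pad, layer$c_in)
    for (j in 1:9) {
      rows <- layer$idx[, j]
      dXp[rows, ] <- dXp[rows, , drop = FALSE] +
        dP[, ((j - 1L) * layer$c_in + 1L):(j * layer$c_in), drop = FALSE]
    }
    list(dx = dXp[layer$inner, , drop = FALSE], dW = dW, db = db)
  } else if (layer$type == "conv1") {
    if (layer$relu) dout <- dout * (cache$out > 0)
    list(dx = tcrossprod(dout, layer$W_),
         dW = crossprod(cache$P, dout), db = colSums(dout))
  } else if (layer$type == "pool") {
    dx <- matrix(0, cache$n_in, layer$c_in)
    idx <- list(layer$i1, layer$i2, layer$i3, layer$i4)
    for (j in 1:4) {
      dx[idx[[j]], ] <- dout * cache$m[[j]]
    }
    list(dx = dx)
  } else if (layer$type == "tconv") {
    db <- colSums(dout)
    dY4 <- matrix(0, nrow(cache$X), 4L * layer$c_out)
    os <- list(layer$o1, layer$o2, layer$o3, layer$o4)
    for (j in 1:4) {
      dY4[, ((j - 1L) * layer$c_out + 1L):(j * layer$c_out)] <- dout[os[[j]], , drop = FALSE]
    }
    list(dx = tcrossprod(dY4, layer$W_), dW = crossprod(cache$X, dY4), db = db)
  } else if (layer$type == "concat") {
    list(dx = dout[, (layer$c_skip + 1L):(layer$c_skip + layer$c_in), drop = FALSE],
         dskip = dout[, seq_len(layer$c_skip), drop = FALSE])
  } else stop("unknown layer type: ", layer$type)
}

# full network pass; layers carry skip_tag (store output) / skip_id (read)
net_forward <- function(model, x, training = FALSE) {
  skips <- list()
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    res <- layer_forward(layer, x, skips, training)
    x <- res$out
    caches[[i]] <- res$cache
    tag <- layer$skip_tag
    if (!is.null(tag)) skips[[tag]] <- x
  }
  list(logits = x, caches = caches)
}

net_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  dskips <- list()   # gradients waiting to be added at the tagged layer
  dout <- dlogits
  for (i in rev(seq_along(model$layers))) {
    layer <- model$layers[[i]]
    tag <- layer$skip_tag
    if (!is.null(tag) && !is.null(dskips[[tag]])) {
      dout <- dout + dskips[[tag]]
    }
    g <- layer_backward(layer, dout, caches[[i]])
    if (!is.null(g$dskip)) {
      id <- layer$skip_id
      dskips[[id]] <- if (is.null(dskips[[id]])) g$dskip else dskips[[id]] + g$dskip
    }
    grads[[i]] <- g[intersect(names(g), c("dW", "db"))]
    dout <- g$dx
  }
  grads
}

# softmax cross-entropy over 2 classes; labels y in {0,1} per pixel
softmax_ce <- function(logits, y) {
  m <- pmax(logits[, 1], logits[, 2])
  lse <- m + log(exp(logits[, 1] - m) + exp(logits[, 2] - m))
  zy <- ifelse(y == 1L, logits[, 2], logits[, 1])
  loss <- mean(lse - zy)
  p2 <- exp(logits[, 2] - lse)
  dz <- cbind((1 - p2) - (y == 0L), p2 - (y == 1L)) / length(y)
  list(loss = loss, dlogits = dz)
}

softmax_fg <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  lse <- m + log(exp(logits[, 1] - m) + exp(logits[, 2] - m))
  exp(logits[, 2] - lse)
}

# Adam ---------------------------------------------------------------------

adam_init <- function(model) {
  st <- lapply(model$layers, function(l) {
    if (is.null(l$W_)) return(NULL)
    list(mW = l$W_ * 0, vW = l$W_ * 0, mb = l$b_ * 0, vb = l$b_ * 0)
  })
  list(t = 0L, layers = st)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(g$dW)) next
    s <- state$layers[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    model$layers[[i]]$W_ <- model$layers[[i]]$W_ -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    model$layers[[i]]$b_ <- model$layers[[i]]$b_ -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state$layers[[i]] <- s
  }
  list(model = model, state = state)
}

add_grads <- function(acc, grads) {
  if (is.null(acc)) return(grads)
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]]) || is.null(grads[[i]]$dW)) next
    acc[[i]]$dW <- acc[[i]]$dW + grads[[i]]$dW
    acc[[i]]$db <- acc[[i]]$db + grads[[i]]$db
  }
  acc
}

scale_grads <- function(grads, f) {
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]]) || is.null(grads[[i]]$dW)) next
    grads[[i]]$dW <- grads[[i]]$dW * f
    grads[[i]]$db <- grads[[i]]$db * f
  }
  grads
}

# per-image standardization of a T1 map before the network sees it
normalize_map <- function(map) {
  x <- as.vector(unclass(map))
  s <- stats::sd(x)
  if (s == 0) s <- 1
  matrix((x - mean(x)) / s, ncol = 1)
}
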