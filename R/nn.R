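# Minimal dense-tensor CNN machinery: im2col convolution on BLAS matrix
# products, 2x2 max pooling, ReLU, global average pooling, softmax
# cross-entropy and Adam. Tensors are arrays of dim (H, W, C, N). Everything
# is plain deterministic R, so identical seeds give identical runs.

# Geometry (output size + gather indices) of a convolution over a fixed
# input shape. idx is a (P x k^2*C) matrix of linear indices into the padded
# single-sample array, rows ordered ho-fastest, columns ordered
# (kh, kw, c) to match the weight layout.
make_conv_geom <- function(H, W, C, k, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Hout <- (Hp - k) %/% stride + 1L
  Wout <- (Wp - k) %/% stride + 1L
  if (Hout < 1L || Wout < 1L) {
    stop("feature map vanished: input ", H, "x", W, " too small for kernel ",
         k, " stride ", stride, call. = FALSE)
  }
  P <- Hout * Wout
  hs <- rep(seq_len(Hout) - 1L, times = Wout) * stride   # 0-based starts
  ws <- rep(seq_len(Wout) - 1L, each = Hout) * stride
  kh <- rep(seq_len(k), times = k * C)
  kw <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  idx <- outer(hs, kh, `+`) + Hp * outer(ws, kw - 1L, `+`) +
    rep((cc - 1L) * Hp * Wp, each = P)
  list(H = H, W = W, C = C, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Hout = Hout, Wout = Wout, P = P,
       idx = idx, sample_len = Hp * Wp * C)
}

pad_input <- function(X, geom) {
  if (geom$pad == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, dim = c(geom$Hp, geom$Wp, d[3], d[4]))
  Xp[geom$pad + seq_len(d[1]), geom$pad + seq_len(d[2]), , ] <- X
  Xp
}

new_conv_layer <- function(geom, Cout, relu = TRUE) {
  fan_in <- geom$k^2 * geom$C
  W <- matrix(stats::rnorm(fan_in * Cout, 0, sqrt(2 / fan_in)),
              nrow = fan_in, ncol = Cout)
  list(type = "conv", geom = geom, Cout = Cout, relu = relu,
       W = W, b = numeric(Cout))
}

conv_forward <- function(layer, X) {
  g <- layer$geom
  N <- dim(X)[4]
  Xp <- pad_input(X, g)
  Xflat <- as.vector(Xp)
  Xcol <- matrix(0, nrow = N * g$P, ncol = ncol(g$idx))
  for (n in seq_len(N)) {
    block <- (n - 1L) * g$P + seq_len(g$P)
    Xcol[block, ] <- Xflat[g$idx + (n - 1L) * g$sample_len]
  }
  Ymat <- Xcol %*% layer$W
  Ymat <- sweep(Ymat, 2L, layer$b, `+`)
  mask <- NULL
  if (layer$relu) {
    mask <- Ymat > 0
    Ymat <- Ymat * mask
  }
  Y <- array(0, dim = c(g$Hout, g$Wout, layer$Cout, N))
  for (n in seq_len(N)) {
    block <- (n - 1L) * g$P + seq_len(g$P)
    Y[, , , n] <- Ymat[block, ]
  }
  list(Y = Y, cache = list(Xcol = Xcol, mask = mask, N = N))
}

conv_backward <- function(layer, cache, dY) {
  g <- layer$geom
  N <- cache$N
  dYmat <- matrix(0, nrow = N * g$P, ncol = layer$Cout)
  for (n in seq_len(N)) {
    block <- (n - 1L) * g$P + seq_len(g$P)
    dYmat[block, ] <- matrix(dY[, , , n], nrow = g$P)
  }
  if (layer$relu) dYmat <- dYmat * cache$mask
  dW <- crossprod(cache$Xcol, dYmat)
  db <- colSums(dYmat)
  dXcol <- tcrossprod(dYmat, layer$W)
  dXp_flat <- numeric(g$sample_len * N)
  offs <- (seq_len(N) - 1L) * g$sample_len
  for (j in seq_len(ncol(g$idx))) {
    tgt <- as.vector(outer(g$idx[, j], offs, `+`))
    dXp_flat[tgt] <- dXp_flat[tgt] + dXcol[, j]
  }
  dXp <- array(dXp_flat, dim = c(g$Hp, g$Wp, g$C, N))
  dX <- if (g$pad > 0L) {
    dXp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , , drop = FALSE]
  } else dXp
  list(dX = dX, dW = dW, db = db)
}

new_pool_layer <- function(H, W) {
  if (H %% 2L != 0L || W %% 2L != 0L) {
    stop("2x2 max pooling needs even feature-map sides, got ", H, "x", W,
         call. = FALSE)
  }
  list(type = "pool", H = H, W = W)
}

pool_forward <- function(layer, X) {
  i1 <- seq(1L, layer$H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, layer$W, 2L); j2 <- j1 + 1L
  A <- list(X[i1, j1, , , drop = FALSE], X[i1, j2, , , drop = FALSE],
            X[i2, j1, , , drop = FALSE], X[i2, j2, , , drop = FALSE])
  Y <- pmax(A[[1]], A[[2]], A[[3]], A[[4]])
  m <- vector("list", 4L)
  taken <- array(FALSE, dim = dim(Y))
  for (q in 1:4) {               # ties route to the first maximal cell
    m[[q]] <- (A[[q]] == Y) & !taken
    taken <- taken | m[[q]]
  }
  list(Y = Y, cache = list(masks = m))
}

pool_backward <- function(layer, cache, dY) {
  i1 <- seq(1L, layer$H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, layer$W, 2L); j2 <- j1 + 1L
  d <- dim(dY)
  dX <- array(0, dim = c(layer$H, layer$W, d[3], d[4]))
  dX[i1, j1, , ] <- dY * cache$masks[[1]]
  dX[i1, j2, , ] <- dY * cache$masks[[2]]
  dX[i2, j1, , ] <- dY * cache$masks[[3]]
  dX[i2, j2, , ] <- dY * cache$masks[[4]]
  dX
}

new_fire_layer <- function(H, W, Cin, squeeze, expand1, expand3) {
  if (squeeze >= expand1 + expand3) {
    stop("fire module invariant violated: squeeze channels (", squeeze,
         ") must be < expand channels (", expand1, " + ", expand3, ")",
         call. = FALSE)
  }
  list(type = "fire",
       squeeze = new_conv_layer(make_conv_geom(H, W, Cin, 1L, 1L, 0L),
                                squeeze, relu = TRUE),
       e1 = new_conv_layer(make_conv_geom(H, W, squeeze, 1L, 1L, 0L),
                           expand1, relu = FALSE),
       e3 = new_conv_layer(make_conv_geom(H, W, squeeze, 3L, 1L, 1L),
                           expand3, relu = FALSE),
       Cout = expand1 + expand3)
}

fire_forward <- function(layer, X) {
  s <- conv_forward(layer$squeeze, X)
  a <- conv_forward(layer$e1, s$Y)
  b <- conv_forward(layer$e3, s$Y)
  d <- dim(a$Y)
  Y <- array(0, dim = c(d[1], d[2], layer$Cout, d[4]))
  c1 <- layer$e1$Cout
  Y[, , seq_len(c1), ] <- a$Y
  Y[, , c1 + seq_len(layer$e3$Cout), ] <- b$Y
  mask <- Y > 0
  list(Y = Y * mask,
       cache = list(s = s$cache, a = a$cache, b = b$cache, mask = mask))
}

fire_backward <- function(layer, cache, dY) {
  dY <- dY * cache$mask
  c1 <- layer$e1$Cout
  ga <- conv_backward(layer$e1, cache$a, dY[, , seq_len(c1), , drop = FALSE])
  gb <- conv_backward(layer$e3, cache$b,
                      dY[, , c1 + seq_len(layer$e3$Cout), , drop = FALSE])
  gs <- conv_backward(layer$squeeze, cache$s, ga$dX + gb$dX)
  list(dX = gs$dX,
       grads = list(squeeze = list(dW = gs$dW, db = gs$db),
                    e1 = list(dW = ga$dW, db = ga$db),
                    e3 = list(dW = gb$dW, db = gb$db)))
}

layer_forward <- function(layer, X) {
  switch(layer$type,
         conv = conv_forward(layer, X),
         pool = pool_forward(layer, X),
         fire = fire_forward(layer, X))
}

layer_backward <- function(layer, cache, dY) {
  switch(layer$type,
         conv = { g <- conv_backward(layer, cache, dY)
                  list(dX = g$dX, grads = list(dW = g$dW, db = g$db)) },
         pool = list(dX = pool_backward(layer, cache, dY), grads = NULL),
         fire = fire_backward(layer, cache, dY))
}

# forward through all layers to logits (K x N): trunk -> global average pool
net_forward <- function(model, X, keep_caches = FALSE) {
  caches <- if (keep_caches) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    out <- layer_forward(model$layers[[i]], X)
    X <- out$Y
    if (keep_caches) caches[[i]] <- out$cache
  }
  d <- dim(X)
  dim(X) <- c(d[1] * d[2], d[3] * d[4])
  Z <- matrix(colMeans(X), nrow = d[3], ncol = d[4])  # K x N
  list(logits = Z, caches = caches, map_dim = d)
}

net_backward <- function(model, fwd, dZ) {
  d <- fwd$map_dim
  dX <- array(rep(as.vector(dZ), each = d[1] * d[2]) / (d[1] * d[2]),
              dim = d)
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    g <- layer_backward(model$layers[[i]], fwd$caches[[i]], dX)
    dX <- g$dX
    grads[i] <- list(g$grads)  # keeps NULL (pool) slots in place
  }
  grads
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2L, apply(Z, 2L, max), `-`)
  E <- exp(Z)
  sweep(E, 2L, colSums(E), `/`)
}

# ---- Adam ------------------------------------------------------------------

adam_init_like <- function(layer) {
  zero <- function(cl) list(mW = 0 * cl$W, vW = 0 * cl$W,
                            mb = 0 * cl$b, vb = 0 * cl$b)
  switch(layer$type,
         conv = zero(layer),
         fire = list(squeeze = zero(layer$squeeze), e1 = zero(layer$e1),
                     e3 = zero(layer$e3)),
         NULL)
}

adam_step_conv <- function(cl, g, st, lr, t, b1 = 0.9, b2 = 0.999,
                           eps = 1e-8) {
  corr <- sqrt(1 - b2^t) / (1 - b1^t)
  st$mW <- b1 * st$mW + (1 - b1) * g$dW
  st$vW <- b2 * st$vW + (1 - b2) * g$dW^2
  cl$W <- cl$W - lr * corr * st$mW / (sqrt(st$vW) + eps)
  st$mb <- b1 * st$mb + (1 - b1) * g$db
  st$vb <- b2 * st$vb + (1 - b2) * g$db^2
  cl$b <- cl$b - lr * corr * st$mb / (sqrt(st$vb) + eps)
  list(layer = cl, state = st)
}

adam_step_layer <- function(layer, grads, state, lr, t) {
  if (is.null(grads)) return(list(layer = layer, state = state))
  if (layer$type == "conv") {
    r <- adam_step_conv(layer, grads, state, lr, t)
    return(list(layer = r$layer, state = r$state))
  }
  for (part in c("squeeze", "e1", "e3")) {
    r <- adam_step_conv(layer[[part]], grads[[part]], state[[part]], lr, t)
    layer[[part]] <- r$layer
    state[[part]] <- r$state
  }
  list(layer = layer, state = state)
}
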