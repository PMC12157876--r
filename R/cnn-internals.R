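# Minimal CNN engine. Feature maps are arrays (h, w, batch, channels);
# convolutions are 3x3, stride 1, zero-padded ("same"), realized as im2col
# patch extraction (compiled, see src/conv_ops.cpp) plus one BLAS GEMM per
# layer; pooling is 2x2 max with stride 2. With the (h, w, batch, channel)
# ordering the GEMM output reshapes straight into the next layer's input,
# so no transposes occur between layers. Activations, losses and the Adam
# optimizer are plain vectorized R.

# X: (h, w, n, cin); W: (9*cin, f); returns list(out = (h, w, n, f), cache)
conv_forward <- function(X, W, b, relu = TRUE, keep_cache = TRUE) {
  d <- dim(X)
  h <- d[1]; w <- d[2]; n <- d[3]; cin <- d[4]
  P <- im2col3(X, h, w, n, cin)
  Y <- P %*% W
  Y <- Y + rep(b, each = nrow(Y))
  mask <- NULL
  if (relu) {
    mask <- Y > 0
    Y <- Y * mask
  }
  dim(Y) <- c(h, w, n, ncol(W))
  list(out = Y,
       cache = if (keep_cache) list(P = P, mask = mask, h = h, w = w,
                                    n = n, cin = cin) else NULL)
}

# dA: (h, w, n, f) gradient wrt conv output; returns dX, dW, db
conv_backward <- function(dA, W, cache) {
  dim(dA) <- c(cache$h * cache$w * cache$n, ncol(W))
  if (!is.null(cache$mask)) dA <- dA * cache$mask
  dW <- crossprod(cache$P, dA)
  db <- colSums(dA)
  dP <- tcrossprod(dA, W) # (p*n, 9*cin)
  list(dX = col2im3(dP, cache$h, cache$w, cache$n, cache$cin),
       dW = dW, db = db)
}

maxpool_forward <- function(X) {
  d <- dim(X)
  r <- maxpool2_fwd(X, d[1], d[2], d[3] * d[4])
  out <- r$out
  dim(out) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  list(out = out, cache = list(argmax = r$argmax, dim = d))
}

maxpool_backward <- function(dM, cache) {
  d <- cache$dim
  dX <- maxpool2_bwd(dM, cache$argmax, d[1], d[2], d[3] * d[4])
  dim(dX) <- d
  dX
}

# A: (n, d); plain affine layer with optional ReLU and inverted dropout
dense_forward <- function(A, W, b, relu = FALSE, dropout = 0, train = FALSE) {
  Z <- A %*% W
  Z <- Z + rep(b, each = nrow(Z))
  mask <- NULL
  dmask <- NULL
  if (relu) {
    mask <- Z > 0
    Z <- Z * mask
  }
  if (train && dropout > 0) {
    dmask <- matrix(stats::runif(length(Z)) >= dropout, nrow(Z), ncol(Z))
    Z <- Z * dmask / (1 - dropout)
  }
  list(out = Z, cache = list(A = A, mask = mask, dmask = dmask,
                             dropout = dropout))
}

dense_backward <- function(dZ, W, cache) {
  if (!is.null(cache$dmask)) dZ <- dZ * cache$dmask / (1 - cache$dropout)
  if (!is.null(cache$mask)) dZ <- dZ * cache$mask
  list(dA = tcrossprod(dZ, W), dW = crossprod(cache$A, dZ), db = colSums(dZ))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

adam_init <- function(pars) {
  lapply(pars, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(pars, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (k in seq_along(pars)) {
    g <- grads[[k]]
    state[[k]]$m <- beta1 * state[[k]]$m + (1 - beta1) * g
    state[[k]]$v <- beta2 * state[[k]]$v + (1 - beta2) * g * g
    mhat <- state[[k]]$m / (1 - beta1^t)
    vhat <- state[[k]]$v / (1 - beta2^t)
    pars[[k]] <- pars[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(pars = pars, state = state)
}

# Full network forward. X: (side, side, n, 3). Returns output plus caches
# when train = TRUE.
cnn_forward <- function(pars, geom, X, train = FALSE, dropout = 0.5) {
  caches <- vector("list", length(geom$conv) * 2L + 2L)
  ci <- 0L
  A <- X
  for (l in seq_along(geom$conv)) {
    cf <- conv_forward(A, pars[[paste0("Wc", l)]], pars[[paste0("bc", l)]],
                       relu = TRUE, keep_cache = train)
    ci <- ci + 1L; caches[[ci]] <- cf$cache
    mp <- maxpool_forward(cf$out)
    ci <- ci + 1L; caches[[ci]] <- if (train) mp$cache else NULL
    A <- mp$out
  }
  d <- dim(A) # (s, s, n, f)
  n <- d[3]
  Fl <- aperm(A, c(1, 2, 4, 3)) # (s, s, f, n); cheap: the smallest map
  dim(Fl) <- c(d[1] * d[2] * d[4], n)
  Fl <- t(Fl)
  fc <- dense_forward(Fl, pars$Wf, pars$bf, relu = TRUE,
                      dropout = dropout, train = train)
  ci <- ci + 1L; caches[[ci]] <- if (train) fc$cache else NULL
  out <- dense_forward(fc$out, pars$Wo, pars$bo, relu = FALSE)
  ci <- ci + 1L; caches[[ci]] <- if (train) out$cache else NULL
  list(out = out$out, caches = caches, feat_dim = d)
}

# Backward pass from dOut (gradient wrt the linear output), mirroring
# cnn_forward. Returns gradients named like pars.
cnn_backward <- function(pars, geom, dOut, caches, feat_dim) {
  nconv <- length(geom$conv)
  grads <- vector("list", length(pars))
  names(grads) <- names(pars)
  ci <- nconv * 2L + 2L
  bo <- dense_backward(dOut, pars$Wo, caches[[ci]])
  grads$Wo <- bo$dW; grads$bo <- bo$db
  ci <- ci - 1L
  bf <- dense_backward(bo$dA, pars$Wf, caches[[ci]])
  grads$Wf <- bf$dW; grads$bf <- bf$db
  dFl <- t(bf$dA)
  dim(dFl) <- feat_dim[c(1, 2, 4, 3)]
  dA <- aperm(dFl, c(1, 2, 4, 3)) # back to (s, s, n, f)
  for (l in rev(seq_along(geom$conv))) {
    ci <- ci - 1L
    dA <- maxpool_backward(dA, caches[[ci]])
    ci <- ci - 1L
    cb <- conv_backward(dA, pars[[paste0("Wc", l)]], caches[[ci]])
    grads[[paste0("Wc", l)]] <- cb$dW
    grads[[paste0("bc", l)]] <- cb$db
    dA <- cb$dX
  }
  grads
}
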