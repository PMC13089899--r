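# Minimal CNN engine: 3x3 same-padding convolutions, ReLU, 2x2 average
# pooling, channel-wise (spatial) dropout, global average pooling and dense
# heads, with hand-written backpropagation and an Adam optimizer.
#
# Batches are stored as matrices with one row per (pixel, image) pair —
# column-major pixels within an image, images stacked — and one column per
# channel. A 3x3 convolution then becomes nine shifted GEMMs, which keeps
# everything inside vectorized BLAS calls.

# The convolution uses a zero-padded buffer so every 3x3 neighbour of an
# interior pixel is a constant index offset; im2col then feeds one GEMM.
# Index vectors are cached per (H, W, N).
.conv_idx_cache <- new.env(parent = emptyenv())

conv_indices <- function(H, W, N) {
  key <- paste(H, W, N, sep = "_")
  cached <- get0(key, envir = .conv_idx_cache)
  if (!is.null(cached)) return(cached)
  Hp <- H + 2L; Wp <- W + 2L
  # padded index of each interior pixel, images stacked
  one <- as.vector(outer(2:(Hp - 1L), (1:(Wp - 2L)) * Hp, `+`))
  interior <- rep(one, N) +
    rep((seq_len(N) - 1L) * Hp * Wp, each = length(one))
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  out <- list(interior = interior,
              off = offs$dy + offs$dx * Hp,
              n_padded = Hp * Wp * N)
  assign(key, out, envir = .conv_idx_cache)
  out
}

pool_indices <- function(H, W, N) {
  key <- paste("p", H, W, N, sep = "_")
  cached <- get0(key, envir = .conv_idx_cache)
  if (!is.null(cached)) return(cached)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  yo <- seq_len(Ho); xo <- seq_len(Wo)
  cell <- function(dy, dx)
    as.vector(outer(2L * yo - 1L + dy, (2L * xo - 2L + dx) * H, `+`))
  one <- list(cell(0L, 0L), cell(1L, 0L), cell(0L, 1L), cell(1L, 1L))
  shift <- rep((seq_len(N) - 1L) * H * W, each = Ho * Wo)
  idx <- lapply(one, function(i) rep(i, N) + shift)
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  assign(key, out, envir = .conv_idx_cache)
  out
}

# W is an array (9, Cin, Cout); flattened so patch columns are grouped in
# nine blocks of Cin.
conv_wmat <- function(W) {
  matrix(aperm(W, c(2, 1, 3)), dim(W)[2] * 9L, dim(W)[3])
}

conv_fwd <- function(X, W, b, idx, return_patches = FALSE) {
  Cin <- dim(W)[2]; Cout <- dim(W)[3]
  M <- nrow(X)
  Xp <- matrix(0, idx$n_padded, Cin)
  Xp[idx$interior, ] <- X
  patches <- matrix(0, M, 9L * Cin)
  for (k in 1:9) {
    patches[, (k - 1L) * Cin + seq_len(Cin)] <-
      Xp[idx$interior + idx$off[k], , drop = FALSE]
  }
  out <- patches %*% conv_wmat(W)
  out <- out + rep(b, each = M)   # column-recycled bias
  if (return_patches) list(out = out, patches = patches) else out
}

conv_bwd <- function(dOut, patches, W, idx) {
  Cin <- dim(W)[2]; Cout <- dim(W)[3]
  dWmat <- crossprod(patches, dOut)
  dW <- aperm(array(dWmat, dim = c(Cin, 9L, Cout)), c(2, 1, 3))
  dP <- dOut %*% t(conv_wmat(W))
  dXp <- matrix(0, idx$n_padded, Cin)
  for (k in 1:9) {
    tgt <- idx$interior + idx$off[k]
    dXp[tgt, ] <- dXp[tgt, , drop = FALSE] +
      dP[, (k - 1L) * Cin + seq_len(Cin), drop = FALSE]
  }
  list(dX = dXp[idx$interior, , drop = FALSE], dW = dW,
       db = colSums(dOut))
}

pool_fwd <- function(X, pidx) {
  (X[pidx$idx[[1]], , drop = FALSE] + X[pidx$idx[[2]], , drop = FALSE] +
     X[pidx$idx[[3]], , drop = FALSE] + X[pidx$idx[[4]], , drop = FALSE]) / 4
}

pool_bwd <- function(dOut, n_in, pidx) {
  dX <- matrix(0, n_in, ncol(dOut))
  for (i in 1:4) dX[pidx$idx[[i]], ] <- dOut / 4
  dX
}

# Backbone: `blocks` convolution stages, each conv -> ReLU -> (spatial
# dropout) -> 2x2 average pool, followed by global average pooling.
backbone_init <- function(channels = c(8L, 16L, 32L), in_ch = 1L, seed = 1L) {
  with_seed(mix_seed(seed, 101L), {
    params <- list()
    cin <- in_ch
    for (i in seq_along(channels)) {
      fan_in <- 9 * cin
      params[[paste0("conv", i, "_W")]] <-
        array(rnorm(9 * cin * channels[i], 0, sqrt(2 / fan_in)),
              dim = c(9, cin, channels[i]))
      params[[paste0("conv", i, "_b")]] <- numeric(channels[i])
      cin <- channels[i]
    }
    params
  })
}

# Forward pass through the backbone. `x` is an array side x side x N (or a
# single matrix). Returns GAP features (N x C) plus a cache for backprop.
# Spatial dropout masks (one Bernoulli draw per image x channel) are drawn
# from the current RNG stream when `dropout_rate > 0` and `dropout_active`.
backbone_fwd <- function(params, x, channels, dropout_rate = 0,
                         dropout_active = FALSE, keep_cache = FALSE) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  side <- dim(x)[1]; N <- dim(x)[3]
  M <- matrix(as.numeric(x), side * side * N, 1L)
  H <- side; W <- side
  cache <- list(patches = list(), pre = list(), masks = list(),
                dims = list(), N = N)
  for (i in seq_along(channels)) {
    idx <- conv_indices(H, W, N)
    cf <- conv_fwd(M, params[[paste0("conv", i, "_W")]],
                   params[[paste0("conv", i, "_b")]], idx,
                   return_patches = keep_cache)
    Z <- if (keep_cache) cf$out else cf
    A <- pmax(Z, 0)
    mask <- NULL
    if (dropout_active && dropout_rate > 0) {
      keep <- matrix(runif(N * ncol(A)) >= dropout_rate, N, ncol(A))
      mask <- keep / (1 - dropout_rate)
      A <- A * mask[rep(seq_len(N), each = H * W), , drop = FALSE]
    }
    pidx <- pool_indices(H, W, N)
    P <- pool_fwd(A, pidx)
    if (keep_cache) {
      cache$patches[[i]] <- cf$patches
      cache$pre[[i]] <- Z
      cache$masks[i] <- list(mask)   # list-assign: mask may be NULL
      cache$dims[[i]] <- c(H, W)
    }
    M <- P
    H <- H %/% 2L; W <- W %/% 2L
  }
  grp <- rep(seq_len(N), each = H * W)
  G <- rowsum(M, grp) / (H * W)
  if (keep_cache) {
    cache$last <- M
    cache$last_dims <- c(H, W)
  }
  list(features = G, cache = cache)
}

backbone_bwd <- function(params, dG, cache, channels) {
  N <- cache$N
  H <- cache$last_dims[1]; W <- cache$last_dims[2]
  grp <- rep(seq_len(N), each = H * W)
  dM <- dG[grp, , drop = FALSE] / (H * W)
  grads <- list()
  for (i in rev(seq_along(channels))) {
    H <- cache$dims[[i]][1]; W <- cache$dims[[i]][2]
    pidx <- pool_indices(H, W, N)
    dA <- pool_bwd(dM, nrow(cache$pre[[i]]), pidx)
    if (!is.null(cache$masks[[i]]))
      dA <- dA * cache$masks[[i]][rep(seq_len(N), each = H * W), ,
                                  drop = FALSE]
    dZ <- dA * (cache$pre[[i]] > 0)
    idx <- conv_indices(H, W, N)
    cb <- conv_bwd(dZ, cache$patches[[i]],
                   params[[paste0("conv", i, "_W")]], idx)
    grads[[paste0("conv", i, "_W")]] <- cb$dW
    grads[[paste0("conv", i, "_b")]] <- cb$db
    dM <- cb$dX
  }
  grads
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
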