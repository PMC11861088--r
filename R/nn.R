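# Internal neural-network primitives: batched pre-norm transformer blocks
# with exact hand-written backpropagation, in plain matrix code.
#
# Activations are stored as (B*n) x d matrices with the tokens of sample b
# occupying rows ((b-1)*n + 1):(b*n); every sample in a batch has the same
# token count n, which the masking scheme guarantees (the mask count is a
# deterministic function of the ratio).

LN_EPS <- 1e-6

# weight init: LeCun/Xavier fan-in scaling keeps activation magnitudes
# comparable across widths (a flat constant would starve narrow presets)
nn_rmat <- function(nr, nc, sd = 1 / sqrt(nr)) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

nn_linear_fwd <- function(X, W, b) {
  Y <- X %*% W
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(Y))
  Y
}

nn_linear_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

nn_ln_fwd <- function(X, g, b) {
  d <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  nr <- nrow(X)
  Y <- xhat * rep(g, each = nr) + rep(b, each = nr)
  list(Y = Y, cache = list(xhat = xhat, inv = inv, g = g))
}

nn_ln_bwd <- function(dY, cache) {
  xhat <- cache$xhat; inv <- cache$inv; g <- cache$g
  d <- ncol(dY)
  dxhat <- dY * rep(g, each = nrow(dY))
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dX <- (dxhat - s1 / d - xhat * (s2 / d)) * inv
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

nn_gelu_fwd <- function(X) X * stats::pnorm(X)
nn_gelu_bwd <- function(dY, X) dY * (stats::pnorm(X) + X * stats::dnorm(X))

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

nn_attn_fwd <- function(X, p, n_heads, n, B) {
  d <- ncol(X); dh <- d %/% n_heads
  QKV <- nn_linear_fwd(X, p$qkv_W, p$qkv_b)
  O <- matrix(0, nrow(X), d)
  A_cache <- vector("list", B * n_heads)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * n + 1):(b * n)
    for (h in seq_len(n_heads)) {
      cq <- ((h - 1) * dh + 1):(h * dh)
      Q <- QKV[rows, cq, drop = FALSE]
      K <- QKV[rows, d + cq, drop = FALSE]
      V <- QKV[rows, 2 * d + cq, drop = FALSE]
      A <- softmax_rows(tcrossprod(Q, K) * scale)
      O[rows, cq] <- A %*% V
      A_cache[[(b - 1) * n_heads + h]] <- A
    }
  }
  Y <- nn_linear_fwd(O, p$proj_W, p$proj_b)
  list(Y = Y, cache = list(X = X, QKV = QKV, O = O, A = A_cache,
                           n_heads = n_heads, n = n, B = B, scale = scale))
}

nn_attn_bwd <- function(dY, p, cache) {
  X <- cache$X; QKV <- cache$QKV; n_heads <- cache$n_heads
  n <- cache$n; B <- cache$B; scale <- cache$scale
  d <- ncol(X); dh <- d %/% n_heads
  lb <- nn_linear_bwd(dY, cache$O, p$proj_W)
  dO <- lb$dX
  dQKV <- matrix(0, nrow(X), 3 * d)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * n + 1):(b * n)
    for (h in seq_len(n_heads)) {
      cq <- ((h - 1) * dh + 1):(h * dh)
      Q <- QKV[rows, cq, drop = FALSE]
      K <- QKV[rows, d + cq, drop = FALSE]
      V <- QKV[rows, 2 * d + cq, drop = FALSE]
      A <- cache$A[[(b - 1) * n_heads + h]]
      dOb <- dO[rows, cq, drop = FALSE]
      dA <- tcrossprod(dOb, V)
      dV <- crossprod(A, dOb)
      dS <- A * (dA - rowSums(dA * A))
      dQKV[rows, cq] <- (dS %*% K) * scale
      dQKV[rows, d + cq] <- crossprod(dS, Q) * scale
      dQKV[rows, 2 * d + cq] <- dV
    }
  }
  lq <- nn_linear_bwd(dQKV, X, p$qkv_W)
  list(dX = lq$dX,
       grads = list(qkv_W = lq$dW, qkv_b = lq$db,
                    proj_W = lb$dW, proj_b = lb$db))
}

nn_block_fwd <- function(X, p, n_heads, n, B) {
  l1 <- nn_ln_fwd(X, p$ln1_g, p$ln1_b)
  at <- nn_attn_fwd(l1$Y, p, n_heads, n, B)
  X1 <- X + at$Y
  l2 <- nn_ln_fwd(X1, p$ln2_g, p$ln2_b)
  H <- nn_linear_fwd(l2$Y, p$fc1_W, p$fc1_b)
  G <- nn_gelu_fwd(H)
  M <- nn_linear_fwd(G, p$fc2_W, p$fc2_b)
  Y <- X1 + M
  list(Y = Y, cache = list(ln1 = l1$cache, attn = at$cache, ln2 = l2$cache,
                           Xln1 = l1$Y, Xln2 = l2$Y, H = H, G = G))
}

nn_block_bwd <- function(dY, p, cache) {
  lf2 <- nn_linear_bwd(dY, cache$G, p$fc2_W)
  dH <- nn_gelu_bwd(lf2$dX, cache$H)
  lf1 <- nn_linear_bwd(dH, cache$Xln2, p$fc1_W)
  l2 <- nn_ln_bwd(lf1$dX, cache$ln2)
  dX1 <- dY + l2$dX
  ab <- nn_attn_bwd(dX1, p, cache$attn)
  l1 <- nn_ln_bwd(ab$dX, cache$ln1)
  dX <- dX1 + l1$dX
  grads <- c(list(ln1_g = l1$dg, ln1_b = l1$db,
                  ln2_g = l2$dg, ln2_b = l2$db,
                  fc1_W = lf1$dW, fc1_b = lf1$db,
                  fc2_W = lf2$dW, fc2_b = lf2$db),
             ab$grads)
  list(dX = dX, grads = grads)
}

nn_init_block <- function(d, mlp_ratio = 4L) {
  list(ln1_g = rep(1, d), ln1_b = rep(0, d),
       qkv_W = nn_rmat(d, 3 * d), qkv_b = rep(0, 3 * d),
       proj_W = nn_rmat(d, d), proj_b = rep(0, d),
       ln2_g = rep(1, d), ln2_b = rep(0, d),
       fc1_W = nn_rmat(d, mlp_ratio * d), fc1_b = rep(0, mlp_ratio * d),
       fc2_W = nn_rmat(mlp_ratio * d, d), fc2_b = rep(0, d))
}

# a stack of pre-norm blocks followed by a final layer norm
nn_vit_fwd <- function(X, blocks, lnf_g, lnf_b, n_heads, n, B) {
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    r <- nn_block_fwd(X, blocks[[i]], n_heads, n, B)
    X <- r$Y
    caches[[i]] <- r$cache
  }
  lf <- nn_ln_fwd(X, lnf_g, lnf_b)
  list(Y = lf$Y, cache = list(blocks = caches, lnf = lf$cache))
}

nn_vit_bwd <- function(dY, blocks, cache) {
  lf <- nn_ln_bwd(dY, cache$lnf)
  dX <- lf$dX
  gblocks <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    r <- nn_block_bwd(dX, blocks[[i]], cache$blocks[[i]])
    dX <- r$dX
    gblocks[[i]] <- r$grads
  }
  list(dX = dX, grads = list(blocks = gblocks, lnf_g = lf$dg, lnf_b = lf$db))
}

# --- parameter-tree utilities ------------------------------------------------

par_map <- function(p, f) {
  if (is.list(p)) return(lapply(p, par_map, f = f))
  f(p)
}

par_map2 <- function(a, b, f) {
  if (is.list(a)) {
    if (!is.list(b) || length(a) != length(b) ||
        !identical(names(a), names(b)))
      stop("parameter structures do not match")
    return(mapply(par_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE))
  }
  if (is.list(b) || length(a) != length(b))
    stop("parameter structures do not match")
  f(a, b)
}

par_zeros_like <- function(p) par_map(p, function(x) x * 0)

par_add <- function(a, b) par_map2(a, b, `+`)

par_count <- function(p) {
  if (is.list(p)) return(sum(vapply(p, par_count, numeric(1))))
  length(p)
}

par_l2 <- function(a, b) sqrt(sum(unlist(par_map2(a, b, function(x, y) sum((x - y)^2)))))
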