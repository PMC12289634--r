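# Differentiable layer primitives (forward + hand-derived backward).
#
# Conventions: a token sequence is an N x C matrix whose tokens enumerate a
# (h, w) grid column-major (row index fastest), so tokens <-> grid is a
# plain reshape: grid array(tok, c(h, w, C)), tokens matrix(G, h*w, C).
# All backward functions take the upstream gradient and the forward cache
# and return gradients for inputs and parameters.

LN_EPS <- 1e-6

trunc_normal <- function(n, std = 0.02) {
  qnorm(runif(n, pnorm(-2), pnorm(2))) * std
}

add_bias <- function(x, b) x + rep(b, each = nrow(x))

linear_fwd <- function(x, W, b) add_bias(x %*% W, b)

# y = x W + b:  returns dx and parameter grads
linear_bwd <- function(dout, x, W) {
  list(dx = dout %*% t(W), dW = crossprod(x, dout), db = colSums(dout))
}

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# --- layer normalization over channels, per token --------------------------

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  list(out = add_bias(xhat * rep(g, each = nrow(x)), b),
       cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  n <- nrow(dout)
  dxhat <- dout * rep(g, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dx = (dxhat - m1 - xhat * m2) * cache$inv,
       dg = colSums(dout * xhat), db = colSums(dout))
}

# --- overlapping patch embedding (strided conv via im2col) -----------------

# geometry: pad = k %/% 2 each side, out = (H + 2p - k) %/% s + 1
patch_geom <- function(H, W, k, s) {
  p <- k %/% 2
  list(p = p, Ho = (H + 2 * p - k) %/% s + 1, Wo = (W + 2 * p - k) %/% s + 1)
}

im2col <- function(x, k, s) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  ge <- patch_geom(H, W, k, s)
  p <- ge$p; Ho <- ge$Ho; Wo <- ge$Wo
  Hp <- H + 2 * p; Wp <- W + 2 * p
  P <- array(0, c(Hp, Wp, Cin))
  P[p + seq_len(H), p + seq_len(W), ] <- x
  N <- Ho * Wo
  ro <- rep(seq_len(Ho), Wo); co <- rep(seq_len(Wo), each = Ho)
  X <- matrix(0, N, k * k * Cin)
  j <- 0L
  for (ch in seq_len(Cin)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    j <- j + 1L
    lin <- ((ro - 1) * s + di) + ((co - 1) * s + dj - 1) * Hp + (ch - 1) * Hp * Wp
    X[, j] <- P[lin]
  }
  list(X = X, Ho = Ho, Wo = Wo, geom = list(k = k, s = s, p = p, H = H, W = W,
                                            Cin = Cin, Hp = Hp, Wp = Wp))
}

im2col_bwd <- function(dX, geom) {
  k <- geom$k; s <- geom$s; Hp <- geom$Hp; Wp <- geom$Wp; Cin <- geom$Cin
  Ho <- (geom$H + 2 * geom$p - k) %/% s + 1
  Wo <- (geom$W + 2 * geom$p - k) %/% s + 1
  ro <- rep(seq_len(Ho), Wo); co <- rep(seq_len(Wo), each = Ho)
  dP <- numeric(Hp * Wp * Cin)
  j <- 0L
  for (ch in seq_len(Cin)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    j <- j + 1L
    lin <- ((ro - 1) * s + di) + ((co - 1) * s + dj - 1) * Hp + (ch - 1) * Hp * Wp
    dP[lin] <- dP[lin] + dX[, j]
  }
  dP <- array(dP, c(Hp, Wp, Cin))
  dP[geom$p + seq_len(geom$H), geom$p + seq_len(geom$W), , drop = FALSE]
}

patch_embed_fwd <- function(x, p, k, s) {
  ic <- im2col(x, k, s)
  tok <- linear_fwd(ic$X, p$W, p$b)
  ln <- layernorm_fwd(tok, p$ln$g, p$ln$b)
  list(tokens = ln$out, h = ic$Ho, w = ic$Wo,
       cache = list(X = ic$X, geom = ic$geom, ln = ln$cache))
}

patch_embed_bwd <- function(dtok, cache, p) {
  lb <- layernorm_bwd(dtok, cache$ln, p$ln$g)
  li <- linear_bwd(lb$dx, cache$X, p$W)
  dx <- im2col_bwd(li$dx, cache$geom)
  list(dx = dx,
       grads = list(W = li$dW, b = li$db, ln = list(g = lb$dg, b = lb$db)))
}

# --- depth-wise 3x3 convolution on a (h, w, E) grid ------------------------

# wt: 9 x E matrix, row k = offset (di, dj) with di inner, di/dj in -1..1
dwconv3_fwd <- function(G, wt, b) {
  h <- dim(G)[1]; w <- dim(G)[2]; E <- dim(G)[3]
  out <- array(rep(b, each = h * w), c(h, w, E))
  kk <- 0L
  for (dj in -1:1) for (di in -1:1) {
    kk <- kk + 1L
    if (max(1, 1 - di) > min(h, h - di) || max(1, 1 - dj) > min(w, w - dj)) next
    ro <- max(1, 1 - di):min(h, h - di); co <- max(1, 1 - dj):min(w, w - dj)
    out[ro, co, ] <- out[ro, co, , drop = FALSE] +
      G[ro + di, co + dj, , drop = FALSE] *
      rep(wt[kk, ], each = length(ro) * length(co))
  }
  out
}

dwconv3_bwd <- function(dO, G, wt) {
  h <- dim(G)[1]; w <- dim(G)[2]; E <- dim(G)[3]
  dG <- array(0, c(h, w, E))
  dw <- matrix(0, 9, E)
  kk <- 0L
  for (dj in -1:1) for (di in -1:1) {
    kk <- kk + 1L
    if (max(1, 1 - di) > min(h, h - di) || max(1, 1 - dj) > min(w, w - dj)) next
    ro <- max(1, 1 - di):min(h, h - di); co <- max(1, 1 - dj):min(w, w - dj)
    sl_d <- dO[ro, co, , drop = FALSE]
    sl_g <- G[ro + di, co + dj, , drop = FALSE]
    dG[ro + di, co + dj, ] <- dG[ro + di, co + dj, , drop = FALSE] +
      sl_d * rep(wt[kk, ], each = length(ro) * length(co))
    dw[kk, ] <- colSums(matrix(sl_d * sl_g, length(ro) * length(co), E))
  }
  list(dG = dG, dw = dw, db = colSums(matrix(dO, h * w, E)))
}

# --- sequence reduction (reshape N x C -> N/R x C*R, then linear) ----------

seq_reduce_reshape <- function(x, R) {
  C <- ncol(x)
  t(matrix(as.vector(t(x)), nrow = C * R))
}

seq_reduce_reshape_bwd <- function(dXhat, C) {
  t(matrix(as.vector(t(dXhat)), nrow = C))
}

# --- efficient multi-head self-attention -----------------------------------

attention_fwd <- function(xn, p, heads, R) {
  N <- nrow(xn); C <- ncol(xn)
  if (C %% heads != 0) stopf("channel width %d not divisible by %d heads", C, heads)
  d <- C %/% heads
  npad <- 0L
  if (R > 1) {
    npad <- (R - N %% R) %% R
    xin <- if (npad > 0) rbind(xn, matrix(0, npad, C)) else xn
    Khat <- seq_reduce_reshape(xin, R)
    xr <- linear_fwd(Khat, p$Wr, p$br)
  } else {
    Khat <- NULL
    xr <- xn
  }
  Q <- linear_fwd(xn, p$Wq, p$bq)
  K <- linear_fwd(xr, p$Wk, p$bk)
  V <- linear_fwd(xr, p$Wv, p$bv)
  O <- matrix(0, N, C)
  A <- vector("list", heads)
  for (hh in seq_len(heads)) {
    idx <- ((hh - 1) * d + 1):(hh * d)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(d)
    A[[hh]] <- softmax_rows(S)
    O[, idx] <- A[[hh]] %*% V[, idx, drop = FALSE]
  }
  out <- linear_fwd(O, p$Wo, p$bo)
  list(out = out,
       cache = list(xn = xn, xr = xr, Khat = Khat, Q = Q, K = K, V = V,
                    A = A, O = O, heads = heads, R = R, npad = npad, d = d))
}

attention_bwd <- function(dout, cache, p) {
  xn <- cache$xn; xr <- cache$xr
  heads <- cache$heads; d <- cache$d; R <- cache$R
  N <- nrow(xn); C <- ncol(xn)
  lo <- linear_bwd(dout, cache$O, p$Wo)
  dO <- lo$dx
  dQ <- matrix(0, N, C); dK <- matrix(0, nrow(xr), C); dV <- matrix(0, nrow(xr), C)
  for (hh in seq_len(heads)) {
    idx <- ((hh - 1) * d + 1):(hh * d)
    A <- cache$A[[hh]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(d)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(d)
  }
  lq <- linear_bwd(dQ, xn, p$Wq)
  lk <- linear_bwd(dK, xr, p$Wk)
  lv <- linear_bwd(dV, xr, p$Wv)
  dxn <- lq$dx
  dxr <- lk$dx + lv$dx
  grads <- list(Wq = lq$dW, bq = lq$db, Wk = lk$dW, bk = lk$db,
                Wv = lv$dW, bv = lv$db, Wo = lo$dW, bo = lo$db)
  if (R > 1) {
    lr <- linear_bwd(dxr, cache$Khat, p$Wr)
    grads$Wr <- lr$dW; grads$br <- lr$db
    dxin <- seq_reduce_reshape_bwd(lr$dx, C)
    dxn <- dxn + dxin[seq_len(N), , drop = FALSE]
  } else {
    dxn <- dxn + dxr
  }
  list(dx = dxn, grads = grads)
}

# --- mix feed-forward network (core, without the residual) -----------------

mixffn_fwd <- function(xn, h, w, p) {
  E <- ncol(p$W1)
  h1 <- linear_fwd(xn, p$W1, p$b1)
  conv <- dwconv3_fwd(array(h1, c(h, w, E)), p$dw, p$bdw)
  pre <- matrix(conv, nrow(xn), E)
  act <- gelu(pre)
  out <- linear_fwd(act, p$W2, p$b2)
  list(out = out, cache = list(xn = xn, h1 = h1, pre = pre, act = act,
                               h = h, w = w, E = E))
}

mixffn_bwd <- function(dout, cache, p) {
  l2 <- linear_bwd(dout, cache$act, p$W2)
  dpre <- l2$dx * gelu_grad(cache$pre)
  G <- array(cache$h1, c(cache$h, cache$w, cache$E))
  cb <- dwconv3_bwd(array(dpre, c(cache$h, cache$w, cache$E)), G, p$dw)
  dh1 <- matrix(cb$dG, nrow(dout), cache$E)
  l1 <- linear_bwd(dh1, cache$xn, p$W1)
  list(dx = l1$dx,
       grads = list(W1 = l1$dW, b1 = l1$db, dw = cb$dw, bdw = cb$db,
                    W2 = l2$dW, b2 = l2$db))
}

# --- bilinear interpolation matrices (half-pixel centers) ------------------

interp_matrix <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_in))
  L <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5   # 0-based source coord
  i0 <- clamp(floor(src), 0, n_in - 1)
  i1 <- pmin(i0 + 1, n_in - 1)
  w1 <- clamp(src - i0, 0, 1)
  for (i in seq_len(n_out)) {
    L[i, i0[i] + 1] <- L[i, i0[i] + 1] + (1 - w1[i])
    L[i, i1[i] + 1] <- L[i, i1[i] + 1] + w1[i]
  }
  L
}

# apply separable interpolation to a (h, w, C) array
apply_interp <- function(G, Lr, Lc) {
  h <- dim(G)[1]; w <- dim(G)[2]; C <- dim(G)[3]
  ho <- nrow(Lr); wo <- nrow(Lc)
  A <- Lr %*% matrix(G, h, w * C)                    # (ho, w*C)
  A <- aperm(array(A, c(ho, w, C)), c(2, 1, 3))      # (w, ho, C)
  B <- Lc %*% matrix(A, w, ho * C)                   # (wo, ho*C)
  aperm(array(B, c(wo, ho, C)), c(2, 1, 3))          # (ho, wo, C)
}

upsample_bilinear <- function(G, ho, wo) {
  apply_interp(G, interp_matrix(dim(G)[1], ho), interp_matrix(dim(G)[2], wo))
}

upsample_bilinear_bwd <- function(dO, h, w) {
  apply_interp(dO, t(interp_matrix(h, dim(dO)[1])), t(interp_matrix(w, dim(dO)[2])))
}
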