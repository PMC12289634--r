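# Test-side oracles, independent of the package implementation.

# queue-based flood-fill labeling of a logical matrix
flood_label <- function(bin, conn = 8) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  offs <- if (conn == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- ((q - 1) %% H) + 1; c <- ((q - 1) %/% H) + 1
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            bin[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- c(queue, (cc - 1) * H + rr)
        }
      }
    }
  }
  lab
}

n_components <- function(bin, conn = 8) max(flood_label(bin, conn), 0L)

# brute-force multi-head attention: softmax(Q K^T / sqrt(d)) V with an
# output projection, sharing the weight list layout of attention_params()
reference_attention <- function(x, p, heads) {
  C <- ncol(x); d <- C / heads
  Q <- x %*% p$Wq + rep(p$bq, each = nrow(x))
  K <- x %*% p$Wk + rep(p$bk, each = nrow(x))
  V <- x %*% p$Wv + rep(p$bv, each = nrow(x))
  O <- matrix(0, nrow(x), C)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * d + 1):(h * d)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(d)
    S <- S - apply(S, 1, max)
    A <- exp(S) / rowSums(exp(S))
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  O %*% p$Wo + rep(p$bo, each = nrow(x))
}

# mildly corrupt a ground-truth mask into a plausible raw prediction:
# a stray speck per class plus a small interior hole
corrupt_mask <- function(mask, seed = 1) {
  set.seed(seed)
  out <- mask
  H <- nrow(mask); W <- ncol(mask)
  for (cls in c(1L, 2L)) {
    bg <- which(out == 0L, arr.ind = TRUE)
    bg <- bg[bg[, 1] > 2 & bg[, 1] < H - 2 & bg[, 2] > 2 & bg[, 2] < W - 2, ,
             drop = FALSE]
    if (nrow(bg) > 0) {
      p <- bg[sample(nrow(bg), 1), ]
      out[p[1] + 0:1, p[2] + 0:1] <- cls     # 4-px stray speck
    }
    inside <- which(out == cls, arr.ind = TRUE)
    inside <- inside[inside[, 1] > 3 & inside[, 1] < H - 3 &
                     inside[, 2] > 3 & inside[, 2] < W - 3, , drop = FALSE]
    if (nrow(inside) > 8) {
      p <- inside[sample(nrow(inside), 1), ]
      hole <- out[p[1] + 0:1, p[2] + 0:1]
      if (all(hole == cls)) out[p[1] + 0:1, p[2] + 0:1] <- 0L
    }
  }
  out
}
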