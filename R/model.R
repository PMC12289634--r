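#' Hierarchical transformer segmentation model
#'
#' A four-stage hierarchical vision-transformer encoder paired with a
#' lightweight all-MLP decoder for per-pixel classification. Each stage
#' embeds overlapping patches (stage 1 at stride 4, later stages stride 2,
#' giving a 1/4, 1/8, 1/16, 1/32 feature pyramid), then applies
#' pre-normalized blocks of sequence-reduced multi-head self-attention and
#' mix feed-forward layers (whose 3x3 depth-wise convolution supplies
#' positional information). The decoder projects every pyramid level to a
#' common width, bilinearly upsamples to the 1/4 grid, concatenates, fuses,
#' classifies, and upsamples logits to the input resolution.
#'
#' @name model
NULL

#' Model configuration
#'
#' @param num_classes segmentation classes (default 3: background,
#'   trachea, supraglottis).
#' @param stage_depths transformer layers per stage (4 integers).
#' @param embed_dims channel width per stage (4 integers, each divisible
#'   by the matching entry of `num_heads`).
#' @param num_heads attention heads per stage.
#' @param reduction_ratios key/value sequence-reduction ratio R per stage.
#' @param patch_kernel,patch_stride patch-embedding window and stride per
#'   stage; stage 1 must have stride 4 (4x4-pixel patches), stages 2-4
#'   stride 2 so cumulative resolutions are 1/4, 1/8, 1/16, 1/32.
#' @param decoder_dim common decoder channel width.
#' @param ffn_expansion channel expansion factor of the mix-FFN.
#' @param in_channels input image channels.
#' @return a `model_config` list.
#' @export
model_config <- function(num_classes = 3L,
                         stage_depths = c(2L, 2L, 2L, 2L),
                         embed_dims = c(32L, 64L, 160L, 256L),
                         num_heads = c(1L, 2L, 5L, 8L),
                         reduction_ratios = c(8L, 4L, 2L, 1L),
                         patch_kernel = c(7L, 3L, 3L, 3L),
                         patch_stride = c(4L, 2L, 2L, 2L),
                         decoder_dim = 256L,
                         ffn_expansion = 4L,
                         in_channels = 3L) {
  for (v in list(stage_depths, embed_dims, num_heads, reduction_ratios,
                 patch_kernel, patch_stride))
    if (length(v) != 4) stopf("per-stage fields must have length 4")
  if (patch_stride[1] != 4 || any(patch_stride[2:4] != 2))
    stopf("stage 1 must use stride 4 and stages 2-4 stride 2")
  if (any(embed_dims %% num_heads != 0))
    stopf("embed_dims must be divisible by num_heads")
  if (any(reduction_ratios < 1)) stopf("reduction ratios must be >= 1")
  structure(list(num_classes = as.integer(num_classes),
                 stage_depths = as.integer(stage_depths),
                 embed_dims = as.integer(embed_dims),
                 num_heads = as.integer(num_heads),
                 reduction_ratios = as.integer(reduction_ratios),
                 patch_kernel = as.integer(patch_kernel),
                 patch_stride = as.integer(patch_stride),
                 decoder_dim = as.integer(decoder_dim),
                 ffn_expansion = as.integer(ffn_expansion),
                 in_channels = as.integer(in_channels)),
            class = "model_config")
}

#' Micro configuration for desk-scale experiments
#'
#' Single-layer stages with narrow channels; used by the test-scale
#' experiments so full training runs stay in CPU minutes.
#' @export
micro_model_config <- function() {
  model_config(stage_depths = c(1L, 1L, 1L, 1L),
               embed_dims = c(16L, 32L, 64L, 128L),
               num_heads = c(1L, 2L, 4L, 8L),
               reduction_ratios = c(8L, 4L, 2L, 1L),
               decoder_dim = 64L, ffn_expansion = 2L)
}

# --- parameter initialization ----------------------------------------------

mat_init <- function(nr, nc) matrix(trunc_normal(nr * nc), nr, nc)

#' @rdname model
#' @param dim,heads,R,expansion,in_ch,kernel layer hyperparameters.
#' @param seed initialization seed.
#' @export
attention_params <- function(dim, heads, R, seed = 1) {
  with_seed(seed, {
    p <- list(Wq = mat_init(dim, dim), bq = numeric(dim),
              Wk = mat_init(dim, dim), bk = numeric(dim),
              Wv = mat_init(dim, dim), bv = numeric(dim),
              Wo = mat_init(dim, dim), bo = numeric(dim))
    if (R > 1) { p$Wr <- mat_init(dim * R, dim); p$br <- numeric(dim) }
    p
  })
}

#' @rdname model
#' @export
mix_ffn_params <- function(dim, expansion = 4, seed = 1) {
  E <- dim * expansion
  with_seed(seed, list(W1 = mat_init(dim, E), b1 = numeric(E),
                       dw = matrix(trunc_normal(9 * E), 9, E), bdw = numeric(E),
                       W2 = mat_init(E, dim), b2 = numeric(dim)))
}

#' @rdname model
#' @export
patch_embed_params <- function(in_ch, kernel, dim, seed = 1) {
  with_seed(seed, list(W = mat_init(kernel * kernel * in_ch, dim),
                       b = numeric(dim),
                       ln = list(g = rep(1, dim), b = numeric(dim))))
}

init_params <- function(config, seed) {
  with_seed(seed, {
    in_ch <- config$in_channels
    stages <- vector("list", 4)
    for (i in 1:4) {
      C <- config$embed_dims[i]
      k <- config$patch_kernel[i]
      R <- config$reduction_ratios[i]
      E <- C * config$ffn_expansion
      blocks <- vector("list", config$stage_depths[i])
      for (j in seq_len(config$stage_depths[i])) {
        attn <- list(Wq = mat_init(C, C), bq = numeric(C),
                     Wk = mat_init(C, C), bk = numeric(C),
                     Wv = mat_init(C, C), bv = numeric(C),
                     Wo = mat_init(C, C), bo = numeric(C))
        if (R > 1) { attn$Wr <- mat_init(C * R, C); attn$br <- numeric(C) }
        blocks[[j]] <- list(
          ln1 = list(g = rep(1, C), b = numeric(C)),
          attn = attn,
          ln2 = list(g = rep(1, C), b = numeric(C)),
          ffn = list(W1 = mat_init(C, E), b1 = numeric(E),
                     dw = matrix(trunc_normal(9 * E), 9, E), bdw = numeric(E),
                     W2 = mat_init(E, C), b2 = numeric(C)))
      }
      stages[[i]] <- list(
        patch = list(W = mat_init(k * k * in_ch, C), b = numeric(C),
                     ln = list(g = rep(1, C), b = numeric(C))),
        blocks = blocks,
        norm = list(g = rep(1, C), b = numeric(C)))
      in_ch <- C
    }
    D <- config$decoder_dim
    decoder <- list(
      proj = lapply(1:4, function(i) list(W = mat_init(config$embed_dims[i], D),
                                          b = numeric(D))),
      fuse = list(W = mat_init(4 * D, D), b = numeric(D)),
      fuse_ln = list(g = rep(1, D), b = numeric(D)),
      cls = list(W = mat_init(D, config$num_classes),
                 b = numeric(config$num_classes)))
    list(stages = stages, decoder = decoder)
  })
}

#' Initialize a model
#'
#' Truncated-normal (sd 0.02) linear weights, zero biases, unit
#' normalization gains; fully determined by `seed`.
#'
#' @param config a [model_config()].
#' @param seed initialization seed.
#' @return a `larynx_model` (list of `config` and `params`).
#' @export
init_model <- function(config = model_config(), seed = 1) {
  structure(list(config = config, params = init_params(config, seed)),
            class = "larynx_model")
}

# --- encoder ---------------------------------------------------------------

# one transformer block with pre-normalization and residuals
block_fwd <- function(tok, h, w, bp, heads, R) {
  l1 <- layernorm_fwd(tok, bp$ln1$g, bp$ln1$b)
  at <- attention_fwd(l1$out, bp$attn, heads, R)
  x1 <- tok + at$out
  l2 <- layernorm_fwd(x1, bp$ln2$g, bp$ln2$b)
  ff <- mixffn_fwd(l2$out, h, w, bp$ffn)
  list(out = x1 + ff$out,
       cache = list(l1 = l1$cache, at = at$cache, l2 = l2$cache, ff = ff$cache))
}

block_bwd <- function(dout, cache, bp) {
  fb <- mixffn_bwd(dout, cache$ff, bp$ffn)
  l2 <- layernorm_bwd(fb$dx, cache$l2, bp$ln2$g)
  dx1 <- dout + l2$dx
  ab <- attention_bwd(dx1, cache$at, bp$attn)
  l1 <- layernorm_bwd(ab$dx, cache$l1, bp$ln1$g)
  list(dx = dx1 + l1$dx,
       grads = list(ln1 = list(g = l1$dg, b = l1$db), attn = ab$grads,
                    ln2 = list(g = l2$dg, b = l2$db), ffn = fb$grads))
}

stage_fwd <- function(x, sp, config, i) {
  pe <- patch_embed_fwd(x, sp$patch, config$patch_kernel[i], config$patch_stride[i])
  tok <- pe$tokens
  bcaches <- vector("list", length(sp$blocks))
  for (j in seq_along(sp$blocks)) {
    bl <- block_fwd(tok, pe$h, pe$w, sp$blocks[[j]],
                    config$num_heads[i], config$reduction_ratios[i])
    tok <- bl$out
    bcaches[[j]] <- bl$cache
  }
  ln <- layernorm_fwd(tok, sp$norm$g, sp$norm$b)
  list(tokens = ln$out, h = pe$h, w = pe$w,
       cache = list(pe = pe$cache, blocks = bcaches, ln = ln$cache))
}

stage_bwd <- function(dtok, cache, sp) {
  ln <- layernorm_bwd(dtok, cache$ln, sp$norm$g)
  d <- ln$dx
  gblocks <- vector("list", length(sp$blocks))
  for (j in rev(seq_along(sp$blocks))) {
    bb <- block_bwd(d, cache$blocks[[j]], sp$blocks[[j]])
    d <- bb$dx
    gblocks[[j]] <- bb$grads
  }
  pb <- patch_embed_bwd(d, cache$pe, sp$patch)
  list(dx = pb$dx,
       grads = list(patch = pb$grads, blocks = gblocks,
                    norm = list(g = ln$dg, b = ln$db)))
}

pad_to_32 <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  Hp <- 32 * ((H + 31) %/% 32); Wp <- 32 * ((W + 31) %/% 32)
  if (Hp == H && Wp == W) return(list(img = img, H = H, W = W))
  out <- array(0, c(Hp, Wp, dim(img)[3]))
  out[seq_len(H), seq_len(W), ] <- img
  list(img = out, H = H, W = W)
}

encoder_fwd <- function(img, config, params) {
  if (length(dim(img)) != 3 || dim(img)[3] != config$in_channels)
    stopf("image must be H x W x %d", config$in_channels)
  if (dim(img)[1] < 32 || dim(img)[2] < 32) stopf("image must be at least 32 x 32")
  pd <- pad_to_32(img)
  x <- pd$img
  levels <- vector("list", 4)
  caches <- vector("list", 4)
  for (i in 1:4) {
    st <- stage_fwd(x, params$stages[[i]], config, i)
    levels[[i]] <- list(tokens = st$tokens, h = st$h, w = st$w)
    caches[[i]] <- st$cache
    x <- array(st$tokens, c(st$h, st$w, config$embed_dims[i]))
  }
  list(levels = levels, caches = caches,
       input_size = c(pd$H, pd$W), padded_size = dim(pd$img)[1:2])
}

encoder_bwd <- function(dlevels, enc, config, params) {
  gstages <- vector("list", 4)
  dgrid <- NULL
  for (i in 4:1) {
    lv <- enc$levels[[i]]
    dtok <- dlevels[[i]]
    if (is.null(dtok)) dtok <- matrix(0, lv$h * lv$w, config$embed_dims[i])
    if (!is.null(dgrid))
      dtok <- dtok + matrix(dgrid, lv$h * lv$w, config$embed_dims[i])
    sb <- stage_bwd(dtok, enc$caches[[i]], params$stages[[i]])
    gstages[[i]] <- sb$grads
    dgrid <- sb$dx
  }
  list(grads = list(stages = gstages), dimage = dgrid)
}

# --- decoder ---------------------------------------------------------------

decoder_fwd <- function(levels, padded_size, input_size, config, params) {
  if (length(levels) != 4) stopf("feature pyramid must have exactly 4 levels")
  D <- config$decoder_dim
  h1 <- levels[[1]]$h; w1 <- levels[[1]]$w
  ups <- vector("list", 4)
  caches <- vector("list", 4)
  for (i in 1:4) {
    lv <- levels[[i]]
    pj <- linear_fwd(lv$tokens, params$decoder$proj[[i]]$W,
                     params$decoder$proj[[i]]$b)
    G <- array(pj, c(lv$h, lv$w, D))
    U <- if (lv$h == h1 && lv$w == w1) G else upsample_bilinear(G, h1, w1)
    ups[[i]] <- matrix(U, h1 * w1, D)
    caches[[i]] <- list(tokens = lv$tokens, h = lv$h, w = lv$w)
  }
  cat4 <- do.call(cbind, ups)
  fu <- linear_fwd(cat4, params$decoder$fuse$W, params$decoder$fuse$b)
  ln <- layernorm_fwd(fu, params$decoder$fuse_ln$g, params$decoder$fuse_ln$b)
  act <- pmax(ln$out, 0)
  lg <- linear_fwd(act, params$decoder$cls$W, params$decoder$cls$b)
  Gl <- array(lg, c(h1, w1, config$num_classes))
  full <- upsample_bilinear(Gl, padded_size[1], padded_size[2])
  logits <- full[seq_len(input_size[1]), seq_len(input_size[2]), , drop = FALSE]
  list(logits = logits,
       cache = list(lvl = caches, cat4 = cat4, fu_ln = ln$cache, act = act,
                    h1 = h1, w1 = w1, padded_size = padded_size,
                    input_size = input_size))
}

decoder_bwd <- function(dlogits, cache, config, params) {
  D <- config$decoder_dim
  ps <- cache$padded_size; is_ <- cache$input_size
  dfull <- array(0, c(ps[1], ps[2], config$num_classes))
  dfull[seq_len(is_[1]), seq_len(is_[2]), ] <- dlogits
  dGl <- upsample_bilinear_bwd(dfull, cache$h1, cache$w1)
  dlg <- matrix(dGl, cache$h1 * cache$w1, config$num_classes)
  lc <- linear_bwd(dlg, cache$act, params$decoder$cls$W)
  dact <- lc$dx * (cache$act > 0)
  ln <- layernorm_bwd(dact, cache$fu_ln, params$decoder$fuse_ln$g)
  lf <- linear_bwd(ln$dx, cache$cat4, params$decoder$fuse$W)
  dlevels <- vector("list", 4)
  gproj <- vector("list", 4)
  for (i in 1:4) {
    cols <- ((i - 1) * D + 1):(i * D)
    dU <- lf$dx[, cols, drop = FALSE]
    lv <- cache$lvl[[i]]
    dG <- if (lv$h == cache$h1 && lv$w == cache$w1)
      array(dU, c(lv$h, lv$w, D))
    else upsample_bilinear_bwd(array(dU, c(cache$h1, cache$w1, D)), lv$h, lv$w)
    dpj <- matrix(dG, lv$h * lv$w, D)
    lp <- linear_bwd(dpj, lv$tokens, params$decoder$proj[[i]]$W)
    dlevels[[i]] <- lp$dx
    gproj[[i]] <- list(W = lp$dW, b = lp$db)
  }
  list(dlevels = dlevels,
       grads = list(proj = gproj,
                    fuse = list(W = lf$dW, b = lf$db),
                    fuse_ln = list(g = ln$dg, b = ln$db),
                    cls = list(W = lc$dW, b = lc$db)))
}

# --- exported operation surface --------------------------------------------

as_token_grid <- function(tokens, h, w) {
  structure(list(tokens = tokens, grid_shape = c(h, w)), class = "token_grid")
}

#' Overlapping patch embedding
#'
#' Splits an image or feature grid into overlapping strided windows,
#' linearly projects each window and normalizes tokens. The output grid is
#' the ceiling division of the input spatial size by the stride.
#'
#' @param x H x W x C array (a matrix is treated as one channel).
#' @param kernel,stride window size and stride.
#' @param out_dim embedding width.
#' @param params optional [patch_embed_params()]; seeded init otherwise.
#' @param seed init seed when `params` is NULL.
#' @return a `token_grid`: list of `tokens` (N x out_dim) and `grid_shape`.
#' @export
overlap_patch_embed <- function(x, kernel = 7, stride = 4, out_dim = 32,
                                params = NULL, seed = 1) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  if (dim(x)[1] < kernel || dim(x)[2] < kernel)
    stopf("input (%d x %d) smaller than kernel %d", dim(x)[1], dim(x)[2], kernel)
  if (is.null(params))
    params <- patch_embed_params(dim(x)[3], kernel, out_dim, seed)
  pe <- patch_embed_fwd(x, params, kernel, stride)
  as_token_grid(pe$tokens, pe$h, pe$w)
}

#' Sequence reduction of a token matrix
#'
#' Reshapes an N x C token sequence to (N/R) x (C*R) by concatenating R
#' consecutive tokens, then maps back to C channels with a learned linear
#' projection. Sequences whose length is not divisible by R are zero-padded.
#'
#' @param K N x C matrix or `token_grid`.
#' @param R reduction ratio >= 1.
#' @param W,b optional projection ((C*R) x C matrix and length-C bias);
#'   when NULL, seeded init is used, except R = 1 which defaults to the
#'   identity map.
#' @param seed init seed.
#' @return the reduced (ceiling(N/R)) x C token matrix.
#' @export
reduce_sequence <- function(K, R, W = NULL, b = NULL, seed = 1) {
  if (inherits(K, "token_grid")) K <- K$tokens
  if (!is_count(R) || R < 1) stopf("R must be an integer >= 1")
  C <- ncol(K); N <- nrow(K)
  if (is.null(W)) {
    W <- if (R == 1) diag(C) else with_seed(seed, mat_init(C * R, C))
  }
  if (is.null(b)) b <- numeric(C)
  npad <- (R - N %% R) %% R
  if (npad > 0) K <- rbind(K, matrix(0, npad, C))
  Khat <- seq_reduce_reshape(K, R)
  linear_fwd(Khat, W, b)
}

#' Efficient multi-head self-attention
#'
#' Scaled dot-product attention where queries keep the full sequence
#' length and keys/values are sequence-reduced by ratio `R`.
#'
#' @param x N x C token matrix or `token_grid`.
#' @param heads number of heads (must divide C).
#' @param R key/value reduction ratio.
#' @param params optional [attention_params()].
#' @param seed init seed when `params` is NULL.
#' @return object of the same type as `x`.
#' @export
efficient_self_attention <- function(x, heads, R = 1, params = NULL, seed = 1) {
  tok <- if (inherits(x, "token_grid")) x$tokens else x
  if (ncol(tok) %% heads != 0)
    stopf("channel width %d not divisible by %d heads", ncol(tok), heads)
  if (is.null(params)) params <- attention_params(ncol(tok), heads, R, seed)
  out <- attention_fwd(tok, params, heads, R)$out
  if (inherits(x, "token_grid"))
    as_token_grid(out, x$grid_shape[1], x$grid_shape[2]) else out
}

#' Mix feed-forward block
#'
#' Channel-expanding linear map, 3x3 depth-wise convolution on the token
#' grid, GELU, channel-contracting linear map, and a residual connection
#' adding the input.
#'
#' @param x a `token_grid` (the convolution needs the grid shape).
#' @param expansion channel expansion factor.
#' @param params optional [mix_ffn_params()].
#' @param seed init seed when `params` is NULL.
#' @return a `token_grid` of the same shape.
#' @export
mix_ffn <- function(x, expansion = 4, params = NULL, seed = 1) {
  if (!inherits(x, "token_grid"))
    stopf("mix_ffn needs a token_grid with a known grid_shape")
  if (is.null(params)) params <- mix_ffn_params(ncol(x$tokens), expansion, seed)
  out <- mixffn_fwd(x$tokens, x$grid_shape[1], x$grid_shape[2], params)$out
  as_token_grid(out + x$tokens, x$grid_shape[1], x$grid_shape[2])
}

#' Encoder forward pass
#'
#' @param image H x W x 3 array, sides >= 32 (zero-padded internally to a
#'   multiple of 32).
#' @param model a `larynx_model`; when NULL a model is initialized from
#'   `config` and `seed`.
#' @param config,seed used when `model` is NULL.
#' @return a `feature_pyramid`: `levels` is a list of 4 `token_grid`s at
#'   1/4, 1/8, 1/16, 1/32 of the (padded) input resolution.
#' @export
encoder_forward <- function(image, model = NULL, config = model_config(),
                            seed = 1) {
  if (is.null(model)) model <- init_model(config, seed)
  enc <- encoder_fwd(image, model$config, model$params)
  structure(list(
    levels = lapply(enc$levels, function(l) as_token_grid(l$tokens, l$h, l$w)),
    input_size = enc$input_size, padded_size = enc$padded_size),
    class = "feature_pyramid")
}

#' Decoder forward pass
#'
#' @param pyramid a `feature_pyramid` from [encoder_forward()].
#' @param model the `larynx_model` whose decoder weights to use; when NULL
#'   initialized from `config` and `seed`.
#' @inheritParams encoder_forward
#' @return logits: H x W x num_classes array at the input resolution.
#' @export
decoder_forward <- function(pyramid, model = NULL, config = model_config(),
                            seed = 1) {
  if (is.null(model)) model <- init_model(config, seed)
  levels <- lapply(pyramid$levels, function(l)
    list(tokens = l$tokens, h = l$grid_shape[1], w = l$grid_shape[2]))
  decoder_fwd(levels, pyramid$padded_size, pyramid$input_size,
              model$config, model$params)$logits
}

#' Per-pixel class prediction from logits
#'
#' Argmax over the class axis; ties break toward the lowest class index
#' (background-favoring).
#'
#' @param logits H x W x K array.
#' @return H x W integer mask with values 0..K-1.
#' @export
logits_to_mask <- function(logits) {
  H <- dim(logits)[1]; W <- dim(logits)[2]; K <- dim(logits)[3]
  m <- max.col(matrix(logits, H * W, K), ties.method = "first") - 1L
  matrix(as.integer(m), H, W)
}

#' Predict a segmentation mask
#'
#' @param object a `larynx_model`.
#' @param image H x W x 3 array in [0, 1].
#' @param ... unused.
#' @return H x W integer class mask.
#' @export
predict.larynx_model <- function(object, image, ...) {
  enc <- encoder_fwd(image, object$config, object$params)
  dec <- decoder_fwd(enc$levels, enc$padded_size, enc$input_size,
                     object$config, object$params)
  logits_to_mask(dec$logits)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized weights plus the configuration.
#' @param model a `larynx_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(config = do.call(model_config, x$config[names(formals(model_config))]),
                 params = x$params), class = "larynx_model")
}
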