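test_that("patch embedding produces the expected token grids", {
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  tg <- overlap_patch_embed(img, kernel = 7, stride = 4, out_dim = 8)
  expect_equal(tg$grid_shape, c(32, 32))     # 4x4-pixel patches
  expect_equal(nrow(tg$tokens), 1024)
  feat <- array(runif(32 * 32 * 8), c(32, 32, 8))
  tg2 <- overlap_patch_embed(feat, kernel = 3, stride = 2, out_dim = 8)
  expect_equal(tg2$grid_shape, c(16, 16))
  expect_error(overlap_patch_embed(array(0, c(4, 4, 3)), kernel = 7),
               "smaller than kernel")
})

test_that("zero input with zero bias embeds to zero tokens", {
  p <- patch_embed_params(3, 7, 8, seed = 2)   # biases are zero-initialized
  tg <- overlap_patch_embed(array(0, c(32, 32, 3)), 7, 4, 8, params = p)
  expect_equal(max(abs(tg$tokens)), 0)
})

test_that("sequence reduction follows the reshape-then-project arithmetic", {
  K <- matrix(rnorm(64 * 8), 64, 8)
  red <- reduce_sequence(K, R = 4, seed = 1)
  expect_equal(dim(red), c(16, 8))            # 64x8 -> 16x32 -> 16x8
  big <- reduce_sequence(matrix(rnorm(1024 * 32), 1024, 32), R = 8, seed = 1)
  expect_equal(dim(big), c(128, 32))
  expect_error(reduce_sequence(K, R = 0), "R must be")
})

test_that("sequence reduction at R=1 with an identity map is the identity", {
  K <- matrix(rnorm(20 * 6), 20, 6)
  expect_equal(reduce_sequence(K, R = 1), K)
})

test_that("reduction concatenates R consecutive tokens before projecting", {
  # selector projection picking the first token of each group exposes the
  # reshape ordering demanded by the (N/R, C*R) semantics
  C <- 3; R <- 2; N <- 6
  K <- matrix(seq_len(N * C), N, C)
  W <- rbind(diag(C), matrix(0, C * (R - 1), C))
  red <- reduce_sequence(K, R, W = W, b = numeric(C))
  expect_equal(red, K[seq(1, N, by = R), ])
})

test_that("sequence-reduced attention matches brute force at R=1", {
  set.seed(42)
  for (case in list(c(N = 16, C = 8, heads = 2), c(N = 9, C = 6, heads = 3),
                    c(N = 12, C = 4, heads = 1))) {
    x <- matrix(rnorm(case["N"] * case["C"]), case["N"], case["C"])
    p <- attention_params(case["C"], case["heads"], R = 1, seed = 11)
    got <- efficient_self_attention(x, heads = case["heads"], R = 1, params = p)
    want <- reference_attention(x, p, case["heads"])
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("attention on constant tokens returns constant tokens", {
  x <- matrix(1, 20, 8)
  out <- efficient_self_attention(x, heads = 2, R = 4, seed = 5)
  expect_lt(max(abs(sweep(out, 2, out[1, ]))), 1e-10)
})

test_that("attention weight rows are probability distributions", {
  x <- matrix(rnorm(24 * 8), 24, 8)
  p <- attention_params(8, 2, R = 4, seed = 3)
  cache <- larynxseg:::attention_fwd(x, p, 2, 4)$cache
  for (A in cache$A) {
    expect_true(all(A >= 0))
    expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
  }
})

test_that("attention errors when heads do not divide the channel width", {
  expect_error(efficient_self_attention(matrix(0, 4, 6), heads = 4), "heads")
})

test_that("mix-FFN with zeroed transform weights is the identity", {
  C <- 8; E <- 2
  p <- mix_ffn_params(C, E, seed = 1)
  p <- lapply(p, function(w) w * 0)
  x <- larynxseg:::as_token_grid(matrix(rnorm(16 * C), 16, C), 4, 4)
  out <- mix_ffn(x, expansion = E, params = p)
  expect_identical(out$tokens, x$tokens)
})

test_that("mix-FFN matches the scalar hand computation on a 1x1 grid", {
  # identity linears, centre-tap depth-wise conv: out = gelu(x) + x
  p <- list(W1 = matrix(1, 1, 1), b1 = 0,
            dw = matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 9, 1), bdw = 0,
            W2 = matrix(1, 1, 1), b2 = 0)
  x <- larynxseg:::as_token_grid(matrix(0.7, 1, 1), 1, 1)
  out <- mix_ffn(x, expansion = 1, params = p)
  expect_equal(out$tokens[1, 1], 0.7 * pnorm(0.7) + 0.7, tolerance = 1e-12)
})

test_that("mix-FFN preserves the token-grid shape", {
  x <- larynxseg:::as_token_grid(matrix(rnorm(35 * 6), 35, 6), 5, 7)
  out <- mix_ffn(x, expansion = 2, seed = 2)
  expect_equal(dim(out$tokens), dim(x$tokens))
  expect_equal(out$grid_shape, x$grid_shape)
  expect_error(mix_ffn(x$tokens), "token_grid")
})

test_that("the encoder emits a 4-level pyramid at 1/4 to 1/32 resolution", {
  model <- init_model(micro_model_config(), 1)
  py <- encoder_forward(array(runif(128 * 128 * 3), c(128, 128, 3)), model)
  expect_length(py$levels, 4)
  expect_equal(lapply(py$levels, `[[`, "grid_shape"),
               list(c(32, 32), c(16, 16), c(8, 8), c(4, 4)))
  py64 <- encoder_forward(array(runif(64 * 64 * 3), c(64, 64, 3)), model)
  expect_equal(lapply(py64$levels, `[[`, "grid_shape"),
               list(c(16, 16), c(8, 8), c(4, 4), c(2, 2)))
  expect_error(encoder_forward(array(0, c(16, 16, 3)), model), "32")
})

test_that("stage-1 tokenization translates with the input", {
  p <- patch_embed_params(3, 7, 8, seed = 4)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  shifted <- array(0, c(64, 64, 3))
  shifted[5:64, , ] <- img[1:60, , ]    # shift down by one stage-1 stride
  t1 <- overlap_patch_embed(img, 7, 4, 8, params = p)
  t2 <- overlap_patch_embed(shifted, 7, 4, 8, params = p)
  G1 <- array(t1$tokens, c(16, 16, 8))
  G2 <- array(t2$tokens, c(16, 16, 8))
  # interior rows, away from boundary padding
  expect_equal(G2[3:16, , ], G1[2:15, , ], tolerance = 1e-10)
})

test_that("the decoder returns full-resolution 3-channel logits", {
  model <- init_model(micro_model_config(), 1)
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  lg <- decoder_forward(encoder_forward(img, model), model)
  expect_equal(dim(lg), c(128, 128, 3))
  img2 <- array(runif(256 * 256 * 3), c(256, 256, 3))
  lg2 <- decoder_forward(encoder_forward(img2, model), model)
  expect_equal(dim(lg2), c(256, 256, 3))
})

test_that("a zero pyramid with zero biases yields spatially constant logits", {
  model <- init_model(micro_model_config(), 1)
  dims <- model$config$embed_dims
  py <- structure(list(levels = lapply(1:4, function(i) {
    g <- 16 / 2^(i - 1)
    larynxseg:::as_token_grid(matrix(0, g * g, dims[i]), g, g)
  }), input_size = c(64, 64), padded_size = c(64, 64)),
  class = "feature_pyramid")
  lg <- decoder_forward(py, model)
  for (k in 1:3) expect_lt(diff(range(lg[, , k])), 1e-12)
  bad <- py; bad$levels <- bad$levels[1:3]
  expect_error(decoder_forward(bad, model), "4 levels")
})

test_that("non-multiple-of-32 inputs are padded and logits cropped back", {
  model <- init_model(micro_model_config(), 1)
  img <- array(runif(100 * 72 * 3), c(100, 72, 3))
  lg <- decoder_forward(encoder_forward(img, model), model)
  expect_equal(dim(lg), c(100, 72, 3))
  expect_identical(dim(predict(model, img)), c(100L, 72L))
})

test_that("argmax prediction breaks ties toward the lowest class", {
  lg <- array(0, c(4, 5, 3))
  lg[, , 1] <- 1
  expect_true(all(logits_to_mask(lg) == 0L))
  lg2 <- array(0, c(6, 6, 3))
  lg2[2:4, 3:5, 2] <- 5
  m <- logits_to_mask(lg2)
  expect_true(all(m[2:4, 3:5] == 1L))
  expect_true(all(m[-(2:4), ] == 0L))
  lg3 <- array(0, c(1, 1, 3))
  lg3[1, 1, ] <- c(0, 7, 7)   # exact tie between classes 1 and 2
  expect_equal(as.vector(logits_to_mask(lg3)), 1L)
})

test_that("model configuration validates its architecture constraints", {
  expect_error(model_config(patch_stride = c(2, 2, 2, 2)), "stride 4")
  expect_error(model_config(embed_dims = c(32, 63, 160, 256)), "divisible")
  expect_error(model_config(stage_depths = c(1, 1, 1)), "length 4")
})

test_that("checkpoints round-trip weights and configuration", {
  dir <- withr::local_tempdir()
  m <- init_model(micro_model_config(), 3)
  path <- file.path(dir, "ckpt.rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$params, m$params)
  expect_equal(unclass(m2$config), unclass(m$config))
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict(m, img), predict(m2, img))
})
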