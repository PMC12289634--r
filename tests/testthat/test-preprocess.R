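make_frame <- function(H, W, boxes) {
  f <- array(0, c(H, W, 3))
  for (b in boxes) f[b$r0 + seq_len(b$h), b$c0 + seq_len(b$w), ] <- b$v
  f
}

test_that("crop bounds find the bright content region", {
  f <- make_frame(100, 120, list(list(r0 = 10, c0 = 20, h = 50, w = 60, v = 0.8)))
  b <- compute_crop_bounds(f)
  expect_equal(unclass(b)[c("row0", "col0", "height", "width")],
               list(row0 = 10L, col0 = 20L, height = 50L, width = 60L))
  full <- compute_crop_bounds(array(1, c(40, 50, 3)))
  expect_equal(c(full$row0, full$col0, full$height, full$width),
               c(0, 0, 40, 50))
  expect_error(compute_crop_bounds(array(0, c(32, 32, 3))), "no content")
})

test_that("crop bounds ignore small secondary regions", {
  f <- make_frame(120, 120, list(
    list(r0 = 30, c0 = 30, h = 40, w = 25, v = 0.9),  # 1000 px
    list(r0 = 100, c0 = 5, h = 5, w = 6, v = 0.9)))   # 30 px
  b <- compute_crop_bounds(f)
  expect_equal(c(b$row0, b$col0, b$height, b$width), c(30, 30, 40, 25))
})

test_that("cropping copies pixels without resampling", {
  f <- array(runif(100 * 100 * 3), c(100, 100, 3))
  full <- crop_frame(f, crop_box(0, 0, 100, 100))
  expect_identical(full, f)
  b <- crop_box(25, 25, 50, 50)
  cr <- crop_frame(f, b)
  expect_identical(cr, f[26:75, 26:75, , drop = FALSE])
  expect_identical(crop_frame(cr, crop_box(0, 0, 50, 50)), cr)
  expect_error(crop_frame(f, crop_box(60, 60, 50, 50)), "bounds")
})

test_that("a pure horizontal flip is an involution on image and mask", {
  s <- render_sample(sample_scene_params(5, 0.3, c(64, 64)))
  cfg <- augment_config(crop_scale_range = c(1, 1), flip_probability = 1,
                        rotation_range_deg = 0)
  f1 <- augment_sample(s, cfg, 1)
  expect_identical(f1$mask, s$mask[, ncol(s$mask):1])
  f2 <- augment_sample(f1, cfg, 2)
  expect_equal(f2$image, s$image, tolerance = 1e-12)
  expect_identical(f2$mask, s$mask)
})

test_that("the identity augmentation configuration is the identity", {
  s <- render_sample(sample_scene_params(5, 0.3, c(64, 64)))
  cfg <- augment_config(crop_scale_range = c(1, 1), flip_probability = 0,
                        rotation_range_deg = 0)
  a <- augment_sample(s, cfg, 3)
  expect_equal(a$image, s$image, tolerance = 1e-12)
  expect_identical(a$mask, s$mask)
})

test_that("augmentation never invents labels and keeps shapes paired", {
  s <- render_sample(sample_scene_params(11, 0.5, c(64, 64)))
  cfg <- augment_config(output_size = c(48, 56))
  for (seed in 1:10) {
    a <- augment_sample(s, cfg, seed)
    expect_identical(dim(a$mask), c(48L, 56L))
    expect_identical(dim(a$image)[1:2], c(48L, 56L))
    expect_true(all(a$mask %in% unique(as.vector(s$mask))))
    expect_true(all(a$mask == round(a$mask)))
  }
  # identical seeds give identical transforms
  expect_identical(augment_sample(s, cfg, 4), augment_sample(s, cfg, 4))
})

test_that("augmentation preserves the image/mask geometric pairing", {
  # binary scene: mask equals thresholding of the image; the relation must
  # survive the joint transform up to resampling at the boundary
  img <- array(0, c(64, 64, 3))
  img[20:45, 15:40, ] <- 1
  s <- structure(list(image = img, mask = matrix(0L, 64, 64)),
                 class = "larynx_sample")
  s$mask[20:45, 15:40] <- 1L
  cfg <- augment_config(crop_scale_range = c(0.7, 0.9))
  for (seed in 1:5) {
    a <- augment_sample(s, cfg, seed)
    thresh <- (a$image[, , 1] > 0.5) * 1L
    expect_lt(mean(thresh != a$mask), 0.05)
  }
})

test_that("split sizes follow floor-on-val/test with remainder to train", {
  sp <- split_dataset(seq_len(340), split_fractions(0.7, 0.2, 0.1), 1)
  expect_equal(lengths(sp), c(train = 238L, val = 68L, test = 34L))
  sp10 <- split_dataset(seq_len(10), split_fractions(0.7, 0.2, 0.1), 1)
  expect_equal(lengths(sp10), c(train = 7L, val = 2L, test = 1L))
  expect_error(split_dataset(1:10, c(0.7, 0.2, 0.2), 1), "sum to 1")
})

test_that("splits partition the ids and are reproducible by seed", {
  for (n in c(3, 17, 101)) {
    ids <- sprintf("img%03d", seq_len(n))
    sp <- split_dataset(ids, split_fractions(0.7, 0.2, 0.1), 5)
    all_ids <- c(sp$train, sp$val, sp$test)
    expect_setequal(all_ids, ids)
    expect_equal(length(all_ids), n)   # pairwise disjoint given the setequal
  }
  a <- split_dataset(1:50, seed = 9); b <- split_dataset(1:50, seed = 9)
  expect_identical(a, b)
  c_ <- split_dataset(1:50, seed = 10)
  expect_false(identical(a, c_))
})

test_that("PCA projection maps identical inputs to coincident points", {
  img <- render_sample(sample_scene_params(1, 0, c(64, 64)))$image
  pts <- project_embeddings(list(img, img, img), "pca")
  expect_equal(dim(pts), c(3, 2))
  expect_lt(max(dist(pts)), 1e-8)
  imgs <- lapply(1:4, function(i)
    render_sample(sample_scene_params(i, 0.4, c(64, 64)))$image)
  dup <- project_embeddings(c(imgs, imgs), "pca")
  expect_equal(dup[1:4, ], dup[5:8, ], tolerance = 1e-8)
  expect_error(project_embeddings(imgs[1:2], "pca"), "at least 3")
})

test_that("augmented samples overlap the original distribution in 2-D", {
  orig <- generate_dataset(12, 3, c(0, 0.5, 0.9), c(64, 64))
  cfg <- augment_config(crop_scale_range = c(1, 1), flip_probability = 1,
                        rotation_range_deg = 0)
  aug <- lapply(seq_along(orig), function(i) augment_sample(orig[[i]], cfg, i))
  imgs <- c(lapply(orig, `[[`, "image"), lapply(aug, `[[`, "image"))
  for (method in c("pca", "tsne")) {
    pts <- project_embeddings(imgs, method, rng_seed = 1)
    g1 <- pts[1:12, , drop = FALSE]; g2 <- pts[13:24, , drop = FALSE]
    centroid_dist <- sqrt(sum((colMeans(g1) - colMeans(g2))^2))
    spread <- mean(c(sqrt(rowSums(sweep(g1, 2, colMeans(g1))^2)),
                     sqrt(rowSums(sweep(g2, 2, colMeans(g2))^2))))
    expect_lt(centroid_dist, 2 * spread)
  }
})
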