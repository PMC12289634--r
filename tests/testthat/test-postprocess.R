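test_that("outlier removal keeps only the dominant structure", {
  m <- matrix(0L, 40, 40)
  m[5:29, 5:24] <- 1L                 # 500 px component
  m[35:37, 35:36] <- 1L               # 6 px stray blob
  out <- remove_outliers(m, 1L)
  expect_equal(sum(out == 1L), 500)
  expect_true(all(out[35:37, 35:36] == 0L))
  # single component and absent class are identities
  single <- matrix(0L, 20, 20); single[3:10, 3:10] <- 1L
  expect_identical(remove_outliers(single, 1L), single)
  expect_identical(remove_outliers(single, 2L), single)
})

test_that("outlier removal respects 8-connectivity", {
  m <- matrix(0L, 12, 12)
  m[2:4, 2:4] <- 1L
  m[5, 5] <- 1L        # diagonal touch: same 8-connected component
  m[9:10, 9:10] <- 1L  # separate smaller blob
  out <- remove_outliers(m, 1L)
  expect_equal(out[5, 5], 1L)
  expect_true(all(out[9:10, 9:10] == 0L))
})

test_that("the min-area-ratio policy keeps comparable components", {
  m <- matrix(0L, 40, 40)
  m[2:11, 2:11] <- 1L     # 100 px
  m[20:27, 20:27] <- 1L   # 64 px
  m[35, 35] <- 1L         # 1 px
  cfg <- post_config(keep_policy = "min_area_ratio", min_area_ratio = 0.5)
  out <- remove_outliers(m, 1L, cfg)
  expect_equal(sum(out == 1L), 164)
})

test_that("gap filling closes enclosed holes only", {
  m <- matrix(0L, 20, 20)
  m[5:14, 5:14] <- 1L
  m[8:10, 8:10] <- 0L      # 3x3 interior hole
  out <- fill_gaps(m, 1L)
  expect_equal(sum(out == 1L), 100)
  expect_equal(sum(out == 1L) - sum(m == 1L), 9)
  # simply connected component is untouched
  s <- matrix(0L, 10, 10); s[2:6, 2:6] <- 1L
  expect_identical(fill_gaps(s, 1L), s)
})

test_that("holes open to the border through a channel are not filled", {
  m <- matrix(0L, 20, 20)
  m[5:14, 5:14] <- 1L
  m[8:10, 8:10] <- 0L
  m[9, 1:7] <- 0L          # channel from the hole to the border
  out <- fill_gaps(m, 1L)
  expect_equal(out[9, 9], 0L)
})

test_that("holes bordered by another class are not claimed", {
  m <- matrix(0L, 20, 20)
  m[5:14, 5:14] <- 1L
  m[8:10, 8:10] <- 0L
  m[9, 9] <- 2L            # foreign class inside the cavity
  out <- fill_gaps(m, 1L)
  expect_equal(out[8, 8], 0L)   # ring now touches class 2, not enclosed by 1
})

test_that("boundary smoothing removes spikes and respects radius 0", {
  m <- matrix(0L, 30, 30)
  m[10:20, 5:25] <- 1L
  expect_identical(smooth_boundaries(m, 1L, 0), m)
  spiky <- m; spiky[9, 15] <- 1L    # single-pixel spike on a straight edge
  sm <- smooth_boundaries(spiky, 1L, 2)
  expect_equal(sm[9, 15], 0L)
  expect_true(all(sm[12:18, 8:22] == 1L))   # interior intact
})

test_that("an already-smooth disc survives smoothing", {
  q <- larynxseg:::ellipse_q(60, 60, c(30, 30), c(20, 20), 0)
  m <- matrix(0L, 60, 60); m[q <= 1] <- 1L
  sm <- smooth_boundaries(m, 1L, 2)
  expect_lt(mean(sm != m), 0.005)
})

test_that("post-processing a clean synthetic mask barely changes it", {
  for (seed in c(1, 6)) {
    m <- render_sample(sample_scene_params(seed, 0.3, c(128, 128)))$mask
    out <- postprocess_mask(m)
    expect_lt(sum(out != m), 0.02 * sum(m > 0))
  }
})

test_that("the full pipeline is idempotent", {
  for (seed in c(3, 8, 15)) {
    m <- corrupt_mask(render_sample(
      sample_scene_params(seed, 0.4, c(96, 96)))$mask, seed)
    p1 <- postprocess_mask(m)
    p2 <- postprocess_mask(p1)
    expect_identical(p2, p1)
  }
})

test_that("post-processing yields one hole-free component per class", {
  for (seed in c(2, 7, 12)) {
    m <- corrupt_mask(render_sample(
      sample_scene_params(seed, 0.2, c(96, 96)))$mask, seed)
    out <- postprocess_mask(m)
    for (cls in 1:2) {
      expect_equal(n_components(out == cls, 8), 1)
      # no enclosed background holes: interior background components = 0
      bg <- flood_label(out == 0L, 4)
      border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
      expect_length(setdiff(unique(as.vector(bg)), c(0L, border)), 0)
    }
    expect_true(all(out %in% c(0L, unique(as.vector(m)))))
  }
})

test_that("post-processing commutes with horizontal flips", {
  fl <- function(m) m[, ncol(m):1]
  for (seed in c(4, 9)) {
    m <- corrupt_mask(render_sample(
      sample_scene_params(seed, 0.5, c(96, 96)))$mask, seed)
    expect_identical(postprocess_mask(fl(m)), fl(postprocess_mask(m)))
  }
})

test_that("post-processing never erases a class present in the input", {
  # severe obstruction: trachea is a sliver thinner than the brush
  m <- render_sample(sample_scene_params(5, 1.0, c(96, 96)))$mask
  expect_gt(sum(m == 1L), 0)
  out <- postprocess_mask(m)
  expect_gt(sum(out == 1L), 0)
})

test_that("smoothing overlaps are resolved by class priority", {
  m <- matrix(0L, 40, 40)
  m[10:30, 10:19] <- 1L
  m[10:30, 20:29] <- 2L
  out <- postprocess_mask(m, post_config(smooth_radius = 3,
                                         class_priority = c(1L, 2L)))
  expect_true(all(out[12:28, 12:17] == 1L))
  expect_true(all(out[12:28, 22:27] == 2L))
  expect_true(all(out %in% 0:2))
})
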