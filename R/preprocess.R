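#' Pre-processing
#'
#' Crop-boundary detection on raw frames (the recorded laryngoscope
#' content area against a black screen-recording background), paired
#' image/mask augmentation, 2-D embedding projections for augmentation
#' sanity checks, and train/val/test splitting.
#'
#' @name preprocess
NULL

#' Crop box
#'
#' Half-open pixel box `[row0, row0+height) x [col0, col0+width)`, 0-based.
#'
#' @param row0,col0 top-left corner (0-based).
#' @param height,width box extent, each >= 1.
#' @return a `crop_box` list.
#' @export
crop_box <- function(row0, col0, height, width) {
  if (height < 1 || width < 1) stopf("crop box must have positive extent")
  if (row0 < 0 || col0 < 0) stopf("crop box origin must be non-negative")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "crop_box")
}

#' Detect the content crop box of a raw frame
#'
#' Thresholds luminance at `threshold`, labels 8-connected bright regions,
#' and returns the bounding box of the largest one.
#'
#' @param frame H x W x 3 array in [0, 1] (a matrix is used as-is).
#' @param threshold luminance threshold; default 10/255.
#' @return a [crop_box()].
#' @export
compute_crop_bounds <- function(frame, threshold = 10 / 255) {
  lum <- if (is.matrix(frame)) frame
         else 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  bright <- lum > threshold
  if (!any(bright)) stopf("no content region: no pixel above threshold")
  lab <- label_components(bright, 8)
  big <- which.max(component_areas(lab))
  idx <- which(lab == big, arr.ind = TRUE)
  r <- range(idx[, 1]); c <- range(idx[, 2])
  crop_box(r[1] - 1L, c[1] - 1L, r[2] - r[1] + 1L, c[2] - c[1] + 1L)
}

#' Crop a frame
#'
#' Copies the pixels inside the box; no resampling.
#'
#' @param frame H x W x C array or H x W matrix.
#' @param box a [crop_box()].
#' @return image of exactly (height, width) spatial size.
#' @export
crop_frame <- function(frame, box) {
  H <- dim(frame)[1]; W <- dim(frame)[2]
  if (box$row0 + box$height > H || box$col0 + box$width > W)
    stopf("crop box exceeds frame bounds")
  rows <- box$row0 + seq_len(box$height)
  cols <- box$col0 + seq_len(box$width)
  if (is.matrix(frame)) frame[rows, cols, drop = FALSE]
  else frame[rows, cols, , drop = FALSE]
}

#' Augmentation configuration
#'
#' Random resized crops, horizontal flips and random rotation, applied
#' identically to image and mask.
#'
#' @param crop_scale_range (low, high) area fraction of the random crop,
#'   0 < low <= high <= 1.
#' @param flip_probability probability of a horizontal flip.
#' @param rotation_range_deg symmetric rotation range (-r, r), degrees.
#' @param output_size (height, width) of the augmented output; NULL keeps
#'   the input size.
#' @return an `augment_config` list.
#' @export
augment_config <- function(crop_scale_range = c(0.6, 1.0),
                           flip_probability = 0.5,
                           rotation_range_deg = 15,
                           output_size = NULL) {
  lo <- crop_scale_range[1]; hi <- crop_scale_range[2]
  if (!(lo > 0 && lo <= hi && hi <= 1))
    stopf("crop_scale_range must satisfy 0 < low <= high <= 1")
  if (flip_probability < 0 || flip_probability > 1)
    stopf("flip_probability must lie in [0, 1]")
  structure(list(crop_scale_range = c(lo, hi),
                 flip_probability = flip_probability,
                 rotation_range_deg = abs(rotation_range_deg),
                 output_size = output_size),
            class = "augment_config")
}

# Inverse-mapping resampler. For every output pixel centre, the affine map
# (flip, scale-to-crop-window, rotation about the window centre) yields a
# source coordinate; images are sampled bilinearly, masks nearest-neighbor.
# Out-of-bounds source pixels read as `fill` (background for masks).
resample_geom <- function(img, mask, out_size, win, angle_deg, flip) {
  H <- dim(mask)[1]; W <- dim(mask)[2]
  Ho <- out_size[1]; Wo <- out_size[2]
  ro <- matrix(seq_len(Ho) - 0.5, Ho, Wo)
  co <- matrix(rep(seq_len(Wo) - 0.5, each = Ho), Ho, Wo)
  if (flip) co <- Wo - co
  # map output to crop-window coordinates
  sr <- win$r0 + ro * win$h / Ho
  sc <- win$c0 + co * win$w / Wo
  # rotate about the window centre
  if (angle_deg != 0) {
    th <- angle_deg * pi / 180
    cr <- win$r0 + win$h / 2; cc <- win$c0 + win$w / 2
    dr <- sr - cr; dc <- sc - cc
    sr <- cr + cos(th) * dr - sin(th) * dc
    sc <- cc + sin(th) * dr + cos(th) * dc
  }
  # nearest-neighbor sampling for the mask
  ri <- ceiling(sr); ci <- ceiling(sc)
  inb <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  m_out <- matrix(0L, Ho, Wo)
  m_out[inb] <- mask[cbind(ri[inb], ci[inb])]
  # bilinear sampling for the image
  r0 <- floor(sr - 0.5); c0 <- floor(sc - 0.5)     # 0-based upper-left pixel
  fr <- (sr - 0.5) - r0; fc <- (sc - 0.5) - c0
  i_out <- array(0, c(Ho, Wo, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    plane <- img[, , ch]
    gv <- function(r0b, c0b) {
      ok <- r0b >= 0 & r0b <= H - 1 & c0b >= 0 & c0b <= W - 1
      v <- matrix(0, Ho, Wo)
      v[ok] <- plane[cbind(r0b[ok] + 1, c0b[ok] + 1)]
      v
    }
    i_out[, , ch] <- gv(r0, c0) * (1 - fr) * (1 - fc) +
      gv(r0 + 1, c0) * fr * (1 - fc) +
      gv(r0, c0 + 1) * (1 - fr) * fc +
      gv(r0 + 1, c0 + 1) * fr * fc
  }
  list(image = i_out, mask = m_out)
}

#' Augment a sample
#'
#' Applies one random geometric transform — resized crop, horizontal flip,
#' rotation — identically to image (bilinear) and mask (nearest-neighbor,
#' so no fractional labels arise). Regions rotated in from outside the
#' frame are filled with background. Randomness is fully determined by
#' `rng_seed`.
#'
#' @param sample a `larynx_sample`.
#' @param config an [augment_config()].
#' @param rng_seed integer seed.
#' @return the augmented `larynx_sample` (params dropped).
#' @export
augment_sample <- function(sample, config = augment_config(), rng_seed = 1) {
  img <- sample$image; mask <- sample$mask
  H <- nrow(mask); W <- ncol(mask)
  out_size <- if (is.null(config$output_size)) c(H, W) else config$output_size
  with_seed(rng_seed, {
    scale <- runif(1, config$crop_scale_range[1], config$crop_scale_range[2])
    # aspect jitter only when the crop is actually random; a degenerate
    # (1, 1) range must reproduce the input window exactly
    aspect <- if (config$crop_scale_range[2] < 1 || config$crop_scale_range[1] < 1)
      exp(runif(1, log(3 / 4), log(4 / 3))) else 1
    ch_ <- sqrt(scale / aspect) * H
    cw_ <- sqrt(scale * aspect) * W
    ch_ <- min(ch_, H); cw_ <- min(cw_, W)
    if (ch_ < 1 || cw_ < 1) stopf("degenerate crop window")
    r0 <- runif(1, 0, H - ch_); c0 <- runif(1, 0, W - cw_)
    flip <- runif(1) < config$flip_probability
    angle <- if (config$rotation_range_deg > 0)
      runif(1, -config$rotation_range_deg, config$rotation_range_deg) else 0
    res <- resample_geom(img, mask, out_size,
                         list(r0 = r0, c0 = c0, h = ch_, w = cw_), angle, flip)
    structure(list(image = res$image, mask = res$mask, params = NULL),
              class = "larynx_sample")
  })
}

#' Double a dataset by augmentation
#'
#' Emits the originals plus exactly one augmented copy per original.
#'
#' @param samples list of `larynx_sample`.
#' @param config an [augment_config()].
#' @param seed master seed; copy i uses a seed derived from (seed, i).
#' @return list of length `2 * length(samples)`; augmented copies follow
#'   the originals.
#' @export
augment_dataset <- function(samples, config = augment_config(), seed = 1) {
  aug <- lapply(seq_along(samples), function(i)
    augment_sample(samples[[i]], config, derive_seed(seed, i)))
  c(samples, aug)
}

#' Split fractions
#'
#' @param train,val,test non-negative fractions summing to 1 (tolerance
#'   1e-9).
#' @return a `split_fractions` list.
#' @export
split_fractions <- function(train = 0.7, val = 0.2, test = 0.1) {
  if (train < 0 || val < 0 || test < 0)
    stopf("fractions must be non-negative")
  if (abs(train + val + test - 1) > 1e-9)
    stopf("fractions must sum to 1, got %g", train + val + test)
  structure(list(train = train, val = val, test = test),
            class = "split_fractions")
}

#' Split identifiers into train/val/test
#'
#' Shuffles by `seed`, then assigns `floor(val * n)` to validation and
#' `floor(test * n)` to test; the remainder goes to training so no sample
#' is lost to rounding.
#'
#' @param ids vector of sample identifiers, length >= 3.
#' @param fractions a [split_fractions()].
#' @param seed shuffle seed.
#' @return list of disjoint `train`, `val`, `test` id vectors covering
#'   `ids`.
#' @export
split_dataset <- function(ids, fractions = split_fractions(), seed = 1) {
  if (!inherits(fractions, "split_fractions"))
    fractions <- do.call(split_fractions, as.list(fractions))
  n <- length(ids)
  if (n < 3) stopf("need at least 3 ids to split")
  n_val <- floor(fractions$val * n)
  n_test <- floor(fractions$test * n)
  perm <- with_seed(seed, sample(n))
  shuffled <- ids[perm]
  val <- shuffled[seq_len(n_val)]
  test <- if (n_test > 0) shuffled[n_val + seq_len(n_test)] else ids[0]
  train <- shuffled[setdiff(seq_len(n), seq_len(n_val + n_test))]
  list(train = train, val = val, test = test)
}

# --- embedding projections -------------------------------------------------

# flattened 32x32 grayscale pixel vector per image
embed_vectors <- function(images) {
  t(vapply(images, function(im) {
    g <- if (length(dim(im)) == 3)
      0.299 * im[, , 1] + 0.587 * im[, , 2] + 0.114 * im[, , 3] else im
    as.vector(upsample_bilinear(array(g, c(dim(g), 1)), 32, 32))
  }, numeric(32 * 32)))
}

# compact exact t-SNE (no tree approximation); adequate for the small
# image sets used in augmentation overlap checks
tsne_embed <- function(X, perplexity = NULL, n_iter = 300, seed = 1) {
  n <- nrow(X)
  if (is.null(perplexity)) perplexity <- max(2, min(30, floor((n - 1) / 3)))
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- 0; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { beta <- beta / 2; next }
      p <- p / sp
      Hent <- -sum(ifelse(p > 0, p * log(p), 0))
      if (abs(Hent - log(perplexity)) < 1e-5) break
      if (Hent > log(perplexity)) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
    for (it in seq_len(n_iter)) {
      mom <- if (it < 100) 0.5 else 0.8
      Pex <- if (it < 100) P * 4 else P     # early exaggeration
      sumY <- rowSums(Y * Y)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pex - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
      gain <- pmax(gain, 0.01)
      inc <- mom * inc - 200 * gain * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Project images to 2-D embeddings
#'
#' Flattens each image to a 32 x 32 grayscale pixel vector and projects
#' the set to two dimensions, for visual checks that augmented data
#' overlaps the original distribution. The PCA path is deterministic up to
#' axis sign; t-SNE is seeded.
#'
#' @param images list of image arrays (equal sizes), length >= 3.
#' @param method `"pca"` or `"tsne"`.
#' @param rng_seed seed for the t-SNE path.
#' @return n x 2 matrix of points, one row per image.
#' @export
project_embeddings <- function(images, method = c("pca", "tsne"),
                               rng_seed = 1) {
  method <- match.arg(method)
  if (length(images) < 3) stopf("need at least 3 images")
  X <- embed_vectors(images)
  if (method == "pca") {
    pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
    Y <- pc$x
    if (ncol(Y) < 2) Y <- cbind(Y, matrix(0, nrow(Y), 2 - ncol(Y)))
    unname(Y[, 1:2, drop = FALSE])
  } else {
    tsne_embed(X, seed = rng_seed)
  }
}
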