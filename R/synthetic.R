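#' Synthetic laryngeal scene generator
#'
#' Seeded generator of laryngeal-like endoscopy frames with exact ground
#' truth. Each scene is a dark elliptical airway opening (trachea, class 1)
#' nested inside an annular mucosal region (supraglottis, class 2) on a
#' textured mid-tone background (class 0). Airway narrowing is controlled by
#' an `obstruction` parameter in [0, 1] which shrinks the trachea minor axis,
#' emulating increasing glottic/supraglottic obstruction severity.
#'
#' @name synthetic
NULL

#' Construct scene parameters
#'
#' Low-level constructor; validates the geometric invariants. Most users
#' want [sample_scene_params()].
#'
#' @param image_size integer (height, width) in pixels, each >= 32.
#' @param trachea_center (row, col) of the shared ellipse centre, pixels.
#' @param trachea_axes (semi-major, semi-minor) of the airway ellipse, px.
#'   The minor axis is stored *after* obstruction scaling.
#' @param trachea_angle rotation of both ellipses, degrees.
#' @param supraglottis_outer_axes (semi-major, semi-minor) of the outer
#'   mucosal ellipse, px.
#' @param obstruction airway narrowing severity in [0, 1].
#' @param illumination global brightness scale in (0, 1].
#' @param noise_sigma additive Gaussian noise sd on [0, 1] intensities.
#' @param seed integer driving texture and noise.
#' @return A `scene_params` object.
#' @export
scene_params <- function(image_size, trachea_center, trachea_axes,
                         trachea_angle, supraglottis_outer_axes,
                         obstruction, illumination, noise_sigma, seed) {
  if (length(image_size) != 2 || any(image_size < 32))
    stopf("image_size must be (height, width) with both >= 32")
  if (obstruction < 0 || obstruction > 1)
    stopf("obstruction must lie in [0, 1], got %g", obstruction)
  if (illumination <= 0 || illumination > 1)
    stopf("illumination must lie in (0, 1]")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (any(trachea_axes <= 0) || any(supraglottis_outer_axes <= 0))
    stopf("ellipse semi-axes must be positive")
  if (trachea_axes[1] >= supraglottis_outer_axes[1] ||
      trachea_axes[2] >= supraglottis_outer_axes[2])
    stopf("trachea ellipse must lie strictly inside the supraglottis ellipse")
  # outer ellipse inside image bounds: bound by the enclosing circle
  r <- max(supraglottis_outer_axes)
  if (trachea_center[1] - r < 0 || trachea_center[1] + r > image_size[1] ||
      trachea_center[2] - r < 0 || trachea_center[2] + r > image_size[2])
    stopf("supraglottis ellipse exceeds image bounds")
  structure(list(
    image_size = as.integer(image_size),
    trachea_center = as.numeric(trachea_center),
    trachea_axes = as.numeric(trachea_axes),
    trachea_angle = as.numeric(trachea_angle),
    supraglottis_outer_axes = as.numeric(supraglottis_outer_axes),
    obstruction = as.numeric(obstruction),
    illumination = as.numeric(illumination),
    noise_sigma = as.numeric(noise_sigma),
    seed = as.integer(seed)
  ), class = "scene_params")
}

#' Sample random scene parameters
#'
#' Draws a random laryngeal scene geometry at a given obstruction severity.
#' All randomness is a pure function of `rng_seed`; the caller's RNG state
#' is untouched. The trachea minor axis scales as `1 - 0.95 * obstruction`
#' so the airway stays non-empty even at full obstruction, keeping
#' per-class metrics defined.
#'
#' @param rng_seed integer seed.
#' @param obstruction airway narrowing in [0, 1].
#' @param image_size (height, width), default 128 x 128.
#' @param angle_range degrees, range of the shared ellipse rotation.
#' @param illum_range range of the global illumination scale.
#' @param noise_range range of the Gaussian noise sd.
#' @param center_jitter centre offset as a fraction of image size.
#' @return A [scene_params()] object.
#' @export
sample_scene_params <- function(rng_seed, obstruction,
                                image_size = c(128L, 128L),
                                angle_range = c(-45, 45),
                                illum_range = c(0.7, 1.0),
                                noise_range = c(0.01, 0.03),
                                center_jitter = 0.04) {
  if (obstruction < 0 || obstruction > 1)
    stopf("obstruction must lie in [0, 1], got %g", obstruction)
  if (length(image_size) != 2 || any(image_size < 32))
    stopf("image_size must be (height, width) with both >= 32")
  H <- image_size[1]; W <- image_size[2]
  with_seed(rng_seed, {
    cr <- H / 2 + runif(1, -center_jitter, center_jitter) * H
    cc <- W / 2 + runif(1, -center_jitter, center_jitter) * W
    max_r <- min(cr, H - cr, cc, W - cc) - 2
    a_out <- runif(1, 0.68, 0.88) * max_r
    b_out <- runif(1, 0.70, 0.95) * a_out
    angle <- runif(1, angle_range[1], angle_range[2])
    a_t <- runif(1, 0.42, 0.58) * a_out
    b_t <- runif(1, 0.45, 0.70) * b_out * (1 - 0.95 * obstruction)
    scene_params(
      image_size = c(H, W),
      trachea_center = c(cr, cc),
      trachea_axes = c(a_t, b_t),
      trachea_angle = angle,
      supraglottis_outer_axes = c(a_out, b_out),
      obstruction = obstruction,
      illumination = runif(1, illum_range[1], illum_range[2]),
      noise_sigma = runif(1, noise_range[1], noise_range[2]),
      seed = derive_seed(rng_seed, 977L)
    )
  })
}

# Squared normalized ellipse coordinate for every pixel; <= 1 is inside.
ellipse_q <- function(H, W, center, axes, angle_deg) {
  th <- angle_deg * pi / 180
  rr <- matrix(seq_len(H) - 0.5, H, W) - center[1]
  cc <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - center[2]
  u <- cc * cos(th) + rr * sin(th)
  v <- -cc * sin(th) + rr * cos(th)
  (u / axes[1])^2 + (v / axes[2])^2
}

#' Render a synthetic laryngeal sample
#'
#' Deterministically renders image and ground-truth mask from scene
#' parameters: identical parameters always give bit-identical pixels.
#' The mask labels the trachea ellipse interior 1, the supraglottis
#' annulus 2 and everything else 0. The image shades the annulus as
#' bright reddish mucosa, the airway dark, and the background mid-tone
#' with a smooth texture; intensities are scaled by `illumination`,
#' perturbed by Gaussian noise of sd `noise_sigma`, and clipped to [0, 1].
#'
#' @param params a [scene_params()] object.
#' @return A `larynx_sample`: list with `image` (H x W x 3 array in [0,1]),
#'   `mask` (H x W integer matrix, values 0/1/2) and `params`.
#' @export
render_sample <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  H <- params$image_size[1]; W <- params$image_size[2]
  qt <- ellipse_q(H, W, params$trachea_center, params$trachea_axes,
                  params$trachea_angle)
  qs <- ellipse_q(H, W, params$trachea_center, params$supraglottis_outer_axes,
                  params$trachea_angle)
  mask <- matrix(0L, H, W)
  mask[qs <= 1] <- 2L
  mask[qt <= 1] <- 1L

  img <- with_seed(params$seed, {
    f1 <- sample(2:5, 1); f2 <- sample(2:5, 1)
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    rr <- matrix(seq_len(H), H, W); cc <- matrix(rep(seq_len(W), each = H), H, W)
    tex <- 0.5 * sin(2 * pi * (f1 * rr / H + f2 * cc / W) + ph1) +
           0.5 * sin(2 * pi * (f2 * rr / H - f1 * cc / W) + ph2)
    tex <- tex / 2  # in [-0.5, 0.5]

    base <- c(0.46, 0.38, 0.40)   # background mucosal mid-tone
    sup  <- c(0.80, 0.38, 0.35)   # supraglottis: bright reddish
    tra  <- c(0.09, 0.05, 0.06)   # trachea: dark airway
    shade_s <- 1 - 0.30 * clamp(qs, 0, 1)   # brighter toward the rim centre
    shade_t <- 0.5 + 0.5 * clamp(qt, 0, 1)  # darkest at the airway centre
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- base[ch] + 0.16 * tex
      plane[mask == 2L] <- (sup[ch] * shade_s + 0.10 * tex)[mask == 2L]
      plane[mask == 1L] <- (tra[ch] * shade_t + 0.02 * tex)[mask == 1L]
      img[, , ch] <- plane
    }
    img <- img * params$illumination
    if (params$noise_sigma > 0)
      img <- img + rnorm(length(img), 0, params$noise_sigma)
    clamp(img, 0, 1)
  })
  structure(list(image = img, mask = mask, params = params),
            class = "larynx_sample")
}

#' Generate a synthetic dataset
#'
#' Generates `n` samples whose obstruction severities cycle through
#' `obstruction_mix` (by default the three strata: open, mild, severe).
#' Fully reproducible from `seed`.
#'
#' @param n number of samples, >= 1.
#' @param seed integer master seed.
#' @param obstruction_mix obstruction values cycled over samples.
#' @param image_size (height, width) of every sample.
#' @param ... further arguments passed to [sample_scene_params()]
#'   (e.g. `illum_range`, `angle_range`) to shift the scene distribution.
#' @return list of `larynx_sample` objects.
#' @export
generate_dataset <- function(n, seed, obstruction_mix = c(0, 0.5, 0.9),
                             image_size = c(128L, 128L), ...) {
  if (!is_count(n) || n < 1) stopf("n must be an integer >= 1")
  if (length(obstruction_mix) < 1 ||
      any(obstruction_mix < 0 | obstruction_mix > 1))
    stopf("obstruction_mix must be non-empty with values in [0, 1]")
  lapply(seq_len(n), function(i) {
    ob <- obstruction_mix[((i - 1) %% length(obstruction_mix)) + 1]
    p <- sample_scene_params(derive_seed(seed, i), ob, image_size, ...)
    render_sample(p)
  })
}

#' Write samples to disk
#'
#' Writes each sample as `<stem>.png` (8-bit RGB) and `<stem>_mask.png`
#' (8-bit single channel with raw class indices 0/1/2), plus a
#' `manifest.csv` with columns stem, obstruction, seed.
#'
#' @param samples list of `larynx_sample`.
#' @param dir output directory (created if missing).
#' @param stems file stems; default `sample_0001`, ...
#' @return invisibly, the manifest data frame.
#' @export
write_samples <- function(samples, dir, stems = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stems)) stems <- sprintf("sample_%04d", seq_along(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    png::writePNG(s$image, file.path(dir, paste0(stems[i], ".png")))
    png::writePNG(s$mask / 255, file.path(dir, paste0(stems[i], "_mask.png")))
  }
  manifest <- data.frame(
    stem = stems,
    obstruction = vapply(samples, function(s)
      if (is.null(s$params)) NA_real_ else s$params$obstruction, numeric(1)),
    seed = vapply(samples, function(s)
      if (is.null(s$params)) NA_integer_ else s$params$seed, integer(1))
  )
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a sample written by [write_samples()]
#'
#' @param dir directory holding the files.
#' @param stem file stem.
#' @return a `larynx_sample` (with `params = NULL`).
#' @export
read_sample <- function(dir, stem) {
  img <- png::readPNG(file.path(dir, paste0(stem, ".png")))
  m <- png::readPNG(file.path(dir, paste0(stem, "_mask.png")))
  if (length(dim(m)) == 3) m <- m[, , 1]
  mask <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  structure(list(image = img, mask = mask, params = NULL),
            class = "larynx_sample")
}
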