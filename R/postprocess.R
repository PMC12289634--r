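#' Mask post-processing
#'
#' Deterministic refinement of predicted class-indexed masks in three steps
#' per class: outlier removal (drop all but the dominant connected
#' structure), gap filling (relabel enclosed background holes), and
#' boundary smoothing (morphological opening then closing with a disc).
#' The steps serve visual quality; they are designed to be neutral with
#' respect to segmentation metrics on reasonable predictions.
#'
#' @name postprocess
NULL

#' Post-processing configuration
#'
#' @param keep_policy `"largest_only"` keeps only the largest 8-connected
#'   component per class; `"min_area_ratio"` keeps every component whose
#'   area is at least `min_area_ratio` times the largest.
#' @param min_area_ratio area ratio threshold in (0, 1], used by the
#'   `"min_area_ratio"` policy.
#' @param smooth_radius disc radius in pixels at the 128 px reference
#'   scale; [postprocess_mask()] rescales it proportionally to the mask's
#'   shorter side. 0 disables smoothing.
#' @param class_priority classes in decreasing priority; when smoothing
#'   makes two classes claim the same pixel, the earlier class wins.
#' @return a `post_config` list.
#' @export
post_config <- function(keep_policy = c("largest_only", "min_area_ratio"),
                        min_area_ratio = 0.25, smooth_radius = 2,
                        class_priority = c(1L, 2L)) {
  keep_policy <- match.arg(keep_policy)
  if (smooth_radius < 0) stopf("smooth_radius must be >= 0")
  if (min_area_ratio <= 0 || min_area_ratio > 1)
    stopf("min_area_ratio must lie in (0, 1]")
  structure(list(keep_policy = keep_policy, min_area_ratio = min_area_ratio,
                 smooth_radius = smooth_radius,
                 class_priority = as.integer(class_priority)),
            class = "post_config")
}

#' Remove outlying components of one class
#'
#' Among 8-connected components of class `cls`, keeps the largest (or,
#' under the `min_area_ratio` policy, all components of comparable size);
#' removed pixels become background. Other classes are untouched. A mask
#' lacking the class is returned unchanged.
#'
#' @param mask H x W integer matrix of class indices.
#' @param cls class label to clean.
#' @param config a [post_config()].
#' @return the cleaned mask.
#' @export
remove_outliers <- function(mask, cls, config = post_config()) {
  bin <- mask == cls
  if (!any(bin)) return(mask)
  lab <- label_components(bin, 8)
  areas <- component_areas(lab)
  keep <- if (config$keep_policy == "largest_only") which.max(areas)
          else which(areas >= config$min_area_ratio * max(areas))
  drop <- bin & !(lab %in% keep)
  mask[drop] <- 0L
  mask
}

#' Fill enclosed background gaps of one class
#'
#' Background regions (class 0, 4-connected) that do not touch the image
#' border and whose entire neighborhood is class `cls` are relabeled `cls`.
#' Exterior background and holes reachable from the border are untouched.
#'
#' @inheritParams remove_outliers
#' @return the filled mask.
#' @export
fill_gaps <- function(mask, cls) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- mask == 0L
  if (!any(bg)) return(mask)
  lab <- label_components(bg, 4)
  border <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  interior <- setdiff(seq_len(max(lab)), c(0L, border))
  for (k in interior) {
    region <- lab == k
    # 4-dilation minus the region = its boundary ring
    dil <- region
    dil[-1, ] <- dil[-1, ] | region[-H, ]
    dil[-H, ] <- dil[-H, ] | region[-1, ]
    dil[, -1] <- dil[, -1] | region[, -W]
    dil[, -W] <- dil[, -W] | region[, -1]
    ring <- dil & !region
    if (all(mask[ring] == cls)) mask[region] <- cls
  }
  mask
}

#' Smooth the boundary of one class
#'
#' Morphological opening followed by closing of the binary mask of `cls`
#' with a disc of the given radius. Pixels carved away become background;
#' pixels claimed by the smoothed shape become `cls`, overwriting whatever
#' was there (use [postprocess_mask()] for priority-aware composition).
#' Radius 0 is the identity.
#'
#' @inheritParams remove_outliers
#' @param radius disc radius, pixels.
#' @return the smoothed mask.
#' @export
smooth_boundaries <- function(mask, cls, radius) {
  if (radius < 1) return(mask)
  bin <- mask == cls
  if (!any(bin)) return(mask)
  sm <- open_close(bin, radius)
  mask[bin & !sm] <- 0L
  mask[sm] <- cls
  mask
}

#' Full mask post-processing pipeline
#'
#' Applies, per class in priority order: outlier removal, gap filling, and
#' boundary smoothing. Pixels claimed by a class during smoothing are only
#' taken from background or from classes of lower priority. Smoothing is
#' skipped for a class when opening/closing would alter more than 10% of
#' its area: such a structure (e.g. the sliver of airway left at full
#' obstruction) is thinner than the brush and would be shredded rather
#' than smoothed, which would also break the metric neutrality of the
#' refinement. The pipeline is idempotent and never introduces classes
#' absent from the input.
#'
#' @param mask H x W integer class-index matrix.
#' @param config a [post_config()].
#' @return the refined mask.
#' @export
postprocess_mask <- function(mask, config = post_config()) {
  prio <- config$class_priority
  radius <- if (config$smooth_radius > 0)
    max(1L, as.integer(round(config$smooth_radius * min(dim(mask)) / 128)))
  else 0L
  for (ci in seq_along(prio)) {
    cls <- prio[ci]
    if (!any(mask == cls)) next
    mask <- remove_outliers(mask, cls, config)
    mask <- fill_gaps(mask, cls)
    if (radius >= 1) {
      bin <- mask == cls
      sm <- open_close(bin, radius)
      if (any(sm) && sum(xor(sm, bin)) <= 0.1 * sum(bin)) {
        lower <- c(0L, if (ci < length(prio)) prio[(ci + 1):length(prio)])
        mask[bin & !sm] <- 0L
        claim <- sm & !bin & matrix(mask %in% lower, nrow(mask))
        mask[claim] <- cls
      }
    }
  }
  mask
}
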