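#' Estimate the scalar background intensity of a channel
#'
#' When a negative-control image (same stain, unstained/control sample) is
#' supplied, background is its median intensity. Without a control, the 5th
#' percentile of the channel itself is used as a conservative proxy.
#'
#' @param channel numeric matrix of non-negative intensities.
#' @param negative_control optional numeric matrix from the stain's negative
#'   control.
#' @return non-negative scalar background estimate (same intensity units).
#' @export
estimate_background <- function(channel, negative_control = NULL) {
  stopifnot(is.matrix(channel), length(channel) > 0)
  if (!is.null(negative_control)) {
    bg <- median(as.numeric(negative_control))
  } else {
    bg <- as.numeric(quantile(channel, 0.05, names = FALSE))
  }
  max(bg, 0)
}

#' Threshold a channel into a binary mask
#'
#' Two threshold rules are supported. `"negative_control"` sets the
#' threshold at a high quantile (default 99.5%) of the stain's negative
#' control, bounding the false-positive pixel rate under the control
#' distribution; `"otsu"` maximizes between-class variance on the channel
#' histogram. Pixels strictly above the threshold are foreground.
#'
#' @param channel numeric intensity matrix.
#' @param negative_control control image, required for
#'   `method = "negative_control"`.
#' @param method `"negative_control"` or `"otsu"`. Defaults to
#'   `"negative_control"` when a control is supplied, else `"otsu"`.
#' @param control_quantile quantile of the control used as threshold.
#' @return logical matrix (the mask) with attributes `threshold`,
#'   `connectivity` (`"8"`) and `method`.
#' @export
threshold_mask <- function(channel, negative_control = NULL, method = NULL,
                           control_quantile = 0.995) {
  stopifnot(is.matrix(channel))
  if (is.null(method)) {
    method <- if (is.null(negative_control)) "otsu" else "negative_control"
  }
  method <- match.arg(method, c("negative_control", "otsu"))
  if (method == "negative_control") {
    if (is.null(negative_control)) {
      stop("method = 'negative_control' requires a negative-control image")
    }
    thr <- as.numeric(quantile(negative_control, control_quantile,
                               names = FALSE))
  } else {
    rng <- range(channel)
    if (diff(rng) == 0) {
      thr <- rng[1]  # flat image: empty mask (strict inequality below)
    } else {
      thr <- EBImage::otsu(EBImage::Image(channel), range = rng)
    }
  }
  mask <- channel > thr
  attr(mask, "threshold") <- thr
  attr(mask, "connectivity") <- "8"
  attr(mask, "method") <- method
  mask
}

#' Remove small objects from a binary mask
#'
#' Drops 8-connected components with fewer than `min_object_px` pixels;
#' all other pixels are untouched.
#'
#' @param mask logical matrix.
#' @param min_object_px minimum component size to keep (>= 1).
#' @return cleaned logical matrix.
#' @export
clean_mask <- function(mask, min_object_px = 1) {
  stopifnot(is.matrix(mask), min_object_px >= 1)
  if (min_object_px == 1 || !any(mask)) return(mask != 0)
  lab <- label8(as_binary_int(mask))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_object_px)
  out <- matrix(lab %in% keep, nrow = nrow(mask))
  for (a in c("threshold", "connectivity", "method")) {
    attr(out, a) <- attr(mask, a)
  }
  out
}

#' Skeletonize a binary mask to a 1-pixel-wide centerline
#'
#' Topology-preserving iterative thinning (Zhang-Suen two-subfield scheme)
#' followed by removal of redundant staircase pixels, so that the result is
#' 1 pixel wide under the 8-connected neighbour rule used by
#' [build_graph()]. The operation is idempotent and preserves the number of
#' connected components.
#'
#' @param mask logical matrix.
#' @return logical matrix skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- as_binary_int(mask)
  sk <- thin_skeleton(m) == 1L
  # parallel thinning can annihilate tiny square components; restore each
  # lost component as its single most interior pixel (a 1-px rod)
  lab <- label8(m)
  lost <- setdiff(unique(lab[lab > 0]), unique(lab[sk]))
  if (length(lost)) {
    dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(m)))
    for (l in lost) {
      idx <- which(lab == l)
      sk[idx[which.max(dm[idx])]] <- TRUE
    }
  }
  sk
}
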