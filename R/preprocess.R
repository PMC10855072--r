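#' Remove hot pixels by local-median replacement
#'
#' For each pixel, the median over the disk of radius `radius` (Euclidean
#' distance, clipped at image edges, center included) is computed; pixels
#' exceeding that median by more than `threshold` are replaced by it. Only
#' bright outliers are touched, matching the behavior of the ImageJ
#' "Remove Outliers" filter used on IMC dual-count images.
#'
#' @param img Numeric matrix (one channel).
#' @param radius Disk radius in pixels, >= 1 (default 2).
#' @param threshold Replacement threshold in dual counts, > 0 (default 50).
#' @return Matrix of the same shape with hot pixels repaired.
#' @export
remove_hot_pixels <- function(img, radius = 2, threshold = 50) {
  stopifnot(is.matrix(img))
  if (length(img) == 0) stop("empty image")
  if (radius < 1) stop("radius must be >= 1")
  if (threshold <= 0) stop("threshold must be > 0")
  H <- nrow(img); W <- ncol(img)
  r <- floor(radius)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= radius^2, ]
  shifted <- matrix(NA_real_, H * W, nrow(off))
  for (s in seq_len(nrow(off))) {
    di <- off$di[s]; dj <- off$dj[s]
    src_r <- (1 + max(0, -di)):(H - max(0, di))
    src_c <- (1 + max(0, -dj)):(W - max(0, dj))
    dst <- matrix(NA_real_, H, W)
    dst[src_r + di, src_c + dj] <- img[src_r, src_c]
    shifted[, s] <- dst
  }
  med <- matrixStats::rowMedians(shifted, na.rm = TRUE)
  out <- img
  hot <- img - med > threshold
  out[hot] <- med[hot]
  out
}

#' Normalize a channel at its 99th percentile
#'
#' Scales the channel by `max(p99, floor)` where `p99` is the 99th
#' percentile over all pixels (zeros included) and `floor` guards weakly
#' expressed channels (at least 10 dual counts by default); values above
#' the divisor saturate at 1.
#'
#' @param img Numeric matrix, nonnegative.
#' @param floor Minimum divisor in dual counts (default 10).
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_p99 <- function(img, floor = 10) {
  stopifnot(is.matrix(img))
  if (any(img < 0)) stop("channel must be nonnegative")
  s <- max(stats::quantile(img, 0.99, names = FALSE), floor)
  pmin(img / s, 1)
}

#' Zero out sub-threshold intensities
#'
#' Values strictly below `low_threshold` are set to 0; values at or above
#' it are unchanged. Per-channel thresholds come from the panel table and
#' default to 0 (identity).
#'
#' @param img Numeric matrix.
#' @param low_threshold Nonnegative scalar.
#' @return Thresholded matrix.
#' @export
apply_low_threshold <- function(img, low_threshold) {
  if (low_threshold < 0) stop("low_threshold must be >= 0")
  img[img < low_threshold] <- 0
  img
}

#' Hot-pixel-clean an entire image
#'
#' Applies [remove_hot_pixels()] to every channel, leaving intensities on
#' the raw dual-count scale (the scale on which cells are quantified).
#'
#' @param image A `MultiplexImage`.
#' @inheritParams remove_hot_pixels
#' @return A `MultiplexImage` with repaired channels.
#' @export
clean_image <- function(image, radius = 2, threshold = 50) {
  stopifnot(inherits(image, "MultiplexImage"))
  for (k in seq_along(image$channels))
    image$data[, , k] <- remove_hot_pixels(image$data[, , k], radius, threshold)
  image
}

#' Build a processed channel sub-stack for a pipeline role
#'
#' Selects the panel channels flagged for `role` (the DNA channel is always
#' appended for segmentation), then applies the fixed preprocessing chain
#' per channel: hot-pixel removal, 99th-percentile normalization, and the
#' panel's per-channel low-intensity threshold. Channel order follows the
#' panel.
#'
#' @param image A `MultiplexImage` (raw dual counts).
#' @param panel Panel `data.frame`.
#' @param role `"segmentation"` or `"clustering"`.
#' @param radius,threshold Hot-pixel filter parameters.
#' @param floor Normalization floor in dual counts.
#' @return A `MultiplexImage` of processed channels in `[0, 1]`.
#' @export
build_stack <- function(image, panel, role = c("segmentation", "clustering"),
                        radius = 2, threshold = 50, floor = 10) {
  role <- match.arg(role)
  stopifnot(inherits(image, "MultiplexImage"))
  wanted <- panel_markers(panel, role)
  if (role == "segmentation" && "DNA" %in% image$channels)
    wanted <- c(wanted, "DNA")
  if (length(wanted) == 0) stop("no channels flagged for role '", role, "'")
  missing <- setdiff(wanted, image$channels)
  if (length(missing) > 0)
    stop("channel(s) missing from image: ", paste(missing, collapse = ", "))
  thr <- stats::setNames(panel$low_threshold, panel$target)
  H <- dim(image$data)[1]; W <- dim(image$data)[2]
  out <- array(0, dim = c(H, W, length(wanted)),
               dimnames = list(NULL, NULL, wanted))
  for (ch in wanted) {
    x <- remove_hot_pixels(image$data[, , ch], radius, threshold)
    x <- normalize_p99(x, floor)
    lt <- if (ch %in% names(thr)) thr[[ch]] else 0
    out[, , ch] <- apply_low_threshold(x, lt)
  }
  multiplex_image(out, wanted, roi_id = image$roi_id,
                  pixel_size = image$pixel_size)
}
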