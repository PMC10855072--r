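# --- small image-filter internals (reflection-padded, separable) ---------

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

.reflect_pad <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(pmin(r:1 + 1L, H), 1:H, pmax(H - seq_len(r), 1L))
  ci <- c(pmin(r:1 + 1L, W), 1:W, pmax(W - seq_len(r), 1L))
  m[ri, ci, drop = FALSE]
}

# separable gaussian blur with reflection padding
.gauss_blur <- function(m, sigma) {
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  p <- .reflect_pad(m, r)
  H <- nrow(m); W <- ncol(m)
  tmp <- matrix(0, H, ncol(p))
  for (t in seq_along(k))
    tmp <- tmp + k[t] * p[(t - 1L) + seq_len(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (t in seq_along(k))
    out <- out + k[t] * tmp[, (t - 1L) + seq_len(W), drop = FALSE]
  out
}

# central-difference gradients with reflected borders
.gradients <- function(m) {
  p <- .reflect_pad(m, 1L)
  H <- nrow(m); W <- ncol(m)
  gy <- (p[3:(H + 2), 2:(W + 1), drop = FALSE] -
         p[1:H, 2:(W + 1), drop = FALSE]) / 2
  gx <- (p[2:(H + 1), 3:(W + 2), drop = FALSE] -
         p[2:(H + 1), 1:W, drop = FALSE]) / 2
  list(gx = gx, gy = gy)
}

.laplacian <- function(m) {
  p <- .reflect_pad(m, 1L)
  H <- nrow(m); W <- ncol(m)
  p[1:H, 2:(W + 1)] + p[3:(H + 2), 2:(W + 1)] +
    p[2:(H + 1), 1:W] + p[2:(H + 1), 3:(W + 2)] - 4 * m
}

#' Compute per-pixel classification features
#'
#' For every channel of the stack and every scale `sigma` in `scales`,
#' five feature kinds are computed on the Gaussian-smoothed channel
#' (reflection padding at borders): the smoothed value itself, gradient
#' magnitude, Laplacian of Gaussian, and the two structure-tensor
#' eigenvalues (high, low). Feature count is therefore
#' `channels x 5 x length(scales)`.
#'
#' @param stack A `MultiplexImage` (typically the segmentation-role stack
#'   from [build_stack()]).
#' @param scales Gaussian scales in pixels, default `c(1, 2, 4)`.
#' @return Object of class `PixelFeatureStack`: `list(dim = c(H, W),
#'   features = (H*W) x F matrix, names)`.
#' @export
compute_pixel_features <- function(stack, scales = c(1, 2, 4)) {
  stopifnot(inherits(stack, "MultiplexImage"))
  nc <- length(stack$channels)
  if (nc < 1) stop("need at least one channel")
  H <- dim(stack$data)[1]; W <- dim(stack$data)[2]
  kinds <- c("gauss", "gradmag", "log", "st_hi", "st_lo")
  F <- nc * length(kinds) * length(scales)
  feats <- matrix(0, H * W, F)
  nm <- character(F)
  col <- 0L
  for (k in seq_len(nc)) {
    ch <- stack$data[, , k]
    for (s in scales) {
      g <- .gauss_blur(ch, s)
      gr <- .gradients(g)
      mag <- sqrt(gr$gx^2 + gr$gy^2)
      lap <- .laplacian(g)
      jxx <- .gauss_blur(gr$gx * gr$gx, s)
      jyy <- .gauss_blur(gr$gy * gr$gy, s)
      jxy <- .gauss_blur(gr$gx * gr$gy, s)
      tr2 <- (jxx + jyy) / 2
      disc <- sqrt(((jxx - jyy) / 2)^2 + jxy^2)
      vals <- list(g, mag, lap, tr2 + disc, tr2 - disc)
      for (v in seq_along(kinds)) {
        col <- col + 1L
        feats[, col] <- as.vector(vals[[v]])
        nm[col] <- sprintf("%s_s%g_%s", stack$channels[k], s, kinds[v])
      }
    }
  }
  colnames(feats) <- nm
  structure(list(dim = c(H, W), features = feats, names = nm),
            class = "PixelFeatureStack")
}

#' Generate training scribbles from synthetic ground truth
#'
#' Emulates interactive classifier annotation: nucleus scribbles are pixels
#' well inside each nucleus (radius eroded by `erode`), cytoplasm scribbles
#' sit on the cytoplasm ring, and background scribbles are pixels farther
#' than `bg_clearance` from every cell footprint. A random subset of up to
#' `n_per_class` pixels per class is returned.
#'
#' @param cells `GroundTruth` `data.frame`.
#' @param image_size `(H, W)`.
#' @param cyto_ring Cytoplasm ring width (um).
#' @param erode Nucleus erosion in um, default 1.5.
#' @param bg_clearance Minimum distance from any cell footprint for
#'   background scribbles, default 1 um (annotating background right up to
#'   the footprint edge keeps the learned cell boundary tight).
#' @param n_per_class Maximum scribble pixels per class, default 2000.
#' @param seed RNG seed for subsampling.
#' @return `data.frame(index, class)` with `index` a linear pixel index and
#'   `class` in `nuclei`/`cytoplasm`/`background`.
#' @export
scribbles_from_truth <- function(cells, image_size = attr(cells, "image_size"),
                                 cyto_ring = attr(cells, "cyto_ring"),
                                 erode = 1.5, bg_clearance = 1,
                                 n_per_class = 2000, seed = 1L) {
  if (is.null(cyto_ring)) cyto_ring <- 2
  H <- image_size[1]; W <- image_size[2]
  set.seed(seed)
  nuc <- integer(0); cyt <- integer(0)
  covered <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(cells))) {
    rn <- cells$nucleus_radius[i]
    inner <- .disk_pixels(cells$x[i], cells$y[i], max(rn - erode, 1), H, W)
    full <- .disk_pixels(cells$x[i], cells$y[i], rn + cyto_ring, H, W)
    nucfull <- .disk_pixels(cells$x[i], cells$y[i], rn, H, W)
    clear <- .disk_pixels(cells$x[i], cells$y[i], rn + cyto_ring + bg_clearance,
                          H, W)
    nuc <- c(nuc, inner)
    cyt <- c(cyt, setdiff(full, nucfull))
    covered[clear] <- TRUE
  }
  bg <- which(!covered)
  pick <- function(v) if (length(v) > n_per_class) sample(v, n_per_class) else v
  nuc <- pick(unique(nuc)); cyt <- pick(unique(cyt)); bg <- pick(bg)
  data.frame(
    index = c(nuc, cyt, bg),
    class = rep(c("nuclei", "cytoplasm", "background"),
                c(length(nuc), length(cyt), length(bg))),
    stringsAsFactors = FALSE
  )
}

#' Train a pixel classifier
#'
#' Random forest over pixel features with sparse scribble labels in the
#' three classes nuclei / cytoplasm / background. Training is deterministic
#' given `seed` and reports out-of-bag accuracy.
#'
#' @param features A `PixelFeatureStack`.
#' @param scribbles `data.frame(index, class)` as from
#'   [scribbles_from_truth()]; at least 50 labeled pixels per class, all
#'   three classes present.
#' @param seed Integer seed.
#' @param num_trees Number of trees, default 100.
#' @return `list(model, oob_accuracy, classes, feature_names)` of class
#'   `PixelClassifier`.
#' @export
train_pixel_classifier <- function(features, scribbles, seed = 1L,
                                   num_trees = 100L) {
  stopifnot(inherits(features, "PixelFeatureStack"))
  classes <- c("nuclei", "cytoplasm", "background")
  missing <- setdiff(classes, unique(scribbles$class))
  if (length(missing) > 0)
    stop("scribbles missing class(es): ", paste(missing, collapse = ", "))
  cnt <- table(scribbles$class)
  if (any(cnt < 50)) stop("need >= 50 labeled pixels per class")
  df <- as.data.frame(features$features[scribbles$index, , drop = FALSE])
  df$.class <- factor(scribbles$class, levels = classes)
  set.seed(seed)
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df, probability = TRUE,
    num.trees = num_trees, seed = seed, num.threads = 1
  )
  structure(
    list(model = fit, oob_accuracy = 1 - fit$prediction.error,
         classes = classes, feature_names = features$names),
    class = "PixelClassifier"
  )
}

#' Predict class probability maps
#'
#' @param classifier A `PixelClassifier`.
#' @param features A `PixelFeatureStack` with the same feature layout the
#'   classifier was trained on.
#' @return Object of class `ProbabilityMaps`: `H x W x 3` array with
#'   per-pixel class posteriors (`nuclei`, `cytoplasm`, `background`)
#'   summing to 1.
#' @export
predict_probability_maps <- function(classifier, features) {
  stopifnot(inherits(classifier, "PixelClassifier"),
            inherits(features, "PixelFeatureStack"))
  if (!identical(classifier$feature_names, features$names))
    stop("feature layout does not match the classifier's training layout")
  pr <- stats::predict(classifier$model,
                       data = as.data.frame(features$features),
                       num.threads = 1)$predictions
  pr <- pr[, classifier$classes, drop = FALSE]
  pr <- pr / rowSums(pr)
  H <- features$dim[1]; W <- features$dim[2]
  maps <- array(pr, dim = c(H, W, 3),
                dimnames = list(NULL, NULL, classifier$classes))
  structure(maps, class = "ProbabilityMaps")
}

#' Segment cells from probability maps
#'
#' CellProfiler-style two-stage segmentation: (1) nucleus foreground =
#' pixels with nuclei posterior >= 0.5; (2) objects smaller than
#' `min_nucleus_area` are dropped; (3) touching nuclei are split by seeded
#' watershed on the negated distance transform; (4) each nucleus is
#' expanded outward by seed competition (propagation on the cytoplasm
#' posterior landscape), restricted to pixels with background posterior
#' < 0.5 and within `max_expand` of a nucleus. Labels are renumbered
#' consecutively from 1.
#'
#' @param probmaps A `ProbabilityMaps`.
#' @param min_nucleus_area Minimum nucleus area in um^2 (= px), default 10.
#' @param max_expand Maximum outward expansion in um, default 5.
#' @return Integer `H x W` label matrix (`LabelMask`); empty (all-zero)
#'   with a warning when no nucleus foreground is found.
#' @export
segment_cells <- function(probmaps, min_nucleus_area = 10, max_expand = 5) {
  stopifnot(inherits(probmaps, "ProbabilityMaps"))
  p_nuc <- probmaps[, , "nuclei"]
  p_cyt <- probmaps[, , "cytoplasm"]
  p_bg <- probmaps[, , "background"]
  fg <- p_nuc >= 0.5
  if (!any(fg)) {
    warning("no nucleus foreground; returning empty mask")
    return(matrix(0L, nrow(p_nuc), ncol(p_nuc)))
  }
  lab <- EBImage::bwlabel(fg)
  areas <- tabulate(lab[lab > 0])
  small <- which(areas < min_nucleus_area)
  if (length(small) > 0) {
    lab[lab %in% small] <- 0L
    fg <- lab > 0
  }
  if (!any(fg)) {
    warning("no nucleus passed min_nucleus_area; returning empty mask")
    return(matrix(0L, nrow(p_nuc), ncol(p_nuc)))
  }
  dm <- EBImage::distmap(fg)
  nuclei <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  nuclei <- EBImage::imageData(nuclei)

  # distance of every pixel to the nearest nucleus pixel
  d_out <- EBImage::imageData(EBImage::distmap(!(nuclei > 0)))
  allowed <- (p_bg < 0.5 & d_out <= max_expand) | nuclei > 0
  expanded <- EBImage::propagate(x = 1 - p_cyt, seeds = nuclei,
                                 mask = allowed, lambda = 1e-4)
  expanded <- EBImage::imageData(expanded)
  keep <- sort(unique(expanded[expanded > 0]))
  out <- matrix(match(expanded, keep, nomatch = 0L),
                nrow(expanded), ncol(expanded))
  storage.mode(out) <- "integer"
  out
}
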