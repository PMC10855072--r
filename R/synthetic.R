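#' Multichannel image container
#'
#' Lightweight container for one ROI: an `H x W x C` array of nonnegative
#' dual-count intensities, one channel per marker (plus optionally a DNA
#' channel), at 1 um^2 per pixel by default.
#'
#' @param data Numeric `H x W x C` array, nonnegative and finite.
#' @param channels Character vector of unique channel names, length `C`.
#' @param roi_id ROI identifier string.
#' @param pixel_size Pixel side length in um (default 1).
#' @return An object of class `MultiplexImage`.
#' @export
multiplex_image <- function(data, channels, roi_id = "roi", pixel_size = 1) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(channels) != dim(data)[3]) stop("channels must match dim(data)[3]")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  if (!all(is.finite(data)) || any(data < 0)) stop("data must be nonnegative and finite")
  dimnames(data)[[3]] <- channels
  structure(
    list(roi_id = roi_id, channels = channels, data = data,
         pixel_size = pixel_size),
    class = "MultiplexImage"
  )
}

#' Extract one channel as a matrix
#' @param image A `MultiplexImage`.
#' @param channel Channel name.
#' @return `H x W` numeric matrix.
#' @export
get_channel <- function(image, channel) {
  if (!channel %in% image$channels) stop("unknown channel: ", channel)
  image$data[, , channel]
}

#' @export
print.MultiplexImage <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("MultiplexImage '%s': %d x %d px, %d channels, %.1f um/px\n",
              x$roi_id, d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

#' Cell-type signature matrix
#'
#' Mean dual-count intensity per (cell type, marker) with a lognormal
#' per-cell dispersion. A cell of type `t` draws, for each marker `m`, a
#' single intensity `mean[t, m] * exp(sigma * Z)`, `Z ~ N(0, 1)`, painted
#' uniformly over its footprint.
#'
#' @param mean_intensity Numeric type x marker matrix, nonnegative, with
#'   rownames (types) and colnames (markers).
#' @param dispersion Lognormal sigma, a scalar or a matrix conformable with
#'   `mean_intensity`; must be positive.
#' @param background Global background level (dual counts) used to check
#'   that every type has at least one distinguishing marker.
#' @return Object of class `SignatureMatrix`.
#' @export
signature_matrix <- function(mean_intensity, dispersion = 0.25, background = 1) {
  stopifnot(is.matrix(mean_intensity),
            !is.null(rownames(mean_intensity)), !is.null(colnames(mean_intensity)))
  if (any(mean_intensity < 0)) stop("signature means must be >= 0")
  if (length(dispersion) == 1)
    dispersion <- matrix(dispersion, nrow(mean_intensity), ncol(mean_intensity),
                         dimnames = dimnames(mean_intensity))
  if (any(dispersion <= 0)) stop("dispersion must be > 0")
  above <- apply(mean_intensity, 1, function(r) any(r > background))
  if (!all(above))
    stop("each type needs >= 1 marker above background: ",
         paste(rownames(mean_intensity)[!above], collapse = ", "))
  structure(
    list(cell_types = rownames(mean_intensity),
         markers = colnames(mean_intensity),
         mean_intensity = mean_intensity,
         dispersion = dispersion,
         background = background),
    class = "SignatureMatrix"
  )
}

#' Default six-phenotype signature matrix
#'
#' Six synthetic cell types over the 28-marker panel, each expressing the
#' markers its phenotype class is annotated by (tumor: ZO-1/PDGFRa/PDGFRb;
#' stromal: aSMA/Collagen I/Desmin/CD44/Vimentin; immune: CD45 with a
#' mono/macrophage flavor; endothelial: CD31/Collagen IV; lymphatic:
#' LYVE-1; "other": Vimentin only, so that no annotation rule claims it).
#' All remaining markers sit at the background level.
#'
#' @param panel Panel `data.frame`, default [imc_panel()].
#' @param background Background mean (dual counts), default 1.
#' @param high Intensity of strongly expressed markers, default 100.
#' @param dispersion Lognormal sigma, default 0.25.
#' @return A `SignatureMatrix` with 6 types.
#' @export
default_signatures <- function(panel = imc_panel(), background = 1,
                               high = 100, dispersion = 0.25) {
  markers <- panel$target
  types <- c("tumor", "stromal", "immune", "endothelial", "lymphatic", "other")
  m <- matrix(background, length(types), length(markers),
              dimnames = list(types, markers))
  set_sig <- function(type, vals) {
    for (mk in names(vals)) m[type, mk] <<- vals[[mk]]
  }
  set_sig("tumor", c("ZO-1" = high, "PDGFRa" = 0.6 * high, "PDGFRb" = 0.6 * high))
  set_sig("stromal", c("aSMA" = high, "CollagenI" = high, "Desmin" = 0.7 * high,
                       "CD44" = 0.5 * high, "Vimentin" = 0.5 * high))
  set_sig("immune", c("CD45" = high, "F4/80" = 0.6 * high, "CD11b" = 0.5 * high))
  set_sig("endothelial", c("CD31" = high, "CollagenIV" = 0.6 * high))
  set_sig("lymphatic", c("LYVE-1" = high, "Vimentin" = 0.3 * high))
  set_sig("other", c("Vimentin" = 0.4 * high))
  signature_matrix(m, dispersion = dispersion, background = background)
}

#' Immune-subtype signature matrix
#'
#' Six immune subtypes over the panel (all CD45-positive), each carrying
#' its canonical lineage marker: F4/80 (mono/macrophage), CD103 (dendritic),
#' Ly6G (neutrophil), CD3+CD4 and CD3+CD8 (T cells), B220 (B cells).
#'
#' @inheritParams default_signatures
#' @return A `SignatureMatrix` with 6 immune subtypes.
#' @export
immune_signatures <- function(panel = imc_panel(), background = 1,
                              high = 100, dispersion = 0.25) {
  markers <- panel$target
  types <- c("mono_mac", "dendritic", "neutrophil", "CD4 T", "CD8 T", "B")
  m <- matrix(background, length(types), length(markers),
              dimnames = list(types, markers))
  m[, "CD45"] <- 0.8 * high
  m["mono_mac", c("F4/80", "CD11b")] <- c(high, 0.6 * high)
  m["dendritic", "CD103"] <- high
  m["neutrophil", c("Ly6G", "CD11b")] <- c(high, 0.5 * high)
  m["CD4 T", c("CD3", "CD4")] <- c(high, high)
  m["CD8 T", c("CD3", "CD8")] <- c(high, high)
  m["B", "B220"] <- high
  signature_matrix(m, dispersion = dispersion, background = background)
}

#' Layout specification for synthetic ROIs
#'
#' Describes where cells of each type are placed. Three modes: `random`
#' (complete spatial randomness under a hard-core constraint, the null
#' substrate for calibration), `core_margin` (tumor-like types confined to
#' the inner core, all others to an outer band, emulating a dense tumor
#' core with a stroma/immune-rich margin), and `paired_attraction` (each
#' cell of type `b` is planted within `max_distance` of some cell of type
#' `a`, used for interaction-recovery tests).
#'
#' @param mode `"random"`, `"core_margin"` or `"paired_attraction"`.
#' @param image_size Integer `(H, W)` in um (= pixels), default `c(500, 500)`.
#' @param n_cells Named integer vector: cells per type.
#' @param min_center_distance Hard-core minimum centroid distance in um;
#'   must be at least twice the nucleus radius.
#' @param attraction For `paired_attraction`: `list(a =, b =, max_distance =)`
#'   with `max_distance` in um.
#' @param margin_band_width Width in um of the outer margin band
#'   (`core_margin` mode), default 100.
#' @param core_types Types confined to the core in `core_margin` mode,
#'   default `"tumor"`.
#' @param nucleus_radius Nucleus radius in um, default 4.
#' @param cyto_ring Cytoplasm ring width in um, default 2.
#' @return Object of class `LayoutSpec`.
#' @export
layout_spec <- function(mode = c("random", "core_margin", "paired_attraction"),
                        image_size = c(500, 500), n_cells,
                        min_center_distance = 12, attraction = NULL,
                        margin_band_width = 100, core_types = "tumor",
                        nucleus_radius = 4, cyto_ring = 2) {
  mode <- match.arg(mode)
  stopifnot(length(image_size) == 2, all(image_size > 0))
  if (is.null(names(n_cells)) && length(n_cells) > 0)
    stop("n_cells must be a named vector (type -> count)")
  if (min_center_distance < 2 * nucleus_radius)
    stop("min_center_distance must be >= 2 * nucleus_radius")
  if (mode == "paired_attraction") {
    if (is.null(attraction) ||
        !all(c("a", "b", "max_distance") %in% names(attraction)))
      stop("paired_attraction mode needs attraction = list(a, b, max_distance)")
    if (attraction$max_distance <= min_center_distance)
      stop("attraction max_distance must exceed min_center_distance, ",
           "or no attracted cell can be placed")
  }
  structure(
    list(mode = mode, image_size = as.integer(image_size),
         n_cells = n_cells, min_center_distance = min_center_distance,
         attraction = attraction, margin_band_width = margin_band_width,
         core_types = core_types, nucleus_radius = nucleus_radius,
         cyto_ring = cyto_ring),
    class = "LayoutSpec"
  )
}

#' Noise specification for synthetic ROIs
#'
#' @param background_mean Mean background level in dual counts, default 1.
#' @param poisson Resample every pixel as Poisson(count) (counting noise)?
#' @param hot_pixel_rate Fraction of pixels per channel turned into hot
#'   pixels; must lie in `[0, 0.01]`.
#' @param hot_pixel_amplitude Dual-count value of planted hot pixels; must
#'   exceed ten times any signature mean in use (checked at render time).
#' @param seed Integer RNG seed for rendering.
#' @return Object of class `NoiseSpec`.
#' @export
noise_spec <- function(background_mean = 1, poisson = TRUE,
                       hot_pixel_rate = 0.001, hot_pixel_amplitude = 2000,
                       seed = 1L) {
  if (hot_pixel_rate < 0 || hot_pixel_rate > 0.01)
    stop("hot_pixel_rate must be in [0, 0.01]")
  structure(
    list(background_mean = background_mean, poisson = poisson,
         hot_pixel_rate = hot_pixel_rate,
         hot_pixel_amplitude = hot_pixel_amplitude, seed = as.integer(seed)),
    class = "NoiseSpec"
  )
}

# uniform point in the allowed rectangle (cell fully inside the image)
.sample_point <- function(image_size, margin) {
  c(stats::runif(1, margin, image_size[2] - margin),   # x = column
    stats::runif(1, margin, image_size[1] - margin))   # y = row
}

.in_bounds <- function(p, image_size, margin) {
  p[1] >= margin && p[1] <= image_size[2] - margin &&
    p[2] >= margin && p[2] <= image_size[1] - margin
}

#' Place synthetic cells
#'
#' Hard-core point process: all pairwise centroid distances are at least
#' `min_center_distance`. Placement is sequential rejection sampling with a
#' bounded attempt count per cell.
#'
#' @param layout A [layout_spec()].
#' @param seed Integer RNG seed.
#' @param max_attempts Attempts per cell before giving up.
#' @return A `GroundTruth` `data.frame` with columns `cell_id`, `type`,
#'   `x`, `y` (um; x = column, y = row), `nucleus_radius`, `mask_label`,
#'   carrying the layout as attributes `image_size` and `cyto_ring`.
#' @export
place_cells <- function(layout, seed = 1L, max_attempts = 5000L) {
  stopifnot(inherits(layout, "LayoutSpec"))
  set.seed(seed)
  n_total <- sum(layout$n_cells)
  empty <- data.frame(cell_id = integer(0), type = character(0),
                      x = numeric(0), y = numeric(0),
                      nucleus_radius = numeric(0), mask_label = integer(0),
                      stringsAsFactors = FALSE)
  attr(empty, "image_size") <- layout$image_size
  attr(empty, "cyto_ring") <- layout$cyto_ring
  if (n_total == 0) return(empty)

  sz <- layout$image_size
  r_cell <- layout$nucleus_radius + layout$cyto_ring
  margin <- r_cell + 1
  dmin2 <- layout$min_center_distance^2
  band <- layout$margin_band_width

  types <- rep(names(layout$n_cells), layout$n_cells)
  if (layout$mode == "paired_attraction") {
    b_type <- layout$attraction$b
    types <- c(sample(types[types != b_type]), types[types == b_type])
  } else {
    types <- sample(types)
  }

  region_ok <- function(type, p) {
    if (layout$mode != "core_margin") return(TRUE)
    # distance to nearest image border
    d_border <- min(p[1], sz[2] - p[1], p[2], sz[1] - p[2])
    if (type %in% layout$core_types) d_border > band else d_border <= band
  }

  pos <- matrix(NA_real_, n_total, 2)
  n_placed <- 0L
  for (i in seq_len(n_total)) {
    ty <- types[i]
    attached <- layout$mode == "paired_attraction" &&
      ty == layout$attraction$b
    if (attached) {
      anchors <- which(types[seq_len(n_placed)] == layout$attraction$a)
      if (length(anchors) == 0) stop("no anchor cells of type ",
                                     layout$attraction$a, " placed")
    }
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      if (attached) {
        anc <- pos[anchors[sample.int(length(anchors), 1)], ]
        rr <- layout$attraction$max_distance * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        p <- anc + rr * c(cos(th), sin(th))
        if (!.in_bounds(p, sz, margin)) next
      } else {
        p <- .sample_point(sz, margin)
      }
      if (!region_ok(ty, p)) next
      if (n_placed > 0) {
        d2 <- (pos[seq_len(n_placed), 1] - p[1])^2 +
              (pos[seq_len(n_placed), 2] - p[2])^2
        if (min(d2) < dmin2) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf(
        "could not place cell %d of %d after %d attempts: density too high for min_center_distance = %g in a %d x %d image",
        i, n_total, max_attempts, layout$min_center_distance, sz[1], sz[2]))
    n_placed <- n_placed + 1L
    pos[i, ] <- p
  }

  out <- data.frame(cell_id = seq_len(n_total), type = types,
                    x = pos[, 1], y = pos[, 2],
                    nucleus_radius = layout$nucleus_radius,
                    mask_label = seq_len(n_total), stringsAsFactors = FALSE)
  attr(out, "image_size") <- sz
  attr(out, "cyto_ring") <- layout$cyto_ring
  out
}

#' Paint the ground-truth label mask
#'
#' Each cell's footprint is the disk of radius `nucleus_radius + cyto_ring`
#' around its centroid; overlaps (possible only at touching footprints under
#' the hard-core constraint) are resolved first-come.
#'
#' @param cells `GroundTruth` `data.frame` from [place_cells()].
#' @param image_size `(H, W)`; defaults to the attribute stored on `cells`.
#' @param cyto_ring Cytoplasm ring width in um.
#' @return Integer `H x W` label matrix (0 = background).
#' @export
truth_mask <- function(cells, image_size = attr(cells, "image_size"),
                       cyto_ring = attr(cells, "cyto_ring")) {
  if (is.null(image_size)) stop("image_size must be supplied")
  if (is.null(cyto_ring)) cyto_ring <- 2
  H <- image_size[1]; W <- image_size[2]
  mask <- matrix(0L, H, W)
  for (i in seq_len(nrow(cells))) {
    r <- cells$nucleus_radius[i] + cyto_ring
    px <- .disk_pixels(cells$x[i], cells$y[i], r, H, W)
    free <- mask[px] == 0L
    mask[px[free]] <- cells$mask_label[i]
  }
  mask
}

# linear indices of pixels whose centers lie within radius r of (x, y)
.disk_pixels <- function(x, y, r, H, W) {
  rows <- max(1, floor(y - r)):min(H, ceiling(y + r))
  cols <- max(1, floor(x - r)):min(W, ceiling(x + r))
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  keep <- (rr - y)^2 + (cc - x)^2 <= r^2
  (cc[keep] - 1L) * H + rr[keep]
}

#' Render a synthetic multichannel ROI
#'
#' Renders each cell as a disk nucleus (DNA channel) with an annular
#' cytoplasm ring; each marker channel paints one lognormal per-cell draw
#' over the full cell footprint on top of a flat background. Optional
#' Poisson counting noise per pixel, then isolated hot pixels set to
#' `hot_pixel_amplitude`. All intensities are rounded to integer dual
#' counts.
#'
#' @param cells `GroundTruth` from [place_cells()].
#' @param signatures A [signature_matrix()].
#' @param noise A [noise_spec()].
#' @param image_size `(H, W)`, defaulting to the attribute on `cells`.
#' @param cyto_ring Cytoplasm ring width (um).
#' @param dna_mean,dna_sigma Lognormal scale and sigma of the per-cell DNA
#'   (iridium intercalator) intensity.
#' @param roi_id ROI identifier.
#' @return `list(image = MultiplexImage, mask = integer matrix,
#'   cells = GroundTruth)`; channels are the signature markers in order
#'   plus a final `"DNA"` channel.
#' @export
render_roi <- function(cells, signatures, noise = noise_spec(),
                       image_size = attr(cells, "image_size"),
                       cyto_ring = attr(cells, "cyto_ring"),
                       dna_mean = 100, dna_sigma = 0.25, roi_id = "roi") {
  stopifnot(inherits(signatures, "SignatureMatrix"),
            inherits(noise, "NoiseSpec"))
  if (is.null(cyto_ring)) cyto_ring <- 2
  unknown <- setdiff(unique(cells$type), signatures$cell_types)
  if (length(unknown) > 0)
    stop("unknown cell type(s): ", paste(unknown, collapse = ", "))
  if (noise$hot_pixel_rate > 0) {
    top <- max(signatures$mean_intensity, dna_mean)
    if (noise$hot_pixel_amplitude <= 10 * top)
      stop("hot_pixel_amplitude must exceed 10 x the largest signature mean")
  }
  H <- image_size[1]; W <- image_size[2]
  markers <- signatures$markers
  channels <- c(markers, "DNA")
  set.seed(noise$seed)

  mask <- truth_mask(cells, image_size, cyto_ring)
  data <- array(noise$background_mean, dim = c(H, W, length(channels)),
                dimnames = list(NULL, NULL, channels))

  for (i in seq_len(nrow(cells))) {
    foot <- which(mask == cells$mask_label[i])
    if (length(foot) == 0) next
    nuc <- .disk_pixels(cells$x[i], cells$y[i], cells$nucleus_radius[i], H, W)
    nuc <- nuc[mask[nuc] == cells$mask_label[i]]
    mu <- signatures$mean_intensity[cells$type[i], ]
    sig <- signatures$dispersion[cells$type[i], ]
    draws <- mu * exp(sig * stats::rnorm(length(mu)))
    for (k in seq_along(markers))
      data[foot + (k - 1L) * H * W] <- draws[k]
    data[nuc + (length(channels) - 1L) * H * W] <-
      dna_mean * exp(dna_sigma * stats::rnorm(1))
  }

  if (noise$poisson)
    data[] <- stats::rpois(length(data), lambda = data)

  if (noise$hot_pixel_rate > 0) {
    for (k in seq_along(channels)) {
      n_hot <- stats::rbinom(1, H * W, noise$hot_pixel_rate)
      if (n_hot == 0) next
      cand <- sample.int(H * W, min(H * W, 3L * n_hot))
      kept <- .keep_isolated(cand, H, W, n_hot)
      data[kept + (k - 1L) * H * W] <- noise$hot_pixel_amplitude
    }
  }

  data[] <- round(data)
  img <- multiplex_image(data, channels, roi_id = roi_id, pixel_size = 1)
  list(image = img, mask = mask, cells = cells)
}

# greedily keep up to n candidates no two of which are 8-adjacent
.keep_isolated <- function(cand, H, W, n) {
  rows <- (cand - 1L) %% H + 1L
  cols <- (cand - 1L) %/% H + 1L
  kept <- integer(0); kr <- integer(0); kc <- integer(0)
  for (i in seq_along(cand)) {
    if (length(kept) >= n) break
    if (length(kept) > 0 &&
        any(abs(kr - rows[i]) <= 1L & abs(kc - cols[i]) <= 1L)) next
    kept <- c(kept, cand[i]); kr <- c(kr, rows[i]); kc <- c(kc, cols[i])
  }
  kept
}

#' Draw per-cell marker intensities without rendering an image
#'
#' Convenience generator for clustering experiments: one lognormal draw per
#' (cell, marker) from the signature matrix, i.e. the distribution of
#' per-cell mean intensities a perfectly segmented ROI would yield.
#'
#' @param n_per_type Named integer vector (cells per type) or a single
#'   count applied to every signature type.
#' @param signatures A [signature_matrix()].
#' @param seed Integer RNG seed.
#' @return `list(intensity = n x marker matrix, type = character vector)`.
#' @export
synth_cell_matrix <- function(n_per_type, signatures, seed = 1L) {
  stopifnot(inherits(signatures, "SignatureMatrix"))
  if (is.null(names(n_per_type)))
    n_per_type <- stats::setNames(rep(n_per_type[1], length(signatures$cell_types)),
                                  signatures$cell_types)
  set.seed(seed)
  types <- rep(names(n_per_type), n_per_type)
  n <- length(types)
  p <- length(signatures$markers)
  mu <- signatures$mean_intensity[types, , drop = FALSE]
  sig <- signatures$dispersion[types, , drop = FALSE]
  x <- mu * exp(sig * matrix(stats::rnorm(n * p), n, p))
  colnames(x) <- signatures$markers
  rownames(x) <- NULL
  list(intensity = x, type = types)
}

#' Write a synthetic fixture to disk
#'
#' Writes the multichannel image (multi-page uint16 TIFF, channel order =
#' panel order then DNA), the label mask (uint16 TIFF), the ground-truth
#' CSV, the panel CSV, and a channel-order CSV. Intensities must be
#' integers in `[0, 65535]`; the round trip through [read_fixture()] is
#' then bit-identical.
#'
#' @param image `MultiplexImage` with integer dual counts.
#' @param mask Integer label matrix.
#' @param cells `GroundTruth` `data.frame`.
#' @param panel Panel `data.frame`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(image, mask, cells, panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- image$data
  if (any(d != round(d)) || max(d) > 65535)
    stop("image intensities must be integers in [0, 65535]")
  if (max(mask) > 65535) stop("mask labels exceed uint16 range")
  pages <- lapply(seq_len(dim(d)[3]), function(k) d[, , k] / 65535)
  tiff::writeTIFF(pages, file.path(dir, "image.tiff"), bits.per.sample = 16)
  tiff::writeTIFF(mask / 65535, file.path(dir, "mask.tiff"), bits.per.sample = 16)
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write_panel(panel, file.path(dir, "panel.csv"))
  utils::write.csv(data.frame(channel = image$channels),
                   file.path(dir, "channels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a synthetic fixture from disk
#'
#' @param dir Directory written by [write_fixture()].
#' @param roi_id ROI id to attach to the image.
#' @return `list(image, mask, cells, panel)`.
#' @export
read_fixture <- function(dir, roi_id = basename(dir)) {
  pages <- tiff::readTIFF(file.path(dir, "image.tiff"), all = TRUE)
  channels <- utils::read.csv(file.path(dir, "channels.csv"),
                              stringsAsFactors = FALSE)$channel
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  data <- array(0, dim = c(H, W, length(pages)))
  for (k in seq_along(pages)) data[, , k] <- round(pages[[k]] * 65535)
  image <- multiplex_image(data, channels, roi_id = roi_id)
  mask <- round(tiff::readTIFF(file.path(dir, "mask.tiff")) * 65535)
  storage.mode(mask) <- "integer"
  cells <- utils::read.csv(file.path(dir, "cells.csv"), stringsAsFactors = FALSE)
  panel <- read_panel(file.path(dir, "panel.csv"))
  list(image = image, mask = mask, cells = cells, panel = panel)
}

#' Match a predicted mask to ground truth by IoU
#'
#' Greedy 1:1 matching: each ground-truth label is matched to the predicted
#' label with the largest intersection-over-union, provided IoU is at least
#' `min_iou` and the predicted label is still unclaimed.
#'
#' @param pred Predicted integer label mask.
#' @param truth Ground-truth integer label mask of the same shape.
#' @param min_iou Minimum IoU for a match, default 0.5.
#' @return `list(matches = data.frame(truth, pred, iou), recovery = fraction
#'   of ground-truth labels matched)`.
#' @export
match_to_truth <- function(pred, truth, min_iou = 0.5) {
  stopifnot(all(dim(pred) == dim(truth)))
  t_lab <- truth[truth > 0 | pred > 0]
  p_lab <- pred[truth > 0 | pred > 0]
  ov <- Matrix::sparseMatrix(i = t_lab + 1L, j = p_lab + 1L,
                             x = rep(1, length(t_lab)),
                             dims = c(max(truth) + 1L, max(pred) + 1L))
  a_t <- Matrix::rowSums(ov); a_p <- Matrix::colSums(ov)
  sm <- Matrix::summary(ov)
  sm <- sm[sm$i > 1 & sm$j > 1, , drop = FALSE]  # drop background row/col
  iou <- sm$x / (a_t[sm$i] + a_p[sm$j] - sm$x)
  ord <- order(-iou)
  used_p <- logical(max(pred) + 1L)
  used_t <- logical(max(truth) + 1L)
  keep <- logical(length(ord))
  for (r in ord) {
    if (iou[r] < min_iou) break
    if (used_t[sm$i[r]] || used_p[sm$j[r]]) next
    used_t[sm$i[r]] <- TRUE; used_p[sm$j[r]] <- TRUE
    keep[r] <- TRUE
  }
  matches <- data.frame(truth = sm$i[keep] - 1L, pred = sm$j[keep] - 1L,
                        iou = iou[keep])
  n_truth <- length(unique(truth[truth > 0]))
  list(matches = matches,
       recovery = if (n_truth == 0) NA_real_ else nrow(matches) / n_truth)
}
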