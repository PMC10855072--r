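#' Quantify cells from a label mask and image
#'
#' Per cell: area (pixel count times `pixel_size^2`, 1 um^2/px by default),
#' centroid (mean pixel coordinate, x = column, y = row), and the mean
#' intensity of every channel over the cell's pixels. Intensities are
#' expected on the hot-pixel-removed raw dual-count scale (see
#' [clean_image()]); the QC thresholds of [qc_filter()] are defined on
#' that scale.
#'
#' @param mask Integer label matrix (0 = background).
#' @param image A `MultiplexImage` of the same spatial shape.
#' @return A `CellTable` `data.frame`: `cell_id`, `roi_id`, `x`, `y`,
#'   `area`, then one mean-intensity column per channel (names as in the
#'   panel; access with `check.names = FALSE` semantics).
#' @export
quantify <- function(mask, image) {
  stopifnot(inherits(image, "MultiplexImage"))
  if (!all(dim(mask) == dim(image$data)[1:2]))
    stop("mask and image shapes differ")
  idx <- which(mask > 0)
  labs <- mask[idx]
  labels <- sort(unique(labs))
  if (length(labels) == 0) {
    out <- data.frame(cell_id = integer(0), roi_id = character(0),
                      x = numeric(0), y = numeric(0), area = numeric(0))
    for (ch in image$channels) out[[ch]] <- numeric(0)
    return(out)
  }
  f <- factor(labs, levels = labels)
  area_px <- as.vector(table(f))
  H <- nrow(mask)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  cx <- rowsum(as.numeric(cols), f)[, 1] / area_px
  cy <- rowsum(as.numeric(rows), f)[, 1] / area_px
  out <- data.frame(cell_id = labels, roi_id = image$roi_id,
                    x = cx, y = cy,
                    area = area_px * image$pixel_size^2,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  HW <- length(mask)
  for (k in seq_along(image$channels)) {
    v <- image$data[idx + (k - 1L) * HW]
    out[[image$channels[k]]] <- rowsum(v, f)[, 1] / area_px
  }
  out
}

#' Marker columns of a cell table
#' @param table A `CellTable`.
#' @return Character vector of marker column names (everything that is not
#'   a bookkeeping or derived column).
#' @export
marker_columns <- function(table) {
  reserved <- c("cell_id", "roi_id", "x", "y", "area", "group",
                "qc_pass", "qc_reason", "cluster_id", "phenotype",
                "immune_subtype")
  setdiff(names(table)[!grepl("_norm$", names(table))], reserved)
}

#' Quality-control filter for segmented objects
#'
#' Excludes objects likely to be debris or segmentation errors. A cell is
#' excluded iff any of: (a) area larger than `max_area` um^2; (b) mean
#' intensity above `high_threshold` in every marker simultaneously; (c)
#' mean intensity below `low_threshold` in every clustering marker
#' simultaneously. Thresholds default to 500 / 2 / 0.01 dual counts. A
#' warning is emitted when more than 2% of cells are discarded.
#'
#' @param table A `CellTable` from [quantify()].
#' @param clustering_markers Nonempty character vector of marker columns
#'   used for clustering (rule c is evaluated on these).
#' @param max_area,high_threshold,low_threshold Rule thresholds.
#' @return `list(cells = surviving rows, report = list(n_area, n_all_high,
#'   n_all_low, n_excluded, n_total, fraction_discarded))`. Rule counts may
#'   overlap; `n_excluded` counts distinct cells.
#' @export
qc_filter <- function(table, clustering_markers,
                      max_area = 500, high_threshold = 2,
                      low_threshold = 0.01) {
  if (length(clustering_markers) == 0) stop("clustering_markers is empty")
  markers <- marker_columns(table)
  missing <- setdiff(clustering_markers, markers)
  if (length(missing) > 0)
    stop("clustering marker(s) not in table: ", paste(missing, collapse = ", "))
  n <- nrow(table)
  if (n == 0) {
    return(list(cells = table,
                report = list(n_area = 0L, n_all_high = 0L, n_all_low = 0L,
                              n_excluded = 0L, n_total = 0L,
                              fraction_discarded = 0)))
  }
  m_all <- as.matrix(table[, markers, drop = FALSE])
  m_clu <- as.matrix(table[, clustering_markers, drop = FALSE])
  rule_a <- table$area > max_area
  rule_b <- rowSums(m_all > high_threshold) == ncol(m_all)
  rule_c <- rowSums(m_clu < low_threshold) == ncol(m_clu)
  drop <- rule_a | rule_b | rule_c
  frac <- mean(drop)
  if (frac > 0.02)
    warning(sprintf("QC discarded %.1f%% of cells (> 2%%)", 100 * frac))
  list(
    cells = table[!drop, , drop = FALSE],
    report = list(n_area = sum(rule_a), n_all_high = sum(rule_b),
                  n_all_low = sum(rule_c), n_excluded = sum(drop),
                  n_total = n, fraction_discarded = frac)
  )
}

#' Arcsinh-transform and percentile-normalize marker intensities
#'
#' Per marker, pooled over all cells of the table (i.e. over all ROIs of a
#' model, which are clustered jointly): `y = asinh(x / cofactor)`, then
#' linear scaling between the `lo` and `hi` quantiles of `y`, clipped to
#' `[0, 1]`. A marker whose two quantiles coincide is set to constant 0.
#' The transform is strictly monotone in the raw intensity inside the
#' clipping range.
#'
#' @param table A QC-filtered `CellTable`.
#' @param markers Marker columns to transform; defaults to all.
#' @param cofactor Arcsinh cofactor, default 1 (5 is the conventional
#'   suspension-cytometry alternative).
#' @param lo,hi Quantile bounds, defaults 0.01 and 0.99.
#' @return The table with one added column `<marker>_norm` per marker,
#'   values in `[0, 1]`.
#' @export
transform_normalize <- function(table, markers = marker_columns(table),
                                cofactor = 1, lo = 0.01, hi = 0.99) {
  for (mk in markers) {
    y <- asinh(table[[mk]] / cofactor)
    q <- stats::quantile(y, c(lo, hi), names = FALSE)
    if (q[2] > q[1]) {
      v <- pmin(pmax((y - q[1]) / (q[2] - q[1]), 0), 1)
    } else {
      v <- rep(0, length(y))
    }
    table[[paste0(mk, "_norm")]] <- v
  }
  table
}

#' Extract the normalized intensity matrix
#'
#' @param table A `CellTable` after [transform_normalize()].
#' @param markers Marker names (without the `_norm` suffix).
#' @return Numeric cell x marker matrix of normalized intensities.
#' @export
normalized_matrix <- function(table, markers) {
  cols <- paste0(markers, "_norm")
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0)
    stop("missing normalized column(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(table[, cols, drop = FALSE])
  colnames(m) <- markers
  m
}

#' Write / read a cell table as CSV
#'
#' Column order is preserved; marker names containing `/` or `-` survive
#' the round trip unmangled.
#'
#' @param table A `CellTable`.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
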