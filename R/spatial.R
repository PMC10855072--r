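#' Boundary pixels of every cell in a label mask
#'
#' A pixel belongs to its cell's boundary when any of its 4-neighbors
#' carries a different label (background included) or lies outside the
#' image.
#'
#' @param mask Integer label matrix (0 = background).
#' @return Named list (one entry per positive label, names = labels) of
#'   two-column matrices `(row, col)` of boundary pixel coordinates.
#' @export
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  ctr <- pad[2:(H + 1), 2:(W + 1)]
  diff4 <- (pad[1:H, 2:(W + 1)] != ctr) |
           (pad[3:(H + 2), 2:(W + 1)] != ctr) |
           (pad[2:(H + 1), 1:W] != ctr) |
           (pad[2:(H + 1), 3:(W + 2)] != ctr)
  idx <- which(ctr > 0 & diff4)
  labs <- ctr[idx]
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  split_idx <- split(seq_along(idx), labs)
  lapply(split_idx, function(s) cbind(row = rows[s], col = cols[s]))
}

#' Border-distance neighbor graph
#'
#' Two cells are neighbors when the minimum Euclidean distance between
#' their boundary pixels is strictly less than `radius` (30 um by
#' default). Candidate pairs are pruned by centroid distance before the
#' exact boundary-to-boundary minimum is computed, so the result equals
#' the brute-force all-pairs computation.
#'
#' @param mask Integer label matrix.
#' @param radius Neighborhood radius in um, default 30.
#' @param pixel_size Pixel side length in um, default 1.
#' @param roi_id ROI identifier.
#' @return Object of class `NeighborGraph`: `list(roi_id, nodes = labels,
#'   edges = two-column matrix of node labels, radius)`.
#' @export
neighbor_graph <- function(mask, radius = 30, pixel_size = 1, roi_id = "roi") {
  bp <- boundary_pixels(mask)
  nodes <- as.integer(names(bp))
  if (length(nodes) == 0)
    return(structure(list(roi_id = roi_id, nodes = integer(0),
                          edges = matrix(integer(0), 0, 2), radius = radius),
                     class = "NeighborGraph"))
  r_px <- radius / pixel_size
  cen <- t(vapply(bp, colMeans, numeric(2)))
  reach <- vapply(seq_along(bp), function(i) {
    sqrt(max((bp[[i]][, 1] - cen[i, 1])^2 + (bp[[i]][, 2] - cen[i, 2])^2))
  }, numeric(1))
  edges <- list()
  n <- length(nodes)
  for (i in seq_len(max(0, n - 1))) {
    dc <- sqrt((cen[(i + 1):n, 1] - cen[i, 1])^2 +
               (cen[(i + 1):n, 2] - cen[i, 2])^2)
    cand <- which(dc < r_px + reach[i] + reach[(i + 1):n]) + i
    for (j in cand) {
      d2 <- outer(bp[[i]][, 1], bp[[j]][, 1], "-")^2 +
            outer(bp[[i]][, 2], bp[[j]][, 2], "-")^2
      if (min(d2) < r_px^2)
        edges[[length(edges) + 1L]] <- c(nodes[i], nodes[j])
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    matrix(integer(0), 0, 2)
  structure(list(roi_id = roi_id, nodes = nodes, edges = edges,
                 radius = radius),
            class = "NeighborGraph")
}

#' Permutation test for phenotype-pair spatial interactions in one ROI
#'
#' For each ordered phenotype pair (A, B), the observed statistic is the
#' mean number of B-phenotype neighbors per A-phenotype cell. The null is
#' built by `n_perm` uniform permutations of the phenotype labels over the
#' nodes (graph fixed). Add-one p-values: `p_enrich = (1 + #\{null >=
#' obs\}) / (n_perm + 1)` and symmetrically for depletion, with ties
#' counted toward the null. The pair score is +1 when `p_enrich < alpha`,
#' -1 when `p_deplete < alpha`, else 0. Pairs whose A or B phenotype is
#' absent from the ROI are `NA` (undefined).
#'
#' @param graph A `NeighborGraph`.
#' @param phenotypes Phenotype per node: either a vector aligned with
#'   `graph$nodes` or a named vector keyed by node label. A factor fixes
#'   the full phenotype universe; characters use the ROI's own levels.
#' @param n_perm Number of permutations, >= 100; default 1000.
#' @param alpha Significance level, default 0.01.
#' @param seed Integer seed.
#' @return Object of class `InteractionResult`: `list(roi_id, observed,
#'   p_enrich, p_deplete, score, n_permutations, alpha, seed)`; all
#'   matrices are phenotype x phenotype (rows = A, cols = B).
#' @export
interaction_test_roi <- function(graph, phenotypes, n_perm = 1000,
                                 alpha = 0.01, seed = 1L) {
  stopifnot(inherits(graph, "NeighborGraph"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- length(graph$nodes)
  if (!is.null(names(phenotypes)))
    phenotypes <- phenotypes[as.character(graph$nodes)]
  if (length(phenotypes) != n)
    stop("phenotypes must cover every node")
  if (anyNA(phenotypes)) stop("every node needs a phenotype")
  f <- if (is.factor(phenotypes)) phenotypes else factor(phenotypes)
  types <- levels(f)
  Tn <- length(types)
  present <- types %in% f

  ei <- match(graph$edges[, 1], graph$nodes)
  ej <- match(graph$edges[, 2], graph$nodes)
  M <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei),
                            x = rep(1, 2 * length(ei)), dims = c(n, n))
  Z <- matrix(0, n, Tn)
  z <- as.integer(f)
  Z[cbind(seq_len(n), z)] <- 1

  stat <- function(perm) {
    zi <- z[perm]
    C <- as.matrix(M %*% Z[perm, , drop = FALSE])
    S <- matrix(NA_real_, Tn, Tn, dimnames = list(types, types))
    cnt <- tabulate(zi, nbins = Tn)
    sums <- rowsum(C, zi)  # rows only for types present in zi
    lev <- as.integer(rownames(sums))
    S[lev, ] <- sums / cnt[lev]
    S
  }
  obs <- stat(seq_len(n))
  set.seed(seed)
  ge <- matrix(0, Tn, Tn); le <- matrix(0, Tn, Tn)
  eps <- 1e-12
  for (p in seq_len(n_perm)) {
    S <- stat(sample.int(n))
    ge <- ge + (S >= obs - eps)
    le <- le + (S <= obs + eps)
  }
  p_enrich <- (1 + ge) / (n_perm + 1)
  p_deplete <- (1 + le) / (n_perm + 1)
  score <- matrix(0, Tn, Tn, dimnames = list(types, types))
  score[p_enrich < alpha] <- 1
  score[p_deplete < alpha] <- -1
  undef <- !present
  for (mat in c("p_enrich", "p_deplete", "score")) {
    m <- get(mat)
    m[undef, ] <- NA; m[, undef] <- NA
    assign(mat, m)
  }
  dimnames(p_enrich) <- dimnames(p_deplete) <- dimnames(obs) <-
    list(types, types)
  structure(
    list(roi_id = graph$roi_id, observed = obs, p_enrich = p_enrich,
         p_deplete = p_deplete, score = score, n_permutations = n_perm,
         alpha = alpha, seed = seed),
    class = "InteractionResult"
  )
}

#' Aggregate interaction scores over ROIs
#'
#' Per ordered phenotype pair, the mean of the defined (non-`NA`) per-ROI
#' scores; ROIs where the pair is undefined are excluded from that pair's
#' mean, and a pair undefined in every ROI stays `NA`.
#'
#' @param results List of `InteractionResult` objects sharing the same
#'   phenotype universe.
#' @return Phenotype x phenotype matrix of averaged scores in `[-1, 1]`.
#' @export
aggregate_scores <- function(results) {
  if (length(results) == 0) stop("empty result list")
  types <- rownames(results[[1]]$score)
  for (r in results)
    if (!identical(rownames(r$score), types))
      stop("results must share the same phenotype universe")
  acc <- matrix(0, length(types), length(types),
                dimnames = list(types, types))
  cnt <- acc
  for (r in results) {
    ok <- !is.na(r$score)
    acc[ok] <- acc[ok] + r$score[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA
  out
}
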