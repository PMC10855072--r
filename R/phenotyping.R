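#' Jaccard-weighted k-nearest-neighbor graph
#'
#' Phenograph-style graph construction: directed kNN by Euclidean distance
#' (k neighbors per cell, self excluded, ties resolved by the search
#' order), symmetrized into an undirected graph whose edge weights are the
#' Jaccard overlap `|N(i) n N(j)| / |N(i) u N(j)|` of the two
#' k-neighborhoods. Zero-weight edges are dropped.
#'
#' @param X Numeric cell x marker matrix (normalized intensities).
#' @param k Number of neighbors, default 100.
#' @return An undirected `igraph` graph with edge attribute `weight` in
#'   `(0, 1]` and one vertex per row of `X`.
#' @export
knn_graph <- function(X, k = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= k)
    stop("n = ", n, " cells but k = ", k, "; lower k below n")
  nn <- RANN::nn2(X, k = min(k + 1L, n))
  idx <- nn$nn.idx
  neigh <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- idx[i, ]
    self <- match(i, row)
    row <- if (is.na(self)) row[seq_len(k)] else row[-self][seq_len(k)]
    neigh[i, ] <- row
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), times = k),
                            j = as.vector(neigh), x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)           # |N(i) n N(j)|
  E <- (A + Matrix::t(A)) > 0          # union of directed kNN edges
  P <- S * E
  sm <- Matrix::summary(methods::as(P, "TsparseMatrix"))
  keep <- sm$i < sm$j & sm$x > 0
  w <- sm$x[keep] / (2 * k - sm$x[keep])
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(sm$i[keep], sm$j[keep]))
  igraph::E(g)$weight <- w
  g
}

#' Louvain community detection
#'
#' Modularity optimization on the weighted kNN graph; deterministic given
#' `seed`. Isolated vertices form singleton communities.
#'
#' @param graph Weighted undirected `igraph` graph.
#' @param seed Integer seed.
#' @return Integer cluster label per vertex (1-based consecutive ids).
#' @export
louvain_cluster <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, weights = igraph::E(graph)$weight)
  as.integer(igraph::membership(cl))
}

#' UMAP embedding for visualization
#'
#' Two-dimensional embedding of the normalized intensity matrix; used for
#' display only, never as clustering input. Deterministic given `seed`
#' (single-threaded optimization).
#'
#' @param X Numeric cell x marker matrix.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size, default 15.
#' @return `n x 2` coordinate matrix.
#' @export
umap_embed <- function(X, seed = 1L, n_neighbors = 15) {
  X <- as.matrix(X)
  if (nrow(X) < 10) stop("need at least 10 points")
  if (nrow(X) <= n_neighbors)
    stop("fewer points than n_neighbors = ", n_neighbors)
  set.seed(seed)
  uwot::umap(X, n_neighbors = n_neighbors, n_threads = 1, n_sgd_threads = 0)
}

#' Per-cluster mean intensity matrix
#'
#' @param X Cell x marker matrix.
#' @param labels Cluster label per row of `X`.
#' @return Cluster x marker matrix of means, rows ordered by label.
#' @export
cluster_means <- function(X, labels) {
  X <- as.matrix(X)
  f <- factor(labels)
  m <- rowsum(X, f) / as.vector(table(f))
  rownames(m) <- levels(f)
  m
}

#' Row-normalize a cluster mean matrix
#'
#' @param M Numeric matrix.
#' @param method `"minmax"` (each row scaled to `[0, 1]`; constant rows
#'   become 0) or `"zscore"`.
#' @return Normalized matrix.
#' @export
row_normalize <- function(M, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  t(apply(M, 1, function(r) {
    if (method == "minmax") {
      rng <- range(r)
      if (rng[2] > rng[1]) (r - rng[1]) / (rng[2] - rng[1]) else r * 0
    } else {
      s <- stats::sd(r)
      if (s > 0) (r - mean(r)) / s else r * 0
    }
  }))
}

#' Cluster-by-marker heatmap matrix
#'
#' Mean intensity per (cluster, marker), then each row min-max scaled to
#' `[0, 1]` (the display convention for per-cluster marker profiles).
#'
#' @param X Cell x marker matrix (normalized intensities).
#' @param labels Cluster label per cell.
#' @param method Row normalization, `"minmax"` (default) or `"zscore"`.
#' @return Cluster x marker matrix; entries in `[0, 1]` for `"minmax"`.
#' @export
cluster_heatmap <- function(X, labels, method = "minmax") {
  if (length(unique(labels)) < 1) stop("need at least one cluster")
  row_normalize(cluster_means(X, labels), method)
}

#' Default phenotype annotation rules
#'
#' Marker sets per phenotype class (endothelial: CD31; lymphatic: LYVE-1;
#' immune: CD45; stromal: aSMA/PDGFRb/Desmin/Collagen I; tumor:
#' ZO-1/CK19/E-cadherin/PanCK) and per immune subtype (F4/80 for
#' mono/macrophages, Ly6G for neutrophils, CD103 for dendritic cells,
#' B220 for B cells, CD3+CD4 and CD3+CD8 for T cells). When `markers` is
#' supplied, each rule is intersected with the available markers and
#' classes left without markers are dropped with a warning.
#'
#' @param markers Optional character vector of available markers.
#' @return `list(classes = named list of marker sets, immune_subtypes =
#'   named list of marker sets)`.
#' @export
default_annotation_rules <- function(markers = NULL) {
  rules <- list(
    classes = list(
      endothelial = "CD31",
      lymphatic = "LYVE-1",
      stromal = c("aSMA", "PDGFRb", "Desmin", "CollagenI"),
      tumor = c("ZO-1", "CK19", "E-cadherin", "PanCK"),
      immune = "CD45"
    ),
    immune_subtypes = list(
      mono_mac = "F4/80",
      dendritic = "CD103",
      neutrophil = "Ly6G",
      "CD4 T" = c("CD3", "CD4"),
      "CD8 T" = c("CD3", "CD8"),
      B = "B220"
    )
  )
  if (!is.null(markers)) {
    prune <- function(lst) {
      lst <- lapply(lst, intersect, y = markers)
      empty <- vapply(lst, length, integer(1)) == 0
      if (any(empty))
        warning("annotation class(es) without available markers dropped: ",
                paste(names(lst)[empty], collapse = ", "))
      lst[!empty]
    }
    rules$classes <- prune(rules$classes)
    rules$immune_subtypes <- prune(rules$immune_subtypes)
  }
  rules
}

#' Annotate clusters into phenotype classes
#'
#' Scores each cluster against each class as the mean, over the class's
#' markers, of the row-normalized (min-max) cluster mean profile. The
#' immune class score is the maximum of the CD45 score and the best immune
#' subtype score, so lineage markers (e.g. CD3/CD8) can establish the
#' immune class on their own. The arg-max class is assigned when its score
#' reaches `min_score`, otherwise the cluster falls to `"other"`; clusters
#' below `min_cluster_frac` of all cells also fall to `"other"`. Immune
#' clusters are sub-typed by the best subtype score at the same cutoff.
#'
#' @param M Cluster x marker mean matrix (any monotone intensity scale).
#' @param rules Rule list from [default_annotation_rules()].
#' @param min_score Minimum row-normalized score for assignment, default 0.5.
#' @param cluster_sizes Optional cell count per cluster (same order as
#'   rows of `M`) used for the small-cluster rule.
#' @param min_cluster_frac Clusters smaller than this fraction of all
#'   cells are labeled `"other"`, default 0.005.
#' @return `data.frame(cluster, phenotype, immune_subtype, score)`, one
#'   row per row of `M`.
#' @export
annotate_clusters <- function(M, rules = default_annotation_rules(colnames(M)),
                              min_score = 0.5, cluster_sizes = NULL,
                              min_cluster_frac = 0.005) {
  all_markers <- unique(unlist(c(rules$classes, rules$immune_subtypes)))
  missing <- setdiff(all_markers, colnames(M))
  if (length(missing) > 0)
    stop("rule marker(s) missing from matrix: ", paste(missing, collapse = ", "))
  R <- row_normalize(M, "minmax")
  score_set <- function(mks) rowMeans(R[, mks, drop = FALSE])
  cls <- vapply(rules$classes, score_set, numeric(nrow(R)))
  cls <- matrix(cls, nrow = nrow(R),
                dimnames = list(rownames(M), names(rules$classes)))
  sub <- vapply(rules$immune_subtypes, score_set, numeric(nrow(R)))
  sub <- matrix(sub, nrow = nrow(R),
                dimnames = list(rownames(M), names(rules$immune_subtypes)))
  if ("immune" %in% colnames(cls) && ncol(sub) > 0)
    cls[, "immune"] <- pmax(cls[, "immune"], apply(sub, 1, max))

  best <- max.col(cls, ties.method = "first")
  best_score <- cls[cbind(seq_len(nrow(cls)), best)]
  phenotype <- ifelse(best_score >= min_score, colnames(cls)[best], "other")

  if (!is.null(cluster_sizes)) {
    frac <- cluster_sizes / sum(cluster_sizes)
    phenotype[frac < min_cluster_frac] <- "other"
  }

  subtype <- rep(NA_character_, nrow(R))
  imm <- which(phenotype == "immune")
  if (length(imm) > 0 && ncol(sub) > 0) {
    bs <- max.col(sub[imm, , drop = FALSE], ties.method = "first")
    ss <- sub[cbind(imm, bs)]
    subtype[imm] <- ifelse(ss >= min_score, colnames(sub)[bs], NA_character_)
  }
  data.frame(
    cluster = if (is.null(rownames(M))) seq_len(nrow(M)) else rownames(M),
    phenotype = phenotype, immune_subtype = subtype,
    score = best_score, stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-ROI phenotype abundance
#'
#' Percentage of each ROI's cells per phenotype (or per immune subtype,
#' still as a percentage of all ROI cells). Phenotype percentages sum to
#' 100 within each ROI; every (ROI, label) combination is reported,
#' including zeros.
#'
#' @param table A `CellTable` with `roi_id` and the `by` column filled.
#' @param group Named character vector mapping ROI id to group (e.g.
#'   core/margin), or a single group name.
#' @param by `"phenotype"` or `"immune_subtype"`.
#' @return An `AbundanceTable` `data.frame`: `roi_id`, `group`, label
#'   column, `n`, `percent`.
#' @export
abundance <- function(table, group, by = c("phenotype", "immune_subtype")) {
  by <- match.arg(by)
  stopifnot(all(c("roi_id", by) %in% names(table)))
  rois <- unique(table$roi_id)
  lab <- table[[by]]
  keep <- !is.na(lab)
  tab <- table(factor(table$roi_id[keep], levels = rois),
               factor(lab[keep]))
  total <- as.vector(table(factor(table$roi_id, levels = rois)))
  empty <- total == 0
  if (any(empty)) {
    warning("empty ROI(s) excluded: ", paste(rois[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]; rois <- rois[!empty]
    total <- total[!empty]
  }
  out <- data.frame(
    roi_id = rep(rois, times = ncol(tab)),
    label = rep(colnames(tab), each = nrow(tab)),
    n = as.vector(tab),
    percent = as.vector(tab) / rep(total, times = ncol(tab)) * 100,
    stringsAsFactors = FALSE
  )
  names(out)[2] <- by
  out$group <- if (length(group) == 1 && is.null(names(group)))
    group else unname(group[out$roi_id])
  out[, c("roi_id", "group", by, "n", "percent")]
}

#' Compare per-ROI abundances between two groups
#'
#' Two-way ANOVA on per-ROI percentages with factors cluster and group,
#' followed by per-cluster between-group contrasts on the pooled residual
#' variance, Sidak-adjusted for the number of clusters compared:
#' `p_adj = 1 - (1 - p)^m`.
#'
#' @param ab An `AbundanceTable` from [abundance()] with exactly two
#'   groups and at least two ROIs per group.
#' @param alpha Significance level on adjusted p-values, default 0.05.
#' @return `data.frame` per cluster: group means, difference, `t`, `df`,
#'   `p`, `p_adj`, `significant`.
#' @export
compare_abundance <- function(ab, alpha = 0.05) {
  label_col <- setdiff(names(ab), c("roi_id", "group", "n", "percent"))[1]
  groups <- unique(ab$group)
  if (length(groups) != 2) stop("exactly two groups required")
  n_roi <- vapply(groups,
                  function(g) length(unique(ab$roi_id[ab$group == g])),
                  integer(1))
  if (any(n_roi < 2)) stop("each group needs >= 2 ROIs")
  ab$cluster <- factor(ab[[label_col]])
  ab$group <- factor(ab$group, levels = groups)
  fit <- stats::aov(percent ~ group * cluster, data = ab)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  df <- stats::df.residual(fit)
  m <- nlevels(ab$cluster)
  res <- lapply(levels(ab$cluster), function(cl) {
    x1 <- ab$percent[ab$cluster == cl & ab$group == groups[1]]
    x2 <- ab$percent[ab$cluster == cl & ab$group == groups[2]]
    d <- mean(x1) - mean(x2)
    se <- sqrt(mse * (1 / length(x1) + 1 / length(x2)))
    t <- d / se
    p <- 2 * stats::pt(-abs(t), df)
    data.frame(cluster = cl, mean_1 = mean(x1), mean_2 = mean(x2),
               diff = d, t = t, df = df, p = p,
               p_adj = sidak_adjust(p, m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", groups)
  out$significant <- out$p_adj < alpha
  out
}

#' Cluster and annotate a cell table
#'
#' Convenience wrapper over the phenotyping stages. Clustering runs on the
#' percentile-normalized intensities (phenograph-style kNN + Louvain);
#' annotation scores are computed on arcsinh-scale cluster means rather
#' than the percentile-normalized values, because percentile normalization
#' stretches markers that are pure background everywhere to mid-scale
#' noise, which would corrupt marker-based class scores.
#'
#' @param table A QC-filtered `CellTable` already passed through
#'   [transform_normalize()].
#' @param clustering_markers Markers used for the kNN graph.
#' @param k Neighborhood size for [knn_graph()], default 100.
#' @param seed Integer seed (Louvain).
#' @param rules Annotation rules; default rules restricted to
#'   `clustering_markers`.
#' @param min_score Annotation score cutoff, default 0.5.
#' @param cofactor Arcsinh cofactor for the annotation-scale means.
#' @param min_cluster_frac Small-cluster cutoff, default 0.005.
#' @return `list(table, clusters)`: the table gains `cluster_id`,
#'   `phenotype` and `immune_subtype` columns; `clusters` is the
#'   annotation `data.frame` from [annotate_clusters()] with cell counts.
#' @export
phenotype_cells <- function(table, clustering_markers, k = 100, seed = 1L,
                            rules = default_annotation_rules(clustering_markers),
                            min_score = 0.5, cofactor = 1,
                            min_cluster_frac = 0.005) {
  X <- normalized_matrix(table, clustering_markers)
  g <- knn_graph(X, k = k)
  cl <- louvain_cluster(g, seed = seed)
  raw <- as.matrix(table[, clustering_markers, drop = FALSE])
  M <- cluster_means(asinh(raw / cofactor), cl)
  sizes <- as.vector(table(factor(cl, levels = rownames(M))))
  ann <- annotate_clusters(M, rules, min_score = min_score,
                           cluster_sizes = sizes,
                           min_cluster_frac = min_cluster_frac)
  ann$n_cells <- sizes
  pos <- match(as.character(cl), ann$cluster)
  table$cluster_id <- cl
  table$phenotype <- ann$phenotype[pos]
  table$immune_subtype <- ann$immune_subtype[pos]
  list(table = table, clusters = ann)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons.
#'
#' @param p Unadjusted p-value(s).
#' @param m Number of comparisons.
#' @return Adjusted p-value(s), capped at 1.
#' @export
sidak_adjust <- function(p, m) pmin(1, -expm1(m * log1p(-p)))
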