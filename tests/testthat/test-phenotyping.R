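test_that("the 3-point kNN graph reproduces hand-computed Jaccard weights", {
  X <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  g <- knn_graph(X, k = 2)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)  # complete graph
  # N(i) = the other two points; |intersection| = 1, |union| = 3
  expect_equal(igraph::E(g)$weight, rep(1 / 3, 3))
})

test_that("kNN graph weights are valid and k is bounded by n", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4)
  g <- knn_graph(X, k = 10)
  w <- igraph::E(g)$weight
  expect_true(all(w > 0 & w <= 1))
  expect_false(igraph::is_directed(g))
  expect_error(knn_graph(X, k = 50), "lower k")

  # duplicated points still give a valid graph
  Xd <- rbind(X, X[1:5, ])
  gd <- knn_graph(Xd, k = 10)
  expect_equal(igraph::vcount(gd), 55)
  expect_true(all(igraph::E(gd)$weight > 0))
  expect_false(any(igraph::which_loop(gd)))
})

test_that("Louvain finds block structure and is deterministic", {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  igraph::E(g)$weight <- 1
  cl <- louvain_cluster(g, seed = 4)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:10])), 1)
  expect_identical(cl, louvain_cluster(g, seed = 4))
  expect_error(louvain_cluster(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("two Gaussian blobs are recovered exactly (ARI = 1)", {
  set.seed(9)
  X <- rbind(matrix(rnorm(500 * 5, 0), 500, 5),
             matrix(rnorm(500 * 5, 8), 500, 5))
  truth <- rep(1:2, each = 500)
  g <- knn_graph(X, k = 100)
  cl <- louvain_cluster(g, seed = 9)
  expect_equal(mclust::adjustedRandIndex(cl, truth), 1.0)
})

test_that("UMAP embeds deterministically and separates blobs", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60 * 4, 0), 60, 4),
             matrix(rnorm(60 * 4, 10), 60, 4))
  e1 <- umap_embed(X, seed = 3)
  expect_equal(dim(e1), c(120, 2))
  expect_identical(e1, umap_embed(X, seed = 3))
  d <- as.matrix(dist(e1))
  intra <- mean(d[1:60, 1:60]); inter <- mean(d[1:60, 61:120])
  expect_gt(inter, intra)
  expect_error(umap_embed(X[1:5, ], seed = 1), "at least 10")
})

test_that("cluster heatmap rows are min-max scaled", {
  X <- matrix(rep(c(2, 4, 6), each = 4), 4, 3)
  colnames(X) <- c("a", "b", "c")
  hm <- cluster_heatmap(X, rep(1, 4))
  expect_equal(as.vector(hm), c(0, 0.5, 1))
  # constant row convention
  expect_equal(as.vector(row_normalize(matrix(5, 1, 3), "minmax")),
               c(0, 0, 0))
  set.seed(1)
  hm2 <- cluster_heatmap(matrix(runif(60), 20, 3), rep(1:2, 10))
  expect_true(all(hm2 >= 0 & hm2 <= 1))
})

test_that("annotation rules assign classes and immune subtypes", {
  mks <- c("CD31", "LYVE-1", "aSMA", "PDGFRb", "Desmin", "CollagenI",
           "ZO-1", "CD45", "F4/80", "CD103", "Ly6G", "CD3", "CD4", "CD8",
           "B220")
  rules <- default_annotation_rules(mks)
  M <- matrix(0, 3, length(mks), dimnames = list(1:3, mks))
  M[1, c("CD3", "CD8")] <- 1          # T-cell lineage markers only
  M[2, "CD31"] <- 1                   # endothelial
  M[3, "aSMA"] <- 1  # one of four stromal markers: best score is only 0.25
  ann <- annotate_clusters(M, rules)
  expect_equal(ann$phenotype, c("immune", "endothelial", "other"))
  expect_equal(ann$immune_subtype[1], "CD8 T")
  expect_true(is.na(ann$immune_subtype[2]))

  expect_error(annotate_clusters(M[, 1:5], rules), "missing")

  # small clusters fall to "other"
  ann2 <- annotate_clusters(M, rules, cluster_sizes = c(1, 1000, 1000),
                            min_cluster_frac = 0.005)
  expect_equal(ann2$phenotype[1], "other")
})

test_that("rules are pruned to available markers with a warning", {
  w <- capture_warnings(r <- default_annotation_rules(c("CD31", "CD45", "ZO-1")))
  expect_match(w, "dropped", all = TRUE)
  expect_named(r$classes, c("endothelial", "tumor", "immune"),
               ignore.order = TRUE)
  expect_equal(r$classes$tumor, "ZO-1")
})

test_that("abundance percentages are exact and conserved", {
  tab <- data.frame(
    roi_id = rep(c("r1", "r2"), c(200, 100)),
    phenotype = c(rep("stromal", 50), rep("tumor", 150),
                  rep("tumor", 100))
  )
  ab <- abundance(tab, group = c(r1 = "core", r2 = "margin"))
  expect_equal(ab$percent[ab$roi_id == "r1" & ab$phenotype == "stromal"], 25)
  sums <- tapply(ab$percent, ab$roi_id, sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  expect_equal(unique(ab$group[ab$roi_id == "r2"]), "margin")
})

test_that("Sidak adjustment matches its closed form", {
  expect_equal(sidak_adjust(0, 6), 0)
  expect_equal(sidak_adjust(0.01, 6), 1 - 0.99^6)
  expect_equal(round(sidak_adjust(0.01, 6), 4), 0.0585)
  expect_equal(sidak_adjust(0.9, 10), 1)
})

test_that("abundance comparison needs two groups with >= 2 ROIs", {
  tab <- data.frame(
    roi_id = rep(c("a1", "a2", "b1"), each = 10),
    phenotype = rep(rep(c("t", "s"), 5), 3)
  )
  ab <- abundance(tab, group = c(a1 = "g1", a2 = "g1", b1 = "g2"))
  expect_error(compare_abundance(ab), ">= 2 ROIs")
})

test_that("abundance comparison detects a planted group shift", {
  set.seed(12)
  mk_ab <- function(shift) {
    rois <- paste0("r", 1:10)
    grp <- rep(c("core", "margin"), each = 5)
    rows <- lapply(1:10, function(i) {
      p <- c(40, 30, 20, 10) + rnorm(4, 0, 2)
      if (grp[i] == "margin") p <- p + c(-15, 15, 0, 0) * shift
      p <- pmax(p, 0.1); p <- p / sum(p) * 100
      data.frame(roi_id = rois[i], group = grp[i],
                 phenotype = c("tumor", "stromal", "immune", "other"),
                 n = NA, percent = p)
    })
    do.call(rbind, rows)
  }
  res <- compare_abundance(mk_ab(1))
  expect_true(res$significant[res$cluster == "tumor"])
  expect_true(res$significant[res$cluster == "stromal"])
  expect_false(res$significant[res$cluster == "other"])
  expect_true(all(res$p_adj >= res$p))
})

test_that("abundance comparison is calibrated under the null", {
  set.seed(77)
  n_sig <- 0; n_tot <- 0
  for (rep_i in 1:200) {
    counts <- stats::rmultinom(10, 400, prob = c(0.4, 0.3, 0.2, 0.1))
    ab <- data.frame(
      roi_id = rep(paste0("r", 1:10), each = 4),
      group = rep(rep(c("g1", "g2"), each = 5), each = 4),
      phenotype = rep(c("a", "b", "c", "d"), 10),
      n = as.vector(counts),
      percent = as.vector(counts) / 4
    )
    res <- compare_abundance(ab)
    n_sig <- n_sig + sum(res$significant)
    n_tot <- n_tot + nrow(res)
  }
  # Sidak-adjusted per-cluster tests: well below the 5% + MC margin
  expect_lte(n_sig / n_tot, 0.05 + 0.03)
})

test_that("end-to-end phenotyping recovers the planted types on a small run", {
  panel <- imc_panel()
  sig <- default_signatures(panel)
  sm <- synth_cell_matrix(c(tumor = 150, stromal = 150, immune = 150,
                            endothelial = 80, lymphatic = 60, other = 80),
                          sig, seed = 14)
  clm <- panel_markers(panel, "clustering")
  tab <- as.data.frame(sm$intensity, check.names = FALSE)
  tab$cell_id <- seq_len(nrow(tab)); tab$roi_id <- "r"
  tab <- transform_normalize(tab, clm)
  ph <- phenotype_cells(tab, clm, k = 30, seed = 14)
  expect_gte(mean(ph$table$phenotype == sm$type), 0.95)
  expect_equal(ph$clusters$immune_subtype[ph$clusters$phenotype == "immune"],
               "mono_mac")
})
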