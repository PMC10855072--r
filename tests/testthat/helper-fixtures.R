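# Shared fixture builders. Everything is generated in code at test time.

# compact three-marker signature set for fast rendering
tiny_signatures <- function(dispersion = 0.25, background = 1) {
  m <- matrix(background, 2, 3,
              dimnames = list(c("A", "B"), c("M1", "M2", "M3")))
  m["A", "M1"] <- 100
  m["B", "M2"] <- 100
  signature_matrix(m, dispersion = dispersion, background = background)
}

tiny_panel <- function() {
  data.frame(
    target = c("M1", "M2", "M3"),
    metal = c("141Pr", "143Nd", "145Nd"),
    use_for_segmentation = c(TRUE, TRUE, FALSE),
    use_for_clustering = c(TRUE, TRUE, TRUE),
    low_threshold = 0,
    stringsAsFactors = FALSE
  )
}

# hand-built probability maps: disks of nuclei posterior 1, a cytoplasm
# ring, background elsewhere
make_probmaps <- function(H, W, centers, r_nuc = 4, ring = 2) {
  nuc <- matrix(0, H, W); cyt <- matrix(0, H, W)
  for (i in seq_len(nrow(centers))) {
    for (rr in 1:H) for (cc in 1:W) {
      d2 <- (rr - centers[i, 2])^2 + (cc - centers[i, 1])^2
      if (d2 <= r_nuc^2) nuc[rr, cc] <- 1
      else if (d2 <= (r_nuc + ring)^2) cyt[rr, cc] <- max(cyt[rr, cc], 1)
    }
  }
  bg <- 1 - pmax(nuc, cyt)
  maps <- array(c(nuc, cyt, bg), dim = c(H, W, 3),
                dimnames = list(NULL, NULL,
                                c("nuclei", "cytoplasm", "background")))
  structure(maps, class = "ProbabilityMaps")
}

# brute-force oracle: neighbor edges from all boundary-pixel pairs
brute_force_edges <- function(mask, radius) {
  bp <- boundary_pixels(mask)
  labs <- as.integer(names(bp))
  edges <- list()
  if (length(labs) >= 2) {
    for (i in 1:(length(labs) - 1)) for (j in (i + 1):length(labs)) {
      d2 <- outer(bp[[i]][, 1], bp[[j]][, 1], "-")^2 +
            outer(bp[[i]][, 2], bp[[j]][, 2], "-")^2
      if (min(d2) < radius^2)
        edges[[length(edges) + 1]] <- c(labs[i], labs[j])
    }
  }
  if (length(edges) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, edges)
}

edge_key <- function(e) {
  if (nrow(e) == 0) return(character(0))
  sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-"))
}

# exact enumeration oracle for a two-type permutation null: enumerate all
# placements of the A labels, return P(stat >= obs) and P(stat <= obs) for
# the ordered pair (A, B)
enumerate_pair_p <- function(adj, labels, a = "A", b = "B") {
  n <- nrow(adj)
  ia <- which(labels == a)
  stat <- function(aset) {
    bset <- setdiff(seq_len(n), aset)
    mean(rowSums(adj[aset, bset, drop = FALSE]))
  }
  obs <- stat(ia)
  sets <- utils::combn(n, length(ia))
  vals <- apply(sets, 2, stat)
  list(obs = obs,
       p_enrich = mean(vals >= obs - 1e-12),
       p_deplete = mean(vals <= obs + 1e-12))
}

# random-disk mask on a small canvas for oracle-equivalence tests
random_disk_mask <- function(seed, H = 64, W = 64, n_min = 5, n_max = 25) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  lay <- layout_spec("random", image_size = c(H, W),
                     n_cells = c(A = n), min_center_distance = 8,
                     nucleus_radius = 3, cyto_ring = 1)
  cells <- place_cells(lay, seed = seed + 1)
  truth_mask(cells)
}
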