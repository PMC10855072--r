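#' IMC antibody panel
#'
#' Returns the 28-marker metal-tagged antibody panel used throughout the
#' package, one row per marker channel in acquisition order. Each entry
#' carries two role flags: `use_for_segmentation` marks membrane/cytoplasm
#' markers fed (together with the DNA channel) to the pixel classifier, and
#' `use_for_clustering` marks the markers used for dimensionality reduction
#' and phenotype clustering. `low_threshold` is the per-channel low-intensity
#' cutoff (dual counts on the normalized scale), 0 by default.
#'
#' @param model Which clustering marker subset to flag: `"orthotopic"`
#'   (19 markers; PanCK/PV1 excluded along with epithelial keratins absent
#'   from that model) or `"kpc"` (21 markers, adding PanCK, CK19 and
#'   E-cadherin).
#' @return A `data.frame` with columns `target`, `metal`,
#'   `use_for_segmentation`, `use_for_clustering`, `low_threshold`.
#' @export
imc_panel <- function(model = c("orthotopic", "kpc")) {
  model <- match.arg(model)
  target <- c("Ly6G", "Vimentin", "MHC-II", "CD45", "PanCK", "Fibrinogen",
              "aSMA", "CK19", "F4/80", "PDGFRa", "uPAR", "PDGFRb",
              "E-cadherin", "CD3", "PV1", "CD4", "CD8", "LYVE-1", "Desmin",
              "CD31", "CollagenIV", "CD206", "CollagenI", "CD44", "CD11b",
              "ZO-1", "CD103", "B220")
  metal <- c("141Pr", "143Nd", "145Nd", "147Sm", "148Nd", "149Sm", "151Eu",
             "152Sm", "153Eu", "154Sm", "155Gd", "156Gd", "158Gd", "159Tb",
             "160Gd", "161Dy", "163Dy", "164Dy", "165Ho", "166Er", "167Er",
             "168Er", "169Tm", "171Yb", "172Yb", "173Yb", "175Lu", "176Yb")
  seg <- target %in% c("CD45", "aSMA", "CD31", "LYVE-1", "Vimentin",
                       "E-cadherin", "ZO-1")
  clu_ortho <- c("Ly6G", "Vimentin", "CD45", "aSMA", "F4/80", "PDGFRa",
                 "PDGFRb", "CD3", "CD4", "CD8", "LYVE-1", "Desmin", "CD31",
                 "CollagenIV", "CollagenI", "CD11b", "ZO-1", "CD103", "B220")
  clu <- if (model == "orthotopic") clu_ortho else
    c(setdiff(clu_ortho, "CD11b"), "PanCK", "CK19", "E-cadherin")
  data.frame(
    target = target,
    metal = metal,
    use_for_segmentation = seg,
    use_for_clustering = target %in% clu,
    low_threshold = 0,
    stringsAsFactors = FALSE
  )
}

#' Extract marker names for a panel role
#'
#' @param panel A panel `data.frame` as returned by [imc_panel()].
#' @param role `"segmentation"`, `"clustering"` or `"all"`.
#' @return Character vector of marker names, in panel order.
#' @export
panel_markers <- function(panel, role = c("all", "segmentation", "clustering")) {
  role <- match.arg(role)
  stopifnot(is.data.frame(panel), "target" %in% names(panel))
  switch(role,
    all = panel$target,
    segmentation = panel$target[panel$use_for_segmentation],
    clustering = panel$target[panel$use_for_clustering]
  )
}

# role flags <-> compact "role" CSV column ("segmentation;clustering", "" = none)
.roles_to_string <- function(panel) {
  vapply(seq_len(nrow(panel)), function(i) {
    paste(c(
      if (panel$use_for_segmentation[i]) "segmentation",
      if (panel$use_for_clustering[i]) "clustering"
    ), collapse = ";")
  }, character(1))
}

#' Write a panel table to CSV
#'
#' Writes columns `target`, `metal`, `role` in panel order; the two role
#' flags are folded into a single semicolon-separated `role` column.
#'
#' @param panel Panel `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(
    target = panel$target,
    metal = panel$metal,
    role = .roles_to_string(panel),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a panel table from CSV
#'
#' Inverse of [write_panel()]; `low_threshold` defaults to 0 when the
#' column is absent.
#'
#' @param path CSV path with columns `target`, `metal`, `role`.
#' @return Panel `data.frame` in the layout of [imc_panel()].
#' @export
read_panel <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("target", "metal", "role") %in% names(raw)))
  if (anyDuplicated(raw$metal)) stop("metal tags must be unique")
  roles <- strsplit(ifelse(is.na(raw$role), "", raw$role), ";", fixed = TRUE)
  data.frame(
    target = raw$target,
    metal = raw$metal,
    use_for_segmentation = vapply(roles, function(r) "segmentation" %in% r, logical(1)),
    use_for_clustering = vapply(roles, function(r) "clustering" %in% r, logical(1)),
    low_threshold = if ("low_threshold" %in% names(raw)) raw$low_threshold else 0,
    stringsAsFactors = FALSE
  )
}
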