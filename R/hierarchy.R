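#' Hierarchical clustering of chromosomes by gain profiles
#'
#' Clusters the panel chromosomes by the Euclidean distance between their
#' per-cell gain columns, with complete-linkage agglomeration. Chromosomes
#' gained early in leukemogenesis are carried by (almost) every cell, so
#' their columns separate from the rest at large distances: position towards
#' the base of the tree is read as earlier acquisition.
#'
#' @param gain_matrix Numeric matrix, rows = cells, columns = panel
#'   chromosomes (per-cell gain integers).
#' @return An `hclust` object over the chromosome columns.
#' @export
chromosome_linkage <- function(gain_matrix) {
  gain_matrix <- as.matrix(gain_matrix)
  if (ncol(gain_matrix) < 2) stop("need at least 2 chromosome columns")
  d <- stats::dist(t(gain_matrix), method = "euclidean")
  stats::hclust(d, method = "complete")
}

#' Cluster unique subclones across samples with row standardization
#'
#' Rows (unique subclones) are standardized to zero mean and unit population
#' SD (the heatmap z-score convention); constant rows become zero vectors
#' and are flagged. Both axes are then clustered with complete-linkage
#' Euclidean agglomeration, ready for heatmap rendering.
#'
#' @param freq_matrix Numeric matrix: rows = unique subclone codes, columns
#'   = samples or groups, entries = clone frequencies.
#' @return List with `z` (row-standardized matrix), `row_tree`, `col_tree`
#'   (`hclust` objects), `constant_rows` (row names flagged).
#' @export
clone_clustering <- function(freq_matrix) {
  m <- as.matrix(freq_matrix)
  z <- t(apply(m, 1, row_zscore))
  dimnames(z) <- dimnames(m)
  const_idx <- which(apply(m, 1, function(r) isTRUE(stats::sd(r) == 0)))
  if (length(const_idx) == nrow(m)) stop("all rows are constant")
  constant <- if (is.null(rownames(m))) const_idx else rownames(m)[const_idx]
  list(z = z,
       row_tree = stats::hclust(stats::dist(z), method = "complete"),
       col_tree = stats::hclust(stats::dist(t(z)), method = "complete"),
       constant_rows = constant)
}

# z-score with population SD; constant rows map to zero
row_zscore <- function(r) {
  s <- stats::sd(r) * sqrt((length(r) - 1) / length(r))
  if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
}

#' Acquisition order of chromosomes from a dendrogram
#'
#' Ranks leaves by the height at which they separate from the remaining
#' set: walking down from the root, at each split the smaller side is
#' assigned the split height and the walk continues into the larger side
#' (at an equal split both sides are assigned and the walk stops). Larger
#' separation heights (closer to the base of the tree) are read as earlier
#' acquisition; equal heights share a rank.
#'
#' @param tree An `hclust` object (e.g. from [chromosome_linkage()]).
#' @return Data frame `label`, `height`, `rank` (1 = base of the tree),
#'   ordered by rank.
#' @export
gain_order <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  labels <- tree$labels
  sep_height <- stats::setNames(rep(NA_real_, length(labels)), labels)

  leaves_of <- function(node) {
    # node: negative = leaf index, positive = merge row
    if (node < 0) return(-node)
    c(leaves_of(tree$merge[node, 1]), leaves_of(tree$merge[node, 2]))
  }
  assign_side <- function(node, h) {
    sep_height[labels[leaves_of(node)]] <<- h
  }
  walk <- function(node) {
    h <- tree$height[node]
    a <- tree$merge[node, 1]; b <- tree$merge[node, 2]
    na <- length(leaves_of(a)); nb <- length(leaves_of(b))
    if (na == nb) {            # equal split: both sides separate here
      assign_side(a, h); assign_side(b, h)
    } else if (na < nb) {      # smaller side peels off; continue into larger
      assign_side(a, h); walk(b)
    } else {
      assign_side(b, h); walk(a)
    }
  }
  walk(nrow(tree$merge))
  out <- data.frame(label = labels, height = unname(sep_height[labels]),
                    stringsAsFactors = FALSE)
  # dense rank on descending height; ties (within numeric tolerance) share
  h_round <- signif(out$height, 12)
  out$rank <- match(h_round, sort(unique(h_round), decreasing = TRUE))
  out[order(out$rank, out$label), ]
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths are merge-height differences, so root-to-leaf path length
#' equals the root merge height.
#'
#' @param tree An `hclust` object.
#' @param path Optional file path; when NULL the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
export_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
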