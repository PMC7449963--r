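#' Binding-site overlap fraction between two motifs
#'
#' The overlap coefficient of two site sets: the number of sites of the
#' smaller set overlapping (by at least `min_bp` bp) any site of the other
#' set, divided by the size of the smaller set. With this denominator a
#' motif whose sites are nested inside a larger motif's site set scores 1,
#' which groups TF families sharing near-identical motifs tightly. Either
#' set empty gives 0.
#'
#' @param sites_a,sites_b Interval tibbles (`chrom`, `start`, `end`).
#' @param min_bp Minimum overlap in bp to count (default 1).
#' @return Overlap fraction in `[0, 1]`; symmetric in its arguments.
#' @export
overlap_fraction <- function(sites_a, sites_b, min_bp = 1L) {
  if (nrow(sites_a) == 0 || nrow(sites_b) == 0) return(0)
  if (nrow(sites_b) < nrow(sites_a)) {
    tmp <- sites_a; sites_a <- sites_b; sites_b <- tmp
  }
  hits <- 0L
  for (ch in unique(sites_a$chrom)) {
    a <- sites_a[sites_a$chrom == ch, ]
    b <- sites_b[sites_b$chrom == ch, ]
    if (nrow(b) == 0) next
    ra <- IRanges::IRanges(a$start + 1L, a$end)
    rb <- IRanges::IRanges(b$start + 1L, b$end)
    hits <- hits + sum(IRanges::countOverlaps(ra, rb, minoverlap = min_bp) > 0)
  }
  hits / nrow(sites_a)
}

#' Pairwise overlap-distance matrix over motifs
#'
#' `D[i, j] = 1 - overlap_fraction(sites of i, sites of j)`.
#'
#' @param sites Binding-site tibble with a `motif_id` column; optionally
#'   pre-filtered to bound sites.
#' @param min_bp Passed to [overlap_fraction()].
#' @return Symmetric distance matrix with motif ids as dimnames (ids in
#'   lexicographic order).
#' @export
overlap_distance_matrix <- function(sites, min_bp = 1L) {
  ids <- sort(unique(sites$motif_id))
  by_id <- split(sites, sites$motif_id)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- 1 - overlap_fraction(by_id[[ids[i]]], by_id[[ids[j]]], min_bp)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Hierarchical motif tree from an overlap-distance matrix
#'
#' Agglomerative clustering (complete linkage by default) of motifs by
#' binding-site overlap distance, with deterministic tie-breaking by
#' lexicographic motif id. A tree height of 0.2 between two motifs means
#' their site sets overlap by 80%. Flat clusters are cut at `cut`
#' (default 0.5, i.e. motifs sharing more than half their sites co-cluster).
#'
#' @param D Symmetric distance matrix from [overlap_distance_matrix()].
#' @param linkage Agglomeration method for [stats::hclust()]
#'   (default "complete").
#' @param cut Height at which flat clusters are extracted (default 0.5).
#' @return A `motif_tree` list: `hclust` (the fit), `newick` (string),
#'   `clusters` (tibble `motif_id`, `cluster`), `cut`, `linkage`.
#'   Single-motif input yields a single-leaf tree with one cluster.
#' @export
build_tree <- function(D, linkage = "complete", cut = 0.5) {
  ids <- sort(rownames(D))
  if (length(ids) < 2) {
    return(structure(list(
      hclust = NULL, newick = sprintf("(%s);", ids[1] %||% ""),
      clusters = tibble(motif_id = ids, cluster = seq_along(ids)),
      cut = cut, linkage = linkage), class = "motif_tree"))
  }
  D <- D[ids, ids]
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  phy <- ape::as.phylo(hc)
  cl <- stats::cutree(hc, h = cut)
  structure(list(
    hclust = hc,
    newick = ape::write.tree(phy),
    clusters = tibble(motif_id = names(cl), cluster = unname(cl)),
    cut = cut, linkage = linkage), class = "motif_tree")
}

#' @export
print.motif_tree <- function(x, ...) {
  n <- nrow(x$clusters)
  cat(sprintf("motif tree: %d motifs, %s linkage, %d clusters at cut %.2f\n",
              n, x$linkage, length(unique(x$clusters$cluster)), x$cut))
  invisible(x)
}

#' Tree distance between two motifs in a fitted motif tree
#'
#' The cophenetic (merge) height at which the two motifs join, i.e. the
#' dendrogram depth separating them.
#'
#' @param tree A `motif_tree` from [build_tree()].
#' @param a,b Motif ids.
#' @return Numeric tree distance.
#' @export
tree_distance <- function(tree, a, b) {
  if (is.null(tree$hclust)) abort("tree has fewer than 2 leaves")
  cm <- as.matrix(stats::cophenetic(tree$hclust))
  cm[a, b]
}
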