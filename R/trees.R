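#' Neighbour-joining tree from a distance matrix, midpoint rooted
#'
#' Builds a neighbour-joining tree from pairwise distances — typically
#' `1 - identity/100` for one gene family across genomes, or `1 - ANI/100`
#' for whole genomes — and midpoint-roots it for display. The topology is
#' independent of taxon input order for distinct distances; ties are resolved
#' by the joining order of the underlying implementation.
#'
#' @param d Symmetric numeric matrix (or `dist`) over at least 3 taxa, with
#'   dimnames.
#' @return An [ape::phylo] tree, midpoint rooted.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) rb_abort("d must be a square matrix")
  if (nrow(d) < 3) rb_abort("need at least 3 taxa")
  if (is.null(rownames(d))) rb_abort("distance matrix needs taxon names")
  if (max(abs(d - t(d))) > 1e-8) rb_abort("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(d))
  phangorn::midpoint(tr)
}

# all non-trivial splits of an unrooted tree, each split canonicalised as the
# sorted side not containing the first taxon
tree_splits <- function(tree, taxa) {
  tr <- ape::unroot(tree)
  bp <- ape::prop.part(tr)
  labels <- attr(bp, "labels")
  splits <- purrr::map(bp, function(idx) sort(labels[idx]))
  splits <- purrr::map(splits, function(s) {
    if (taxa[1] %in% s) sort(setdiff(taxa, s)) else s
  })
  # keep non-trivial splits only (2 <= |side| <= n - 2)
  n <- length(taxa)
  splits <- purrr::keep(splits, function(s) length(s) >= 2 && length(s) <= n - 2)
  unique(purrr::map_chr(splits, paste, collapse = "|"))
}

#' Robinson-Foulds distance and discordant splits between two trees
#'
#' Compares two unrooted topologies on the same leaf set: the RF distance is
#' the number of non-trivial bipartitions present in exactly one of the
#' trees, and those bipartitions are returned explicitly. Rooting is ignored
#' (it is presentational for midpoint-rooted NJ trees).
#'
#' @param t1,t2 [ape::phylo] trees with identical leaf sets.
#' @return List with `rf_distance` (integer) and `discordant_splits`
#'   (character vector, each split as `taxon|taxon|...`).
#' @export
compare_trees <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    rb_abort("trees have different leaf sets (no pruning is performed)")
  }
  taxa <- sort(t1$tip.label)
  s1 <- tree_splits(t1, taxa)
  s2 <- tree_splits(t2, taxa)
  disc <- c(setdiff(s1, s2), setdiff(s2, s1))
  list(rf_distance = length(disc), discordant_splits = disc)
}
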