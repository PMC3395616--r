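# Phylogenetic (tree path) and functional (gene-family Jaccard) distances
# between clades, and their join onto network edges.

#' Pairwise leaf distances from a newick tree
#'
#' Path-length (patristic) distances: the sum of branch lengths along the
#' path between every pair of leaves, via [ape::cophenetic.phylo()].
#'
#' @param tree Newick text, a path to a newick file, or an `ape::phylo`
#'   object. Branch lengths are required; missing lengths are an error,
#'   never defaulted.
#' @return Symmetric numeric matrix with leaf names on both dimensions.
#' @export
leaf_distances <- function(tree) {
  phy <- if (inherits(tree, "phylo")) {
    tree
  } else if (file.exists(tree)) {
    ape::read.tree(tree)
  } else {
    ape::read.tree(text = tree)
  }
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop("tree has missing branch lengths", call. = FALSE)
  }
  stats::cophenetic(phy)
}

#' Median leaf-pair distance between two clades
#'
#' The distance between two (possibly internal) clades is the median over
#' all cross pairs of their descendant leaves; a leaf shared by both sets
#' contributes its zero self-distance.
#'
#' @param a,b Character vectors of leaf names.
#' @param dist_matrix Leaf distance matrix from [leaf_distances()] (or any
#'   symmetric distance matrix, e.g. gene-family Jaccard distances).
#' @return The median cross-pair distance.
#' @export
clade_distance <- function(a, b, dist_matrix) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  unknown <- setdiff(c(a, b), rownames(dist_matrix))
  if (length(unknown)) {
    stop("leaves not in distance matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  stats::median(dist_matrix[a, b, drop = FALSE])
}

#' Filter gene-family profiles to prevalent families
#'
#' Retains gene families present in at least `min_frac` of the entities
#' (boundary inclusive) and intersects every profile with the retained
#' universe.
#'
#' @param profiles Named list of character vectors (entity -> set of
#'   family ids).
#' @param min_frac Minimum presence fraction (default 0.10).
#' @return A list: `profiles` (filtered), `universe` (retained family
#'   ids).
#' @export
filter_profiles <- function(profiles, min_frac = 0.10) {
  stopifnot(min_frac > 0, min_frac < 1)
  profiles <- lapply(profiles, unique)
  fam <- table(unlist(profiles))
  universe <- names(fam)[fam >= min_frac * length(profiles)]
  list(
    profiles = lapply(profiles, intersect, y = universe),
    universe = universe
  )
}

#' Jaccard distance between two gene-family profiles
#'
#' `1 - |a intersect b| / |a union b|`: the fraction of non-shared
#' families, the functional distance between two genomes.
#'
#' @param a,b Character vectors (sets of family ids); at least one must
#'   be non-empty.
#' @return Distance in \[0, 1\]; `NA` when both sets are empty.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  1 - length(intersect(a, b)) / u
}

#' Pairwise Jaccard distance matrix over profiles
#' @param profiles Named list of family-id sets (after
#'   [filter_profiles()]).
#' @return Symmetric distance matrix named by entity.
#' @export
jaccard_matrix <- function(profiles) {
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(names(profiles), names(profiles)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) d[i, j] <- d[j, i] <- jaccard_distance(profiles[[i]],
                                                        profiles[[j]])
    }
  }
  d
}

#' Annotate network edges with phylogenetic and functional distances
#'
#' Joins per-edge clade distances (median leaf-pair, via
#' [clade_distance()]) from a phylogenetic and a functional distance
#' matrix onto the merged network — the scatter table comparing
#' evolutionary relatedness with shared functional potential. Lineages
#' absent from a distance source are flagged (`covered = FALSE`) and get
#' `NA` distances, never dropped silently.
#'
#' @param net A `merged_network` tibble.
#' @param clade_leaves Named list: lineage -> character vector of leaf
#'   names present in the distance matrices.
#' @param phylo Leaf distance matrix from [leaf_distances()].
#' @param func Entity distance matrix from [jaccard_matrix()] (or a
#'   profile list to be converted).
#' @return A tibble: edge columns plus `phylo_dist`, `func_dist`,
#'   `within_site`, `covered`.
#' @export
annotate_edges <- function(net, clade_leaves, phylo, func) {
  if (is.list(func) && !is.matrix(func)) func <- jaccard_matrix(func)
  nodes <- network_nodes(net)
  lin_a <- nodes$lineage[match(net$feature_a, nodes$feature)]
  lin_b <- nodes$lineage[match(net$feature_b, nodes$feature)]
  site_a <- nodes$body_site[match(net$feature_a, nodes$feature)]
  site_b <- nodes$body_site[match(net$feature_b, nodes$feature)]
  dist_for <- function(la, lb, m) {
    leaves_a <- clade_leaves[[la]]
    leaves_b <- clade_leaves[[lb]]
    if (is.null(leaves_a) || is.null(leaves_b) ||
        !all(c(leaves_a, leaves_b) %in% rownames(m))) {
      return(NA_real_)
    }
    clade_distance(leaves_a, leaves_b, m)
  }
  pd <- mapply(dist_for, lin_a, lin_b, MoreArgs = list(m = phylo))
  fd <- mapply(dist_for, lin_a, lin_b, MoreArgs = list(m = func))
  tibble::tibble(
    feature_a = net$feature_a, feature_b = net$feature_b,
    sign = net$sign, q = net$q,
    within_site = site_a == site_b,
    phylo_dist = unname(pd), func_dist = unname(fd),
    covered = !is.na(pd) & !is.na(fd)
  )
}
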