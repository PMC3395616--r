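MEASURES <- c("pearson", "spearman", "bray_curtis", "kld")

#' Score the association between two abundance profiles
#'
#' The ensemble combines two correlation measures (Pearson, Spearman) and
#' two dissimilarity measures (Bray-Curtis, symmetrized Kullback-Leibler).
#' Dissimilarity inputs are rescaled to sum one before computation; KLD
#' additionally receives a pseudocount (added, then renormalized) so that
#' zero entries do not produce infinite divergences.
#'
#' @param measure One of `"pearson"`, `"spearman"`, `"bray_curtis"`,
#'   `"kld"`.
#' @param x,y Equal-length abundance vectors (length >= 3).
#' @param pseudocount Smoothing constant for KLD (default 1e-6).
#' @return The score: correlations in \[-1, 1\] (`NA` for zero-variance
#'   input), Bray-Curtis in \[0, 1\], symmetrized KLD >= 0.
#' @examples
#' assoc_score("bray_curtis", c(0.2, 0.8), c(0.5, 0.5))
#' @export
assoc_score <- function(measure, x, y, pseudocount = 1e-6) {
  measure <- match.arg(measure, MEASURES)
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (measure %in% c("pearson", "spearman")) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    return(stats::cor(x, y, method = measure))
  }
  if (sum(x) <= 0 || sum(y) <= 0) {
    stop("zero-sum vector passed to a dissimilarity measure", call. = FALSE)
  }
  x <- x / sum(x)
  y <- y / sum(y)
  if (measure == "bray_curtis") {
    return(sum(abs(x - y)) / sum(x + y))
  }
  # symmetrized KLD with pseudocount smoothing
  x <- x + pseudocount
  x <- x / sum(x)
  y <- y + pseudocount
  y <- y / sum(y)
  sum(x * log(x / y)) + sum(y * log(y / x))
}

# admissible unordered feature pairs: parent/descendant (or identical)
# lineages are excluded only within the same body site
admissible_pairs <- function(meta) {
  n <- nrow(meta)
  if (n < 2) {
    return(tibble::tibble(i = integer(0), j = integer(0)))
  }
  idx <- utils::combn(n, 2)
  i <- idx[1, ]
  j <- idx[2, ]
  same_site <- meta$body_site[i] == meta$body_site[j]
  related <- lineage_related_chr(meta$lineage[i], meta$lineage[j])
  keep <- !(same_site & related)
  tibble::tibble(i = i[keep], j = j[keep])
}

#' Measure-specific candidate edges from a composite matrix
#'
#' Scores all admissible unordered feature pairs with one measure and
#' returns the top- and bottom-ranking edges in the measure's native
#' ordering (defaults: 1,000 each). Pairs of clades in ancestor/descendant
#' relation within the same body site are never scored. Columns where
#' either feature is missing are dropped pairwise; pairs observed in fewer
#' than `min_obs` common columns are not ranked.
#'
#' @param composite A composite tibble from [build_composite()].
#' @param measure Measure name (see [assoc_score()]).
#' @param n_top,n_bottom Number of highest-/lowest-scoring edges to keep.
#' @param min_obs Minimum jointly observed columns per pair (default 10).
#' @param pseudocount Passed to [assoc_score()] for KLD.
#' @return A tibble: `feature_a`, `feature_b`, `measure`, `score`,
#'   `n_obs`, `rank_side` (`"top"` or `"bottom"`). Ties at the cut are
#'   broken by lexicographic feature id.
#' @export
candidate_edges <- function(composite, measure, n_top = 1000,
                            n_bottom = 1000, min_obs = 10,
                            pseudocount = 1e-6) {
  measure <- match.arg(measure, MEASURES)
  stopifnot(n_top >= 0, n_bottom >= 0)
  meta <- composite_meta(composite)
  m <- composite_matrix(composite)
  pr <- admissible_pairs(meta)
  if (nrow(pr) == 0) {
    return(tibble::tibble(
      feature_a = character(0), feature_b = character(0),
      measure = character(0), score = numeric(0),
      n_obs = integer(0), rank_side = character(0)
    ))
  }
  obs <- !is.na(m)
  n_obs <- vapply(seq_len(nrow(pr)),
                  function(k) sum(obs[pr$i[k], ] & obs[pr$j[k], ]),
                  integer(1))
  score <- vapply(seq_len(nrow(pr)), function(k) {
    use <- obs[pr$i[k], ] & obs[pr$j[k], ]
    if (sum(use) < 3) return(NA_real_)
    x <- m[pr$i[k], use]
    y <- m[pr$j[k], use]
    if (measure %in% c("bray_curtis", "kld") &&
        (sum(x) <= 0 || sum(y) <= 0)) {
      return(NA_real_)
    }
    assoc_score(measure, x, y, pseudocount = pseudocount)
  }, numeric(1))

  # order each pair so feature_a < feature_b for a stable edge identity
  fa <- rownames(m)[pr$i]
  fb <- rownames(m)[pr$j]
  swap <- fa > fb
  tmp <- fa[swap]
  fa[swap] <- fb[swap]
  fb[swap] <- tmp

  edges <- tibble::tibble(
    feature_a = fa, feature_b = fb, measure = measure,
    score = score, n_obs = as.integer(n_obs)
  )
  edges <- edges[!is.na(edges$score) & edges$n_obs >= min_obs, , drop = FALSE]
  if (nrow(edges) < n_top + n_bottom) {
    message("fewer admissible pairs (", nrow(edges), ") than requested (",
            n_top + n_bottom, "); returning all")
  }
  ord_desc <- order(-edges$score, edges$feature_a, edges$feature_b)
  ord_asc <- order(edges$score, edges$feature_a, edges$feature_b)
  top_idx <- utils::head(ord_desc, n_top)
  bottom_idx <- setdiff(utils::head(ord_asc, n_bottom), top_idx)
  out <- dplyr::bind_rows(
    dplyr::mutate(edges[top_idx, , drop = FALSE], rank_side = "top"),
    dplyr::mutate(edges[bottom_idx, , drop = FALSE], rank_side = "bottom")
  )
  out
}
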