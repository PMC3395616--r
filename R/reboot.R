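# ReBoot: permutation-renormalization nulls plus bootstrap confidence
# distributions for association scores on compositional data.
#
# Relative abundances sum to one per sample, so an increase in one taxon
# forces apparent decreases in the others; naive permutation tests ignore
# this and over-call negative associations. The null here permutes only
# the target feature across samples and then renormalizes each sample,
# so the null distribution carries exactly the correlation induced by
# compositionality and nothing else.

new_resample_dist <- function(kind, values, n_iter, seed, n_dropped = 0L) {
  structure(
    list(kind = kind, values = values, n_iter = n_iter, seed = seed,
         n_dropped = as.integer(n_dropped)),
    class = "reboot_dist"
  )
}

# deterministic 31-bit seed derived from a master seed and a string key,
# so per-edge resampling is reproducible and order-independent
derive_seed <- function(master, key) {
  h <- as.double(master %% 2147483629)
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

# Precompute everything a resampling scheme needs for one edge: the
# jointly observed columns, the two feature value vectors, and, for the
# renormalized null, the terminal rows of the permuted feature's body-site
# block (renormalization operates on terminal phylotypes and clade
# features are re-derived as sums over their terminal descendants).
reboot_context <- function(composite, feature_a, feature_b,
                           permute = c("second", "first")) {
  permute <- match.arg(permute)
  meta <- composite_meta(composite)
  m <- composite_matrix(composite)
  ia <- match(feature_a, meta$feature)
  ib <- match(feature_b, meta$feature)
  if (is.na(ia) || is.na(ib)) {
    stop("edge features not present in composite", call. = FALSE)
  }
  # lexicographically second feature is permuted by default
  ord <- order(c(feature_a, feature_b))
  idx <- c(ia, ib)[ord]
  it <- if (permute == "second") idx[2] else idx[1]
  ip <- setdiff(c(ia, ib), it)
  cols <- which(!is.na(m[ia, ]) & !is.na(m[ib, ]))
  block <- which(meta$body_site == meta$body_site[it])
  term <- block[is_terminal_row(meta$lineage[block])]
  target_leaves <- if (it %in% term) {
    it
  } else {
    term[startsWith(meta$lineage[term], paste0(meta$lineage[it], "|"))]
  }
  partner_same_block <- meta$body_site[ip] == meta$body_site[it]
  partner_leaves <- if (!partner_same_block) {
    integer(0)
  } else if (ip %in% term) {
    ip
  } else {
    term[startsWith(meta$lineage[term], paste0(meta$lineage[ip], "|"))]
  }
  L <- m[term, cols, drop = FALSE]
  L[is.na(L)] <- 0
  list(
    target = m[it, cols], partner = m[ip, cols],
    target_is_second = (it == idx[2]),
    block_colsum = colSums(L),
    target_contrib = colSums(m[target_leaves, cols, drop = FALSE]),
    partner_contrib = if (partner_same_block) {
      colSums(m[partner_leaves, cols, drop = FALSE])
    } else {
      NULL
    },
    n = length(cols)
  )
}

#' Permutation null distribution for one candidate edge
#'
#' Per iteration, the values of one member of the pair (by default the
#' lexicographically second feature) are permuted across the jointly
#' observed columns. With `renormalize = TRUE` every column of the
#' permuted feature's terminal-phylotype block is then rescaled to its
#' original constant sum and both features re-derived before the measure
#' is recomputed; this retains the association induced by compositionality
#' alone. With `renormalize = FALSE` the measure is recomputed on the
#' plainly permuted values (the point-null scheme used for the
#' dissimilarity measures, which are intrinsically robust to
#' compositionality).
#'
#' @param composite A composite tibble.
#' @param feature_a,feature_b Feature ids of the edge.
#' @param measure Measure name (see [assoc_score()]).
#' @param n_iter Number of permutations (default 1000).
#' @param seed Integer seed; identical seeds give identical distributions.
#' @param renormalize Renormalize columns after permuting (default `TRUE`).
#' @param permute Which member to permute (`"second"` or `"first"`).
#' @param pseudocount Passed to [assoc_score()].
#' @return A `reboot_dist`: list with `kind`, `values` (finite scores),
#'   `n_iter`, `seed`, `n_dropped` (non-finite draws removed).
#' @export
permutation_null <- function(composite, feature_a, feature_b, measure,
                             n_iter = 1000, seed = 1, renormalize = TRUE,
                             permute = "second", pseudocount = 1e-6) {
  stopifnot(n_iter >= 2)
  ctx <- reboot_context(composite, feature_a, feature_b, permute = permute)
  set.seed(seed)
  vals <- vapply(seq_len(n_iter), function(i) {
    perm <- sample.int(ctx$n)
    if (renormalize) {
      s_new <- ctx$block_colsum - ctx$target_contrib +
        ctx$target_contrib[perm]
      t_new <- ctx$target_contrib[perm] / s_new
      p_new <- if (is.null(ctx$partner_contrib)) {
        ctx$partner
      } else {
        ctx$partner_contrib / s_new
      }
    } else {
      t_new <- ctx$target[perm]
      p_new <- ctx$partner
    }
    sc <- tryCatch(
      assoc_score(measure, t_new, p_new, pseudocount = pseudocount),
      error = function(e) NA_real_
    )
    if (is.null(sc) || !length(sc)) NA_real_ else sc
  }, numeric(1))
  keep <- is.finite(vals)
  new_resample_dist("permutation_null", vals[keep], n_iter, seed,
                    n_dropped = sum(!keep))
}

#' Bootstrap score distribution for one candidate edge
#'
#' Per iteration, jointly observed columns are resampled with replacement
#' and the measure recomputed on the pair, giving a confidence
#' distribution around the observed score.
#'
#' @inheritParams permutation_null
#' @return A `reboot_dist` of kind `"bootstrap"`.
#' @export
bootstrap_distribution <- function(composite, feature_a, feature_b, measure,
                                   n_iter = 1000, seed = 1,
                                   pseudocount = 1e-6) {
  stopifnot(n_iter >= 2)
  ctx <- reboot_context(composite, feature_a, feature_b)
  set.seed(seed)
  vals <- vapply(seq_len(n_iter), function(i) {
    idx <- sample.int(ctx$n, replace = TRUE)
    sc <- tryCatch(
      assoc_score(measure, ctx$target[idx], ctx$partner[idx],
                  pseudocount = pseudocount),
      error = function(e) NA_real_
    )
    if (is.null(sc) || !length(sc)) NA_real_ else sc
  }, numeric(1))
  keep <- is.finite(vals)
  new_resample_dist("bootstrap", vals[keep], n_iter, seed,
                    n_dropped = sum(!keep))
}

dist_values <- function(x) if (inherits(x, "reboot_dist")) x$values else x

#' Pooled-variance z-test of a bootstrap distribution against a null
#'
#' z = (mean(boot) - mean(null)) / s_pooled with the two-sample pooled
#' standard deviation; the returned p is the upper-tail standard normal
#' probability, so a bootstrap distribution far above the null gives a
#' small p.
#'
#' @param boot,null `reboot_dist` objects or numeric vectors.
#' @return One-sided p-value in \[0, 1\]; `NA` if the pooled sd is zero.
#' @export
pooled_z_pvalue <- function(boot, null) {
  b <- dist_values(boot)
  n <- dist_values(null)
  stopifnot(length(b) >= 2, length(n) >= 2)
  s2 <- ((length(b) - 1) * stats::var(b) + (length(n) - 1) * stats::var(n)) /
    (length(b) + length(n) - 2)
  if (s2 <= 0) return(NA_real_)
  z <- (mean(b) - mean(n)) / sqrt(s2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' z-test of a bootstrap distribution against a point null
#'
#' Used for the dissimilarity measures: the null point is the mean of the
#' plain-permutation distribution and the bootstrap spread supplies the
#' scale.
#'
#' @param boot A `reboot_dist` or numeric vector.
#' @param null_point The permutation-mean null value.
#' @return Upper-tail one-sided p; `NA` when the bootstrap is degenerate.
#' @export
point_null_pvalue <- function(boot, null_point) {
  b <- dist_values(boot)
  stopifnot(length(b) >= 2, is.finite(null_point))
  s <- stats::sd(b)
  if (s <= 0) return(NA_real_)
  stats::pnorm((mean(b) - null_point) / s, lower.tail = FALSE)
}

#' Tail-adjust a one-sided p-value to the co-presence orientation
#'
#' Oriented p-values encode both significance and direction: values below
#' 0.5 indicate co-presence, values above 0.5 exclusion. For correlation
#' measures the upper-tail p already has this orientation; for
#' dissimilarities (where a LOW score means co-presence) the tail is
#' flipped.
#'
#' @param p One-sided upper-tail p-value(s) in \[0, 1\].
#' @param measure Measure name; determines whether the tail is flipped.
#' @return A tibble with `p_oriented` and `direction` (+1 co-presence,
#'   -1 exclusion).
#' @export
tail_adjust <- function(p, measure) {
  measure <- match.arg(measure, MEASURES)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  oriented <- if (measure %in% c("bray_curtis", "kld")) 1 - p else p
  tibble::tibble(
    p_oriented = oriented,
    direction = ifelse(oriented < 0.5, 1L, -1L)
  )
}

#' Bootstrap stability filter
#'
#' An edge is stable when its observed score lies inside the central 95%
#' interval (2.5th to 97.5th percentile, inclusive) of its bootstrap
#' distribution.
#'
#' @param observed Observed score.
#' @param boot A `reboot_dist` or numeric vector.
#' @param lo,hi Percentile bounds (defaults 2.5, 97.5).
#' @return Logical.
#' @export
stability_filter <- function(observed, boot, lo = 2.5, hi = 97.5) {
  b <- dist_values(boot)
  stopifnot(length(b) >= 1)
  q <- stats::quantile(b, c(lo, hi) / 100, names = FALSE)
  observed >= q[1] && observed <= q[2]
}

#' Leave-one-out influence check for outlier-driven edges
#'
#' Flags an edge whose association depends on a single extreme column:
#' removing one column either changes the sign of a correlation score or
#' moves the score across the supplied candidate threshold.
#'
#' @param composite A composite tibble.
#' @param feature_a,feature_b Edge features.
#' @param measure Measure name.
#' @param threshold Optional candidate-selection cutoff; crossing it under
#'   leave-one-out flags the edge.
#' @param pseudocount Passed to [assoc_score()].
#' @return Logical: `TRUE` when the edge is outlier-driven.
#' @export
influence_check <- function(composite, feature_a, feature_b, measure,
                            threshold = NULL, pseudocount = 1e-6) {
  ctx <- reboot_context(composite, feature_a, feature_b)
  obs <- assoc_score(measure, ctx$target, ctx$partner,
                     pseudocount = pseudocount)
  if (!is.finite(obs)) return(TRUE)
  loo <- vapply(seq_len(ctx$n), function(j) {
    sc <- tryCatch(
      assoc_score(measure, ctx$target[-j], ctx$partner[-j],
                  pseudocount = pseudocount),
      error = function(e) NA_real_
    )
    if (!length(sc)) NA_real_ else sc
  }, numeric(1))
  loo <- loo[is.finite(loo)]
  if (!length(loo)) return(TRUE)
  flagged <- FALSE
  if (measure %in% c("pearson", "spearman") && obs != 0) {
    flagged <- any(sign(loo) != sign(obs) & loo != 0)
  }
  if (!is.null(threshold)) {
    flagged <- flagged || any((obs > threshold) != (loo > threshold))
  }
  flagged
}

#' ReBoot significance for a table of candidate edges
#'
#' Runs the full edge-level scheme: a bootstrap confidence distribution
#' for every edge, a renormalized permutation null for the correlation
#' measures, and a plain-permutation point null for the dissimilarities;
#' p-values come from the pooled z-test (correlations) or the point-null
#' z-test (dissimilarities), are tail-adjusted to the co-presence
#' orientation, and each edge carries its bootstrap stability flag and
#' optional leave-one-out influence flag. Per-edge seeds are derived
#' deterministically from `seed` and the edge identity, so results do not
#' depend on edge order.
#'
#' @param composite A composite tibble.
#' @param edges Candidate edge tibble from [candidate_edges()].
#' @param n_perm,n_boot Resampling iteration counts (paper-scale default
#'   1000; reduce for exploratory runs).
#' @param seed Master integer seed.
#' @param dataset Dataset label recorded on each row (e.g. clinical
#'   center).
#' @param check_influence Run [influence_check()] per edge (default
#'   `TRUE`).
#' @param max_drop_frac Edges whose resamples lose more than this fraction
#'   of draws to non-finite scores are discarded (default 0.1).
#' @param pseudocount Passed to [assoc_score()].
#' @return An edge evidence tibble: `feature_a`, `feature_b`, `measure`,
#'   `dataset`, `score`, `p_oriented`, `direction`, `stable`, `flagged`,
#'   `reason` (`NA` for usable rows).
#' @export
reboot_edges <- function(composite, edges, n_perm = 1000, n_boot = 1000,
                         seed = 1, dataset = "all",
                         check_influence = TRUE, max_drop_frac = 0.1,
                         pseudocount = 1e-6) {
  if (nrow(edges) == 0) {
    return(tibble::tibble(
      feature_a = character(0), feature_b = character(0),
      measure = character(0), dataset = character(0), score = numeric(0),
      p_oriented = numeric(0), direction = integer(0), stable = logical(0),
      flagged = logical(0), reason = character(0)
    ))
  }
  purrr::map_dfr(seq_len(nrow(edges)), function(k) {
    e <- edges[k, ]
    key <- paste(e$feature_a, e$feature_b, e$measure, dataset, sep = "~")
    corr <- e$measure %in% c("pearson", "spearman")
    boot <- bootstrap_distribution(
      composite, e$feature_a, e$feature_b, e$measure, n_iter = n_boot,
      seed = derive_seed(seed, paste0(key, "#boot")),
      pseudocount = pseudocount
    )
    null <- permutation_null(
      composite, e$feature_a, e$feature_b, e$measure, n_iter = n_perm,
      seed = derive_seed(seed, paste0(key, "#perm")),
      renormalize = corr, pseudocount = pseudocount
    )
    reason <- NA_character_
    if (boot$n_dropped > max_drop_frac * n_boot ||
        null$n_dropped > max_drop_frac * n_perm) {
      reason <- "unstable_resamples"
    }
    p1 <- if (corr) {
      pooled_z_pvalue(boot, null)
    } else {
      point_null_pvalue(boot, mean(null$values))
    }
    if (is.na(p1) && is.na(reason)) reason <- "degenerate_distribution"
    adj <- tail_adjust(if (is.na(p1)) 0.5 else p1, e$measure)
    tibble::tibble(
      feature_a = e$feature_a, feature_b = e$feature_b,
      measure = e$measure, dataset = dataset, score = e$score,
      p_oriented = ifelse(is.na(p1), NA_real_, adj$p_oriented),
      direction = adj$direction,
      stable = stability_filter(e$score, boot),
      flagged = if (check_influence) {
        influence_check(composite, e$feature_a, e$feature_b, e$measure,
                        pseudocount = pseudocount)
      } else {
        FALSE
      },
      reason = reason
    )
  })
}
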