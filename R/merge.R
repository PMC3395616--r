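# Evidence merging: Simes combination over (method x dataset) evidence
# sources, Benjamini-Hochberg-Yekutieli FDR control, direction voting.

#' Simes combined p-value
#'
#' With order statistics p(1) <= ... <= p(m), returns
#' min_i (m * p(i) / i), capped at 1. Valid under positive dependence, so
#' it is suited to combining the non-independent evidence networks.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return The combined p-value.
#' @examples
#' simes_pvalue(c(0.01, 0.04)) # 0.02
#' @export
simes_pvalue <- function(pvals) {
  stopifnot(length(pvals) >= 1)
  if (any(pvals <= 0 | pvals > 1 | !is.finite(pvals))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  p <- sort(pvals)
  min(1, min(m * p / seq_len(m)))
}

#' Benjamini-Hochberg-Yekutieli q-values
#'
#' Step-up FDR correction valid under arbitrary dependence (the
#' Benjamini-Yekutieli variant with the harmonic-sum inflation factor),
#' computed via [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values.
#' @return q-values, element-wise >= the input p-values.
#' @export
bhy_qvalues <- function(pvals) {
  stopifnot(length(pvals) >= 1)
  stats::p.adjust(pvals, method = "BY")
}

#' Consensus direction vote over evidence sources
#'
#' Sums the +1/-1 directions contributed by distinct (method, dataset)
#' sources. A zero total means the sources disagree irreconcilably and
#' the edge is removed downstream.
#'
#' @param directions Integer vector of +1/-1 votes.
#' @return A list: `direction_score` (the sum) and `sign` (+1, -1, or 0).
#' @export
direction_vote <- function(directions) {
  stopifnot(all(directions %in% c(-1L, 1L)))
  s <- sum(directions)
  list(direction_score = as.integer(s), sign = as.integer(sign(s)))
}

#' Assemble the merged, FDR-controlled signed network
#'
#' Collects the oriented p-values each edge earned across evidence
#' sources (methods x datasets), folds them to two-sided p-values
#' (`2 * min(p, 1 - p)`, so strong exclusions count like strong
#' co-presences), Simes-combines over the sources in which the edge was
#' actually a surviving candidate, corrects across all edges with
#' Benjamini-Hochberg-Yekutieli, and keeps edges with `q <= q_cut`, at
#' least `min_support` supporting sources, and a non-zero direction vote.
#' Absent evidence contributes nothing (no p = 1 imputation); unstable,
#' influence-flagged, or reason-carrying rows are dropped first.
#'
#' @param evidence One edge-evidence tibble, or a list of them, as
#'   produced by [reboot_edges()] / [gblm_compendium()].
#' @param q_cut FDR cutoff (default 0.05).
#' @param min_support Minimum number of supporting sources (default 2).
#' @param intersect_datasets If `TRUE`, Simes-combine per dataset first
#'   and keep only edges significant in every dataset (the strict
#'   intersection variant; default `FALSE`).
#' @return A `merged_network` tibble: `feature_a`, `feature_b`,
#'   `p_simes`, `q`, `direction_score`, `support`, `sign`.
#' @export
assemble_network <- function(evidence, q_cut = 0.05, min_support = 2,
                             intersect_datasets = FALSE) {
  if (is.data.frame(evidence)) evidence <- list(evidence)
  ev <- dplyr::bind_rows(evidence)
  empty <- tibble::tibble(
    feature_a = character(0), feature_b = character(0),
    p_simes = numeric(0), q = numeric(0), direction_score = integer(0),
    support = integer(0), sign = integer(0)
  )
  if (nrow(ev) == 0) return(structure(empty, class = c("merged_network",
                                                       class(empty))))
  ev <- ev[!is.na(ev$p_oriented), , drop = FALSE]
  if ("stable" %in% names(ev)) ev <- ev[ev$stable, , drop = FALSE]
  if ("flagged" %in% names(ev)) ev <- ev[!ev$flagged, , drop = FALSE]
  if ("reason" %in% names(ev)) ev <- ev[is.na(ev$reason), , drop = FALSE]
  if (nrow(ev) == 0) return(structure(empty, class = c("merged_network",
                                                       class(empty))))
  # two-sided fold of the tail-adjusted encoding; direction kept separately
  ev$p2 <- pmin(1, pmax(2 * pmin(ev$p_oriented, 1 - ev$p_oriented),
                        .Machine$double.xmin))
  combine <- function(df) {
    vote <- direction_vote(df$direction)
    tibble::tibble(
      p_simes = simes_pvalue(df$p2),
      direction_score = vote$direction_score,
      support = nrow(df),
      sign = vote$sign
    )
  }
  if (intersect_datasets) {
    per_ds <- ev |>
      dplyr::group_by(.data$feature_a, .data$feature_b, .data$dataset) |>
      dplyr::group_modify(~combine(.x)) |>
      dplyr::ungroup()
    net <- per_ds |>
      dplyr::group_by(.data$feature_a, .data$feature_b) |>
      dplyr::summarise(
        n_ds = dplyr::n(),
        p_simes = max(.data$p_simes),
        direction_score = as.integer(sum(.data$direction_score)),
        support = as.integer(sum(.data$support)),
        sign = as.integer(sign(sum(.data$direction_score))),
        .groups = "drop"
      )
    net <- net[net$n_ds == length(unique(ev$dataset)), , drop = FALSE]
    net$n_ds <- NULL
  } else {
    net <- ev |>
      dplyr::group_by(.data$feature_a, .data$feature_b) |>
      dplyr::group_modify(~combine(.x)) |>
      dplyr::ungroup()
  }
  net$q <- bhy_qvalues(net$p_simes)
  net <- net[net$q <= q_cut & net$support >= min_support & net$sign != 0, ,
             drop = FALSE]
  net <- net[, c("feature_a", "feature_b", "p_simes", "q",
                 "direction_score", "support", "sign")]
  structure(net, class = c("merged_network", class(net)))
}

# node table (feature, lineage, body_site) derived from edge feature ids;
# randomized networks carry their full node set as an attribute so
# isolated nodes survive
network_nodes <- function(net) {
  feats <- attr(net, "nodes", exact = TRUE)
  if (is.null(feats)) feats <- unique(c(net$feature_a, net$feature_b))
  feats <- sort(feats)
  parts <- strsplit(feats, "@", fixed = TRUE)
  tibble::tibble(
    feature = feats,
    lineage = vapply(parts, `[`, character(1), 1),
    body_site = vapply(parts, `[`, character(1), 2)
  )
}

#' Convert a merged network to an igraph graph
#'
#' Nodes carry `lineage` and `body_site` attributes parsed from the
#' feature ids; edges carry `q`, `direction_score`, `support`, `sign`.
#'
#' @param net A `merged_network` tibble.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  nodes <- network_nodes(net)
  igraph::graph_from_data_frame(
    d = as.data.frame(net[, c("feature_a", "feature_b", "q",
                              "direction_score", "support", "sign")]),
    directed = FALSE,
    vertices = as.data.frame(nodes)
  )
}

#' Write / read a merged network
#'
#' `write_network_tsv()` writes the edge list as TSV and round-trips
#' exactly through `read_network_tsv()`. `write_network_graphml()`
#' exports the annotated graph as GraphML via igraph.
#'
#' @param net A `merged_network` tibble.
#' @param path Output path.
#' @return `path` invisibly (writers); a `merged_network` (reader).
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(as.data.frame(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  df <- tibble::as_tibble(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  )
  df$direction_score <- as.integer(df$direction_score)
  df$support <- as.integer(df$support)
  df$sign <- as.integer(df$sign)
  structure(df, class = c("merged_network", class(df)))
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
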