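# Network-level statistics for the merged co-occurrence network: degree
# distributions with log-log power-law fits, clustering, path lengths,
# Markov clustering plus modularity, and randomization enrichment tests.

#' Least-squares power-law fit on a log-log degree histogram
#'
#' Fits `log(count) ~ log(k)` over non-zero histogram bins by ordinary
#' least squares — the regression-line convention for reporting scale-free
#' degree distributions (deliberately, not maximum-likelihood exponent
#' estimation).
#'
#' @param k Degree values (positive).
#' @param count Frequency of each degree (positive; non-integer allowed).
#' @return A list: `slope`, `intercept`, `adj_r2`; `NULL` if fewer than 5
#'   usable bins.
#' @export
fit_power_law <- function(k, count) {
  keep <- k > 0 & count > 0
  k <- k[keep]
  count <- count[keep]
  if (length(unique(k)) < 5) return(NULL)
  fit <- stats::lm(log(count) ~ log(k))
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    adj_r2 = suppressWarnings(summary(fit)$adj.r.squared)
  )
}

#' Per-node degrees and the degree-distribution power-law fit
#'
#' @param net A `merged_network` tibble (must carry a `sign` column for
#'   the positive/negative split).
#' @return A list: `degrees` (tibble `feature`, `degree`, `pos_degree`,
#'   `neg_degree`) and `fit` (see [fit_power_law()]; `NULL` when the
#'   degree histogram has fewer than 5 distinct non-zero values).
#' @export
degree_stats <- function(net) {
  nodes <- network_nodes(net)
  ends <- c(net$feature_a, net$feature_b)
  sgn <- rep(net$sign, 2)
  deg <- function(f) tabulate(match(f, nodes$feature), nrow(nodes))
  degrees <- tibble::tibble(
    feature = nodes$feature,
    degree = deg(ends),
    pos_degree = deg(ends[sgn > 0]),
    neg_degree = deg(ends[sgn < 0])
  )
  h <- table(degrees$degree[degrees$degree > 0])
  list(
    degrees = degrees,
    fit = fit_power_law(as.numeric(names(h)), as.numeric(h))
  )
}

#' Local clustering coefficients and their mean
#'
#' Node coefficient `2 * t / (k (k - 1))` with `t` the number of edges
#' among the node's neighbours; 0 for nodes with degree < 2.
#'
#' @param net A `merged_network` tibble.
#' @return A list: `per_node` (tibble `feature`, `clustering`) and `mean`.
#' @export
clustering_coefficient <- function(net) {
  g <- as_igraph(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  list(
    per_node = tibble::tibble(feature = igraph::V(g)$name, clustering = cc),
    mean = mean(cc)
  )
}

#' Mean shortest-path length over connected pairs
#'
#' Unweighted breadth-first distances averaged over all ordered pairs of
#' nodes in the same connected component; cross-component pairs are
#' excluded rather than imputed.
#'
#' @param net A `merged_network` tibble.
#' @return The mean path length (NaN for an edgeless network).
#' @export
average_path_length <- function(net) {
  igraph::mean_distance(as_igraph(net), directed = FALSE,
                        unconnected = TRUE)
}

#' Markov clustering (MCL) of a network
#'
#' Adds a self-loop of weight 1 to every node, column-normalizes the
#' adjacency matrix to a stochastic flow matrix, and alternates expansion
#' (matrix squaring) with inflation (element-wise power followed by
#' column renormalization) until the largest element change falls below
#' `tol` or `max_iter` rounds pass. Clusters are the connected components
#' of the converged flow matrix; every node is assigned to exactly one
#' cluster.
#'
#' @param net A `merged_network` tibble, or a square (signed) adjacency
#'   matrix; edge signs are ignored (absolute weight 1).
#' @param inflation Inflation exponent (> 1).
#' @param tol Convergence tolerance on the max element change.
#' @param max_iter Iteration cap.
#' @return A list: `membership` (named integer vector), `n_clusters`,
#'   `inflation`, `converged`.
#' @export
mcl_cluster <- function(net, inflation = 1.3, tol = 1e-6, max_iter = 100) {
  stopifnot(inflation > 1)
  A <- if (is.matrix(net)) {
    (abs(net) > 0) * 1
  } else {
    as.matrix(igraph::as_adjacency_matrix(as_igraph(net)))
  }
  n <- nrow(A)
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < 1e-12] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("MCL did not converge within ", max_iter,
                          " iterations")
  keep <- M > 1e-6
  g <- igraph::graph_from_adjacency_matrix(keep | t(keep), mode = "max")
  memb <- igraph::components(g)$membership
  names(memb) <- rownames(A)
  list(membership = memb, n_clusters = max(memb), inflation = inflation,
       converged = converged)
}

#' Network modularity of a partition
#'
#' Q = sum over clusters of (e_cc - a_c^2), where e_cc is the fraction of
#' edges inside cluster c and a_c the fraction of edge endpoints in c.
#'
#' @param net A `merged_network` tibble.
#' @param membership Cluster assignment named by feature id (or in node
#'   order of [network_nodes()]).
#' @return Modularity Q; errors on an edgeless network.
#' @export
network_modularity <- function(net, membership) {
  if (nrow(net) == 0) stop("modularity undefined for an edgeless network",
                           call. = FALSE)
  ca <- membership[net$feature_a]
  cb <- membership[net$feature_b]
  m <- nrow(net)
  clusters <- unique(c(ca, cb))
  e_cc <- vapply(clusters, function(c) sum(ca == c & cb == c) / m,
                 numeric(1))
  a_c <- vapply(clusters, function(c) (sum(ca == c) + sum(cb == c)) / (2 * m),
                numeric(1))
  sum(e_cc - a_c^2)
}

#' Uniform edge-reassignment randomization of a network
#'
#' Keeps the node set and the edge count, redraws the edges uniformly
#' among unordered node pairs without replacement, and shuffles the signs
#' along with the edges.
#'
#' @param net A `merged_network` tibble.
#' @param seed Integer seed.
#' @return A `merged_network` tibble with the randomized edges.
#' @export
randomize_network <- function(net, seed = 1) {
  nodes <- network_nodes(net)$feature
  n <- length(nodes)
  n_edges <- nrow(net)
  n_pairs <- n * (n - 1) / 2
  if (n_edges > n_pairs) stop("more edges than node pairs", call. = FALSE)
  set.seed(seed)
  pick <- sample.int(n_pairs, n_edges)
  # unrank unordered pair index -> (i, j), i < j, lexicographic order
  i <- as.integer(ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * pick)))
  before <- function(i) (i - 1) * n - (i - 1) * i / 2 # pairs with first < i
  i <- i - (pick <= before(i)) + (pick > before(i + 1))
  j <- pick - before(i) + i
  sgn <- sample(net$sign)
  out <- tibble::tibble(
    feature_a = pmin(nodes[i], nodes[j]),
    feature_b = pmax(nodes[i], nodes[j]),
    p_simes = NA_real_, q = NA_real_,
    direction_score = as.integer(sgn), support = 1L,
    sign = as.integer(sgn)
  )
  out <- structure(out, class = c("merged_network", class(out)))
  attr(out, "nodes") <- nodes
  out
}

#' Scan MCL inflation values and test modularity against random networks
#'
#' Clusters the network at every inflation value in `grid`, keeps the one
#' with the highest modularity, and compares that modularity with the
#' best modularity of `n_random` edge-reassigned random networks (same
#' node and edge counts). The empirical p uses the +1 correction.
#'
#' @param net A `merged_network` tibble.
#' @param grid Inflation values (default `seq(1.2, 2, by = 0.1)`).
#' @param n_random Number of random networks (default 100).
#' @param seed Integer seed.
#' @return A list: `inflation`, `Q`, `p`, `membership`, `scan` (tibble of
#'   per-inflation Q).
#' @export
scan_inflation <- function(net, grid = seq(1.2, 2, by = 0.1),
                           n_random = 100, seed = 1) {
  best_q <- function(network) {
    qs <- vapply(grid, function(inf) {
      network_modularity(network,
                         mcl_cluster(network, inflation = inf)$membership)
    }, numeric(1))
    list(q = max(qs), idx = which.max(qs), qs = qs)
  }
  obs <- best_q(net)
  rand_q <- vapply(seq_len(n_random), function(r) {
    best_q(randomize_network(net, seed = derive_seed(seed, paste0("rand", r))))$q
  }, numeric(1))
  list(
    inflation = grid[obs$idx],
    Q = obs$q,
    p = (1 + sum(rand_q >= obs$q)) / (1 + n_random),
    membership = mcl_cluster(net, inflation = grid[obs$idx])$membership,
    scan = tibble::tibble(inflation = grid, Q = obs$qs)
  )
}

# edge counts touching a node set, per category
count_edges_for_set <- function(net, set) {
  a_in <- net$feature_a %in% set
  b_in <- net$feature_b %in% set
  any_in <- a_in | b_in
  c(
    all = sum(any_in),
    positive = sum(any_in & net$sign > 0),
    negative = sum(any_in & net$sign < 0),
    intra = sum(a_in & b_in),
    cross = sum(xor(a_in, b_in))
  )
}

#' Connectivity enrichment of node groups against random node sets
#'
#' For each node group (e.g. a body site's nodes) and each edge category
#' (all incident, positive, negative, intra-group, cross-group), compares
#' the observed edge count with the distribution over `n_iter` random
#' node sets of the same size drawn from the network. Nominal p-values
#' use the +1 correction and are Bonferroni-multiplied by the number of
#' (group, category) tests.
#'
#' @param net A `merged_network` tibble.
#' @param node_groups Named list of feature-id character vectors.
#' @param n_iter Random draws (default 1000).
#' @param seed Integer seed.
#' @param n_tests Bonferroni multiplier (default: groups x categories).
#' @return A tibble: `group`, `category`, `observed`, `p_nominal`,
#'   `p_corrected`.
#' @export
node_set_enrichment <- function(net, node_groups, n_iter = 1000, seed = 1,
                                n_tests = NULL) {
  nodes <- network_nodes(net)$feature
  cats <- c("all", "positive", "negative", "intra", "cross")
  if (is.null(n_tests)) n_tests <- length(node_groups) * length(cats)
  purrr::imap_dfr(node_groups, function(group, gname) {
    if (length(group) > length(nodes)) {
      stop("group larger than network", call. = FALSE)
    }
    obs <- count_edges_for_set(net, group)
    set.seed(derive_seed(seed, paste0("enrich~", gname)))
    rand <- t(vapply(seq_len(n_iter), function(i) {
      count_edges_for_set(net, sample(nodes, length(group)))
    }, numeric(length(cats))))
    purrr::map_dfr(seq_along(cats), function(ci) {
      p_nom <- (1 + sum(rand[, ci] >= obs[ci])) / (1 + n_iter)
      tibble::tibble(
        group = gname, category = cats[ci],
        observed = as.integer(obs[ci]),
        p_nominal = p_nom,
        p_corrected = min(1, p_nom * n_tests)
      )
    })
  })
}

# per unordered group-pair edge counts and normalized link fractions
group_pair_counts <- function(net, grouping, sign_filter = NULL) {
  e <- net
  if (!is.null(sign_filter)) e <- e[e$sign == sign_filter, , drop = FALSE]
  ga <- grouping[e$feature_a]
  gb <- grouping[e$feature_b]
  lo <- pmin(ga, gb)
  hi <- pmax(ga, gb)
  sizes <- table(grouping)
  labels <- sort(names(sizes))
  pairs <- expand.grid(a = labels, b = labels, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    a <- pairs$a[k]
    b <- pairs$b[k]
    cnt <- sum(lo == a & hi == b, na.rm = TRUE)
    cap <- if (a == b) {
      sizes[[a]] * (sizes[[a]] - 1) / 2
    } else {
      sizes[[a]] * sizes[[b]]
    }
    tibble::tibble(group_a = a, group_b = b, count = cnt,
                   capacity = cap,
                   fraction = if (cap > 0) cnt / cap else NA_real_)
  })
}

#' Enrichment of edges between node group pairs
#'
#' Counts the edges between every unordered pair of node groups (body
#' sites or taxonomic classes), normalizes by the number of links the two
#' groups could form (`|A|*|B|`, or `|A|*(|A|-1)/2` within a group), and
#' assesses significance against `n_iter` edge-reassigned random
#' networks. Positive and negative edges can be tested separately via
#' `sign_filter`.
#'
#' @param net A `merged_network` tibble.
#' @param grouping Named character vector: feature id -> group label.
#' @param n_iter Random networks (default 1000).
#' @param seed Integer seed.
#' @param sign_filter Optional +1 or -1 to restrict to one edge sign.
#' @param p_cut Significance cutoff on the empirical p (default 0.05).
#' @return A tibble: `group_a`, `group_b`, `count`, `capacity`,
#'   `fraction`, `p`, `significant`.
#' @export
group_pair_enrichment <- function(net, grouping, n_iter = 1000, seed = 1,
                                  sign_filter = NULL, p_cut = 0.05) {
  obs <- group_pair_counts(net, grouping, sign_filter)
  rand_counts <- matrix(0, nrow = nrow(obs), ncol = n_iter)
  for (r in seq_len(n_iter)) {
    rn <- randomize_network(net, seed = derive_seed(seed, paste0("gp", r)))
    rand_counts[, r] <- group_pair_counts(rn, grouping, sign_filter)$count
  }
  obs$p <- vapply(seq_len(nrow(obs)), function(k) {
    (1 + sum(rand_counts[k, ] >= obs$count[k])) / (1 + n_iter)
  }, numeric(1))
  obs$significant <- obs$p <= p_cut
  obs
}

#' Table-2-style partition of network edges
#'
#' Splits the edges of a merged network by body area and site: totals,
#' edges within one body area, within one body site, per-area totals, and
#' cross-site edges within each area, with the percentages the partition
#' implies (area and within-area percentages are fractions of the network
#' total; cross-site percentages are fractions of the area's edges).
#'
#' @param net A `merged_network` tibble.
#' @param site_area Tibble mapping `body_site` to `body_area`.
#' @return A tibble: `category`, `count`, `percent`, `percent_of`.
#' @export
edge_partition <- function(net, site_area) {
  nodes <- network_nodes(net)
  area <- stats::setNames(site_area$body_area, site_area$body_site)
  sa <- area[nodes$body_site[match(net$feature_a, nodes$feature)]]
  sb <- area[nodes$body_site[match(net$feature_b, nodes$feature)]]
  site_a <- nodes$body_site[match(net$feature_a, nodes$feature)]
  site_b <- nodes$body_site[match(net$feature_b, nodes$feature)]
  total <- nrow(net)
  within_area <- sum(sa == sb)
  within_site <- sum(site_a == site_b)
  rows <- list(
    tibble::tibble(category = "total", count = total,
                   percent = 100, percent_of = "total"),
    tibble::tibble(category = "within_area", count = within_area,
                   percent = 100 * within_area / total,
                   percent_of = "total"),
    tibble::tibble(category = "within_site", count = within_site,
                   percent = 100 * within_site / within_area,
                   percent_of = "within_area")
  )
  for (ar in sort(unique(site_area$body_area))) {
    in_area <- sa == ar & sb == ar
    cnt <- sum(in_area)
    cross <- sum(in_area & site_a != site_b)
    rows <- c(rows, list(
      tibble::tibble(category = paste0("area:", ar), count = cnt,
                     percent = 100 * cnt / total, percent_of = "total"),
      tibble::tibble(category = paste0("cross_site:", ar), count = cross,
                     percent = if (cnt > 0) 100 * cross / cnt else NA_real_,
                     percent_of = paste0("area:", ar))
    ))
  }
  dplyr::bind_rows(rows)
}
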