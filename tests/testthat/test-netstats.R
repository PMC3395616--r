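# Degree statistics, clustering, path lengths, MCL, modularity,
# randomization enrichment.

triangle <- function(x, site = "gut") {
  toy_network(cbind(nn(x, site), nn(c(x[-1], x[1]), site)))
}

two_triangles <- function() {
  net <- dplyr::bind_rows(triangle(1:3), triangle(4:6))
  structure(net, class = c("merged_network", class(net)))
}

test_that("degree stats count signed degrees on a star graph", {
  hub <- nn(0)
  leaves <- nn(1:10)
  net <- toy_network(cbind(rep(hub, 10), leaves),
                     signs = rep(c(1L, -1L), 5))
  ds <- degree_stats(net)
  expect_equal(ds$degrees$degree[ds$degrees$feature == hub], 10)
  expect_true(all(ds$degrees$degree[ds$degrees$feature != hub] == 1))
  expect_equal(ds$degrees$pos_degree[ds$degrees$feature == hub], 5)
  expect_null(ds$fit) # two distinct degree values only
})

test_that("power-law fit recovers the exact synthetic exponent", {
  k <- 1:50
  fit <- fit_power_law(k, 1e6 * k^-2)
  expect_equal(fit$slope, -2, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
  expect_null(fit_power_law(1:4, c(4, 3, 2, 1)))
})

test_that("clustering coefficients match brute-force triangle counting", {
  expect_equal(clustering_coefficient(triangle(1:3))$mean, 1)
  path3 <- toy_network(cbind(nn(1:2), nn(2:3)))
  expect_equal(clustering_coefficient(path3)$mean, 0)

  # 5-node fixture vs exhaustive neighbour enumeration
  edges <- cbind(nn(c(1, 1, 2, 2, 3, 4)), nn(c(2, 3, 3, 4, 5, 5)))
  net <- toy_network(edges)
  cc <- clustering_coefficient(net)
  adj <- matrix(0, 5, 5, dimnames = list(nn(1:5), nn(1:5)))
  for (r in seq_len(nrow(edges))) {
    adj[edges[r, 1], edges[r, 2]] <- adj[edges[r, 2], edges[r, 1]] <- 1
  }
  oracle <- vapply(nn(1:5), function(v) {
    nb <- names(which(adj[v, ] == 1))
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
  got <- cc$per_node$clustering[match(nn(1:5), cc$per_node$feature)]
  expect_equal(unname(got), unname(oracle))
})

test_that("average path length averages within components only", {
  k4 <- toy_network(t(combn(nn(1:4), 2)))
  expect_equal(average_path_length(k4), 1)
  path3 <- toy_network(cbind(nn(1:2), nn(2:3)))
  expect_equal(average_path_length(path3), 4 / 3)
  disjoint <- toy_network(cbind(nn(c(1, 3)), nn(c(2, 4))))
  expect_equal(average_path_length(disjoint), 1)
})

test_that("MCL finds components, symmetry, and singletons correctly", {
  part <- mcl_cluster(two_triangles(), inflation = 1.3)
  expect_equal(part$n_clusters, 2)
  # clusters match connected components exactly
  comp_id <- rep(1:2, each = 3)
  names(comp_id) <- nn(1:6)
  expect_true(all(table(part$membership, comp_id[names(part$membership)])
                  %in% c(0, 3)))

  k5 <- toy_network(t(combn(nn(1:5), 2)))
  expect_equal(mcl_cluster(k5, inflation = 1.3)$n_clusters, 1)

  single <- matrix(0, 1, 1, dimnames = list("a", "a"))
  expect_equal(mcl_cluster(single, inflation = 1.5)$n_clusters, 1)
})

test_that("MCL clusters refine connected components", {
  set.seed(30)
  # two random connected blobs
  e1 <- t(combn(nn(1:6), 2))
  e1 <- e1[sample(nrow(e1), 9), ]
  e2 <- t(combn(nn(7:12), 2))
  e2 <- e2[sample(nrow(e2), 9), ]
  net <- toy_network(rbind(e1, e2))
  g <- as_igraph(net)
  comp <- igraph::components(g)$membership
  part <- mcl_cluster(net, inflation = 2)$membership
  for (cl in unique(part)) {
    members <- names(part)[part == cl]
    expect_equal(length(unique(comp[members])), 1)
  }
})

test_that("modularity matches the cluster-fraction formula", {
  tt <- two_triangles()
  memb <- setNames(rep(1:2, each = 3), nn(1:6))
  expect_equal(network_modularity(tt, memb), 0.5)
  expect_equal(network_modularity(tt, setNames(rep(1, 6), nn(1:6))), 0)
  # igraph cross-check as an independent implementation
  g <- as_igraph(tt)
  expect_equal(network_modularity(tt, memb),
               igraph::modularity(g, memb[igraph::V(g)$name]))
  # random partition of K6 has near-zero modularity
  k6 <- toy_network(t(combn(nn(1:6), 2)))
  memb2 <- setNames(rep(1:2, 3), nn(1:6))
  expect_lt(network_modularity(k6, memb2), 0.05)
  # brute-force value for that partition: e = 6/15 inside, a_c = 1/2 each
  expect_equal(network_modularity(k6, memb2), 6 / 15 - 2 * 0.25)
  expect_error(network_modularity(toy_network(matrix(character(0), 0, 2)),
                                  memb), "edgeless")
})

test_that("randomize_network preserves counts, varies structure, reproduces", {
  hub <- nn(0)
  net <- toy_network(cbind(rep(hub, 10), nn(1:10)))
  r1 <- randomize_network(net, seed = 5)
  expect_equal(nrow(r1), nrow(net))
  # the full node set is preserved (isolates carried as an attribute)
  expect_setequal(rebootnet:::network_nodes(r1)$feature,
                  unique(c(net$feature_a, net$feature_b)))
  expect_false(any(r1$feature_a == r1$feature_b))
  expect_identical(r1, randomize_network(net, seed = 5))
  # a star's degree sequence is destroyed with high probability
  diff_seen <- any(vapply(1:20, function(s) {
    r <- randomize_network(net, seed = s)
    max(table(c(r$feature_a, r$feature_b))) < 10
  }, logical(1)))
  expect_true(diff_seen)
  # no duplicate edges ever (sampling without replacement)
  for (s in 1:5) {
    r <- randomize_network(net, seed = s)
    expect_equal(anyDuplicated(paste(r$feature_a, r$feature_b)), 0)
  }
})

test_that("inflation scan flags planted modules but not random graphs", {
  set.seed(31)
  blocks <- list(nn(1:8), nn(9:16), nn(17:24))
  edges <- NULL
  for (b in blocks) {
    pr <- t(combn(b, 2))
    edges <- rbind(edges, pr[runif(nrow(pr)) < 0.5, ])
  }
  cross <- t(combn(nn(1:24), 2))
  cross <- cross[runif(nrow(cross)) < 0.02, ]
  net <- toy_network(rbind(edges, cross))
  net <- net[!duplicated(paste(net$feature_a, net$feature_b)), ]
  class(net) <- c("merged_network", class(tibble::tibble()))
  scan <- scan_inflation(net, grid = c(1.3, 1.6, 2), n_random = 50,
                         seed = 2)
  expect_lte(scan$p, 0.02)
  expect_gt(scan$Q, 0.2)
  # Erdos-Renyi graph: modularity not exceptional
  all_pairs <- t(combn(nn(1:24), 2))
  er <- toy_network(all_pairs[sample(nrow(all_pairs), nrow(net)), ])
  scan_er <- scan_inflation(er, grid = c(1.3, 1.6, 2), n_random = 50,
                            seed = 3)
  expect_gt(scan_er$p, 0.05)
  # determinism
  scan2 <- scan_inflation(net, grid = c(1.3, 1.6, 2), n_random = 50,
                          seed = 2)
  expect_identical(scan$Q, scan2$Q)
  expect_identical(scan$p, scan2$p)
})

test_that("node-set enrichment detects a planted clique", {
  clique <- t(combn(nn(1:6), 2))
  sparse <- cbind(nn(7:19), nn(8:20))
  net <- toy_network(rbind(clique, sparse))
  groups <- list(clique = nn(1:6), spread = nn(c(7, 10, 13, 16, 19, 20)))
  enr <- node_set_enrichment(net, groups, n_iter = 500, seed = 4)
  p_intra <- enr$p_corrected[enr$group == "clique" &
                               enr$category == "intra"]
  expect_lte(p_intra, 0.05)
  expect_true(all(enr$p_nominal >= 1 / 501 & enr$p_nominal <= 1))
  # group = all nodes: every random draw ties the observation, p = 1
  all_nodes <- unique(c(net$feature_a, net$feature_b))
  enr_all <- node_set_enrichment(net, list(all = all_nodes),
                                 n_iter = 100, seed = 5)
  expect_true(all(enr_all$p_nominal == 1))
  expect_error(node_set_enrichment(net, list(too_big = nn(1:100)),
                                   n_iter = 10, seed = 1), "larger")
})

test_that("group-pair enrichment finds saturated bipartite blocks", {
  a_nodes <- nn(1:4, "gut")
  b_nodes <- nn(5:8, "tongue")
  c_nodes <- nn(9:12, "skin")
  bip <- as.matrix(expand.grid(a_nodes, b_nodes, stringsAsFactors = FALSE))
  net <- toy_network(rbind(bip, cbind(c_nodes[1], c_nodes[2])))
  grouping <- setNames(
    c(rep("A", 4), rep("B", 4), rep("C", 4)),
    c(a_nodes, b_nodes, c_nodes)
  )
  enr <- group_pair_enrichment(net, grouping, n_iter = 300, seed = 6)
  ab <- enr[enr$group_a == "A" & enr$group_b == "B", ]
  expect_equal(ab$fraction, 1)
  expect_true(ab$significant)
  expect_true(all(enr$fraction >= 0 & enr$fraction <= 1, na.rm = TRUE))
})

test_that("edge partition mirrors the area/site accounting", {
  site_area <- tibble::tibble(
    body_site = c("gut", "tongue", "saliva"),
    body_area = c("gut", "oral", "oral")
  )
  net <- toy_network(rbind(
    cbind(nn(1, "tongue"), nn(2, "tongue")), # within oral, within site
    cbind(nn(1, "tongue"), nn(2, "saliva")), # within oral, cross site
    cbind(nn(3, "gut"), nn(4, "gut")),       # within gut
    cbind(nn(5, "gut"), nn(5, "tongue"))     # between areas
  ))
  part <- edge_partition(net, site_area)
  get <- function(cat) part[part$category == cat, ]
  expect_equal(get("total")$count, 4)
  expect_equal(get("within_area")$count, 3)
  expect_equal(get("within_area")$percent, 75)
  expect_equal(get("area:oral")$count, 2)
  expect_equal(get("cross_site:oral")$percent, 50)
  expect_equal(get("within_site")$count, 2)
  expect_equal(get("within_site")$percent, 100 * 2 / 3)
})
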