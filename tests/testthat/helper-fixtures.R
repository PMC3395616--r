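# Small fixtures built in code, shared across test files.

# count tibble from a matrix with lineage rownames
count_tbl <- function(m, lineages = rownames(m),
                      samples = colnames(m)) {
  if (is.null(samples)) samples <- paste0("smp", seq_len(ncol(m)))
  colnames(m) <- samples
  tibble::as_tibble(cbind(
    tibble::tibble(lineage = lineages),
    as.data.frame(m, check.names = FALSE)
  ))
}

# metadata for single-dataset samples; body_site per sample
sample_md <- function(samples, body_site = "gut",
                      subject = paste0("S", seq_along(samples)),
                      visit = "V1", dataset = "d1") {
  tibble::tibble(
    sample_id = samples, subject = subject, visit = visit,
    body_site = rep(body_site, length.out = length(samples)),
    dataset = dataset
  )
}

# a 4-leaf, 3-level count fixture with deterministic values
leaf_fixture <- function(n_samples = 6, seed = 42) {
  set.seed(seed)
  lineages <- c(
    "Bacteria|Firmicutes|Bacilli", "Bacteria|Firmicutes|Clostridia",
    "Bacteria|Bacteroidetes|Bacteroidia", "Bacteria|Proteobacteria|Gamma"
  )
  m <- matrix(rpois(4 * n_samples, 20) + 1, nrow = 4,
              dimnames = list(lineages, paste0("smp", seq_len(n_samples))))
  count_tbl(m)
}

# composite from a simulated single-site table
sim_fixture <- function(n_taxa = 12, n_samples = 40, depth = 5000,
                        seed = 7, ...) {
  sim <- simulate_counts(n_taxa = n_taxa, n_samples = n_samples,
                         depth = depth, seed = seed, ...)
  comp <- build_composite(to_relative(sim$counts), sim$metadata)
  list(sim = sim, comp = comp)
}

# small deterministic merged network
toy_network <- function(edges, signs = rep(1L, nrow(edges))) {
  net <- tibble::tibble(
    feature_a = pmin(edges[, 1], edges[, 2]),
    feature_b = pmax(edges[, 1], edges[, 2]),
    p_simes = 0.01, q = 0.01,
    direction_score = as.integer(signs), support = 2L,
    sign = as.integer(signs)
  )
  structure(net, class = c("merged_network", class(net)))
}

# node names with site suffix so network_nodes() can parse them
nn <- function(x, site = "gut") paste0("Bacteria|T", x, "@", site)
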