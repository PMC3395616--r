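# End-to-end orchestration: counts -> composite -> evidence (ensemble +
# GBLM) per dataset -> merged network -> summary statistics.

default_config <- function() {
  list(
    measures = c("pearson", "spearman", "bray_curtis", "kld"),
    min_count = 2, min_samples = 2, suspect_frac = 0.01,
    aggregate = FALSE, zero_frac_cutoff = 2 / 3,
    n_top = 1000, n_bottom = 1000, min_obs = 10,
    n_perm = 1000, n_boot = 1000,
    gblm = FALSE, gblm_grid = c(50, 100, 150), gblm_nu = 0.1,
    gblm_n_boot = 20, gblm_n_perm = 20,
    q_cut = 0.05, min_support = 2,
    seed = 1, output_dir = NULL
  )
}

#' Run the full co-occurrence inference pipeline
#'
#' Reads (or simulates) a count table with sample metadata, applies the
#' rare-taxon and suspect-sample filters, normalizes to relative
#' abundances, builds one composite matrix per dataset label, collects
#' candidate edges per measure with ReBoot significance (plus GBLM
#' evidence when enabled), merges all evidence into the signed
#' FDR-controlled network, and summarizes network statistics. Every
#' random draw derives from `seed`, so identical configurations
#' reproduce identical outputs.
#'
#' @param config A named list (unset keys fall back to defaults), or a
#'   path to a YAML file with the same keys. Either `counts_path` +
#'   `metadata_path`, or `simulate` (a list of [simulate_counts()]
#'   arguments) must be provided.
#' @return A list: `network` (merged_network), `evidence` (tibble),
#'   `stats` (list), `composites` (per dataset), `config` (the resolved
#'   configuration), invisibly written to `output_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)

  if (!is.null(cfg$simulate)) {
    sim <- do.call(simulate_counts, cfg$simulate)
    counts <- sim$counts
    metadata <- sim$metadata
    truth <- sim$truth
  } else if (!is.null(cfg$counts_path)) {
    counts <- read_count_table(cfg$counts_path)
    metadata <- read_sample_metadata(cfg$metadata_path)
    truth <- NULL
  } else {
    stop("config must provide `simulate` or `counts_path`", call. = FALSE)
  }

  counts <- filter_rare_taxa(counts, cfg$min_count, cfg$min_samples)
  suspects <- flag_suspect_samples(counts, cfg$suspect_frac)
  if (nrow(suspects) > 0) {
    counts <- counts[, !(names(counts) %in% suspects$sample_id),
                     drop = FALSE]
    metadata <- metadata[!metadata$sample_id %in% suspects$sample_id, ,
                         drop = FALSE]
  }
  rel <- to_relative(counts)
  if (isTRUE(cfg$aggregate)) rel <- aggregate_clades(rel)

  datasets <- unique(metadata$dataset)
  composites <- list()
  evidence <- list()
  for (ds in datasets) {
    md <- metadata[metadata$dataset == ds, , drop = FALSE]
    keep_cols <- c("lineage", md$sample_id)
    comp <- build_composite(rel[, names(rel) %in% keep_cols, drop = FALSE],
                            md, cfg$zero_frac_cutoff)
    composites[[ds]] <- comp
    for (ms in cfg$measures) {
      cand <- candidate_edges(comp, ms, n_top = cfg$n_top,
                              n_bottom = cfg$n_bottom,
                              min_obs = cfg$min_obs)
      evidence[[paste(ds, ms, sep = "/")]] <- reboot_edges(
        comp, cand, n_perm = cfg$n_perm, n_boot = cfg$n_boot,
        seed = derive_seed(cfg$seed, paste0(ds, "/", ms)), dataset = ds
      )
    }
    if (isTRUE(cfg$gblm)) {
      evidence[[paste(ds, "gblm", sep = "/")]] <- gblm_compendium(
        comp, dataset = ds, grid = cfg$gblm_grid, nu = cfg$gblm_nu,
        n_boot = cfg$gblm_n_boot, n_perm = cfg$gblm_n_perm,
        seed = derive_seed(cfg$seed, paste0(ds, "/gblm"))
      )$evidence
    }
  }
  ev <- dplyr::bind_rows(evidence)
  net <- assemble_network(ev, q_cut = cfg$q_cut,
                          min_support = cfg$min_support)

  stats <- list(
    n_edges = nrow(net),
    n_nodes = nrow(network_nodes(net)),
    n_positive = sum(net$sign > 0),
    n_negative = sum(net$sign < 0)
  )
  if (nrow(net) > 0) {
    ds_stats <- degree_stats(net)
    stats$mean_clustering <- clustering_coefficient(net)$mean
    stats$mean_path_length <- average_path_length(net)
    stats$power_law <- ds_stats$fit
  }

  result <- list(network = net, evidence = ev, stats = stats,
                 composites = composites, truth = truth, config = cfg)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_network_tsv(net, file.path(cfg$output_dir, "network.tsv"))
    write_network_graphml(net, file.path(cfg$output_dir, "network.graphml"))
    utils::write.table(as.data.frame(ev),
                       file.path(cfg$output_dir, "evidence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(
      yaml::as.yaml(list(
        config = cfg[order(names(cfg))],
        config_hash = derive_seed(0, paste(deparse(cfg[order(names(cfg))]),
                                           collapse = "")),
        stats = stats,
        r_version = as.character(getRversion())
      )),
      file.path(cfg$output_dir, "provenance.yaml")
    )
  }
  invisible(result)
}
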