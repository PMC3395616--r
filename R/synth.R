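# Synthetic compositional count tables with known ground truth, plus the
# operating-characteristic simulations that exercise the ReBoot scheme.

#' Simulate sparse compositional count tables with planted associations
#'
#' Latent absolute abundances are drawn log-normally per taxon; planted
#' positive pairs share a latent Gaussian factor at the stated
#' correlation, negative pairs load on the factor with opposite signs. An
#' optional dominant high-variance taxon acts as a compositional
#' confounder: its swings drag all relative abundances with it without
#' any true association among the remaining taxa. Counts are drawn
#' multinomially per sample at the given depth, so column sums equal the
#' depth exactly. Lineages come from a three-level hierarchy
#' (`Bacteria|Phylum_k|Taxon_i`). With `n_sites > 1`, the same subjects
#' are observed in every site and a shared per-subject factor couples the
#' sites.
#'
#' @param n_taxa Number of terminal taxa (>= 5).
#' @param n_samples Number of samples per site (>= 20).
#' @param depth Sequencing depth per sample (>= 100).
#' @param pos_pairs,neg_pairs Number of planted positive/negative taxon
#'   pairs (disjoint taxa).
#' @param strength Latent correlation of planted pairs, in (0, 1].
#' @param dominant Add a dominant high-variance taxon (default `FALSE`).
#' @param log_mean_sd Spread of per-taxon log baseline abundances.
#' @param log_sd Per-sample log-abundance standard deviation.
#' @param dominant_log_sd Log-sd of the dominant taxon (default 1.2,
#'   i.e. several-fold abundance swings between samples).
#' @param dominant_shift Log-mean advantage of the dominant taxon
#'   (default 2, putting its median share near 10% of the community).
#' @param n_sites Number of body sites (default 1).
#' @param site_coupling Fraction of per-sample variance shared across a
#'   subject's sites when `n_sites > 1` (default 0.3).
#' @param dataset Dataset label written to the metadata.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list: `counts` (count tibble), `metadata` (sample metadata
#'   tibble), `truth` (planted pairs, dominant taxon, parameters).
#' @export
simulate_counts <- function(n_taxa = 50, n_samples = 200, depth = 10000,
                            pos_pairs = 0, neg_pairs = 0, strength = 0.9,
                            dominant = FALSE, log_mean_sd = 1, log_sd = 0.7,
                            dominant_log_sd = 1.2, dominant_shift = 2,
                            n_sites = 1, site_coupling = 0.3,
                            dataset = "sim", seed = 1) {
  stopifnot(n_taxa >= 5, n_samples >= 20, depth >= 100,
            strength > 0, strength <= 1)
  n_planted <- 2 * (pos_pairs + neg_pairs)
  if (n_planted > n_taxa - as.integer(dominant)) {
    stop("more planted pairs than available taxa", call. = FALSE)
  }
  set.seed(seed)
  phylum <- ceiling(seq_len(n_taxa) / 5)
  lineages <- sprintf("Bacteria|Phylum_%02d|Taxon_%03d", phylum,
                      seq_len(n_taxa))
  mu <- stats::rnorm(n_taxa, 0, log_mean_sd)
  sdv <- rep(log_sd, n_taxa)
  dom_idx <- integer(0)
  if (dominant) {
    dom_idx <- n_taxa # last taxon is the confounder
    mu[dom_idx] <- dominant_shift
    sdv[dom_idx] <- dominant_log_sd
  }
  avail <- setdiff(seq_len(n_taxa), dom_idx)
  pos <- if (pos_pairs > 0) {
    matrix(avail[seq_len(2 * pos_pairs)], ncol = 2, byrow = TRUE)
  } else {
    matrix(integer(0), ncol = 2)
  }
  avail <- setdiff(avail, pos)
  neg <- if (neg_pairs > 0) {
    matrix(avail[seq_len(2 * neg_pairs)], ncol = 2, byrow = TRUE)
  } else {
    matrix(integer(0), ncol = 2)
  }

  subjects <- sprintf("S%03d", seq_len(n_samples))
  sites <- sprintf("site%d", seq_len(n_sites))
  counts_list <- list()
  md_list <- list()
  subj_factor <- matrix(stats::rnorm(n_taxa * n_samples), n_taxa, n_samples)
  for (s in seq_len(n_sites)) {
    eps <- matrix(stats::rnorm(n_taxa * n_samples), n_taxa, n_samples)
    if (n_sites > 1) {
      eps <- sqrt(site_coupling) * subj_factor +
        sqrt(1 - site_coupling) * eps
    }
    plant <- function(pairs, sgn) {
      for (r in seq_len(nrow(pairs))) {
        z <- stats::rnorm(n_samples)
        i <- pairs[r, 1]
        j <- pairs[r, 2]
        eps[i, ] <<- sqrt(strength) * z +
          sqrt(1 - strength) * stats::rnorm(n_samples)
        eps[j, ] <<- sgn * sqrt(strength) * z +
          sqrt(1 - strength) * stats::rnorm(n_samples)
      }
    }
    plant(pos, 1)
    plant(neg, -1)
    abund <- exp(mu + sdv * eps)
    cnt <- apply(abund, 2, function(a) {
      stats::rmultinom(1, size = depth, prob = a / sum(a))
    })
    colnames(cnt) <- paste0(subjects, "_", sites[s])
    counts_list[[s]] <- cnt
    md_list[[s]] <- tibble::tibble(
      sample_id = colnames(cnt), subject = subjects, visit = "V1",
      body_site = sites[s], dataset = dataset
    )
  }
  counts <- tibble::as_tibble(cbind(
    tibble::tibble(lineage = lineages),
    as.data.frame(do.call(cbind, counts_list), check.names = FALSE)
  ))
  pair_tbl <- function(pairs, strength) {
    tibble::tibble(
      taxon_a = lineages[pmin(pairs[, 1], pairs[, 2])],
      taxon_b = lineages[pmax(pairs[, 1], pairs[, 2])],
      strength = rep(strength, nrow(pairs))
    )
  }
  list(
    counts = counts,
    metadata = dplyr::bind_rows(md_list),
    truth = list(
      positive_pairs = pair_tbl(pos, strength),
      negative_pairs = pair_tbl(neg, strength),
      dominant = if (dominant) lineages[dom_idx] else NULL,
      seed = seed, depth = depth, n_taxa = n_taxa, n_samples = n_samples
    )
  )
}

#' Edge-recovery metrics of an inferred network against planted truth
#'
#' Compares inferred edges (as unordered lineage pairs, body site
#' stripped) with the planted positive and negative pairs.
#'
#' @param net A `merged_network` tibble (or any tibble with `feature_a`,
#'   `feature_b`, `sign`).
#' @param truth Truth list from [simulate_counts()].
#' @return A tibble: `precision`, `recall`, `sign_accuracy` (on true
#'   positives), `fpr` (false inferred edges over non-planted taxon
#'   pairs), `tp`, `fp`, `fn`.
#' @export
evaluate_recovery <- function(net, truth) {
  strip <- function(f) sub("@.*$", "", f)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~~")
  planted <- dplyr::bind_rows(
    dplyr::mutate(truth$positive_pairs, expected_sign = 1L),
    dplyr::mutate(truth$negative_pairs, expected_sign = -1L)
  )
  planted_keys <- key(planted$taxon_a, planted$taxon_b)
  if (nrow(net) > 0) {
    inf <- tibble::tibble(
      key = key(strip(net$feature_a), strip(net$feature_b)),
      sign = net$sign
    )
    inf <- inf[!duplicated(inf$key), , drop = FALSE]
  } else {
    inf <- tibble::tibble(key = character(0), sign = integer(0))
  }
  tp_keys <- intersect(inf$key, planted_keys)
  fp <- sum(!inf$key %in% planted_keys)
  n_taxa <- truth$n_taxa
  n_pairs <- n_taxa * (n_taxa - 1) / 2
  sign_ok <- if (length(tp_keys)) {
    mean(inf$sign[match(tp_keys, inf$key)] ==
           planted$expected_sign[match(tp_keys, planted_keys)])
  } else {
    NA_real_
  }
  tibble::tibble(
    precision = if (nrow(inf)) length(tp_keys) / nrow(inf) else NA_real_,
    recall = if (nrow(planted)) length(tp_keys) / nrow(planted) else
      NA_real_,
    sign_accuracy = sign_ok,
    fpr = fp / max(1, n_pairs - nrow(planted)),
    tp = length(tp_keys), fp = fp,
    fn = nrow(planted) - length(tp_keys)
  )
}

# composite matrix straight from a simulation (single pipeline path used
# by the operating-characteristic simulations below)
sim_composite <- function(sim, zero_frac_cutoff = 2 / 3) {
  build_composite(to_relative(sim$counts), sim$metadata,
                  zero_frac_cutoff = zero_frac_cutoff)
}

#' False-positive rate of the ReBoot test on association-free data
#'
#' Simulates compositional data with no planted associations but one
#' dominant high-variance taxon and runs the Pearson ReBoot test on the
#' pairs where compositionality acts: `n_pairs` pairs joining the
#' confounder with random background taxa, plus the same number of random
#' background pairs. Reports the fraction significant at `alpha` on the
#' two-sided scale (`2 * min(p, 1 - p) < alpha`). With
#' `renormalize = FALSE` the null is a naive permutation, quantifying how
#' badly compositionality inflates the test on identical data.
#'
#' @param n_reps Simulation replicates.
#' @param n_pairs Confounder-involving pairs per replicate (matched by as
#'   many background pairs).
#' @param n_taxa,n_samples,depth Passed to [simulate_counts()].
#' @param n_iter Permutation/bootstrap iterations per edge.
#' @param alpha Two-sided significance level (default 0.05).
#' @param renormalize Use the renormalized null (default `TRUE`).
#' @param seed Integer seed.
#' @return The false-positive rate over all tested pairs.
#' @export
reboot_null_fpr <- function(n_reps = 20, n_pairs = 10, n_taxa = 50,
                            n_samples = 200, depth = 10000, n_iter = 100,
                            alpha = 0.05, renormalize = TRUE, seed = 1) {
  hits <- 0L
  total <- 0L
  for (rep in seq_len(n_reps)) {
    sim <- simulate_counts(n_taxa = n_taxa, n_samples = n_samples,
                           depth = depth, dominant = TRUE,
                           seed = derive_seed(seed, paste0("fpr", rep)))
    comp <- sim_composite(sim)
    dom <- paste0(sim$truth$dominant, "@", "site1")
    feats <- setdiff(comp$feature, dom)
    set.seed(derive_seed(seed, paste0("fprpairs", rep)))
    with_dom <- cbind(sample(feats, min(n_pairs, length(feats))), dom)
    bg <- t(replicate(n_pairs, sample(feats, 2)))
    pairs <- rbind(with_dom, bg)
    pairs <- t(apply(pairs, 1, sort))
    pairs <- pairs[!duplicated(paste(pairs[, 1], pairs[, 2])), ,
                   drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      boot <- bootstrap_distribution(
        comp, pairs[r, 1], pairs[r, 2], "pearson", n_iter = n_iter,
        seed = derive_seed(seed, paste(rep, r, "b"))
      )
      null <- permutation_null(
        comp, pairs[r, 1], pairs[r, 2], "pearson", n_iter = n_iter,
        seed = derive_seed(seed, paste(rep, r, "p")),
        renormalize = renormalize
      )
      p1 <- pooled_z_pvalue(boot, null)
      if (!is.na(p1)) {
        total <- total + 1L
        if (2 * min(p1, 1 - p1) < alpha) hits <- hits + 1L
      }
    }
  }
  hits / total
}

#' Power of the ReBoot test on planted positive pairs
#'
#' Simulates data with planted positive pairs at the given latent
#' correlation and reports the fraction detected at oriented p < `alpha`
#' by the renormalized Pearson ReBoot test.
#'
#' @inheritParams reboot_null_fpr
#' @param strength Planted latent correlation (default 0.9).
#' @param pairs_per_rep Planted pairs per replicate.
#' @return Detection rate over all planted pairs.
#' @export
reboot_power <- function(n_reps = 20, pairs_per_rep = 3, strength = 0.9,
                         n_taxa = 50, n_samples = 200, depth = 10000,
                         n_iter = 100, alpha = 0.05, seed = 1) {
  detected <- 0L
  total <- 0L
  for (rep in seq_len(n_reps)) {
    sim <- simulate_counts(n_taxa = n_taxa, n_samples = n_samples,
                           depth = depth, pos_pairs = pairs_per_rep,
                           strength = strength,
                           seed = derive_seed(seed, paste0("pow", rep)))
    comp <- sim_composite(sim)
    tp <- sim$truth$positive_pairs
    for (r in seq_len(nrow(tp))) {
      fa <- paste0(tp$taxon_a[r], "@site1")
      fb <- paste0(tp$taxon_b[r], "@site1")
      if (!all(c(fa, fb) %in% comp$feature)) next
      boot <- bootstrap_distribution(
        comp, fa, fb, "pearson", n_iter = n_iter,
        seed = derive_seed(seed, paste(rep, r, "b"))
      )
      null <- permutation_null(
        comp, fa, fb, "pearson", n_iter = n_iter,
        seed = derive_seed(seed, paste(rep, r, "p"))
      )
      p1 <- pooled_z_pvalue(boot, null)
      total <- total + 1L
      if (!is.na(p1) && p1 < alpha) detected <- detected + 1L
    }
  }
  detected / total
}
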