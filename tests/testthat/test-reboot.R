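# Permutation-renormalization bootstrap significance.

test_that("pooled z-test matches the closed-form normal tail", {
  set.seed(2)
  boot <- rnorm(20, 0.5, 0.1)
  null <- rnorm(20, 0.1, 0.12)
  s2 <- (19 * var(boot) + 19 * var(null)) / 38
  z <- (mean(boot) - mean(null)) / sqrt(s2)
  expect_equal(pooled_z_pvalue(boot, null), pnorm(z, lower.tail = FALSE),
               tolerance = 1e-12)
  # symmetry fixed point
  expect_equal(pooled_z_pvalue(c(0, 1, 0, 1), c(1, 0, 1, 0)), 0.5)
  # extreme separation
  expect_lt(pooled_z_pvalue(rnorm(50, 0.8, 0.01), rnorm(50, 0, 0.01)),
            1e-10)
})

test_that("point-null z-test matches hand computation", {
  set.seed(3)
  boot <- rnorm(20, 0.3, 0.05)
  expect_equal(
    point_null_pvalue(boot, 0.4),
    pnorm((mean(boot) - 0.4) / sd(boot), lower.tail = FALSE),
    tolerance = 1e-12
  )
  expect_equal(point_null_pvalue(c(0.4, 0.5, 0.6), 0.5), 0.5)
})

test_that("tail adjustment orients all measures toward co-presence", {
  expect_equal(tail_adjust(0.01, "pearson")$p_oriented, 0.01)
  expect_equal(tail_adjust(0.01, "pearson")$direction, 1L)
  expect_equal(tail_adjust(0.99, "pearson")$direction, -1L)
  # high dissimilarity (small upper-tail p) means exclusion
  adj <- tail_adjust(0.02, "bray_curtis")
  expect_equal(adj$p_oriented, 0.98)
  expect_equal(adj$direction, -1L)
  adj2 <- tail_adjust(0.97, "kld")
  expect_equal(adj2$p_oriented, 0.03)
  expect_equal(adj2$direction, 1L)
})

test_that("stability filter uses the central bootstrap interval inclusively", {
  set.seed(4)
  b <- rnorm(1000)
  q <- quantile(b, c(0.025, 0.975), names = FALSE)
  expect_true(stability_filter(median(b), b))
  expect_true(stability_filter(q[1], b))
  expect_false(stability_filter(max(b) + 1, b))
  expect_false(stability_filter(min(b) - 1, b))
  # matches an independent sort-based computation at several cuts
  for (obs in c(-2.5, -1, 0, 1, 2.5)) {
    expect_equal(stability_filter(obs, b), obs >= q[1] && obs <= q[2])
  }
})

test_that("resampling distributions are seed-deterministic", {
  fx <- sim_fixture(n_taxa = 8, n_samples = 30)
  feats <- fx$comp$feature[1:2]
  d1 <- permutation_null(fx$comp, feats[1], feats[2], "pearson",
                         n_iter = 50, seed = 99)
  d2 <- permutation_null(fx$comp, feats[1], feats[2], "pearson",
                         n_iter = 50, seed = 99)
  expect_identical(d1$values, d2$values)
  b1 <- bootstrap_distribution(fx$comp, feats[1], feats[2], "bray_curtis",
                               n_iter = 50, seed = 7)
  b2 <- bootstrap_distribution(fx$comp, feats[1], feats[2], "bray_curtis",
                               n_iter = 50, seed = 7)
  expect_identical(b1$values, b2$values)
})

test_that("plain permutation null is centered at zero without confounding", {
  fx <- sim_fixture(n_taxa = 10, n_samples = 60, seed = 21)
  feats <- sort(fx$comp$feature)[1:2]
  d <- permutation_null(fx$comp, feats[1], feats[2], "pearson",
                        n_iter = 400, seed = 5, renormalize = FALSE)
  se <- sd(d$values) / sqrt(length(d$values))
  expect_lt(abs(mean(d$values)), 3 * se + 0.02)
})

test_that("renormalized null reproduces the compositional bias", {
  # a dominant high-variance taxon drags all relative abundances with it;
  # the renormalized null must carry that bias while the naive null sits
  # at zero
  sim <- simulate_counts(n_taxa = 20, n_samples = 150, depth = 20000,
                         dominant = TRUE, dominant_shift = 3,
                         dominant_log_sd = 2, seed = 31)
  comp <- build_composite(to_relative(sim$counts), sim$metadata)
  dom <- paste0(sim$truth$dominant, "@site1")
  passive <- sort(setdiff(comp$feature, dom))

  # pair with the confounder: strongly negative null mean, near the
  # observed spurious anticorrelation
  m <- composite_matrix(comp)
  nd <- permutation_null(comp, passive[1], dom, "pearson",
                         n_iter = 500, seed = 8)
  naive_d <- permutation_null(comp, passive[1], dom, "pearson",
                              n_iter = 500, seed = 8, renormalize = FALSE)
  expect_lt(mean(nd$values), -0.1)
  expect_lt(abs(mean(naive_d$values)), 0.05)

  # passive pair: the null mean is (mildly) negative, matching the
  # sum-constraint bias, and agrees with a brute-force full-matrix
  # renormalization oracle at Monte-Carlo precision
  np <- permutation_null(comp, passive[1], passive[2], "pearson",
                         n_iter = 2000, seed = 9)
  expect_lt(mean(np$values), 0)
  brute <- local({
    target <- passive[2] # lexicographically second member is permuted
    it <- match(target, rownames(m))
    ia <- match(passive[1], rownames(m))
    set.seed(101)
    vapply(seq_len(5000), function(i) {
      M <- m
      M[it, ] <- M[it, sample.int(ncol(M))]
      M <- sweep(M, 2, colSums(M), "/")
      cor(M[ia, ], M[it, ])
    }, numeric(1))
  })
  se <- sqrt(sd(brute)^2 / 5000 + sd(np$values)^2 / 2000)
  expect_lt(abs(mean(np$values) - mean(brute)), 4 * se)
})

test_that("bootstrap mean tracks the observed score", {
  fx <- sim_fixture(n_taxa = 8, n_samples = 50, seed = 13)
  comp <- fx$comp
  feats <- sort(comp$feature)[1:2]
  m <- composite_matrix(comp)
  obs <- cor(m[feats[1], ], m[feats[2], ])
  b <- bootstrap_distribution(comp, feats[1], feats[2], "pearson",
                              n_iter = 500, seed = 3)
  expect_lt(abs(mean(b$values) - obs), 3 * sd(b$values))
  # degenerate identical pair: Bray-Curtis bootstrap draws are all zero
  comp2 <- comp
  i2 <- match(feats[2], comp2$feature)
  comp2[i2, -(1:3)] <- comp2[match(feats[1], comp$feature), -(1:3)]
  b0 <- bootstrap_distribution(comp2, feats[1], feats[2], "bray_curtis",
                               n_iter = 50, seed = 3)
  expect_true(all(b0$values == 0))
})

test_that("influence check flags outlier-driven associations only", {
  x <- c(rep(0.1, 19), 5)
  y <- c(0.1 + rnorm(19, 0, 0.02), 5)
  samples <- paste0("s", 1:20)
  tbl <- count_tbl(rbind(`A|x` = x, `A|y` = y,
                         `A|z` = rep(1, 20)), samples = samples)
  comp <- build_composite(to_relative(tbl), sample_md(samples),
                          zero_frac_cutoff = 1)
  expect_true(influence_check(comp, "A|x@gut", "A|y@gut", "pearson"))
  # a perfectly correlated pair is never flagged
  tbl2 <- count_tbl(rbind(`A|x` = 1:20, `A|y` = 2 * (1:20),
                          `A|z` = rep(1, 20)), samples = samples)
  comp2 <- build_composite(to_relative(tbl2), sample_md(samples),
                           zero_frac_cutoff = 1)
  expect_false(influence_check(comp2, "A|x@gut", "A|y@gut", "pearson"))
})

test_that("reboot_edges produces oriented evidence deterministically", {
  fx <- sim_fixture(n_taxa = 8, n_samples = 40, seed = 17)
  suppressMessages(
    cand <- candidate_edges(fx$comp, "pearson", n_top = 3, n_bottom = 3,
                            min_obs = 5)
  )
  ev1 <- reboot_edges(fx$comp, cand, n_perm = 50, n_boot = 50, seed = 1,
                      dataset = "d1", check_influence = FALSE)
  ev2 <- reboot_edges(fx$comp, cand, n_perm = 50, n_boot = 50, seed = 1,
                      dataset = "d1", check_influence = FALSE)
  expect_identical(ev1$p_oriented, ev2$p_oriented)
  expect_true(all(ev1$p_oriented >= 0 & ev1$p_oriented <= 1, na.rm = TRUE))
  expect_true(all(ev1$direction %in% c(-1L, 1L)))
  # evidence rows are order-independent: per-edge seeds hash the identity
  ev3 <- reboot_edges(fx$comp, cand[rev(seq_len(nrow(cand))), ],
                      n_perm = 50, n_boot = 50, seed = 1, dataset = "d1",
                      check_influence = FALSE)
  merged <- dplyr::inner_join(
    ev1, ev3, by = c("feature_a", "feature_b", "measure")
  )
  expect_equal(merged$p_oriented.x, merged$p_oriented.y)
})
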