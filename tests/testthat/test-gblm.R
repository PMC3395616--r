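# Component-wise boosted linear models.

make_X <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("x%02d", 1:p)))
}

test_that("boosting converges to the OLS slope on a single predictor", {
  X <- make_X(100, 1)
  y <- 2 * X[, 1] # noise-free
  mod <- boost_linear(X, y, n_iter = 150, nu = 0.1)
  expect_equal(unname(mod$coefficients["x01"]), 2, tolerance = 1e-3)
  expect_equal(mod$nominal_score, 1, tolerance = 1e-3)
  # geometric residual decay: after k rounds a fraction (1 - nu)^k remains
  mod50 <- boost_linear(X, y, n_iter = 50, nu = 0.1)
  expect_equal(unname(mod50$coefficients["x01"]), 2 * (1 - 0.9^50),
               tolerance = 1e-6)
})

test_that("n_iter = 0 returns the intercept-only model", {
  X <- make_X(30, 3)
  y <- rnorm(30)
  mod <- boost_linear(X, y, n_iter = 0)
  expect_length(mod$coefficients, 0)
  expect_equal(mod$intercept, mean(y))
  expect_equal(mod$nominal_score, 0)
})

test_that("duplicated predictors share the coefficient mass of one", {
  X1 <- make_X(80, 1, seed = 4)
  set.seed(5)
  y <- 1.5 * X1[, 1] + rnorm(80, 0, 0.1)
  single <- boost_linear(X1, y, n_iter = 100)
  Xdup <- cbind(X1, X1)
  colnames(Xdup) <- c("a", "b")
  dup <- boost_linear(Xdup, y, n_iter = 100)
  expect_equal(sum(dup$coefficients), sum(single$coefficients),
               tolerance = 1e-8)
})

test_that("training RSS is non-increasing in boosting iterations", {
  X <- make_X(60, 5, seed = 6)
  set.seed(7)
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(60, 0, 0.5)
  r2 <- vapply(c(0, 5, 10, 25, 50, 100), function(k) {
    boost_linear(X, y, n_iter = k)$nominal_score
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("boosted logistic model separates and stays neutral as appropriate", {
  x <- c(seq(-3, -1, length.out = 50), seq(1, 3, length.out = 50))
  y <- rep(c(0, 1), each = 50)
  set.seed(8)
  X <- cbind(sep = x)
  mod <- boost_logistic(X, y, n_iter = 150)
  expect_equal(mod$nominal_score, 1) # perfectly separable -> AUC 1
  expect_equal(boost_logistic(X, y, n_iter = 0)$nominal_score, 0.5)
  # independent predictor: AUC near 0.5
  Xn <- cbind(noise = rnorm(400))
  yn <- rbinom(400, 1, 0.5)
  expect_lt(abs(boost_logistic(Xn, yn, n_iter = 50)$nominal_score - 0.5),
            0.1)
  expect_error(boost_logistic(X, rep(1, 100), 10), "single-class")
})

test_that("cv_select is seed-deterministic and spots pure noise", {
  X <- make_X(100, 5, seed = 9)
  set.seed(10)
  y <- 2 * X[, 2] + rnorm(100, 0, 0.3)
  s1 <- cv_select(X, y, seed = 42)
  s2 <- cv_select(X, y, seed = 42)
  expect_identical(s1, s2)
  expect_gt(s1$cv_score, 0.8)
  # pure-noise target: held-out R^2 at or below zero
  set.seed(11)
  ynull <- rnorm(100)
  expect_lt(cv_select(X, ynull, seed = 1)$cv_score, 0.05)
})

test_that("adjusted R^2 matches the closed formula and guards small n", {
  expect_equal(adjusted_r2(1, 20, 3), 1)
  expect_equal(adjusted_r2(0.5, 11, 1), 1 - 0.5 * 10 / 9)
  expect_equal(adjusted_r2(0.0, 11, 1), 1 - 1 * 10 / 9)
  expect_true(is.na(adjusted_r2(0.9, 5, 4)))
})

test_that("model quality reflects AUCs below one half and takes the minimum", {
  expect_equal(model_quality(0.3, 0.8, binary = TRUE), 0.7)
  expect_equal(model_quality(0.4, 0.6, binary = FALSE), 0.4)
  expect_equal(model_quality(0.5, 0.5, binary = TRUE), 0.5)
})

test_that("prefilter excludes the target's lineage relatives within a site", {
  samples <- paste0("s", 1:30)
  set.seed(12)
  m <- matrix(runif(5 * 30) + 0.2, 5,
              dimnames = list(c("B|F", "B|F|C", "B|F|C|G", "B|X", "B|Y"),
                              samples))
  comp <- build_composite(to_relative(count_tbl(m, samples = samples)),
                          sample_md(samples), zero_frac_cutoff = 1)
  src <- prefilter_sources(comp, "gut", "gut", "B|F|C", alpha = 1)
  expect_false(any(c("B|F@gut", "B|F|C@gut", "B|F|C|G@gut") %in% src))
  expect_true(all(src %in% c("B|X@gut", "B|Y@gut")))
})

test_that("prefilter retains the same lineage across sites and rejects noise", {
  samples <- paste0("s", 1:60)
  md <- tibble::tibble(
    sample_id = samples, subject = rep(sprintf("S%02d", 1:30), 2),
    visit = "V1", body_site = rep(c("gut", "tongue"), each = 30),
    dataset = "d1"
  )
  set.seed(13)
  base <- runif(30) + 0.2
  m <- rbind(
    `B|F` = c(base, base + runif(30, 0, 0.05)), # same clade, both sites
    `B|X` = runif(60) + 0.2,
    `B|Y` = runif(60) + 0.2
  )
  comp <- build_composite(to_relative(count_tbl(m, samples = samples)), md,
                          zero_frac_cutoff = 1)
  src <- prefilter_sources(comp, "tongue", "gut", "B|F", alpha = 0.05)
  expect_true("B|F@tongue" %in% src) # cross-site self is a valid source

  # independent white-noise sources are excluded at ~ the nominal rate
  # (composite built directly so no sum constraint couples the rows)
  set.seed(14)
  n_kept <- 0
  n_tot <- 0
  for (i in 1:20) {
    lin <- c("B|T", sprintf("B|N%02d", 1:20))
    cmp <- tibble::as_tibble(cbind(
      tibble::tibble(feature = paste0(lin, "@gut"), lineage = lin,
                     body_site = "gut"),
      as.data.frame(matrix(runif(21 * 30), 21,
                           dimnames = list(NULL, paste0("S", 1:30, ":V1"))))
    ))
    src2 <- prefilter_sources(cmp, "gut", "gut", "B|T", alpha = 0.05)
    n_tot <- n_tot + 20
    n_kept <- n_kept + length(src2)
  }
  expect_lt(n_kept / n_tot, 0.12) # ~5% expected under the null
})

test_that("planted predictors are recovered with few spurious selections", {
  # 3 active of 30 predictors, n = 200, SNR 5; the fitted pipeline
  # (prefilter + CV-selected boosting) must find all 3 actives with at
  # most 2 spurious picks in at least 80% of seeds
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(200 * 30), 200, 30,
                dimnames = list(NULL, sprintf("x%02d", 1:30)))
    beta <- c(1, -1, 0.8)
    signal <- X[, 1:3] %*% beta
    y <- drop(signal) + rnorm(200, 0, sd(signal) / sqrt(5))
    keep <- vapply(seq_len(30), function(j) {
      suppressWarnings(cor.test(X[, j], y, method = "spearman",
                                exact = FALSE)$p.value) < 0.05
    }, logical(1))
    Xk <- X[, keep, drop = FALSE]
    sel <- cv_select(Xk, y, seed = s)
    mod <- boost_linear(Xk, y, sel$n_iter)
    picked <- names(mod$coefficients)
    actives <- sprintf("x%02d", 1:3)
    if (all(actives %in% picked) &&
        length(setdiff(picked, actives)) <= 2) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 16)
})

test_that("gblm significance separates planted signal from noise", {
  samples <- paste0("s", 1:80)
  set.seed(15)
  src <- runif(80) + 0.2
  m <- rbind(
    `B|S` = src,
    `B|T` = 0.8 * src + rnorm(80, 0, 0.05) + 0.3,
    `B|N` = runif(80) + 0.2,
    `B|Z` = runif(80) + 0.2
  )
  comp <- build_composite(to_relative(count_tbl(m, samples = samples)),
                          sample_md(samples), zero_frac_cutoff = 1)
  mod <- fit_gblm(comp, "gut", "gut", "B|T", seed = 3)
  expect_true(mod$retained)
  expect_true("B|S@gut" %in% names(mod$coefficients))
  sig <- gblm_significance(comp, mod, seed = 3)
  expect_false(sig$discarded)
  expect_lt(sig$p, 0.05)
  # identical seed, identical p
  sig2 <- gblm_significance(comp, mod, seed = 3)
  expect_identical(sig$p, sig2$p)
})

test_that("tidy and glance expose the model in broom layout", {
  X <- make_X(50, 3, seed = 16)
  y <- X[, 1] + rnorm(50, 0, 0.2)
  mod <- boost_linear(X, y, 50)
  td <- tidy(mod)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term[1], "(Intercept)")
  gl <- glance(mod)
  expect_true(all(c("n_boost", "n_selected", "nominal_score") %in%
                    names(gl)))
  expect_equal(gl$n_selected, length(mod$coefficients))
})
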