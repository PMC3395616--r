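# Generalized boosted linear models: sparse linear (or logistic) models
# predicting one target feature from source-site features, built by
# component-wise L2 boosting with cross-validated complexity selection.

#' Admissible source features for a GBLM target
#'
#' Sources are features of the source body site whose Spearman correlation
#' with the target is nominally significant (p < `alpha`). When source and
#' target site coincide, the target clade itself and all of its ancestors
#' and descendants are excluded, so a clade is never predicted from
#' abundances it is arithmetically part of.
#'
#' @param composite A composite tibble.
#' @param source_site,target_site Body-site labels.
#' @param target_lineage Lineage of the target clade in `target_site`.
#' @param alpha Spearman p-value threshold (default 0.05).
#' @return Character vector of admissible source feature ids (possibly
#'   empty).
#' @export
prefilter_sources <- function(composite, source_site, target_site,
                              target_lineage, alpha = 0.05) {
  meta <- composite_meta(composite)
  m <- composite_matrix(composite)
  target_feature <- paste0(target_lineage, "@", target_site)
  it <- match(target_feature, meta$feature)
  if (is.na(it)) stop("target feature not in composite: ", target_feature,
                      call. = FALSE)
  cand <- which(meta$body_site == source_site)
  if (source_site == target_site) {
    rel <- meta$lineage[cand] == target_lineage |
      lineage_related_chr(meta$lineage[cand],
                          rep(target_lineage, length(cand)))
    cand <- cand[!rel]
  }
  if (!length(cand)) return(character(0))
  y <- m[it, ]
  keep <- vapply(cand, function(i) {
    use <- !is.na(y) & !is.na(m[i, ])
    if (sum(use) < 4) return(FALSE)
    ct <- suppressWarnings(
      stats::cor.test(m[i, use], y[use], method = "spearman", exact = FALSE)
    )
    is.finite(ct$p.value) && ct$p.value < alpha
  }, logical(1))
  meta$feature[cand[keep]]
}

new_gblm <- function(coefficients, intercept, n_boost, nominal_score,
                     binary, selected_path) {
  structure(
    list(coefficients = coefficients, intercept = intercept,
         n_boost = n_boost, nominal_score = nominal_score, binary = binary,
         selected_path = selected_path),
    class = "gblm"
  )
}

#' Component-wise L2-boosted linear model
#'
#' Starts from the intercept-only model (mean of `y`); each boosting round
#' fits every candidate predictor alone to the current residuals by least
#' squares, selects the one that most reduces the residual sum of squares,
#' adds `nu` times its coefficient to the model, and updates the
#' residuals. The number of distinct selected predictors is at most
#' `n_iter`, so the model is sparse by construction.
#'
#' @param X Numeric matrix, samples in rows, candidate predictors in
#'   columns (column names required).
#' @param y Numeric response vector.
#' @param n_iter Number of boosting rounds.
#' @param nu Learning rate (default 0.1).
#' @return A `gblm` object: non-zero `coefficients` (on the original
#'   predictor scale), `intercept`, `n_boost`, `nominal_score` (training
#'   R^2), and the per-round `selected_path`.
#' @export
boost_linear <- function(X, y, n_iter, nu = 0.1) {
  stopifnot(is.numeric(y), n_iter >= 0, nu > 0)
  if (is.null(X) || NCOL(X) == 0) {
    return(new_gblm(numeric(0), mean(y), 0L, 0, FALSE, character(0)))
  }
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), !is.null(colnames(X)))
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  ok <- sdev > 0
  Z <- sweep(sweep(X[, ok, drop = FALSE], 2, mu[ok], "-"), 2, sdev[ok], "/")
  beta <- stats::setNames(numeric(ncol(Z)), colnames(Z))
  r <- y - mean(y)
  tss <- sum(r^2)
  path <- character(0)
  if (tss > 0 && ncol(Z) > 0) {
    ztz <- colSums(Z^2)
    for (it in seq_len(n_iter)) {
      ztr <- drop(crossprod(Z, r))
      gain <- ztr^2 / ztz
      j <- which.max(gain)
      b <- nu * ztr[j] / ztz[j]
      beta[j] <- beta[j] + b
      r <- r - b * Z[, j]
      path <- c(path, colnames(Z)[j])
    }
  }
  nz <- beta != 0
  coef_orig <- beta[nz] / sdev[ok][nz]
  intercept <- mean(y) - sum(coef_orig * mu[ok][nz])
  r2 <- if (tss > 0) 1 - sum(r^2) / tss else 0
  new_gblm(coef_orig, intercept, as.integer(n_iter), r2, FALSE, path)
}

#' Component-wise boosted logistic model for binary targets
#'
#' Gradient boosting on the negative log-likelihood of the logit model:
#' each round fits every predictor alone by least squares to the current
#' gradient (`y - p`), adds `nu` times the best fit to the linear score,
#' and recomputes the fitted probabilities. Scored by AUC.
#'
#' @inheritParams boost_linear
#' @param y Binary 0/1 response.
#' @return A `gblm` object with `nominal_score` the training AUC.
#' @export
boost_logistic <- function(X, y, n_iter, nu = 0.1) {
  stopifnot(all(y %in% c(0, 1)), n_iter >= 0, nu > 0)
  if (length(unique(y)) < 2) {
    stop("single-class binary target", call. = FALSE)
  }
  if (is.null(X) || NCOL(X) == 0) {
    return(new_gblm(numeric(0), stats::qlogis(mean(y)), 0L, 0.5, TRUE,
                    character(0)))
  }
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), !is.null(colnames(X)))
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  ok <- sdev > 0
  Z <- sweep(sweep(X[, ok, drop = FALSE], 2, mu[ok], "-"), 2, sdev[ok], "/")
  beta <- stats::setNames(numeric(ncol(Z)), colnames(Z))
  f0 <- stats::qlogis(mean(y))
  f <- rep(f0, length(y))
  path <- character(0)
  if (ncol(Z) > 0) {
    ztz <- colSums(Z^2)
    for (it in seq_len(n_iter)) {
      u <- y - stats::plogis(f)
      ztu <- drop(crossprod(Z, u))
      j <- which.max(ztu^2 / ztz)
      b <- nu * ztu[j] / ztz[j]
      beta[j] <- beta[j] + b
      f <- f + b * Z[, j]
      path <- c(path, colnames(Z)[j])
    }
  }
  nz <- beta != 0
  coef_orig <- beta[nz] / sdev[ok][nz]
  intercept <- f0 - sum(coef_orig * mu[ok][nz])
  new_gblm(coef_orig, intercept, as.integer(n_iter),
           auc_score(stats::plogis(f), y), TRUE, path)
}

#' @export
predict.gblm <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  eta <- rep(object$intercept, nrow(newdata))
  if (length(object$coefficients)) {
    eta <- eta + drop(newdata[, names(object$coefficients), drop = FALSE] %*%
                        object$coefficients)
  }
  if (object$binary && type == "response") stats::plogis(eta) else eta
}

# Mann-Whitney AUC of scores against binary labels
auc_score <- function(score, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated selection of the boosting iteration count
#'
#' k-fold cross-validation (seeded shuffle for fold assignment) over a
#' grid of iteration counts; the grid value with the best mean held-out
#' root-mean-square error (continuous) or AUC (binary) is chosen.
#'
#' @param X Predictor matrix (samples x predictors).
#' @param y Response (numeric, or 0/1 for `binary = TRUE`).
#' @param grid Candidate iteration counts (default `c(50, 100, 150)`).
#' @param k Number of folds (default 10; reduced with a warning when
#'   fewer samples than folds).
#' @param seed Integer seed for the fold shuffle.
#' @param nu Learning rate.
#' @param binary Fit the logistic variant.
#' @return A list: `n_iter` (chosen grid value) and `cv_score` (pooled
#'   held-out R^2 for continuous targets, AUC for binary).
#' @export
cv_select <- function(X, y, grid = c(50, 100, 150), k = 10, seed = 1,
                      nu = 0.1, binary = FALSE) {
  n <- length(y)
  if (n < k) {
    warning("fewer samples than folds; reducing k to ", n)
    k <- n
  }
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  X <- as.matrix(X)
  fit_fun <- if (binary) boost_logistic else boost_linear
  pred <- matrix(NA_real_, nrow = n, ncol = length(grid))
  for (f in seq_len(k)) {
    test <- fold == f
    for (g in seq_along(grid)) {
      mod <- fit_fun(X[!test, , drop = FALSE], y[!test], grid[g], nu = nu)
      pred[test, g] <- predict(mod, X[test, , drop = FALSE],
                               type = if (binary) "response" else "link")
    }
  }
  if (binary) {
    scores <- apply(pred, 2, auc_score, y = y)
    best <- which.max(scores)
  } else {
    rmse <- sqrt(colMeans((pred - y)^2))
    best <- which.min(rmse)
    scores <- 1 - colSums((pred - y)^2) / sum((y - mean(y))^2)
  }
  list(n_iter = grid[best], cv_score = scores[best])
}

#' Adjusted R-squared penalizing non-zero parameter count
#'
#' AR^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1).
#'
#' @param r2 Unadjusted R^2.
#' @param n Number of training samples.
#' @param p Number of non-zero parameters.
#' @return Adjusted R^2; `NA` when `n <= p + 1` (model must be
#'   discarded).
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) return(NA_real_)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Final model quality score
#'
#' Binary models first have AUCs below 0.5 reflected to `1 - AUC` (AUC is
#' not computed directionally); the reported quality is the minimum of
#' the cross-validated and nominal scores.
#'
#' @param cv,nominal Cross-validated and full-data R^2/AUC.
#' @param binary Whether the scores are AUCs.
#' @return The quality score.
#' @export
model_quality <- function(cv, nominal, binary = FALSE) {
  if (binary) {
    cv <- max(cv, 1 - cv)
    nominal <- max(nominal, 1 - nominal)
  }
  min(cv, nominal)
}

# design matrix (samples x sources) and response for a (ss, ts, tt) tuple,
# restricted to columns where the target and every source are observed
gblm_design <- function(composite, sources, target_feature) {
  m <- composite_matrix(composite)
  rows <- c(target_feature, sources)
  sub <- m[rows, , drop = FALSE]
  cols <- colSums(is.na(sub)) == 0
  list(
    X = t(sub[sources, cols, drop = FALSE]),
    y = sub[target_feature, cols],
    cols = which(cols)
  )
}

#' Fit one GBLM for a (source site, target site, target clade) tuple
#'
#' Runs the source prefilter, cross-validated iteration selection and the
#' final boosted fit, and attaches the adjusted-R^2 quality score. Models
#' with no admissible sources, too few samples, or AR^2 <= 0 are returned
#' with `retained = FALSE`.
#'
#' @inheritParams prefilter_sources
#' @param grid,k,nu,seed Passed to [cv_select()] / [boost_linear()].
#' @return A `gblm` object augmented with `source_site`, `target_site`,
#'   `target_lineage`, `cv_score`, `ar2`, `quality`, `retained`; or
#'   `NULL` when no sources pass the prefilter.
#' @export
fit_gblm <- function(composite, source_site, target_site, target_lineage,
                     alpha = 0.05, grid = c(50, 100, 150), k = 10,
                     nu = 0.1, seed = 1) {
  sources <- prefilter_sources(composite, source_site, target_site,
                               target_lineage, alpha = alpha)
  if (!length(sources)) return(NULL)
  target_feature <- paste0(target_lineage, "@", target_site)
  d <- gblm_design(composite, sources, target_feature)
  if (length(d$y) < max(k, 10) || stats::sd(d$y) == 0) return(NULL)
  sel <- cv_select(d$X, d$y, grid = grid, k = k, seed = seed, nu = nu)
  mod <- boost_linear(d$X, d$y, sel$n_iter, nu = nu)
  n_par <- length(mod$coefficients)
  ar2 <- adjusted_r2(mod$nominal_score, length(d$y), n_par)
  mod$source_site <- source_site
  mod$target_site <- target_site
  mod$target_lineage <- target_lineage
  mod$sources <- sources
  mod$cv_score <- sel$cv_score
  mod$ar2 <- ar2
  mod$quality <- model_quality(sel$cv_score, mod$nominal_score)
  mod$retained <- is.finite(ar2) && ar2 > 0
  mod$seed <- seed
  mod$nu <- nu
  mod
}

#' Resampling significance for a retained GBLM
#'
#' Refits the model on bootstrap resamples of the samples (the AR^2 of
#' these refits forms a confidence distribution; the model is discarded
#' if its observed AR^2 falls outside the central 90% interval) and on
#' permutations of the target values with sample-wise renormalization of
#' the target site's terminal block (the compositional null). The p-value
#' is the pooled z-test of the bootstrap distribution against the null.
#'
#' @param composite A composite tibble.
#' @param model A retained `gblm` from [fit_gblm()].
#' @param n_boot,n_perm Number of refits per distribution (default 20).
#' @param seed Integer seed.
#' @return A list: `p` (NA when the model is discarded), `discarded`,
#'   `reason`, `boot_ar2`, `null_ar2`.
#' @export
gblm_significance <- function(composite, model, n_boot = 20, n_perm = 20,
                              seed = 1) {
  stopifnot(inherits(model, "gblm"))
  target_feature <- paste0(model$target_lineage, "@", model$target_site)
  d <- gblm_design(composite, model$sources, target_feature)
  refit_ar2 <- function(X, y) {
    mod <- boost_linear(X, y, model$n_boost, nu = model$nu)
    adjusted_r2(mod$nominal_score, length(y), length(mod$coefficients))
  }
  set.seed(derive_seed(seed, paste0(target_feature, "#gblm-boot")))
  boot_ar2 <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(length(d$y), replace = TRUE)
    refit_ar2(d$X[idx, , drop = FALSE], d$y[idx])
  }, numeric(1))
  boot_ar2 <- boot_ar2[is.finite(boot_ar2)]
  if (length(boot_ar2) < 2) {
    return(list(p = NA_real_, discarded = TRUE,
                reason = "degenerate_bootstrap", boot_ar2 = boot_ar2,
                null_ar2 = numeric(0)))
  }
  ci <- stats::quantile(boot_ar2, c(0.05, 0.95), names = FALSE)
  if (model$ar2 < ci[1] || model$ar2 > ci[2]) {
    return(list(p = NA_real_, discarded = TRUE, reason = "unstable_ar2",
                boot_ar2 = boot_ar2, null_ar2 = numeric(0)))
  }
  # compositional null: permute the target across samples, renormalize the
  # target site's terminal block column-wise, and renormalize same-site
  # sources by the updated column sums
  meta <- composite_meta(composite)
  m <- composite_matrix(composite)
  block <- which(meta$body_site == model$target_site)
  term <- block[is_terminal_row(meta$lineage[block])]
  L <- m[term, d$cols, drop = FALSE]
  L[is.na(L)] <- 0
  s0 <- colSums(L)
  same_site <- meta$body_site[match(model$sources, meta$feature)] ==
    model$target_site
  set.seed(derive_seed(seed, paste0(target_feature, "#gblm-perm")))
  null_ar2 <- vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(length(d$y))
    y_new <- d$y[perm]
    s_new <- s0 - d$y + y_new
    Xp <- d$X
    if (any(same_site)) {
      Xp[, same_site] <- sweep(Xp[, same_site, drop = FALSE], 1, s_new, "/")
    }
    refit_ar2(Xp, y_new / s_new)
  }, numeric(1))
  null_ar2 <- null_ar2[is.finite(null_ar2)]
  if (length(null_ar2) < 2 || (stats::sd(boot_ar2) == 0 &&
                               stats::sd(null_ar2) == 0)) {
    return(list(p = NA_real_, discarded = TRUE,
                reason = "degenerate_null", boot_ar2 = boot_ar2,
                null_ar2 = null_ar2))
  }
  list(p = pooled_z_pvalue(boot_ar2, null_ar2), discarded = FALSE,
       reason = NA_character_, boot_ar2 = boot_ar2, null_ar2 = null_ar2)
}

#' Fit the GBLM compendium and emit pairwise edge evidence
#'
#' Fits one model per (source site, target site, target clade)
#' combination, keeps models with positive adjusted R^2 that survive the
#' resampling checks, and attributes each model's p-value to its
#' (target, selected source) clade pairs with the coefficient sign as
#' direction — the pairwise evidence the network merge consumes.
#'
#' @param composite A composite tibble.
#' @param dataset Dataset label stamped on the evidence rows.
#' @param targets Optional subset of target feature ids.
#' @param alpha,grid,k,nu Model-fitting parameters (see [fit_gblm()]).
#' @param n_boot,n_perm Resampling counts for [gblm_significance()].
#' @param seed Master seed.
#' @return A list: `models` (list of retained `gblm` objects with `p`)
#'   and `evidence` (tibble in the edge-evidence layout; `p_oriented`
#'   encodes the model p with the coefficient sign:
#'   `p/2` for positive, `1 - p/2` for negative coefficients).
#' @export
gblm_compendium <- function(composite, dataset = "all", targets = NULL,
                            alpha = 0.05, grid = c(50, 100, 150), k = 10,
                            nu = 0.1, n_boot = 20, n_perm = 20, seed = 1) {
  meta <- composite_meta(composite)
  sites <- unique(meta$body_site)
  if (is.null(targets)) targets <- meta$feature
  models <- list()
  rows <- list()
  for (tf in targets) {
    ti <- match(tf, meta$feature)
    for (ss in sites) {
      mod <- fit_gblm(composite, ss, meta$body_site[ti], meta$lineage[ti],
                      alpha = alpha, grid = grid, k = k, nu = nu,
                      seed = derive_seed(seed, paste0(tf, "@", ss)))
      if (is.null(mod) || !mod$retained || !length(mod$coefficients)) next
      sig <- gblm_significance(composite, mod, n_boot = n_boot,
                               n_perm = n_perm, seed = seed)
      if (sig$discarded || is.na(sig$p)) next
      mod$p <- sig$p
      models[[length(models) + 1]] <- mod
      for (st in names(mod$coefficients)) {
        pair <- sort(c(tf, st))
        dir <- ifelse(mod$coefficients[[st]] > 0, 1L, -1L)
        rows[[length(rows) + 1]] <- tibble::tibble(
          feature_a = pair[1], feature_b = pair[2], measure = "gblm",
          dataset = dataset, score = unname(mod$coefficients[[st]]),
          p_oriented = if (dir > 0) sig$p / 2 else 1 - sig$p / 2,
          direction = dir, stable = TRUE, flagged = FALSE,
          reason = NA_character_
        )
      }
    }
  }
  evidence <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(
      feature_a = character(0), feature_b = character(0),
      measure = character(0), dataset = character(0), score = numeric(0),
      p_oriented = numeric(0), direction = integer(0), stable = logical(0),
      flagged = logical(0), reason = character(0)
    )
  # a clade pair may be touched by several models; keep the strongest
  if (nrow(evidence) > 1) {
    evidence <- evidence |>
      dplyr::group_by(.data$feature_a, .data$feature_b) |>
      dplyr::arrange(pmin(.data$p_oriented, 1 - .data$p_oriented),
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  list(models = models, evidence = evidence)
}

#' @importFrom generics tidy
#' @export
tidy.gblm <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @importFrom generics glance
#' @export
glance.gblm <- function(x, ...) {
  tibble::tibble(
    n_boost = x$n_boost,
    n_selected = length(x$coefficients),
    nominal_score = x$nominal_score,
    cv_score = x$cv_score %||% NA_real_,
    ar2 = x$ar2 %||% NA_real_,
    quality = x$quality %||% NA_real_,
    p = x$p %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gblm <- function(x, ...) {
  kind <- if (x$binary) "boosted logistic" else "boosted linear"
  cat(sprintf("<gblm> %s model: %d rounds, %d selected predictors\n",
              kind, x$n_boost, length(x$coefficients)))
  invisible(x)
}
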