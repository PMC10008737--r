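# Copy-number signature pipeline: six per-sample CN feature distributions,
# mixture-model categorization, non-negative signature decomposition and a
# logistic model mapping signature exposures to a chromothripsis
# probability score (CPS).

.cn_feature_names <- c("segsize", "cn", "cn_change", "bp_per_arm",
                       "osc_chain", "bp_per_10mb")

#' Extract the six copy-number features from a profile
#'
#' Features: segment sizes (bp); absolute segment copy numbers; absolute CN
#' differences between adjacent segments (one per breakpoint); breakpoint
#' counts per chromosome arm; lengths of oscillating CN segment chains
#' (maximal two-state alternating runs of at least 3 segments); breakpoint
#' counts per 10 Mb bin (bins tiled from position 1, partial terminal bins
#' kept, counts not length-normalized).  Arms and bins without breakpoints
#' contribute no values, so feature event totals scale with genome
#' instability rather than genome size.
#'
#' @param p a filtered [cn_profile].
#' @return named list of six non-negative numeric vectors
#'   (class `cn_features`).
#' @export
extract_cn_features <- function(p) {
  seg <- p$segments
  bp <- breakpoints(p)
  segsize <- if (nrow(seg)) seg$end - seg$start + 1 else numeric(0)
  cn <- seg$cn
  cn_change <- if (nrow(bp)) abs(bp$right_cn - bp$left_cn) else numeric(0)
  bp_per_arm <- numeric(0)
  if (nrow(bp)) {
    gi <- match(bp$chrom, p$genome$chrom)
    arm <- ifelse(!is.na(gi) & bp$position > p$genome$arm_boundary[gi],
                  "q", "p")
    bp_per_arm <- as.numeric(table(paste(bp$chrom, arm)))
  }
  osc_chain <- numeric(0)
  for (s in split(seg, seg$chrom)) {
    if (nrow(s) < 3) next
    runs <- oscillating_runs(s$cn[order(s$start)])
    osc_chain <- c(osc_chain, runs[runs >= 3])
  }
  bp_per_10mb <- if (nrow(bp)) {
    as.numeric(table(paste(bp$chrom, ceiling(bp$position / 1e7))))
  } else numeric(0)
  structure(
    list(segsize = segsize, cn = as.numeric(cn), cn_change = cn_change,
         bp_per_arm = bp_per_arm, osc_chain = osc_chain,
         bp_per_10mb = bp_per_10mb),
    class = "cn_features"
  )
}

# Fit a univariate Gaussian mixture to pooled feature values.  Returns
# component parameters ordered by mean; a feature with < 2 distinct values
# collapses to a single forced category.
fit_feature_mixture <- function(values, max_components, seed, log_scale) {
  x <- if (log_scale) log10(values) else values
  if (length(unique(x)) < 2) {
    return(list(G = 1L, mean = mean(x), sd = 0, pro = 1,
                log_scale = log_scale, forced = TRUE))
  }
  init <- NULL
  if (length(x) > 2000) {
    init <- list(subset = withr::with_seed(seed,
                                           sample.int(length(x), 2000)))
  }
  fit <- tryCatch(
    suppressWarnings(Mclust(
      x, G = 2:max_components, modelNames = c("E", "V"),
      initialization = init, verbose = FALSE
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(G = 1L, mean = mean(x), sd = stats::sd(x), pro = 1,
                log_scale = log_scale, forced = TRUE))
  }
  mu <- fit$parameters$mean
  sigmasq <- fit$parameters$variance$sigmasq
  if (length(sigmasq) == 1) sigmasq <- rep(sigmasq, fit$G)
  o <- order(mu)
  list(G = fit$G, mean = as.numeric(mu[o]),
       sd = sqrt(as.numeric(sigmasq[o])), pro = as.numeric(fit$parameters$pro[o]),
       log_scale = log_scale, forced = FALSE)
}

# Maximum-posterior component assignment under stored mixture parameters.
assign_mixture <- function(values, mix) {
  if (!length(values)) return(integer(0))
  x <- if (mix$log_scale) log10(values) else values
  if (mix$G == 1L) return(rep(1L, length(x)))
  sd <- pmax(mix$sd, 1e-6)
  ll <- vapply(seq_len(mix$G), function(k) {
    log(mix$pro[k]) + stats::dnorm(x, mix$mean[k], sd[k], log = TRUE)
  }, numeric(length(x)))
  if (length(x) == 1) ll <- matrix(ll, nrow = 1)
  max.col(ll, ties.method = "first")
}

#' Categorize cohort CN features into a count matrix
#'
#' Pools each of the six features across the cohort, fits univariate
#' Gaussian mixtures (equal- and free-variance families, components
#' `2:max_components`, BIC selection; segment size on log10 scale), assigns
#' every event to its maximum-posterior component, and tallies counts per
#' sample.  Features with fewer than two distinct values collapse to a
#' single forced category with a warning.
#'
#' @param features named list of `cn_features` (one per sample).
#' @param max_components maximum mixture components per feature.
#' @param seed seed (used for subsampled mixture initialization).
#' @return object of class `cn_category_model`: `matrix` (samples x
#'   categories), `mixtures`, `registry` (category column names).
#' @export
categorize_features <- function(features, max_components = 6, seed = 1) {
  stopifnot(length(features) >= 1)
  if (length(features) < 20)
    warning("fewer than 20 samples; mixture categories may be unstable")
  mixtures <- list()
  for (f in .cn_feature_names) {
    pooled <- unlist(lapply(features, `[[`, f), use.names = FALSE)
    if (length(unique(pooled)) < 2)
      warning("feature ", f, " is (near-)constant; using a single category")
    mixtures[[f]] <- fit_feature_mixture(
      pooled, max_components,
      seed = substream_seed(seed, match(f, .cn_feature_names)),
      log_scale = (f == "segsize")
    )
  }
  registry <- unlist(lapply(.cn_feature_names, function(f) {
    paste0(f, "_", seq_len(mixtures[[f]]$G))
  }))
  M <- t(vapply(features, function(fv) {
    categorize_sample(fv, mixtures, registry)
  }, numeric(length(registry))))
  rownames(M) <- names(features)
  structure(list(matrix = M, mixtures = mixtures, registry = registry),
            class = "cn_category_model")
}

# Counts vector for one sample under frozen mixture parameters.
categorize_sample <- function(fv, mixtures, registry) {
  counts <- stats::setNames(numeric(length(registry)), registry)
  for (f in .cn_feature_names) {
    v <- fv[[f]]
    v <- v[v > 0 | f %in% c("cn", "cn_change")]  # guard log10(0) for sizes
    comp <- assign_mixture(v, mixtures[[f]])
    if (length(comp)) {
      tab <- table(paste0(f, "_", comp))
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  counts
}

#' Apply a fitted category model to new profiles
#'
#' @param model a `cn_category_model`.
#' @param features a `cn_features` object or list of them.
#' @return counts matrix with columns matching the training registry.
#' @export
predict_categories <- function(model, features) {
  if (inherits(features, "cn_features")) features <- list(features)
  M <- t(vapply(features, function(fv) {
    categorize_sample(fv, model$mixtures, model$registry)
  }, numeric(length(model$registry))))
  rownames(M) <- names(features)
  M
}

# KL-divergence objective of a non-negative factorization.
kl_objective <- function(M, W, H, eps = 1e-12) {
  WH <- W %*% H + eps
  sum(ifelse(M > 0, M * log(M / WH), 0) - M + WH)
}

kl_nmf_once <- function(M, K, max_iter, tol, eps = 1e-12) {
  n <- nrow(M); C <- ncol(M)
  W <- matrix(stats::runif(n * K, 0.1, 1), n, K)
  H <- matrix(stats::runif(K * C, 0.1, 1), K, C)
  obj <- kl_objective(M, W, H)
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (M / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * ((M / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = n)
    if (it %% 10 == 0) {
      new_obj <- kl_objective(M, W, H)
      if (abs(obj - new_obj) < tol * (abs(obj) + 1)) {
        obj <- new_obj
        break
      }
      obj <- new_obj
    }
  }
  list(W = W, H = H, objective = kl_objective(M, W, H))
}

#' Extract copy-number signatures by restarted KL-NMF
#'
#' Non-negative decomposition `M ~ E %*% t(S)` of the samples-x-categories
#' count matrix, by multiplicative-update NMF under generalized
#' Kullback-Leibler divergence, restarted `n_restarts` times from seeded
#' random initializations with the best objective kept.  Signature columns
#' are simplex-normalized (sum to 1) with the scale absorbed into the
#' exposures.  With `K = "auto"`, K is chosen over `2:max_k` at the elbow
#' of the reconstruction-error curve (greatest second difference).
#'
#' @param M samples x categories count matrix.
#' @param K number of signatures, or `"auto"`.
#' @param seed seed.
#' @param n_restarts random restarts.
#' @param max_iter maximum multiplicative updates per restart.
#' @param tol relative objective-change convergence tolerance.
#' @param max_k largest K tried when `K = "auto"`.
#' @return object of class `cn_signature_fit`: `signatures` (categories x
#'   K, columns sum to 1), `exposures` (samples x K), `objective`, `K`.
#' @export
extract_signatures <- function(M, K = 3, seed = 1, n_restarts = 10,
                               max_iter = 2000, tol = 1e-9,
                               max_k = min(8, ncol(M) - 1)) {
  M <- as.matrix(M)
  if (identical(K, "auto")) {
    ks <- 2:max_k
    errs <- vapply(ks, function(k) {
      extract_signatures(M, k, seed = seed, n_restarts = max(2, n_restarts %/% 3),
                         max_iter = max_iter, tol = tol)$objective
    }, numeric(1))
    K <- if (length(ks) <= 2) ks[which.min(errs)] else {
      d2 <- diff(diff(errs))
      ks[which.max(d2) + 1L]
    }
  }
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (K > ncol(M)) stop("K exceeds the number of categories")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- withr::with_seed(substream_seed(seed, 7000 + r),
                            kl_nmf_once(M, K, max_iter, tol))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  S <- t(best$H)
  scale <- colSums(S)
  S <- sweep(S, 2, scale, "/")
  E <- sweep(best$W, 2, scale, "*")
  colnames(S) <- colnames(E) <- paste0("CNS", seq_len(K))
  rownames(S) <- colnames(M)
  rownames(E) <- rownames(M)
  structure(list(signatures = S, exposures = E, objective = best$objective,
                 K = K, seed = seed),
            class = "cn_signature_fit")
}

# Non-negative least-squares exposures of count vectors against frozen
# signature columns.
nnls_exposures <- function(signatures, counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  E <- t(apply(counts, 1, function(m) {
    pracma::lsqnonneg(signatures, as.numeric(m))$x
  }))
  colnames(E) <- colnames(signatures)
  E
}

#' Fit the chromothripsis-score GLM with cross-validated AUC
#'
#' Logistic regression (binomial, logit link) of chromothripsis labels on
#' signature exposures, with stratified k-fold cross-validation: held-out
#' probabilities are pooled and their rank AUC reported, then the model is
#' refit on all samples.  If the unpenalized fit separates perfectly, an
#' L2-penalized (ridge) fit is substituted and the penalty recorded.
#'
#' @param exposures samples x K exposure matrix.
#' @param labels logical vector (TRUE = chromothripsis).
#' @param folds number of CV folds.
#' @param seed seed controlling fold assignment.
#' @param ridge_lambda penalty used on separation fallback.
#' @return object of class `cps_glm`: `coefficients` (intercept first),
#'   `cv_auc`, `fold_assignments`, `penalized`, `seed`.
#' @export
fit_cps_model <- function(exposures, labels, folds = 10, seed = 1,
                          ridge_lambda = 1e-2) {
  exposures <- as.matrix(exposures)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to fit the CPS model")
  stopifnot(folds >= 2, nrow(exposures) == length(labels))
  # canonical sample order (by name when available) so fold assignment --
  # and hence the CV AUC -- is invariant to the order samples arrive in
  canon <- if (!is.null(rownames(exposures)) &&
                 !anyDuplicated(rownames(exposures))) {
    order(rownames(exposures))
  } else seq_along(labels)
  fold_of <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- canon[labels[canon] == cls]
    pos <- withr::with_seed(substream_seed(seed, 9000 + cls),
                            sample(seq_along(idx)))
    fold_of[idx[pos]] <- rep_len(seq_len(folds), length(idx))
  }
  fit_one <- function(X, y) {
    d <- data.frame(y = y, X)
    w <- character(0)
    g <- withCallingHandlers(
      stats::glm(y ~ ., data = d, family = stats::binomial()),
      warning = function(cond) {
        w <<- c(w, conditionMessage(cond))
        invokeRestart("muffleWarning")
      }
    )
    separated <- any(grepl("numerically 0 or 1|did not converge", w)) ||
      g$deviance < 1e-4 ||  # complete separation converges to zero deviance
      any(abs(stats::coef(g)[-1]) > 20, na.rm = TRUE)
    if (separated) {
      Xr <- if (ncol(X) == 1) cbind(X, 0) else X  # glmnet needs >= 2 columns
      rg <- glmnet::glmnet(Xr, as.numeric(y), family = "binomial",
                           alpha = 0, lambda = ridge_lambda)
      cf <- as.numeric(c(rg$a0, as.matrix(rg$beta)))[seq_len(ncol(X) + 1)]
      list(coef = cf, penalized = TRUE)
    } else {
      cf <- stats::coef(g)
      cf[is.na(cf)] <- 0
      list(coef = as.numeric(cf), penalized = FALSE)
    }
  }
  pred <- numeric(length(labels))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    m <- fit_one(exposures[tr, , drop = FALSE], labels[tr])
    pred[!tr] <- stats::plogis(
      m$coef[1] + exposures[!tr, , drop = FALSE] %*% m$coef[-1]
    )
  }
  cv_auc <- rank_auc(pred, labels)
  final <- fit_one(exposures, labels)
  structure(list(coefficients = final$coef, cv_auc = cv_auc,
                 fold_assignments = fold_of, penalized = final$penalized,
                 ridge_lambda = if (final$penalized) ridge_lambda else NULL,
                 seed = seed),
            class = "cps_glm")
}

#' Train the full chromothripsis-score model on a cohort
#'
#' Chains feature extraction, mixture categorization, signature extraction
#' and the logistic score model.  Training exposures fed to the GLM are
#' recomputed by non-negative least squares against the final frozen
#' signatures, so scoring a training profile with [score_cps()] reproduces
#' its in-sample fitted probability.
#'
#' @param profiles named list of filtered [cn_profile] objects.
#' @param labels logical chromothripsis labels (same order).
#' @param K signatures to extract (or `"auto"`).
#' @param max_components mixture components bound per feature.
#' @param folds CV folds for the reported AUC.
#' @param seed seed.
#' @return object of class `cps_model` bundling the category model,
#'   signatures, GLM and `cv_auc`.
#' @export
train_cps <- function(profiles, labels, K = 3, max_components = 6,
                      folds = 10, seed = 1) {
  features <- lapply(profiles, extract_cn_features)
  cat_model <- categorize_features(features, max_components = max_components,
                                   seed = seed)
  sig_fit <- extract_signatures(cat_model$matrix, K = K, seed = seed)
  E <- nnls_exposures(sig_fit$signatures, cat_model$matrix)
  glm_fit <- fit_cps_model(E, labels, folds = folds, seed = seed)
  structure(list(category_model = cat_model,
                 signatures = sig_fit$signatures,
                 glm = glm_fit, cv_auc = glm_fit$cv_auc, seed = seed),
            class = "cps_model")
}

#' Score a profile with a trained CPS model
#'
#' Features are categorized with the frozen training mixtures (no refit),
#' exposures computed by non-negative least squares against the frozen
#' signatures, and the GLM applied; the result is a probability in [0, 1].
#'
#' @param model a `cps_model` from [train_cps()].
#' @param p a filtered [cn_profile], or a list of them.
#' @return named numeric vector of scores in \[0, 1\].
#' @export
score_cps <- function(model, p) {
  if (inherits(p, "cn_profile")) p <- stats::setNames(list(p), p$sample_id)
  features <- lapply(p, extract_cn_features)
  M <- predict_categories(model$category_model, features)
  if (!identical(colnames(M), rownames(model$signatures)))
    stop("category registry mismatch between model and input")
  E <- nnls_exposures(model$signatures, M)
  cf <- model$glm$coefficients
  scores <- as.numeric(stats::plogis(cf[1] + E %*% cf[-1]))
  stats::setNames(scores, names(p))
}

#' Persist a CPS model as JSON
#'
#' @param model a `cps_model`.
#' @param path output file.
#' @export
save_cps_model <- function(model, path) {
  payload <- list(
    registry = model$category_model$registry,
    mixtures = model$category_model$mixtures,
    signatures = list(values = unname(model$signatures),
                      categories = rownames(model$signatures),
                      names = colnames(model$signatures)),
    glm = model$glm[c("coefficients", "cv_auc", "penalized", "seed")],
    ridge_lambda = model$glm$ridge_lambda,
    seed = model$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a CPS model saved by [save_cps_model()]
#'
#' @param path JSON file.
#' @return a `cps_model` (category count matrix omitted).
#' @export
load_cps_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mixtures <- lapply(j$mixtures, function(m) {
    m$G <- as.integer(m$G)
    m
  })
  S <- as.matrix(j$signatures$values)
  dimnames(S) <- list(j$signatures$categories, j$signatures$names)
  glm_fit <- structure(
    list(coefficients = as.numeric(j$glm$coefficients),
         cv_auc = j$glm$cv_auc, penalized = isTRUE(j$glm$penalized),
         ridge_lambda = j$ridge_lambda, seed = j$glm$seed),
    class = "cps_glm"
  )
  structure(list(
    category_model = structure(
      list(matrix = NULL, mixtures = mixtures, registry = j$registry),
      class = "cn_category_model"
    ),
    signatures = S, glm = glm_fit, cv_auc = j$glm$cv_auc, seed = j$seed
  ), class = "cps_model")
}
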