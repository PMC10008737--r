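test_that("the six CN features are computed as defined", {
  flat <- toy_profile(list("chrA", 1, 100e6, 2))
  fv <- extract_cn_features(flat)
  expect_equal(fv$segsize, 1e8)
  expect_equal(fv$cn, 2)
  expect_length(fv$cn_change, 0)
  expect_length(fv$bp_per_arm, 0)
  expect_length(fv$bp_per_10mb, 0)
  expect_length(fv$osc_chain, 0)

  p <- toy_profile(
    list("chrA", 1, 25e6, 2), list("chrA", 25e6 + 1, 50e6, 3),
    list("chrA", 50e6 + 1, 75e6, 2), list("chrA", 75e6 + 1, 100e6, 3)
  )
  fv2 <- extract_cn_features(p)
  expect_equal(fv2$cn_change, c(1, 1, 1))
  expect_equal(fv2$osc_chain, 4)
  expect_equal(sum(fv2$bp_per_arm), 3)

  # 20 breakpoints planted within one 10 Mb span land in one bin
  k <- 20
  bounds <- seq(30e6 + 1e5, 30e6 + 9e6, length.out = k)
  rows <- c(
    list(list("chrA", 1, bounds[1] - 1, 2)),
    lapply(seq_len(k - 1), function(j)
      list("chrA", bounds[j], bounds[j + 1] - 1, 2 + j %% 2)),
    list(list("chrA", bounds[k], 100e6, 2))
  )
  p3 <- do.call(toy_profile, c(rows, list(genome = toy_genome(c(chrA = 100e6)))))
  fv3 <- extract_cn_features(p3)
  expect_equal(nrow(breakpoints(p3)), k)
  expect_equal(fv3$bp_per_10mb, k)
})

test_that("category counts conserve events and BIC finds planted components", {
  # two well-separated Gaussians in segment size are recovered
  set.seed(23)
  n_rec <- 0
  for (rep in 1:10) {
    features <- lapply(1:20, function(s) {
      list(segsize = c(10^rnorm(30, 5, 0.15), 10^rnorm(30, 7.2, 0.15)),
           cn = rep(2, 2), cn_change = numeric(0),
           bp_per_arm = numeric(0), osc_chain = numeric(0),
           bp_per_10mb = numeric(0))
    })
    names(features) <- sprintf("S%02d", 1:20)
    cm <- suppressWarnings(categorize_features(features, seed = rep))
    if (cm$mixtures$segsize$G == 2) n_rec <- n_rec + 1
    # row sums conserve events per sample
    expect_equal(unname(rowSums(cm$matrix)), rep(62, 20))
  }
  expect_gte(n_rec, 9)
})

test_that("constant features collapse to a single forced category", {
  fv <- list(segsize = c(1e6, 2e6, 4e6), cn = c(2, 2, 2), cn_change = 1,
             bp_per_arm = 1, osc_chain = numeric(0), bp_per_10mb = 1)
  features <- rep(list(fv), 25)
  names(features) <- sprintf("S%02d", 1:25)
  warns <- capture_warnings(cm <- categorize_features(features, seed = 1))
  expect_true(any(grepl("single category", warns)))
  expect_equal(cm$mixtures$cn$G, 1L)
  expect_equal(unname(cm$matrix[, "cn_1"]), rep(3, 25))
})

test_that("rank-1 KL-NMF equals the outer product of marginals", {
  set.seed(31)
  M <- matrix(rpois(200, 8), 20, 10)
  fit <- extract_signatures(M, K = 1, seed = 2, n_restarts = 3)
  # closed form: signature = column marginal / total
  expect_equal(unname(fit$signatures[, 1]), colSums(M) / sum(M),
               tolerance = 1e-6)
  expect_equal(unname(fit$exposures[, 1]), rowSums(M), tolerance = 1e-6)
})

test_that("planted signatures are recovered with high cosine similarity", {
  n <- 150; C <- 24; K <- 3
  make_cohort <- function(seed) {
    withr::with_seed(seed, {
      S <- matrix(rgamma(C * K, 0.3), C, K)
      S <- sweep(S, 2, colSums(S), "/")
      E <- matrix(rgamma(n * K, 1.5, rate = 1 / 60), n, K)
      M <- matrix(rpois(n * C, E %*% t(S)), n, C)
      list(S = S, M = M)
    })
  }
  for (seed in 1:2) {
    truth <- make_cohort(seed)
    fit <- extract_signatures(truth$M, K = K, seed = seed, n_restarts = 6)
    m <- match_signatures(truth$S, fit$signatures)
    expect_gt(min(m$cosines), 0.9)
  }
})

test_that("exposures are non-negative and K is bounded by the category count", {
  set.seed(37)
  M <- matrix(rpois(300, 5), 30, 10)
  fit <- extract_signatures(M, K = 3, seed = 1, n_restarts = 3)
  expect_true(all(fit$exposures >= 0))
  expect_true(all(fit$signatures >= 0))
  expect_equal(unname(colSums(fit$signatures)), rep(1, 3))
  expect_error(extract_signatures(M, K = 11), "exceeds")
})

test_that("CPS GLM: null labels give chance AUC, seeds fix folds, classes required", {
  set.seed(41)
  E <- matrix(rgamma(400 * 3, 2), 400, 3)
  labels <- rep(c(TRUE, FALSE), 200)
  fit <- fit_cps_model(E, labels, folds = 10, seed = 5)
  expect_gt(fit$cv_auc, 0.4)
  expect_lt(fit$cv_auc, 0.6)

  fit2 <- fit_cps_model(E, labels, folds = 10, seed = 5)
  expect_identical(fit$fold_assignments, fit2$fold_assignments)
  expect_identical(fit$cv_auc, fit2$cv_auc)

  expect_error(fit_cps_model(E, rep(TRUE, 400)), "both classes")
})

test_that("perfect separation falls back to a recorded ridge fit", {
  E <- matrix(c(rep(0, 50), rep(10, 50)), ncol = 1)
  labels <- rep(c(FALSE, TRUE), each = 50)
  fit <- fit_cps_model(E, labels, folds = 5, seed = 1)
  expect_true(fit$penalized)
  expect_false(is.null(fit$ridge_lambda))
  expect_gt(fit$cv_auc, 0.95)
})

test_that("scoring training samples reproduces in-sample fitted probabilities", {
  cfg <- sim_config(n_samples = 60, seed = 71)
  co <- simulate_cohort_profiles(cfg)
  filt <- lapply(co$profiles, filter_profile)
  model <- suppressWarnings(train_cps(filt, co$labels, K = 2, folds = 5,
                                      seed = 71))
  scores <- score_cps(model, filt)
  expect_true(all(scores >= 0 & scores <= 1))
  # in-sample fitted probabilities from the stored GLM over NNLS exposures
  cf <- model$glm$coefficients
  M <- predict_categories(model$category_model,
                          lapply(filt, extract_cn_features))
  E <- t(apply(M, 1, function(m)
    pracma::lsqnonneg(model$signatures, as.numeric(m))$x))
  expect_equal(unname(scores),
               unname(as.numeric(plogis(cf[1] + E %*% cf[-1]))),
               tolerance = 1e-12)
  # planted samples score above background-only ones
  expect_gt(median(scores[co$labels]), median(scores[!co$labels]))

  # persistence round-trip preserves scores exactly enough for reuse
  path <- withr::local_tempfile(fileext = ".json")
  save_cps_model(model, path)
  reloaded <- load_cps_model(path)
  expect_equal(score_cps(reloaded, filt), scores, tolerance = 1e-10)
})

test_that("CPS is invariant to sample order and deterministic in the seed", {
  cfg <- sim_config(n_samples = 60, seed = 81)
  co <- simulate_cohort_profiles(cfg)
  filt <- lapply(co$profiles, filter_profile)
  m1 <- suppressWarnings(train_cps(filt, co$labels, K = 2, folds = 5, seed = 9))
  m2 <- suppressWarnings(train_cps(filt, co$labels, K = 2, folds = 5, seed = 9))
  expect_identical(m1$cv_auc, m2$cv_auc)
  expect_identical(m1$glm$coefficients, m2$glm$coefficients)

  # fold assignment is keyed on sample names, so the CV AUC does not
  # depend on the order samples arrive in
  perm <- withr::with_seed(1, sample(seq_along(filt)))
  E <- t(apply(m1$category_model$matrix, 1, function(m)
    pracma::lsqnonneg(m1$signatures, as.numeric(m))$x))
  rownames(E) <- rownames(m1$category_model$matrix)
  f_a <- fit_cps_model(E, co$labels, folds = 5, seed = 9)
  f_b <- fit_cps_model(E[perm, ], co$labels[perm], folds = 5, seed = 9)
  expect_equal(f_a$cv_auc, f_b$cv_auc)
})
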