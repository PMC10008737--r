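rand_expr <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, 5, 1.5), n_genes, n_samples)
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("s%02d", seq_len(n_samples)))
    m
  })
}

test_that("ssGSEA matches the independent running-sum oracle", {
  for (trial in 1:30) {
    expr <- rand_expr(50, 3, seed = 100 + trial)
    set <- withr::with_seed(trial, sample(rownames(expr), 8))
    sc <- ssgsea(expr, list(S = set))
    expect_equal(unname(sc["S", ]), ssgsea_oracle(expr, set),
                 tolerance = 1e-9)
  }
})

test_that("ssGSEA extremes behave: whole-matrix set and top-rank placement", {
  expr <- rand_expr(20, 2, seed = 7)
  # set = all genes: out-set ECDF is empty; score equals the oracle's limit
  sc_all <- ssgsea(expr, list(ALL = rownames(expr)))
  expect_equal(unname(sc_all["ALL", ]),
               ssgsea_oracle(expr, rownames(expr)), tolerance = 1e-9)

  # genes occupying the top |S| ranks maximize the score over all
  # placements of a 3-gene set in a 10-gene toy sample
  expr1 <- matrix(seq(10, 1), ncol = 1,
                  dimnames = list(letters[1:10], "s1"))
  combos <- combn(letters[1:10], 3, simplify = FALSE)
  # extremal property is for the raw running-sum integral (normalization
  # rescales by the running range, which depends on the placement)
  scores <- vapply(combos, function(gs)
    unname(ssgsea(expr1, list(S = gs), normalize = FALSE)["S", 1]),
    numeric(1))
  top <- which(vapply(combos, function(gs)
    setequal(gs, letters[1:3]), logical(1)))
  expect_equal(which.max(scores), top)

  # identical samples get identical columns
  expr2 <- cbind(expr[, 1], expr[, 1])
  colnames(expr2) <- c("a", "b")
  rownames(expr2) <- rownames(expr)
  sc2 <- ssgsea(expr2, list(S = rownames(expr)[1:5]))
  expect_equal(sc2[, "a"], sc2[, "b"])

  expect_warning(ssgsea(expr, list(BAD = c("nope1", "nope2"))),
                 "no overlapping genes")
})

test_that("geometric-mean scores: closed cases, homogeneity, positivity guard", {
  expr <- matrix(c(4, 9, 1, 1), nrow = 2,
                 dimnames = list(c("gA", "gB"), c("s1", "s2")))
  sc <- geometric_mean_scores(expr, list(S = c("gA", "gB")), pseudocount = 0)
  expect_equal(unname(sc["S", "s1"]), 6)

  single <- geometric_mean_scores(expr, list(S = "gA"), pseudocount = 0)
  expect_equal(unname(single["S", ]), unname(expr["gA", ]))

  sc4 <- geometric_mean_scores(expr * 4, list(S = c("gA", "gB")),
                               pseudocount = 0)
  expect_equal(unname(sc4["S", ]), 4 * unname(sc["S", ]))

  expr_neg <- expr; expr_neg["gA", "s1"] <- -2
  expect_error(geometric_mean_scores(expr_neg, list(S = c("gA", "gB")),
                                     pseudocount = 0), "gA")
})

test_that("cell ratios follow score rows and detect the planted deficit", {
  scores <- matrix(c(2, 2, 2, 2, 1, 1, 1, 1), nrow = 4, byrow = FALSE,
                   dimnames = list(c("CD8_T", "Treg", "TAM", "MDSC"),
                                   c("s1", "s2")))
  scores[, 2] <- c(4, 2, 2, 2)
  attr(scores, "method") <- "geometric_mean"
  r <- cell_ratios(scores)
  expect_equal(r$cd8_treg, c(1, 2))
  expect_equal(r$log2_cd8_treg, c(0, 1))

  scores2 <- scores; scores2["CD8_T", ] <- scores["CD8_T", ] * 2
  attr(scores2, "method") <- "geometric_mean"
  r2 <- cell_ratios(scores2)
  expect_equal(r2$cd8_treg, 2 * r$cd8_treg)
  expect_equal(r2$cd8_tam, 2 * r$cd8_tam)
  expect_equal(r2$cd8_mdsc, 2 * r$cd8_mdsc)

  # planted deficit in chromothripsis samples is detected by Wilcoxon
  labels <- stats::setNames(rep(c(TRUE, FALSE), each = 200),
                            sprintf("S%03d", 1:400))
  cfg <- sim_config(n_samples = 400, n_genes = 600, signature_effect = 2,
                    seed = 90)
  sim <- simulate_expression(cfg, labels)
  gm <- geometric_mean_scores(sim$expr, sim$sets, expr_scale = "log2")
  rr <- cell_ratios(gm)
  w <- stats::wilcox.test(rr$cd8_treg[labels], rr$cd8_treg[!labels],
                          alternative = "less")
  expect_lt(w$p.value, 1e-6)
})

test_that("cytokine ratio composes from geometric means and hits closed forms", {
  expr <- matrix(5, nrow = 8, ncol = 2,
                 dimnames = list(c("IFNG", "IL1A", "IL1B", "IL2",
                                   "IL4", "IL10", "IL11", "TGFB1"),
                                 c("s1", "s2")))
  expect_equal(unname(cytokine_ratio(expr, pseudocount = 0)), c(0, 0))

  expr2 <- expr
  expr2[c("IFNG", "IL1A", "IL1B", "IL2"), ] <- 20  # 4x anti panel
  expect_equal(unname(cytokine_ratio(expr2, pseudocount = 0)), c(2, 2))

  # compositional: equals the ratio of two geometric_mean_scores calls
  expr3 <- rand_expr(40, 4, seed = 3)
  rownames(expr3)[1:8] <- c("IFNG", "IL1A", "IL1B", "IL2",
                            "IL4", "IL10", "IL11", "TGFB1")
  direct <- cytokine_ratio(expr3, pseudocount = 1)
  gm <- geometric_mean_scores(
    expr3, list(pro = c("IFNG", "IL1A", "IL1B", "IL2"),
                anti = c("IL4", "IL10", "IL11", "TGFB1")), pseudocount = 1)
  expect_equal(unname(direct), unname(log2(gm["pro", ] / gm["anti", ])))

  expect_warning(cytokine_ratio(expr3[-1, ]), "absent")
})

test_that("pathway differential is signed toward non-chromothripsis and antisymmetric", {
  scores <- rand_expr(10, 40, seed = 13)
  rownames(scores) <- sprintf("path%02d", 1:10)
  groups <- rep(c(TRUE, FALSE), 20)

  # identical groups -> t = 0, p = 1
  sym <- scores
  sym[, groups] <- sym[, !groups]
  res0 <- pathway_differential(sym, groups)
  expect_equal(res0$t, rep(0, 10))
  expect_equal(res0$p_value, rep(1, 10))

  # planted +2 SD shift in the non-chromothripsis group of one set
  shifted <- scores
  shifted["path03", !groups] <- shifted["path03", !groups] + 2 * sd(shifted["path03", ])
  res <- pathway_differential(shifted, groups)
  expect_equal(res$set[which.max(abs(res$t))], "path03")
  expect_gt(res$t[res$set == "path03"], 0)

  # swapping group labels flips every t
  res_swap <- pathway_differential(shifted, !groups)
  expect_equal(res_swap$t, -res$t)

  # zero variance in both groups is flagged
  flatrow <- scores
  flatrow["path01", ] <- 1
  resf <- pathway_differential(flatrow, groups)
  expect_true(resf$flagged[resf$set == "path01"])
  expect_error(pathway_differential(scores, rep(TRUE, 40)), "both groups")
})

test_that("total infiltration score is the mean (or sum) over sets", {
  scores <- matrix(1:6, nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(total_infiltration_score(scores)), c(2, 5))
  expect_equal(unname(total_infiltration_score(scores, "sum")), c(6, 15))
})

test_that("GMT round-trip preserves sets", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g4", "g5"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})
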