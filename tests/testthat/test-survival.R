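test_that("median grouping uses a strict threshold with ties going low", {
  expect_equal(median_groups(1:4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(median_groups(c(1, 2, 2, 3)), c(FALSE, FALSE, FALSE, TRUE))
  # odd n with distinct values: (n-1)/2 members in the high group
  for (n in c(5, 9, 15)) {
    v <- withr::with_seed(n, sample(seq_len(n)))
    expect_equal(sum(median_groups(v)), (n - 1) / 2)
  }
  expect_error(median_groups(rep(3, 5)), "all values equal")
})

test_that("KM estimator matches the hand product-limit and empirical survival", {
  # times 1..4, all events, one group
  res <- km_logrank(c(1, 2, 3, 4), rep(1, 4), rep(c("a", "b"), 2))
  # no censoring: KM equals empirical survival within each group
  for (g in c("a", "b")) {
    cc <- res$curves[res$curves$group == g, ]
    expect_equal(cc$surv, c(0.5, 0))
  }

  # hand product-limit for times 1..4, all events: steps 0.75/0.5/0.25/0,
  # median = 2 (earliest time with S <= 0.5)
  one <- survival::survfit(survival::Surv(c(1, 2, 3, 4), rep(1, 4)) ~ 1)
  expect_equal(one$surv, c(0.75, 0.5, 0.25, 0))

  tt <- c(1, 2, 3, 4, 10, 11, 12, 13)
  grp <- rep(c("lo", "hi"), each = 4)
  r <- km_logrank(tt, rep(1, 8), grp)
  expect_equal(unname(r$median_survival["lo"]), 2)
  expect_equal(unname(r$median_survival["hi"]), 11)
})

test_that("identical groups give log-rank chi-square 0 and p 1", {
  time <- rep(c(2, 5, 8, 11), 2)
  event <- rep(c(1, 0, 1, 1), 2)
  group <- rep(c("a", "b"), each = 4)
  r <- km_logrank(time, event, group)
  expect_equal(r$chisq, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
})

test_that("high-CPS groups have shorter survival under the planted hazard", {
  cps <- stats::setNames(runif(600), sprintf("S%03d", 1:600))
  cfg <- sim_config(n_samples = 600, seed = 55)
  cl <- simulate_survival(cps, cfg, seed = 56)
  grp <- median_groups(cps)
  r <- km_logrank(cl$os_time, cl$os_event, grp)
  expect_lt(unname(r$median_survival["TRUE"]),
            unname(r$median_survival["FALSE"]))
  expect_lt(r$p_value, 0.01)
})

test_that("Cox reparameterization: negating a continuous covariate inverts the HR", {
  set.seed(61)
  x <- rnorm(200)
  time <- rexp(200, 0.05 * exp(0.5 * x))
  event <- rep(1, 200)
  a <- cox_univariate(time, event, x, binary = FALSE)
  b <- cox_univariate(time, event, -x, binary = FALSE)
  expect_equal(a$hr, 1 / b$hr, tolerance = 1e-8)
  expect_true(a$ci[1] < a$hr && a$hr < a$ci[2])
  expect_error(cox_univariate(time, rep(0, 200), x), "no events")
})

test_that("Cox recovers a planted binary hazard ratio", {
  hrs <- vapply(1:40, function(i) {
    withr::with_seed(700 + i, {
      grp <- rep(c(0, 1), each = 300)
      t_ev <- rexp(600, 0.03 * exp(log(1.9) * grp))
      cens <- rexp(600, 0.03 * 0.25)
      cox_univariate(pmin(t_ev, cens), as.integer(t_ev <= cens),
                     as.logical(grp))$hr
    })
  }, numeric(1))
  expect_gt(mean(hrs), 1.75)
  expect_lt(mean(hrs), 2.05)
})

test_that("AUC(t) matches pairwise concordance without censoring and is monotone-invariant", {
  set.seed(71)
  n <- 60
  time <- rexp(n, 0.1)
  marker <- rank(-time) + rnorm(n, 0, 3)  # informative marker
  grid <- quantile(time, c(0.25, 0.5, 0.75))
  res <- time_dependent_auc(time, rep(1, n), marker, grid)
  for (j in seq_along(grid)) {
    expect_equal(res$auc[j], cd_auc_oracle(time, marker, grid[j]),
                 tolerance = 1e-12)
  }
  # strictly monotone transform of the marker leaves AUC unchanged
  res2 <- time_dependent_auc(time, rep(1, n), exp(marker / 10), grid)
  expect_equal(res2$auc, res$auc, tolerance = 1e-12)
  expect_true(all(res$auc >= 0 & res$auc <= 1))

  # marker equal to the true event-time order is a perfect marker
  res3 <- time_dependent_auc(time, rep(1, n), rank(-time), grid)
  expect_equal(res3$auc, rep(1, 3))

  # null marker stays near 0.5
  res4 <- time_dependent_auc(time, rep(1, n), rnorm(n), grid)
  expect_true(all(abs(res4$auc - 0.5) < 0.25))

  expect_warning(time_dependent_auc(time, rep(1, n), marker,
                                    c(12, max(time) + 1)), "beyond")
})

test_that("IPCW AUC handles censoring sensibly", {
  set.seed(73)
  n <- 400
  x <- rnorm(n)
  t_ev <- rexp(n, 0.04 * exp(0.8 * x))
  cens <- rexp(n, 0.01)
  time <- pmin(t_ev, cens)
  event <- as.integer(t_ev <= cens)
  res <- time_dependent_auc(time, event, x, c(12, 24))
  expect_true(all(res$auc > 0.6))  # informative marker stays discriminative
})

test_that("responder definitions follow RECIST durations; Fisher is symmetric", {
  response <- c("CR", "PR", "SD", "SD", "PD", "SD")
  sd_dur <- c(NA, NA, 7, 5, NA, NA)
  groups <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_warning(rr <- response_rates(response, sd_dur, groups),
                 "without duration")
  # SD 7 months responds, SD 5 months does not, SD NA excluded
  expect_equal(unname(rr$responder$table["FALSE", "TRUE"]), 1)  # low group
  expect_equal(unname(rr$objective$rates), c(0, 2 / 3),
               tolerance = 1e-12)

  all_cr <- response_rates(rep("CR", 8), rep(NA, 8),
                           rep(c(TRUE, FALSE), 4))
  expect_equal(unname(all_cr$responder$rates), c(1, 1))
  expect_equal(all_cr$responder$p_value, 1)

  # (3,7 / 6,4) against the enumeration oracle, and row/col swap invariance
  resp <- c(rep("CR", 3), rep("PD", 7), rep("CR", 6), rep("PD", 4))
  grp <- rep(c(TRUE, FALSE), c(10, 10))
  rr2 <- response_rates(resp, rep(NA, 20), grp)
  expect_equal(rr2$objective$p_value, fisher_oracle(3, 7, 6, 4),
               tolerance = 1e-10)
  rr2_swap <- response_rates(resp, rep(NA, 20), !grp)
  expect_equal(rr2_swap$objective$p_value, rr2$objective$p_value)
})
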