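test_that("pearson matches the closed-form estimator and flags degenerate input", {
  expect_equal(pearson(1:10, 1:10)$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1))$r, -1)

  set.seed(20)
  x <- rnorm(10); y <- rnorm(10)
  res <- pearson(x, y)
  oracle_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, oracle_r, tolerance = 1e-12)
  tstat <- oracle_r * sqrt(8 / (1 - oracle_r^2))
  expect_equal(res$p, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)

  const <- pearson(rep(1, 10), y)
  expect_false(const$defined)
  expect_true(is.na(const$r))
  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(1:2, 2:3), "at least 3")

  # symmetry and affine invariance (up to sign of the scale)
  expect_equal(pearson(x, y)$r, pearson(y, x)$r)
  expect_equal(pearson(3 * x + 7, y)$r, res$r)
  expect_equal(pearson(-2 * x, y)$r, -res$r)
})

test_that("ERD and coherence reports have the prescribed shapes", {
  set.seed(21)
  n <- 40
  ci_tab <- data.frame(trial_id = 1:n, ci = runif(n, 0.005, 0.3))
  erd_tab <- data.frame(trial_id = 1:n,
                        matrix(rnorm(n * 18), n,
                               dimnames = list(NULL, paste0("f", 1:18))),
                        check.names = FALSE)
  rep_erd <- correlate_erd(erd_tab, ci_tab)
  expect_equal(nrow(rep_erd), 18L)
  expect_true(all(abs(rep_erd$r) <= 1))
  expect_equal(rep_erd$p_bonferroni, pmin(rep_erd$p * 18, 1))

  erd_tab$f3 <- 1  # constant feature -> undefined, flagged not dropped
  rep2 <- correlate_erd(erd_tab, ci_tab)
  expect_false(rep2$defined[rep2$feature == "f3"])
  expect_equal(nrow(rep2), 18L)

  coh_tab <- data.frame(trial_id = 1:n,
                        matrix(runif(n * 6), n,
                               dimnames = list(NULL, paste0("g", 1:6))),
                        check.names = FALSE)
  rep_coh <- correlate_coherence(coh_tab, ci_tab)
  expect_equal(nrow(rep_coh), 6L)

  coh_tab[paste0("g", 1:6)] <- 1  # all-identical channels: coherence 1
  rep3 <- correlate_coherence(coh_tab, ci_tab)
  expect_true(all(!rep3$defined))
})

test_that("ann evaluation equals pearson on the same vectors and demands coverage", {
  set.seed(22)
  n <- 30
  ci_tab <- data.frame(trial_id = 1:n, ci = runif(n, 0.01, 0.3))
  pred <- data.frame(trial_id = 1:n, predicted_ci = ci_tab$ci,
                     n_test_appearances = 7L)
  rep1 <- evaluate_ann(pred, ci_tab)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$r, 1)

  pred$predicted_ci <- rnorm(n)
  rep2 <- evaluate_ann(pred, ci_tab)
  expect_equal(rep2$r, pearson(pred$predicted_ci, ci_tab$ci)$r)

  expect_error(evaluate_ann(pred[-1, ], ci_tab), "every trial")
})

test_that("approach comparison flags when the network beats the best univariate r", {
  mk <- function(approach, rs, ps = rep(0.5, length(rs))) {
    data.frame(approach = approach, feature = seq_along(rs), r = rs, p = ps,
               n = 240, defined = TRUE,
               p_bonferroni = pmin(ps * length(rs), 1), significant = ps < 0.01)
  }
  reports <- list(mk("erd", c(0.1, -0.05)), mk("coherence", c(0.08)),
                  mk("ann", 0.7, 0.001))
  cmp <- compare_approaches(reports)
  expect_equal(cmp$ann_beats_this[cmp$approach == "erd"], TRUE)
  expect_equal(cmp$ann_beats_this[cmp$approach == "coherence"], TRUE)
  expect_true(is.na(cmp$ann_beats_this[cmp$approach == "ann"]))
  expect_equal(cmp$n_significant, c(0L, 0L, 1L))

  same <- list(mk("erd", 0.7), mk("ann", 0.7))
  expect_equal(compare_approaches(same)$ann_beats_this[1], FALSE)
  expect_error(compare_approaches(reports[1]), "at least 2")
})

test_that("uncorrected type-I rate across null features matches alpha", {
  # 200 simulated null sessions x 18 features at alpha = 0.05
  set.seed(23)
  alpha <- 0.05
  hits <- 0L; total <- 0L
  for (b in 1:200) {
    y <- rnorm(60)
    X <- matrix(rnorm(60 * 18), 60)
    p <- apply(X, 2, function(col) pearson(col, y)$p)
    hits <- hits + sum(p < alpha); total <- total + 18L
  }
  rate <- hits / total
  ciw <- 3 * sqrt(alpha * (1 - alpha) / total)
  expect_lt(abs(rate - alpha), ciw)
})

test_that("permutation bound sits near the analytic max-statistic null level", {
  set.seed(24)
  n <- 240; p <- 24
  X <- matrix(rnorm(n * p), n)
  y <- rnorm(n)
  bound <- perm_null_max_abs_r(X, y, n_perm = 500, seed = 1)
  # analytic approximation: 95th percentile of the max of 24 |N(0, 1/sqrt(n-1))|
  z <- qnorm(1 - (1 - 0.95^(1 / p)) / 2) / sqrt(n - 1)
  expect_equal(bound, z, tolerance = 0.15)
  # observed max on null data stays under the bound most of the time
  expect_lt(max(abs(cor(X, y))), bound * 1.3)
})
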