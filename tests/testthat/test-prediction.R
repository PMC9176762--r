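test_that("cross-validation folds are balanced and reproducible", {
  f <- make_cv_folds(10, 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(unname(table(f)), rep(2L, 5), ignore_attr = TRUE)
  f11 <- make_cv_folds(11, 5, seed = 1)
  expect_equal(sort(as.integer(table(f11)), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L))
  expect_identical(make_cv_folds(100, 5, seed = 9), make_cv_folds(100, 5, seed = 9))
  expect_error(make_cv_folds(3, 5), "at least as many")
})

test_that("logistic predictions reproduce the contingency-table closed form", {
  feat <- tibble::tibble(x = factor(c(rep(1, 100), rep(0, 100))))
  y <- c(rep(1, 20), rep(0, 80), rep(1, 5), rep(0, 95))
  pr <- fit_predict_logistic(feat, y, folds = NULL)
  p1 <- pr$p_hat[1]; p0 <- pr$p_hat[101]
  expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), (20 * 95) / (80 * 5),
               tolerance = 1e-6)
  expect_equal(p1, 0.2, tolerance = 1e-6)
})

test_that("degenerate all-negative training folds predict (near) zero", {
  feat <- tibble::tibble(x = rnorm(40))
  y <- rep(0L, 40)
  pr <- suppressWarnings(fit_predict_logistic(feat, y, folds = NULL))
  expect_true(all(pr$p_hat <= 1e-3))
})

test_that("logistic coefficients are recovered from a known model", {
  n <- 50000
  withr::with_seed(2024, {
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
    lp <- -2 + 0.8 * x1 - 0.5 * x2
    y <- rbinom(n, 1, plogis(lp))
  })
  X <- cbind(1, x1, x2)
  co <- gcsrasch:::logistic_coefs(X, y)
  mu <- drop(plogis(X %*% co))
  fisher <- crossprod(X, X * (mu * (1 - mu)))
  se <- sqrt(diag(solve(fisher)))
  expect_true(all(abs(co - c(-2, 0.8, -0.5)) < 3 * se))
})

test_that("every case receives exactly one out-of-fold prediction", {
  withr::with_seed(3, {
    feat <- tibble::tibble(a = rnorm(200), b = factor(rbinom(200, 2, 0.5)))
    y <- rbinom(200, 1, 0.3)
  })
  folds <- make_cv_folds(200, 5, seed = 4)
  pr <- fit_predict_logistic(feat, y, folds)
  expect_equal(sort(pr$id), 1:200)
  expect_equal(anyDuplicated(pr$id), 0)
  expect_true(all(pr$p_hat >= 0 & pr$p_hat <= 1))
  expect_equal(pr$fold, folds)
})

test_that("random forests never beat the base rate on pure noise", {
  withr::with_seed(11, {
    feat <- tibble::tibble(a = rnorm(600), b = rnorm(600))
    y <- rbinom(600, 1, 0.3)
  })
  folds <- make_cv_folds(600, 5, seed = 2)
  pf <- fit_predict_forest(feat, y, folds, tree_grid = c(100, 250), seed = 4)
  base <- mean((mean(y) - y)^2)
  expect_gte(score_summary(pf)$brier, base - 0.005)
  # deterministic given seed
  pf2 <- fit_predict_forest(feat, y, folds, tree_grid = c(100, 250), seed = 4)
  expect_equal(pf$p_hat, pf2$p_hat)
  # grid of size one skips the inner search
  pf1 <- fit_predict_forest(feat, y, folds, tree_grid = 100, seed = 4)
  expect_equal(attr(pf1, "chosen_trees"), rep(100, 5))
})

test_that("score summaries follow the Brier and log-loss definitions", {
  mk <- function(p, y) tibble::tibble(id = seq_along(p), fold = 1L,
                                      p_hat = p, y = y, model = "m")
  expect_equal(score_summary(mk(c(1, 0, 1), c(1, 0, 1)))$brier, 0)
  expect_equal(score_summary(mk(rep(0.5, 4), c(0, 1, 0, 1)))$brier, 0.25)
  s <- score_summary(mk(c(0.8, 0.3), c(1, 0)))
  expect_equal(s$brier, (0.04 + 0.09) / 2)
  expect_equal(s$brier_se, sd(c(0.04, 0.09)) / sqrt(2))
  expect_equal(s$logloss, mean(-log(c(0.8, 0.7))))
  # the base-rate predictor scores exactly ybar(1 - ybar)
  y <- rbinom(500, 1, 0.2)
  expect_equal(score_summary(mk(rep(mean(y), 500), y))$brier,
               mean(y) * (1 - mean(y)))
  # perfect certain predictions have finite log loss via clipping
  expect_true(is.finite(score_summary(mk(c(1, 0), c(1, 0)))$logloss))
})

test_that("the signed-rank test matches enumeration, symmetry and the reference", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p_value, 2 / 32)
  # antisymmetric differences: p = 1
  expect_equal(wilcoxon_signed_rank(c(-2, -1, 1, 2))$p_value, 1)
  expect_warning(out <- wilcoxon_signed_rank(rep(0, 6)), "zero")
  expect_equal(out$p_value, 1)
  # brute-force oracle on random tied inputs, n <= 10
  withr::with_seed(3, {
    for (i in 1:15) {
      d <- round(rnorm(sample(5:10, 1)), 1)
      expect_equal(wilcoxon_signed_rank(d)$p_value, brute_force_signed_rank(d),
                   tolerance = 1e-12)
    }
  })
  # agreement with the reference implementation on tie-free input
  d <- c(1.5, -0.3, 2.2, 0.7, -1.1, 0.4, 3.0, -0.2)
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               wilcox.test(d, exact = TRUE)$p.value)
  # large n switches to the corrected normal approximation
  dn <- withr::with_seed(8, rnorm(200, 0.1))
  expect_equal(wilcoxon_signed_rank(dn)$method, "normal approximation")
  expect_equal(wilcoxon_signed_rank(dn)$p_value,
               wilcox.test(dn, correct = TRUE, exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("risk-difference counts and strata follow the definitions", {
  mk <- function(p) tibble::tibble(id = seq_along(p), fold = 1L, p_hat = p,
                                   y = 0L, model = "m")
  p0 <- seq(0.1, 0.5, length.out = 10)
  same <- risk_difference_analysis(mk(p0), mk(p0))
  expect_equal(same$counts$n_exceed, c(0L, 0L, 0L))
  up <- risk_difference_analysis(mk(p0), mk(p0 + 0.03))
  expect_equal(up$counts$n_exceed, c(10L, 0L, 0L))
  expect_equal(up$counts$pct, c(100, 0, 0))
  expect_true(all(up$deltas$delta > 0))
  # 10-case toy with 3 exceedances at 2.5%, 1 at 5%
  p1 <- p0 + c(0.03, 0.06, -0.04, rep(0, 7))
  rd <- risk_difference_analysis(mk(p0), mk(p1))
  expect_equal(rd$counts$n_exceed, c(3L, 1L, 0L))
  expect_equal(rd$counts$pct, c(30, 10, 0))
  # stratified summaries require matching cases
  expect_error(risk_difference_analysis(mk(p0), mk(p1[1:5])), "different cases")
  cov <- tibble::tibble(id = 1:10, iss = rep(c(9, 17), 5),
                        age = seq(20, 65, 5),
                        region = rep(c("Head", "Chest"), 5))
  rd2 <- risk_difference_analysis(mk(p0), mk(p1), covariates = cov)
  expect_equal(sum(rd2$strata$n[rd2$strata$stratifier == "region"]), 3)
  expect_setequal(unique(rd2$strata$stratifier), c("iss", "age_bin", "region"))
})
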