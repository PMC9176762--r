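test_that("category probabilities follow the partial credit model", {
  expect_equal(pcm_category_probs(0, c(0)), c(0.5, 0.5))
  # adjacent categories are equiprobable at the threshold
  p <- pcm_category_probs(0.7, c(-1, 0.7, 2))
  expect_equal(p[2], p[3])
  # direct evaluation with unnormalised weights (1, e, 1)
  expect_equal(pcm_category_probs(0, c(-1, 1)),
               c(1, exp(1), 1) / (2 + exp(1)), tolerance = 1e-12)
  # rows sum to one and the expected score is strictly increasing in theta
  set.seed(42)
  for (i in 1:20) {
    delta <- runif(sample(1:5, 1), -3, 3)
    theta <- seq(-5, 5, length.out = 41)
    p <- pcm_category_probs(theta, delta)
    expect_true(all(abs(rowSums(p) - 1) < 1e-12))
    es <- p %*% (0:length(delta))
    expect_true(all(diff(es) > 0))
  }
})

test_that("elementary symmetric functions match pattern enumeration", {
  # two dichotomous items with unit weights: binomial pattern counts
  expect_equal(unname(elementary_symmetric(list(c(1, 1), c(1, 1)))),
               c(1, 2, 1))
  # gamma_0 is always the single all-zero pattern
  set.seed(1)
  w <- lapply(c(3, 4, 5), function(m) c(1, exp(-cumsum(runif(m, -2, 2)))))
  expect_equal(elementary_symmetric(w, r = 0), 1)
  # GCS-shaped items: full vector vs exhaustive enumeration over 120 patterns
  g <- elementary_symmetric(w)
  pat <- expand.grid(0:3, 0:4, 0:5)
  brute <- vapply(0:12, function(r) {
    rows <- pat[rowSums(pat) == r, , drop = FALSE]
    sum(apply(rows, 1, function(p) {
      w[[1]][p[1] + 1] * w[[2]][p[2] + 1] * w[[3]][p[3] + 1]
    }))
  }, numeric(1))
  expect_equal(unname(g), brute, tolerance = 1e-12)
  expect_error(elementary_symmetric(w, r = 13), "outside")
})

test_that("two-item dichotomous CML matches the closed-form conditional estimator", {
  x <- rbind(
    matrix(rep(c(1L, 0L), 20), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), 10), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 1L), 5), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 0L), 5), ncol = 2, byrow = TRUE)
  )
  fit <- fit_pcm(response_matrix(x, c(1L, 1L)))
  expect_equal(unname(diff(unlist(fit$thresholds))), log(20 / 10),
               tolerance = 1e-7)
})

test_that("thresholds are recovered from simulated data and bias shrinks with n", {
  truth <- list(a = c(-1, 1), b = c(-1.5, 0, 1.5), c = c(0.5, -0.5, 1))
  shift <- mean(vapply(truth, mean, numeric(1)))
  truth_c <- lapply(truth, function(d) d - shift)
  rm <- simulate_pcm(truth, 5000, theta_sd = 1.5, seed = 101)
  fit <- fit_pcm(rm)
  expect_lt(max(abs(unlist(fit$thresholds) - unlist(truth_c))), 0.1)
  err_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      f <- fit_pcm(simulate_pcm(truth, n, theta_sd = 1.5, seed = s))
      max(abs(unlist(f$thresholds) - unlist(truth_c)))
    }, numeric(1)))
  }
  expect_lt(err_at(5000, 301:305), err_at(500, 301:305))
})

test_that("the fit is invariant to person order and to extreme-score persons", {
  truth <- list(a = c(-0.5, 0.5), b = c(-1, 0, 1))
  rm <- simulate_pcm(truth, 800, theta_sd = 1.5, seed = 17)
  fit <- fit_pcm(rm)
  perm <- withr::with_seed(1, sample(nrow(rm$responses)))
  fit_perm <- fit_pcm(response_matrix(rm$responses[perm, ], rm$maxima))
  expect_equal(fit_perm$thresholds, fit$thresholds, tolerance = 1e-8)
  # add 100 extreme persons: calibration unchanged (the stated rationale
  # for excluding extreme scores)
  extremes <- rbind(
    matrix(rep(c(0L, 0L), 50), ncol = 2, byrow = TRUE),
    matrix(rep(c(2L, 3L), 50), ncol = 2, byrow = TRUE)
  )
  colnames(extremes) <- colnames(rm$responses)
  fit_ext <- fit_pcm(response_matrix(rbind(rm$responses, extremes), rm$maxima))
  expect_equal(fit_ext$thresholds, fit$thresholds, tolerance = 1e-8)
  expect_equal(fit_ext$n_valid, fit$n_valid)
})

test_that("null categories abort with a structured error", {
  x <- cbind(c(0L, 2L, 2L, 0L, 2L), c(0L, 1L, 0L, 1L, 1L))
  expect_error(fit_pcm(response_matrix(x, c(2L, 1L))),
               "null category.*item1.*1")
})

test_that("person estimation is monotone, symmetric and extrapolates extremes", {
  # symmetric instrument: half-maximum raw score sits at theta = 0
  fit <- structure(list(
    thresholds = list(a = c(-1, 1), b = c(-2, 2)),
    locations = c(a = 0, b = 0), maxima = c(a = 2L, b = 2L),
    items = c("a", "b")), class = "pcm_fit")
  x <- rbind(c(0L, 0L), c(1L, 1L), c(0L, 2L), c(2L, 2L), c(1L, 2L), c(2L, 1L))
  rm <- response_matrix(x, c(2L, 2L))
  pers <- estimate_persons(rm, fit)
  expect_equal(pers$theta[pers$raw_score == 2][1], 0, tolerance = 1e-8)
  # strictly increasing in the raw score
  uniq <- pers[!duplicated(pers$raw_score), ]
  uniq <- uniq[order(uniq$raw_score), ]
  expect_true(all(diff(uniq$theta) > 0))
  expect_equal(pers$extreme, rowSums(x) %in% c(0L, 4L))
  # single dichotomous item, extrapolated r = eps = 0.3
  fit1 <- structure(list(thresholds = list(a = 0), locations = c(a = 0),
                         maxima = c(a = 1L), items = "a"), class = "pcm_fit")
  rm1 <- response_matrix(matrix(c(0L, 1L), ncol = 1), 1L)
  p1 <- estimate_persons(rm1, fit1, extreme_eps = 0.3)
  expect_equal(p1$theta[1], log(0.3 / 0.7), tolerance = 1e-8)
  expect_true(all(p1$extreme))
})
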