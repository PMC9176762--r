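test_that("standardized residuals are zero at the expectation and follow Bernoulli arithmetic", {
  fit <- structure(list(thresholds = list(a = 0, b = 0),
                        locations = c(a = 0, b = 0),
                        maxima = c(a = 1L, b = 1L), items = c("a", "b")),
                   class = "pcm_fit")
  rm <- response_matrix(rbind(c(1L, 0L), c(0L, 1L)), c(1L, 1L))
  persons <- tibble::tibble(person = 1:2, raw_score = c(1L, 1L),
                            theta = c(0, 0), se = 1, extreme = FALSE)
  # location-conditioned moments: E = 0.5, Var = 0.25 -> z = (1 - 0.5)/0.5 = 1
  res <- standardized_residuals(rm, fit, persons, conditional = FALSE)
  expect_equal(res$residual[res$person == 1 & res$item == "a"], 1)
  expect_equal(res$residual[res$person == 1 & res$item == "b"], -1)
  # a response exactly at the (conditional) expectation has z = 0
  res_c <- standardized_residuals(rm, fit, persons, conditional = TRUE)
  expect_equal(res_c$expected, rep(0.5, 4))
  expect_equal(abs(res_c$residual), rep(1, 4))
})

test_that("residuals on model-simulated data have mean zero and unit variance", {
  truth <- list(a = c(-1.2, 0, 1.2), b = c(-1.5, -0.5, 0.5, 1.5),
                c = c(-2, -1, 0, 1, 2))
  rm <- simulate_pcm(truth, 4000, theta_sd = 1.5, seed = 77)
  fit <- fit_pcm(rm)
  persons <- estimate_persons(rm, fit)
  res <- standardized_residuals(rm, fit, persons)
  expect_equal(mean(res$residual), 0, tolerance = 0.03)
  expect_equal(var(res$residual), 1, tolerance = 0.05)
})

test_that("the Wilson-Hilferty transform standardises chi-square sums", {
  # at Y = nu the statistic equals sqrt(2/(9 nu)), vanishing with nu
  expect_equal(fit_residual_transform(1000, 1000), 0, tolerance = 0.02)
  expect_lt(abs(fit_residual_transform(1e6, 1e6)),
            abs(fit_residual_transform(1000, 1000)))
  expect_lt(fit_residual_transform(40, 100), 0)
  expect_error(fit_residual_transform(1, 1), "nu >= 2")
  # distributional oracle: chi-square(100) draws map to standard normal
  # (500 draws: enough to catch a wrong transform without over-powering the
  # KS test against the O(1/nu) error of the cube-root approximation)
  y <- withr::with_seed(123, rchisq(500, df = 100))
  z <- fit_residual_transform(y, 100)
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
  expect_equal(mean(z), 0, tolerance = 0.15)
  expect_equal(sd(z), 1, tolerance = 0.15)
})

test_that("item-trait chi-square has the configured degrees of freedom", {
  truth <- list(a = c(-1, 1), b = c(-0.5, 0.5), c = c(0, 1))
  rm <- simulate_pcm(truth, 600, theta_sd = 1.5, seed = 31)
  fit <- fit_pcm(rm)
  persons <- estimate_persons(rm, fit)
  ch <- item_trait_chi_square(rm, fit, persons, n_class_intervals = 6)
  expect_equal(ch$df, 15)
  expect_equal(sum(ch$cells$contribution), ch$chi_square)
  expect_gte(ch$p_value, 0)
  expect_lte(ch$p_value, 1)
  ch4 <- item_trait_chi_square(rm, fit, persons, n_class_intervals = 4)
  expect_equal(ch4$df, 9)
  expect_error(item_trait_chi_square(rm, fit, persons, 1), "n_class_intervals")
})

test_that("PSI follows its defining formula, including negative values", {
  mk <- function(theta, se) {
    tibble::tibble(person = seq_along(theta), raw_score = 1L,
                   theta = theta, se = se, extreme = FALSE)
  }
  expect_equal(psi(mk(c(-1, 0, 1, 2), 0)), 1)
  v <- var(c(-1, 0, 1, 2))
  expect_equal(psi(mk(c(-1, 0, 1, 2), sqrt(v))), 0)
  # Var = 0.5, mean SE^2 = 1 -> PSI = -1
  theta <- c(-0.5, 0.5) * sqrt(2)  # sample variance 1... rescale below
  theta <- theta / sqrt(var(theta)) * sqrt(0.5)
  expect_equal(psi(mk(theta, 1)), -1)
  expect_error(psi(mk(c(1, 1), 1)), "zero variance")
})

test_that("Cronbach's alpha matches closed-form cases", {
  x <- cbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L))
  expect_equal(cronbach_alpha(response_matrix(x, c(2L, 2L, 2L))), 1)
  # hand-computed toy with zero inter-item covariance
  toy <- response_matrix(rbind(c(0L, 1L), c(1L, 1L), c(0L, 0L), c(1L, 0L)),
                         c(1L, 1L))
  expect_equal(cronbach_alpha(toy), 0)
  # independent items at large n: alpha near zero
  ind <- withr::with_seed(5, cbind(rbinom(5000, 3, 0.5), rbinom(5000, 3, 0.5)))
  expect_equal(cronbach_alpha(response_matrix(ind, c(3L, 3L))), 0,
               tolerance = 0.06)
})

test_that("threshold ordering flags exactly the reversed adjacent pairs", {
  fit <- structure(list(thresholds = list(a = c(-1, 0, 1), b = c(0.5, -0.5)),
                        locations = c(a = 0, b = 0),
                        maxima = c(a = 3L, b = 2L), items = c("a", "b")),
                   class = "pcm_fit")
  tor <- threshold_order_report(fit)
  expect_false(any(tor$disordered[tor$item == "a"]))
  expect_true(tor$disordered[tor$item == "b"])
})

test_that("category curves cross at thresholds and expose never-modal categories", {
  fit <- structure(list(thresholds = list(a = c(0.8), b = c(1, -1),
                                          c = c(-1, 1)),
                        locations = c(a = 0.8, b = 0, c = 0),
                        maxima = c(a = 1L, b = 2L, c = 2L),
                        items = c("a", "b", "c")), class = "pcm_fit")
  curves <- category_probability_curves(fit, seq(-4, 4, by = 0.01))
  # dichotomous curves cross at delta
  at <- curves[curves$item == "a" & abs(curves$theta - 0.8) < 1e-9, ]
  expect_equal(at$prob[at$category == 0], at$prob[at$category == 1],
               tolerance = 1e-12)
  nm <- never_modal(curves)
  # disordered item: middle category never modal; ordered item: all modal
  expect_true(nm$never_modal[nm$item == "b" & nm$category == 1])
  expect_false(any(nm$never_modal[nm$item == "c"]))
})

test_that("the diagnostic report separates with- and without-extreme reliability", {
  truth <- disordered_thresholds()
  rm <- simulate_pcm(truth, 1500, theta_mean = 2.5, theta_sd = 1.5, seed = 55)
  expect_gt(sum(is_extreme(rm)), 50) # skew guarantees extremes
  rep <- rasch_diagnostics(rm)
  expect_equal(rep$n_valid + rep$n_extreme, 1500)
  expect_lt(rep$psi_with_extremes, rep$psi_no_extremes)
  expect_equal(rep$df, 15)
})

test_that("the four-sample design has the documented sizes and is seed-deterministic", {
  truth <- list(a = c(0, 0.5), b = c(-0.5, 0.5), c = c(-1, 1))
  rm <- simulate_pcm(truth, 8000, theta_sd = 2, seed = 12)
  d1 <- run_sample_design(rm, seed = 3, n_small = 300)
  d2 <- run_sample_design(rm, seed = 3, n_small = 300)
  expect_equal(d1$chi_square, d2$chi_square)
  expect_equal(d1$n_valid[d1$sample == "1_nonextreme"], sum(!is_extreme(rm)))
  expect_equal(d1$n_extreme[d1$sample == "1_nonextreme"], 0)
  expect_equal(d1$n_drawn[d1$sample == "2_random500"], 300)
  expect_equal(d1$n_drawn[d1$sample == "3_ten_percent"], floor(0.1 * 8000))
  s3 <- d1[d1$sample == "3_ten_percent", ]
  expect_equal(s3$n_valid + s3$n_extreme, floor(0.1 * 8000))
})
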