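#' Standardized response residuals
#'
#' Residuals `z = (x - E[X]) / sqrt(Var(X))` for non-extreme persons. By
#' default the moments condition on the person's total raw score (the same
#' conditioning used by the CML fit), which makes the residuals exactly
#' mean-zero and unit-variance under the model despite the person locations
#' being estimated from the totals. `conditional = FALSE` uses the moments
#' given the estimated location `theta` instead; these are the classical
#' person-parameter residuals but are variance-deflated by the constraint
#' that residuals sum to zero within each person.
#'
#' @param rm A [response_matrix()].
#' @param fit A [fit_pcm()] result.
#' @param persons Output of [estimate_persons()] for `rm`.
#' @param conditional Condition moments on the raw total (default) or on the
#'   estimated location.
#' @return A tibble `person`, `item`, `observed`, `expected`, `residual`
#'   covering non-extreme persons; cells with zero model variance are
#'   excluded and counted in the `n_zero_variance` attribute.
#' @export
standardized_residuals <- function(rm, fit, persons, conditional = TRUE) {
  keep <- !persons$extreme
  x <- rm$responses[keep, , drop = FALSE]
  r <- persons$raw_score[keep]
  theta <- persons$theta[keep]
  n <- nrow(x)
  items <- fit$items
  E <- V <- matrix(NA_real_, n, length(items))
  if (conditional) {
    w <- pcm_weights(fit$thresholds)
    dists <- conditional_item_dists(w)
    for (i in seq_along(items)) {
      sc <- 0:fit$maxima[i]
      e_by_r <- drop(crossprod(dists[[i]], sc))
      v_by_r <- drop(crossprod(dists[[i]], sc^2)) - e_by_r^2
      E[, i] <- e_by_r[r + 1]
      V[, i] <- v_by_r[r + 1]
    }
  } else {
    uniq <- sort(unique(theta))
    for (i in seq_along(items)) {
      mom <- pcm_moments(uniq, fit$thresholds[[i]])
      pos <- match(theta, uniq)
      E[, i] <- mom$mean[pos]
      V[, i] <- mom$var[pos]
    }
  }
  out <- tibble::tibble(
    person = rep(persons$person[keep], times = length(items)),
    item = rep(items, each = n),
    observed = as.integer(x),
    expected = as.vector(E),
    variance = as.vector(V),
    residual = (as.integer(x) - as.vector(E)) / sqrt(as.vector(V))
  )
  zero <- !is.finite(out$residual)
  res <- out[!zero, c("person", "item", "observed", "expected", "residual")]
  attr(res, "n_zero_variance") <- sum(zero)
  res
}

#' Wilson-Hilferty standardized fit residual
#'
#' Standardizes a sum of squared residuals `y` against its chi-square
#' reference with `nu` degrees of freedom via the Wilson-Hilferty cube-root
#' transform: `((y/nu)^(1/3) - (1 - 2/(9 nu))) / sqrt(2/(9 nu))`. Values near
#' 0 indicate fit in line with model expectation; negative values indicate
#' less misfit than expected (over-discrimination), positive values more.
#'
#' @param y Sum of squared standardized residuals.
#' @param nu Number of contributing residuals.
#' @return The standardized fit residual.
#' @export
fit_residual_transform <- function(y, nu) {
  if (any(nu < 2)) stop("fit residual requires nu >= 2", call. = FALSE)
  ((y / nu)^(1 / 3) - (1 - 2 / (9 * nu))) / sqrt(2 / (9 * nu))
}

#' Item and person fit residuals
#'
#' Applies [fit_residual_transform()] to the per-item (over persons) and
#' per-person (over items) sums of squared standardized residuals.
#'
#' @param residuals Output of [standardized_residuals()].
#' @return A tibble `item`, `n`, `fit_residual` (for `item_fit_residuals`)
#'   or `person`, `n`, `fit_residual` (for `person_fit_residuals`).
#' @export
item_fit_residuals <- function(residuals) {
  residuals |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(n = dplyr::n(),
                     fit_residual = fit_residual_transform(sum(.data$residual^2),
                                                           dplyr::n()),
                     .groups = "drop")
}

#' @rdname item_fit_residuals
#' @export
person_fit_residuals <- function(residuals) {
  residuals |>
    dplyr::group_by(.data$person) |>
    dplyr::summarise(n = dplyr::n(),
                     fit_residual = fit_residual_transform(sum(.data$residual^2),
                                                           dplyr::n()),
                     .groups = "drop")
}

#' Item-trait interaction chi-square
#'
#' Persons are ranked by estimated location (ties broken by person index)
#' and cut into `n_class_intervals` equal-count class intervals. For every
#' item-by-interval cell the contribution is
#' `(sum(observed) - sum(expected))^2 / sum(variance)`; contributions are
#' summed over all cells, with `df = n_items * (n_class_intervals - 1)` and
#' the p-value from the upper chi-square tail.
#'
#' @inheritParams standardized_residuals
#' @param n_class_intervals Number of class intervals (G >= 2).
#' @return An `item_trait_chisq` list: `chi_square`, `df`, `p_value`,
#'   `n_class_intervals` and the per-cell table.
#' @export
item_trait_chi_square <- function(rm, fit, persons, n_class_intervals = 6) {
  stopifnot(n_class_intervals >= 2)
  keep <- !persons$extreme
  x <- rm$responses[keep, , drop = FALSE]
  r <- persons$raw_score[keep]
  theta <- persons$theta[keep]
  n <- nrow(x)
  if (n < n_class_intervals) stop("empty class interval: fewer persons than intervals",
                                  call. = FALSE)
  ord <- order(theta, seq_len(n))
  interval <- integer(n)
  interval[ord] <- ceiling(seq_len(n) * n_class_intervals / n)

  w <- pcm_weights(fit$thresholds)
  dists <- conditional_item_dists(w)
  cells <- purrr::map_dfr(seq_along(fit$items), function(i) {
    sc <- 0:fit$maxima[i]
    e_by_r <- drop(crossprod(dists[[i]], sc))
    v_by_r <- drop(crossprod(dists[[i]], sc^2)) - e_by_r^2
    tibble::tibble(
      item = fit$items[i],
      interval = interval,
      observed = x[, i],
      expected = e_by_r[r + 1],
      variance = v_by_r[r + 1]
    )
  }) |>
    dplyr::group_by(.data$item, .data$interval) |>
    dplyr::summarise(n = dplyr::n(),
                     observed = sum(.data$observed),
                     expected = sum(.data$expected),
                     variance = sum(.data$variance),
                     .groups = "drop") |>
    dplyr::mutate(contribution = ifelse(.data$variance > 0,
                                        (.data$observed - .data$expected)^2 /
                                          .data$variance, 0))
  chi <- sum(cells$contribution)
  df <- length(fit$items) * (n_class_intervals - 1)
  structure(list(
    chi_square = chi,
    df = df,
    p_value = stats::pchisq(chi, df, lower.tail = FALSE),
    n_class_intervals = n_class_intervals,
    cells = cells
  ), class = "item_trait_chisq")
}

#' @export
print.item_trait_chisq <- function(x, ...) {
  cat(sprintf("Item-trait interaction chi-square: %.2f on %d df (G = %d), p = %.3g\n",
              x$chi_square, x$df, x$n_class_intervals, x$p_value))
  invisible(x)
}

#' Person separation index
#'
#' `PSI = (Var(theta_hat) - mean(SE^2)) / Var(theta_hat)`: the proportion of
#' observed person-location variance not attributable to estimation error.
#' Can be negative when the error variance exceeds the observed spread, as
#' happens in extreme-dominated samples with extrapolated estimates.
#'
#' @param persons Output of [estimate_persons()].
#' @param include_extremes Keep extreme persons (with their extrapolated
#'   estimates) or drop them.
#' @return A scalar.
#' @export
psi <- function(persons, include_extremes = FALSE) {
  p <- if (include_extremes) persons else persons[!persons$extreme, ]
  if (nrow(p) < 2) stop("PSI requires at least two persons", call. = FALSE)
  v <- stats::var(p$theta)
  if (v == 0) stop("PSI undefined: zero variance of person estimates",
                   call. = FALSE)
  (v - mean(p$se^2)) / v
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / Var(total score))` with
#' sample variances over the included persons.
#'
#' @param rm A [response_matrix()].
#' @param include_extremes Keep persons with extreme totals.
#' @return A scalar.
#' @export
cronbach_alpha <- function(rm, include_extremes = TRUE) {
  x <- rm$responses
  if (!include_extremes) x <- x[!is_extreme(rm), , drop = FALSE]
  k <- ncol(x)
  if (k < 2) stop("alpha requires at least two items", call. = FALSE)
  tot_var <- stats::var(rowSums(x))
  if (tot_var == 0) stop("alpha undefined: zero total-score variance",
                         call. = FALSE)
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / tot_var)
}

#' Threshold ordering report
#'
#' Flags each adjacent pair of Andrich thresholds that is reversed
#' (disordered): pair `k` is disordered when `delta_k >= delta_{k+1}`,
#' the signature of a response category that is never the most probable at
#' any level of the trait.
#'
#' @param fit A [fit_pcm()] result.
#' @return A tibble `item`, `pair`, `delta_lower`, `delta_upper`,
#'   `disordered`.
#' @export
threshold_order_report <- function(fit) {
  purrr::map_dfr(seq_along(fit$items), function(i) {
    d <- fit$thresholds[[i]]
    if (length(d) < 2) return(tibble::tibble())
    tibble::tibble(
      item = fit$items[i],
      pair = seq_len(length(d) - 1),
      delta_lower = d[-length(d)],
      delta_upper = d[-1],
      disordered = d[-length(d)] >= d[-1]
    )
  })
}

#' Category probability curves
#'
#' Evaluates the PCM category probabilities of every item along a grid of
#' person locations, in the long plot-ready format of the classical
#' Rasch-Andrich threshold plots. A category is *never modal* when it is not
#' the most probable response at any grid point.
#'
#' @param fit A [fit_pcm()] result.
#' @param theta_grid Numeric grid of person locations (logits).
#' @return A tibble `item`, `category`, `theta`, `prob` of class
#'   `gcs_curves`; per-category modality flags are available via
#'   [never_modal()].
#' @export
category_probability_curves <- function(fit, theta_grid = seq(-6, 6, by = 0.05)) {
  stopifnot(all(is.finite(theta_grid)))
  out <- purrr::map_dfr(seq_along(fit$items), function(i) {
    p <- pcm_category_probs(theta_grid, fit$thresholds[[i]])
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    tibble::tibble(
      item = fit$items[i],
      category = rep(0:fit$maxima[i], each = length(theta_grid)),
      theta = rep(theta_grid, times = fit$maxima[i] + 1),
      prob = as.vector(p)
    )
  })
  class(out) <- c("gcs_curves", class(out))
  out
}

#' @rdname category_probability_curves
#' @param curves Output of [category_probability_curves()].
#' @return For `never_modal()`: a tibble `item`, `category`, `never_modal`.
#' @export
never_modal <- function(curves) {
  curves |>
    dplyr::group_by(.data$item, .data$theta) |>
    dplyr::mutate(modal = .data$prob == max(.data$prob)) |>
    dplyr::group_by(.data$item, .data$category) |>
    dplyr::summarise(never_modal = !any(.data$modal), .groups = "drop")
}

#' Full Rasch diagnostic report for one sample
#'
#' Fits the PCM and assembles one row of the summary fit battery: item and
#' person fit residual means and SDs, the item-trait interaction chi-square,
#' and both reliability statistics (PSI and Cronbach's alpha), each computed
#' with and without the extreme-total persons.
#'
#' @param rm A [response_matrix()].
#' @param n_class_intervals Class intervals for the chi-square.
#' @param extreme_eps Extrapolation offset for extreme person estimates.
#' @param conditional Moment conditioning for residuals
#'   (see [standardized_residuals()]).
#' @return A one-row tibble of class `fit_report`; the underlying `pcm_fit`
#'   is attached as the `fit` attribute.
#' @export
rasch_diagnostics <- function(rm, n_class_intervals = 6, extreme_eps = 0.3,
                              conditional = TRUE) {
  fit <- fit_pcm(rm)
  persons <- estimate_persons(rm, fit, extreme_eps = extreme_eps)
  res <- standardized_residuals(rm, fit, persons, conditional = conditional)
  ifr <- item_fit_residuals(res)
  pfr <- person_fit_residuals(res)
  chs <- item_trait_chi_square(rm, fit, persons, n_class_intervals)
  has_ext <- any(persons$extreme)
  rep <- tibble::tibble(
    n_valid = fit$n_valid,
    n_extreme = fit$n_extreme,
    item_fit_mean = mean(ifr$fit_residual),
    item_fit_sd = stats::sd(ifr$fit_residual),
    person_fit_mean = mean(pfr$fit_residual),
    person_fit_sd = stats::sd(pfr$fit_residual),
    chi_square = chs$chi_square,
    df = chs$df,
    p_value = chs$p_value,
    psi_with_extremes = if (has_ext) psi(persons, include_extremes = TRUE)
                        else psi(persons, include_extremes = FALSE),
    psi_no_extremes = psi(persons, include_extremes = FALSE),
    alpha_with_extremes = cronbach_alpha(rm, include_extremes = TRUE),
    alpha_no_extremes = cronbach_alpha(rm, include_extremes = FALSE)
  )
  attr(rep, "fit") <- fit
  class(rep) <- c("fit_report", class(rep))
  rep
}

#' Four-sample analysis design
#'
#' Reproduces the four-sample reporting scheme used to keep fit statistics
#' interpretable in very large, extreme-dominated cohorts: (1) the complete
#' non-extreme sample; (2) a random `n_small` drawn from sample 1; (3) a
#' random 10% of the full complete sample (floor rule), which is dominated
#' by extreme totals; (4) a random draw from sample 3 sized so that the
#' expected number of *valid* (non-extreme) cases is about `n_small`, with
#' its extreme cases retained for the with-extremes reliability statistics.
#' Each sample is fitted and diagnosed; deterministic given `seed`.
#'
#' @param rm The full complete-GCS [response_matrix()].
#' @param seed Integer seed.
#' @param n_class_intervals Class intervals for the chi-square.
#' @param n_small Size of the interpretable sub-samples (default 500).
#' @return A tibble of four `fit_report` rows with a `sample` label column.
#' @export
run_sample_design <- function(rm, seed = 1L, n_class_intervals = 6,
                              n_small = 500L) {
  n <- nrow(rm$responses)
  ext <- is_extreme(rm)
  withr::with_seed(seed, {
    idx1 <- which(!ext)
    idx2 <- sample(idx1, min(n_small, length(idx1)))
    idx3 <- sample(n, floor(0.1 * n))
    valid_frac <- mean(!ext[idx3])
    idx4 <- sample(idx3, min(round(n_small / valid_frac), length(idx3)))
    samples <- list(
      "1_nonextreme" = idx1,
      "2_random500" = idx2,
      "3_ten_percent" = idx3,
      "4_random500_of_3" = idx4
    )
    purrr::imap_dfr(samples, function(idx, label) {
      rep <- rasch_diagnostics(rm_subset(rm, idx), n_class_intervals)
      dplyr::bind_cols(tibble::tibble(sample = label, n_drawn = length(idx)),
                       rep)
    })
  })
}
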