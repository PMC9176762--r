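#' Balanced cross-validation fold assignment
#'
#' Random fold labels with sizes differing by at most one; deterministic
#' given `seed`.
#'
#' @param n Number of cases.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`.
#' @export
make_cv_folds <- function(n, k = 5L, seed = 1L) {
  if (n < k) stop("need at least as many cases as folds", call. = FALSE)
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Build mortality-model features from registry records
#'
#' Encodes the three GCS sub-scores as categorical indicators plus the
#' summed total as numeric (the sub-scores and the total are jointly
#' identified only under the categorical coding), optionally rescored with a
#' [collapse_map()], and optionally augmented with the ancillary covariates
#' (age, sex, total ISS, most-severely-injured region) as additive effects.
#'
#' @param records Complete-GCS registry tibble.
#' @param map Optional [collapse_map()] applied before encoding.
#' @param ancillary Include age, sex, ISS and region.
#' @return A feature tibble aligned with `records`.
#' @export
mortality_features <- function(records, map = NULL, ancillary = FALSE) {
  rm <- as_response_matrix(records, map = map)
  x <- rm$responses
  out <- tibble::tibble(
    eye = factor(x[, "eye"], levels = 0:rm$maxima["eye"]),
    verbal = factor(x[, "verbal"], levels = 0:rm$maxima["verbal"]),
    motor = factor(x[, "motor"], levels = 0:rm$maxima["motor"]),
    gcs_total = as.numeric(rowSums(x))
  )
  if (ancillary) {
    out$age <- records$age
    out$sex <- records$sex
    out$iss <- as.numeric(records$iss)
    out$region <- records$region
  }
  out
}

#' Out-of-fold logistic predictions
#'
#' Per fold, a maximum-likelihood logistic regression is fitted on the
#' training folds and predicted on the held-out fold, so that every case
#' receives exactly one out-of-fold predicted probability. Under complete or
#' quasi-complete separation (or other non-convergence) the fold falls back
#' to a lightly ridge-penalised fit (penalty 1e-6) and a warning is logged.
#'
#' @param features Feature tibble (see [mortality_features()]).
#' @param y Binary outcome vector (0/1 or a two-level factor; the second
#'   level is the event).
#' @param folds Fold assignment from [make_cv_folds()], or `NULL` to fit and
#'   predict in-sample on the full data.
#' @param ids Optional case identifiers (defaults to row numbers).
#' @return A `prediction_result` tibble: `id`, `fold`, `p_hat`, `y`,
#'   `model`.
#' @export
fit_predict_logistic <- function(features, y, folds = NULL, ids = NULL) {
  y <- as_binary_outcome(y)
  X <- stats::model.matrix(~ ., data = features)
  n <- nrow(X)
  if (is.null(ids)) ids <- seq_len(n)
  if (is.null(folds)) folds <- rep(0L, n)
  p_hat <- numeric(n)
  for (f in sort(unique(folds))) {
    test <- if (f == 0L) rep(TRUE, n) else folds == f
    train <- if (f == 0L) rep(TRUE, n) else !test
    coefs <- logistic_coefs(X[train, , drop = FALSE], y[train])
    p_hat[test] <- stats::plogis(drop(X[test, , drop = FALSE] %*% coefs))
  }
  structure(tibble::tibble(id = ids, fold = folds, p_hat = p_hat, y = y,
                           model = "logistic"),
            class = c("prediction_result", class(tibble::tibble())))
}

logistic_coefs <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  # runaway coefficients are the operational signature of (quasi-)separation
  if (!fit$converged || any(!is.finite(coefs)) || max(abs(coefs)) > 20) {
    warning("separation or non-convergence in logistic fit; using ridge fallback (penalty 1e-6)",
            call. = FALSE)
    coefs <- ridge_logistic(X, y, lambda = 1e-6)
  }
  coefs
}

# Ridge-penalised logistic regression by penalised IRLS (all coefficients
# penalised, so the system stays non-singular under complete separation).
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 100L) {
  beta <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(X, y - mu)) - lambda * beta
    H <- crossprod(X, X * w)
    diag(H) <- diag(H) + lambda
    step <- solve(H, g)
    # dampen early steps to keep IRLS stable far from the optimum
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  stats::setNames(drop(beta), colnames(X))
}

as_binary_outcome <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  y
}

#' Out-of-fold random-forest predictions with nested tuning
#'
#' Per outer fold, an inner `inner_k`-fold grid search over the number of
#' trees selects the value with the best inner-CV Brier score (ties favour
#' fewer trees); a forest with the selected size is then fitted on the full
#' training portion and predicts the held-out fold probabilistically. A grid
#' of size one skips the inner search. Deterministic given `seed`.
#'
#' @inheritParams fit_predict_logistic
#' @param tree_grid Candidate numbers of trees.
#' @param inner_k Inner folds for the grid search.
#' @param seed Integer seed.
#' @return A `prediction_result` tibble with a `chosen_trees` attribute
#'   (one entry per outer fold).
#' @export
fit_predict_forest <- function(features, y, folds,
                               tree_grid = c(100, 250, 500, 1000, 2000),
                               inner_k = 3L, seed = 1L) {
  y <- as_binary_outcome(y)
  df <- as.data.frame(features)
  df$.y <- factor(y, levels = c(0, 1))
  n <- nrow(df)
  ids <- seq_len(n)
  p_hat <- numeric(n)
  chosen <- integer(0)
  for (f in sort(unique(folds))) {
    test <- folds == f
    train_df <- df[!test, , drop = FALSE]
    best <- tree_grid[1]
    if (length(tree_grid) > 1) {
      inner <- make_cv_folds(nrow(train_df), inner_k, seed = seed + f)
      inner_brier <- vapply(tree_grid, function(nt) {
        sq <- numeric(nrow(train_df))
        for (g in seq_len(inner_k)) {
          it <- inner == g
          fit <- ranger::ranger(
            dependent.variable.name = ".y", data = train_df[!it, , drop = FALSE],
            num.trees = nt, probability = TRUE, seed = seed + 97L * f + g,
            num.threads = 1
          )
          pp <- stats::predict(fit, data = train_df[it, , drop = FALSE],
                               num.threads = 1)$predictions[, "1"]
          sq[it] <- (pp - (as.integer(train_df$.y[it]) - 1L))^2
        }
        mean(sq)
      }, numeric(1))
      best <- tree_grid[which.min(inner_brier)]
    }
    chosen <- c(chosen, best)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = train_df,
      num.trees = best, probability = TRUE, seed = seed + 31L * f,
      num.threads = 1
    )
    p_hat[test] <- stats::predict(fit, data = df[test, , drop = FALSE],
                                  num.threads = 1)$predictions[, "1"]
  }
  out <- structure(tibble::tibble(id = ids, fold = folds, p_hat = p_hat,
                                  y = y, model = "random_forest"),
                   class = c("prediction_result", class(tibble::tibble())))
  attr(out, "chosen_trees") <- chosen
  out
}

#' Proper scoring-rule summary of out-of-fold predictions
#'
#' Brier score (mean squared error of the predicted probability) with its
#' empirical standard error (sample SD of the per-case squared errors over
#' the square root of n), and the log loss with predictions clipped to
#' `[1e-15, 1 - 1e-15]`.
#'
#' @param pred A `prediction_result` tibble.
#' @return A one-row tibble `model`, `brier`, `brier_se`, `logloss`, `n`.
#' @export
score_summary <- function(pred) {
  stopifnot(nrow(pred) > 0)
  sq <- (pred$p_hat - pred$y)^2
  p <- pmin(pmax(pred$p_hat, 1e-15), 1 - 1e-15)
  tibble::tibble(
    model = pred$model[1],
    brier = mean(sq),
    brier_se = stats::sd(sq) / sqrt(length(sq)),
    logloss = mean(-(pred$y * log(p) + (1 - pred$y) * log1p(-p))),
    n = length(sq)
  )
}

#' Wilcoxon signed-rank test
#'
#' Two-sided test of symmetry about zero for paired differences. Zero
#' differences are dropped (the classical convention) and ties among the
#' absolute values are mid-ranked. Up to 25 non-zero differences the exact
#' null distribution of the signed-rank sum is computed by dynamic
#' programming over the (doubled, hence integer) mid-ranks, which remains
#' exact in the presence of ties; above 25 the normal approximation with
#' continuity and tie corrections is used.
#'
#' @param diffs Numeric vector of paired differences.
#' @return A list `statistic` (positive-rank sum W), `p_value`,
#'   `n_nonzero`, `method`.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L, method = "degenerate"))
  }
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= 25) {
    # distribution of 2W over sign patterns: coefficients of prod (1 + z^(2r))
    r2 <- as.integer(round(2 * rk))
    coefs <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), coefs[seq_len(length(coefs) - ri)])
      coefs <- coefs + shifted
    }
    probs <- coefs / 2^n
    w2 <- as.integer(round(2 * W))
    p_lo <- sum(probs[seq_len(w2 + 1L)])
    p_hi <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n_nonzero = n, method = method)
}

#' Individual-level risk-difference analysis
#'
#' Compares per-case out-of-fold predicted probabilities from two models of
#' the same cases. Differences are signed `rescored - original`, so a
#' systematic tendency of the rescored model to predict lower risks shows as
#' negative mass. For each threshold the count and percentage of cases with
#' `|difference|` above it are reported; cases above the smallest threshold
#' are additionally summarised stratified by ISS, age in 5-year bins and
#' body region when covariates are supplied.
#'
#' @param pred_original,pred_rescored `prediction_result` tibbles over the
#'   same case ids.
#' @param thresholds Absolute-difference thresholds.
#' @param covariates Optional tibble with columns `id`, `iss`, `age`,
#'   `region` for the stratified summaries.
#' @return A `risk_difference` list: `counts` (per threshold), `deltas`
#'   (per case) and `strata` (long-format summaries, or `NULL`).
#' @export
risk_difference_analysis <- function(pred_original, pred_rescored,
                                     thresholds = c(0.025, 0.05, 0.10),
                                     covariates = NULL) {
  if (!setequal(pred_original$id, pred_rescored$id)) {
    stop("the two prediction sets cover different cases", call. = FALSE)
  }
  merged <- dplyr::inner_join(
    dplyr::select(pred_original, "id", p_original = "p_hat"),
    dplyr::select(pred_rescored, "id", p_rescored = "p_hat"),
    by = "id"
  )
  merged$delta <- merged$p_rescored - merged$p_original
  n <- nrow(merged)
  counts <- tibble::tibble(
    threshold = thresholds,
    n_exceed = vapply(thresholds, function(t) sum(abs(merged$delta) > t),
                      integer(1))
  )
  counts$pct <- counts$n_exceed / n * 100
  strata <- NULL
  if (!is.null(covariates)) {
    sub <- merged[abs(merged$delta) > min(thresholds), c("id", "delta")]
    sub <- dplyr::inner_join(sub, covariates, by = "id")
    sub$age_bin <- cut(sub$age, breaks = seq(0, 120, by = 5), right = FALSE)
    summarise_by <- function(data, var) {
      data |>
        dplyr::group_by(level = as.character(.data[[var]])) |>
        dplyr::summarise(n = dplyr::n(),
                         mean_delta = mean(.data$delta),
                         median_delta = stats::median(.data$delta),
                         q25 = stats::quantile(.data$delta, 0.25),
                         q75 = stats::quantile(.data$delta, 0.75),
                         .groups = "drop") |>
        dplyr::mutate(stratifier = var, .before = 1)
    }
    strata <- dplyr::bind_rows(
      summarise_by(sub, "iss"),
      summarise_by(sub, "age_bin"),
      summarise_by(sub, "region")
    )
  }
  structure(list(counts = counts, deltas = merged, strata = strata),
            class = "risk_difference")
}

#' @export
print.risk_difference <- function(x, ...) {
  cat("Individual-level risk differences (rescored - original):\n")
  print(x$counts)
  invisible(x)
}
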