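#' Partial credit model category probabilities
#'
#' For a person at location `theta` and an item with Andrich thresholds
#' `delta_1..delta_m`, the probability of scoring `x` is proportional to
#' `exp(sum_{k <= x} (theta - delta_k))`, with the empty sum equal to 0. At
#' `theta = delta_k` the categories `k - 1` and `k` are equiprobable.
#'
#' @param theta Numeric vector of person locations (logits).
#' @param thresholds Numeric vector of item thresholds (logits).
#' @return If `theta` has length 1, a probability vector of length
#'   `length(thresholds) + 1`; otherwise a matrix with one row per `theta`.
#' @export
pcm_category_probs <- function(theta, thresholds) {
  stopifnot(all(is.finite(thresholds)))
  m <- length(thresholds)
  cum <- c(0, cumsum(thresholds))
  lw <- outer(theta, 0:m) - rep(cum, each = length(theta))
  lw <- lw - apply(lw, 1, max)
  w <- exp(lw)
  p <- w / rowSums(w)
  if (length(theta) == 1) drop(p) else p
}

# Expected score and variance of an item response given theta.
pcm_moments <- function(theta, thresholds) {
  p <- pcm_category_probs(theta, thresholds)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  x <- 0:length(thresholds)
  e <- drop(p %*% x)
  v <- drop(p %*% x^2) - e^2
  list(mean = e, var = v)
}

#' Elementary symmetric functions of PCM category weights
#'
#' The conditional likelihood of the PCM given a person's total score `r`
#' normalises by `gamma_r`, the sum over all response patterns with total
#' `r` of the product of the per-item category weights
#' `exp(-sum_{k <= x} delta_ik)`. The full vector `gamma_0..gamma_M` is
#' computed by the stable recursive convolution over items.
#'
#' @param weights List of per-item non-negative weight vectors; element `i`
#'   has length `m_i + 1` (index 1 corresponds to score 0).
#' @param r Optional total score; if supplied, the scalar `gamma_r` is
#'   returned, otherwise the whole vector (named by total score).
#' @return Numeric vector or scalar.
#' @export
elementary_symmetric <- function(weights, r = NULL) {
  g <- Reduce(function(acc, w) {
    out <- numeric(length(acc) + length(w) - 1)
    for (j in seq_along(w)) {
      idx <- seq_along(acc) + j - 1
      out[idx] <- out[idx] + acc * w[j]
    }
    out
  }, weights, accumulate = FALSE)
  names(g) <- 0:(length(g) - 1)
  if (is.null(r)) return(g)
  if (r < 0 || r > length(g) - 1) {
    stop(sprintf("total score r = %s outside [0, %d]", r, length(g) - 1),
         call. = FALSE)
  }
  unname(g[r + 1])
}

# Per-item weight vectors exp(-cumsum(delta)) from a threshold list,
# rescaled per item for numerical stability (all conditional quantities are
# invariant to per-item rescaling; the log-scale constants are returned for
# exact log-likelihoods).
pcm_weights <- function(thresholds) {
  lw <- lapply(thresholds, function(d) c(0, -cumsum(d)))
  shift <- vapply(lw, max, numeric(1))
  w <- Map(function(l, s) exp(l - s), lw, shift)
  attr(w, "log_shift") <- shift
  w
}

# Conditional distribution of item i's response given the total score:
# P(X_i = x | R = r) = w_i[x] * gamma^(-i)[r - x] / gamma[r].
# Returns a list with per-item matrices P[x + 1, r + 1].
conditional_item_dists <- function(weights) {
  gamma <- elementary_symmetric(weights)
  M <- length(gamma) - 1
  lapply(seq_along(weights), function(i) {
    g_rest <- if (length(weights) == 1) 1 else
      elementary_symmetric(weights[-i])
    m_i <- length(weights[[i]]) - 1
    p <- matrix(0, nrow = m_i + 1, ncol = M + 1)
    for (x in 0:m_i) {
      rr <- x:(x + length(g_rest) - 1)
      p[x + 1, rr + 1] <- weights[[i]][x + 1] * g_rest
    }
    sweep(p, 2, gamma, `/`)
  })
}

#' Fit PCM item parameters by conditional maximum likelihood
#'
#' Maximises the likelihood of the item responses conditional on each
#' person's total score, which frees the item thresholds from any assumption
#' about the person distribution. Persons with an extreme total (0 or the
#' maximum) contribute nothing to the conditional likelihood and are
#' ignored; this is why extreme scores do not alter item calibrations.
#' Newton-Raphson iterations with analytic gradient and Hessian run on the
#' elementary symmetric functions; the solution is identified by centring so
#' that the mean item location (mean of each item's thresholds, averaged
#' over items) is zero.
#'
#' @param rm A [response_matrix()].
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the maximum absolute (projected)
#'   gradient.
#' @return A `pcm_fit` object: per-item `thresholds`, item `locations`,
#'   the conditional `logLik`, iteration count and convergence metadata.
#' @export
fit_pcm <- function(rm, max_iter = 200L, tol = 1e-8) {
  maxima <- rm$maxima
  items <- colnames(rm$responses)
  keep <- !is_extreme(rm)
  x <- rm$responses[keep, , drop = FALSE]
  n_extreme <- sum(!keep)
  if (nrow(x) < 2) stop("fewer than two non-extreme persons", call. = FALSE)

  # null-category check among non-extreme persons
  for (i in seq_along(maxima)) {
    seen <- tabulate(x[, i] + 1L, nbins = maxima[i] + 1L)
    if (any(seen == 0)) {
      stop(sprintf(
        "null category: item '%s' has no observations in category %s; collapse categories before fitting",
        items[i], paste(which(seen == 0) - 1L, collapse = ", ")),
        call. = FALSE)
    }
  }

  K <- sum(maxima)
  # sufficient statistics: S_ik = #persons with x_i >= k; n_r = total-score counts
  S <- unlist(lapply(seq_along(maxima), function(i) {
    vapply(seq_len(maxima[i]), function(k) sum(x[, i] >= k), numeric(1))
  }))
  r_all <- rowSums(x)
  M <- sum(maxima)
  n_r <- tabulate(r_all + 1L, nbins = M + 1L)

  split_idx <- rep(seq_along(maxima), maxima)
  expand_delta <- function(p) {
    d1 <- -sum(p)
    split(c(d1, p), split_idx)
  }

  loglik_grad_hess <- function(p, need_hess = TRUE) {
    delta <- expand_delta(p)
    w <- pcm_weights(delta)
    shift <- attr(w, "log_shift")
    gamma <- elementary_symmetric(w)
    ll <- -sum(S * unlist(delta)) -
      sum(n_r * (log(gamma) + sum(shift)))
    dists <- conditional_item_dists(w)
    # P(X_i >= k | r) for each threshold parameter
    ge <- matrix(0, nrow = K, ncol = M + 1)
    row0 <- 0L
    for (i in seq_along(maxima)) {
      cs <- apply(dists[[i]], 2, function(col) rev(cumsum(rev(col))))
      for (k in seq_len(maxima[i])) ge[row0 + k, ] <- cs[k + 1, ]
      row0 <- row0 + maxima[i]
    }
    grad <- -S + as.vector(ge %*% n_r)
    H <- NULL
    if (need_hess) {
      # H[(ik),(jl)] = -sum_r n_r Cov(1{X_i>=k}, 1{X_j>=l} | r)
      H <- matrix(0, K, K)
      row_item <- split_idx
      row_k <- unlist(lapply(maxima, seq_len))
      for (aa in seq_len(K)) {
        for (bb in aa:K) {
          i <- row_item[aa]; k <- row_k[aa]
          j <- row_item[bb]; l <- row_k[bb]
          if (i == j) {
            e_ab <- ge[if (k >= l) aa else bb, ]
          } else {
            e_ab <- joint_ge(w, gamma, i, k, j, l)
          }
          cov_r <- e_ab - ge[aa, ] * ge[bb, ]
          H[aa, bb] <- H[bb, aa] <- -sum(n_r * cov_r)
        }
      }
    }
    list(ll = ll, grad = grad, hess = H)
  }

  # chain rule onto the K-1 free parameters (delta_1 = -sum(free))
  to_free <- function(g) g[-1] - g[1]
  hess_free <- function(H) {
    A <- rbind(-1, diag(K - 1))
    t(A) %*% H %*% A
  }

  p <- rep(0, K - 1)
  cur <- loglik_grad_hess(p)
  iter <- 0L
  repeat {
    gf <- to_free(cur$grad)
    if (max(abs(gf)) < tol || iter >= max_iter) break
    Hf <- hess_free(cur$hess)
    step <- tryCatch(solve(Hf, gf), error = function(e) gf / max(abs(diag(Hf)), 1))
    # Newton ascent: p_new = p - H^{-1} g (H negative definite)
    lambda <- 1
    repeat {
      p_new <- p - lambda * step
      new <- loglik_grad_hess(p_new)
      if (new$ll >= cur$ll - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    p <- p_new
    cur <- new
    iter <- iter + 1L
  }
  gf <- to_free(cur$grad)
  converged <- max(abs(gf)) < tol
  if (!converged) {
    stop(sprintf("conditional ML did not converge in %d iterations (max |gradient| = %.3g)",
                 max_iter, max(abs(gf))), call. = FALSE)
  }

  delta <- expand_delta(p)
  # identification: mean item location = 0 (a pure shift leaves the
  # conditional likelihood unchanged)
  locs <- vapply(delta, mean, numeric(1))
  shift <- mean(locs)
  delta <- lapply(delta, function(d) d - shift)
  names(delta) <- items

  structure(list(
    thresholds = delta,
    locations = vapply(delta, mean, numeric(1)),
    maxima = maxima,
    items = items,
    logLik = cur$ll,
    iterations = iter,
    converged = converged,
    max_abs_gradient = max(abs(gf)),
    n_valid = nrow(x),
    n_extreme = n_extreme,
    score_counts = n_r
  ), class = "pcm_fit")
}

# E[1{X_i >= k} 1{X_j >= l} | r] for i != j via the esf of the remaining items.
joint_ge <- function(w, gamma, i, k, j, l) {
  rest <- setdiff(seq_along(w), c(i, j))
  g_rest <- if (length(rest) == 0) 1 else elementary_symmetric(w[rest])
  M <- length(gamma) - 1
  num <- numeric(M + 1)
  m_i <- length(w[[i]]) - 1
  m_j <- length(w[[j]]) - 1
  for (xx in k:m_i) {
    for (yy in l:m_j) {
      rr <- (xx + yy):(xx + yy + length(g_rest) - 1)
      num[rr + 1] <- num[rr + 1] + w[[i]][xx + 1] * w[[j]][yy + 1] * g_rest
    }
  }
  num / gamma
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat(sprintf("<pcm_fit: %d items, %d valid persons (%d extreme ignored); logLik %.2f, %d iterations>\n",
              length(x$items), x$n_valid, x$n_extreme, x$logLik, x$iterations))
  for (i in seq_along(x$items)) {
    cat(sprintf("  %s: %s\n", x$items[i],
                paste(sprintf("%.3f", x$thresholds[[i]]), collapse = ", ")))
  }
  invisible(x)
}

#' Estimate person locations from a fitted PCM
#'
#' For each raw total score, the location solves `sum_i E[X_i | theta] = r`
#' (the ML estimate under the PCM); the standard error is
#' `1 / sqrt(sum_i Var(X_i | theta))`. Extreme raw scores (0 or the maximum)
#' carry no finite ML estimate and are extrapolated by solving at
#' `r = eps` and `r = max - eps` respectively; they are flagged `extreme`.
#'
#' @param rm A [response_matrix()].
#' @param fit A [fit_pcm()] result.
#' @param extreme_eps Score-unit offset used for the extreme-score
#'   extrapolation (default 0.3).
#' @return A tibble with columns `person`, `raw_score`, `theta`, `se`,
#'   `extreme`, one row per person in `rm` (row order preserved).
#' @export
estimate_persons <- function(rm, fit, extreme_eps = 0.3) {
  r <- total_scores(rm)
  M <- sum(fit$maxima)
  uniq <- sort(unique(r))
  est <- vapply(uniq, function(ri) {
    target <- if (ri == 0) extreme_eps else if (ri == M) M - extreme_eps else ri
    theta_for_score(target, fit$thresholds)
  }, numeric(2))
  theta <- est[1, match(r, uniq)]
  se <- est[2, match(r, uniq)]
  tibble::tibble(
    person = seq_along(r),
    raw_score = r,
    theta = theta,
    se = se,
    extreme = r == 0L | r == M
  )
}

# Solve sum_i E[X_i | theta] = target; returns c(theta, se).
theta_for_score <- function(target, thresholds) {
  f <- function(th) {
    sum(vapply(thresholds, function(d) pcm_moments(th, d)$mean, numeric(1))) -
      target
  }
  root <- stats::uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
  info <- sum(vapply(thresholds, function(d) pcm_moments(root, d)$var,
                     numeric(1)))
  c(root, 1 / sqrt(info))
}
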