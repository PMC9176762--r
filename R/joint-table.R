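#' Default GCS sub-score marginal frequencies of the emulated registry
#'
#' The per-category response frequencies of the complete adult trauma cohort
#' that the synthetic registry reproduces exactly (Eye categories 1-4,
#' Verbal 1-5, Motor 1-6; each vector sums to the complete-sample size).
#'
#' @return A named list of three integer vectors.
#' @export
gcs_registry_marginals <- function() {
  list(
    eye = c(16347L, 2844L, 12122L, 289890L),
    verbal = c(15622L, 6359L, 3813L, 26261L, 269148L),
    motor = c(11072L, 1579L, 1626L, 3332L, 10950L, 292644L)
  )
}

#' Build the joint Eye x Verbal x Motor frequency table
#'
#' Constructs a 4 x 5 x 6 integer array over the GCS categories whose three
#' one-dimensional marginals equal the supplied targets exactly, with the two
#' extreme response patterns pinned: cell (1,1,1) (total GCS 3) holds exactly
#' `extreme3` records and cell (4,5,6) (total GCS 15) exactly `extreme15`.
#' The remaining (non-extreme) mass is spread by iterative proportional
#' fitting of the residual marginals, with the two extreme cells as
#' structural zeros and the independence table as the starting point, and is
#' then rounded to integers in a way that preserves every marginal exactly
#' (largest-remainder rounding to the grand total followed by single-unit
#' repair moves along one axis at a time, which leave the other two marginals
#' untouched).
#'
#' @param marginals Named list of three count vectors (`eye`, `verbal`,
#'   `motor`), each summing to the same total.
#' @param extreme3 Count allocated to the all-minimum pattern E1V1M1.
#' @param extreme15 Count allocated to the all-maximum pattern E4V5M6.
#' @return A `joint_gcs_table`: an integer array with a `non_extreme` count
#'   attribute.
#' @export
build_joint_gcs_table <- function(marginals = gcs_registry_marginals(),
                                  extreme3 = 8000L,
                                  extreme15 = 264786L) {
  me <- marginals$eye; mv <- marginals$verbal; mm <- marginals$motor
  totals <- c(sum(me), sum(mv), sum(mm))
  if (length(unique(totals)) != 1) {
    stop("marginal vectors must share a common total", call. = FALSE)
  }
  n <- totals[1]
  a <- as.integer(extreme3); b <- as.integer(extreme15)
  min_first <- min(me[1], mv[1], mm[1])
  min_last <- min(me[length(me)], mv[length(mv)], mm[length(mm)])
  if (a < 0 || a > min_first) {
    stop(sprintf(
      "infeasible extreme3 = %d: must lie in [0, %d] (minimum of the three first-category marginals)",
      a, min_first), call. = FALSE)
  }
  if (b < 0 || b > min_last) {
    stop(sprintf(
      "infeasible extreme15 = %d: must lie in [0, %d] (minimum of the three last-category marginals)",
      b, min_last), call. = FALSE)
  }
  if (a + b > n) {
    stop("infeasible: extreme3 + extreme15 exceeds the marginal total",
         call. = FALSE)
  }

  re <- me; re[1] <- re[1] - a; re[length(re)] <- re[length(re)] - b
  rv <- mv; rv[1] <- rv[1] - a; rv[length(rv)] <- rv[length(rv)] - b
  rmm <- mm; rmm[1] <- rmm[1] - a; rmm[length(rmm)] <- rmm[length(rmm)] - b

  dims <- c(length(me), length(mv), length(mm))
  forbidden <- matrix(c(1L, 1L, 1L, dims), ncol = 3, byrow = TRUE)

  n_res <- n - a - b
  tab <- if (n_res > 0) {
    fit <- ipf3(list(re, rv, rmm), forbidden)
    round_preserve_margins(fit, list(re, rv, rmm), forbidden)
  } else {
    array(0L, dims)
  }
  tab[1, 1, 1] <- a
  tab[dims[1], dims[2], dims[3]] <- tab[dims[1], dims[2], dims[3]] + b

  stopifnot(
    identical(as.integer(apply(tab, 1, sum)), as.integer(me)),
    identical(as.integer(apply(tab, 2, sum)), as.integer(mv)),
    identical(as.integer(apply(tab, 3, sum)), as.integer(mm))
  )
  structure(tab,
            non_extreme = n_res,
            extreme3 = a, extreme15 = b,
            class = c("joint_gcs_table", "array"))
}

# Iterative proportional fitting of a 3-way array to three 1-D margins,
# with structural-zero cells. Starts from the independence table.
ipf3 <- function(margins, forbidden, tol = 1e-10, max_iter = 5000) {
  d <- lengths(margins)
  n <- sum(margins[[1]])
  a <- outer(outer(margins[[1]], margins[[2]]), margins[[3]]) / n^2
  dim(a) <- d
  for (r in seq_len(nrow(forbidden))) {
    a[forbidden[r, 1], forbidden[r, 2], forbidden[r, 3]] <- 0
  }
  for (iter in seq_len(max_iter)) {
    for (k in 1:3) {
      cur <- apply(a, k, sum)
      scale <- ifelse(cur > 0, margins[[k]] / cur, 0)
      a <- sweep(a, k, scale, `*`)
    }
    dev <- max(vapply(1:3, function(k) max(abs(apply(a, k, sum) - margins[[k]])),
                      numeric(1)))
    if (dev < tol * n) return(a)
  }
  stop("iterative proportional fitting did not converge", call. = FALSE)
}

# Round a non-negative array to integers with all 1-D margins preserved
# exactly. Largest-remainder rounding fixes the grand total; margins are then
# repaired one dimension at a time with single-unit moves along that
# dimension only (such moves cannot disturb the other margins). Forbidden
# cells never receive mass.
round_preserve_margins <- function(a, margins, forbidden) {
  d <- dim(a)
  flat <- as.vector(a)
  x <- lr_round(flat, total = sum(margins[[1]]))
  x <- array(x, d)
  forb <- array(FALSE, d)
  for (r in seq_len(nrow(forbidden))) {
    forb[forbidden[r, 1], forbidden[r, 2], forbidden[r, 3]] <- TRUE
  }
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (k in 1:3) {
    repeat {
      dev <- apply(x, k, sum) - margins[[k]]
      if (all(dev == 0)) break
      i_over <- which(dev > 0)[1]
      i_under <- which(dev < 0)[1]
      # candidate donor cells in the surplus slice with positive count whose
      # counterpart in the deficit slice is allowed
      sel <- idx[, k] == i_over & x[idx] > 0
      cand <- idx[sel, , drop = FALSE]
      tgt <- cand; tgt[, k] <- i_under
      ok <- !forb[tgt]
      if (!any(ok)) stop("margin repair failed (no movable cell)", call. = FALSE)
      cand <- cand[ok, , drop = FALSE]; tgt <- tgt[ok, , drop = FALSE]
      # prefer moving where rounding overshot most / undershot most
      over_amt <- x[cand] - a[cand]
      pick <- which.max(over_amt)
      x[matrix(cand[pick, ], 1)] <- x[matrix(cand[pick, ], 1)] - 1L
      x[matrix(tgt[pick, ], 1)] <- x[matrix(tgt[pick, ], 1)] + 1L
    }
  }
  storage.mode(x) <- "integer"
  x
}
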