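# Internal helpers shared across modules.

# Largest-remainder rounding of a non-negative vector to integers with a fixed
# total. Handles the (rare) case where floor() already overshoots the target.
lr_round <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= -1e-9), is.finite(total))
  x <- pmax(x, 0)
  f <- floor(x + 1e-9)
  rem <- as.integer(round(total - sum(f)))
  if (rem > 0L) {
    ord <- order(x - f, decreasing = TRUE)
    bump <- ord[seq_len(rem)]
    f[bump] <- f[bump] + 1
  } else if (rem < 0L) {
    ord <- order(x - f)
    k <- 0L
    for (i in ord) {
      if (k == -rem) break
      if (f[i] > 0) {
        f[i] <- f[i] - 1
        k <- k + 1L
      }
    }
    if (k != -rem) stop("lr_round: cannot reach target total", call. = FALSE)
  }
  as.integer(f)
}

# Piecewise-linear quantile function through (p, q) knots.
pl_quantile <- function(p, knots_p, knots_q) {
  stats::approx(knots_p, knots_q, xout = p, rule = 2)$y
}

gcs_items <- c("eye", "verbal", "motor")

# Number of response categories per GCS item (categories 1..k).
gcs_n_categories <- c(eye = 4L, verbal = 5L, motor = 6L)

gcs_regions <- c("Abdomen", "Chest", "Head", "Limbs", "Spine",
                 "Multiple", "Other", "Face")
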