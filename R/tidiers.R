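#' @importFrom generics tidy glance
NULL

#' Tidy a fitted partial credit model
#'
#' One row per Andrich threshold: item, threshold index, estimate, and the
#' item location (mean of its thresholds).
#'
#' @param x A `pcm_fit` object.
#' @param ... Unused.
#' @return A tibble `item`, `threshold`, `estimate`, `item_location`.
#' @export
tidy.pcm_fit <- function(x, ...) {
  purrr::map_dfr(seq_along(x$items), function(i) {
    tibble::tibble(
      item = x$items[i],
      threshold = seq_along(x$thresholds[[i]]),
      estimate = x$thresholds[[i]],
      item_location = x$locations[i]
    )
  })
}

#' @rdname tidy.pcm_fit
#' @return For `glance()`: a one-row tibble with fit-level summaries.
#' @export
glance.pcm_fit <- function(x, ...) {
  tibble::tibble(
    n_valid = x$n_valid,
    n_extreme = x$n_extreme,
    n_items = length(x$items),
    logLik = x$logLik,
    iterations = x$iterations,
    converged = x$converged,
    max_abs_gradient = x$max_abs_gradient
  )
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
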