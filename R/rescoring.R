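#' Construct a category collapse map
#'
#' A collapse map recodes each item's original categories to a smaller
#' ordered set: per item, a non-decreasing surjective mapping onto
#' `0..m'_i`. Element `j` of each vector is the new 0-based code of the
#' original 0-based score `j - 1` (equivalently, of original category `j`).
#'
#' @param ... Named integer vectors, one per item.
#' @return A `collapse_map` object.
#' @export
collapse_map <- function(...) {
  maps <- lapply(list(...), as.integer)
  if (length(maps) == 1 && is.list(maps[[1]]) && is.null(names(maps))) {
    maps <- lapply(maps[[1]], as.integer)
  }
  for (nm in names(maps)) {
    v <- maps[[nm]]
    if (v[1] != 0L) stop(sprintf("map for '%s' must start at 0", nm), call. = FALSE)
    d <- diff(v)
    if (any(d < 0L)) stop(sprintf("map for '%s' must be non-decreasing", nm),
                          call. = FALSE)
    if (any(d > 1L)) stop(sprintf("map for '%s' must be surjective (no skipped codes)", nm),
                          call. = FALSE)
  }
  structure(maps, class = "collapse_map")
}

#' @export
print.collapse_map <- function(x, ...) {
  cat("<collapse_map>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(unclass(x)[[nm]], collapse = " ")))
  }
  invisible(x)
}

#' The published GCS rescore map
#'
#' The post-hoc scoring amendment derived from the disordered-threshold
#' analysis: Eye categories 2 and 3 merge (opening eyes to any stimulus,
#' sound or pain), Verbal 2 and 3 merge (incomprehensible sounds or
#' inappropriate words are not distinguished... the merged code covers
#' confused or inappropriate words below orientated speech), and Motor 2-4
#' merge (any movement other than localizing). The rescored sub-scales have
#' maxima (2, 3, 3) and a summed range of 0-8.
#'
#' @return A [collapse_map()] with elements `eye`, `verbal`, `motor`.
#' @export
published_rescore_map <- function() {
  collapse_map(
    eye = c(0L, 1L, 1L, 2L),
    verbal = c(0L, 1L, 1L, 2L, 3L),
    motor = c(0L, 1L, 1L, 1L, 2L, 3L)
  )
}

#' Apply a collapse map to a response matrix
#'
#' Element-wise recode of the 0-based responses; the new per-item maxima are
#' taken from the map ranges. Row order is preserved.
#'
#' @param rm A [response_matrix()].
#' @param map A [collapse_map()] whose items cover the matrix items and
#'   whose vectors cover the matrix maxima.
#' @return A recoded [response_matrix()].
#' @export
apply_collapse <- function(rm, map) {
  items <- colnames(rm$responses)
  missing_items <- setdiff(items, names(map))
  if (length(missing_items) > 0) {
    stop("collapse map missing items: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  out <- rm$responses
  new_max <- integer(length(items))
  for (i in seq_along(items)) {
    v <- unclass(map)[[items[i]]]
    if (length(v) != rm$maxima[i] + 1L) {
      stop(sprintf("map for '%s' has %d codes but the item has %d categories",
                   items[i], length(v), rm$maxima[i] + 1L), call. = FALSE)
    }
    out[, i] <- v[rm$responses[, i] + 1L]
    new_max[i] <- max(v)
  }
  response_matrix(out, new_max)
}

#' Number of category merges encoded by a collapse map
#' @param map A [collapse_map()].
#' @return Total number of merged adjacent pairs across items.
#' @export
n_merges <- function(map) {
  sum(vapply(unclass(map), function(v) (length(v) - 1L) - max(v), integer(1)))
}

#' Enumerate candidate collapses for one item
#'
#' All monotone surjective recodes of an item with `item_max + 1` categories
#' that merge only adjacent categories, touch at least one disordered
#' threshold pair, and perform at most `max_collapses` merges. A merge
#' erases one threshold; a disordered pair `k` (i.e. `delta_k >=
#' delta_{k+1}`) is touched when threshold `k` or `k + 1` is erased.
#' Candidates are returned in a deterministic lexicographic order of the
#' erased-threshold sets.
#'
#' @param item_max The item's maximum 0-based score (number of thresholds).
#' @param disorder_flags Logical vector of length `item_max - 1`, one per
#'   adjacent threshold pair (see [threshold_order_report()]).
#' @param max_collapses Maximum number of merges.
#' @return A list of integer recode vectors (same convention as
#'   [collapse_map()]); empty when no pair is disordered.
#' @export
enumerate_collapse_candidates <- function(item_max, disorder_flags,
                                          max_collapses = 2L) {
  stopifnot(length(disorder_flags) == item_max - 1)
  if (!any(disorder_flags)) return(list())
  touched <- sort(unique(c(which(disorder_flags), which(disorder_flags) + 1L)))
  out <- list()
  for (size in seq_len(min(max_collapses, item_max - 1L))) {
    sets <- utils::combn(item_max, size, simplify = FALSE)
    for (s in sets) {
      if (!any(s %in% touched)) next
      # new code of 0-based score x = number of kept thresholds <= x
      v <- vapply(0:item_max, function(x) sum(setdiff(seq_len(item_max), s) <= x),
                  integer(1))
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

#' Enumerate full collapse maps from a threshold-order report
#'
#' Combines per-item candidates from [enumerate_collapse_candidates()]
#' across items (items without disorder keep their identity recode; items
#' with disorder may also stay identity, but at least one item must change).
#'
#' @param order_report Output of [threshold_order_report()].
#' @param max_collapses Per-item merge cap.
#' @return A list of [collapse_map()] objects in deterministic order.
#' @export
enumerate_collapse_maps <- function(order_report, max_collapses = 2L) {
  items <- unique(order_report$item)
  per_item <- lapply(items, function(it) {
    rows <- order_report[order_report$item == it, ]
    m <- nrow(rows) + 1L
    identity <- 0:m
    cands <- enumerate_collapse_candidates(m, rows$disordered, max_collapses)
    c(list(identity), cands)
  })
  names(per_item) <- items
  grid <- expand.grid(lapply(per_item, seq_along))
  maps <- list()
  for (g in seq_len(nrow(grid))) {
    sel <- as.integer(grid[g, ])
    if (all(sel == 1L)) next # all-identity
    m <- stats::setNames(
      lapply(seq_along(items), function(i) per_item[[i]][[sel[i]]]), items)
    maps[[length(maps) + 1L]] <- collapse_map(m)
  }
  maps
}

#' Refit and rank candidate rescorings
#'
#' Applies each candidate map, refits the PCM, runs the diagnostic battery
#' and ranks the candidates: first by absence of residual threshold
#' disorder, then by the item-trait chi-square (smaller is better), then by
#' PSI (larger is better); ties favour fewer merges. Null categories created
#' by a collapse are legal inputs here: such candidates are recorded with
#' `NA` diagnostics rather than aborting the comparison.
#'
#' @param rm A [response_matrix()].
#' @param maps List of [collapse_map()] objects (may include the identity).
#' @param n_class_intervals Class intervals for the chi-square.
#' @param seed Seed recorded for reproducibility of the ranking run.
#' @return A tibble, one row per candidate, ranked; the map itself is in the
#'   `map` list-column.
#' @export
compare_rescorings <- function(rm, maps, n_class_intervals = 6, seed = 1L) {
  rows <- purrr::imap_dfr(maps, function(map, i) {
    rec <- apply_collapse(rm, map)
    rep <- tryCatch(rasch_diagnostics(rec, n_class_intervals),
                    error = function(e) NULL)
    if (is.null(rep)) {
      return(tibble::tibble(
        candidate = i, merges = n_merges(map), disorder_remaining = NA_integer_,
        chi_square = NA_real_, p_value = NA_real_, psi_no_extremes = NA_real_,
        fitted = FALSE, map = list(map)
      ))
    }
    tor <- threshold_order_report(attr(rep, "fit"))
    tibble::tibble(
      candidate = i,
      merges = n_merges(map),
      disorder_remaining = sum(tor$disordered),
      chi_square = rep$chi_square,
      p_value = rep$p_value,
      psi_no_extremes = rep$psi_no_extremes,
      fitted = TRUE,
      map = list(map)
    )
  })
  rows |>
    dplyr::arrange(!.data$fitted, .data$disorder_remaining > 0,
                   .data$chi_square, dplyr::desc(.data$psi_no_extremes),
                   .data$merges)
}

#' Serialize a collapse map to JSON
#'
#' @param map A [collapse_map()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
collapse_map_json <- function(map, path = NULL) {
  js <- jsonlite::toJSON(unclass(map), auto_unbox = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
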