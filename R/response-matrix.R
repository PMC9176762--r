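#' Construct a response matrix
#'
#' A persons-by-items matrix of integer responses rebased to `0..m_i`, the
#' input format of the partial credit model engine.
#'
#' @param responses Integer matrix (persons in rows, items in columns) with
#'   values in `0..maxima[i]` per column. Column names are item names.
#' @param maxima Integer vector of per-item maximum scores `m_i`.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(responses, maxima) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  maxima <- as.integer(maxima)
  if (ncol(responses) != length(maxima)) {
    stop("length(maxima) must equal ncol(responses)", call. = FALSE)
  }
  if (is.null(colnames(responses))) {
    colnames(responses) <- paste0("item", seq_len(ncol(responses)))
  }
  names(maxima) <- colnames(responses)
  if (anyNA(responses)) stop("response matrix has missing cells", call. = FALSE)
  for (i in seq_along(maxima)) {
    if (any(responses[, i] < 0L | responses[, i] > maxima[i])) {
      stop(sprintf("responses for item '%s' outside 0..%d",
                   colnames(responses)[i], maxima[i]), call. = FALSE)
    }
  }
  structure(list(responses = responses, maxima = maxima),
            class = "response_matrix")
}

#' Convert complete registry records to a response matrix
#'
#' Rebases the GCS categories to 0-based scores: under identity scoring,
#' category `c` maps to `c - 1`, so the item maxima become (3, 4, 5) for
#' (Eye, Verbal, Motor). A [collapse_map()] may be supplied to apply a
#' category recode instead. Row order is preserved.
#'
#' @param records A registry tibble in which every record has a complete GCS
#'   (see [apply_exclusions()]).
#' @param map Optional [collapse_map()]; `NULL` means identity scoring.
#' @return A [response_matrix()] with items `eye`, `verbal`, `motor`.
#' @export
as_response_matrix <- function(records, map = NULL) {
  sub <- as.matrix(records[, gcs_items])
  if (anyNA(sub)) {
    stop("records with incomplete GCS encountered; apply_exclusions() first",
         call. = FALSE)
  }
  rebased <- sub - 1L
  colnames(rebased) <- gcs_items
  rm <- response_matrix(rebased, maxima = gcs_n_categories - 1L)
  if (!is.null(map)) rm <- apply_collapse(rm, map) # nolint: defined in rescoring
  rm
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix: %d persons x %d items; maxima %s>\n",
              nrow(x$responses), ncol(x$responses),
              paste(x$maxima, collapse = "/")))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Person total scores of a response matrix
#' @param rm A [response_matrix()].
#' @return Integer vector of row sums.
#' @export
total_scores <- function(rm) as.integer(rowSums(rm$responses))

#' Flag extreme persons (minimum or maximum possible total)
#' @param rm A [response_matrix()].
#' @return Logical vector; `TRUE` where the total is 0 or `sum(maxima)`.
#' @export
is_extreme <- function(rm) {
  r <- total_scores(rm)
  r == 0L | r == sum(rm$maxima)
}

# Row subset, keeping the class and maxima.
rm_subset <- function(rm, idx) {
  response_matrix(rm$responses[idx, , drop = FALSE], rm$maxima)
}

#' @importFrom generics tidy
#' @export
tidy.response_matrix <- function(x, ...) {
  tibble::tibble(
    person = rep(seq_len(nrow(x$responses)), times = ncol(x$responses)),
    item = rep(colnames(x$responses), each = nrow(x$responses)),
    response = as.integer(x$responses)
  )
}
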