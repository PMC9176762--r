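#' Read a trauma-registry CSV
#'
#' Reads per-patient registry records: demographics (age, sex), Injury
#' Severity Score (ISS), most-severely-injured body region, the three Glasgow
#' Coma Scale sub-scores (Eye 1-4, Verbal 1-5, Motor 1-6) and the 30-day
#' all-cause mortality outcome. Blank GCS sub-scores are read as missing
#' (a partial GCS); a blank outcome is read as missing.
#'
#' If the file carries a `gcs_total` column, rows whose sub-scores are missing
#' but whose reported summed score is 3 or 15 have their breakdown inferred
#' (all-minimum or all-maximum responses, the only patterns compatible with
#' those totals) and are treated as complete.
#'
#' @param path Path to a comma-separated, UTF-8 file with a header row naming
#'   at least `age`, `sex`, `iss`, `region`, `eye`, `verbal`, `motor` and
#'   `outcome`. An `id` column is optional (row numbers are used otherwise).
#' @return A tibble with one row per record and columns `id`, `age`, `sex`,
#'   `iss`, `region`, `eye`, `verbal`, `motor`, `outcome30d`. The source path
#'   is recorded in the `provenance` attribute.
#' @export
read_registry <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("age", "sex", "iss", "region", "eye", "verbal", "motor", "outcome")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("registry file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  rec <- tibble::tibble(
    id = if ("id" %in% names(raw)) raw$id else sprintf("row%d", seq_len(n)),
    age = suppressWarnings(as.numeric(raw$age)),
    sex = raw$sex,
    iss = suppressWarnings(as.integer(raw$iss)),
    region = raw$region,
    eye = suppressWarnings(as.integer(raw$eye)),
    verbal = suppressWarnings(as.integer(raw$verbal)),
    motor = suppressWarnings(as.integer(raw$motor)),
    outcome30d = raw$outcome
  )

  if ("gcs_total" %in% names(raw)) {
    total <- suppressWarnings(as.integer(raw$gcs_total))
    partial <- is.na(rec$eye) | is.na(rec$verbal) | is.na(rec$motor)
    inf3 <- partial & !is.na(total) & total == 3L
    inf15 <- partial & !is.na(total) & total == 15L
    rec$eye[inf3] <- 1L; rec$verbal[inf3] <- 1L; rec$motor[inf3] <- 1L
    rec$eye[inf15] <- 4L; rec$verbal[inf15] <- 5L; rec$motor[inf15] <- 6L
  }

  bad <- validate_records(rec)
  if (length(bad) > 0) {
    # +1 to convert the data row index to the file line number (header = line 1)
    stop("rejected registry rows (file line: reason):\n",
         paste(sprintf("  line %d: %s", as.integer(names(bad)) + 1L, bad),
               collapse = "\n"), call. = FALSE)
  }
  if (anyDuplicated(rec$id)) {
    stop("duplicate record ids in registry file", call. = FALSE)
  }

  rec$sex <- factor(rec$sex, levels = c("male", "female"))
  rec$region <- factor(rec$region, levels = gcs_regions)
  rec$outcome30d <- factor(rec$outcome30d, levels = c("alive", "dead"))
  attr(rec, "provenance") <- path
  rec
}

# Returns a named character vector: names are offending row indices,
# values are the reasons.
validate_records <- function(rec) {
  msgs <- character(0)
  flag <- function(rows, reason) {
    if (any(rows, na.rm = TRUE)) {
      idx <- which(rows)
      out <- stats::setNames(rep(reason, length(idx)), idx)
      msgs <<- c(msgs, out)
    }
  }
  flag(!is.na(rec$age) & rec$age < 0, "age below 0")
  flag(is.na(rec$age), "age missing or non-numeric")
  flag(!is.na(rec$sex) & !rec$sex %in% c("male", "female"), "sex not male/female")
  flag(!is.na(rec$iss) & (rec$iss < 1 | rec$iss > 75), "ISS outside 1-75")
  flag(!is.na(rec$region) & !rec$region %in% gcs_regions, "unknown body region")
  flag(!is.na(rec$eye) & (rec$eye < 1 | rec$eye > 4),
       "eye response outside 1-4")
  flag(!is.na(rec$verbal) & (rec$verbal < 1 | rec$verbal > 5),
       "verbal response outside 1-5")
  flag(!is.na(rec$motor) & (rec$motor < 1 | rec$motor > 6),
       "motor response outside 1-6")
  flag(!is.na(rec$outcome30d) & !rec$outcome30d %in% c("alive", "dead"),
       "outcome not alive/dead/blank")
  msgs
}

#' Write registry records to CSV
#'
#' Inverse of [read_registry()]: the written file round-trips bit-exactly
#' through `read_registry()`.
#'
#' @param records A registry tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path) {
  out <- records
  out$sex <- as.character(out$sex)
  out$region <- as.character(out$region)
  out$outcome <- as.character(out$outcome30d)
  out$outcome30d <- NULL
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Apply the cohort exclusion filters
#'
#' Sequential, disjoint exclusions: paediatric records (age below 18) are
#' removed first, then adult records without all three GCS sub-scores. The
#' stage-by-stage accounting is attached as the `exclusion_log` attribute
#' (retrievable with [exclusion_log()]), and satisfies
#' `n_input = n_paediatric + n_incomplete_gcs + n_retained`.
#'
#' @param records A registry tibble (see [read_registry()]).
#' @return The retained records, with an `exclusion_log` attribute.
#' @export
apply_exclusions <- function(records) {
  n_input <- nrow(records)
  ped <- records$age < 18
  adults <- records[!ped, , drop = FALSE]
  incomplete <- is.na(adults$eye) | is.na(adults$verbal) | is.na(adults$motor)
  retained <- adults[!incomplete, , drop = FALSE]
  log <- tibble::tibble(
    n_input = n_input,
    n_paediatric = sum(ped),
    n_incomplete_gcs = sum(incomplete),
    n_retained = nrow(retained)
  )
  attr(retained, "exclusion_log") <- log
  attr(retained, "provenance") <- attr(records, "provenance")
  retained
}

#' @rdname apply_exclusions
#' @param x An object returned by [apply_exclusions()].
#' @export
exclusion_log <- function(x) {
  log <- attr(x, "exclusion_log")
  if (is.null(log)) stop("no exclusion log attached; run apply_exclusions() first",
                         call. = FALSE)
  log
}

#' Drop records with a missing 30-day outcome
#'
#' Case-wise deletion of records whose outcome is unrecorded, used to build
#' the complete modelling dataset. The number dropped is attached as the
#' `n_dropped` attribute.
#'
#' @param records A registry tibble.
#' @return Records with an observed outcome.
#' @export
drop_missing_outcome <- function(records) {
  keep <- !is.na(records$outcome30d)
  out <- records[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "exclusion_log") <- attr(records, "exclusion_log")
  out
}
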