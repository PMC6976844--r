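## Cohort files are plain delimited text: header time,event,age (order- and
## case-insensitive), '.' decimal separator, UTF-8. Extra columns are kept
## in the file but ignored by the model.

#' Read a cohort file
#'
#' Reads a CSV of survival records, validates each row, and keeps only rows
#' that pass. Rejected rows are itemized (count and reason) in the ingest
#' report attached as attribute `"ingest"` and retrievable with
#' [ingest_report()].
#'
#' Required columns (any order, any case): `time` (non-negative years),
#' `event` (0 censored / 1 event), `age` (finite years). A missing required
#' column or an unparseable file is a fatal error; an invalid row only
#' rejects that row.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame of records with an `"ingest"` attribute.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("cannot parse '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  names(raw) <- tolower(names(raw))
  for (col in c("time", "event", "age"))
    if (!col %in% names(raw))
      stop("required column '", col, "' not found in ", path, call. = FALSE)

  t <- suppressWarnings(as.numeric(raw$time))
  d <- suppressWarnings(as.numeric(raw$event))
  a <- suppressWarnings(as.numeric(raw$age))
  reason <- character(nrow(raw))
  reason[is.na(a) | !is.finite(a)] <- "age missing or not finite"
  reason[is.na(d) | !d %in% c(0, 1)] <- "event not in {0,1}"
  reason[is.na(t) | t < 0] <- "time missing or negative"
  ok <- reason == ""
  out <- data.frame(time = t[ok], event = d[ok], age = a[ok])
  attr(out, "ingest") <- list(
    n_read = nrow(raw),
    n_kept = sum(ok),
    n_rejected = sum(!ok),
    reasons = if (any(!ok)) table(reason[!ok]) else
      table(factor(character(0))))
  out
}

#' Ingest report of a cohort read from file
#'
#' @param cohort A data frame returned by [read_cohort()].
#' @return List with `n_read`, `n_kept`, `n_rejected` and a `reasons` table.
#' @export
ingest_report <- function(cohort) attr(cohort, "ingest")

#' Write a cohort file
#'
#' Writes records as `time,event,age` CSV. When the cohort carries
#' generating truth (see [generate_cohort()]) and `truth = TRUE`, a sidecar
#' file with suffix `.truth.csv` is written next to it.
#'
#' @param cohort Data frame of survival records.
#' @param path Output CSV path.
#' @param truth Also write the truth sidecar if available (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, truth = FALSE) {
  cohort <- validate_records(cohort, allow_empty = TRUE)
  utils::write.csv(cohort[, c("time", "event", "age")], path,
                   row.names = FALSE, quote = FALSE)
  if (truth && !is.null(attr(cohort, "truth"))) {
    tp <- sub("\\.csv$", "", path)
    utils::write.csv(attr(cohort, "truth"), paste0(tp, ".truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
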