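#' Remove duplicate reports, keeping the most recent version per case
#'
#' Spontaneous reporting systems receive several versions of the same case;
#' per FDA practice only the most recently received version is analyzed.
#' Exactly one report per `case_id` is retained: the one with the greatest
#' receipt date, ties broken by the greatest `primary_id` (compared
#' lexicographically after zero-padding to a common width). A missing
#' receipt date sorts before any present date. The operation partitions its
#' input and is idempotent.
#'
#' @param x A [report_set()].
#' @return A list with components `kept` and `removed`, both `report_set`s;
#'   `kept` carries a `deduplicate` provenance row.
#' @export
deduplicate <- function(x) {
  stopifnot(inherits(x, "report_set"))
  demo <- x$demo
  pid <- demo$primary_id
  w <- max(nchar(pid), 0L)
  pid_pad <- formatC(pid, width = w, flag = "0")
  rec <- ifelse(is.na(demo$receipt_date), -1L, demo$receipt_date)
  o <- order(demo$case_id, rec, pid_pad)
  keep_last <- !duplicated(demo$case_id[o], fromLast = TRUE)
  keep_ids <- pid[o][keep_last]

  kept <- subset_reports(x, keep_ids)
  kept <- log_step(kept, "deduplicate", nrow(demo), nrow(demo) - length(keep_ids))
  removed <- subset_reports(x, setdiff(pid, keep_ids))
  removed$provenance <- kept$provenance
  list(kept = kept, removed = removed)
}

#' Exclude reports where therapy with a drug started after event onset
#'
#' A report cannot attribute the event to a drug that was first administered
#' after the event occurred. A report is removed iff it contains the given
#' ingredient, both the ingredient's earliest therapy start date and the
#' report's event date are present, and the start date is strictly after
#' the event date (a same-day start is retained). Reports with either date
#' missing are conservatively kept. Requires [normalize_drugs()] to have
#' run so ingredient membership is decidable.
#'
#' @param x A [report_set()] with normalized drugs.
#' @param ingredient Canonical ingredient name (lower-case).
#' @return A list with components `kept` and `removed`; `kept` carries a
#'   provenance row named `exclude_post_event_<ingredient>`.
#' @export
exclude_post_event <- function(x, ingredient) {
  stopifnot(inherits(x, "report_set"), is.character(ingredient),
            length(ingredient) == 1L)
  if (all(is.na(x$drugs$mapped)) && nrow(x$drugs)) {
    stop("drugs are not normalized; run normalize_drugs() first")
  }
  d <- x$drugs
  rel <- !is.na(d$ingredient) & d$ingredient == ingredient & !is.na(d$start_date)
  earliest <- tapply(d$start_date[rel], d$primary_id[rel], min)

  demo <- x$demo
  m <- match(demo$primary_id, names(earliest))
  start <- unname(earliest[m])
  has_ing <- demo$primary_id %in% d$primary_id[!is.na(d$ingredient) &
                                                 d$ingredient == ingredient]
  remove <- has_ing & !is.na(start) & !is.na(demo$event_date) &
    start > demo$event_date

  kept <- subset_reports(x, demo$primary_id[!remove])
  kept <- log_step(kept, paste0("exclude_post_event_", ingredient),
                   nrow(demo), sum(remove))
  removed <- subset_reports(x, demo$primary_id[remove])
  removed$provenance <- kept$provenance
  list(kept = kept, removed = removed)
}
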