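#' Report-set container
#'
#' A `report_set` holds a collection of spontaneous adverse-event reports in
#' column-oriented form: one `demo` row per report (keyed by `primary_id`),
#' plus `drugs` and `reactions` tables keyed by the same identifier, and a
#' `provenance` log recording every transformation applied to the set.
#'
#' @details
#' Column schema:
#' \describe{
#'   \item{demo}{`primary_id` (character, unique), `case_id` (character),
#'     `receipt_date` / `event_date` (integer `YYYYMMDD`, `NA` when missing),
#'     `receipt_prec` / `event_prec` (one of `"day"`, `"month"`, `"year"`,
#'     `"missing"`; partial dates are padded to the first day/month for
#'     comparison and flagged here), `sex` (`"female"`, `"male"`,
#'     `"unknown"`), `age_years` (numeric, `NA` when missing), `weight_kg`
#'     (numeric), `country` (character, `"unknown"` when absent).}
#'   \item{drugs}{`primary_id`, `drug_seq` (integer, unique within report),
#'     `verbatim_name`, `prod_ai` (active-ingredient string as reported),
#'     `role` (`"suspect"`, `"concomitant"`, `"interacting"`, `"unknown"`),
#'     `start_date` / `start_prec` (earliest therapy start, `YYYYMMDD`),
#'     `ingredient` (canonical name once [normalize_drugs()] has run, else
#'     `NA`), `mapped` (logical; `NA` before normalization).}
#'   \item{reactions}{`primary_id`, `pt_code` (MedDRA preferred-term numeric
#'     code, `NA` when only a term name was reported), `pt_name`.}
#'   \item{provenance}{`step`, `n_in`, `n_removed`, `n_out`; every row
#'     satisfies `n_in == n_removed + n_out`.}
#' }
#'
#' @param demo,drugs,reactions Data frames following the schema above.
#' @param provenance Optional provenance data frame.
#' @return An object of class `report_set`.
#' @seealso [read_faers_quarter()], [write_faers_quarter()]
#' @export
report_set <- function(demo, drugs, reactions, provenance = NULL) {
  if (is.null(provenance)) {
    provenance <- data.frame(step = character(), n_in = integer(),
                             n_removed = integer(), n_out = integer(),
                             stringsAsFactors = FALSE)
  }
  x <- structure(list(demo = demo, drugs = drugs, reactions = reactions,
                      provenance = provenance),
                 class = "report_set")
  validate_report_set(x)
  x
}

validate_report_set <- function(x) {
  stopifnot(is.data.frame(x$demo), is.data.frame(x$drugs),
            is.data.frame(x$reactions))
  if (anyDuplicated(x$demo$primary_id)) {
    stop("report_set invariant violated: duplicated primary_id in demo")
  }
  pv <- x$provenance
  if (nrow(pv) && any(pv$n_in != pv$n_removed + pv$n_out)) {
    stop("report_set invariant violated: provenance rows must satisfy ",
         "n_in == n_removed + n_out")
  }
  invisible(x)
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d reports, %d drug rows, %d reaction rows\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$reactions)))
  if (nrow(x$provenance)) {
    cat("provenance:\n")
    print(x$provenance, row.names = FALSE)
  }
  invisible(x)
}

#' Number of reports in a report set
#' @param x A `report_set`.
#' @return Integer count of reports (distinct `primary_id`).
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "report_set"))
  nrow(x$demo)
}

#' Provenance log of a report set
#' @param x A `report_set`.
#' @return Data frame with columns `step`, `n_in`, `n_removed`, `n_out`.
#' @export
provenance <- function(x) {
  stopifnot(inherits(x, "report_set"))
  x$provenance
}

# Append one provenance row; enforces the counting identity at the source.
log_step <- function(x, step, n_in, n_removed) {
  stopifnot(n_in >= n_removed)
  x$provenance <- rbind(x$provenance, data.frame(
    step = step, n_in = as.integer(n_in), n_removed = as.integer(n_removed),
    n_out = as.integer(n_in - n_removed), stringsAsFactors = FALSE))
  x
}

# Subset a report_set to the reports named by `keep_ids` (character vector of
# primary_id). Does not touch provenance.
subset_reports <- function(x, keep_ids) {
  x$demo <- x$demo[x$demo$primary_id %in% keep_ids, , drop = FALSE]
  x$drugs <- x$drugs[x$drugs$primary_id %in% keep_ids, , drop = FALSE]
  x$reactions <- x$reactions[x$reactions$primary_id %in% keep_ids, , drop = FALSE]
  rownames(x$demo) <- rownames(x$drugs) <- rownames(x$reactions) <- NULL
  x
}
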