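#' Analysis configuration for drug-drug interaction signal detection
#'
#' Bundles the exposure definitions and statistical settings of a
#' case/non-case disproportionality analysis: the target drug whose
#' single-exposure reports form the reference group, the comparator drugs
#' (each analyzed alone and in combination with the target), the MedDRA
#' preferred-term code defining the event, the confidence level, the
#' minimum case count of the signal rule, and the synonym dictionary used
#' for name normalization.
#'
#' @param target Canonical name of the reference drug.
#' @param comparators Character vector of canonical comparator drug names;
#'   must not contain the target.
#' @param event_pt_code MedDRA preferred-term numeric code of the event of
#'   interest (default 10047570, visual hallucination).
#' @param ci_level Confidence-interval coverage probability in (0, 1).
#' @param min_cases Minimum number of cases for signal eligibility.
#' @param dictionary A [drug_dictionary()] covering target and comparators.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(target = "voriconazole",
                            comparators = c("levodopa", "risperidone",
                                            "chlorpromazine"),
                            event_pt_code = 10047570L,
                            ci_level = 0.95,
                            min_cases = 3L,
                            dictionary = default_drug_dictionary()) {
  target <- tolower(target)
  comparators <- tolower(comparators)
  if (target %in% comparators) stop("target must not be among comparators")
  if (anyDuplicated(comparators)) stop("comparators must be distinct")
  if (!(is.numeric(ci_level) && length(ci_level) == 1L &&
        ci_level > 0 && ci_level < 1)) {
    stop("ci_level must be a single number in (0, 1)")
  }
  if (!(is.numeric(min_cases) && min_cases >= 1)) {
    stop("min_cases must be >= 1")
  }
  event_pt_code <- as.integer(event_pt_code)
  if (is.na(event_pt_code) || event_pt_code <= 0L) {
    stop("event_pt_code must be a positive integer")
  }
  structure(list(target = target, comparators = comparators,
                 event_pt_code = event_pt_code, ci_level = ci_level,
                 min_cases = as.integer(min_cases), dictionary = dictionary),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat("  target:      ", x$target, "\n")
  cat("  comparators: ", paste(x$comparators, collapse = ", "), "\n")
  cat(sprintf("  event PT code: %d | CI level: %g | min cases: %d\n",
              x$event_pt_code, x$ci_level, x$min_cases))
  invisible(x)
}

#' Exposure-group labels used by the analysis
#'
#' @param config An [analysis_config()].
#' @return Character vector: each comparator alone, then each
#'   `target+comparator` combination (the index groups, in display order).
#' @export
index_group_labels <- function(config) {
  c(config$comparators, paste0(config$target, "+", config$comparators))
}

#' Assign each report to an exposure group
#'
#' Let S be the set of study drugs (target plus comparators) present in a
#' report. Assignment: S = \{target\} gives `"reference"`; S = one
#' comparator gives that comparator's single-drug group; S = \{target, one
#' comparator\} gives the `"target+comparator"` combination group; any
#' other S with two or more study drugs gives `"excluded"` (groups must be
#' disjoint); an empty S gives `"none"` (not in the analysis). Drugs
#' outside the study set never affect assignment.
#'
#' @param x A [report_set()] with normalized drugs.
#' @param config An [analysis_config()].
#' @return Character vector of group labels, one per report, named by
#'   `primary_id` and aligned with `x$demo`.
#' @export
assign_groups <- function(x, config) {
  stopifnot(inherits(x, "report_set"), inherits(config, "analysis_config"))
  d <- x$drugs
  study <- !is.na(d$ingredient) &
    d$ingredient %in% c(config$target, config$comparators)
  u <- unique(d[study, c("primary_id", "ingredient")])
  group_from_exposure(x$demo$primary_id, u$primary_id, u$ingredient, config)
}

# Shared assignment kernel: `pid` are all report ids; (`exp_pid`, `exp_ing`)
# are distinct report-by-study-drug exposure pairs.
group_from_exposure <- function(pid, exp_pid, exp_ing, config) {
  n_study <- tabulate(factor(exp_pid, levels = pid), nbins = length(pid))
  target_pids <- exp_pid[exp_ing == config$target]
  has_target <- pid %in% target_pids
  n_comp <- n_study - as.integer(has_target)

  comp_pid <- exp_pid[exp_ing != config$target]
  comp_ing <- exp_ing[exp_ing != config$target]
  single <- !(duplicated(comp_pid) | duplicated(comp_pid, fromLast = TRUE))
  comp_of <- comp_ing[single][match(pid, comp_pid[single])]

  out <- rep("excluded", length(pid))
  out[n_study == 0L] <- "none"
  out[has_target & n_comp == 0L] <- "reference"
  i <- !has_target & n_comp == 1L
  out[i] <- comp_of[i]
  i <- has_target & n_comp == 1L
  out[i] <- paste0(config$target, "+", comp_of[i])
  names(out) <- pid
  out
}

#' Build 2x2 case/non-case tables per index group
#'
#' A report is a case iff any of its reactions carries the configured event
#' preferred-term code (set semantics: a term listed twice counts once).
#' One table is produced per index group, all sharing the reference group's
#' case/non-case margin (`c`, `d`).
#'
#' @param x A [report_set()].
#' @param groups Group labels as returned by [assign_groups()] (recomputed
#'   when `NULL`).
#' @param config An [analysis_config()].
#' @return Data frame with columns `group`, `a`, `b`, `c`, `d`: cases and
#'   non-cases in the index group, then in the reference group. Index
#'   groups with no reports get `a = b = 0`.
#' @export
build_contingency <- function(x, config, groups = NULL) {
  stopifnot(inherits(x, "report_set"), inherits(config, "analysis_config"))
  if (is.null(groups)) groups <- assign_groups(x, config)
  stopifnot(length(groups) == nrow(x$demo))

  case_ids <- unique(x$reactions$primary_id[
    !is.na(x$reactions$pt_code) &
      x$reactions$pt_code == config$event_pt_code])
  is_case <- x$demo$primary_id %in% case_ids

  ref <- groups == "reference"
  if (!any(ref)) stop("configuration error: reference group is empty")
  cc <- sum(ref & is_case)
  dd <- sum(ref & !is_case)

  labs <- index_group_labels(config)
  a <- vapply(labs, function(g) sum(groups == g & is_case), integer(1))
  b <- vapply(labs, function(g) sum(groups == g & !is_case), integer(1))
  data.frame(group = labs, a = unname(a), b = unname(b),
             c = cc, d = dd, stringsAsFactors = FALSE, row.names = NULL)
}

#' Reporting odds ratio
#'
#' Point estimate `(a*d) / (b*c)` from a 2x2 case/non-case table. Undefined
#' (`NA`) when any cell is zero — no continuity correction is applied.
#'
#' @param a,b Cases and non-cases in the index group.
#' @param c,d Cases and non-cases in the reference group.
#' @return Numeric vector of odds ratios (`NA` where undefined).
#' @export
ror <- function(a, b, c, d) {
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ifelse(ok, (a * d) / (b * c), NA_real_)
}

#' Woolf (log-normal) confidence interval for the reporting odds ratio
#'
#' `exp(log(ROR) -/+ z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the exact
#' two-sided standard-normal quantile for the requested level. Undefined
#' (`NA` bounds) when any cell is zero. The interval is symmetric on the
#' log scale: `sqrt(lower * upper)` equals the point estimate.
#'
#' @inheritParams ror
#' @param level Coverage probability in (0, 1).
#' @return Data frame with columns `lower` and `upper`.
#' @export
woolf_ci <- function(a, b, c, d, level = 0.95) {
  stopifnot(level > 0, level < 1)
  est <- ror(a, b, c, d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(lower = exp(log(est) - z * se), upper = exp(log(est) + z * se))
}

#' Wald test on the log reporting odds ratio
#'
#' Two-sided p-value `2 * (1 - Phi(|log(ROR)| / SE))` with
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. Undefined (`NA`) when any cell is
#' zero. For an ROR above one, `p < 1 - level` holds exactly when the
#' lower Woolf bound at `level` exceeds one (both derive from the same z
#' statistic).
#'
#' @inheritParams ror
#' @return Numeric vector of two-sided p-values.
#' @export
wald_p <- function(a, b, c, d) {
  est <- ror(a, b, c, d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  2 * stats::pnorm(-abs(log(est)) / se)
}

#' Event occurrence as a percentage of non-cases
#'
#' Computed as `100 * a / b` — cases per hundred non-cases, not per hundred
#' reports — and rounded half-up to one decimal. This matches the reporting
#' convention of the analysis the package reproduces (e.g. 3 cases against
#' 17 non-cases is 17.6); it is an idiosyncrasy, not the usual proportion.
#' Zero cases give 0; a zero non-case count with cases present is undefined.
#'
#' @inheritParams ror
#' @return Numeric vector of percentages to one decimal.
#' @export
occurrence_pct <- function(a, b) {
  out <- ifelse(a == 0, 0, ifelse(b > 0, round_half_up(100 * a / b, 1),
                                  NA_real_))
  out
}

#' Disproportionality signal rule
#'
#' A result is a signal iff it is defined (all four cells positive), the
#' lower confidence bound exceeds one, and the case count reaches the
#' configured minimum (default three).
#'
#' @param ci_low Lower confidence bound (`NA` when undefined).
#' @param n_cases Case count `a`.
#' @param min_cases Minimum case count.
#' @return Logical vector.
#' @export
is_signal <- function(ci_low, n_cases, min_cases = 3L) {
  !is.na(ci_low) & ci_low > 1 & n_cases >= min_cases
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (the convention used
#' for the displayed tables), unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
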