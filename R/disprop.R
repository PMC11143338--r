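#' Fit a case/non-case disproportionality analysis
#'
#' The central estimator of the package: for each index exposure group it
#' computes the reporting odds ratio against the shared reference group,
#' the Woolf confidence interval, the Wald p-value on the log odds ratio,
#' the occurrence percentage, and the signal flag (lower bound above one
#' with at least `min_cases` cases). Groups with any zero cell have
#' undefined statistics, rendered as dashes.
#'
#' @param x Either a data frame of 2x2 tables with columns `group`, `a`,
#'   `b`, `c`, `d` (as from [build_contingency()]), or a [report_set()],
#'   in which case groups and tables are built first.
#' @param ... Passed to methods.
#' @return An object of class `disprop_ror` with components `tables` (the
#'   2x2 counts), `estimates` (one row per index group with `cases`,
#'   `non_cases`, `ror`, `ci_low`, `ci_high`, `p_value`, `occurrence_pct`,
#'   `defined`, `signal`), `reference` (reference-group cases/non-cases),
#'   `ci_level`, `min_cases` and `call`.
#' @seealso [print.disprop_ror()], [summary.disprop_ror()]
#' @examples
#' tabs <- data.frame(group = "levodopa", a = 1582, b = 89228,
#'                    c = 323, d = 22516)
#' fit <- disprop_ror(tabs)
#' coef(fit)
#' confint(fit)
#' @export
disprop_ror <- function(x, ...) UseMethod("disprop_ror")

#' @rdname disprop_ror
#' @param ci_level Confidence-interval coverage probability.
#' @param min_cases Minimum case count of the signal rule.
#' @export
disprop_ror.data.frame <- function(x, ci_level = 0.95, min_cases = 3L, ...) {
  required <- c("group", "a", "b", "c", "d")
  if (!all(required %in% names(x))) {
    stop("tables must have columns ", paste(required, collapse = ", "))
  }
  if (any(x[required[-1]] < 0)) stop("cell counts must be non-negative")
  est <- with(x, {
    ci <- woolf_ci(a, b, c, d, level = ci_level)
    data.frame(group = group, cases = a, non_cases = b,
               ror = ror(a, b, c, d),
               ci_low = ci$lower, ci_high = ci$upper,
               p_value = wald_p(a, b, c, d),
               occurrence_pct = occurrence_pct(a, b),
               defined = a > 0 & b > 0 & c > 0 & d > 0,
               stringsAsFactors = FALSE)
  })
  est$signal <- is_signal(est$ci_low, est$cases, min_cases)
  structure(list(tables = x, estimates = est,
                 reference = c(cases = x$c[1L], non_cases = x$d[1L]),
                 ci_level = ci_level, min_cases = as.integer(min_cases),
                 call = match.call()),
            class = "disprop_ror")
}

#' @rdname disprop_ror
#' @param config An [analysis_config()]; supplies `ci_level` and
#'   `min_cases` for the report-set method.
#' @param groups Optional precomputed group labels from [assign_groups()].
#' @export
disprop_ror.report_set <- function(x, config = analysis_config(),
                                   groups = NULL, ...) {
  tabs <- build_contingency(x, config, groups = groups)
  fit <- disprop_ror(tabs, ci_level = config$ci_level,
                     min_cases = config$min_cases, ...)
  fit$call <- match.call()
  fit
}

#' Format a disproportionality fit as a display table
#'
#' Renders the fitted estimates the way disproportionality tables are
#' printed: a reference row, RORs and CI bounds rounded half-up to three
#' decimals, p-values to three decimals with `"<0.001"` below that
#' precision, and dashes for undefined (zero-cell) statistics.
#'
#' @param x A `disprop_ror` fit.
#' @param ... Unused.
#' @return Character data frame with columns `exposure`, `cases`,
#'   `non_cases`, `ror_ci` and `p_value`.
#' @export
format.disprop_ror <- function(x, ...) {
  e <- x$estimates
  fmt3 <- function(v) sprintf("%.3f", round_half_up(v, 3))
  ror_ci <- ifelse(e$defined,
                   paste0(fmt3(e$ror), " (", fmt3(e$ci_low), "-",
                          fmt3(e$ci_high), ")"),
                   "-")
  pv <- ifelse(!e$defined, "-",
               ifelse(e$p_value < 0.0005, "<0.001", fmt3(e$p_value)))
  rbind(
    data.frame(exposure = "reference", cases = x$reference[["cases"]],
               non_cases = x$reference[["non_cases"]],
               ror_ci = "reference", p_value = "reference",
               stringsAsFactors = FALSE),
    data.frame(exposure = e$group, cases = e$cases, non_cases = e$non_cases,
               ror_ci = ror_ci, p_value = pv, stringsAsFactors = FALSE))
}

#' @export
print.disprop_ror <- function(x, ...) {
  cat(sprintf(
    "Case/non-case disproportionality analysis (ROR, Woolf %g%% CI)\n",
    100 * x$ci_level))
  print(format(x), row.names = FALSE)
  sig <- x$estimates$group[x$estimates$signal]
  cat(sprintf("signal rule: lower CI bound > 1 and >= %d cases -> %s\n",
              x$min_cases,
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}

#' Summarize a disproportionality fit
#'
#' @param object A `disprop_ror` fit.
#' @param ... Unused.
#' @return Object of class `summary.disprop_ror`: the estimates data frame
#'   plus reference counts and settings.
#' @export
summary.disprop_ror <- function(object, ...) {
  structure(list(estimates = object$estimates,
                 reference = object$reference,
                 ci_level = object$ci_level, min_cases = object$min_cases),
            class = "summary.disprop_ror")
}

#' @export
print.summary.disprop_ror <- function(x, ...) {
  cat(sprintf("reference group: %d cases / %d non-cases\n",
              x$reference[["cases"]], x$reference[["non_cases"]]))
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.disprop_ror <- function(object, ...) {
  stats::setNames(object$estimates$ror, object$estimates$group)
}

#' @export
confint.disprop_ror <- function(object, parm, level = NULL, ...) {
  e <- object$estimates
  if (is.null(level) || level == object$ci_level) {
    ci <- cbind(lower = e$ci_low, upper = e$ci_high)
  } else {
    t <- object$tables
    w <- woolf_ci(t$a, t$b, t$c, t$d, level = level)
    ci <- cbind(lower = w$lower, upper = w$upper)
  }
  rownames(ci) <- e$group
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
as.data.frame.disprop_ror <- function(x, ...) {
  x$estimates
}
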