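#' Demographics summary per exposure group
#'
#' Summarizes each exposure group the way baseline tables of spontaneous
#' reporting studies are laid out: sex counts with percentages, age and
#' weight medians with interquartile ranges (computed over non-missing
#' values by linear interpolation between order statistics), unknown counts
#' with percentages, and a country frequency table showing the top-N
#' countries by reference-group frequency plus `Others` and `Unknown` rows.
#'
#' @param x A [report_set()].
#' @param groups Group labels from [assign_groups()], aligned with reports.
#' @param group_order Which groups to summarize, in order; defaults to
#'   reference followed by every index group present in `groups`.
#' @param top_countries Number of named country rows (default 10).
#' @return Object of class `faers_demographics`: a list with one summary
#'   per group (`n`, `sex`, `age`, `weight`, `country`). Empty groups have
#'   their numeric summaries marked not computable (`NA`).
#' @export
demographics_table <- function(x, groups, group_order = NULL,
                               top_countries = 10L) {
  stopifnot(inherits(x, "report_set"), length(groups) == nrow(x$demo))
  if (is.null(group_order)) {
    present <- unique(groups)
    group_order <- c("reference", setdiff(present, c("reference", "none",
                                                     "excluded")))
  }

  ref_country <- x$demo$country[groups == "reference"]
  named <- table(ref_country[ref_country != "unknown"])
  named <- names(sort(named, decreasing = TRUE))
  named <- utils::head(named, top_countries)

  out <- lapply(group_order, function(g) {
    d <- x$demo[groups == g, , drop = FALSE]
    summarize_group(d, named)
  })
  names(out) <- group_order
  structure(out, class = "faers_demographics")
}

summarize_group <- function(d, named_countries) {
  n <- nrow(d)
  pct <- function(k) if (n == 0) NA_real_ else round_half_up(100 * k / n, 1)

  sex_lvls <- c("female", "male", "unknown")
  sex_n <- vapply(sex_lvls, function(s) sum(d$sex == s), integer(1))
  sex <- data.frame(sex = sex_lvls, n = unname(sex_n),
                    pct = pct(unname(sex_n)), stringsAsFactors = FALSE)

  num_summary <- function(v) {
    known <- v[!is.na(v)]
    if (length(known) == 0L) {
      list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
           unknown_n = n, unknown_pct = pct(n))
    } else {
      q <- unname(stats::quantile(known, c(0.25, 0.5, 0.75), type = 7))
      list(median = q[2], q1 = q[1], q3 = q[3],
           unknown_n = n - length(known), unknown_pct = pct(n - length(known)))
    }
  }

  cn <- vapply(named_countries, function(co) sum(d$country == co), integer(1))
  other <- sum(!(d$country %in% c(named_countries, "unknown")))
  unk <- sum(d$country == "unknown")
  country <- data.frame(
    country = c(named_countries, "Others", "Unknown"),
    n = c(unname(cn), other, unk),
    pct = pct(c(unname(cn), other, unk)),
    stringsAsFactors = FALSE)

  list(n = n, sex = sex, age = num_summary(d$age_years),
       weight = num_summary(d$weight_kg), country = country)
}

#' @export
print.faers_demographics <- function(x, ...) {
  for (g in names(x)) {
    s <- x[[g]]
    cat(sprintf("== %s (n = %d) ==\n", g, s$n))
    if (s$n == 0L) next
    cat("  sex: ", paste(sprintf("%s %d (%.1f%%)", s$sex$sex, s$sex$n,
                                 s$sex$pct), collapse = ", "), "\n")
    fmt_num <- function(lab, u, v) {
      if (is.na(v$median)) {
        cat(sprintf("  %s: unknown (%d unknown, %.1f%%)\n", lab,
                    v$unknown_n, v$unknown_pct))
      } else {
        cat(sprintf("  %s: median %.1f %s [IQR %.1f-%.1f], %d unknown (%.1f%%)\n",
                    lab, v$median, u, v$q1, v$q3, v$unknown_n, v$unknown_pct))
      }
    }
    fmt_num("age", "y", s$age)
    fmt_num("weight", "kg", s$weight)
    top <- utils::head(s$country[s$country$n > 0, , drop = FALSE], 5L)
    if (nrow(top)) {
      cat("  countries:", paste(sprintf("%s %d (%.1f%%)", top$country,
                                        top$n, top$pct), collapse = ", "),
          "\n")
    }
  }
  invisible(x)
}
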