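#' Run the full signal-detection pipeline on raw FAERS-dialect tables
#'
#' Executes the complete data-collection and analysis flow: ingest the four
#' quarterly tables, normalize drug names, keep the most recent report per
#' case, exclude reports where a study drug was first administered after
#' event onset (applied per study drug), assign exposure groups, build the
#' case/non-case tables, and fit the disproportionality statistics. Every
#' filtering step is logged with `(n_in, n_removed, n_out)` so the data
#' flow can be regenerated mechanically, and every input report ends in
#' exactly one terminal category.
#'
#' @param raw_dir Directory containing `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `THER.txt`; alternatively pass an ingested set via `reports`.
#' @param config An [analysis_config()].
#' @param reports A [report_set()] to analyze instead of reading `raw_dir`.
#' @param top_countries Rows in the demographics country table.
#' @return Object of class `faers_analysis`: list with `fit` (a
#'   [disprop_ror()] object), `demographics`, `provenance`, `disposition`
#'   (terminal category counts), `groups`, `reports` (the analyzed set) and
#'   `config`.
#' @export
run_faers_pipeline <- function(raw_dir = NULL, config = analysis_config(),
                               reports = NULL, top_countries = 10L) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(reports)) {
    if (is.null(raw_dir)) stop("supply raw_dir or reports")
    paths <- file.path(raw_dir, c("DEMO.txt", "DRUG.txt", "REAC.txt",
                                  "THER.txt"))
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files)) {
      stop("read stage: input table(s) not found: ",
           paste(basename(missing_files), collapse = ", "))
    }
    reports <- read_faers_quarter(paths[1], paths[2], paths[3], paths[4])
  }
  stopifnot(inherits(reports, "report_set"))
  n_input <- n_reports(reports)

  x <- normalize_drugs(reports, config$dictionary)

  dd <- deduplicate(x)
  x <- dd$kept
  n_dup <- n_reports(dd$removed)

  n_post <- 0L
  for (ing in c(config$target, config$comparators)) {
    pe <- exclude_post_event(x, ing)
    x <- pe$kept
    n_post <- n_post + n_reports(pe$removed)
  }

  groups <- assign_groups(x, config)
  fit <- disprop_ror(x, config, groups = groups)
  demographics <- demographics_table(x, groups, top_countries = top_countries)

  analyzed <- c("reference", index_group_labels(config))
  disposition <- c(
    stats::setNames(vapply(analyzed, function(g) sum(groups == g),
                           integer(1)), paste0("analyzed:", analyzed)),
    `excluded:duplicate` = n_dup,
    `excluded:post_event` = n_post,
    `excluded:other_drug` = sum(groups == "excluded"),
    `not_in_analysis` = sum(groups == "none"))
  stopifnot(sum(disposition) == n_input)

  structure(list(fit = fit, demographics = demographics,
                 provenance = provenance(x), disposition = disposition,
                 groups = groups, reports = x, config = config),
            class = "faers_analysis")
}

#' @export
print.faers_analysis <- function(x, ...) {
  cat("FAERS-style disproportionality pipeline\n\n")
  cat("report disposition:\n")
  print(data.frame(category = names(x$disposition),
                   n = unname(x$disposition)), row.names = FALSE)
  cat("\n")
  print(x$fit)
  invisible(x)
}

#' Write pipeline outputs as plain-text tables
#'
#' Emits `results.tsv` (exposure, cases, non_cases, ror, ci_low, ci_high,
#' p_value, occurrence_pct, signal; undefined statistics as `-`),
#' `demographics.txt` and `provenance.log` into `out_dir`. Output is
#' deterministic: identical analyses produce byte-identical files.
#'
#' @param x A `faers_analysis` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(x, out_dir) {
  stopifnot(inherits(x, "faers_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  e <- x$fit$estimates
  fmt3 <- function(v, defined) ifelse(defined, sprintf("%.3f",
                                                       round_half_up(v, 3)), "-")
  res <- data.frame(
    exposure = c("reference", e$group),
    cases = c(x$fit$reference[["cases"]], e$cases),
    non_cases = c(x$fit$reference[["non_cases"]], e$non_cases),
    ror = c("reference", fmt3(e$ror, e$defined)),
    ci_low = c("reference", fmt3(e$ci_low, e$defined)),
    ci_high = c("reference", fmt3(e$ci_high, e$defined)),
    p_value = c("reference",
                ifelse(!e$defined, "-",
                       ifelse(e$p_value < 0.0005, "<0.001",
                              sprintf("%.3f", round_half_up(e$p_value, 3))))),
    occurrence_pct = c("", sprintf("%.1f", e$occurrence_pct)),
    signal = c("", ifelse(e$signal, "yes", "no")),
    stringsAsFactors = FALSE)
  res_path <- file.path(out_dir, "results.tsv")
  utils::write.table(res, res_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  demo_path <- file.path(out_dir, "demographics.txt")
  con <- file(demo_path, open = "wt")
  sink(con); print(x$demographics); sink(); close(con)

  prov_path <- file.path(out_dir, "provenance.log")
  pv <- x$provenance
  disp <- sprintf("disposition %s n=%d", names(x$disposition),
                  unname(x$disposition))
  writeLines(c(sprintf("step=%s n_in=%d n_removed=%d n_out=%d",
                       pv$step, pv$n_in, pv$n_removed, pv$n_out), disp),
             prov_path)
  invisible(c(results = res_path, demographics = demo_path,
              provenance = prov_path))
}

#' Read an analysis configuration from a YAML file
#'
#' Schema: scalar keys `target`, `event_pt_code`, `ci_level`, `min_cases`;
#' sequence `comparators`; mapping `dictionary` from canonical ingredient
#' to a list of synonyms. Missing keys fall back to the
#' [analysis_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- analysis_config()
  dict <- if (!is.null(y$dictionary)) {
    do.call(drug_dictionary, lapply(y$dictionary, as.character))
  } else {
    defaults$dictionary
  }
  analysis_config(
    target = y$target %||% defaults$target,
    comparators = as.character(y$comparators %||% defaults$comparators),
    event_pt_code = y$event_pt_code %||% defaults$event_pt_code,
    ci_level = y$ci_level %||% defaults$ci_level,
    min_cases = y$min_cases %||% defaults$min_cases,
    dictionary = dict)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
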