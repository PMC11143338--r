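#' Drug synonym dictionary
#'
#' A dictionary maps each canonical active ingredient (lower-case) to the
#' set of verbatim strings — generic names, brand names, salt forms,
#' fixed-dose combination spellings — that identify it in drug-name fields.
#' Matching in [normalize_drugs()] is case-insensitive on whole
#' semicolon-separated field components.
#'
#' @param ... Named character vectors: `canonical = c("synonym", ...)`.
#'   The canonical name itself is always included as a synonym.
#' @return An object of class `drug_dictionary` (a named list).
#' @examples
#' drug_dictionary(voriconazole = c("vfend"))
#' @export
drug_dictionary <- function(...) {
  d <- list(...)
  if (length(d) == 0L) stop("dictionary must contain at least one ingredient")
  if (is.null(names(d)) || any(names(d) == "")) {
    stop("every dictionary entry must be named by its canonical ingredient")
  }
  names(d) <- tolower(names(d))
  d <- lapply(seq_along(d), function(i) {
    unique(c(names(d)[i], tolower(trimws(as.character(d[[i]])))))
  }) |> stats::setNames(tolower(names(d)))
  all_syn <- unlist(d, use.names = FALSE)
  if (anyDuplicated(all_syn)) {
    dup <- unique(all_syn[duplicated(all_syn)])
    stop("synonym sets must be pairwise disjoint across ingredients; ",
         "shared: ", paste(dup, collapse = ", "))
  }
  structure(d, class = "drug_dictionary")
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat(sprintf("<drug_dictionary> %d ingredients\n", length(x)))
  for (ing in names(x)) {
    cat(sprintf("  %s: %s\n", ing, paste(x[[ing]], collapse = ", ")))
  }
  invisible(x)
}

#' Default dictionary for the voriconazole / dopaminergic-drug analysis
#'
#' Covers voriconazole (incl. VFEND), levodopa (incl. the common fixed-dose
#' carbidopa and benserazide combinations — an inclusion assumption, see the
#' package vignette), risperidone (incl. RISPERDAL) and chlorpromazine
#' (incl. THORAZINE, LARGACTIL). Fully overridable: pass any
#' [drug_dictionary()] to the preprocessing and analysis functions.
#'
#' @return A `drug_dictionary`.
#' @export
default_drug_dictionary <- function() {
  drug_dictionary(
    voriconazole = c("vfend", "voriconazol"),
    levodopa = c("l-dopa", "carbidopa\\levodopa", "carbidopa/levodopa",
                 "levodopa/carbidopa", "levodopa\\carbidopa",
                 "benserazide/levodopa", "levodopa/benserazide",
                 "carbidopa and levodopa", "sinemet", "madopar", "stalevo",
                 "rytary", "duopa"),
    risperidone = c("risperdal", "risperdal consta", "perseris"),
    chlorpromazine = c("thorazine", "largactil",
                       "chlorpromazine hydrochloride")
  )
}

#' Normalize drug names against a dictionary
#'
#' Assigns each drug entry its canonical `ingredient`: the active-ingredient
#' field (`prod_ai`) is tried first, then the verbatim drug name, matched
#' case-insensitively on whole semicolon-separated components. Entries
#' matching no synonym are marked unmapped (`mapped = FALSE`,
#' `ingredient = NA`) and their reports are retained.
#'
#' @param x A [report_set()].
#' @param dictionary A [drug_dictionary()].
#' @return `x` with `ingredient` and `mapped` filled in on the drugs table
#'   and a provenance row counting unmapped entries.
#' @export
normalize_drugs <- function(x, dictionary = default_drug_dictionary()) {
  stopifnot(inherits(x, "report_set"))
  if (!inherits(dictionary, "drug_dictionary")) {
    dictionary <- do.call(drug_dictionary, as.list(dictionary))
  }
  lookup <- stats::setNames(
    rep(names(dictionary), lengths(dictionary)),
    unlist(dictionary, use.names = FALSE))

  ing <- match_drug_field(x$drugs$prod_ai, lookup)
  miss <- is.na(ing)
  ing[miss] <- match_drug_field(x$drugs$verbatim_name[miss], lookup)

  x$drugs$ingredient <- ing
  x$drugs$mapped <- !is.na(ing)
  log_step(x, "normalize_drugs_unmapped_entries", nrow(x$drugs), sum(is.na(ing)))
}

# Match one character field vector against the synonym lookup. Fast path:
# whole-field match; fields containing ';' fall back to per-component
# matching, first matching component wins (field order).
match_drug_field <- function(v, lookup) {
  key <- trimws(tolower(as.character(v)))
  out <- unname(lookup[key])
  multi <- is.na(out) & grepl(";", key, fixed = TRUE)
  if (any(multi)) {
    out[multi] <- vapply(strsplit(key[multi], ";", fixed = TRUE),
      function(parts) {
        hits <- lookup[trimws(parts)]
        hits <- hits[!is.na(hits)]
        if (length(hits)) hits[[1L]] else NA_character_
      }, character(1))
  }
  out
}
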