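#' Read one quarter of FAERS-dialect ASCII tables
#'
#' Reads the four `$`-delimited tables of the public FAERS quarterly ASCII
#' distribution (post-2012 column set) and assembles one report per distinct
#' `primaryid` in DEMO, joining drugs (and their therapy start dates via
#' `drug_seq`/`dsg_drug_seq`) and reactions by `primaryid`.
#'
#' @details
#' Required columns: DEMO carries `primaryid`, `caseid`, `fda_dt`,
#' `event_dt`, `sex`, `age`, `age_cod`, `wt`, `wt_cod`, `occr_country`;
#' DRUG carries `primaryid`, `drug_seq`, `drugname`, `prod_ai`, `role_cod`;
#' REAC carries `primaryid`, `pt`; THER carries `primaryid`,
#' `dsg_drug_seq`, `start_dt`. A missing required column is a fatal format
#' error naming the file and the column.
#'
#' Ages are normalized to years from `age_cod` (`YR`, `MON`, `DY`; months
#' and days use a 365.25-day year), weights to kilograms from `wt_cod`
#' (`KG`, `LBS`, `GMS`); unrecognized codes yield a missing value.
#' Unparsable dates are set to missing and counted in provenance, never
#' fatal. Partial dates (`YYYY`, `YYYYMM`) are padded to the first
#' day/month and flagged through the precision columns.
#'
#' The `pt` field of REAC is parsed as a MedDRA preferred-term numeric code
#' when it is all digits, otherwise it is kept as a term name with a missing
#' code (the public files ship names; code-keyed extracts and the synthetic
#' generator ship codes — event matching downstream is by code).
#'
#' DRUG/REAC/THER rows whose `primaryid` does not appear in DEMO are
#' dropped and counted in provenance, as are DEMO rows without any drug row.
#'
#' @param demo_path,drug_path,reac_path,ther_path Paths to the four tables.
#' @return A [report_set()].
#' @export
read_faers_quarter <- function(demo_path, drug_path, reac_path, ther_path) {
  demo_raw <- read_faers_table(demo_path,
    c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age", "age_cod",
      "wt", "wt_cod", "occr_country"))
  drug_raw <- read_faers_table(drug_path,
    c("primaryid", "drug_seq", "drugname", "prod_ai", "role_cod"))
  reac_raw <- read_faers_table(reac_path, c("primaryid", "pt"))
  ther_raw <- read_faers_table(ther_path,
    c("primaryid", "dsg_drug_seq", "start_dt"))

  pv <- data.frame(step = character(), n_in = integer(),
                   n_removed = integer(), n_out = integer(),
                   stringsAsFactors = FALSE)
  add <- function(step, n_in, n_removed) {
    rbind(pv, data.frame(step = step, n_in = as.integer(n_in),
                         n_removed = as.integer(n_removed),
                         n_out = as.integer(n_in - n_removed),
                         stringsAsFactors = FALSE))
  }

  # one report per distinct primaryid
  dup_demo <- duplicated(demo_raw$primaryid)
  if (any(dup_demo)) {
    pv <- add("demo_duplicate_primaryid", nrow(demo_raw), sum(dup_demo))
    demo_raw <- demo_raw[!dup_demo, , drop = FALSE]
  }

  rec <- parse_faers_date(demo_raw$fda_dt)
  evt <- parse_faers_date(demo_raw$event_dt)
  n_bad_dates <- sum(rec$bad) + sum(evt$bad)
  pv <- add("demo_unparsable_dates", 2L * nrow(demo_raw), n_bad_dates)

  age_years <- normalize_age(demo_raw$age, demo_raw$age_cod)
  weight_kg <- normalize_weight(demo_raw$wt, demo_raw$wt_cod)

  demo <- data.frame(
    primary_id = demo_raw$primaryid,
    case_id = demo_raw$caseid,
    receipt_date = rec$date, receipt_prec = rec$prec,
    event_date = evt$date, event_prec = evt$prec,
    sex = normalize_sex(demo_raw$sex),
    age_years = age_years,
    weight_kg = weight_kg,
    country = ifelse(trimws(demo_raw$occr_country) == "", "unknown",
                     trimws(demo_raw$occr_country)),
    stringsAsFactors = FALSE)

  # drop orphan rows (primaryid absent from DEMO)
  orphan <- !(drug_raw$primaryid %in% demo$primary_id)
  pv <- add("drug_orphan_rows", nrow(drug_raw), sum(orphan))
  drug_raw <- drug_raw[!orphan, , drop = FALSE]
  orphan <- !(reac_raw$primaryid %in% demo$primary_id)
  pv <- add("reac_orphan_rows", nrow(reac_raw), sum(orphan))
  reac_raw <- reac_raw[!orphan, , drop = FALSE]
  orphan <- !(ther_raw$primaryid %in% demo$primary_id)
  pv <- add("ther_orphan_rows", nrow(ther_raw), sum(orphan))
  ther_raw <- ther_raw[!orphan, , drop = FALSE]

  # therapy start: earliest parsable start_dt per (primaryid, drug_seq)
  st <- parse_faers_date(ther_raw$start_dt)
  pv <- add("ther_unparsable_dates", nrow(ther_raw), sum(st$bad))
  ther_key <- paste(ther_raw$primaryid, ther_raw$dsg_drug_seq, sep = "\r")
  keep_st <- !is.na(st$date)
  start_by_key <- if (any(keep_st)) {
    o <- order(ther_key[keep_st], st$date[keep_st])
    k <- ther_key[keep_st][o]
    first <- !duplicated(k)
    data.frame(key = k[first], start_date = st$date[keep_st][o][first],
               start_prec = st$prec[keep_st][o][first],
               stringsAsFactors = FALSE)
  } else {
    data.frame(key = character(), start_date = integer(),
               start_prec = character(), stringsAsFactors = FALSE)
  }

  drug_key <- paste(drug_raw$primaryid, drug_raw$drug_seq, sep = "\r")
  m <- match(drug_key, start_by_key$key)
  drugs <- data.frame(
    primary_id = drug_raw$primaryid,
    drug_seq = suppressWarnings(as.integer(drug_raw$drug_seq)),
    verbatim_name = drug_raw$drugname,
    prod_ai = drug_raw$prod_ai,
    role = normalize_role(drug_raw$role_cod),
    start_date = start_by_key$start_date[m],
    start_prec = ifelse(is.na(m), "missing", start_by_key$start_prec[m]),
    ingredient = NA_character_,
    mapped = NA,
    stringsAsFactors = FALSE)

  pt <- trimws(reac_raw$pt)
  is_code <- grepl("^[0-9]+$", pt)
  reactions <- data.frame(
    primary_id = reac_raw$primaryid,
    pt_code = ifelse(is_code, suppressWarnings(as.integer(pt)), NA_integer_),
    pt_name = ifelse(is_code, "", pt),
    stringsAsFactors = FALSE)

  # reports must carry at least one drug
  no_drug <- !(demo$primary_id %in% drugs$primary_id)
  pv <- add("demo_without_drug_rows", nrow(demo), sum(no_drug))
  demo <- demo[!no_drug, , drop = FALSE]
  reactions <- reactions[reactions$primary_id %in% demo$primary_id, , drop = FALSE]
  drugs <- drugs[drugs$primary_id %in% demo$primary_id, , drop = FALSE]

  rownames(demo) <- rownames(drugs) <- rownames(reactions) <- NULL
  report_set(demo, drugs, reactions, pv)
}

read_faers_table <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "$", header = TRUE, quote = "",
                          comment.char = "", colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = character(0), blank.lines.skip = TRUE)
  names(df) <- tolower(trimws(names(df)))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("format error in %s: missing required column '%s'",
                 basename(path), missing_cols[[1L]]))
  }
  df
}

normalize_sex <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unknown", length(x))
  out[x == "F"] <- "female"
  out[x == "M"] <- "male"
  out
}

normalize_role <- function(x) {
  x <- toupper(trimws(x))
  out <- rep("unknown", length(x))
  out[x %in% c("PS", "SS")] <- "suspect"
  out[x == "C"] <- "concomitant"
  out[x == "I"] <- "interacting"
  out
}

normalize_age <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(trimws(age)))
  cod <- toupper(trimws(age_cod))
  out <- rep(NA_real_, length(v))
  out[cod == "YR"] <- v[cod == "YR"]
  out[cod == "DEC"] <- v[cod == "DEC"] * 10
  out[cod == "MON"] <- v[cod == "MON"] / 12
  out[cod == "WK"] <- v[cod == "WK"] * 7 / 365.25
  out[cod == "DY"] <- v[cod == "DY"] / 365.25
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

normalize_weight <- function(wt, wt_cod) {
  v <- suppressWarnings(as.numeric(trimws(wt)))
  cod <- toupper(trimws(wt_cod))
  out <- rep(NA_real_, length(v))
  out[cod == "KG"] <- v[cod == "KG"]
  out[cod == "LBS"] <- v[cod == "LBS"] * 0.45359237
  out[cod == "GMS"] <- v[cod == "GMS"] / 1000
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Write a report set as FAERS-dialect ASCII tables
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt` in the same
#' `$`-delimited dialect that [read_faers_quarter()] consumes, so that a
#' freshly ingested set round-trips field-for-field (missing values included).
#' Ages are written in years (`YR`), weights in kilograms (`KG`); partial
#' dates are written at their original precision; a THER row is emitted only
#' for drug entries with a present therapy start date. The canonical
#' `ingredient` column is not part of the dialect and is therefore not
#' serialized; re-run [normalize_drugs()] after reading.
#'
#' @param x A [report_set()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_faers_quarter <- function(x, out_dir) {
  stopifnot(inherits(x, "report_set"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  num <- function(v) ifelse(is.na(v), "", formatC(v, format = "g", digits = 15))
  sex_code <- c(female = "F", male = "M", unknown = "")

  demo_out <- data.frame(
    primaryid = x$demo$primary_id,
    caseid = x$demo$case_id,
    fda_dt = format_faers_date(x$demo$receipt_date, x$demo$receipt_prec),
    event_dt = format_faers_date(x$demo$event_date, x$demo$event_prec),
    sex = sex_code[x$demo$sex],
    age = num(x$demo$age_years),
    age_cod = ifelse(is.na(x$demo$age_years), "", "YR"),
    wt = num(x$demo$weight_kg),
    wt_cod = ifelse(is.na(x$demo$weight_kg), "", "KG"),
    occr_country = ifelse(x$demo$country == "unknown", "", x$demo$country),
    stringsAsFactors = FALSE)

  role_code <- c(suspect = "PS", concomitant = "C", interacting = "I",
                 unknown = "")
  drug_out <- data.frame(
    primaryid = x$drugs$primary_id,
    drug_seq = x$drugs$drug_seq,
    drugname = x$drugs$verbatim_name,
    prod_ai = x$drugs$prod_ai,
    role_cod = role_code[x$drugs$role],
    stringsAsFactors = FALSE)

  reac_out <- data.frame(
    primaryid = x$reactions$primary_id,
    pt = ifelse(is.na(x$reactions$pt_code), x$reactions$pt_name,
                as.character(x$reactions$pt_code)),
    stringsAsFactors = FALSE)

  has_start <- !is.na(x$drugs$start_date)
  ther_out <- data.frame(
    primaryid = x$drugs$primary_id[has_start],
    dsg_drug_seq = x$drugs$drug_seq[has_start],
    start_dt = format_faers_date(x$drugs$start_date[has_start],
                                 x$drugs$start_prec[has_start]),
    stringsAsFactors = FALSE)

  paths <- c(DEMO = file.path(out_dir, "DEMO.txt"),
             DRUG = file.path(out_dir, "DRUG.txt"),
             REAC = file.path(out_dir, "REAC.txt"),
             THER = file.path(out_dir, "THER.txt"))
  write_dollar_table(demo_out, paths[["DEMO"]])
  write_dollar_table(drug_out, paths[["DRUG"]])
  write_dollar_table(reac_out, paths[["REAC"]])
  write_dollar_table(ther_out, paths[["THER"]])
  invisible(paths)
}

write_dollar_table <- function(df, path) {
  for (col in names(df)) {
    if (any(grepl("[$\n]", df[[col]]))) {
      stop("field value contains the '$' delimiter or a newline in column ",
           col, "; the dialect has no quoting")
    }
  }
  utils::write.table(df, path, sep = "$", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
}
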