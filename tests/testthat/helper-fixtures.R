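# In-code fixtures: tiny report sets and raw FAERS-dialect files built at
# test time. No binary or stored data.

new_demo <- function(pid, case = pid, receipt = NA_integer_,
                     event = NA_integer_, sex = "unknown",
                     age = NA_real_, wt = NA_real_, country = "unknown") {
  n <- length(pid)
  data.frame(
    primary_id = as.character(pid),
    case_id = rep_len(as.character(case), n),
    receipt_date = rep_len(as.integer(receipt), n),
    receipt_prec = ifelse(is.na(rep_len(receipt, n)), "missing", "day"),
    event_date = rep_len(as.integer(event), n),
    event_prec = ifelse(is.na(rep_len(event, n)), "missing", "day"),
    sex = rep_len(sex, n), age_years = rep_len(as.numeric(age), n),
    weight_kg = rep_len(as.numeric(wt), n),
    country = rep_len(country, n), stringsAsFactors = FALSE)
}

new_drugs <- function(pid, name, prod_ai = toupper(name), seq = NULL,
                      role = "suspect", start = NA_integer_) {
  n <- length(pid)
  if (is.null(seq)) seq <- stats::ave(seq_len(n), pid, FUN = seq_along)
  data.frame(
    primary_id = as.character(pid), drug_seq = as.integer(seq),
    verbatim_name = rep_len(name, n),
    prod_ai = rep_len(prod_ai, n), role = rep_len(role, n),
    start_date = rep_len(as.integer(start), n),
    start_prec = ifelse(is.na(rep_len(start, n)), "missing", "day"),
    ingredient = NA_character_, mapped = NA, stringsAsFactors = FALSE)
}

new_reac <- function(pid, code) {
  data.frame(primary_id = as.character(pid),
             pt_code = as.integer(code), pt_name = "",
             stringsAsFactors = FALSE)
}

# A 3-report set: voriconazole-alone case report (event), levodopa report,
# voriconazole+levodopa report.
tiny_set <- function() {
  demo <- new_demo(c("1", "2", "3"), receipt = c(20200110, 20200111, 20200112),
                   event = c(20200101, 20200102, 20200103))
  drugs <- rbind(
    new_drugs("1", "VFEND", "VORICONAZOLE", seq = 1),
    new_drugs("2", "LEVODOPA", seq = 1),
    new_drugs("3", "VORICONAZOLE", seq = 1),
    new_drugs("3", "LEVODOPA", seq = 2))
  reac <- new_reac(c("1", "2", "3"), c(10047570, 10000001, 10000002))
  report_set(demo, drugs, reac)
}

# Raw $-delimited quarter with one orphan DRUG row, a partial event date,
# unit conversions, and a name-valued REAC entry.
write_raw_quarter <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(
    "primaryid$caseid$fda_dt$event_dt$sex$age$age_cod$wt$wt_cod$occr_country",
    "1001$C1$20200115$20200105$F$57$YR$64$KG$US",
    "1002$C2$20210301$2020$M$24$MON$154.32$LBS$"),
    file.path(dir, "DEMO.txt"))
  writeLines(c(
    "primaryid$drug_seq$drugname$prod_ai$role_cod",
    "1001$1$VFEND$VORICONAZOLE$PS",
    "1001$2$SOME OTHER MED$$C",
    "1002$1$CARBIDOPA\\LEVODOPA$$SS",
    "9999$1$GHOST$$PS"),
    file.path(dir, "DRUG.txt"))
  writeLines(c(
    "primaryid$pt",
    "1001$10047570",
    "1002$Headache"),
    file.path(dir, "REAC.txt"))
  writeLines(c(
    "primaryid$dsg_drug_seq$start_dt",
    "1001$1$20200103",
    "1002$1$202001"),
    file.path(dir, "THER.txt"))
  dir
}

study_config <- function(...) analysis_config(...)

# Simulation settings with complete dates, for exact oracle agreement.
complete_date_config <- function(n_cases = 2000L, ...) {
  simulation_config(
    n_cases = n_cases,
    demo_missing_rates = c(sex = 0.10, age = 0.25, weight = 0.70,
                           country = 0.05, event_date = 0,
                           therapy_start = 0),
    ...)
}
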