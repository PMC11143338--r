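#' Configuration for the synthetic FAERS-like report generator
#'
#' Defines the statistical structure of a simulated spontaneous-reporting
#' extract: exposure prevalences for a target drug and its comparators,
#' a baseline event probability in the reference (target-alone) group,
#' group-specific true reporting-odds multipliers, duplicate-report and
#' post-event therapy-start rates, a non-study "other drug" rate,
#' demographic missingness and country weights. The generator gives every
#' downstream stage a known ground truth without access to the real
#' database.
#'
#' @param n_cases Number of distinct cases (case ids) to simulate.
#' @param duplicate_rate Probability that a case has two or more report
#'   versions; a duplicated case gets `1 + Geometric(0.5)` extra versions,
#'   capped at five reports total.
#' @param post_event_rate Probability, for a target-exposed case with a
#'   known event date, that the target therapy start postdates the event.
#' @param exposure_probs Named numeric: marginal exposure probability per
#'   study drug. The first name is the target unless `target` is given.
#' @param co_exposure_probs Named numeric of joint excess probabilities for
#'   drug pairs, named `"drugA+drugB"`; with that probability both drugs
#'   are forced present on top of the independent draws.
#' @param baseline_event_prob Event probability among reference-exposed
#'   cases.
#' @param odds_multiplier Named numeric of true reporting-odds multipliers
#'   by group label (e.g. `c("voriconazole+levodopa" = 12)`); unnamed
#'   groups have multiplier 1. A group's event odds are
#'   `multiplier * baseline_odds`.
#' @param other_drug_rate Probability a case carries an additional
#'   non-study drug (a single synthetic ingredient, `OTHERMED`).
#' @param demo_missing_rates Named numeric missingness probabilities for
#'   `sex`, `age`, `weight`, `country`, `event_date`, `therapy_start`.
#' @param country_weights Named positive weights for country sampling
#'   (normalized internally).
#' @param target Canonical name of the target drug.
#' @param seed Integer RNG seed (may also be passed to [simulate_faers()]).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_cases = 10000L,
    duplicate_rate = 0.17,
    post_event_rate = 0.03,
    exposure_probs = c(voriconazole = 0.10, levodopa = 0.08,
                       risperidone = 0.09, chlorpromazine = 0.02),
    co_exposure_probs = NULL,
    baseline_event_prob = 0.014,
    odds_multiplier = NULL,
    other_drug_rate = 0.30,
    demo_missing_rates = c(sex = 0.10, age = 0.25, weight = 0.70,
                           country = 0.05, event_date = 0.05,
                           therapy_start = 0.15),
    country_weights = c(US = 0.40, JP = 0.10, FR = 0.08, GB = 0.06,
                        DE = 0.05, CA = 0.04, IT = 0.03, ES = 0.03,
                        NL = 0.02, AU = 0.02, BR = 0.04, CN = 0.04,
                        IN = 0.04, KR = 0.03, SE = 0.02),
    target = names(exposure_probs)[1L],
    seed = NULL) {
  cfg <- structure(list(
    n_cases = as.integer(n_cases), duplicate_rate = duplicate_rate,
    post_event_rate = post_event_rate, exposure_probs = exposure_probs,
    co_exposure_probs = co_exposure_probs %||% stats::setNames(numeric(0),
                                                               character(0)),
    baseline_event_prob = baseline_event_prob,
    odds_multiplier = odds_multiplier %||% stats::setNames(numeric(0),
                                                           character(0)),
    other_drug_rate = other_drug_rate,
    demo_missing_rates = demo_missing_rates,
    country_weights = country_weights, target = tolower(target),
    seed = seed), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  chk01 <- function(v, what) {
    if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
      stop("invalid simulation config: ", what, " must lie in [0, 1]")
    }
  }
  if (is.na(cfg$n_cases) || cfg$n_cases < 1L) {
    stop("invalid simulation config: n_cases must be >= 1")
  }
  chk01(cfg$duplicate_rate, "duplicate_rate")
  chk01(cfg$post_event_rate, "post_event_rate")
  chk01(cfg$exposure_probs, "exposure_probs")
  chk01(cfg$co_exposure_probs, "co_exposure_probs")
  chk01(cfg$baseline_event_prob, "baseline_event_prob")
  chk01(cfg$other_drug_rate, "other_drug_rate")
  chk01(cfg$demo_missing_rates, "demo_missing_rates")
  if (any(cfg$odds_multiplier <= 0)) {
    stop("invalid simulation config: odds multipliers must be > 0")
  }
  if (is.null(names(cfg$exposure_probs)) ||
      !(cfg$target %in% tolower(names(cfg$exposure_probs)))) {
    stop("invalid simulation config: target must be a named exposure drug")
  }
  if (any(cfg$country_weights <= 0)) {
    stop("invalid simulation config: country_weights must be positive")
  }
  req <- c("sex", "age", "weight", "country", "event_date", "therapy_start")
  if (!all(req %in% names(cfg$demo_missing_rates))) {
    stop("invalid simulation config: demo_missing_rates must name ",
         paste(req, collapse = ", "))
  }
  invisible(cfg)
}

# Integer day (Date epoch) -> YYYYMMDD integer, via one lookup over the
# value range; cheap even for hundreds of thousands of dates.
day2ymd <- function(day) {
  r <- range(day, na.rm = TRUE)
  days <- seq(r[1], r[2])
  ymd <- as.integer(format(as.Date(days, origin = "1970-01-01"), "%Y%m%d"))
  out <- ymd[day - r[1] + 1L]
  out
}

#' Generate a synthetic FAERS-like report set with ground truth
#'
#' Simulates spontaneous reports under the structure described in
#' [simulation_config()]: case-level drug exposures (independent draws plus
#' optional pairwise excess), a group assignment identical in logic to
#' [assign_groups()], a case-level event indicator whose odds are the
#' group's multiplier times the baseline odds (so deduplication does not
#' bias event frequency — duplicates copy the case), therapy start dates at
#' or before event onset except for the configured fraction of target
#' exposures that strictly postdate it, duplicate report versions with
#' strictly increasing receipt dates (the last-received version is
#' canonical), demographic missingness and country sampling. Identical
#' `(config, seed)` pairs produce identical output.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; overrides `config$seed`.
#' @return A list of class `faers_sim` with `reports` (a [report_set()] of
#'   raw, un-deduplicated reports) and `truth` (a data frame with one row
#'   per report: `primary_id`, `case_id`, `group`, `event`,
#'   `is_duplicate`, `is_post_event`, `canonical`).
#' @export
simulate_faers <- function(config = simulation_config(), seed = config$seed) {
  validate_simulation_config(config)
  if (is.null(seed)) stop("a seed is required for reproducible generation")
  set.seed(as.integer(seed))

  n <- config$n_cases
  drugs <- tolower(names(config$exposure_probs))
  k <- length(drugs)
  target <- config$target
  mr <- config$demo_missing_rates

  # --- case-level exposures -------------------------------------------------
  E <- matrix(stats::runif(n * k) < rep(config$exposure_probs, each = n),
              nrow = n, ncol = k, dimnames = list(NULL, drugs))
  for (pair in names(config$co_exposure_probs)) {
    both <- tolower(strsplit(pair, "+", fixed = TRUE)[[1L]])
    if (length(both) != 2L || !all(both %in% drugs)) {
      stop("co_exposure_probs pair '", pair, "' must name two study drugs")
    }
    force_on <- stats::runif(n) < config$co_exposure_probs[[pair]]
    E[force_on, both] <- TRUE
  }
  other <- stats::runif(n) < config$other_drug_rate
  other[rowSums(E) == 0L & !other] <- TRUE  # every report carries >= 1 drug

  # --- group labels and event indicator ------------------------------------
  idx <- which(E, arr.ind = TRUE)
  group <- group_from_exposure(seq_len(n), idx[, 1L], drugs[idx[, 2L]],
                               list(target = target))
  names(group) <- NULL
  mult <- rep(1, n)
  has_m <- group %in% names(config$odds_multiplier)
  mult[has_m] <- config$odds_multiplier[group[has_m]]
  base_odds <- config$baseline_event_prob / (1 - config$baseline_event_prob)
  p_event <- mult * base_odds / (1 + mult * base_odds)
  event <- stats::runif(n) < p_event

  # --- case-level dates -----------------------------------------------------
  d0 <- as.integer(as.Date("2004-01-01"))
  d1 <- as.integer(as.Date("2023-03-31"))
  ev_day <- d0 + floor(stats::runif(n) * (d1 - d0 + 1))
  ev_missing <- stats::runif(n) < mr[["event_date"]]
  post_event <- E[, target] & !ev_missing &
    stats::runif(n) < config$post_event_rate
  receipt0 <- ev_day + stats::rpois(n, 30) + 1L

  # --- case-level demographics ---------------------------------------------
  sex <- ifelse(stats::runif(n) < 0.45, "female", "male")
  sex[stats::runif(n) < mr[["sex"]]] <- "unknown"
  age <- round(pmin(pmax(stats::rnorm(n, 58, 18), 0), 100))
  age[stats::runif(n) < mr[["age"]]] <- NA_real_
  weight <- round(pmin(pmax(stats::rnorm(n, 70, 15), 30), 150), 1)
  weight[stats::runif(n) < mr[["weight"]]] <- NA_real_
  cw <- config$country_weights / sum(config$country_weights)
  country <- sample(names(cw), n, replace = TRUE, prob = cw)
  country[stats::runif(n) < mr[["country"]]] <- "unknown"

  # --- case-level drug rows -------------------------------------------------
  start_day <- rep(NA_integer_, nrow(idx))
  case_of_row <- idx[, 1L]
  drug_of_row <- drugs[idx[, 2L]]
  is_target_row <- drug_of_row == target
  pe_row <- is_target_row & post_event[case_of_row]
  # at-or-before-event starts (uniform within the year before onset);
  # cases with unknown onset anchor on the report window instead
  anchor <- ifelse(ev_missing[case_of_row],
                   d0 + floor(stats::runif(nrow(idx)) * (d1 - d0 + 1)),
                   ev_day[case_of_row])
  start_day <- anchor - floor(stats::runif(nrow(idx)) * 366)
  start_day[pe_row] <- ev_day[case_of_row[pe_row]] +
    1L + floor(stats::runif(sum(pe_row)) * 90)
  start_missing <- stats::runif(nrow(idx)) < mr[["therapy_start"]] & !pe_row
  start_day[start_missing] <- NA_integer_

  cd <- data.frame(case = case_of_row, drug = drug_of_row,
                   role = ifelse(is_target_row, "suspect", "concomitant"),
                   start_day = start_day, stringsAsFactors = FALSE)
  if (any(other)) {
    cd <- rbind(cd, data.frame(case = which(other), drug = "othermed",
                               role = "unknown", start_day = NA_integer_,
                               stringsAsFactors = FALSE))
  }
  cd <- cd[order(cd$case), , drop = FALSE]

  # --- case-level reactions -------------------------------------------------
  event_code <- 10047570L
  bg_pool <- setdiff(10000001L:10000030L, event_code)
  n_bg <- sample(1:3, n, replace = TRUE)
  rx <- data.frame(case = rep(seq_len(n), n_bg),
                   pt_code = sample(bg_pool, sum(n_bg), replace = TRUE))
  if (any(event)) {
    rx <- rbind(data.frame(case = which(event), pt_code = event_code), rx)
  }
  rx <- rx[order(rx$case), , drop = FALSE]

  # --- expand cases to report versions (duplicates) ------------------------
  dup <- stats::runif(n) < config$duplicate_rate
  extras <- integer(n)
  if (any(dup)) extras[dup] <- pmin(1L + stats::rgeom(sum(dup), 0.5), 4L)
  n_ver <- 1L + extras
  case_idx <- rep(seq_len(n), n_ver)
  version <- sequence(n_ver)
  N <- length(case_idx)

  gap <- ifelse(version == 1L, 0L, 1L + stats::rpois(N, 20))
  cs <- cumsum(as.numeric(gap))
  first <- version == 1L
  base <- cs[first]  # gap at version 1 is 0
  receipt_day <- receipt0[case_idx] + as.integer(cs - base[case_idx])

  primary_id <- as.character(10000000L + seq_len(N))
  case_id <- as.character(90000000L + case_idx)
  canonical <- version == n_ver[case_idx]

  ev_rep <- ifelse(ev_missing[case_idx], NA_integer_, ev_day[case_idx])
  all_days <- c(receipt_day, ev_rep, cd$start_day)
  ymd_all <- rep(NA_integer_, length(all_days))
  ok <- !is.na(all_days)
  ymd_all[ok] <- day2ymd(all_days[ok])
  receipt_ymd <- ymd_all[seq_len(N)]
  event_ymd <- ymd_all[N + seq_len(N)]
  start_ymd <- ymd_all[2L * N + seq_len(nrow(cd))]

  demo <- data.frame(
    primary_id = primary_id, case_id = case_id,
    receipt_date = receipt_ymd, receipt_prec = "day",
    event_date = event_ymd,
    event_prec = ifelse(is.na(event_ymd), "missing", "day"),
    sex = sex[case_idx], age_years = age[case_idx],
    weight_kg = weight[case_idx], country = country[case_idx],
    stringsAsFactors = FALSE)

  # expand case-level drug/reaction rows to every report version
  expand <- function(tbl, value_cols) {
    kc <- tabulate(tbl$case, nbins = n)
    o <- c(0L, cumsum(kc))  # row offset of each case within tbl
    rep_row <- rep(seq_len(N), kc[case_idx])
    within <- sequence(kc[case_idx])
    tbl_i <- rep(o[case_idx], kc[case_idx]) + within
    cbind(data.frame(primary_id = primary_id[rep_row], seq = within,
                     stringsAsFactors = FALSE),
          tbl[tbl_i, value_cols, drop = FALSE])
  }

  dr <- expand(cd, c("drug", "role", "start_day"))
  dr_start_ymd <- rep(NA_integer_, nrow(dr))
  okd <- !is.na(dr$start_day)
  if (any(okd)) dr_start_ymd[okd] <- day2ymd(dr$start_day[okd])
  drugs_df <- data.frame(
    primary_id = dr$primary_id, drug_seq = dr$seq,
    verbatim_name = toupper(dr$drug),
    prod_ai = ifelse(dr$drug == "othermed", "", toupper(dr$drug)),
    role = dr$role,
    start_date = dr_start_ymd,
    start_prec = ifelse(is.na(dr_start_ymd), "missing", "day"),
    ingredient = NA_character_, mapped = NA, stringsAsFactors = FALSE)

  rr <- expand(rx, "pt_code")
  reactions_df <- data.frame(primary_id = rr$primary_id,
                             pt_code = rr$pt_code, pt_name = "",
                             stringsAsFactors = FALSE)
  rownames(demo) <- rownames(drugs_df) <- rownames(reactions_df) <- NULL

  truth <- data.frame(
    primary_id = primary_id, case_id = case_id,
    group = group[case_idx], event = event[case_idx],
    is_duplicate = !canonical, is_post_event = post_event[case_idx],
    canonical = canonical, stringsAsFactors = FALSE)

  structure(list(reports = report_set(demo, drugs_df, reactions_df),
                 truth = truth, config = config),
            class = "faers_sim")
}

#' @export
print.faers_sim <- function(x, ...) {
  cat(sprintf("<faers_sim> %d reports from %d cases\n",
              nrow(x$truth), x$config$n_cases))
  print(table(x$truth$group[x$truth$canonical]))
  invisible(x)
}

#' Brute-force contingency tables from simulation ground truth
#'
#' Enumerates the canonical (non-duplicate), non-post-event reports of a
#' ground-truth table and tallies case/non-case counts per exposure group
#' against the reference group. This is the independent oracle for
#' [build_contingency()]: no pipeline code is involved, only direct
#' counting over truth flags.
#'
#' @param truth Ground-truth data frame from [simulate_faers()] (the
#'   `truth` component), or a `faers_sim` object.
#' @param groups Index-group labels to tabulate, in order; defaults to all
#'   groups present other than `reference`, `none` and `excluded`.
#' @return Data frame with columns `group`, `a`, `b`, `c`, `d` and
#'   `realized_ror`. Empty when the truth table has no rows.
#' @export
realized_tables <- function(truth, groups = NULL) {
  if (inherits(truth, "faers_sim")) truth <- truth$truth
  sub <- truth[truth$canonical & !truth$is_post_event, , drop = FALSE]
  sub <- sub[!(sub$group %in% c("none", "excluded")), , drop = FALSE]
  if (is.null(groups)) {
    groups <- sort(setdiff(unique(sub$group), "reference"))
  }
  if (nrow(sub) == 0L || length(groups) == 0L) {
    return(data.frame(group = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(),
                      realized_ror = numeric(), stringsAsFactors = FALSE))
  }
  cc <- sum(sub$group == "reference" & sub$event)
  dd <- sum(sub$group == "reference" & !sub$event)
  a <- vapply(groups, function(g) sum(sub$group == g & sub$event), integer(1))
  b <- vapply(groups, function(g) sum(sub$group == g & !sub$event), integer(1))
  data.frame(group = groups, a = unname(a), b = unname(b), c = cc, d = dd,
             realized_ror = ror(unname(a), unname(b), cc, dd),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a simulated report set plus ground truth to disk
#'
#' Emits the four FAERS-dialect tables via [write_faers_quarter()] and a
#' tab-delimited `ground_truth.tsv` (intended for tests only, not part of
#' the analysis dialect).
#'
#' @param sim A `faers_sim` object.
#' @param out_dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_sim <- function(sim, out_dir) {
  stopifnot(inherits(sim, "faers_sim"))
  paths <- write_faers_quarter(sim$reports, out_dir)
  gt <- file.path(out_dir, "ground_truth.tsv")
  utils::write.table(sim$truth, gt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, ground_truth = gt))
}
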