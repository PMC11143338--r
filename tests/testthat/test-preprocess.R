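test_that("deduplicate keeps the most recent report per case", {
  # distinct cases: everything kept
  x <- tiny_set()
  out <- deduplicate(x)
  expect_equal(n_reports(out$kept), 3L)
  expect_equal(n_reports(out$removed), 0L)

  # same case, different receipt dates: later one kept
  demo <- new_demo(c("10", "11"), case = "C", receipt = c(20200101, 20210101))
  x <- report_set(demo, new_drugs(c("10", "11"), "VFEND"),
                  new_reac(c("10", "11"), 1))
  out <- deduplicate(x)
  expect_equal(out$kept$demo$primary_id, "11")

  # receipt-date tie: greatest primary_id wins (zero-padded comparison)
  demo <- new_demo(c("9", "10"), case = "C", receipt = 20200101)
  x <- report_set(demo, new_drugs(c("9", "10"), "VFEND"),
                  new_reac(c("9", "10"), 1))
  out <- deduplicate(x)
  expect_equal(out$kept$demo$primary_id, "10")

  # missing receipt date sorts before any present date
  demo <- new_demo(c("20", "21"), case = "C",
                   receipt = c(NA, 20000101))
  x <- report_set(demo, new_drugs(c("20", "21"), "VFEND"),
                  new_reac(c("20", "21"), 1))
  out <- deduplicate(x)
  expect_equal(out$kept$demo$primary_id, "21")
})

test_that("deduplicate partitions its input, is idempotent and order-robust", {
  sim <- simulate_faers(simulation_config(n_cases = 400L), seed = 3L)
  x <- sim$reports
  out <- deduplicate(x)
  expect_equal(n_reports(out$kept) + n_reports(out$removed), n_reports(x))
  expect_length(intersect(out$kept$demo$primary_id,
                          out$removed$demo$primary_id), 0L)
  # idempotent
  again <- deduplicate(out$kept)
  expect_equal(n_reports(again$removed), 0L)
  expect_equal(sort(again$kept$demo$primary_id),
               sort(out$kept$demo$primary_id))
  # invariant to input ordering
  perm <- withr::with_seed(99, sample(n_reports(x)))
  xs <- x
  xs$demo <- xs$demo[perm, ]
  rownames(xs$demo) <- NULL
  out2 <- deduplicate(xs)
  expect_setequal(out2$kept$demo$primary_id, out$kept$demo$primary_id)
})

test_that("deduplicate agrees with generator ground truth", {
  sim <- simulate_faers(simulation_config(n_cases = 1500L), seed = 21L)
  out <- deduplicate(sim$reports)
  canonical <- sim$truth$primary_id[sim$truth$canonical]
  expect_setequal(out$kept$demo$primary_id, canonical)
})

test_that("post-event exclusion removes strictly-after starts only", {
  mk <- function(start, event) {
    x <- report_set(new_demo("1", receipt = 20200201, event = event),
                    new_drugs("1", "VFEND", "VORICONAZOLE", start = start),
                    new_reac("1", 1))
    normalize_drugs(x)
  }
  # start after event: removed
  out <- exclude_post_event(mk(20200110, 20200105), "voriconazole")
  expect_equal(n_reports(out$removed), 1L)
  # same-day start: kept (not strictly after)
  out <- exclude_post_event(mk(20200105, 20200105), "voriconazole")
  expect_equal(n_reports(out$removed), 0L)
  # missing start or event date: conservatively kept
  out <- exclude_post_event(mk(NA, 20200105), "voriconazole")
  expect_equal(n_reports(out$removed), 0L)
  out <- exclude_post_event(mk(20200110, NA), "voriconazole")
  expect_equal(n_reports(out$removed), 0L)
  # the drug itself must be present for the rule to bite
  x <- normalize_drugs(report_set(
    new_demo("1", event = 20200105),
    new_drugs("1", "LEVODOPA", start = 20200110),
    new_reac("1", 1)))
  out <- exclude_post_event(x, "voriconazole")
  expect_equal(n_reports(out$removed), 0L)
})

test_that("earliest therapy start decides post-event status", {
  x <- report_set(
    new_demo("1", event = 20200105),
    rbind(new_drugs("1", "VFEND", "VORICONAZOLE", seq = 1, start = 20200110),
          new_drugs("1", "VORICONAZOLE", seq = 2, start = 20200101)),
    new_reac("1", 1))
  x <- normalize_drugs(x)
  out <- exclude_post_event(x, "voriconazole")
  expect_equal(n_reports(out$removed), 0L)  # earliest start predates event
})

test_that("post-event exclusion partitions, is idempotent, matches ground truth", {
  sim <- simulate_faers(complete_date_config(n_cases = 1500L), seed = 8L)
  x <- normalize_drugs(sim$reports)
  out <- exclude_post_event(x, "voriconazole")
  expect_equal(n_reports(out$kept) + n_reports(out$removed), n_reports(x))
  again <- exclude_post_event(out$kept, "voriconazole")
  expect_equal(n_reports(again$removed), 0L)
  flagged <- sim$truth$primary_id[sim$truth$is_post_event]
  expect_setequal(out$removed$demo$primary_id, flagged)
})

test_that("drug-name normalization matches the dictionary as specified", {
  dict <- drug_dictionary(
    voriconazole = c("vfend"),
    levodopa = c("carbidopa\\levodopa", "carbidopa/levodopa"))

  x <- report_set(
    new_demo(c("1", "2", "3", "4")),
    rbind(new_drugs("1", "VFEND", ""),
          new_drugs("2", "CARBIDOPA\\LEVODOPA", ""),
          new_drugs("3", "MYSTERYDRUG", ""),
          # prod_ai wins over verbatim name; semicolon components match whole
          new_drugs("4", "SOME BRAND", "PARACETAMOL; VORICONAZOLE")),
    new_reac(c("1", "2", "3", "4"), 1))
  x <- normalize_drugs(x, dict)
  d <- x$drugs[order(x$drugs$primary_id), ]
  expect_equal(d$ingredient, c("voriconazole", "levodopa", NA, "voriconazole"))
  expect_equal(d$mapped, c(TRUE, TRUE, FALSE, TRUE))
  # unmapped drugs never drop the report
  expect_equal(n_reports(x), 4L)
  pv <- provenance(x)
  expect_equal(pv$n_removed[pv$step == "normalize_drugs_unmapped_entries"], 1L)
})

test_that("overlapping synonym sets are rejected", {
  expect_error(drug_dictionary(a = c("x"), b = c("x")), "disjoint")
  # canonical name colliding with another ingredient's synonym also overlaps
  expect_error(drug_dictionary(a = character(0), b = c("a")), "disjoint")
})
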