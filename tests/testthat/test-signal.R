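# Published 2x2 tables used throughout: index (a, b) vs reference (c, d).
ref <- c(c = 323, d = 22516)
tab_levodopa <- c(a = 1582, b = 89228, ref)
tab_combo <- c(a = 3, b = 17, ref)
tab_risp_combo <- c(a = 2, b = 81, ref)

test_that("ror reproduces the published point estimates and zero-cell rule", {
  expect_equal(round_half_up(do.call(ror, as.list(tab_levodopa)), 3), 1.236)
  expect_equal(round_half_up(do.call(ror, as.list(tab_combo)), 3), 12.302)
  # identity: equal odds in both groups
  expect_equal(ror(7, 13, 7, 13), 1)
  expect_equal(ror(2, 5, 8, 20), 1)
  # any zero cell is undefined, no continuity correction
  expect_true(is.na(ror(0, 26, 323, 22516)))
  expect_true(is.na(ror(5, 0, 3, 7)))
})

test_that("woolf_ci reproduces the published bounds and collapses as level -> 0", {
  ci <- do.call(woolf_ci, as.list(tab_combo))
  expect_equal(round_half_up(ci$lower, 3), 3.587)
  expect_equal(round_half_up(ci$upper, 3), 42.183)
  ci <- do.call(woolf_ci, as.list(tab_levodopa))
  expect_equal(round_half_up(ci$lower, 3), 1.096)
  expect_equal(round_half_up(ci$upper, 3), 1.394)
  # interval collapses to the point estimate in the level -> 0 limit
  ci <- woolf_ci(12, 34, 56, 78, level = 1e-12)
  expect_equal(ci$lower, ror(12, 34, 56, 78), tolerance = 1e-6)
  expect_equal(ci$upper, ror(12, 34, 56, 78), tolerance = 1e-6)
  expect_true(is.na(woolf_ci(0, 26, 323, 22516)$lower))
})

test_that("wald_p reproduces the published p-values", {
  expect_equal(round_half_up(do.call(wald_p, as.list(tab_risp_combo)), 3), 0.449)
  expect_equal(round_half_up(do.call(wald_p, as.list(tab_levodopa)), 3), 0.001)
  expect_lt(do.call(wald_p, as.list(tab_combo)), 0.001)
  expect_equal(wald_p(9, 21, 9, 21), 1)
  expect_true(is.na(wald_p(0, 26, 323, 22516)))
})

test_that("occurrence percentage uses the cases-per-non-cases convention", {
  expect_equal(occurrence_pct(3, 17), 17.6)
  expect_equal(occurrence_pct(1582, 89228), 1.8)
  expect_equal(occurrence_pct(0, 26), 0)
})

test_that("signal rule needs a lower bound above one AND enough cases", {
  expect_true(is_signal(ci_low = 3.587, n_cases = 3))
  expect_false(is_signal(ci_low = 0.421, n_cases = 2))
  expect_false(is_signal(ci_low = 1.5, n_cases = 2))   # case clause alone
  expect_false(is_signal(ci_low = 0.9, n_cases = 100)) # CI clause alone
  expect_false(is_signal(ci_low = NA_real_, n_cases = 50))
})

test_that("antisymmetry: swapping index and reference inverts ROR and CI", {
  set.seed(101)
  for (i in 1:25) {
    t <- sample(1:500, 4, replace = TRUE)
    expect_equal(ror(t[1], t[2], t[3], t[4]),
                 1 / ror(t[3], t[4], t[1], t[2]))
    ci <- woolf_ci(t[1], t[2], t[3], t[4])
    ci_sw <- woolf_ci(t[3], t[4], t[1], t[2])
    expect_equal(ci$lower, 1 / ci_sw$upper)
    expect_equal(ci$upper, 1 / ci_sw$lower)
  }
})

test_that("CI and Wald test are coherent and the interval is log-symmetric", {
  set.seed(202)
  for (i in 1:50) {
    t <- sample(1:400, 4, replace = TRUE)
    est <- ror(t[1], t[2], t[3], t[4])
    ci <- woolf_ci(t[1], t[2], t[3], t[4], level = 0.95)
    p <- wald_p(t[1], t[2], t[3], t[4])
    # sqrt(lower * upper) == ROR within 1e-9 relative tolerance
    expect_equal(sqrt(ci$lower * ci$upper), est, tolerance = 1e-9)
    # for ROR > 1: lower bound above 1 iff p < 0.05 (same z statistic)
    if (est > 1) expect_identical(ci$lower > 1, p < 0.05)
  }
  # monotonicity: one more case strictly increases the ROR
  expect_true(all(ror(2:50, 77, 31, 1000) > ror(1:49, 77, 31, 1000)))
})

test_that("group assignment follows the exposure-set rules", {
  cfg <- analysis_config()
  mk <- function(drug_names) {
    pids <- rep("1", length(drug_names))
    x <- report_set(new_demo("1"),
                    new_drugs(pids, drug_names, toupper(drug_names)),
                    new_reac("1", 1))
    assign_groups(normalize_drugs(x, cfg$dictionary), cfg)[["1"]]
  }
  expect_equal(mk("VORICONAZOLE"), "reference")
  expect_equal(mk("LEVODOPA"), "levodopa")
  expect_equal(mk(c("VORICONAZOLE", "LEVODOPA")), "voriconazole+levodopa")
  expect_equal(mk(c("LEVODOPA", "RISPERIDONE")), "excluded")
  expect_equal(mk(c("VORICONAZOLE", "LEVODOPA", "RISPERIDONE")), "excluded")
  expect_equal(mk("ASPIRIN"), "none")
  # non-study drugs never affect assignment
  expect_equal(mk(c("VORICONAZOLE", "ASPIRIN")), "reference")
  expect_equal(mk(c("VORICONAZOLE", "LEVODOPA", "ASPIRIN")),
               "voriconazole+levodopa")
  # duplicate entries of the same drug are one exposure
  expect_equal(mk(c("VORICONAZOLE", "VFEND")), "reference")
})

test_that("build_contingency counts cases by event PT with set semantics", {
  cfg <- analysis_config()
  demo <- new_demo(as.character(1:7))
  drugs <- rbind(
    new_drugs(as.character(1:5), "VORICONAZOLE"),  # reference group
    new_drugs(as.character(6:7), "LEVODOPA"))
  # reference: reports 1,2 are cases; index: report 6 is a case (PT twice)
  reac <- rbind(new_reac(c("1", "2"), 10047570),
                new_reac(c("3", "4", "5"), 10000001),
                new_reac(c("6", "6"), 10047570),
                new_reac("7", 10000002))
  x <- normalize_drugs(report_set(demo, drugs, reac), cfg$dictionary)
  tab <- build_contingency(x, cfg)
  lev <- tab[tab$group == "levodopa", ]
  expect_equal(unlist(lev[c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 1L, 2L, 3L))

  # empty reference group is a configuration error
  x2 <- normalize_drugs(report_set(new_demo("1"), new_drugs("1", "LEVODOPA"),
                                   new_reac("1", 1)), cfg$dictionary)
  expect_error(build_contingency(x2, cfg), "reference group is empty")
})

test_that("disprop_ror fit object exposes the classic accessor methods", {
  tabs <- data.frame(
    group = c("levodopa", "voriconazole+levodopa",
              "voriconazole+chlorpromazine"),
    a = c(1582, 3, 0), b = c(89228, 17, 26), c = 323, d = 22516)
  fit <- disprop_ror(tabs)
  expect_s3_class(fit, "disprop_ror")
  expect_equal(round_half_up(unname(coef(fit))[1:2], 3), c(1.236, 12.302))
  expect_true(is.na(coef(fit)[["voriconazole+chlorpromazine"]]))
  ci <- confint(fit)
  expect_equal(round_half_up(ci["voriconazole+levodopa", "lower"], 3), 3.587)

  disp <- format(fit)
  expect_equal(disp$ror_ci[disp$exposure == "voriconazole+levodopa"],
               "12.302 (3.587-42.183)")
  expect_equal(disp$p_value[disp$exposure == "voriconazole+levodopa"], "<0.001")
  expect_equal(disp$ror_ci[disp$exposure == "voriconazole+chlorpromazine"], "-")
  expect_output(print(fit), "voriconazole\\+levodopa")

  s <- summary(fit)
  expect_s3_class(s, "summary.disprop_ror")
  expect_equal(as.data.frame(fit)$cases, c(1582, 3, 0))
})
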