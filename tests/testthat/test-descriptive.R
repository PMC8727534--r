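test_that("ages convert to years across unit codes before banding", {
  expect_equal(assign_age_band(17.9, "YR"), "<18")
  expect_equal(assign_age_band(216, "MON"), "18-44")   # exactly 18 years
  expect_equal(assign_age_band(NA, ""), "Unknown")
  expect_equal(assign_age_band(c(1.7, 64, 75, 780, 9), c("DEC", "YR", "YR", "WK", "HR")),
               c("<18", "45-64", ">74", "<18", "<18"))
  expect_equal(assign_age_band(-5, "YR"), "Unknown")
})

test_that("demographics table counts, percentages and known-only denominators", {
  reps <- h_reports(
    demo = rbind(h_demo("1", age = "10", sex = "F", country = "US", occp = "MD"),
                 h_demo("2", age = "50", sex = "M", country = "GB", occp = "OT"),
                 h_demo("3", age = "70", sex = "F", country = "JP", occp = "CN"),
                 h_demo("4", age = "", age_cod = "", sex = "", country = "",
                        occp = "")),
    reac = h_reac(c("1", "2", "3", "4"), "Nausea"),
    outc = rbind(h_outc("1", "DE"), h_outc("1", "HO"), h_outc("2", "HO")))
  tab <- demographics_table(reps)

  age <- tab[tab$characteristic == "age", ]
  expect_equal(sum(age$n[age$category %in%
                           c("<18", "18-44", "45-64", "65-74", ">74",
                             "Unknown")]), 4L)
  expect_equal(age$pct[age$category == "<18"], 25)
  expect_equal(age$pct_known[age$category == "<18"],
               pct_half_up(1, 3))                     # 33.33, known-only
  expect_equal(age$n[age$category == ">=65"], 1L)

  sex <- tab[tab$characteristic == "sex", ]
  expect_equal(sex$n, c(2L, 1L, 1L))
  expect_equal(sex$pct_known[1:2], pct_half_up(c(2, 1), 3))

  region <- tab[tab$characteristic == "region", ]
  expect_equal(region$n[region$category == "North America"], 1L)
  expect_equal(region$n[region$category == "Unknown"], 1L)

  out <- tab[tab$characteristic == "outcome", ]
  expect_equal(out$n[out$category == "Hospitalization"], 2L)
  # outcomes may exceed the cohort: a case can carry several
  expect_equal(sum(out$n), 3L)
})

test_that("single-valued characteristics close to 100% and known-only >= all-cases", {
  out <- synth_faers(synthetic_params(n_reports = 2000, seed = 31),
                     dir <- tempfile("dm"))
  reps <- deduplicate_cases(assemble_reports(read_faers_tables(dir)))
  tab <- demographics_table(reps)
  for (ch in c("age", "sex", "region", "reporter")) {
    rows <- tab[tab$characteristic == ch & tab$category != ">=65", ]
    expect_lt(abs(sum(rows$pct) - 100), 0.05 * nrow(rows))
    known <- rows[!is.na(rows$pct_known) & rows$category != "Unknown", ]
    if (nrow(known)) expect_true(all(known$pct_known >= known$pct))
  }
})

test_that("outcome rates report both denominators", {
  reps <- h_reports(
    demo = h_demo(c("1", "2", "3", "4")),
    reac = h_reac(c("1", "2", "3", "4"), "Nausea"),
    outc = rbind(h_outc("1", "DE"), h_outc("2", "HO"),
                 h_outc("3", "DE"), h_outc("3", "HO")))
  r <- outcome_rates(reps)
  expect_equal(r$death_rate, 2 / 4)
  expect_equal(r$death_rate_with_outcome, 2 / 3)
  expect_equal(r$hosp_rate, 2 / 4)
  expect_false(r$undefined_with_outcome)

  r0 <- outcome_rates(h_reports(demo = h_demo("9"), reac = h_reac("9", "X")))
  expect_true(r0$undefined_with_outcome)
  expect_true(is.na(r0$death_rate_with_outcome))
})

test_that("published outcome counts give the published death and hospitalization story", {
  # cohort with the published ibuprofen outcome counts planted
  n <- 2453
  ids <- as.character(seq_len(n))
  outc <- rbind(h_outc(ids[1:178], "DE"), h_outc(ids[1:1778], "HO"),
                h_outc(ids[1:37], "DS"), h_outc(ids[1:323], "LT"),
                h_outc(ids[1:1327], "OT"), h_outc(ids[1:28], "RI"),
                h_outc(ids[1:2], "CA"))
  reps <- h_reports(demo = h_demo(ids), reac = h_reac(ids, "Anuria"),
                    outc = outc)
  r <- outcome_rates(reps)
  expect_equal(r$counts[["DE"]], 178L)
  expect_equal(r$counts[["HO"]], 1778L)
  expect_equal(pct_half_up(r$counts[["DE"]], n), 7.26)  # 178/2453, all-cases
  expect_equal(pct_half_up(r$counts[["HO"]], n), 72.48)

  cmp <- compare_rates(178, 2453, 570, 1288)
  expect_equal(cmp$test_name, "fisher_exact")
  expect_lt(cmp$p_value, 1e-4)
  expect_true(cmp$significant)
})

test_that("Fisher p equals exhaustive hypergeometric enumeration; chi2 path engages", {
  exact_fisher <- function(k1, n1, k2, n2) {
    # enumerate all tables with the same margins; two-sided by summing
    # probabilities <= observed (with fisher.test's relative tolerance)
    m <- k1 + k2
    lo <- max(0, m - n2); hi <- min(m, n1)
    pr <- dhyper(lo:hi, n1, n2, m)
    sum(pr[pr <= dhyper(k1, n1, n2, m) * (1 + 1e-7)])
  }
  expect_equal(compare_rates(5, 10, 5, 10)$p_value, 1)
  expect_equal(compare_rates(9, 10, 1, 10)$p_value, exact_fisher(9, 10, 1, 10))
  set.seed(3)
  for (i in 1:50) {
    n1 <- sample(1:15, 1); n2 <- sample(1:15, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(compare_rates(k1, n1, k2, n2)$p_value,
                 exact_fisher(k1, n1, k2, n2))
  }
  big <- compare_rates(150, 1000, 100, 1000, method = "pearson_chi2")
  expect_equal(big$test_name, "pearson_chi2")
  expect_equal(big$statistic,
               unname(chisq.test(matrix(c(150, 850, 100, 900), 2,
                                        byrow = TRUE),
                                 correct = FALSE)$statistic))
  small <- compare_rates(1, 3, 2, 3, method = "pearson_chi2")
  expect_equal(small$test_name, "fisher_exact")  # expected counts < 5
  expect_error(compare_rates(0, 0, 1, 2), "empty")
})

test_that("dose summaries reproduce the published overdose tables", {
  s <- dose_summary(ibu_doses, threshold_g = 12)
  expect_equal(s$n, 20L)
  expect_equal(s$median_grams, 12)
  expect_equal(s$count_at_or_above_threshold, 11L)

  s2 <- dose_summary(apap_doses, threshold_g = 16)
  expect_equal(s2$n, 33L)
  expect_equal(s2$count_at_or_above_threshold, 23L)
  expect_equal(s2$median_grams, 27)   # computed from the printed doses

  s3 <- dose_summary(5)
  expect_equal(s3$median_grams, 5)
  expect_equal(s3$iqr, c(5, 5))

  s4 <- dose_summary(c(NA_real_, NA_real_))
  expect_equal(s4$reason, "no dosed cases")
  expect_equal(s4$n_missing, 2L)
})

test_that("complication ranking counts non-target PTs with alphabetical tie-break", {
  ids <- as.character(1:200)
  reac <- rbind(h_reac(ids, "Acute kidney injury", code = "10069339"),
                h_reac(ids[1:174], "Vomiting"),
                h_reac(ids[1:40], "Hypotension"),
                h_reac(ids[1:40], "Metabolic acidosis"),
                h_reac(ids[1], "Vomiting"))          # duplicate within case
  reps <- h_reports(demo = h_demo(ids), reac = reac)
  rk <- complication_ranking(reps, kidney_injury_pts())
  expect_equal(rk$pt[1], "Vomiting")
  expect_equal(rk$n_cases[1], 174L)                  # per-case, not per-row
  expect_equal(rk$pt[2:3], c("Hypotension", "Metabolic acidosis"))

  none <- h_reports(demo = h_demo("1"),
                    reac = h_reac("1", "Anuria", code = "10002847"))
  expect_equal(nrow(complication_ranking(none, kidney_injury_pts())), 0L)

  # generator ground truth: planted co-occurrence counts
  out <- synth_faers(synthetic_params(n_reports = 2000, duplicate_rate = 0,
                                      seed = 19), dir <- tempfile("ck"),
                     dialect = "csv")
  reps2 <- deduplicate_cases(assemble_reports(read_faers_tables(dir)))
  coh <- build_cohorts(reps2, ibuprofen_config())
  sub <- subset_reports(reps2, coh$ibuprofen$cases)
  rk2 <- complication_ranking(sub, kidney_injury_pts(), k = Inf)
  # independent recount from the raw generated REAC table
  raw <- read.csv(file.path(dir, "REAC.csv"), colClasses = "character")
  raw <- raw[raw$PRIMARYID %in% sub$demo$primaryid &
               !(raw$PT_CODE %in% kidney_injury_pts()$code), ]
  truth <- table(raw$PT[!duplicated(paste(raw$PRIMARYID, raw$PT))])
  for (i in seq_len(nrow(rk2))) {
    expect_equal(rk2$n_cases[i], unname(as.integer(truth[rk2$pt[i]])))
  }
})
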