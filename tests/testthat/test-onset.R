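cf <- ibuprofen_config()

onset_fixture <- function(event, start) {
  h_reports(demo = h_demo("1", event = event),
            drug = h_drug("1", "IBUPROFEN", start = start),
            reac = h_reac("1", "Anuria", code = "10002847"))
}

test_that("onset is whole days from earliest PS start, with the exclusion rules", {
  r <- compute_onset(onset_fixture("20200106", "20200101"), cf)
  expect_true(r$included)
  expect_equal(r$onset_days, 5L)

  # same-day start and event: included with onset 0
  expect_equal(compute_onset(onset_fixture("20200101", "20200101"), cf)$onset_days, 0L)

  # event strictly before start: "incorrect input"
  r2 <- compute_onset(onset_fixture("20200301", "20200310"), cf)
  expect_false(r2$included)
  expect_equal(r2$exclusion_reason, "event_before_start")

  # month-precision event date: excluded as partial, never imputed
  r3 <- compute_onset(onset_fixture("202003", "20200301"), cf)
  expect_equal(r3$exclusion_reason, "partial_date")

  # missing start date
  r4 <- compute_onset(onset_fixture("20200301", ""), cf)
  expect_equal(r4$exclusion_reason, "missing_date")

  # several PS start dates: earliest is used
  reps <- h_reports(
    demo = h_demo("1", event = "20200110"),
    drug = rbind(h_drug("1", "IBUPROFEN", seq = 1, start = "20200108"),
                 h_drug("1", "ADVIL", seq = 2, start = "20200101")),
    reac = h_reac("1", "Anuria", code = "10002847"))
  expect_equal(compute_onset(reps, cf)$onset_days, 9L)
})

test_that("onset summaries use included records only", {
  rec <- structure(data.frame(
    primaryid = as.character(1:6),
    onset_days = c(0L, 2L, 5L, 20L, 100L, NA),
    included = c(rep(TRUE, 5), FALSE),
    exclusion_reason = c(rep("none", 5), "partial_date"),
    stringsAsFactors = FALSE), class = c("onset_records", "data.frame"))
  s <- onset_summary(rec)
  expect_equal(s$median_days, 5)
  expect_equal(s$n_included, 5L)
  expect_equal(unname(s$exclusions["partial_date"]), 1L)

  one <- rec[3, ]; one$included <- TRUE
  s1 <- onset_summary(one)
  expect_equal(s1$median_days, 5)      # the single record {5}
  expect_equal(s1$iqr, c(5, 5))
  expect_equal(s1$mean_days, 5)

  none <- rec[6, ]
  expect_equal(onset_summary(none)$reason, "no included onset records")
})

test_that("exclusion accounting partitions the cohort and shifts cancel", {
  out <- synth_faers(synthetic_params(n_reports = 2500, duplicate_rate = 0,
                                      seed = 23), dir <- tempfile("on"))
  reps <- deduplicate_cases(assemble_reports(read_faers_tables(dir)))
  coh <- subset_reports(reps, build_cohorts(reps, cf)$ibuprofen$cases)
  rec <- compute_onset(coh, cf)
  s <- onset_summary(rec)
  expect_equal(s$n_included + sum(s$exclusions[c("missing_date",
                                                 "partial_date",
                                                 "event_before_start")]),
               n_reports(coh))

  # shift equivariance: +k days on every start and event date
  k <- 37L
  shift <- function(df, ycol, mcol, dcol, pcol) {
    full <- df[[pcol]] == "day"
    d <- as.Date(sprintf("%04d-%02d-%02d", df[[ycol]][full],
                         df[[mcol]][full], df[[dcol]][full])) + k
    df[[ycol]][full] <- as.integer(format(d, "%Y"))
    df[[mcol]][full] <- as.integer(format(d, "%m"))
    df[[dcol]][full] <- as.integer(format(d, "%d"))
    df
  }
  coh2 <- coh
  coh2$demo <- shift(coh2$demo, "event_year", "event_month", "event_day",
                     "event_precision")
  coh2$drug <- shift(coh2$drug, "start_year", "start_month", "start_day",
                     "start_precision")
  rec2 <- compute_onset(coh2, cf)
  expect_equal(rec2$onset_days, rec$onset_days)
  expect_equal(rec2$exclusion_reason, rec$exclusion_reason)
})

test_that("rank-sum comparison matches exhaustive permutation at 3+3", {
  # identical groups: maximal p
  expect_equal(compare_onset(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  x <- c(1, 2, 3); y <- c(10, 20, 30)
  cmp <- compare_onset(x, y)
  expect_equal(cmp$u, 0)       # no x exceeds any y
  # exhaustive: all C(6,3) assignments of the pooled values to group 1
  pool <- c(x, y)
  combs <- combn(6, 3)
  u_all <- apply(combs, 2, function(ix) {
    g1 <- pool[ix]; g2 <- pool[-ix]
    sum(outer(g1, g2, ">"))
  })
  u_obs <- sum(outer(x, y, ">"))
  p_exact <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5))
  expect_equal(cmp$p_value, p_exact)

  # U-statistic symmetry on tie-free data
  set.seed(11)
  for (i in 1:20) {
    a <- sample(1000, 8); b <- sample(2000:3000, 6)
    u1 <- compare_onset(a, b)$u
    u2 <- compare_onset(b, a)$u
    expect_equal(u1 + u2, length(a) * length(b))
  }
  expect_error(compare_onset(numeric(0), 1:3), "at least one")
})

test_that("configured onset medians are recovered and separate at n = 500", {
  p <- synthetic_params(n_reports = 26000, duplicate_rate = 0,
                        missing_date_rate = 0, partial_date_rate = 0,
                        drug_exposure_prob = c(0.2, 0.2),
                        baseline_event_prob = 0.1, planted_rr = 2.4,
                        seed = 29)
  out <- synth_faers(p, dir <- tempfile("om"))
  reps <- deduplicate_cases(assemble_reports(read_faers_tables(dir)))
  coh <- build_cohorts(reps, list(ibuprofen_config(), acetaminophen_config()))
  rec_ibu <- compute_onset(subset_reports(reps, coh$ibuprofen$cases),
                           ibuprofen_config())
  rec_apap <- compute_onset(subset_reports(reps, coh$acetaminophen$cases),
                            acetaminophen_config())
  s_ibu <- onset_summary(rec_ibu); s_apap <- onset_summary(rec_apap)
  expect_gte(s_ibu$n_included, 500)
  expect_gte(s_apap$n_included, 500)
  expect_lte(abs(s_ibu$median_days - 5), 1)   # configured median 5 days
  expect_lte(abs(s_apap$median_days - 2), 1)  # configured median 2 days
  expect_lt(compare_onset(rec_apap, rec_ibu)$p_value, 1e-4)
})
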