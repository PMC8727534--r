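cf_ibu <- ibuprofen_config()
cf_apap <- acetaminophen_config()

test_that("drug matching requires the PS role and survives dose/form tokens", {
  expect_equal(normalize_drug_name("ibuprofen 200mg tablet"), "IBUPROFEN")
  expect_equal(normalize_drug_name("Advil (Liqui-Gels) 200 MG"), "ADVIL LIQUI GELS")

  reps <- h_reports(
    demo = h_demo(c("1", "2", "3")),
    drug = rbind(h_drug("1", "IBUPROFEN", role = "PS"),
                 h_drug("2", "Advil", role = "C"),
                 h_drug("3", "ibuprofen 200mg tablet", role = "PS")),
    reac = h_reac(c("1", "2", "3"), "Nausea"))
  m <- match_target_drug(reps, cf_ibu)
  expect_equal(unname(m), c(TRUE, FALSE, TRUE))
})

test_that("event matching works by PT code or by name", {
  reps <- h_reports(
    demo = h_demo(c("1", "2", "3")),
    reac = rbind(h_reac("1", "Some verbatim AKI", code = "10069339"),
                 h_reac("2", "Nausea"),
                 h_reac("3", "Tubulointerstitial nephritis")))
  m <- match_target_event(reps, cf_ibu)
  expect_equal(unname(m), c(TRUE, FALSE, TRUE))
})

test_that("suicide flag fires on indication terms or dose above threshold", {
  reps <- h_reports(
    demo = h_demo(c("1", "2", "3")),
    drug = rbind(h_drug("1", "ACETAMINOPHEN", dose_amt = "600", dose_unit = "MG"),
                 h_drug("2", "ACETAMINOPHEN", dose_amt = "600", dose_unit = "MG"),
                 h_drug("3", "ACETAMINOPHEN", dose_amt = "15", dose_unit = "G")),
    reac = h_reac(c("1", "2", "3"), "Anuria", code = "10002847"),
    indi = rbind(h_indi("1", "Suicide attempt"), h_indi("2", "Pyrexia")))
  s <- flag_suicide(reps, cf_apap)
  expect_equal(unname(s), c(TRUE, FALSE, TRUE))
})

test_that("contingency cells partition the universe", {
  # one report per cell
  reps <- h_reports(
    demo = h_demo(c("1", "2", "3", "4")),
    drug = rbind(h_drug("1", "IBUPROFEN"), h_drug("3", "IBUPROFEN"),
                 h_drug("2", "ASPIRIN"), h_drug("4", "ASPIRIN")),
    reac = rbind(h_reac("1", "Anuria", code = "10002847"),
                 h_reac("2", "Oliguria", code = "10030302"),
                 h_reac("3", "Nausea"), h_reac("4", "Rash")))
  t <- build_contingency(reps, cf_ibu)
  expect_equal(unlist(t[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(t$n, n_reports(reps))
  expect_error(build_contingency(subset_reports(reps, character(0)), cf_ibu),
               "empty")
})

test_that("cells match a brute-force recount on a synthetic universe", {
  out <- synth_faers(synthetic_params(n_reports = 10000, duplicate_rate = 0,
                                      missing_date_rate = 0,
                                      partial_date_rate = 0, seed = 21),
                     dir <- tempfile("cb"))
  reps <- deduplicate_cases(assemble_reports(read_faers_tables(dir)))
  t <- build_contingency(reps, cf_ibu)

  # brute force: loop every report and classify it independently
  syn <- normalize_drug_name(cf_ibu$synonyms)
  cells <- c(a = 0, b = 0, c = 0, d = 0)
  for (pid in reps$demo$primaryid) {
    d <- reps$drug[reps$drug$primaryid == pid, ]
    r <- reps$reac[reps$reac$primaryid == pid, ]
    dm <- any(d$role_cod == "PS" &
                (normalize_drug_name(d$drugname) %in% syn |
                   normalize_drug_name(d$prod_ai) %in% syn))
    em <- any(r$pt_code %in% cf_ibu$target_pts$code |
                toupper(r$pt) %in% toupper(cf_ibu$target_pts$pt))
    cell <- if (dm && em) "a" else if (em) "b" else if (dm) "c" else "d"
    cells[cell] <- cells[cell] + 1
  }
  expect_equal(unlist(t[c("a", "b", "c", "d")]), cells)
  # and equals the generator's ground truth
  expect_equal(unlist(t[c("a", "b", "c", "d")]),
               unlist(ledger_contingency(out$ledger, "IBUPROFEN")[
                 c("a", "b", "c", "d")]))
})

test_that("removing suicide reports changes only the cells they occupied", {
  out <- synth_faers(synthetic_params(n_reports = 4000, duplicate_rate = 0,
                                      suicide_rate = 0.1, seed = 8),
                     dir <- tempfile("su"))
  reps <- deduplicate_cases(assemble_reports(read_faers_tables(dir)))
  t_all <- build_contingency(reps, cf_ibu)
  su <- flag_suicide(reps, cf_ibu)
  t_excl <- build_contingency(reps, cf_ibu, exclude = names(su)[su])

  # recount the excluded reports' own cells
  kept <- subset_reports(reps, names(su)[!su])
  t_kept <- build_contingency(kept, cf_ibu)
  expect_equal(unlist(t_excl[c("a", "b", "c", "d")]),
               unlist(t_kept[c("a", "b", "c", "d")]))
  expect_equal(t_excl$n, t_all$n - sum(su))
})

test_that("a report matching both drugs lands in both cohorts; flow counts match truth", {
  reps <- h_reports(
    demo = h_demo(c("1", "2")),
    drug = rbind(h_drug("1", "IBUPROFEN", seq = 1),
                 h_drug("1", "TYLENOL", seq = 2),
                 h_drug("2", "ASPIRIN")),
    reac = rbind(h_reac("1", "Renal impairment", code = "10062237"),
                 h_reac("2", "Nausea")))
  flow <- build_cohorts(reps, list(cf_ibu, cf_apap))
  expect_equal(flow$ibuprofen$cases, "1")
  expect_equal(flow$acetaminophen$cases, "1")
  expect_equal(flow$ibuprofen$flow$n,
               c(2, 1, 1, 1, 0))

  # empty event universe: flow shows 0 after the event filter
  reps0 <- h_reports(demo = h_demo("9"), drug = h_drug("9", "IBUPROFEN"),
                     reac = h_reac("9", "Nausea"))
  flow0 <- build_cohorts(reps0, cf_ibu)
  expect_equal(length(flow0$ibuprofen$cases), 0L)
  expect_equal(flow0$ibuprofen$flow$n[3], 0)

  # planted memberships equal the generator bookkeeping
  out <- synth_faers(synthetic_params(n_reports = 3000, duplicate_rate = 0,
                                      seed = 13), dir <- tempfile("fl"))
  reps2 <- deduplicate_cases(assemble_reports(read_faers_tables(dir)))
  flow2 <- build_cohorts(reps2, list(cf_ibu, cf_apap))
  led <- out$ledger
  expect_equal(length(flow2$ibuprofen$cases),
               sum(led$drug == "IBUPROFEN" & led$event))
  expect_equal(length(flow2$acetaminophen$cases),
               sum(led$drug == "ACETAMINOPHEN" & led$event))
  expect_equal(length(flow2$ibuprofen$cases_suicide),
               sum(led$drug == "IBUPROFEN" & led$event & led$suicide))
})

test_that("dedup and suicide exclusion commute when duplicates share indications", {
  out <- synth_faers(synthetic_params(n_reports = 1500, duplicate_rate = 0.5,
                                      suicide_rate = 0.1, seed = 17),
                     dir <- tempfile("cm"))
  raw <- assemble_reports(read_faers_tables(dir))

  dd_first <- deduplicate_cases(raw)
  su1 <- flag_suicide(dd_first, cf_ibu)
  a <- sort(names(su1)[!su1 & unname(match_target_drug(dd_first, cf_ibu) &
                                       match_target_event(dd_first, cf_ibu))])

  su_raw <- flag_suicide(raw, cf_ibu)
  kept <- deduplicate_cases(subset_reports(raw, names(su_raw)[!su_raw]))
  b <- sort(names(which(match_target_drug(kept, cf_ibu) &
                          match_target_event(kept, cf_ibu))))
  expect_equal(a, b)
})

test_that("config files round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  write_cohort_config(cf_ibu, f)
  back <- read_cohort_config(f)
  expect_equal(back$synonyms, cf_ibu$synonyms)
  expect_equal(back$target_pts, cf_ibu$target_pts)
  expect_equal(back$suicide_dose_threshold_g, cf_ibu$suicide_dose_threshold_g)
  expect_equal(nrow(kidney_injury_pts()), 17L)
  expect_false("Dialysis" %in% kidney_injury_pts(include_dialysis = FALSE)$pt)
})
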