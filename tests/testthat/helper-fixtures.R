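# In-code fixture builders: tiny FAERS-style tables written as CSV (or
# "$"-delimited ASCII) to a temp dir and read back through the package's
# own readers.

options(faerspv.quiet = TRUE)

h_demo <- function(primaryid, caseid = primaryid, fda = "20200101",
                   event = "20200110", age = "30", age_cod = "YR",
                   sex = "F", country = "US", occp = "MD") {
  data.frame(PRIMARYID = primaryid, CASEID = caseid, FDA_DT = fda,
             EVENT_DT = event, AGE = age, AGE_COD = age_cod, SEX = sex,
             OCCR_COUNTRY = country, OCCP_COD = occp, stringsAsFactors = FALSE)
}

h_drug <- function(primaryid, name, role = "PS", seq = 1, ai = name,
                   dose_amt = "", dose_unit = "", start = "") {
  data.frame(PRIMARYID = primaryid, CASEID = primaryid, DRUG_SEQ = seq,
             DRUGNAME = name, PROD_AI = ai, ROLE_COD = role,
             DOSE_AMT = dose_amt, DOSE_UNIT = dose_unit, START_DT = start,
             stringsAsFactors = FALSE)
}

h_reac <- function(primaryid, pt, code = "") {
  data.frame(PRIMARYID = primaryid, CASEID = primaryid, PT = pt,
             PT_CODE = code, stringsAsFactors = FALSE)
}

h_outc <- function(primaryid, code) {
  data.frame(PRIMARYID = primaryid, CASEID = primaryid, OUTC_COD = code,
             stringsAsFactors = FALSE)
}

h_indi <- function(primaryid, term, seq = 1) {
  data.frame(PRIMARYID = primaryid, CASEID = primaryid, INDI_DRUG_SEQ = seq,
             INDI_PT = term, stringsAsFactors = FALSE)
}

h_ther <- function(primaryid, start, seq = 1) {
  data.frame(PRIMARYID = primaryid, CASEID = primaryid, DSG_DRUG_SEQ = seq,
             START_DT = start, stringsAsFactors = FALSE)
}

h_empty <- function(tb) {
  df <- switch(tb,
               demo = h_demo("x"),
               drug = h_drug("x", "y"),
               reac = h_reac("x", "y"),
               outc = h_outc("x", "y"),
               indi = h_indi("x", "y"),
               ther = h_ther("x", "y"))
  df[0, , drop = FALSE]
}

# write the six tables (missing ones empty) and return the directory
h_write <- function(demo = NULL, drug = NULL, reac = NULL, outc = NULL,
                    indi = NULL, ther = NULL, dialect = "csv",
                    dir = tempfile("fix")) {
  dir.create(dir)
  tabs <- list(demo = demo, drug = drug, reac = reac, outc = outc,
               indi = indi, ther = ther)
  sep <- if (dialect == "csv") "," else "$"
  ext <- if (dialect == "csv") ".csv" else ".txt"
  for (tb in names(tabs)) {
    df <- tabs[[tb]] %||% h_empty(tb)
    lines <- c(paste(names(df), collapse = sep),
               if (nrow(df)) do.call(paste, c(unname(df), sep = sep)))
    writeLines(lines, file.path(dir, paste0(toupper(tb), ext)))
  }
  dir
}

`%||%` <- function(a, b) if (is.null(a)) b else a

h_reports <- function(..., dedup = FALSE) {
  reps <- assemble_reports(read_faers_tables(h_write(...)))
  if (dedup) deduplicate_cases(reps) else reps
}

# a tiny single-drug parameter set for fast ledger-level simulation
h_params1 <- function(n, rr, p_exp = 0.05, p0 = 0.02, seed = 1, ...) {
  synthetic_params(n_reports = n, target_drugs = "IBUPROFEN",
                   drug_exposure_prob = p_exp, planted_rr = rr,
                   baseline_event_prob = p0, onset_median_days = 5,
                   seed = seed, ...)
}

# doses transcribed from the published intentional-overdose tables
ibu_doses <- c(2.4, 9.6, 9.6, 9.6, 9.6, 6.4, 6.4, 12, 12, 23, 23, 8, 8,
               12.4, 28.8, 95.4, 12, 105, 24, 100)
apap_doses <- c(50, 40, 30, 15, 40, 40, 40, 16, 16, 16, 16, 8, 8, 28, 28,
                40, 40, 90, 3, 3, 16, 30, 30, 3, 2, 8, 8, 20, 7, 50, 27,
                50, 28)
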