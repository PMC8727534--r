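# Assembly of raw tables into case reports, and FDA-style deduplication.
#
# A `faers_reports` object is relational rather than nested: one `demo` row
# per report plus child tables (drug, reac, outc, indi) keyed by PRIMARYID.
# This keeps 10^4--10^5 report universes fast in base R while exposing the
# same per-case content as a nested record.

dose_unit_to_grams <- c(MG = 1e-3, G = 1, GM = 1, KG = 1e3, UG = 1e-6,
                        MCG = 1e-6, NG = 1e-9)

col_or <- function(df, name, default = "") {
  if (name %in% names(df)) df[[name]] else rep(default, nrow(df))
}

#' Assemble case reports from raw tables
#'
#' Builds one case report per distinct PRIMARYID in DEMO, attaching drug
#' entries (with start dates joined from THER by drug sequence), reaction
#' Preferred Terms (deduplicated to unique terms per report), outcome codes
#' (as a set) and indications. Child rows whose PRIMARYID is absent from
#' DEMO are counted and skipped. Partial dates keep explicit precision.
#'
#' @param tables a \code{raw_tables} object from \code{\link{read_faers_tables}}.
#' @return an object of class \code{faers_reports}: list of data.frames
#'   \code{demo}, \code{drug}, \code{reac}, \code{outc}, \code{indi}, sorted
#'   by numeric PRIMARYID, with attributes counting skipped orphans and
#'   unconvertible doses.
#' @export
assemble_reports <- function(tables) {
  stopifnot(inherits(tables, "raw_tables"))

  demo_raw <- tables$demo
  if (anyDuplicated(demo_raw$PRIMARYID)) {
    pv_log("demo: duplicate PRIMARYID rows; keeping first occurrence")
    demo_raw <- demo_raw[!duplicated(demo_raw$PRIMARYID), , drop = FALSE]
  }
  ev <- parse_faers_date(demo_raw$EVENT_DT)
  country <- if ("OCCR_COUNTRY" %in% names(demo_raw)) demo_raw$OCCR_COUNTRY
             else demo_raw$REPORTER_COUNTRY
  demo <- data.frame(
    primaryid = demo_raw$PRIMARYID,
    caseid = demo_raw$CASEID,
    fda_dt = partial_as_date(parse_faers_date(demo_raw$FDA_DT)),
    event_year = ev$year, event_month = ev$month, event_day = ev$day,
    event_precision = ev$precision,
    age = suppressWarnings(as.numeric(demo_raw$AGE)),
    age_cod = toupper(trimws(demo_raw$AGE_COD)),
    sex = toupper(trimws(demo_raw$SEX)),
    country = toupper(trimws(country)),
    occp_cod = toupper(trimws(demo_raw$OCCP_COD)),
    stringsAsFactors = FALSE)

  keep_ids <- demo$primaryid
  n_orphans <- 0L
  filter_children <- function(df) {
    ok <- df$PRIMARYID %in% keep_ids
    n_orphans <<- n_orphans + sum(!ok)
    df[ok, , drop = FALSE]
  }

  dr <- filter_children(tables$drug)
  seq_within <- function(ids) stats::ave(seq_along(ids), ids, FUN = seq_along)
  drug_seq <- if ("DRUG_SEQ" %in% names(dr)) {
    suppressWarnings(as.integer(dr$DRUG_SEQ))
  } else seq_within(dr$PRIMARYID)
  dose_amt <- suppressWarnings(as.numeric(dr$DOSE_AMT))
  unit <- toupper(trimws(dr$DOSE_UNIT))
  factor_g <- dose_unit_to_grams[unit]
  dose_grams <- dose_amt * as.numeric(factor_g)
  n_bad_unit <- sum(!is.na(dose_amt) & unit != "" & is.na(factor_g))
  if (n_bad_unit > 0) {
    pv_log(sprintf("drug: %d dose(s) with unknown unit treated as missing", n_bad_unit))
  }

  # drug start date: START_DT on DRUG if present, else joined from THER
  start_raw <- col_or(dr, "START_DT")
  th <- filter_children(tables$ther)
  th_seq <- if ("DSG_DRUG_SEQ" %in% names(th)) {
    suppressWarnings(as.integer(th$DSG_DRUG_SEQ))
  } else seq_within(th$PRIMARYID)
  key <- paste(dr$PRIMARYID, drug_seq, sep = "\r")
  th_key <- paste(th$PRIMARYID, th_seq, sep = "\r")
  joined <- th$START_DT[match(key, th_key)]
  use_join <- is.na(start_raw) | start_raw == ""
  start_raw[use_join] <- ifelse(is.na(joined[use_join]), "", joined[use_join])
  sd <- parse_faers_date(start_raw)

  drug <- data.frame(
    primaryid = dr$PRIMARYID, drug_seq = drug_seq,
    drugname = dr$DRUGNAME, prod_ai = dr$PROD_AI,
    role_cod = toupper(trimws(dr$ROLE_COD)),
    dose_amt = dose_amt, dose_unit = unit, dose_grams = dose_grams,
    start_year = sd$year, start_month = sd$month, start_day = sd$day,
    start_precision = sd$precision, stringsAsFactors = FALSE)

  rc <- filter_children(tables$reac)
  reac <- data.frame(primaryid = rc$PRIMARYID, pt = trimws(rc$PT),
                     pt_code = trimws(col_or(rc, "PT_CODE")),
                     stringsAsFactors = FALSE)
  reac_key <- paste(reac$primaryid,
                    ifelse(reac$pt_code != "", reac$pt_code, toupper(reac$pt)),
                    sep = "\r")
  reac <- reac[!duplicated(reac_key), , drop = FALSE]

  oc <- filter_children(tables$outc)
  outc <- data.frame(primaryid = oc$PRIMARYID,
                     outc_cod = toupper(trimws(oc$OUTC_COD)),
                     stringsAsFactors = FALSE)
  outc <- outc[!duplicated(paste(outc$primaryid, outc$outc_cod, sep = "\r")), ,
               drop = FALSE]

  ind <- filter_children(tables$indi)
  indi <- data.frame(primaryid = ind$PRIMARYID,
                     indi_drug_seq = suppressWarnings(
                       as.integer(col_or(ind, "INDI_DRUG_SEQ", NA))),
                     indi_pt = trimws(ind$INDI_PT), stringsAsFactors = FALSE)

  if (n_orphans > 0) {
    pv_log(sprintf("skipped %d child row(s) with PRIMARYID absent from demo",
                   n_orphans))
  }

  ord <- order(suppressWarnings(as.numeric(demo$primaryid)), demo$primaryid)
  demo <- demo[ord, , drop = FALSE]
  sort_child <- function(df, extra = NULL) {
    o <- order(suppressWarnings(as.numeric(df$primaryid)), df$primaryid,
               if (!is.null(extra)) df[[extra]] else seq_len(nrow(df)))
    df[o, , drop = FALSE]
  }
  out <- list(demo = reset_rows(demo),
              drug = reset_rows(sort_child(drug, "drug_seq")),
              reac = reset_rows(sort_child(reac)),
              outc = reset_rows(sort_child(outc)),
              indi = reset_rows(sort_child(indi)))
  structure(out, n_orphans = n_orphans, n_bad_dose_unit = n_bad_unit,
            class = "faers_reports")
}

reset_rows <- function(df) { rownames(df) <- NULL; df }

#' Number of case reports
#' @param reports a \code{faers_reports} object.
#' @return integer count of reports (rows of demo).
#' @export
n_reports <- function(reports) nrow(reports$demo)

#' Subset reports by PRIMARYID
#' @param reports a \code{faers_reports} object.
#' @param primaryids PRIMARYIDs to keep.
#' @return a \code{faers_reports} object restricted to those reports.
#' @export
subset_reports <- function(reports, primaryids) {
  out <- lapply(reports, function(df) {
    reset_rows(df[df$primaryid %in% primaryids, , drop = FALSE])
  })
  structure(out, class = "faers_reports")
}

#' Deduplicate case reports the FDA way
#'
#' FAERS cases are resubmitted as new versions under the same CASEID with new
#' PRIMARYIDs. Exactly one report per CASEID is retained: the one with the
#' latest FDA receipt date (\code{FDA_DT}); ties are broken by the larger
#' PRIMARYID. A missing receipt date sorts earliest.
#'
#' @param reports a \code{faers_reports} object.
#' @return a deduplicated \code{faers_reports} object with attribute
#'   \code{n_removed} (number of superseded versions dropped).
#' @export
deduplicate_cases <- function(reports) {
  demo <- reports$demo
  fda_key <- as.numeric(demo$fda_dt)
  fda_key[is.na(fda_key)] <- -Inf
  pid_key <- suppressWarnings(as.numeric(demo$primaryid))
  pid_key[is.na(pid_key)] <- -Inf
  ord <- order(demo$caseid, fda_key, pid_key)
  last <- !duplicated(demo$caseid[ord], fromLast = TRUE)
  keep <- demo$primaryid[ord][last]
  n_removed <- nrow(demo) - length(keep)
  out <- subset_reports(reports, keep)
  attr(out, "n_removed") <- n_removed
  if (n_removed > 0) pv_log(sprintf("deduplication removed %d report version(s)",
                                    n_removed))
  out
}

#' @export
print.faers_reports <- function(x, ...) {
  cat(sprintf("faers_reports: %d case reports\n", n_reports(x)))
  cat(sprintf("  drug entries: %d | reactions: %d | outcomes: %d | indications: %d\n",
              nrow(x$drug), nrow(x$reac), nrow(x$outc), nrow(x$indi)))
  rem <- attr(x, "n_removed")
  if (!is.null(rem)) cat(sprintf("  deduplicated (%d versions removed)\n", rem))
  invisible(x)
}

#' Write assembled reports to the interchange format
#'
#' One JSON object per line (NDJSON), nesting each report's drug entries,
#' reactions, outcomes and indications. \code{\link{read_reports}} restores
#' the object field-for-field.
#'
#' @param reports a \code{faers_reports} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_reports <- function(reports, path) {
  demo <- reports$demo
  by_id <- function(df) split(df, factor(df$primaryid, levels = demo$primaryid))
  drugs <- by_id(reports$drug); reacs <- by_id(reports$reac)
  outcs <- by_id(reports$outc); indis <- by_id(reports$indi)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(demo))) {
    rec <- list(
      primaryid = demo$primaryid[i], caseid = demo$caseid[i],
      fda_dt = if (is.na(demo$fda_dt[i])) "" else format(demo$fda_dt[i], "%Y%m%d"),
      event_date = format_partial_date(demo$event_year[i], demo$event_month[i],
                                       demo$event_day[i]),
      age = demo$age[i], age_cod = demo$age_cod[i], sex = demo$sex[i],
      country = demo$country[i], occp_cod = demo$occp_cod[i],
      drugs = unname(lapply(seq_len(nrow(drugs[[i]])), function(j) {
        d <- drugs[[i]][j, ]
        list(drug_seq = d$drug_seq, drugname = d$drugname, prod_ai = d$prod_ai,
             role_cod = d$role_cod, dose_amt = d$dose_amt, dose_unit = d$dose_unit,
             start_date = format_partial_date(d$start_year, d$start_month,
                                              d$start_day))
      })),
      reactions = unname(lapply(seq_len(nrow(reacs[[i]])), function(j) {
        list(pt = reacs[[i]]$pt[j], pt_code = reacs[[i]]$pt_code[j])
      })),
      outcomes = as.list(outcs[[i]]$outc_cod),
      indications = unname(lapply(seq_len(nrow(indis[[i]])), function(j) {
        list(indi_drug_seq = indis[[i]]$indi_drug_seq[j],
             indi_pt = indis[[i]]$indi_pt[j])
      })))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Read reports from the interchange format
#' @param path NDJSON file written by \code{\link{write_reports}}.
#' @return a \code{faers_reports} object.
#' @export
read_reports <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  chr1 <- function(x) if (is.null(x)) "" else as.character(x)
  num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  int1 <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)

  demo_ev <- parse_faers_date(vapply(recs, function(r) chr1(r$event_date), ""))
  demo <- data.frame(
    primaryid = vapply(recs, function(r) chr1(r$primaryid), ""),
    caseid = vapply(recs, function(r) chr1(r$caseid), ""),
    fda_dt = partial_as_date(parse_faers_date(
      vapply(recs, function(r) chr1(r$fda_dt), ""))),
    event_year = demo_ev$year, event_month = demo_ev$month,
    event_day = demo_ev$day, event_precision = demo_ev$precision,
    age = vapply(recs, function(r) num1(r$age), 0),
    age_cod = vapply(recs, function(r) chr1(r$age_cod), ""),
    sex = vapply(recs, function(r) chr1(r$sex), ""),
    country = vapply(recs, function(r) chr1(r$country), ""),
    occp_cod = vapply(recs, function(r) chr1(r$occp_cod), ""),
    stringsAsFactors = FALSE)

  gather <- function(field, fn) {
    do.call(rbind, lapply(recs, function(r) {
      items <- r[[field]]
      if (length(items) == 0) return(NULL)
      do.call(rbind, lapply(items, fn, pid = r$primaryid))
    }))
  }
  drug <- gather("drugs", function(d, pid) {
    sdt <- parse_faers_date(chr1(d$start_date))
    unit <- chr1(d$dose_unit)
    amt <- num1(d$dose_amt)
    data.frame(primaryid = chr1(pid), drug_seq = int1(d$drug_seq),
               drugname = chr1(d$drugname), prod_ai = chr1(d$prod_ai),
               role_cod = chr1(d$role_cod), dose_amt = amt, dose_unit = unit,
               dose_grams = amt * as.numeric(dose_unit_to_grams[unit]),
               start_year = sdt$year, start_month = sdt$month,
               start_day = sdt$day, start_precision = sdt$precision,
               stringsAsFactors = FALSE)
  })
  reac <- gather("reactions", function(rc, pid) {
    data.frame(primaryid = chr1(pid), pt = chr1(rc$pt), pt_code = chr1(rc$pt_code),
               stringsAsFactors = FALSE)
  })
  outc <- gather("outcomes", function(oc, pid) {
    data.frame(primaryid = chr1(pid), outc_cod = chr1(oc), stringsAsFactors = FALSE)
  })
  indi <- gather("indications", function(ind, pid) {
    data.frame(primaryid = chr1(pid), indi_drug_seq = int1(ind$indi_drug_seq),
               indi_pt = chr1(ind$indi_pt), stringsAsFactors = FALSE)
  })
  if (is.null(drug)) drug <- data.frame(primaryid = character(), drug_seq = integer(),
    drugname = character(), prod_ai = character(), role_cod = character(),
    dose_amt = numeric(), dose_unit = character(), dose_grams = numeric(),
    start_year = integer(), start_month = integer(), start_day = integer(),
    start_precision = character(), stringsAsFactors = FALSE)
  if (is.null(reac)) reac <- data.frame(primaryid = character(), pt = character(),
    pt_code = character(), stringsAsFactors = FALSE)
  if (is.null(outc)) outc <- data.frame(primaryid = character(),
    outc_cod = character(), stringsAsFactors = FALSE)
  if (is.null(indi)) indi <- data.frame(primaryid = character(),
    indi_drug_seq = integer(), indi_pt = character(), stringsAsFactors = FALSE)
  structure(list(demo = reset_rows(demo), drug = reset_rows(drug),
                 reac = reset_rows(reac), outc = reset_rows(outc),
                 indi = reset_rows(indi)),
            class = "faers_reports")
}
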