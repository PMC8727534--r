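# Readers for FAERS-style quarterly tables.
#
# Two dialects are accepted: the FDA's "$"-delimited ASCII quarter files and
# CSV files with the same column names. Column names are matched
# case-insensitively; extra columns are carried along untouched.

# required / optional column sets per table (upper case)
faers_schema <- function() {
  list(
    demo = list(required = c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT",
                             "AGE", "AGE_COD", "SEX", "OCCP_COD"),
                one_of = list(c("OCCR_COUNTRY", "REPORTER_COUNTRY")),
                optional = character()),
    drug = list(required = c("PRIMARYID", "CASEID", "DRUGNAME", "PROD_AI",
                             "ROLE_COD", "DOSE_AMT", "DOSE_UNIT"),
                one_of = list(),
                optional = c("DRUG_SEQ", "START_DT")),
    reac = list(required = c("PRIMARYID", "CASEID", "PT"),
                one_of = list(), optional = "PT_CODE"),
    outc = list(required = c("PRIMARYID", "CASEID", "OUTC_COD"),
                one_of = list(), optional = character()),
    indi = list(required = c("PRIMARYID", "CASEID", "INDI_PT"),
                one_of = list(), optional = "INDI_DRUG_SEQ"),
    ther = list(required = c("PRIMARYID", "CASEID", "START_DT"),
                one_of = list(), optional = "DSG_DRUG_SEQ")
  )
}

# Read a delimited text file as all-character data.frame.
# UTF-8 first, latin1 fallback (historical FAERS quarters mix encodings).
# Rows whose field count disagrees with the header are counted and logged,
# never silently dropped into misaligned columns.
read_delim_table <- function(path, sep) {
  raw <- readLines(path, warn = FALSE, encoding = "bytes")
  if (any(!validUTF8(raw))) raw <- iconv(raw, from = "latin1", to = "UTF-8")
  raw <- sub("\r$", "", raw)
  if (length(raw) == 0) stop("file has no header row: ", path, call. = FALSE)
  # sentinel keeps trailing empty fields, which strsplit would drop
  parts <- lapply(strsplit(paste0(raw, sep, "\x01"), sep, fixed = TRUE),
                  function(p) p[-length(p)])
  header <- toupper(trimws(parts[[1]]))
  body <- parts[-1]
  # trailing delimiter tolerance: a row may have one empty trailing field
  nf <- lengths(body)
  ok <- nf == length(header) |
    (nf == length(header) + 1L & vapply(body, function(p) p[length(p)] == "", TRUE))
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    pv_log(sprintf("%s: skipped %d malformed row(s) (field count != %d)",
                   basename(path), n_bad, length(header)))
  }
  body <- body[ok]
  if (length(body) == 0) {
    df <- as.data.frame(matrix(character(0), nrow = 0, ncol = length(header)),
                        stringsAsFactors = FALSE)
    names(df) <- header
  } else {
    m <- t(vapply(body, function(p) p[seq_along(header)], character(length(header))))
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- header
  }
  attr(df, "n_malformed") <- n_bad
  df
}

check_schema <- function(df, table, schema) {
  sch <- schema[[table]]
  have <- names(df)
  missing <- setdiff(sch$required, have)
  for (grp in sch$one_of) {
    if (!any(grp %in% have)) missing <- c(missing, paste(grp, collapse = " or "))
  }
  if (length(missing) > 0) {
    stop(sprintf(
      "table '%s' is missing required column(s): %s\nexpected schema: %s%s",
      table, paste(missing, collapse = ", "),
      paste(sch$required, collapse = ", "),
      if (length(sch$one_of)) paste0(", plus one of {",
        paste(vapply(sch$one_of, paste, "", collapse = "/"), collapse = "}, {"), "}")
      else ""), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read FAERS-style quarterly tables
#'
#' Reads the six quarter tables (DEMO, DRUG, REAC, OUTC, INDI, THER) into a
#' \code{raw_tables} object. Files may be the FDA's \code{"$"}-delimited
#' ASCII or CSV with identical column names (case-insensitive).
#'
#' @param paths named character vector or list with elements
#'   \code{demo, drug, reac, outc, indi, ther}, or a single directory
#'   containing files whose names start with those table names.
#' @param dialect \code{"faers_ascii"} (\code{"$"}-delimited) or \code{"csv"}.
#'   Default \code{"auto"} sniffs the DEMO header line.
#' @return an object of class \code{raw_tables}: a list of six all-character
#'   data.frames with upper-case column names, plus a \code{log} attribute
#'   counting malformed rows per table.
#' @export
read_faers_tables <- function(paths, dialect = c("auto", "faers_ascii", "csv")) {
  dialect <- match.arg(dialect)
  tabs <- c("demo", "drug", "reac", "outc", "indi", "ther")
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths)) {
    dir <- paths
    paths <- sapply(tabs, function(tb) {
      hit <- list.files(dir, pattern = paste0("^", tb), ignore.case = TRUE,
                        full.names = TRUE)
      if (length(hit) == 0) NA_character_ else hit[[1]]
    })
  }
  paths <- unlist(paths)
  missing_tab <- tabs[!(tabs %in% names(paths)) | is.na(paths[tabs])]
  if (length(missing_tab) > 0) {
    stop("missing input file for table(s): ", paste(missing_tab, collapse = ", "),
         call. = FALSE)
  }
  for (tb in tabs) {
    if (!file.exists(paths[[tb]])) {
      stop(sprintf("file for table '%s' does not exist: %s", tb, paths[[tb]]),
           call. = FALSE)
    }
  }
  if (dialect == "auto") {
    hdr <- readLines(paths[["demo"]], n = 1, warn = FALSE)
    dialect <- if (grepl("$", hdr, fixed = TRUE)) "faers_ascii" else "csv"
  }
  sep <- if (dialect == "faers_ascii") "$" else ","
  schema <- faers_schema()
  out <- lapply(tabs, function(tb) {
    df <- read_delim_table(paths[[tb]], sep)
    check_schema(df, tb, schema)
    df
  })
  names(out) <- tabs
  structure(out,
            log = sapply(out, function(d) attr(d, "n_malformed") %||% 0L),
            class = "raw_tables")
}

#' @export
print.raw_tables <- function(x, ...) {
  cat("FAERS-style raw tables\n")
  for (tb in names(x)) {
    cat(sprintf("  %-5s %6d rows, %d cols\n", tb, nrow(x[[tb]]), ncol(x[[tb]])))
  }
  bad <- attr(x, "log")
  if (!is.null(bad) && any(bad > 0)) {
    cat("  malformed rows skipped:",
        paste(sprintf("%s=%d", names(bad)[bad > 0], bad[bad > 0]), collapse = ", "),
        "\n")
  }
  invisible(x)
}
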