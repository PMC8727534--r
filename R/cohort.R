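# Cohort selection: target-drug matching (primary-suspect role), target-event
# matching by MedDRA Preferred Term, the suicide/overdose exclusion, and the
# 2x2 contingency table underlying all four disproportionality statistics.

#' Default kidney-injury Preferred Term list
#'
#' The 17 MedDRA Preferred Terms (with codes) defining the kidney-injury
#' event set used by the shipped configurations. "Dialysis" names a
#' procedure rather than an injury but is part of the default set; drop it
#' with \code{include_dialysis = FALSE}.
#'
#' @param include_dialysis keep the "Dialysis" PT (default TRUE).
#' @return data.frame with columns \code{pt} (term name) and \code{code}.
#' @export
kidney_injury_pts <- function(include_dialysis = TRUE) {
  pts <- data.frame(
    pt = c("Acute kidney injury", "Subacute kidney injury",
           "Acute prerenal failure", "Renal failure acute ischemic",
           "Blood creatinine increased", "Blood urea abnormal",
           "Glomerular filtration rate decreased", "Renal impairment",
           "Oliguria", "Anuria", "Dialysis", "Proteinuria",
           "Nephrosis osmotic", "Renal tubular injury", "Nephropathy toxic",
           "Nephritis allergic", "Tubulointerstitial nephritis"),
    code = c("10069339", "10081980", "10001017", "10038439", "10005483",
             "10005846", "10018358", "10062237", "10030302", "10002847",
             "10061105", "10037032", "10029163", "10078933", "10029155",
             "10029120", "10048302"),
    stringsAsFactors = FALSE)
  if (!include_dialysis) pts <- pts[pts$pt != "Dialysis", , drop = FALSE]
  reset_rows(pts)
}

default_suicide_terms <- function() {
  c("intentional overdose", "poisoning deliberate", "suicidal ideation",
    "suicide attempt", "intentional product misuse", "overdose")
}

#' Cohort configuration
#'
#' Bundles everything needed to select one drug's event cohort: the drug
#' synonym list (brand and generic names), the target Preferred Term set,
#' the study window, and the suicide/intentional-overdose rules.
#'
#' @param drug label for the configuration (e.g. \code{"ibuprofen"}).
#' @param synonyms character vector of brand + generic names.
#' @param target_pts data.frame with columns \code{pt} and \code{code}
#'   (default: the 17 kidney-injury PTs).
#' @param window length-2 Date vector (study period); reports are not
#'   filtered by date unless \code{apply_window = TRUE} in the builders.
#' @param suicide_terms indication terms flagging intentional use
#'   (case-insensitive substring match).
#' @param suicide_dose_threshold_g daily dose in grams above which a report
#'   is flagged as intentional regardless of indication.
#' @return an object of class \code{cohort_config}.
#' @export
cohort_config <- function(drug, synonyms,
                          target_pts = kidney_injury_pts(),
                          window = as.Date(c("2004-01-01", "2021-03-31")),
                          suicide_terms = default_suicide_terms(),
                          suicide_dose_threshold_g = 12) {
  stopifnot(length(synonyms) >= 1, nrow(target_pts) >= 1,
            suicide_dose_threshold_g > 0)
  structure(list(drug = drug, synonyms = synonyms, target_pts = target_pts,
                 window = as.Date(window), suicide_terms = suicide_terms,
                 suicide_dose_threshold_g = suicide_dose_threshold_g),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort_config '%s': %d synonym(s), %d target PT(s), window %s..%s\n",
              x$drug, length(x$synonyms), nrow(x$target_pts),
              format(x$window[1]), format(x$window[2])))
  cat(sprintf("  suicide: %d term(s), dose threshold %g g\n",
              length(x$suicide_terms), x$suicide_dose_threshold_g))
  invisible(x)
}

#' Shipped ibuprofen configuration
#' @inheritParams cohort_config
#' @return a \code{cohort_config} for ibuprofen-associated kidney injury.
#' @export
ibuprofen_config <- function(target_pts = kidney_injury_pts()) {
  cohort_config("ibuprofen",
                synonyms = c("IBUPROFEN", "ADVIL", "MOTRIN", "NUROFEN",
                             "BRUFEN", "MIDOL", "IBUPROFEN LYSINE",
                             "IBUPROFEN SODIUM", "CALDOLOR", "NEOPROFEN"),
                target_pts = target_pts)
}

#' Shipped acetaminophen configuration
#' @inheritParams cohort_config
#' @return a \code{cohort_config} for acetaminophen-associated kidney injury.
#' @export
acetaminophen_config <- function(target_pts = kidney_injury_pts()) {
  cohort_config("acetaminophen",
                synonyms = c("ACETAMINOPHEN", "PARACETAMOL", "TYLENOL",
                             "PANADOL", "APAP", "OFIRMEV", "CALPOL",
                             "DOLIPRANE", "EFFERALGAN", "PERFALGAN"),
                target_pts = target_pts)
}

#' Read / write a cohort configuration file
#'
#' YAML with keys \code{drug}, \code{synonyms}, \code{target_pts}
#' (list of \code{pt}/\code{code} pairs), \code{window},
#' \code{suicide_terms}, \code{suicide_dose_threshold_g}.
#'
#' @param path YAML file path.
#' @return \code{read_cohort_config}: a \code{cohort_config}.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  pts <- do.call(rbind, lapply(y$target_pts, function(p) {
    data.frame(pt = p$pt, code = as.character(p$code), stringsAsFactors = FALSE)
  }))
  cohort_config(y$drug, unlist(y$synonyms), pts, as.Date(unlist(y$window)),
                unlist(y$suicide_terms), y$suicide_dose_threshold_g)
}

#' @rdname read_cohort_config
#' @param config a \code{cohort_config} to serialize.
#' @export
write_cohort_config <- function(config, path) {
  y <- list(drug = config$drug, synonyms = as.list(config$synonyms),
            target_pts = lapply(seq_len(nrow(config$target_pts)), function(i) {
              list(pt = config$target_pts$pt[i], code = config$target_pts$code[i])
            }),
            window = as.list(format(config$window)),
            suicide_terms = as.list(config$suicide_terms),
            suicide_dose_threshold_g = config$suicide_dose_threshold_g)
  yaml::write_yaml(y, path)
  invisible(path)
}

# tokens that are dose amounts or pharmaceutical forms, stripped before
# matching verbatim drug strings against the synonym list
.form_tokens <- c("TABLET", "TABLETS", "TAB", "TABS", "CAPSULE", "CAPSULES",
                  "CAP", "CAPS", "CAPLET", "CAPLETS", "ORAL", "SOLUTION",
                  "SUSPENSION", "SYRUP", "INJECTION", "IV", "GEL", "CREAM",
                  "DROPS", "SOFTGEL", "LIQUID", "CHEWABLE", "ER", "XR", "SR",
                  "EC", "MG", "G", "GM", "MCG", "ML", "UNKNOWN")

#' Normalize a verbatim drug name
#'
#' Upper-cases, strips punctuation, and drops dose/form tokens
#' (e.g. \code{"ibuprofen 200mg tablet"} becomes \code{"IBUPROFEN"}) so the
#' result can be matched exactly against a synonym list.
#'
#' @param x character vector of verbatim drug names.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[^A-Z0-9]+", " ", x)
  vapply(strsplit(trimws(x), " +"), function(tok) {
    drop <- grepl("^[0-9.]+(MG|G|GM|MCG|ML)?$", tok) | tok %in% .form_tokens
    paste(tok[!drop], collapse = " ")
  }, character(1))
}

# per-report logical vectors, named by primaryid -------------------------

match_pid <- function(reports, pids) {
  out <- reports$demo$primaryid %in% pids
  names(out) <- reports$demo$primaryid
  out
}

#' Match reports against the target drug
#'
#' TRUE for a report iff some drug entry has primary-suspect role (PS) and a
#' name (verbatim DRUGNAME or active ingredient PROD_AI) that normalizes to
#' one of the configured synonyms.
#'
#' @param reports a \code{faers_reports} object.
#' @param config a \code{cohort_config}.
#' @return named logical vector, one element per report.
#' @export
match_target_drug <- function(reports, config) {
  match_pid(reports, drug_matched_rows(reports, config, role = "PS"))
}

# primaryids having a drug row matching the synonyms (optionally by role)
drug_matched_rows <- function(reports, config, role = NULL) {
  d <- reports$drug
  syn <- normalize_drug_name(config$synonyms)
  hit <- normalize_drug_name(d$drugname) %in% syn |
    (d$prod_ai != "" & normalize_drug_name(d$prod_ai) %in% syn)
  if (!is.null(role)) hit <- hit & d$role_cod %in% role
  unique(d$primaryid[hit])
}

#' Match reports against the target event set
#'
#' TRUE iff any reaction's PT code (preferred when present) or PT name
#' (case-insensitive) is in the configured target set.
#'
#' @inheritParams match_target_drug
#' @return named logical vector, one element per report.
#' @export
match_target_event <- function(reports, config) {
  r <- reports$reac
  codes <- config$target_pts$code
  names_up <- toupper(config$target_pts$pt)
  hit <- (r$pt_code != "" & r$pt_code %in% codes) | toupper(r$pt) %in% names_up
  match_pid(reports, unique(r$primaryid[hit]))
}

#' Flag suicide / intentional-overdose reports
#'
#' TRUE iff any indication term contains one of the configured suicide terms
#' (case-insensitive substring), or the total reported dose of the target
#' drug exceeds the configured threshold in grams. Doses with unknown units
#' are treated as missing during assembly.
#'
#' @inheritParams match_target_drug
#' @return named logical vector, one element per report.
#' @export
flag_suicide <- function(reports, config) {
  ind <- tolower(reports$indi$indi_pt)
  term_hit <- Reduce(`|`, lapply(tolower(config$suicide_terms),
                                 function(tm) grepl(tm, ind, fixed = TRUE)),
                     rep(FALSE, length(ind)))
  pid_terms <- unique(reports$indi$primaryid[term_hit])

  d <- reports$drug
  syn <- normalize_drug_name(config$synonyms)
  is_target <- normalize_drug_name(d$drugname) %in% syn |
    (d$prod_ai != "" & normalize_drug_name(d$prod_ai) %in% syn)
  dosed <- is_target & !is.na(d$dose_grams)
  pid_dose <- character(0)
  if (any(dosed)) {
    tot <- tapply(d$dose_grams[dosed], d$primaryid[dosed], sum)
    pid_dose <- names(tot)[tot > config$suicide_dose_threshold_g]
  }

  match_pid(reports, union(pid_terms, pid_dose))
}

#' Build per-drug cohorts with selection flow counts
#'
#' Applies the drug filter (primary-suspect synonym match), the event filter
#' (target PT set) and the suicide exclusion for each configuration, and
#' records the count surviving each step for a CONSORT-style flow diagram.
#'
#' @param reports a deduplicated \code{faers_reports} object.
#' @param configs a list of \code{cohort_config} objects (or a single one).
#' @return an object of class \code{cohort_flow}: per drug, the PRIMARYIDs of
#'   all cases, suicide-excluded cases and suicide-only cases, plus the flow
#'   table.
#' @export
build_cohorts <- function(reports, configs) {
  if (inherits(configs, "cohort_config")) configs <- list(configs)
  names(configs) <- vapply(configs, function(cf) cf$drug, "")
  n_univ <- n_reports(reports)
  out <- lapply(configs, function(cf) {
    dm <- match_target_drug(reports, cf)
    em <- match_target_event(reports, cf)
    su <- flag_suicide(reports, cf)
    case <- dm & em
    list(cases = names(case)[case],
         cases_excl_suicide = names(case)[case & !su],
         cases_suicide = names(case)[case & su],
         flow = data.frame(
           step = c("universe", "target drug (PS)", "target drug + event",
                    "after suicide exclusion", "suicide subset"),
           n = c(n_univ, sum(dm), sum(case), sum(case & !su), sum(case & su)),
           stringsAsFactors = FALSE))
  })
  structure(out, n_universe = n_univ, class = "cohort_flow")
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat(sprintf("cohort selection flow (universe: %d deduplicated reports)\n",
              attr(x, "n_universe")))
  for (drug in names(x)) {
    cat(" ", drug, "\n")
    fl <- x[[drug]]$flow
    for (i in seq_len(nrow(fl))) {
      cat(sprintf("    %-28s %8d\n", fl$step[i], fl$n[i]))
    }
  }
  invisible(x)
}

#' Build the 2x2 contingency table for a drug-event pair
#'
#' Cell definitions over a deduplicated report universe:
#' \code{a} reports with the suspect drug (primary-suspect role) and the
#' suspect reaction; \code{b} the reaction with other medications; \code{c}
#' the suspect drug with other reactions; \code{d} other medications and
#' other reactions. Every report falls in exactly one cell, so
#' \code{a+b+c+d} equals the universe size.
#'
#' @param reports a deduplicated \code{faers_reports} object.
#' @param config a \code{cohort_config} naming the drug and event set.
#' @param exclude PRIMARYIDs to drop from the universe first (e.g. the
#'   suicide subset), or NULL.
#' @return an object of class \code{contingency2x2} with elements
#'   \code{a,b,c,d,n}.
#' @export
build_contingency <- function(reports, config, exclude = NULL) {
  if (!is.null(exclude)) {
    reports <- subset_reports(
      reports, setdiff(reports$demo$primaryid, exclude))
  }
  if (n_reports(reports) == 0) {
    stop("empty report universe: no disproportionality statistics computable",
         call. = FALSE)
  }
  dm <- match_target_drug(reports, config)
  em <- match_target_event(reports, config)
  contingency2x2(a = sum(dm & em), b = sum(!dm & em),
                 c = sum(dm & !em), d = sum(!dm & !em))
}

#' Construct a 2x2 contingency table
#' @param a,b,c,d non-negative integer cell counts (drug+event, event only,
#'   drug only, neither).
#' @return an object of class \code{contingency2x2}.
#' @export
contingency2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == floor(cells)))
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "contingency2x2")
}

#' @export
print.contingency2x2 <- function(x, ...) {
  cat("2x2 contingency table (reports)\n")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("event", "other event"),
                              c("drug (PS)", "other drug")))
  print(t(m))
  cat("N =", x$n, "\n")
  invisible(x)
}
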