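# Synthetic spontaneous-report generator.
#
# Emulates FAERS-style quarterly tables with a planted drug-event relative
# risk so every pipeline stage (parsing, assembly, deduplication, cohort
# selection, 2x2 screening, onset analysis) can be validated against a
# per-report ground-truth ledger. Two layers:
#   synth_truth()  draws the per-report ground truth (exposure, event,
#                  suicide flag, true onset, number of duplicate versions),
#   synth_faers()  materializes that truth as DEMO/DRUG/REAC/OUTC/INDI/THER
#                  files, adding duplicates, missing and partial dates.
# Identical parameters (including the seed) give byte-identical files.

default_background_drugs <- function() {
  c("ASPIRIN", "METFORMIN", "LISINOPRIL", "OMEPRAZOLE", "ATORVASTATIN",
    "AMOXICILLIN", "LEVOTHYROXINE", "AMLODIPINE", "SERTRALINE", "GABAPENTIN")
}

default_background_pts <- function() {
  data.frame(
    pt = c("Vomiting", "Nausea", "Hypotension", "Metabolic acidosis",
           "Pyrexia", "Headache", "Hepatotoxicity", "Diarrhoea", "Rash",
           "Dizziness", "Abdominal pain", "Dyspnoea"),
    code = c("10047700", "10028813", "10021097", "10027417", "10037660",
             "10019211", "10019851", "10012735", "10037844", "10013573",
             "10000081", "10013968"),
    stringsAsFactors = FALSE)
}

#' Parameters for the synthetic report generator
#'
#' Defaults emulate the surveillance scenario the shipped configurations
#' target: two analgesics with a planted relative risk of 2.4 against a
#' kidney-injury PT set, log-normal onset with medians 5 and 2 days, a
#' duplicate-version rate giving roughly 1.5 raw versions per case, and
#' demographic margins matching the published ibuprofen cohort.
#'
#' @param n_reports number of distinct cases (> 0).
#' @param target_drugs character vector of target drug names.
#' @param drug_exposure_prob per-drug probability that a case's primary
#'   suspect is that drug (recycled; probabilities must sum to < 1).
#' @param planted_rr per-drug relative risk of the target event versus the
#'   unexposed baseline (recycled).
#' @param baseline_event_prob probability of the target event without
#'   exposure.
#' @param target_pts,background_pts PT data.frames (columns \code{pt},
#'   \code{code}).
#' @param background_drugs pool of non-target drug names.
#' @param duplicate_rate probability that a case carries one extra
#'   resubmitted version.
#' @param missing_date_rate,partial_date_rate probabilities that a date
#'   field is blank / truncated to month precision.
#' @param age_dist,sex_dist,region_dist,reporter_dist named probability
#'   vectors over the demographic categories (must sum to 1).
#' @param outcome_probs_case,outcome_probs_background per-outcome-code
#'   probabilities for target drug+event cases and for everything else.
#' @param onset_median_days per-target-drug median of the log-normal
#'   time-to-onset, in days (recycled).
#' @param onset_sigma log-scale sigma of the onset distribution.
#' @param suicide_rate probability that an exposed case is an intentional
#'   overdose (suicide indication term + overdose-scale dose).
#' @param suicide_dose_meanlog,suicide_dose_sdlog,normal_dose_meanlog,normal_dose_sdlog
#'   log-normal dose models (grams) for intentional and normal use.
#' @param window length-2 Date vector for report and start dates.
#' @param seed master RNG seed; every table derives its own stream from it.
#' @return object of class \code{synthetic_params}.
#' @export
synthetic_params <- function(
    n_reports = 10000,
    target_drugs = c("IBUPROFEN", "ACETAMINOPHEN"),
    drug_exposure_prob = 0.02,
    planted_rr = 2.4,
    baseline_event_prob = 0.05,
    target_pts = kidney_injury_pts(),
    background_pts = default_background_pts(),
    background_drugs = default_background_drugs(),
    duplicate_rate = 0.5,
    missing_date_rate = 0.1,
    partial_date_rate = 0.1,
    age_dist = c("<18" = 0.176, "18-44" = 0.187, "45-64" = 0.233,
                 "65-74" = 0.139, ">74" = 0.104, Unknown = 0.161),
    sex_dist = c(F = 0.437, M = 0.437, Unknown = 0.126),
    region_dist = c(Africa = 0.001, Asia = 0.025, Europe = 0.611,
                    Oceania = 0.015, "North America" = 0.323,
                    "South America" = 0.004, Unknown = 0.021),
    reporter_dist = c(CN = 0.062, LW = 0.002, PH = 0.148, MD = 0.281,
                      OT = 0.326, Unknown = 0.181),
    outcome_probs_case = c(DE = 0.074, HO = 0.735, LT = 0.134, DS = 0.015,
                           OT = 0.549, RI = 0.012, CA = 0.001),
    outcome_probs_background = c(DE = 0.02, HO = 0.15, LT = 0.02, DS = 0.005,
                                 OT = 0.2, RI = 0.005, CA = 0.001),
    onset_median_days = c(5, 2),
    onset_sigma = 1.5,
    suicide_rate = 0.02,
    suicide_dose_meanlog = log(12), suicide_dose_sdlog = 0.8,
    normal_dose_meanlog = log(0.8), normal_dose_sdlog = 0.5,
    window = as.Date(c("2004-01-01", "2021-03-31")),
    seed = 1) {
  k <- length(target_drugs)
  drug_exposure_prob <- rep_len(drug_exposure_prob, k)
  planted_rr <- rep_len(planted_rr, k)
  onset_median_days <- rep_len(onset_median_days, k)
  p <- list(n_reports = n_reports, target_drugs = target_drugs,
            drug_exposure_prob = drug_exposure_prob, planted_rr = planted_rr,
            baseline_event_prob = baseline_event_prob,
            target_pts = target_pts, background_pts = background_pts,
            background_drugs = background_drugs,
            duplicate_rate = duplicate_rate,
            missing_date_rate = missing_date_rate,
            partial_date_rate = partial_date_rate,
            age_dist = age_dist, sex_dist = sex_dist,
            region_dist = region_dist, reporter_dist = reporter_dist,
            outcome_probs_case = outcome_probs_case,
            outcome_probs_background = outcome_probs_background,
            onset_median_days = onset_median_days, onset_sigma = onset_sigma,
            suicide_rate = suicide_rate,
            suicide_dose_meanlog = suicide_dose_meanlog,
            suicide_dose_sdlog = suicide_dose_sdlog,
            normal_dose_meanlog = normal_dose_meanlog,
            normal_dose_sdlog = normal_dose_sdlog,
            window = as.Date(window), seed = as.integer(seed))
  validate_synthetic_params(p)
  structure(p, class = "synthetic_params")
}

validate_synthetic_params <- function(p) {
  if (!is.numeric(p$n_reports) || p$n_reports < 1) {
    stop("n_reports must be a positive integer", call. = FALSE)
  }
  probs <- c(p$drug_exposure_prob, p$baseline_event_prob, p$duplicate_rate,
             p$missing_date_rate, p$partial_date_rate, p$suicide_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(p$planted_rr <= 0)) stop("planted_rr must be > 0", call. = FALSE)
  if (any(p$baseline_event_prob * p$planted_rr > 1)) {
    stop("impossible parameters: baseline_event_prob * planted_rr > 1",
         call. = FALSE)
  }
  if (sum(p$drug_exposure_prob) > 1) {
    stop("drug exposure probabilities sum to more than 1", call. = FALSE)
  }
  for (nm in c("age_dist", "sex_dist", "region_dist", "reporter_dist")) {
    if (abs(sum(p[[nm]]) - 1) > 1e-6) {
      stop(nm, " must sum to 1", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# sub-seed per table so adding columns to one table never perturbs another's
# draws; kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 97 + k * 1000003) %% 2147483647)
}

#' Draw the per-report ground truth ("the ledger")
#'
#' @param params a \code{synthetic_params} object.
#' @return data.frame with one row per case: \code{caseid}, \code{drug}
#'   (\code{""} if unexposed), \code{event}, \code{suicide},
#'   \code{onset_days} (NA unless an exposed event case), \code{n_versions}.
#' @export
synth_truth <- function(params) {
  p <- params
  set.seed(derive_seed(p$seed, 0L))
  n <- p$n_reports
  k <- length(p$target_drugs)
  drug <- sample(c(p$target_drugs, ""), n, replace = TRUE,
                 prob = c(p$drug_exposure_prob, 1 - sum(p$drug_exposure_prob)))
  idx <- match(drug, p$target_drugs)  # NA for unexposed
  p_event <- ifelse(is.na(idx), p$baseline_event_prob,
                    p$baseline_event_prob * p$planted_rr[idx])
  event <- stats::rbinom(n, 1, p_event) == 1
  suicide <- drug != "" & stats::rbinom(n, 1, p$suicide_rate) == 1
  onset <- rep(NA_integer_, n)
  tc <- !is.na(idx) & event
  if (any(tc)) {
    med <- p$onset_median_days[idx[tc]]
    onset[tc] <- as.integer(round(stats::rlnorm(sum(tc), log(med),
                                                p$onset_sigma)))
  }
  n_versions <- 1L + stats::rbinom(n, 1, p$duplicate_rate)
  data.frame(caseid = sprintf("%08d", 10000000L + seq_len(n)),
             drug = drug, event = event, suicide = suicide,
             onset_days = onset, n_versions = n_versions,
             stringsAsFactors = FALSE)
}

#' Realized relative risk from the ground-truth ledger
#'
#' The drug-event relative risk actually realized in a generated universe,
#' for calibrating recovery tests against sampling noise.
#'
#' @param ledger data.frame from \code{\link{synth_truth}} (or the ledger
#'   CSV re-read).
#' @param drug target drug name (default: the ledger's first exposed drug).
#' @return realized P(event | exposed) / P(event | unexposed).
#' @export
empirical_rr <- function(ledger, drug = NULL) {
  if (is.null(drug)) drug <- ledger$drug[ledger$drug != ""][1]
  exp_ <- ledger$drug == drug
  r1 <- mean(ledger$event[exp_])
  # universal exposure: the unexposed stratum is empty, compare to overall
  r0 <- if (any(!exp_)) mean(ledger$event[!exp_]) else mean(ledger$event)
  r1 / r0
}

#' 2x2 cell counts from the ground-truth ledger
#' @inheritParams empirical_rr
#' @return a \code{contingency2x2} of the true per-case cells.
#' @export
ledger_contingency <- function(ledger, drug = NULL) {
  if (is.null(drug)) drug <- ledger$drug[ledger$drug != ""][1]
  exp_ <- ledger$drug == drug
  contingency2x2(a = sum(exp_ & ledger$event), b = sum(!exp_ & ledger$event),
                 c = sum(exp_ & !ledger$event), d = sum(!exp_ & !ledger$event))
}

region_countries <- list(
  Africa = c("ZA", "EG", "NG"), Asia = c("JP", "CN", "IN", "KR"),
  Europe = c("GB", "FR", "DE", "IT", "ES"), Oceania = c("AU", "NZ"),
  "North America" = c("US", "CA", "MX"),
  "South America" = c("BR", "AR", "CO"), Unknown = "")

# degrade a YYYYMMDD date string vector to "" / YYYYMM at the given rates
degrade_dates <- function(x, missing_rate, partial_rate) {
  n <- length(x)
  u <- stats::runif(n)
  x[u < missing_rate] <- ""
  part <- u >= missing_rate & u < missing_rate + partial_rate
  x[part] <- substr(x[part], 1, 6)
  x
}

#' Generate FAERS-style tables from synthetic parameters
#'
#' Draws the ground truth with \code{\link{synth_truth}}, then writes the
#' six quarter tables to \code{dir} along with \code{ledger.csv}. Duplicate
#' cases appear as extra PRIMARYIDs sharing a CASEID with later receipt
#' dates, so deduplication has a well-defined correct answer. Date fields
#' are degraded to missing/month precision at the configured rates
#' (the FDA receipt date \code{FDA_DT} is always complete).
#'
#' @param params a \code{synthetic_params} object.
#' @param dir output directory (created if needed).
#' @param dialect \code{"faers_ascii"} (\code{"$"}-delimited, files
#'   \code{DEMO.txt} ...) or \code{"csv"}.
#' @return invisibly, a list with \code{paths} (named file paths),
#'   \code{ledger} (the truth data.frame) and \code{ledger_path}.
#' @export
synth_faers <- function(params, dir, dialect = c("faers_ascii", "csv")) {
  dialect <- match.arg(dialect)
  p <- params
  truth <- synth_truth(p)
  n <- nrow(truth)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  # case-level attributes (one draw per case, shared by duplicate versions)
  set.seed(derive_seed(p$seed, 1L))
  band <- sample(names(p$age_dist), n, TRUE, p$age_dist)
  lo <- c("<18" = 0, "18-44" = 18, "45-64" = 45, "65-74" = 65, ">74" = 75)
  hi <- c("<18" = 17, "18-44" = 44, "45-64" = 64, "65-74" = 74, ">74" = 99)
  u_age <- stats::runif(n)
  age <- ifelse(band == "Unknown", NA_integer_,
                floor(lo[band] + u_age * (hi[band] + 1 - lo[band])))
  sex <- sample(names(p$sex_dist), n, TRUE, p$sex_dist)
  sex[sex == "Unknown"] <- ""
  region <- sample(names(p$region_dist), n, TRUE, p$region_dist)
  country <- vapply(region, function(rg) {
    cc <- region_countries[[rg]]
    if (length(cc) == 1) cc else sample(cc, 1)
  }, "")
  occp <- sample(names(p$reporter_dist), n, TRUE, p$reporter_dist)
  occp[occp == "Unknown"] <- ""

  span <- as.integer(p$window[2] - p$window[1])
  start_date <- p$window[1] + floor(stats::runif(n, 0, span - 120))
  event_date <- ifelse(is.na(truth$onset_days),
                       start_date + floor(stats::runif(n, 0, 120)),
                       start_date + truth$onset_days)
  event_date <- as.Date(event_date, origin = "1970-01-01")
  fda_base <- event_date + floor(stats::runif(n, 1, 60))

  exposed <- truth$drug != ""
  suicide <- truth$suicide
  dose_g <- ifelse(suicide,
                   stats::rlnorm(n, p$suicide_dose_meanlog, p$suicide_dose_sdlog),
                   stats::rlnorm(n, p$normal_dose_meanlog, p$normal_dose_sdlog))
  dose_mg <- round(dose_g * 1000)

  # expand to versions: each extra version is a resubmission 30 days later
  vcount <- truth$n_versions
  ci <- rep(seq_len(n), vcount)          # case index per version row
  ver <- sequence(vcount)
  primaryid <- paste0(truth$caseid[ci], ver)
  fda_dt <- format(fda_base[ci] + (ver - 1L) * 30L, "%Y%m%d")
  nv <- length(ci)

  set.seed(derive_seed(p$seed, 2L))  # demo stream
  event_dt <- degrade_dates(format(event_date[ci], "%Y%m%d"),
                            p$missing_date_rate, p$partial_date_rate)
  demo <- data.frame(
    PRIMARYID = primaryid, CASEID = truth$caseid[ci], FDA_DT = fda_dt,
    EVENT_DT = event_dt,
    AGE = ifelse(is.na(age[ci]), "", as.character(age[ci])),
    AGE_COD = ifelse(is.na(age[ci]), "", "YR"),
    SEX = sex[ci], OCCR_COUNTRY = country[ci], OCCP_COD = occp[ci],
    stringsAsFactors = FALSE)

  set.seed(derive_seed(p$seed, 3L))  # drug/ther stream
  n_bg <- 1L + stats::rbinom(nv, 2, 0.35)
  verbatim <- ifelse(stats::runif(nv) < 0.3,
                     paste(truth$drug[ci], "200MG TABLET"), truth$drug[ci])
  erow <- which(exposed[ci])
  tgt <- data.frame(row = erow, seq = rep(1L, length(erow)),
                    name = verbatim[erow],
                    ai = truth$drug[ci][erow],
                    role = rep("PS", length(erow)),
                    dose_amt = as.character(dose_mg[ci][erow]),
                    dose_unit = rep("MG", length(erow)),
                    stringsAsFactors = FALSE)
  bg_row <- rep(seq_len(nv), n_bg)
  bg_seq <- sequence(n_bg) + as.integer(exposed[ci][bg_row])
  bg_name <- sample(p$background_drugs, length(bg_row), TRUE)
  bg_role <- ifelse(bg_seq == 1L, "PS",
                    sample(c("SS", "C", "I"), length(bg_row), TRUE))
  bg <- data.frame(row = bg_row, seq = bg_seq, name = bg_name, ai = bg_name,
                   role = bg_role, dose_amt = "", dose_unit = "",
                   stringsAsFactors = FALSE)
  dr <- rbind(tgt, bg)
  dr <- dr[order(dr$row, dr$seq), , drop = FALSE]
  drug <- data.frame(
    PRIMARYID = primaryid[dr$row], CASEID = truth$caseid[ci][dr$row],
    DRUG_SEQ = dr$seq, DRUGNAME = dr$name, PROD_AI = dr$ai,
    ROLE_COD = dr$role, DOSE_AMT = dr$dose_amt, DOSE_UNIT = dr$dose_unit,
    stringsAsFactors = FALSE)
  start_dt_full <- format(start_date[ci][dr$row] +
                            ifelse(dr$role == "PS", 0L,
                                   floor(stats::runif(nrow(dr), 0, 30))),
                          "%Y%m%d")
  ther <- data.frame(
    PRIMARYID = primaryid[dr$row], CASEID = truth$caseid[ci][dr$row],
    DSG_DRUG_SEQ = dr$seq,
    START_DT = degrade_dates(start_dt_full, p$missing_date_rate,
                             p$partial_date_rate),
    stringsAsFactors = FALSE)

  set.seed(derive_seed(p$seed, 4L))  # reac stream
  ev <- truth$event[ci]
  tp <- sample(nrow(p$target_pts), nv, TRUE)
  n_bg_pt <- stats::rpois(nv, 0.7)
  n_bg_pt[!ev & n_bg_pt == 0] <- 1L  # reactions are never empty
  tgt_re <- data.frame(row = which(ev), pt = p$target_pts$pt[tp[ev]],
                       code = p$target_pts$code[tp[ev]],
                       stringsAsFactors = FALSE)
  re_row <- rep(seq_len(nv), n_bg_pt)
  bpt <- sample(nrow(p$background_pts), length(re_row), TRUE)
  bg_re <- data.frame(row = re_row, pt = p$background_pts$pt[bpt],
                      code = p$background_pts$code[bpt],
                      stringsAsFactors = FALSE)
  re <- rbind(tgt_re, bg_re)
  re <- re[order(re$row), , drop = FALSE]
  reac <- data.frame(PRIMARYID = primaryid[re$row],
                     CASEID = truth$caseid[ci][re$row], PT = re$pt,
                     PT_CODE = re$code, stringsAsFactors = FALSE)

  set.seed(derive_seed(p$seed, 5L))  # outc stream
  is_case <- exposed & truth$event
  oc_list <- lapply(names(p$outcome_probs_case), function(code) {
    pr <- ifelse(is_case[ci], p$outcome_probs_case[[code]],
                 p$outcome_probs_background[[code]])
    hit <- which(stats::rbinom(nv, 1, pr) == 1)
    data.frame(row = hit, code = rep(code, length(hit)),
               stringsAsFactors = FALSE)
  })
  oc <- do.call(rbind, oc_list)
  oc <- oc[order(oc$row, oc$code), , drop = FALSE]
  outc <- data.frame(PRIMARYID = primaryid[oc$row],
                     CASEID = truth$caseid[ci][oc$row], OUTC_COD = oc$code,
                     stringsAsFactors = FALSE)

  set.seed(derive_seed(p$seed, 6L))  # indi stream
  sui <- suicide[ci]
  sui_term <- sample(c("Intentional overdose", "Poisoning deliberate",
                       "Suicidal ideation", "Suicide attempt"),
                     nv, TRUE)
  norm_has <- stats::runif(nv) < 0.7
  norm_term <- sample(c("Pain", "Pyrexia", "Headache", "Arthralgia",
                        "Inflammation"), nv, TRUE)
  keep <- sui | norm_has
  indi <- data.frame(PRIMARYID = primaryid[keep],
                     CASEID = truth$caseid[ci][keep],
                     INDI_DRUG_SEQ = 1L,
                     INDI_PT = ifelse(sui[keep], sui_term[keep],
                                      norm_term[keep]),
                     stringsAsFactors = FALSE)

  sep <- if (dialect == "faers_ascii") "$" else ","
  ext <- if (dialect == "faers_ascii") ".txt" else ".csv"
  tables <- list(demo = demo, drug = drug, reac = reac, outc = outc,
                 indi = indi, ther = ther)
  paths <- vapply(names(tables), function(tb) {
    path <- file.path(dir, paste0(toupper(tb), ext))
    df <- tables[[tb]]
    lines <- c(paste(names(df), collapse = sep),
               do.call(paste, c(unname(df), sep = sep)))
    writeLines(lines, path)
    path
  }, "")

  ledger_path <- file.path(dir, "ledger.csv")
  utils::write.csv(truth, ledger_path, row.names = FALSE)
  invisible(list(paths = paths, ledger = truth, ledger_path = ledger_path))
}
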