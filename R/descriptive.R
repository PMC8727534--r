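# Descriptive analyses of a selected cohort: demographics and outcome tables,
# rate comparisons, intentional-overdose dose summaries, and co-reported
# complication rankings.

age_bands <- c("<18", "18-44", "45-64", "65-74", ">74", "Unknown")

# years per unit code; DEC = decades, HR = hours
age_unit_years <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
                    DY = 1 / 365.25, HR = 1 / 8766)

#' Convert an age to years and assign the report-table band
#'
#' Units: DEC (decades), YR, MON, WK, DY, HR. A missing unit with a present
#' value is taken as years (the dominant reporting convention); missing,
#' negative or unconvertible ages band as \code{"Unknown"}.
#'
#' @param age_value numeric vector of reported ages.
#' @param age_unit character vector of unit codes.
#' @return character vector of bands among
#'   \code{c("<18","18-44","45-64","65-74",">74","Unknown")}.
#' @export
#' @examples
#' assign_age_band(c(17.9, 216, NA), c("YR", "MON", ""))
assign_age_band <- function(age_value, age_unit) {
  age_unit <- toupper(trimws(age_unit))
  fac <- age_unit_years[age_unit]
  fac[age_unit == ""] <- 1
  yrs <- age_value * unname(fac)
  band <- rep("Unknown", length(yrs))
  ok <- !is.na(yrs) & yrs >= 0
  if (any(!is.na(yrs) & yrs < 0)) {
    pv_log(sprintf("%d negative age(s) treated as Unknown",
                   sum(!is.na(yrs) & yrs < 0)))
  }
  band[ok & yrs < 18] <- "<18"
  band[ok & yrs >= 18 & yrs < 45] <- "18-44"
  band[ok & yrs >= 45 & yrs < 65] <- "45-64"
  band[ok & yrs >= 65 & yrs < 75] <- "65-74"
  band[ok & yrs >= 75] <- ">74"
  band
}

occp_labels <- c(CN = "Consumer", LW = "Lawyer", PH = "Pharmacist",
                 MD = "Physician", HP = "Other health-professional",
                 OT = "Other health-professional",
                 RN = "Other health-professional")

outcome_labels <- c(DE = "Death", HO = "Hospitalization", LT = "Life-Threatening",
                    DS = "Disability", CA = "Congenital Anomaly",
                    RI = "Required Intervention", OT = "Other Serious")

#' Clinical-characteristics table for a cohort
#'
#' Counts and percentages per category of age band, sex, region and reporter
#' occupation (each summing to the cohort size), plus outcome frequencies
#' (a case may carry several outcomes, so these need not sum to the cohort).
#' Percentages are over the cohort size, half-up at 2 decimals; for age and
#' sex a known-only percentage (denominator excluding Unknown) is also
#' reported, and age additionally carries a \code{">=65"} aggregate row.
#'
#' @param cohort a \code{faers_reports} object restricted to the cohort.
#' @return object of class \code{demographics_table}: a data.frame with
#'   columns \code{characteristic}, \code{category}, \code{n}, \code{pct},
#'   \code{pct_known} (NA where not applicable).
#' @export
demographics_table <- function(cohort) {
  demo <- cohort$demo
  ncoh <- nrow(demo)

  tab_rows <- function(characteristic, values, levels, known_pct = FALSE,
                       aggregate_65 = FALSE) {
    cnt <- table(factor(values, levels = levels))
    n_known <- sum(cnt[names(cnt) != "Unknown"])
    rows <- data.frame(
      characteristic = characteristic, category = levels,
      n = as.integer(cnt), pct = pct_half_up(as.integer(cnt), ncoh),
      pct_known = NA_real_, stringsAsFactors = FALSE)
    if (known_pct && n_known > 0) {
      i <- rows$category != "Unknown"
      rows$pct_known[i] <- pct_half_up(rows$n[i], n_known)
    }
    if (aggregate_65) {
      n65 <- sum(cnt[c("65-74", ">74")])
      rows <- rbind(rows, data.frame(
        characteristic = characteristic, category = ">=65", n = n65,
        pct = pct_half_up(n65, ncoh),
        pct_known = if (n_known > 0) pct_half_up(n65, n_known) else NA_real_,
        stringsAsFactors = FALSE))
    }
    rows
  }

  sex <- ifelse(demo$sex %in% c("F", "M"),
                ifelse(demo$sex == "F", "Female", "Male"), "Unknown")
  reporter <- occp_labels[demo$occp_cod]
  reporter[is.na(reporter)] <- "Unknown"
  region <- country_to_region(demo$country)

  out <- rbind(
    tab_rows("age", assign_age_band(demo$age, demo$age_cod), age_bands,
             known_pct = TRUE, aggregate_65 = TRUE),
    tab_rows("sex", sex, c("Female", "Male", "Unknown"), known_pct = TRUE),
    tab_rows("region", region,
             c("Africa", "Asia", "Europe", "Oceania", "North America",
               "South America", "Unknown")),
    tab_rows("reporter", unname(reporter),
             c("Consumer", "Lawyer", "Pharmacist", "Physician",
               "Other health-professional", "Unknown")))

  oc <- cohort$outc
  oc_lab <- outcome_labels[oc$outc_cod]
  cnt <- table(factor(oc_lab, levels = unname(outcome_labels[c(
    "DE", "HO", "DS", "LT", "OT", "RI", "CA")])))
  out <- rbind(out, data.frame(
    characteristic = "outcome", category = names(cnt), n = as.integer(cnt),
    pct = pct_half_up(as.integer(cnt), ncoh), pct_known = NA_real_,
    stringsAsFactors = FALSE))
  structure(reset_rows(out), n_cohort = ncoh, class = c("demographics_table",
                                                        "data.frame"))
}

#' Outcome frequencies and death / hospitalization rates
#'
#' Reports every outcome code's frequency and the death and hospitalization
#' rates under both denominators: all cases, and cases with at least one
#' recorded outcome. When no case carries an outcome the with-outcome rates
#' are undefined (NA) and flagged.
#'
#' @param cohort a \code{faers_reports} object restricted to the cohort.
#' @return list with \code{n_cases}, \code{n_with_outcome}, \code{counts}
#'   (named by outcome code), \code{death_rate}, \code{hosp_rate},
#'   \code{death_rate_with_outcome}, \code{hosp_rate_with_outcome},
#'   \code{undefined_with_outcome}.
#' @export
outcome_rates <- function(cohort) {
  n_cases <- n_reports(cohort)
  oc <- cohort$outc
  n_with <- length(unique(oc$primaryid))
  counts <- table(factor(oc$outc_cod, levels = names(outcome_labels)))
  rate <- function(code, denom) {
    if (denom == 0) NA_real_ else unname(counts[code]) / denom
  }
  list(n_cases = n_cases, n_with_outcome = n_with,
       counts = stats::setNames(as.integer(counts), names(counts)),
       death_rate = rate("DE", n_cases), hosp_rate = rate("HO", n_cases),
       death_rate_with_outcome = rate("DE", n_with),
       hosp_rate_with_outcome = rate("HO", n_with),
       undefined_with_outcome = n_with == 0)
}

#' Compare two proportions
#'
#' Two-sided Fisher exact test by default; Pearson's chi-squared (no
#' continuity correction) when \code{method = "pearson_chi2"} and all
#' expected counts are at least 5 (otherwise falls back to Fisher with a
#' message).
#'
#' @param k1,n1 successes and size of group 1.
#' @param k2,n2 successes and size of group 2.
#' @param method \code{"fisher_exact"} or \code{"pearson_chi2"}.
#' @return list with \code{rate1}, \code{rate2}, \code{test_name},
#'   \code{statistic} (NA for Fisher), \code{p_value}, and
#'   \code{significant} at the 0.001 level used in report tables.
#' @export
compare_rates <- function(k1, n1, k2, n2,
                          method = c("fisher_exact", "pearson_chi2")) {
  method <- match.arg(method)
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  if (n1 == 0 || n2 == 0) stop("empty group: rates undefined", call. = FALSE)
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (method == "pearson_chi2") {
    expd <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expd < 5)) {
      pv_log("expected count < 5; using Fisher's exact test instead")
      method <- "fisher_exact"
    }
  }
  if (method == "pearson_chi2") {
    ht <- stats::chisq.test(m, correct = FALSE)
    statistic <- unname(ht$statistic)
  } else {
    ht <- stats::fisher.test(m)
    statistic <- NA_real_
  }
  list(rate1 = k1 / n1, rate2 = k2 / n2, test_name = method,
       statistic = statistic, p_value = unname(ht$p.value),
       significant = unname(ht$p.value) < 0.001)
}

#' Dose summary for an intentional-overdose subset
#'
#' Median and IQR (linear-interpolation quartiles) of doses in grams, and
#' the count at or above a threshold. Missing doses are excluded and
#' counted.
#'
#' @param doses_g numeric vector of doses in grams (NA = missing).
#' @param threshold_g threshold for the at-or-above count (default 12).
#' @return list with \code{n}, \code{median_grams}, \code{iqr} = c(q1, q3),
#'   \code{count_at_or_above_threshold}, \code{threshold_grams},
#'   \code{n_missing}; all-NA summary with a \code{reason} when no doses.
#' @export
#' @examples
#' dose_summary(c(2.4, 12, 23, NA), threshold_g = 12)
dose_summary <- function(doses_g, threshold_g = 12) {
  n_missing <- sum(is.na(doses_g))
  x <- doses_g[!is.na(doses_g)]
  if (length(x) == 0) {
    return(list(n = 0L, median_grams = NA_real_, iqr = c(NA_real_, NA_real_),
                count_at_or_above_threshold = NA_integer_,
                threshold_grams = threshold_g, n_missing = n_missing,
                reason = "no dosed cases"))
  }
  q <- quartiles(x)
  list(n = length(x), median_grams = q[2], iqr = c(q[1], q[3]),
       count_at_or_above_threshold = sum(x >= threshold_g),
       threshold_grams = threshold_g, n_missing = n_missing, reason = NULL)
}

#' Rank complications co-reported with the target event
#'
#' Counts, per non-target reaction PT, the number of cohort cases reporting
#' it alongside the target event; sorted by descending count with
#' alphabetical tie-break.
#'
#' @param cohort a \code{faers_reports} object restricted to the cohort
#'   (cases already matched on the target event).
#' @param target_pts data.frame of target PTs (columns \code{pt},
#'   \code{code}) to exclude from the ranking.
#' @param k number of top complications to keep (default 10); \code{Inf}
#'   for all.
#' @return data.frame with columns \code{rank}, \code{pt}, \code{n_cases}.
#' @export
complication_ranking <- function(cohort, target_pts, k = 10) {
  r <- cohort$reac
  is_target <- (r$pt_code != "" & r$pt_code %in% target_pts$code) |
    toupper(r$pt) %in% toupper(target_pts$pt)
  r <- r[!is_target, , drop = FALSE]
  if (nrow(r) == 0) {
    return(data.frame(rank = integer(), pt = character(), n_cases = integer(),
                      stringsAsFactors = FALSE))
  }
  cnt <- table(r$pt[!duplicated(paste(r$primaryid, toupper(r$pt)))])
  ord <- order(-as.integer(cnt), names(cnt))
  top <- utils::head(ord, k)
  data.frame(rank = seq_along(top), pt = names(cnt)[top],
             n_cases = as.integer(cnt)[top], stringsAsFactors = FALSE)
}

#' Bar chart of the top complications
#' @param ranking data.frame from \code{\link{complication_ranking}}.
#' @param main plot title.
#' @return invisibly, the bar midpoints.
#' @export
plot_complications <- function(ranking, main = "Top complications") {
  old <- graphics::par(mar = c(5, 12, 3, 1)); on.exit(graphics::par(old))
  invisible(graphics::barplot(rev(ranking$n_cases), names.arg = rev(ranking$pt),
                              horiz = TRUE, las = 1, main = main,
                              xlab = "co-reported cases"))
}
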