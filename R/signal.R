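# Disproportionality statistics on a 2x2 report table and their decision
# criteria.
#
# With a = drug+event, b = event only, c = drug only, d = neither,
# N = a+b+c+d and s = sqrt(1/a + 1/b + 1/c + 1/d):
#
#   ROR  = (a/b)/(c/d),            95% CI = ROR * exp(+-1.96 s)
#   PRR  = [a/(a+c)] / [b/(b+d)],  chi2 = Pearson over all four cells
#   IC   = log2( a N / ((a+c)(a+b)) ),   IC025 = IC   * exp(-1.96 s)
#   EBGM =       a N / ((a+c)(a+b)),     EB05  = EBGM * exp(-1.64 s)
#
# The IC025/EB05 bounds are the multiplicative closed forms used by the
# surveillance study this package reproduces; they are NOT the canonical
# BCPNN posterior or gamma-Poisson shrinkage intervals. In particular
# IC025 keeps the sign of IC, so the "IC025 > 0" criterion is equivalent to
# IC > 0 (observed co-reporting above expectation). See the methods
# vignette for the consequences under the null.

cell_se <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

#' Reporting odds ratio with 95\% confidence interval
#'
#' @param t a \code{contingency2x2} (see \code{\link{contingency2x2}}).
#' @param correction additive continuity correction applied to every cell
#'   when any cell is zero (default 0 = report the statistic as undefined).
#' @return list with \code{ror}, \code{ci95} = c(low, high), and
#'   \code{reason} (NULL, or why the result is undefined/NA).
#' @export
compute_ror <- function(t, correction = 0) {
  w <- with_cells(t, correction)
  if (!is.null(w$reason)) return(list(ror = NA_real_, ci95 = c(NA_real_, NA_real_),
                                      reason = w$reason))
  ror <- (w$a * w$d) / (w$b * w$c)
  s <- cell_se(w$a, w$b, w$c, w$d)
  list(ror = ror, ci95 = ror * exp(c(-1, 1) * 1.96 * s), reason = NULL)
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' The chi-squared statistic is the Pearson sum over all four cells with
#' expectations from the row and column margins; no Yates correction unless
#' \code{yates = TRUE}.
#'
#' @inheritParams compute_ror
#' @param yates apply the Yates continuity correction to chi-squared.
#' @return list with \code{prr}, \code{chi2}, \code{reason}.
#' @export
compute_prr <- function(t, correction = 0, yates = FALSE) {
  w <- with_cells(t, correction)
  if (!is.null(w$reason) && w$zero_margin) {
    return(list(prr = NA_real_, chi2 = NA_real_, reason = w$reason))
  }
  a <- w$a; b <- w$b; c <- w$c; d <- w$d
  if ((a + c) == 0 || (b + d) == 0) {
    return(list(prr = NA_real_, chi2 = NA_real_, reason = "zero margin"))
  }
  prr <- (a / (a + c)) / (b / (b + d))
  n <- a + b + c + d
  obs <- c(a, b, c, d)
  expd <- c((a + b) * (a + c), (a + b) * (b + d),
            (c + d) * (a + c), (c + d) * (b + d)) / n
  if (any(expd == 0)) {
    chi2 <- NA_real_
  } else {
    dev <- abs(obs - expd)
    if (yates) dev <- pmax(dev - 0.5, 0)
    chi2 <- sum(dev^2 / expd)
  }
  list(prr = prr, chi2 = chi2,
       reason = if (!is.null(w$reason)) w$reason else NULL)
}

#' Information component (BCPNN) with its printed lower bound
#'
#' \code{ic = log2(aN / ((a+c)(a+b)))}; the bound
#' \code{ic025 = ic * exp(-1.96 s)} is only defined for \code{ic > 0}
#' (logarithm of a non-positive value otherwise) and is then flagged as
#' undefined, not thrown.
#'
#' @inheritParams compute_ror
#' @return list with \code{ic}, \code{ic025}, \code{reason}.
#' @export
compute_bcpnn <- function(t, correction = 0) {
  w <- with_cells(t, correction)
  if (!is.null(w$reason)) return(list(ic = NA_real_, ic025 = NA_real_,
                                      reason = w$reason))
  rrr <- w$a * w$n / ((w$a + w$c) * (w$a + w$b))
  ic <- log2(rrr)
  if (ic <= 0) {
    return(list(ic = ic, ic025 = NA_real_, reason = "ic <= 0: lower bound undefined"))
  }
  s <- cell_se(w$a, w$b, w$c, w$d)
  list(ic = ic, ic025 = ic * exp(-1.96 * s), reason = NULL)
}

#' Empirical Bayes geometric mean (MGPS closed form) with EB05
#'
#' \code{ebgm = aN / ((a+c)(a+b))} (identically \code{2^ic}) and
#' \code{eb05 = ebgm * exp(-1.64 s)}, the one-sided 95\% lower bound.
#'
#' @inheritParams compute_ror
#' @return list with \code{ebgm}, \code{eb05}, \code{reason}.
#' @export
compute_mgps <- function(t, correction = 0) {
  w <- with_cells(t, correction)
  if (!is.null(w$reason)) return(list(ebgm = NA_real_, eb05 = NA_real_,
                                      reason = w$reason))
  ebgm <- w$a * w$n / ((w$a + w$c) * (w$a + w$b))
  s <- cell_se(w$a, w$b, w$c, w$d)
  list(ebgm = ebgm, eb05 = ebgm * exp(-1.64 * s), reason = NULL)
}

# shared zero-cell handling: correction > 0 adds it to every cell,
# correction = 0 marks the statistics undefined
with_cells <- function(t, correction) {
  stopifnot(inherits(t, "contingency2x2"))
  # numeric: margin products overflow 32-bit integers at FAERS scale
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  zero <- any(c(a, b, c, d) == 0)
  if (zero && correction > 0) {
    a <- a + correction; b <- b + correction
    c <- c + correction; d <- d + correction
    zero <- FALSE
  }
  list(a = a, b = b, c = c, d = d, n = a + b + c + d,
       zero_margin = zero,
       reason = if (zero) "zero cell (no continuity correction)" else NULL)
}

#' Compute all four disproportionality statistics for one pair
#'
#' @param t a \code{contingency2x2}, or the cell \code{a} when \code{b,c,d}
#'   are given.
#' @param b,c,d optional cell counts when \code{t} is given as \code{a}.
#' @param correction additive continuity correction for zero cells
#'   (0 = undefined results instead).
#' @param yates Yates correction for the chi-squared.
#' @return object of class \code{signal_scores}: \code{n} (co-occurrence
#'   count a), \code{ror}, \code{ror_low}, \code{ror_high}, \code{prr},
#'   \code{chi2}, \code{ic}, \code{ic025}, \code{ebgm}, \code{eb05},
#'   \code{criteria} (see \code{\link{evaluate_criteria}}) and
#'   \code{reasons} for any undefined member.
#' @export
#' @examples
#' s <- signal_scores(contingency2x2(40, 10, 10, 40))
#' s$ebgm            # 1.6
#' s$criteria$any_positive
signal_scores <- function(t, b = NULL, c = NULL, d = NULL,
                          correction = 0, yates = FALSE) {
  if (!inherits(t, "contingency2x2")) t <- contingency2x2(t, b, c, d)
  ror <- compute_ror(t, correction)
  prr <- compute_prr(t, correction, yates)
  bc <- compute_bcpnn(t, correction)
  mg <- compute_mgps(t, correction)
  s <- structure(list(
    n = t$a, table = t,
    ror = ror$ror, ror_low = ror$ci95[1], ror_high = ror$ci95[2],
    prr = prr$prr, chi2 = prr$chi2,
    ic = bc$ic, ic025 = bc$ic025,
    ebgm = mg$ebgm, eb05 = mg$eb05,
    reasons = Filter(Negate(is.null),
                     list(ror = ror$reason, prr = prr$reason,
                          bcpnn = bc$reason, mgps = mg$reason))),
    class = "signal_scores")
  s$criteria <- evaluate_criteria(s)
  s
}

#' Evaluate the four signal criteria
#'
#' Criteria: ROR -- lower 95\% CI bound > 1 and N >= 2; PRR -- PRR >= 2,
#' chi-squared >= 4 and N >= 3; BCPNN -- IC025 > 0; MGPS -- EB05 >= 2 and
#' N > 0. An undefined statistic never satisfies its criterion. The pair is
#' a positive signal if at least one algorithm meets its criterion.
#'
#' @param s a \code{signal_scores} object, or any list carrying the fields
#'   \code{n, ror_low, prr, chi2, ic025, eb05} (e.g. values transcribed from
#'   a published signal table).
#' @return list of logicals \code{ror_positive}, \code{prr_positive},
#'   \code{bcpnn_positive}, \code{mgps_positive}, \code{any_positive}.
#' @export
#' @examples
#' # all four criteria met:
#' evaluate_criteria(list(n = 2451, ror_low = 2.36, prr = 2.39,
#'                        chi2 = 2002.94, ic025 = 1.20, eb05 = 2.30))
evaluate_criteria <- function(s) {
  met <- function(x, test) !is.null(x) && !is.na(x) && test(x)
  flags <- list(
    ror_positive = met(s$ror_low, function(x) x > 1) &&
      met(s$n, function(x) x >= 2),
    prr_positive = met(s$prr, function(x) x >= 2) &&
      met(s$chi2, function(x) x >= 4) && met(s$n, function(x) x >= 3),
    bcpnn_positive = met(s$ic025, function(x) x > 0),
    mgps_positive = met(s$eb05, function(x) x >= 2) &&
      met(s$n, function(x) x > 0))
  flags$any_positive <- flags$ror_positive || flags$prr_positive ||
    flags$bcpnn_positive || flags$mgps_positive
  flags
}

#' @export
print.signal_scores <- function(x, ...) {
  f2 <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", round_half_up(v, 2)))
  star <- function(flag) if (isTRUE(flag)) "*" else ""
  cr <- x$criteria
  cat(sprintf("signal scores (N = %d; a,b,c,d = %d,%d,%d,%d)\n",
              x$n, x$table$a, x$table$b, x$table$c, x$table$d))
  cat(sprintf("  ROR  %s (%s, %s)%s\n", f2(x$ror), f2(x$ror_low),
              f2(x$ror_high), star(cr$ror_positive)))
  cat(sprintf("  PRR  %s (chi2 %s)%s\n", f2(x$prr), f2(x$chi2),
              star(cr$prr_positive)))
  cat(sprintf("  IC   %s (IC025 %s)%s\n", f2(x$ic), f2(x$ic025),
              star(cr$bcpnn_positive)))
  cat(sprintf("  EBGM %s (EB05 %s)%s\n", f2(x$ebgm), f2(x$eb05),
              star(cr$mgps_positive)))
  cat(if (cr$any_positive) "  => positive signal (>=1 criterion met)\n"
      else "  => no signal\n")
  if (length(x$reasons)) {
    cat("  undefined:", paste(sprintf("%s (%s)", names(x$reasons),
                                      unlist(x$reasons)), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.signal_scores <- function(x, ...) {
  cr <- x$criteria
  data.frame(a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
             ROR = x$ror, ROR_low = x$ror_low, ROR_high = x$ror_high,
             PRR = x$prr, chi2 = x$chi2, IC = x$ic, IC025 = x$ic025,
             EBGM = x$ebgm, EB05 = x$eb05,
             ror_positive = cr$ror_positive, prr_positive = cr$prr_positive,
             bcpnn_positive = cr$bcpnn_positive, mgps_positive = cr$mgps_positive,
             any_positive = cr$any_positive, stringsAsFactors = FALSE)
}

#' Screen drug-event pairs across a report universe
#'
#' Builds the 2x2 table and all four statistics for every combination of
#' drug configuration and Preferred Term set.
#'
#' @param reports a deduplicated \code{faers_reports} object.
#' @param drug_configs list of \code{cohort_config} objects (one per drug).
#' @param pt_sets named list of PT data.frames (columns \code{pt},
#'   \code{code}); default: each config's own target set.
#' @param correction,yates passed to \code{\link{signal_scores}}.
#' @return data.frame with one row per (drug, pt-set) pair: identifiers,
#'   cells, statistics, criterion flags and any undefined-reason annotation;
#'   rows ordered by drug then pt-set name.
#' @export
screen_pairs <- function(reports, drug_configs, pt_sets = NULL,
                         correction = 0, yates = FALSE) {
  if (inherits(drug_configs, "cohort_config")) drug_configs <- list(drug_configs)
  if (!is.null(pt_sets) && length(pt_sets) == 0) {
    return(data.frame(drug = character(), pt_set = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- list()
  for (cf in drug_configs) {
    sets <- if (is.null(pt_sets)) {
      stats::setNames(list(cf$target_pts), cf$drug)
    } else pt_sets
    for (ps_name in sort(names(sets))) {
      cf2 <- cf
      cf2$target_pts <- sets[[ps_name]]
      t <- build_contingency(reports, cf2)
      s <- signal_scores(t, correction = correction, yates = yates)
      row <- cbind(data.frame(drug = cf$drug, pt_set = ps_name,
                              stringsAsFactors = FALSE),
                   as.data.frame(s))
      row$note <- if (length(s$reasons)) {
        paste(sprintf("%s: %s", names(s$reasons), unlist(s$reasons)),
              collapse = "; ")
      } else ""
      rows[[paste(cf$drug, ps_name)]] <- row
    }
  }
  reset_rows(do.call(rbind, rows))
}

#' Write a signal table to CSV
#' @param x data.frame from \code{\link{screen_pairs}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_signal_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
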