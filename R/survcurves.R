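#' Kaplan-Meier dementia-free survival curve
#'
#' Product-limit estimator with Greenwood standard errors, computed with
#' the survival package. At tied times events precede censorings (the
#' standard convention). The median is the first time at which the
#' survival estimate drops to 0.5 or below; the mean is the restricted
#' mean up to the largest observed time.
#'
#' @param times follow-up times in months (> 0).
#' @param events logical/0-1 event (conversion) indicators.
#' @return a `km_curve`: `time`, `n_risk`, `n_event`, `survival`, `se`
#'   (Greenwood), `median` (`NA` if the curve never reaches 0.5),
#'   `restricted_mean`, `restricted_mean_se`, `n`, `n_events`, `n_censored`,
#'   and the underlying `survfit` object.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) > 0, all(times > 0))
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  smry <- summary(fit)
  tbl <- summary(fit, rmean = max(times))$table
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  structure(list(time = smry$time, n_risk = smry$n.risk,
                 n_event = smry$n.event, survival = smry$surv,
                 se = smry$std.err,
                 median = med,
                 restricted_mean = unname(tbl["rmean"]),
                 restricted_mean_se = unname(tbl["se(rmean)"]),
                 n = length(times), n_events = sum(events),
                 n_censored = sum(events == 0),
                 fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: n = %d (%d events, %d censored); median %s, restricted mean %.1f +/- %.1f months\n",
              x$n, x$n_events, x$n_censored,
              if (is.na(x$median)) "not reached" else sprintf("%.1f", x$median),
              x$restricted_mean, x$restricted_mean_se))
  invisible(x)
}

#' Survival probability at a given time
#'
#' Step-function evaluation of a [km_estimate()] curve.
#'
#' @param km a `km_curve`.
#' @param t time in months.
#' @return estimated S(t).
#' @export
km_survival_at <- function(km, t) {
  if (length(km$time) == 0 || t < min(km$time)) return(1)
  idx <- max(which(km$time <= t))
  km$survival[idx]
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' @param times_a,events_a follow-up and event indicators, group A.
#' @param times_b,events_b same for group B.
#' @return list with `chi_sq`, `df` (= 1), `p`, `observed`, `expected`.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) > 0, length(times_b) > 0)
  times <- c(times_a, times_b)
  events <- as.integer(as.logical(c(events_a, events_b)))
  grp <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  if (sum(events) == 0) {
    return(list(chi_sq = 0, df = 1L, p = 1, observed = c(0, 0),
                expected = c(0, 0)))
  }
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ grp)
  list(chi_sq = unname(sd_$chisq), df = 1L,
       p = stats::pchisq(sd_$chisq, 1, lower.tail = FALSE),
       observed = unname(sd_$obs), expected = unname(sd_$exp))
}

#' Conversion summary for the MCI follow-up analysis
#'
#' Computes, among MCI subjects with follow-up: the crude percentage of
#' converters among PIB-positives, the negative predictive value
#' (percentage of PIB-negatives who did not convert), and the annual
#' conversion rate of the positive group, operationalized as
#' `100 * (1 - S_KM(12 months))`; a person-years estimate
#' (`100 * converters / total follow-up years`) is reported alongside
#' because the derivation behind a single published annual rate is rarely
#' stated.
#'
#' @param cohort data.frame with columns `diagnosis`, `classification`
#'   (`"positive"`/`"negative"`), `followup_months`, `converted`,
#'   `conversion_month`.
#' @return list of summary quantities (fields are `NA` with a warning when
#'   a stratum is empty).
#' @export
conversion_summary <- function(cohort) {
  mci <- cohort[cohort$diagnosis == "MCI" & !is.na(cohort$followup_months), ,
                drop = FALSE]
  if (nrow(mci) == 0) stop("no MCI subjects with follow-up", call. = FALSE)
  pos <- mci[mci$classification == "positive", , drop = FALSE]
  neg <- mci[mci$classification == "negative", , drop = FALSE]

  out <- list(n_positive = nrow(pos), n_negative = nrow(neg),
              n_converted_positive = sum(pos$converted, na.rm = TRUE),
              n_converted_negative = sum(neg$converted, na.rm = TRUE),
              crude_pct_positive_converted = NA_real_, npv_pct = NA_real_,
              annual_rate_pct = NA_real_, person_years_rate_pct = NA_real_,
              km_median = NA_real_, km_restricted_mean = NA_real_,
              km_restricted_mean_se = NA_real_)
  if (nrow(pos) == 0) {
    warning("no PIB-positive MCI subjects; positive-group fields undefined")
  } else {
    out$crude_pct_positive_converted <- 100 * mean(pos$converted)
    tt <- ifelse(pos$converted, pos$conversion_month, pos$followup_months)
    km <- km_estimate(tt, pos$converted)
    out$annual_rate_pct <- 100 * (1 - km_survival_at(km, 12))
    out$person_years_rate_pct <-
      100 * sum(pos$converted) / (sum(tt) / 12)
    out$km_median <- km$median
    out$km_restricted_mean <- km$restricted_mean
    out$km_restricted_mean_se <- km$restricted_mean_se
  }
  if (nrow(neg) == 0) {
    warning("no PIB-negative MCI subjects; NPV undefined")
  } else {
    out$npv_pct <- 100 * mean(!neg$converted)
  }
  out
}
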