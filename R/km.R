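# Survival after a qualifying diagnosis: per-carrier time-to-event rows
# ready for any survival package, plus a reference product-limit estimator
# used to test the export. Death from any cause is the endpoint; time is in
# whole years from diagnosis, which follows from the integer-age data model.

#' Export time-to-event rows for Kaplan-Meier analysis
#'
#' One row per carrier whose first index-organ diagnosis is incident
#' (at or after inclusion, within follow-up) and falls inside the query's
#' age range; carriers never diagnosed are absent. Time runs from diagnosis
#' to exit: `time = (age_at_death or age_at_last_observation) -
#' age_at_diagnosis`, with `event = 1` for death (any cause) and 0 for
#' censoring. Rows with zero follow-up (diagnosed at the last observation,
#' alive) are retained but flagged, so the row count always matches the
#' number of qualifying diagnoses; downstream estimation treats them as
#' censored at time 0.
#'
#' Under the default `censor_policy = "first_target_event"` the number of
#' rows equals the summed event count `d` of [incidence_table()] for the
#' same query with `organs = index_organs`.
#'
#' @param cohort a valid [lynch_cohort].
#' @param query a [query_spec]; its filters, age range and policies select
#'   the qualifying carriers.
#' @param index_organs organ set defining the index diagnosis (default: the
#'   query's target organs).
#' @return A data.frame of class `"km_rows"` with columns `carrier_id`,
#'   `stratum` (gene/gender/organ of the index diagnosis), `time`, `event`,
#'   `zero_followup`. Zero rows when no carrier qualifies.
#' @export
km_export <- function(cohort, query, index_organs = query$organs) {
  stopifnot(inherits(cohort, "lynch_cohort"), inherits(query, "query_spec"))
  if (length(index_organs) == 0L) {
    lc_error("index_organs must be non-empty", "lynchcohort_domain_error")
  }
  q <- query
  q$organs <- index_organs
  w <- carrier_windows(cohort, q)
  w <- w[!is.na(w$event_age) & w$event_age >= q$age_min &
           w$event_age < q$age_max & w$event_age >= w$start, , drop = FALSE]
  time <- w$last_obs - w$event_age
  out <- data.frame(
    carrier_id = w$carrier_id,
    stratum = if (nrow(w)) paste(w$gene, w$gender, w$event_organ, sep = "/")
              else character(),
    time = as.integer(time),
    event = as.integer(w$dead),
    zero_followup = time == 0L & !w$dead,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("km_rows", "data.frame"))
}

#' Product-limit (Kaplan-Meier) survival estimate
#'
#' The standard product-limit estimator over time-to-event rows, provided
#' as a reference implementation for checking exports. At tied times,
#' deaths precede censorings: a row censored at `t` is still in the risk
#' set for deaths at `t`. Survival starts at 1 and is non-increasing.
#'
#' @param rows a data.frame with columns `time` (>= 0) and `event` (1 =
#'   death, 0 = censored), e.g. from [km_export()].
#' @return A data.frame of class `"km_curve"` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#'   Attribute `n` is the number of input rows.
#' @examples
#' km_estimate(data.frame(time = c(1, 2, 3), event = 1))
#' @export
km_estimate <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) {
    lc_error("no rows to estimate from", "lynchcohort_empty_input")
  }
  if (any(rows$time < 0)) {
    lc_error("negative survival time", "lynchcohort_domain_error")
  }
  tt <- sort(unique(rows$time))
  n_risk <- vapply(tt, function(t) sum(rows$time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(rows$time == t & rows$event == 1),
                    numeric(1))
  n_censor <- vapply(tt, function(t) sum(rows$time == t & rows$event == 0),
                     numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv),
            class = c("km_curve", "data.frame"), n = nrow(rows))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Product-limit survival estimate (%d subjects, %d deaths)\n",
              attr(x, "n"), sum(x$n_event)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ..., main = "Survival after diagnosis",
                          xlab = "Years since diagnosis",
                          ylab = "Survival probability") {
  tt <- c(0, x$time)
  ss <- c(1, x$survival)
  graphics::plot(tt, ss, type = "s", ylim = c(0, 1), lwd = 2, main = main,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
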