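# Engine core: left-truncated, right-censored person-time on an integer age
# grid. All interval logic is half-open [a, a+1): a carrier observed from
# inclusion age a to last-observation age b contributes b - a whole
# person-years. A diagnosis at integer age e happened at some point inside
# [e, e+1), so the event's year itself is at-risk time: under event
# censoring the window ends at e + 1, which keeps every rate <= 1 and every
# counted event inside at-risk time.

# Per-carrier selection and window computation, vectorised over the cohort.
# Returns one row per carrier passing the categorical filters and the
# prevalent policy, with the raw risk window [start, end) (not yet clipped
# to the query age range) and the counted first qualifying event age (NA if
# none). This single routine backs incidence_table() and km_export() so the
# two outputs can never disagree on who qualifies.
carrier_windows <- function(cohort, query, organs = query$organs) {
  car <- cohort$carriers
  fu <- cohort$followup
  ev <- cohort$events

  keep <- car$gene %in% query$genes &
    car$gender %in% query$genders &
    car$carrier_status %in% query$statuses
  if (!is.null(query$regions)) keep <- keep & car$region %in% query$regions
  car <- car[keep, , drop = FALSE]
  if (nrow(car) == 0L) {
    return(data.frame(carrier_id = character(), gene = character(),
                      gender = character(), start = integer(),
                      end = integer(), event_age = integer(),
                      event_organ = character(), dead = logical(),
                      last_obs = integer(), stringsAsFactors = FALSE))
  }
  ids <- car$carrier_id
  fu <- fu[match(ids, fu$carrier_id), , drop = FALSE]
  inc <- fu$age_at_inclusion
  last <- fu$age_at_last_observation

  ev <- ev[ev$carrier_id %in% ids, , drop = FALSE]
  ev_idx <- match(ev$carrier_id, ids)
  ev_inc <- inc[ev_idx]
  ev_last <- last[ev_idx]
  is_target <- ev$organ %in% organs
  prevalent <- ev$age_at_diagnosis < ev_inc
  incident <- !prevalent & ev$age_at_diagnosis <= ev_last

  # prevalent-case policy: exclusion is per carrier, the history is kept
  excl <- rep(FALSE, length(ids))
  if (query$prevalent_policy == "exclude_target_organ_prevalent") {
    hit <- unique(ev_idx[prevalent & is_target])
    excl[hit] <- TRUE
  } else if (query$prevalent_policy == "exclude_any_prevalent") {
    excl[unique(ev_idx[prevalent])] <- TRUE
  }

  first_at <- function(use) {
    a <- rep(NA_integer_, length(ids))
    if (any(use)) {
      mins <- tapply(ev$age_at_diagnosis[use], ev_idx[use], min)
      a[as.integer(names(mins))] <- as.integer(mins)
    }
    a
  }
  first_target <- first_at(incident & is_target)
  first_any <- first_at(incident)

  # risk window end and the event that is counted, by censoring policy.
  # Only the first qualifying target-organ event per carrier is ever
  # counted (the carrier is the unit of observation).
  end <- last
  event_age <- rep(NA_integer_, length(ids))
  if (query$censor_policy == "first_target_event") {
    cens <- !is.na(first_target)
    end[cens] <- first_target[cens] + 1L
    event_age <- first_target
  } else if (query$censor_policy == "first_any_cancer") {
    cens <- !is.na(first_any)
    end[cens] <- first_any[cens] + 1L
    # the target event counts only if it is the first cancer overall
    hit <- !is.na(first_target) & first_target == first_any
    event_age[hit] <- first_target[hit]
  } else { # admin_only: window [inc, last); event must fall in at-risk time
    hit <- !is.na(first_target) & first_target < last
    event_age[hit] <- first_target[hit]
  }

  ev_organ <- rep(NA_character_, length(ids))
  has <- which(!is.na(event_age))
  if (length(has)) {
    m <- incident & is_target &
      ev$age_at_diagnosis == event_age[ev_idx] & ev_idx %in% has
    if (any(m)) {
      # ties (two target organs at the same age): first alphabetically
      org <- tapply(ev$organ[m], ev_idx[m], function(o) sort(o)[1L])
      ev_organ[as.integer(names(org))] <- as.character(org)
    }
  }

  out <- data.frame(carrier_id = ids, gene = car$gene, gender = car$gender,
                    start = as.integer(inc), end = as.integer(end),
                    event_age = event_age, event_organ = ev_organ,
                    dead = fu$dead, last_obs = as.integer(last),
                    stringsAsFactors = FALSE)
  out[!excl, , drop = FALSE]
}

#' Risk window for a single carrier
#'
#' Computes the half-open at-risk age interval `[risk_start, risk_end)` for
#' one carrier under a query's prevalent-case and censoring policies.
#' `risk_start` is the age at inclusion (left truncation). `risk_end` is the
#' age at last observation, unless a qualifying incident event censors
#' follow-up, in which case the window ends at `event age + 1` -- the year
#' of diagnosis is itself at-risk time. An empty window (`NULL`) results
#' when the prevalent policy excludes the carrier or the window has no
#' length.
#'
#' @param follow_up a one-row data.frame (or list) with `age_at_inclusion`
#'   and `age_at_last_observation`.
#' @param events data.frame of this carrier's events (`organ`,
#'   `age_at_diagnosis`); may have zero rows.
#' @param query a [query_spec].
#' @return Integer vector `c(risk_start, risk_end)`, or `NULL` for an empty
#'   window.
#' @examples
#' q <- query_spec(organs = "colorectum")
#' fu <- list(age_at_inclusion = 40, age_at_last_observation = 50)
#' risk_window(fu, data.frame(organ = character(),
#'                            age_at_diagnosis = integer()), q)  # 40 50
#' risk_window(fu, data.frame(organ = "colorectum",
#'                            age_at_diagnosis = 45), q)         # 40 46
#' @export
risk_window <- function(follow_up, events, query) {
  inc <- as.integer(follow_up$age_at_inclusion)
  last <- as.integer(follow_up$age_at_last_observation)
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(organ = character(), age_at_diagnosis = integer(),
                         stringsAsFactors = FALSE)
  }
  is_target <- events$organ %in% query$organs
  prevalent <- events$age_at_diagnosis < inc
  if (query$prevalent_policy == "exclude_target_organ_prevalent" &&
      any(prevalent & is_target)) return(NULL)
  if (query$prevalent_policy == "exclude_any_prevalent" && any(prevalent)) {
    return(NULL)
  }
  incident <- !prevalent & events$age_at_diagnosis <= last
  end <- last
  if (query$censor_policy == "first_target_event" && any(incident & is_target)) {
    end <- min(events$age_at_diagnosis[incident & is_target]) + 1L
  } else if (query$censor_policy == "first_any_cancer" && any(incident)) {
    end <- min(events$age_at_diagnosis[incident]) + 1L
  }
  if (inc >= end) return(NULL)
  c(as.integer(inc), as.integer(end))
}

#' Split a risk window into one-year age contributions
#'
#' Expands a half-open window `[a, b)` on the integer age grid into one
#' person-year per covered age: the Lexis expansion along the age axis that
#' underlies every person-year denominator in the package.
#'
#' @param window integer vector `c(a, b)` with `a <= b`, or `NULL`.
#' @return Named integer vector mapping each age year in `[a, b)` to 1;
#'   empty for a zero-length or `NULL` window. The values total `b - a`.
#' @examples
#' split_person_years(c(40, 43))  # 40 -> 1, 41 -> 1, 42 -> 1
#' split_person_years(c(50, 50))  # empty
#' @export
split_person_years <- function(window) {
  if (is.null(window) || window[2L] <= window[1L]) {
    return(structure(integer(0), names = character(0)))
  }
  yrs <- seq.int(window[1L], window[2L] - 1L)
  structure(rep(1L, length(yrs)), names = as.character(yrs))
}

#' Tabulate events, person-years and annual incidence rates by age cohort
#'
#' The central engine output: for a filtering selection, the number of
#' first incident target-organ events `d`, the person-years at risk `y`,
#' and the annual incidence rate `r = d / y` in each age bin. Carriers are
#' left-truncated at inclusion and censored per the query's policy; an
#' event is counted in the bin containing its age at diagnosis; person-time
#' outside the query's age range is discarded.
#'
#' @param cohort a valid [lynch_cohort].
#' @param query a [query_spec].
#' @return A data.frame of class `"incidence_table"` with columns
#'   `bin_start`, `bin_end`, `d`, `y`, `r` (`r` is `NA`, not 0/0, in bins
#'   with no person-time). Attributes: `query`, `n_carriers` (carriers
#'   contributing to the selection) and `empty_selection` (`TRUE` when no
#'   carrier matches the filters; the table is then all-zero rather than an
#'   error).
#' @seealso [summary.incidence_table()] adds Garwood confidence intervals;
#'   [cumulative_incidence()] accumulates the rates.
#' @export
incidence_table <- function(cohort, query) {
  stopifnot(inherits(cohort, "lynch_cohort"), inherits(query, "query_spec"))
  w <- carrier_windows(cohort, query)
  bins <- query_bins(query)
  nb <- nrow(bins)

  y <- numeric(nb)
  d <- integer(nb)
  if (nrow(w)) {
    # overlap of each carrier window with each bin, in whole years
    for (i in seq_len(nb)) {
      y[i] <- sum(pmax(0L, pmin(w$end, bins$bin_end[i]) -
                         pmax(w$start, bins$bin_start[i])))
    }
    ce <- w$event_age
    ok <- !is.na(ce) & ce >= query$age_min & ce < query$age_max &
      ce >= w$start
    if (any(ok)) {
      idx <- findInterval(ce[ok], c(bins$bin_start, query$age_max))
      tab <- tabulate(idx, nbins = nb)
      d <- as.integer(tab)
    }
  }
  out <- data.frame(bin_start = bins$bin_start, bin_end = bins$bin_end,
                    d = d, y = as.numeric(y),
                    r = ifelse(y > 0, d / y, NA_real_))
  structure(out,
            class = c("incidence_table", "data.frame"),
            query = query,
            n_carriers = nrow(w),
            empty_selection = nrow(w) == 0L)
}

#' @export
print.incidence_table <- function(x, ...) {
  q <- attr(x, "query")
  cat(sprintf("Age-cohort incidence table (%s; %d carrier(s) in selection)\n",
              paste(q$organs, collapse = "+"), attr(x, "n_carriers")))
  if (isTRUE(attr(x, "empty_selection"))) {
    cat("  [empty selection: no carrier matches the filters]\n")
  }
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("  total: d = %d, y = %s person-years\n", sum(x$d),
              format(sum(x$y))))
  invisible(x)
}

#' Per-bin rates with exact Poisson confidence intervals
#'
#' @param object an [incidence_table()].
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return The table with `ci_low` and `ci_high` columns added (Garwood
#'   intervals; `NA` where `y = 0`), plus a pooled-total attribute
#'   `pooled` (a one-row [poisson_ci()] result over all bins).
#' @export
summary.incidence_table <- function(object, level = 0.95, ...) {
  out <- as.data.frame(object)
  out$ci_low <- NA_real_
  out$ci_high <- NA_real_
  has <- out$y > 0
  if (any(has)) {
    ci <- poisson_ci(out$d[has], out$y[has], level = level)
    out$ci_low[has] <- ci$ci_low
    out$ci_high[has] <- ci$ci_high
  }
  pooled <- if (sum(object$y) > 0) {
    poisson_ci(sum(object$d), sum(object$y), level = level)
  }
  structure(out, class = c("summary.incidence_table", "data.frame"),
            pooled = pooled, level = level)
}

#' @export
print.summary.incidence_table <- function(x, ...) {
  cat(sprintf("Age-cohort rates with %g%% Garwood intervals\n",
              100 * attr(x, "level")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  p <- attr(x, "pooled")
  if (!is.null(p)) {
    cat(sprintf("  pooled rate: %.5f (%.5f, %.5f) per person-year\n",
                p$rate, p$ci_low, p$ci_high))
  }
  invisible(x)
}

#' @export
plot.incidence_table <- function(x, ..., main = "Annual incidence by age",
                                 xlab = "Age (years)",
                                 ylab = "Events per person-year") {
  mid <- (x$bin_start + x$bin_end) / 2
  graphics::plot(mid, x$r, type = "s", main = main, xlab = xlab, ylab = ylab,
                 ...)
  graphics::points(mid, x$r, pch = 16)
  invisible(x)
}

#' Carrier head counts by status and region
#'
#' Counts the carriers included in the cohort by carrier status and
#' geographical region. This is a head count of everyone in the cohort --
#' including non-carriers, carriers of unknown status and carriers with
#' zero person-years of follow-up -- not a person-time denominator.
#'
#' @param cohort a [lynch_cohort].
#' @return A data.frame of class `"carrier_counts"` with columns
#'   `carrier_status`, `region`, `n`, sorted by status then region, with a
#'   `total` attribute equal to the number of carriers. Counts always sum
#'   to the total and are invariant to input row order.
#' @export
carrier_counts <- function(cohort) {
  stopifnot(inherits(cohort, "lynch_cohort"))
  car <- cohort$carriers
  if (nrow(car) == 0L) {
    out <- data.frame(carrier_status = character(), region = character(),
                      n = integer(), stringsAsFactors = FALSE)
  } else {
    agg <- as.data.frame(table(carrier_status = car$carrier_status,
                               region = car$region),
                         stringsAsFactors = FALSE)
    agg <- agg[agg$Freq > 0L, , drop = FALSE]
    out <- data.frame(carrier_status = agg$carrier_status,
                      region = agg$region, n = as.integer(agg$Freq),
                      stringsAsFactors = FALSE)
    out <- out[order(out$carrier_status, out$region), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("carrier_counts", "data.frame"),
            total = nrow(car))
}

#' @export
print.carrier_counts <- function(x, ...) {
  cat("Carriers included, by carrier status and region\n")
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  cat(sprintf("  total: %d\n", attr(x, "total")))
  invisible(x)
}
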