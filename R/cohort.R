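#' Construct a carrier-centric cohort
#'
#' Assembles the three cohort tables into a single object. The carrier is
#' the primary unit of observation: each carrier appears exactly once in
#' `carriers`, holds exactly one prospective follow-up window in `followup`,
#' and zero or more diagnosed cancers in `events`. Events diagnosed before
#' the inclusion age are legal data (prevalent history); they are retained
#' and handled by the prevalent-case policy at query time, never deleted.
#'
#' @param carriers data.frame with columns `carrier_id`, `gene`, `gender`,
#'   `region`, `carrier_status`.
#' @param followup data.frame with columns `carrier_id`, `age_at_inclusion`,
#'   `age_at_last_observation`, `dead` (logical or 0/1), `age_at_death`
#'   (`NA` unless dead).
#' @param events data.frame with columns `carrier_id`, `organ`,
#'   `age_at_diagnosis`. May have zero rows.
#' @param gene_levels,organ_levels controlled vocabularies to validate
#'   against; defaults are [mmr_genes] and [organ_vocabulary].
#' @param validate if `TRUE` (default), run [validate_cohort()] and fail with
#'   a classed `lynchcohort_validation_error` on any violation. Set to
#'   `FALSE` to build a deliberately inconsistent cohort for inspection.
#'
#' @return An object of class `"lynch_cohort"`: a list with elements
#'   `carriers`, `followup`, `events`, `gene_levels`, `organ_levels`.
#' @seealso [validate_cohort()], [read_cohort()], [incidence_table()]
#' @examples
#' coh <- lynch_cohort(
#'   carriers = data.frame(carrier_id = "C1", gene = "MLH1",
#'                         gender = "female", region = "NO",
#'                         carrier_status = "pathogenic"),
#'   followup = data.frame(carrier_id = "C1", age_at_inclusion = 40L,
#'                         age_at_last_observation = 50L, dead = FALSE,
#'                         age_at_death = NA_integer_),
#'   events = data.frame(carrier_id = character(), organ = character(),
#'                       age_at_diagnosis = integer())
#' )
#' coh
#' @export
lynch_cohort <- function(carriers, followup, events = NULL,
                         gene_levels = mmr_genes,
                         organ_levels = organ_vocabulary,
                         validate = TRUE) {
  carriers <- as.data.frame(carriers, stringsAsFactors = FALSE)
  followup <- as.data.frame(followup, stringsAsFactors = FALSE)
  if (is.null(events)) {
    events <- data.frame(carrier_id = character(), organ = character(),
                         age_at_diagnosis = integer(),
                         stringsAsFactors = FALSE)
  }
  events <- as.data.frame(events, stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      lc_error(sprintf("%s table is missing column(s): %s", what,
                       paste(miss, collapse = ", ")),
               "lynchcohort_missing_column", columns = miss)
    }
  }
  need(carriers, c("carrier_id", "gene", "gender", "region",
                   "carrier_status"), "carriers")
  need(followup, c("carrier_id", "age_at_inclusion",
                   "age_at_last_observation", "dead", "age_at_death"),
       "followup")
  need(events, c("carrier_id", "organ", "age_at_diagnosis"), "events")

  carriers$carrier_id <- as.character(carriers$carrier_id)
  followup$carrier_id <- as.character(followup$carrier_id)
  events$carrier_id <- as.character(events$carrier_id)
  followup$dead <- as.logical(followup$dead)

  x <- structure(
    list(carriers = carriers, followup = followup, events = events,
         gene_levels = gene_levels, organ_levels = organ_levels),
    class = "lynch_cohort")
  if (validate) {
    rep <- validate_cohort(x)
    if (nrow(rep) > 0L) {
      lc_error(
        sprintf("cohort failed validation with %d violation(s); first: [%s] %s (%s)",
                nrow(rep), rep$carrier_id[1L], rep$rule[1L], rep$detail[1L]),
        "lynchcohort_validation_error", report = rep)
    }
  }
  x
}

#' Check every cohort invariant
#'
#' Examines a cohort against the full set of structural invariants and
#' returns a report of every violation found -- it never stops at the first.
#' Violations are data, not exceptions: an empty report means the cohort is
#' valid and will be accepted by every downstream operation.
#'
#' Rules checked (rule codes in the report):
#' \describe{
#'   \item{duplicate_carrier_id}{a carrier id occurs more than once (the
#'     carrier must never be duplicated or split)}
#'   \item{unknown_gene / unknown_gender / unknown_carrier_status /
#'     unknown_organ}{label outside the configured vocabulary}
#'   \item{missing_followup / duplicate_followup / orphan_followup /
#'     orphan_event}{exactly one follow-up window per carrier; every row
#'     must reference an existing carrier}
#'   \item{non_integer_age / age_out_of_range}{ages are whole years in
#'     \[0, 110\]}
#'   \item{inclusion_after_last_observation}{age at inclusion must not
#'     exceed age at last observation}
#'   \item{death_age_mismatch}{dead carriers need an age at death equal to
#'     the age at last observation; alive carriers must have none}
#'   \item{event_after_last_observation}{a diagnosis recorded after the end
#'     of observation}
#' }
#'
#' @param cohort a [lynch_cohort] object (typically built with
#'   `validate = FALSE` when violations are expected).
#' @return A data.frame of class `"cohort_validation"` with columns
#'   `carrier_id`, `rule`, `detail`; zero rows when the cohort is valid.
#'   The function is pure: calling it twice returns identical reports.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "lynch_cohort"))
  car <- cohort$carriers
  fu <- cohort$followup
  ev <- cohort$events
  out <- list()
  add <- function(id, rule, detail) {
    out[[length(out) + 1L]] <<- data.frame(
      carrier_id = as.character(id), rule = rule, detail = detail,
      stringsAsFactors = FALSE)
  }

  dup <- unique(car$carrier_id[duplicated(car$carrier_id)])
  for (id in dup) add(id, "duplicate_carrier_id", "carrier_id occurs more than once")

  bad <- !(car$gene %in% cohort$gene_levels)
  for (i in which(bad)) {
    add(car$carrier_id[i], "unknown_gene", sprintf("gene '%s'", car$gene[i]))
  }
  bad <- !(car$gender %in% genders)
  for (i in which(bad)) {
    add(car$carrier_id[i], "unknown_gender", sprintf("gender '%s'", car$gender[i]))
  }
  bad <- !(car$carrier_status %in% carrier_statuses)
  for (i in which(bad)) {
    add(car$carrier_id[i], "unknown_carrier_status",
        sprintf("carrier_status '%s'", car$carrier_status[i]))
  }

  ids <- unique(car$carrier_id)
  for (id in setdiff(ids, fu$carrier_id)) {
    add(id, "missing_followup", "carrier has no follow-up record")
  }
  for (id in unique(fu$carrier_id[duplicated(fu$carrier_id)])) {
    add(id, "duplicate_followup", "more than one follow-up record")
  }
  for (id in setdiff(fu$carrier_id, ids)) {
    add(id, "orphan_followup", "follow-up references unknown carrier")
  }
  for (id in unique(setdiff(ev$carrier_id, ids))) {
    add(id, "orphan_event", "event references unknown carrier")
  }

  chk_age <- function(id, a, what) {
    ok_num <- is.numeric(a) && is.finite(a)
    if (!ok_num || a != trunc(a)) {
      add(id, "non_integer_age", sprintf("%s = %s", what, format(a)))
    } else if (a < 0 || a > AGE_MAX) {
      add(id, "age_out_of_range", sprintf("%s = %s outside [0, %d]", what,
                                          format(a), AGE_MAX))
    }
  }
  for (i in seq_len(nrow(fu))) {
    id <- fu$carrier_id[i]
    chk_age(id, fu$age_at_inclusion[i], "age_at_inclusion")
    chk_age(id, fu$age_at_last_observation[i], "age_at_last_observation")
    inc <- fu$age_at_inclusion[i]
    last <- fu$age_at_last_observation[i]
    if (is.finite(inc) && is.finite(last) && inc > last) {
      add(id, "inclusion_after_last_observation",
          sprintf("inclusion %s > last observation %s", inc, last))
    }
    dead <- isTRUE(fu$dead[i])
    aod <- fu$age_at_death[i]
    if (dead) {
      if (is.na(aod)) {
        add(id, "death_age_mismatch", "dead but age_at_death absent")
      } else {
        chk_age(id, aod, "age_at_death")
        if (is.finite(last) && is.finite(aod) && aod != last) {
          add(id, "death_age_mismatch",
              sprintf("age_at_death %s != age_at_last_observation %s", aod, last))
        }
      }
    } else if (!is.na(aod)) {
      add(id, "death_age_mismatch", "alive but age_at_death present")
    }
  }

  last_by_id <- fu$age_at_last_observation[match(ev$carrier_id, fu$carrier_id)]
  for (i in seq_len(nrow(ev))) {
    id <- ev$carrier_id[i]
    if (!(ev$organ[i] %in% cohort$organ_levels)) {
      add(id, "unknown_organ", sprintf("organ '%s'", ev$organ[i]))
    }
    chk_age(id, ev$age_at_diagnosis[i], "age_at_diagnosis")
    if (!is.na(last_by_id[i]) && is.finite(ev$age_at_diagnosis[i]) &&
        ev$age_at_diagnosis[i] > last_by_id[i]) {
      add(id, "event_after_last_observation",
          sprintf("diagnosis at %s after last observation %s",
                  ev$age_at_diagnosis[i], last_by_id[i]))
    }
  }

  rep <- if (length(out)) do.call(rbind, out) else {
    data.frame(carrier_id = character(), rule = character(),
               detail = character(), stringsAsFactors = FALSE)
  }
  class(rep) <- c("cohort_validation", "data.frame")
  rep
}

#' @export
print.cohort_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Cohort validation: no violations.\n")
  } else {
    cat(sprintf("Cohort validation: %d violation(s)\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.lynch_cohort <- function(x, ...) {
  cat(sprintf("Prospective carrier cohort: %d carriers, %d events\n",
              nrow(x$carriers), nrow(x$events)))
  cat(sprintf("  genes:  %s\n",
              paste(names(table(x$carriers$gene)), table(x$carriers$gene),
                    sep = "=", collapse = ", ")))
  py <- sum(pmax(x$followup$age_at_last_observation -
                   x$followup$age_at_inclusion, 0))
  cat(sprintf("  follow-up: %s person-years (inclusion to last observation)\n",
              format(py)))
  invisible(x)
}

#' @export
summary.lynch_cohort <- function(object, ...) {
  fu <- object$followup
  s <- list(
    n_carriers = nrow(object$carriers),
    n_events = nrow(object$events),
    by_gene_gender = table(gene = object$carriers$gene,
                           gender = object$carriers$gender),
    by_organ = if (nrow(object$events)) table(object$events$organ) else table(character()),
    person_years = sum(pmax(fu$age_at_last_observation - fu$age_at_inclusion, 0)),
    inclusion_age = summary(fu$age_at_inclusion),
    deaths = sum(fu$dead, na.rm = TRUE)
  )
  class(s) <- "summary.lynch_cohort"
  s
}

#' @export
print.summary.lynch_cohort <- function(x, ...) {
  cat(sprintf("Carriers: %d   Events: %d   Deaths: %d   Person-years: %s\n",
              x$n_carriers, x$n_events, x$deaths, format(x$person_years)))
  cat("\nCarriers by gene and gender:\n")
  print(x$by_gene_gender)
  if (length(x$by_organ)) {
    cat("\nEvents by organ:\n")
    print(x$by_organ)
  }
  cat("\nAge at inclusion:\n")
  print(x$inclusion_age)
  invisible(x)
}
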