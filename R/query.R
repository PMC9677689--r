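#' Describe a filtering selection for incidence queries
#'
#' A query specification restricts the cohort (genes, genders, regions,
#' carrier statuses), names the target organs that define the event of
#' interest, fixes the age range and bin width of the tabulation, and
#' chooses how prevalent cancers and censoring are handled. Every
#' downstream tabulation consumes one of these objects, so any selection
#' the data admit can be expressed without touching the engine.
#'
#' @param genes character subset of the cohort's gene vocabulary
#'   (default: all four MMR genes).
#' @param genders subset of `c("female", "male")`.
#' @param regions character vector of region labels, or `NULL` for all.
#' @param statuses carrier statuses to include. Defaults to
#'   `"pathogenic"`: non-carriers and carriers of unknown status appear in
#'   [carrier_counts()] but enter incidence computations only when selected
#'   here explicitly.
#' @param organs target organs defining a qualifying event.
#' @param age_min,age_max half-open age range `[age_min, age_max)` in whole
#'   years. Defaults 25 and 75, the usual reporting range for carrier risks.
#' @param bin_width positive integer width of the age cohorts (default 5).
#'   A final narrower bin is created if the range is not a multiple.
#' @param prevalent_policy what to do with carriers whose cancer predates
#'   inclusion: `"exclude_target_organ_prevalent"` (default) drops carriers
#'   with a pre-inclusion cancer in a target organ,
#'   `"exclude_any_prevalent"` drops carriers with any pre-inclusion cancer,
#'   `"include_all"` keeps everyone (prevalent events still never count as
#'   incident events).
#' @param censor_policy when at-risk time ends, beyond administrative
#'   censoring at last observation: `"first_target_event"` (default) ends
#'   follow-up after the year of the first incident target-organ diagnosis,
#'   `"first_any_cancer"` after the first incident diagnosis in any organ,
#'   `"admin_only"` never censors on events.
#'
#' @return An object of class `"query_spec"`.
#' @seealso [incidence_table()], [risk_window()], [km_export()]
#' @examples
#' query_spec(genes = "MSH2", genders = "female", organs = "endometrium")
#' @export
query_spec <- function(genes = mmr_genes,
                       genders = c("female", "male"),
                       regions = NULL,
                       statuses = "pathogenic",
                       organs = "colorectum",
                       age_min = 25L, age_max = 75L,
                       bin_width = 5L,
                       prevalent_policy = c("exclude_target_organ_prevalent",
                                            "exclude_any_prevalent",
                                            "include_all"),
                       censor_policy = c("first_target_event",
                                         "first_any_cancer",
                                         "admin_only")) {
  prevalent_policy <- match.arg(prevalent_policy)
  censor_policy <- match.arg(censor_policy)
  if (!is_count(bin_width) || bin_width < 1) {
    lc_error("bin_width must be a positive integer", "lynchcohort_domain_error")
  }
  if (!is_whole(age_min) || !is_whole(age_max) || age_min >= age_max) {
    lc_error("age range must satisfy integer age_min < age_max",
             "lynchcohort_domain_error")
  }
  bad <- setdiff(genders, c("female", "male"))
  if (length(bad)) {
    lc_error(sprintf("unknown gender(s): %s", paste(bad, collapse = ", ")),
             "lynchcohort_domain_error")
  }
  bad <- setdiff(statuses, carrier_statuses)
  if (length(bad)) {
    lc_error(sprintf("unknown carrier status(es): %s (legal: %s)",
                     paste(bad, collapse = ", "),
                     paste(carrier_statuses, collapse = ", ")),
             "lynchcohort_domain_error")
  }
  if (length(organs) == 0L) {
    lc_error("at least one target organ is required", "lynchcohort_domain_error")
  }
  structure(
    list(genes = genes, genders = genders, regions = regions,
         statuses = statuses, organs = organs,
         age_min = as.integer(age_min), age_max = as.integer(age_max),
         bin_width = as.integer(bin_width),
         prevalent_policy = prevalent_policy, censor_policy = censor_policy),
    class = "query_spec")
}

# bin edges covering [age_min, age_max); last bin may be narrower
query_bins <- function(query) {
  edges <- seq(query$age_min, query$age_max, by = query$bin_width)
  if (edges[length(edges)] < query$age_max) edges <- c(edges, query$age_max)
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1L])
}

#' @export
print.query_spec <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "<all>" else paste(v, collapse = ", ")
  cat("Incidence query\n")
  cat(sprintf("  genes:    %s\n", fmt(x$genes)))
  cat(sprintf("  genders:  %s\n", fmt(x$genders)))
  cat(sprintf("  regions:  %s\n", fmt(x$regions)))
  cat(sprintf("  statuses: %s\n", fmt(x$statuses)))
  cat(sprintf("  target organs: %s\n", fmt(x$organs)))
  cat(sprintf("  ages [%d, %d) in %d-year bins\n", x$age_min, x$age_max,
              x$bin_width))
  cat(sprintf("  prevalent: %s; censoring: %s\n", x$prevalent_policy,
              x$censor_policy))
  invisible(x)
}
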