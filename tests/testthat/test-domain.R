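one_carrier <- function() {
  list(
    carriers = data.frame(carrier_id = "C1", gene = "MLH1",
                          gender = "female", region = "NO",
                          carrier_status = "pathogenic",
                          stringsAsFactors = FALSE),
    followup = data.frame(carrier_id = "C1", age_at_inclusion = 40L,
                          age_at_last_observation = 50L, dead = FALSE,
                          age_at_death = NA_integer_,
                          stringsAsFactors = FALSE),
    events = data.frame(carrier_id = character(), organ = character(),
                        age_at_diagnosis = integer(),
                        stringsAsFactors = FALSE))
}

test_that("a consistent cohort yields an empty validation report", {
  d <- one_carrier()
  coh <- lynch_cohort(d$carriers, d$followup, d$events)
  rep <- validate_cohort(coh)
  expect_s3_class(rep, "cohort_validation")
  expect_identical(nrow(rep), 0L)
})

test_that("validation reports every violation without stopping at the first", {
  d <- one_carrier()
  d$carriers <- rbind(d$carriers, d$carriers)  # duplicated carrier
  d$carriers$gene[2] <- "BRCA1"                # outside vocabulary
  d$followup <- rbind(d$followup, data.frame(
    carrier_id = "C1", age_at_inclusion = 60L,
    age_at_last_observation = 58L,             # inclusion after last obs
    dead = TRUE, age_at_death = 60L,           # death age mismatch
    stringsAsFactors = FALSE))
  d$events <- data.frame(carrier_id = "X9", organ = "colorectum",
                         age_at_diagnosis = 45L, stringsAsFactors = FALSE)
  coh <- lynch_cohort(d$carriers, d$followup, d$events, validate = FALSE)
  rep <- validate_cohort(coh)
  expect_setequal(
    unique(rep$rule),
    c("duplicate_carrier_id", "unknown_gene", "duplicate_followup",
      "inclusion_after_last_observation", "death_age_mismatch",
      "orphan_event"))
  expect_true(any(rep$carrier_id == "C1" & rep$rule == "duplicate_carrier_id"))
  expect_true(any(rep$carrier_id == "X9" & rep$rule == "orphan_event"))
})

test_that("death bookkeeping is checked in both directions", {
  d <- one_carrier()
  d$followup$dead <- TRUE
  d$followup$age_at_death <- 48L  # != last observation 50
  rep <- validate_cohort(lynch_cohort(d$carriers, d$followup, d$events,
                                      validate = FALSE))
  expect_true(any(rep$rule == "death_age_mismatch"))

  d <- one_carrier()
  d$followup$age_at_death <- 50L  # alive but an age at death recorded
  rep <- validate_cohort(lynch_cohort(d$carriers, d$followup, d$events,
                                      validate = FALSE))
  expect_true(any(rep$rule == "death_age_mismatch"))
})

test_that("fractional and out-of-range ages are flagged", {
  d <- one_carrier()
  d$followup$age_at_inclusion <- 40.5
  d$events <- data.frame(carrier_id = "C1", organ = "colorectum",
                         age_at_diagnosis = 120L, stringsAsFactors = FALSE)
  rep <- validate_cohort(lynch_cohort(d$carriers, d$followup, d$events,
                                      validate = FALSE))
  expect_true(any(rep$rule == "non_integer_age"))
  expect_true(any(rep$rule == "age_out_of_range"))
})

test_that("validation is idempotent and side-effect free", {
  coh <- random_cohort(30, seed = 11)
  r1 <- validate_cohort(coh)
  r2 <- validate_cohort(coh)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 0L)
})

test_that("the constructor enforces validity unless told otherwise", {
  d <- one_carrier()
  d$carriers$gene <- "EPCAM"
  expect_error(lynch_cohort(d$carriers, d$followup, d$events),
               class = "lynchcohort_validation_error")
  # the gene set is a configurable enumeration
  coh <- lynch_cohort(d$carriers, d$followup, d$events,
                      gene_levels = c(mmr_genes, "EPCAM"))
  expect_identical(nrow(validate_cohort(coh)), 0L)
})

test_that("query_spec rejects inconsistent selections", {
  expect_error(query_spec(age_min = 50, age_max = 40),
               class = "lynchcohort_domain_error")
  expect_error(query_spec(bin_width = 0),
               class = "lynchcohort_domain_error")
  expect_error(query_spec(genders = "other"),
               class = "lynchcohort_domain_error")
  expect_error(query_spec(organs = character()),
               class = "lynchcohort_domain_error")
})

test_that("valid cohorts are accepted by every downstream operation", {
  coh <- random_cohort(25, seed = 21)
  q <- query_spec(organs = c("colorectum", "endometrium"))
  expect_no_error({
    incidence_table(coh, q)
    carrier_counts(coh)
    km_export(coh, q)
  })
})
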