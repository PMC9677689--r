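q_colo <- function(...) query_spec(organs = "colorectum", ...)

test_that("risk windows honour truncation, event censoring and prevalence", {
  q <- q_colo()
  fu <- list(age_at_inclusion = 40L, age_at_last_observation = 50L)
  no_ev <- data.frame(organ = character(), age_at_diagnosis = integer())

  expect_identical(risk_window(fu, no_ev, q), c(40L, 50L))

  # the diagnosis year itself is at-risk time: window ends after it
  ev45 <- data.frame(organ = "colorectum", age_at_diagnosis = 45L)
  expect_identical(risk_window(fu, ev45, q), c(40L, 46L))

  # a non-target cancer does not censor under first_target_event
  other <- data.frame(organ = "endometrium", age_at_diagnosis = 45L)
  expect_identical(risk_window(fu, other, q), c(40L, 50L))
  q_any <- q_colo(censor_policy = "first_any_cancer")
  expect_identical(risk_window(fu, other, q_any), c(40L, 46L))

  # target-organ cancer before inclusion excludes the carrier by default
  prev <- data.frame(organ = "colorectum", age_at_diagnosis = 38L)
  expect_null(risk_window(fu, prev, q))
  expect_identical(risk_window(fu, prev, q_colo(prevalent_policy = "include_all")),
                   c(40L, 50L))

  # zero-length observation
  fu0 <- list(age_at_inclusion = 50L, age_at_last_observation = 50L)
  expect_null(risk_window(fu0, no_ev, q))
})

test_that("windows split into one person-year per covered age", {
  expect_identical(split_person_years(c(40L, 43L)),
                   c(`40` = 1L, `41` = 1L, `42` = 1L))
  expect_identical(split_person_years(c(23L, 26L)),
                   c(`23` = 1L, `24` = 1L, `25` = 1L))
  expect_length(split_person_years(c(50L, 50L)), 0L)
  expect_length(split_person_years(NULL), 0L)
  for (s in 1:20) {
    a <- sample(0:100, 1)
    b <- a + sample(0:10, 1)
    expect_identical(sum(split_person_years(c(a, b))), b - a)
  }
})

test_that("the fixture cohort tabulates to the hand-computed table", {
  coh <- read_fixture_cohort()
  q <- q_colo(age_min = 40L, age_max = 50L, bin_width = 5L)
  tab <- incidence_table(coh, q)
  expect_identical(tab$bin_start, c(40L, 45L))
  expect_identical(tab$d, c(0L, 1L))
  expect_identical(tab$y, c(10, 6))
  expect_equal(tab$r, c(0, 1 / 6))
  expect_false(attr(tab, "empty_selection"))
})

test_that("tabulation on an empty or non-matching selection is flagged, not an error", {
  coh <- read_fixture_cohort()
  q <- query_spec(genes = "PMS2", organs = "colorectum")
  tab <- incidence_table(coh, q)
  expect_true(attr(tab, "empty_selection"))
  expect_true(all(tab$d == 0L) && all(tab$y == 0))
  expect_true(all(is.na(tab$r)))
})

test_that("doubling every carrier doubles d and y and leaves rates unchanged", {
  coh <- random_cohort(30, seed = 5)
  twice <- coh
  c2 <- coh$carriers
  c2$carrier_id <- paste0(c2$carrier_id, "bis")
  f2 <- coh$followup
  f2$carrier_id <- paste0(f2$carrier_id, "bis")
  e2 <- coh$events
  e2$carrier_id <- paste0(e2$carrier_id, "bis")
  twice <- lynch_cohort(rbind(coh$carriers, c2), rbind(coh$followup, f2),
                        rbind(coh$events, e2))
  q <- q_colo(age_min = 25L, age_max = 75L)
  t1 <- incidence_table(coh, q)
  t2 <- incidence_table(twice, q)
  expect_identical(t2$d, 2L * t1$d)
  expect_identical(t2$y, 2 * t1$y)
  expect_equal(t2$r, t1$r)
})

test_that("adding a gene to the selection never decreases any d or y", {
  coh <- random_cohort(40, seed = 8)
  for (org in list("colorectum", c("endometrium", "ovary"))) {
    smaller <- query_spec(genes = c("MLH1", "MSH6"), organs = org)
    larger <- query_spec(genes = c("MLH1", "MSH6", "MSH2"), organs = org)
    ts <- incidence_table(coh, smaller)
    tl <- incidence_table(coh, larger)
    expect_true(all(tl$d >= ts$d))
    expect_true(all(tl$y >= ts$y))
  }
})

test_that("events counted never exceed carriers at risk in the bin", {
  for (s in 1:10) {
    coh <- random_cohort(30, seed = 300 + s)
    q <- query_spec(organs = sample(organ_vocabulary, 2),
                    censor_policy = "first_target_event",
                    age_min = 20L, age_max = 80L)
    tab <- incidence_table(coh, q)
    expect_true(all(tab$d <= tab$y))
    expect_true(all(is.na(tab$r) | tab$r <= 1))
  }
})

test_that("head counts by status and region sum to the cohort total", {
  coh <- read_fixture_cohort()
  cnt <- carrier_counts(coh)
  expect_identical(attr(cnt, "total"), 3L)
  expect_identical(sum(cnt$n), 3L)
  expect_identical(cnt$n[cnt$region == "NO"], 2L)
  expect_identical(cnt$n[cnt$region == "UK"], 1L)
  expect_true(all(cnt$carrier_status == "pathogenic"))

  # permutation invariance
  coh2 <- lynch_cohort(coh$carriers[c(3, 1, 2), ], coh$followup[c(2, 3, 1), ],
                       coh$events)
  expect_identical(as.data.frame(carrier_counts(coh2)), as.data.frame(cnt))

  empty <- lynch_cohort(coh$carriers[0, ], coh$followup[0, ])
  cnt0 <- carrier_counts(empty)
  expect_identical(nrow(cnt0), 0L)
  expect_identical(attr(cnt0, "total"), 0L)
})

test_that("zero-length follow-up carriers count as heads but contribute no person-time", {
  carriers <- data.frame(carrier_id = "Z1", gene = "MSH2", gender = "male",
                         region = "NO", carrier_status = "pathogenic")
  followup <- data.frame(carrier_id = "Z1", age_at_inclusion = 40L,
                         age_at_last_observation = 40L, dead = FALSE,
                         age_at_death = NA_integer_)
  coh <- lynch_cohort(carriers, followup)
  expect_identical(attr(carrier_counts(coh), "total"), 1L)
  tab <- incidence_table(coh, q_colo(age_min = 25L, age_max = 75L))
  expect_identical(sum(tab$y), 0)
})
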