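# Fixtures built in code: random valid cohorts, random queries, and
# independent brute-force oracles the engine is checked against.

fixture_paths <- function() {
  p <- system.file("extdata", package = "lynchcohort")
  list(carriers = file.path(p, "carriers.csv"),
       followup = file.path(p, "followup.csv"),
       events = file.path(p, "events.csv"))
}

read_fixture_cohort <- function() {
  fp <- fixture_paths()
  read_cohort(fp$carriers, fp$followup, fp$events)
}

random_cohort <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("R%04d", seq_len(n))
  incl <- sample(20:70, n, replace = TRUE)
  len <- sample(0:25, n, replace = TRUE)
  last <- pmin(incl + len, 110L)
  dead <- stats::runif(n) < 0.2
  carriers <- data.frame(
    carrier_id = ids,
    gene = sample(mmr_genes, n, replace = TRUE),
    gender = sample(c("female", "male"), n, replace = TRUE),
    region = sample(c("NO", "UK", "DE"), n, replace = TRUE),
    carrier_status = sample(carrier_statuses, n, replace = TRUE,
                            prob = c(0.8, 0.1, 0.1)),
    stringsAsFactors = FALSE)
  followup <- data.frame(
    carrier_id = ids, age_at_inclusion = incl,
    age_at_last_observation = last, dead = dead,
    age_at_death = ifelse(dead, last, NA_integer_),
    stringsAsFactors = FALSE)
  nev <- stats::rpois(n, 0.8)
  ev <- lapply(which(nev > 0), function(i) {
    lo <- max(0L, incl[i] - 20L)
    data.frame(carrier_id = ids[i],
               organ = sample(organ_vocabulary, nev[i], replace = TRUE),
               age_at_diagnosis = lo +
                 sample.int(last[i] - lo + 1L, nev[i], replace = TRUE) - 1L,
               stringsAsFactors = FALSE)
  })
  events <- if (length(ev)) do.call(rbind, ev) else NULL
  lynch_cohort(carriers, followup, events)
}

random_query <- function(seed) {
  set.seed(seed + 10000L)
  amin <- sample(20:40, 1)
  query_spec(
    genes = sample(mmr_genes, sample(1:4, 1)),
    genders = sample(list("female", "male", c("female", "male")), 1)[[1]],
    regions = sample(list(NULL, "NO", c("NO", "UK")), 1)[[1]],
    statuses = sample(list("pathogenic", carrier_statuses), 1)[[1]],
    organs = sample(organ_vocabulary, sample(1:3, 1)),
    age_min = amin,
    age_max = amin + sample(c(10, 25, 50), 1),
    bin_width = sample(c(1, 5, 10), 1),
    prevalent_policy = sample(c("exclude_target_organ_prevalent",
                                "exclude_any_prevalent", "include_all"), 1),
    censor_policy = sample(c("first_target_event", "first_any_cancer",
                             "admin_only"), 1))
}

# Brute-force person-time oracle: iterates every carrier x every single age
# year and tests membership, attributing person-years and the counted first
# event to bins by linear scan. Deliberately loop-based and independent of
# the engine's interval arithmetic.
oracle_tabulate <- function(cohort, query) {
  edges <- seq(query$age_min, query$age_max, by = query$bin_width)
  if (edges[length(edges)] < query$age_max) edges <- c(edges, query$age_max)
  nb <- length(edges) - 1L
  d <- integer(nb)
  y <- numeric(nb)
  car <- cohort$carriers
  for (i in seq_len(nrow(car))) {
    if (!(car$gene[i] %in% query$genes)) next
    if (!(car$gender[i] %in% query$genders)) next
    if (!is.null(query$regions) && !(car$region[i] %in% query$regions)) next
    if (!(car$carrier_status[i] %in% query$statuses)) next
    f <- cohort$followup[cohort$followup$carrier_id == car$carrier_id[i], ]
    e <- cohort$events[cohort$events$carrier_id == car$carrier_id[i], ,
                       drop = FALSE]
    inc <- f$age_at_inclusion
    last <- f$age_at_last_observation
    is_t <- e$organ %in% query$organs
    prev <- e$age_at_diagnosis < inc
    if (query$prevalent_policy == "exclude_target_organ_prevalent" &&
        any(prev & is_t)) next
    if (query$prevalent_policy == "exclude_any_prevalent" && any(prev)) next
    inc_ev <- !prev & e$age_at_diagnosis <= last
    ft <- if (any(inc_ev & is_t)) min(e$age_at_diagnosis[inc_ev & is_t]) else NA
    fa <- if (any(inc_ev)) min(e$age_at_diagnosis[inc_ev]) else NA
    end <- last
    ce <- NA
    if (query$censor_policy == "first_target_event") {
      if (!is.na(ft)) end <- ft + 1L
      ce <- ft
    } else if (query$censor_policy == "first_any_cancer") {
      if (!is.na(fa)) end <- fa + 1L
      if (!is.na(ft) && ft == fa) ce <- ft
    } else {
      if (!is.na(ft) && ft < last) ce <- ft
    }
    for (a in seq.int(inc, length.out = max(0L, end - inc))) {
      if (a >= query$age_min && a < query$age_max) {
        for (b in seq_len(nb)) {
          if (a >= edges[b] && a < edges[b + 1L]) {
            y[b] <- y[b] + 1
            break
          }
        }
      }
    }
    if (!is.na(ce) && ce >= query$age_min && ce < query$age_max && ce >= inc) {
      for (b in seq_len(nb)) {
        if (ce >= edges[b] && ce < edges[b + 1L]) {
          d[b] <- d[b] + 1L
          break
        }
      }
    }
  }
  list(d = d, y = y)
}

# total clipped window length, for the conservation identity
oracle_window_total <- function(cohort, query) {
  tot <- 0L
  fu <- cohort$followup
  keep_ids <- cohort$carriers$carrier_id[
    cohort$carriers$gene %in% query$genes &
      cohort$carriers$gender %in% query$genders &
      cohort$carriers$carrier_status %in% query$statuses &
      (if (is.null(query$regions)) TRUE
       else cohort$carriers$region %in% query$regions)]
  for (id in keep_ids) {
    f <- fu[fu$carrier_id == id, ]
    e <- cohort$events[cohort$events$carrier_id == id, , drop = FALSE]
    w <- risk_window(f, e, query)
    if (is.null(w)) next
    lo <- max(w[1L], query$age_min)
    hi <- min(w[2L], query$age_max)
    tot <- tot + max(0L, hi - lo)
  }
  tot
}

random_km_rows <- function(seed) {
  set.seed(seed + 20000L)
  n <- sample(3:40, 1)
  data.frame(carrier_id = sprintf("K%03d", seq_len(n)),
             stratum = "x",
             time = sample(0:15, n, replace = TRUE),
             event = sample(0:1, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# single-stratum, constant-hazard simulation: the controlled condition used
# for frequency and coverage checks
flat_config <- function(n, h, seed, incl_age = 30L, fu_years = 20L,
                        death = 0) {
  sim_config(
    n_carriers = n,
    gene_probs = c(MLH1 = 1),
    gender_probs = c(female = 1),
    region_probs = c(NO = 1),
    hazard_spec = data.frame(gene = "MLH1", gender = "female",
                             organ = "colorectum", age_lo = 0L,
                             age_hi = 110L, hazard = h),
    inclusion_age_dist = stats::setNames(1, incl_age),
    followup_years_dist = stats::setNames(1, fu_years),
    post_dx_death_hazard = death,
    seed = seed)
}
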