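# Synthetic prospective cohorts with known ground truth. Cancer onset per
# organ is a discrete per-year Bernoulli process: in the year [t, t+1) an
# event occurs with probability p_t = 1 - exp(-h_t), h_t the annual hazard
# of the carrier's (gene, gender, organ) stratum. The discrete form matches
# the integer-age data model exactly, so engine estimates can be compared
# with truth without a continuous-time approximation error.

#' Illustrative default hazard specification
#'
#' A piecewise-constant annual hazard table by gene, gender and organ over
#' the age bands 25-40, 40-50, 50-60 and 60-75 (zero outside). The values
#' are illustrative Lynch-like magnitudes -- higher colorectal hazards for
#' MLH1/MSH2 than MSH6/PMS2, male-dominant colorectal risk for MLH1,
#' substantial gynaecological hazards, MSH2-dominant urinary tract and
#' prostate risk -- chosen to exercise the engine, not calibrated to any
#' published risk table.
#'
#' @return A data.frame with columns `gene`, `gender`, `organ`, `age_lo`,
#'   `age_hi`, `hazard` (events per person-year).
#' @export
default_hazards <- function() {
  band <- function(gene, gender, organ, h) {
    data.frame(gene = gene, gender = gender, organ = organ,
               age_lo = c(25L, 40L, 50L, 60L), age_hi = c(40L, 50L, 60L, 75L),
               hazard = h, stringsAsFactors = FALSE)
  }
  rbind(
    band("MLH1", "male",   "colorectum", c(0.004, 0.012, 0.016, 0.020)),
    band("MLH1", "female", "colorectum", c(0.003, 0.009, 0.012, 0.016)),
    band("MSH2", "male",   "colorectum", c(0.003, 0.010, 0.014, 0.018)),
    band("MSH2", "female", "colorectum", c(0.003, 0.008, 0.011, 0.014)),
    band("MSH6", "male",   "colorectum", c(0.001, 0.002, 0.004, 0.006)),
    band("MSH6", "female", "colorectum", c(0.001, 0.002, 0.004, 0.006)),
    band("PMS2", "male",   "colorectum", c(0.0005, 0.001, 0.002, 0.004)),
    band("PMS2", "female", "colorectum", c(0.0005, 0.001, 0.002, 0.004)),
    band("MLH1", "female", "endometrium", c(0.002, 0.008, 0.015, 0.014)),
    band("MSH2", "female", "endometrium", c(0.002, 0.010, 0.018, 0.018)),
    band("MSH6", "female", "endometrium", c(0.001, 0.008, 0.016, 0.016)),
    band("PMS2", "female", "endometrium", c(0.0005, 0.002, 0.005, 0.005)),
    band("MLH1", "female", "ovary", c(0.001, 0.004, 0.004, 0.003)),
    band("MSH2", "female", "ovary", c(0.002, 0.005, 0.005, 0.004)),
    band("MSH6", "female", "ovary", c(0.001, 0.003, 0.004, 0.003)),
    band("PMS2", "female", "ovary", c(0.0002, 0.0005, 0.001, 0.001)),
    band("MSH2", "male",   "urinary_tract", c(0, 0.001, 0.002, 0.004)),
    band("MSH2", "female", "urinary_tract", c(0, 0.001, 0.002, 0.003)),
    band("MLH1", "male",   "urinary_tract", c(0, 0.0005, 0.001, 0.002)),
    band("MLH1", "female", "urinary_tract", c(0, 0.0005, 0.001, 0.002)),
    band("MSH2", "male",   "prostate", c(0, 0, 0.004, 0.008)),
    band("MLH1", "male",   "prostate", c(0, 0, 0.002, 0.004)),
    band("MSH6", "male",   "prostate", c(0, 0, 0.002, 0.004)),
    band("MSH2", "male",   "brain", c(0.0005, 0.0005, 0.0005, 0.0005)),
    band("MSH2", "female", "brain", c(0.0005, 0.0005, 0.0005, 0.0005))
  )
}

#' Configure a synthetic-cohort simulation
#'
#' Bundles and validates every parameter of the generator. Defaults emulate
#' a multi-centre prospective carrier registry: 2,000 carriers (the order
#' of magnitude a first pooled analysis needs), four MMR genes, balanced
#' genders, five contributing regions, inclusion concentrated in early
#' adulthood and follow-up of up to ~25 years under annual administrative
#' censoring.
#'
#' @param n_carriers number of carriers (default 2000).
#' @param gene_probs,gender_probs,region_probs,status_probs named
#'   categorical distributions (must sum to 1). Non-pathogenic carriers
#'   receive zero tumour hazard; they appear in count outputs only.
#' @param hazard_spec data.frame of piecewise-constant annual hazards with
#'   columns `gene`, `gender`, `organ`, `age_lo`, `age_hi`, `hazard`
#'   (default [default_hazards()]). Bands may not overlap within a
#'   stratum-organ; age gaps mean hazard 0 and are filled in automatically
#'   so the bands always tile \[0, 110).
#' @param inclusion_age_dist named probability vector over integer
#'   inclusion ages. Default: ages 25-60 with weights proportional to a
#'   discretised Normal(35, 10).
#' @param followup_years_dist named probability vector over integer years
#'   from inclusion to administrative censoring. Default: uniform on 3-22.
#' @param post_dx_death_hazard annual probability of death in each year
#'   from the first incident diagnosis onwards (default 0.04).
#' @param seed integer RNG seed (default 1); [simulate_cohort()] is
#'   deterministic given the config.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_carriers = 2000L,
                       gene_probs = c(MLH1 = 0.38, MSH2 = 0.33,
                                      MSH6 = 0.21, PMS2 = 0.08),
                       gender_probs = c(female = 0.5, male = 0.5),
                       region_probs = c(Norway = 0.22, Netherlands = 0.18,
                                        UK = 0.18, Germany = 0.22,
                                        Spain = 0.20),
                       status_probs = c(pathogenic = 1),
                       hazard_spec = default_hazards(),
                       inclusion_age_dist = NULL,
                       followup_years_dist = NULL,
                       post_dx_death_hazard = 0.04,
                       seed = 1L) {
  cfg_err <- function(msg) lc_error(msg, "lynchcohort_config_error")
  if (!is_count(n_carriers) || n_carriers < 1) {
    cfg_err("n_carriers must be a positive integer")
  }
  chk_dist <- function(p, what, labels = NULL) {
    if (is.null(names(p)) || any(names(p) == "")) {
      cfg_err(sprintf("%s must be a named probability vector", what))
    }
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8) {
      cfg_err(sprintf("%s must be probabilities summing to 1", what))
    }
    if (!is.null(labels) && length(setdiff(names(p), labels))) {
      cfg_err(sprintf("%s has labels outside the vocabulary: %s", what,
                      paste(setdiff(names(p), labels), collapse = ", ")))
    }
    p
  }
  gene_probs <- chk_dist(gene_probs, "gene_probs", mmr_genes)
  gender_probs <- chk_dist(gender_probs, "gender_probs", genders)
  region_probs <- chk_dist(region_probs, "region_probs")
  status_probs <- chk_dist(status_probs, "status_probs", carrier_statuses)
  if (is.null(inclusion_age_dist)) {
    ages <- 25:60
    w <- stats::dnorm(ages, 35, 10)
    inclusion_age_dist <- stats::setNames(w / sum(w), ages)
  }
  inclusion_age_dist <- chk_dist(inclusion_age_dist, "inclusion_age_dist")
  if (is.null(followup_years_dist)) {
    followup_years_dist <- stats::setNames(rep(1 / 20, 20), 3:22)
  }
  followup_years_dist <- chk_dist(followup_years_dist, "followup_years_dist")
  if (any(is.na(suppressWarnings(as.integer(names(inclusion_age_dist))))) ||
      any(is.na(suppressWarnings(as.integer(names(followup_years_dist)))))) {
    cfg_err("age and duration distributions must be named by integers")
  }
  if (!is.numeric(post_dx_death_hazard) || post_dx_death_hazard < 0 ||
      post_dx_death_hazard > 1) {
    cfg_err("post_dx_death_hazard must be a probability in [0, 1]")
  }
  need <- c("gene", "gender", "organ", "age_lo", "age_hi", "hazard")
  if (!is.data.frame(hazard_spec) || length(setdiff(need, names(hazard_spec)))) {
    cfg_err(sprintf("hazard_spec needs columns: %s", paste(need, collapse = ", ")))
  }
  if (any(hazard_spec$hazard < 0) || any(!is.finite(hazard_spec$hazard))) {
    cfg_err("hazards must be finite and non-negative")
  }
  if (any(hazard_spec$age_lo >= hazard_spec$age_hi)) {
    cfg_err("hazard bands need age_lo < age_hi")
  }
  bad_organ <- setdiff(hazard_spec$organ, organ_vocabulary)
  if (length(bad_organ)) {
    cfg_err(sprintf("hazard_spec organs outside vocabulary: %s",
                    paste(bad_organ, collapse = ", ")))
  }
  # overlap check per (gene, gender, organ); gaps become hazard 0 later
  key <- paste(hazard_spec$gene, hazard_spec$gender, hazard_spec$organ)
  for (k in unique(key)) {
    b <- hazard_spec[key == k, , drop = FALSE]
    b <- b[order(b$age_lo), , drop = FALSE]
    if (nrow(b) > 1L && any(b$age_lo[-1L] < b$age_hi[-nrow(b)])) {
      cfg_err(sprintf("overlapping hazard bands for %s", k))
    }
  }
  structure(
    list(n_carriers = as.integer(n_carriers), gene_probs = gene_probs,
         gender_probs = gender_probs, region_probs = region_probs,
         status_probs = status_probs, hazard_spec = hazard_spec,
         inclusion_age_dist = inclusion_age_dist,
         followup_years_dist = followup_years_dist,
         post_dx_death_hazard = post_dx_death_hazard,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort configuration: %d carriers, seed %d\n",
              x$n_carriers, x$seed))
  cat(sprintf("  genes: %s\n", paste(names(x$gene_probs), x$gene_probs,
                                     sep = "=", collapse = ", ")))
  cat(sprintf("  hazard strata: %d bands over %d (gene, gender, organ) combinations\n",
              nrow(x$hazard_spec),
              length(unique(paste(x$hazard_spec$gene, x$hazard_spec$gender,
                                  x$hazard_spec$organ)))))
  cat(sprintf("  post-diagnosis death hazard: %g per year\n",
              x$post_dx_death_hazard))
  invisible(x)
}

# per-year event probability vector over ages 0..109 for one stratum-organ
hazard_to_p <- function(bands) {
  h <- numeric(AGE_MAX)
  for (i in seq_len(nrow(bands))) {
    lo <- max(0L, bands$age_lo[i])
    hi <- min(AGE_MAX, bands$age_hi[i])
    if (lo < hi) h[(lo + 1L):hi] <- bands$hazard[i]
  }
  1 - exp(-h)
}

# first-event year for each uniform draw u given per-year probabilities p:
# survival S(t) = prod_{j < t} (1 - p_j); event in year t iff
# S(t+1) <= u < S(t); NA when the full span is survived.
draw_event_age <- function(u, p) {
  S <- cumprod(1 - p) # S[t] = P(no event in years 0..t-1), t = 1..110
  k <- findInterval(u, rev(S)) # how many S values are <= u
  age <- length(S) - k
  age[k == 0L] <- NA_integer_
  as.integer(age)
}

#' Generate a synthetic prospective cohort with known truth
#'
#' Draws carriers (gene, gender, region, status), an inclusion age and an
#' administrative censoring age; walks each organ's discrete hazard from
#' birth so that events can predate inclusion (prevalent history, which is
#' retained); applies an annual death hazard from the first incident
#' diagnosis onwards, truncating follow-up at death; and returns the cohort
#' together with the generating hazard table. Deterministic given the
#' config's seed. Only pathogenic carriers receive tumour hazards. Events
#' that would occur after the end of observation are unobserved and absent.
#'
#' @param config a [sim_config()].
#' @return An object of class `"sim_cohort"`: list with `cohort` (a
#'   validated [lynch_cohort]), `truth` (the hazard table with the per-year
#'   event probability `p = 1 - exp(-hazard)` added) and `config`.
#' @seealso [recover_rates()] compares engine estimates against `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_carriers
  hs <- config$hazard_spec

  with_seed(config$seed, {
    draw <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)
    gene <- draw(config$gene_probs, n)
    gender <- draw(config$gender_probs, n)
    region <- draw(config$region_probs, n)
    status <- draw(config$status_probs, n)
    incl <- as.integer(draw(config$inclusion_age_dist, n))
    fu_years <- as.integer(draw(config$followup_years_dist, n))
    admin_end <- pmin(incl + fu_years, AGE_MAX)

    ids <- sprintf("SIM%05d", seq_len(n))
    ev_id <- character(0); ev_organ <- character(0); ev_age <- integer(0)

    key <- paste(hs$gene, hs$gender, hs$organ)
    for (k in unique(key)) {
      b <- hs[key == k, , drop = FALSE]
      members <- which(gene == b$gene[1L] & gender == b$gender[1L] &
                         status == "pathogenic")
      if (!length(members)) next
      p <- hazard_to_p(b)
      age <- draw_event_age(stats::runif(length(members)), p)
      hit <- !is.na(age)
      ev_id <- c(ev_id, ids[members[hit]])
      ev_organ <- c(ev_organ, rep(b$organ[1L], sum(hit)))
      ev_age <- c(ev_age, age[hit])
    }

    # death hazard from the first incident (post-inclusion) diagnosis
    last_obs <- admin_end
    dead <- rep(FALSE, n)
    midx <- match(ev_id, ids)
    inc_ev <- ev_age >= incl[midx] & ev_age <= admin_end[midx]
    first_dx <- rep(NA_integer_, n)
    if (any(inc_ev)) {
      mins <- tapply(ev_age[inc_ev], midx[inc_ev], min)
      first_dx[as.integer(names(mins))] <- as.integer(mins)
    }
    q <- config$post_dx_death_hazard
    has_dx <- which(!is.na(first_dx))
    if (length(has_dx) && q > 0) {
      death_age <- first_dx[has_dx] + stats::rgeom(length(has_dx), q)
      cut <- death_age < admin_end[has_dx]
      dead[has_dx[cut]] <- TRUE
      last_obs[has_dx[cut]] <- pmin(death_age[cut], AGE_MAX)
    }

    keep_ev <- ev_age <= last_obs[midx]
    carriers <- data.frame(carrier_id = ids, gene = gene, gender = gender,
                           region = region, carrier_status = status,
                           stringsAsFactors = FALSE)
    followup <- data.frame(
      carrier_id = ids, age_at_inclusion = incl,
      age_at_last_observation = as.integer(last_obs), dead = dead,
      age_at_death = ifelse(dead, as.integer(last_obs), NA_integer_),
      stringsAsFactors = FALSE)
    events <- data.frame(carrier_id = ev_id[keep_ev],
                         organ = ev_organ[keep_ev],
                         age_at_diagnosis = ev_age[keep_ev],
                         stringsAsFactors = FALSE)
    events <- events[order(events$carrier_id, events$organ,
                           events$age_at_diagnosis), , drop = FALSE]
    rownames(events) <- NULL

    truth <- hs
    truth$p <- 1 - exp(-truth$hazard)
    structure(
      list(cohort = lynch_cohort(carriers, followup, events),
           truth = truth, config = config),
      class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort with known ground truth\n")
  print(x$cohort)
  cat(sprintf("  seed %d; truth: %d hazard bands\n", x$config$seed,
              nrow(x$truth)))
  invisible(x)
}

# y-weighted true per-year event probability for one bin of a query over
# the truth table; only usable when the selection is a single (gene,
# gender) stratum so the estimand is unambiguous.
true_bin_p <- function(truth, query, bin_start, bin_end) {
  b <- truth[truth$gene %in% query$genes & truth$gender %in% query$genders &
               truth$organ %in% query$organs, , drop = FALSE]
  yrs <- seq.int(bin_start, bin_end - 1L)
  # per at-risk year: probability of an event in any target organ
  pyr <- rep(0, length(yrs))
  for (org in unique(b$organ)) {
    po <- hazard_to_p(b[b$organ == org, , drop = FALSE])
    pyr <- 1 - (1 - pyr) * (1 - po[yrs + 1L])
  }
  mean(pyr)
}

#' Compare engine estimates with the generating truth
#'
#' Runs [incidence_table()] on a simulated cohort and sets each bin's
#' estimated rate against the true per-year event probability implied by
#' the generating hazards, with Garwood interval coverage flags. The
#' selection must resolve to a single (gene, gender) stratum so that the
#' true rate is well defined.
#'
#' @param sim a `"sim_cohort"` from [simulate_cohort()].
#' @param query a [query_spec] selecting one gene and one gender.
#' @param level confidence level for the Garwood intervals.
#' @return A data.frame with columns `bin_start`, `bin_end`, `true_p`, `d`,
#'   `y`, `rate`, `ci_low`, `ci_high`, `covered`; attribute `pooled` holds
#'   the same comparison for the person-time-weighted pooled rate.
#' @export
recover_rates <- function(sim, query, level = 0.95) {
  stopifnot(inherits(sim, "sim_cohort"))
  if (length(query$genes) != 1L || length(query$genders) != 1L) {
    lc_error("recover_rates needs a single (gene, gender) stratum",
             "lynchcohort_domain_error")
  }
  tab <- incidence_table(sim$cohort, query)
  truep <- vapply(seq_len(nrow(tab)), function(i) {
    true_bin_p(sim$truth, query, tab$bin_start[i], tab$bin_end[i])
  }, numeric(1))
  out <- data.frame(bin_start = tab$bin_start, bin_end = tab$bin_end,
                    true_p = truep, d = tab$d, y = tab$y,
                    rate = tab$r, ci_low = NA_real_, ci_high = NA_real_,
                    covered = NA)
  has <- tab$y > 0
  if (any(has)) {
    ci <- poisson_ci(tab$d[has], tab$y[has], level = level)
    out$ci_low[has] <- ci$ci_low
    out$ci_high[has] <- ci$ci_high
    out$covered[has] <- ci$ci_low <= truep[has] & truep[has] <= ci$ci_high
  }
  pooled <- NULL
  if (sum(tab$y) > 0) {
    pci <- poisson_ci(sum(tab$d), sum(tab$y), level = level)
    ptrue <- sum(truep * tab$y) / sum(tab$y)
    pooled <- data.frame(true_p = ptrue, d = pci$d, y = pci$y,
                         rate = pci$rate, ci_low = pci$ci_low,
                         ci_high = pci$ci_high,
                         covered = pci$ci_low <= ptrue & ptrue <= pci$ci_high)
  }
  structure(out, pooled = pooled, level = level)
}
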