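# Annual rates -> exact Poisson intervals -> cumulative incidence.
#
# Cumulative incidence is the discrete product over one-year steps,
#   Q(a) = 1 - prod_{t in [start, a)} (1 - r(t)),
# with r(t) read from the age bin covering year t. This matches the
# integer-age person-time model exactly: each at-risk carrier-year is a
# Bernoulli trial, so the per-year rate is a probability and the product
# form is the natural accumulator.

#' Exact (Garwood) Poisson confidence interval for an incidence rate
#'
#' For `d` events over `y` person-years, the rate `d / y` with the exact
#' chi-square-based interval:
#' lower `= qchisq(alpha/2, 2d) / (2y)` (0 when `d = 0`), upper
#' `= qchisq(1 - alpha/2, 2d + 2) / (2y)`. Exact intervals are used instead
#' of normal approximations because small event counts dominate rare-cancer
#' strata.
#'
#' @param d non-negative integer event count(s).
#' @param y person-years at risk, strictly positive. Recycled against `d`.
#' @param level confidence level in (0, 1), default 0.95.
#' @return A data.frame of class `"rate_estimate"` with columns `d`, `y`,
#'   `rate`, `ci_low`, `ci_high` and attribute `level`. Always satisfies
#'   `0 <= ci_low <= rate <= ci_high`.
#' @examples
#' poisson_ci(0, 100)   # upper limit qchisq(0.975, 2) / 200 = 0.0369
#' poisson_ci(10, 100)  # 0.100 (0.0480, 0.1839)
#' @export
poisson_ci <- function(d, y, level = 0.95) {
  if (any(!is_whole(d)) || any(d < 0)) {
    lc_error("event count d must be a non-negative integer",
             "lynchcohort_domain_error")
  }
  if (any(!is.finite(y)) || any(y <= 0)) {
    lc_error("person-years y must be positive", "lynchcohort_domain_error")
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    lc_error("level must be in (0, 1)", "lynchcohort_domain_error")
  }
  n <- max(length(d), length(y))
  d <- rep_len(as.numeric(d), n)
  y <- rep_len(as.numeric(y), n)
  alpha <- 1 - level
  lo <- ifelse(d == 0, 0, stats::qchisq(alpha / 2, 2 * d) / (2 * y))
  hi <- stats::qchisq(1 - alpha / 2, 2 * d + 2) / (2 * y)
  structure(data.frame(d = d, y = y, rate = d / y, ci_low = lo, ci_high = hi),
            class = c("rate_estimate", "data.frame"), level = level)
}

# Map each whole year in [start, end) to the bin index supplying its rate.
# Bins with y = 0 have no rate of their own; their years inherit the most
# recent earlier rate (carry-forward), with a warning. A year covered by no
# bin, or with no earlier rate to carry, is a coverage error naming the
# first such age.
year_rate_bins <- function(table, start_age, end_age) {
  yrs <- seq.int(start_age, end_age - 1L)
  idx <- findInterval(yrs, c(table$bin_start, max(table$bin_end)))
  bad <- idx < 1L | idx > nrow(table)
  bad[!bad] <- yrs[!bad] >= table$bin_end[idx[!bad]]
  if (any(bad)) {
    lc_error(sprintf("no age bin covers age %d", yrs[which(bad)[1L]]),
             "lynchcohort_coverage_error", age = yrs[which(bad)[1L]])
  }
  defined <- !is.na(table$r)
  if (!all(defined[idx])) {
    src <- cummax(ifelse(defined, seq_len(nrow(table)), 0L))
    if (src[idx[1L]] == 0L) {
      a <- yrs[which(src[idx] == 0L)[1L]]
      lc_error(sprintf(
        "no rate available at age %d (bin has no person-time and no earlier rate to carry forward)",
        a), "lynchcohort_coverage_error", age = a)
    }
    warning("bins with zero person-years: carrying the most recent earlier rate forward",
            call. = FALSE)
    idx <- src[idx]
  }
  idx
}

# product-form accumulator; rates clamped into [0, 1]
accumulate_q <- function(rates) {
  if (any(rates > 1)) {
    warning("annual rate(s) above 1 clamped to 1 in the cumulative product",
            call. = FALSE)
  }
  p <- pmin(pmax(rates, 0), 1)
  c(0, 1 - cumprod(1 - p))
}

new_cuminc <- function(age, Q, lo, hi, start_age, level) {
  structure(data.frame(age = age, Q = Q, ci_low = lo, ci_high = hi),
            class = c("cuminc_curve", "data.frame"),
            start_age = start_age, level = level)
}

#' Cumulative cancer incidence from an age-cohort table
#'
#' Accumulates the annual rates of an [incidence_table()] into the
#' cumulative probability `Q(a)` of a first target-organ cancer by age `a`,
#' conditional on being event-free at `start_age`:
#' `Q(a) = 1 - prod(1 - r(t))` over whole years `t` in `[start_age, a)`.
#' The curve is evaluated at every integer age, starts at `Q(start_age) =
#' 0`, is non-decreasing and bounded in \[0, 1\]. Rates above 1 (possible
#' with tiny denominators) are clamped with a warning.
#'
#' @param table an [incidence_table()], or any data.frame with columns
#'   `bin_start`, `bin_end`, `r`.
#' @param start_age integer age at which accumulation starts; must be
#'   covered by the table.
#' @param end_age integer age at which the curve ends (exclusive of further
#'   accumulation; the curve's last point is at `end_age`). Defaults to the
#'   table's last bin end.
#' @return A data.frame of class `"cuminc_curve"` with columns `age`, `Q`,
#'   `ci_low`, `ci_high` (the interval columns are `NA` here; use
#'   [cumulative_ci()] for a confidence band).
#' @examples
#' tab <- data.frame(bin_start = 25, bin_end = 75, r = 0.01)
#' cc <- cumulative_incidence(tab, 25, 75)
#' tail(cc, 1)  # Q(75) = 1 - 0.99^50 = 0.3950
#' @export
cumulative_incidence <- function(table, start_age,
                                 end_age = max(table$bin_end)) {
  if (!is_whole(start_age) || !is_whole(end_age) || start_age >= end_age) {
    lc_error("need integer start_age < end_age", "lynchcohort_domain_error")
  }
  idx <- year_rate_bins(table, start_age, end_age)
  Q <- accumulate_q(table$r[idx])
  new_cuminc(seq.int(start_age, end_age), Q, NA_real_, NA_real_,
             start_age, NA_real_)
}

#' Cumulative incidence from any current age
#'
#' The interactive "risk from my age" view: identical to
#' [cumulative_incidence()] with `start_age = current_age`, i.e. the risk
#' for a carrier known to be event-free at their current age. Satisfies the
#' conditioning identity
#' `Q_c(a) = (Q0(a) - Q0(c)) / (1 - Q0(c))` against the curve started at
#' the table minimum. Ages below 25 are allowed with a warning: published
#' carrier risks are conventionally reported from age 25 onwards, and
#' younger strata are usually too thin to support a stable curve.
#'
#' @param table as in [cumulative_incidence()].
#' @param current_age the carrier's current (event-free) age.
#' @param end_age last age of the curve.
#' @return A `"cuminc_curve"` data.frame.
#' @export
conditional_curve <- function(table, current_age,
                              end_age = max(table$bin_end)) {
  if (is_whole(current_age) && current_age < 25) {
    warning("current_age below 25: risks are conventionally reported from age 25 onwards",
            call. = FALSE)
  }
  cumulative_incidence(table, start_age = current_age, end_age = end_age)
}

#' Parametric-bootstrap confidence band for a cumulative incidence curve
#'
#' Propagates Poisson uncertainty in the per-bin event counts to the whole
#' curve: each replicate redraws `d* ~ Poisson(d)` per bin with the
#' person-years fixed, recomputes the curve, and the band is the pointwise
#' percentile interval at the requested level. The seed is a required,
#' recorded parameter so every band is reproducible.
#'
#' @param table as in [cumulative_incidence()]; needs columns `d`, `y`,
#'   `r`, `bin_start`, `bin_end`.
#' @param start_age,end_age curve range, as in [cumulative_incidence()].
#' @param level confidence level (default 0.95).
#' @param reps bootstrap replicates, at least 100 (default 2000).
#' @param seed integer RNG seed (required; stored on the result).
#' @return A `"cuminc_curve"` data.frame whose `ci_low`/`ci_high` columns
#'   hold the band; attribute `reps` and `seed` record the run.
#' @export
cumulative_ci <- function(table, start_age, end_age = max(table$bin_end),
                          level = 0.95, reps = 2000, seed) {
  if (missing(seed) || !is_whole(seed)) {
    lc_error("an integer seed is required for the bootstrap band",
             "lynchcohort_domain_error")
  }
  if (!is_count(reps) || reps < 100) {
    lc_error("reps must be an integer >= 100", "lynchcohort_domain_error")
  }
  point <- cumulative_incidence(table, start_age, end_age)
  idx <- suppressWarnings(year_rate_bins(table, start_age, end_age))
  nb <- nrow(table)
  nyr <- length(idx)

  qs <- with_seed(seed, {
    dstar <- matrix(stats::rpois(reps * nb, rep(table$d, each = reps)),
                    nrow = reps)
    rstar <- sweep(dstar, 2L, table$y, "/")  # Inf/NaN only where y = 0 ...
    rstar[, table$y == 0] <- NA_real_        # ... which idx never points at
    ryr <- rstar[, idx, drop = FALSE]
    ryr <- pmin(pmax(ryr, 0), 1)
    logs <- log1p(-ryr)
    qmat <- 1 - exp(t(apply(logs, 1L, cumsum)))
    if (nyr == 1L) qmat <- matrix(qmat, ncol = 1L)
    qmat
  })
  alpha <- 1 - level
  lo <- c(0, apply(qs, 2L, stats::quantile, probs = alpha / 2, names = FALSE))
  hi <- c(0, apply(qs, 2L, stats::quantile, probs = 1 - alpha / 2,
                   names = FALSE))
  structure(new_cuminc(point$age, point$Q, lo, hi, start_age, level),
            reps = as.integer(reps), seed = as.integer(seed))
}

#' @export
print.cuminc_curve <- function(x, ...) {
  s <- attr(x, "start_age")
  lev <- attr(x, "level")
  cat(sprintf("Cumulative incidence from age %d to %d\n", s, max(x$age)))
  if (!is.na(lev)) {
    cat(sprintf("  %g%% bootstrap band (%d replicates, seed %d)\n",
                100 * lev, attr(x, "reps"), attr(x, "seed")))
  }
  show <- x[x$age %in% union(seq(s, max(x$age), by = 5), max(x$age)), ]
  print.data.frame(show, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.cuminc_curve <- function(x, ..., main = NULL,
                              xlab = "Age (years)",
                              ylab = "Cumulative incidence") {
  if (is.null(main)) {
    main <- sprintf("Cumulative incidence from age %d", attr(x, "start_age"))
  }
  graphics::plot(x$age, x$Q, type = "l", lwd = 2, ylim = c(0, max(
    1e-6, x$ci_high, x$Q, na.rm = TRUE)), main = main, xlab = xlab,
    ylab = ylab, ...)
  if (!all(is.na(x$ci_low))) {
    graphics::lines(x$age, x$ci_low, lty = 2)
    graphics::lines(x$age, x$ci_high, lty = 2)
  }
  invisible(x)
}
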