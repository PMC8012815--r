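# Independent oracles used to freeze expected values. These deliberately
# use naive, direct formulations (explicit loops, numerical integration)
# so they share no code path with the implementation they check.

# Normalized power by explicit enumeration of every trailing window.
np_brute_force <- function(power, window = 30L) {
  means <- vapply(window:length(power), function(t) {
    mean(power[(t - window + 1L):t])
  }, numeric(1))
  mean(means^4)^0.25
}

# Predictive CDF of the next observation under the normal-normal model,
# by numerical integration over the athlete-mean prior.
predictive_cdf_numeric <- function(q, mu0, tau, sigma, xs) {
  w <- function(theta) {
    lik <- vapply(theta, function(th) prod(stats::dnorm(xs, th, sigma)),
                  numeric(1))
    lik * stats::dnorm(theta, mu0, tau)
  }
  num <- stats::integrate(function(th) stats::pnorm(q, th, sigma) * w(th),
                          mu0 - 12 * tau, mu0 + 12 * tau,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(w, mu0 - 12 * tau, mu0 + 12 * tau,
                          rel.tol = 1e-10)$value
  num / den
}

# Predictive quantile from the numeric CDF via root finding.
predictive_quantile_numeric <- function(p, mu0, tau, sigma, xs) {
  stats::uniroot(
    function(q) predictive_cdf_numeric(q, mu0, tau, sigma, xs) - p,
    interval = c(mu0 - 20 * (tau + sigma), mu0 + 20 * (tau + sigma)),
    tol = 1e-9
  )$root
}

# Exhaustive scan for the extreme 12-week periods over a daily record.
extreme_brute_force <- function(dates, tss, span = 84L) {
  all_days <- seq(min(dates), max(dates), by = "day")
  load <- stats::setNames(rep(0, length(all_days)), as.character(all_days))
  agg <- tapply(tss, as.character(dates), sum)
  load[names(agg)] <- agg
  n_win <- length(all_days) - span + 1L
  sums <- vapply(seq_len(n_win), function(i) {
    sum(load[i:(i + span - 1L)])
  }, numeric(1))
  list(
    high = list(start = all_days[which.max(sums)], tss = max(sums)),
    low = list(start = all_days[which.min(sums)], tss = min(sums))
  )
}

# A small clean passport series at chosen one-sided tail positions:
# each value is placed at the given upper-tail probability of the
# predictive distribution current at that step.
values_at_tails <- function(params, tails) {
  state <- new_passport(params)
  vals <- numeric(length(tails))
  for (i in seq_along(tails)) {
    pred <- abpmonitor:::pp_predictive(state)
    x <- stats::qnorm(tails[i], pred$mean, pred$sd, lower.tail = FALSE)
    v <- if (params$transform == "log") exp(x) else x
    vals[i] <- v
    state <- passport_update(state, v)
  }
  list(values = vals, state = state)
}

ref_table1 <- function() {
  readr::read_csv(
    system.file("extdata", "reference_cohort_table1.csv",
                package = "abpmonitor"),
    show_col_types = FALSE
  )
}
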