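#' Marker model parameters for the adaptive passport model
#'
#' Bundles the population prior and variance components of the
#' normal-normal adaptive model used to derive individual reference
#' limits. The athlete's true marker level is modeled as
#' \eqn{\theta \sim N(\mu_0, \tau^2)} (between-subject), and observed
#' values as \eqn{x_i \sim N(\theta, \sigma^2)} (within-subject,
#' analytical plus biological), in transformed units. A `log` transform
#' is used for right-skewed positive markers such as Ret%, which also
#' guarantees positive limits in natural units.
#'
#' @param marker Marker name (e.g., `"hb"`, `"off_score"`, `"ret_pct"`).
#' @param mu0 Prior (population) mean, transformed units.
#' @param tau Between-subject SD, transformed units; > 0.
#' @param sigma Within-subject SD, transformed units; > 0.
#' @param transform `"identity"` or `"log"`.
#' @param specificity_single Two-sided specificity of the single-value
#'   limits (default 0.99).
#' @param specificity_sequence Specificity of the 2-5 sample sequence
#'   rule (default 0.999).
#' @return An object of class `marker_params`.
#' @export
marker_params <- function(marker, mu0, tau, sigma,
                          transform = c("identity", "log"),
                          specificity_single = 0.99,
                          specificity_sequence = 0.999) {
  transform <- match.arg(transform)
  stopifnot(is.finite(mu0), is.finite(tau), is.finite(sigma))
  if (tau <= 0 || sigma <= 0) {
    stop("marker_params: tau and sigma must be > 0", call. = FALSE)
  }
  if (specificity_single <= 0.5 || specificity_single >= 1 ||
      specificity_sequence <= 0.5 || specificity_sequence >= 1) {
    stop("marker_params: specificities must be in (0.5, 1)", call. = FALSE)
  }
  structure(
    list(marker = marker, mu0 = mu0, tau = tau, sigma = sigma,
         transform = transform,
         specificity_single = specificity_single,
         specificity_sequence = specificity_sequence),
    class = "marker_params"
  )
}

#' Default marker model parameters
#'
#' Package defaults for the three monitored markers in a male endurance
#' cohort: hemoglobin concentration (g/dL, identity), OFF-score
#' (arbitrary units, identity) and Ret% (log transform). These are
#' configuration values, not population claims: all calibration and
#' flagging properties of the model hold for any valid parameter set.
#'
#' @return Named list of [marker_params()] objects
#'   (`hb`, `off_score`, `ret_pct`).
#' @export
default_marker_params <- function() {
  list(
    hb = marker_params("hb", mu0 = 14.6, tau = 0.9, sigma = 0.45),
    off_score = marker_params("off_score", mu0 = 90, tau = 12, sigma = 8),
    ret_pct = marker_params("ret_pct", mu0 = log(1.1), tau = 0.25,
                            sigma = 0.15, transform = "log")
  )
}

#' Initialize an empty passport state
#'
#' @param params A [marker_params()] object.
#' @return A `passport_state` with no incorporated values. The first
#'   sample is therefore judged against the population-based limits
#'   \eqn{\mu_0 \pm z\sqrt{\tau^2+\sigma^2}}; subsequent limits adapt to
#'   the individual.
#' @export
new_passport <- function(params) {
  stopifnot(inherits(params, "marker_params"))
  structure(
    list(params = params, n = 0L, sum_x = 0,
         values = numeric(0), dates = as.Date(character(0)),
         lower = numeric(0), upper = numeric(0),
         atpf_single = logical(0), atpf_sequence = logical(0),
         tail_lower = numeric(0), tail_upper = numeric(0)),
    class = "passport_state"
  )
}

pp_transform <- function(x, params) {
  if (params$transform == "log") log(x) else x
}

pp_back <- function(x, params) {
  if (params$transform == "log") exp(x) else x
}

# Posterior for the athlete mean and the predictive distribution of the
# next transformed value, given the running sufficient statistics.
pp_predictive <- function(state) {
  p <- state$params
  prec <- 1 / p$tau^2 + state$n / p$sigma^2
  m <- (p$mu0 / p$tau^2 + state$sum_x / p$sigma^2) / prec
  v <- p$sigma^2 + 1 / prec
  list(mean = m, sd = sqrt(v))
}

#' Individual predictive reference limits
#'
#' Returns the current lower and upper individual limits in natural
#' units. In transformed units the limits are
#' \eqn{m \pm z \sqrt{\sigma^2 + 1/(1/\tau^2 + n/\sigma^2)}} where
#' \eqn{m} is the posterior mean of the athlete's level and \eqn{z} the
#' two-sided normal quantile for the single-value specificity. With no
#' observations this reduces to the population band
#' \eqn{\mu_0 \pm z\sqrt{\tau^2 + \sigma^2}}; the band shrinks
#' monotonically toward \eqn{\pm z\sigma} as samples accumulate.
#'
#' @param state A `passport_state`.
#' @return Named numeric vector `c(lower, upper)` in natural units.
#' @export
predictive_limits <- function(state) {
  stopifnot(inherits(state, "passport_state"))
  pred <- pp_predictive(state)
  z <- stats::qnorm((1 + state$params$specificity_single) / 2)
  c(lower = pp_back(pred$mean - z * pred$sd, state$params),
    upper = pp_back(pred$mean + z * pred$sd, state$params))
}

#' Incorporate a new value into a passport
#'
#' Evaluates the value against the limits computed from the state
#' *before* incorporation (so the first sample is judged against the
#' population prior) and then updates the running statistics. A
#' single-value atypical finding (ATPF) is raised only on strict
#' exceedance: a value exactly on a limit does not flag (ties resolved in
#' the athlete's favor). The sequence ATPF over the last 2-5 values (see
#' [sequence_atpf()]) is also evaluated after incorporation.
#'
#' @param state A `passport_state`.
#' @param value New observation, natural units; must be finite (and
#'   positive under a log transform).
#' @param date Optional collection date.
#' @return The updated `passport_state`; the flag for this sample is
#'   `state$atpf_single[state$n]` / `state$atpf_sequence[state$n]`.
#' @export
passport_update <- function(state, value, date = NA) {
  stopifnot(inherits(state, "passport_state"))
  if (!is.finite(value)) {
    stop("passport_update: value must be finite", call. = FALSE)
  }
  if (state$params$transform == "log" && value <= 0) {
    stop("passport_update: log-transformed marker requires value > 0",
         call. = FALSE)
  }
  lim <- predictive_limits(state)
  flag <- value < lim[["lower"]] || value > lim[["upper"]]

  pred <- pp_predictive(state)
  x <- pp_transform(value, state$params)
  state$n <- state$n + 1L
  state$sum_x <- state$sum_x + x
  state$values <- c(state$values, value)
  state$dates <- c(state$dates, as.Date(date))
  state$lower <- c(state$lower, lim[["lower"]])
  state$upper <- c(state$upper, lim[["upper"]])
  state$atpf_single <- c(state$atpf_single, flag)
  state$tail_upper <- c(state$tail_upper,
                        stats::pnorm(x, pred$mean, pred$sd,
                                     lower.tail = FALSE))
  state$tail_lower <- c(state$tail_lower,
                        stats::pnorm(x, pred$mean, pred$sd))
  seq_flag <- any(vapply(2:5, function(k) {
    if (state$n < k) FALSE else sequence_atpf(state, k)
  }, logical(1)))
  state$atpf_sequence <- c(state$atpf_sequence, seq_flag)
  state
}

#' Sequence atypical finding over the last k values
#'
#' The sequence rule asks whether the last `k_window` (2-5) values
#' jointly deviate to the same side more than normal physiological
#' variation allows at the sequence specificity (default 99.9%). Each
#' value's one-sided tail probability is taken against the predictive
#' distribution that was current *before* that value was incorporated;
#' the joint statistic is the product of the per-sample tails on the
#' common most-extreme side (upper tails and lower tails evaluated
#' separately). The flag fires when either product falls below
#' \eqn{1 - } sequence specificity.
#'
#' @param state A `passport_state` with at least `k_window` values.
#' @param k_window Sequence length, 2-5.
#' @return Logical.
#' @export
sequence_atpf <- function(state, k_window) {
  stopifnot(inherits(state, "passport_state"))
  if (!k_window %in% 2:5) {
    stop("sequence_atpf: k_window must be in 2..5", call. = FALSE)
  }
  if (state$n < k_window) {
    stop("sequence_atpf: state has fewer values than k_window",
         call. = FALSE)
  }
  idx <- (state$n - k_window + 1L):state$n
  alpha <- 1 - state$params$specificity_sequence
  prod(state$tail_upper[idx]) < alpha || prod(state$tail_lower[idx]) < alpha
}

#' Shortest absolute distance to the closest individual limit
#'
#' @param value Observed value, natural units.
#' @param lower,upper Individual limits, `lower < upper`.
#' @return `min(|value - lower|, |value - upper|)`; values outside the
#'   band are measured to the nearest limit. Vectorized.
#' @examples
#' distance_to_limits(14.0, 12.5, 15.5)  # 1.5 (midpoint: half the band)
#' distance_to_limits(16.0, 12.5, 15.5)  # 0.5
#' @export
distance_to_limits <- function(value, lower, upper) {
  if (any(lower >= upper)) {
    stop("distance_to_limits: lower must be < upper", call. = FALSE)
  }
  pmin(abs(value - lower), abs(value - upper))
}

#' Summarize distances to individual limits
#'
#' @param distances Numeric vector of per-sample distances (natural units).
#' @param thresholds Distances below which samples count as "close to a
#'   limit".
#' @return A list with `mean_distance` and a tibble (`threshold`,
#'   `count`, `pct`) where `pct` is `100 * count / length(distances)`
#'   rounded to 1 decimal and `count` counts distances strictly below
#'   the threshold.
#' @export
summarize_distances <- function(distances, thresholds = c(0.1, 0.5)) {
  if (length(distances) == 0) {
    stop("summarize_distances: no distances supplied", call. = FALSE)
  }
  counts <- vapply(thresholds, function(th) sum(distances < th), numeric(1))
  list(
    mean_distance = mean(distances),
    near_limit = tibble::tibble(
      threshold = thresholds,
      count = counts,
      pct = round(100 * counts / length(distances), 1)
    )
  )
}

#' Run a full passport for one athlete and marker
#'
#' Feeds an ordered series of values through [passport_update()] and
#' returns the per-sample profile in the passport export layout.
#'
#' @param params A [marker_params()] object.
#' @param values Ordered marker values, natural units.
#' @param dates Optional collection dates (same length).
#' @return A tibble with `sample_index`, `date`, `value`, `lower`,
#'   `upper`, `distance`, `atpf_single`, `atpf_sequence`.
#' @export
run_passport <- function(params, values, dates = NULL) {
  if (is.null(dates)) dates <- as.Date(rep(NA, length(values)))
  stopifnot(length(dates) == length(values))
  state <- new_passport(params)
  for (i in seq_along(values)) {
    state <- passport_update(state, values[i], dates[i])
  }
  tibble::tibble(
    sample_index = seq_len(state$n),
    date = as.Date(state$dates),
    value = state$values,
    lower = state$lower,
    upper = state$upper,
    distance = distance_to_limits(state$values, state$lower, state$upper),
    atpf_single = state$atpf_single,
    atpf_sequence = state$atpf_sequence
  )
}

#' Estimate marker model parameters from cohort data
#'
#' Moment-based empirical estimate of the population prior from a
#' longitudinal table: the within-subject SD is the root mean
#' within-athlete variance and the between-subject SD is the SD of the
#' athlete means with the sampling contribution of the within-subject
#' noise removed (floored at 10% of the within-subject SD so the prior
#' stays proper).
#'
#' @param data Tibble with columns `athlete_id` and the marker column.
#' @param marker Name of the marker column.
#' @param transform `"identity"` or `"log"`.
#' @param ... Passed to [marker_params()] (specificities).
#' @return A [marker_params()] object.
#' @export
estimate_marker_params <- function(data, marker,
                                   transform = c("identity", "log"), ...) {
  transform <- match.arg(transform)
  x <- data[[marker]]
  if (transform == "log") x <- log(x)
  d <- tibble::tibble(athlete_id = data$athlete_id, x = x)
  per <- dplyr::summarise(
    dplyr::group_by(d, .data$athlete_id),
    m = mean(.data$x), v = stats::var(.data$x), n = dplyr::n(),
    .groups = "drop"
  )
  sigma2 <- stats::weighted.mean(per$v, per$n - 1, na.rm = TRUE)
  tau2 <- stats::var(per$m) - sigma2 / mean(per$n)
  tau2 <- max(tau2, 0.01 * sigma2)
  marker_params(marker, mu0 = mean(per$m), tau = sqrt(tau2),
                sigma = sqrt(sigma2), transform = transform, ...)
}

#' Plot a passport profile
#'
#' Value line with the adaptive limit envelope, one panel per marker if
#' `profile` carries a `marker` column.
#'
#' @param profile A profile tibble from [run_passport()] (optionally
#'   with a `marker` column for faceting).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_passport <- function(profile, title = "ABP profile") {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$sample_index)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey85"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value)) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$value, color = .data$atpf_single)
    ) +
    ggplot2::scale_color_manual(
      values = c(`FALSE` = "black", `TRUE` = "red"), guide = "none"
    ) +
    ggplot2::labs(x = "sample", y = "value", title = title) +
    ggplot2::theme_minimal()
  if ("marker" %in% names(profile)) {
    p <- p + ggplot2::facet_wrap(~marker, scales = "free_y")
  }
  p
}
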