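#' Mixed-model time effect for a repeated-measures marker
#'
#' Fits `value ~ occasion` with occasion as a categorical fixed factor
#' and a random intercept per athlete (REML, via `nlme::lme`), and
#' returns the occasion F test. This is the repeated-measures analysis
#' used to ask whether a marker changes over the monitoring year.
#'
#' Degenerate inputs with zero residual variance (all values identical,
#' or noise-free occasion shifts) cannot be fitted by REML; the
#' function then falls back to a fixed-effects `lm(value ~ athlete +
#' occasion)` F test (identical occasion test under balance), and for
#' fully constant data reports F = 0, p = 1.
#'
#' @param data Tibble with columns `athlete_id`, `occasion`, `value`.
#' @param df_method `"residual"` (nlme default) or `"satterthwaite"`
#'   (via lmerTest, if installed).
#' @return A list `f`, `df1`, `df2`, `p`, `engine`.
#' @export
mixed_time_effect <- function(data, df_method = c("residual",
                                                  "satterthwaite")) {
  df_method <- match.arg(df_method)
  if (length(unique(data$occasion)) < 2) {
    stop("mixed_time_effect: need at least two occasions", call. = FALSE)
  }
  if (length(unique(data$athlete_id)) < 2) {
    stop("mixed_time_effect: need at least two athletes", call. = FALSE)
  }
  d <- data.frame(athlete_id = factor(data$athlete_id),
                  occasion = factor(data$occasion),
                  value = data$value)
  if (stats::sd(d$value) == 0) {
    return(list(f = 0, df1 = nlevels(d$occasion) - 1L,
                df2 = nrow(d) - nlevels(d$occasion) -
                  nlevels(d$athlete_id) + 1L,
                p = 1, engine = "constant"))
  }
  if (df_method == "satterthwaite" &&
      requireNamespace("lmerTest", quietly = TRUE)) {
    fit <- lmerTest::lmer(value ~ occasion + (1 | athlete_id), data = d)
    an <- stats::anova(fit, ddf = "Satterthwaite")
    return(list(f = an[["F value"]][1], df1 = an[["NumDF"]][1],
                df2 = an[["DenDF"]][1], p = an[["Pr(>F)"]][1],
                engine = "lmerTest"))
  }
  fit <- tryCatch(
    nlme::lme(value ~ occasion, random = ~ 1 | athlete_id, data = d,
              method = "REML"),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    an <- stats::anova(fit)
    i <- rownames(an) == "occasion"
    return(list(f = an[["F-value"]][i], df1 = an[["numDF"]][i],
                df2 = an[["denDF"]][i], p = an[["p-value"]][i],
                engine = "nlme"))
  }
  fit <- stats::lm(value ~ athlete_id + occasion, data = d)
  an <- stats::anova(fit)
  i <- rownames(an) == "occasion"
  f <- an[["F value"]][i]
  p <- an[["Pr(>F)"]][i]
  if (is.nan(f)) { # zero residual *and* zero occasion variance
    f <- 0; p <- 1
  }
  list(f = f, df1 = an[["Df"]][i], df2 = an[["Df"]][rownames(an) ==
                                                      "Residuals"],
       p = p, engine = "lm-fallback")
}

#' Mixed-model effect of a time-dependent covariate on a marker
#'
#' Fits `value ~ load` with a random intercept per athlete and returns
#' the slope (marker units per a.u. of load), its F test and confidence
#' interval. Used to quantify, e.g., how hemoglobin concentration
#' responds to the acute training load accumulated before each sample.
#'
#' @param data Tibble with `athlete_id`, `value`, `load` (and
#'   `occasion` when `include_time = TRUE`).
#' @param include_time Also include the categorical occasion factor
#'   (default `FALSE`: covariate-only model).
#' @param level Confidence level for the slope interval.
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @return A tibble with `estimate`, `se`, `ci_lower`, `ci_upper`, `f`,
#'   `df1`, `df2`, `p`, `engine`.
#' @export
covariate_effect <- function(data, include_time = FALSE, level = 0.95,
                             df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  if (length(unique(data$athlete_id)) < 2) {
    stop("covariate_effect: need at least two athletes", call. = FALSE)
  }
  if (stats::sd(data$load) == 0) {
    stop("covariate_effect: covariate is constant", call. = FALSE)
  }
  d <- data.frame(athlete_id = factor(data$athlete_id),
                  value = data$value, load = data$load)
  form <- value ~ load
  if (include_time) {
    d$occasion <- factor(data$occasion)
    form <- value ~ load + occasion
  }
  if (df_method == "satterthwaite" &&
      requireNamespace("lmerTest", quietly = TRUE)) {
    fit <- lmerTest::lmer(stats::update(form, . ~ . + (1 | athlete_id)),
                          data = d)
    sm <- stats::coef(summary(fit))
    an <- stats::anova(fit, ddf = "Satterthwaite")
    i <- rownames(an) == "load"
    est <- sm["load", "Estimate"]
    se <- sm["load", "Std. Error"]
    df2 <- an[["DenDF"]][i]
    tcrit <- stats::qt(1 - (1 - level) / 2, df2)
    return(tibble::tibble(
      estimate = est, se = se, ci_lower = est - tcrit * se,
      ci_upper = est + tcrit * se, f = an[["F value"]][i],
      df1 = an[["NumDF"]][i], df2 = df2, p = an[["Pr(>F)"]][i],
      engine = "lmerTest"
    ))
  }
  fit <- tryCatch(
    nlme::lme(form, random = ~ 1 | athlete_id, data = d, method = "REML"),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    tt <- summary(fit)$tTable
    est <- tt["load", "Value"]
    se <- tt["load", "Std.Error"]
    df2 <- tt["load", "DF"]
    an <- stats::anova(fit)
    i <- rownames(an) == "load"
    tcrit <- stats::qt(1 - (1 - level) / 2, df2)
    return(tibble::tibble(
      estimate = est, se = se, ci_lower = est - tcrit * se,
      ci_upper = est + tcrit * se, f = an[["F-value"]][i],
      df1 = an[["numDF"]][i], df2 = df2, p = an[["p-value"]][i],
      engine = "nlme"
    ))
  }
  # zero-residual degenerate input: fixed-effects fallback
  fit <- stats::lm(stats::update(form, . ~ athlete_id + .), data = d)
  sm <- stats::coef(summary(fit))
  est <- sm["load", "Estimate"]
  se <- sm["load", "Std. Error"]
  df2 <- fit$df.residual
  tcrit <- stats::qt(1 - (1 - level) / 2, df2)
  an <- stats::anova(fit)
  i <- rownames(an) == "load"
  tibble::tibble(
    estimate = est, se = se,
    ci_lower = est - tcrit * se, ci_upper = est + tcrit * se,
    f = an[["F value"]][i], df1 = an[["Df"]][i], df2 = df2,
    p = an[["Pr(>F)"]][i], engine = "lm-fallback"
  )
}

#' Percent variation series within athletes
#'
#' Per athlete, the percent change of each value relative to a
#' baseline: the previous measurement (default) or the athlete's first
#' measurement. Values must be time-ordered within athlete.
#'
#' @param data Tibble with `athlete_id` and `value`, ordered in time
#'   within athlete.
#' @param baseline `"previous"` (consecutive-sample change) or
#'   `"first"`.
#' @return Tibble `athlete_id`, `index` (index of the later sample) and
#'   `pct`.
#' @examples
#' pct_change_series(tibble::tibble(athlete_id = "a", value = c(10, 11)))
#' @export
pct_change_series <- function(data, baseline = c("previous", "first")) {
  baseline <- match.arg(baseline)
  out <- lapply(split(seq_len(nrow(data)), data$athlete_id), function(ii) {
    v <- data$value[ii]
    if (length(v) < 2) {
      stop("pct_change_series: need at least 2 values per athlete",
           call. = FALSE)
    }
    ref <- if (baseline == "previous") v[-length(v)] else rep(v[1],
                                                              length(v) - 1)
    if (any(ref == 0)) {
      stop("pct_change_series: zero baseline value", call. = FALSE)
    }
    tibble::tibble(athlete_id = data$athlete_id[ii[1]],
                   index = 2:length(v),
                   pct = 100 * (v[-1] - ref) / ref)
  })
  dplyr::bind_rows(out)
}

#' Pearson correlation between two percent-variation series
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return List `r`, `p`, `n` from the product-moment correlation test.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("pearson_corr: need equal lengths >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_corr: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` elementwise, delegated to [stats::p.adjust()].
#'
#' @param p P-values in `[0, 1]`.
#' @param m Number of comparisons (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Percent change between two summary values
#'
#' `100 * (new - reference) / reference`. Note the asymmetry: swapping
#' the roles of the two values does not negate the result (the two
#' directions satisfy `(1 + p1/100) * (1 + p2/100) = 1`, not
#' `p1 = -p2`).
#'
#' @param reference Baseline value (nonzero).
#' @param new Comparison value.
#' @return Percent change (unrounded; tables round to 1 decimal).
#' @export
percent_change <- function(reference, new) {
  if (any(reference == 0)) {
    stop("percent_change: zero reference", call. = FALSE)
  }
  100 * (new - reference) / reference
}

#' Polynomial time contrasts with Bonferroni adjustment
#'
#' Orthogonal-polynomial contrasts over the ordered occasions of a
#' fitted time-effect model, Bonferroni-adjusted. Requires the
#' `emmeans` package.
#'
#' @param data Tibble with `athlete_id`, `occasion`, `value`.
#' @return Tibble with `contrast`, `estimate`, `p_adj`.
#' @export
time_polynomial_contrasts <- function(data) {
  if (!requireNamespace("emmeans", quietly = TRUE)) {
    stop("time_polynomial_contrasts requires the 'emmeans' package",
         call. = FALSE)
  }
  d <- data.frame(athlete_id = factor(data$athlete_id),
                  occasion = factor(data$occasion),
                  value = data$value)
  fit <- nlme::lme(value ~ occasion, random = ~ 1 | athlete_id, data = d,
                   method = "REML")
  em <- emmeans::emmeans(fit, "occasion")
  ct <- summary(emmeans::contrast(em, "poly", adjust = "bonferroni"))
  tibble::tibble(contrast = as.character(ct$contrast),
                 estimate = ct$estimate, p_adj = ct$p.value)
}

#' Per-athlete and cohort summary table
#'
#' Per-athlete mean and SD of each variable of a long-format table,
#' plus a cohort row holding the unweighted mean (and SD) of the
#' per-athlete means — the aggregation convention of cohort summary
#' tables in longitudinal monitoring studies.
#'
#' @param data Long tibble with `athlete_id`, `variable`, `value`.
#' @return A tibble with `athlete_id` (the cohort row is `"Mean"`),
#'   `variable`, `mean`, `sd`.
#' @export
cohort_table <- function(data) {
  if (nrow(data) == 0) stop("cohort_table: empty input", call. = FALSE)
  data$athlete_id <- as.character(data$athlete_id)
  per <- dplyr::summarise(
    dplyr::group_by(data, .data$athlete_id, .data$variable),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  cohort <- dplyr::summarise(
    dplyr::group_by(per, .data$variable),
    sd = stats::sd(.data$mean), mean = mean(.data$mean),
    .groups = "drop"
  )
  cohort <- cohort[, c("variable", "mean", "sd")]
  cohort <- dplyr::mutate(cohort, athlete_id = "Mean", .before = 1)
  dplyr::bind_rows(per, cohort)
}
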