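#' Normalized power of a ride
#'
#' Standard 30-s rolling fourth-power algorithm on a 1 Hz power series:
#' trailing 30-s moving averages (first window complete at sample 30)
#' are raised to the fourth power, averaged, and the fourth root taken.
#' By the power-mean inequality NP is never below the arithmetic mean
#' power, with equality only for constant power. Recording gaps should
#' be zero-filled before calling (coasting convention).
#'
#' @param power_w Per-second power series, watts; length >= 30.
#' @param window_s Rolling window, seconds (default 30).
#' @return Normalized power, W.
#' @examples
#' normalized_power(rep(250, 1200))  # 250
#' @export
normalized_power <- function(power_w, window_s = 30L) {
  n <- length(power_w)
  if (n < window_s) {
    stop(sprintf("normalized_power: need at least %d samples, got %d",
                 window_s, n), call. = FALSE)
  }
  if (any(!is.finite(power_w)) || any(power_w < 0)) {
    stop("normalized_power: power must be finite and non-negative",
         call. = FALSE)
  }
  cs <- cumsum(c(0, power_w))
  roll <- (cs[(window_s + 1):(n + 1)] - cs[1:(n - window_s + 1)]) / window_s
  mean(roll^4)^0.25
}

#' Training Stress Score of a session
#'
#' \eqn{TSS = (t \cdot NP \cdot IF) / (FTP \cdot 3600) \times 100}
#' with \eqn{IF = NP / FTP}; one hour ridden exactly at threshold scores
#' 100. Equivalently \eqn{TSS = 100 (t/3600) (NP/FTP)^2}.
#'
#' @param t_s Session duration, seconds.
#' @param np_w Normalized power, W.
#' @param ftp_w Functional threshold power, W.
#' @return TSS, arbitrary units. Vectorized.
#' @examples
#' tss(3600, 300, 300)  # 100
#' tss(7200, 240, 300)  # 128
#' @export
tss <- function(t_s, np_w, ftp_w) {
  if (any(ftp_w <= 0)) stop("tss: ftp must be positive", call. = FALSE)
  if (any(t_s < 0) || any(np_w < 0)) {
    stop("tss: duration and power must be non-negative", call. = FALSE)
  }
  intensity <- np_w / ftp_w
  (t_s * np_w * intensity) / (ftp_w * 3600) * 100
}

#' Functional threshold power from a 20-minute test
#'
#' FTP is taken as 95% of the average power of a recent all-out 20-min
#' effort and held fixed for the whole analysis period.
#'
#' @param p20_w Average power over the 20-min test, W.
#' @return FTP, W.
#' @export
ftp_from_test <- function(p20_w) {
  if (any(p20_w <= 0)) stop("ftp_from_test: p20 must be positive",
                            call. = FALSE)
  0.95 * p20_w
}

#' Windowed training load before an anchor date
#'
#' Sums the TSS of the sessions whose start date falls in the half-open
#' calendar window `[anchor - span_days, anchor)`: the sampling day
#' itself is excluded (no exercise is allowed in the hours preceding a
#' blood collection, and its partial day would bias the load). Sessions
#' are attributed to windows by start date only. The conventional spans
#' are 5 days (acute load, ATL) and 42 days (chronic load, CTL).
#'
#' @param sessions Tibble with at least `start` (Date or datetime) and
#'   `tss`.
#' @param anchor_date Anchor (blood-sampling) date.
#' @param span_days Window length in days; values other than 5 or 42
#'   are accepted with a warning.
#' @return A list `cumulated` (a.u.) and `mean_daily` (a.u./day); both 0
#'   for an empty window.
#' @export
window_load <- function(sessions, anchor_date, span_days) {
  if (!span_days %in% c(5, 42)) {
    warning(sprintf("window_load: unconventional span of %d days",
                    span_days), call. = FALSE)
  }
  anchor_date <- as.Date(anchor_date)
  d <- as.Date(sessions$start)
  sel <- d >= anchor_date - span_days & d < anchor_date
  total <- sum(sessions$tss[sel])
  list(cumulated = total, mean_daily = total / span_days)
}

#' Acute and chronic load at each blood-sampling date
#'
#' @param sessions Session tibble (`athlete_id`, `start`, `tss`).
#' @param anchors Tibble with `athlete_id` and `date` (sampling dates).
#' @param spans Named vector of window lengths (default ATL 5, CTL 42).
#' @return `anchors` with one cumulated and one daily-mean column per
#'   span (e.g., `atl`, `atl_daily`, `ctl`, `ctl_daily`).
#' @export
load_at_anchors <- function(sessions, anchors,
                            spans = c(atl = 5, ctl = 42)) {
  out <- anchors
  for (nm in names(spans)) {
    cum <- numeric(nrow(anchors))
    for (i in seq_len(nrow(anchors))) {
      s <- sessions[sessions$athlete_id == anchors$athlete_id[i], ,
                    drop = FALSE]
      cum[i] <- window_load(s, anchors$date[i], spans[[nm]])$cumulated
    }
    out[[nm]] <- cum
    out[[paste0(nm, "_daily")]] <- cum / spans[[nm]]
  }
  out
}

#' Highest- and lowest-load 12-week periods
#'
#' Slides an 84-day (12-week) window day by day over the daily TSS
#' record and returns the windows with maximal and minimal cumulative
#' TSS. Only complete windows inside the record bounds are considered;
#' ties are broken by the earliest start date. Days absent from the
#' record count as zero load.
#'
#' @param daily Tibble with `date` and `tss` (one row per day with
#'   training; missing days are zero-filled internally).
#' @param window_weeks Window length in weeks (default 12).
#' @return A list with `high` and `low`, each `list(start, end, tss)`.
#' @export
extreme_periods <- function(daily, window_weeks = 12) {
  span <- as.integer(window_weeks) * 7L
  dates <- seq(min(as.Date(daily$date)), max(as.Date(daily$date)), by = "day")
  if (length(dates) < span) {
    stop(sprintf("extreme_periods: record covers %d days; need >= %d",
                 length(dates), span), call. = FALSE)
  }
  tss_by_day <- stats::setNames(rep(0, length(dates)), as.character(dates))
  agg <- tapply(daily$tss, as.character(as.Date(daily$date)), sum)
  tss_by_day[names(agg)] <- agg
  cs <- cumsum(c(0, tss_by_day))
  n_win <- length(dates) - span + 1L
  win_sum <- cs[(span + 1):(span + n_win)] - cs[1:n_win]
  hi <- which.max(win_sum)  # which.max/min return the earliest tie
  lo <- which.min(win_sum)
  mk <- function(i) list(start = dates[i], end = dates[i + span - 1L],
                         tss = unname(win_sum[i]))
  list(high = mk(hi), low = mk(lo))
}

#' Seasonal cumulative load
#'
#' Cumulative TSS over the three winter months (December, January,
#' February) and the three summer months (June, July, August), by
#' calendar month membership of the session day.
#'
#' @param daily Tibble with `date` and `tss`.
#' @return A list `winter` and `summer` (cumulated a.u.). Warns when
#'   the record does not touch all six months, in which case the sums
#'   are partial.
#' @export
seasonal_load <- function(daily) {
  if (nrow(daily) == 0) return(list(winter = 0, summer = 0))
  mo <- as.integer(format(as.Date(daily$date), "%m"))
  covered <- unique(as.integer(format(
    seq(min(as.Date(daily$date)), max(as.Date(daily$date)), by = "day"),
    "%m"
  )))
  need <- c(12, 1, 2, 6, 7, 8)
  if (!all(need %in% covered)) {
    warning("seasonal_load: record does not cover all winter/summer months; sums are partial",
            call. = FALSE)
  }
  list(winter = sum(daily$tss[mo %in% c(12, 1, 2)]),
       summer = sum(daily$tss[mo %in% c(6, 7, 8)]))
}

#' Hypoxic dose in kilometer-hours
#'
#' For each exposure block the dose is (total hours of exposure) x
#' (mean altitude in km); the total is the sum over blocks, so the dose
#' is additive over any partition of the exposures. A block covering
#' `start` to `end` inclusive with `hours_per_day` hours contributes
#' `n_days * hours_per_day * altitude_km`. For progressive protocols an
#' `altitude_end_m` column gives the final altitude and the mean of the
#' two endpoints is used (linear ramp).
#'
#' @param exposures Tibble with `start`, `end` (Dates, inclusive),
#'   `hours_per_day` and `altitude_m` (optionally `altitude_end_m`).
#' @return Dose in km·h.
#' @examples
#' hypoxic_dose(tibble::tibble(
#'   start = as.Date("2019-09-20"), end = as.Date("2019-10-16"),
#'   hours_per_day = 24, altitude_m = 2750
#' ))  # 1782
#' @export
hypoxic_dose <- function(exposures) {
  if (nrow(exposures) == 0) return(0)
  if (any(exposures$hours_per_day <= 0 | exposures$hours_per_day > 24)) {
    stop("hypoxic_dose: hours_per_day must be in (0, 24]", call. = FALSE)
  }
  if (any(exposures$altitude_m < 0)) {
    stop("hypoxic_dose: altitude must be non-negative", call. = FALSE)
  }
  days <- as.integer(as.Date(exposures$end) - as.Date(exposures$start)) + 1L
  if (any(days <= 0)) {
    stop("hypoxic_dose: end must not precede start", call. = FALSE)
  }
  alt <- exposures$altitude_m
  if ("altitude_end_m" %in% names(exposures)) {
    alt_end <- exposures$altitude_end_m
    alt <- ifelse(is.na(alt_end), alt, (alt + alt_end) / 2)
  }
  sum(days * exposures$hours_per_day * alt / 1000)
}

#' Read a training-session log from CSV
#'
#' One row per session: `athlete_id`, `start` (datetime or date),
#' `duration_s`, `np_w`, `ftp_w` and optionally a precomputed `tss`.
#' A missing `tss` column is computed with [tss()].
#'
#' @param path CSV path.
#' @return Tibble of sessions.
#' @export
read_sessions <- function(path) {
  req <- c("athlete_id", "start", "duration_s", "np_w", "ftp_w")
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(req, hdr)
  if (length(missing) > 0) {
    stop(sprintf("session file '%s' is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      athlete_id = readr::col_character(),
      start = readr::col_datetime(),
      .default = readr::col_double()
    ),
    show_col_types = FALSE
  )
  if (!"tss" %in% names(df)) {
    df$tss <- tss(df$duration_s, df$np_w, df$ftp_w)
  }
  df
}

#' Read a hypoxic-exposure log from CSV
#'
#' Columns: `athlete_id`, `start`, `end` (dates, inclusive),
#' `hours_per_day`, `altitude_m`, optional `altitude_end_m` for
#' progressive protocols.
#'
#' @param path CSV path.
#' @return Tibble of exposures.
#' @export
read_exposures <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      athlete_id = readr::col_character(),
      start = readr::col_date(), end = readr::col_date(),
      .default = readr::col_double()
    ),
    show_col_types = FALSE
  )
}

#' Daily TSS series from a session log
#'
#' @param sessions Session tibble (`start`, `tss`).
#' @return Tibble `date`, `tss` (summed per calendar day).
#' @export
daily_tss <- function(sessions) {
  d <- tibble::tibble(date = as.Date(sessions$start), tss = sessions$tss)
  dplyr::summarise(dplyr::group_by(d, .data$date),
                   tss = sum(.data$tss), .groups = "drop")
}
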