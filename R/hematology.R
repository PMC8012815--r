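#' OFF-score (erythropoiesis stimulation index)
#'
#' Computes the OFF-score from hemoglobin concentration and reticulocyte
#' percentage: \eqn{OFF = 10 \cdot [Hb] - 60\sqrt{Ret\%}} with `hb` in g/dL.
#' The factor 10 converts hemoglobin to g/L; internally the package keeps
#' hemoglobin in g/dL everywhere and the conversion lives only here.
#' High OFF-scores indicate suppressed erythropoiesis relative to the
#' circulating hemoglobin level (e.g., after withdrawal of a blood
#' manipulation), low scores indicate stimulation.
#'
#' @param hb Hemoglobin concentration, g/dL. Must be positive.
#' @param ret_pct Reticulocyte percentage. Must be strictly positive
#'   (the square root makes 0 a boundary with no diagnostic meaning).
#' @return OFF-score in arbitrary units, vectorized over inputs.
#' @examples
#' off_score(14.0, 1.0)   # 80
#' off_score(14.4, 0.76)  # ~91.7
#' @export
off_score <- function(hb, ret_pct) {
  if (any(!is.finite(hb)) || any(!is.finite(ret_pct))) {
    stop("off_score: inputs must be finite", call. = FALSE)
  }
  if (any(hb <= 0)) stop("off_score: hb must be positive", call. = FALSE)
  if (any(ret_pct <= 0)) {
    stop("off_score: ret_pct must be strictly positive", call. = FALSE)
  }
  hb * 10 - 60 * sqrt(ret_pct)
}

#' Analyzer replicate acceptance rule
#'
#' Blood analyses are run in immediate duplicate; a pair is accepted when
#' the two results agree within the marker-specific tolerance:
#' 0.1 g/dL for hemoglobin, and for Ret% 0.15 percentage points when the
#' pair mean is below 1% or 0.25 when it is 1% or above. On acceptance the
#' first result is the recorded value.
#'
#' The Ret% tolerance bracket is chosen by the pair mean, and equality
#' (mean exactly 1%) takes the wider 0.25 tolerance; the pass/fail
#' decision is symmetric in the two replicate values.
#'
#' @param marker `"hb"` or `"ret_pct"`.
#' @param value_1,value_2 The two replicate results (same units as marker);
#'   `value_1` is the first-run result and becomes the recorded value on pass.
#' @return A list with `pass` (logical), `recorded` (`value_1` on pass,
#'   `NA` on fail), `difference` and `tolerance`.
#' @examples
#' validate_replicates("hb", 14.20, 14.30)      # pass, recorded 14.20
#' validate_replicates("ret_pct", 1.30, 1.54)   # pass (mean >= 1 => 0.25)
#' @export
validate_replicates <- function(marker, value_1, value_2) {
  marker <- match.arg(marker, c("hb", "ret_pct"))
  if (!is.finite(value_1) || !is.finite(value_2) ||
      value_1 <= 0 || value_2 <= 0) {
    stop("validate_replicates: replicate values must be positive and finite",
         call. = FALSE)
  }
  diff <- abs(value_1 - value_2)
  tol <- if (marker == "hb") {
    0.1
  } else if (mean(c(value_1, value_2)) < 1) {
    0.15
  } else {
    0.25
  }
  pass <- diff <= tol + 1e-9  # boundary inclusive, robust to binary decimals
  list(
    pass = pass,
    recorded = if (pass) value_1 else NA_real_,
    difference = diff,
    tolerance = tol
  )
}

blood_required_cols <- c("athlete_id", "collection_time", "hb", "ret_pct")
blood_numeric_cols <- c(
  "hb", "ret_pct", "hct", "rbc", "mcv", "mch", "mchc", "off_score", "abps",
  "hb_rep1", "hb_rep2", "ret_rep1", "ret_rep2"
)

#' Read a blood-sample table from CSV
#'
#' One row per analyzer result. Required columns: `athlete_id`,
#' `collection_time` (ISO-8601 datetime, timezone-naive, stored as UTC),
#' `hb` (g/dL), `ret_pct` (%). Recognized optional columns: `hct`
#' (fraction of 1), `rbc` (10^12/L), `mcv` (fL), `mch` (pg), `mchc`
#' (g/dL), `off_score`, `abps` (externally supplied score), and replicate
#' pairs `hb_rep1`/`hb_rep2`, `ret_rep1`/`ret_rep2`. A missing
#' `off_score` column is computed from `hb` and `ret_pct`.
#'
#' @param path CSV file path.
#' @return A tibble of blood samples ordered by athlete and time.
#' @seealso [write_blood_samples()], [blood_qc()]
#' @export
read_blood_samples <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(blood_required_cols, hdr)
  if (length(missing) > 0) {
    stop(sprintf("blood file '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      athlete_id = readr::col_character(),
      collection_time = readr::col_datetime(),
      .default = readr::col_double()
    ),
    show_col_types = FALSE
  )
  if (nrow(df) == 0) {
    stop(sprintf("blood file '%s' contains no samples", path), call. = FALSE)
  }
  if (!"off_score" %in% names(df)) {
    df$off_score <- off_score(df$hb, df$ret_pct)
  }
  dplyr::arrange(df, .data$athlete_id, .data$collection_time)
}

#' Write a blood-sample table to CSV
#'
#' Writes the schema read by [read_blood_samples()] (ISO-8601 datetimes,
#' full numeric precision) so that read/write round-trips are exact at
#' the stored precision.
#'
#' @param samples Tibble of blood samples.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_blood_samples <- function(samples, path) {
  out <- samples
  out$collection_time <- format(out$collection_time, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(out, path)
  invisible(path)
}

#' Blood-sample quality control
#'
#' Applies physiological range checks and internal-consistency checks to a
#' blood-sample table and, where replicate columns are present, the
#' duplicate-analysis acceptance rule of [validate_replicates()]. Rows
#' failing any check are quarantined with a reason rather than dropped
#' silently.
#'
#' Checks: `hb` in (5, 25) g/dL; `ret_pct` in (0, 10); `hct` in
#' (0.15, 0.70) when present; a supplied `off_score` must agree with
#' `off_score(hb, ret_pct)` to 0.01; when `hb`, `hct` and `mchc` are all
#' present, `|mchc - hb/hct|` must be within `mchc_tol`; replicate pairs
#' must pass the marker tolerance and, on pass, the recorded value is the
#' first replicate.
#'
#' @param samples Blood-sample tibble (see [read_blood_samples()]).
#' @param mchc_tol Tolerance (g/dL) for the MCHC consistency check.
#' @return A list with `clean` (accepted rows, replicate-recorded values
#'   applied) and `quarantined` (rejected rows plus a `qc_reason` column).
#' @export
blood_qc <- function(samples, mchc_tol = 1.0) {
  n <- nrow(samples)
  reasons <- character(n)
  add_reason <- function(reasons, bad, msg) {
    bad[is.na(bad)] <- FALSE
    ifelse(bad, ifelse(reasons == "", msg, paste(reasons, msg, sep = "; ")),
           reasons)
  }
  reasons <- add_reason(reasons, samples$hb <= 5 | samples$hb >= 25,
                        "hb outside (5, 25) g/dL")
  reasons <- add_reason(reasons, samples$ret_pct <= 0 | samples$ret_pct >= 10,
                        "ret_pct outside (0, 10) %")
  if ("hct" %in% names(samples)) {
    reasons <- add_reason(reasons, samples$hct <= 0.15 | samples$hct >= 0.70,
                          "hct outside (0.15, 0.70)")
  }
  if ("off_score" %in% names(samples)) {
    expected <- off_score(samples$hb, samples$ret_pct)
    reasons <- add_reason(reasons, abs(samples$off_score - expected) > 0.01 +
                            1e-9, "off_score inconsistent with hb/ret_pct")
  }
  if (all(c("hct", "mchc") %in% names(samples))) {
    reasons <- add_reason(
      reasons,
      abs(samples$mchc - samples$hb / samples$hct) > mchc_tol,
      "mchc inconsistent with hb/hct"
    )
  }
  rec <- samples
  for (m in c("hb", "ret_pct")) {
    c1 <- if (m == "hb") "hb_rep1" else "ret_rep1"
    c2 <- if (m == "hb") "hb_rep2" else "ret_rep2"
    if (all(c(c1, c2) %in% names(samples))) {
      for (i in seq_len(n)) {
        v1 <- samples[[c1]][i]
        v2 <- samples[[c2]][i]
        if (is.na(v1) || is.na(v2)) next
        res <- validate_replicates(m, v1, v2)
        if (!res$pass) {
          reasons[i] <- if (reasons[i] == "") {
            sprintf("%s replicates differ by %.3g > %.3g", m,
                    res$difference, res$tolerance)
          } else {
            paste(reasons[i], sprintf("%s replicate disagreement", m),
                  sep = "; ")
          }
        } else {
          rec[[m]][i] <- res$recorded
        }
      }
    }
  }
  bad <- reasons != ""
  quarantined <- samples[bad, , drop = FALSE]
  if (any(bad)) quarantined$qc_reason <- reasons[bad]
  list(clean = rec[!bad, , drop = FALSE], quarantined = quarantined)
}
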