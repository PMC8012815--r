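#' Gas and hemoglobin constants for the CO-rebreathing computation
#'
#' Ideal gas constant R = 0.08206 L·atm/(mol·K), hemoglobin molar mass
#' 6.44e4 g/mol, and 4 CO binding sites per hemoglobin molecule.
#' @return Named list `r_gas`, `hb_molar_mass`, `co_per_hb`.
#' @export
gas_constants <- function() {
  list(r_gas = 0.08206, hb_molar_mass = 6.44e4, co_per_hb = 4)
}

#' Absorbed CO volume
#'
#' The CO left in the rebreathing circuit is measured after the
#' rebreathing phase and subtracted from the administered bolus.
#'
#' @param co_bolus_ml CO bolus introduced into the circuit, mL (ambient
#'   conditions).
#' @param co_unabsorbed_ml CO remaining unabsorbed, mL.
#' @return Absorbed CO volume in liters.
#' @examples
#' co_absorbed_volume(107, 7)  # 0.1 L
#' @export
co_absorbed_volume <- function(co_bolus_ml, co_unabsorbed_ml) {
  if (any(co_unabsorbed_ml < 0) || any(co_unabsorbed_ml >= co_bolus_ml)) {
    stop("co_absorbed_volume: need 0 <= unabsorbed < bolus", call. = FALSE)
  }
  (co_bolus_ml - co_unabsorbed_ml) / 1000
}

#' A CO-rebreathing session record
#'
#' Validates the raw measurements of one session. HbCO% is analyzed in
#' triplicate before and after rebreathing; the rise in the triplicate
#' means is the dilution signal.
#'
#' @param athlete_id Athlete identifier.
#' @param date Session date.
#' @param body_mass_kg Body mass, kg.
#' @param co_bolus_ml CO bolus, mL (typically 1.5 mL/kg).
#' @param co_unabsorbed_ml Unabsorbed CO, mL.
#' @param hbco_pre,hbco_post HbCO%, triplicate numeric vectors.
#' @param p_atm Ambient pressure, atm; must lie in (0.5, 1.1).
#' @param temp_k Temperature, K; must lie in (270, 320).
#' @param hb_gdl Concurrent hemoglobin concentration, g/dL (for volume
#'   derivation), optional.
#' @param hct Concurrent (venous) hematocrit, fraction, optional.
#' @return An object of class `rebreathing_session`.
#' @export
rebreathing_session <- function(athlete_id, date, body_mass_kg,
                                co_bolus_ml, co_unabsorbed_ml,
                                hbco_pre, hbco_post,
                                p_atm, temp_k,
                                hb_gdl = NA_real_, hct = NA_real_) {
  if (co_unabsorbed_ml >= co_bolus_ml) {
    stop("rebreathing_session: unabsorbed CO must be below the bolus",
         call. = FALSE)
  }
  if (mean(hbco_post) <= mean(hbco_pre)) {
    stop("rebreathing_session: post-rebreathing HbCO% must exceed pre",
         call. = FALSE)
  }
  if (temp_k <= 270 || temp_k >= 320) {
    stop("rebreathing_session: temperature outside (270, 320) K",
         call. = FALSE)
  }
  if (p_atm <= 0.5 || p_atm >= 1.1) {
    stop("rebreathing_session: pressure outside (0.5, 1.1) atm",
         call. = FALSE)
  }
  structure(
    list(athlete_id = athlete_id, date = as.Date(date),
         body_mass_kg = body_mass_kg, co_bolus_ml = co_bolus_ml,
         co_unabsorbed_ml = co_unabsorbed_ml,
         hbco_pre = hbco_pre, hbco_post = hbco_post,
         p_atm = p_atm, temp_k = temp_k,
         hb_gdl = hb_gdl, hct = hct),
    class = "rebreathing_session"
  )
}

#' Total hemoglobin mass from a CO mole balance
#'
#' The absorbed CO (bolus minus the unabsorbed remainder) is converted
#' to moles with the ideal gas law, \eqn{n_{CO} = P V / (R T)}; one
#' hemoglobin molecule binds four CO molecules, so the CO-tagged
#' hemoglobin is \eqn{n_{CO}/4}; the dilution principle scales tagged to
#' total hemoglobin through the HbCO% rise,
#' \eqn{n_{Hb,total} = n_{Hb,tagged} \cdot 100 / \Delta HbCO}; and the
#' molar mass 6.44e4 g/mol gives the mass. \eqn{\Delta HbCO} is the
#' difference of the post- and pre-rebreathing triplicate means, in
#' percentage points.
#'
#' @param session A [rebreathing_session()], or a pressure in atm when
#'   calling with the raw arguments.
#' @param v_co_l Absorbed CO volume, L (raw-argument form).
#' @param temp_k Temperature, K (raw-argument form).
#' @param delta_hbco HbCO% rise, percentage points (raw-argument form).
#' @param delta_floor Warn when `delta_hbco` falls below this floor
#'   (default 2 percentage points), where the dilution readout loses
#'   precision.
#' @return Total hemoglobin mass, g.
#' @examples
#' hbmass(1.0, v_co_l = 0.1, temp_k = 293.15, delta_hbco = 6.5)  # ~1029.7 g
#' @export
hbmass <- function(session, v_co_l = NULL, temp_k = NULL,
                   delta_hbco = NULL, delta_floor = 2) {
  if (inherits(session, "rebreathing_session")) {
    p_atm <- session$p_atm
    v_co_l <- co_absorbed_volume(session$co_bolus_ml,
                                 session$co_unabsorbed_ml)
    temp_k <- session$temp_k
    delta_hbco <- mean(session$hbco_post) - mean(session$hbco_pre)
  } else {
    p_atm <- session
  }
  if (delta_hbco <= 0) {
    stop("hbmass: HbCO% rise must be positive", call. = FALSE)
  }
  if (delta_hbco < delta_floor) {
    warning(sprintf(
      "hbmass: HbCO%% rise %.2f below %.2f points; precision is degraded",
      delta_hbco, delta_floor
    ), call. = FALSE)
  }
  k <- gas_constants()
  n_co <- p_atm * v_co_l / (k$r_gas * temp_k)
  n_hb_tagged <- n_co / k$co_per_hb
  n_hb_total <- n_hb_tagged * 100 / delta_hbco
  n_hb_total * k$hb_molar_mass
}

#' HbCO% rise implied by a known hemoglobin mass
#'
#' Inverse of [hbmass()]; used to construct sessions with a known truth
#' (e.g., by the synthetic cohort generator).
#'
#' @param hbmass_g Total hemoglobin mass, g.
#' @param p_atm Pressure, atm.
#' @param v_co_l Absorbed CO volume, L.
#' @param temp_k Temperature, K.
#' @return HbCO% rise in percentage points.
#' @export
delta_hbco_for_hbmass <- function(hbmass_g, p_atm, v_co_l, temp_k) {
  k <- gas_constants()
  n_co <- p_atm * v_co_l / (k$r_gas * temp_k)
  (n_co / k$co_per_hb) * 100 / (hbmass_g / k$hb_molar_mass)
}

#' Blood, red-cell and plasma volumes from hemoglobin mass
#'
#' Standard hemoglobin-dilution identity: blood volume is the mass of
#' circulating hemoglobin divided by its concentration,
#' \eqn{BV = Hbmass / [Hb] \times 100} (mL with `[Hb]` in g/dL); the
#' red-cell volume applies the body/venous hematocrit correction factor
#' `f_cell` to the venous hematocrit, \eqn{RCV = BV \cdot Hct \cdot
#' f_{cell}}; plasma volume is the remainder, so `pv + rcv = bv`
#' exactly.
#'
#' @param hbmass_g Total hemoglobin mass, g.
#' @param hb_gdl Hemoglobin concentration, g/dL.
#' @param hct Venous hematocrit, fraction of 1.
#' @param f_cell Body/venous hematocrit ratio (default 0.91).
#' @return Named list `bv`, `rcv`, `pv` in mL.
#' @examples
#' blood_volumes(1000, 14.0, 0.44, 0.91)
#' @export
blood_volumes <- function(hbmass_g, hb_gdl, hct, f_cell = 0.91) {
  if (any(hbmass_g <= 0) || any(hb_gdl <= 0)) {
    stop("blood_volumes: hbmass and hb must be positive", call. = FALSE)
  }
  if (any(hct < 0) || any(hct * f_cell > 1)) {
    stop("blood_volumes: need 0 <= hct * f_cell <= 1", call. = FALSE)
  }
  bv <- hbmass_g / hb_gdl * 100
  rcv <- bv * hct * f_cell
  list(bv = bv, rcv = rcv, pv = bv - rcv)
}

#' First-order uncertainty budget for one session
#'
#' Propagates the stated instrument typical errors (0.1 mL on the
#' unabsorbed-CO reading; HbCO% analyzer SD on each of the six
#' triplicate readings) into a relative standard error on Hbmass.
#' The point estimate from [hbmass()] is never corrected; this is a
#' reporting aid only.
#'
#' @param session A [rebreathing_session()].
#' @param co_meter_te_ml Typical error of the unabsorbed-CO reading, mL.
#' @param hbco_read_sd SD of a single HbCO% reading, percentage points.
#' @return List with `hbmass_g`, `rel_se` and the two contributions.
#' @export
hbmass_uncertainty <- function(session, co_meter_te_ml = 0.1,
                               hbco_read_sd = 0.14) {
  stopifnot(inherits(session, "rebreathing_session"))
  v <- co_absorbed_volume(session$co_bolus_ml, session$co_unabsorbed_ml)
  delta <- mean(session$hbco_post) - mean(session$hbco_pre)
  rel_v <- (co_meter_te_ml / 1000) / v
  rel_delta <- hbco_read_sd * sqrt(2 / 3) / delta
  list(
    hbmass_g = hbmass(session),
    rel_se = sqrt(rel_v^2 + rel_delta^2),
    rel_from_co_meter = rel_v,
    rel_from_hbco = rel_delta
  )
}

#' Read CO-rebreathing sessions from CSV
#'
#' One row per session with columns `athlete_id`, `date`,
#' `body_mass_kg`, `co_bolus_ml`, `co_unabsorbed_ml`,
#' `hbco_pre_1..3`, `hbco_post_1..3`, `p_atm`, `temp_k` and optional
#' `hb_gdl`, `hct`.
#'
#' @param path CSV path.
#' @return A tibble of session rows.
#' @export
read_rebreathing <- function(path) {
  req <- c("athlete_id", "date", "body_mass_kg", "co_bolus_ml",
           "co_unabsorbed_ml", paste0("hbco_pre_", 1:3),
           paste0("hbco_post_", 1:3), "p_atm", "temp_k")
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(req, hdr)
  if (length(missing) > 0) {
    stop(sprintf("rebreathing file '%s' is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  readr::read_csv(
    path,
    col_types = readr::cols(
      athlete_id = readr::col_character(),
      date = readr::col_date(),
      .default = readr::col_double()
    ),
    show_col_types = FALSE
  )
}

#' Per-session hemoglobin mass and volume table
#'
#' Applies [hbmass()] and [blood_volumes()] to each row of a session
#' table (see [read_rebreathing()]).
#'
#' @param sessions Session tibble.
#' @param f_cell Body/venous hematocrit correction factor.
#' @return Tibble with `athlete_id`, `date`, `hbmass_g`, `bv_ml`,
#'   `rcv_ml`, `pv_ml` (volumes `NA` where `hb_gdl`/`hct` are absent).
#' @export
hbmass_table <- function(sessions, f_cell = 0.91) {
  rows <- lapply(seq_len(nrow(sessions)), function(i) {
    r <- sessions[i, ]
    s <- rebreathing_session(
      r$athlete_id, r$date, r$body_mass_kg, r$co_bolus_ml,
      r$co_unabsorbed_ml,
      c(r$hbco_pre_1, r$hbco_pre_2, r$hbco_pre_3),
      c(r$hbco_post_1, r$hbco_post_2, r$hbco_post_3),
      r$p_atm, r$temp_k,
      hb_gdl = if ("hb_gdl" %in% names(r)) r$hb_gdl else NA_real_,
      hct = if ("hct" %in% names(r)) r$hct else NA_real_
    )
    m <- hbmass(s)
    if (is.finite(s$hb_gdl) && is.finite(s$hct)) {
      vol <- blood_volumes(m, s$hb_gdl, s$hct, f_cell)
    } else {
      vol <- list(bv = NA_real_, rcv = NA_real_, pv = NA_real_)
    }
    tibble::tibble(athlete_id = r$athlete_id, date = as.Date(r$date),
                   hbmass_g = m, bv_ml = vol$bv, rcv_ml = vol$rcv,
                   pv_ml = vol$pv)
  })
  dplyr::bind_rows(rows)
}
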