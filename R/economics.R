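# Default cost constants for the scaled-up batch SFE plant (2016 Tunis
# prices, USD; specific solvent-cycle energies in kJ per kg CO2 circulated).
DEFAULT_PRICES <- list(leaves = 1.35, co2 = 0.15, ethanol = 0.97,
                       electricity = 217.10, labor_hourly = 6.60,
                       labor_monthly = 1475.60)
DEFAULT_ENERGIES <- c(cooling = -261.29, heating = 219.2, pumping = 55.0196)
CEPCI_REF <- 580          # plant-cost index of the FCI table's base year
LAB_Q_ANCHOR <- 3.36e-5   # kg/s solvent at the laboratory scale
LAB_FEED_ANCHOR <- 0.023  # kg feed at the laboratory scale

#' Describe a batch extraction plant costing scenario
#'
#' Collects the plant geometry, schedule, prices and energies the
#' cost-of-manufacturing model needs. Defaults describe the bundled leaf
#' extraction case study: a two-vessel plant running 60-minute batches for
#' 8000 h/yr, bed packed at 296 kg/m^3, solvent flow scaled from the
#' laboratory anchor by constant solvent-to-feed ratio, two salaried
#' operators, 2\% CO2 makeup, no ethanol use and no waste-treatment cost.
#'
#' @param vessel_volume extraction vessel volume (m^3).
#' @param yield_pct extraction yield (% w/w), > 0.
#' @param n_vessels number of vessels (two alternate so one is always
#'   extracting; the batch count is set by the schedule).
#' @param batch_time batch duration (h).
#' @param annual_hours operating hours per year.
#' @param bed_density bed packing density (kg/m^3).
#' @param q_co2 solvent mass flow while extracting (kg/s); default scales the
#'   laboratory anchor by the feed-mass ratio (constant solvent-to-feed
#'   ratio, which preserves the dimensionless extraction time per batch).
#' @param prices list of unit prices (USD): `leaves`, `co2`, `ethanol` per
#'   kg, `electricity` per MWh, `labor_hourly` per h, `labor_monthly` per
#'   month.
#' @param specific_energies kJ per kg of circulated CO2 for cooling, heating
#'   and pumping (cooling is conventionally negative; magnitudes are
#'   charged at the electricity tariff).
#' @param co2_loss_frac fraction of circulated CO2 lost per cycle.
#' @param ethanol_kg_yr annual ethanol use for cleaning (kg).
#' @param workers_per_shift operators per shift.
#' @param shifts_per_day shifts per day.
#' @param labor_mode how operating labor is charged: `"payroll"` (default;
#'   `workers_per_shift` salaried operators at the monthly wage),
#'   `"on_duty"` (`workers_per_shift` paid hourly for every operating hour)
#'   or `"headcount"` (`workers_per_shift * shifts_per_day` salaried
#'   operators).
#' @param fci_usd fixed capital investment (USD); default looked up from the
#'   bundled vessel-cost table via [fci_lookup()].
#' @param cepci_now plant cost index used to scale the FCI table.
#' @return an object of class `cost_scenario`.
#' @export
cost_scenario <- function(vessel_volume = 0.1, yield_pct = 0.3,
                          n_vessels = 2, batch_time = 1,
                          annual_hours = 8000, bed_density = 296,
                          q_co2 = NULL, prices = DEFAULT_PRICES,
                          specific_energies = DEFAULT_ENERGIES,
                          co2_loss_frac = 0.02, ethanol_kg_yr = 0,
                          workers_per_shift = 2, shifts_per_day = 3,
                          labor_mode = c("payroll", "on_duty", "headcount"),
                          fci_usd = NULL, cepci_now = CEPCI_REF) {
  labor_mode <- match.arg(labor_mode)
  stopifnot(vessel_volume > 0, yield_pct > 0, batch_time > 0,
            annual_hours > 0, bed_density > 0,
            co2_loss_frac >= 0, co2_loss_frac < 1,
            workers_per_shift > 0, shifts_per_day > 0)
  feed_batch <- bed_density * vessel_volume
  if (is.null(q_co2))
    q_co2 <- LAB_Q_ANCHOR * feed_batch / LAB_FEED_ANCHOR
  if (is.null(fci_usd))
    fci_usd <- fci_lookup(vessel_volume, cepci_now)
  structure(list(vessel_volume = vessel_volume, yield_pct = yield_pct,
                 n_vessels = n_vessels, batch_time = batch_time,
                 annual_hours = annual_hours, bed_density = bed_density,
                 q_co2 = q_co2, prices = prices,
                 specific_energies = specific_energies,
                 co2_loss_frac = co2_loss_frac,
                 ethanol_kg_yr = ethanol_kg_yr,
                 workers_per_shift = workers_per_shift,
                 shifts_per_day = shifts_per_day, labor_mode = labor_mode,
                 fci_usd = fci_usd, cepci_now = cepci_now),
            class = "cost_scenario")
}

#' @export
print.cost_scenario <- function(x, ...) {
  cat(sprintf("Cost scenario: %g m^3 vessel (x%d), yield %.2f%%\n",
              x$vessel_volume, x$n_vessels, x$yield_pct))
  cat(sprintf("  %g h batches, %g h/yr, bed %.0f kg/m^3, Q = %.4g kg/s\n",
              x$batch_time, x$annual_hours, x$bed_density, x$q_co2))
  cat(sprintf("  FCI = %s USD (index %g), labor mode '%s'\n",
              format(round(x$fci_usd), big.mark = ","), x$cepci_now,
              x$labor_mode))
  invisible(x)
}

#' Fixed capital investment of an SFE unit
#'
#' Looks up the bundled installed-cost table for two-vessel supercritical
#' extraction units (tabulated at 0.1--1.0 m^3, cost-index base 580).
#' Tabulated volumes return the table value exactly; intermediate volumes
#' are interpolated log-log; volumes outside the table are flagged and
#' extrapolated from the nearest segment.
#'
#' @param vessel_volume vessel volume (m^3).
#' @param cepci_now plant cost index; FCI scales linearly as
#'   `cepci_now/580`.
#' @return the fixed capital investment (USD).
#' @examples
#' fci_lookup(0.1)   # 853975
#' @export
fci_lookup <- function(vessel_volume, cepci_now = CEPCI_REF) {
  stopifnot(all(vessel_volume > 0), cepci_now > 0)
  tab <- fci_table()
  v <- tab$volume_m3
  f <- tab$fci_usd
  vapply(vessel_volume, function(vol) {
    scale <- cepci_now / CEPCI_REF
    hit <- which(abs(v - vol) < 1e-12)
    if (length(hit) == 1) return(f[hit] * scale)
    if (vol < min(v) || vol > max(v))
      warning(sprintf("volume %g m^3 outside the cost table [%g, %g]; %s",
                      vol, min(v), max(v), "extrapolating"), call. = FALSE)
    lv <- log(v); lf <- log(f)
    i <- findInterval(vol, v, all.inside = TRUE)
    slope <- (lf[i + 1] - lf[i]) / (lv[i + 1] - lv[i])
    exp(lf[i] + slope * (log(vol) - lv[i])) * scale
  }, numeric(1))
}

#' Solvent-flow scale-up between SFE units
#'
#' The square-law scale-up rule relating the solvent flow that preserves the
#' kinetic behaviour between two units of different feed mass and bed
#' geometry:
#' \deqn{Q_2 = Q_1 (F_2/F_1)^2 (H_{B1}/H_{B2}) (d_{B1}/d_{B2}).}
#'
#' @param Q1 solvent flow of the reference unit (kg/s).
#' @param F1,F2 feed masses of the reference and target units (kg).
#' @param HB1,HB2 bed heights (m).
#' @param dB1,dB2 bed diameters (m).
#' @return the target unit solvent flow `Q2` (kg/s).
#' @export
scale_up_flow <- function(Q1, F1, F2, HB1, HB2, dB1, dB2) {
  stopifnot(Q1 > 0, F1 > 0, F2 > 0, HB1 > 0, HB2 > 0, dB1 > 0, dB2 > 0)
  Q1 * (F2 / F1)^2 * (HB1 / HB2) * (dB1 / dB2)
}

#' Annual schedule and mass balance of the plant
#'
#' @param scenario a [cost_scenario()].
#' @return a list: `batches_yr`, `feed_kg_batch`, `feed_kg_yr`,
#'   `extract_kg_yr`, `co2_circulated_kg_yr`, `co2_makeup_kg_yr`.
#' @export
annual_balance <- function(scenario) {
  stopifnot(inherits(scenario, "cost_scenario"))
  batches <- scenario$annual_hours / scenario$batch_time
  feed_batch <- scenario$bed_density * scenario$vessel_volume
  feed_yr <- feed_batch * batches
  extract_yr <- feed_yr * scenario$yield_pct / 100
  co2_circ <- scenario$q_co2 * scenario$batch_time * 3600 * batches
  list(batches_yr = batches, feed_kg_batch = feed_batch,
       feed_kg_yr = feed_yr, extract_kg_yr = extract_yr,
       co2_circulated_kg_yr = co2_circ,
       co2_makeup_kg_yr = scenario$co2_loss_frac * co2_circ)
}

labor_cost <- function(scenario) {
  p <- scenario$prices
  switch(scenario$labor_mode,
         payroll = scenario$workers_per_shift * p$labor_monthly * 12,
         on_duty = scenario$workers_per_shift * p$labor_hourly *
           scenario$annual_hours,
         headcount = scenario$workers_per_shift * scenario$shifts_per_day *
           p$labor_monthly * 12)
}

#' Annual cost of manufacturing breakdown
#'
#' Turton-style cost of manufacturing with fixed multipliers:
#' \deqn{COM = 0.340\,FCI + 2.73\,C_{OL} + 1.23\,(C_{UT} + C_{WT} + C_{RM}).}
#' Utilities charge the magnitudes of the three specific solvent-cycle
#' energies, applied to the circulated CO2 mass, at the electricity tariff.
#' Raw materials cover the leaf feed, the CO2 makeup and any ethanol use;
#' waste treatment is zero (the solvent is recycled and spent leaves are
#' reusable). The COM multiplier on FCI already contains depreciation.
#'
#' @param scenario a [cost_scenario()].
#' @return an object of class `cost_breakdown`: annual `fci_term`, `c_ol`,
#'   `c_ut`, `c_wt`, `c_rm`, `com` (USD/yr), `extract_kg_yr`, `com_per_kg`
#'   (USD/kg), category `shares` (percent of COM) and the balance.
#' @export
cost_breakdown <- function(scenario) {
  stopifnot(inherits(scenario, "cost_scenario"))
  bal <- annual_balance(scenario)
  p <- scenario$prices
  c_ol <- labor_cost(scenario)
  energy_kj <- sum(abs(scenario$specific_energies)) * bal$co2_circulated_kg_yr
  c_ut <- p$electricity * energy_kj / 3.6e6   # kJ -> MWh
  c_rm <- p$leaves * bal$feed_kg_yr + p$co2 * bal$co2_makeup_kg_yr +
    p$ethanol * scenario$ethanol_kg_yr
  c_wt <- 0
  fci_term <- 0.340 * scenario$fci_usd
  com <- fci_term + 2.73 * c_ol + 1.23 * (c_ut + c_wt + c_rm)
  shares <- 100 * c(fci = fci_term, labor = 2.73 * c_ol,
                    utilities = 1.23 * c_ut, waste = 1.23 * c_wt,
                    raw_material = 1.23 * c_rm) / com
  structure(list(fci_term = fci_term, c_ol = c_ol, c_ut = c_ut,
                 c_wt = c_wt, c_rm = c_rm, com = com,
                 extract_kg_yr = bal$extract_kg_yr,
                 com_per_kg = com / bal$extract_kg_yr,
                 shares = shares, balance = bal, scenario = scenario),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  usd <- function(v) format(round(v, 2), big.mark = ",", nsmall = 2)
  cat("Annual cost of manufacturing\n")
  cat(sprintf("  0.340 FCI : %s USD/yr\n", usd(x$fci_term)))
  cat(sprintf("  2.73 C_OL : %s USD/yr\n", usd(2.73 * x$c_ol)))
  cat(sprintf("  1.23 C_UT : %s USD/yr\n", usd(1.23 * x$c_ut)))
  cat(sprintf("  1.23 C_RM : %s USD/yr\n", usd(1.23 * x$c_rm)))
  cat(sprintf("  COM       : %s USD/yr\n", usd(x$com)))
  cat(sprintf("  extract   : %s kg/yr -> %s USD/kg\n",
              format(signif(x$extract_kg_yr, 6)), usd(x$com_per_kg)))
  invisible(x)
}

#' Manufacturing cost matrix over vessel volume and yield
#'
#' Evaluates `com_per_kg` for every (volume, yield) pair of a base scenario.
#' COM itself does not depend on yield, so each row is exactly inversely
#' proportional to the yield axis.
#'
#' @param volumes vessel volumes (m^3).
#' @param yields extraction yields (% w/w).
#' @param base a [cost_scenario()] providing every other setting.
#' @return a list with `com_per_kg` (matrix, volumes x yields),
#'   `com_usd_yr` (per volume) and `shares` (cost-category percentage matrix,
#'   volumes x categories).
#' @export
com_matrix <- function(volumes = c(0.1, 0.2, 0.4, 0.6, 1.0),
                       yields = c(0.3, 0.5, 0.7, 1.0, 1.5),
                       base = cost_scenario()) {
  stopifnot(inherits(base, "cost_scenario"))
  m <- matrix(NA_real_, length(volumes), length(yields),
              dimnames = list(paste0(volumes, " m^3"), paste0(yields, "%")))
  com_yr <- numeric(length(volumes))
  shares <- NULL
  for (i in seq_along(volumes)) {
    sc <- base
    sc$vessel_volume <- volumes[i]
    sc$q_co2 <- LAB_Q_ANCHOR * sc$bed_density * volumes[i] / LAB_FEED_ANCHOR
    sc$fci_usd <- fci_lookup(volumes[i], sc$cepci_now)
    for (j in seq_along(yields)) {
      sc$yield_pct <- yields[j]
      cb <- cost_breakdown(sc)
      m[i, j] <- cb$com_per_kg
    }
    com_yr[i] <- cb$com
    shares <- rbind(shares, cb$shares)
  }
  rownames(shares) <- rownames(m)
  list(com_per_kg = m, com_usd_yr = stats::setNames(com_yr, rownames(m)),
       shares = shares)
}
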