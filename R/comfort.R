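# Fanger PMV/PPD (ISO 7730 heat balance) and cost-orientation transforms.

#' Operator profile
#'
#' Personal parameters entering the PMV computation. Office defaults:
#' 1.2 met of metabolic activity and 1.2 clo of clothing insulation.
#'
#' @param operator_id Identifier string.
#' @param clo Clothing insulation (clo, 1 clo = 0.155 m2K/W); must be > 0.
#' @param met Metabolic rate (met, 1 met = 58.15 W/m2); must be > 0.
#' @return An `operator_profile` list.
#' @export
operator_profile <- function(operator_id, clo = 1.2, met = 1.2) {
  if (clo <= 0 || met <= 0) stop("clo and met must be positive")
  structure(list(operator_id = as.character(operator_id), clo = clo, met = met),
            class = "operator_profile")
}

#' Environment defaults for PMV
#'
#' Quantities not measured by the sensor set: mean radiant temperature
#' (25 °C default, well-insulated walls), relative air velocity (0.1 m/s,
#' below the 0.2 m/s PMV applicability bound) and external work (0 met,
#' sedentary office activity).
#'
#' @param mean_radiant_temp Mean radiant temperature, °C.
#' @param air_velocity Relative air velocity, m/s (>= 0).
#' @param external_work External work, met.
#' @return An `environment_defaults` list.
#' @export
environment_defaults <- function(mean_radiant_temp = 25, air_velocity = 0.1,
                                 external_work = 0) {
  if (air_velocity < 0) stop("air velocity must be >= 0")
  structure(list(mean_radiant_temp = mean_radiant_temp,
                 air_velocity = air_velocity,
                 external_work = external_work),
            class = "environment_defaults")
}

#' Acceptability ranges for the IEQ (derived) variables
#'
#' Regulatory comfort bounds used to define the cost transformations (they
#' never filter data): pm2.5 below 40 μg/m³; PMV within \[-2, 2\] with 0 the
#' comfort target; desk illuminance at least 300 lux; noise below 87 dB.
#'
#' @param pm25_max,pmv_range,pmv_target,illuminance_min,sound_max Bounds.
#' @return An `acceptability_ranges` list.
#' @export
acceptability_ranges <- function(pm25_max = 40, pmv_range = c(-2, 2),
                                 pmv_target = 0, illuminance_min = 300,
                                 sound_max = 87) {
  if (pmv_range[1L] > pmv_range[2L]) stop("pmv_range bounds must be ordered")
  structure(list(pm25_max = pm25_max, pmv_range = pmv_range,
                 pmv_target = pmv_target, illuminance_min = illuminance_min,
                 sound_max = sound_max),
            class = "acceptability_ranges")
}

# Scalar ISO 7730 PMV: iterative heat-balance solution for the clothing
# surface temperature, then the thermal-load equation. tol is on tcl/100.
.pmv_core <- function(ta, tr, vel, rh, met, clo, wme, tol = 1e-7, maxit = 150L) {
  pa <- rh * 10 * exp(16.6536 - 4030.183 / (ta + 235))  # vapour pressure, Pa
  icl <- 0.155 * clo
  m <- met * 58.15
  w <- wme * 58.15
  mw <- m - w
  fcl <- if (icl <= 0.078) 1 + 1.29 * icl else 1.05 + 0.645 * icl
  hcf <- 12.1 * sqrt(vel)
  taa <- ta + 273
  tra <- tr + 273

  tcla <- taa + (35.5 - ta) / (3.5 * icl + 0.1)
  p1 <- icl * fcl
  p2 <- p1 * 3.96
  p3 <- p1 * 100
  p4 <- p1 * taa
  p5 <- 308.7 - 0.028 * mw + p2 * (tra / 100)^4
  xn <- tcla / 100
  xf <- tcla / 50
  hc <- hcf
  it <- 0L
  while (abs(xn - xf) > tol) {
    it <- it + 1L
    if (it > maxit)
      stop("PMV clothing-temperature iteration did not converge")
    xf <- (xf + xn) / 2
    hcn <- 2.38 * abs(100 * xf - taa)^0.25
    hc <- max(hcf, hcn)
    xn <- (p5 + p4 * hc - p2 * xf^4) / (100 + p3 * hc)
  }
  tcl <- 100 * xn - 273

  hl1 <- 3.05e-3 * (5733 - 6.99 * mw - pa)            # skin diffusion
  hl2 <- if (mw > 58.15) 0.42 * (mw - 58.15) else 0    # sweat evaporation
  hl3 <- 1.7e-5 * m * (5867 - pa)                      # latent respiration
  hl4 <- 0.0014 * m * (34 - ta)                        # dry respiration
  hl5 <- 3.96 * fcl * (xn^4 - (tra / 100)^4)           # radiation
  hl6 <- fcl * hc * (tcl - ta)                         # convection
  ts <- 0.303 * exp(-0.036 * m) + 0.028
  ts * (mw - hl1 - hl2 - hl3 - hl4 - hl5 - hl6)
}

#' Predicted Mean Vote (Fanger / ISO 7730)
#'
#' Heat-balance thermal sensation index on the -3 (cold) ... +3 (hot) scale,
#' 0 = neutral. The clothing surface temperature is solved iteratively to a
#' tolerance of 1e-5 °C; non-convergence after 150 iterations is an error.
#' Inputs outside the usual applicability window (10-30 °C, 30-70 %RH) only
#' raise a warning.
#'
#' @param air_temp Air temperature, °C.
#' @param mean_radiant_temp Mean radiant temperature, °C.
#' @param air_velocity Relative air velocity, m/s.
#' @param rh Relative humidity, %.
#' @param met Metabolic rate, met.
#' @param clo Clothing insulation, clo.
#' @param external_work External work, met (0 for office activity).
#' @return PMV, dimensionless; vectorised over the inputs.
#' @examples
#' pmv(air_temp = 24, mean_radiant_temp = 25, air_velocity = 0.1,
#'     rh = 50, met = 1.2, clo = 1.2)
#' @export
pmv <- function(air_temp, mean_radiant_temp = 25, air_velocity = 0.1,
                rh = 50, met = 1.2, clo = 1.2, external_work = 0) {
  if (any(air_temp < 10 | air_temp > 30))
    warning("air temperature outside the 10-30 °C applicability window")
  if (any(rh < 30 | rh > 70))
    warning("relative humidity outside the 30-70 %RH applicability window")
  unname(mapply(.pmv_core, air_temp, mean_radiant_temp, air_velocity, rh,
                met, clo, external_work))
}

#' Predicted Percentage of Dissatisfied
#'
#' Closed-form ISO 7730 mapping from PMV to the expected percentage of
#' thermally dissatisfied occupants; even in PMV with a 5% minimum at
#' neutrality.
#'
#' @param pmv PMV value(s).
#' @return PPD in percent.
#' @examples
#' ppd(0)    # 5
#' ppd(1)
#' @export
ppd <- function(pmv) {
  100 - 95 * exp(-0.03353 * pmv^4 - 0.2179 * pmv^2)
}

#' Derive category-level variables from a raw hourly panel
#'
#' Collapses the thermal-comfort proxies (air temperature + relative
#' humidity) into a single PMV column computed per hour with the operator's
#' profile; every other column is carried through unchanged. The result is a
#' per-operator raw panel with one column per IEQ category.
#'
#' @param panel Raw-oriented [ieq_panel()] containing `temperature` and
#'   `humidity` columns.
#' @param profile An [operator_profile()].
#' @param env An [environment_defaults()].
#' @return A raw [ieq_panel] with a `pmv` column in place of
#'   temperature/humidity.
#' @export
derive_categories <- function(panel, profile = operator_profile("op"),
                              env = environment_defaults()) {
  if (!inherits(panel, "ieq_panel")) stop("expected an ieq_panel")
  if (panel_orientation(panel) != "raw") stop("panel must be raw-oriented")
  cols <- colnames(panel)
  need <- c("temperature", "humidity")
  miss <- setdiff(need, cols)
  if (length(miss))
    stop(sprintf("panel is missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  pmv_col <- pmv(air_temp = panel[, "temperature"],
                 mean_radiant_temp = env$mean_radiant_temp,
                 air_velocity = env$air_velocity,
                 rh = panel[, "humidity"],
                 met = profile$met, clo = profile$clo,
                 external_work = env$external_work)
  # pmv takes the slot of the first thermal proxy to preserve column order
  new_names <- cols
  new_names[new_names == "temperature"] <- "pmv"
  new_names <- new_names[new_names != "humidity"]
  m <- cbind(pmv = pmv_col,
             unclass_panel(panel)[, setdiff(cols, need), drop = FALSE])
  m <- m[, new_names, drop = FALSE]
  ieq_panel(m, "raw")
}

#' Transform a derived panel to cost orientation
#'
#' Applies the category-specific transformations after which every variable
#' is to be minimised: PMV becomes its absolute distance from the comfort
#' target (0), illuminance becomes the absolute distance from the 300 lux
#' task minimum, and pm2.5 and sound level are used as-is. Applying the
#' transform twice is rejected via the orientation flag.
#'
#' @param panel Raw-oriented per-operator [ieq_panel()] with columns among
#'   `pmv`, `illuminance`, `pm25`, `sound`.
#' @param ranges An [acceptability_ranges()].
#' @return A cost-oriented [ieq_panel].
#' @examples
#' m <- cbind(pmv = c(0.191, -0.05), illuminance = c(592.7, 585.2),
#'            pm25 = c(9.3, 8.4), sound = c(46.4, 46.6))
#' rownames(m) <- c("9", "10")
#' to_cost_panel(ieq_panel(m, "raw"))
#' @export
to_cost_panel <- function(panel, ranges = acceptability_ranges()) {
  if (!inherits(panel, "ieq_panel")) stop("expected an ieq_panel")
  if (panel_orientation(panel) == "cost")
    stop("panel is already cost-oriented; refusing to transform twice")
  m <- unclass_panel(panel)
  known <- c("pmv", "illuminance", "pm25", "sound")
  unknown <- setdiff(colnames(m), known)
  if (length(unknown))
    stop(sprintf("no cost transformation defined for column(s): %s",
                 paste(unknown, collapse = ", ")))
  if ("pmv" %in% colnames(m))
    m[, "pmv"] <- abs(m[, "pmv"] - ranges$pmv_target)
  if ("illuminance" %in% colnames(m))
    m[, "illuminance"] <- abs(m[, "illuminance"] - ranges$illuminance_min)
  ieq_panel(m, "cost")
}
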