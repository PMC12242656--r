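#' Economic parameters for the batch process
#'
#' Bundles all prices, reactor design figures and cost coefficients used by
#' the per-batch economics: product price and recovery/purity, feedstock and
#' utility prices, the reactor geometry and compression figures behind the
#' aeration/agitation/cooling models, the downstream step coefficients, and
#' the mineral-medium recipe priced per compound.  Every value can be
#' overridden; defaults give the 200 m3 reference batch.
#'
#' @param ... overrides of any top-level field (named exactly as in the
#'   returned list); nested lists (`reactor`, `heat`, `downstream`,
#'   `sterilization`) are merged field-wise.
#' @param medium optional replacement data.frame with columns `compound`,
#'   `conc_g_l`, `price_usd_kg`.
#' @return object of class `econ_parameters`.
#' @export
econ_parameters <- function(..., medium = NULL) {
  p <- list(
    phb_price = 5.5,            # USD/kg polymer
    recovery = 0.97,            # fraction of polymer recovered downstream
    purity = 0.98,              # fraction of recovered mass that is PHB
    glucose_price = 350,        # USD/ton
    steam_price = 4,            # USD/ton
    electricity_price = 126,    # USD/MWh
    solvent_price = 1.15,       # USD/L
    wastewater_price = 0.5,     # USD/m3
    turnaround_h = 12,          # cleaning + preparation between batches
    month_h = 720,              # 30-day month
    reactor = list(
      volume = 200,             # m3 working volume
      diameter = 5,             # m
      pressure = 263200,        # Pa, head pressure
      inlet_pressure = 101325,  # Pa, ambient
      gamma = 1.4,              # isentropic exponent of air
      compressor_efficiency = 0.7,
      o2_transfer_efficiency = 0.20,  # bubble-to-broth transfer fraction
      o2_fraction_air = 0.2095,
      temperature_K = 298.15,
      medium_density = 1032,    # kg/m3
      anaerobic_agitation = 0.83,  # 1/s (50 rpm)
      power_number = 4,
      o2_sat_mg_l = 7.0,        # dissolved O2 saturation
      o2_setpoint_mg_l = 2.0,   # held dissolved O2
      kla_ceiling_s = 0.2       # physically plausible ceiling, 1/s
    ),
    heat = list(
      K_o2 = 0.50,              # kJ per mmol O2 (aerobic metabolic heat)
      K_anaerobic = 235,        # kJ per mol glucose (anaerobic)
      cooling_cop = 4           # chiller coefficient of performance
    ),
    downstream = list(
      homogenization_kwh_kg = 0.35,   # per kg CDW processed
      homogenization_basis = "total", # residual + PHB
      centrifugation_kwh_m3 = 0.5,
      centrifugation_passes = 3,      # first spin + two wash spins
      extraction_l_kg = 9.25,         # solvent per kg CDW
      extraction_basis = "residual",
      drying_steam_kg_kg = 2          # steam per kg PHB
    ),
    sterilization = list(
      cp_kj_kg_k = 4.18,        # medium ~ water
      delta_t_k = 96,           # 25 -> 121 degC
      steam_latent_kj_kg = 2202 # saturated steam near 121 degC
    ),
    medium = data.frame(
      compound = c("Na2HPO4", "KH2PO4", "(NH4)2SO4",
                   "ferric ammonium citrate", "MgSO4.7H2O", "CaCl2.2H2O",
                   "kanamycin"),
      conc_g_l = c(3.5, 1.5, 1.0, 0.06, 0.20, 0.01, 0.05),
      price_usd_kg = c(1.2, 1.3, 0.25, 2.0, 0.35, 0.3, 150)
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop("unknown economic parameter(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(dots)) {
    if (is.list(p[[nm]]) && !is.data.frame(p[[nm]])) {
      sub <- dots[[nm]]
      bad <- setdiff(names(sub), names(p[[nm]]))
      if (length(bad)) {
        stop("unknown field(s) in '", nm, "': ", paste(bad, collapse = ", "))
      }
      p[[nm]][names(sub)] <- sub
    } else {
      p[[nm]] <- dots[[nm]]
    }
  }
  if (!is.null(medium)) {
    stopifnot(all(c("compound", "conc_g_l", "price_usd_kg") %in%
                    names(medium)))
    p$medium <- medium
  }
  stopifnot(p$recovery > 0, p$recovery <= 1, p$purity > 0, p$purity <= 1)
  class(p) <- "econ_parameters"
  p
}

#' Revenue from PHB sales of one batch
#'
#' `titer x volume x recovery x purity x price`: only the recovered,
#' polymer-grade fraction of the titer is sold.
#'
#' @param result a `simulation_result`.
#' @param p an [econ_parameters()].
#' @return USD per batch.
#' @export
revenue <- function(result, p) {
  result$titer * p$reactor$volume * p$recovery * p$purity * p$phb_price
}

#' Raw-material (glucose) cost of one batch
#'
#' Charged on the full glucose allotment (initial concentration times
#' working volume), which is identical across scenarios of one campaign and
#' therefore never changes their ranking.
#'
#' @inheritParams revenue
#' @return USD per batch.
#' @export
raw_material_cost <- function(result, p) {
  glucose_kg <- result$setup$initial_glucose * p$reactor$volume
  glucose_kg * p$glucose_price / 1000
}

# inlet air volumetric flow (m3/s) required to supply an O2 demand given in
# mmol O2 per hour, at the configured transfer efficiency
.air_flow_m3s <- function(o2_mmol_h, p) {
  Rgas <- 8.314
  o2_supply <- o2_mmol_h / p$reactor$o2_transfer_efficiency / 1000  # mol/h
  air_mol_h <- o2_supply / p$reactor$o2_fraction_air
  air_mol_h * Rgas * p$reactor$temperature_K /
    p$reactor$inlet_pressure / 3600
}

# isentropic compressor power (kW) for an inlet air flow in m3/s
.compressor_kw <- function(q_m3s, p) {
  r <- p$reactor
  g <- r$gamma
  r$inlet_pressure * q_m3s / r$compressor_efficiency * (g / (g - 1)) *
    ((r$pressure / r$inlet_pressure)^((g - 1) / g) - 1) / 1000
}

#' Aeration (compressor) cost of one batch
#'
#' The oxygen uptake rate is taken as `vo2max x X(t)` (dissolved oxygen is
#' controlled, so cells draw at their maximum), inflated by the bubble
#' transfer efficiency to an inlet air flow at ambient conditions, converted
#' to isentropic compressor power and integrated over the batch.  Power is
#' linear in biomass, so the exact integral uses the integrator's
#' \eqn{\int X dt} state rather than a trajectory quadrature.
#'
#' @inheritParams revenue
#' @return USD per batch (0 for anaerobic operation).
#' @export
aeration_cost <- function(result, p) {
  if (result$regime != "aerobic") {
    message("anaerobic regime: aeration cost is 0")
    return(0)
  }
  # OUR integral in mmol/L: vo2max * int X dt; demand is per reactor, so x V
  our_int <- result$vo2max * result$x_integral          # mmol h/L
  q_per_mmol_h <- .air_flow_m3s(1, p)                   # m3/s per (mmol/h)
  kw_per_mmol_h <- .compressor_kw(q_per_mmol_h, p)
  kwh <- kw_per_mmol_h * our_int * p$reactor$volume * 1000
  kwh * p$electricity_price / 1000
}

#' Aerobic agitation (stirring) cost of one batch
#'
#' The oxygen transfer balance OTR = OUR fixes the required volumetric
#' transfer coefficient kLa(t) through the driving force (saturation minus
#' held dissolved-oxygen setpoint); the stirred-tank correlation
#' \eqn{k_La = 0.002 (P_S/V)^{0.7} V_{super}^{0.2}} is then inverted for the
#' gassed stirring power \eqn{P_S(t)}, which is integrated over the
#' trajectory.  Scenarios whose peak kLa demand exceeds the configured
#' physical ceiling are flagged with a warning attribute.
#'
#' @inheritParams revenue
#' @return USD per batch (0 for anaerobic operation), with attribute
#'   `kla_exceeded` when the ceiling was hit.
#' @export
agitation_cost_aerobic <- function(result, p) {
  if (result$regime != "aerobic") {
    message("anaerobic regime: use agitation_cost_anaerobic()")
    return(0)
  }
  r <- p$reactor
  tr <- result$trajectory
  our <- result$vo2max * tr$X                           # mmol/L/h
  dC <- (r$o2_sat_mg_l - r$o2_setpoint_mg_l)            # mg/L driving force
  kla_s <- our * molar_masses()[["oxygen"]] / dC / 3600 # 1/s
  q <- .air_flow_m3s(our * r$volume * 1000, p)          # m3/s over time
  vsup <- q / (pi * r$diameter^2 / 4)                   # m/s
  ps <- ifelse(kla_s > 0 & vsup > 0,
               r$volume * (kla_s / (0.002 * vsup^0.2))^(1 / 0.7), 0)  # W
  kwh <- .trapz(tr$time, ps) / 1000
  cost <- kwh * p$electricity_price / 1000
  attr(cost, "kla_exceeded") <- any(kla_s > r$kla_ceiling_s)
  if (isTRUE(attr(cost, "kla_exceeded"))) {
    warning("required kLa exceeds the configured ceiling of ",
            r$kla_ceiling_s, " 1/s; scenario flagged", call. = FALSE)
  }
  cost
}

#' Anaerobic agitation cost of one batch
#'
#' Without oxygen transfer demands agitation only maintains homogeneity at a
#' fixed low speed, so the ungassed power draw is the constant
#' \eqn{P_S = c \rho N^3 d^5} for the whole operation time.
#'
#' @inheritParams revenue
#' @return USD per batch.
#' @export
agitation_cost_anaerobic <- function(result, p) {
  r <- p$reactor
  ps_w <- r$power_number * r$medium_density * r$anaerobic_agitation^3 *
    r$diameter^5
  kwh <- ps_w * result$t_op / 1000
  kwh * p$electricity_price / 1000
}

#' Cooling cost of one batch
#'
#' Metabolic heat release: aerobic cultures release `K_o2` kJ per mmol of
#' oxygen consumed; anaerobic cultures release `K_anaerobic` kJ per mol of
#' glucose consumed.  Heat is removed by electrically driven chilling at the
#' configured coefficient of performance.
#'
#' @inheritParams revenue
#' @return USD per batch.
#' @export
cooling_cost <- function(result, p) {
  heat_kj <- if (result$regime == "aerobic") {
    p$heat$K_o2 * result$oxygen_consumed * 1000   # mol -> mmol
  } else {
    p$heat$K_anaerobic * result$glucose_consumed
  }
  kwh <- heat_kj / 3600 / p$heat$cooling_cop
  kwh * p$electricity_price / 1000
}

#' Upstream (medium + sterilization) cost of one batch
#'
#' Constant across scenarios by construction: the medium recipe and volume
#' do not depend on the simulation outcome.  Compound masses are the recipe
#' concentrations times the working volume; sterilization steam is the
#' sensible heat to raise the medium from 25 to 121 degC divided by the
#' latent heat of the supply steam.
#'
#' @param p an [econ_parameters()].
#' @return USD per batch, with attribute `breakdown`.
#' @export
upstream_cost <- function(p) {
  v_l <- p$reactor$volume * 1000
  compound_kg <- p$medium$conc_g_l * v_l / 1000
  medium_usd <- sum(compound_kg * p$medium$price_usd_kg)
  s <- p$sterilization
  medium_mass_kg <- p$reactor$medium_density * p$reactor$volume
  steam_kg <- medium_mass_kg * s$cp_kj_kg_k * s$delta_t_k /
    s$steam_latent_kj_kg
  steril_usd <- steam_kg * p$steam_price / 1000
  structure(medium_usd + steril_usd,
            breakdown = c(medium = medium_usd, sterilization = steril_usd))
}

#' Downstream processing cost of one batch
#'
#' Cell disruption (homogenization, charged per kg CDW), broth
#' centrifugation (per m3 per pass: one harvest spin plus two wash spins),
#' solvent extraction (L solvent per kg CDW), polymer drying (kg steam per
#' kg PHB) and wastewater treatment (per m3 of broth).  The CDW basis of
#' homogenization defaults to total biomass (residual cells + polymer) and
#' of extraction to residual biomass; both are configurable.
#'
#' @inheritParams revenue
#' @return USD per batch, with attribute `items` (named breakdown).
#' @export
downstream_cost <- function(result, p) {
  d <- p$downstream
  v <- p$reactor$volume
  residual_kg <- result$final_biomass * v
  phb_kg <- result$titer * v
  total_kg <- residual_kg + phb_kg
  basis <- function(which) if (which == "total") total_kg else residual_kg
  items <- c(
    homogenization = d$homogenization_kwh_kg * basis(d$homogenization_basis) *
      p$electricity_price / 1000,
    centrifugation = d$centrifugation_kwh_m3 * v * d$centrifugation_passes *
      p$electricity_price / 1000,
    extraction = d$extraction_l_kg * basis(d$extraction_basis) *
      p$solvent_price,
    drying = d$drying_steam_kg_kg * phb_kg * p$steam_price / 1000,
    wastewater = v * p$wastewater_price
  )
  structure(sum(items), items = items)
}

#' Assemble the per-batch economics and the monthly gross profit
#'
#' Gross profit is revenue minus raw material, reactor operation (aeration +
#' agitation + cooling), upstream and downstream costs.  The number of
#' batches per month is the (real-valued) rate `720 / (t_op + turnaround)`,
#' and the monthly gross profit is the per-batch gross profit times that
#' rate.
#'
#' @inheritParams revenue
#' @return object of class `batch_economics`: itemised costs, `gross_profit`,
#'   `n_batches_per_month`, `monthly_gross_profit`.
#' @export
monthly_gross_profit <- function(result, p = econ_parameters()) {
  stopifnot(inherits(result, "simulation_result"))
  aer <- if (result$regime == "aerobic") aeration_cost(result, p) else 0
  agi <- if (result$regime == "aerobic") {
    suppressWarnings(agitation_cost_aerobic(result, p))
  } else {
    agitation_cost_anaerobic(result, p)
  }
  cool <- cooling_cost(result, p)
  ds <- downstream_cost(result, p)
  us <- upstream_cost(p)
  rev <- revenue(result, p)
  rm <- raw_material_cost(result, p)
  op <- as.numeric(aer) + as.numeric(agi) + cool
  gp <- rev - (rm + op + as.numeric(us) + as.numeric(ds))
  nbat <- p$month_h / (result$t_op + p$turnaround_h)
  structure(list(
    revenue = rev,
    raw_material = rm,
    upstream = as.numeric(us),
    operation = c(aeration = as.numeric(aer), agitation = as.numeric(agi),
                  cooling = cool),
    downstream = attr(ds, "items"),
    gross_profit = gp,
    n_batches_per_month = nbat,
    monthly_gross_profit = gp * nbat,
    kla_exceeded = isTRUE(attr(agi, "kla_exceeded"))
  ), class = "batch_economics")
}

#' @export
print.batch_economics <- function(x, ...) {
  cat("<batch_economics>\n")
  cat(sprintf("  revenue       %10.0f USD/batch\n", x$revenue))
  cat(sprintf("  raw material  %10.0f\n", x$raw_material))
  cat(sprintf("  operation     %10.0f  (aeration %.0f, agitation %.0f, cooling %.0f)\n",
              sum(x$operation), x$operation[["aeration"]],
              x$operation[["agitation"]], x$operation[["cooling"]]))
  cat(sprintf("  upstream      %10.0f\n", x$upstream))
  cat(sprintf("  downstream    %10.0f\n", sum(x$downstream)))
  cat(sprintf("  gross profit  %10.0f USD/batch x %.2f batches/month\n",
              x$gross_profit, x$n_batches_per_month))
  cat(sprintf("  monthly gross profit %10.0f USD/month\n",
              x$monthly_gross_profit))
  invisible(x)
}

# trapezoidal rule on possibly irregular time grids
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n]) / 2)
}
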