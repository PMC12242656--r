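#' Equipment item for capital-cost scaling
#'
#' @param name free text.
#' @param ref_cost reference purchase cost, USD.
#' @param ref_size reference capacity (any consistent unit).
#' @param ref_index CEPCI index of the reference cost's year.
#' @param target_size capacity to scale to.
#' @return object of class `equipment_item`.
#' @export
equipment_item <- function(name, ref_cost, ref_size, ref_index,
                           target_size) {
  stopifnot(ref_cost > 0, ref_size > 0, ref_index > 0)
  if (!is.numeric(target_size) || target_size <= 0) {
    stop("equipment '", name, "': target size must be positive")
  }
  structure(list(name = name, ref_cost = ref_cost, ref_size = ref_size,
                 ref_index = ref_index, target_size = target_size),
            class = "equipment_item")
}

#' Read an equipment list from CSV
#'
#' Columns: `name`, `ref_cost`, `ref_size`, `ref_index`, `target_size`.
#'
#' @param path CSV file.
#' @return list of [equipment_item()].
#' @export
read_equipment <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "ref_cost", "ref_size", "ref_index", "target_size")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("equipment CSV lacks column(s): ", paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(d)), function(i) {
    equipment_item(d$name[i], d$ref_cost[i], d$ref_size[i], d$ref_index[i],
                   d$target_size[i])
  })
}

#' Finance parameters
#'
#' The 10-year project-economics assumptions: tax and discount rates,
#' straight-line depreciation with a salvage value of 5% of the direct
#' fixed capital, the CEPCI base index for cost inflation, and the standard
#' factor chain from equipment purchase cost to total investment.
#'
#' @param horizon years of operation.
#' @param tax_rate fraction.
#' @param discount_rate fraction.
#' @param salvage_frac salvage value as a fraction of DFC.
#' @param cepci_target CEPCI index of the costing base year.
#' @param tpdc_factors named multipliers on purchase cost for the total
#'   plant direct cost.
#' @param tpic_factors multipliers on TPDC for the indirect cost.
#' @param tpc_extras multipliers on TPC (contractor's fee, contingency).
#' @param ti_extras multipliers on DFC (working capital, start-up).
#' @return object of class `finance_parameters`.
#' @export
finance_parameters <- function(horizon = 10, tax_rate = 0.34,
                               discount_rate = 0.12, salvage_frac = 0.05,
                               cepci_target = 824.5,
                               tpdc_factors = c(installation = 0.50,
                                                piping = 0.40,
                                                instrumentation = 0.35,
                                                insulation = 0.03,
                                                electrical = 0.15,
                                                buildings = 0.45,
                                                yard = 0.15,
                                                auxiliary = 0.50),
                               tpic_factors = c(engineering = 0.25,
                                                construction = 0.354),
                               tpc_extras = c(contractor = 0.05,
                                              contingency = 0.10),
                               ti_extras = c(working_capital = 0.10,
                                             startup = 0.05)) {
  stopifnot(horizon >= 1, tax_rate >= 0, tax_rate <= 1,
            salvage_frac >= 0, salvage_frac <= 1)
  structure(list(horizon = horizon, tax_rate = tax_rate,
                 discount_rate = discount_rate, salvage_frac = salvage_frac,
                 cepci_target = cepci_target, tpdc_factors = tpdc_factors,
                 tpic_factors = tpic_factors, tpc_extras = tpc_extras,
                 ti_extras = ti_extras),
            class = "finance_parameters")
}

#' Scale an equipment cost by capacity and cost index
#'
#' The six-tenths rule with CEPCI inflation:
#' \deqn{Cost = Cost_{ref} (Size/Size_{ref})^{0.6} \cdot I_{target}/I_{ref}}
#'
#' @param item an [equipment_item()].
#' @param target_index CEPCI of the base year.
#' @param exponent capacity-scaling exponent (0.6).
#' @return USD.
#' @export
scale_equipment_cost <- function(item, target_index = 824.5,
                                 exponent = 0.6) {
  stopifnot(inherits(item, "equipment_item"))
  item$ref_cost * (item$target_size / item$ref_size)^exponent *
    target_index / item$ref_index
}

#' Assemble direct fixed capital and total investment
#'
#' Purchase cost (PC) is the sum of scaled equipment costs; the standard
#' multiplier chain then gives total plant direct cost
#' (PC x (1 + sum of direct factors)), indirect cost (TPDC x sum of indirect
#' factors), total plant cost (TPDC + TPIC), direct fixed capital
#' (TPC x (1 + contractor + contingency)) and total investment
#' (DFC x (1 + working capital + start-up)).
#'
#' @param equipment list of [equipment_item()].
#' @param fp a [finance_parameters()].
#' @return list with `purchase_cost`, `tpdc`, `tpic`, `tpc`, `dfc`,
#'   `total_investment`.
#' @export
build_investment <- function(equipment, fp = finance_parameters()) {
  pc <- sum(vapply(equipment, scale_equipment_cost, 0,
                   target_index = fp$cepci_target))
  tpdc <- pc * (1 + sum(fp$tpdc_factors))
  tpic <- tpdc * sum(fp$tpic_factors)
  tpc <- tpdc + tpic
  dfc <- tpc * (1 + sum(fp$tpc_extras))
  ti <- dfc * (1 + sum(fp$ti_extras))
  list(purchase_cost = pc, tpdc = tpdc, tpic = tpic, tpc = tpc, dfc = dfc,
       total_investment = ti)
}

#' Ten-year project finance metrics
#'
#' From the monthly gross profit of the chosen scenario: annual depreciation
#' is straight-line on the depreciable DFC (DFC less salvage) over the
#' horizon; annual net profit is the after-tax annual gross profit net of
#' depreciation; net cash flows add depreciation back (it is not a cash
#' outflow) with the total investment as the year-0 outlay and the salvage
#' value realised in the final year.  ROI is annual net profit over total
#' investment; payback is its reciprocal (undefined for non-positive
#' profit); NPV discounts the cash flows at the configured rate; IRR is the
#' discount rate zeroing the NPV, found by bracketed root-finding on
#' (-0.99, 10) and reported as `NA` when the cash-flow profile admits no
#' sign change.
#'
#' @param mgp monthly gross profit, USD/month.
#' @param dfc direct fixed capital, USD.
#' @param total_investment USD; must be positive.
#' @param fp a [finance_parameters()].
#' @return object of class `finance_report`: `annual_net_profit`,
#'   `roi_pct`, `payback_years`, `npv`, `irr_pct`, `cash_flows` (years
#'   0..horizon), plus the inputs.
#' @export
finance_metrics <- function(mgp, dfc, total_investment,
                            fp = finance_parameters()) {
  if (total_investment <= 0) stop("total investment must be positive")
  dep <- dfc * (1 - fp$salvage_frac) / fp$horizon
  annual_gp <- 12 * mgp
  net_profit <- (annual_gp - dep) * (1 - fp$tax_rate)
  ncf <- c(-total_investment, rep(net_profit + dep, fp$horizon))
  ncf[fp$horizon + 1L] <- ncf[fp$horizon + 1L] + dfc * fp$salvage_frac
  npv_at <- function(r) sum(ncf / (1 + r)^(0:fp$horizon))
  irr <- .irr(ncf)
  structure(list(
    total_investment = total_investment,
    dfc = dfc,
    annual_net_profit = net_profit,
    roi_pct = 100 * net_profit / total_investment,
    payback_years = if (net_profit > 0) total_investment / net_profit
                    else NA_real_,
    npv = npv_at(fp$discount_rate),
    irr_pct = irr,
    cash_flows = ncf
  ), class = "finance_report")
}

# bracketed root of the NPV-vs-rate function on (-0.99, 10); NA when no
# sign change exists; multi-root profiles flagged via attribute
.irr <- function(ncf, lower = -0.99, upper = 10, tol = 1e-9) {
  npv <- function(r) sum(ncf / (1 + r)^(seq_along(ncf) - 1L))
  grid <- c(seq(lower, 1, by = 0.01), seq(1.1, upper, by = 0.1))
  vals <- vapply(grid, npv, 0)
  sgn <- sign(vals)
  flips <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  if (!length(flips)) return(NA_real_)
  root <- stats::uniroot(npv, c(grid[flips[1L]], grid[flips[1L] + 1L]),
                         tol = tol)$root
  out <- 100 * root
  if (length(flips) > 1L) attr(out, "multiple_roots") <- TRUE
  out
}

#' @export
print.finance_report <- function(x, ...) {
  cat("<finance_report>\n")
  cat(sprintf("  total investment   %12.0f USD (DFC %.0f)\n",
              x$total_investment, x$dfc))
  cat(sprintf("  annual net profit  %12.0f USD/year\n", x$annual_net_profit))
  cat(sprintf("  ROI %.1f %% | payback %s years | NPV %.0f USD | IRR %s %%\n",
              x$roi_pct,
              if (is.na(x$payback_years)) "-" else
                sprintf("%.1f", x$payback_years),
              x$npv,
              if (is.na(x$irr_pct)) "-" else sprintf("%.1f", x$irr_pct)))
  invisible(x)
}
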