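#' Scenario table
#'
#' The output container of both scan procedures: one row per scenario with
#' the control variable, the bioprocess quadruple, PHB content and monthly
#' gross profit, plus the three distinguished rows used for decision making:
#' the unconstrained best (highest monthly gross profit), the best within a
#' realistic PHB-content cap (default 85 wt%, the literature ceiling for
#' intracellular accumulation), and the breakeven row (first scenario in
#' grid order with non-negative monthly gross profit).
#'
#' @param rows data.frame of scenario rows.
#' @param control_name name of the control variable column ("phb_flux" or
#'   "growth_fraction").
#' @param content_cap PHB content cap (wt%) for the capped-best selection;
#'   the cap restricts only the selection, never the simulations.
#' @return object of class `scenario_table` (a data.frame with attributes
#'   `best_row`, `best_row_within_cap`, `breakeven_row`, `control`).
#' @export
scenario_table <- function(rows, control_name, content_cap = 85) {
  ok <- rows$status == "ok" & !is.na(rows$monthly_gross_profit)
  best <- if (any(ok)) which.max(ifelse(ok, rows$monthly_gross_profit, -Inf))
          else NA_integer_
  capped <- ok & rows$phb_content <= content_cap
  best_cap <- if (any(capped)) {
    which.max(ifelse(capped, rows$monthly_gross_profit, -Inf))
  } else NA_integer_
  breakeven <- which(ok & rows$monthly_gross_profit >= 0)[1L]
  structure(rows, class = c("scenario_table", "data.frame"),
            control = control_name, content_cap = content_cap,
            best_row = best, best_row_within_cap = best_cap,
            breakeven_row = if (length(breakeven)) breakeven else NA_integer_)
}

#' @export
print.scenario_table <- function(x, ...) {
  cat("<scenario_table> control: ", attr(x, "control"), ", ",
      nrow(x), " scenarios\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  b <- attr(x, "best_row")
  bc <- attr(x, "best_row_within_cap")
  be <- attr(x, "breakeven_row")
  fmt <- function(i) if (is.na(i)) "none" else
    paste0("row ", i, " (", attr(x, "control"), " = ", x[[1L]][i], ")")
  cat("  best: ", fmt(b), " | best within ", attr(x, "content_cap"),
      " wt%: ", fmt(bc), " | breakeven: ", fmt(be), "\n", sep = "")
  invisible(x)
}

.scenario_row <- function(control, result, econ, p) {
  data.frame(control = control,
             final_biomass = result$final_biomass,
             yield = result$yield,
             titer = result$titer,
             productivity = result$productivity,
             phb_content = result$phb_content,
             monthly_gross_profit = econ$monthly_gross_profit,
             t_op = result$t_op,
             status = "ok")
}

.failed_row <- function(control, msg) {
  data.frame(control = control, final_biomass = NA_real_, yield = NA_real_,
             titer = NA_real_, productivity = NA_real_,
             phb_content = NA_real_, monthly_gross_profit = NA_real_,
             t_op = NA_real_, status = paste0("failed: ", msg))
}

#' Growth-associated production trade-off sweep
#'
#' Scans the trade-off between biomass and product formation: each scenario
#' fixes a progressively larger PHB synthesis flux (the growth objective
#' still drives the LP) and runs a full batch simulation plus economics.
#' The default grid is the integers from 0 up to the maximum feasible PHB
#' flux — found by FBA with the PHB exchange as objective under the kinetic
#' uptake bound at the initial glucose concentration — plus that exact
#' maximum.
#'
#' @inheritParams simulate_batch
#' @param econ an [econ_parameters()].
#' @param flux_grid optional numeric vector of fixed PHB fluxes
#'   (mmol/gCDW/h) replacing the default grid.
#' @param phb_reaction reaction whose flux is fixed (the PHB exchange).
#' @param content_cap see [scenario_table()].
#' @return a [scenario_table()] with control column `phb_flux`.
#' @export
sweep_growth_associated <- function(model, kinetics, setup = batch_setup(),
                                    econ = econ_parameters(),
                                    flux_grid = NULL,
                                    phb_reaction = "EX_phb_e",
                                    content_cap = 85) {
  if (!phb_reaction %in% names(model$reactions)) {
    stop("no PHB pathway in model (missing reaction '", phb_reaction, "')")
  }
  if (is.null(flux_grid)) {
    C0 <- setup$initial_glucose / molar_masses()[["glucose"]] * 1000
    u0 <- uptake_rate(kinetics, C0)
    ov <- stats::setNames(list(c(-u0, 0)), model$exchange_ids[["glucose"]])
    if ("oxygen" %in% names(model$exchange_ids)) {
      ov[[model$exchange_ids[["oxygen"]]]] <-
        if (setup$regime == "aerobic") c(-kinetics$vo2max, 0) else c(0, 0)
    }
    fmax <- solve_fba(model, bounds = ov, objective = phb_reaction,
                      parsimonious = FALSE)
    if (fmax$status != "optimal") {
      stop("cannot determine the maximum PHB flux: FBA status '",
           fmax$status, "'")
    }
    flux_grid <- unique(c(seq(0, floor(fmax$objective_value)),
                          fmax$objective_value))
  }
  rows <- lapply(flux_grid, function(fx) {
    tryCatch({
      fixed <- if (fx > 0) stats::setNames(fx, phb_reaction) else NULL
      res <- simulate_batch(model, kinetics, setup, fixed_fluxes = fixed)
      .scenario_row(fx, res, monthly_gross_profit(res, econ), econ)
    }, error = function(e) .failed_row(fx, conditionMessage(e)))
  })
  rows <- do.call(rbind, rows)
  names(rows)[1L] <- "phb_flux"
  scenario_table(rows, "phb_flux", content_cap)
}

#' Two-phase glucose-allocation sweep
#'
#' Scans how much of the fixed total glucose allotment should feed the
#' growth phase versus the production phase: one [simulate_two_phase()] plus
#' economics per grid fraction, from (almost) everything to growth down to a
#' production-only batch.
#'
#' @inheritParams sweep_growth_associated
#' @param fraction_grid fractions of total glucose (mol basis) allocated to
#'   the growth phase; default 100% down to 0% in 10% steps.
#' @param production_objective reaction maximised in the production phase.
#' @return a [scenario_table()] with control column `growth_fraction`.
#' @export
sweep_two_phase <- function(model, kinetics, setup = batch_setup(),
                            econ = econ_parameters(),
                            fraction_grid = seq(1, 0, by = -0.1),
                            production_objective = "EX_phb_e",
                            content_cap = 85) {
  if (!production_objective %in% names(model$reactions)) {
    stop("no PHB pathway in model (missing reaction '",
         production_objective, "')")
  }
  rows <- lapply(fraction_grid, function(fr) {
    tryCatch({
      res <- simulate_two_phase(model, kinetics, setup, growth_fraction = fr,
                                production_objective = production_objective)
      .scenario_row(fr, res, monthly_gross_profit(res, econ), econ)
    }, error = function(e) .failed_row(fr, conditionMessage(e)))
  })
  rows <- do.call(rbind, rows)
  names(rows)[1L] <- "growth_fraction"
  scenario_table(rows, "growth_fraction", content_cap)
}
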