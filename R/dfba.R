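#' Batch simulation setup
#'
#' Defaults describe the reference batch: 200 m3 working volume, 25 g/L
#' initial glucose and 0.25 gCDW/L initial biomass, i.e. a fixed total
#' glucose allotment of 5000 kg so that alternative scenarios are compared
#' on the same substrate basis.
#'
#' @param working_volume reactor working volume, m3.
#' @param initial_glucose g/L.
#' @param initial_biomass gCDW/L.
#' @param tracked_species names of external species whose concentrations are
#'   integrated (species absent from the model are silently skipped; glucose
#'   is always tracked).
#' @param regime `"aerobic"` (oxygen exchange opened at the kinetic maximum
#'   uptake) or `"anaerobic"` (oxygen exchange closed).
#' @param glucose_threshold depletion threshold, mmol/L; integration stops
#'   when glucose falls below it.
#' @param t_max integration horizon, h (safety cap, not an operating time).
#' @param rtol,atol integrator tolerances.
#' @return object of class `batch_setup`.
#' @export
batch_setup <- function(working_volume = 200, initial_glucose = 25,
                        initial_biomass = 0.25,
                        tracked_species = c("glucose", "ammonia", "phb",
                                            "acetate", "lactate", "ethanol",
                                            "formate", "succinate"),
                        regime = c("aerobic", "anaerobic"),
                        glucose_threshold = 1e-3, t_max = 500,
                        rtol = 1e-7, atol = 1e-9) {
  regime <- match.arg(regime)
  stopifnot(working_volume > 0, initial_glucose >= 0, initial_biomass >= 0,
            glucose_threshold > 0, t_max > 0)
  structure(list(working_volume = working_volume,
                 initial_glucose = initial_glucose,
                 initial_biomass = initial_biomass,
                 tracked_species = unique(c("glucose", tracked_species)),
                 regime = regime,
                 glucose_threshold = glucose_threshold,
                 t_max = t_max, rtol = rtol, atol = atol),
            class = "batch_setup")
}

#' Simulate a batch culture by dynamic FBA (direct approach)
#'
#' Integrates the batch mass balances \eqn{dX/dt = \mu X},
#' \eqn{dS/dt = -\nu_S X}, \eqn{dP/dt = \nu_P X} with the FBA linear program
#' embedded in the right-hand side: at every integrator evaluation the
#' glucose exchange lower bound is set to minus the kinetic uptake rate at
#' the current glucose concentration, the LP is (re-)solved (warm-started,
#' parsimonious), and the exchange fluxes of the tracked species drive the
#' concentration derivatives.  A stiff-capable adaptive integrator with root
#' finding is used; integration terminates on glucose depletion or on
#' metabolic arrest (LP infeasible, e.g. when a fixed production flux can no
#' longer be sustained), in which case all rates are set to zero and the
#' event is recorded.
#'
#' @param model a [metabolic_model()].
#' @param kinetics an [uptake_kinetics()].
#' @param setup a [batch_setup()].
#' @param objective objective reaction id; default the model's biomass
#'   reaction.
#' @param fixed_fluxes named numeric vector of fluxes to pin (lb = ub),
#'   e.g. `c(EX_phb_e = 11)` for growth-associated production scans.
#' @return object of class `simulation_result`: the trajectory (data.frame
#'   with time, biomass `X`, and one mmol/L column per tracked species) plus
#'   the derived bioprocess quadruple — `final_biomass` (residual gCDW/L),
#'   `yield` (g PHB/g glucose, initial-glucose basis), `titer` (g PHB/L),
#'   `productivity` (g PHB/L/h) — and `t_op` (h), `phb_content` (wt%),
#'   `oxygen_consumed` / `glucose_consumed` (mol), `glucose_residual`
#'   (mmol/L), `x_integral` (gCDW h/L, the time integral of biomass driving
#'   aeration/cooling costs) and the terminal `events` table.
#' @export
simulate_batch <- function(model, kinetics, setup = batch_setup(),
                           objective = NULL, fixed_fluxes = NULL) {
  phases <- list(list(objective = objective, target = NULL,
                      fixed_fluxes = fixed_fluxes))
  .dfba_run(model, kinetics, setup, phases)
}

#' Simulate a two-phase (growth then production) batch
#'
#' Phase 1 maximises growth until the cumulative glucose consumption
#' reaches `growth_fraction` of the total glucose allotment (event detection
#' on the consumption integral); the objective then switches to
#' `production_objective` — biomass formation is not forced to zero, the LP
#' simply redirects flux — until glucose depletion.  `growth_fraction = 0`
#' skips the growth phase entirely; `growth_fraction = 1` degenerates to a
#' plain growth batch.
#'
#' @inheritParams simulate_batch
#' @param growth_fraction fraction (mol basis) of total glucose allocated to
#'   the growth phase, in \[0, 1\].
#' @param production_objective reaction id maximised in the production
#'   phase (typically the PHB exchange).
#' @return a `simulation_result`, as [simulate_batch()].
#' @export
simulate_two_phase <- function(model, kinetics, setup = batch_setup(),
                               growth_fraction,
                               production_objective = "EX_phb_e") {
  stopifnot(growth_fraction >= 0, growth_fraction <= 1)
  total_mmol_l <- setup$initial_glucose / molar_masses()[["glucose"]] * 1000
  phases <- list()
  if (growth_fraction > 0) {
    phases <- c(phases, list(list(
      objective = NULL,
      target = if (growth_fraction < 1) growth_fraction * total_mmol_l
               else NULL,
      fixed_fluxes = NULL)))
  }
  if (growth_fraction < 1) {
    phases <- c(phases, list(list(objective = production_objective,
                                  target = NULL, fixed_fluxes = NULL)))
  }
  .dfba_run(model, kinetics, setup, phases)
}

# shared integrator: phases is a list of (objective, consumption target,
# fixed fluxes); each phase runs until its target, glucose depletion,
# arrest, or t_max
.dfba_run <- function(model, kinetics, setup, phases) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(kinetics, "uptake_kinetics"),
            inherits(setup, "batch_setup"))
  ex <- model$exchange_ids
  if (!"glucose" %in% names(ex)) {
    stop("model has no glucose exchange; cannot run a glucose batch")
  }
  species <- intersect(setup$tracked_species, names(ex))
  glc_ex <- ex[["glucose"]]
  o2_ex <- if ("oxygen" %in% names(ex)) ex[["oxygen"]] else NULL
  mm <- molar_masses()
  C0 <- setup$initial_glucose / mm[["glucose"]] * 1000   # mmol/L

  # state: X, one concentration per tracked species, cumulative glucose
  # consumption, cumulative O2 consumption, integral of X
  y0 <- c(X = setup$initial_biomass,
          stats::setNames(rep(0, length(species)), species),
          cum_glc = 0, cum_o2 = 0, x_int = 0)
  y0["glucose"] <- C0
  isp <- 1L + seq_along(species)
  icg <- length(species) + 2L
  ico <- icg + 1L
  ixi <- ico + 1L

  events <- data.frame(time = numeric(0), event = character(0))
  env <- new.env(parent = emptyenv())
  env$warm1 <- NULL
  env$warm2 <- NULL
  traj <- NULL
  t0 <- 0
  status <- "t_max"

  for (ph in seq_along(phases)) {
    phase <- phases[[ph]]
    static <- list()
    if (!is.null(o2_ex)) {
      static[[o2_ex]] <- if (setup$regime == "aerobic")
        c(-kinetics$vo2max, 0) else c(0, 0)
    }
    if (!is.null(phase$fixed_fluxes)) {
      for (id in names(phase$fixed_fluxes)) {
        static[[id]] <- rep(phase$fixed_fluxes[[id]], 2)
      }
    }
    prob <- .fba_problem(model, bounds = static,
                         objective = phase$objective %||%
                           model$biomass_reaction_id)
    glc_j <- match(glc_ex, prob$rxns)
    ex_j <- match(ex[species], prob$rxns)
    mu_j <- match(model$biomass_reaction_id, prob$rxns)
    o2_j <- if (is.null(o2_ex)) NA_integer_ else match(o2_ex, prob$rxns)
    zero <- rep(0, nrow(prob$S))
    env$arrested <- FALSE

    eval_fluxes <- function(C) {
      lb <- prob$lb
      u <- uptake_rate(kinetics, max(C, 0))
      lb[glc_j] <- -u
      if (prob$ub[glc_j] > 0) prob$ub[glc_j] <- 0
      sol <- lp_solve(prob$obj, prob$S, zero, lb, prob$ub,
                      warm = env$warm1)
      if (sol$status != "optimal") return(NULL)
      env$warm1 <- sol$state
      p2 <- prob
      p2$lb <- lb
      psol <- .pfba_minimize(p2, sol$value, warm = env$warm2)
      if (is.null(psol)) return(sol$x)
      env$warm2 <- psol$state
      psol$v
    }

    rhs <- function(t, y, parms) {
      if (env$arrested) return(list(rep(0, length(y))))
      X <- max(y[[1L]], 0)
      v <- eval_fluxes(y[["glucose"]])
      if (is.null(v)) {
        env$arrested <- TRUE
        return(list(rep(0, length(y))))
      }
      d <- numeric(length(y))
      d[1L] <- v[mu_j] * X
      d[isp] <- v[ex_j] * X
      d[icg] <- -v[glc_j] * X
      if (!is.na(o2_j)) d[ico] <- -v[o2_j] * X
      d[ixi] <- X
      list(d)
    }
    rootfun <- function(t, y, parms) {
      r <- c(y[["glucose"]] - setup$glucose_threshold,
             if (env$arrested) -1 else 1)
      if (!is.null(phase$target)) r <- c(r, y[["cum_glc"]] - phase$target)
      r
    }

    # initial feasibility must hold before integrating the first phase
    if (ph == 1L && is.null(eval_fluxes(y0[["glucose"]]))) {
      stop("initial state is infeasible under the kinetic bounds and fixed ",
           "fluxes; nothing to integrate")
    }
    times <- seq(t0, setup$t_max, length.out = max(
      50L, ceiling((setup$t_max - t0) / 0.25)))
    out <- deSolve::lsodar(y0, times, rhs, parms = NULL,
                           rtol = setup$rtol, atol = setup$atol,
                           rootfunc = rootfun)
    out <- as.data.frame(out)
    traj <- if (is.null(traj)) out else rbind(traj, out[-1L, ])
    tend <- out$time[nrow(out)]
    yend <- unlist(out[nrow(out), -1L])
    reason <- if (env$arrested) {
      "metabolic_arrest"
    } else if (yend[["glucose"]] <= setup$glucose_threshold * 1.01) {
      "glucose_depleted"
    } else if (!is.null(phase$target) &&
               yend[["cum_glc"]] >= phase$target * (1 - 1e-6)) {
      "phase_switch"
    } else {
      "t_max"
    }
    events <- rbind(events, data.frame(time = tend, event = reason))
    y0 <- yend
    t0 <- tend
    status <- reason
    if (reason != "phase_switch") break
  }

  # derived bioprocess quantities
  names(traj)[1:2] <- c("time", "X")
  X_end <- y0[["X"]]
  phb_mmol <- if ("phb" %in% species) y0[["phb"]] else 0
  titer <- phb_mmol * mm[["phb"]] / 1000
  t_op <- t0
  res <- list(
    trajectory = traj[, c("time", "X", species)],
    final_biomass = X_end,
    titer = titer,
    yield = phb_yield(titer, setup$initial_glucose),
    t_op = t_op,
    productivity = if (t_op > 0) titer / t_op else 0,
    phb_content = phb_content(titer, X_end),
    oxygen_consumed = y0[["cum_o2"]] * setup$working_volume,
    glucose_consumed = y0[["cum_glc"]] * setup$working_volume,
    glucose_residual = max(y0[["glucose"]], 0),
    x_integral = y0[["x_int"]],
    events = events,
    terminal = status,
    regime = setup$regime,
    vo2max = kinetics$vo2max,
    setup = setup
  )
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", x$regime, " batch, t_op = ",
      round(x$t_op, 2), " h (", x$terminal, ")\n", sep = "")
  cat(sprintf("  final biomass %.3f gCDW/L | titer %.3f g/L | yield %.3f g/g | productivity %.3f g/L/h | PHB content %.2f wt%%\n",
              x$final_biomass, x$titer, x$yield, x$productivity,
              x$phb_content))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PHB content in weight percent
#'
#' Total biomass is residual cell dry weight plus accumulated polymer; the
#' PHB content is the polymer's share of that total:
#' `100 * titer / (residual_biomass + titer)`.
#'
#' @param titer g PHB/L.
#' @param residual_biomass gCDW/L (polymer-free cell mass).
#' @return weight percent, in \[0, 100\].
#' @export
phb_content <- function(titer, residual_biomass) {
  total <- residual_biomass + titer
  ifelse(total > 0, 100 * titer / total, 0)
}

#' Product yield on the initial-glucose basis
#'
#' `titer / initial_glucose` (g product per g glucose allotted).  When a
#' batch arrests with residual substrate the consumed-basis yield differs;
#' the residual is reported separately in the simulation result.
#'
#' @param titer g/L.
#' @param initial_glucose g/L.
#' @return g product / g glucose.
#' @export
phb_yield <- function(titer, initial_glucose) {
  ifelse(initial_glucose > 0, titer / initial_glucose, 0)
}
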