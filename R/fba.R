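#' Solve the FBA linear program
#'
#' Maximises the objective flux subject to steady-state mass balance
#' \eqn{S\nu = 0} and flux bounds \eqn{\nu_{min} \le \nu \le \nu_{max}}.
#' When alternate optima exist the reported flux vector is, by default, the
#' parsimonious representative: a secondary LP minimises the sum of absolute
#' fluxes at the fixed optimal objective, making flux values reproducible
#' across solvers and pivot orders (objective values are unaffected).
#'
#' @param model a [metabolic_model()].
#' @param bounds named list of bound overrides, `reaction id -> c(lb, ub)`
#'   (use `NA` to keep one side).
#' @param objective reaction id, or a named numeric vector of objective
#'   coefficients; `NULL` uses the model's stored objective.
#' @param parsimonious apply the secondary absolute-flux minimisation.
#' @param warm opaque warm-start state from a previous `flux_solution` on
#'   the same model (its `state` attribute).
#' @return object of class `flux_solution`: list with `objective_value`,
#'   `fluxes` (named, mmol/gCDW/h; biomass in 1/h), and `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`).  Infeasibility is a
#'   status, never an error, so DFBA stepping can handle arrest gracefully.
#' @export
solve_fba <- function(model, bounds = NULL, objective = NULL,
                      parsimonious = TRUE, warm = NULL) {
  prob <- .fba_problem(model, bounds, objective)
  sol <- lp_solve(prob$obj, prob$S, rep(0, nrow(prob$S)), prob$lb, prob$ub,
                  maximize = TRUE, warm = warm$primary)
  if (sol$status != "optimal") {
    return(structure(list(objective_value = NA_real_,
                          fluxes = stats::setNames(
                            rep(NA_real_, length(prob$obj)), prob$rxns),
                          status = sol$status),
                     state = NULL, class = "flux_solution"))
  }
  fluxes <- stats::setNames(sol$x, prob$rxns)
  state <- list(primary = sol$state)
  if (parsimonious) {
    psol <- .pfba_minimize(prob, sol$value, warm = warm$secondary)
    if (!is.null(psol)) {
      fluxes <- stats::setNames(psol$v, prob$rxns)
      state$secondary <- psol$state
    }
  }
  structure(list(objective_value = sol$value, fluxes = fluxes,
                 status = "optimal"),
            state = state, class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective value: ", format(x$objective_value), "\n", sep = "")
    nz <- x$fluxes[abs(x$fluxes) > 1e-9]
    cat("  non-zero fluxes: ", length(nz), " of ", length(x$fluxes),
        "\n", sep = "")
  }
  invisible(x)
}

# assemble S, bounds and objective with overrides applied
.fba_problem <- function(model, bounds = NULL, objective = NULL) {
  S <- stoichiometric_matrix(model)
  bd <- model_bounds(model)
  rxns <- colnames(S)
  if (!is.null(bounds)) {
    bad <- setdiff(names(bounds), rxns)
    if (length(bad)) {
      stop("bound overrides reference unknown reaction(s): ",
           paste(bad, collapse = ", "))
    }
    for (id in names(bounds)) {
      b <- bounds[[id]]
      if (length(b) != 2L) stop("override for '", id, "' must be c(lb, ub)")
      if (!is.na(b[1])) bd$lb[id] <- b[1]
      if (!is.na(b[2])) bd$ub[id] <- b[2]
    }
  }
  obj <- bd$obj
  if (!is.null(objective)) {
    if (is.character(objective)) {
      if (!objective %in% rxns) {
        stop("objective reaction '", objective, "' not in model")
      }
      obj <- stats::setNames(rep(0, length(rxns)), rxns)
      obj[objective] <- 1
    } else {
      bad <- setdiff(names(objective), rxns)
      if (length(bad)) {
        stop("objective references unknown reaction(s): ",
             paste(bad, collapse = ", "))
      }
      obj <- stats::setNames(rep(0, length(rxns)), rxns)
      obj[names(objective)] <- objective
    }
  }
  list(S = S, lb = bd$lb, ub = bd$ub, obj = obj, rxns = rxns)
}

# secondary LP: min sum|v| subject to S v = 0, bounds, and objective pinned
# at its optimum.  Split v = p - q with p, q >= 0; an extra surplus variable
# keeps the objective row as `obj' v >= value` (equivalent to equality at
# the optimum of a maximisation).
.pfba_minimize <- function(prob, value, warm = NULL) {
  n <- length(prob$rxns)
  S2 <- cbind(prob$S, -prob$S)
  objrow <- c(prob$obj, -prob$obj)
  A <- rbind(cbind(S2, 0), c(objrow, -1))
  b <- c(rep(0, nrow(prob$S)), value)
  lb <- c(pmax(prob$lb, 0), pmax(-prob$ub, 0), 0)
  ub <- c(pmax(prob$ub, 0), pmax(-prob$lb, 0), Inf)
  cost <- c(rep(1, 2 * n), 0)
  sol <- lp_solve(cost, A, b, lb, ub, maximize = FALSE, warm = warm)
  if (sol$status != "optimal") return(NULL)
  list(v = sol$x[seq_len(n)] - sol$x[n + seq_len(n)], state = sol$state)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux compatible with the
#' (fraction of the) optimal objective value: the objective is constrained
#' to at least `fraction_of_optimum` times its optimum (an equality at the
#' default fraction of 1, since no feasible flux vector can exceed the
#' optimum) and each reaction flux is minimised and maximised in turn.
#'
#' @inheritParams solve_fba
#' @param fraction_of_optimum dimensionless, in (0, 1]; default 1.
#' @param reactions reaction ids to analyse (default: all).
#' @return object of class `fva_result`: data.frame with columns `reaction`,
#'   `min`, `max`; the FBA objective value is stored in
#'   `attr(, "objective_value")`.
#' @export
run_fva <- function(model, bounds = NULL, objective = NULL,
                    fraction_of_optimum = 1, reactions = NULL) {
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1)
  prob <- .fba_problem(model, bounds, objective)
  base <- lp_solve(prob$obj, prob$S, rep(0, nrow(prob$S)), prob$lb, prob$ub)
  if (base$status != "optimal") {
    stop("FVA requires an optimal base solution; FBA status was '",
         base$status, "'")
  }
  pinned <- fraction_of_optimum * base$value
  # objective row with surplus: obj' v - s = pinned, s >= 0
  A <- rbind(cbind(prob$S, 0), c(prob$obj, -1))
  b <- c(rep(0, nrow(prob$S)), pinned)
  lb <- c(prob$lb, 0)
  ub <- c(prob$ub, Inf)
  ids <- if (is.null(reactions)) prob$rxns else {
    bad <- setdiff(reactions, prob$rxns)
    if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
    reactions
  }
  nv <- length(prob$rxns) + 1L
  res <- matrix(NA_real_, length(ids), 2,
                dimnames = list(ids, c("min", "max")))
  warmst <- NULL
  for (id in ids) {
    cost <- stats::setNames(rep(0, nv), NULL)
    cost[match(id, prob$rxns)] <- 1
    for (dir in c("min", "max")) {
      s <- lp_solve(cost, A, b, lb, ub, maximize = (dir == "max"),
                    warm = warmst)
      if (s$status != "optimal") {
        stop("FVA subproblem ", dir, "(", id, ") returned '", s$status,
             "' with objective pinned at ", format(pinned))
      }
      res[id, dir] <- s$value
      warmst <- s$state
    }
  }
  out <- data.frame(reaction = ids, min = res[, "min"], max = res[, "max"],
                    row.names = NULL)
  # clip solver noise so min <= max holds exactly
  swap <- out$min > out$max
  if (any(swap)) {
    mid <- (out$min[swap] + out$max[swap]) / 2
    out$min[swap] <- mid
    out$max[swap] <- mid
  }
  structure(out, objective_value = base$value, class = c("fva_result",
                                                         "data.frame"))
}
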