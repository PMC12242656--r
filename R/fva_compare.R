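#' Scenario constraints from experimental yields
#'
#' @param glucose_uptake glucose uptake magnitude, mmol/gCDW/h (applied as a
#'   pinned negative exchange flux).
#' @param yields named numeric vector of product yields in g product per g
#'   glucose (names: tracked-species names such as `"phb"`, `"acetate"`),
#'   converted to pinned exchange fluxes via molar masses.
#' @param fixed_fluxes named numeric vector of additional reaction fluxes to
#'   pin.
#' @param objective objective reaction id (`NULL`: model default).
#' @return object of class `scenario_constraint`.
#' @export
scenario_constraint <- function(glucose_uptake, yields = NULL,
                                fixed_fluxes = NULL, objective = NULL) {
  stopifnot(glucose_uptake > 0)
  structure(list(glucose_uptake = glucose_uptake, yields = yields,
                 fixed_fluxes = fixed_fluxes, objective = objective),
            class = "scenario_constraint")
}

#' Constrain a model with experimental yields
#'
#' A yield of y g product per g glucose at an uptake of u mmol glucose per
#' gCDW per h pins the product exchange flux to
#' \eqn{y \cdot u \cdot M_{glc}/M_{product}} mmol/gCDW/h.  The glucose
#' exchange is pinned at -u.  An infeasibility check runs immediately so
#' that impossible constraint sets (e.g. yields implying more than 100% of
#' the carbon) fail loudly, naming the pinned constraints.
#'
#' @param model a [metabolic_model()].
#' @param constraint a [scenario_constraint()].
#' @param masses molar masses, g/mol, named by tracked-species name; see
#'   [molar_masses()].
#' @return the constrained model.
#' @export
constrain_with_yields <- function(model, constraint,
                                  masses = molar_masses()) {
  stopifnot(inherits(constraint, "scenario_constraint"))
  ex <- model$exchange_ids
  u <- constraint$glucose_uptake
  model <- set_bounds(model, ex[["glucose"]], lb = -u, ub = -u)
  pinned <- stats::setNames(-u, ex[["glucose"]])
  for (sp in names(constraint$yields)) {
    if (!sp %in% names(ex)) {
      stop("species '", sp, "' has no exchange reaction in the model")
    }
    if (!sp %in% names(masses)) {
      stop("no molar mass configured for species '", sp, "'")
    }
    flux <- constraint$yields[[sp]] * u * masses[["glucose"]] / masses[[sp]]
    model <- set_bounds(model, ex[[sp]], lb = flux, ub = flux)
    pinned[ex[[sp]]] <- flux
  }
  for (id in names(constraint$fixed_fluxes)) {
    fx <- constraint$fixed_fluxes[[id]]
    model <- set_bounds(model, id, lb = fx, ub = fx)
    pinned[id] <- fx
  }
  if (!is.null(constraint$objective)) {
    model <- set_objective(model, constraint$objective)
  }
  chk <- solve_fba(model, parsimonious = FALSE)
  if (chk$status != "optimal") {
    stop("constraint set is ", chk$status, "; pinned fluxes were: ",
         paste(names(pinned), format(pinned, digits = 4), sep = " = ",
               collapse = ", "))
  }
  model
}

#' Compare two FVA envelopes and classify intervention candidates
#'
#' Classifies every reaction shared by a reference scenario (typically
#' experimentally constrained) and a target scenario (typically the
#' best-performing simulation) by how its feasible flux range changes:
#' `knockout_candidate` (active in the reference, pinned to \[0, 0\] in the
#' target — deleting the gene moves the cell toward the target),
#' `reversal` (the range flips sign entirely), `forced_minimum` (the target
#' requires strictly more minimum flux — overexpression candidates), or
#' `unchanged`.  Reactions present in only one input are reported in the
#' `unshared` attribute, not classified.
#'
#' @param reference,target [run_fva()] results.
#' @param tolerance classification tolerance, mmol/gCDW/h (LP noise floor).
#' @return data.frame with columns `reaction`, `ref_min`, `ref_max`,
#'   `target_min`, `target_max`, `classification`, `range_change`, sorted by
#'   classification then absolute range change.
#' @export
diff_fva <- function(reference, target, tolerance = 1e-6) {
  shared <- intersect(reference$reaction, target$reaction)
  ri <- match(shared, reference$reaction)
  ti <- match(shared, target$reaction)
  rmin <- reference$min[ri]; rmax <- reference$max[ri]
  tmin <- target$min[ti]; tmax <- target$max[ti]
  zero <- function(lo, hi) abs(lo) <= tolerance & abs(hi) <= tolerance
  cls <- rep("unchanged", length(shared))
  cls[tmin > rmin + tolerance] <- "forced_minimum"
  pos <- function(lo) lo > tolerance
  neg <- function(hi) hi < -tolerance
  cls[(pos(rmin) & neg(tmax)) | (neg(rmax) & pos(tmin))] <- "reversal"
  cls[zero(tmin, tmax) & !zero(rmin, rmax)] <- "knockout_candidate"
  change <- abs(tmin - rmin) + abs(tmax - rmax)
  out <- data.frame(reaction = shared, ref_min = rmin, ref_max = rmax,
                    target_min = tmin, target_max = tmax,
                    classification = cls, range_change = change)
  ord <- order(factor(out$classification,
                      levels = c("knockout_candidate", "reversal",
                                 "forced_minimum", "unchanged")),
               -out$range_change)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "unshared") <- list(
    reference_only = setdiff(reference$reaction, shared),
    target_only = setdiff(target$reaction, shared))
  out
}
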