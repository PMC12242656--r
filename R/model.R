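#' Create a metabolite
#'
#' Metabolites are the rows of the stoichiometric matrix.  The `formula`
#' field is an elemental formula string (possibly empty) used for mass
#' balance checks of added reactions; `compartment` is a short tag such as
#' `"c"` (cytosol) or `"e"` (extracellular).
#'
#' @param id short unique identifier (BiGG style, e.g. `"accoa_c"`).
#' @param name free-text name.
#' @param formula elemental formula string, may be `""`.
#' @param compartment non-empty compartment tag.
#' @return object of class `dyseep_metabolite`.
#' @export
metabolite <- function(id, name = id, formula = "", compartment) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (missing(compartment) || !nzchar(compartment)) {
    stop("metabolite '", id, "': compartment must be non-empty")
  }
  structure(list(id = id, name = name, formula = formula,
                 compartment = compartment),
            class = "dyseep_metabolite")
}

#' Create a reaction
#'
#' A reaction is a column of the stoichiometric matrix together with flux
#' bounds (mmol/gCDW/h) and an objective weight.  Negative stoichiometric
#' coefficients denote consumption.
#'
#' @param id short unique identifier.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient; must be non-empty.
#' @param lower_bound,upper_bound flux bounds with `lower_bound <=
#'   upper_bound`.
#' @param objective_coefficient dimensionless objective weight.
#' @param name free-text name.
#' @return object of class `dyseep_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound, upper_bound,
                     objective_coefficient = 0, name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector")
  }
  if (!is.numeric(lower_bound) || !is.numeric(upper_bound) ||
      length(lower_bound) != 1L || length(upper_bound) != 1L ||
      is.na(lower_bound) || is.na(upper_bound)) {
    stop("reaction '", id, "': bounds must be single non-missing numbers")
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound exceeds upper_bound")
  }
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 objective_coefficient = as.numeric(objective_coefficient)),
            class = "dyseep_reaction")
}

#' Assemble a constraint-based metabolic model
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param id model identifier.
#' @param biomass_reaction_id id of the biomass (growth) reaction; defaults
#'   to the single reaction with a non-zero objective coefficient when one
#'   exists.
#' @return object of class `metabolic_model` with elements `metabolites` and
#'   `reactions` (both named lists), `biomass_reaction_id`, and
#'   `exchange_ids`, a named character vector mapping tracked-species names
#'   (glucose, oxygen, phb, acetate, ...) to exchange-reaction ids.
#' @export
metabolic_model <- function(metabolites, reactions, id = "model",
                            biomass_reaction_id = NULL) {
  met_ids <- vapply(metabolites, `[[`, "", "id")
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  for (r in reactions) {
    unknown <- setdiff(names(r$stoichiometry), met_ids)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  if (is.null(biomass_reaction_id)) {
    obj <- rxn_ids[vapply(reactions, `[[`, 0, "objective_coefficient") != 0]
    biomass_reaction_id <- if (length(obj) == 1L) obj else NA_character_
  } else if (!biomass_reaction_id %in% rxn_ids) {
    stop("biomass_reaction_id '", biomass_reaction_id,
         "' does not resolve to a reaction")
  }
  m <- structure(list(id = id, metabolites = metabolites,
                      reactions = reactions,
                      biomass_reaction_id = biomass_reaction_id,
                      exchange_ids = character(0)),
                 class = "metabolic_model")
  m$exchange_ids <- .map_exchanges(m)
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", length(x$metabolites),
      "   reactions: ", length(x$reactions), "\n", sep = "")
  cat("  biomass reaction: ", x$biomass_reaction_id, "\n", sep = "")
  if (length(x$exchange_ids)) {
    cat("  tracked exchanges: ",
        paste(names(x$exchange_ids), x$exchange_ids, sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Exchange reactions of a model
#'
#' An exchange reaction is detected structurally: a reaction with exactly one
#' participating metabolite (the universal constraint-based convention, with
#' negative flux meaning uptake).
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  ids <- vapply(model$reactions,
                function(r) length(r$stoichiometry) == 1L, NA)
  names(model$reactions)[ids]
}

# tracked-species name -> known extracellular metabolite ids (BiGG dialect
# first, a few common alternatives after)
.species_aliases <- list(
  glucose  = c("glc__D_e", "glc_D_e", "glc_e"),
  oxygen   = c("o2_e"),
  ammonia  = c("nh4_e", "nh3_e"),
  phb      = c("phb_e"),
  acetate  = c("ac_e"),
  lactate  = c("lac__D_e", "lac__L_e", "lac_D_e", "lac_L_e"),
  ethanol  = c("etoh_e"),
  formate  = c("for_e"),
  succinate = c("succ_e"),
  co2      = c("co2_e"),
  proton   = c("h_e")
)

# map tracked-species names to exchange reaction ids present in the model
.map_exchanges <- function(model) {
  ex <- exchange_reactions(model)
  ex_met <- vapply(model$reactions[ex],
                   function(r) names(r$stoichiometry), "")
  out <- character(0)
  for (sp in names(.species_aliases)) {
    hit <- ex[ex_met %in% .species_aliases[[sp]]]
    if (length(hit)) out[sp] <- hit[1L]
  }
  out
}

#' Stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, one row per metabolite, one column per
#'   reaction, with `dimnames`.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- names(model$metabolites)
  rxns <- names(model$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' Flux bounds and objective of a model
#'
#' @param model a `metabolic_model`.
#' @return list with numeric vectors `lb`, `ub`, `obj`, named by reaction id.
#' @export
model_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
       ub = vapply(model$reactions, `[[`, 0, "upper_bound"),
       obj = vapply(model$reactions, `[[`, 0, "objective_coefficient"))
}

#' Modify reaction bounds
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lb,ub new bounds; `NULL` keeps the current value.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  if (!id %in% names(model$reactions)) {
    stop("unknown reaction '", id, "'")
  }
  r <- model$reactions[[id]]
  if (!is.null(lb)) r$lower_bound <- as.numeric(lb)
  if (!is.null(ub)) r$upper_bound <- as.numeric(ub)
  if (r$lower_bound > r$upper_bound) {
    stop("reaction '", id, "': lower_bound exceeds upper_bound")
  }
  model$reactions[[id]] <- r
  model
}

#' Set the model objective
#'
#' Clears all objective coefficients and sets the given reaction's weight.
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param coefficient objective weight.
#' @return the modified model.
#' @export
set_objective <- function(model, id, coefficient = 1) {
  if (!id %in% names(model$reactions)) {
    stop("unknown reaction '", id, "'")
  }
  for (j in seq_along(model$reactions)) {
    model$reactions[[j]]$objective_coefficient <- 0
  }
  model$reactions[[id]]$objective_coefficient <- coefficient
  model
}

# add metabolites/reactions (internal plumbing for augmentations)
.add_metabolites <- function(model, mets) {
  for (mt in mets) {
    if (mt$id %in% names(model$metabolites)) next
    model$metabolites[[mt$id]] <- mt
  }
  model
}

.add_reactions <- function(model, rxns) {
  for (r in rxns) {
    if (r$id %in% names(model$reactions)) {
      stop("reaction '", r$id, "' already present in model '", model$id, "'")
    }
    unknown <- setdiff(names(r$stoichiometry), names(model$metabolites))
    if (length(unknown)) {
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    model$reactions[[r$id]] <- r
  }
  model$exchange_ids <- .map_exchanges(model)
  model
}

#' Parse an elemental formula
#'
#' @param formula string such as `"C4H6O2"`.
#' @return named numeric vector of element counts (empty for `""`).
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  els <- sub("[0-9]*$", "", parts)
  cnt <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
  tapply(cnt, els, sum)
}

#' Elemental imbalance of a reaction
#'
#' Sums element counts over the stoichiometry using the model's metabolite
#' formulas.  Exchange-style reactions (single metabolite) are inherently
#' unbalanced and should be exempted by the caller.
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @return named numeric vector of net element production (all zero for a
#'   balanced reaction); `NULL` when any participating formula is missing.
#' @export
reaction_imbalance <- function(model, id) {
  r <- model$reactions[[id]]
  if (is.null(r)) stop("unknown reaction '", id, "'")
  tot <- setNames(numeric(0), character(0))
  for (met in names(r$stoichiometry)) {
    f <- model$metabolites[[met]]$formula
    if (is.na(f) || !nzchar(f)) return(NULL)
    el <- parse_formula(f)
    for (e in names(el)) {
      tot[e] <- (if (e %in% names(tot)) tot[e] else 0) +
        r$stoichiometry[[met]] * el[[e]]
    }
  }
  tot
}
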