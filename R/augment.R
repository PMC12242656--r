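#' Default species-id map for model augmentation
#'
#' Augmentations resolve precursor/cofactor species through a configurable
#' id map because different genome-scale reconstructions use different id
#' schemes.  The defaults are the BiGG dialect ids.
#'
#' @return named character vector mapping roles (`accoa`, `coa`, `nadph`,
#'   `nadp`, `nadh`, `nad`, `h`) to metabolite ids.
#' @export
default_species_map <- function() {
  c(accoa = "accoa_c", coa = "coa_c",
    nadph = "nadph_c", nadp = "nadp_c",
    nadh = "nadh_c", nad = "nad_c",
    h = "h_c")
}

#' Add the PHB synthesis pathway to a model
#'
#' Inserts the three-step poly-3-hydroxybutyrate route of natural producers
#' — beta-ketothiolase (PhaA), acetoacetyl-CoA reductase (PhaB) and PHB
#' synthase (PhaC) — plus an artificial export/exchange pair.  The reductase
#' cofactor is selectable: the natural *C. necator* enzyme is
#' NADPH-dependent, while pathways with NADH affinity are known from other
#' organisms.  Because FBA assumes intracellular steady state, the
#' intracellularly accumulated polymer is modelled through an artificial
#' export reaction (analogous to the artificial biomass drain); the exported
#' monomer (C4H6O2, 86 g/mol) is later re-interpreted as stored PHB when
#' computing titers and PHB content.
#'
#' All three enzymatic reactions are elementally balanced given the monomer
#' formula; the export/exchange pair is exempt, following the standard
#' exchange convention.  Pre-existing reactions are never modified.
#'
#' @param model a [metabolic_model()] containing cytosolic acetyl-CoA, CoA,
#'   the chosen cofactor pair, and protons.
#' @param cofactor `"NADPH"` (PhaB of *C. necator*) or `"NADH"`.
#' @param species_map id map, see [default_species_map()].
#' @return the augmented model.
#' @export
add_phb_pathway <- function(model, cofactor = c("NADPH", "NADH"),
                            species_map = default_species_map()) {
  cofactor <- match.arg(cofactor)
  map <- default_species_map()
  map[names(species_map)] <- species_map
  need <- c("accoa", "coa", "h",
            if (cofactor == "NADPH") c("nadph", "nadp") else c("nadh", "nad"))
  absent <- map[need][!map[need] %in% names(model$metabolites)]
  if (length(absent)) {
    stop("cannot add PHB pathway: missing precursor species ",
         paste(absent, collapse = ", "))
  }
  red <- if (cofactor == "NADPH") {
    stats::setNames(c(-1, -1, -1, 1, 1),
                    c("aacoa_c", map[["nadph"]], map[["h"]],
                      "hbcoa__R_c", map[["nadp"]]))
  } else {
    stats::setNames(c(-1, -1, -1, 1, 1),
                    c("aacoa_c", map[["nadh"]], map[["h"]],
                      "hbcoa__R_c", map[["nad"]]))
  }
  mets <- list(
    metabolite("aacoa_c", "acetoacetyl-CoA", "C25H36N7O18P3S", "c"),
    metabolite("hbcoa__R_c", "(R)-3-hydroxybutyryl-CoA",
               "C25H38N7O18P3S", "c"),
    metabolite("phb_c", "PHB monomer", "C4H6O2", "c"),
    metabolite("phb_e", "PHB monomer (external)", "C4H6O2", "e")
  )
  rxns <- list(
    reaction("PHAA",
             stats::setNames(c(-2, 1, 1),
                             c(map[["accoa"]], "aacoa_c", map[["coa"]])),
             0, 1000, name = "beta-ketothiolase (PhaA)"),
    reaction("PHAB", red, 0, 1000,
             name = paste0("acetoacetyl-CoA reductase (PhaB, ", cofactor,
                           ")")),
    reaction("PHAC",
             stats::setNames(c(-1, 1, 1),
                             c("hbcoa__R_c", "phb_c", map[["coa"]])),
             0, 1000, name = "PHB synthase (PhaC)"),
    reaction("PHBt", c(phb_c = -1, phb_e = 1), 0, 1000,
             name = "artificial PHB export"),
    reaction("EX_phb_e", c(phb_e = -1), 0, 1000, name = "PHB exchange")
  )
  dup <- intersect(vapply(rxns, `[[`, "", "id"), names(model$reactions))
  if (length(dup)) {
    stop("PHB pathway already present (duplicate reaction ids: ",
         paste(dup, collapse = ", "), ")")
  }
  model <- .add_metabolites(model, mets)
  .add_reactions(model, rxns)
}

#' Add a glucose exchange/transport chain to a model
#'
#' Used for reconstructions of organisms that cannot naturally grow on
#' glucose (e.g. *C. necator* H16) but can be engineered to import it:
#' inserts an external glucose species, its exchange reaction (closed for
#' uptake by default at -10 mmol/gCDW/h), and a transport reaction into the
#' cytosol.
#'
#' @param model a [metabolic_model()] lacking a glucose exchange; the
#'   cytosolic glucose species is created when absent.
#' @param glucose_e,glucose_c ids of the external/cytosolic glucose species.
#' @param uptake_bound lower bound placed on the new exchange (negative =
#'   uptake allowed).
#' @return the augmented model.
#' @export
add_glucose_transport <- function(model, glucose_e = "glc__D_e",
                                  glucose_c = "glc__D_c",
                                  uptake_bound = -10) {
  if ("glucose" %in% names(model$exchange_ids)) {
    stop("model '", model$id, "' already imports glucose (exchange ",
         model$exchange_ids[["glucose"]], ")")
  }
  mets <- list(metabolite(glucose_e, "D-glucose (external)", "C6H12O6", "e"))
  if (!glucose_c %in% names(model$metabolites)) {
    mets <- c(mets, list(metabolite(glucose_c, "D-glucose", "C6H12O6", "c")))
  }
  rxns <- list(
    reaction("EX_glc__D_e", stats::setNames(-1, glucose_e), uptake_bound, 0,
             name = "glucose exchange"),
    reaction("GLCt_added", stats::setNames(c(-1, 1), c(glucose_e, glucose_c)),
             0, 1000, name = "glucose transport (added)")
  )
  model <- .add_metabolites(model, mets)
  .add_reactions(model, rxns)
}
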