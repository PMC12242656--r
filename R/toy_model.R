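#' Build the self-contained toy model
#'
#' A ~19-reaction aerobic heterotroph used throughout the test-suite and the
#' examples: glucose uptake, lumped glycolysis + pyruvate dehydrogenase to
#' acetyl-CoA (with NADH/ATP/CO2 bookkeeping), a lactate overflow branch,
#' transhydrogenase (NADPH supply), lumped respiration (P/O = 2), acetate
#' secretion, an ATP maintenance sink, and a biomass reaction drawing
#' acetyl-CoA, ATP and NADPH.  All cofactor species carry real elemental
#' formulas so that pathway augmentations can be mass-balance-checked, and
#' the network is small enough that every FBA optimum used in the tests has
#' a closed-form value derived by hand from the balance equations.
#'
#' With glucose uptake bound \eqn{g} and unconstrained oxygen the maximum
#' growth rate is \eqn{g/13}; with oxygen uptake capped at 15 mmol/gCDW/h it
#' is \eqn{(2g+75)/151} for \eqn{g \ge 7.8}.  The biomass composition (2
#' acetyl-CoA, 150 ATP, 2 NADPH per gram) yields about 0.43 g biomass per g
#' glucose, a realistic aerobic heterotroph figure.
#'
#' @return a [metabolic_model()] with biomass objective and glucose/oxygen
#'   exchange bounds of -10 and -15 mmol/gCDW/h.
#' @export
make_toy_model <- function() {
  M <- list(
    metabolite("glc__D_e", "D-glucose (external)", "C6H12O6", "e"),
    metabolite("glc__D_c", "D-glucose", "C6H12O6", "c"),
    metabolite("accoa_c", "acetyl-CoA", "C23H34N7O17P3S", "c"),
    metabolite("coa_c", "coenzyme A", "C21H32N7O16P3S", "c"),
    metabolite("atp_c", "ATP", "C10H12N5O13P3", "c"),
    metabolite("adp_c", "ADP", "C10H12N5O10P2", "c"),
    metabolite("nad_c", "NAD+", "C21H26N7O14P2", "c"),
    metabolite("nadh_c", "NADH", "C21H27N7O14P2", "c"),
    metabolite("nadp_c", "NADP+", "C21H25N7O17P3", "c"),
    metabolite("nadph_c", "NADPH", "C21H26N7O17P3", "c"),
    metabolite("h_c", "proton", "H", "c"),
    metabolite("h_e", "proton (external)", "H", "e"),
    metabolite("o2_e", "oxygen (external)", "O2", "e"),
    metabolite("o2_c", "oxygen", "O2", "c"),
    metabolite("ac_c", "acetate", "C2H3O2", "c"),
    metabolite("ac_e", "acetate (external)", "C2H3O2", "e"),
    metabolite("co2_c", "carbon dioxide", "CO2", "c"),
    metabolite("co2_e", "carbon dioxide (external)", "CO2", "e"),
    metabolite("lac__D_c", "D-lactate", "C3H5O3", "c"),
    metabolite("lac__D_e", "D-lactate (external)", "C3H5O3", "e")
  )
  R <- list(
    reaction("EX_glc__D_e", c(glc__D_e = -1), -10, 0,
             name = "glucose exchange"),
    reaction("GLCt", c(glc__D_e = -1, glc__D_c = 1), 0, 1000,
             name = "glucose transport"),
    reaction("GLYCL",
             c(glc__D_c = -1, coa_c = -2, nad_c = -4, adp_c = -2,
               accoa_c = 2, co2_c = 2, nadh_c = 4, atp_c = 2, h_c = 4),
             0, 1000, name = "glycolysis + PDH (lumped)"),
    reaction("LDHFERM", c(glc__D_c = -1, adp_c = -2, lac__D_c = 2,
                          atp_c = 2), 0, 1000,
             name = "homolactic fermentation (lumped)"),
    reaction("THD", c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
             0, 1000, name = "transhydrogenase"),
    reaction("RESP", c(nadh_c = -1, o2_c = -0.5, adp_c = -2, nad_c = 1,
                       atp_c = 2), 0, 1000,
             name = "respiration, P/O = 2 (lumped)"),
    reaction("O2t", c(o2_e = -1, o2_c = 1), 0, 1000, name = "O2 diffusion"),
    reaction("EX_o2_e", c(o2_e = -1), -15, 0, name = "oxygen exchange"),
    reaction("ACKr", c(accoa_c = -1, adp_c = -1, ac_c = 1, coa_c = 1,
                       atp_c = 1), 0, 1000,
             name = "acetate overflow (Pta-AckA, lumped)"),
    reaction("ACt", c(ac_c = -1, ac_e = 1), 0, 1000,
             name = "acetate transport"),
    reaction("EX_ac_e", c(ac_e = -1), 0, 1000, name = "acetate exchange"),
    reaction("CO2t", c(co2_c = -1, co2_e = 1), 0, 1000,
             name = "CO2 diffusion"),
    reaction("EX_co2_e", c(co2_e = -1), 0, 1000, name = "CO2 exchange"),
    reaction("LACt", c(lac__D_c = -1, lac__D_e = 1), 0, 1000,
             name = "lactate transport"),
    reaction("EX_lac__D_e", c(lac__D_e = -1), 0, 1000,
             name = "lactate exchange"),
    reaction("Ht", c(h_c = -1, h_e = 1), -1000, 1000,
             name = "proton diffusion"),
    reaction("EX_h_e", c(h_e = -1), -1000, 1000, name = "proton exchange"),
    reaction("ATPM", c(atp_c = -1, adp_c = 1), 0, 1000,
             name = "ATP maintenance / hydrolysis sink"),
    reaction("BIOMASS_toy",
             c(accoa_c = -2, atp_c = -150, nadph_c = -2,
               coa_c = 2, adp_c = 150, nadp_c = 2),
             0, 1000, objective_coefficient = 1, name = "biomass")
  )
  metabolic_model(M, R, id = "toy_aerobe",
                  biomass_reaction_id = "BIOMASS_toy")
}
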