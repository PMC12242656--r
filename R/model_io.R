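#' Read a constraint-based model
#'
#' Supports the BiGG-style JSON dialect (the canonical on-disk format of this
#' package) and SBML level 3 with the FBC extension for bounds and
#' objectives.  Flux bounds are mandatory: a reaction without explicit bounds
#' is a parse error, never silently defaulted.
#'
#' @param path file path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by file extension).
#' @return a [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format, json = .load_bigg_json(path), sbml = .load_sbml(path))
}

#' Write a constraint-based model
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @param format `"json"` (BiGG dialect), `"sbml"` (level 3 + FBC), or
#'   `"auto"` by extension.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format, json = .save_bigg_json(model, path),
         sbml = .save_sbml(model, path))
  invisible(path)
}

# ---- BiGG JSON ------------------------------------------------------------

.load_bigg_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("not a BiGG-style model JSON (missing 'metabolites'/'reactions'): ",
         path)
  }
  mets <- lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite without id in ", path)
    comp <- m$compartment
    if (is.null(comp) || !nzchar(comp)) {
      # BiGG ids carry the compartment as a suffix
      comp <- sub("^.*_([a-z][a-z0-9]?)$", "\\1", m$id)
      if (identical(comp, m$id)) comp <- "c"
    }
    metabolite(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               formula = if (is.null(m$formula)) "" else m$formula,
               compartment = comp)
  })
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in ", path)
    if (is.null(r$lower_bound) || is.null(r$upper_bound)) {
      stop("reaction '", r$id, "' has no flux bounds in ", path)
    }
    st <- unlist(r$metabolites)
    if (is.null(st) || !length(st)) {
      stop("reaction '", r$id, "' has empty stoichiometry in ", path)
    }
    reaction(id = r$id, name = if (is.null(r$name)) r$id else r$name,
             stoichiometry = st,
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             objective_coefficient =
               if (is.null(r$objective_coefficient)) 0
               else r$objective_coefficient)
  })
  metabolic_model(mets, rxns,
                  id = if (is.null(doc$id)) basename(path) else doc$id)
}

.save_bigg_json <- function(model, path) {
  doc <- list(
    metabolites = unname(lapply(model$metabolites, function(m) {
      list(id = m$id, name = m$name, compartment = m$compartment,
           formula = m$formula)
    })),
    reactions = unname(lapply(model$reactions, function(r) {
      list(id = r$id, name = r$name,
           metabolites = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           objective_coefficient = r$objective_coefficient,
           gene_reaction_rule = "")
    })),
    genes = list(),
    id = model$id,
    version = "1"
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

# ---- SBML level 3 + FBC ---------------------------------------------------

.FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.load_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path,
                                           ": ", conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[[1]], fbc = .FBC)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)
  # bound parameters
  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))
  species <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- lapply(species, function(sp) {
    id <- xml2::xml_attr(sp, "id")
    comp <- xml2::xml_attr(sp, "compartment")
    if (is.na(comp) || !nzchar(comp)) {
      stop("species '", id, "' lacks a compartment in ", path)
    }
    frm <- xml2::xml_attr(sp, "chemicalFormula",
                          ns = character(0), default = NA_character_)
    if (is.na(frm)) {
      frm <- xml2::xml_attr(sp, "fbc:chemicalFormula", ns, NA_character_)
    }
    metabolite(id = id,
               name = {
                 nm <- xml2::xml_attr(sp, "name")
                 if (is.na(nm)) id else nm
               },
               formula = if (is.na(frm)) "" else frm,
               compartment = comp)
  })
  rnodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rnodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    lbid <- xml2::xml_attr(rn, "fbc:lowerFluxBound", ns, NA_character_)
    ubid <- xml2::xml_attr(rn, "fbc:upperFluxBound", ns, NA_character_)
    if (is.na(lbid) || is.na(ubid) ||
        !lbid %in% names(pval) || !ubid %in% names(pval)) {
      stop("reaction '", id, "' lacks FBC flux-bound annotations in ", path)
    }
    st <- c()
    for (sr in xml2::xml_find_all(
           rn, "./s:listOfReactants/s:speciesReference", ns)) {
      st[xml2::xml_attr(sr, "species")] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(
           rn, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      st[sp] <- (if (sp %in% names(st)) st[sp] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    reaction(id = id,
             name = {
               nm <- xml2::xml_attr(rn, "name")
               if (is.na(nm)) id else nm
             },
             stoichiometry = st,
             lower_bound = pval[[lbid]], upper_bound = pval[[ubid]])
  })
  # objective
  obj <- xml2::xml_find_all(
    mdl, ".//fbc:listOfObjectives/fbc:objective[1]/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  model <- metabolic_model(
    mets, rxns,
    id = {
      nm <- xml2::xml_attr(mdl, "id")
      if (is.na(nm)) basename(path) else nm
    })
  for (fo in obj) {
    rid <- xml2::xml_attr(fo, "fbc:reaction", ns)
    coef <- as.numeric(xml2::xml_attr(fo, "fbc:coefficient", ns, "1"))
    if (rid %in% names(model$reactions)) {
      model$reactions[[rid]]$objective_coefficient <- coef
    }
  }
  bm <- names(model$reactions)[
    vapply(model$reactions, `[[`, 0, "objective_coefficient") != 0]
  if (length(bm) == 1L) model$biomass_reaction_id <- bm
  model
}

.save_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="', .FBC, '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(model$id), '" fbc:strict="true">'))
  comps <- unique(vapply(model$metabolites, `[[`, "", "compartment"))
  lines <- c(lines, "    <listOfCompartments>",
             paste0('      <compartment id="', esc(comps),
                    '" constant="true"/>'),
             "    </listOfCompartments>",
             "    <listOfSpecies>")
  for (m in model$metabolites) {
    frm <- if (nzchar(m$formula))
      paste0(' fbc:chemicalFormula="', esc(m$formula), '"') else ""
    lines <- c(lines, paste0(
      '      <species id="', esc(m$id), '" name="', esc(m$name),
      '" compartment="', esc(m$compartment),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
      ' constant="false"', frm, "/>"))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  bnd_id <- function(i, side) paste0("B_", side, "_", i)
  rids <- names(model$reactions)
  for (i in seq_along(rids)) {
    r <- model$reactions[[i]]
    lines <- c(lines,
      paste0('      <parameter id="', bnd_id(i, "lo"), '" value="',
             num(r$lower_bound), '" constant="true"/>'),
      paste0('      <parameter id="', bnd_id(i, "up"), '" value="',
             num(r$upper_bound), '" constant="true"/>'))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_along(rids)) {
    r <- model$reactions[[i]]
    lines <- c(lines, paste0(
      '      <reaction id="', esc(r$id), '" name="', esc(r$name),
      '" reversible="', if (r$lower_bound < 0) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="', bnd_id(i, "lo"),
      '" fbc:upperFluxBound="', bnd_id(i, "up"), '">'))
    st <- r$stoichiometry
    rea <- st[st < 0]
    pro <- st[st > 0]
    if (length(rea)) {
      lines <- c(lines, "        <listOfReactants>",
                 paste0('          <speciesReference species="',
                        esc(names(rea)), '" stoichiometry="', num(-rea),
                        '" constant="true"/>'),
                 "        </listOfReactants>")
    }
    if (length(pro)) {
      lines <- c(lines, "        <listOfProducts>",
                 paste0('          <speciesReference species="',
                        esc(names(pro)), '" stoichiometry="', num(pro),
                        '" constant="true"/>'),
                 "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  objs <- model$reactions[
    vapply(model$reactions, `[[`, 0, "objective_coefficient") != 0]
  if (length(objs)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      "        <fbc:listOfFluxObjectives>")
    for (r in objs) {
      lines <- c(lines, paste0(
        '          <fbc:fluxObjective fbc:reaction="', esc(r$id),
        '" fbc:coefficient="', num(r$objective_coefficient), '"/>'))
    }
    lines <- c(lines,
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
}
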