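#' Read a metabolic model from JSON or SBML
#'
#' The JSON dialect is a minimal subset of the COBRA JSON schema: a
#' `metabolites` array (objects with `id` and optional `compartment`) and a
#' `reactions` array (objects with `id`, `lower_bound`, `upper_bound`, a
#' `metabolites` map of stoichiometric coefficients, and an optional
#' `objective` flag). SBML input is Level 3 with the FBC package; the active
#' FBC objective supplies the biomass reaction and the conventional `M_`/`R_`
#' id prefixes are stripped.
#'
#' @param path File path.
#' @param format `"json"` or `"sbml"` (default guessed from the extension).
#' @param objective Optional reaction id overriding the objective declared in
#'   the file. A model with no declared objective and no override is an error.
#' @return A [tl_model()].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       objective = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format,
    json = .read_model_json(path, objective),
    sbml = .read_model_sbml(path, objective)
  )
}

.read_model_json <- function(path, objective = NULL) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("JSON parse failure in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("JSON model must contain 'metabolites' and 'reactions' arrays")
  }
  met_ids <- vapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite entry without 'id'")
    m$id
  }, character(1))
  comps <- vapply(doc$metabolites, function(m) {
    if (is.null(m$compartment)) NA_character_ else m$compartment
  }, character(1))
  comps <- ifelse(is.na(comps), met_compartment(met_ids), comps)

  rxn_ids <- vapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction entry without 'id'")
    r$id
  }, character(1))
  lb <- vapply(doc$reactions, function(r) {
    if (is.null(r$lower_bound)) 0 else as.numeric(r$lower_bound)
  }, numeric(1))
  ub <- vapply(doc$reactions, function(r) {
    if (is.null(r$upper_bound)) 1000 else as.numeric(r$upper_bound)
  }, numeric(1))

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(doc$reactions)) {
    st <- doc$reactions[[k]]$metabolites
    if (is.null(st) || length(st) == 0) next
    idx <- match(names(st), met_ids)
    if (anyNA(idx)) {
      stop("reaction '", rxn_ids[k], "' references unknown metabolite(s): ",
           paste(names(st)[is.na(idx)], collapse = ", "))
    }
    ii <- c(ii, idx); jj <- c(jj, rep(k, length(st)))
    xx <- c(xx, vapply(st, as.numeric, numeric(1)))
  }
  S <- Matrix::sparseMatrix(
    i = ii, j = jj, x = xx, dims = c(length(met_ids), length(rxn_ids)),
    dimnames = list(met_ids, rxn_ids)
  )
  if (is.null(objective)) {
    flagged <- rxn_ids[vapply(doc$reactions, function(r) isTRUE(r$objective),
                              logical(1))]
    if (length(flagged) != 1) {
      stop("model declares ", length(flagged),
           " objective reactions; exactly one is required ",
           "(or pass `objective=`)")
    }
    objective <- flagged
  }
  tl_model(S, lb, ub, objective, compartments = comps)
}

.read_model_sbml <- function(path, objective = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  ns <- xml2::xml_ns(doc)
  strip <- function(x) sub("^[MR]_", "", x)

  species <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  if (length(species) == 0) stop("SBML file has no species (listOfSpecies)")
  met_ids <- strip(xml2::xml_attr(species, "id"))
  comps <- xml2::xml_attr(species, "compartment")
  comps <- ifelse(is.na(comps), met_compartment(met_ids), comps)

  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rxns <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (length(rxns) == 0) stop("SBML file has no reactions (listOfReactions)")
  rxn_ids <- strip(xml2::xml_attr(rxns, "id"))

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  for (k in seq_along(rxns)) {
    node <- rxns[[k]]
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lb[k] <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]]
             else if (rev) -1000 else 0
    ub[k] <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]]
             else 1000
    add <- function(refs, sgn) {
      for (sr in refs) {
        sp <- strip(xml2::xml_attr(sr, "species"))
        sto <- xml2::xml_attr(sr, "stoichiometry")
        sto <- if (is.na(sto)) 1 else as.numeric(sto)
        if (is.na(sto)) stop("bad stoichiometry on speciesReference for '",
                             sp, "' in reaction '", rxn_ids[k], "'")
        idx <- match(sp, met_ids)
        if (is.na(idx)) stop("reaction '", rxn_ids[k],
                             "' references unknown species '", sp, "'")
        ii <<- c(ii, idx); jj <<- c(jj, k); xx <<- c(xx, sgn * sto)
      }
    }
    add(xml2::xml_find_all(node, "./*[local-name()='listOfReactants']/*"), -1)
    add(xml2::xml_find_all(node, "./*[local-name()='listOfProducts']/*"), +1)
  }
  S <- Matrix::sparseMatrix(
    i = ii, j = jj, x = xx, dims = c(length(met_ids), length(rxn_ids)),
    dimnames = list(met_ids, rxn_ids), use.last.ij = FALSE
  )
  if (is.null(objective)) {
    fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (inherits(fo, "xml_missing")) {
      stop("SBML file declares no FBC objective; pass `objective=` explicitly")
    }
    objective <- strip(xml2::xml_attr(fo, "reaction"))
  }
  tl_model(S, lb, ub, objective, compartments = comps)
}

#' Write a model to the JSON dialect or to SBML L3/FBC
#'
#' `read_model(write_model(m, p), ...)` is the identity on the model contents
#' (up to element order) for the JSON dialect.
#'
#' @param model A [tl_model()].
#' @param path Output file path.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "json") .write_model_json(model, path) else
    .write_model_sbml(model, path)
  invisible(path)
}

.write_model_json <- function(model, path) {
  mets <- purrr::pmap(model$metabolites, function(id, compartment) {
    list(id = id, compartment = compartment)
  })
  S <- model$S
  rxns <- purrr::pmap(
    list(model$reactions$id, model$reactions$lb, model$reactions$ub,
         seq_len(ncol(S))),
    function(id, lb, ub, k) {
      col <- S[, k]
      nz <- which(col != 0)
      list(
        id = id, lower_bound = lb, upper_bound = ub,
        metabolites = as.list(stats::setNames(as.numeric(col[nz]),
                                              rownames(S)[nz])),
        objective = identical(id, model$objective)
      )
    }
  )
  jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.write_model_sbml <- function(model, path) {
  S <- model$S
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="thermolump_model" fbc:strict="true">',
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            unique(model$metabolites$compartment)),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf('      <species id="M_%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            esc(model$metabolites$id), model$metabolites$compartment),
    '    </listOfSpecies>',
    '    <listOfParameters>',
    sprintf('      <parameter id="lb_%d" value="%.17g" constant="true"/>',
            seq_len(ncol(S)), model$reactions$lb),
    sprintf('      <parameter id="ub_%d" value="%.17g" constant="true"/>',
            seq_len(ncol(S)), model$reactions$ub),
    '    </listOfParameters>',
    '    <listOfReactions>'
  )
  for (k in seq_len(ncol(S))) {
    col <- S[, k]
    sub <- which(col < 0); prod <- which(col > 0)
    rev <- model$reactions$lb[k] < 0
    lines <- c(lines, sprintf(
      '      <reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%d" fbc:upperFluxBound="ub_%d">',
      esc(model$reactions$id[k]), tolower(as.character(rev)), k, k))
    if (length(sub)) {
      lines <- c(lines, '        <listOfReactants>',
                 sprintf('          <speciesReference species="M_%s" stoichiometry="%.17g" constant="true"/>',
                         esc(rownames(S)[sub]), -as.numeric(col[sub])),
                 '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>',
                 sprintf('          <speciesReference species="M_%s" stoichiometry="%.17g" constant="true"/>',
                         esc(rownames(S)[prod]), as.numeric(col[prod])),
                 '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            esc(model$objective)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
}
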