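#' Construct a stoichiometric metabolic model
#'
#' The central container: a sparse stoichiometric matrix `S` (metabolites in
#' rows, reactions in columns), per-reaction flux bounds, per-metabolite
#' compartments, and a designated objective (biomass) reaction. Reversibility
#' is encoded purely in the bounds (`lb < 0 < ub`).
#'
#' @param S Matrix (dense or sparse) with row names = metabolite ids and
#'   column names = reaction ids. Stoichiometric coefficients are
#'   dimensionless; negative entries are substrates, positive are products.
#' @param lb,ub Numeric flux bounds, one per reaction (same units throughout
#'   the model, conventionally mmol/gDW/h).
#' @param objective Reaction id of the biomass/objective reaction.
#' @param compartments Optional character vector of compartments, one per
#'   metabolite. By default parsed from the trailing `_<compartment>` suffix
#'   of the metabolite id (BiGG convention); ids without a suffix get `"c"`.
#' @return An object of class `tl_model`.
#' @examples
#' S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A_c", "B_c"), "r1"))
#' m <- tl_model(S, lb = 0, ub = 10, objective = "r1")
#' @export
tl_model <- function(S, lb, ub, objective, compartments = NULL) {
  S <- methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix")
  met_ids <- rownames(S)
  rxn_ids <- colnames(S)
  if (is.null(met_ids) || is.null(rxn_ids)) {
    stop("S must carry metabolite ids as rownames and reaction ids as colnames")
  }
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids")
  lb <- rep_len(as.numeric(lb), ncol(S))
  ub <- rep_len(as.numeric(ub), ncol(S))
  if (any(lb > ub)) stop("lower bound exceeds upper bound for some reaction")
  if (!objective %in% rxn_ids) {
    stop("objective reaction '", objective, "' not among reaction ids")
  }
  if (is.null(compartments)) compartments <- met_compartment(met_ids)
  stopifnot(length(compartments) == nrow(S))
  structure(
    list(
      metabolites = tibble::tibble(id = met_ids, compartment = compartments),
      reactions = tibble::tibble(id = rxn_ids, lb = lb, ub = ub),
      S = S,
      objective = objective,
      split_map = NULL
    ),
    class = "tl_model"
  )
}

#' Parse compartment labels from metabolite ids
#'
#' Uses the trailing `_<compartment>` suffix (BiGG convention); ids without a
#' recognisable suffix default to `"c"` (cytosol).
#'
#' @param ids Character vector of metabolite ids.
#' @return Character vector of compartment labels.
#' @export
met_compartment <- function(ids) {
  comp <- sub("^.*_([A-Za-z0-9]+)$", "\\1", ids)
  comp[comp == ids] <- "c"
  comp
}

#' Strip the compartment suffix from a metabolite id
#' @param ids Character vector of metabolite ids.
#' @return Ids without their trailing `_<compartment>` suffix.
#' @export
met_species <- function(ids) {
  out <- sub("_([A-Za-z0-9]+)$", "", ids)
  out[out == ""] <- ids[out == ""]
  out
}

#' @export
print.tl_model <- function(x, ...) {
  nrev <- sum(x$reactions$lb < 0 & x$reactions$ub > 0)
  cat(sprintf(
    "<tl_model> %d metabolites x %d reactions (%d reversible), objective: %s\n",
    nrow(x$metabolites), nrow(x$reactions), nrev, x$objective
  ))
  invisible(x)
}

#' Validate internal consistency of a model
#'
#' Checks the structural invariants: unique ids, dimension agreement between
#' `S` and the metabolite/reaction tables, bounds ordering, and presence of
#' the objective reaction.
#'
#' @param model A [tl_model()].
#' @return The model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "tl_model"))
  with(model, {
    if (!identical(rownames(S), metabolites$id)) stop("S rows out of sync")
    if (!identical(colnames(S), reactions$id)) stop("S columns out of sync")
    if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
    if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
    if (any(reactions$lb > reactions$ub)) stop("lb > ub")
    if (!objective %in% reactions$id) stop("objective reaction missing")
  })
  invisible(model)
}

#' Flux balance analysis
#'
#' Maximises flux through the objective reaction subject to the steady-state
#' constraint `S v = 0` and the flux bounds.
#'
#' @param model A [tl_model()].
#' @return A list with `objective` (optimal objective value) and `fluxes`
#'   (a tibble of reaction id and flux).
#' @export
fba <- function(model) {
  validate_model(model)
  n <- nrow(model$reactions)
  cvec <- as.numeric(model$reactions$id == model$objective)
  res <- tl_solve(tl_lp(
    c = cvec, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
    lb = model$reactions$lb, ub = model$reactions$ub, sense = "max"
  ))
  if (res$status != "optimal") {
    stop("FBA did not reach an optimum (status: ", res$status, ")")
  }
  list(
    objective = res$objective,
    fluxes = tibble::tibble(reaction_id = model$reactions$id, flux = res$x)
  )
}
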