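#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with `lb < 0 < ub` is replaced by a forward copy
#' (`<id>_fwd`, original column, bounds `[0, ub]`) and a reverse copy
#' (`<id>_rev`, negated column, bounds `[0, -lb]`). Irreversible reactions
#' are kept as they are. The mapping between originals and split pairs is
#' retained in `model$split_map`. Splitting preserves the steady-state flux
#' space: net fluxes of the split model biject onto fluxes of the original.
#'
#' @param model A [tl_model()].
#' @return A [tl_model()] with direction-explicit columns.
#' @export
split_reversible <- function(model) {
  validate_model(model)
  rx <- model$reactions
  rev_idx <- which(rx$lb < 0 & rx$ub > 0)
  if (length(rev_idx) == 0) {
    model$split_map <- tibble::tibble(original = character(0),
                                      forward = character(0),
                                      reverse = character(0))
    return(model)
  }
  cols <- list(); ids <- character(0); lb <- numeric(0); ub <- numeric(0)
  split_map <- list()
  for (k in seq_len(nrow(rx))) {
    col <- model$S[, k, drop = FALSE]
    if (k %in% rev_idx) {
      fwd <- paste0(rx$id[k], "_fwd"); rev <- paste0(rx$id[k], "_rev")
      cols <- c(cols, list(col, -col))
      ids <- c(ids, fwd, rev)
      lb <- c(lb, 0, 0); ub <- c(ub, rx$ub[k], -rx$lb[k])
      split_map[[length(split_map) + 1]] <-
        tibble::tibble(original = rx$id[k], forward = fwd, reverse = rev)
    } else {
      cols <- c(cols, list(col))
      ids <- c(ids, rx$id[k]); lb <- c(lb, rx$lb[k]); ub <- c(ub, rx$ub[k])
    }
  }
  S2 <- do.call(cbind, cols)
  colnames(S2) <- ids
  objective <- if (model$objective %in% ids) model$objective
               else paste0(model$objective, "_fwd")
  out <- tl_model(S2, lb, ub, objective,
                  compartments = model$metabolites$compartment)
  out$split_map <- dplyr::bind_rows(split_map)
  out
}

#' Classify reactions by role
#'
#' * `biomass`: the objective reaction;
#' * `exchange`: exactly one nonzero stoichiometric entry;
#' * `transport`: the same chemical species (id stripped of its compartment
#'   suffix) appears in at least two compartments within the reaction;
#' * `internal`: everything else.
#'
#' @param model A [tl_model()].
#' @return A tibble with columns `reaction_id` and `role`.
#' @export
classify_reactions <- function(model) {
  validate_model(model)
  S <- model$S
  comp <- model$metabolites$compartment
  species <- met_species(model$metabolites$id)
  role <- vapply(seq_len(ncol(S)), function(k) {
    if (identical(model$reactions$id[k], model$objective)) return("biomass")
    nz <- which(S[, k] != 0)
    if (length(nz) == 1) return("exchange")
    sp <- species[nz]; cp <- comp[nz]
    cross <- any(vapply(unique(sp), function(s) {
      length(unique(cp[sp == s])) >= 2
    }, logical(1)))
    if (cross) "transport" else "internal"
  }, character(1))
  tibble::tibble(reaction_id = model$reactions$id, role = role)
}

#' Extract the reduced system of thermodynamically undetermined reactions
#'
#' Columns are the undetermined reactions (no reaction-level dG0 and at least
#' one participant lacking dfG0), excluding the biomass and exchange
#' reactions, and optionally excluding transport reactions. Rows are all
#' metabolites appearing in those columns; the subset lacking dfG0 is
#' flagged as `unknown_rows`. An all-determined model yields an empty system.
#'
#' @param model A reversible-split [tl_model()] (see [split_reversible()]).
#' @param thermo A [thermo_data()] object derived against `model`.
#' @param include_transport Should internal transport reactions be
#'   lump-eligible? Default TRUE.
#' @return An object of class `tl_reduced` with fields `R` (dense matrix),
#'   `unknown_rows`, `met_index`, `split_pairs`.
#' @export
extract_reduced_system <- function(model, thermo, include_transport = TRUE) {
  validate_model(model)
  roles <- classify_reactions(model)
  drop_roles <- c("biomass", "exchange", if (!include_transport) "transport")
  eligible <- model$reactions$id[
    model$reactions$id %in% thermo$unknown_reactions &
      !(roles$role %in% drop_roles)]
  if (length(eligible) == 0) {
    return(structure(
      list(R = matrix(0, 0, 0), unknown_rows = character(0),
           met_index = integer(0),
           split_pairs = model$split_map %||%
             tibble::tibble(original = character(0), forward = character(0),
                            reverse = character(0))),
      class = "tl_reduced"))
  }
  sub <- model$S[, eligible, drop = FALSE]
  keep <- which(Matrix::rowSums(sub != 0) > 0)
  R <- as.matrix(sub[keep, , drop = FALSE])
  structure(
    list(
      R = R,
      unknown_rows = intersect(rownames(R), thermo$unknown_metabolites),
      met_index = stats::setNames(keep, rownames(R)),
      split_pairs = model$split_map %||%
        tibble::tibble(original = character(0), forward = character(0),
                       reverse = character(0))
    ),
    class = "tl_reduced"
  )
}

#' @export
print.tl_reduced <- function(x, ...) {
  cat(sprintf("<tl_reduced> %d metabolites x %d reactions (%d unknown rows)\n",
              nrow(x$R), ncol(x$R), length(x$unknown_rows)))
  invisible(x)
}

#' Partition unknown metabolites into independent groups
#'
#' Builds the bipartite graph on unknown metabolites and the reduced-system
#' reactions (edge when the coefficient is nonzero, after metabolites with
#' known dfG0 have been removed) and returns the connected components'
#' metabolite sides. Two groups never share a reaction column among their
#' unknown rows, which is what licenses lumping them independently. Ordering
#' is deterministic: groups by smallest member metabolite index, members by
#' model index.
#'
#' @param rs A [extract_reduced_system()] result.
#' @return A tibble with one row per group: `group_id`, `members` (list
#'   column), `reactions` (list column), `size`.
#' @export
partition_groups <- function(rs) {
  stopifnot(inherits(rs, "tl_reduced"))
  empty <- tibble::tibble(group_id = integer(0), members = list(),
                          reactions = list(), size = integer(0))
  if (length(rs$unknown_rows) == 0) return(empty)
  Ru <- rs$R[rs$unknown_rows, , drop = FALSE]
  met_nodes <- paste0("m::", rownames(Ru))
  rxn_nodes <- paste0("r::", colnames(Ru))
  nz <- which(Ru != 0, arr.ind = TRUE)
  edges <- rbind(met_nodes[nz[, 1]], rxn_nodes[nz[, 2]])
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(met_nodes, rxn_nodes))
  if (length(edges)) g <- g + igraph::edges(as.vector(edges))
  comp <- igraph::components(g)
  membership <- comp$membership
  groups <- list()
  for (cid in seq_len(comp$no)) {
    nodes <- names(membership)[membership == cid]
    mets <- sub("^m::", "", nodes[startsWith(nodes, "m::")])
    if (length(mets) == 0) next
    mets <- mets[order(rs$met_index[mets])]
    rxns_touched <- colnames(Ru)[Matrix::colSums(
      Ru[mets, , drop = FALSE] != 0) > 0]
    groups[[length(groups) + 1]] <- list(members = mets,
                                         reactions = rxns_touched)
  }
  if (length(groups) == 0) return(empty)
  ord <- order(vapply(groups, function(g) min(rs$met_index[g$members]),
                      numeric(1)))
  groups <- groups[ord]
  tibble::tibble(
    group_id = seq_along(groups),
    members = purrr::map(groups, "members"),
    reactions = purrr::map(groups, "reactions"),
    size = vapply(groups, function(g) length(g$members), integer(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
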