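#' Thermodynamic annotation of a model
#'
#' Records which metabolites carry a standard Gibbs free energy of formation
#' (dfG0, kJ/mol) and derives the thermodynamically undetermined sets: a
#' metabolite is *unknown* when it has no dfG0 entry; a reaction is
#' *unknown* when it has no reaction-level dG0 override and touches at least
#' one unknown metabolite. A reaction-level override marks a reaction known
#' even if a participant lacks dfG0.
#'
#' @param model A [tl_model()].
#' @param dfG0 Named numeric vector: metabolite id -> dfG0 (kJ/mol).
#'   Metabolites absent from the vector (or mapped to NA) are unknown.
#' @param dG0_override Optional named numeric vector: reaction id -> dG0
#'   (kJ/mol), taking precedence over metabolite-wise computation.
#' @return An object of class `tl_thermo` with fields `dfG0`, `dG0_override`,
#'   `unknown_metabolites`, `unknown_reactions`.
#' @export
thermo_data <- function(model, dfG0 = numeric(0), dG0_override = numeric(0)) {
  validate_model(model)
  dfG0 <- dfG0[!is.na(dfG0)]
  if (anyDuplicated(names(dfG0))) stop("duplicate metabolite ids in dfG0")
  extra <- setdiff(names(dfG0), model$metabolites$id)
  if (length(extra)) {
    warning("dfG0 entries for metabolites absent from the model: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "")
    dfG0 <- dfG0[setdiff(names(dfG0), extra)]
  }
  dG0_override <- dG0_override[!is.na(dG0_override)]
  extra_r <- setdiff(names(dG0_override), model$reactions$id)
  if (length(extra_r)) {
    warning("dG0 overrides for reactions absent from the model: ",
            paste(utils::head(extra_r, 5), collapse = ", "))
    dG0_override <- dG0_override[setdiff(names(dG0_override), extra_r)]
  }
  unknown_mets <- setdiff(model$metabolites$id, names(dfG0))
  touches_unknown <- Matrix::colSums(
    model$S[model$metabolites$id %in% unknown_mets, , drop = FALSE] != 0) > 0
  unknown_rxns <- model$reactions$id[
    touches_unknown & !(model$reactions$id %in% names(dG0_override))]
  structure(
    list(dfG0 = dfG0, dG0_override = dG0_override,
         unknown_metabolites = unknown_mets,
         unknown_reactions = unknown_rxns),
    class = "tl_thermo"
  )
}

#' @export
print.tl_thermo <- function(x, ...) {
  cat(sprintf(
    "<tl_thermo> %d dfG0 entries, %d reaction overrides; %d unknown metabolites, %d undetermined reactions\n",
    length(x$dfG0), length(x$dG0_override),
    length(x$unknown_metabolites), length(x$unknown_reactions)))
  invisible(x)
}

#' Read a thermodynamic annotation table
#'
#' Expects a UTF-8 tab-separated file with a header row and columns
#' `metabolite_id` and `dfG0_kJ_per_mol`; an empty cell or the sentinel
#' `NA` marks the metabolite as lacking a formation energy. An optional
#' second file provides reaction-level dG0 overrides (`reaction_id`,
#' `dG0_kJ_per_mol`). Ids not present in the model are reported as warnings,
#' not errors.
#'
#' @param path Path to the metabolite table.
#' @param model The [tl_model()] the table annotates.
#' @param overrides_path Optional path to a reaction-level override table.
#' @return A [thermo_data()] object.
#' @export
read_thermo <- function(path, model, overrides_path = NULL) {
  if (!file.exists(path)) stop("thermo file not found: ", path)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("metabolite_id", "dfG0_kJ_per_mol")
  if (!all(need %in% names(tab))) {
    stop("thermo table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$metabolite_id)) {
    dup <- tab$metabolite_id[duplicated(tab$metabolite_id)][1]
    stop("duplicate metabolite_id in thermo table: ", dup)
  }
  raw <- tab$dfG0_kJ_per_mol
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(val))
  if (length(bad)) {
    stop("malformed numeric dfG0 cell at row ", bad[1] + 1L,
         " ('", raw[bad[1]], "')")
  }
  dfG0 <- stats::setNames(val, tab$metabolite_id)
  dG0_override <- numeric(0)
  if (!is.null(overrides_path)) {
    otab <- readr::read_tsv(overrides_path,
                            col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    need_o <- c("reaction_id", "dG0_kJ_per_mol")
    if (!all(need_o %in% names(otab))) {
      stop("override table must have columns: ", paste(need_o, collapse = ", "))
    }
    if (anyDuplicated(otab$reaction_id)) stop("duplicate reaction_id in override table")
    oval <- suppressWarnings(as.numeric(otab$dG0_kJ_per_mol))
    obad <- which(!is.na(otab$dG0_kJ_per_mol) & otab$dG0_kJ_per_mol != "NA" &
                    otab$dG0_kJ_per_mol != "" & is.na(oval))
    if (length(obad)) stop("malformed numeric dG0 cell at row ", obad[1] + 1L)
    dG0_override <- stats::setNames(oval, otab$reaction_id)
  }
  thermo_data(model, dfG0, dG0_override)
}

#' Write a thermodynamic annotation table
#'
#' Inverse of [read_thermo()]: every model metabolite gets a row; unknown
#' metabolites get the sentinel `NA`.
#'
#' @param thermo A [thermo_data()] object.
#' @param model The annotated [tl_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermo <- function(thermo, model, path) {
  tab <- tibble::tibble(
    metabolite_id = model$metabolites$id,
    dfG0_kJ_per_mol = unname(thermo$dfG0[model$metabolites$id])
  )
  readr::write_tsv(tab, path, na = "NA")
  invisible(path)
}

#' Standard Gibbs free energy change of model reactions
#'
#' dG0_j = sum_i s_ij dfG0_i for reactions whose participants all carry a
#' formation energy; reaction-level overrides take precedence. Undetermined
#' reactions get NA.
#'
#' @param model A [tl_model()].
#' @param thermo A [thermo_data()] object.
#' @return A tibble with columns `reaction_id`, `dG0`, `determined`.
#' @export
reaction_dG0 <- function(model, thermo) {
  dfG0 <- rep(NA_real_, nrow(model$metabolites))
  names(dfG0) <- model$metabolites$id
  dfG0[names(thermo$dfG0)] <- thermo$dfG0
  S <- model$S
  dG0 <- vapply(seq_len(ncol(S)), function(k) {
    col <- S[, k]
    nz <- which(col != 0)
    if (length(nz) == 0) return(NA_real_)
    vals <- dfG0[nz]
    if (anyNA(vals)) NA_real_ else sum(as.numeric(col[nz]) * vals)
  }, numeric(1))
  names(dG0) <- model$reactions$id
  ov <- thermo$dG0_override
  dG0[names(ov)] <- ov
  tibble::tibble(
    reaction_id = model$reactions$id,
    dG0 = unname(dG0),
    determined = !is.na(dG0)
  )
}
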