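#' Assemble a lump report from a lumping run
#'
#' Flattens a `tl_lump_run` into three serialisable pieces: the composition
#' table (which primitive reactions, with which coefficients, form each
#' lump), the net-stoichiometry table, and a stats block with the LP and
#' group counters. When thermodynamic data are supplied the dG0 of each lump
#' is included (always computable for accepted lumps).
#'
#' @param run A `tl_lump_run` from [combined_procedure()],
#'   [sequential_lump()] or [naive_iterative()].
#' @param thermo Optional [thermo_data()] used to attach dG0 values.
#' @return An object of class `tl_lump_report`: a list with tibbles
#'   `lumps`, `composition`, `stoichiometry` and a list `stats`.
#' @export
lump_report <- function(run, thermo = NULL) {
  stopifnot(inherits(run, "tl_lump_run"))
  n <- length(run$lumps)
  ids <- sprintf("L%d", seq_len(n))
  lumps <- purrr::map2_dfr(run$lumps, ids, function(l, id) {
    tibble::tibble(
      lump_id = id, seed = l$seed, group_id = l$group_id, mode = l$mode,
      n_lps = l$n_lps,
      n_reactions = nrow(l$alpha),
      dG0 = if (is.null(thermo)) NA_real_ else lump_dG0(l, thermo)
    )
  })
  if (n == 0) {
    lumps <- tibble::tibble(lump_id = character(0), seed = character(0),
                            group_id = integer(0), mode = character(0),
                            n_lps = integer(0), n_reactions = integer(0),
                            dG0 = numeric(0))
  }
  composition <- purrr::map2_dfr(run$lumps, ids, function(l, id) {
    dplyr::mutate(l$alpha, lump_id = id, .before = 1)
  })
  if (n == 0) {
    composition <- tibble::tibble(lump_id = character(0),
                                  reaction_id = character(0),
                                  alpha = numeric(0))
  }
  stoichiometry <- purrr::map2_dfr(run$lumps, ids, function(l, id) {
    dplyr::mutate(l$y, lump_id = id, .before = 1)
  })
  if (n == 0) {
    stoichiometry <- tibble::tibble(lump_id = character(0),
                                    metabolite_id = character(0),
                                    coefficient = numeric(0))
  }
  structure(
    list(
      lumps = lumps, composition = composition, stoichiometry = stoichiometry,
      stats = c(run$counts,
                list(n_lumps = n,
                     n_eliminated = length(run$eliminated),
                     eliminated = as.list(run$eliminated)))
    ),
    class = "tl_lump_report"
  )
}

#' @export
print.tl_lump_report <- function(x, ...) {
  cat(sprintf("<tl_lump_report> %d lump(s), %d eliminated metabolite(s), %d LPs\n",
              x$stats$n_lumps, x$stats$n_eliminated, x$stats$lps_total))
  invisible(x)
}

.report_files <- function(dir) {
  list(
    composition = file.path(dir, "lump_composition.tsv"),
    stoichiometry = file.path(dir, "lump_stoichiometry.tsv"),
    lumps = file.path(dir, "lump_summary.tsv"),
    stats = file.path(dir, "lump_stats.json")
  )
}

#' Write a lump report to disk
#'
#' Emits tab-separated composition, net-stoichiometry and summary tables
#' plus a JSON stats block into `dir`. Validates the report invariants
#' first: all coefficients nonnegative and no eliminated metabolite with a
#' nonzero net coefficient. Round-trips losslessly through
#' [read_lump_report()].
#'
#' @param report A [lump_report()].
#' @param dir Output directory (created if missing).
#' @param tol Zero tolerance for the invariant check.
#' @return `dir`, invisibly.
#' @export
write_lump_report <- function(report, dir, tol = 1e-9) {
  stopifnot(inherits(report, "tl_lump_report"))
  if (any(report$composition$alpha < -tol)) {
    stop("invalid report: negative lump coefficient")
  }
  elim <- unlist(report$stats$eliminated)
  offending <- report$stoichiometry$metabolite_id[
    report$stoichiometry$metabolite_id %in% elim &
      abs(report$stoichiometry$coefficient) > tol]
  if (length(offending)) {
    stop("invalid report: eliminated metabolite(s) with nonzero net ",
         "stoichiometry: ", paste(unique(offending), collapse = ", "))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- .report_files(dir)
  readr::write_tsv(report$composition, f$composition)
  readr::write_tsv(report$stoichiometry, f$stoichiometry)
  readr::write_tsv(report$lumps, f$lumps)
  jsonlite::write_json(report$stats, f$stats, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(dir)
}

#' Read a lump report written by [write_lump_report()]
#'
#' @param dir Directory containing the report files.
#' @return A `tl_lump_report`.
#' @export
read_lump_report <- function(dir) {
  f <- .report_files(dir)
  missing <- !vapply(f, file.exists, logical(1))
  if (any(missing)) {
    stop("lump report incomplete in '", dir, "': missing ",
         paste(basename(unlist(f[missing])), collapse = ", "))
  }
  composition <- readr::read_tsv(
    f$composition,
    col_types = readr::cols(lump_id = "c", reaction_id = "c", alpha = "d"),
    progress = FALSE)
  stoichiometry <- readr::read_tsv(
    f$stoichiometry,
    col_types = readr::cols(lump_id = "c", metabolite_id = "c",
                            coefficient = "d"),
    progress = FALSE)
  lumps <- readr::read_tsv(
    f$lumps,
    col_types = readr::cols(lump_id = "c", seed = "c", group_id = "i",
                            mode = "c", n_lps = "i", n_reactions = "i",
                            dG0 = "d"),
    progress = FALSE)
  stats <- jsonlite::read_json(f$stats, simplifyVector = TRUE)
  stats$eliminated <- as.list(unlist(stats$eliminated) %||% character(0))
  structure(
    list(lumps = lumps, composition = composition,
         stoichiometry = stoichiometry, stats = stats),
    class = "tl_lump_report"
  )
}

#' Rebuild lump records from a report
#'
#' Converts a (possibly re-read) report back into the in-memory lump-record
#' list consumed by [build_tmfa()].
#'
#' @param report A `tl_lump_report`.
#' @return A list of lump records.
#' @export
report_to_lumps <- function(report) {
  ids <- report$lumps$lump_id
  purrr::map(seq_along(ids), function(t) {
    id <- ids[t]
    list(
      lump_id = id,
      seed = report$lumps$seed[t],
      group_id = report$lumps$group_id[t],
      mode = report$lumps$mode[t],
      n_lps = report$lumps$n_lps[t],
      alpha = dplyr::select(
        dplyr::filter(report$composition, .data$lump_id == id),
        "reaction_id", "alpha"),
      y = dplyr::select(
        dplyr::filter(report$stoichiometry, .data$lump_id == id),
        "metabolite_id", "coefficient")
    )
  })
}
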