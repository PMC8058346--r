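#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a lumping run into one row per lump reaction member
#'
#' @param x A `tl_lump_run`.
#' @param ... Unused.
#' @return A tibble with columns `lump_id`, `seed`, `group_id`, `mode`,
#'   `reaction_id`, `alpha`.
#' @exportS3Method generics::tidy
tidy.tl_lump_run <- function(x, ...) {
  if (length(x$lumps) == 0) {
    return(tibble::tibble(lump_id = character(0), seed = character(0),
                          group_id = integer(0), mode = character(0),
                          reaction_id = character(0), alpha = numeric(0)))
  }
  purrr::imap_dfr(x$lumps, function(l, i) {
    dplyr::mutate(l$alpha,
                  lump_id = sprintf("L%d", i), seed = l$seed,
                  group_id = l$group_id, mode = l$mode, .before = 1)
  })
}

#' One-row summary of a lumping run
#'
#' @param x A `tl_lump_run`.
#' @param ... Unused.
#' @return A tibble with the LP and group counters and the number of
#'   eliminated metabolites.
#' @exportS3Method generics::glance
glance.tl_lump_run <- function(x, ...) {
  tibble::tibble(
    n_lumps = length(x$lumps),
    n_eliminated = length(x$eliminated),
    lps_total = x$counts$lps_total,
    lps_group = x$counts$lps_group,
    lps_sequential = x$counts$lps_sequential,
    groups_total = x$counts$groups_total,
    groups_group_success = x$counts$groups_group_success
  )
}

#' Plot Gibbs free energy variability ranges
#'
#' One horizontal segment per reaction from `dG_min` to `dG_max`, coloured
#' by reversibility class, with the zero line marking the irreversibility
#' threshold.
#'
#' @param object A [dG_variability()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tl_dG_ranges <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$reaction_id <- stats::reorder(df$reaction_id, df$dG_max)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$reaction_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$dG_min, xend = .data$dG_max,
                                       yend = .data$reaction_id,
                                       colour = .data$classification),
                          linewidth = 1.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(Delta * G ~ "(kJ/mol)"), y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the LP budget of a lumping run
#'
#' Bar chart of LPs solved per phase (group vs sequential), the quantity the
#' combined procedure is designed to reduce.
#'
#' @param object A `tl_lump_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tl_lump_run <- function(object, ...) {
  df <- tibble::tibble(
    phase = c("group", "sequential"),
    lps = c(object$counts$lps_group, object$counts$lps_sequential)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$lps)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "linear programs solved") +
    ggplot2::theme_minimal()
}
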